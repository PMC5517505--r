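test_that("Pearson r and p match independent formula evaluation and edge cases", {
  expect_equal(pearson_with_p(1:5, 2 * (1:5) + 3), c(r = 1, p = 0))
  expect_equal(pearson_with_p(1:5, -(1:5)), c(r = -1, p = 0))

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  got <- pearson_with_p(x, y)
  # direct re-evaluation of the defining formulas
  r0 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t0 <- r0 * sqrt((5 - 2) / (1 - r0^2))
  p0 <- 2 * stats::pt(-abs(t0), df = 3)
  expect_equal(unname(got["r"]), r0, tolerance = 1e-12)
  expect_equal(unname(got["p"]), p0, tolerance = 1e-10)
  # cross-check against the standard test
  ct <- stats::cor.test(x, y)
  expect_equal(unname(got["r"]), unname(ct$estimate), tolerance = 1e-12)
  expect_equal(unname(got["p"]), ct$p.value, tolerance = 1e-10)

  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
  expect_error(pearson_with_p(1:4, 1:5), "equal length")
})

test_that("network construction follows the |r| and p gates", {
  # identical pair plus an anti-correlated partner: full triangle at |r| = 1
  expr <- forced_expression()
  expect_message(net <- build_network(expr, r_min = 0.9, p_max = 0.05),
                 "constant")
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 3L)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("g1 g2", "g1 g3", "g2 g3"))
  expect_identical(net$nodes$degree[net$nodes$gene_id == "g4"], 0L)
  expect_identical(net$nodes$core_number[net$nodes$gene_id %in% c("g1", "g2", "g3")],
                   rep(2L, 3))
  # the g3 edges carry negative r
  expect_true(all(net$edges$r[net$edges$to == "g3"] < 0))

  # constant-only input: no edges at all
  expr0 <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 2), s2 = c(1, 2),
                          s3 = c(1, 2))
  expect_message(net0 <- build_network(expr0), "constant")
  expect_identical(nrow(net0$edges), 0L)
  expect_identical(net0$nodes$degree, c(0L, 0L))

  expect_error(build_network(expr[, 1:3]), "at least 3 samples")
  expect_error(build_network(expr, genes = "nope"), "not present")
})

test_that("network construction is invariant to gene input order", {
  ds <- simulate_counts(sim_config(n_genes = 150, n_conditions = 10,
                                   n_de_genes = 0, n_modules = 2,
                                   module_size = 10, seed = 13))
  expr <- rpkm(ds$counts, ds$totals)
  n1 <- build_network(expr)
  perm <- withr::with_seed(14, sample(nrow(expr)))
  n2 <- build_network(expr[perm, ])
  expect_equal(n1$edges, n2$edges)
  expect_equal(n1$nodes, n2$nodes)
})

test_that("k-core decomposition: canonical graphs", {
  # triangle plus pendant
  net <- network_from_edges(
    c("A", "B", "C", "D"),
    tibble::tibble(from = c("A", "A", "B", "C"), to = c("B", "C", "C", "D")))
  core <- kcore_decompose(net)
  expect_identical(core, c(A = 2L, B = 2L, C = 2L, D = 1L))
  expect_true(all(net$nodes$core_number <= net$nodes$degree))

  # empty graph and edgeless nodes
  empty <- network_from_edges(character(0),
                              tibble::tibble(from = character(), to = character()))
  expect_identical(kcore_decompose(empty), stats::setNames(integer(0), character(0)))
  lone <- network_from_edges(c("A", "B"),
                             tibble::tibble(from = character(), to = character()))
  expect_identical(kcore_decompose(lone), c(A = 0L, B = 0L))
})

test_that("k-core matches brute-force peeling and igraph on random graphs", {
  withr::local_seed(15)
  for (i in 1:50) {
    g <- random_graph(sample(5:50, 1), runif(1, 0.02, 0.4))
    net <- network_from_edges(g$nodes, g$edges)
    core <- kcore_decompose(net)
    expect_identical(core, brute_kcore(sort(g$nodes), g$edges)[names(core)])
    if (nrow(g$edges) > 0) {
      ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                          vertices = sort(g$nodes))
      expect_identical(core[igraph::V(ig)$name],
                       stats::setNames(as.integer(igraph::coreness(ig)),
                                       igraph::V(ig)$name))
    }
    # structural invariants
    expect_true(all(net$nodes$core_number <= net$nodes$degree))
    expect_identical(sum(net$nodes$degree), 2L * nrow(net$edges))
    for (k in unique(core)) {
      sub <- names(core)[core >= k]
      if (k > 0 && length(sub) > 0) {
        e <- g$edges[g$edges$from %in% sub & g$edges$to %in% sub, ]
        deg <- table(factor(c(e$from, e$to), levels = sub))
        expect_gte(min(deg), k)
      }
    }
  }
})

test_that("removing an edge never increases a core number", {
  withr::local_seed(16)
  g <- random_graph(20, 0.3)
  base <- kcore_decompose(network_from_edges(g$nodes, g$edges))
  for (e in sample(nrow(g$edges), 5)) {
    pruned <- kcore_decompose(network_from_edges(g$nodes, g$edges[-e, ]))
    expect_true(all(pruned <= base))
  }
})

test_that("gene ranking follows (core desc, degree desc, id asc) with ties by id", {
  hub <- network_from_edges(
    c("H", sprintf("L%d", 1:5)),
    tibble::tibble(from = "H", to = sprintf("L%d", 1:5)))
  expect_identical(rank_core_genes(hub, top = 1)$gene_id, "H")

  two_tri <- network_from_edges(
    sprintf("T%d", 1:6),
    tibble::tibble(from = c("T1", "T1", "T2", "T4", "T4", "T5"),
                   to = c("T2", "T3", "T3", "T5", "T6", "T6")))
  expect_identical(rank_core_genes(two_tri, top = 6)$gene_id,
                   sprintf("T%d", 1:6))

  withr::local_seed(17)
  for (i in 1:10) {
    g <- random_graph(sample(10:40, 1), runif(1, 0.05, 0.3))
    net <- network_from_edges(g$nodes, g$edges)
    got <- rank_core_genes(net, top = length(g$nodes))
    # independent re-sort of independently recomputed keys
    key <- tibble::tibble(
      gene_id = sort(g$nodes),
      core = brute_kcore(sort(g$nodes), g$edges),
      deg = as.integer(table(factor(c(g$edges$from, g$edges$to),
                                    levels = sort(g$nodes))))
    )
    ord <- key[order(-key$core, -key$deg, key$gene_id), ]
    expect_identical(got$gene_id, ord$gene_id)
  }
})

test_that("tidy and glance summarize the network object", {
  net <- network_from_edges(
    c("A", "B", "C"),
    tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C")))
  expect_identical(tidy(net), net$edges)
  g <- glance(net)
  expect_identical(g$n_nodes, 3L)
  expect_identical(g$n_edges, 3L)
  expect_identical(g$max_core, 2L)
  expect_equal(g$density, 1)
})
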