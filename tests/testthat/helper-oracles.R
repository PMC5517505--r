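# Independent oracles used across the suite. Each is deliberately written
# from a different route than the implementation it checks.

# Benjamini-Hochberg step-up, brute force: sort ascending, p * m / i, cummin
# from the top, restore input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(1, adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact Poisson-ratio two-sided p-value via the negative-binomial identity:
# Y | x ~ NB(size = x + 1, prob = n1 / (n1 + n2)).
ac_oracle <- function(x, y, n1, n2) {
  pr <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = pr)
  upper <- if (y == 0) 1 else stats::pnbinom(y - 1, size = x + 1, prob = pr,
                                             lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# Hypergeometric upper tail by counting draws with exact binomial
# coefficients (exact in double precision for N <= 30).
enum_hyper_upper <- function(N, M, n, m) {
  j <- m:min(M, n)
  sum(choose(M, j) * choose(N - M, n - j)) / choose(N, n)
}

# k-core by definition: a node's core number is the largest k such that it
# survives repeated deletion of nodes with degree < k.
brute_kcore <- function(nodes, edges) {
  core <- stats::setNames(integer(length(nodes)), nodes)
  k <- 1L
  repeat {
    alive <- nodes
    e <- edges
    repeat {
      deg <- table(factor(c(e$from, e$to), levels = alive))
      drop <- alive[deg[alive] < k]
      if (length(drop) == 0) break
      alive <- setdiff(alive, drop)
      e <- e[e$from %in% alive & e$to %in% alive, ]
    }
    if (length(alive) == 0) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Erdos-Renyi style random graph on node labels "N01"...
random_graph <- function(n, p_edge) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(from = nodes[pairs[keep, 1]],
                          to = nodes[pairs[keep, 2]])
  list(nodes = nodes, edges = edges)
}

# Wrap an explicit edge list as a coexpression_network object so graph
# operations can be tested on arbitrary topologies.
network_from_edges <- function(nodes, edges) {
  edges <- dplyr::mutate(edges,
                         r = if (nrow(edges)) 1 else numeric(0),
                         p = if (nrow(edges)) 0 else numeric(0))
  edges <- dplyr::arrange(edges, from, to)
  degree <- table(factor(c(edges$from, edges$to), levels = sort(nodes)))
  core <- ogdrscreen:::kcore_numbers(sort(nodes), edges)
  structure(list(
    nodes = tibble::tibble(gene_id = sort(nodes),
                           degree = as.integer(degree[sort(nodes)]),
                           core_number = unname(core[sort(nodes)])),
    edges = edges, n_samples = NA_integer_, r_min = NA_real_, p_max = NA_real_
  ), class = "coexpression_network")
}
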