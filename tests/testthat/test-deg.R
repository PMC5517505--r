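test_that("RPKM matches the closed form cell-wise", {
  cm <- tibble::tibble(gene_id = c("A", "B"), length_bp = c(1000L, 500L),
                       s1 = c(100L, 0L))
  tt <- tibble::tibble(sample_id = "s1", total_mapped_reads = 1e7)
  expect_identical(rpkm(cm, tt)$s1, c(10, 0))

  # random matrix against independent re-evaluation of the formula
  withr::local_seed(1)
  n <- 50; k <- 5
  cm <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("G%02d", 1:n),
                   length_bp = sample(200:5000, n)),
    tibble::as_tibble(matrix(rpois(n * k, 300), n, k,
                             dimnames = list(NULL, paste0("s", 1:k))))
  )
  tt <- tibble::tibble(sample_id = paste0("s", 1:k),
                       total_mapped_reads = runif(k, 1e6, 5e7))
  out <- rpkm(cm, tt)
  for (j in 1:k) {
    expected <- vapply(1:n, function(i)
      1e9 * cm[[paste0("s", j)]][i] /
        (tt$total_mapped_reads[j] * cm$length_bp[i]), 0)
    rel <- abs(out[[paste0("s", j)]] - expected) / pmax(expected, 1e-300)
    expect_lt(max(rel[expected > 0]), 1e-12)
    expect_identical(out[[paste0("s", j)]][expected == 0],
                     rep(0, sum(expected == 0)))
  }
})

test_that("exact Poisson-ratio test: closed-form cases, symmetry, monotonicity", {
  expect_identical(ac_test(0, 0, 1e6, 1e6), 1)
  expect_identical(ac_test(25, 25, 1e6, 1e6), 1)
  expect_error(ac_test(-1, 5, 1e6, 1e6), "nonnegative")
  expect_error(ac_test(1, 5, 0, 1e6), "positive")

  # p(0|0) with equal depths is 1/2 per tail, so the capped p-value is 1,
  # and the one-tail values are exactly 1/2 each under the conditional law
  pr <- 1 / 2
  expect_equal(stats::pnbinom(0, size = 1, prob = pr), 0.5)

  # the p-value depends on the depths only through their ratio
  withr::local_seed(2)
  for (i in 1:20) {
    x <- rpois(1, 200); y <- rpois(1, 50)
    n1 <- runif(1, 5e5, 5e7); n2 <- runif(1, 5e5, 5e7)
    expect_equal(ac_test(x, y, n1, n2), ac_test(x, y, 10 * n1, 10 * n2),
                 tolerance = 1e-12)
  }
  # conditioning on the first library makes the test only asymptotically
  # exchange-symmetric; at moderate counts the swapped p-values agree closely
  for (i in 1:20) {
    x <- rpois(1, 500); y <- rpois(1, 300)
    n1 <- runif(1, 5e5, 5e7); n2 <- runif(1, 5e5, 5e7)
    a <- ac_test(x, y, n1, n2); b <- ac_test(y, x, n2, n1)
    expect_lt(abs(log(a) - log(b)), 0.05 * abs(log(a)) + 0.7)
  }

  # monotone in |y - x| for equal depths
  p_seq <- ac_test(50, c(50, 60, 75, 100, 150, 5), 1e6, 1e6)
  expect_true(all(diff(p_seq[1:5]) <= 0))
  expect_lt(p_seq[6], p_seq[1])
})

test_that("exact Poisson-ratio test matches the negative-binomial tail identity", {
  # a strong depletion at depth 1e6, then 200 randomized cases
  expect_equal(ac_test(50, 5, 1e6, 1e6), ac_oracle(50, 5, 1e6, 1e6),
               tolerance = 1e-10)
  withr::local_seed(3)
  for (i in 1:200) {
    x <- rpois(1, exp(runif(1, 0, 8)))
    y <- rpois(1, exp(runif(1, 0, 8)))
    n1 <- runif(1, 1e5, 1e8); n2 <- runif(1, 1e5, 1e8)
    p <- ac_test(x, y, n1, n2)
    p0 <- ac_oracle(x, y, n1, n2)
    expect_equal(p, p0, tolerance = 1e-10,
                 label = sprintf("ac_test(%d, %d, %g, %g)", x, y, n1, n2))
  }
})

test_that("FDR column reproduces a brute-force BH step-up", {
  withr::local_seed(4)
  for (i in 1:20) {
    p <- runif(sample(c(10, 100, 1000, 10000), 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, method = "BH"), brute_bh(p),
                 tolerance = 1e-12)
  }
  # and through the caller itself
  ds <- simulate_counts(sim_config(n_genes = 300, n_de_genes = 20,
                                   n_modules = 0, seed = 6))
  deg <- call_degs(ds$counts, ds$totals, "OGD45_R0h", "OGD0_R0h", keep_all = TRUE)
  expect_equal(deg$fdr, brute_bh(deg$p_raw), tolerance = 1e-12)
})

test_that("the six-gene fixture is called exactly as an independent per-gene oracle says", {
  deg <- call_degs(toy_counts(), toy_totals(), "trt", "ref", keep_all = TRUE)
  # independent route: NB-tail p per gene, brute-force BH, floored-RPKM ratio
  cm <- toy_counts()
  p0 <- vapply(1:6, function(i) ac_oracle(cm$ref[i], cm$trt[i], 1e6, 1e6), 0)
  fdr0 <- brute_bh(p0)
  r_ref <- pmax(1e9 * cm$ref / (1e6 * cm$length_bp), 0.01)
  r_trt <- pmax(1e9 * cm$trt / (1e6 * cm$length_bp), 0.01)
  lfc0 <- log2(r_trt / r_ref)
  expected <- cm$gene_id[abs(lfc0) >= 1 & fdr0 <= 0.001]
  expect_setequal(deg$gene_id[deg$significant], expected)
  # G1 (4-fold up) and G3 (drop to zero) must be among the calls
  expect_true(all(c("G1", "G3") %in% deg$gene_id[deg$significant]))
  ord <- match(deg$gene_id, cm$gene_id)
  expect_equal(deg$p_raw, p0[ord], tolerance = 1e-10)
  expect_equal(deg$log2_ratio, lfc0[ord], tolerance = 1e-12)
  expect_identical(deg$direction, ifelse(deg$log2_ratio > 0, "up", "down"))
})

test_that("untestable and unchanged genes are handled per contract", {
  cm <- tibble::tibble(gene_id = c("Z", "E", "U"), length_bp = 1000L,
                       ref = c(0L, 100L, 10L), trt = c(0L, 100L, 400L))
  tt <- tibble::tibble(sample_id = c("ref", "trt"), total_mapped_reads = c(1e6, 1e6))
  deg <- call_degs(cm, tt, "trt", "ref", keep_all = TRUE)
  # double-zero gene excluded from testing and the BH denominator
  expect_setequal(deg$gene_id, c("E", "U"))
  expect_equal(deg$fdr, brute_bh(deg$p_raw))
  e_row <- deg[deg$gene_id == "E", ]
  expect_identical(e_row$p_raw, 1)
  expect_identical(e_row$log2_ratio, 0)
  expect_false(e_row$significant)

  expect_error(call_degs(cm, tt, "trt", "trt"), "must differ")
  expect_error(call_degs(cm, tt, "nope", "ref"), "not found")
})

test_that("DEG calling is invariant to input row order", {
  ds <- simulate_counts(sim_config(n_genes = 200, n_de_genes = 15,
                                   n_modules = 0, seed = 8))
  deg1 <- call_degs(ds$counts, ds$totals, "OGD45_R0h", "OGD0_R0h")
  perm <- withr::with_seed(9, sample(nrow(ds$counts)))
  deg2 <- call_degs(ds$counts[perm, ], ds$totals, "OGD45_R0h", "OGD0_R0h")
  expect_equal(deg1, deg2)
})

test_that("planted-null data yields essentially no calls at FDR 0.001", {
  calls <- vapply(1:20, function(s) {
    ds <- simulate_counts(sim_config(n_genes = 2000, n_de_genes = 0,
                                     n_modules = 0, n_conditions = 2,
                                     seed = 100 + s))
    nrow(call_degs(ds$counts, ds$totals, "cond02", "cond01"))
  }, 0)
  expect_lte(mean(calls), 1)
})
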