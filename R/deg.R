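#' Reads per kilobase per million mapped reads (RPKM)
#'
#' Applies `rpkm = 1e9 * C / (N * L)` cell-wise, where `C` is the read count
#' of a gene in a library, `N` the library's total mapped reads, and `L` the
#' gene length in bp. Zero counts give zero RPKM.
#'
#' @param counts counts tibble (`gene_id`, `length_bp`, sample columns).
#' @param totals totals tibble (`sample_id`, `total_mapped_reads`).
#' @return tibble with `gene_id` and one RPKM column per sample, same row
#'   order as the input.
#' @export
rpkm <- function(counts, totals) {
  validate_counts(counts, totals)
  sample_ids <- setdiff(names(counts), c("gene_id", "length_bp"))
  n_map <- stats::setNames(totals$total_mapped_reads, totals$sample_id)
  out <- tibble::tibble(gene_id = counts$gene_id)
  for (s in sample_ids) {
    out[[s]] <- 1e9 * counts[[s]] / (n_map[[s]] * counts$length_bp)
  }
  out
}

#' Exact Poisson-ratio test for two single libraries
#'
#' Tests whether a gene's underlying expression rate differs between two
#' libraries without replicates, conditioning on the total count `x + y`.
#' Under the null the count `y` in the second library given `x` in the first
#' follows
#' \deqn{p(y \mid x) = \left(\frac{n_2}{n_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1 + n_2/n_1)^{x+y+1}},}
#' i.e. a negative binomial in `y`. The two-sided p-value is
#' `2 * min(P(Y <= y), P(Y >= y))` capped at 1. All tail sums are evaluated
#' in log space by direct summation on the smaller side, so tiny p-values
#' keep full relative accuracy.
#'
#' @param x,y nonnegative integer counts in library 1 and library 2
#'   (vectorized; recycled).
#' @param n1,n2 positive total mapped reads of the two libraries.
#' @return numeric vector of two-sided p-values.
#' @export
ac_test <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive", call. = FALSE)
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) ac_test_one(x[i], y[i], n1[i], n2[i]), 0)
}

ac_test_one <- function(x, y, n1, n2) {
  ratio <- n2 / n1
  log_q <- log(ratio) - log1p(ratio)   # log P(failure) of the NB in y
  log_p <- -log1p(ratio)               # log P(success)
  logpmf <- function(k) {
    lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) +
      (x + 1) * log_p + k * log_q
  }
  logsumexp <- function(l) {
    m <- max(l)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(l - m)))
  }
  mean_y <- (x + 1) * ratio
  if (y <= mean_y) {
    lower <- exp(logsumexp(logpmf(0:y)))
    upper <- 1 - lower + exp(logpmf(y))
  } else {
    # sum the upper tail directly until the remainder is negligible;
    # beyond the mode terms decay at least geometrically with rate q
    upper_log <- ac_upper_tail_log(x, y, logpmf, log_q)
    upper <- exp(upper_log)
    lower <- 1 - upper + exp(logpmf(y))
  }
  min(1, 2 * min(lower, upper))
}

ac_upper_tail_log <- function(x, y, logpmf, log_q) {
  q <- exp(log_q)
  block <- 512L
  start <- y
  acc <- -Inf
  repeat {
    ks <- start:(start + block - 1L)
    l <- logpmf(ks)
    m <- max(l, acc)
    acc <- m + log(sum(exp(l - m)) + exp(acc - m))
    last <- l[block]
    # geometric remainder bound once past the mode: sum_{k>K} <= pmf(K) q/(1-q)
    ratio_next <- q * (x + start + block) / (start + block)
    if (ratio_next < 1 && last + log(ratio_next) - log1p(-ratio_next) < acc + log(1e-17))
      break
    start <- start + block
    if (start > y + 1e7) break  # safety net; unreachable for sane inputs
  }
  acc
}

#' Call differentially expressed genes between two single libraries
#'
#' Per gene, the raw p-value comes from [ac_test()] on the raw counts of the
#' treatment and reference libraries; FDR is Benjamini-Hochberg across all
#' tested genes of the comparison; the log2 ratio is computed on RPKM with
#' each RPKM floored at `rpkm_floor` so ratios stay finite when one library
#' drops to zero. Genes with zero counts in both libraries are untestable
#' and excluded (also from the BH denominator). A gene is called
#' differentially expressed when `|log2_ratio| >= log2(fc_threshold)` and
#' `fdr <= fdr_threshold`.
#'
#' @param counts counts tibble (`gene_id`, `length_bp`, sample columns).
#' @param totals totals tibble.
#' @param treatment,reference sample ids to compare (treatment vs reference).
#' @param fc_threshold fold-change gate (default 2, i.e. `|log2_ratio| >= 1`).
#' @param fdr_threshold BH-FDR gate (default 0.001).
#' @param rpkm_floor floor applied to each RPKM before the ratio.
#' @param keep_all if `TRUE`, return all tested genes with a `significant`
#'   column instead of only the calls.
#' @return tibble sorted by `fdr`, then `|log2_ratio|` descending, ties by
#'   gene id: `gene_id`, `treatment`, `reference`, `count_ref`, `count_trt`,
#'   `rpkm_ref`, `rpkm_trt`, `log2_ratio`, `p_raw`, `fdr`, `direction`
#'   (`"up"` iff `log2_ratio > 0`), and `significant` when `keep_all`.
#' @export
call_degs <- function(counts, totals, treatment, reference,
                      fc_threshold = 2, fdr_threshold = 0.001,
                      rpkm_floor = 0.01, keep_all = FALSE) {
  validate_counts(counts, totals)
  sample_ids <- setdiff(names(counts), c("gene_id", "length_bp"))
  for (s in c(treatment, reference)) {
    if (!s %in% sample_ids)
      stop("sample \"", s, "\" not found in counts", call. = FALSE)
  }
  if (identical(treatment, reference))
    stop("treatment and reference must differ", call. = FALSE)

  n_map <- stats::setNames(totals$total_mapped_reads, totals$sample_id)
  n_trt <- n_map[[treatment]]
  n_ref <- n_map[[reference]]
  x_trt <- counts[[treatment]]
  x_ref <- counts[[reference]]

  testable <- x_trt + x_ref > 0
  tbl <- tibble::tibble(
    gene_id = counts$gene_id[testable],
    treatment = treatment,
    reference = reference,
    count_ref = x_ref[testable],
    count_trt = x_trt[testable],
    rpkm_ref = 1e9 * x_ref[testable] / (n_ref * counts$length_bp[testable]),
    rpkm_trt = 1e9 * x_trt[testable] / (n_trt * counts$length_bp[testable])
  )
  tbl <- tbl |>
    dplyr::mutate(
      log2_ratio = log2(pmax(.data$rpkm_trt, rpkm_floor) /
                          pmax(.data$rpkm_ref, rpkm_floor)),
      p_raw = ac_test(.data$count_ref, .data$count_trt, n_ref, n_trt),
      fdr = stats::p.adjust(.data$p_raw, method = "BH"),
      direction = ifelse(.data$log2_ratio > 0, "up", "down"),
      significant = abs(.data$log2_ratio) >= log2(fc_threshold) &
        .data$fdr <= fdr_threshold
    ) |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$log2_ratio)), .data$gene_id)
  if (!keep_all) {
    tbl <- dplyr::filter(tbl, .data$significant) |>
      dplyr::select(-"significant")
  }
  tbl
}
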