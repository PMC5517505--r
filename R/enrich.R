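#' Upper-tail hypergeometric probability
#'
#' `P(X >= m)` where `X ~ Hypergeometric(N, M, n)`: the probability of
#' drawing at least `m` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `M` are annotated to
#' the term. Evaluated through the exact distribution function
#' (`stats::phyper`), which sums the tail directly and keeps full relative
#' accuracy for small p.
#'
#' @param N universe size.
#' @param M genes annotated to the term within the universe.
#' @param n drawn genes (the DEG list restricted to the universe).
#' @param m drawn genes annotated to the term.
#' @return the upper-tail probability.
#' @export
hypergeom_upper_tail <- function(N, M, n, m) {
  stopifnot(length(N) == 1, length(M) == 1, length(n) == 1, length(m) == 1)
  if (any(c(N, M, n, m) < 0) || M > N || n > N || m > min(M, n))
    stop("invalid hypergeometric bounds: need 0 <= m <= min(M, n), M <= N, n <= N",
         call. = FALSE)
  if (m == 0) return(1)
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis of a DEG list
#'
#' For every term, counts `N` (universe genes annotated to at least one term
#' of the namespace), `M` (universe genes annotated to the term), `n` (DEGs
#' in the universe) and `m` (DEGs annotated to the term), computes the
#' upper-tail hypergeometric p-value, a Bonferroni-adjusted p
#' (`min(1, p * T)` over the `T` terms tested in the namespace), and a
#' Benjamini-Hochberg FDR-adjusted p. The significance gate is
#' `p_fdr <= alpha` (default 0.05). Namespaces are corrected independently.
#'
#' The universe convention follows GO::TermFinder: the supplied `universe`
#' (typically all genes quantified/tested in the comparison) is intersected,
#' per namespace, with the genes annotated to at least one term, and both
#' the DEG list and every term's members are restricted to that
#' intersection before counting. Terms with `m = 0` are still tested
#' (p = 1) and appear in the output.
#'
#' @param deg_genes character vector of differentially expressed gene ids.
#' @param universe character vector of background gene ids.
#' @param gene_sets tibble with `term_id`, `description`, `namespace`,
#'   list-column `members` (see [read_gmt()]).
#' @param alpha FDR significance threshold (`p_fdr <= alpha` is significant).
#' @return tibble sorted by `p_raw` then `term_id` within namespace:
#'   `term_id`, `description`, `namespace`, `N`, `M`, `n`, `m`, `p_raw`,
#'   `p_bonferroni`, `p_fdr`, `significant`.
#' @export
enrich_gene_sets <- function(deg_genes, universe, gene_sets, alpha = 0.05) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  stopifnot(is.data.frame(gene_sets), nrow(gene_sets) > 0)
  deg_genes <- unique(deg_genes)
  universe <- unique(universe)
  gene_sets |>
    dplyr::group_by(.data$namespace) |>
    dplyr::group_modify(~ enrich_one_namespace(deg_genes, universe, .x, alpha)) |>
    dplyr::ungroup() |>
    dplyr::relocate("namespace", .after = "description")
}

enrich_one_namespace <- function(deg_genes, universe, sets, alpha) {
  annotated <- unique(unlist(sets$members))
  uni <- intersect(universe, annotated)
  degs <- intersect(deg_genes, uni)
  N <- length(uni)
  n <- length(degs)
  res <- purrr::map2_dfr(sets$members, seq_len(nrow(sets)), function(mem, i) {
    mem_u <- intersect(mem, uni)
    M <- length(mem_u)
    m <- length(intersect(degs, mem_u))
    tibble::tibble(
      term_id = sets$term_id[i],
      description = sets$description[i],
      N = N, M = M, n = n, m = m,
      p_raw = if (N == 0) 1 else hypergeom_upper_tail(N, M, n, m)
    )
  })
  T_tested <- nrow(res)
  res |>
    dplyr::mutate(
      p_bonferroni = pmin(1, .data$p_raw * T_tested),
      p_fdr = stats::p.adjust(.data$p_raw, method = "BH"),
      significant = .data$p_fdr <= alpha
    ) |>
    dplyr::arrange(.data$p_raw, .data$term_id)
}
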