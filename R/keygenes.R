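#' Screen differentially expressed genes for key regulators
#'
#' Applies three selection criteria to a comparison's DEG list:
#' \enumerate{
#'   \item magnitude: `|log2_ratio| > log2_gate` (default 1.5, strict
#'     inequality, so a ratio of exactly 1.5 fails);
#'   \item pathway: membership in at least one significantly enriched term
#'     (any namespace) of the same comparison;
#'   \item mechanism: membership in a curated list of genes with known
#'     pathologic roles (e.g. calcium overload, oxygen-radical production).
#' }
#' In `strict` mode a gene is selected when all enabled criteria hold; in
#' `any_two` mode when the (mandatory) magnitude criterion plus at least one
#' of the other two hold. When `mechanism` is `NULL` criterion 3 is
#' disabled: `passes_mechanism` is `NA` and selection uses the remaining
#' criteria. Network degree and core number annotate the report and break
#' ties in the ordering but are not a gate.
#'
#' @param degs DEG tibble from [call_degs()] (one comparison).
#' @param enrichment enrichment tibble from [enrich_gene_sets()] for the
#'   same comparison.
#' @param gene_sets the gene-set tibble used for the enrichment.
#' @param mechanism character vector of known-mechanism gene ids, or `NULL`
#'   to disable criterion 3.
#' @param network optional `coexpression_network` for the comparison; when
#'   `NULL` the `degree`/`core_number` columns are `NA`.
#' @param mode `"strict"` (all criteria) or `"any_two"`.
#' @param log2_gate magnitude gate on `|log2_ratio|` (strict `>`).
#' @return tibble sorted by `selected` (selected first), core number and
#'   `|log2_ratio|` descending, gene id ascending: `gene_id`, `treatment`,
#'   `reference`, `log2_ratio`, `passes_magnitude`, `passes_pathway`,
#'   `passes_mechanism`, `degree`, `core_number`, `selected`.
#' @export
screen_key_genes <- function(degs, enrichment, gene_sets, mechanism = NULL,
                             network = NULL, mode = c("strict", "any_two"),
                             log2_gate = 1.5) {
  mode <- match.arg(mode)
  if (nrow(degs) == 0) {
    return(tibble::tibble(
      gene_id = character(), treatment = character(), reference = character(),
      log2_ratio = numeric(), passes_magnitude = logical(),
      passes_pathway = logical(), passes_mechanism = logical(),
      degree = integer(), core_number = integer(), selected = logical()))
  }
  sig_terms <- enrichment$term_id[enrichment$significant]
  pathway_genes <- unique(unlist(
    gene_sets$members[gene_sets$term_id %in% sig_terms]))

  out <- degs |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      treatment = .data$treatment,
      reference = .data$reference,
      log2_ratio = .data$log2_ratio,
      passes_magnitude = abs(.data$log2_ratio) > log2_gate,
      passes_pathway = .data$gene_id %in% pathway_genes,
      passes_mechanism = if (is.null(mechanism)) NA else .data$gene_id %in% mechanism
    )
  if (!is.null(network)) {
    out <- dplyr::left_join(out, network$nodes, by = "gene_id")
  } else {
    out$degree <- NA_integer_
    out$core_number <- NA_integer_
  }
  mech_ok <- if (is.null(mechanism)) TRUE else out$passes_mechanism
  out$selected <- if (mode == "strict") {
    out$passes_magnitude & out$passes_pathway & mech_ok
  } else if (is.null(mechanism)) {
    out$passes_magnitude & out$passes_pathway
  } else {
    out$passes_magnitude & (out$passes_pathway | out$passes_mechanism)
  }
  out |>
    dplyr::arrange(dplyr::desc(.data$selected),
                   dplyr::desc(dplyr::coalesce(.data$core_number, -1L)),
                   dplyr::desc(abs(.data$log2_ratio)),
                   .data$gene_id)
}
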