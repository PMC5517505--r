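#' Pipeline configuration
#'
#' Collects paths, comparisons and thresholds for [run_pipeline()]. The
#' default comparison list mirrors a five-condition OGD/R design: OGD vs
#' control, then each reperfusion time point vs OGD.
#'
#' @param counts_path,totals_path count matrix and totals sidecar
#'   (see [read_counts()]).
#' @param gmt_paths named character vector of GMT files, one per namespace,
#'   e.g. `c(GO = "go.gmt", KEGG = "kegg.gmt")`.
#' @param mechanism_path optional plain gene list of known-mechanism genes;
#'   `NULL` disables the screen's third criterion.
#' @param out_dir output directory (created if needed).
#' @param comparisons list of `c(treatment, reference)` sample-id pairs;
#'   `NULL` selects the OGD/R default for a five-sample matrix (sample 2 vs
#'   sample 1, then samples 3..5 each vs sample 2, in file column order).
#' @param fc_threshold,fdr_threshold DEG gates (see [call_degs()]).
#' @param enrich_alpha enrichment FDR gate (see [enrich_gene_sets()]).
#' @param r_min,p_max network edge gates (see [build_network()]).
#' @param log2_gate key-gene magnitude gate (see [screen_key_genes()]).
#' @param screen_mode `"strict"` or `"any_two"`.
#' @param seed seed echoed in the manifest (the pipeline stages themselves
#'   are deterministic; the seed matters only when a simulation feeds them).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path, totals_path, gmt_paths,
                            mechanism_path = NULL, out_dir,
                            comparisons = NULL,
                            fc_threshold = 2, fdr_threshold = 0.001,
                            enrich_alpha = 0.05, r_min = 0.9, p_max = 0.05,
                            log2_gate = 1.5,
                            screen_mode = c("strict", "any_two"),
                            seed = 1L) {
  screen_mode <- match.arg(screen_mode)
  stopifnot(fc_threshold >= 1, fdr_threshold > 0, fdr_threshold <= 1,
            enrich_alpha > 0, enrich_alpha <= 1,
            r_min >= 0, r_min <= 1, p_max > 0, p_max <= 1, log2_gate >= 0)
  if (is.null(names(gmt_paths)) || any(!nzchar(names(gmt_paths))))
    stop("gmt_paths must be a named vector (names are namespace tags)",
         call. = FALSE)
  structure(list(
    counts_path = counts_path, totals_path = totals_path,
    gmt_paths = gmt_paths, mechanism_path = mechanism_path,
    out_dir = out_dir, comparisons = comparisons,
    fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
    enrich_alpha = enrich_alpha, r_min = r_min, p_max = p_max,
    log2_gate = log2_gate, screen_mode = screen_mode,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

default_comparisons <- function(sample_ids) {
  if (length(sample_ids) < 2)
    stop("need at least 2 samples to form a comparison", call. = FALSE)
  if (length(sample_ids) < 3)
    return(list(c(sample_ids[2], sample_ids[1])))
  c(list(c(sample_ids[2], sample_ids[1])),
    lapply(sample_ids[-(1:2)], function(s) c(s, sample_ids[2])))
}

#' Run the full screening pipeline
#'
#' Executes quantification, DEG calling, GO/KEGG-style enrichment,
#' co-expression network construction and the key-gene screen for every
#' configured comparison, writes all report tables under `out_dir`, and
#' returns (and writes) a run manifest recording parameters and per-stage
#' record counts. Given identical inputs and configuration the run is
#' deterministic and its outputs byte-identical.
#'
#' Outputs per comparison `<trt>_vs_<ref>`: `deg_<cmp>.tsv` (all tested
#' genes, `significant` column), `enrichment_<cmp>.tsv`,
#' `network_<cmp>.graphml`, `edges_<cmp>.tsv`, `keygenes_<cmp>.tsv`; plus
#' `rpkm.tsv` and `manifest.json` at the top level.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cm <- read_counts(config$counts_path, config$totals_path)
  sample_ids <- setdiff(names(cm$counts), c("gene_id", "length_bp"))
  comparisons <- config$comparisons
  if (is.null(comparisons)) comparisons <- default_comparisons(sample_ids)
  for (cmp in comparisons) {
    bad <- setdiff(cmp, sample_ids)
    if (length(bad) > 0)
      stop("comparison references unknown sample \"", bad[1], "\"", call. = FALSE)
    if (cmp[1] == cmp[2])
      stop("comparison treatment and reference are identical (\"", cmp[1], "\")",
           call. = FALSE)
  }
  gene_sets <- purrr::imap_dfr(config$gmt_paths,
                               function(p, ns) read_gmt(p, namespace = ns))
  mechanism <- if (!is.null(config$mechanism_path))
    read_gene_list(config$mechanism_path) else NULL
  if (!is.null(mechanism) && length(mechanism) == 0)
    stop("mechanism gene list is empty", call. = FALSE)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  expr <- rpkm(cm$counts, cm$totals)
  write_report(expr, file.path(config$out_dir, "rpkm.tsv"))

  per_cmp <- purrr::map(comparisons, function(cmp) {
    run_one_comparison(cmp[1], cmp[2], cm, expr, gene_sets, mechanism, config)
  })

  manifest <- list(
    package = "ogdrscreen",
    version = as.character(utils::packageVersion("ogdrscreen")),
    seed = config$seed,
    parameters = list(
      fc_threshold = config$fc_threshold, fdr_threshold = config$fdr_threshold,
      enrich_alpha = config$enrich_alpha, r_min = config$r_min,
      p_max = config$p_max, log2_gate = config$log2_gate,
      screen_mode = config$screen_mode, rpkm_floor = 0.01
    ),
    inputs = list(counts = config$counts_path, totals = config$totals_path,
                  gene_sets = as.list(config$gmt_paths),
                  mechanism = config$mechanism_path),
    n_genes = nrow(cm$counts),
    n_samples = length(sample_ids),
    comparisons = purrr::map(per_cmp, "summary")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

run_one_comparison <- function(treatment, reference, cm, expr, gene_sets,
                               mechanism, config) {
  tag <- paste0(treatment, "_vs_", reference)
  out <- function(name) file.path(config$out_dir, paste0(name, "_", tag, ".tsv"))

  deg_all <- call_degs(cm$counts, cm$totals, treatment, reference,
                       fc_threshold = config$fc_threshold,
                       fdr_threshold = config$fdr_threshold,
                       keep_all = TRUE)
  write_report(deg_all, out("deg"))
  degs <- dplyr::filter(deg_all, .data$significant)

  enr <- enrich_gene_sets(degs$gene_id, universe = deg_all$gene_id,
                          gene_sets, alpha = config$enrich_alpha)
  write_report(enr, out("enrichment"))

  net <- build_network(expr, genes = degs$gene_id,
                       r_min = config$r_min, p_max = config$p_max)
  node_attrs <- dplyr::left_join(net$nodes,
                                 dplyr::select(degs, "gene_id", "log2_ratio"),
                                 by = "gene_id")
  net_annot <- net
  net_annot$nodes <- node_attrs
  write_network(net_annot,
                graphml_path = file.path(config$out_dir,
                                         paste0("network_", tag, ".graphml")),
                edges_path = out("edges"))

  keys <- screen_key_genes(degs, enr, gene_sets, mechanism = mechanism,
                           network = net, mode = config$screen_mode,
                           log2_gate = config$log2_gate)
  write_report(keys, out("keygenes"))

  list(summary = list(
    treatment = treatment, reference = reference,
    genes_tested = nrow(deg_all),
    degs = nrow(degs),
    degs_up = sum(degs$direction == "up"),
    degs_down = sum(degs$direction == "down"),
    significant_terms = sum(enr$significant),
    network_nodes = nrow(net$nodes),
    network_edges = nrow(net$edges),
    key_genes = sum(keys$selected)
  ))
}
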