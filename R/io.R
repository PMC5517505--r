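#' Read a count matrix and its totals sidecar
#'
#' The counts file is tab-separated with header `gene_id`, `length_bp`, then
#' one column per library; the totals sidecar is tab-separated with columns
#' `sample_id` and `total_mapped_reads` (total mapped reads may exceed the
#' column sums, since reads also map outside the quantified gene set).
#' All parsers here reject malformed input rather than coerce it.
#'
#' @param path counts file path.
#' @param totals_path totals sidecar path.
#' @return list with `counts` (tibble) and `totals` (tibble), validated.
#' @export
read_counts <- function(path, totals_path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    length_bp = readr::col_double(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(counts)))
    stop("counts file ", path, ": first columns must be gene_id, length_bp",
         call. = FALSE)
  totals <- readr::read_tsv(totals_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    total_mapped_reads = readr::col_double()
  ), progress = FALSE)
  validate_counts(counts, totals, path = path, totals_path = totals_path)
  counts$length_bp <- as.integer(counts$length_bp)
  counts <- dplyr::mutate(counts, dplyr::across(
    !dplyr::all_of(c("gene_id", "length_bp")), as.integer))
  list(counts = counts, totals = totals)
}

#' Validate a count matrix against its totals
#'
#' Checks identifier uniqueness, integer nonnegative counts, positive gene
#' lengths, positive totals, and the sample correspondence between the two
#' tables. Errors name the offending gene/sample and (for file input) the
#' line number.
#'
#' @param counts counts tibble (`gene_id`, `length_bp`, sample columns).
#' @param totals totals tibble (`sample_id`, `total_mapped_reads`).
#' @param path,totals_path optional file names used in error messages.
#' @return the validated inputs, invisibly.
#' @export
validate_counts <- function(counts, totals, path = "counts", totals_path = "totals") {
  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup) > 0) {
    line <- which(duplicated(counts$gene_id))[1] + 1L  # +1 for header
    stop(path, " line ", line, ": duplicated gene id \"", dup[1], "\"",
         call. = FALSE)
  }
  if (any(counts$length_bp <= 0 | counts$length_bp != round(counts$length_bp))) {
    bad <- which(counts$length_bp <= 0 | counts$length_bp != round(counts$length_bp))[1]
    stop(path, " line ", bad + 1L, ": gene length must be a positive integer (gene \"",
         counts$gene_id[bad], "\")", call. = FALSE)
  }
  sample_ids <- setdiff(names(counts), c("gene_id", "length_bp"))
  if (length(sample_ids) == 0)
    stop(path, ": no sample columns found", call. = FALSE)
  for (s in sample_ids) {
    v <- counts[[s]]
    if (any(is.na(v) | v < 0 | v != round(v))) {
      bad <- which(is.na(v) | v < 0 | v != round(v))[1]
      stop(path, " line ", bad + 1L, ": non-integer or negative count in sample \"",
           s, "\"", call. = FALSE)
    }
  }
  dup_s <- totals$sample_id[duplicated(totals$sample_id)]
  if (length(dup_s) > 0)
    stop(totals_path, ": duplicated sample id \"", dup_s[1], "\"", call. = FALSE)
  missing <- setdiff(sample_ids, totals$sample_id)
  if (length(missing) > 0)
    stop(totals_path, ": missing total mapped reads for sample \"",
         missing[1], "\"", call. = FALSE)
  if (any(!is.finite(totals$total_mapped_reads) | totals$total_mapped_reads <= 0)) {
    bad <- which(!is.finite(totals$total_mapped_reads) | totals$total_mapped_reads <= 0)[1]
    stop(totals_path, ": total mapped reads must be positive (sample \"",
         totals$sample_id[bad], "\")", call. = FALSE)
  }
  invisible(list(counts = counts, totals = totals))
}

#' Write a count matrix and its totals sidecar
#'
#' @param counts counts tibble.
#' @param totals totals tibble.
#' @param path,totals_path output file paths.
#' @return the input, invisibly.
#' @export
write_counts <- function(counts, totals, path, totals_path) {
  readr::write_tsv(counts, path, progress = FALSE)
  readr::write_tsv(totals, totals_path, progress = FALSE)
  invisible(list(counts = counts, totals = totals))
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is `term_id<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate member ids within a line are dropped with a warning; duplicate
#' term ids across lines are an error; lines with fewer than three fields
#' are an error naming the line.
#'
#' @param path GMT file path.
#' @param namespace namespace tag attached to every term (`"GO"`, `"KEGG"`,
#'   or `"custom"`).
#' @return tibble: `term_id`, `description`, `namespace`, list-column
#'   `members`.
#' @export
read_gmt <- function(path, namespace = "custom") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0)
    stop(path, " line ", short[1], ": GMT line has fewer than 3 fields",
         call. = FALSE)
  term_ids <- vapply(fields, `[[`, "", 1L)
  dup <- term_ids[duplicated(term_ids)]
  if (length(dup) > 0)
    stop(path, ": duplicated term id \"", dup[1], "\"", call. = FALSE)
  members <- lapply(seq_along(fields), function(i) {
    m <- fields[[i]][-(1:2)]
    u <- unique(m)
    if (length(u) < length(m))
      warning(path, " line ", i, ": dropped duplicated member ids in term \"",
              term_ids[i], "\"", call. = FALSE)
    u
  })
  tibble::tibble(
    term_id = term_ids,
    description = vapply(fields, `[[`, "", 2L),
    namespace = namespace,
    members = members
  )
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets tibble as returned by [read_gmt()] or
#'   [simulate_gene_sets()].
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- purrr::pmap_chr(
    gene_sets[c("term_id", "description", "members")],
    function(term_id, description, members)
      paste(c(term_id, description, members), collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(gene_sets)
}

#' Read a plain gene list (one identifier per line)
#'
#' Used for the curated known-mechanism gene list of the key-gene screen.
#' Blank lines and lines starting with `#` are skipped; duplicates are
#' collapsed.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write a plain gene list
#' @param genes character vector.
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path, useBytes = TRUE)
  invisible(genes)
}

#' Export a co-expression network as GraphML and/or an edge list
#'
#' The GraphML document carries node attributes `gene_id`, `degree`,
#' `core_number` (and `log2_ratio` when present in the node table) and edge
#' attributes `r` and `p`. The edge list is tab-separated with columns
#' `gene_a`, `gene_b`, `r`, `p` (floats at 6 significant digits).
#'
#' @param network a `coexpression_network` object from [build_network()].
#' @param graphml_path optional GraphML output path.
#' @param edges_path optional edge-list output path.
#' @return the network, invisibly.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  stopifnot(inherits(network, "coexpression_network"))
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      d = as.data.frame(network$edges),
      directed = FALSE,
      vertices = as.data.frame(network$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    edges <- network$edges |>
      dplyr::rename(gene_a = "from", gene_b = "to") |>
      dplyr::mutate(dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
    readr::write_tsv(edges, edges_path, progress = FALSE)
  }
  invisible(network)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path edge-list path.
#' @return tibble: `gene_a`, `gene_b`, `r`, `p`.
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    r = readr::col_double(),
    p = readr::col_double()
  ), progress = FALSE)
}

#' Serialize / restore a simulation truth object
#'
#' Truth objects are stored as JSON so external harnesses can consume them.
#'
#' @param truth truth list from [simulate_counts()] / [simulate_gene_sets()].
#' @param path file path.
#' @return `write_truth()`: the input, invisibly; `read_truth()`: the truth
#'   list with tibble components restored.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(de_genes = truth$de_genes,
         module_assignments = truth$module_assignments,
         enriched_terms = truth$enriched_terms,
         gene_ids = truth$gene_ids,
         config = truth$config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$de_genes <- tibble::as_tibble(x$de_genes)
  x$module_assignments <- tibble::as_tibble(x$module_assignments)
  x$enriched_terms <- as.character(x$enriched_terms)
  x
}

#' Write a report table (tab-separated, 6 significant digits)
#'
#' Shared writer for DEG, enrichment, and key-gene tables: tab-separated,
#' fixed column order as produced by the corresponding stage, floats
#' rendered at 6 significant digits, UTF-8.
#'
#' @param tbl a tibble.
#' @param path output path.
#' @return the input tibble, invisibly.
#' @export
write_report <- function(tbl, path) {
  out <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.list),
                                          ~ vapply(.x, paste, "", collapse = ",")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(tbl)
}
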