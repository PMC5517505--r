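# Small deterministic fixtures built in code.

# Two-sample count table; trt/ref counts chosen so the six genes span clear
# calls, boundary cases, and a zero-dropout.
toy_counts <- function() {
  tibble::tibble(
    gene_id = sprintf("G%d", 1:6),
    length_bp = rep(1000L, 6),
    ref = c(250L, 100L, 80L, 11L, 2600L, 0L),
    trt = c(1000L, 100L, 0L, 10L, 5000L, 3L)
  )
}

toy_totals <- function() {
  tibble::tibble(sample_id = c("ref", "trt"),
                 total_mapped_reads = c(1e6, 1e6))
}

# Expression matrix whose correlation structure is fully forced: g1 == g2,
# g3 anti-correlated with both, g4 constant.
forced_expression <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    s1 = c(1, 1, 8, 5), s2 = c(2, 2, 4, 5),
    s3 = c(4, 4, 2, 5), s4 = c(8, 8, 1, 5)
  )
}

write_sim_inputs <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    totals = file.path(dir, "totals.tsv"),
    go = file.path(dir, "go.gmt"),
    kegg = file.path(dir, "kegg.gmt"),
    mech = file.path(dir, "mechanism.txt")
  )
  write_counts(ds$counts, ds$totals, paths$counts, paths$totals)
  write_gmt(dplyr::filter(ds$gene_sets, namespace == "GO"), paths$go)
  write_gmt(dplyr::filter(ds$gene_sets, namespace == "KEGG"), paths$kegg)
  mech <- sort(unique(ds$truth$de_genes$gene_id))[1:30]
  write_gene_list(mech, paths$mech)
  paths
}
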