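#' Simulation configuration for an OGD/R-style count time course
#'
#' Builds the validated parameter list consumed by [simulate_counts()] and
#' [simulate_gene_sets()]. Defaults emulate a five-condition oxygen-glucose
#' deprivation/reperfusion design with one sequencing library per condition:
#' a control library plus an OGD library and three reperfusion time points.
#'
#' The count model is negative binomial at the gene level: each gene draws a
#' baseline expression (expected RPKM in the reference condition) from a
#' log-normal, multiplied by a per-gene gamma factor with variance
#' `dispersion` shared across all libraries of the experiment; counts in each
#' library are then Poisson around the length- and depth-scaled rate. The
#' marginal distribution of each count is negative binomial with the given
#' overdispersion, while library-to-library noise is purely Poisson -- the
#' sampling regime of a replicate-free design in which every condition is a
#' single library prepared from the same culture batch. `dispersion = 0`
#' collapses to Poisson throughout.
#'
#' @param n_genes number of genes.
#' @param n_conditions number of conditions (one library per condition by
#'   default); values above 5 give the extended-profile mode used for
#'   correlation-recovery experiments.
#' @param n_replicates libraries per condition. Defaults to 1, matching the
#'   single-library-per-condition design; exposed for power studies.
#' @param mean_library_size expected total mapped reads per library. Realized
#'   per-library totals are drawn uniformly within 10% of this value.
#' @param gene_length_log_mean,gene_length_log_sd log-normal parameters
#'   (natural-log bp) for transcript lengths; lengths are floored at 200 bp.
#' @param baseline_expression_log_mean,baseline_expression_log_sd log-normal
#'   parameters (natural log) for the expected reference-condition RPKM.
#' @param dispersion negative-binomial overdispersion of the per-gene rate
#'   (variance of the shared gamma factor); 0 means Poisson.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param de_log2fc_range ordered pair: absolute log2 fold-change bounds for
#'   planted DE genes (uniform draw).
#' @param de_up_fraction probability a planted DE gene is up-regulated.
#'   The default 0.9 mirrors the strongly up-dominated response of acute
#'   OGD (on the order of 950 up vs 80 down genes).
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per module. Module genes are drawn from genes not
#'   planted as DE so truth labels stay disjoint.
#' @param module_correlation target pairwise Pearson correlation of
#'   within-module expression profiles, in `[0, 1)`.
#' @param n_gene_sets number of gene sets emitted by [simulate_gene_sets()].
#' @param gene_set_size_range ordered integer pair of set-size bounds.
#' @param n_enriched_sets how many sets are constructed to be enriched among
#'   planted DE genes.
#' @param enriched_set_de_fraction fraction of each enriched set's members
#'   drawn from planted DE genes, in `(0, 1]`.
#' @param seed integer seed; identical configurations (including seed) yield
#'   bit-identical output.
#'
#' @return a list of class `sim_config`.
#' @seealso [simulate_counts()], [simulate_gene_sets()], [simulate_dataset()]
#' @export
sim_config <- function(n_genes = 2000,
                       n_conditions = 5,
                       n_replicates = 1,
                       mean_library_size = 5e6,
                       gene_length_log_mean = log(1800),
                       gene_length_log_sd = 0.6,
                       baseline_expression_log_mean = log(10),
                       baseline_expression_log_sd = 1.2,
                       dispersion = 0.05,
                       n_de_genes = 100,
                       de_log2fc_range = c(2, 4),
                       de_up_fraction = 0.9,
                       n_modules = 3,
                       module_size = 20,
                       module_correlation = 0.95,
                       n_gene_sets = 50,
                       gene_set_size_range = c(10L, 40L),
                       n_enriched_sets = 5,
                       enriched_set_de_fraction = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_conditions = as.integer(n_conditions),
    n_replicates = as.integer(n_replicates),
    mean_library_size = as.numeric(mean_library_size),
    gene_length_log_mean = gene_length_log_mean,
    gene_length_log_sd = gene_length_log_sd,
    baseline_expression_log_mean = baseline_expression_log_mean,
    baseline_expression_log_sd = baseline_expression_log_sd,
    dispersion = as.numeric(dispersion),
    n_de_genes = as.integer(n_de_genes),
    de_log2fc_range = as.numeric(de_log2fc_range),
    de_up_fraction = as.numeric(de_up_fraction),
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    module_correlation = as.numeric(module_correlation),
    n_gene_sets = as.integer(n_gene_sets),
    gene_set_size_range = as.integer(gene_set_size_range),
    n_enriched_sets = as.integer(n_enriched_sets),
    enriched_set_de_fraction = as.numeric(enriched_set_de_fraction),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  err <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (cfg$n_genes < 1) err("n_genes must be positive")
  if (cfg$n_conditions < 1) err("n_conditions must be positive")
  if (cfg$n_replicates < 1) err("n_replicates must be positive")
  if (cfg$mean_library_size <= 0) err("mean_library_size must be positive")
  if (cfg$dispersion < 0) err("dispersion must be nonnegative")
  if (cfg$n_de_genes < 0) err("n_de_genes must be nonnegative")
  if (cfg$n_de_genes > cfg$n_genes) err("n_de_genes exceeds n_genes")
  if (cfg$n_modules < 0) err("n_modules must be nonnegative")
  if (cfg$n_modules > 0 && cfg$module_size < 1) err("module_size must be positive")
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    err("n_modules * module_size exceeds n_genes")
  if (cfg$n_de_genes + cfg$n_modules * cfg$module_size > cfg$n_genes)
    err("n_de_genes + n_modules * module_size exceeds n_genes (DE and module genes are disjoint)")
  if (cfg$module_correlation < 0 || cfg$module_correlation >= 1)
    err("module_correlation must lie in [0, 1)")
  if (length(cfg$de_log2fc_range) != 2 || diff(cfg$de_log2fc_range) < 0)
    err("de_log2fc_range must be an ordered (low <= high) pair")
  if (any(cfg$de_log2fc_range < 0)) err("de_log2fc_range bounds are absolute log2 fold changes and must be nonnegative")
  if (cfg$de_up_fraction < 0 || cfg$de_up_fraction > 1) err("de_up_fraction must lie in [0, 1]")
  if (cfg$n_gene_sets < 1) err("n_gene_sets must be positive")
  if (length(cfg$gene_set_size_range) != 2 || diff(cfg$gene_set_size_range) < 0 ||
      cfg$gene_set_size_range[1] < 1)
    err("gene_set_size_range must be an ordered pair of positive integers")
  if (cfg$n_enriched_sets < 0) err("n_enriched_sets must be nonnegative")
  if (cfg$n_enriched_sets > cfg$n_gene_sets) err("n_enriched_sets exceeds n_gene_sets")
  if (cfg$enriched_set_de_fraction <= 0 || cfg$enriched_set_de_fraction > 1)
    err("enriched_set_de_fraction must lie in (0, 1]")
  invisible(cfg)
}

# Condition labels: paper-style names for the canonical 5-condition design,
# generic zero-padded labels otherwise.
condition_labels <- function(n_conditions) {
  if (n_conditions == 5) {
    c("OGD0_R0h", "OGD45_R0h", "OGD45_R6h", "OGD45_R12h", "OGD45_R18h")
  } else {
    sprintf("cond%02d", seq_len(n_conditions))
  }
}

# Standard deviation (log2 units) of the latent condition profile shared by
# module genes. Large relative to sequencing noise so module correlation is
# dominated by the planted latent factor.
MODULE_PROFILE_SD <- 2

#' Simulate a count matrix with planted ground truth
#'
#' Generates a genes x libraries read-count table following the model
#' described in [sim_config()]: log-normal baseline expression, planted DE
#' genes whose expected expression is multiplied by `2^log2fc` in every
#' non-reference condition, module genes sharing a latent per-condition
#' profile that induces pairwise correlation close to `module_correlation`,
#' and per-library Poisson sampling around gamma-heterogeneous gene rates
#' (marginally negative binomial).
#'
#' @param config a [sim_config()] object.
#' @return a list with components
#'   \describe{
#'     \item{counts}{tibble: `gene_id`, `length_bp`, one integer column per library.}
#'     \item{totals}{tibble: `sample_id`, `total_mapped_reads`.}
#'     \item{truth}{list with `de_genes` (tibble `treatment`, `reference`,
#'       `gene_id`, `log2fc`), `module_assignments` (tibble `gene_id`,
#'       `module`), `enriched_terms` (character, filled by
#'       [simulate_gene_sets()]), `gene_ids`, and the config echo.}
#'   }
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(cfg) {
  n_genes <- cfg$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  conds <- condition_labels(cfg$n_conditions)
  if (cfg$n_replicates == 1) {
    sample_ids <- conds
    sample_cond <- seq_len(cfg$n_conditions)
  } else {
    grid <- expand.grid(rep = seq_len(cfg$n_replicates),
                        cond = seq_len(cfg$n_conditions))
    sample_ids <- sprintf("%s_r%d", conds[grid$cond], grid$rep)
    sample_cond <- grid$cond
  }
  n_samp <- length(sample_ids)

  lengths_bp <- pmax(200L, as.integer(round(
    stats::rlnorm(n_genes, cfg$gene_length_log_mean, cfg$gene_length_log_sd))))
  baseline_rpkm <- stats::rlnorm(n_genes, cfg$baseline_expression_log_mean,
                                 cfg$baseline_expression_log_sd)
  totals <- as.numeric(round(
    cfg$mean_library_size * stats::runif(n_samp, 0.9, 1.1)))

  # planted DE genes: expression multiplied by 2^lfc in conditions 2..K
  de_idx <- if (cfg$n_de_genes > 0) sort(sample.int(n_genes, cfg$n_de_genes)) else integer(0)
  lfc_mag <- stats::runif(cfg$n_de_genes, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2])
  lfc_sign <- ifelse(stats::runif(cfg$n_de_genes) < cfg$de_up_fraction, 1, -1)
  lfc <- lfc_mag * lfc_sign

  # module genes drawn from non-DE genes; shared latent condition profile
  pool <- setdiff(seq_len(n_genes), de_idx)
  module_idx <- integer(0)
  module_of <- integer(0)
  if (cfg$n_modules > 0) {
    module_idx <- sort(sample(pool, cfg$n_modules * cfg$module_size))
    module_of <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
  }

  # log2-space condition offsets
  offset <- matrix(0, n_genes, cfg$n_conditions)
  if (cfg$n_modules > 0) {
    rho <- cfg$module_correlation
    for (k in seq_len(cfg$n_modules)) {
      f <- stats::rnorm(cfg$n_conditions)
      members <- module_idx[module_of == k]
      eps <- matrix(stats::rnorm(length(members) * cfg$n_conditions),
                    length(members), cfg$n_conditions)
      offset[members, ] <- MODULE_PROFILE_SD *
        (sqrt(rho) * matrix(f, length(members), cfg$n_conditions, byrow = TRUE) +
           sqrt(1 - rho) * eps)
    }
  }

  de_mult <- matrix(1, n_genes, cfg$n_conditions)
  if (cfg$n_de_genes > 0 && cfg$n_conditions > 1) {
    de_mult[de_idx, 2:cfg$n_conditions] <- 2^lfc
  }

  # shared gamma rate factor (gene-level heterogeneity; Poisson per library)
  gamma_fac <- if (cfg$dispersion > 0) {
    stats::rgamma(n_genes, shape = 1 / cfg$dispersion, scale = cfg$dispersion)
  } else {
    rep(1, n_genes)
  }

  counts <- matrix(0L, n_genes, n_samp, dimnames = list(gene_ids, sample_ids))
  for (s in seq_len(n_samp)) {
    cond <- sample_cond[s]
    mu <- baseline_rpkm * gamma_fac * de_mult[, cond] * 2^offset[, cond] *
      lengths_bp * totals[s] / 1e9
    counts[, s] <- stats::rpois(n_genes, mu)
  }

  de_tbl <- if (cfg$n_de_genes > 0 && cfg$n_conditions > 1) {
    tidyr::crossing(treatment = sample_ids[sample_cond > 1]) |>
      dplyr::mutate(reference = sample_ids[match(1, sample_cond)]) |>
      tidyr::crossing(tibble::tibble(gene_id = gene_ids[de_idx], log2fc = lfc)) |>
      dplyr::select("treatment", "reference", "gene_id", "log2fc") |>
      dplyr::arrange(.data$treatment, .data$gene_id)
  } else {
    tibble::tibble(treatment = character(), reference = character(),
                   gene_id = character(), log2fc = numeric())
  }

  counts_tbl <- dplyr::bind_cols(
    tibble::tibble(gene_id = gene_ids, length_bp = lengths_bp),
    tibble::as_tibble(as.data.frame(counts))
  )
  totals_tbl <- tibble::tibble(sample_id = sample_ids, total_mapped_reads = totals)

  truth <- list(
    de_genes = de_tbl,
    module_assignments = tibble::tibble(gene_id = gene_ids[module_idx],
                                        module = module_of),
    enriched_terms = character(0),
    gene_ids = gene_ids,
    config = unclass(cfg)
  )
  list(counts = counts_tbl, totals = totals_tbl, truth = truth)
}

#' Simulate gene-set annotations with planted enrichment
#'
#' Emits `n_gene_sets` gene sets. `n_enriched_sets` of them draw a fraction
#' `enriched_set_de_fraction` of their members from the planted DE genes
#' recorded in `truth`, the remainder uniformly from non-DE genes; the other
#' sets sample members uniformly from all genes. Planted term ids are added
#' to `truth$enriched_terms`. Namespaces alternate between `"GO"` and
#' `"KEGG"` so both enrichment namespaces are exercised.
#'
#' @param config the [sim_config()] used for [simulate_counts()].
#' @param truth the truth object returned by [simulate_counts()].
#' @return list with `gene_sets` (tibble: `term_id`, `description`,
#'   `namespace`, list-column `members`) and the updated `truth`.
#' @export
simulate_gene_sets <- function(config, truth) {
  validate_sim_config(config)
  stopifnot(is.list(truth), !is.null(truth$gene_ids))
  de_ids <- unique(truth$de_genes$gene_id)
  sizes_seed <- config$seed + 1L  # distinct stream from the count draw
  withr::with_seed(sizes_seed, {
    n_sets <- config$n_gene_sets
    lo <- config$gene_set_size_range[1]
    hi <- config$gene_set_size_range[2]
    sizes <- lo + sample.int(hi - lo + 1L, n_sets, replace = TRUE) - 1L
    enriched <- seq_len(config$n_enriched_sets)
    need_de <- ceiling(config$enriched_set_de_fraction * sizes[enriched])
    if (length(enriched) > 0 && any(need_de > length(de_ids)))
      stop("invalid simulation config: enriched sets require more DE genes (",
           max(need_de), ") than planted (", length(de_ids), ")", call. = FALSE)
    non_de <- setdiff(truth$gene_ids, de_ids)
    members <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      if (i %in% enriched) {
        k <- need_de[i]
        members[[i]] <- sort(c(sample(de_ids, k),
                               sample(non_de, sizes[i] - k)))
      } else {
        members[[i]] <- sort(sample(truth$gene_ids, sizes[i]))
      }
    }
    term_ids <- sprintf("SET%03d", seq_len(n_sets))
    gene_sets <- tibble::tibble(
      term_id = term_ids,
      description = sprintf("synthetic gene set %d", seq_len(n_sets)),
      namespace = rep(c("GO", "KEGG"), length.out = n_sets),
      members = members
    )
    truth$enriched_terms <- term_ids[enriched]
    list(gene_sets = gene_sets, truth = truth)
  })
}

#' Simulate a complete dataset (counts, totals, gene sets, truth)
#'
#' Convenience wrapper chaining [simulate_counts()] and
#' [simulate_gene_sets()].
#'
#' @inheritParams simulate_counts
#' @return list with `counts`, `totals`, `gene_sets`, `truth`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_counts(config)
  gs <- simulate_gene_sets(config, sim$truth)
  list(counts = sim$counts, totals = sim$totals,
       gene_sets = gs$gene_sets, truth = gs$truth)
}
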