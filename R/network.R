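#' Pearson correlation with a two-sided t-test p-value
#'
#' Sample Pearson correlation of two equal-length profiles, with the
#' two-sided p-value from `t = r * sqrt((L - 2) / (1 - r^2))` against a
#' Student-t with `L - 2` degrees of freedom. `|r| = 1` maps to `p = 0`.
#'
#' @param x,y numeric profiles of equal length `L >= 3`, each with nonzero
#'   variance.
#' @return named numeric vector `c(r = , p = )`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance profile: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  # perfectly collinear profiles can land a rounding error below 1
  if (1 - abs(r) < 1e-12) r <- sign(r)
  c(r = r, p = cor_p(r, length(x)))
}

cor_p <- function(r, L) {
  d <- dim(r)
  r <- pmin(1, pmax(-1, r))
  r[1 - abs(r) < 1e-12] <- sign(r[1 - abs(r) < 1e-12])
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt((L - 2) / (1 - r^2)), df = L - 2))
  dim(p) <- d
  p
}

#' Build a gene co-expression network from significantly correlated pairs
#'
#' Profiles are `log2(RPKM + 1)` per gene across all samples of the
#' expression matrix. Every unordered gene pair with `|r| >= r_min` and
#' `p <= p_max` becomes an edge (the sign of `r` is kept as an edge
#' attribute); genes with no qualifying partner remain as isolated nodes.
#' Genes with constant profiles cannot be correlated and are kept as
#' isolated nodes with a message. Degree and core number (see
#' [kcore_decompose()]) are computed for every node.
#'
#' @param expression RPKM tibble from [rpkm()] (`gene_id` + sample columns).
#' @param genes gene ids to include (typically the DEGs of a comparison);
#'   defaults to all genes in `expression`.
#' @param r_min minimum absolute Pearson correlation for an edge.
#' @param p_max maximum correlation-test p-value for an edge.
#' @return an object of class `coexpression_network`: list with
#'   `nodes` (tibble `gene_id`, `degree`, `core_number`), `edges` (tibble
#'   `from`, `to`, `r`, `p`, with `from < to` and rows sorted), `n_samples`,
#'   `r_min`, `p_max`.
#' @export
build_network <- function(expression, genes = NULL, r_min = 0.9, p_max = 0.05) {
  sample_ids <- setdiff(names(expression), "gene_id")
  if (length(sample_ids) < 3)
    stop("need at least 3 samples to test correlations", call. = FALSE)
  if (is.null(genes)) genes <- expression$gene_id
  missing <- setdiff(genes, expression$gene_id)
  if (length(missing) > 0)
    stop("genes not present in expression matrix: ", missing[1], call. = FALSE)
  genes <- sort(unique(genes))
  mat <- as.matrix(expression[match(genes, expression$gene_id), sample_ids])
  rownames(mat) <- genes
  prof <- log2(mat + 1)

  variable <- apply(prof, 1, stats::sd) > 0
  if (any(!variable))
    message(sum(!variable), " gene(s) with constant profiles kept as isolated nodes")

  edges <- tibble::tibble(from = character(), to = character(),
                          r = numeric(), p = numeric())
  if (sum(variable) >= 2) {
    R <- stats::cor(t(prof[variable, , drop = FALSE]))
    P <- cor_p(R, length(sample_ids))
    hit <- which(upper.tri(R) & abs(R) >= r_min & P <= p_max, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      ids <- rownames(R)
      edges <- tibble::tibble(
        from = ids[hit[, 1]], to = ids[hit[, 2]],
        r = R[hit], p = P[hit]
      ) |>
        dplyr::mutate(tmp_from = pmin(.data$from, .data$to),
                      tmp_to = pmax(.data$from, .data$to),
                      from = .data$tmp_from, to = .data$tmp_to) |>
        dplyr::select(-"tmp_from", -"tmp_to") |>
        dplyr::arrange(.data$from, .data$to)
    }
  }

  degree <- table(factor(c(edges$from, edges$to), levels = genes))
  core <- kcore_numbers(genes, edges)
  nodes <- tibble::tibble(
    gene_id = genes,
    degree = as.integer(degree[genes]),
    core_number = unname(core[genes])
  )
  structure(
    list(nodes = nodes, edges = edges, n_samples = length(sample_ids),
         r_min = r_min, p_max = p_max),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Co-expression network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|r| >= ", x$r_min, ", p <= ", x$p_max, ", ",
      x$n_samples, " samples)\n", sep = "")
  if (nrow(x$nodes) > 0)
    cat("max core number: ", max(x$nodes$core_number), "\n", sep = "")
  invisible(x)
}

#' k-core decomposition by iterative peeling
#'
#' Computes every node's core number: the largest `k` such that the node
#' belongs to a subgraph in which all nodes have at least `k` neighbors
#' within the subgraph. Matula-Beck style peeling: at threshold `k`,
#' repeatedly remove the minimum-degree node (ties broken by gene id, which
#' makes the removal order deterministic; core numbers are independent of
#' tie-breaking) while the minimum degree is `<= k`, recording `k` as the
#' core number of each removed node, then increase `k`.
#'
#' @param network a `coexpression_network` from [build_network()].
#' @return named integer vector: core number per node.
#' @export
kcore_decompose <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  kcore_numbers(network$nodes$gene_id, network$edges)
}

kcore_numbers <- function(nodes, edges) {
  nodes <- sort(nodes)
  n <- length(nodes)
  core <- stats::setNames(integer(n), nodes)
  if (n == 0) return(core)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    a <- idx[edges$from]; b <- idx[edges$to]
    for (e in seq_along(a)) {
      adj[[a[e]]] <- c(adj[[a[e]]], b[e])
      adj[[b[e]]] <- c(adj[[b[e]]], a[e])
    }
  }
  deg <- vapply(adj, length, 1L)
  alive <- rep(TRUE, n)
  k <- 0L
  remaining <- n
  while (remaining > 0) {
    repeat {
      cand <- which(alive & deg <= k)
      if (length(cand) == 0) break
      v <- cand[1]  # nodes are sorted, so this is the lexicographic tie-break
      core[v] <- k
      alive[v] <- FALSE
      remaining <- remaining - 1L
      nb <- adj[[v]]
      nb <- nb[alive[nb]]
      deg[nb] <- deg[nb] - 1L
    }
    k <- k + 1L
  }
  core
}

#' Rank genes by network centrality
#'
#' Orders nodes by core number (descending), then degree (descending), then
#' gene id (ascending), and returns the top of the list.
#'
#' @param network a `coexpression_network`.
#' @param top how many genes to return.
#' @return tibble: `gene_id`, `degree`, `core_number`, first `top` rows of
#'   the ranking.
#' @export
rank_core_genes <- function(network, top = 10L) {
  stopifnot(inherits(network, "coexpression_network"), top >= 1)
  network$nodes |>
    dplyr::arrange(dplyr::desc(.data$core_number), dplyr::desc(.data$degree),
                   .data$gene_id) |>
    dplyr::slice_head(n = top)
}

#' Tidy a co-expression network into its edge table
#'
#' @param x a `coexpression_network`.
#' @param ... unused.
#' @return the edge tibble (`from`, `to`, `r`, `p`).
#' @importFrom generics tidy
#' @export
tidy.coexpression_network <- function(x, ...) x$edges

#' One-row summary of a co-expression network
#'
#' @param x a `coexpression_network`.
#' @param ... unused.
#' @return tibble with `n_nodes`, `n_edges`, `max_degree`, `max_core`,
#'   `density`.
#' @importFrom generics glance
#' @export
glance.coexpression_network <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble::tibble(
    n_nodes = n,
    n_edges = nrow(x$edges),
    max_degree = if (n > 0) max(x$nodes$degree) else 0L,
    max_core = if (n > 0) max(x$nodes$core_number) else 0L,
    density = if (n > 1) nrow(x$edges) / (n * (n - 1) / 2) else NA_real_
  )
}
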