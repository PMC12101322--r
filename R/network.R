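#' Filter an edge list by confidence
#'
#' Keeps edges with confidence at or above the threshold; the node
#' universe is unchanged, so nodes losing all edges stay in the network
#' as isolates.
#'
#' @param el An `edge_list`.
#' @param min_confidence Threshold in `[0, 1]`.
#' @return A filtered `edge_list`.
#' @export
filter_by_confidence <- function(el, min_confidence) {
  stopifnot(inherits(el, "edge_list"),
            min_confidence >= 0, min_confidence <= 1)
  keep <- el$edges$confidence >= min_confidence
  edge_list(el$edges[keep, , drop = FALSE], universe = el$universe)
}

#' Interaction-network summary statistics
#'
#' Node, edge and degree summaries plus the average local clustering
#' coefficient. The average degree denominator is the full node
#' universe including isolated nodes (`2 * n_edges / n_universe`). The
#' local clustering coefficient of a node is the fraction of its
#' neighbour pairs that are themselves connected; nodes of degree < 2
#' contribute 0 and are included in the mean.
#'
#' @param el An `edge_list`.
#' @param background_edge_prob Optional background edge probability; if
#'   supplied, `expected_edges` and `enrichment_p` are filled via
#'   [enrich_edges()].
#' @return List of class `network_stats`: `n_universe`, `n_interacting`,
#'   `n_edges`, `avg_degree`, `avg_clustering`, `expected_edges`,
#'   `enrichment_p`.
#' @export
summarize_network <- function(el, background_edge_prob = NULL) {
  stopifnot(inherits(el, "edge_list"))
  g <- igraph::graph_from_data_frame(el$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = el$universe)
  deg <- igraph::degree(g)
  n <- length(el$universe)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  stats <- list(n_universe = n,
                n_interacting = sum(deg >= 1L),
                n_edges = nrow(el$edges),
                avg_degree = 2 * nrow(el$edges) / n,
                avg_clustering = mean(cc),
                expected_edges = NA_real_,
                enrichment_p = NA_real_)
  if (!is.null(background_edge_prob)) {
    en <- enrich_edges(nrow(el$edges), n, background_edge_prob)
    stats$expected_edges <- en$expected_edges
    stats$enrichment_p <- en$enrichment_p
  }
  structure(stats, class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "network: %d nodes (%d interacting), %d edges, avg degree %.2f, avg clustering %.3f\n",
    x$n_universe, x$n_interacting, x$n_edges, x$avg_degree,
    x$avg_clustering))
  if (!is.na(x$expected_edges))
    cat(sprintf("expected edges %.1f, enrichment p = %.3g\n",
                x$expected_edges, x$enrichment_p))
  invisible(x)
}

#' Edge-count enrichment against a binomial null
#'
#' Expected edges and the upper-tail probability of observing at least
#' the observed edge count when every one of the `choose(n, 2)` node
#' pairs is independently an edge with the background probability. This
#' explicit binomial null is a documented replacement for proprietary
#' degree-corrected interaction-database nulls and is not numerically
#' comparable to them. P-values are floored at `1e-16`.
#'
#' @param observed_edges Observed edge count.
#' @param universe_size Number of nodes (>= 2).
#' @param background_edge_prob Background per-pair edge probability in
#'   `(0, 1)`.
#' @return List with `expected_edges` and `enrichment_p`.
#' @export
enrich_edges <- function(observed_edges, universe_size,
                         background_edge_prob) {
  stopifnot(universe_size >= 2,
            background_edge_prob > 0, background_edge_prob < 1)
  pairs <- choose(universe_size, 2)
  expected <- background_edge_prob * pairs
  p <- pbinom(observed_edges - 1, size = pairs, prob = background_edge_prob,
              lower.tail = FALSE)
  list(expected_edges = expected, enrichment_p = max(p, 1e-16))
}

#' Estimate a background edge probability from an edge list
#'
#' Observed edge density of a background network: edges divided by node
#' pairs.
#'
#' @param el An `edge_list` representing the background.
#' @return Probability in `(0, 1)`.
#' @export
background_edge_prob <- function(el) {
  stopifnot(inherits(el, "edge_list"), length(el$universe) >= 2)
  nrow(el$edges) / choose(length(el$universe), 2)
}

#' Network summaries over a ladder of confidence thresholds
#'
#' @param el An `edge_list`.
#' @param thresholds Confidence thresholds to analyze (defaults to the
#'   conventional low / medium / high / highest ladder).
#' @param background_edge_prob Optional background probability passed to
#'   [summarize_network()].
#' @return Data frame with one row per threshold and all
#'   `network_stats` fields.
#' @export
network_scan <- function(el, thresholds = c(0.15, 0.4, 0.7, 0.9),
                         background_edge_prob = NULL) {
  rows <- lapply(thresholds, function(th) {
    st <- summarize_network(filter_by_confidence(el, th),
                            background_edge_prob)
    data.frame(min_confidence = th, n_universe = st$n_universe,
               n_interacting = st$n_interacting, n_edges = st$n_edges,
               avg_degree = st$avg_degree,
               avg_clustering = st$avg_clustering,
               expected_edges = st$expected_edges,
               enrichment_p = st$enrichment_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
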