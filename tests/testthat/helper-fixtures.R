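# shared fixture builders for the test suite

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_proteins <- function() {
  data.frame(protein_id = c("P1", "P2"),
             sequence = c("MKKLVDEEST", "AAAAILVF"),
             stringsAsFactors = FALSE)
}

# long track table from a named list of per-source value vectors
tracks_df <- function(protein_id, sources) {
  do.call(rbind, lapply(names(sources), function(s) {
    v <- sources[[s]]
    data.frame(protein_id = protein_id, source = s,
               position = seq_along(v), value = v,
               stringsAsFactors = FALSE)
  }))
}

# inverse Box-Cox: the generation side of the lambda-recovery oracle
inv_boxcox <- function(z, lambda) {
  if (lambda == 0) exp(z) else (lambda * z + 1)^(1 / lambda)
}

# dense-grid argmax of the Box-Cox profile log-likelihood; independent
# of the estimator's grid + golden-section search path
grid_lambda_oracle <- function(values, step = 5e-4, interval = c(-2, 2)) {
  grid <- seq(interval[1L], interval[2L], by = step)
  n <- length(values)
  slog <- sum(log(values))
  ll <- vapply(grid, function(l) {
    z <- if (l == 0) log(values) else (values^l - 1) / l
    -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slog
  }, numeric(1L))
  grid[which.max(ll)]
}

# brute-force local clustering from an adjacency matrix: triangles over
# possible neighbour pairs, degree-<2 nodes contribute 0
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(adj[nb, nb, drop = FALSE]) / 2
    tri / choose(k, 2)
  }, numeric(1L))
  mean(cc)
}

adj_to_edge_list <- function(adj, ids = NULL) {
  n <- nrow(adj)
  ids <- ids %||% paste0("N", seq_len(n))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edge_list(data.frame(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                       confidence = rep(1, nrow(idx)),
                       stringsAsFactors = FALSE),
            universe = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
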