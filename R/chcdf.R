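# Kyte-Doolittle hydropathy scale; scaled to [0,1] as (KD + 4.5) / 9
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Default charge-hydropathy boundary
#'
#' Linear boundary in (mean scaled Kyte-Doolittle hydropathy, mean
#' absolute net charge) space separating compact from extended-disordered
#' proteins: `charge = slope * hydropathy + intercept` with slope 2.785
#' and intercept -1.151 (the standard charge-hydropathy classifier
#' constants). Fully configurable via a boundary-config file.
#'
#' @return List with `slope` and `intercept`.
#' @export
default_ch_boundary <- function() list(slope = 2.785, intercept = -1.151)

#' Default CDF boundary points
#'
#' Placeholder boundary for the cumulative-distribution-function
#' classifier: seven points at score abscissae 0.1-0.7 with ordinates on
#' the line `fraction = score + 0.15`. The canonical boundary
#' coordinates of the upstream classifier are not publicly printed, so
#' this default is explicitly non-canonical and intended to be replaced
#' through [read_boundary_config()] when calibrated coordinates are
#' available.
#'
#' @return Data frame with columns `score` and `fraction`.
#' @export
default_cdf_boundary <- function() {
  s <- seq(0.1, 0.7, by = 0.1)
  data.frame(score = s, fraction = s + 0.15)
}

#' Read a CH/CDF boundary configuration from JSON
#'
#' Expected layout:
#' `{"ch": {"slope": s, "intercept": b}, "cdf": {"points": [[s, f], ...]}}`.
#' Missing components fall back to the package defaults.
#'
#' @param path Path to a JSON file.
#' @return List with elements `ch` (list `slope`, `intercept`) and `cdf`
#'   (data frame `score`, `fraction`).
#' @export
read_boundary_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- cfg$ch %||% default_ch_boundary()
  if (is.null(ch$slope) || is.null(ch$intercept) || ch$slope <= 0)
    stop("CH boundary needs a positive slope and an intercept")
  cdf <- default_cdf_boundary()
  if (!is.null(cfg$cdf$points)) {
    pts <- cfg$cdf$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    cdf <- data.frame(score = pts[, 1L], fraction = pts[, 2L])
  }
  validate_cdf_boundary(cdf)
  list(ch = list(slope = ch$slope, intercept = ch$intercept), cdf = cdf)
}

validate_cdf_boundary <- function(boundary) {
  stopifnot(is.data.frame(boundary),
            all(c("score", "fraction") %in% names(boundary)),
            nrow(boundary) >= 1L)
  if (any(diff(boundary$score) <= 0))
    stop("CDF boundary abscissae must be strictly increasing")
  if (any(boundary$score < 0 | boundary$score > 1) ||
      any(boundary$fraction < 0 | boundary$fraction > 1))
    stop("CDF boundary points must lie in [0, 1] x [0, 1]")
  invisible(boundary)
}

#' Charge-hydropathy coordinates of a sequence
#'
#' Mean absolute net charge (K, R = +1; D, E = -1; all other residues,
#' including H, contribute 0 unless `his_charge` is set) and mean scaled
#' Kyte-Doolittle hydropathy (`(KD + 4.5) / 9`; `X` contributes the
#' scale midpoint 0.5). Termini are ignored by the charge model.
#'
#' @param sequence Amino-acid sequence string.
#' @param his_charge Charge assigned to histidine (default 0).
#' @return Named numeric vector with `mean_abs_net_charge` and
#'   `mean_scaled_hydropathy`.
#' @export
ch_coordinates <- function(sequence, his_charge = 0) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (length(chars) == 0L) stop("empty sequence")
  charge <- c(K = 1, R = 1, D = -1, E = -1, H = his_charge)
  q <- charge[chars]
  q[is.na(q)] <- 0
  hyd <- (KYTE_DOOLITTLE[chars] + 4.5) / 9
  hyd[is.na(hyd)] <- 0.5  # X
  c(mean_abs_net_charge = abs(sum(q)) / length(chars),
    mean_scaled_hydropathy = mean(hyd))
}

#' Signed distance from the CH boundary
#'
#' Vertical distance of a protein's charge-hydropathy point above the
#' boundary line; positive values fall on the disordered side.
#'
#' @param coords Output of [ch_coordinates()] (or any vector/list with
#'   the two named components).
#' @param boundary CH boundary (list `slope`, `intercept`).
#' @return Signed real.
#' @export
ch_delta <- function(coords, boundary = default_ch_boundary()) {
  coords[["mean_abs_net_charge"]] -
    (boundary$slope * coords[["mean_scaled_hydropathy"]] + boundary$intercept)
}

#' Cumulative distribution of residue disorder scores
#'
#' For each abscissa `s`, the fraction of residues with score `<= s`.
#'
#' @param values Per-residue disorder scores in `[0, 1]`.
#' @param abscissae Score abscissae to evaluate at.
#' @return Numeric vector of cumulative fractions.
#' @export
cdf_curve <- function(values, abscissae) {
  vapply(abscissae, function(s) mean(values <= s), numeric(1L))
}

#' Signed mean distance from the CDF boundary
#'
#' Mean, over the boundary abscissae, of (curve value - boundary
#' ordinate). A curve above the boundary (positive delta) indicates an
#' ordered protein: most residues have low disorder scores.
#'
#' @param values Per-residue disorder scores in `[0, 1]`.
#' @param boundary CDF boundary data frame (`score`, `fraction`).
#' @return Signed real.
#' @export
cdf_delta <- function(values, boundary = default_cdf_boundary()) {
  validate_cdf_boundary(boundary)
  mean(cdf_curve(values, boundary$score) - boundary$fraction)
}

#' CH-CDF quadrant assignment
#'
#' Partition of the (delta_cdf, delta_ch) plane:
#' * Q1: `delta_cdf >= 0` and `delta_ch < 0` - ordered by both.
#' * Q2: `delta_cdf < 0` and `delta_ch < 0` - CH ordered, CDF
#'   disordered (putative molten globules).
#' * Q3: `delta_cdf < 0` and `delta_ch >= 0` - disordered by both.
#' * Q4: `delta_cdf >= 0` and `delta_ch >= 0` - CH disordered, CDF
#'   ordered.
#' Ties at zero resolve to the ordered side on the CDF axis and the
#' disordered side on the CH axis (a documented, arbitrary convention).
#'
#' @param delta_cdf,delta_ch Numeric vectors of signed boundary
#'   distances.
#' @return Character vector of quadrant labels.
#' @export
assign_quadrant <- function(delta_cdf, delta_ch) {
  ifelse(delta_cdf >= 0,
         ifelse(delta_ch < 0, "Q1", "Q4"),
         ifelse(delta_ch < 0, "Q2", "Q3"))
}

#' CH-CDF phase-space table for a proteome
#'
#' Computes charge-hydropathy coordinates from each sequence, the CH and
#' CDF boundary distances, and the quadrant assignment.
#'
#' @param proteins Protein table.
#' @param tracks Long track table of disorder scores.
#' @param source Which predictor's track feeds the CDF (default: first
#'   source in the table, alphabetically).
#' @param ch_boundary,cdf_boundary Boundary specifications.
#' @return Data frame with one row per protein: `protein_id`,
#'   `mean_abs_net_charge`, `mean_scaled_hydropathy`, `delta_ch`,
#'   `delta_cdf`, `quadrant`.
#' @export
chcdf_classify <- function(proteins, tracks, source = NULL,
                           ch_boundary = default_ch_boundary(),
                           cdf_boundary = default_cdf_boundary()) {
  source <- source %||% sort(unique(tracks$source))[1L]
  ids <- intersect(proteins$protein_id,
                   unique(tracks$protein_id[tracks$source == source]))
  rows <- lapply(ids, function(id) {
    seq <- proteins$sequence[proteins$protein_id == id]
    co <- ch_coordinates(seq)
    dch <- ch_delta(co, ch_boundary)
    dcdf <- cdf_delta(track_values(tracks, id, source), cdf_boundary)
    data.frame(protein_id = id,
               mean_abs_net_charge = co[["mean_abs_net_charge"]],
               mean_scaled_hydropathy = co[["mean_scaled_hydropathy"]],
               delta_ch = dch, delta_cdf = dcdf,
               quadrant = assign_quadrant(dcdf, dch),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
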