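#' Average disorder score (ADS)
#'
#' Arithmetic mean of a per-residue disorder score track.
#'
#' @param values Numeric vector of per-residue scores.
#' @return Mean score.
#' @export
compute_ads <- function(values) {
  if (length(values) == 0L) stop("empty score track")
  mean(values)
}

#' Percentage of predicted intrinsically disordered residues (PPIDR)
#'
#' Percentage of residues whose disorder score is strictly greater than
#' the threshold. The inequality is strict: a residue scoring exactly at
#' the threshold is not counted as disordered.
#'
#' @param values Numeric vector of per-residue scores.
#' @param threshold Disorder call threshold (default 0.5).
#' @return Percentage in `[0, 100]`.
#' @export
compute_ppidr <- function(values, threshold = 0.5) {
  if (length(values) == 0L) stop("empty score track")
  100 * sum(values > threshold) / length(values)
}

DISORDER_CATEGORIES <- c("highly_ordered", "moderately_disordered",
                         "highly_disordered")

#' Three-tier disorder category from PPIDR
#'
#' Highly ordered for PPIDR < 10, moderately disordered for
#' 10 <= PPIDR < 30, highly disordered for PPIDR >= 30.
#'
#' @param ppidr Numeric vector of PPIDR percentages in `[0, 100]`.
#' @return Character vector of category labels.
#' @export
classify_by_ppidr <- function(ppidr) {
  if (any(ppidr < 0 | ppidr > 100))
    stop("PPIDR outside [0, 100]")
  ifelse(ppidr < 10, DISORDER_CATEGORIES[1L],
         ifelse(ppidr < 30, DISORDER_CATEGORIES[2L], DISORDER_CATEGORIES[3L]))
}

#' Three-tier disorder category from ADS
#'
#' Highly ordered for ADS < 0.25, moderately disordered for
#' 0.25 <= ADS < 0.5, highly disordered for ADS >= 0.5.
#'
#' @param ads Numeric vector of average disorder scores in `[0, 1]`.
#' @return Character vector of category labels.
#' @export
classify_by_ads <- function(ads) {
  if (any(ads < 0 | ads > 1))
    stop("ADS outside [0, 1]")
  ifelse(ads < 0.25, DISORDER_CATEGORIES[1L],
         ifelse(ads < 0.5, DISORDER_CATEGORIES[2L], DISORDER_CATEGORIES[3L]))
}

#' Per-protein disorder summary across predictor sources
#'
#' Computes ADS and PPIDR for every (protein, source) track, then
#' arithmetic means across the selected sources per protein, and assigns
#' the three-tier categories from the mean PPIDR and mean ADS.
#'
#' @param tracks Long track table (`protein_id`, `source`, `position`,
#'   `value`) of disorder scores in `[0, 1]`.
#' @param proteins Protein table; summaries are produced for proteins
#'   that have at least one track.
#' @param sources_for_mean Sources to average over (default: all sources
#'   present for each protein). If given, every listed source must be
#'   present for every summarized protein.
#' @param threshold PPIDR disorder-call threshold.
#' @return A list of class `disorder_summary` with elements
#'   `per_source` (one row per protein and source: `ads`, `ppidr`,
#'   `category_by_ppidr`, `category_by_ads`) and `summary` (one row per
#'   protein: `mean_ads`, `mean_ppidr`, `category_by_ppidr`,
#'   `category_by_ads`).
#' @export
summarize_disorder <- function(tracks, proteins, sources_for_mean = NULL,
                               threshold = 0.5) {
  ids <- intersect(proteins$protein_id, unique(tracks$protein_id))
  key <- factor(paste(tracks$protein_id, tracks$source, sep = "\r"))
  n_per <- tabulate(key)
  sums <- rowsum(tracks$value, key)[, 1L]
  hits <- rowsum(as.numeric(tracks$value > threshold), key)[, 1L]
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  per_source <- data.frame(
    protein_id = vapply(parts, `[`, "", 1L),
    source = vapply(parts, `[`, "", 2L),
    ads = as.numeric(sums / n_per),
    ppidr = as.numeric(100 * hits / n_per),
    stringsAsFactors = FALSE)
  per_source$category_by_ppidr <- classify_by_ppidr(per_source$ppidr)
  per_source$category_by_ads <- classify_by_ads(pmin(per_source$ads, 1))
  per_source <- per_source[order(per_source$protein_id, per_source$source), ,
                           drop = FALSE]
  rownames(per_source) <- NULL

  by_protein <- split(per_source, per_source$protein_id)
  rows <- lapply(ids, function(id) {
    ps <- by_protein[[id]]
    use <- sources_for_mean %||% ps$source
    missing <- setdiff(use, ps$source)
    if (length(missing) > 0L)
      stop("protein ", id, " is missing requested source(s): ",
           paste(missing, collapse = ", "))
    ps <- ps[ps$source %in% use, , drop = FALSE]
    data.frame(protein_id = id,
               n_sources = nrow(ps),
               mean_ads = mean(ps$ads),
               mean_ppidr = mean(ps$ppidr),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary$category_by_ppidr <- classify_by_ppidr(summary$mean_ppidr)
  summary$category_by_ads <- classify_by_ads(pmin(summary$mean_ads, 1))
  summary <- summary[order(summary$protein_id), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(per_source = per_source, summary = summary,
                 sources_for_mean = sources_for_mean, threshold = threshold),
            class = "disorder_summary")
}

#' @export
print.disorder_summary <- function(x, ...) {
  cat("disorder_summary:", nrow(x$summary), "proteins,",
      length(unique(x$per_source$source)), "sources\n")
  print(table(x$summary$category_by_ppidr))
  invisible(x)
}

#' Tally proteins per disorder category
#'
#' Counts proteins in each three-tier category, either from the mean
#' PPIDR across sources (`by = "mean"`) or per individual source
#' (`by = "source"`), covering both readings of a cross-model tally.
#'
#' @param ds A `disorder_summary`.
#' @param by `"mean"` or `"source"`.
#' @return Data frame of counts.
#' @export
disorder_category_counts <- function(ds, by = c("mean", "source")) {
  by <- match.arg(by)
  if (by == "mean") {
    tab <- table(factor(ds$summary$category_by_ppidr,
                        levels = DISORDER_CATEGORIES))
    data.frame(category = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    out <- aggregate(protein_id ~ source + category_by_ppidr,
                     data = ds$per_source, FUN = length)
    names(out)[3L] <- "n"
    out[order(out$source, out$category_by_ppidr), , drop = FALSE]
  }
}

#' Mean disorder profile across sources
#'
#' Residue-wise arithmetic mean across all sources covering a protein,
#' returned as a derived track with source label `"MDP"`.
#'
#' @param tracks Long track table of disorder scores.
#' @return Long track table with `source == "MDP"`.
#' @export
mean_disorder_profile <- function(tracks) {
  key <- paste(tracks$protein_id, tracks$position, sep = "\r")
  m <- tapply(tracks$value, key, mean)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(protein_id = vapply(parts, `[`, "", 1L),
                    source = "MDP",
                    position = as.integer(vapply(parts, `[`, "", 2L)),
                    value = as.numeric(m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
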