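#' Droplet-driver / droplet-client classification
#'
#' A protein with phase-separation probability `p_llps >= 0.60` is a
#' droplet-driver (can phase-separate autonomously); below that it is a
#' droplet-client (partitions into condensates via interactions).
#'
#' @param p_llps Numeric vector of LLPS probabilities in `[0, 1]`.
#' @param threshold Driver threshold (default 0.60, inclusive).
#' @return Character vector: `"driver"` or `"client"`.
#' @export
classify_role <- function(p_llps, threshold = 0.60) {
  if (any(p_llps < 0 | p_llps > 1))
    stop("p_llps outside [0, 1]")
  ifelse(p_llps >= threshold, "driver", "client")
}

#' Call droplet-promoting regions (DPRs)
#'
#' Maximal runs of consecutive residues with droplet-promoting
#' probability `p_dp >= threshold`, kept when at least `min_len`
#' residues long. Runs truncated by the sequence ends still count.
#'
#' @param p_dp Numeric vector of per-residue droplet-promoting
#'   probabilities in `[0, 1]`.
#' @param threshold Residue inclusion threshold (default 0.60,
#'   inclusive).
#' @param min_len Minimum region length (default 5).
#' @return Data frame with columns `start`, `end` (1-based inclusive),
#'   sorted by start.
#' @export
call_dprs <- function(p_dp, threshold = 0.60, min_len = 5L) {
  r <- rle(p_dp >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Call aggregation hot-spots
#'
#' Residues combining a high droplet-promoting probability with a high
#' interaction-mode divergence, indicating predisposition to aggregation
#' within condensates.
#'
#' @param p_dp Per-residue droplet-promoting probabilities.
#' @param s_bind Per-residue interaction-mode divergence scores
#'   (non-negative).
#' @param dp_threshold `p_dp` threshold (default 0.60, inclusive).
#' @param sbind_threshold `s_bind` threshold (default 2.2, inclusive).
#' @return Integer vector of residue indices, ascending.
#' @export
call_hotspots <- function(p_dp, s_bind, dp_threshold = 0.60,
                          sbind_threshold = 2.2) {
  if (length(p_dp) != length(s_bind))
    stop("p_dp and s_bind tracks differ in length (",
         length(p_dp), " vs ", length(s_bind), ")")
  which(p_dp >= dp_threshold & s_bind >= sbind_threshold)
}

#' Call context-dependent interaction zones
#'
#' Residues whose binding-mode diversity is high enough that their
#' interaction behaviour may switch with the cellular environment.
#'
#' @param s_bind Per-residue interaction-mode divergence scores.
#' @param threshold Inclusion threshold (default 2.25, inclusive). The
#'   default differs from the hot-spot divergence threshold (2.2); both
#'   are kept as independent named parameters.
#' @return Integer vector of residue indices, ascending.
#' @export
call_context_zones <- function(s_bind, threshold = 2.25) {
  which(s_bind >= threshold)
}

format_intervals <- function(iv) {
  if (nrow(iv) == 0L) return("")
  paste(paste0(iv$start, "-", iv$end), collapse = ";")
}

#' Per-protein LLPS profiles
#'
#' Combines the per-protein phase-separation probability with the
#' residue-level droplet-promoting and binding-divergence tracks to
#' classify each protein's role and call its droplet-promoting regions,
#' aggregation hot-spots and context-dependent interaction zones.
#'
#' @param llps Data frame with columns `protein_id`, `p_llps`.
#' @param tracks Long track table holding the residue-level tracks.
#' @param dp_source,sbind_source Source labels of the droplet-promoting
#'   probability and binding-divergence tracks.
#' @param role_threshold,dp_threshold,min_len,sbind_threshold,
#'   context_threshold Calling parameters (see the individual calling
#'   functions).
#' @return List of class `llps_profiles` with elements `summary` (one
#'   row per protein: `protein_id`, `p_llps`, `role`, `n_dprs`,
#'   `dpr_intervals`, `n_hotspots`, `n_context_zones`) and `regions`
#'   (one row per DPR: `protein_id`, `start`, `end`).
#' @export
llps_profiles <- function(llps, tracks, dp_source = "p_dp",
                          sbind_source = "s_bind", role_threshold = 0.60,
                          dp_threshold = 0.60, min_len = 5L,
                          sbind_threshold = 2.2, context_threshold = 2.25) {
  stopifnot(all(c("protein_id", "p_llps") %in% names(llps)))
  llps <- llps[order(llps$protein_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(llps)), function(i) {
    id <- llps$protein_id[i]
    p_dp <- track_values(tracks, id, dp_source)
    s_bind <- track_values(tracks, id, sbind_source)
    dprs <- call_dprs(p_dp, dp_threshold, min_len)
    hs <- call_hotspots(p_dp, s_bind, dp_threshold, sbind_threshold)
    cz <- call_context_zones(s_bind, context_threshold)
    list(summary = data.frame(
           protein_id = id,
           p_llps = llps$p_llps[i],
           role = classify_role(llps$p_llps[i], role_threshold),
           n_dprs = nrow(dprs),
           dpr_intervals = format_intervals(dprs),
           n_hotspots = length(hs),
           n_context_zones = length(cz),
           stringsAsFactors = FALSE),
         regions = if (nrow(dprs) > 0L)
           cbind(data.frame(protein_id = id, stringsAsFactors = FALSE), dprs)
         else NULL)
  })
  summary <- do.call(rbind, lapply(rows, `[[`, "summary"))
  regions <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(rows, `[[`, "regions")))
  if (is.null(regions))
    regions <- data.frame(protein_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  rownames(summary) <- rownames(regions) <- NULL
  structure(list(summary = summary, regions = regions),
            class = "llps_profiles")
}

#' @export
print.llps_profiles <- function(x, ...) {
  cat("llps_profiles:", nrow(x$summary), "proteins,",
      sum(x$summary$role == "driver"), "drivers,",
      nrow(x$regions), "droplet-promoting regions\n")
  invisible(x)
}
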