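#' Consensus disorder calls for one protein
#'
#' A residue is called consensus-disordered when the fraction of
#' predictor tracks scoring it above `call_threshold` is at least
#' `agreement`. The denominator is the number of tracks supplied for the
#' protein.
#'
#' @param track_matrix Numeric matrix, residues in rows, one column per
#'   predictor track.
#' @param agreement Required agreement fraction in `(0, 1]`
#'   (default 0.75, inclusive).
#' @param call_threshold Per-track disorder call threshold (strict `>`).
#' @return Logical vector of per-residue consensus calls.
#' @export
consensus_track <- function(track_matrix, agreement = 0.75,
                            call_threshold = 0.5) {
  if (!(agreement > 0 && agreement <= 1))
    stop("agreement must lie in (0, 1]")
  m <- as.matrix(track_matrix)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("need at least one track")
  rowMeans(m > call_threshold) >= agreement
}

#' Consensus calls for every protein in a track table
#'
#' @param tracks Long track table of disorder scores.
#' @param proteins Protein table.
#' @param sources Sources to use (default all).
#' @inheritParams consensus_track
#' @return Named list of logical vectors, one per protein with tracks.
#' @export
consensus_tracks <- function(tracks, proteins, sources = NULL,
                             agreement = 0.75, call_threshold = 0.5) {
  if (!is.null(sources)) tracks <- tracks[tracks$source %in% sources, ,
                                          drop = FALSE]
  ids <- intersect(proteins$protein_id, unique(tracks$protein_id))
  out <- lapply(ids, function(id) {
    srcs <- sort(unique(tracks$source[tracks$protein_id == id]))
    m <- vapply(srcs, function(s) track_values(tracks, id, s),
                numeric(nchar(proteins$sequence[proteins$protein_id == id])))
    consensus_track(as.matrix(m), agreement, call_threshold)
  })
  names(out) <- ids
  out
}

#' Maximal consensus-disordered runs as 1-based intervals
#'
#' @param calls Logical vector of per-residue calls.
#' @return Data frame with columns `start`, `end` (1-based inclusive).
#' @export
consensus_regions <- function(calls) {
  r <- rle(as.logical(calls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Count consensus-disordered residues inside a domain interval
#'
#' @param calls Logical consensus vector for the domain's protein.
#' @param start,end Domain interval, 1-based inclusive.
#' @return Non-negative integer count.
#' @export
overlap_residues <- function(calls, start, end) {
  if (start < 1L || end > length(calls) || start > end)
    stop("domain interval [", start, ", ", end,
         "] invalid for track of length ", length(calls))
  sum(calls[start:end])
}

#' Disordered-residue counts per domain superfamily
#'
#' For every superfamily, sums the consensus-disordered residues over
#' all of its annotated intervals across proteins, and lists the
#' affected proteins (those contributing at least one overlap residue).
#' By default positions under two intervals of the same superfamily
#' count once per interval; set `dedupe = TRUE` to count unique
#' positions per protein instead.
#'
#' @param consensus Named list of logical call vectors (see
#'   [consensus_tracks()]).
#' @param domains Domain annotation table.
#' @param dedupe Count each consensus-disordered position at most once
#'   per (protein, superfamily).
#' @return Data frame sorted by superfamily: `superfamily`,
#'   `disordered_residues`, `n_proteins`, `proteins_affected`
#'   (semicolon-joined ids).
#' @export
superfamily_report <- function(consensus, domains, dedupe = FALSE) {
  domains <- domains[domains$protein_id %in% names(consensus), , drop = FALSE]
  sfs <- sort(unique(domains$superfamily))
  rows <- lapply(sfs, function(sf) {
    dm <- domains[domains$superfamily == sf, , drop = FALSE]
    per_protein <- vapply(unique(dm$protein_id), function(id) {
      calls <- consensus[[id]]
      iv <- dm[dm$protein_id == id, , drop = FALSE]
      if (dedupe) {
        pos <- unique(unlist(Map(seq.int, iv$start, iv$end)))
        sum(calls[pos])
      } else {
        sum(vapply(seq_len(nrow(iv)), function(j)
          overlap_residues(calls, iv$start[j], iv$end[j]), numeric(1L)))
      }
    }, numeric(1L))
    affected <- sort(names(per_protein)[per_protein > 0])
    data.frame(superfamily = sf,
               disordered_residues = sum(per_protein),
               n_proteins = length(affected),
               proteins_affected = paste(affected, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Four-stage analysis funnel
#'
#' Stage 1: proteins with at least one disorder track. Stage 2: the
#' subset with at least one consensus-disordered residue. Stage 3: the
#' subset of stage 1 with at least one domain annotation. Stage 4: the
#' subset meeting stages 2 and 3 with at least one consensus-disordered
#' residue inside a domain interval.
#'
#' @param proteins Protein table.
#' @param tracks Long disorder track table.
#' @param domains Domain annotation table.
#' @inheritParams consensus_track
#' @return List of class `funnel_counts`: `n_with_tracks`,
#'   `n_consensus_positive`, `n_with_domains`, `n_overlap`, and the
#'   protein id sets behind each count.
#' @export
funnel <- function(proteins, tracks, domains, agreement = 0.75,
                   call_threshold = 0.5) {
  cons <- consensus_tracks(tracks, proteins, agreement = agreement,
                           call_threshold = call_threshold)
  with_tracks <- names(cons)
  positive <- names(cons)[vapply(cons, any, logical(1L))]
  with_domains <- intersect(with_tracks, unique(domains$protein_id))
  overlap_ids <- Filter(function(id) {
    dm <- domains[domains$protein_id == id, , drop = FALSE]
    any(vapply(seq_len(nrow(dm)), function(j)
      overlap_residues(cons[[id]], dm$start[j], dm$end[j]) > 0, logical(1L)))
  }, intersect(positive, with_domains))
  structure(list(n_with_tracks = length(with_tracks),
                 n_consensus_positive = length(positive),
                 n_with_domains = length(with_domains),
                 n_overlap = length(overlap_ids),
                 ids = list(with_tracks = with_tracks,
                            consensus_positive = positive,
                            with_domains = with_domains,
                            overlap = sort(unlist(overlap_ids)))),
            class = "funnel_counts")
}

#' @export
print.funnel_counts <- function(x, ...) {
  cat("analysis funnel:\n",
      "  with tracks:        ", x$n_with_tracks, "\n",
      "  consensus positive: ", x$n_consensus_positive, "\n",
      "  with domains:       ", x$n_with_domains, "\n",
      "  disorder-domain overlap:", x$n_overlap, "\n", sep = "")
  invisible(x)
}

#' Hypergeometric set enrichment with BH correction
#'
#' For each annotation term, the upper-tail hypergeometric probability
#' of drawing at least the observed overlap between the query set and
#' the term's set when sampling `|query|` ids from the universe without
#' replacement. P-values are Benjamini-Hochberg adjusted across all
#' tested terms.
#'
#' @param query Character vector of query ids (must be a subset of the
#'   universe).
#' @param annotation Named list mapping term -> character vector of ids;
#'   each set is intersected with the universe before testing.
#' @param universe Character vector of background ids.
#' @return Data frame sorted by adjusted p then term: `term`,
#'   `term_size`, `overlap_count`, `p_value`, `p_adjusted`.
#' @export
set_enrichment <- function(query, annotation, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(as.character(query))
  out <- setdiff(query, universe)
  if (length(out) > 0L)
    stop("query id(s) not in universe: ", paste(out, collapse = ", "))
  N <- length(universe)
  k <- length(query)
  rows <- lapply(names(annotation), function(term) {
    m_set <- intersect(unique(as.character(annotation[[term]])), universe)
    m <- length(m_set)
    q <- length(intersect(query, m_set))
    p <- phyper(q - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(term = term, term_size = m, overlap_count = q, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_adjusted, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
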