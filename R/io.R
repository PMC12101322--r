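#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a protein table. The header token up to the
#' first whitespace becomes the protein identifier; sequences are
#' upper-cased and validated against the 20 canonical amino-acid letters
#' plus `X`.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `protein_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("not a valid FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  validate_proteins(data.frame(protein_id = ids, sequence = unname(seqs),
                               stringsAsFactors = FALSE))
}

#' Validate a protein table
#'
#' Checks identifier uniqueness, non-empty sequences, and the residue
#' alphabet (20 canonical letters plus `X`).
#'
#' @param proteins Data frame with columns `protein_id`, `sequence`.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_proteins <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  dup <- proteins$protein_id[duplicated(proteins$protein_id)]
  if (length(dup) > 0L)
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  if (any(nchar(proteins$sequence) < 1L))
    stop("empty sequence for protein ",
         proteins$protein_id[nchar(proteins$sequence) < 1L][1L])
  for (i in seq_len(nrow(proteins))) {
    chars <- strsplit(proteins$sequence[i], "")[[1L]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0L)
      stop("illegal residue '", chars[bad[1L]], "' at position ", bad[1L],
           " in protein ", proteins$protein_id[i])
  }
  proteins
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Data frame with columns `protein_id`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  proteins <- proteins[order(proteins$protein_id), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$protein_id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read per-residue score tracks
#'
#' Reads a long-format TSV of per-residue scores (columns `protein_id`,
#' `source`, `position`, `value`) and validates each (protein, source)
#' track: positions must form a gap-free run `1..L` where `L` is the
#' protein's sequence length, and values must lie within `value_range`.
#'
#' @param path Path to a TSV file.
#' @param proteins Protein table the tracks refer to.
#' @param value_range Closed interval values must fall in; use
#'   `c(0, Inf)` for unbounded non-negative tracks such as
#'   binding-mode-divergence scores.
#' @return A long data frame with columns `protein_id`, `source`,
#'   `position`, `value`.
#' @export
read_tracks <- function(path, proteins, value_range = c(0, 1)) {
  tr <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(protein_id = "character",
                                  source = "character",
                                  position = "integer",
                                  value = "numeric"))
  need <- c("protein_id", "source", "position", "value")
  if (!all(need %in% names(tr)))
    stop("track file must have columns: ", paste(need, collapse = ", "))
  validate_tracks(tr[need], proteins, value_range)
}

#' Validate a long track table against a protein table
#'
#' @inheritParams read_tracks
#' @param tracks Long data frame of per-residue scores.
#' @return The validated track table, sorted by protein, source, position.
#' @export
validate_tracks <- function(tracks, proteins, value_range = c(0, 1)) {
  unknown <- setdiff(unique(tracks$protein_id), proteins$protein_id)
  if (length(unknown) > 0L)
    stop("track(s) for unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  bad <- tracks$value < value_range[1L] | tracks$value > value_range[2L]
  if (any(bad))
    stop("track value out of range [", value_range[1L], ", ", value_range[2L],
         "] for protein ", tracks$protein_id[bad][1L],
         " source ", tracks$source[bad][1L],
         " position ", tracks$position[bad][1L])
  len <- setNames(nchar(proteins$sequence), proteins$protein_id)
  key <- paste(tracks$protein_id, tracks$source, sep = "\r")
  for (k in unique(key)) {
    rows <- tracks[key == k, , drop = FALSE]
    id <- rows$protein_id[1L]
    pos <- sort(rows$position)
    if (anyDuplicated(pos))
      stop("duplicate position for protein ", id, " source ", rows$source[1L])
    L <- len[[id]]
    if (length(pos) != L || !identical(as.integer(pos), seq_len(L)))
      stop("track for protein ", id, " source ", rows$source[1L],
           " does not cover positions 1..", L,
           " without gaps (got ", length(pos), " positions)")
  }
  tracks <- tracks[order(tracks$protein_id, tracks$source, tracks$position), ,
                   drop = FALSE]
  rownames(tracks) <- NULL
  tracks
}

#' Extract one track's values as a numeric vector
#'
#' @param tracks Long track table.
#' @param protein_id,source Track key.
#' @return Numeric vector ordered by position.
#' @export
track_values <- function(tracks, protein_id, source) {
  sel <- tracks$protein_id == protein_id & tracks$source == source
  if (!any(sel))
    stop("no track for protein ", protein_id, " source ", source)
  rows <- tracks[sel, , drop = FALSE]
  rows$value[order(rows$position)]
}

#' Read domain annotations
#'
#' Reads a TSV of domain intervals (columns `protein_id`, `superfamily`,
#' `start`, `end`; 1-based inclusive coordinates) and validates each
#' interval against the protein's length.
#'
#' @param path Path to a TSV file.
#' @param proteins Protein table.
#' @return Data frame with columns `protein_id`, `superfamily`, `start`,
#'   `end`.
#' @export
read_domains <- function(path, proteins) {
  dm <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(protein_id = "character",
                                  superfamily = "character",
                                  start = "integer", end = "integer"))
  need <- c("protein_id", "superfamily", "start", "end")
  if (!all(need %in% names(dm)))
    stop("domain file must have columns: ", paste(need, collapse = ", "))
  validate_domains(dm[need], proteins)
}

#' Validate domain annotations
#'
#' @param domains Data frame of domain intervals.
#' @param proteins Protein table.
#' @return The validated, sorted domain table.
#' @export
validate_domains <- function(domains, proteins) {
  unknown <- setdiff(unique(domains$protein_id), proteins$protein_id)
  if (length(unknown) > 0L)
    stop("domain(s) for unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  len <- setNames(nchar(proteins$sequence), proteins$protein_id)
  bad <- domains$start > domains$end
  if (any(bad))
    stop("domain with start > end on protein ", domains$protein_id[bad][1L],
         " (", domains$start[bad][1L], " > ", domains$end[bad][1L], ")")
  if (any(domains$start < 1L))
    stop("domain start < 1 on protein ",
         domains$protein_id[domains$start < 1L][1L])
  over <- domains$end > len[domains$protein_id]
  if (any(over))
    stop("domain end exceeds protein length on protein ",
         domains$protein_id[over][1L])
  domains <- domains[order(domains$protein_id, domains$superfamily,
                           domains$start, domains$end), , drop = FALSE]
  rownames(domains) <- NULL
  domains
}

#' Construct an interaction edge list
#'
#' An `edge_list` couples a node universe with an undirected, scored edge
#' table. Self-loops, duplicate undirected pairs, endpoints outside the
#' universe and confidences outside `[0, 1]` are rejected.
#'
#' @param edges Data frame with columns `node_a`, `node_b`, `confidence`.
#' @param universe Character vector of node identifiers; defaults to the
#'   sorted set of endpoints.
#' @return An object of class `edge_list`: a list with elements
#'   `universe` and `edges`.
#' @export
edge_list <- function(edges, universe = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "confidence") %in% names(edges)))
  edges <- edges[, c("node_a", "node_b", "confidence"), drop = FALSE]
  if (any(edges$confidence < 0 | edges$confidence > 1))
    stop("edge confidence outside [0, 1]")
  if (any(edges$node_a == edges$node_b))
    stop("self-loop edge on node ",
         edges$node_a[edges$node_a == edges$node_b][1L])
  # canonical orientation so undirected duplicates are detectable
  flip <- edges$node_a > edges$node_b
  tmp <- edges$node_a[flip]
  edges$node_a[flip] <- edges$node_b[flip]
  edges$node_b[flip] <- tmp
  key <- paste(edges$node_a, edges$node_b, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate undirected edge: ",
         gsub("\r", " -- ", key[duplicated(key)][1L]))
  if (is.null(universe)) {
    universe <- sort(unique(c(edges$node_a, edges$node_b)))
  } else {
    universe <- sort(unique(as.character(universe)))
    out <- setdiff(c(edges$node_a, edges$node_b), universe)
    if (length(out) > 0L)
      stop("edge endpoint(s) outside universe: ", paste(out, collapse = ", "))
  }
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(universe = universe, edges = edges), class = "edge_list")
}

#' @export
print.edge_list <- function(x, ...) {
  cat("edge_list:", length(x$universe), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read an interaction edge list from TSV
#'
#' @param path Path to a TSV with columns `node_a`, `node_b`,
#'   `confidence`.
#' @param universe Optional node universe (see [edge_list()]).
#' @param thousand_scale If `TRUE`, integer confidences on the 0-1000
#'   convention of common interaction databases are divided by 1000.
#' @return An `edge_list`.
#' @export
read_edges <- function(path, universe = NULL, thousand_scale = FALSE) {
  ed <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(node_a = "character",
                                  node_b = "character",
                                  confidence = "numeric"))
  need <- c("node_a", "node_b", "confidence")
  if (!all(need %in% names(ed)))
    stop("edge file must have columns: ", paste(need, collapse = ", "))
  if (thousand_scale) ed$confidence <- ed$confidence / 1000
  edge_list(ed[need], universe = universe)
}

#' Write an edge list to TSV
#'
#' @param el An `edge_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(el, path) {
  stopifnot(inherits(el, "edge_list"))
  write_table(el$edges, path)
}

#' Write a table deterministically
#'
#' Tab-separated, header included, rows sorted by all columns left to
#' right so that repeated runs are byte-identical.
#'
#' @param records Data frame.
#' @param path Output path.
#' @param sort_rows Sort rows by all columns before writing.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, sort_rows = TRUE) {
  if (sort_rows && nrow(records) > 1L)
    records <- records[do.call(order, unname(as.list(records))), ,
                       drop = FALSE]
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
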