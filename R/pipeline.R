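#' Assemble a pipeline configuration
#'
#' Collects the input paths and analysis thresholds for [run_all()].
#' All thresholds default to the pipeline's standard values.
#'
#' @param fasta,disorder_tracks,llps_tracks,llps,domains,edges Input
#'   file paths (FASTA and TSVs; see the reader functions for layouts).
#'   `domains` and `edges` may be `NULL` to skip those stages.
#' @param out_dir Output directory.
#' @param sources_for_mean Disorder sources averaged for the mean PPIDR
#'   (default: all).
#' @param cdf_source Source feeding the CDF classifier (default: first
#'   alphabetically).
#' @param agreement Consensus agreement fraction.
#' @param confidence_levels Network confidence ladder.
#' @param background_edge_prob Background edge probability for network
#'   enrichment (`NULL` to skip enrichment).
#' @param boundary_config Optional JSON path overriding the CH/CDF
#'   boundaries.
#' @param fixed_lambda Optional fixed Box-Cox exponent for the
#'   association stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, disorder_tracks, llps_tracks, llps,
                            domains = NULL, edges = NULL,
                            out_dir = "disphase_out",
                            sources_for_mean = NULL, cdf_source = NULL,
                            agreement = 0.75,
                            confidence_levels = c(0.15, 0.4, 0.7, 0.9),
                            background_edge_prob = NULL,
                            boundary_config = NULL, fixed_lambda = NULL) {
  cfg <- list(fasta = fasta, disorder_tracks = disorder_tracks,
              llps_tracks = llps_tracks, llps = llps, domains = domains,
              edges = edges, out_dir = out_dir,
              sources_for_mean = sources_for_mean, cdf_source = cdf_source,
              agreement = agreement, confidence_levels = confidence_levels,
              background_edge_prob = background_edge_prob,
              boundary_config = boundary_config,
              fixed_lambda = fixed_lambda)
  paths <- c(fasta, disorder_tracks, llps_tracks, llps, domains, edges,
             boundary_config)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (!(agreement > 0 && agreement <= 1))
    stop("agreement must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full disorder-LLPS analysis pipeline
#'
#' Stage order: disorder metrics, CH-CDF classification, consensus
#' disorder and domain overlap, LLPS profiling, disorder-LLPS
#' regression, network summaries, run manifest. Every stage writes its
#' table(s) into the output directory; the result object carries the
#' same tables in memory for [protein_report()].
#'
#' @param config A `pipeline_config`.
#' @return List of class `pipeline_result` with elements `disorder`,
#'   `chcdf`, `consensus`, `consensus_regions`, `superfamilies`,
#'   `funnel`, `llps`, `association`, `network`, `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  proteins <- run_stage("read_fasta", read_fasta(config$fasta))
  tracks <- run_stage("read_tracks",
                      read_tracks(config$disorder_tracks, proteins))
  ltr <- run_stage("read_llps_tracks",
                   read_tracks(config$llps_tracks, proteins,
                               value_range = c(0, Inf)))
  llps_tab <- run_stage("read_llps", {
    x <- read.delim(config$llps, stringsAsFactors = FALSE)
    if (!all(c("protein_id", "p_llps") %in% names(x)))
      stop("LLPS table must have columns protein_id, p_llps")
    x
  })

  boundaries <- if (is.null(config$boundary_config))
    list(ch = default_ch_boundary(), cdf = default_cdf_boundary())
  else run_stage("read_boundary_config",
                 read_boundary_config(config$boundary_config))

  ds <- run_stage("disorder_metrics",
                  summarize_disorder(tracks, proteins,
                                     config$sources_for_mean))
  per_source_wide <- ds$per_source
  write_table(ds$summary, file.path(out, "disorder_summary.tsv"))
  write_table(per_source_wide, file.path(out, "disorder_per_source.tsv"))

  chcdf <- run_stage("chcdf",
                     chcdf_classify(proteins, tracks,
                                    source = config$cdf_source,
                                    ch_boundary = boundaries$ch,
                                    cdf_boundary = boundaries$cdf))
  write_table(chcdf, file.path(out, "chcdf.tsv"))

  cons <- run_stage("consensus",
                    consensus_tracks(tracks, proteins,
                                     agreement = config$agreement))
  regions <- do.call(rbind, lapply(names(cons), function(id) {
    r <- consensus_regions(cons[[id]])
    if (nrow(r) == 0L) return(NULL)
    cbind(data.frame(protein_id = id, stringsAsFactors = FALSE), r)
  }))
  if (is.null(regions))
    regions <- data.frame(protein_id = character(), start = integer(),
                          end = integer())
  write_table(regions, file.path(out, "consensus_regions.tsv"))

  superfam <- NULL
  fun <- NULL
  if (!is.null(config$domains)) {
    domains <- run_stage("read_domains",
                         read_domains(config$domains, proteins))
    superfam <- run_stage("superfamily_report",
                          superfamily_report(cons, domains))
    fun <- run_stage("funnel",
                     funnel(proteins, tracks, domains,
                            agreement = config$agreement))
    write_table(superfam, file.path(out, "superfamily_report.tsv"))
    write_table(data.frame(stage = c("with_tracks", "consensus_positive",
                                     "with_domains", "overlap"),
                           n = c(fun$n_with_tracks,
                                 fun$n_consensus_positive,
                                 fun$n_with_domains, fun$n_overlap)),
                file.path(out, "funnel.tsv"), sort_rows = FALSE)
  }

  lp <- run_stage("llps_profiles", llps_profiles(llps_tab, ltr))
  write_table(lp$summary, file.path(out, "llps_summary.tsv"))
  write_table(lp$regions, file.path(out, "llps_regions.tsv"))

  assoc <- run_stage("association",
                     run_association(ds, llps_tab,
                                     fixed_lambda = config$fixed_lambda))
  jsonlite::write_json(list(lambda = assoc$lambda,
                            coefficients = as.list(assoc$coefficients),
                            r_squared = assoc$r_squared,
                            f_pvalue = assoc$f_pvalue, n = assoc$n),
                       file.path(out, "association.json"),
                       auto_unbox = TRUE, digits = NA)
  write_table(cbind(data.frame(protein_id = assoc$protein_id),
                    assoc$diagnostics),
              file.path(out, "association_diagnostics.tsv"))

  net <- NULL
  if (!is.null(config$edges)) {
    el <- run_stage("read_edges", {
      raw <- read_edges(config$edges)
      # isolates matter: the universe is the proteome plus any
      # first-shell interactors present in the edge file
      edge_list(raw$edges,
                universe = union(raw$universe, proteins$protein_id))
    })
    net <- run_stage("network",
                     network_scan(el, config$confidence_levels,
                                  config$background_edge_prob))
    write_table(net, file.path(out, "network.tsv"), sort_rows = FALSE)
  }

  inputs <- Filter(Negate(is.null),
                   config[c("fasta", "disorder_tracks", "llps_tracks",
                            "llps", "domains", "edges")])
  manifest <- list(
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    config = config[c("sources_for_mean", "cdf_source", "agreement",
                      "confidence_levels", "background_edge_prob",
                      "fixed_lambda")],
    version = as.character(packageVersion("disphase")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(proteins = proteins, disorder = ds, chcdf = chcdf,
                 consensus = cons, consensus_regions = regions,
                 superfamilies = superfam, funnel = fun, llps = lp,
                 association = assoc, network = net,
                 edges = if (is.null(config$edges)) NULL else el,
                 manifest = manifest, out_dir = out),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$proteins), "proteins; outputs in",
      x$out_dir, "\n")
  invisible(x)
}

#' Single-protein summary report
#'
#' Collects one protein's disorder metrics, CH-CDF quadrant, consensus
#' regions, LLPS role and regions, and its degree and local clustering
#' coefficient within the supplied network. A protein absent from the
#' network reports degree 0. Degrees and PPIDR round to 2 decimals,
#' probabilities to 4, in the written report.
#'
#' @param result A `pipeline_result`.
#' @param protein_id Protein identifier.
#' @param write_to Optional directory; if given, the report is written
#'   as both JSON and a one-row CSV.
#' @return The report as a named list.
#' @export
protein_report <- function(result, protein_id, write_to = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!protein_id %in% result$proteins$protein_id)
    stop("unknown protein id: ", protein_id)
  dsum <- result$disorder$summary
  drow <- dsum[dsum$protein_id == protein_id, , drop = FALSE]
  crow <- result$chcdf[result$chcdf$protein_id == protein_id, ,
                       drop = FALSE]
  lrow <- result$llps$summary[
    result$llps$summary$protein_id == protein_id, , drop = FALSE]
  regs <- result$consensus_regions[
    result$consensus_regions$protein_id == protein_id, , drop = FALSE]

  degree <- 0L
  clustering <- 0
  if (!is.null(result$edges)) {
    el <- result$edges
    if (protein_id %in% el$universe) {
      g <- igraph::graph_from_data_frame(
        el$edges[, c("node_a", "node_b")], directed = FALSE,
        vertices = el$universe)
      degree <- unname(igraph::degree(g)[protein_id])
      clustering <- unname(igraph::transitivity(
        g, type = "local", vids = protein_id, isolates = "zero"))
    }
  }

  rep <- list(protein_id = protein_id,
              mean_ads = round(drow$mean_ads, 4),
              mean_ppidr = round(drow$mean_ppidr, 2),
              category_by_ppidr = drow$category_by_ppidr,
              category_by_ads = drow$category_by_ads,
              quadrant = if (nrow(crow) > 0L) crow$quadrant else NA_character_,
              delta_ch = if (nrow(crow) > 0L) round(crow$delta_ch, 4)
                         else NA_real_,
              delta_cdf = if (nrow(crow) > 0L) round(crow$delta_cdf, 4)
                          else NA_real_,
              consensus_regions = if (nrow(regs) > 0L)
                paste(paste0(regs$start, "-", regs$end), collapse = ";")
                else "",
              p_llps = if (nrow(lrow) > 0L) round(lrow$p_llps, 4)
                       else NA_real_,
              role = if (nrow(lrow) > 0L) lrow$role else NA_character_,
              dpr_intervals = if (nrow(lrow) > 0L) lrow$dpr_intervals
                              else "",
              n_hotspots = if (nrow(lrow) > 0L) lrow$n_hotspots
                           else NA_integer_,
              n_context_zones = if (nrow(lrow) > 0L) lrow$n_context_zones
                                else NA_integer_,
              degree = degree,
              local_clustering = round(clustering, 4))
  if (!is.null(write_to)) {
    dir.create(write_to, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(rep,
                         file.path(write_to,
                                   paste0("report_", protein_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write.table(as.data.frame(rep),
                file.path(write_to, paste0("report_", protein_id, ".csv")),
                sep = ",", quote = TRUE, row.names = FALSE)
  }
  rep
}
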