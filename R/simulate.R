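# residue sets driving the planted composition classes
DISORDER_PROMOTING <- c("D", "E", "K", "S", "P", "Q")
ORDER_PROMOTING <- c("I", "L", "V", "F", "W", "Y")

# deterministic sub-stream seeds: one global seed fans out into
# independent per-component / per-protein streams, so adding proteins
# leaves earlier proteins' draws untouched
substream_seed <- function(seed, component, index = 0L) {
  # double arithmetic stays exact well past 2^31 * 48271; reduce before
  # converting so the result always fits an R integer
  base <- ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483629
  as.integer((base + component * 1009 + index * 7) %% 2147483629)
}

#' Configuration for the synthetic proteome generator
#'
#' Defines the planted statistical structure of a synthetic
#' acrosome-like proteome: the composition-class mix controlling the
#' ordered / moderately disordered / highly disordered split, the
#' per-predictor track noise, the logistic coupling between true
#' disorder fraction and latent LLPS propensity, and the interaction
#' network's background density and planted module enrichment.
#'
#' The default class weights target roughly a 19 / 42 / 39 percent
#' ordered / moderate / disordered split. The default LLPS coupling and
#' noise were fixed once by the shipped calibration script
#' (`scripts/calibrate_coupling.R`) so that the planted population R-squared
#' of the quadratic disorder-LLPS regression is about 0.65.
#'
#' @param seed Integer master seed.
#' @param n_proteins Number of proteins (default 250).
#' @param length_range Sequence length range in residues.
#' @param class_weights Named weights (`ordered`, `mixed`,
#'   `disordered`) summing to 1.
#' @param n_predictors Number of disorder predictor tracks.
#' @param predictor_noise_sd Per-residue noise SD added independently to
#'   each predictor track before clipping to `[0, 1]`.
#' @param llps_coupling Coefficients `(a0, a1, a2)` of the logistic
#'   link `p = plogis(a0 + a1 d + a2 d^2)` from true disorder fraction
#'   `d` to latent LLPS propensity.
#' @param llps_noise_sd Logit-scale noise SD on the observed LLPS
#'   probability.
#' @param n_superfamilies Number of domain superfamily labels.
#' @param domains_per_protein Mean domain count per protein (Poisson).
#' @param sbind_scale Scale of the gamma-distributed binding-divergence
#'   track (shape fixed at 1.3), controlling the high tail.
#' @param network_background_prob Background per-pair edge probability.
#' @param network_enrichment_factor Multiplier on the background
#'   probability for pairs within the planted module.
#' @param module_size Number of proteins in the planted network module
#'   (default: 20 percent of the proteome, so 50 at the default size).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_proteins = 250L,
                             length_range = c(100L, 1200L),
                             class_weights = c(ordered = 0.19,
                                               mixed = 0.42,
                                               disordered = 0.39),
                             n_predictors = 3L,
                             predictor_noise_sd = 0.15,
                             llps_coupling = c(-2.6, 10.5, -4.5),
                             llps_noise_sd = 1.13,
                             n_superfamilies = 12L,
                             domains_per_protein = 1.5,
                             sbind_scale = 1.0,
                             network_background_prob = 0.03,
                             network_enrichment_factor = 8,
                             module_size = NULL) {
  module_size <- module_size %||% max(2L, as.integer(round(0.2 * n_proteins)))
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              class_weights = class_weights,
              n_predictors = as.integer(n_predictors),
              predictor_noise_sd = predictor_noise_sd,
              llps_coupling = llps_coupling, llps_noise_sd = llps_noise_sd,
              n_superfamilies = as.integer(n_superfamilies),
              domains_per_protein = domains_per_protein,
              sbind_scale = sbind_scale,
              network_background_prob = network_background_prob,
              network_enrichment_factor = network_enrichment_factor,
              module_size = as.integer(module_size))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (cfg$n_proteins < 1L) stop("n_proteins must be positive")
  if (cfg$length_range[1L] < 30L || diff(cfg$length_range) < 0L)
    stop("length_range must be increasing with minimum >= 30")
  if (abs(sum(cfg$class_weights) - 1) > 1e-8)
    stop("class_weights must sum to 1")
  if (any(cfg$class_weights < 0)) stop("class_weights must be non-negative")
  if (cfg$n_predictors < 1L) stop("n_predictors must be positive")
  if (cfg$predictor_noise_sd < 0 || cfg$llps_noise_sd < 0)
    stop("noise SDs must be non-negative")
  if (length(cfg$llps_coupling) != 3L)
    stop("llps_coupling must have 3 coefficients")
  if (cfg$network_background_prob <= 0 || cfg$network_background_prob >= 1)
    stop("network_background_prob must lie in (0, 1)")
  if (cfg$network_enrichment_factor <= 0)
    stop("network_enrichment_factor must be positive")
  if (cfg$module_size < 2L || cfg$module_size > cfg$n_proteins)
    stop("module_size must lie in [2, n_proteins]")
  if (cfg$n_superfamilies < 1L) stop("n_superfamilies must be positive")
  if (cfg$domains_per_protein < 0) stop("domains_per_protein must be >= 0")
  invisible(cfg)
}

# moving average with shrinking windows at the sequence ends
moving_avg <- function(x, half_width = 7L) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_width, 1L)
  hi <- pmin(seq_len(n) + half_width, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# per-class target disorder fractions; ranges sit strictly inside the
# three-tier category bands so the planted class survives thresholding
CLASS_FRACTION_RANGES <- list(ordered = c(0.01, 0.07),
                              mixed = c(0.13, 0.27),
                              disordered = c(0.34, 0.90))

# class-specific residue frequencies: disorder-promoting residues
# boosted in the disordered class, order-promoting in the ordered class
class_composition <- function(class) {
  w <- setNames(rep(1, 20L), AA_CANONICAL)
  if (class == "disordered") {
    w[DISORDER_PROMOTING] <- 4
    w[ORDER_PROMOTING] <- 0.5
  } else if (class == "ordered") {
    w[ORDER_PROMOTING] <- 4
    w[DISORDER_PROMOTING] <- 0.5
  } else {
    w[DISORDER_PROMOTING] <- 2
  }
  w / sum(w)
}

generate_one_protein <- function(cfg, i) {
  set.seed(substream_seed(cfg$seed, 1L, i))
  class <- sample(names(cfg$class_weights), 1L, prob = cfg$class_weights)
  L <- sample(seq(cfg$length_range[1L], cfg$length_range[2L]), 1L)
  comp <- class_composition(class)
  sequence <- paste(sample(AA_CANONICAL, L, replace = TRUE, prob = comp),
                    collapse = "")
  rng <- CLASS_FRACTION_RANGES[[class]]
  u <- runif(1L, rng[1L], rng[2L])

  # latent per-residue signal: smoothed disorder-promoting composition,
  # quantile-centred so that a fraction ~u of residues crosses 0.5,
  # then a logistic map into [0,1]
  ind <- as.numeric(strsplit(sequence, "")[[1L]] %in% DISORDER_PROMOTING)
  w <- moving_avg(ind, half_width = 7L)
  # sub-resolution jitter breaks the heavy ties of the windowed mean so
  # the quantile threshold carves out a fraction within ~1/L of u
  w <- w + runif(L, 0, 1e-9)
  q <- quantile(w, 1 - u, names = FALSE, type = 7)
  signal <- plogis(10 * (w - q))
  d_true <- mean(w > q)

  preds <- vapply(seq_len(cfg$n_predictors), function(j)
    pmin(1, pmax(0, signal + rnorm(L, 0, cfg$predictor_noise_sd))),
    numeric(L))

  a <- cfg$llps_coupling
  eta <- a[1L] + a[2L] * d_true + a[3L] * d_true^2
  latent_p <- plogis(eta)
  p_llps <- plogis(eta + rnorm(1L, 0, cfg$llps_noise_sd))

  p_dp <- pmin(1, pmax(0, signal * (0.35 + 0.75 * p_llps) +
                            rnorm(L, 0, 0.05)))
  s_bind <- rgamma(L, shape = 1.3, scale = cfg$sbind_scale)

  set.seed(substream_seed(cfg$seed, 2L, i))
  n_dom <- rpois(1L, cfg$domains_per_protein)
  doms <- NULL
  if (n_dom > 0L) {
    len <- pmin(L, 30L + floor(runif(n_dom) * pmin(170L, L - 30L + 1L)))
    start <- 1L + floor(runif(n_dom) * (L - len + 1L))
    doms <- data.frame(
      superfamily = sprintf("SF%03d",
                            sample.int(cfg$n_superfamilies, n_dom,
                                       replace = TRUE)),
      start = as.integer(start), end = as.integer(start + len - 1L),
      stringsAsFactors = FALSE)
  }

  list(class = class, sequence = sequence, d_true = d_true,
       signal = signal, preds = preds, latent_p = latent_p,
       p_llps = p_llps, p_dp = p_dp, s_bind = s_bind, domains = doms)
}

#' Generate a synthetic acrosome-like proteome
#'
#' Generates sequences, multi-predictor per-residue disorder tracks,
#' per-protein LLPS probabilities with residue-level droplet-promoting
#' and binding-divergence tracks, domain annotations, and an
#' interaction network with a planted enriched module - all with
#' planted, configurable statistical structure. The generator is fully
#' deterministic given the configuration seed.
#'
#' @param config A `synthetic_config`.
#' @return List of class `synthetic_proteome`: `config`, `proteins`,
#'   `tracks` (disorder predictor tracks, sources `pred1..k`),
#'   `llps` (per-protein `p_llps`), `llps_tracks` (sources `p_dp`,
#'   `s_bind`), `domains`, `edges` (an `edge_list`), and `truth` (the
#'   planted per-protein values).
#' @export
generate_proteome <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  ids <- sprintf("SYN%04d", seq_len(cfg$n_proteins))
  gen <- lapply(seq_len(cfg$n_proteins), function(i)
    generate_one_protein(cfg, i))

  proteins <- data.frame(protein_id = ids,
                         sequence = vapply(gen, `[[`, "", "sequence"),
                         stringsAsFactors = FALSE)

  lens <- nchar(proteins$sequence)
  src_names <- sprintf("pred%d", seq_len(cfg$n_predictors))
  tracks <- data.frame(
    protein_id = rep(rep(ids, lens), times = cfg$n_predictors),
    source = rep(src_names, each = sum(lens)),
    position = rep(unlist(lapply(lens, seq_len)), times = cfg$n_predictors),
    value = unlist(lapply(seq_len(cfg$n_predictors), function(j)
      unlist(lapply(gen, function(g) g$preds[, j])))),
    stringsAsFactors = FALSE)

  llps_tracks <- data.frame(
    protein_id = rep(rep(ids, lens), times = 2L),
    source = rep(c("p_dp", "s_bind"), each = sum(lens)),
    position = rep(unlist(lapply(lens, seq_len)), times = 2L),
    value = c(unlist(lapply(gen, `[[`, "p_dp")),
              unlist(lapply(gen, `[[`, "s_bind"))),
    stringsAsFactors = FALSE)

  llps <- data.frame(protein_id = ids,
                     p_llps = vapply(gen, `[[`, numeric(1L), "p_llps"),
                     stringsAsFactors = FALSE)

  dom_rows <- Filter(Negate(is.null), lapply(seq_along(gen), function(i) {
    d <- gen[[i]]$domains
    if (is.null(d)) return(NULL)
    cbind(data.frame(protein_id = ids[i], stringsAsFactors = FALSE), d)
  }))
  domains <- if (length(dom_rows) > 0L) do.call(rbind, dom_rows) else
    data.frame(protein_id = character(), superfamily = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  domains <- validate_domains(domains, proteins)

  set.seed(substream_seed(cfg$seed, 3L))
  module <- sort(sample(ids, cfg$module_size))
  pairs <- which(upper.tri(matrix(0, cfg$n_proteins, cfg$n_proteins)),
                 arr.ind = TRUE)
  a <- ids[pairs[, 1L]]
  b <- ids[pairs[, 2L]]
  prob <- rep(cfg$network_background_prob, nrow(pairs))
  in_mod <- (a %in% module) & (b %in% module)
  prob[in_mod] <- pmin(1, cfg$network_background_prob *
                            cfg$network_enrichment_factor)
  hit <- runif(nrow(pairs)) < prob
  edges <- data.frame(node_a = a[hit], node_b = b[hit],
                      confidence = round(runif(sum(hit), 0.15, 1), 3),
                      stringsAsFactors = FALSE)
  el <- edge_list(edges, universe = ids)

  truth <- data.frame(protein_id = ids,
                      class = vapply(gen, `[[`, "", "class"),
                      length = lens,
                      disorder_fraction = vapply(gen, `[[`, numeric(1L),
                                                 "d_true"),
                      latent_p_llps = vapply(gen, `[[`, numeric(1L),
                                             "latent_p"),
                      p_llps = llps$p_llps,
                      in_module = ids %in% module,
                      stringsAsFactors = FALSE)

  structure(list(config = cfg, proteins = proteins, tracks = tracks,
                 llps = llps, llps_tracks = llps_tracks, domains = domains,
                 edges = el, truth = truth),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat("synthetic_proteome:", nrow(x$proteins), "proteins, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Planted per-protein values of a synthetic proteome
#'
#' Regenerates (deterministically) the exact latent values used by
#' [generate_proteome()] for the same configuration: true disorder
#' fraction, composition class, latent and observed LLPS propensity,
#' and planted-module membership.
#'
#' @param config A `synthetic_config`.
#' @return Data frame with one row per protein.
#' @export
truth_table <- function(config) {
  generate_proteome(config)$truth
}

#' Write a synthetic proteome to disk
#'
#' Writes the FASTA, all track / domain / edge TSVs, the truth table,
#' and the resolved configuration (JSON, including the seed) for
#' provenance.
#'
#' @param sim A `synthetic_proteome`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_proteome <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_proteome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  write_table(sim$tracks, file.path(dir, "disorder_tracks.tsv"))
  write_table(sim$llps_tracks, file.path(dir, "llps_tracks.tsv"))
  write_table(sim$llps, file.path(dir, "llps.tsv"))
  write_table(sim$domains, file.path(dir, "domains.tsv"))
  write_edges(sim$edges, file.path(dir, "edges.tsv"))
  write_table(sim$truth, file.path(dir, "truth.csv"))
  jsonlite::write_json(unclass(sim$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
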