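test_that("the generator is byte-deterministic given the seed", {
  cfg <- synthetic_config(seed = 101, n_proteins = 12,
                          length_range = c(50L, 120L))
  s1 <- generate_proteome(cfg)
  s2 <- generate_proteome(cfg)
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$llps, s2$llps)
  expect_identical(s1$domains, s2$domains)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$truth, s2$truth)
  # different seed changes the draw
  s3 <- generate_proteome(synthetic_config(seed = 102, n_proteins = 12,
                                           length_range = c(50L, 120L)))
  expect_false(identical(s1$proteins$sequence, s3$proteins$sequence))
})

test_that("adding proteins leaves earlier proteins' draws untouched", {
  small <- generate_proteome(synthetic_config(seed = 7, n_proteins = 10,
                                              length_range = c(50L, 100L)))
  large <- generate_proteome(synthetic_config(seed = 7, n_proteins = 20,
                                              length_range = c(50L, 100L)))
  expect_identical(small$proteins$sequence,
                   large$proteins$sequence[1:10])
  expect_identical(small$truth$disorder_fraction,
                   large$truth$disorder_fraction[1:10])
})

test_that("invalid configurations fail before any generation", {
  expect_error(synthetic_config(n_proteins = 0), "positive")
  expect_error(synthetic_config(class_weights = c(ordered = 0.5,
                                                  mixed = 0.5,
                                                  disordered = 0.5)),
               "sum to 1")
  expect_error(synthetic_config(network_background_prob = 0), "\\(0, 1\\)")
  expect_error(synthetic_config(module_size = 1000), "module_size")
  expect_error(synthetic_config(predictor_noise_sd = -1), "non-negative")
})

test_that("emitted artifacts pass the package's own validation", {
  sim <- generate_proteome(synthetic_config(seed = 13, n_proteins = 25,
                                            length_range = c(60L, 150L)))
  expect_silent(validate_proteins(sim$proteins))
  expect_silent(validate_tracks(sim$tracks, sim$proteins))
  expect_silent(validate_tracks(sim$llps_tracks, sim$proteins,
                                value_range = c(0, Inf)))
  expect_silent(validate_domains(sim$domains, sim$proteins))
  expect_true(all(sim$llps$p_llps >= 0 & sim$llps$p_llps <= 1))
  expect_equal(nrow(sim$truth), 25L)
})

test_that("zero-noise tracks reproduce the planted disorder exactly", {
  cfg <- synthetic_config(seed = 17, n_proteins = 40,
                          length_range = c(80L, 200L),
                          predictor_noise_sd = 0)
  sim <- generate_proteome(cfg)
  ds <- summarize_disorder(sim$tracks, sim$proteins)
  m <- merge(ds$summary, sim$truth, by = "protein_id")
  # mean PPIDR of noiseless tracks equals the planted disorder fraction
  expect_equal(m$mean_ppidr / 100, m$disorder_fraction, tolerance = 1e-9)
  # classification of the mean PPIDR recovers the planted class
  map <- c(ordered = "highly_ordered", mixed = "moderately_disordered",
           disordered = "highly_disordered")
  expect_equal(m$category_by_ppidr, unname(map[m$class]))
})

test_that("predictor noise degrades inter-predictor correlation monotonically", {
  cors <- vapply(c(0.05, 0.2, 0.5), function(sd) {
    sim <- generate_proteome(synthetic_config(seed = 19, n_proteins = 15,
                                              length_range = c(80L, 160L),
                                              predictor_noise_sd = sd))
    v1 <- sim$tracks$value[sim$tracks$source == "pred1"]
    v2 <- sim$tracks$value[sim$tracks$source == "pred2"]
    cor(v1, v2)
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("module edges are enriched at roughly background x factor", {
  cfg <- synthetic_config(seed = 23, n_proteins = 120,
                          length_range = c(50L, 80L),
                          network_background_prob = 0.05,
                          network_enrichment_factor = 6, module_size = 40)
  rates <- t(vapply(1:15, function(k) {
    cfg_k <- synthetic_config(seed = 23 + k, n_proteins = 120,
                              length_range = c(50L, 80L),
                              network_background_prob = 0.05,
                              network_enrichment_factor = 6,
                              module_size = 40)
    sim <- generate_proteome(cfg_k)
    mod <- sim$truth$protein_id[sim$truth$in_module]
    e <- sim$edges$edges
    in_mod <- e$node_a %in% mod & e$node_b %in% mod
    mod_pairs <- choose(length(mod), 2)
    out_pairs <- choose(120, 2) - mod_pairs
    c(sum(in_mod) / mod_pairs, sum(!in_mod) / out_pairs)
  }, numeric(2)))
  # binomial-CI style check on the pooled empirical rates
  expect_lt(abs(mean(rates[, 1]) - 0.30), 0.03)
  expect_lt(abs(mean(rates[, 2]) - 0.05), 0.01)
})

test_that("the truth table matches a regenerated proteome", {
  cfg <- synthetic_config(seed = 31, n_proteins = 10,
                          length_range = c(50L, 90L))
  tt <- truth_table(cfg)
  sim <- generate_proteome(cfg)
  expect_identical(tt, sim$truth)
  expect_equal(nrow(tt), cfg$n_proteins)
})
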