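test_that("consensus calling uses an inclusive agreement fraction", {
  # 4 tracks, residue with 3 calls: 3/4 = 0.75 >= 0.75 -> disordered
  m <- matrix(c(0.9, 0.9, 0.9, 0.1,
                0.9, 0.9, 0.1, 0.1), nrow = 2, byrow = TRUE)
  calls <- consensus_track(m, agreement = 0.75)
  expect_equal(calls, c(TRUE, FALSE))

  # single track: consensus equals the thresholded calls
  v <- matrix(c(0.9, 0.2, 0.6), ncol = 1)
  expect_equal(consensus_track(v), c(TRUE, FALSE, TRUE))

  expect_error(consensus_track(m, agreement = 0), "agreement")
  expect_error(consensus_track(m, agreement = 1.5), "agreement")
})

test_that("raising agreement never converts a residue to disordered", {
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(runif(200), ncol = 4)
    grid <- seq(0.25, 1, by = 0.05)
    prev <- consensus_track(m, agreement = grid[1])
    for (a in grid[-1]) {
      cur <- consensus_track(m, agreement = a)
      expect_true(all(prev | !cur))  # cur TRUE implies prev TRUE
      prev <- cur
    }
  }
})

test_that("overlap counting is plain interval arithmetic", {
  calls <- rep(FALSE, 40)
  calls[15:30] <- TRUE
  expect_equal(overlap_residues(calls, 10, 20), 6)
  expect_equal(overlap_residues(calls, 1, 5), 0)
  expect_equal(overlap_residues(rep(TRUE, 40), 7, 19), 13)
  expect_error(overlap_residues(calls, 30, 45), "invalid")
  expect_true(overlap_residues(calls, 10, 20) <=
                min(11, sum(calls)))
})

test_that("superfamily totals add across intervals and proteins", {
  calls_p1 <- rep(FALSE, 50); calls_p1[1:10] <- TRUE
  cons <- list(P1 = calls_p1, P2 = rep(FALSE, 30))
  dm <- data.frame(protein_id = c("P1", "P1", "P2"),
                   superfamily = "SF1",
                   start = c(8, 1, 5), end = c(20, 4, 10))
  rep1 <- superfamily_report(cons, dm)
  expect_equal(rep1$disordered_residues, 3 + 4)  # [8,10] + [1,4]
  expect_equal(rep1$proteins_affected, "P1")
  expect_equal(rep1$n_proteins, 1L)

  # dedupe counts overlapping positions once
  dm2 <- data.frame(protein_id = "P1", superfamily = "SF1",
                    start = c(1, 5), end = c(10, 12))
  expect_equal(superfamily_report(cons, dm2)$disordered_residues, 10 + 6)
  expect_equal(superfamily_report(cons, dm2,
                                  dedupe = TRUE)$disordered_residues, 10)
})

test_that("superfamily report equals a position-by-position recount", {
  sim <- generate_proteome(synthetic_config(seed = 19, n_proteins = 30,
                                            length_range = c(60L, 200L),
                                            domains_per_protein = 2.5))
  cons <- consensus_tracks(sim$tracks, sim$proteins)
  rep1 <- superfamily_report(cons, sim$domains)
  # oracle: per superfamily, walk every interval position by position
  for (i in seq_len(nrow(rep1))) {
    sf <- rep1$superfamily[i]
    dm <- sim$domains[sim$domains$superfamily == sf, ]
    total <- 0L
    affected <- character()
    for (j in seq_len(nrow(dm))) {
      id <- dm$protein_id[j]
      if (!id %in% names(cons)) next
      cnt <- 0L
      for (pos in dm$start[j]:dm$end[j])
        if (cons[[id]][pos]) cnt <- cnt + 1L
      total <- total + cnt
      if (cnt > 0L) affected <- union(affected, id)
    }
    expect_equal(rep1$disordered_residues[i], total)
    expect_equal(rep1$proteins_affected[i],
                 paste(sort(affected), collapse = ";"))
  }
  # invariance to row order of the domain table
  shuffled <- sim$domains[sample(nrow(sim$domains)), ]
  expect_equal(superfamily_report(cons, shuffled), rep1)
})

test_that("the four-stage funnel nests correctly", {
  sim <- generate_proteome(synthetic_config(seed = 23, n_proteins = 40,
                                            length_range = c(60L, 150L)))
  fn <- funnel(sim$proteins, sim$tracks, sim$domains)
  expect_gte(fn$n_with_tracks, fn$n_consensus_positive)
  expect_gte(fn$n_with_tracks, fn$n_with_domains)
  expect_gte(fn$n_consensus_positive, fn$n_overlap)
  expect_gte(fn$n_with_domains, fn$n_overlap)
  # brute-force per-protein recount
  cons <- consensus_tracks(sim$tracks, sim$proteins)
  n_pos <- sum(vapply(cons, any, logical(1)))
  expect_equal(fn$n_consensus_positive, n_pos)
  overlap <- 0L
  for (id in names(cons)) {
    dm <- sim$domains[sim$domains$protein_id == id, ]
    hit <- FALSE
    for (j in seq_len(nrow(dm)))
      if (any(cons[[id]][dm$start[j]:dm$end[j]])) hit <- TRUE
    if (hit) overlap <- overlap + 1L
  }
  expect_equal(fn$n_overlap, overlap)

  # no domains: stages 3 and 4 are zero
  no_dom <- sim$domains[0, ]
  fn0 <- funnel(sim$proteins, sim$tracks, no_dom)
  expect_equal(fn0$n_with_domains, 0L)
  expect_equal(fn0$n_overlap, 0L)
})

test_that("hypergeometric enrichment matches closed forms and BH by hand", {
  universe <- paste0("g", 1:10)
  res <- set_enrichment(query = paste0("g", 1:4),
                        annotation = list(T1 = paste0("g", 1:5)),
                        universe = universe)
  expect_equal(res$p_value, choose(5, 4) * choose(5, 0) / choose(10, 4),
               tolerance = 1e-12)

  # zero overlap: upper tail from 0 is exactly 1
  res0 <- set_enrichment(query = paste0("g", 1:3),
                         annotation = list(T1 = paste0("g", 8:10)),
                         universe = universe)
  expect_equal(res0$p_value[res0$overlap_count == 0], 1)

  expect_error(set_enrichment("a", list(T1 = "a"), character()), "empty")
  expect_error(set_enrichment("zz", list(T1 = "g1"), universe),
               "not in universe")
})

test_that("BH adjustment follows the step-up procedure", {
  # raw (0.01, 0.02, 0.03) -> adjusted (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  set.seed(4)
  universe <- paste0("g", 1:40)
  ann <- lapply(1:6, function(i) sample(universe, 12))
  names(ann) <- paste0("T", 1:6)
  res <- set_enrichment(sample(universe, 10), ann, universe)
  expect_true(all(diff(res$p_adjusted) >= -1e-15))  # sorted output
  expect_true(all(res$p_adjusted <= 1))
  # adjusted values are a non-decreasing function of raw-p rank
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-15))
})
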