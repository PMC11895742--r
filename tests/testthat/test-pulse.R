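test_that("recovery is occupancy among range-through taxa, floored at eps", {
  occs <- as_occurrences(occ_df(
    c("a", "a", "b", "b", "c", "c", "d", "d", "a"),
    c("2", "6", "2", "6", "2", "6", "2", "6", "4")), col20)
  r <- compute_ranges(occs, col20)
  rec <- estimate_recovery(r, col20)
  expect_equal(rec$p[2], 1)          # all 4 range-through taxa occur in bed 2
  expect_equal(rec$p[4], 0.25)       # 1 of 4 range-through taxa occurs
  eps <- 1 / (2 * nrow(r))
  expect_equal(rec$p[10], eps)       # no range-through taxa: floor
  expect_true(all(rec$p >= eps & rec$p <= 1))
  expect_error(estimate_recovery(r, col20[0, ]), "empty")
})

test_that("complete sampling and one LAD bed give a zero-loglik single pulse", {
  lads <- make_lads(rep(7, 12))
  rec <- constant_recovery(col20, 1)
  m <- fit_k_pulses(lads, rec, 1, col20)
  expect_equal(m$k, 1)
  expect_equal(m$pulse_beds, "7")
  expect_equal(m$loglik, 0)
  expect_true(all(m$assignment == 1))
})

test_that("two LAD clusters under complete sampling yield pulses at both beds", {
  lads <- make_lads(c(rep(5, 8), rep(20, 8)))
  rec <- constant_recovery(col20, 1)
  m <- fit_k_pulses(lads, rec, 2, col20)
  expect_equal(m$pulse_beds, c("5", "20"))
  expect_equal(unname(m$assignment), rep(1:2, each = 8))
  expect_error(fit_k_pulses(lads, rec, 3, col20), "fewer distinct LAD beds")
})

test_that("fit_k_pulses equals the brute-force placement scan exactly", {
  # random instances with <= 8 distinct LAD beds and k <= 3
  set.seed(11)
  for (rep in 1:30) {
    n_beds <- sample(4:8, 1)
    beds <- sort(sample(3:18, n_beds))
    lads <- make_lads(sample(beds, 25, replace = TRUE))
    p <- runif(20, 0.2, 0.95)
    rec <- constant_recovery(col20, 1)
    rec$p <- p
    for (k in 1:min(3, length(unique(lads)))) {
      fit <- fit_k_pulses(lads, rec, k, col20)
      oracle <- oracle_pulse_scan(lads, p, k)
      expect_equal(fit$loglik, oracle$ll, tolerance = 1e-10)
      expect_equal(fit$pulse_pos, oracle$pulses)
    }
  }
})

test_that("pulse model likelihoods are nested in k", {
  set.seed(12)
  lads <- make_lads(sample(c(5, 6, 10, 14, 15), 40, replace = TRUE))
  rec <- constant_recovery(col20, 0.7)
  ll <- vapply(1:4, function(k) fit_k_pulses(lads, rec, k, col20)$loglik,
               numeric(1))
  expect_true(all(diff(ll) >= -1e-10))
})

test_that("with complete sampling pulses sit at LAD cluster maxima", {
  # reduces to constrained k-medoids: each selected pulse is the top of its
  # assigned LAD cluster; verified by enumeration on a small instance
  lads <- make_lads(c(3, 4, 4, 9, 10, 10, 16, 17, 17, 17, 3, 9))
  rec <- constant_recovery(col20, 1)
  m <- fit_k_pulses(lads, rec, 3, col20)
  for (j in seq_len(3)) {
    members <- lads[m$assignment == j]
    expect_equal(m$pulse_pos[j], max(members))
  }
  oracle <- oracle_pulse_scan(lads, rep(1, 20), 3)
  expect_equal(m$loglik, oracle$ll, tolerance = 1e-10)
})

test_that("interval fit matches its grid-scan oracle and complete-sampling limit", {
  lads <- make_lads(c(5, 9, 12, 15, 18, 20, 7, 11, 16, 19))
  rec <- constant_recovery(col20, 1)
  m <- fit_interval(lads, rec, col20)
  expect_equal(m$k, 0)
  expect_equal(m$interval_beds, c("5", "20"))

  set.seed(13)
  p <- runif(20, 0.3, 0.9)
  rec$p <- p
  m2 <- fit_interval(lads, rec, col20)
  oracle <- oracle_interval_scan(lads, p)
  expect_equal(m2$loglik, oracle$ll, tolerance = 1e-8)
  expect_equal(m2$interval_pos, oracle$bounds)

  expect_error(fit_interval(make_lads(rep(7, 5)), rec, col20), "single distinct")
})

test_that("interval bounds are recovered within 2 beds under thinned sampling", {
  cfg <- sim_config(60, col20, interval_beds = c("5", "18"), recovery = 0.7,
                    seed = 301)
  sim <- simulate_occurrences(cfg)
  r <- compute_ranges(sim$occurrences, col20)
  m <- fit_interval(lads_from_ranges(r, col20), constant_recovery(col20, 0.7),
                    col20)
  expect_lte(abs(m$interval_pos[1] - 5), 2)
  expect_lte(abs(m$interval_pos[2] - 18), 2)
})

test_that("a thinned single pulse is recovered within one bed", {
  cfg <- sim_config(50, col20, pulse_beds = "18", recovery = 0.6, seed = 302)
  sim <- simulate_occurrences(cfg)
  r <- compute_ranges(sim$occurrences, col20)
  lads <- lads_from_ranges(r, col20)
  m <- fit_k_pulses(lads, constant_recovery(col20, 0.6), 1, col20)
  expect_lte(abs(m$pulse_pos - 18), 1)
  # fitted optimum equals exhaustive scan
  oracle <- oracle_pulse_scan(lads, rep(0.6, 20), 1)
  expect_equal(m$loglik, oracle$ll, tolerance = 1e-10)
})

test_that("pulse-count selection: trivial complete-sampling cases", {
  rec <- constant_recovery(col20, 1)
  m1 <- select_pulse_count(make_lads(rep(9, 15)), rec, col20, seed = 1)
  expect_equal(m1$k, 1)
  m2 <- select_pulse_count(make_lads(c(rep(5, 12), rep(17, 12))), rec, col20,
                           seed = 1)
  expect_equal(m2$k, 2)
})

test_that("pulse-count selection is deterministic given a seed", {
  cfg <- sim_config(40, col20, pulse_beds = c("8", "16"), recovery = 0.7,
                    seed = 303)
  sim <- simulate_occurrences(cfg)
  r <- compute_ranges(sim$occurrences, col20)
  lads <- lads_from_ranges(r, col20)
  rec <- constant_recovery(col20, 0.7)
  m1 <- select_pulse_count(lads, rec, col20, n_boot = 99, seed = 7)
  m2 <- select_pulse_count(lads, rec, col20, n_boot = 99, seed = 7)
  expect_equal(m1$k, m2$k)
  expect_equal(attr(m1, "lrt_pvalues"), attr(m2, "lrt_pvalues"))
})

test_that("bootstrap pulse CIs: zero width under complete sampling, reproducible", {
  rec <- constant_recovery(col20, 1)
  lads <- make_lads(rep(9, 15))
  m <- fit_k_pulses(lads, rec, 1, col20)
  ci <- pulse_confidence(m, lads, rec, col20, n_boot = 99, seed = 5)
  expect_equal(unname(ci$pulse_cis[1, "low"]), unname(ci$pulse_cis[1, "high"]))
  expect_equal(unname(ci$pulse_cis[1, "low"]), m$pulse_heights[1])

  cfg <- sim_config(40, col20, pulse_beds = "14", recovery = 0.7, seed = 304)
  sim <- simulate_occurrences(cfg)
  r <- compute_ranges(sim$occurrences, col20)
  lads2 <- lads_from_ranges(r, col20)
  rec2 <- constant_recovery(col20, 0.7)
  m2 <- fit_k_pulses(lads2, rec2, 1, col20)
  c1 <- pulse_confidence(m2, lads2, rec2, col20, n_boot = 99, seed = 6)
  c2 <- pulse_confidence(m2, lads2, rec2, col20, n_boot = 99, seed = 6)
  expect_equal(c1$pulse_cis, c2$pulse_cis)
})

test_that("bootstrap pulse CI covers the true pulse at roughly nominal rate", {
  # scaled coverage simulation at C = 0.9, modest replicate count
  set.seed(15)
  covered <- replicate(60, {
    cfg <- sim_config(50, col20, pulse_beds = "14", recovery = 0.7,
                      seed = sample.int(1e6, 1))
    sim <- simulate_occurrences(cfg)
    r <- compute_ranges(sim$occurrences, col20)
    lads <- lads_from_ranges(r, col20)
    rec <- constant_recovery(col20, 0.7)
    m <- fit_k_pulses(lads, rec, 1, col20)
    ci <- pulse_confidence(m, lads, rec, col20, n_boot = 99, C = 0.9,
                           seed = sample.int(1e6, 1))
    truth <- bed_midpoints(col20)[["14"]]
    ci$pulse_cis[1, "low"] - 0.51 <= truth && truth <= ci$pulse_cis[1, "high"] + 0.51
  })
  expect_gt(mean(covered), 0.75)
})

test_that("per-clade pulse analysis flags depauperate clades and separates pulses", {
  col <- col20
  cfgA <- sim_config(30, col, pulse_beds = "6", recovery = 0.85, seed = 305)
  cfgB <- sim_config(30, col, pulse_beds = "16", recovery = 0.85, seed = 306)
  simA <- simulate_occurrences(cfgA)$occurrences
  simB <- simulate_occurrences(cfgB)$occurrences
  simA$clade <- "Brachiopoda"
  simB$clade <- "Mollusca"
  simB$taxon <- paste0(simB$taxon, "_B")
  few <- occ_df(c("x", "x", "y", "y"), c("2", "3", "2", "4"),
                clade = "Bryozoa")
  occs <- as_occurrences(rbind(as.data.frame(simA), as.data.frame(simB), few),
                         col)
  ranges <- compute_ranges(occs, col)
  res <- per_clade_pulses(ranges, col, min_richness = 10, n_boot = 99,
                          seed = 8)
  expect_identical(res$Bryozoa, "insufficient")
  expect_lte(abs(res$Brachiopoda$pulse_pos[res$Brachiopoda$k] - 6), 1)
  expect_lte(abs(res$Mollusca$pulse_pos[res$Mollusca$k] - 16), 1)
})
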