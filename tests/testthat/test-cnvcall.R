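test_that("emission means follow the admixture expectation", {
  expect_equal(emission_mean(2, 0), 0)
  expect_equal(emission_mean(2, 0.73), 0)
  expect_equal(emission_mean(1, 1), -1)
  expect_equal(emission_mean(1, 0.25), log2(0.875))
  expect_equal(emission_mean(3, 0.5), log2(1.25))
  # degenerate pure-tumor homozygous deletion is capped, not -Inf
  expect_equal(emission_mean(0, 1), -8)
  expect_error(emission_mean(-1, 0.5), "non-negative")
  expect_error(emission_mean(1, 1.5), "0, 1")
})

test_that("hmm_config validates states, grid and priors", {
  expect_error(hmm_config(states = c(1, 3)), "neutral")
  expect_error(hmm_config(tumor_fraction_grid = c(0.2, 0.1)), "increasing")
  expect_error(hmm_config(self_transition = 1), "0, 1")
  expect_error(hmm_config(state_prior = c(0.5, 0.5)), "probability vector")
  expect_error(hmm_config(emission_sd = -1), "positive")
})

test_that("Viterbi decodes obvious profiles correctly", {
  g <- toy_genome(lengths = c(5e6, 4e6, 3e6))
  grid <- build_bin_grid(g, 1e6)
  # all bins at zero: all-neutral whatever the tumor fraction
  p0 <- make_profile(grid, rep(0, 12))
  path <- viterbi_path(p0, hmm_config(), 0.3)
  expect_true(all(path == 2))
  # single strong monosomy bin at f = 1 lands in state 1
  g1 <- genome_model("1", 1e6, 5e5)
  grid1 <- build_bin_grid(g1, 1e6)
  p1 <- make_profile(grid1, -1)
  expect_equal(as.integer(viterbi_path(p1, hmm_config(emission_sd = 0.1), 1)),
               1L)
})

test_that("Viterbi matches exhaustive enumeration on random profiles", {
  cfg <- hmm_config(states = c(1L, 2L, 3L), emission_sd = 0.2,
                    self_transition = 0.95)
  means <- emission_mean(cfg$states, 0.4)
  log_prior <- log(c(0.025, 0.95, 0.025))
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    vals <- rnorm(n, 0, 0.3)
    g <- genome_model("1", n * 1e6, n * 5e5)
    grid <- build_bin_grid(g, 1e6)
    p <- make_profile(grid, vals)
    got <- viterbi_path(p, hmm_config(states = cfg$states, emission_sd = 0.2,
                                      self_transition = 0.95,
                                      state_prior = c(0.025, 0.95, 0.025)),
                        0.4)
    want <- cfg$states[brute_force_viterbi(vals, means, 0.2, 0.95, log_prior)]
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("tumor-fraction estimation recovers the null and reports the curve", {
  g <- toy_genome(lengths = c(10e6, 10e6, 10e6))
  grid <- build_bin_grid(g, 1e6)
  p <- make_profile(grid, rep(0, 30))
  est <- estimate_tumor_fraction(p)
  expect_equal(est$f_hat, 0)  # parsimony: exact ties resolve to smallest f
  expect_equal(length(est$log_likelihood), length(est$grid))
  expect_true(all(is.finite(est$log_likelihood)))
})

test_that("halving the grid step moves f_hat at most one coarse step", {
  g <- grch37_genome()
  grid <- build_bin_grid(g, 1e6)
  cfg <- sim_config(grid, n_fragments = 5e6, tumor_fraction = 0.2,
                    profile = uveal_archetypes()$monosomy3_8qgain, seed = 31)
  p <- to_log2_profile(simulate_bin_counts(cfg))
  coarse <- hmm_config(tumor_fraction_grid = seq(0, 0.5, by = 0.02))
  fine <- hmm_config(tumor_fraction_grid = seq(0, 0.5, by = 0.01))
  f_coarse <- estimate_tumor_fraction(p, coarse)$f_hat
  f_fine <- estimate_tumor_fraction(p, fine)$f_hat
  expect_lte(abs(f_fine - f_coarse), 0.02 + 1e-12)
})

test_that("segments are maximal constant-state runs with gap handling", {
  g <- genome_model("1", 8e6, 4e6)
  grid <- build_bin_grid(g, 1e6)
  vals <- c(0, 0, 0, -0.2, -0.2, -0.2, 0, 0)
  p <- make_profile(grid, vals)
  path <- structure(c(2L, 2L, 2L, 1L, 1L, 1L, 2L, 2L), ordinals = 0:7)
  segs <- segments_from_path(path, p)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$n_bins, c(3, 3, 2))
  expect_equal(segs$state, c(2L, 1L, 2L))
  expect_equal(segs$mean_log2[2], -0.2)
  # all-neutral path: one segment per chromosome
  gt <- toy_genome(lengths = c(3e6, 3e6, 3e6))
  gridt <- build_bin_grid(gt, 1e6)
  pt <- make_profile(gridt, rep(0, 9))
  patht <- structure(rep(2L, 9), ordinals = 0:8)
  expect_equal(nrow(segments_from_path(patht, pt)), 3)
  # a loss run split by 2 masked bins breaks with max_gap_bins = 1
  vals2 <- c(-0.2, -0.2, NA, NA, -0.2, -0.2, 0, 0)
  p2 <- make_profile(grid, vals2)
  path2 <- structure(c(1L, 1L, 1L, 1L, 2L, 2L), ordinals = c(0:1, 4:7))
  segs2 <- segments_from_path(path2, p2, max_gap_bins = 1)
  expect_equal(sum(segs2$state == 1), 2)
  # but a single masked bin is bridged
  path3 <- structure(c(1L, 1L, 1L, 2L), ordinals = c(0, 1, 3, 4))
  p3 <- make_profile(grid, c(-0.2, -0.2, NA, -0.2, 0, 0, 0, 0))
  segs3 <- segments_from_path(path3, p3, max_gap_bins = 1)
  expect_equal(sum(segs3$state == 1), 1)
  expect_equal(segs3$n_bins[segs3$state == 1], 3)
})

test_that("threshold caller applies the printed cutoffs and probe rules", {
  g <- genome_model("1", 10e6, 5e6)
  grid <- build_bin_grid(g, 1e6)
  # 5 bins at -0.02: below the -0.015 loss cutoff -> one loss segment
  p <- make_profile(grid, c(rep(-0.02, 5), rep(0, 5)))
  segs <- threshold_call(p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, 1L)
  expect_equal(segs$n_bins, 5)
  # a 1%-depletion chromosome sits above the cutoff: log2(0.99) = -0.0145
  p2 <- make_profile(grid, rep(log2(0.99), 10))
  expect_equal(nrow(threshold_call(p2)), 0)
  # 2 qualifying bins do not satisfy the 3-probe minimum
  p3 <- make_profile(grid, c(rep(-0.5, 2), rep(0, 8)))
  expect_equal(nrow(threshold_call(p3)), 0)
  # a gap larger than the probe spacing cuts the segment
  p4 <- make_profile(grid, c(-0.5, -0.5, 0, -0.5, -0.5, 0, 0, 0, 0, 0))
  expect_equal(nrow(threshold_call(p4)), 0)  # two 2-bin runs, both short
  p5 <- make_profile(grid, c(-0.5, -0.5, -0.5, 0, -0.5, -0.5, 0, 0, 0, 0))
  segs5 <- threshold_call(p5)
  expect_equal(nrow(segs5), 1)
  expect_equal(segs5$n_bins, 3)
  # gains use the 0.035 cutoff
  p6 <- make_profile(grid, c(rep(0.04, 4), rep(0.02, 6)))
  segs6 <- threshold_call(p6)
  expect_equal(segs6$state, 3L)
  expect_equal(segs6$n_bins, 4)
  expect_error(threshold_call(p, loss_cut = 0.1), "negative")
  expect_error(threshold_call(p, gain_cut = -0.1), "positive")
})

test_that("chromosome-level calls follow the majority rule", {
  g <- genome_model("3", 10e6, 5e6)
  grid <- build_bin_grid(g, 1e6)
  p <- make_profile(grid, rep(0, 10))
  seg_loss6 <- data.frame(chromosome = "3", start_bin = 0L, end_bin = 5L,
                          state = 1L, mean_log2 = -0.2, n_bins = 6L)
  cc <- chromosome_call(seg_loss6, p, "3")
  expect_equal(cc$call, "loss")
  expect_equal(cc$supporting_bin_fraction, 0.6)
  # no aberrant segments: neutral with fraction 0
  seg_none <- seg_loss6[0, ]
  cc0 <- chromosome_call(seg_none, p, "3")
  expect_equal(cc0$call, "neutral")
  expect_equal(cc0$supporting_bin_fraction, 0)
  # a 50/50 loss-gain tie stays neutral
  segs_tie <- data.frame(chromosome = "3", start_bin = c(0L, 5L),
                         end_bin = c(4L, 9L), state = c(1L, 3L),
                         mean_log2 = c(-0.2, 0.2), n_bins = c(5L, 5L))
  expect_equal(chromosome_call(segs_tie, p, "3")$call, "neutral")
  # fully masked region is an error
  pm <- make_profile(grid, rep(NA_real_, 10))
  expect_error(chromosome_call(seg_loss6, pm, "3"), "unmasked")
})

test_that("deeper losses never flip a called loss back to neutral", {
  g <- grch37_genome()
  grid <- build_bin_grid(g, 1e6)
  full <- (grid$end_bp - grid$start_bp) == 1e6 &
    !grid$chromosome %in% c("X", "Y")
  on3 <- grid$chromosome == "3"
  depths <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  called <- sapply(depths, function(d) {
    vals <- ifelse(full, ifelse(on3 & full, log2(1 - d), 0), NA)
    p <- make_profile(grid, vals)
    fit <- hmm_call(p)
    chromosome_call(fit$segments, p, "3")$call == "loss"
  })
  expect_true(all(diff(called) >= 0))  # once called, deeper stays called
  expect_true(called[length(called)])
})

test_that("copy-neutral LOH yields no calls anywhere", {
  g <- grch37_genome()
  grid <- build_bin_grid(g, 1e6)
  # allelic imbalance without dosage change: read depth stays diploid
  cfg <- sim_config(grid, n_fragments = 25e6, tumor_fraction = 0.3,
                    profile = cnv_profile(), seed = 37)
  p <- to_log2_profile(simulate_bin_counts(cfg))
  fit <- hmm_call(p)
  for (r in c("1p", "3", "6p", "8q")) {
    expect_equal(chromosome_call(fit$segments, p, r)$call, "neutral")
  }
})
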