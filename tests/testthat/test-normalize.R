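test_that("GC correction is the identity when there is no bias", {
  g <- toy_genome(lengths = c(5e6, 4e6, 3e6))
  grid <- build_bin_grid(g, 1e6)
  bc <- binned_counts(grid, rep(100, 12), gc = seq(0.3, 0.6, length.out = 12))
  out <- gc_correct(bc)
  expect_equal(out$counts, bc$counts, tolerance = 1e-9)
  # single occupied stratum: untouched
  bc2 <- binned_counts(grid, rep(100, 12), gc = rep(0.45, 12))
  expect_equal(gc_correct(bc2)$counts, bc2$counts)
  # missing GC: warning, no-op
  bc3 <- binned_counts(grid, rep(100, 12))
  expect_warning(out3 <- gc_correct(bc3), "no GC")
  expect_equal(out3$counts, bc3$counts)
  expect_false(out3$meta$gc_corrected)
})

test_that("GC correction removes at least 90% of an exponential bias", {
  g <- grch37_genome()
  grid <- build_bin_grid(g, 1e6)
  cfg <- sim_config(grid, n_fragments = 5e6, gc_bias_strength = 0.5, seed = 13)
  bc <- simulate_bin_counts(cfg)
  full <- (grid$end_bp - grid$start_bp) == 1e6
  slope_before <- coef(lm(bc$counts[full] ~ bc$gc[full]))[2]
  corr <- gc_correct(bc)
  slope_after <- coef(lm(corr$counts[full] ~ corr$gc[full]))[2]
  expect_lt(abs(slope_after), 0.1 * abs(slope_before))
  # zero counts stay zero
  bc$counts[5] <- 0
  expect_equal(gc_correct(bc)$counts[5], 0)
})

test_that("reference scaling factor is the mean over non-zero bins", {
  gm <- mini_genome()
  grid <- build_bin_grid(gm, 1e6)
  counts <- rep(500, nrow(grid))
  # reference bins: 2q (bins 10-19 of chr2), all of chr4, 12q
  ref <- c(region_bins(grid, "2q"), region_bins(grid, "4"),
           region_bins(grid, "12q")) + 1
  counts[ref] <- 100
  counts[ref[1:2]] <- c(110, 90)
  bc <- binned_counts(grid, counts)
  expect_equal(reference_scaling_factor(bc), 100)
  # zero bins are excluded, not averaged in
  counts2 <- counts
  counts2[ref[3]] <- 0
  expect_equal(reference_scaling_factor(binned_counts(grid, counts2)), 100)
  # homogeneity of degree 1
  expect_equal(reference_scaling_factor(binned_counts(grid, counts * 7)),
               700)
  # all-zero references are an error
  counts3 <- counts
  counts3[ref] <- 0
  expect_error(reference_scaling_factor(binned_counts(grid, counts3)),
               "unusable")
})

test_that("log2 profile anchors to the reference and masks zero bins", {
  gm <- mini_genome()
  grid <- build_bin_grid(gm, 1e6)
  counts <- rep(100, nrow(grid))
  counts[1] <- 200   # one doubled bin on chr2p
  counts[2] <- 50    # one halved
  counts[3] <- 0     # one missing
  bc <- binned_counts(grid, counts)
  p <- to_log2_profile(bc, gc_correction = FALSE, mask_sex = FALSE)
  expect_equal(p$scaling_factor, 100)
  expect_equal(p$log2[1], 1)
  expect_equal(p$log2[2], -1)
  expect_true(is.na(p$log2[3]))
  expect_equal(p$mask_reason[3], "zero_count")
  expect_equal(p$log2[4], 0)
})

test_that("normalized profile is invariant under global rescaling", {
  g <- grch37_genome()
  grid <- build_bin_grid(g, 1e6)
  cfg <- sim_config(grid, n_fragments = 2e6, seed = 17)
  bc <- simulate_bin_counts(cfg)
  p1 <- to_log2_profile(bc)
  bc7 <- binned_counts(grid, bc$counts * 7, gc = bc$gc)
  p7 <- to_log2_profile(bc7)
  expect_equal(p7$log2, p1$log2, tolerance = 1e-9)
  expect_equal(p7$scaling_factor, 7 * p1$scaling_factor, tolerance = 1e-9)
})

test_that("copy-neutral references keep the baseline near zero at depth", {
  g <- grch37_genome()
  grid <- build_bin_grid(g, 1e6)
  cfg <- sim_config(grid, n_fragments = 25e6, tumor_fraction = 0.3,
                    profile = uveal_archetypes()$monosomy3_8qgain, seed = 19)
  p <- to_log2_profile(simulate_bin_counts(cfg))
  ref <- c(region_bins(grid, "2q"), region_bins(grid, "4"),
           region_bins(grid, "12q")) + 1
  expect_lt(abs(median(p$log2[ref], na.rm = TRUE)), 0.01)
  # and the planted monosomy sits at its closed-form expectation
  cfg2 <- sim_config(grid, n_fragments = 25e6, tumor_fraction = 0.5,
                     profile = cnv_profile(data.frame(region = "3",
                                                      copy_number = 1)),
                     seed = 21)
  p2 <- to_log2_profile(simulate_bin_counts(cfg2))
  on3 <- region_bins(grid, "3") + 1
  expect_lt(abs(median(p2$log2[on3], na.rm = TRUE) - log2(0.75)), 0.02)
})

test_that("an aberrant reference chromosome shifts all other ratios", {
  g <- grch37_genome()
  grid <- build_bin_grid(g, 1e6)
  gain4 <- cnv_profile(data.frame(region = "4", copy_number = 4))
  cfg <- sim_config(grid, n_fragments = 5e6, tumor_fraction = 0.5,
                    profile = gain4, gc_bias_strength = 0, seed = 23)
  p <- to_log2_profile(simulate_bin_counts(cfg))
  cfg0 <- sim_config(grid, n_fragments = 5e6, tumor_fraction = 0,
                     gc_bias_strength = 0, seed = 23)
  p0 <- to_log2_profile(simulate_bin_counts(cfg0))
  not4 <- !(p$grid$chromosome %in% c("4", "X", "Y"))
  # the chromosome-4 gain inflates the scaling factor, pushing every
  # other bin's ratio down: why the least-affected chromosomes were chosen
  expect_lt(median(p$log2[not4], na.rm = TRUE),
            median(p0$log2[not4], na.rm = TRUE) - 0.05)
})

test_that("recentering subtracts the chosen region's median", {
  gm <- mini_genome()
  grid <- build_bin_grid(gm, 1e6)
  counts <- rep(110, nrow(grid))
  counts[region_bins(grid, "12q") + 1] <- 100
  bc <- binned_counts(grid, counts)
  p <- to_log2_profile(bc, recenter = "12q", gc_correction = FALSE)
  expect_equal(median(p$log2[region_bins(grid, "12q") + 1], na.rm = TRUE), 0)
})

test_that("short terminal bins are masked by default", {
  g <- grch37_genome()
  grid <- build_bin_grid(g, 1e6)
  cfg <- sim_config(grid, n_fragments = 2e6, seed = 29)
  p <- to_log2_profile(simulate_bin_counts(cfg))
  short <- which((grid$end_bp - grid$start_bp) < 5e5 &
                   !grid$chromosome %in% c("X", "Y"))
  expect_true(all(p$mask_reason[short] == "short_bin"))
  expect_true(all(is.na(p$log2[short])))
})
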