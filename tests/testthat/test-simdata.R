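test_that("cnv_profile rejects redundant and overlapping events", {
  expect_error(cnv_profile(data.frame(region = "3", copy_number = 2)),
               "redundant")
  expect_error(cnv_profile(data.frame(region = c("3", "3q"),
                                      copy_number = c(1, 3))),
               "overlapping")
  expect_error(cnv_profile(data.frame(region = "3", copy_number = -1)),
               "non-negative")
  p <- cnv_profile(data.frame(region = c("3p", "3q"), copy_number = c(1, 1)))
  expect_equal(nrow(p$events), 2)
})

test_that("uveal archetypes encode the recurrent karyotypes", {
  a <- uveal_archetypes()
  expect_equal(nrow(a$neutral$events), 0)
  expect_setequal(a$fig4_metastatic$events$region,
                  c("1p", "3", "5q", "10p", "1q", "8q"))
  losses <- a$fig4_metastatic$events
  expect_true(all(losses$copy_number[losses$region %in%
                                       c("1p", "3", "5q", "10p")] == 1))
  expect_true(all(losses$copy_number[losses$region %in% c("1q", "8q")] == 3))
  m38 <- a$monosomy3_8qgain$events
  expect_equal(nrow(m38), 2)
  expect_equal(m38$copy_number[m38$region == "3"], 1)
  expect_equal(m38$copy_number[m38$region == "8q"], 3)
})

test_that("expected bin weights follow the admixture formula", {
  g <- toy_genome(lengths = c(5e6, 4e6, 3e6))  # full-width bins only
  grid <- build_bin_grid(g, 1e6)
  # background only, no GC bias: uniform over equal-width bins
  cfg <- sim_config(grid, n_fragments = 1000, tumor_fraction = 0,
                    gc_bias_strength = 0, seed = 1)
  w <- expected_bin_weights(cfg)$weights
  expect_equal(w, rep(1 / 12, 12))
  # f = 0.5 monosomy 3: chr3 factor (0.5*2 + 0.5*1)/2 = 0.75
  cfg2 <- sim_config(grid, tumor_fraction = 0.5, gc_bias_strength = 0,
                     profile = cnv_profile(data.frame(region = "3",
                                                      copy_number = 1)),
                     seed = 1)
  w2 <- expected_bin_weights(cfg2)$weights
  on3 <- grid$chromosome == "3"
  expect_equal(unique(round(w2[on3] / w2[!on3][1], 10)), 0.75)
  # pure tumor with copy 4: factor 2 relative to diploid bins
  cfg3 <- sim_config(grid, tumor_fraction = 1, gc_bias_strength = 0,
                     profile = cnv_profile(data.frame(region = "3",
                                                      copy_number = 4)),
                     seed = 1)
  w3 <- expected_bin_weights(cfg3)$weights
  expect_equal(unique(round(w3[on3] / w3[!on3][1], 10)), 2)
  # a neutral profile at f = 0.5 equals the diploid weights
  cfg4 <- sim_config(grid, tumor_fraction = 0.5, gc_bias_strength = 0,
                     seed = 1)
  expect_equal(expected_bin_weights(cfg4)$weights, w)
})

test_that("simulated counts are seeded, conserved and carry the signal", {
  g <- toy_genome(lengths = c(5e6, 4e6, 3e6))
  grid <- build_bin_grid(g, 1e6)
  cfg <- sim_config(grid, n_fragments = 1000, gc_bias_strength = 0, seed = 42)
  c1 <- simulate_bin_counts(cfg)
  c2 <- simulate_bin_counts(cfg)
  expect_identical(c1$counts, c2$counts)
  expect_equal(sum(c1$counts), 1000)  # multinomial conservation
  # planted monosomy 3 at f = 0.5: regional depletion to 0.75 within 3 SE
  gg <- grch37_genome()
  gridg <- build_bin_grid(gg, 1e6)
  cfg2 <- sim_config(gridg, n_fragments = 5e6, tumor_fraction = 0.5,
                     gc_bias_strength = 0,
                     profile = cnv_profile(data.frame(region = "3",
                                                      copy_number = 1)),
                     seed = 7)
  bc <- simulate_bin_counts(cfg2)
  on3 <- gridg$chromosome == "3" & (gridg$end_bp - gridg$start_bp) == 1e6
  dip <- gridg$chromosome %in% c("4", "5") &
    (gridg$end_bp - gridg$start_bp) == 1e6
  ratio <- mean(bc$counts[on3]) / mean(bc$counts[dip])
  se <- sqrt(1 / sum(bc$counts[on3]) + 1 / sum(bc$counts[dip])) * ratio
  expect_lt(abs(ratio - 0.75), 3 * se)
})

test_that("overdispersed counts remain seeded and roughly conserved", {
  g <- toy_genome(lengths = c(5e6, 4e6, 3e6))
  grid <- build_bin_grid(g, 1e6)
  cfg <- sim_config(grid, n_fragments = 1e5, overdispersion = 0.2,
                    gc_bias_strength = 0, seed = 3)
  c1 <- simulate_bin_counts(cfg)
  expect_identical(c1$counts, simulate_bin_counts(cfg)$counts)
  # gamma-mixed Poisson: total close to n but not exactly conserved
  expect_gt(sum(c1$counts), 0.5 * 1e5)
  v <- var(c1$counts)
  m <- mean(c1$counts)
  expect_gt(v / m, 2)  # clearly super-Poisson at this dispersion
})

test_that("loss depletion is monotone in tumor fraction", {
  g <- toy_genome(lengths = c(5e6, 4e6, 3e6))
  grid <- build_bin_grid(g, 1e6)
  prof <- cnv_profile(data.frame(region = "3", copy_number = 1))
  fs <- seq(0, 1, by = 0.2)
  w3 <- sapply(fs, function(f) {
    cfg <- sim_config(grid, tumor_fraction = f, profile = prof,
                      gc_bias_strength = 0, seed = 1)
    sum(expected_bin_weights(cfg)$weights[grid$chromosome == "3"])
  })
  expect_true(all(diff(w3) < 0))
  gain <- cnv_profile(data.frame(region = "2", copy_number = 3))
  w2 <- sapply(fs, function(f) {
    cfg <- sim_config(grid, tumor_fraction = f, profile = gain,
                      gc_bias_strength = 0, seed = 1)
    sum(expected_bin_weights(cfg)$weights[grid$chromosome == "2"])
  })
  expect_true(all(diff(w2) > 0))
})

test_that("simulated fragments follow the configured length mixture", {
  g <- toy_genome(lengths = c(5e6, 4e6, 3e6))
  grid <- build_bin_grid(g, 1e6)
  # background only: empirical mean matches the truncated-normal mean
  cfg <- sim_config(grid, n_fragments = 20000, tumor_fraction = 0,
                    gc_bias_strength = 0, fraglen_background = c(167, 40),
                    seed = 5)
  fr <- simulate_fragments(cfg)
  expect_equal(nrow(fr), 20000)
  mu <- truncnorm_mean(167, 40, 50, 400)
  se <- 40 / sqrt(20000)
  expect_lt(abs(mean(fr$insert_size) - mu), 3 * se)
  expect_true(all(fr$start >= 0))
  len <- g$length_bp[match(fr$chromosome, g$chromosome)]
  expect_true(all(fr$start + fr$insert_size <= len))
  # tumor fragments are enriched in the 80-150 window, as the component
  # masses computed from the normal CDF predict
  cfg2 <- sim_config(grid, n_fragments = 30000, tumor_fraction = 0.3,
                     gc_bias_strength = 0,
                     fraglen_tumor = c(120, 15),
                     fraglen_background = c(167, 20), seed = 6)
  fr2 <- simulate_fragments(cfg2)
  in_win <- fr2$insert_size >= 80 & fr2$insert_size <= 150
  p_tumor <- mean(in_win[fr2$origin == "tumor"])
  p_bg <- mean(in_win[fr2$origin == "background"])
  expect_gt(p_tumor, p_bg)
  expect_gt(truncnorm_mass(120, 15, 50, 400, 80, 150),
            truncnorm_mass(167, 20, 50, 400, 80, 150))
  # and the empirical masses agree with the CDF computation
  expect_lt(abs(p_tumor - truncnorm_mass(120, 15, 50, 400, 79.5, 150.5)),
            0.02)
  expect_lt(abs(p_bg - truncnorm_mass(167, 20, 50, 400, 79.5, 150.5)),
            0.02)
})

test_that("sim_config validates its invariants", {
  g <- toy_genome()
  grid <- build_bin_grid(g, 1e6)
  expect_error(sim_config(grid, n_fragments = 0), "positive")
  expect_error(sim_config(grid, tumor_fraction = 1.2), "0, 1")
  expect_error(sim_config(grid, overdispersion = -1), "non-negative")
})
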