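test_that("strain effects honor zero variance, determinism and PSD checks", {
  cfg <- tiny_config(context_sds = c(0, 0, 0, 0))
  p <- draw_strain_effects(cfg, 5L)
  expect_true(all(p$a == 0))

  cfg2 <- tiny_config()
  expect_identical(draw_strain_effects(cfg2, 7L), draw_strain_effects(cfg2, 7L))

  bad <- cfg2
  bad$context_corr[1, 2] <- bad$context_corr[2, 1] <- 1.5
  expect_error(draw_strain_effects(bad, 1L), "positive semi-definite")
})

test_that("independent contexts give near-zero sample correlations at large n", {
  cfg <- sim_config(n_blocks = 500, context_corr = diag(4), seed = 3L)
  p <- draw_strain_effects(cfg, 11L) # 2000 strains
  cc <- cor(p$a)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("noncompetitive trials censor, order by effect size and bookkeep", {
  # baseline far beyond the censor: every trial unmated, latency empty
  cfg <- tiny_config(baseline_latency = c(virgin = 1e8, nonvirgin = 1e8),
                     latency_log_sd = 0.1)
  p <- draw_strain_effects(cfg, 2L)
  tr <- simulate_noncompetitive(p, cfg, 3L)
  expect_false(any(tr$mated))
  expect_true(all(is.na(tr$latency_min)))

  # row count = blocks x 16 pairs x 2 statuses x trials per cell
  cfg2 <- tiny_config(n_noncomp_trials_per_cell = c(virgin = 3, nonvirgin = 2))
  tr2 <- simulate_noncompetitive(draw_strain_effects(cfg2, 1L), cfg2, 2L)
  expect_equal(nrow(tr2), 2 * 16 * (3 + 2))
  # every male-by-female pair of a block is run at the per-status count
  cells <- dplyr::count(tr2, block, male_strain, female_strain,
                        female_status)
  expect_equal(nrow(cells), 2 * 16 * 2)
  expect_true(all(cells$n[cells$female_status == "virgin"] == 3))
  expect_true(all(cells$n[cells$female_status == "nonvirgin"] == 2))

  # a strain at +2 sigma must out-mate one at -2 sigma
  cfg3 <- sim_config(n_blocks = 1, n_noncomp_trials_per_cell = 80, seed = 4L)
  p3 <- draw_strain_effects(cfg3, 4L)
  p3$a[, ] <- 0
  p3$a["S01", ] <- 2 * cfg3$context_sds
  p3$a["S02", ] <- -2 * cfg3$context_sds
  tr3 <- simulate_noncompetitive(p3, cfg3, 5L)
  rate <- tapply(tr3$mated, tr3$male_strain, mean)
  expect_gt(rate[["S01"]], rate[["S02"]])
})

test_that("competitive vials are symmetric under equal effects and track winners", {
  # equal effects: each strain wins about a quarter of the mated vials
  cfg <- sim_config(n_blocks = 1, context_sds = rep(0, 4),
                    female_strain_sd = 0,
                    color_effects = c(black = 0, blue = 0, green = 0, red = 0),
                    n_comp_vials_per_cell = c(virgin = 700, nonvirgin = 0),
                    seed = 6L)
  p <- draw_strain_effects(cfg, 6L)
  cv <- simulate_competitive(p, cfg, 7L)
  mated <- cv[cv$mated, ]
  shares <- prop.table(table(mated$winner_strain))
  expect_equal(length(shares), 4)
  expect_lt(max(abs(shares - 0.25)), 0.03)

  # winner is always one of the vial's four males
  ms <- as.matrix(mated[paste0("male_strain_", 1:4)])
  expect_true(all(rowSums(ms == mated$winner_strain) == 1))

  # an overwhelmingly advantaged strain wins essentially always
  p2 <- p
  p2$a["S01", ] <- 10
  cv2 <- simulate_competitive(p2, cfg, 8L)
  expect_gt(mean(cv2$winner_strain[cv2$mated] == "S01"), 0.99)

  # fewer than 4 strains per block is rejected
  cfg3 <- tiny_config(strains_per_block = 3)
  expect_error(simulate_competitive(draw_strain_effects(cfg3, 1L), cfg3, 1L),
               "4 strains")
})

test_that("fitness records are null-symmetric without planted effects", {
  cfg <- sim_config(n_blocks = 5, n_fitness_reps = 7,
                    inbreeding_effect = 0, mf_interaction_sd = 0,
                    fitness_resid_sd = 0, wt_advantage = 0,
                    block_effects = rep(0, 5), seed = 8L)
  p <- draw_strain_effects(cfg, 8L)
  fr <- simulate_fitness(p, cfg, 9L)
  # 5 blocks x (12 between x 7 + 4 within x 14) x 2 sexes
  expect_equal(nrow(fr), 5 * (12 * 7 + 4 * 14) * 2)
  # equal Poisson rates: mean score ~ 0 and within ~ between
  expect_lt(abs(mean(fr$w)), 0.03)
  expect_lt(abs(mean(fr$w[fr$cross == "within"]) -
                  mean(fr$w[fr$cross == "between"])), 0.05)
  # within-strain crosses carry double replication
  tab <- table(fr$cross) / c(12 * 2 * 5, 4 * 2 * 5)
  expect_equal(unname(tab[["within"]] / tab[["between"]]), 2)

  expect_identical(simulate_fitness(p, cfg, 9L), fr)

  bad <- cfg
  bad$mean_offspring <- -1
  expect_error(simulate_fitness(p, bad, 1L), "non-negative")
})

test_that("viability vials respect binomial support and zero-inflation", {
  cfg <- tiny_config(viability_rate = 1, unfertilized_rate = 0,
                     viab_resid_sd = 0, viab_f_strain_sd = 0,
                     viab_inbreeding = 0)
  p <- draw_strain_effects(cfg, 3L)
  vr <- simulate_viability(p, cfg, 4L)
  expect_true(all(vr$adults == vr$eggs))

  cfg2 <- sim_config(n_blocks = 5, n_viability_reps = 50,
                     zero_egg_rate = 0.4, seed = 10L)
  p2 <- draw_strain_effects(cfg2, 10L)
  vr2 <- simulate_viability(p2, cfg2, 11L)
  expect_equal(nrow(vr2), 5 * (12 * 50 + 4 * 100)) # 5,000 vials
  expect_lt(abs(mean(vr2$eggs == 0) - 0.4), 0.02)
  expect_true(all(vr2$adults <= vr2$eggs))

  bad <- cfg
  bad$viability_rate <- 1.5
  expect_error(simulate_viability(p, bad, 1L), "\\[0, 1\\]")
})

test_that("morphology wings reproduce the mean geometry and plant outliers", {
  cfg <- tiny_config(n_wings_per_strain = 25)
  p <- draw_strain_effects(cfg, 12L)
  mo <- simulate_morphology(p, cfg, 13L)
  expect_equal(nrow(mo$landmarks), 8 * 25 * 9)
  wl <- wing_length(mo$landmarks)
  true_len <- sqrt(sum((cfg$landmark_mean_shape[9, ] -
                          cfg$landmark_mean_shape[3, ])^2))
  expect_lt(abs(mean(wl$wing_length_mm) - true_len), 0.05)

  # zero noise: all wings of a strain identical after alignment
  cfg0 <- tiny_config(landmark_noise_sd = 0, strain_shape_sd = 0,
                      strain_size_sd = 0, wing_size_sd = 0, outlier_rate = 0,
                      n_wings_per_strain = 5)
  mo0 <- simulate_morphology(draw_strain_effects(cfg0, 1L), cfg0, 2L)
  sp0 <- gpa_align(mo0$landmarks)
  spread <- apply(sp0$aligned, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)

  bad <- cfg
  bad$landmark_mean_shape <- matrix(0, 5, 2)
  expect_error(simulate_morphology(p, bad, 1L), "9 x 2")
})

test_that("a full study is a deterministic function of its config", {
  cfg <- tiny_config()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$noncompetitive, s2$noncompetitive)
  expect_identical(s1$competitive, s2$competitive)
  expect_identical(s1$morphology, s2$morphology)
  expect_identical(s1$true_params$a, s2$true_params$a)
  # all 32 strain-by-status cells of each block are covered
  nc <- s1$noncompetitive
  cells <- dplyr::distinct(nc, block, male_strain, female_strain,
                           female_status)
  expect_equal(nrow(cells), 2 * 16 * 2)
  expect_true(all(!duplicated(s1$competitive$vial)))
})
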