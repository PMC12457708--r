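test_that("the Polya-Gamma draw matches its closed-form mean", {
  # E[PG(1, z)] = tanh(z/2) / (2 z), = 1/4 at z = 0
  withr::with_seed(17, {
    for (z in c(0, 1, 3)) {
      x <- matevar:::rpg1_vec(rep(z, 50000))
      ev <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
      expect_lt(abs(mean(x) - ev), 0.003)
      expect_true(all(x > 0))
    }
  })
})

test_that("mode and HDCI match closed-form normal quantiles", {
  withr::with_seed(2, x <- rnorm(1e6))
  s <- mode_hdci(x, mass = 0.95)
  expect_lt(abs(s$mode), 0.02)
  expect_lt(abs(s$.lower + 1.96), 0.02)
  expect_lt(abs(s$.upper - 1.96), 0.02)

  # degenerate sample: a point mass
  s0 <- mode_hdci(rep(3.5, 10))
  expect_equal(c(s0$mode, s0$.lower, s0$.upper), c(3.5, 3.5, 3.5))

  # right-skewed sample: mode below the mean
  withr::with_seed(29, y <- exp(rnorm(20000)))
  sy <- mode_hdci(y, lower_bound = 0)
  expect_lt(sy$mode, mean(y))

  expect_error(mode_hdci(x, mass = 1.2), "mass")
  expect_warning(mode_hdci(rnorm(50)), "fewer than 100")
})

test_that("interval-versus-zero testing uses strict exclusion", {
  mk <- function(lo, hi) tibble::tibble(.lower = lo, .upper = hi)
  expect_true(test_correlation_vs_zero(mk(0.17, 0.99)))
  expect_false(test_correlation_vs_zero(mk(-0.63, 0.93)))
  expect_false(test_correlation_vs_zero(mk(0, 0.5)))
  expect_true(test_correlation_vs_zero(mk(-0.9, -0.2)))
})

test_that("strain-mean correlations behave at the extremes", {
  a <- make_binary(setNames(c(0.1, 0.3, 0.5, 0.7), LETTERS[1:4]), 40)
  expect_equal(strain_mean_correlation(a, a), 1)
  # construct success columns whose strain means are exactly mirrored
  b <- a
  b$success <- 1L - a$success
  expect_equal(strain_mean_correlation(a, b), -1)
  expect_error(strain_mean_correlation(a[a$male_strain == "A", ], a),
               "3 shared strains")
})

test_that("model fitting validates its inputs", {
  dat <- make_binary(setNames(rep(0.3, 4), LETTERS[1:4]), 10)
  bad <- dat
  bad$success[1] <- 2L
  expect_error(fit_choice_model(bad, quick_spec()), "binary")
  solo <- dat[dat$male_strain == "A", ]
  expect_error(fit_choice_model(solo, quick_spec()), "single male strain")
  off <- dat
  off$context <- "V?C?"
  expect_error(fit_choice_model(off, quick_spec()), "context")
})

test_that("complete separation is tolerated with a warning", {
  dat <- make_binary(setNames(c(0.5, 0.5, 0.5, 1), LETTERS[1:4]), 12,
                     seed = 19)
  dat$success[dat$male_strain == "D"] <- 1L
  expect_warning(fit_choice_model(dat, quick_spec(iter = 300)), "separation")
})

test_that("posterior pooling concatenates draws and is order-invariant", {
  dat <- make_binary(setNames(c(0.2, 0.35, 0.3, 0.4), LETTERS[1:4]), 15,
                     seed = 5)
  f1 <- suppressWarnings(fit_choice_model(dat, quick_spec(iter = 300, seed = 1)))
  f2 <- suppressWarnings(fit_choice_model(dat, quick_spec(iter = 300, seed = 2)))
  pooled <- pool_posteriors(list(f1, f2))
  expect_equal(nrow(pooled$draws), nrow(f1$draws) + nrow(f2$draws))
  expect_equal(sort(unique(pooled$draws$.resample)), 1:2)

  # pooling copies of one fit leaves inference unchanged: intervals are
  # exactly reproduced (they depend only on the empirical distribution)
  # and modes up to the bandwidth's mild draw-count dependence
  same <- pool_posteriors(list(f1, f1, f1))
  t_same <- tidy(same, check_rhat = FALSE)
  t_f1 <- tidy(f1, check_rhat = FALSE)
  expect_equal(t_same$.lower, t_f1$.lower)
  expect_equal(t_same$.upper, t_f1$.upper)
  expect_equal(t_same$mode, t_f1$mode, tolerance = 0.1)

  # order invariance of pooled summaries
  p12 <- tidy(pool_posteriors(list(f1, f2)), check_rhat = FALSE)
  p21 <- tidy(pool_posteriors(list(f2, f1)), check_rhat = FALSE)
  expect_equal(p12$mode, p21$mode, tolerance = 1e-12)

  f_other <- suppressWarnings(fit_choice_model(
    dplyr::mutate(dat, male_strain = paste0(male_strain, "x")),
    quick_spec(iter = 300)))
  expect_error(pool_posteriors(list(f1, f_other)), "differing parameter")
})

test_that("sampling is reproducible and every correlation draw is valid", {
  cfg <- tiny_config(n_noncomp_trials_per_cell = 8, n_comp_vials_per_cell = 8)
  study <- simulate_study(cfg)
  nc_bin <- binarize_latency(study$noncompetitive)
  vials <- dplyr::filter(study$competitive, mated & !is.na(winner_strain))
  dat <- dplyr::bind_rows(nc_bin, resample_competitive(vials, 3L))
  fit1 <- suppressWarnings(fit_choice_model(dat, quick_spec(iter = 400)))
  fit2 <- suppressWarnings(fit_choice_model(dat, quick_spec(iter = 400)))
  expect_equal(fit1$draws, fit2$draws)

  # reconstruct each draw's R and check positive semi-definiteness
  rn <- fit1$parameters[grepl("^R\\[", fit1$parameters)]
  expect_length(rn, 6)
  idx <- utils::combn(4, 2)
  sub <- fit1$draws[seq(1, nrow(fit1$draws), by = 7), rn]
  ok <- apply(as.matrix(sub), 1, function(r) {
    R <- diag(4)
    R[t(idx)] <- r[c(1, 2, 4, 3, 5, 6)]
    R[t(idx[2:1, ])] <- R[t(idx)]
    min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -1e-8
  })
  expect_true(all(ok))

  # the convergence gate refuses to summarize bad chains unless overridden
  fit_bad <- fit1
  fit_bad$rhat["sigma[V+C+]"] <- 1.3
  expect_error(tidy(fit_bad), "R-hat")
  expect_s3_class(tidy(fit_bad, check_rhat = FALSE), "tbl_df")
})

test_that("draw bookkeeping matches the chains-by-iterations convention", {
  expect_equal(retained_draws(4, 20000, 0.5, 10), 4000)
  expect_equal(retained_draws(2, 600, 0.5, 2), 300)
  fit <- suppressWarnings(fit_choice_model(
    make_binary(setNames(rep(0.3, 4), LETTERS[1:4]), 10, seed = 2),
    quick_spec(chains = 2, iter = 600, thin = 2)))
  expect_equal(nrow(fit$draws), retained_draws(2, 600, 0.5, 2))
})

test_that("relabeling contexts permutes the estimated SDs", {
  # moderately informative single-strain-effect data in two contexts with
  # different true variances; swapping the labels must swap the estimates
  p <- setNames(plogis(qlogis(0.3) + c(-0.8, -0.3, 0.3, 0.8)), LETTERS[1:4])
  d_hi <- make_binary(p, 60, context = "V+C-", seed = 7)
  d_lo <- make_binary(setNames(rep(0.3, 4), LETTERS[1:4]), 60,
                      context = "V-C-", seed = 8)
  dat <- dplyr::bind_rows(d_hi, d_lo)
  swapped <- dat
  swapped$context <- ifelse(dat$context == "V+C-", "V-C-", "V+C-")
  f1 <- suppressWarnings(fit_choice_model(dat, quick_spec(iter = 1200, seed = 3)))
  f2 <- suppressWarnings(fit_choice_model(swapped, quick_spec(iter = 1200, seed = 3)))
  s1 <- tidy(f1, check_rhat = FALSE)
  s2 <- tidy(f2, check_rhat = FALSE)
  m1 <- setNames(s1$mode, s1$parameter)
  m2 <- setNames(s2$mode, s2$parameter)
  expect_lt(abs(m1[["sigma[V+C-]"]] - m2[["sigma[V-C-]"]]), 0.2)
  expect_lt(abs(m1[["sigma[V-C-]"]] - m2[["sigma[V+C-]"]]), 0.2)
  # and the high-variance context is correctly identified in both fits
  expect_gt(m1[["sigma[V+C-]"]], m1[["sigma[V-C-]"]])
  expect_gt(m2[["sigma[V-C-]"]], m2[["sigma[V+C-]"]])
})
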