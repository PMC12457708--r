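test_that("log-ratio scores evaluate, bound and reject correctly", {
  expect_equal(fitness_score(0, 0), 0)
  expect_equal(fitness_score(99, 49), log(2))
  expect_error(fitness_score(-1, 3), "non-negative")

  # antisymmetry and monotonicity over a grid of counts
  grid <- expand.grid(a = c(0, 1, 5, 40, 200), b = c(0, 2, 7, 33, 150))
  expect_equal(fitness_score(grid$a, grid$b), -fitness_score(grid$b, grid$a))
  w <- fitness_score(grid$a, grid$b)
  expect_true(all(fitness_score(grid$a + 1, grid$b) > w))
  expect_true(all(fitness_score(grid$a, grid$b + 1) < w))

  expect_equal(viability_score(10, 10), log(11))
  a <- c(1, 4, 9)
  expect_equal(viability_score(2 * a, a), rep(0, 3))
  expect_error(viability_score(3, 4), "exceed")
})

test_that("viability filtering removes zero-egg then zero-adult rows", {
  toy <- tibble::tibble(eggs = c(0L, 3L, 4L, 0L, 2L),
                        adults = c(0L, 0L, 2L, 0L, 1L))
  f <- filter_viability(toy)
  expect_equal(nrow(f$records), 2)
  expect_equal(f$n_zero_egg, 2)
  expect_equal(f$n_zero_adult, 1)
  expect_equal(f$records$eggs, c(4L, 2L))

  clean <- tibble::tibble(eggs = c(3L, 5L), adults = c(1L, 5L))
  f2 <- filter_viability(clean)
  expect_equal(f2$records, clean)
  expect_equal(f2$n_zero_egg + f2$n_zero_adult, 0)

  f3 <- filter_viability(toy[0, ])
  expect_equal(nrow(f3$records), 0)
  expect_equal(f3$n_zero_egg, 0)
})

sim_cross_scores <- function(seed, mf_sd = 0, strain_sd = 0, resid_sd = 1,
                             inbreeding = 0, reps = 10, n_blocks = 5) {
  withr::with_seed(seed, {
    grid <- purrr::map_dfr(seq_len(n_blocks), function(b) {
      ss <- sprintf("S%02d", (b - 1) * 4 + 1:4)
      tidyr::expand_grid(block = b, m_strain = ss, f_strain = ss,
                         rep = seq_len(reps))
    })
    u <- rnorm(n_blocks * 16, sd = mf_sd)
    names(u) <- with(dplyr::distinct(grid, m_strain, f_strain),
                     paste(m_strain, f_strain))
    me <- rnorm(n_blocks * 4, sd = strain_sd)
    names(me) <- sprintf("S%02d", seq_len(n_blocks * 4))
    grid$cross <- ifelse(grid$m_strain == grid$f_strain, "within", "between")
    grid$w <- u[paste(grid$m_strain, grid$f_strain)] + me[grid$m_strain] +
      ifelse(grid$cross == "within", -inbreeding, 0) +
      rnorm(nrow(grid), sd = resid_sd)
    grid
  })
}

test_that("the mixed model recovers a planted interaction variance", {
  ests <- vapply(1:15, function(i) {
    # interaction variance 0.3^2 = 0.09 on the score scale
    d <- sim_cross_scores(100 + i, mf_sd = 0.3, resid_sd = 1)
    fit <- fit_cross_lmm(d, "w")
    fit$variances$variance[fit$variances$term == "m_strain:f_strain"]
  }, numeric(1))
  expect_gte(mean(ests >= 0.04 & ests <= 0.16), 0.8)
})

test_that("a null simulation yields near-zero strain variances and flat LRTs", {
  d <- sim_cross_scores(7, mf_sd = 0, strain_sd = 0, resid_sd = 1)
  fit <- fit_cross_lmm(d, "w")
  strain_vars <- fit$variances$variance[fit$variances$term != "Residual"]
  expect_true(all(strain_vars < 0.02))
  expect_true(all(fit$lrt$p_value > 0.3))
  # variances are never negative and residual variance is recovered
  expect_true(all(fit$variances$variance >= 0))
  expect_lt(abs(fit$variances$variance[fit$variances$term == "Residual"] - 1),
            0.15)
})

test_that("the cross contrast recovers the planted inbreeding deficit", {
  d <- sim_cross_scores(21, resid_sd = 0.8, inbreeding = 0.6, reps = 12)
  fit <- fit_cross_lmm(d, "w")
  emm <- fit$emm
  contrast <- emm$emmean[emm$level == "between"] -
    emm$emmean[emm$level == "within"]
  se <- sqrt(sum(emm$se^2))
  expect_lt(abs(contrast - 0.6), 3 * se)
  # and the Wald table tests block and cross
  expect_setequal(fit$wald$term, c("block", "cross"))
})

test_that("marginal means reduce to group means in balanced designs", {
  withr::with_seed(3, {
    d <- tidyr::expand_grid(g = c("a", "b"), h = c("x", "y"),
                            rep = 1:6)
    d$y <- rnorm(nrow(d)) + ifelse(d$g == "a", 1, 0)
  })
  fit <- stats::lm(y ~ g + h, data = d)
  mm <- marginal_means(fit, "g")
  expect_equal(mm$emmean, as.numeric(tapply(d$y, d$g, mean)),
               tolerance = 1e-8)
})

test_that("marginal means equal the equal-weight average of cell predictions", {
  # unbalanced two-factor toy: the emm for each level of g must match the
  # plain average of that level's predicted cell means over h
  withr::with_seed(9, {
    d <- tibble::tibble(
      g = c("a", "a", "a", "a", "b", "b", "b"),
      h = c("x", "x", "x", "y", "x", "y", "y"),
      y = c(1.2, 0.8, 1.1, 2.5, -0.3, 0.9, 1.4))
  })
  fit <- stats::lm(y ~ g + h, data = d)
  grid <- tidyr::expand_grid(g = c("a", "b"), h = c("x", "y"))
  grid$pred <- predict(fit, newdata = grid)
  oracle <- tapply(grid$pred, grid$g, mean)
  mm <- marginal_means(fit, "g")
  expect_equal(mm$emmean, as.numeric(oracle[mm$level]), tolerance = 1e-8)
})

test_that("marginal-mean standard errors shrink like one over root n", {
  se_at <- function(reps) {
    d <- sim_cross_scores(5, resid_sd = 1, reps = reps)
    fit <- fit_cross_lmm(d, "w")
    mean(fit$emm$se)
  }
  ratio <- se_at(4) / se_at(16)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("residual outlier filtering removes exactly the planted row", {
  d <- sim_cross_scores(11, resid_sd = 0.5)
  fit <- fit_cross_lmm(d, "w")
  res <- residuals(fit$model)
  # no gross outliers: nothing is removed at a generous multiplier
  f0 <- residual_outlier_filter(d, fit$model, k = 8)
  expect_equal(f0$n_removed, 0)
  # k = Inf is the identity
  fI <- residual_outlier_filter(d, fit$model, k = Inf)
  expect_equal(nrow(fI$records), nrow(d))

  # plant one wild residual and refit: that row alone is dropped
  d2 <- d
  d2$w[37] <- d2$w[37] + 10 * IQR(res)
  fit2 <- fit_cross_lmm(d2, "w")
  f2 <- residual_outlier_filter(d2, fit2$model, k = 2)
  expect_gte(f2$n_removed, 1)
  expect_false(d2$w[37] %in% f2$records$w)
})

test_that("model contracts are enforced", {
  d <- sim_cross_scores(2)
  expect_error(fit_cross_lmm(dplyr::filter(d, cross == "between"), "w"),
               "cross levels")
  expect_error(fit_cross_lmm(d[, -2], "w"), "missing")
})
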