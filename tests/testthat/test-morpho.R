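base_wing <- function() default_wing_shape()

test_that("centroid size matches the hand value for a unit square", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
})

test_that("alignment is invariant to rigid motion and scale, and idempotent", {
  shp <- base_wing()
  withr::with_seed(5, {
    copies <- lapply(1:12, function(i) {
      s <- runif(1, 0.3, 3)
      th <- runif(1, 0, 2 * pi)
      (shp %*% rot2(th)) * s +
        matrix(runif(2, -5, 5), 9, 2, byrow = TRUE)
    })
  })
  lm <- wings_from_coords(copies)
  sp <- gpa_align(lm)
  expect_true(sp$converged)
  # all aligned configurations coincide
  spread <- apply(sp$aligned, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
  # centroid sizes reflect the applied scales, unit size after alignment
  expect_equal(unname(apply(sp$aligned, 1, function(v)
    centroid_size(matrix(v, ncol = 2, byrow = TRUE)))),
    rep(1, 12), tolerance = 1e-8)

  # idempotence: re-aligning the aligned output is a no-op
  lm2 <- purrr::map_dfr(seq_len(nrow(sp$aligned)), function(i) {
    co <- matrix(sp$aligned[i, ], ncol = 2, byrow = TRUE)
    tibble::tibble(wing_id = paste0("r", i), landmark = 1:9,
                   x = co[, 1], y = co[, 2])
  })
  sp2 <- gpa_align(lm2)
  expect_lt(max(abs(sp2$aligned - sp$aligned)), 1e-6)
})

test_that("alignment preserves inter-configuration Procrustes distances", {
  withr::with_seed(11, {
    wigs <- lapply(1:8, function(i)
      base_wing() + matrix(rnorm(18, sd = 0.02), 9, 2))
  })
  sp_raw <- gpa_align(wings_from_coords(wigs))
  # apply one common rigid motion + scale to every raw configuration
  moved <- lapply(wigs, function(co)
    (co %*% rot2(1.1)) * 2.7 + matrix(c(3, -4), 9, 2, byrow = TRUE))
  sp_mov <- gpa_align(wings_from_coords(moved))
  expect_lt(max(abs(dist(sp_raw$aligned) - dist(sp_mov$aligned))), 1e-6)
})

test_that("degenerate configurations are rejected", {
  flat <- wings_from_coords(list(matrix(1, 9, 2), matrix(1, 9, 2)))
  expect_error(gpa_align(flat), "degenerate")
  one <- wings_from_coords(list(base_wing()))
  expect_error(gpa_align(one), "at least two")
})

make_shape_sample <- function(n = 60, noise = 0.01, seed = 21) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- runif(1, 0.8, 1.2)
      th <- runif(1, 0, 2 * pi)
      ((base_wing() + matrix(rnorm(18, sd = noise), 9, 2)) %*% rot2(th)) * s
    })
  })
}

test_that("nine-landmark shape spaces have exactly fourteen nonzero PCs", {
  sp <- shape_pca(gpa_align(wings_from_coords(make_shape_sample())))
  expect_equal(sp$n_nonzero, 2 * 9 - 4)
  # trace conservation: eigenvalues sum to the total aligned variance
  total_var <- sum(apply(sp$aligned, 2, var))
  expect_equal(sum(sp$eigenvalues), total_var, tolerance = 1e-10)
  # scores are centered
  sc <- as.matrix(sp$scores[paste0("PC", 1:14)])
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  # full reconstruction from all PCs
  recon <- sc %*% t(sp$loadings[, 1:14]) +
    matrix(colMeans(sp$aligned), nrow(sc), 18, byrow = TRUE)
  expect_lt(max(abs(recon - sp$aligned)), 1e-8)
})

test_that("the PC sign convention makes scores reproducible", {
  lm <- wings_from_coords(make_shape_sample())
  sp1 <- shape_pca(gpa_align(lm))
  sp2 <- shape_pca(gpa_align(lm))
  expect_identical(sp1$scores, sp2$scores)
  expect_gte(sp1$loadings["x2", "PC1"], 0)
})

test_that("Mahalanobis flags planted outliers at the chi-square threshold", {
  expect_equal(round(mahalanobis_critical(15, 0.001), 2), 37.70)

  withr::with_seed(31, {
    X <- matrix(rnorm(200 * 15), 200, 15)
  })
  X[7, ] <- X[7, ] + 20 / sqrt(15) # a 20-SD multivariate displacement
  colnames(X) <- c(paste0("PC", 1:14), "size")
  out <- mahalanobis_outliers(tibble::as_tibble(X))
  expect_true(out$.outlier[7])
  expect_equal(attr(out, "critical"), qchisq(0.999, 15))
  # a point at the sample mean is never flagged
  X2 <- rbind(X, colMeans(X))
  out2 <- mahalanobis_outliers(tibble::as_tibble(X2))
  expect_false(out2$.outlier[201])
  expect_lt(out2$.mahalanobis[201], 0.5)

  # affine rescaling of one trait leaves the flags unchanged
  X3 <- X
  X3[, 3] <- X3[, 3] * 10
  out3 <- mahalanobis_outliers(tibble::as_tibble(X3))
  expect_equal(out3$.outlier, out$.outlier)

  sing <- tibble::as_tibble(X[, 1:3])
  sing$dup <- sing$PC1
  expect_error(mahalanobis_outliers(sing), "singular")
})

test_that("wing length uses landmarks 3 and 9 with the image scale", {
  co <- base_wing()
  co[3, ] <- c(0, 0)
  co[9, ] <- c(3, 4)
  lm <- wings_from_coords(list(co))
  expect_equal(wing_length(lm)$wing_length_mm, 5)
  lm$scale <- 0.5
  expect_equal(wing_length(lm)$wing_length_mm, 2.5)
  # invariant to rigid motion of the whole configuration
  lm_rot <- wings_from_coords(list(co %*% rot2(0.7) +
                                     matrix(c(2, 1), 9, 2, byrow = TRUE)))
  expect_equal(wing_length(lm_rot)$wing_length_mm, 5, tolerance = 1e-10)
})

test_that("strain-mean regressions report marginal F tests on 1 and n-4 df", {
  withr::with_seed(41, {
    st <- tibble::tibble(
      strain = sprintf("S%02d", 1:20),
      wing_length_mm = rnorm(20, 1.5, 0.05),
      pc1 = rnorm(20, 0, 0.01),
      comb_teeth = rnorm(20, 21, 1))
    st$success <- 0.25 + 2 * (st$wing_length_mm - 1.5) + rnorm(20, 0, 0.03)
  })
  res <- strain_trait_regression(st, "success")
  expect_equal(unique(res$df2), 16L)
  expect_equal(unique(res$df1), 1L)
  # the planted wing-length signal is detected; the inert traits are not
  expect_lt(res$p_value[res$term == "wing_length_mm"], 0.01)
  expect_gt(min(res$p_value[res$term != "wing_length_mm"]), 0.01)
  # marginal F equals the squared t of the OLS fit
  fit <- stats::lm(success ~ wing_length_mm + pc1 + comb_teeth, data = st)
  expect_equal(res$statistic,
               unname(summary(fit)$coefficients[-1, "t value"]^2))
  expect_error(strain_trait_regression(st[1:4, ], "success"), "too few")
})

test_that("TPS files round-trip landmark configurations", {
  lm <- wings_from_coords(make_shape_sample(n = 3), scale = 0.01)
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(lm, path)
  back <- read_tps(path)
  expect_equal(back$x, lm$x)
  expect_equal(back$y, lm$y)
  expect_equal(back$scale, lm$scale)
  expect_equal(unique(back$wing_id), unique(lm$wing_id))
})
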