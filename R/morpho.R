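#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid — the size measure removed by the full Procrustes fit.
#'
#' @param coords A k x 2 coordinate matrix.
#' @return A scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # sqrt(2)
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  cc <- sweep(coords, 2, colMeans(coords))
  sqrt(sum(cc^2))
}

landmarks_to_array <- function(landmarks) {
  assert_columns(landmarks, c("wing_id", "landmark", "x", "y"),
                 "landmark table")
  ids <- unique(landmarks$wing_id)
  ks <- table(landmarks$wing_id)
  if (length(unique(ks)) != 1)
    abort("all wings must have the same number of landmarks")
  k <- unname(ks[1])
  lm_sorted <- dplyr::arrange(landmarks, match(.data$wing_id, ids),
                              .data$landmark)
  arr <- array(NA_real_, c(k, 2, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  arr[, 1, ] <- matrix(lm_sorted$x, k)
  arr[, 2, ] <- matrix(lm_sorted$y, k)
  arr
}

# optimal rotation Q (det +1) aligning row-config X onto M: X %*% Q
procrustes_rotation <- function(X, M) {
  C <- crossprod(X, M)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalized Procrustes alignment of wing landmark configurations
#'
#' Iterative full Procrustes superimposition: each configuration is
#' centered at its centroid, scaled to unit centroid size, and rotated onto
#' the current mean shape; the mean is then recomputed, re-normalized to
#' unit centroid size, and the cycle repeats until it stabilizes. Centroid
#' sizes are retained from before scaling. The first wing seeds the
#' reference, so the output orientation is reproducible.
#'
#' @param landmarks Long landmark tibble: `wing_id`, `landmark`, `x`, `y`,
#'   plus any metadata columns (`strain`, `vial`, `scale`) carried through.
#' @param tol Convergence threshold on the change in mean shape.
#' @param max_iter Iteration cap.
#' @return A `shape_space` object: `aligned` (wings x 2k matrix, columns
#'   `x1, y1, ...`), `info` (per-wing metadata with `centroid_size`),
#'   `mean_shape`, `iterations`, `converged`.
#' @export
gpa_align <- function(landmarks, tol = 1e-8, max_iter = 100) {
  arr <- landmarks_to_array(landmarks)
  n <- dim(arr)[3]
  k <- dim(arr)[1]
  if (n < 2) abort("need at least two wings to align")

  sizes <- numeric(n)
  for (i in seq_len(n)) {
    arr[, , i] <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
    sizes[i] <- sqrt(sum(arr[, , i]^2))
    if (sizes[i] <= 0 || !is.finite(sizes[i]))
      abort(paste0("degenerate (coincident) landmarks in wing ",
                   dimnames(arr)[[3]][i]))
    arr[, , i] <- arr[, , i] / sizes[i]
  }

  mean_shape <- arr[, , 1]
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    for (i in seq_len(n))
      arr[, , i] <- arr[, , i] %*% procrustes_rotation(arr[, , i], mean_shape)
    new_mean <- apply(arr, c(1, 2), mean)
    new_mean <- new_mean / sqrt(sum(sweep(new_mean, 2,
                                          colMeans(new_mean))^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }

  # orthogonal tangent-space projection at the mean: removes the residual
  # radial (size-constraint) direction so that exactly 2k - 4 shape
  # dimensions carry variance (translation is removed exactly by centering
  # and the rotation direction by the rotation optimality condition)
  mvec <- as.vector(t(mean_shape))
  mvec <- mvec / sqrt(sum(mvec^2))
  aligned <- t(apply(arr, 3, function(m) {
    v <- as.vector(t(m))
    v - (sum(v * mvec) - 1) * mvec
  }))
  colnames(aligned) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))

  meta <- landmarks |>
    dplyr::distinct(.data$wing_id, .keep_all = TRUE) |>
    dplyr::select(-dplyr::any_of(c("landmark", "x", "y")))
  info <- dplyr::left_join(
    tibble::tibble(wing_id = dimnames(arr)[[3]], centroid_size = sizes),
    meta, by = "wing_id")

  structure(list(aligned = aligned, info = info, mean_shape = mean_shape,
                 k = k, iterations = it, converged = converged),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("<shape_space>", nrow(x$aligned), "wings,", x$k, "landmarks")
  if (!is.null(x$eigenvalues))
    cat(";", x$n_nonzero, "nonzero PCs")
  cat("\n")
  invisible(x)
}

#' Principal components of aligned shape coordinates
#'
#' Eigen-decomposition of the covariance of the aligned coordinates. For k
#' 2D landmarks the full Procrustes fit removes 4 degrees of freedom
#' (2 translation, 1 rotation, 1 scale), so exactly 2k - 4 components —
#' 14 for nine landmarks — carry variance. Scores are centered. Signs are
#' fixed deterministically: PC1 is oriented so its loading on landmark 2's
#' x-coordinate is non-negative, later PCs so their largest-magnitude
#' loading is positive.
#'
#' @param space A [gpa_align()] result.
#' @return The `shape_space` augmented with `scores` (tibble), `loadings`,
#'   `eigenvalues` and `n_nonzero`.
#' @export
shape_pca <- function(space) {
  if (!inherits(space, "shape_space")) abort("expected a shape_space")
  pc <- prcomp(space$aligned, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  n_nonzero <- sum(ev > max(ev) * 1e-9)

  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    ref <- if (j == 1) l["x2"] else l[which.max(abs(l))]
    if (is.na(ref) || ref >= 0) 1 else -1
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)

  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(space$info, scores)

  space$scores <- scores
  space$loadings <- pc$rotation
  space$eigenvalues <- ev
  space$n_nonzero <- n_nonzero
  space
}

#' Flag multivariate outliers by Mahalanobis distance
#'
#' Squared Mahalanobis distance of each row to the pooled sample mean under
#' the pooled sample covariance, flagged against the upper-tail chi-square
#' quantile at df = number of traits. With the 14 shape PCs plus centroid
#' size and `alpha = 0.001` the threshold is 37.70.
#'
#' @param traits A tibble/matrix whose numeric columns are the traits;
#'   non-numeric identifier columns are carried through.
#' @param alpha Upper-tail probability of the flagging threshold.
#' @return The input with `.mahalanobis` and `.outlier` columns; the
#'   threshold is in the `"critical"` attribute.
#' @export
mahalanobis_outliers <- function(traits, alpha = 0.001) {
  df <- tibble::as_tibble(traits)
  num <- vapply(df, is.numeric, logical(1))
  X <- as.matrix(df[num])
  if (ncol(X) < 1) abort("no numeric trait columns")
  cv <- cov(X)
  rk <- qr(cv)$rank
  if (rk < ncol(X))
    abort(paste0("trait covariance is singular (rank ", rk, " < ",
                 ncol(X), " traits)"))
  d2 <- mahalanobis(X, colMeans(X), cv)
  crit <- mahalanobis_critical(df = ncol(X), alpha = alpha)
  out <- dplyr::mutate(df, .mahalanobis = d2, .outlier = d2 > crit)
  attr(out, "critical") <- crit
  out
}

#' Wing length from raw landmark coordinates
#'
#' Euclidean distance between two landmarks (by default the third and
#' ninth) in the original digitized coordinates, multiplied by the per-wing
#' scale factor to give millimetres. Landmark indexing is 1-based.
#'
#' @param landmarks Long landmark tibble with `wing_id`, `landmark`, `x`,
#'   `y` and optionally `scale` (mm per digitized unit; defaults to 1).
#' @param from,to Landmark indices.
#' @return A tibble: `wing_id`, `wing_length_mm`.
#' @export
wing_length <- function(landmarks, from = 3, to = 9) {
  assert_columns(landmarks, c("wing_id", "landmark", "x", "y"),
                 "landmark table")
  if (!"scale" %in% names(landmarks)) landmarks$scale <- 1
  landmarks |>
    dplyr::filter(.data$landmark %in% c(from, to)) |>
    dplyr::arrange(.data$wing_id, .data$landmark) |>
    dplyr::group_by(.data$wing_id) |>
    dplyr::summarise(
      wing_length_mm = sqrt(diff(.data$x)^2 + diff(.data$y)^2) *
        .data$scale[1],
      .groups = "drop")
}

#' Strain-mean multiple regression of mating success on morphology
#'
#' Ordinary least squares of per-strain mating success on per-strain trait
#' means, with an intercept. Each predictor is reported with its marginal
#' (partial) F statistic on 1 and n - p - 1 denominator degrees of freedom:
#' with 20 strains and three predictors the denominator df is 16.
#'
#' @param strain_table One row per strain: the response column plus the
#'   predictor columns.
#' @param response Name of the response column.
#' @param predictors Names of the predictor columns.
#' @return A tibble: `term`, `estimate`, `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
strain_trait_regression <- function(strain_table, response,
                                    predictors = c("wing_length_mm", "pc1",
                                                   "comb_teeth")) {
  assert_columns(strain_table, c(response, predictors), "strain table")
  n <- nrow(strain_table)
  p <- length(predictors)
  if (n <= p + 1) abort("too few strains for the regression")
  form <- as.formula(paste(response, "~",
                           paste(predictors, collapse = " + ")))
  fit <- stats::lm(form, data = strain_table)
  s <- summary(fit)$coefficients
  tibble::tibble(
    term = predictors,
    estimate = unname(s[predictors, "Estimate"]),
    statistic = unname(s[predictors, "t value"]^2),
    df1 = 1L,
    df2 = n - p - 1L,
    p_value = unname(s[predictors, "Pr(>|t|)"])
  )
}
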