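# run expr under a given seed, restoring the caller's RNG state afterwards
# so generators are pure functions of (input, seed)
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  invisible(df)
}

#' Critical Mahalanobis distance threshold
#'
#' Upper-tail chi-square quantile used to flag multivariate outliers: with
#' 14 shape principal components plus centroid size (15 traits) and
#' `alpha = 0.001` the threshold is 37.70.
#'
#' @param df Degrees of freedom (number of traits).
#' @param alpha Upper-tail probability.
#' @return The squared-distance threshold (a scalar).
#' @export
#' @examples
#' mahalanobis_critical(df = 15, alpha = 0.001)
mahalanobis_critical <- function(df = 15, alpha = 0.001) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  qchisq(1 - alpha, df = df)
}

#' Number of posterior draws retained by an MCMC run
#'
#' Bookkeeping for the sampling convention used throughout: the first
#' `warmup` fraction of each chain is discarded and the remainder thinned.
#' Four chains of 20,000 iterations with half warmup and thinning interval
#' 10 retain 4,000 draws.
#'
#' @param chains Number of chains.
#' @param iter Iterations per chain (including warmup).
#' @param warmup Fraction of each chain discarded as warmup.
#' @param thin Thinning interval.
#' @return Total retained draw count across chains.
#' @export
#' @examples
#' retained_draws(chains = 4, iter = 20000, warmup = 0.5, thin = 10)
retained_draws <- function(chains = 4, iter = 20000, warmup = 0.5, thin = 10) {
  stopifnot(chains >= 1, iter >= 1, warmup >= 0, warmup < 1, thin >= 1)
  w <- floor(iter * warmup)
  chains * ((iter - w) %/% thin)
}

# split-chain potential scale reduction factor for one parameter;
# x is an iterations x chains matrix of retained draws
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (!is.finite(W) || W <= 0) {
    # constant chains: identical constants are converged by convention
    if (isTRUE(all.equal(max(sub), min(sub)))) return(1)
    return(NA_real_)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
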