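#' Settings for the hierarchical Bernoulli-logit choice model
#'
#' The joint model links mating success across the four contexts through a
#' shared male-strain effect: for noncompetitive rows
#' `logit(p) = mu_k + a[m, k] + b[f, k]` and for competitive rows
#' `logit(p) = mu_k + gamma_color + a[m, k]`, where each strain's `a[m, ]`
#' is multivariate normal with per-context SDs `sigma_k` and correlation
#' matrix `R`. Priors: half-Student-t(3, 0, 2.5) on all SDs, LKJ(1)
#' (uniform over correlation matrices) on `R`, Student-t(3, 0, 2.5) on
#' intercepts and improper flat priors on color contrasts. No
#' male-by-female interaction and no block term are included.
#'
#' The default run length is 4 chains of
#' 20,000 iterations, first half discarded as warmup, thinning interval 10,
#' hence 4,000 retained draws.
#'
#' @param chains,iter,warmup,thin MCMC run length; `warmup` is the fraction
#'   of each chain discarded.
#' @param seed Integer seed for the sampler.
#' @param sd_prior_df,sd_prior_scale Half-t prior on the random-effect SDs.
#' @param intercept_df,intercept_scale Student-t prior on intercepts.
#' @param max_rhat Largest split-chain scale reduction tolerated when
#'   summarizing.
#' @return A `choice_model_spec` list.
#' @export
choice_model_spec <- function(chains = 4, iter = 20000, warmup = 0.5,
                              thin = 10, seed = 1L, sd_prior_df = 3,
                              sd_prior_scale = 2.5, intercept_df = 3,
                              intercept_scale = 2.5, max_rhat = 1.05) {
  stopifnot(chains >= 1, iter >= 20, warmup > 0, warmup < 1, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = warmup, thin = as.integer(thin),
                 seed = as.integer(seed), sd_prior_df = sd_prior_df,
                 sd_prior_scale = sd_prior_scale, intercept_df = intercept_df,
                 intercept_scale = intercept_scale, max_rhat = max_rhat),
            class = "choice_model_spec")
}

#' Fit the joint multi-context choice model
#'
#' Takes a binary-outcome table covering one or more contexts (typically
#' the binarized noncompetitive trials bound to one competitive resample,
#' covering all four) and samples the posterior of the hierarchical
#' Bernoulli-logit model of [choice_model_spec()] with a Polya-Gamma Gibbs
#' sampler. Female-strain effects are included for each noncompetitive
#' context with at least two female strains; a color fixed effect is
#' included when competitive rows carry more than one color.
#'
#' Strains with all-success or all-failure records (separation) are
#' tolerated — the priors regularize them — but trigger a warning. A
#' context represented by a single male strain is rejected: its variance is
#' unidentifiable.
#'
#' @param data Binary-outcome tibble: `context`, `male_strain`, `success`,
#'   optionally `female_strain` and `color`.
#' @param spec A [choice_model_spec()].
#' @return A `choice_fit` object holding the draw tibble (one column per
#'   parameter plus `.chain`, `.iteration`, `.resample`), split-chain R-hat
#'   per parameter and sampler metadata.
#' @export
fit_choice_model <- function(data, spec = choice_model_spec()) {
  assert_columns(data, c("context", "male_strain", "success"), "choice data")
  if (!all(data$context %in% mv_contexts()))
    abort("unknown context label in choice data")
  if (!all(data$success %in% c(0L, 1L, TRUE, FALSE)))
    abort("success must be binary")

  contexts <- intersect(mv_contexts(), unique(data$context))
  K <- length(contexts)
  ctx <- match(data$context, contexts) - 1L

  strains <- sort(unique(data$male_strain))
  S <- length(strains)
  per_ctx <- tapply(data$male_strain, data$context,
                    function(x) length(unique(x)))
  if (any(per_ctx < 2))
    abort(paste0("context ", names(per_ctx)[which(per_ctx < 2)[1]],
                 " has a single male strain; its variance is unidentifiable"))
  male <- match(data$male_strain, strains) - 1L

  # separation diagnostics
  sep <- data |>
    dplyr::group_by(.data$context, .data$male_strain) |>
    dplyr::summarise(p = mean(as.numeric(.data$success)), .groups = "drop") |>
    dplyr::filter(.data$p %in% c(0, 1))
  if (nrow(sep) > 0)
    warn(paste0(nrow(sep), " strain-by-context cell(s) show complete ",
                "separation; priors regularize their effects"))

  # female-strain effects: noncompetitive contexts with >= 2 female strains
  fem <- rep(-1L, nrow(data))
  fctx <- rep(-1L, nrow(data))
  fem_ctx <- character(0)
  fstrains <- character(0)
  if ("female_strain" %in% names(data)) {
    nc <- data$context %in% mv_noncomp_contexts() & !is.na(data$female_strain)
    fem_ctx <- intersect(mv_noncomp_contexts(), unique(data$context[nc]))
    fem_ctx <- fem_ctx[vapply(fem_ctx, function(k)
      length(unique(data$female_strain[nc & data$context == k])) >= 2,
      logical(1))]
    if (length(fem_ctx) > 0) {
      keep <- nc & data$context %in% fem_ctx
      fstrains <- sort(unique(data$female_strain[keep]))
      fem[keep] <- match(data$female_strain[keep], fstrains) - 1L
      fctx[keep] <- match(data$context[keep], fem_ctx) - 1L
    }
  }
  F_ <- length(fstrains)
  KF <- length(fem_ctx)

  # fixed-effect design: one intercept per context (t prior) plus color
  # treatment contrasts shared across competitive contexts (flat prior)
  X <- matrix(0, nrow(data), K)
  X[cbind(seq_len(nrow(data)), ctx + 1L)] <- 1
  colnames(X) <- paste0("mu[", contexts, "]")
  tprior <- rep(1L, K)
  col_levels <- character(0)
  if ("color" %in% names(data)) {
    cc <- data$context %in% mv_comp_contexts() & !is.na(data$color)
    col_levels <- sort(unique(data$color[cc]))
    if (length(col_levels) > 1) {
      for (lv in col_levels[-1]) {
        X <- cbind(X, as.numeric(cc & data$color == lv))
        colnames(X)[ncol(X)] <- paste0("gamma[", lv, "]")
        tprior <- c(tprior, 0L)
      }
    }
  }

  ncpc <- K * (K - 1L) / 2L
  warmup_iters <- as.integer(floor(spec$iter * spec$warmup))
  y <- as.integer(data$success)

  # correlation entries are stored row-wise over the lower triangle:
  # (2,1), (3,1), (3,2), (4,1), ...
  pair_names <- character(0)
  if (ncpc > 0) {
    idx <- which(lower.tri(matrix(0, K, K)), arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    pair_names <- paste0("R[", contexts[idx[, "col"]], ",",
                         contexts[idx[, "row"]], "]")
  }
  par_names <- c(colnames(X), paste0("sigma[", contexts, "]"), pair_names,
                 if (KF > 0) paste0("tau[", fem_ctx, "]"),
                 paste0("a[", rep(strains, K), ",",
                        rep(contexts, each = S), "]"),
                 if (KF > 0) paste0("b[", rep(fstrains, KF), ",",
                                    rep(fem_ctx, each = F_), "]"))

  chains <- local_seed(spec$seed, {
    purrr::map(seq_len(spec$chains), function(ch) {
      init <- list(beta = rnorm(ncol(X), 0, 0.2),
                   a = matrix(rnorm(S * K, 0, 0.2), S, K),
                   logsig = log(runif(K, 0.2, 0.8)),
                   zcpc = rnorm(max(ncpc, 1), 0, 0.3),
                   b = matrix(rnorm(max(F_, 1) * max(KF, 1), 0, 0.2),
                              max(F_, 1), max(KF, 1)),
                   logtau = log(runif(max(KF, 1), 0.2, 0.8)))
      run_choice_chain(y, ctx, male, fem, fctx, X, tprior, S, F_, K, KF,
                       spec$iter, warmup_iters, spec$thin,
                       spec$intercept_df, spec$intercept_scale,
                       spec$sd_prior_df, spec$sd_prior_scale, init)
    })
  })

  draw_mats <- purrr::map(chains, "draws")
  n_keep <- nrow(draw_mats[[1]])
  draws <- purrr::imap_dfr(draw_mats, function(m, ch) {
    colnames(m) <- par_names
    d <- tibble::as_tibble(m)
    d$.chain <- ch
    d$.iteration <- seq_len(n_keep)
    d
  })
  draws$.resample <- 1L

  rhat <- vapply(par_names, function(p) {
    split_rhat(matrix(draws[[p]], nrow = n_keep, ncol = spec$chains))
  }, numeric(1))

  structure(list(
    draws = draws, parameters = par_names, contexts = contexts,
    strains = strains, female_strains = fstrains, female_contexts = fem_ctx,
    colors = col_levels, spec = spec, rhat = rhat,
    accept = c(sigma = mean(purrr::map_dbl(chains, "accept_sigma")),
               corr = mean(purrr::map_dbl(chains, "accept_corr"))),
    n_obs = nrow(data), n_resamples = 1L, pooled = FALSE
  ), class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("<choice_fit>", length(x$contexts), "context(s),", length(x$strains),
      "male strains,", x$n_obs, "rows\n")
  cat(sprintf("  %d draws (%d resample set%s); max R-hat %.3f\n",
              nrow(x$draws), x$n_resamples,
              if (x$n_resamples > 1) "s" else "", max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Pool posterior draws across resample fits
#'
#' Concatenates the retained draws of several fits of the same model to
#' different competitive resample sets, keeping resample provenance. The
#' pooled posterior accounts for the random sampling of males; it is
#' equivalent to running proportionally more iterations and leaves
#' noncompetitive information untouched.
#'
#' @param fits A list of `choice_fit` objects with identical parameters.
#' @return A pooled `choice_fit`.
#' @export
pool_posteriors <- function(fits) {
  if (length(fits) < 1) abort("need at least one fit to pool")
  pn <- fits[[1]]$parameters
  same <- vapply(fits, function(f) identical(f$parameters, pn), logical(1))
  if (!all(same)) abort("fits have differing parameter sets; cannot pool")
  draws <- purrr::imap_dfr(fits, function(f, i) {
    d <- f$draws
    d$.resample <- i
    d
  })
  out <- fits[[1]]
  out$draws <- draws
  out$rhat <- do.call(pmax, c(purrr::map(fits, "rhat"), list(na.rm = TRUE)))
  out$n_resamples <- length(fits)
  out$pooled <- TRUE
  out
}

#' Fit the choice model across repeated competitive resamples
#'
#' Convenience wrapper: builds `n_resamples` one-male-per-vial resample
#' sets, binds each to the (fixed) noncompetitive binary rows, fits the
#' joint model once per set, and pools the posteriors.
#'
#' @param noncomp_binary Binarized noncompetitive rows
#'   ([binarize_latency()]); may be `NULL` for competition-only fits.
#' @param vials Mated competitive vials with identified winners.
#' @param n_resamples Number of resample sets.
#' @param spec A [choice_model_spec()]; each resample's sampler seed is
#'   offset by its index.
#' @param resample_seed Seed for the male resampling.
#' @return A pooled `choice_fit`.
#' @export
fit_resampled_choice_model <- function(noncomp_binary, vials,
                                       n_resamples = 100,
                                       spec = choice_model_spec(),
                                       resample_seed = spec$seed + 1000L) {
  sets <- build_resample_sets(vials, n_resamples, resample_seed)
  fits <- purrr::imap(sets, function(s, i) {
    dat <- if (is.null(noncomp_binary)) s else
      dplyr::bind_rows(noncomp_binary, s)
    sp <- spec
    sp$seed <- spec$seed + i
    fit_choice_model(dat, sp)
  })
  pool_posteriors(fits)
}

#' Posterior mode and highest-density credible interval
#'
#' The mode is the argmax of a Gaussian kernel density over the draws
#' (Silverman's bandwidth); for boundary-constrained parameters such as
#' SDs, draws are reflected at the boundary to avoid boundary bias, which
#' matters because SD posteriors are typically right-skewed. The interval
#' is the shortest contiguous window containing `ceiling(mass * n)` sorted
#' draws (the unimodal highest-density interval).
#'
#' @param samples Numeric draw vector (at least 100 draws recommended).
#' @param mass Probability mass of the interval.
#' @param lower_bound Optional reflection boundary (e.g. 0 for SDs).
#' @param parameter Optional parameter label carried into the output.
#' @return A one-row tibble: `parameter`, `mode`, `.lower`, `.upper`,
#'   `.mass`.
#' @export
#' @examples
#' mode_hdci(rnorm(5000), mass = 0.95)
mode_hdci <- function(samples, mass = 0.95, lower_bound = NULL,
                      parameter = NA_character_) {
  if (!(mass > 0 && mass < 1)) abort("mass must lie in (0, 1)")
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n == 0) abort("no finite draws to summarize")
  if (diff(range(samples)) == 0) {
    return(tibble::tibble(parameter = parameter, mode = samples[1],
                          .lower = samples[1], .upper = samples[1],
                          .mass = mass))
  }
  if (n < 100)
    warn("fewer than 100 draws; mode and interval will be unstable")

  if (!is.null(lower_bound)) {
    d <- density(c(samples, 2 * lower_bound - samples), n = 2048)
    # the reflected estimate is only data-supported from the smallest draw
    # upward; below it the apparent density is pure kernel leakage
    keep <- d$x >= max(lower_bound, min(samples))
    mode <- d$x[keep][which.max(d$y[keep])]
  } else {
    d <- density(samples, n = 2048)
    mode <- d$x[which.max(d$y)]
  }

  xs <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) {
    lo <- xs[1]; hi <- xs[n]
  } else {
    starts <- seq_len(n - m + 1)
    widths <- xs[starts + m - 1] - xs[starts]
    i <- which.min(widths)
    lo <- xs[i]; hi <- xs[i + m - 1]
  }
  tibble::tibble(parameter = parameter, mode = mode, .lower = lo,
                 .upper = hi, .mass = mass)
}

#' Does a credible interval exclude zero?
#'
#' The interval test used for cross-context correlations: significant iff
#' zero lies strictly outside `[.lower, .upper]`; an interval touching
#' zero does not count as excluding it.
#'
#' @param summary A one-row summary (from [mode_hdci()] or [tidy()]).
#' @return `TRUE` iff 0 is outside the interval.
#' @export
test_correlation_vs_zero <- function(summary) {
  lo <- summary$.lower %||% summary$lower
  hi <- summary$.upper %||% summary$upper
  if (is.null(lo) || is.null(hi)) abort("summary must carry interval bounds")
  unname(lo > 0 | hi < 0)
}

#' Pearson correlation of strain-mean success between two tables
#'
#' The simple (phenotypic strain-mean) analogue of the model-based
#' cross-context correlation: per-strain success proportions are computed
#' in each table and correlated across the strains common to both.
#'
#' @param a,b Binary-outcome tibbles with `male_strain` and `success`.
#' @return The Pearson correlation (scalar).
#' @export
strain_mean_correlation <- function(a, b) {
  sm <- function(x) {
    assert_columns(x, c("male_strain", "success"))
    x |>
      dplyr::group_by(.data$male_strain) |>
      dplyr::summarise(p = mean(as.numeric(.data$success)), .groups = "drop")
  }
  j <- dplyr::inner_join(sm(a), sm(b), by = "male_strain",
                         suffix = c("_a", "_b"))
  if (nrow(j) < 3) abort("need at least 3 shared strains to correlate")
  cor(j$p_a, j$p_b)
}

#' Maximum a posteriori estimate for a single-context instance
#'
#' Joint posterior mode of the intercept and the male-strain effects for a
#' one-context binary table, holding the strain-effect SD fixed — a small
#' deterministic companion to the sampler, useful for verification against
#' exhaustive grid search on tiny instances.
#'
#' @param data One-context binary-outcome tibble.
#' @param sigma Fixed male-strain effect SD.
#' @param spec A [choice_model_spec()] supplying the intercept prior.
#' @return Named vector: `mu` then one `a[strain]` per strain.
#' @export
choice_model_map <- function(data, sigma = 1,
                             spec = choice_model_spec()) {
  assert_columns(data, c("context", "male_strain", "success"))
  if (length(unique(data$context)) != 1)
    abort("choice_model_map expects a single context")
  strains <- sort(unique(data$male_strain))
  m <- match(data$male_strain, strains)
  y <- as.numeric(data$success)
  neg_log_post <- function(par) {
    mu <- par[1]
    a <- par[-1]
    eta <- mu + a[m]
    ll <- sum(y * eta - log1p(exp(eta)))
    lp <- dt(mu / spec$intercept_scale, df = spec$intercept_df, log = TRUE) -
      log(spec$intercept_scale) +
      sum(dnorm(a, 0, sigma, log = TRUE))
    -(ll + lp)
  }
  fit <- optim(rep(0, length(strains) + 1), neg_log_post, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  setNames(fit$par, c("mu", paste0("a[", strains, "]")))
}

#' @describeIn fit_choice_model Posterior summaries (mode and 95% HDCI) for
#'   the population-level parameters. Refuses to summarize when the largest
#'   split-chain R-hat exceeds the fit's configured tolerance unless
#'   `check_rhat = FALSE`.
#' @param x A `choice_fit`.
#' @param mass Interval mass.
#' @param check_rhat Enforce the convergence gate.
#' @param all_parameters Include strain-level effects.
#' @param ... Unused.
#' @export
tidy.choice_fit <- function(x, mass = 0.95, check_rhat = TRUE,
                            all_parameters = FALSE, ...) {
  mx <- max(x$rhat, na.rm = TRUE)
  if (check_rhat && is.finite(mx) && mx > x$spec$max_rhat)
    abort(paste0("largest split-chain R-hat is ", sprintf("%.3f", mx),
                 " (> ", x$spec$max_rhat, "); chains have not converged. ",
                 "Run longer or pass check_rhat = FALSE to override."))
  pars <- x$parameters
  if (!all_parameters)
    pars <- pars[!grepl("^[ab]\\[", pars)]
  purrr::map_dfr(pars, function(p) {
    lb <- if (grepl("^(sigma|tau)\\[", p)) 0 else NULL
    s <- mode_hdci(x$draws[[p]], mass = mass, lower_bound = lb,
                   parameter = p)
    s$rhat <- unname(x$rhat[p])
    s
  })
}

#' @export
glance.choice_fit <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$draws), n_chains = x$spec$chains,
                 n_resamples = x$n_resamples,
                 max_rhat = max(x$rhat, na.rm = TRUE),
                 accept_sigma = unname(x$accept["sigma"]),
                 accept_corr = unname(x$accept["corr"]),
                 n_obs = x$n_obs)
}
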