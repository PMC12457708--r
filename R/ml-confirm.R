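#' Maximum-likelihood confirmation fit for a single context
#'
#' Fits the single-context logistic mixed model by maximum (marginal)
#' likelihood, integrating the random effects with an adaptive Gaussian
#' (Laplace) approximation: noncompetitive contexts get male-strain and
#' female-strain intercepts, competitive contexts a color fixed effect and
#' a male-strain intercept. Used to confirm the Bayesian variance
#' estimates, with variances tested by likelihood-ratio tests.
#'
#' @param data Binary-outcome tibble covering (at least) `context`.
#' @param context The context label to fit.
#' @return An `ml_context_fit` list: `sigma` (tibble of random-effect SDs),
#'   `fixef`, `logLik`, `converged`, and the underlying model.
#' @export
ml_fit_context <- function(data, context) {
  if (!context %in% data$context)
    abort(paste0("no rows for context ", context))
  d <- dplyr::filter(data, .data$context == !!context)
  d$success <- as.numeric(d$success)
  comp <- context %in% mv_comp_contexts()
  if (comp && "color" %in% names(d) && length(unique(d$color)) > 1) {
    form <- success ~ color + (1 | male_strain)
  } else if (!comp && "female_strain" %in% names(d) &&
             length(unique(d$female_strain)) > 1) {
    form <- success ~ 1 + (1 | male_strain) + (1 | female_strain)
  } else {
    form <- success ~ 1 + (1 | male_strain)
  }
  fit <- suppressMessages(lme4::glmer(form, data = d, family = binomial()))
  vc <- lme4::VarCorr(fit)
  sig <- tibble::tibble(
    term = names(vc),
    sd = vapply(vc, function(v) sqrt(unname(v[1, 1])), numeric(1)))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(context = context, sigma = sig,
                 fixef = lme4::fixef(fit), logLik = as.numeric(logLik(fit)),
                 converged = conv, model = fit, formula = form),
            class = "ml_context_fit")
}

#' @export
print.ml_context_fit <- function(x, ...) {
  cat("<ml_context_fit>", x$context, " logLik", sprintf("%.2f", x$logLik), "\n")
  print(x$sigma)
  invisible(x)
}

#' Likelihood-ratio test of a variance component
#'
#' One-degree-of-freedom LRT of a nested random effect. The statistic is
#' clamped at zero (a variance estimated on the boundary gives equal
#' likelihoods), in which case the test prints statistic 0, p 1.
#'
#' @param loglik_full,loglik_reduced Log-likelihoods of the nested fits
#'   (numeric or `logLik`).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
lrt_random_effect <- function(loglik_full, loglik_reduced) {
  stat <- max(0, 2 * (as.numeric(loglik_full) - as.numeric(loglik_reduced)))
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Likelihood-ratio test of the male-strain variance in one context
#'
#' Fits the full [ml_fit_context()] model and its reduction without the
#' male-strain intercept, and returns the boundary-clamped LRT together
#' with the estimated SD.
#'
#' @inheritParams ml_fit_context
#' @return A one-row tibble: `context`, `sigma_male`, `statistic`, `df`,
#'   `p_value`.
#' @export
ml_lrt_male_strain <- function(data, context) {
  full <- ml_fit_context(data, context)
  d <- dplyr::filter(data, .data$context == !!context)
  d$success <- as.numeric(d$success)
  red_form <- stats::update(full$formula, . ~ . - (1 | male_strain))
  has_re <- grepl("\\|", deparse(red_form[[3]]))
  red_ll <- if (any(has_re)) {
    as.numeric(logLik(suppressMessages(
      lme4::glmer(red_form, data = d, family = binomial()))))
  } else {
    as.numeric(logLik(stats::glm(red_form, data = d, family = binomial())))
  }
  lrt <- lrt_random_effect(full$logLik, red_ll)
  sig <- full$sigma$sd[full$sigma$term == "male_strain"]
  tibble::tibble(context = context, sigma_male = sig,
                 statistic = lrt$statistic, df = lrt$df,
                 p_value = lrt$p_value)
}

#' Jackknifed cross-context covariance of strain mean success
#'
#' Delete-one-strain jackknife of the covariance between per-strain success
#' proportions in two tables (the resampling companion to the
#' likelihood-ratio variance tests). The covariance uses the n-1
#' denominator; the standard error is the SD of the pseudovalues divided by
#' the square root of the number of strains.
#'
#' @param a,b Binary-outcome tibbles with `male_strain` and `success`.
#' @return A one-row tibble: `covariance`, `se`, `n_strains`.
#' @export
jackknife_strain_covariance <- function(a, b) {
  sm <- function(x) x |>
    dplyr::group_by(.data$male_strain) |>
    dplyr::summarise(p = mean(as.numeric(.data$success)), .groups = "drop")
  j <- dplyr::inner_join(sm(a), sm(b), by = "male_strain",
                         suffix = c("_a", "_b"))
  n <- nrow(j)
  if (n < 3) abort("need at least 3 shared strains to jackknife")
  theta <- cov(j$p_a, j$p_b)
  loo <- vapply(seq_len(n), function(i) cov(j$p_a[-i], j$p_b[-i]),
                numeric(1))
  pseudo <- n * theta - (n - 1) * loo
  tibble::tibble(covariance = theta, se = sd(pseudo) / sqrt(n),
                 n_strains = n)
}
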