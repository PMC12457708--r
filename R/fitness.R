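#' Log-ratio fitness score
#'
#' Competitive reproductive success of a wild-type focal against a
#' brown-eyed standard: `w = ln((wt + 1) / (be + 1))`. Strictly increasing
#' in the wild-type count, strictly decreasing in the brown-eyed count, and
#' antisymmetric under swapping the two.
#'
#' @param wt Wild-type offspring count(s).
#' @param be Brown-eyed offspring count(s).
#' @return Numeric score(s).
#' @export
#' @examples
#' fitness_score(99, 49) # log(2)
fitness_score <- function(wt, be) {
  if (any(wt < 0, na.rm = TRUE) || any(be < 0, na.rm = TRUE))
    abort("offspring counts must be non-negative")
  log((wt + 1) / (be + 1))
}

#' Log-ratio egg-to-adult viability score
#'
#' The fitness score with adults substituted for wild-type offspring and
#' failed eggs (`eggs - adults`) for brown-eyed offspring:
#' `ln((adults + 1) / (eggs - adults + 1))`.
#'
#' @param eggs Egg count(s).
#' @param adults Adult count(s); must not exceed eggs.
#' @return Numeric score(s).
#' @export
#' @examples
#' viability_score(10, 10) # log(11)
viability_score <- function(eggs, adults) {
  if (any(eggs < 0, na.rm = TRUE) || any(adults < 0, na.rm = TRUE))
    abort("counts must be non-negative")
  if (any(adults > eggs, na.rm = TRUE))
    abort("adults cannot exceed eggs")
  log((adults + 1) / (eggs - adults + 1))
}

#' Filter uninformative viability vials
#'
#' Removes, in order, vials with no eggs (uninformative for egg-to-adult
#' viability) and then vials with no adults (which may simply reflect no
#' mating), reporting both counts.
#'
#' @param records Viability tibble with `eggs` and `adults`.
#' @return A list: `records` (kept rows), `n_zero_egg`, `n_zero_adult`.
#' @export
filter_viability <- function(records) {
  assert_columns(records, c("eggs", "adults"), "viability table")
  zero_egg <- records$eggs == 0
  kept <- records[!zero_egg, , drop = FALSE]
  zero_adult <- kept$adults == 0
  list(records = tibble::as_tibble(kept[!zero_adult, , drop = FALSE]),
       n_zero_egg = sum(zero_egg),
       n_zero_adult = sum(zero_adult))
}

#' Gaussian mixed-model decomposition of fitness or viability scores
#'
#' Fits (by REML) the linear mixed model with male-strain, female-strain
#' and their interaction as random effects and block and cross (within-
#' versus between-strain) as categorical fixed effects, using sum-to-zero
#' contrasts. Random-effect variances are tested by one-df likelihood-ratio
#' tests on matching ML refits (boundary-clamped); fixed effects by type-II
#' Wald chi-square tests; and the cross contrast is summarized by estimated
#' marginal means (equal factor weights, random effects at zero).
#'
#' @param scores Tibble with `block`, `m_strain`, `f_strain`, the response
#'   column, and optionally `cross` (derived from the strains otherwise).
#' @param response Name of the response column.
#' @return A `cross_lmm` object: variance estimates, LRT and Wald tables,
#'   marginal means, and the underlying `lmerMod`.
#' @export
fit_cross_lmm <- function(scores, response = "w") {
  assert_columns(scores, c("block", "m_strain", "f_strain", response),
                 "score table")
  d <- tibble::as_tibble(scores)
  if (!"cross" %in% names(d))
    d$cross <- ifelse(d$m_strain == d$f_strain, "within", "between")
  if (length(unique(d$cross)) < 2)
    abort("both cross levels (within and between) must be present")
  if (length(unique(d$m_strain)) < 2 || length(unique(d$f_strain)) < 2)
    abort("need at least two strains on each side of the cross")
  d$block <- factor(d$block)
  d$cross <- factor(d$cross, levels = c("within", "between"))
  d$.resp <- d[[response]]

  ctr <- list(block = "contr.sum", cross = "contr.sum")
  form <- .resp ~ block + cross + (1 | m_strain) + (1 | f_strain) +
    (1 | m_strain:f_strain)
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                     contrasts = ctr))

  vc <- as.data.frame(lme4::VarCorr(fit))
  variances <- tibble::tibble(
    term = sub("^m_strain:f_strain$", "m_strain:f_strain", vc$grp),
    variance = vc$vcov)

  # one-df LRTs per random term, via ML refits
  full_ml <- suppressMessages(lme4::lmer(form, data = d, REML = FALSE,
                                         contrasts = ctr))
  drop_one <- function(term) {
    red <- stats::update(stats::formula(full_ml),
                         paste(". ~ . - (1 |", term, ")"))
    red_fit <- if (grepl("\\|", deparse(red[[3]], width.cutoff = 500))) {
      suppressMessages(lme4::lmer(red, data = d, REML = FALSE,
                                  contrasts = ctr))
    } else {
      stats::lm(red, data = d, contrasts = ctr)
    }
    lrt_random_effect(logLik(full_ml), logLik(red_fit))
  }
  lrt <- purrr::map_dfr(
    c("m_strain", "f_strain", "m_strain:f_strain"),
    function(tm) dplyr::mutate(drop_one(tm), term = tm, .before = 1))

  wald <- car::Anova(fit, type = 2, test.statistic = "Chisq")
  wald <- tibble::tibble(term = rownames(wald), chisq = wald$Chisq,
                         df = wald$Df, p_value = wald$`Pr(>Chisq)`)

  emm <- marginal_means(fit, "cross")

  structure(list(model = fit, variances = variances, lrt = lrt,
                 wald = wald, emm = emm, response = response,
                 n = nrow(d), data = d),
            class = "cross_lmm")
}

#' @export
print.cross_lmm <- function(x, ...) {
  cat("<cross_lmm>", x$response, "on", x$n, "records\n")
  v <- x$variances
  cat("  variances (x100):",
      paste(sprintf("%s=%.2f", v$term, 100 * v$variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @describeIn fit_cross_lmm Tidy table mirroring the standard report
#'   layout: one row per fixed-effect test, cross level (with marginal mean
#'   and SE) and random-effect variance (scaled by 100).
#' @param x A `cross_lmm`.
#' @param ... Unused.
#' @export
tidy.cross_lmm <- function(x, ...) {
  fixed <- x$wald |>
    dplyr::transmute(effect = paste0(.data$term, " (fixed)"),
                     level = NA_character_, emm = NA_real_, se = NA_real_,
                     variance_x100 = NA_real_, df = .data$df,
                     statistic = .data$chisq, p_value = .data$p_value)
  emm <- x$emm |>
    dplyr::transmute(effect = "cross (fixed)", level = .data$level,
                     emm = .data$emmean, se = .data$se,
                     variance_x100 = NA_real_, df = NA_integer_,
                     statistic = NA_real_, p_value = NA_real_)
  rand <- dplyr::left_join(x$variances, x$lrt, by = "term") |>
    dplyr::transmute(effect = paste0(.data$term, " (random)"),
                     level = NA_character_, emm = NA_real_, se = NA_real_,
                     variance_x100 = 100 * .data$variance, df = .data$df,
                     statistic = .data$statistic, p_value = .data$p_value)
  resid <- x$variances |>
    dplyr::filter(.data$term == "Residual") |>
    dplyr::transmute(effect = "Residual", level = NA_character_,
                     emm = NA_real_, se = NA_real_,
                     variance_x100 = 100 * .data$variance, df = NA_integer_,
                     statistic = NA_real_, p_value = NA_real_)
  rand <- dplyr::filter(rand, .data$effect != "Residual (random)")
  dplyr::bind_rows(fixed, emm, rand, resid)
}

#' @export
glance.cross_lmm <- function(x, ...) {
  tibble::tibble(n = x$n, response = x$response,
                 logLik = as.numeric(logLik(x$model)),
                 sigma_residual = stats::sigma(x$model))
}

#' Remove residual outliers relative to zero
#'
#' Drops rows whose model residual exceeds `k` times the interquartile
#' range of the residuals in absolute value (the band is anchored at zero,
#' not at the median). A single pass; the caller refits on the kept rows.
#'
#' @param scores The data the model was fit to (same row order).
#' @param model A fitted model with [residuals()].
#' @param k Band half-width in IQR multiples; `Inf` keeps everything.
#' @return A list: `records` (kept rows), `n_removed`.
#' @export
residual_outlier_filter <- function(scores, model, k = 2) {
  r <- residuals(model)
  if (length(r) != nrow(scores))
    abort("model residuals do not match the score table rows")
  band <- k * IQR(r)
  keep <- is.finite(r) & (abs(r) <= band | is.infinite(band))
  list(records = tibble::as_tibble(scores[keep, , drop = FALSE]),
       n_removed = sum(!keep))
}

#' Estimated marginal means for a fixed factor
#'
#' Predicted response per factor level, averaged over the levels of the
#' other fixed factors with equal weights and with random effects at zero.
#'
#' @param model A fitted (mixed) model.
#' @param factor Name of the fixed factor.
#' @return A tibble: `level`, `emmean`, `se`, `df`.
#' @export
marginal_means <- function(model, factor) {
  em <- emmeans::emmeans(model, specs = factor,
                         lmer.df = "asymptotic", weights = "equal")
  s <- as.data.frame(em)
  tibble::tibble(level = as.character(s[[1]]), emmean = s$emmean,
                 se = s$SE, df = s$df)
}
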