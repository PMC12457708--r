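#' Draw the true strain-level parameters of a synthetic study
#'
#' Realizes the latent structure the downstream models estimate: one
#' four-variate male-strain effect per strain (zero-mean normal with SDs
#' `context_sds` and correlation `context_corr`), independent per-context
#' female-strain responsiveness effects, male-by-female cross effects for
#' fitness, and female-strain viability effects.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the draw is a pure function of (config, seed).
#' @return A `true_params` list with elements `a` (strains x 4 contexts),
#'   `b` (strains x 4), `u` (within-block cross effects), `viab_f`,
#'   `strains` (strain-to-block map) and the echoed `config`.
#' @export
draw_strain_effects <- function(config, seed = config$seed) {
  check_corr_matrix(config$context_corr, 4)
  n_strain <- config$n_blocks * config$strains_per_block
  strains <- tibble::tibble(
    strain = sprintf("S%02d", seq_len(n_strain)),
    block = rep(seq_len(config$n_blocks), each = config$strains_per_block)
  )
  local_seed(seed, {
    # eigen square root keeps the zero-variance and singular-correlation
    # cases valid (chol would fail there)
    e <- eigen(config$context_corr, symmetric = TRUE)
    rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
    z <- matrix(rnorm(n_strain * 4), n_strain, 4)
    a <- z %*% rt
    a <- sweep(a, 2, config$context_sds, `*`)
    dimnames(a) <- list(strains$strain, mv_contexts())

    b <- matrix(rnorm(n_strain * 4, sd = config$female_strain_sd),
                n_strain, 4, dimnames = list(strains$strain, mv_contexts()))

    u <- tidyr::expand_grid(block = seq_len(config$n_blocks),
                            m_idx = seq_len(config$strains_per_block),
                            f_idx = seq_len(config$strains_per_block))
    u$m_strain <- strains$strain[(u$block - 1) * config$strains_per_block + u$m_idx]
    u$f_strain <- strains$strain[(u$block - 1) * config$strains_per_block + u$f_idx]
    u$u <- rnorm(nrow(u), sd = config$mf_interaction_sd)
    u <- dplyr::select(u, "block", "m_strain", "f_strain", "u")

    viab_f <- setNames(rnorm(n_strain, sd = config$viab_f_strain_sd),
                       strains$strain)

    structure(list(a = a, b = b, u = u, viab_f = viab_f,
                   strains = strains, config = config),
              class = "true_params")
  })
}

#' @export
print.true_params <- function(x, ...) {
  cat("<true_params>", nrow(x$a), "strains x 4 contexts\n")
  invisible(x)
}

block_strains <- function(params, b) {
  params$strains$strain[params$strains$block == b]
}

#' Simulate noncompetitive (single-pair) mating trials
#'
#' Each trial pairs one male with one virgin or non-virgin female of the
#' same block. Log latency is the status baseline minus the male-strain and
#' female-strain effects for the matching context, plus Gaussian noise
#' (a log-normal race); trials are censored at `censor_minutes`, with
#' censored rows keeping `mated = FALSE` and an empty latency.
#'
#' @param params A [draw_strain_effects()] result.
#' @param config A [sim_config()]; defaults to the one inside `params`.
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `trial`, `block`,
#'   `female_strain`, `male_strain`, `female_status`, `context`,
#'   `latency_min`, `mated`.
#' @export
simulate_noncompetitive <- function(params, config = params$config,
                                    seed = config$seed + 2L) {
  grid <- purrr::map_dfr(seq_len(config$n_blocks), function(b) {
    ss <- block_strains(params, b)
    tidyr::expand_grid(block = b, female_strain = ss, male_strain = ss,
                       female_status = mv_statuses())
  })
  grid$n <- config$n_noncomp_trials_per_cell[grid$female_status]
  trials <- tidyr::uncount(grid, weights = .data$n)
  trials$context <- status_context(trials$female_status, competitive = FALSE)
  trials$trial <- sprintf("nc_%05d", seq_len(nrow(trials)))

  local_seed(seed, {
    mu <- log(config$baseline_latency[trials$female_status]) -
      params$a[cbind(trials$male_strain, trials$context)] -
      params$b[cbind(trials$female_strain, trials$context)]
    lat <- exp(mu + rnorm(nrow(trials), sd = config$latency_log_sd))
    trials$mated <- lat <= config$censor_minutes
    trials$latency_min <- ifelse(trials$mated, lat, NA_real_)
  })
  dplyr::select(tibble::as_tibble(trials), "trial", "block", "female_strain",
                "male_strain", "female_status", "context", "latency_min",
                "mated")
}

#' Simulate competitive (four-male) mating trials
#'
#' One male from each of the block's four strains, abdomens dyed a
#' strain-specific color (every color appears in every block), is presented
#' to a single female. Each male draws a log-normal latency from the status
#' baseline minus his strain, color and the female's responsiveness
#' effects; the vial's winner is the fastest male provided he beats the
#' censor, otherwise the vial is retained but flagged unmated.
#'
#' @inheritParams simulate_noncompetitive
#' @return A tibble with one row per vial: `vial`, `block`, `female_strain`,
#'   `female_status`, `context`, `male_strain_1..4`, `color_1..4`,
#'   `winner_strain`, `winner_color`, `latency_min`, `mated`.
#' @export
simulate_competitive <- function(params, config = params$config,
                                 seed = config$seed + 3L) {
  if (config$strains_per_block != 4)
    abort("competitive trials require exactly 4 strains per block")
  cols <- mv_colors()
  grid <- purrr::map_dfr(seq_len(config$n_blocks), function(b) {
    ss <- block_strains(params, b)
    tidyr::expand_grid(block = b, female_strain = ss,
                       female_status = mv_statuses())
  })
  grid$n <- config$n_comp_vials_per_cell[grid$female_status]
  vials <- tidyr::uncount(grid, weights = .data$n)
  vials$context <- status_context(vials$female_status, competitive = TRUE)
  vials$vial <- sprintf("cv_%05d", seq_len(nrow(vials)))
  n <- nrow(vials)

  # strain -> color map rotates across blocks so each color is seen with
  # different strains
  strain_color <- function(b, j) cols[((j - 1 + (b - 1)) %% 4) + 1]

  # strains-by-block lookup (row = within-block slot, column = block)
  sb <- vapply(seq_len(config$n_blocks),
               function(b) block_strains(params, b), character(4))

  local_seed(seed, {
    lat <- matrix(NA_real_, n, 4)
    ms <- matrix(NA_character_, n, 4)
    cl <- matrix(NA_character_, n, 4)
    for (j in 1:4) {
      ms[, j] <- sb[j, vials$block]
      cl[, j] <- strain_color(vials$block, j)
      mu <- log(config$baseline_latency_comp[vials$female_status]) -
        params$a[cbind(ms[, j], vials$context)] -
        config$color_effects[cl[, j]] -
        params$b[cbind(vials$female_strain, vials$context)]
      lat[, j] <- exp(mu + rnorm(n, sd = config$latency_log_sd))
    }
    jmin <- max.col(-lat)
    best <- lat[cbind(seq_len(n), jmin)]
    vials$mated <- best <= config$censor_minutes
    vials$winner_strain <- ifelse(vials$mated, ms[cbind(seq_len(n), jmin)],
                                  NA_character_)
    vials$winner_color <- ifelse(vials$mated, cl[cbind(seq_len(n), jmin)],
                                 NA_character_)
    vials$latency_min <- ifelse(vials$mated, best, NA_real_)
    for (j in 1:4) {
      vials[[paste0("male_strain_", j)]] <- ms[, j]
      vials[[paste0("color_", j)]] <- cl[, j]
    }
  })
  dplyr::select(tibble::as_tibble(vials), "vial", "block", "female_strain",
                "female_status", "context",
                dplyr::starts_with("male_strain_"),
                dplyr::starts_with("color_"),
                "winner_strain", "winner_color", "latency_min", "mated")
}

#' Simulate competitive-fitness records
#'
#' Full-factorial within-block strain crosses; a focal wild-type fly from
#' each cross competes against a brown-eyed standard, and the offspring of
#' both are counted. Within-strain crosses get double replication (all
#' between-strain crosses are reciprocal). Wild-type counts are Poisson with
#' log rate `wt_advantage + block + cross + u[m,f] + noise`; within-strain
#' rows carry the
#' `-inbreeding_effect` deficit; brown-eyed counts are Poisson at the
#' baseline rate.
#'
#' @inheritParams simulate_noncompetitive
#' @return A tibble: `block`, `m_strain`, `f_strain`, `sex`, `cross`,
#'   `wt`, `be`, `w` (the log-ratio fitness score).
#' @export
simulate_fitness <- function(params, config = params$config,
                             seed = config$seed + 4L) {
  if (config$mean_offspring < 0) abort("mean_offspring must be non-negative")
  grid <- purrr::map_dfr(seq_len(config$n_blocks), function(b) {
    ss <- block_strains(params, b)
    tidyr::expand_grid(block = b, m_strain = ss, f_strain = ss,
                       sex = c("male", "female"))
  })
  grid$cross <- ifelse(grid$m_strain == grid$f_strain, "within", "between")
  grid$n <- config$n_fitness_reps * ifelse(grid$cross == "within", 2L, 1L)
  rec <- tidyr::uncount(grid, weights = .data$n)

  u_key <- paste(params$u$m_strain, params$u$f_strain)
  u_map <- setNames(params$u$u, u_key)

  local_seed(seed, {
    lograte <- log(config$mean_offspring) + config$wt_advantage +
      config$block_effects[rec$block] +
      ifelse(rec$cross == "within", -config$inbreeding_effect, 0) +
      u_map[paste(rec$m_strain, rec$f_strain)] +
      rnorm(nrow(rec), sd = config$fitness_resid_sd)
    rec$wt <- rpois(nrow(rec), exp(lograte))
    rec$be <- rpois(nrow(rec), config$mean_offspring)
  })
  rec$w <- fitness_score(rec$wt, rec$be)
  dplyr::select(tibble::as_tibble(rec), "block", "m_strain", "f_strain",
                "sex", "cross", "wt", "be", "w")
}

#' Simulate egg-to-adult viability records
#'
#' Single-pair crosses in the same full-factorial design. Vials are
#' zero-inflated (no eggs) at `zero_egg_rate`; otherwise eggs are Poisson
#' and adults binomial with a logit-scale success modified by the
#' female-strain effect and the within-cross deficit.
#'
#' @inheritParams simulate_noncompetitive
#' @return A tibble: `block`, `m_strain`, `f_strain`, `cross`, `eggs`,
#'   `adults`, `w` (log-ratio viability score).
#' @export
simulate_viability <- function(params, config = params$config,
                               seed = config$seed + 5L) {
  if (config$viability_rate < 0 || config$viability_rate > 1)
    abort("viability_rate must lie in [0, 1]")
  grid <- purrr::map_dfr(seq_len(config$n_blocks), function(b) {
    ss <- block_strains(params, b)
    tidyr::expand_grid(block = b, m_strain = ss, f_strain = ss)
  })
  grid$cross <- ifelse(grid$m_strain == grid$f_strain, "within", "between")
  grid$n <- config$n_viability_reps * ifelse(grid$cross == "within", 2L, 1L)
  rec <- tidyr::uncount(grid, weights = .data$n)

  local_seed(seed, {
    empty <- runif(nrow(rec)) < config$zero_egg_rate
    eggs <- ifelse(empty, 0L, rpois(nrow(rec), config$mean_eggs))
    p <- plogis(qlogis(config$viability_rate) +
                  params$viab_f[rec$f_strain] +
                  ifelse(rec$cross == "within", -config$viab_inbreeding, 0) +
                  rnorm(nrow(rec), sd = config$viab_resid_sd))
    unfert <- runif(nrow(rec)) < config$unfertilized_rate
    rec$eggs <- as.integer(eggs)
    rec$adults <- ifelse(unfert, 0L, rbinom(nrow(rec), rec$eggs, p))
  })
  rec$w <- viability_score(rec$eggs, rec$adults)
  dplyr::select(tibble::as_tibble(rec), "block", "m_strain", "f_strain",
                "cross", "eggs", "adults", "w")
}

#' Simulate nine-landmark wing configurations and sex-comb counts
#'
#' Each wing is the mean shape plus a strain-level shape shift, a strain and
#' individual size factor and isotropic landmark noise, after which a random
#' rotation, translation and digitizing scale are applied (so alignment has
#' real work to do). A configured fraction of wings are planted gross shape
#' outliers: one landmark is displaced by `outlier_shift` noise SDs. Comb
#' tooth counts are rounded normal with a strain effect.
#'
#' @inheritParams simulate_noncompetitive
#' @return A list with `landmarks` (long tibble: `wing_id`, `strain`,
#'   `vial`, `landmark`, `x`, `y`, `scale` in mm per digitized unit) and
#'   `wings` (`wing_id`, `strain`, `vial`, `comb_teeth`, `planted_outlier`).
#' @export
simulate_morphology <- function(params, config = params$config,
                                seed = config$seed + 6L) {
  if (!all(dim(config$landmark_mean_shape) == c(9, 2)))
    abort("landmark_mean_shape must be a 9 x 2 coordinate matrix")
  strains <- params$strains$strain
  nw <- config$n_wings_per_strain

  local_seed(seed, {
    shape_eff <- lapply(strains, function(s)
      matrix(rnorm(18, sd = config$strain_shape_sd), 9, 2))
    names(shape_eff) <- strains
    size_eff <- setNames(rnorm(length(strains), sd = config$strain_size_sd),
                         strains)
    comb_eff <- setNames(rnorm(length(strains), sd = config$comb_strain_sd),
                         strains)

    wings <- tidyr::expand_grid(strain = strains, idx = seq_len(nw))
    wings$wing_id <- sprintf("w_%s_%02d", wings$strain, wings$idx)
    wings$vial <- sample(config$n_vials_per_strain, nrow(wings),
                         replace = TRUE)
    wings$comb_teeth <- as.integer(round(
      config$comb_mean + comb_eff[wings$strain] +
        rnorm(nrow(wings), sd = config$comb_sd)))
    wings$planted_outlier <- runif(nrow(wings)) < config$outlier_rate

    lm_list <- vector("list", nrow(wings))
    for (i in seq_len(nrow(wings))) {
      s <- wings$strain[i]
      co <- (config$landmark_mean_shape + shape_eff[[s]] +
               matrix(rnorm(18, sd = config$landmark_noise_sd), 9, 2)) *
        exp(size_eff[s] + rnorm(1, sd = config$wing_size_sd))
      if (wings$planted_outlier[i]) {
        lm_i <- sample(9, 1)
        ang <- runif(1, 0, 2 * pi)
        co[lm_i, ] <- co[lm_i, ] + config$outlier_shift *
          config$landmark_noise_sd * c(cos(ang), sin(ang))
      }
      th <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      px_per_mm <- runif(1, 80, 120)
      co <- (co %*% rot + matrix(runif(2, -2, 2), 9, 2, byrow = TRUE)) *
        px_per_mm
      lm_list[[i]] <- tibble::tibble(
        wing_id = wings$wing_id[i], strain = s, vial = wings$vial[i],
        landmark = 1:9, x = co[, 1], y = co[, 2], scale = 1 / px_per_mm)
    }
    list(landmarks = dplyr::bind_rows(lm_list),
         wings = dplyr::select(wings, "wing_id", "strain", "vial",
                               "comb_teeth", "planted_outlier"))
  })
}

#' Simulate a complete synthetic study
#'
#' Runs every generator with seeds derived from the master seed by fixed
#' offsets (+1 effects, +2 noncompetitive, +3 competitive, +4 fitness,
#' +5 viability, +6 morphology) and returns all tables together with the
#' true parameters, so parameter-recovery checks can compare estimates
#' against truth.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list: `noncompetitive`, `competitive`, `fitness`,
#'   `viability`, `morphology`, `true_params`, `config`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_blocks = 1,
#'   n_noncomp_trials_per_cell = 2, n_comp_vials_per_cell = 2,
#'   n_fitness_reps = 1, n_viability_reps = 1, n_wings_per_strain = 3))
#' nrow(study$noncompetitive)
simulate_study <- function(config = sim_config()) {
  params <- draw_strain_effects(config, config$seed + 1L)
  structure(list(
    noncompetitive = simulate_noncompetitive(params, config, config$seed + 2L),
    competitive = simulate_competitive(params, config, config$seed + 3L),
    fitness = simulate_fitness(params, config, config$seed + 4L),
    viability = simulate_viability(params, config, config$seed + 5L),
    morphology = simulate_morphology(params, config, config$seed + 6L),
    true_params = params,
    config = config
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>\n")
  cat(sprintf("  %d noncompetitive trials, %d competitive vials\n",
              nrow(x$noncompetitive), nrow(x$competitive)))
  cat(sprintf("  %d fitness records, %d viability vials, %d wings\n",
              nrow(x$fitness), nrow(x$viability), nrow(x$morphology$wings)))
  invisible(x)
}
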