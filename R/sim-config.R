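#' Configuration of a synthetic mate-choice study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' describe the design this package emulates: five replicate blocks of four
#' isofemale strains (20 strains in all), noncompetitive single-pair latency
#' trials censored at two hours, four-male competition vials with dye-marked
#' males, full-factorial within-block fitness and viability crosses with
#' within-strain crosses at double replication, and nine-landmark right-wing
#' configurations with sex-comb tooth counts.
#'
#' Strain-level male effects enter the mating-latency model as a
#' four-variate normal deviate per strain, one coordinate per context
#' (`V+C+`, `V-C+`, `V+C-`, `V-C-`), with standard deviations `context_sds`
#' and correlation matrix `context_corr`; the same effect drives both the
#' single-male latency and the competitive race, which is what a
#' cross-context correlation presupposes.
#'
#' @param n_blocks Number of replicate blocks.
#' @param strains_per_block Isofemale strains per block (each strain belongs
#'   to exactly one block).
#' @param n_noncomp_trials_per_cell Noncompetitive trials per block x
#'   female-strain x male-strain cell; either one count or a named pair
#'   `c(virgin = , nonvirgin = )`.
#' @param n_comp_vials_per_cell Competition vials per block x female-strain
#'   cell, same recycling rule.
#' @param censor_minutes Trial duration; pairs not mating by this time are
#'   censored.
#' @param context_sds Length-4 vector of male-strain effect SDs on the
#'   log-latency / logit scale, ordered as `mv_contexts()`.
#' @param context_corr 4x4 correlation matrix of male-strain effects across
#'   contexts (symmetric, unit diagonal, positive semi-definite).
#' @param female_strain_sd SD of female-strain responsiveness effects.
#' @param baseline_latency Median latency (minutes) of a neutral pair, named
#'   pair by female status; the virgin/non-virgin defaults give roughly 91%
#'   and 39% of noncompetitive trials mating before the censor.
#' @param baseline_latency_comp As above for the competitive race (the vial
#'   mates when the fastest of four males beats the censor), tuned so that
#'   roughly 93% of virgin and 47% of non-virgin vials mate.
#' @param latency_log_sd Residual SD of log latency.
#' @param color_effects Named length-4 vector of abdomen-dye effects on the
#'   log-latency scale (positive = faster); small values reproduce win
#'   shares near 25% per color.
#' @param inbreeding_effect Mean log-ratio fitness deficit of within-strain
#'   crosses.
#' @param mf_interaction_sd SD of male-strain by female-strain cross effects
#'   on fitness.
#' @param block_effects Per-block shifts of the fitness log rate.
#' @param mean_offspring Expected offspring count per competitor in a
#'   fitness vial.
#' @param fitness_resid_sd SD of the vial-level log-rate noise on wild-type
#'   counts (residual variation beyond Poisson).
#' @param wt_advantage Baseline log-rate advantage of experimental
#'   wild-type flies over the brown-eyed standard.
#' @param n_fitness_reps Fitness replicates per between-strain cross and sex;
#'   within-strain crosses get twice as many (between-strain crosses are
#'   reciprocal).
#' @param viability_rate Egg-to-adult probability of a typical
#'   between-strain cross (the overall adults/eggs ratio comes out lower
#'   once vial heterogeneity, within-cross deficits and unfertilized vials
#'   act on it).
#' @param mean_eggs Mean egg count of non-empty viability vials.
#' @param zero_egg_rate Proportion of viability vials with no eggs.
#' @param viab_f_strain_sd SD of female-strain viability effects (logit).
#' @param viab_resid_sd SD of vial-level logit-viability heterogeneity.
#' @param unfertilized_rate Proportion of egg-laying vials whose eggs are
#'   unfertilized (no adults emerge), emulating vials where the pair never
#'   mated.
#' @param viab_inbreeding Logit-scale viability deficit of within-strain
#'   crosses.
#' @param n_viability_reps Viability replicates per between-strain cross;
#'   within-strain doubled.
#' @param landmark_mean_shape 9x2 matrix of mean wing landmark coordinates
#'   in mm; the distance between landmarks 3 and 9 is the mean wing length.
#' @param landmark_noise_sd Isotropic per-landmark digitizing/biological
#'   noise, mm.
#' @param strain_shape_sd SD of per-strain landmark shape shifts, mm.
#' @param strain_size_sd SD of per-strain log wing-size factors.
#' @param wing_size_sd SD of per-wing log size factors.
#' @param comb_mean Mean total sex-comb tooth count (both legs).
#' @param comb_sd Within-strain SD of tooth counts.
#' @param comb_strain_sd Among-strain SD of tooth counts.
#' @param outlier_rate Proportion of wings planted as gross shape outliers.
#' @param outlier_shift Displacement of the planted outlier landmark, in
#'   multiples of `landmark_noise_sd`.
#' @param n_wings_per_strain Wings measured per strain.
#' @param n_vials_per_strain Rearing vials wings are attributed to.
#' @param seed Master seed; per-operation seeds are derived by fixed offsets.
#'
#' @return A `sim_config` object (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_blocks = 2, n_noncomp_trials_per_cell = 4)
#' cfg$n_blocks
sim_config <- function(n_blocks = 5,
                       strains_per_block = 4,
                       n_noncomp_trials_per_cell = c(virgin = 19, nonvirgin = 15),
                       n_comp_vials_per_cell = c(virgin = 21, nonvirgin = 32),
                       censor_minutes = 120,
                       context_sds = c(0.27, 0.41, 0.32, 0.38),
                       context_corr = default_context_corr(),
                       female_strain_sd = 0.5,
                       baseline_latency = c(virgin = 16, nonvirgin = 182),
                       baseline_latency_comp = c(virgin = 110, nonvirgin = 660),
                       latency_log_sd = 1.5,
                       color_effects = c(black = 0.035, blue = -0.01,
                                         green = -0.035, red = 0.025),
                       inbreeding_effect = 0.6,
                       mf_interaction_sd = 0.45,
                       block_effects = NULL,
                       mean_offspring = 40,
                       fitness_resid_sd = 1.6,
                       wt_advantage = 0.7,
                       n_fitness_reps = 10,
                       viability_rate = 0.84,
                       mean_eggs = 24,
                       zero_egg_rate = 0.44,
                       viab_f_strain_sd = 0.4,
                       viab_resid_sd = 1.0,
                       unfertilized_rate = 0.09,
                       viab_inbreeding = 0.5,
                       n_viability_reps = 10,
                       landmark_mean_shape = default_wing_shape(),
                       landmark_noise_sd = 0.01,
                       strain_shape_sd = 0.005,
                       strain_size_sd = 0.03,
                       wing_size_sd = 0.02,
                       comb_mean = 21,
                       comb_sd = 1.2,
                       comb_strain_sd = 0.8,
                       outlier_rate = 0.008,
                       outlier_shift = 15,
                       n_wings_per_strain = 39,
                       n_vials_per_strain = 6,
                       seed = 1L) {
  if (is.null(block_effects))
    block_effects <- rep_len(c(0, 0.35, -0.2, 0.15, -0.3), n_blocks)

  cfg <- list(
    n_blocks = as.integer(n_blocks),
    strains_per_block = as.integer(strains_per_block),
    n_noncomp_trials_per_cell = recycle_by_status(n_noncomp_trials_per_cell),
    n_comp_vials_per_cell = recycle_by_status(n_comp_vials_per_cell),
    censor_minutes = censor_minutes,
    context_sds = setNames(as.numeric(context_sds), mv_contexts()),
    context_corr = context_corr,
    female_strain_sd = female_strain_sd,
    baseline_latency = recycle_by_status(baseline_latency),
    baseline_latency_comp = recycle_by_status(baseline_latency_comp),
    latency_log_sd = latency_log_sd,
    color_effects = setNames(as.numeric(color_effects), mv_colors()),
    inbreeding_effect = inbreeding_effect,
    mf_interaction_sd = mf_interaction_sd,
    block_effects = rep_len(block_effects, n_blocks),
    mean_offspring = mean_offspring,
    fitness_resid_sd = fitness_resid_sd,
    wt_advantage = wt_advantage,
    n_fitness_reps = as.integer(n_fitness_reps),
    viability_rate = viability_rate,
    mean_eggs = mean_eggs,
    zero_egg_rate = zero_egg_rate,
    viab_f_strain_sd = viab_f_strain_sd,
    viab_resid_sd = viab_resid_sd,
    unfertilized_rate = unfertilized_rate,
    viab_inbreeding = viab_inbreeding,
    n_viability_reps = as.integer(n_viability_reps),
    landmark_mean_shape = landmark_mean_shape,
    landmark_noise_sd = landmark_noise_sd,
    strain_shape_sd = strain_shape_sd,
    strain_size_sd = strain_size_sd,
    wing_size_sd = wing_size_sd,
    comb_mean = comb_mean,
    comb_sd = comb_sd,
    comb_strain_sd = comb_strain_sd,
    outlier_rate = outlier_rate,
    outlier_shift = outlier_shift,
    n_wings_per_strain = as.integer(n_wings_per_strain),
    n_vials_per_strain = as.integer(n_vials_per_strain),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

recycle_by_status <- function(x) {
  if (length(x) == 1) x <- c(virgin = unname(x), nonvirgin = unname(x))
  if (is.null(names(x)) || !setequal(names(x), mv_statuses()))
    names(x) <- mv_statuses()
  x[mv_statuses()]
}

#' @rdname sim_config
#' @export
default_context_corr <- function() {
  r <- matrix(c(1.00, 0.46, 0.43, 0.28,
                0.46, 1.00, 0.18, 0.02,
                0.43, 0.18, 1.00, 0.80,
                0.28, 0.02, 0.80, 1.00), 4, 4)
  dimnames(r) <- list(mv_contexts(), mv_contexts())
  r
}

#' @rdname sim_config
#' @export
default_wing_shape <- function() {
  m <- matrix(c(0.10, 0.22,
                0.45, 0.35,
                0.10, 0.05,
                0.90, 0.45,
                1.35, 0.30,
                0.80, -0.10,
                1.30, -0.05,
                1.45, 0.35,
                1.60, 0.10), ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

validate_sim_config <- function(cfg) {
  if (cfg$strains_per_block < 2)
    abort("strains_per_block must be at least 2")
  if (cfg$censor_minutes <= 0) abort("censor_minutes must be positive")
  sds <- c(cfg$context_sds, cfg$female_strain_sd, cfg$latency_log_sd,
           cfg$mf_interaction_sd, cfg$fitness_resid_sd, cfg$viab_f_strain_sd,
           cfg$landmark_noise_sd, cfg$strain_shape_sd, cfg$strain_size_sd,
           cfg$wing_size_sd, cfg$comb_sd, cfg$comb_strain_sd)
  if (any(sds < 0)) abort("all standard deviations must be non-negative")
  check_corr_matrix(cfg$context_corr, 4)
  if (cfg$mean_offspring < 0) abort("mean_offspring must be non-negative")
  if (cfg$viability_rate < 0 || cfg$viability_rate > 1)
    abort("viability_rate must lie in [0, 1]")
  if (cfg$zero_egg_rate < 0 || cfg$zero_egg_rate > 1)
    abort("zero_egg_rate must lie in [0, 1]")
  if (cfg$unfertilized_rate < 0 || cfg$unfertilized_rate > 1)
    abort("unfertilized_rate must lie in [0, 1]")
  if (!is.matrix(cfg$landmark_mean_shape) ||
      !all(dim(cfg$landmark_mean_shape) == c(9, 2)))
    abort("landmark_mean_shape must be a 9 x 2 coordinate matrix")
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1)
    abort("outlier_rate must lie in [0, 1]")
  cfg
}

check_corr_matrix <- function(r, d) {
  if (!is.matrix(r) || !all(dim(r) == c(d, d)))
    abort(paste0("context_corr must be a ", d, " x ", d, " matrix"))
  if (max(abs(r - t(r))) > 1e-8) abort("context_corr must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8)
    abort("context_corr must have a unit diagonal")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    abort("context_corr is not positive semi-definite")
  invisible(r)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d blocks x %d strains; censor %g min\n", x$n_blocks,
              x$strains_per_block, x$censor_minutes))
  cat("  context SDs:", paste(sprintf("%s=%.2f", names(x$context_sds),
                                      x$context_sds), collapse = ", "), "\n")
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
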