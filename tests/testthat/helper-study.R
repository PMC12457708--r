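# small study configurations and hand-built tables shared across tests

tiny_config <- function(...) {
  defaults <- list(n_blocks = 2, n_noncomp_trials_per_cell = 4,
                   n_comp_vials_per_cell = 5, n_fitness_reps = 2,
                   n_viability_reps = 2, n_wings_per_strain = 6, seed = 99L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

quick_spec <- function(chains = 2, iter = 600, thin = 2, seed = 1L, ...) {
  choice_model_spec(chains = chains, iter = iter, warmup = 0.5, thin = thin,
                    seed = seed, ...)
}

# a binary-outcome table built directly from per-strain success
# probabilities (bypasses the latency machinery)
make_binary <- function(p_by_strain, n_per_strain, context = "V+C-",
                        seed = 1, female_strains = 4) {
  strains <- names(p_by_strain)
  n <- length(strains) * n_per_strain
  noncomp <- context %in% c("V+C-", "V-C-")
  withr::with_seed(seed, {
    fs <- if (noncomp)
      sample(sprintf("F%02d", seq_len(female_strains)), n, replace = TRUE)
    else rep(NA_character_, n)
    cl <- if (!noncomp)
      sample(c("black", "blue", "green", "red"), n, replace = TRUE)
    else rep(NA_character_, n)
    tibble::tibble(
      block = 1L,
      context = context,
      male_strain = rep(strains, each = n_per_strain),
      female_strain = fs,
      color = cl,
      success = rbinom(n, 1, rep(p_by_strain, each = n_per_strain)),
      source_vial = sprintf("v%05d", seq_len(n))
    )
  })
}

# competitive vial table with a fixed winner in every vial
make_vials <- function(n, winner = "A", seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    vial = sprintf("cv%05d", seq_len(n)),
    block = 1L,
    female_strain = "A",
    female_status = rep(c("virgin", "nonvirgin"), length.out = n),
    context = status_context(rep(c("virgin", "nonvirgin"), length.out = n),
                             TRUE),
    male_strain_1 = "A", male_strain_2 = "B",
    male_strain_3 = "C", male_strain_4 = "D",
    color_1 = "black", color_2 = "blue",
    color_3 = "green", color_4 = "red",
    winner_strain = winner,
    winner_color = "black",
    latency_min = 10,
    mated = TRUE
  ))
}

# wing landmark long table from an array of configurations
wings_from_coords <- function(coord_list, scale = 1) {
  purrr::imap_dfr(coord_list, function(co, i) {
    tibble::tibble(wing_id = paste0("w", i), strain = "S01", vial = 1L,
                   landmark = seq_len(nrow(co)), x = co[, 1], y = co[, 2],
                   scale = scale)
  })
}

rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
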