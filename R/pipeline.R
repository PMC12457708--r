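# CSV schemas for every table the pipeline reads or writes. Each entry
# gives readr column types plus row-level validity checks.
mv_schemas <- function() {
  list(
    noncompetitive = list(
      cols = readr::cols(trial = "c", block = "i", female_strain = "c",
                         male_strain = "c", female_status = "c",
                         context = "c", latency_min = "d", mated = "l"),
      checks = list(
        list(fn = function(d) d$female_status %in% mv_statuses(),
             msg = "female_status must be virgin/nonvirgin"),
        list(fn = function(d) d$mated %in% c(TRUE, FALSE),
             msg = "mated must be logical"))),
    competitive = list(
      cols = readr::cols(vial = "c", block = "i", female_strain = "c",
                         female_status = "c", context = "c",
                         male_strain_1 = "c", male_strain_2 = "c",
                         male_strain_3 = "c", male_strain_4 = "c",
                         color_1 = "c", color_2 = "c", color_3 = "c",
                         color_4 = "c", winner_strain = "c",
                         winner_color = "c", latency_min = "d",
                         mated = "l"),
      checks = list(
        list(fn = function(d) {
          ms <- as.matrix(d[paste0("male_strain_", 1:4)])
          is.na(d$winner_strain) | rowSums(ms == d$winner_strain) > 0
        }, msg = "winner_strain must be one of the vial's males"))),
    binary = list(
      cols = readr::cols(block = "i", context = "c", male_strain = "c",
                         female_strain = "c", color = "c", success = "i",
                         source_vial = "c"),
      checks = list(
        list(fn = function(d) d$success %in% c(0L, 1L),
             msg = "success must be 0 or 1"),
        list(fn = function(d) d$context %in% mv_contexts(),
             msg = "unknown context label"))),
    fitness = list(
      cols = readr::cols(block = "i", m_strain = "c", f_strain = "c",
                         sex = "c", cross = "c", wt = "i", be = "i",
                         w = "d"),
      checks = list(
        list(fn = function(d) d$wt >= 0 & d$be >= 0,
             msg = "offspring counts must be non-negative"))),
    viability = list(
      cols = readr::cols(block = "i", m_strain = "c", f_strain = "c",
                         cross = "c", eggs = "i", adults = "i", w = "d"),
      checks = list(
        list(fn = function(d) d$adults <= d$eggs & d$adults >= 0,
             msg = "adults must lie in [0, eggs]"))),
    landmarks = list(
      cols = readr::cols(wing_id = "c", strain = "c", vial = "i",
                         landmark = "i", x = "d", y = "d", scale = "d"),
      checks = list(
        list(fn = function(d) d$landmark >= 1 & d$landmark <= 9,
             msg = "landmark index must be 1..9"),
        list(fn = function(d) d$scale > 0, msg = "scale must be positive"))),
    wings = list(
      cols = readr::cols(wing_id = "c", strain = "c", vial = "i",
                         comb_teeth = "i", planted_outlier = "l"),
      checks = list())
  )
}

#' Read or write a pipeline CSV with schema validation
#'
#' `read_table()` reads a CSV (skipping `#` provenance comment lines),
#' checks it against the named schema and reports any violating row
#' numbers; `write_table()` writes the table with a provenance comment
#' header. The round trip is lossless for every schema.
#'
#' @param path File path.
#' @param schema One of `"noncompetitive"`, `"competitive"`, `"binary"`,
#'   `"fitness"`, `"viability"`, `"landmarks"`, `"wings"`.
#' @return `read_table()` returns a tibble; `write_table()` the path,
#'   invisibly.
#' @export
read_table <- function(path, schema) {
  sch <- mv_schemas()[[schema]]
  if (is.null(sch)) abort(paste0("unknown schema: ", schema))
  d <- suppressWarnings(readr::read_csv(path, comment = "#",
                                        col_types = sch$cols,
                                        progress = FALSE))
  expected <- names(sch$cols$cols)
  missing <- setdiff(expected, names(d))
  if (length(missing) > 0)
    abort(paste0(path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (nrow(d) > 0) {
    for (chk in sch$checks) {
      ok <- chk$fn(d)
      ok[is.na(ok)] <- TRUE
      if (!all(ok))
        abort(paste0(path, ": ", chk$msg, " (row ",
                     paste(head(which(!ok), 5), collapse = ", "), ")"))
    }
  }
  d
}

#' @rdname read_table
#' @param table The tibble to write.
#' @param provenance Named character vector written as `# key=value`
#'   comment lines (timestamps are deliberately excluded so identical runs
#'   produce byte-identical tables).
#' @export
write_table <- function(table, path, provenance = NULL) {
  header <- character(0)
  if (!is.null(provenance))
    header <- paste0("# ", names(provenance), "=", provenance)
  writeLines(header, path)
  readr::write_csv(table, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read landmark configurations from a TPS file
#'
#' Minimal TPS support: `LM=` blocks with one x/y pair per line and
#' optional `ID=` and `SCALE=` records.
#'
#' @param path TPS file path.
#' @return A long landmark tibble (`wing_id`, `landmark`, `x`, `y`,
#'   `scale`).
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  out <- list()
  i <- 1
  wing <- 0
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i])) abort("malformed TPS file: expected LM=")
    k <- as.integer(sub("^LM=", "", lines[i]))
    coords <- do.call(rbind, strsplit(lines[i + seq_len(k)], "[ \t]+"))
    i <- i + k + 1
    id <- NULL
    scale <- 1
    while (i <= length(lines) && !grepl("^LM=", lines[i])) {
      if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
      if (grepl("^SCALE=", lines[i]))
        scale <- as.numeric(sub("^SCALE=", "", lines[i]))
      i <- i + 1
    }
    wing <- wing + 1
    out[[wing]] <- tibble::tibble(
      wing_id = id %||% paste0("tps_", wing), landmark = seq_len(k),
      x = as.numeric(coords[, 1]), y = as.numeric(coords[, 2]),
      scale = scale)
  }
  dplyr::bind_rows(out)
}

#' @rdname read_tps
#' @param landmarks Long landmark tibble.
#' @export
write_tps <- function(landmarks, path) {
  ids <- unique(landmarks$wing_id)
  lines <- unlist(lapply(ids, function(id) {
    d <- dplyr::arrange(landmarks[landmarks$wing_id == id, ], .data$landmark)
    c(paste0("LM=", nrow(d)), paste(d$x, d$y),
      paste0("ID=", id),
      paste0("SCALE=", if ("scale" %in% names(d)) d$scale[1] else 1))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> trial prep -> resampled choice-model
#' fit -> fitness/viability mixed models (with one residual-outlier pass
#' and refit) -> morphometrics -> strain-mean regressions, writing every
#' table as CSV with a seed/version provenance header plus a run log. All
#' randomness derives from the master seed, inputs are never mutated, and
#' rerunning an identical configuration reproduces the tables byte for
#' byte.
#'
#' @param config A named list (or path to a YAML file): `seed`; `sim` (a
#'   list of [sim_config()] overrides) or `input` (a list of CSV paths:
#'   `noncompetitive`, `competitive`, `fitness`, `viability`, `landmarks`,
#'   `wings`); `prep` (`quantile`, `n_resamples`); `mcmc` (`chains`,
#'   `iter`, `warmup`, `thin`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report bundle: the fitted objects and the paths
#'   of the written tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("seed"))
    if (is.null(config[[field]]))
      abort(paste0("pipeline config is missing required field: ", field))
  if (is.null(config$sim) && is.null(config$input))
    abort("pipeline config needs either a `sim` block or an `input` block")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  log_lines <- c(paste0("run started ", format(Sys.time())),
                 paste0("seed ", seed))
  prov <- c(seed = seed,
            package = paste0("matevar ",
                             as.character(utils::packageVersion("matevar"))))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e))))
  }

  # ---- inputs ----
  if (!is.null(config$sim)) {
    cfg <- stage("simulate",
                 do.call(sim_config, c(config$sim, list(seed = seed))))
    study <- stage("simulate", simulate_study(cfg))
    noncomp <- study$noncompetitive
    comp <- study$competitive
    fitness <- study$fitness
    viability <- study$viability
    landmarks <- study$morphology$landmarks
    wings <- study$morphology$wings
    write_table(noncomp, file.path(out_dir, "noncompetitive.csv"), prov)
    write_table(comp, file.path(out_dir, "competitive.csv"), prov)
    write_table(fitness, file.path(out_dir, "fitness.csv"), prov)
    write_table(viability, file.path(out_dir, "viability.csv"), prov)
    write_table(landmarks, file.path(out_dir, "landmarks.csv"), prov)
    write_table(wings, file.path(out_dir, "wings.csv"), prov)
    jsonlite::write_json(
      list(a = study$true_params$a, b = study$true_params$b,
           strains = study$true_params$strains),
      file.path(out_dir, "true_params.json"), digits = NA)
    log_lines <- c(log_lines, "simulated study written")
  } else {
    inp <- config$input
    noncomp <- stage("read", read_table(inp$noncompetitive, "noncompetitive"))
    comp <- stage("read", read_table(inp$competitive, "competitive"))
    fitness <- if (!is.null(inp$fitness))
      stage("read", read_table(inp$fitness, "fitness"))
    viability <- if (!is.null(inp$viability))
      stage("read", read_table(inp$viability, "viability"))
    landmarks <- if (!is.null(inp$landmarks))
      stage("read", read_table(inp$landmarks, "landmarks"))
    wings <- if (!is.null(inp$wings))
      stage("read", read_table(inp$wings, "wings"))
  }

  # ---- trial prep ----
  quantile_ <- config$prep$quantile %||% 0.25
  n_resamples <- config$prep$n_resamples %||% 100
  nc_bin <- stage("prep", binarize_latency(noncomp, quantile = quantile_))
  vials <- dplyr::filter(comp, .data$mated & !is.na(.data$winner_strain))
  log_lines <- c(log_lines,
                 paste0(nrow(comp) - nrow(vials),
                        " unmated/unidentified vials excluded"))

  # ---- choice model over resamples ----
  spec <- choice_model_spec(
    chains = config$mcmc$chains %||% 4,
    iter = config$mcmc$iter %||% 20000,
    warmup = config$mcmc$warmup %||% 0.5,
    thin = config$mcmc$thin %||% 10,
    seed = seed + 100L)
  fit <- stage("fit-choice",
               fit_resampled_choice_model(nc_bin, vials, n_resamples, spec,
                                          resample_seed = seed + 200L))
  table1 <- stage("fit-choice", table1_report(fit))
  write_table(table1, file.path(out_dir, "table1_choice.csv"), prov)

  sm_noncomp <- strain_mean_correlation(
    dplyr::filter(nc_bin, .data$context == "V+C-"),
    dplyr::filter(nc_bin, .data$context == "V-C-"))
  one_set <- resample_competitive(vials, seed + 201L)
  sm_comp <- tryCatch(strain_mean_correlation(
    dplyr::filter(one_set, .data$context == "V+C+"),
    dplyr::filter(one_set, .data$context == "V-C+")),
    error = function(e) NA_real_)
  write_table(tibble::tibble(arena = c("noncompetitive", "competitive"),
                             correlation = c(sm_noncomp, sm_comp)),
              file.path(out_dir, "strain_mean_correlations.csv"), prov)

  # ---- fitness / viability ----
  fit_trait <- function(d, label) {
    m1 <- fit_cross_lmm(d, "w")
    filt <- residual_outlier_filter(m1$data, m1$model, k = 2)
    m2 <- fit_cross_lmm(filt$records, "w")
    log_lines <<- c(log_lines, paste0(label, ": ", filt$n_removed,
                                      " residual outliers removed"))
    m2
  }
  table2 <- NULL
  lmms <- list()
  if (!is.null(fitness)) {
    lmms$male_fitness <- stage("fit-fitness",
      fit_trait(dplyr::filter(fitness, .data$sex == "male"), "male fitness"))
    lmms$female_fitness <- stage("fit-fitness",
      fit_trait(dplyr::filter(fitness, .data$sex == "female"),
                "female fitness"))
  }
  if (!is.null(viability)) {
    kept <- stage("fit-fitness", filter_viability(viability))
    log_lines <- c(log_lines,
                   paste0("viability: ", kept$n_zero_egg, " zero-egg and ",
                          kept$n_zero_adult, " zero-adult vials removed"))
    lmms$viability <- stage("fit-fitness", fit_trait(kept$records,
                                                     "viability"))
  }
  if (length(lmms) > 0) {
    table2 <- purrr::imap_dfr(lmms, function(m, nm)
      dplyr::mutate(tidy(m), trait = nm, .before = 1))
    write_table(table2, file.path(out_dir, "table2_fitness.csv"), prov)
  }

  # ---- morphometrics ----
  morpho_tab <- NULL
  if (!is.null(landmarks)) {
    space <- stage("morpho", shape_pca(gpa_align(landmarks)))
    npc <- min(space$n_nonzero, 14)
    traits <- dplyr::select(space$scores, "wing_id",
                            dplyr::all_of(paste0("PC", seq_len(npc))))
    traits$size <- space$info$centroid_size
    flags <- stage("morpho",
                   mahalanobis_outliers(dplyr::select(traits, -"wing_id")))
    keep_ids <- traits$wing_id[!flags$.outlier]
    log_lines <- c(log_lines, paste0("morphometrics: ",
                                     sum(flags$.outlier),
                                     " outlier wings removed"))
    wl <- wing_length(landmarks)
    per_wing <- space$scores |>
      dplyr::filter(.data$wing_id %in% keep_ids) |>
      dplyr::left_join(wl, by = "wing_id")
    if (!is.null(wings))
      per_wing <- dplyr::left_join(
        per_wing, dplyr::select(wings, "wing_id", "comb_teeth"),
        by = "wing_id")
    strain_means <- per_wing |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(wing_length_mm = mean(.data$wing_length_mm),
                       pc1 = mean(.data$PC1),
                       comb_teeth = mean(.data$comb_teeth), .groups = "drop")
    succ <- nc_bin |>
      dplyr::group_by(.data$context, .data$male_strain) |>
      dplyr::summarise(success = mean(.data$success), .groups = "drop")
    morpho_tab <- purrr::map_dfr(mv_noncomp_contexts(), function(k) {
      st <- dplyr::inner_join(
        strain_means,
        dplyr::filter(succ, .data$context == k) |>
          dplyr::select(strain = "male_strain", "success"),
        by = "strain")
      dplyr::mutate(strain_trait_regression(st, "success"),
                    context = k, .before = 1)
    })
    write_table(morpho_tab, file.path(out_dir, "morpho_regression.csv"),
                prov)
  }

  log_lines <- c(log_lines, paste0("run finished ", format(Sys.time())))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(list(seed = seed, package = unname(prov["package"])),
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE)

  invisible(list(choice_fit = fit, table1 = table1, lmms = lmms,
                 table2 = table2, morpho = morpho_tab,
                 strain_mean_correlations =
                   c(noncompetitive = sm_noncomp, competitive = sm_comp),
                 out_dir = out_dir))
}

#' Choice-model report shaped like a variance/correlation matrix table
#'
#' Long table with one row per matrix cell: diagonal cells are the
#' male-strain SDs per context, off-diagonal cells the cross-context
#' correlations, each with posterior mode, 95% HDCI and the
#' interval-excludes-zero flag for correlations.
#'
#' @param fit A `choice_fit`.
#' @param mass Interval mass.
#' @return A tibble: `row_context`, `col_context`, `quantity`, `mode`,
#'   `lower`, `upper`, `excludes_zero`.
#' @export
table1_report <- function(fit, mass = 0.95) {
  s <- tidy(fit, mass = mass, check_rhat = FALSE)
  ctx <- fit$contexts
  rows <- list()
  for (i in seq_along(ctx)) {
    for (j in seq_len(i)) {
      if (i == j) {
        p <- paste0("sigma[", ctx[i], "]")
        q <- "sd"
      } else {
        p <- paste0("R[", ctx[j], ",", ctx[i], "]")
        q <- "correlation"
      }
      r <- s[s$parameter == p, ]
      if (nrow(r) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        row_context = ctx[i], col_context = ctx[j], quantity = q,
        mode = r$mode, lower = r$.lower, upper = r$.upper,
        excludes_zero = if (q == "correlation")
          test_correlation_vs_zero(r) else NA)
    }
  }
  dplyr::bind_rows(rows)
}
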