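#' Binarize noncompetitive latencies at a per-group quantile
#'
#' Makes single-pair latency trials comparable with the ~25%-success
#' competitive data: within every block x female-status group, a trial is
#' scored a success iff it mated and its latency is at or below the group's
#' latency quantile (default the 25th percentile), computed over all trials
#' in the group with censored trials counted as slower than any observed
#' latency. If a group's raw mated fraction is already below the target
#' quantile the raw mated flags are returned unchanged for that group.
#'
#' Ties at the threshold all count as successes (the inclusive rule keeps
#' the map deterministic and monotone), and the quantile is the
#' linear-interpolation empirical quantile.
#'
#' @param trials A noncompetitive trial table (see
#'   [simulate_noncompetitive()]): `block`, `female_status`, `latency_min`,
#'   `mated`, plus identifier columns carried through.
#' @param quantile Target success proportion per group.
#' @return A binary-outcome tibble: `block`, `context`, `male_strain`,
#'   `female_strain`, `color` (`NA` for these rows), `success` (0/1),
#'   `source_vial`, plus `female_status`, `latency_min` and `mated`
#'   (re-coded to the binarized success) so the operation can be re-applied.
#' @export
binarize_latency <- function(trials, quantile = 0.25) {
  assert_columns(trials, c("block", "female_status", "male_strain",
                           "latency_min", "mated"), "trial table")
  if (!(quantile > 0 && quantile < 1)) abort("quantile must lie in (0, 1)")
  if (nrow(trials) == 0) abort("trial table is empty")
  if (!all(trials$female_status %in% mv_statuses()))
    abort("unknown female mating status label in trial table")

  out <- trials |>
    dplyr::group_by(.data$block, .data$female_status) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) == 0)
        abort(paste0("empty trial group: block ", key$block, ", ",
                     key$female_status))
      lat <- ifelse(g$mated, g$latency_min, Inf)
      if (mean(g$mated) < quantile) {
        g$success <- as.integer(g$mated)
      } else {
        thr <- quantile(lat, probs = quantile, type = 7, names = FALSE)
        g$success <- as.integer(g$mated & lat <= thr)
      }
      g
    }) |>
    dplyr::ungroup()

  out$context <- status_context(out$female_status, competitive = FALSE)
  out$color <- NA_character_
  out$source_vial <- if ("trial" %in% names(out)) out$trial else
    sprintf("nc_%05d", seq_len(nrow(out)))
  out$mated <- out$success == 1L
  out$latency_min <- ifelse(out$mated, out$latency_min, NA_real_)
  dplyr::select(out, "block", "context", "male_strain",
                dplyr::any_of("female_strain"),
                "color", "success", "source_vial", "female_status",
                "latency_min", "mated")
}

#' Resample one male per competitive vial
#'
#' Converts dependent four-male vials to independent binary rows: one of
#' the four males is sampled uniformly and scored successful iff his strain
#' is the vial's winner, so each row succeeds with probability 1/4. All
#' input vials must have an identified winner; drop unmated vials (which
#' carry no usable outcome) before calling.
#'
#' @param vials A competitive vial table (see [simulate_competitive()]).
#' @param seed Integer seed; the resample is deterministic given the seed.
#' @return A binary-outcome tibble: `block`, `context`, `male_strain`,
#'   `female_strain` (`NA`; the model excludes female effects in the
#'   competitive contexts), `color`, `success`, `source_vial`.
#' @export
resample_competitive <- function(vials, seed) {
  assert_columns(vials, c("vial", "block", "female_status", "winner_strain",
                          paste0("male_strain_", 1:4), paste0("color_", 1:4)),
                 "vial table")
  bad <- which(is.na(vials$winner_strain))
  if (length(bad) > 0)
    abort(paste0(length(bad), " vial(s) without an identified winner ",
                 "(e.g. row ", bad[1], "); drop unmated or unidentified ",
                 "vials before resampling"))
  n <- nrow(vials)
  ms <- as.matrix(vials[paste0("male_strain_", 1:4)])
  cl <- as.matrix(vials[paste0("color_", 1:4)])
  ok <- rowSums(ms == vials$winner_strain, na.rm = TRUE) > 0
  if (!all(ok))
    abort(paste0("winner strain is not among the vial's males (row ",
                 which(!ok)[1], ")"))
  j <- local_seed(seed, sample.int(4L, n, replace = TRUE))
  tibble::tibble(
    block = vials$block,
    context = status_context(vials$female_status, competitive = TRUE),
    male_strain = ms[cbind(seq_len(n), j)],
    female_strain = NA_character_,
    color = cl[cbind(seq_len(n), j)],
    success = as.integer(ms[cbind(seq_len(n), j)] == vials$winner_strain),
    source_vial = vials$vial
  )
}

#' Build repeated competitive resample sets
#'
#' Repeats [resample_competitive()] `n_resamples` times with sub-seeds
#' derived as `seed + i`; the choice model is fit once per set and the
#' posteriors pooled. Noncompetitive data are never resampled.
#'
#' @inheritParams resample_competitive
#' @param n_resamples Number of resample sets (the reference analysis uses
#'   100).
#' @return A list of `n_resamples` binary-outcome tibbles.
#' @export
build_resample_sets <- function(vials, n_resamples = 100, seed = 1L) {
  if (n_resamples < 1) abort("n_resamples must be at least 1")
  purrr::map(seq_len(n_resamples),
             function(i) resample_competitive(vials, seed + i))
}
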