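#' Canonical double-gamma HRF kernel
#'
#' Difference-of-gammas hemodynamic impulse response (shape/rate 6/1 minus
#' 16/1 scaled by 1/6), sampled at the TR, truncated at `duration` seconds,
#' and scaled to peak 1. The impulse response peaks 4--6 s after the event.
#'
#' @param tr Sampling interval, seconds (default 0.75).
#' @param duration Kernel support, seconds (default 32).
#' @return Numeric kernel vector (first sample at t = 0).
#' @export
hrf_kernel <- function(tr = 0.75, duration = 32) {
  stopifnot(tr > 0)
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Convolve neural timecourses with the HRF
#'
#' Causal FFT convolution of one or more neural timecourses with the
#' double-gamma HRF, truncated to the input length (output length equals
#' input length). Linear: `conv(a + b) = conv(a) + conv(b)`.
#'
#' @param x Numeric vector, or a TR x series matrix (each column convolved).
#' @param tr Sampling interval, seconds (default 0.75).
#' @param kernel Optional kernel override (default [hrf_kernel()] at `tr`).
#' @return Convolved series, same shape as `x`.
#' @export
hrf_convolve <- function(x, tr = 0.75, kernel = NULL) {
  if (is.null(kernel)) kernel <- hrf_kernel(tr)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(X)
  L <- n + length(kernel) - 1L
  Hf <- stats::fft(c(kernel, numeric(L - length(kernel))))
  Xf <- stats::mvfft(rbind(X, matrix(0, L - n, ncol(X))))
  Y <- Re(stats::mvfft(Xf * Hf, inverse = TRUE)) / L
  Y <- Y[seq_len(n), , drop = FALSE]
  if (vec) drop(Y) else Y
}

#' Synthetic voxel population
#'
#' Draws a population of simulated voxels with compressive-spatial-summation
#' isotropic-Gaussian receptive fields: centers uniform over a disc,
#' Gaussian width and multiplicative gain uniform over the given ranges.
#' Feature preference tags every voxel of a region (a feature dimension map
#' prefers one dimension as a whole).
#'
#' @param n Number of voxels.
#' @param roi ROI label.
#' @param preferred Preferred feature dimension: `"color"`, `"motion"`, or
#'   `"none"`.
#' @param sigma_range Length-2 range of RF widths (degrees). Motion-
#'   selective regions should be given larger widths than color-selective
#'   ones.
#' @param gain_range Length-2 range of response gains.
#' @param ecc_max RF centers drawn uniformly over a disc of this radius
#'   (degrees, default 8).
#' @param compressive_exponent Output nonlinearity exponent in (0, 1]
#'   (default 0.5).
#' @return Data frame with columns `voxel`, `roi`, `preferred`, `x`, `y`,
#'   `sigma`, `gain`, `expo`.
#' @export
synth_voxels <- function(n, roi = "ROI", preferred = c("none", "color", "motion"),
                         sigma_range = c(0.8, 1.6), gain_range = c(0.8, 1.2),
                         ecc_max = 8, compressive_exponent = 0.5) {
  preferred <- match.arg(preferred)
  stopifnot(n >= 1, all(sigma_range > 0),
            compressive_exponent > 0, compressive_exponent <= 1)
  r <- ecc_max * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(voxel = paste0(roi, "_v", seq_len(n)), roi = roi,
             preferred = preferred,
             x = r * cos(th), y = r * sin(th),
             sigma = stats::runif(n, sigma_range[1], sigma_range[2]),
             gain = stats::runif(n, gain_range[1], gain_range[2]),
             expo = compressive_exponent,
             stringsAsFactors = FALSE)
}

#' Receptive-field pixel profiles for a voxel population
#'
#' Peak-1 isotropic Gaussian of each voxel's receptive field evaluated at
#' every pixel center; precompute once per grid and reuse across trials.
#'
#' @param voxels A [synth_voxels()] data frame.
#' @param grid A [visual_field_grid()].
#' @return A p pixels x m voxels matrix.
#' @export
vrf_profiles <- function(voxels, grid) {
  dx <- outer(grid$coords[, 1], voxels$x, `-`)
  dy <- outer(grid$coords[, 2], voxels$y, `-`)
  exp(-(dx^2 + dy^2) / (2 * rep(voxels$sigma^2, each = nrow(grid$coords))))
}

#' Compressive spatial summation response
#'
#' Response of each voxel to a binary stimulus mask under the compressive
#' spatial summation model: the mask is integrated under the voxel's
#' Gaussian RF (scaled by pixel area, so the drive is resolution-robust and
#' in deg^2 units) and passed through a compressive power law,
#' `r = gain * drive^expo`. An empty mask gives 0.
#'
#' @param voxels A [synth_voxels()] data frame.
#' @param mask A [stimulus_mask()].
#' @param profiles Optional precomputed [vrf_profiles()] for `voxels` on
#'   the mask's grid.
#' @return Length-m vector of responses (arbitrary neural units).
#' @export
vrf_response <- function(voxels, mask, profiles = NULL) {
  stopifnot(inherits(mask, "stim_mask"))
  if (is.null(profiles)) profiles <- vrf_profiles(voxels, mask$grid)
  idx <- which(mask$values > 0)
  px_area <- mask$grid$pixel_size^2
  drive <- px_area * colSums(profiles[idx, , drop = FALSE])
  if (length(idx) == 0L) drive <- numeric(nrow(voxels))
  voxels$gain * drive^voxels$expo
}

#' Attentional modulation specification
#'
#' Gain model applied on attend-color / attend-motion trials (attend-
#' fixation responses are never modulated):
#' * `spatial_gain` multiplies responses of voxels whose RF center lies
#'   within `gate_radius` of the stimulus (covert spatial attention to the
#'   stimulus location, identical for both stimulus conditions);
#' * under the `"local"` regime, `feature_gain` additionally multiplies the
#'   spatially gated voxels whose preferred dimension matches the attended
#'   one (enhancement confined to the stimulus location);
#' * under the `"global"` regime, `feature_gain` multiplies and
#'   `baseline_shift` is added to every voxel of the attended dimension
#'   regardless of RF position (map-wide enhancement).
#'
#' @param regime `"local"` or `"global"`.
#' @param spatial_gain Multiplicative spatial-attention factor (>= 0).
#' @param feature_gain Multiplicative feature-attention factor (>= 0).
#' @param baseline_shift Additive map-wide term, global regime only.
#' @param gate_radius Radius (degrees) of the spatial gate around the
#'   stimulus center (default 2.5: the 1.5 degree stimulus plus RF
#'   spillover).
#' @return Object of class `modulation_spec`.
#' @export
modulation_spec <- function(regime = c("local", "global"), spatial_gain = 1.3,
                            feature_gain = NULL, baseline_shift = NULL,
                            gate_radius = 2.5) {
  regime <- match.arg(regime)
  if (is.null(feature_gain)) feature_gain <- if (regime == "local") 1.1 else 1.0
  if (is.null(baseline_shift)) baseline_shift <- if (regime == "local") 0 else 0.3
  stopifnot(spatial_gain >= 0, feature_gain >= 0, gate_radius > 0)
  structure(list(regime = regime, spatial_gain = spatial_gain,
                 feature_gain = feature_gain, baseline_shift = baseline_shift,
                 gate_radius = gate_radius),
            class = "modulation_spec")
}

#' Attention-modulated voxel response
#'
#' Applies the [modulation_spec()] gain model to the compressive-summation
#' response of each voxel for one trial.
#'
#' @param voxels A [synth_voxels()] data frame.
#' @param mask The trial's [stimulus_mask()].
#' @param condition `"F"` (attend fixation), `"C"` (attend color), or
#'   `"M"` (attend motion).
#' @param spec A [modulation_spec()].
#' @param profiles Optional precomputed [vrf_profiles()].
#' @return Length-m vector of modulated responses.
#' @export
modulated_response <- function(voxels, mask, condition, spec,
                               profiles = NULL) {
  stopifnot(inherits(spec, "modulation_spec"),
            condition %in% c("F", "C", "M"))
  r <- vrf_response(voxels, mask, profiles)
  if (condition == "F") return(r)
  attended <- if (condition == "C") "color" else "motion"
  near <- sqrt((voxels$x - mask$center[1])^2 +
                 (voxels$y - mask$center[2])^2) <= spec$gate_radius
  r[near] <- r[near] * spec$spatial_gain
  match_pref <- voxels$preferred == attended
  if (spec$regime == "local") {
    sel <- near & match_pref
    r[sel] <- r[sel] * spec$feature_gain
  } else {
    r[match_pref] <- r[match_pref] * spec$feature_gain + spec$baseline_shift
  }
  r
}

#' Attention-task run schedule
#'
#' One run of the feature-selective attention task: 24 trials (8 each of
#' attend fixation, color, motion, shuffled), each trial a 1 s letter cue,
#' 0.5 s blank, and 3 s stimulus at 5 degree eccentricity and a random
#' polar angle, separated by ITIs drawn from a balanced multiset within
#' 6--9 s whose run mean is exactly 7.5 s; 3 s blank at run start and
#' 10.5 s at run end, for a total duration of 301.5 s.
#'
#' @param seed Integer seed.
#' @param stim_ecc Stimulus eccentricity, degrees (default 5).
#' @return Data frame (one row per trial) with columns `trial`, `onset_s`
#'   (cue onset), `cue_dur_s`, `blank_s`, `stim_onset_s`, `stim_dur_s`,
#'   `iti_s`, `condition`, `stim_angle_deg`, `stim_ecc_deg`; attributes
#'   `total_duration_s` and `start_blank_s`/`end_blank_s`.
#' @export
make_attention_schedule <- function(seed, stim_ecc = 5) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  n <- 24L
  condition <- sample(rep(c("F", "C", "M"), each = 8L))
  iti <- sample(rep(c(6, 7.5, 9), each = 8L))
  angle <- stats::runif(n, 0, 360)
  trial_len <- 1 + 0.5 + 3  # cue + blank + stimulus
  onset <- 3 + cumsum(c(0, utils::head(trial_len + iti, -1)))
  out <- data.frame(trial = seq_len(n), onset_s = onset, cue_dur_s = 1,
                    blank_s = 0.5, stim_onset_s = onset + 1.5, stim_dur_s = 3,
                    iti_s = iti, condition = condition,
                    stim_angle_deg = angle, stim_ecc_deg = stim_ecc,
                    stringsAsFactors = FALSE)
  attr(out, "start_blank_s") <- 3
  attr(out, "end_blank_s") <- 10.5
  attr(out, "total_duration_s") <- 3 + sum(trial_len + iti) + 10.5
  out
}

#' Spatial-mapping-task run schedule
#'
#' One run of the visuospatial mapping task: 43 trials of a 3 s flickering
#' checkerboard whose position is drawn from a 37-location hexagonal grid
#' (one pass through the grid, plus 6 re-drawn positions for the
#' target-present trials, which are flagged for downstream exclusion) with
#' uniform circular jitter of 0.5 degree radius; the grid base position is
#' rotated by 30 degrees on every other run (odd `run_index`). ITIs drawn
#' from {6, 8.25} s; 3 s start and 10.5 s end blanks.
#'
#' @param seed Integer seed.
#' @param run_index Run number (grid rotated 30 degrees when odd).
#' @param spacing Hexagonal grid spacing, degrees (default 2.83).
#' @param n_rings Grid rings (default 3: 37 positions).
#' @param jitter_radius Uniform circular jitter radius, degrees (default
#'   0.5).
#' @param iti_set Candidate ITIs, seconds (default `c(6, 8.25)`).
#' @return Data frame (one row per trial): `trial`, `onset_s` (stimulus
#'   onset), `stim_dur_s`, `iti_s`, `x`, `y`, `base_index`, `target`,
#'   `run_index`; attribute `total_duration_s`.
#' @export
make_mapping_schedule <- function(seed, run_index = 1L, spacing = 2.83,
                                  n_rings = 3L, jitter_radius = 0.5,
                                  iti_set = c(6, 8.25)) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  base <- build_triangular_grid(spacing, n_rings)
  if (run_index %% 2 == 1) base <- rotate_points(base, 30)
  n_grid <- nrow(base)
  n_targets <- 6L
  base_index <- c(seq_len(n_grid), sample.int(n_grid, n_targets, replace = TRUE))
  target <- c(rep(FALSE, n_grid), rep(TRUE, n_targets))
  ord <- sample.int(n_grid + n_targets)
  base_index <- base_index[ord]; target <- target[ord]
  n <- n_grid + n_targets
  jr <- jitter_radius * sqrt(stats::runif(n))
  jt <- stats::runif(n, 0, 2 * pi)
  x <- base[base_index, 1] + jr * cos(jt)
  y <- base[base_index, 2] + jr * sin(jt)
  iti <- sample(iti_set, n, replace = TRUE)
  onset <- 3 + cumsum(c(0, utils::head(3 + iti, -1)))
  out <- data.frame(trial = seq_len(n), onset_s = onset, stim_dur_s = 3,
                    iti_s = iti, x = x, y = y, base_index = base_index,
                    target = target, run_index = as.integer(run_index))
  attr(out, "total_duration_s") <- 3 + sum(3 + iti) + 10.5
  out
}

# neural boxcar (TR x m) from per-trial amplitudes: amplitude held during
# [stim_onset, stim_onset + dur)
neural_series <- function(onsets, durations, amplitudes, n_tr, tr) {
  m <- ncol(amplitudes)
  X <- matrix(0, n_tr, m)
  t_tr <- (seq_len(n_tr) - 1) * tr
  for (i in seq_along(onsets)) {
    idx <- which(t_tr >= onsets[i] - 1e-9 & t_tr < onsets[i] + durations[i] - 1e-9)
    X[idx, ] <- X[idx, ] + rep(amplitudes[i, ], each = length(idx))
  }
  X
}

#' Simulation configuration
#'
#' Validated parameter set for [simulate_dataset()]. Defaults are the
#' desk-scale study conditions: 20 subjects, two feature-selective regions
#' (a color map with smaller receptive fields and a motion map with larger
#' ones), 4 mapping and 8 attention runs per subject at TR 0.75 s, and
#' i.i.d. Gaussian TR noise of SD 1 on responses of order 1.
#'
#' @param ... Overrides of the default fields (unknown names are an error):
#'   `n_subjects`, `n_voxels_per_roi`, `n_mapping_runs`, `n_attention_runs`,
#'   `regime`, `spatial_gain`, `feature_gain`, `baseline_shift`,
#'   `gate_radius`, `noise_sd`, `compressive_exponent`, `sigma_color`,
#'   `sigma_motion`, `rf_ecc_max`, `tr`, `half_extent`, `n_pixels`,
#'   `stim_radius`, `stim_ecc`, `basis_spacing`, `basis_rings`,
#'   `size_constant`.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  defaults <- list(
    n_subjects = 20L, n_voxels_per_roi = 200L,
    n_mapping_runs = 4L, n_attention_runs = 8L,
    regime = "local", spatial_gain = 1.3, feature_gain = NULL,
    baseline_shift = NULL, gate_radius = 2.5,
    noise_sd = 3.0, compressive_exponent = 0.5,
    sigma_color = c(0.8, 1.6), sigma_motion = c(1.6, 3.2), rf_ecc_max = 8,
    tr = 0.75, half_extent = 9.15, n_pixels = 91L,
    stim_radius = 1.5, stim_ecc = 5,
    basis_spacing = 2.83, basis_rings = 3L, size_constant = 1.25 * 2.83)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, override)
  if (!cfg$regime %in% c("local", "global"))
    stop("regime must be 'local' or 'global'")
  # regime presets for the feature-attention terms unless overridden
  if (is.null(cfg$feature_gain))
    cfg$feature_gain <- if (cfg$regime == "local") 1.1 else 1.0
  if (is.null(cfg$baseline_shift))
    cfg$baseline_shift <- if (cfg$regime == "local") 0 else 0.3
  bad <- names(which(!vapply(cfg[c("noise_sd", "spatial_gain", "feature_gain",
                                   "gate_radius", "tr")],
                             function(v) is.numeric(v) && v >= 0, logical(1))))
  if (length(bad)) stop("invalid configuration value(s): ",
                        paste(bad, collapse = ", "))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a complete synthetic experiment
#'
#' Generates, for every subject, a voxel population for a color-selective
#' and a motion-selective region, `n_mapping_runs` spatial-mapping runs and
#' `n_attention_runs` feature-selective attention runs: per-trial neural
#' amplitudes from the compressive-summation RF model (modulated on
#' attention runs per the configured regime), boxcar neural timecourses at
#' the TR, double-gamma HRF convolution, and i.i.d. Gaussian noise per TR.
#' Per-voxel variance explained is computed from the noiseless vs. noisy
#' series. Fully deterministic given `master_seed`.
#'
#' @param config A [sim_config()].
#' @param master_seed Integer master seed.
#' @return Object of class `fd_simulation`: `config`, `master_seed`,
#'   `modulation` (the [modulation_spec()] used), `grid`, and `subjects` --
#'   a list, each with `voxels` (metadata incl. `variance_explained`),
#'   `mapping` and `attention` (lists of runs, each `list(bold, events,
#'   tr)`).
#' @export
simulate_dataset <- function(config = sim_config(), master_seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(master_seed, kind = "Mersenne-Twister")
  subj_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  grid <- visual_field_grid(config$half_extent, config$n_pixels)
  spec <- modulation_spec(config$regime, config$spatial_gain,
                          config$feature_gain, config$baseline_shift,
                          config$gate_radius)
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    simulate_subject(config, grid, spec, subj_seeds[s], s)
  })
  structure(list(config = config, master_seed = master_seed,
                 modulation = spec, grid = grid, subjects = subjects),
            class = "fd_simulation")
}

simulate_subject <- function(cfg, grid, spec, seed, subject_id) {
  set.seed(seed, kind = "Mersenne-Twister")
  voxels <- rbind(
    synth_voxels(cfg$n_voxels_per_roi, roi = "color", preferred = "color",
                 sigma_range = cfg$sigma_color, ecc_max = cfg$rf_ecc_max,
                 compressive_exponent = cfg$compressive_exponent),
    synth_voxels(cfg$n_voxels_per_roi, roi = "motion", preferred = "motion",
                 sigma_range = cfg$sigma_motion, ecc_max = cfg$rf_ecc_max,
                 compressive_exponent = cfg$compressive_exponent))
  profiles <- vrf_profiles(voxels, grid)
  kern <- hrf_kernel(cfg$tr)
  m <- nrow(voxels)

  make_run <- function(events, onsets, amps) {
    total <- attr(events, "total_duration_s")
    n_tr <- as.integer(round(total / cfg$tr))
    neural <- neural_series(onsets, rep(3, length(onsets)), amps, n_tr, cfg$tr)
    clean <- hrf_convolve(neural, cfg$tr, kern)
    noisy <- clean + matrix(stats::rnorm(n_tr * m, sd = cfg$noise_sd), n_tr, m)
    colnames(noisy) <- voxels$voxel
    list(bold = noisy, clean = clean, events = events, tr = cfg$tr)
  }

  mapping <- lapply(seq_len(cfg$n_mapping_runs), function(r) {
    ev <- make_mapping_schedule(sample.int(.Machine$integer.max - 1L, 1),
                                run_index = r, spacing = cfg$basis_spacing,
                                n_rings = cfg$basis_rings)
    amps <- t(vapply(seq_len(nrow(ev)), function(i) {
      msk <- stimulus_mask(grid, c(ev$x[i], ev$y[i]), cfg$stim_radius)
      vrf_response(voxels, msk, profiles)
    }, numeric(m)))
    make_run(ev, ev$onset_s, amps)
  })

  attention <- lapply(seq_len(cfg$n_attention_runs), function(r) {
    ev <- make_attention_schedule(sample.int(.Machine$integer.max - 1L, 1),
                                  stim_ecc = cfg$stim_ecc)
    th <- ev$stim_angle_deg * pi / 180
    amps <- t(vapply(seq_len(nrow(ev)), function(i) {
      ctr <- ev$stim_ecc_deg[i] * c(cos(th[i]), sin(th[i]))
      msk <- stimulus_mask(grid, ctr, cfg$stim_radius)
      modulated_response(voxels, msk, ev$condition[i], spec, profiles)
    }, numeric(m)))
    make_run(ev, ev$stim_onset_s, amps)
  })

  # variance explained: squared correlation of noiseless and noisy series
  all_clean <- do.call(rbind, c(lapply(mapping, `[[`, "clean"),
                                lapply(attention, `[[`, "clean")))
  all_noisy <- do.call(rbind, c(lapply(mapping, `[[`, "bold"),
                                lapply(attention, `[[`, "bold")))
  ve <- vapply(seq_len(m), function(j) {
    if (stats::sd(all_clean[, j]) == 0 || stats::sd(all_noisy[, j]) == 0) return(0)
    stats::cor(all_clean[, j], all_noisy[, j])^2
  }, numeric(1))
  voxels$variance_explained <- ve
  # drop the large noiseless copies from the returned object
  mapping <- lapply(mapping, function(r) { r$clean <- NULL; r })
  attention <- lapply(attention, function(r) { r$clean <- NULL; r })
  list(subject = subject_id, voxels = voxels, mapping = mapping,
       attention = attention)
}
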