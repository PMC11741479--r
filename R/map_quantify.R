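#' Mean map activation within a disk
#'
#' Unweighted mean over pixels whose centers lie strictly within `radius`
#' of `center`. The default radius (1.5 degrees) matches the stimulus size,
#' so the value summarizes the stimulus representation at a known location.
#'
#' @param map A `recon_map` (or a list with `grid` and per-pixel `values`).
#' @param center Length-2 disk center, degrees.
#' @param radius Disk radius, degrees (default 1.5).
#' @return Scalar mean activation (map units).
#' @export
disk_mean <- function(map, center, radius = 1.5) {
  stopifnot(length(center) == 2, radius > 0)
  g <- map$grid
  d2 <- (g$coords[, 1] - center[1])^2 + (g$coords[, 2] - center[2])^2
  sel <- d2 < radius^2
  if (!any(sel))
    stop("no pixel centers fall inside the disk; grid too coarse for this radius")
  mean(map$values[sel])
}

#' Location opposite fixation
#'
#' Point reflection of a stimulus center through fixation: `(x, y) ->
#' (-x, -y)`. Eccentricity is preserved; used to probe map activation at
#' the location opposite the stimulus, where nothing was presented.
#'
#' @param center Length-2 stimulus center, degrees; must be away from
#'   fixation.
#' @return Length-2 coordinates of the opposite location.
#' @export
opposite_point <- function(center) {
  stopifnot(length(center) == 2, all(is.finite(center)))
  if (sqrt(sum(center^2)) == 0)
    stop("stimulus at fixation has no opposite location")
  -as.numeric(center)
}

#' Attention modulation index
#'
#' Difference in activation between the attend-motion and attend-color
#' conditions (`motion - color`). Positive values indicate a stronger
#' response when motion is attended. Deliberately not normalized by the
#' sum, since activations can be negative in map units.
#'
#' @param motion_activation Activation under attend-motion.
#' @param color_activation Activation under attend-color.
#' @return `motion_activation - color_activation` (map units).
#' @export
ami <- function(motion_activation, color_activation) {
  motion_activation - color_activation
}

#' Average a trial timeseries over the hemodynamic response window
#'
#' Mean of the TRs whose onset times t (relative to the reference event,
#' cue onset by default) satisfy `window[1] <= t <= window[2]`; both
#' endpoints inclusive by default (`right_inclusive = FALSE` drops the
#' right endpoint). At the default TR of 0.75 s and window 4.5--7.5 s this
#' selects 5 TRs (indices 6..10 counting the reference TR as 0).
#'
#' @param series Per-TR values for one trial, with element 1 at the
#'   reference event (t = 0).
#' @param window Length-2 window `(start, end)` in seconds.
#' @param tr Repetition time, seconds (default 0.75).
#' @param right_inclusive Include TRs with `t == window[2]` (default TRUE).
#' @return Scalar window mean.
#' @export
window_average <- function(series, window = c(4.5, 7.5), tr = 0.75,
                           right_inclusive = TRUE) {
  stopifnot(length(window) == 2, window[1] < window[2], tr > 0)
  idx <- window_tr_indices(window, tr, right_inclusive)
  if (max(idx) > length(series))
    stop("window extends past the end of the trial timeseries")
  mean(series[idx])
}

# 1-based TR indices covered by a window (reference event at index 1, t = 0)
window_tr_indices <- function(window, tr, right_inclusive = TRUE) {
  t <- seq(0, window[2] + tr, by = tr)
  keep <- t >= window[1] - 1e-9 &
    (if (right_inclusive) t <= window[2] + 1e-9 else t < window[2] - 1e-9)
  which(keep)
}

#' Univariate ROI response per trial
#'
#' Mean window-averaged response across all visually responsive voxels of a
#' region (those whose receptive-field model explains at least
#' `ve_threshold` of their timeseries variance; 5% by default).
#'
#' @param trials An n_trials x m_voxels matrix of window-averaged responses
#'   (e.g. from [epoch_trials()] with the window policy), or a
#'   [trial_activations()].
#' @param variance_explained Length-m vector of per-voxel variance
#'   explained, in `[0, 1]`.
#' @param ve_threshold Inclusion threshold (default 0.05).
#' @return Length-n vector of per-trial ROI means.
#' @export
univariate_roi_response <- function(trials, variance_explained,
                                    ve_threshold = 0.05) {
  B <- if (inherits(trials, "trial_activations")) trials$values else as.matrix(trials)
  if (length(variance_explained) != ncol(B))
    stop("variance_explained must have one value per voxel")
  keep <- variance_explained >= ve_threshold
  if (!any(keep))
    stop("no voxel passes the variance-explained threshold")
  rowMeans(B[, keep, drop = FALSE])
}
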