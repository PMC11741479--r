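#' Trial-by-voxel activation matrix
#'
#' Container for per-trial BOLD response estimates, one row per trial and
#' one column per voxel. `role` distinguishes the independent training set
#' (spatial mapping task) from the test set (attention task).
#'
#' @param values An n_trials x m_voxels numeric matrix; all finite.
#' @param role `"training"` or `"test"`.
#' @param trial_ids Optional trial identifiers (length n_trials).
#' @return Object of class `trial_activations`.
#' @export
trial_activations <- function(values, role = c("training", "test"),
                              trial_ids = NULL) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("activations must be finite")
  if (ncol(values) < 1L) stop("need at least one voxel")
  if (is.null(trial_ids)) trial_ids <- seq_len(nrow(values))
  if (length(trial_ids) != nrow(values))
    stop("trial_ids length must match the trial count")
  structure(list(values = values, role = role, trial_ids = trial_ids),
            class = "trial_activations")
}

#' Estimate voxel encoding weights (forward model fit)
#'
#' Ordinary least squares fit of the forward model `B1 = C1 W`: each voxel's
#' training responses are regressed on the channel design matrix,
#' independently per voxel (a univariate step), giving the k channels x
#' m voxels weight matrix. Solved with a QR least-squares solver; the
#' normal-equations solution is identical on well-conditioned inputs.
#'
#' The returned weights are the single encoding model reused for all test
#' conditions, so reconstructions across conditions are comparable on the
#' same footing.
#'
#' @param design A `design_matrix` from [masks_to_channels()] (or an n x k
#'   matrix).
#' @param training A [trial_activations()] (or n x m matrix).
#' @param max_condition Condition-number threshold above which the design is
#'   rejected as rank deficient.
#' @return Object of class `iem_weights` with fields `values` (k x m) and
#'   `condition_number`.
#' @export
estimate_weights <- function(design, training, max_condition = 1e8) {
  C1 <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  B1 <- if (inherits(training, "trial_activations")) training$values else as.matrix(training)
  if (nrow(C1) != nrow(B1))
    stop("design and training activations disagree on trial count")
  k <- ncol(C1)
  if (nrow(C1) < k)
    stop("need at least as many training trials as channels")
  never <- which(colSums(abs(C1)) == 0)
  if (length(never))
    stop("design is rank deficient: channel(s) never stimulated: ",
         paste(never, collapse = ", "))
  kap <- kappa(C1, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop(sprintf("design matrix ill-conditioned (condition number %.3g)", kap))
  qr_C <- qr(C1)
  if (qr_C$rank < k) {
    dropped <- setdiff(seq_len(k), sort(qr_C$pivot[seq_len(qr_C$rank)]))
    stop("design is rank deficient; offending channel(s): ",
         paste(dropped, collapse = ", "))
  }
  W <- qr.coef(qr_C, B1)
  dimnames(W) <- list(NULL, colnames(B1))
  structure(list(values = W, condition_number = kap), class = "iem_weights")
}

#' Invert voxel activation patterns into channel estimates
#'
#' Model inversion: given the estimated weights, maps each test-trial
#' activation pattern back onto the information channels,
#' `C2_hat = B2 W' (W W')^{-1}` -- the channel activations that, through the
#' forward model, best explain the observed multi-voxel pattern.
#'
#' @param test A [trial_activations()] (or n x m matrix) of test patterns.
#' @param weights An `iem_weights` from [estimate_weights()].
#' @param max_condition Condition-number threshold for `W W'`.
#' @return An n_trials x k_channels matrix of channel estimates.
#' @export
invert_channels <- function(test, weights, max_condition = 1e10) {
  B2 <- if (inherits(test, "trial_activations")) test$values else as.matrix(test)
  stopifnot(inherits(weights, "iem_weights"))
  W <- weights$values
  if (ncol(B2) != ncol(W))
    stop("test activations and weights disagree on voxel count")
  if (ncol(W) < nrow(W))
    stop("need at least as many voxels as channels to invert")
  WWt <- W %*% t(W)
  kap <- kappa(WWt, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop(sprintf("W W' is ill-conditioned (condition number %.3g); cannot invert", kap))
  est <- B2 %*% t(W) %*% solve(WWt)
  dimnames(est) <- NULL
  est
}

#' Render a reconstructed visual-field map
#'
#' Weights each filter's spatial profile by its reconstructed channel
#' activation and sums the weighted filters, giving a pixelized map of the
#' visual field. Linear in the channel estimates.
#'
#' @param channels Length-k channel activation vector for one trial.
#' @param basis A [channel_basis()].
#' @param grid A [visual_field_grid()].
#' @param frame Coordinate frame label carried on the map (`"screen"` or
#'   `"aligned"`).
#' @param reference_angle For aligned maps, the polar angle (degrees) at
#'   which the stimulus appears.
#' @param filter_matrix Optional precomputed [render_basis()] output
#'   (must match `basis`/`grid`); avoids re-rendering in tight loops.
#' @return Object of class `recon_map` with fields `grid`, `values`
#'   (length-p vector), `frame`, `reference_angle`.
#' @export
reconstruct_map <- function(channels, basis, grid, frame = "screen",
                            reference_angle = NA_real_,
                            filter_matrix = NULL) {
  channels <- as.numeric(channels)
  if (length(channels) != nrow(basis$centers))
    stop("channel count does not match the basis")
  if (is.null(filter_matrix)) filter_matrix <- render_basis(basis, grid)
  values <- drop(filter_matrix %*% channels)
  structure(list(grid = grid, values = values, frame = frame,
                 reference_angle = reference_angle),
            class = "recon_map")
}

#' Rotation-align a trial's reconstruction
#'
#' Because the attention-task stimulus appears at a random polar angle on
#' every trial, per-trial maps are aligned before averaging by rotating the
#' filter centers by `reference_angle - trial_stimulus_angle` about
#' fixation, so every trial's stimulus lands at the reference angle (at its
#' true eccentricity).
#'
#' @param channels Length-k channel estimates for the trial.
#' @param basis A [channel_basis()].
#' @param trial_stimulus_angle The trial's stimulus polar angle, degrees.
#' @param reference_angle Common polar angle to align stimuli to, degrees
#'   (default 0, the rightward horizontal meridian).
#' @param grid A [visual_field_grid()].
#' @return An aligned `recon_map`.
#' @export
align_trial <- function(channels, basis, trial_stimulus_angle,
                        reference_angle = 0, grid) {
  stopifnot(is.finite(trial_stimulus_angle), is.finite(reference_angle))
  rot <- basis
  rot$centers <- rotate_points(basis$centers,
                               reference_angle - trial_stimulus_angle)
  reconstruct_map(channels, rot, grid, frame = "aligned",
                  reference_angle = reference_angle)
}

#' Rotation-align trials by re-estimating the model with rotated filters
#'
#' Exact trial alignment: the filter centers are rotated by
#' `trial_stimulus_angle - reference_angle`, the voxel weights are
#' re-estimated on the training data under the rotated basis, the test
#' pattern is inverted through that model, and the map is rendered on the
#' unrotated basis -- so the stimulus appears at the reference angle. For a
#' rotation-equivariant voxel population this is exactly equivariant for
#' any rotation in the symmetry group of the training stimulus set (e.g.
#' multiples of 30 degrees when the mapping grid is run at two 30-degree
#' rotations), unlike the cheaper render-side [align_trial()].
#'
#' @param test A [trial_activations()] (or matrix/vector) of test
#'   pattern(s) for trials sharing one stimulus angle.
#' @param masks Training stimulus masks (as for [masks_to_channels()]).
#' @param training Training [trial_activations()] (or matrix).
#' @param basis A [channel_basis()].
#' @param grid A [visual_field_grid()].
#' @param trial_stimulus_angle Stimulus polar angle of the test trial(s),
#'   degrees.
#' @param reference_angle Polar angle to align to (default 0).
#' @return A single aligned `recon_map` (one test row) or a list of them.
#' @export
align_by_refit <- function(test, masks, training, basis, grid,
                           trial_stimulus_angle, reference_angle = 0) {
  B2 <- if (inherits(test, "trial_activations")) test$values
        else if (is.null(dim(test))) matrix(test, nrow = 1)
        else as.matrix(test)
  rot <- basis
  rot$centers <- rotate_points(basis$centers,
                               trial_stimulus_angle - reference_angle)
  design <- masks_to_channels(masks, render_basis(rot, grid))
  W <- estimate_weights(design, training)
  ch <- invert_channels(B2, W)
  fm <- render_basis(basis, grid)
  maps <- lapply(seq_len(nrow(ch)), function(i)
    reconstruct_map(ch[i, ], basis, grid, frame = "aligned",
                    reference_angle = reference_angle, filter_matrix = fm))
  if (length(maps) == 1L) maps[[1]] else maps
}

#' Average reconstructions by condition
#'
#' Pixelwise mean of aligned maps: first across trials within condition
#' within subject, then unweighted across subjects, so subjects with
#' unequal trial counts contribute equally.
#'
#' @param maps List of `recon_map` objects on one grid and frame.
#' @param conditions Condition label per map.
#' @param subjects Subject identifier per map (default: one subject).
#' @return Named list (one per condition level) of mean `recon_map`s.
#' @export
average_maps <- function(maps, conditions, subjects = NULL) {
  stopifnot(length(maps) == length(conditions))
  if (is.null(subjects)) subjects <- rep(1L, length(maps))
  frames <- unique(vapply(maps, `[[`, character(1), "frame"))
  if (length(frames) != 1L)
    stop("cannot average maps in mixed coordinate frames: ",
         paste(frames, collapse = ", "))
  np <- unique(vapply(maps, function(m) m$grid$n_pixels, integer(1)))
  if (length(np) != 1L) stop("cannot average maps on different grids")
  V <- do.call(cbind, lapply(maps, `[[`, "values"))
  out <- lapply(unique(conditions), function(cond) {
    subj_means <- lapply(unique(subjects), function(s) {
      sel <- conditions == cond & subjects == s
      if (!any(sel)) return(NULL)
      rowMeans(V[, sel, drop = FALSE])
    })
    subj_means <- Filter(Negate(is.null), subj_means)
    m <- maps[[match(cond, conditions)]]
    m$values <- rowMeans(do.call(cbind, subj_means))
    m
  })
  names(out) <- unique(conditions)
  out
}
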