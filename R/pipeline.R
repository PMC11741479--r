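#' Epoch a run's timeseries into per-trial responses
#'
#' Extracts each trial's response from a TR x voxel BOLD matrix, referenced
#' to per-trial event onsets (cue onsets for the attention task,
#' stimulus onsets for the mapping task). With the `"window"` policy each
#' trial is summarized by the mean over the hemodynamic window
#' (4.5--7.5 s after the reference event by default); the `"per_tr"` policy
#' returns each window TR separately. Trials never cross run boundaries:
#' epoch runs one at a time.
#'
#' @param bold TR x voxel matrix for one run.
#' @param onsets Per-trial reference-event onsets, seconds from run start
#'   (must fall on the TR raster).
#' @param tr Repetition time, seconds (default 0.75).
#' @param policy `"window"` (default) or `"per_tr"`.
#' @param window Length-2 response window, seconds after the reference
#'   event (default `c(4.5, 7.5)`).
#' @param right_inclusive Passed to the window TR selection (default TRUE).
#' @return For `"window"`: an n_trials x m matrix. For `"per_tr"`: an
#'   n_trials x n_window_TRs x m array.
#' @export
epoch_trials <- function(bold, onsets, tr = 0.75,
                         policy = c("window", "per_tr"),
                         window = c(4.5, 7.5), right_inclusive = TRUE) {
  policy <- match.arg(policy)
  bold <- as.matrix(bold)
  n_tr <- nrow(bold)
  ref <- round(onsets / tr) + 1L
  if (any(abs(onsets / tr - (ref - 1L)) > 1e-6))
    stop("event onsets must fall on the TR raster")
  rel <- window_tr_indices(window, tr, right_inclusive) - 1L
  over <- which(ref + max(rel) > n_tr)
  if (length(over))
    stop("trial(s) extend past the end of the run: ",
         paste(over, collapse = ", "))
  if (policy == "window") {
    out <- t(vapply(ref, function(r0) colMeans(bold[r0 + rel, , drop = FALSE]),
                    numeric(ncol(bold))))
    dimnames(out) <- list(NULL, colnames(bold))
    out
  } else {
    arr <- array(NA_real_, c(length(ref), length(rel), ncol(bold)))
    for (i in seq_along(ref)) arr[i, , ] <- bold[ref[i] + rel, , drop = FALSE]
    arr
  }
}

# per-voxel scaling of a run's timeseries: mean-centering (default; affine,
# preserves the linearity the IEM condition contrasts rely on), z-scoring
# (constant voxels map to 0), or raw
scale_run <- function(bold, method = c("center", "zscore", "raw")) {
  method <- match.arg(method)
  if (method == "raw") return(bold)
  out <- sweep(bold, 2, colMeans(bold))
  if (method == "zscore") {
    sd <- apply(bold, 2, stats::sd)
    sd[sd == 0] <- 1
    out <- sweep(out, 2, sd, `/`)
  }
  out
}

#' Fit the spatial encoding model for one subject's region
#'
#' Training stage of the IEM pipeline: per-voxel z-scoring within run
#' (configurable), stimulus-locked window averaging of the mapping runs,
#' target-trial exclusion, stimulus-mask-to-channel conversion, and OLS
#' weight estimation. Only voxels whose variance explained reaches
#' `ve_threshold` are used. The returned model carries the fitted weights,
#' the basis, grid, and kept-voxel set, and is reused unchanged for every
#' test condition.
#'
#' @param subject One subject's data (element of
#'   `simulate_dataset()$subjects`, or an equivalent list with `voxels` and
#'   `mapping` runs).
#' @param roi Restrict to voxels of this ROI label (default: all).
#' @param basis A [channel_basis()].
#' @param grid A [visual_field_grid()] for mask rendering.
#' @param train_window Stimulus-locked response window for the mapping
#'   trials, seconds (default `c(3.75, 7.5)`).
#' @param scale Per-voxel scaling within run before epoching: `"center"`
#'   (mean removal, default), `"zscore"`, or `"raw"`. Centering is the
#'   default because it is affine and so preserves the exact linearity of
#'   condition contrasts through the inversion.
#' @param stim_radius Mapping stimulus radius, degrees (default 1.5).
#' @param ve_threshold Voxel inclusion threshold on variance explained
#'   (default 0.05; ignored if the metadata has no `variance_explained`).
#' @return List of class `iem_model`: `weights`, `basis`, `grid`,
#'   `filter_matrix`, `voxels` (kept metadata), `design`, `scale`.
#' @export
fit_encoding_model <- function(subject, roi = NULL, basis, grid,
                               train_window = c(3.75, 7.5),
                               scale = c("center", "zscore", "raw"),
                               stim_radius = 1.5, ve_threshold = 0.05) {
  scale <- match.arg(scale)
  vox <- subject$voxels
  keep <- rep(TRUE, nrow(vox))
  if (!is.null(roi)) keep <- keep & vox$roi == roi
  if (!is.null(vox$variance_explained))
    keep <- keep & vox$variance_explained >= ve_threshold
  if (!any(keep)) stop("no voxel passes the inclusion criteria")
  fm <- render_basis(basis, grid)
  tr <- subject$mapping[[1]]$tr
  pieces <- lapply(subject$mapping, function(run) {
    ev <- run$events
    B <- run$bold[, keep, drop = FALSE]
    B <- scale_run(B, scale)
    trials <- epoch_trials(B, ev$onset_s, tr, "window", train_window)
    est <- !ev$target
    list(B = trials[est, , drop = FALSE],
         masks = lapply(which(est), function(i)
           stimulus_mask(grid, c(ev$x[i], ev$y[i]), stim_radius)))
  })
  B1 <- do.call(rbind, lapply(pieces, `[[`, "B"))
  masks <- do.call(c, lapply(pieces, `[[`, "masks"))
  design <- masks_to_channels(masks, fm)
  weights <- estimate_weights(design, trial_activations(B1, "training"))
  structure(list(weights = weights, basis = basis, grid = grid,
                 filter_matrix = fm, voxels = vox[keep, , drop = FALSE],
                 keep = keep, design = design, scale = scale),
            class = "iem_model")
}

#' Reconstruct attention-task trials through a fitted model
#'
#' Test stage: per-voxel scaling within run (matching the training stage),
#' cue-locked window averaging, and model inversion of every attention
#' trial into channel estimates.
#'
#' @param subject One subject's data (with `attention` runs).
#' @param model An `iem_model` from [fit_encoding_model()].
#' @param window Cue-locked response window, seconds (default
#'   `c(4.5, 7.5)`).
#' @return List with `channels` (n_trials x k) and `events` (row-bound
#'   attention events with a `run` column).
#' @export
reconstruct_attention <- function(subject, model, window = c(4.5, 7.5)) {
  tr <- subject$attention[[1]]$tr
  pieces <- lapply(seq_along(subject$attention), function(r) {
    run <- subject$attention[[r]]
    B <- run$bold[, model$keep, drop = FALSE]
    B <- scale_run(B, model$scale)
    trials <- epoch_trials(B, run$events$onset_s, tr, "window", window)
    ev <- run$events
    ev$run <- r
    list(ch = invert_channels(trial_activations(trials, "test"),
                              model$weights),
         events = ev)
  })
  list(channels = do.call(rbind, lapply(pieces, `[[`, "ch")),
       events = do.call(rbind, lapply(pieces, `[[`, "events")))
}

#' Disk-based quantification of reconstructed trials
#'
#' For every trial, renders the reconstructed map and takes the mean
#' activation within a stimulus-sized disk at the trial's true stimulus
#' location and at the location opposite fixation. Measuring in screen
#' coordinates at the known per-trial location is identical to rotation-
#' aligning the map first and measuring at the reference location (the
#' alignment is a rigid rotation of map and disk together).
#'
#' @param recon Output of [reconstruct_attention()].
#' @param model The `iem_model` used.
#' @param radius Disk radius, degrees (default 1.5, the stimulus radius).
#' @return Tidy data frame: `run`, `trial`, `condition`,
#'   `stim_angle_deg`, `stim`, `opposite`, `selectivity`
#'   (`stim - opposite`).
#' @export
quantify_trials <- function(recon, model, radius = 1.5) {
  ev <- recon$events
  th <- ev$stim_angle_deg * pi / 180
  cx <- ev$stim_ecc_deg * cos(th)
  cy <- ev$stim_ecc_deg * sin(th)
  g <- model$grid
  fm <- model$filter_matrix
  n <- nrow(ev)
  stim <- opp <- numeric(n)
  for (i in seq_len(n)) {
    ctr <- c(cx[i], cy[i])
    dm <- function(center) {
      d2 <- (g$coords[, 1] - center[1])^2 + (g$coords[, 2] - center[2])^2
      sel <- d2 < radius^2
      if (!any(sel)) stop("grid too coarse for the quantification disk")
      mean(fm[sel, , drop = FALSE] %*% recon$channels[i, ])
    }
    stim[i] <- dm(ctr)
    opp[i] <- dm(opposite_point(ctr))
  }
  data.frame(run = ev$run, trial = ev$trial, condition = ev$condition,
             stim_angle_deg = ev$stim_angle_deg, stim = stim, opposite = opp,
             selectivity = stim - opp, stringsAsFactors = FALSE)
}

#' Run the full synthetic IEM experiment and its statistics
#'
#' End-to-end orchestrator: simulate (or accept) a dataset, fit the
#' encoding model per subject and region from the mapping runs, invert and
#' quantify every attention trial, average within condition per subject,
#' and run the permutation statistical battery per region:
#' feature-condition (attend color vs. motion) permuted paired t tests on
#' stimulus-location activation, opposite-location activation, and spatial
#' selectivity (stimulus - opposite), plus the attention modulation index
#' (AMI, motion - color at the stimulus location).
#'
#' @param sim A `fd_simulation` from [simulate_dataset()], or a
#'   [sim_config()] to simulate with.
#' @param master_seed Seed used (a) for simulation when `sim` is a config
#'   and (b) to derive the permutation seeds.
#' @param n_iter Permutation iterations per test (default 1000).
#' @param out_dir Optional directory; if given, tidy result tables and the
#'   configuration echo are written there as tab-separated text.
#' @param scale Per-voxel within-run scaling passed to
#'   [fit_encoding_model()] (default `"center"`).
#' @return List of class `fd_analysis`: `subject_means` (tidy per-subject
#'   condition means: subject, roi, condition, stim, opposite,
#'   selectivity), `ami` (per subject x roi), `stats` (tidy test table with
#'   observed statistic, df, effect size and permutation p), `config`,
#'   `master_seed`.
#' @export
run_pipeline <- function(sim, master_seed = 1L, n_iter = 1000,
                         out_dir = NULL, scale = c("center", "zscore", "raw")) {
  scale <- match.arg(scale)
  if (inherits(sim, "sim_config")) sim <- simulate_dataset(sim, master_seed)
  stopifnot(inherits(sim, "fd_simulation"))
  cfg <- sim$config
  basis <- channel_basis(cfg$basis_spacing, cfg$basis_rings,
                         cfg$size_constant)
  grid <- sim$grid
  rois <- unique(sim$subjects[[1]]$voxels$roi)

  rows <- list()
  for (subject in sim$subjects) {
    for (roi in rois) {
      model <- fit_encoding_model(subject, roi = roi, basis = basis,
                                  grid = grid, scale = scale,
                                  stim_radius = cfg$stim_radius)
      recon <- reconstruct_attention(subject, model)
      q <- quantify_trials(recon, model, radius = cfg$stim_radius)
      agg <- stats::aggregate(q[c("stim", "opposite", "selectivity")],
                              by = list(condition = q$condition), mean)
      agg$subject <- subject$subject
      agg$roi <- roi
      rows[[length(rows) + 1L]] <- agg
    }
  }
  subject_means <- do.call(rbind, rows)
  subject_means <- subject_means[, c("subject", "roi", "condition",
                                     "stim", "opposite", "selectivity")]

  # permutation seeds: one master seed spawns one stream per test
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(master_seed + 1L, kind = "Mersenne-Twister")
  next_seed <- function() sample.int(.Machine$integer.max - 1L, 1)

  stats_rows <- list()
  ami_rows <- list()
  for (roi in rois) {
    sm <- subject_means[subject_means$roi == roi, ]
    wide <- function(measure, cond)
      sm[sm$condition == cond, measure][order(sm[sm$condition == cond, "subject"])]
    for (measure in c("stim", "opposite", "selectivity")) {
      res <- perm_paired_t(wide(measure, "C"), wide(measure, "M"),
                           seed = next_seed(), n_iter = n_iter)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        roi = roi, test = paste0(measure, "_C_vs_M"),
        t = res$parametric$t, df = res$parametric$df,
        d_z = res$parametric$d_z, p_perm = res$p, seed = res$seed)
    }
    a <- ami(wide("stim", "M"), wide("stim", "C"))
    ami_rows[[length(ami_rows) + 1L]] <- data.frame(
      roi = roi, subject = sort(unique(sm$subject)), ami = a)
    res <- perm_paired_t(wide("stim", "M"), wide("stim", "C"),
                         seed = next_seed(), n_iter = n_iter)
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      roi = roi, test = "ami_stim_vs_zero",
      t = res$parametric$t, df = res$parametric$df,
      d_z = res$parametric$d_z, p_perm = res$p, seed = res$seed)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  stats_tbl <- do.call(rbind, stats_rows)
  stats_tbl$p_fdr <- fdr_bh(stats_tbl$p_perm)$adjusted
  ami_tbl <- do.call(rbind, ami_rows)

  out <- structure(list(subject_means = subject_means, ami = ami_tbl,
                        stats = stats_tbl, config = cfg,
                        master_seed = sim$master_seed),
                   class = "fd_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- provenance_header(cfg, sim$master_seed)
    write_table_with_header(subject_means,
                            file.path(out_dir, "subject_means.tsv"), prov)
    write_table_with_header(ami_tbl, file.path(out_dir, "ami.tsv"), prov)
    write_table_with_header(stats_tbl, file.path(out_dir, "stats.tsv"), prov)
    write_config(cfg, file.path(out_dir, "config.txt"),
                 extra = c(master_seed = sim$master_seed))
  }
  out
}
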