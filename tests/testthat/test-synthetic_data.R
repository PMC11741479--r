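test_that("HRF kernel and convolution behave like a causal linear system", {
  k <- hrf_kernel(0.75)
  expect_equal(max(k), 1)
  peak_t <- (which.max(k) - 1) * 0.75
  expect_gte(peak_t, 4); expect_lte(peak_t, 6)
  expect_equal(hrf_convolve(rep(0, 50)), rep(0, 50))
  # impulse response reproduces the kernel, delayed by nothing
  x <- rep(0, 60); x[5] <- 1
  y <- hrf_convolve(x, 0.75)
  expect_equal(y[5:(4 + length(k))], k, tolerance = 1e-9)
  expect_equal(y[1:4], rep(0, 4), tolerance = 1e-12)
  expect_equal(y[(5 + length(k)):60], rep(0, 60 - 4 - length(k)),
               tolerance = 1e-12)
  # linearity and matrix columns processed independently
  a <- rnorm(80); b <- rnorm(80)
  expect_equal(hrf_convolve(a + b), hrf_convolve(a) + hrf_convolve(b),
               tolerance = 1e-9)
  M <- cbind(a, b)
  expect_equal(hrf_convolve(M)[, 1], hrf_convolve(a), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("compressive summation responses integrate the RF under the mask", {
  g <- small_grid()
  vox <- polar_voxels(eccs = c(2.5, 5), angle_step = 90)
  empty <- stimulus_mask(g, c(5, 0), 1.5)
  empty$values <- numeric(length(empty$values))
  expect_equal(vrf_response(vox, empty), rep(0, nrow(vox)))
  # linear voxels (exponent 1) are additive over disjoint stimuli
  lin <- vox; lin$expo <- 1
  m1 <- stimulus_mask(g, c(5, 0), 1.5)
  m2 <- stimulus_mask(g, c(-5, 0), 1.5)
  both <- m1; both$values <- m1$values + m2$values
  expect_equal(vrf_response(lin, both),
               vrf_response(lin, m1) + vrf_response(lin, m2),
               tolerance = 1e-9)
  # compressive voxels are subadditive
  cmp <- vox; cmp$expo <- 0.5
  r_both <- vrf_response(cmp, both)
  r_sum <- vrf_response(cmp, m1) + vrf_response(cmp, m2)
  active <- r_sum > 1e-6
  expect_true(all(r_both[active] < r_sum[active]))
})

test_that("attention schedules respect the run's printed timing", {
  for (seed in c(1, 17, 999)) {
    sch <- make_attention_schedule(seed)
    expect_equal(nrow(sch), 24)
    expect_equal(attr(sch, "total_duration_s"), 301.5)
    expect_equal(unname(table(sch$condition)), rep(8L, 3), ignore_attr = TRUE)
    expect_true(all(sch$iti_s >= 6 & sch$iti_s <= 9))
    expect_equal(mean(sch$iti_s), 7.5)
    expect_equal(sch$stim_onset_s, sch$onset_s + 1.5)
    expect_equal(sch$onset_s[1], 3)
    # last trial's events fit inside the run
    expect_equal(max(sch$onset_s) + 4.5 + sch$iti_s[24] + 10.5, 301.5)
  }
  expect_false(identical(make_attention_schedule(1)$condition,
                         make_attention_schedule(2)$condition))
})

test_that("mapping schedules cover the grid once plus flagged targets", {
  sch <- make_mapping_schedule(5, run_index = 2)
  expect_equal(nrow(sch), 43)
  expect_equal(sum(sch$target), 6)
  est <- sch[!sch$target, ]
  expect_equal(nrow(est), 37)
  expect_equal(sort(est$base_index), 1:37)   # one pass through the grid
  base <- build_triangular_grid(2.83, 3)
  jit <- sqrt((est$x - base[est$base_index, 1])^2 +
                (est$y - base[est$base_index, 2])^2)
  expect_true(all(jit <= 0.5 + 1e-12))
  expect_true(all(sch$iti_s %in% c(6, 8.25)))
  # odd runs carry the 30-degree rotated grid
  odd <- make_mapping_schedule(5, run_index = 1)
  base_rot <- rotate_points(base, 30)
  est_odd <- odd[!odd$target, ]
  jit_odd <- sqrt((est_odd$x - base_rot[est_odd$base_index, 1])^2 +
                    (est_odd$y - base_rot[est_odd$base_index, 2])^2)
  expect_true(all(jit_odd <= 0.5 + 1e-12))
})

test_that("modulated responses implement the local and global gain regimes", {
  g <- small_grid()
  vox <- data.frame(voxel = c("near", "far"), roi = "motion",
                    preferred = "motion", x = c(5, -5), y = 0,
                    sigma = 1.2, gain = 1, expo = 0.5,
                    stringsAsFactors = FALSE)
  mask <- stimulus_mask(g, c(5, 0), 1.5)
  base <- vrf_response(vox, mask)
  neutral <- modulation_spec("local", spatial_gain = 1, feature_gain = 1)
  for (cond in c("F", "C", "M"))
    expect_equal(modulated_response(vox, mask, cond, neutral), base)
  loc <- modulation_spec("local", spatial_gain = 1.3, feature_gain = 1.5)
  glo <- modulation_spec("global", spatial_gain = 1.3, feature_gain = 1.0,
                         baseline_shift = 0.3)
  # attend fixation never modulates
  expect_equal(modulated_response(vox, mask, "F", loc), base)
  # near voxel: spatial gain on both stimulus conditions, feature gain
  # only when the preferred dimension is attended (local regime)
  rC <- modulated_response(vox, mask, "C", loc)
  rM <- modulated_response(vox, mask, "M", loc)
  expect_equal(rC[1], base[1] * 1.3)
  expect_equal(rM[1], base[1] * 1.3 * 1.5)
  # far voxel under local: spatial gate excludes it entirely
  expect_equal(rC[2], base[2])
  expect_equal(rM[2], rC[2])
  # far voxel under global: attending its dimension lifts it additively
  gC <- modulated_response(vox, mask, "C", glo)
  gM <- modulated_response(vox, mask, "M", glo)
  expect_gt(gM[2], gC[2])
  expect_equal(gM[2], base[2] + 0.3)
})

test_that("simulated datasets are deterministic with honest ground truth", {
  cfg <- tiny_sim_config(noise_sd = 0)
  s1 <- simulate_dataset(cfg, 42)
  s2 <- simulate_dataset(cfg, 42)
  expect_identical(s1$subjects[[1]]$mapping[[1]]$bold,
                   s2$subjects[[1]]$mapping[[1]]$bold)
  expect_identical(s1$subjects[[2]]$attention[[2]]$bold,
                   s2$subjects[[2]]$attention[[2]]$bold)
  expect_false(identical(s1$subjects[[1]]$voxels$x,
                         simulate_dataset(cfg, 43)$subjects[[1]]$voxels$x))
  # noiseless series equal the HRF-convolved modulated amplitudes
  sub <- s1$subjects[[1]]
  run <- sub$attention[[1]]
  ev <- run$events
  g <- s1$grid
  prof <- vrf_profiles(sub$voxels, g)
  th <- ev$stim_angle_deg[3] * pi / 180
  msk <- stimulus_mask(g, 5 * c(cos(th), sin(th)), cfg$stim_radius)
  amp <- modulated_response(sub$voxels, msk, ev$condition[3], s1$modulation,
                            prof)
  # reconstruct the expected series for one voxel from first principles
  n_tr <- nrow(run$bold)
  x <- rep(0, n_tr)
  t_tr <- (seq_len(n_tr) - 1) * 0.75
  for (i in seq_len(nrow(ev))) {
    thi <- ev$stim_angle_deg[i] * pi / 180
    mi <- stimulus_mask(g, 5 * c(cos(thi), sin(thi)), cfg$stim_radius)
    ai <- modulated_response(sub$voxels, mi, ev$condition[i], s1$modulation,
                             prof)[7]
    on <- ev$stim_onset_s[i]
    x[t_tr >= on - 1e-9 & t_tr < on + 3 - 1e-9] <- ai
  }
  expect_equal(run$bold[, 7], hrf_convolve(x, 0.75), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(amp[7], 0)  # sanity: the probed trial drives some response
})

test_that("variance explained decreases with the noise level", {
  ve <- vapply(c(0.5, 1, 2), function(ns) {
    sim <- simulate_dataset(sim_config(n_subjects = 1, n_voxels_per_roi = 40,
                                       n_mapping_runs = 1,
                                       n_attention_runs = 1, n_pixels = 61L,
                                       noise_sd = ns), 7)
    mean(sim$subjects[[1]]$voxels$variance_explained)
  }, numeric(1))
  expect_true(all(diff(ve) < 0))
})

test_that("invalid simulation configurations are rejected by key", {
  expect_error(sim_config(not_a_key = 1, also_bad = 2), "not_a_key, also_bad")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(regime = "both"), "local")
})
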