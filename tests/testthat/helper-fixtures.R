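# shared fixture builders; everything is generated in code at test time

small_grid <- function(n = 61) visual_field_grid(9.15, n)

# deterministic voxel population on a polar lattice: rotation-equivariant
# by construction (symmetric under multiples of the angular step)
polar_voxels <- function(angle_step = 15, eccs = c(1.25, 2.5, 3.75, 5, 6.25, 7.5),
                         sigma = 1.2, expo = 0.5) {
  ang <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  pts <- expand.grid(a = ang, e = eccs)
  data.frame(voxel = paste0("v", seq_len(nrow(pts) + 1)), roi = "syn",
             preferred = "none",
             x = c(0, pts$e * cos(pts$a)), y = c(0, pts$e * sin(pts$a)),
             sigma = sigma, gain = 1, expo = expo,
             stringsAsFactors = FALSE)
}

# the full mapping-position set: hexagonal grid at both run rotations
mapping_masks <- function(grid, spacing = 2.83, n_rings = 3, radius = 1.5) {
  pos <- rbind(build_triangular_grid(spacing, n_rings),
               rotate_points(build_triangular_grid(spacing, n_rings), 30))
  lapply(seq_len(nrow(pos)), function(i) stimulus_mask(grid, pos[i, ], radius))
}

# tiny simulation for pipeline-level tests
tiny_sim_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, n_voxels_per_roi = 60,
                                 n_mapping_runs = 2, n_attention_runs = 2,
                                 n_pixels = 61L),
                            list(...))
  do.call(sim_config, args)
}
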