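# Shared desk-scale phantom builders. Two grids are used throughout:
#  - thickness grid: full 1 x 1 mm field (coarse laterally) so the
#    200-600 um annulus fits;
#  - octa grid: 4 um/px lateral sampling over a ~0.5 x 0.4 mm field so
#    capillary-calibre vessels are resolved; the ONH exclusion radius is
#    reduced accordingly.
# Fixtures are cached per R session because several test files reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

thickness_config <- function(seed = 1L, noise_sigma = 0.1,
                             motion_amplitude_px = 2, ...) {
  phantom_config(n_repeats = 3L, n_fast = 64L, n_slow = 48L, n_depth = 280L,
                 dx_fast = 1000 / 64, dx_slow = 1000 / 48, dz = 2,
                 noise_sigma = noise_sigma,
                 motion_amplitude_px = motion_amplitude_px,
                 seed = seed, ...)
}

octa_config <- function(seed = 1L, noise_sigma = 0.12, ...) {
  phantom_config(n_repeats = 5L, n_fast = 128L, n_slow = 96L, n_depth = 280L,
                 dx_fast = 4, dx_slow = 4, dz = 2,
                 noise_sigma = noise_sigma, seed = seed, ...)
}

octa_run_config <- function() {
  rc <- default_run_config()
  rc$onh_exclusion_um <- 120
  rc
}

# Noise-free, flat geometry (no curvature, no ONH pinch or saturation,
# no motion, no vessels): integer-pixel boundaries, exactly
# piecewise-constant A-scans.
flat_config <- function(seed = 1L, ...) {
  args <- list(n_repeats = 2L, n_fast = 48L, n_slow = 32L, n_depth = 280L,
               dx_fast = 1000 / 48, dx_slow = 1000 / 32, dz = 2,
               layer_thickness_um = c(`RNFL/GCL` = 30, IPL = 36, INL = 24,
                                      OPL = 12, PRC = 100, RPE = 12),
               rpe_base_depth_um = 300,
               curvature_radius_um = Inf,
               onh_pinch_floor = 1, onh_radius_um = 1e-3,
               vessel_specs = list(SVP = list(), ICP = list(), DCP = list()),
               motion_amplitude_px = 0, noise_sigma = 0, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

# random thickness-grid phantom: jittered layer thicknesses, curvature
# and motion, noise up to the requested level
random_thickness_config <- function(seed, noise_sigma = 0.15) {
  set.seed(seed + 7000L)
  th <- c(`RNFL/GCL` = 30, IPL = 36, INL = 25, OPL = 12, PRC = 100,
          RPE = 11) * stats::runif(6L, 0.9, 1.1)
  thickness_config(seed = seed,
                   noise_sigma = stats::runif(1L, 0.05, noise_sigma),
                   motion_amplitude_px = stats::runif(1L, 0, 2.5),
                   layer_thickness_um = th,
                   curvature_radius_um = stats::runif(1L, 1500, 4000))
}

# ground-truth boundary position in the flattened frame of repeat `r`;
# `discrete = TRUE` returns the first voxel row of the deeper layer
# (the segmenter's convention), the exact noise-free target
gt_in_flat_frame <- function(truth, flat, boundary, repeat_idx = 1L,
                             discrete = FALSE) {
  gt_px <- truth$boundary_depths_um[[boundary]] / truth$config$dz
  app <- sweep(gt_px, 1L, truth$frame_shifts[, repeat_idx], `+`)
  if (discrete) app <- ceiling(app)
  app - flat$shift_record[, , repeat_idx]
}

# cohort whose mouse means all equal the group mean exactly (each
# mouse's two eyes mirrored about it): the REML mouse variance is 0 by
# construction, pinning the Satterthwaite OLS limit deterministically
mirrored_cohort <- function(group_means, sd_eye, n_mice_per_group, seed) {
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (g in names(group_means)) {
    for (m in seq_len(n_mice_per_group)) {
      k <- k + 1L
      e <- stats::rnorm(1L, 0, sd_eye)
      rows[[k]] <- data.frame(mouse_id = sprintf("m%04d", k), group = g,
                              eye = c("L", "R"),
                              value = group_means[[g]] + c(e, -e))
    }
  }
  do.call(rbind, rows)
}

annulus_mask <- function(cfg, r_in = 200, r_out = 600) {
  cc <- list(y = (seq_len(cfg$n_slow) - 0.5) * cfg$dx_slow,
             x = (seq_len(cfg$n_fast) - 0.5) * cfg$dx_fast)
  d2 <- outer((cc$y - cfg$onh_center_um[2])^2,
              (cc$x - cfg$onh_center_um[1])^2, `+`)
  d2 >= r_in^2 & d2 < r_out^2
}
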