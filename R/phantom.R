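# Synthetic PS-OCT phantom: layered murine retina with a depolarizing RPE
# band, spherical bowing, an ONH depression, three vascular plexuses with
# decorrelating flow signal, per-frame axial motion and speckle-like noise.
# Every downstream stage of the pipeline is validated against the exhaustive
# ground truth this module emits.

#' Retinal layer names (inner to outer)
#' @export
oct_layers <- function() c("RNFL/GCL", "IPL", "INL", "OPL", "PRC", "RPE")

#' Segmented boundary names (inner to outer)
#' @export
oct_boundaries <- function() {
  c("ILM", "RNFL/GCL-IPL", "IPL-INL", "INL-OPL", "OPL-PRC", "PRC-RPE",
    "RPE-bottom")
}

#' Vascular plexus names (superficial to deep)
#' @export
oct_plexuses <- function() c("SVP", "ICP", "DCP")

#' Default vessel specifications for the phantom
#'
#' Builds a per-plexus list of vessel tubes. Each vessel is a polyline in
#' physical en-face coordinates (µm; columns x = fast, y = slow) with a
#' diameter and a flow-decorrelation level in [0, 1]. The default layout
#' mimics the murine retinal circulation: large superficial vessels
#' radiating from the optic nerve head, and finer capillary meshes in the
#' intermediate and deep plexuses.
#'
#' @param extent_um field extent `c(x_fast, y_slow)` in µm
#' @param center_um ONH centre `c(x_fast, y_slow)` in µm
#' @param seed layout seed (the vessel layout is part of the phantom
#'   anatomy and is reproducible given the seed); the ambient RNG state
#'   is restored on exit
#' @export
default_vessel_specs <- function(extent_um, center_um = extent_um / 2,
                                 seed = 1042L) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    })
  }
  set.seed(seed)
  vess <- function(path, d, dec) list(path = path, diameter_um = d,
                                      decorrelation = dec)
  # large vessels radiating from the ONH, with a bent midpoint
  spoke <- function(theta) {
    r1 <- max(extent_um)  # clipped by the field when rasterized
    bend <- stats::runif(1, -0.15, 0.15)
    mid <- center_um + (0.45 * r1) * c(cos(theta + bend), sin(theta + bend))
    rbind(center_um + 60 * c(cos(theta), sin(theta)),
          mid,
          center_um + r1 * c(cos(theta), sin(theta)))
  }
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L] +
    stats::runif(6L, -0.25, 0.25) + 0.3
  svp <- lapply(ang, function(th) vess(spoke(th), 24, 1.0))
  # a family of roughly parallel capillaries with jittered spacing and
  # per-vessel orientation; irregular on purpose (real capillary meshes
  # are not periodic, and a periodic layout would mimic the line
  # artifacts the de-striping stage removes)
  fam <- function(theta0, spacing, d, dec, jitter = 0.2) {
    diag_len <- sqrt(sum(extent_um^2))
    offs <- seq(-diag_len / 2, diag_len / 2, by = spacing)
    offs <- offs + stats::runif(length(offs), -jitter, jitter) * spacing
    lapply(offs, function(o) {
      th <- theta0 + stats::runif(1, -0.2, 0.2)
      nrm <- c(-sin(th), cos(th))
      p0 <- extent_um / 2 + o * nrm
      dirv <- c(cos(th), sin(th))
      vess(rbind(p0 - diag_len * dirv, p0 + diag_len * dirv), d, dec)
    })
  }
  icp <- fam(pi / 4 + stats::runif(1, -0.3, 0.3), 140, 12, 0.8)
  dcp <- c(fam(stats::runif(1, -0.2, 0.2), 150, 14, 0.9),
           fam(pi / 2 + stats::runif(1, -0.2, 0.2), 150, 14, 0.9))
  list(SVP = svp, ICP = icp, DCP = dcp)
}

#' Phantom configuration
#'
#' Geometry defaults follow the acquisition protocol the pipeline targets:
#' 5 repeated B-scans at 400 slow-axis positions, 512 A-lines per B-scan,
#' over a ~1 x 1 mm field centred on the optic nerve head. Layer
#' thicknesses default to healthy-mouse magnitudes (total retina ~214 µm).
#' Reflectivity levels are piecewise constant per layer with plexiform
#' layers brighter than nuclear layers, so every boundary carries an
#' intensity step. The cross-polarized channel is near background
#' everywhere except the melanin-bearing RPE band, whose amplitude is
#' `depol_contrast` times background.
#'
#' @param n_repeats,n_fast,n_slow,n_depth grid sizes
#' @param dx_fast,dx_slow,dz pixel spacing in µm/px
#' @param layer_thickness_um named thicknesses for the six sublayers (µm)
#' @param reflectivity mean co-polarized reflectivity per region
#'   (vitreous, six layers, below-RPE)
#' @param rpe_base_depth_um depth of the RPE top at the field centre
#'   (default 55% of the axial range)
#' @param curvature_radius_um radius of the spherical retinal bowing
#' @param onh_center_um ONH centre `c(x_fast, y_slow)` µm (default field centre)
#' @param onh_radius_um radius of the ONH depression
#' @param onh_pinch_floor minimum inner-layer thickness fraction retained at
#'   the ONH centre (keeps boundary ordering strict)
#' @param vessel_specs per-plexus vessel list (see [default_vessel_specs()])
#' @param motion_amplitude_px SD of the integer per-frame axial shifts
#' @param noise_sigma relative SD of the multiplicative speckle-like noise
#' @param depol_contrast cross-polarized amplification inside the RPE band
#' @param cross_background cross-polarized background level
#' @param seed RNG seed
#' @return a `phantom_config` list, validated
#' @export
phantom_config <- function(n_repeats = 5L, n_fast = 512L, n_slow = 400L,
                           n_depth = 1024L,
                           dx_fast = 1000 / 512, dx_slow = 1000 / 400,
                           dz = 2,
                           layer_thickness_um = c(`RNFL/GCL` = 30, IPL = 36,
                                                  INL = 25, OPL = 12,
                                                  PRC = 100, RPE = 11),
                           reflectivity = c(vitreous = 0.05,
                                            `RNFL/GCL` = 0.90, IPL = 0.70,
                                            INL = 0.35, OPL = 0.65,
                                            PRC = 0.30, RPE = 0.95,
                                            below = 0.10),
                           rpe_base_depth_um = NULL,
                           curvature_radius_um = 1700,
                           onh_center_um = NULL, onh_radius_um = 100,
                           onh_pinch_floor = 0.25,
                           vessel_specs = NULL,
                           motion_amplitude_px = 2,
                           noise_sigma = 0.1,
                           depol_contrast = 15,
                           cross_background = 0.02,
                           seed = 1L) {
  extent <- c(n_fast * dx_fast, n_slow * dx_slow)
  if (is.null(rpe_base_depth_um)) rpe_base_depth_um <- 0.55 * n_depth * dz
  if (is.null(onh_center_um)) onh_center_um <- extent / 2
  if (is.null(vessel_specs)) {
    vessel_specs <- default_vessel_specs(extent, onh_center_um,
                                         seed = as.integer(seed) + 1000L)
  }
  cfg <- list(n_repeats = as.integer(n_repeats), n_fast = as.integer(n_fast),
              n_slow = as.integer(n_slow), n_depth = as.integer(n_depth),
              dx_fast = dx_fast, dx_slow = dx_slow, dz = dz,
              layer_thickness_um = layer_thickness_um,
              reflectivity = reflectivity,
              rpe_base_depth_um = rpe_base_depth_um,
              curvature_radius_um = curvature_radius_um,
              onh_center_um = onh_center_um, onh_radius_um = onh_radius_um,
              onh_pinch_floor = onh_pinch_floor,
              vessel_specs = vessel_specs,
              motion_amplitude_px = motion_amplitude_px,
              noise_sigma = noise_sigma,
              depol_contrast = depol_contrast,
              cross_background = cross_background,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

#' @noRd
validate_phantom_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!all(ok)) rt_stop("PhantomConfigError",
                          "invalid phantom config: field '%s' %s", field, why)
  }
  chk(cfg$n_repeats >= 1, "n_repeats", "must be >= 1")
  for (f in c("n_fast", "n_slow", "n_depth")) {
    chk(cfg[[f]] >= 8, f, "must be >= 8")
  }
  for (f in c("dx_fast", "dx_slow", "dz")) {
    chk(cfg[[f]] > 0, f, "must be > 0")
  }
  th <- cfg$layer_thickness_um
  chk(length(th) == 6L && !is.null(names(th)) &&
        setequal(names(th), oct_layers()),
      "layer_thickness_um", "must name the six sublayers")
  chk(th > 0, "layer_thickness_um", "thicknesses must all be > 0")
  chk(sum(th) + cfg$rpe_base_depth_um < cfg$n_depth * cfg$dz,
      "layer_thickness_um",
      "sum of thicknesses + rpe_base_depth_um must fit the axial range")
  chk(sum(th[setdiff(oct_layers(), "RPE")]) < cfg$rpe_base_depth_um,
      "rpe_base_depth_um", "must leave room for the retina above the RPE")
  extent <- c(cfg$n_fast * cfg$dx_fast, cfg$n_slow * cfg$dx_slow)
  chk(cfg$onh_radius_um < min(extent) / 2, "onh_radius_um",
      "must be smaller than half the field extent")
  chk(cfg$onh_pinch_floor > 0 && cfg$onh_pinch_floor <= 1, "onh_pinch_floor",
      "must be in (0, 1]")
  decs <- unlist(lapply(cfg$vessel_specs,
                        function(pl) vapply(pl, `[[`, 1, "decorrelation")))
  chk(is.null(decs) || all(decs >= 0 & decs <= 1), "vessel_specs",
      "decorrelation levels must lie in [0, 1]")
  chk(cfg$noise_sigma >= 0, "noise_sigma", "must be >= 0")
  chk(cfg$motion_amplitude_px >= 0, "motion_amplitude_px", "must be >= 0")
  invisible(cfg)
}

# Rasterize a polyline tube onto the en-face grid: TRUE where the pixel
# centre lies within diameter/2 of any segment.
#' @noRd
rasterize_vessel <- function(n_slow, n_fast, dx_slow, dx_fast, path, radius) {
  cc <- enface_coords(n_slow, n_fast, dx_slow, dx_fast)
  px <- matrix(rep(cc$x, each = n_slow), n_slow, n_fast)
  py <- matrix(rep(cc$y, times = n_fast), n_slow, n_fast)
  mask <- matrix(FALSE, n_slow, n_fast)
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2
    mask <- mask | (d2 <= radius^2)
  }
  mask
}

# Analytic geometry of the phantom: boundary depth maps (µm), thickness
# maps, vessel masks and per-pixel decorrelation/radius maps.
#' @noRd
phantom_geometry <- function(cfg) {
  ns <- cfg$n_slow; nf <- cfg$n_fast
  d2 <- dist2_map(ns, nf, cfg$dx_slow, cfg$dx_fast, cfg$onh_center_um)
  r <- sqrt(d2)
  sag <- d2 / (2 * cfg$curvature_radius_um)
  # ONH: inner layers pinch toward (but not to) zero inside the disk
  pinch <- ifelse(r < cfg$onh_radius_um,
                  cfg$onh_pinch_floor + (1 - cfg$onh_pinch_floor) *
                    (r / cfg$onh_radius_um)^2,
                  1)
  th <- cfg$layer_thickness_um
  thmap <- list()
  for (ly in oct_layers()) {
    scale <- if (ly %in% c("RNFL/GCL", "IPL", "INL", "OPL")) pinch else 1
    thmap[[ly]] <- th[[ly]] * scale
    if (is.matrix(scale) || length(scale) > 1) {
      thmap[[ly]] <- matrix(thmap[[ly]], ns, nf)
    } else {
      thmap[[ly]] <- matrix(th[[ly]], ns, nf)
    }
  }
  rpe_top <- cfg$rpe_base_depth_um + sag
  B <- list()
  B[["PRC-RPE"]] <- rpe_top
  B[["OPL-PRC"]] <- rpe_top - thmap[["PRC"]]
  B[["INL-OPL"]] <- B[["OPL-PRC"]] - thmap[["OPL"]]
  B[["IPL-INL"]] <- B[["INL-OPL"]] - thmap[["INL"]]
  B[["RNFL/GCL-IPL"]] <- B[["IPL-INL"]] - thmap[["IPL"]]
  B[["ILM"]] <- B[["RNFL/GCL-IPL"]] - thmap[["RNFL/GCL"]]
  B[["RPE-bottom"]] <- rpe_top + thmap[["RPE"]]
  B <- B[oct_boundaries()]

  vmask <- list(); vdec <- list(); vrad <- list()
  for (pl in oct_plexuses()) {
    m <- matrix(FALSE, ns, nf)
    dec <- matrix(0, ns, nf)
    rad <- matrix(0, ns, nf)
    for (v in cfg$vessel_specs[[pl]]) {
      vm <- rasterize_vessel(ns, nf, cfg$dx_slow, cfg$dx_fast,
                             v$path, v$diameter_um / 2)
      m <- m | vm
      dec[vm] <- pmax(dec[vm], v$decorrelation)
      rad[vm] <- pmax(rad[vm], v$diameter_um / 2)
    }
    vmask[[pl]] <- m; vdec[[pl]] <- dec; vrad[[pl]] <- rad
  }
  # plexus tube centre depths (µm): mid-slab positions; tubes are
  # clamped to their anatomical slab so a capillary never leaks
  # decorrelation into the neighboring plexus' projection
  vcz <- list(SVP = (B[["ILM"]] + B[["IPL-INL"]]) / 2,
              ICP = (B[["IPL-INL"]] + B[["INL-OPL"]]) / 2,
              DCP = (B[["INL-OPL"]] + B[["OPL-PRC"]]) / 2)
  vslab <- list(SVP = list(B[["ILM"]], B[["IPL-INL"]]),
                ICP = list(B[["IPL-INL"]], B[["INL-OPL"]]),
                DCP = list(B[["INL-OPL"]], B[["OPL-PRC"]]))
  list(boundaries = B, thickness = thmap, onh_r = r,
       vmask = vmask, vdec = vdec, vrad = vrad, vcz = vcz, vslab = vslab)
}

#' Generate a synthetic PS-OCT volume with ground truth
#'
#' Returns the raw two-channel volume (with curvature, per-frame axial
#' motion and speckle-like noise applied) together with the analytic ground
#' truth: boundary depth maps, per-layer thickness maps, per-plexus vessel
#' masks and the injected frame shifts.
#'
#' Noise model: each voxel's mean reflectivity is modulated by a shared
#' multiplicative speckle factor `1 - s + s*E` (E ~ Exp(1), s =
#' `noise_sigma`) that is identical across repeats (static tissue), while
#' voxels inside a vessel tube blend in a per-repeat fully developed
#' speckle draw weighted by the vessel's decorrelation level. At
#' decorrelation 1 the repeats are i.i.d. exponential, the limit the
#' angiography estimator is tested against. The ONH disk is fully
#' decorrelated throughout the retina depth (saturated angiogram signal,
#' as the real pipeline must exclude).
#'
#' @param config a [phantom_config()]
#' @return list with elements `volume` (a `raw_volume`) and `truth`
#'   (a `ground_truth`)
#' @export
generate_phantom <- function(config) {
  cfg <- validate_phantom_config(config)
  set.seed(cfg$seed)
  ns <- cfg$n_slow; nf <- cfg$n_fast; nd <- cfg$n_depth; nr <- cfg$n_repeats
  geo <- phantom_geometry(cfg)

  # integer per-frame axial shifts, zero-mean discretized normal
  raw_sh <- matrix(stats::rnorm(ns * nr), ns, nr)
  frame_shifts <- round(cfg$motion_amplitude_px * raw_sh)

  lv_co <- cfg$reflectivity[c("vitreous", oct_layers(), "below")]
  lv_cr <- c(cfg$cross_background,
             rep(cfg$cross_background, 5L),
             cfg$depol_contrast * cfg$cross_background,
             cfg$cross_background)

  co <- array(0, c(nd, nf, ns, nr))
  cr <- array(0, c(nd, nf, ns, nr))
  zpx <- seq_len(nd) - 1  # 0-based voxel depth (px)
  s <- cfg$noise_sigma
  Bpx <- lapply(geo$boundaries, function(b) b / cfg$dz)
  onh_cols <- geo$onh_r < cfg$onh_radius_um

  for (si in seq_len(ns)) {
    cnt <- matrix(0L, nd, nf)
    for (b in Bpx) cnt <- cnt + outer(zpx, b[si, ], `>=`)
    region <- cnt + 1L
    M <- matrix(lv_co[region], nd, nf)
    Mx <- matrix(lv_cr[region], nd, nf)

    D <- matrix(0, nd, nf)
    for (pl in oct_plexuses()) {
      cols <- which(geo$vmask[[pl]][si, ])
      for (f in cols) {
        czpx <- geo$vcz[[pl]][si, f] / cfg$dz
        rpx <- geo$vrad[[pl]][si, f] / cfg$dz
        sl_up <- geo$vslab[[pl]][[1]][si, f] / cfg$dz
        sl_lo <- geo$vslab[[pl]][[2]][si, f] / cfg$dz
        rows <- which(abs(zpx - czpx) <= rpx & zpx >= sl_up & zpx < sl_lo)
        if (!length(rows)) rows <- which.min(abs(zpx - czpx))
        D[rows, f] <- pmax(D[rows, f], geo$vdec[[pl]][si, f])
      }
    }
    oc <- which(onh_cols[si, ])
    for (f in oc) {
      rows <- zpx >= Bpx[["ILM"]][si, f] & zpx < Bpx[["RPE-bottom"]][si, f]
      D[rows, f] <- 1
    }

    S <- 1 - s + s * matrix(stats::rexp(nd * nf), nd, nf)
    Sx <- 1 - s + s * matrix(stats::rexp(nd * nf), nd, nf)
    static_co <- M * ((1 - D) * S)
    static_cr <- Mx * ((1 - D) * Sx)
    for (ri in seq_len(nr)) {
      X <- matrix(stats::rexp(nd * nf), nd, nf)
      Xx <- matrix(stats::rexp(nd * nf), nd, nf)
      vco <- static_co + M * D * X
      vcr <- static_cr + Mx * D * Xx
      sh <- frame_shifts[si, ri]
      if (sh != 0) {
        for (f in seq_len(nf)) {
          vco[, f] <- shift_vec(vco[, f], -sh)
          vcr[, f] <- shift_vec(vcr[, f], -sh)
        }
      }
      co[, , si, ri] <- vco
      cr[, , si, ri] <- vcr
    }
  }

  volume <- raw_volume(co, cr, dz = cfg$dz, dx_fast = cfg$dx_fast,
                       dx_slow = cfg$dx_slow,
                       meta = list(onh_center_um = cfg$onh_center_um,
                                   scan_id = sprintf("phantom-%d", cfg$seed)))
  truth <- structure(list(boundary_depths_um = geo$boundaries,
                          layer_thickness_maps_um = geo$thickness,
                          vessel_masks = geo$vmask,
                          frame_shifts = frame_shifts,
                          onh_radius_um = cfg$onh_radius_um,
                          config = cfg),
                     class = "ground_truth")
  list(volume = volume, truth = truth)
}

#' Construct a raw two-channel PS-OCT volume
#'
#' Arrays are indexed `[depth, fast, slow, repeat]`; depth coordinates are
#' 0-based and increase away from the vitreous. En-face maps throughout the
#' package are indexed `[slow, fast]`.
#'
#' @param co_pol,cross_pol numeric 4-d arrays of identical shape
#' @param dz,dx_fast,dx_slow pixel spacings (µm/px)
#' @param meta named list of acquisition labels (mouse, eye, model,
#'   genotype, sex, onh_center_um, scan_id, ...)
#' @export
raw_volume <- function(co_pol, cross_pol, dz, dx_fast, dx_slow,
                       meta = list()) {
  if (!identical(dim(co_pol), dim(cross_pol))) {
    rt_stop("VolumeShapeError", "co- and cross-polarized shapes differ")
  }
  if (length(dim(co_pol)) != 4L) {
    rt_stop("VolumeShapeError",
            "volume must be [depth, fast, slow, repeat] (4-d)")
  }
  if (any(c(dz, dx_fast, dx_slow) <= 0)) {
    rt_stop("VolumeShapeError", "pixel spacings must be > 0")
  }
  structure(list(co_pol = co_pol, cross_pol = cross_pol, dz = dz,
                 dx_fast = dx_fast, dx_slow = dx_slow, meta = meta),
            class = "raw_volume")
}

#' @export
dim.raw_volume <- function(x) dim(x$co_pol)

#' @export
print.raw_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(paste0("<raw_volume> %d depth x %d fast x %d slow x %d",
                     " repeats; dz=%.3g dx_fast=%.3g dx_slow=%.3g um/px\n"),
              d[1], d[2], d[3], d[4], x$dz, x$dx_fast, x$dx_slow))
  invisible(x)
}

#' Cohort simulation configuration
#'
#' A two-level random-effects data generator matching the model fitted by
#' the statistics stage: eye value = group mean + mouse intercept
#' N(0, sd_mouse^2) + residual N(0, sd_eye^2).
#'
#' @param group_means per-group true means (µm or %); names become group
#'   labels (default `g1`, `g2`, ...)
#' @param sd_mouse between-mouse SD (>= 0)
#' @param sd_eye residual (within-mouse, between-eye) SD (> 0)
#' @param n_mice_per_group mice per group
#' @param eyes_per_mouse eyes measured per mouse (default 2)
#' @param outcome_name label carried in the table
#' @param seed RNG seed
#' @export
cohort_config <- function(group_means, sd_mouse, sd_eye,
                          n_mice_per_group, eyes_per_mouse = 2L,
                          outcome_name = "TOTAL", seed = 1L) {
  if (sd_mouse < 0) rt_stop("CohortConfigError", "field 'sd_mouse' must be >= 0")
  if (sd_eye <= 0) rt_stop("CohortConfigError", "field 'sd_eye' must be > 0")
  if (length(group_means) < 1) {
    rt_stop("CohortConfigError", "field 'group_means' must be non-empty")
  }
  if (is.null(names(group_means))) {
    names(group_means) <- sprintf("g%d", seq_along(group_means))
  }
  structure(list(group_means = group_means, sd_mouse = sd_mouse,
                 sd_eye = sd_eye,
                 n_mice_per_group = as.integer(n_mice_per_group),
                 eyes_per_mouse = as.integer(eyes_per_mouse),
                 outcome_name = outcome_name, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a cohort measurement table
#'
#' @param config a [cohort_config()]
#' @return data.frame with columns `mouse_id`, `group`, `sex`, `eye`,
#'   `outcome_name`, `value`
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  groups <- names(cfg$group_means)
  rows <- list()
  midx <- 0L
  eyes <- c("L", "R", sprintf("E%d", seq_len(max(0L, cfg$eyes_per_mouse - 2L)) + 2L))
  for (g in groups) {
    for (m in seq_len(cfg$n_mice_per_group)) {
      midx <- midx + 1L
      intercept <- stats::rnorm(1L, 0, cfg$sd_mouse)
      vals <- cfg$group_means[[g]] + intercept +
        stats::rnorm(cfg$eyes_per_mouse, 0, cfg$sd_eye)
      rows[[midx]] <- data.frame(
        mouse_id = sprintf("m%04d", midx),
        group = g,
        sex = if (m %% 2L == 0L) "F" else "M",
        eye = eyes[seq_len(cfg$eyes_per_mouse)],
        outcome_name = cfg$outcome_name,
        value = vals,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
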