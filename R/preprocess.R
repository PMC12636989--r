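# Preprocessing: RPE detection from the cross-polarized channel,
# flattening of the retina to a plane, and compensation of residual
# inter-frame axial motion. The melanin-rich RPE scrambles polarization,
# so in the cross-polarized channel it is the only strong band; its top
# edge is found per A-scan as the maximum of a derivative-of-Gaussian
# response along depth.

#' Segment the RPE from the cross-polarized channel
#'
#' For each A-scan of each frame, returns the 0-based depth (px) of the
#' strongest positive axial edge of the cross-polarized depolarization
#' band, i.e. the top of the RPE. Each frame's en-face map is
#' median-filtered to suppress outliers.
#'
#' @param volume a `raw_volume` (or `flat_volume`)
#' @param sigma depth Gaussian smoothing SD (px) before differentiation
#' @param window optional `c(z_min, z_max)` 0-based search window (px)
#' @param median_k running-median kernel (odd; 1 disables) applied along
#'   the fast axis of each frame's map; filtering stays within the frame
#'   because neighboring B-scans carry different axial motion
#' @param noise_factor the volume must show a band contrast (per-column
#'   max over median of the smoothed cross-polarized signal) of at least
#'   this factor, otherwise a `NoDepolarizingLayer` error is raised
#' @return array `[slow, fast, repeat]` of 0-based RPE depths (px)
#' @export
segment_rpe_crosspol <- function(volume, sigma = 2, window = NULL,
                                 median_k = 5L, noise_factor = 5) {
  cr <- volume$cross_pol
  d <- dim(cr)
  nd <- d[1]; nf <- d[2]; ns <- d[3]; nr <- d[4]
  if (is.null(window)) window <- c(0L, nd - 1L)
  if (window[1] < 0 || window[2] >= nd || window[2] - window[1] < 2) {
    rt_stop("ValidationError", "invalid RPE search window [%s, %s]",
            window[1], window[2])
  }
  rows <- (window[1] + 1L):(window[2] + 1L)
  k <- gauss_kernel(sigma)

  # band-contrast screen on a subsample of frames
  contr <- numeric(0)
  for (si in unique(round(seq(1, ns, length.out = min(ns, 8L))))) {
    sm <- filter_cols(cr[, , si, 1L], k)
    cmax <- apply(sm, 2L, max)
    cmed <- apply(sm, 2L, stats::median)
    contr <- c(contr, cmax / pmax(cmed, .Machine$double.eps))
  }
  if (stats::median(contr) < noise_factor) {
    rt_stop("NoDepolarizingLayer",
            paste0("cross-polarized channel shows no depolarizing band ",
                   "(contrast %.2f < %.2f); is this PS-OCT data?"),
            stats::median(contr), noise_factor)
  }

  out <- array(NA_real_, c(ns, nf, nr))
  for (ri in seq_len(nr)) {
    for (si in seq_len(ns)) {
      sm <- filter_cols(cr[, , si, ri], k)
      dd <- sm - rbind(sm[1L, , drop = FALSE], sm[-nd, , drop = FALSE])
      idx <- max.col(t(dd[rows, , drop = FALSE]), ties.method = "first")
      m <- window[1] + idx - 1L
      if (median_k > 1L && nf > median_k) {
        m <- as.numeric(stats::runmed(m, median_k, endrule = "median"))
      }
      out[si, , ri] <- m
    }
  }
  out
}

#' Flatten a volume to a planar RPE and align repeats
#'
#' Every A-scan is integer-shifted along depth (zero padding) so that its
#' segmented RPE sits at `rpe_depth_px`. Repeats are first aligned to
#' repeat 1 by a rigid per-frame axial shift, the rounded median of the
#' difference between the frame's RPE map and repeat 1's (axial bulk
#' motion is rigid per frame, and the median is immune to the per-column
#' detection jitter, which is common to all repeats of a static scene);
#' the per-column flattening shift then comes from repeat 1's map. This
#' compensates residual inter-frame motion while keeping static voxels
#' bit-identical across repeats, which the angiography stage relies on.
#' Integer shifts preserve within-column distances, so layer thicknesses
#' are unchanged by construction.
#'
#' @param volume a `raw_volume`
#' @param rpe_map optional `[slow, fast, repeat]` RPE depth array from
#'   [segment_rpe_crosspol()] (computed if missing)
#' @param rpe_depth_px target 0-based RPE depth (default: rounded median
#'   of the map)
#' @param clip_frac error if an applied shift would push rows whose
#'   co-polarized intensity exceeds `clip_frac` times the column maximum
#'   out of the depth range (`OutOfDepthRange`)
#' @param ... passed to [segment_rpe_crosspol()]
#' @return a `flat_volume`: both channels `[depth, fast, slow, repeat]`,
#'   `rpe_depth_px`, and `shift_record` `[slow, fast, repeat]`
#' @export
flatten_volume <- function(volume, rpe_map = NULL, rpe_depth_px = NULL,
                           clip_frac = 0.5, ...) {
  if (is.null(rpe_map)) rpe_map <- segment_rpe_crosspol(volume, ...)
  if (any(!is.finite(rpe_map))) {
    rt_stop("ValidationError", "rpe_map must be finite everywhere")
  }
  d <- dim(volume$co_pol)
  nd <- d[1]; nf <- d[2]; ns <- d[3]; nr <- d[4]
  if (is.null(rpe_depth_px)) rpe_depth_px <- round(stats::median(rpe_map))
  if (rpe_depth_px < 0 || rpe_depth_px >= nd) {
    rt_stop("OutOfDepthRange", "target RPE depth %s outside [0, %d)",
            rpe_depth_px, nd)
  }
  # rigid per-frame repeat alignment relative to repeat 1
  rep_shift <- matrix(0L, ns, nr)
  if (nr > 1L) {
    for (ri in 2:nr) {
      for (si in seq_len(ns)) {
        rep_shift[si, ri] <-
          as.integer(round(stats::median(rpe_map[si, , ri] -
                                           rpe_map[si, , 1L])))
      }
    }
  }
  base <- round(rpe_map[, , 1L]) - rpe_depth_px  # [slow, fast]
  shifts <- array(0L, c(ns, nf, nr))
  for (ri in seq_len(nr)) shifts[, , ri] <- base + rep_shift[, ri]
  co <- volume$co_pol
  cr <- volume$cross_pol
  for (ri in seq_len(nr)) {
    for (si in seq_len(ns)) {
      for (f in seq_len(nf)) {
        sh <- shifts[si, f, ri]
        if (sh == 0L) next
        v <- co[, f, si, ri]
        dropped <- if (sh > 0L) v[seq_len(min(sh, nd))] else
          v[(nd + max(sh, -nd) + 1L):nd]
        if (max(dropped) > clip_frac * max(v)) {
          rt_stop("OutOfDepthRange",
                  paste0("flattening shift %d at (slow=%d, fast=%d, ",
                         "repeat=%d) would clip tissue"), sh, si, f, ri)
        }
        co[, f, si, ri] <- shift_vec(v, sh)
        cr[, f, si, ri] <- shift_vec(cr[, f, si, ri], sh)
      }
    }
  }
  structure(list(co_pol = co, cross_pol = cr,
                 rpe_depth_px = rpe_depth_px, shift_record = shifts,
                 dz = volume$dz, dx_fast = volume$dx_fast,
                 dx_slow = volume$dx_slow, meta = volume$meta),
            class = c("flat_volume", "raw_volume"))
}

#' Repeat-averaged co-polarized volume
#' @param flat a `flat_volume`
#' @return array `[depth, fast, slow]`
#' @export
mean_copol <- function(flat) {
  d <- dim(flat$co_pol)
  if (d[4] == 1L) return(array(flat$co_pol, d[1:3]))
  out <- flat$co_pol[, , , 1L]
  for (ri in 2:d[4]) out <- out + flat$co_pol[, , , ri]
  out / d[4]
}

#' Quality-control screen
#'
#' Computes the mean image SNR (mean tissue intensity over mean background
#' above the retina) and the fraction of A-scans whose column maximum
#' falls below a floor (vignetting); a volume is included when
#' `snr >= snr_min` and `vignetting_fraction <= v_max`. Mirrors the manual
#' exclusion of scans with low signal, strong vignetting or acquisition
#' errors.
#'
#' @param volume a `raw_volume`
#' @param snr_min minimum mean SNR
#' @param v_max maximum tolerated vignetting fraction
#' @param bg_frac fraction of the shallowest depth rows treated as
#'   background (vitreous)
#' @param col_floor_frac an A-scan is vignetted when its maximum is below
#'   this fraction of the median column maximum
#' @return list `mean_snr`, `vignetting_fraction`, `include`
#' @export
qc_screen <- function(volume, snr_min = 3, v_max = 0.25, bg_frac = 0.1,
                      col_floor_frac = 0.25) {
  co <- volume$co_pol
  d <- dim(co)
  nbg <- max(1L, floor(bg_frac * d[1]))
  bg <- mean(co[seq_len(nbg), , , , drop = FALSE])
  tissue_vox <- co[co > 2 * bg]
  tis <- if (length(tissue_vox)) mean(tissue_vox) else 0
  snr <- if (bg > 0) tis / bg else 0
  colmax <- apply(co[, , , 1L, drop = FALSE], c(2L, 3L), max)
  floorv <- col_floor_frac * stats::median(colmax)
  vfrac <- mean(colmax < floorv)
  list(mean_snr = snr, vignetting_fraction = vfrac,
       include = (snr >= snr_min) && (vfrac <= v_max))
}
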