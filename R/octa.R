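# OCT angiography: motion-contrast volume from repeated B-scans, maximum
# intensity projection per vascular slab, multi-scale Frangi vesselness
# binarization with a majority vote, spectral de-striping, SVP projection
# artifact removal, subregion SNR confidence masking, and vessel density.

#' Decorrelation angiogram from aligned repeats
#'
#' Per voxel, the mean over all C(R, 2) repeat pairs of the normalized
#' absolute intensity difference |I_i - I_j| / (I_i + I_j + eps). Values
#' lie in \[0, 1\]: static voxels give ~0, fully decorrelated exponential
#' speckle gives expectation 1/2. The estimator is invariant to a common
#' global rescaling of all repeats.
#'
#' @param flat a `flat_volume` (repeats aligned)
#' @param eps stabilizer in the denominator
#' @return decorrelation array `[depth, fast, slow]`
#' @export
compute_angiogram <- function(flat, eps = 1e-9) {
  co <- flat$co_pol
  d <- dim(co)
  if (d[4] < 2L) {
    rt_stop("InsufficientRepeats",
            "angiography needs >= 2 aligned repeats, got %d", d[4])
  }
  acc <- array(0, d[1:3])
  npairs <- 0L
  for (i in seq_len(d[4] - 1L)) {
    for (j in (i + 1L):d[4]) {
      a <- co[, , , i]
      b <- co[, , , j]
      acc <- acc + abs(a - b) / (a + b + eps)
      npairs <- npairs + 1L
    }
  }
  acc / npairs
}

#' Default vascular slab definitions
#'
#' SVP: ILM to IPL-INL; ICP: IPL-INL to INL-OPL; DCP: INL-OPL to OPL-PRC.
#' Overridable: any named list mapping plexus to
#' `c(upper_boundary, lower_boundary)` names.
#' @export
default_slabs <- function() {
  list(SVP = c("ILM", "IPL-INL"),
       ICP = c("IPL-INL", "INL-OPL"),
       DCP = c("INL-OPL", "OPL-PRC"))
}

#' Maximum intensity projection of the angiogram within a vascular slab
#'
#' Per column, the maximum over depth rows in `[upper, lower)` between the
#' slab's bounding boundaries. Columns with an empty slab get value 0; the
#' number of such columns is attached as attribute `"n_empty"`.
#'
#' @param angio `[depth, fast, slow]` decorrelation array
#' @param bounds a `boundary_set`
#' @param plexus `"SVP"`, `"ICP"` or `"DCP"`
#' @param slabs slab definition list (see [default_slabs()])
#' @return en-face matrix `[slow, fast]`
#' @export
slab_project <- function(angio, bounds, plexus, slabs = default_slabs()) {
  if (!plexus %in% names(slabs)) {
    rt_stop("ValidationError", "unknown plexus '%s'", plexus)
  }
  bn <- slabs[[plexus]]
  up <- bounds$depths[[bn[1]]]  # [slow, fast], 0-based px
  lo <- bounds$depths[[bn[2]]]
  d <- dim(angio)
  nd <- d[1]; nf <- d[2]; ns <- d[3]
  out <- matrix(0, ns, nf)
  n_empty <- 0L
  for (si in seq_len(ns)) {
    sl <- angio[, , si]
    for (f in seq_len(nf)) {
      r0 <- ceiling(up[si, f]) + 1L     # 1-based first voxel with z >= upper
      r1 <- ceiling(lo[si, f])          # last voxel with z < lower
      r0 <- max(r0, 1L); r1 <- min(r1, nd)
      if (r1 < r0) { n_empty <- n_empty + 1L; next }
      out[si, f] <- max(sl[r0:r1, f])
    }
  }
  if (n_empty > 0L) {
    warning(sprintf("slab '%s': %d empty columns set to 0", plexus, n_empty))
  }
  attr(out, "n_empty") <- n_empty
  out
}

#' Frangi vesselness at one scale
#'
#' Hessian-eigenvalue ridge filter for bright tubular structures:
#' with |l1| <= |l2| the eigenvalues of the scale-normalized Gaussian
#' Hessian (gamma = 2), vesselness is
#' `exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` where
#' `S = sqrt(l1^2 + l2^2)`, for l2 < 0 and 0 otherwise. `c` defaults to
#' half the maximum of S over the image.
#'
#' @param img en-face matrix
#' @param sigma_px filter scale (px)
#' @param beta blobness weight
#' @export
frangi_vesselness <- function(img, sigma_px, beta = 0.5) {
  sigma_px <- max(sigma_px, 0.6)
  g0 <- gauss_kernel(sigma_px, 0L)
  g1 <- gauss_kernel(sigma_px, 1L)
  g2 <- gauss_kernel(sigma_px, 2L)
  s2 <- sigma_px^2
  hyy <- s2 * filter_sep(img, g2, g0)
  hxx <- s2 * filter_sep(img, g0, g2)
  hxy <- s2 * filter_sep(img, g1, g1)
  tmp <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  m <- (hxx + hyy) / 2
  e1 <- m + tmp
  e2 <- m - tmp
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)   # |l1| <= |l2|
  l2 <- ifelse(swap, e1, e2)
  S <- sqrt(l1^2 + l2^2)
  cpar <- max(S) / 2
  v <- matrix(0, nrow(img), ncol(img))
  sel <- l2 < 0
  if (cpar > 0 && any(sel)) {
    rb2 <- (l1[sel] / l2[sel])^2
    v[sel] <- exp(-rb2 / (2 * beta^2)) *
      (1 - exp(-S[sel]^2 / (2 * cpar^2)))
  }
  v
}

#' Majority vote over a list of binary maps
#'
#' A pixel is positive iff it is positive in a strict majority of the
#' maps (>= 3 of 5; for an even count, ties are negative).
#'
#' @param binaries list of logical matrices of identical shape
#' @export
majority_vote <- function(binaries) {
  k <- length(binaries)
  acc <- Reduce(`+`, binaries)
  acc >= (k %/% 2L + 1L)
}

#' Multi-scale vesselness binarization
#'
#' For each physical scale: Frangi vesselness (the scale is the Gaussian
#' SD of the Hessian filter, converted to px from the spacing),
#' normalized to \[0, 1\], then an adaptive local-mean threshold
#' (`v > local_mean - offset`); the final mask is the strict-majority vote
#' over the per-scale binaries. The default scales span 4-12 µm in 2 µm
#' steps, highlighting vasculature of different calibres.
#'
#' @param enface en-face angiogram `[slow, fast]` (non-negative)
#' @param scales_um filter scales (Gaussian SD, µm)
#' @param spacing_um en-face spacing (µm/px; scalar or `c(dslow, dfast)`,
#'   averaged)
#' @param window_px adaptive-threshold window size
#' @param offset adaptive-threshold offset (subtracted from local mean)
#' @param beta Frangi blobness weight
#' @return logical `[slow, fast]` mask; per-scale binaries in attribute
#'   `"per_scale"`
#' @export
multiscale_binarize <- function(enface, scales_um = c(4, 6, 8, 10, 12),
                                spacing_um = 2, window_px = 64L,
                                offset = -0.04, beta = 0.5) {
  if (any(enface < 0)) {
    rt_stop("ValidationError", "enface map must be non-negative")
  }
  sp <- mean(spacing_um)
  bins <- lapply(scales_um, function(sc) {
    v <- frangi_vesselness(enface, sc / sp, beta)
    mx <- max(v)
    if (mx > 0) v <- v / mx
    v > box_mean(v, window_px) - offset
  })
  out <- majority_vote(bins)
  attr(out, "per_scale") <- bins
  out
}

#' Suppress periodic line artifacts in an en-face map
#'
#' Inter-frame motion can masquerade as vasculature and appears as
#' periodic vertical or horizontal lines. Pure horizontal/vertical
#' stripes concentrate their spectral energy exactly on the two
#' frequency axes, whereas ordinary image structures spread comparable
#' energy into the neighboring off-axis bins; an axis bin is therefore
#' flagged as stripe energy when its magnitude exceeds `peak_factor`
#' times the median of its nearest off-axis neighbors (the lowest
#' `exclude_low` frequencies are left untouched) and is attenuated, an
#' oriented band-rejection equivalent to notch Gabor filtering.
#'
#' @param enface en-face matrix
#' @param peak_factor detection threshold relative to the off-axis
#'   continuum at the same frequency
#' @param exclude_low number of low-frequency bins left untouched
#' @param atten attenuation factor applied to detected bins
#' @export
remove_line_artifacts <- function(enface, peak_factor = 5,
                                  exclude_low = 2L, atten = 0.01) {
  F <- stats::fft(enface)
  nr <- nrow(F); nc <- ncol(F)
  freq_ok <- function(i, n) pmin(i - 1L, n - i + 1L) > exclude_low
  # vertical-frequency axis (kx = 0): horizontal stripes
  off_c <- c(2L, 3L, nc - 1L, nc)
  for (i in which(freq_ok(seq_len(nr), nr))) {
    cont <- stats::median(Mod(F[i, off_c]))
    if (Mod(F[i, 1L]) > peak_factor * max(cont, .Machine$double.eps)) {
      F[i, 1L] <- F[i, 1L] * atten
    }
  }
  # horizontal-frequency axis (ky = 0): vertical stripes
  off_r <- c(2L, 3L, nr - 1L, nr)
  for (j in which(freq_ok(seq_len(nc), nc))) {
    cont <- stats::median(Mod(F[off_r, j]))
    if (Mod(F[1L, j]) > peak_factor * max(cont, .Machine$double.eps)) {
      F[1L, j] <- F[1L, j] * atten
    }
  }
  Re(stats::fft(F, inverse = TRUE)) / (nr * nc)
}

#' Remove SVP projection artifacts from a deeper plexus mask
#'
#' Large superficial vessels shadow decorrelation into the deeper slabs;
#' the SVP binary mask is subtracted from the ICP/DCP masks and values
#' below zero are set to zero: `max(target - svp, 0)` elementwise.
#'
#' @param target_binary ICP or DCP logical mask
#' @param svp_binary final SVP logical mask
#' @export
remove_projection_artifacts <- function(target_binary, svp_binary) {
  if (!identical(dim(target_binary), dim(svp_binary))) {
    rt_stop("ValidationError", "mask shapes differ")
  }
  target_binary & !svp_binary
}

#' Subregion SNR confidence masking
#'
#' The field is tiled into `subregion_px` x `subregion_px` blocks. Per
#' block, SNR = mean angiogram signal inside the binarized vessel mask
#' over the mean signal in the remainder (the noise floor); blocks with
#' SNR below `threshold_snf` ("times stronger than the noise floor") are
#' excluded, as are blocks with no vessel or no background pixels
#' (flagged).
#'
#' @param enface en-face angiogram
#' @param binary vessel mask
#' @param subregion_px tile size (px)
#' @param threshold_snf inclusion threshold (x noise floor)
#' @param exclude optional logical mask of pixels ignored entirely
#'   (neither vessel nor noise floor), e.g. the removed ONH disk, which
#'   otherwise saturates the noise-floor estimate
#' @return list `snr` (per-tile matrix), `inclusion_mask` (per-pixel
#'   logical), `flagged` (per-tile logical: degenerate tiles)
#' @export
snr_mask <- function(enface, binary, subregion_px = 64L, threshold_snf = 20,
                     exclude = NULL) {
  nr <- nrow(enface); nc <- ncol(enface)
  if (is.null(exclude)) exclude <- matrix(FALSE, nr, nc)
  ti <- ceiling(nr / subregion_px); tj <- ceiling(nc / subregion_px)
  snr <- matrix(NA_real_, ti, tj)
  flagged <- matrix(FALSE, ti, tj)
  incl <- matrix(FALSE, nr, nc)
  for (a in seq_len(ti)) {
    rows <- ((a - 1L) * subregion_px + 1L):min(a * subregion_px, nr)
    for (b in seq_len(tj)) {
      cols <- ((b - 1L) * subregion_px + 1L):min(b * subregion_px, nc)
      e <- enface[rows, cols]
      m <- binary[rows, cols]
      keep <- !exclude[rows, cols]
      e <- e[keep]; m <- m[keep]
      nv <- sum(m); nb <- sum(!m)
      if (nv == 0L || nb == 0L) {
        flagged[a, b] <- TRUE
        next
      }
      vm <- mean(e[m]); bm <- mean(e[!m])
      snr[a, b] <- if (bm > 0) vm / bm else if (vm > 0) Inf else NA_real_
      if (!is.na(snr[a, b]) && snr[a, b] >= threshold_snf) {
        incl[rows, cols] <- TRUE
      }
    }
  }
  list(snr = snr, inclusion_mask = incl, flagged = flagged)
}

#' Disk mask around the ONH centre
#'
#' @param n_slow,n_fast grid size
#' @param spacing_um `c(dx_slow, dx_fast)` µm/px
#' @param center_um ONH centre `c(x_fast, y_slow)` µm
#' @param radius_um exclusion radius (µm)
#' @export
onh_disk_mask <- function(n_slow, n_fast, spacing_um, center_um,
                          radius_um) {
  dist2_map(n_slow, n_fast, spacing_um[1], spacing_um[2], center_um) <=
    radius_um^2
}

#' Vessel density within the confidence region
#'
#' Density (%) = 100 x positive pixels / all pixels, both counted within
#' `inclusion_mask` minus `onh_mask`.
#'
#' @param binary vessel mask
#' @param inclusion_mask SNR confidence mask (default: everything)
#' @param onh_mask excluded ONH disk (default: nothing)
#' @return list `density`, `included_area_fraction`, `n_included`
#' @export
vessel_density <- function(binary, inclusion_mask = NULL, onh_mask = NULL) {
  if (is.null(inclusion_mask)) {
    inclusion_mask <- matrix(TRUE, nrow(binary), ncol(binary))
  }
  if (is.null(onh_mask)) onh_mask <- matrix(FALSE, nrow(binary), ncol(binary))
  roi <- inclusion_mask & !onh_mask
  n <- sum(roi)
  if (n == 0L) {
    rt_stop("EmptyROI", "no pixels left after SNR and ONH exclusion")
  }
  list(density = 100 * sum(binary[roi]) / n,
       included_area_fraction = n / length(binary),
       n_included = n)
}

#' Full angiography chain for one plexus
#'
#' Projection -> de-striping -> multi-scale binarization -> (ICP/DCP) SVP
#' mask subtraction -> SNR confidence masking -> ONH removal -> density.
#'
#' @param angio decorrelation volume
#' @param bounds a `boundary_set`
#' @param plexus plexus name
#' @param svp_binary final SVP mask (required for ICP/DCP)
#' @param config a [default_run_config()]-style list
#' @param onh_center_um ONH centre (µm)
#' @return list with `enface`, `binary`, `snr`, `inclusion_mask`,
#'   `onh_mask`, `density` (a density result list), `threshold_snf`
#' @export
quantify_plexus <- function(angio, bounds, plexus, svp_binary = NULL,
                            config = default_run_config(),
                            onh_center_um = NULL) {
  spacing <- config$spacing_um
  enf <- slab_project(angio, bounds, plexus, config$slabs)
  enf <- remove_line_artifacts(enf)
  enf[enf < 0] <- 0
  bin <- multiscale_binarize(enf, config$frangi$scales_um, spacing,
                             config$frangi$window_px, config$frangi$offset,
                             config$frangi$beta)
  if (plexus != "SVP") {
    if (is.null(svp_binary)) {
      rt_stop("ValidationError", "ICP/DCP quantification needs the SVP mask")
    }
    bin <- remove_projection_artifacts(bin, svp_binary)
  }
  onh <- if (is.null(onh_center_um)) {
    matrix(FALSE, nrow(enf), ncol(enf))
  } else {
    onh_disk_mask(nrow(enf), ncol(enf), spacing, onh_center_um,
                  config$onh_exclusion_um)
  }
  bin <- bin & !onh
  thr <- config$snf[[plexus]]
  sm <- snr_mask(enf, bin, config$subregion_px, thr, exclude = onh)
  dens <- vessel_density(bin, sm$inclusion_mask, onh)
  list(plexus = plexus, enface = enf, binary = bin, snr = sm$snr,
       inclusion_mask = sm$inclusion_mask, onh_mask = onh,
       density = dens, threshold_snf = thr)
}
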