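# Graph-based retinal layer segmentation. Each B-scan is turned into a
# column-monotone graph whose nodes are pixels; edges between horizontally
# adjacent nodes (8-connected, one row step at most per column) carry
# weight w(a, b) = 2 - (g(a) + g(b)) + w_min, where g is the signed
# vertical gradient normalized to [0, 1] with the requested polarity
# (the Chiu/Srinivasan construction). A boundary is the lowest-weight
# left-to-right path, found iteratively per boundary in depth bands
# anchored to the boundaries already found.

#' Build the edge-weight field for a B-scan
#'
#' The vertical gradient is a backward difference along depth (the value
#' at row k is I\[k\] - I\[k-1\], so an ideal dark-to-bright step at row r
#' puts its maximum on r, the first bright row: the package's boundary
#' convention). The signed gradient is normalized per B-scan to \[0, 1\];
#' a constant image normalizes to 0.5 everywhere, making every edge weight
#' equal to `1 + w_min` and the shortest path purely geometric.
#'
#' @param bscan numeric matrix `[depth, fast]`, finite
#' @param polarity `"dark-to-bright"` or `"bright-to-dark"`
#' @param w_min minimum edge weight (default 1e-5)
#' @return an `oct_weight_graph`: node field `gn`, `w_min`, `polarity`
#' @export
build_weight_graph <- function(bscan,
                               polarity = c("dark-to-bright",
                                            "bright-to-dark"),
                               w_min = 1e-5) {
  polarity <- match.arg(polarity)
  if (!all(is.finite(bscan))) {
    rt_stop("ValidationError", "bscan must be finite")
  }
  nd <- nrow(bscan)
  g <- bscan - rbind(bscan[1L, , drop = FALSE], bscan[-nd, , drop = FALSE])
  if (polarity == "bright-to-dark") g <- -g
  rng <- range(g)
  gn <- if (diff(rng) == 0) {
    matrix(0.5, nrow(g), ncol(g))
  } else {
    (g - rng[1]) / diff(rng)
  }
  structure(list(gn = gn, w_min = w_min, polarity = polarity),
            class = "oct_weight_graph")
}

#' Weight of an edge between two nodes of a weight graph
#'
#' @param graph an `oct_weight_graph`
#' @param a,b nodes as `c(depth_px, fast_px)` (0-based)
#' @export
edge_weight <- function(graph, a, b) {
  2 - (graph$gn[a[1] + 1L, a[2] + 1L] + graph$gn[b[1] + 1L, b[2] + 1L]) +
    graph$w_min
}

# Core DP shortest path on the column-monotone graph. `upper`/`lower` are
# 1-based per-column row bounds (inclusive). Ties break toward smaller
# depth. Returns 1-based rows per column plus the total path cost.
#' @noRd
shortest_path_band <- function(gn, w_min, upper, lower) {
  nd <- nrow(gn); nc <- ncol(gn)
  upper <- pmin(pmax(as.integer(round(upper)), 1L), nd)
  lower <- pmin(pmax(as.integer(round(lower)), 1L), nd)
  lower <- pmax(lower, upper)
  rmin <- min(upper); rmax <- max(lower)
  H <- rmax - rmin + 1L
  rows <- rmin:rmax
  sub <- gn[rows, , drop = FALSE]
  inf <- Inf
  mask_col <- function(v, ci) {
    v[rows < upper[ci] | rows > lower[ci]] <- inf
    v
  }
  dist <- mask_col(rep(0, H), 1L)
  ptr <- matrix(0L, H, nc)  # predecessor offset: -1, 0, +1 relative row
  a_prev <- dist + (1 - sub[, 1L])
  for (ci in 2:nc) {
    c_up <- c(inf, a_prev[-H])       # predecessor one row shallower
    c_st <- a_prev
    c_dn <- c(a_prev[-1L], inf)      # predecessor one row deeper
    best <- pmin(c_up, c_st, c_dn)
    off <- integer(H)
    off[c_dn == best] <- 1L
    off[c_st == best] <- 0L
    off[c_up == best] <- -1L         # last write wins: prefer shallower
    dist <- best + (1 - sub[, ci]) + w_min
    dist <- mask_col(dist, ci)
    ptr[, ci] <- off
    a_prev <- dist + (1 - sub[, ci])
    a_prev[!is.finite(dist)] <- inf
  }
  if (!any(is.finite(dist))) {
    rt_stop("ValidationError", "empty search band: no feasible path")
  }
  path <- integer(nc)
  r <- which.min(dist)  # first minimum = smallest depth on ties
  cost <- dist[r]
  path[nc] <- r
  for (ci in nc:2) {
    r <- r + ptr[r, ci]
    path[ci - 1L] <- r
  }
  list(rows = path + rmin - 1L, cost = cost)
}

#' Segment one boundary in a B-scan
#'
#' Finds the lowest-weight column-monotone path through the weight graph,
#' restricted to a depth band. Returns one 0-based depth per fast-axis
#' column. Ties break toward smaller depth; on a featureless image the
#' path is the horizontal line at the top of the band.
#'
#' @param bscan numeric matrix `[depth, fast]`
#' @param polarity gradient polarity of the boundary
#' @param band `c(z_min, z_max)` 0-based inclusive depth band; height
#'   must be >= 3 px
#' @param w_min minimum edge weight
#' @return integer vector of 0-based depths, one per column, with the
#'   total path cost as attribute `"cost"`
#' @export
segment_boundary <- function(bscan, polarity, band, w_min = 1e-5) {
  nd <- nrow(bscan)
  if (length(band) != 2L || band[1] < 0 || band[2] >= nd ||
      band[2] - band[1] + 1 < 3) {
    rt_stop("ValidationError",
            "band [%s, %s] invalid: need 0 <= z_min, z_max < %d, height >= 3",
            band[1], band[2], nd)
  }
  gr <- build_weight_graph(bscan, polarity, w_min)
  nc <- ncol(bscan)
  res <- shortest_path_band(gr$gn, gr$w_min,
                            rep(band[1] + 1L, nc), rep(band[2] + 1L, nc))
  structure(res$rows - 1L, cost = res$cost)
}

#' Segment all seven retinal boundaries of a flattened volume
#'
#' Boundaries are found per B-scan on the repeat-averaged volume in a
#' fixed order: the RPE top and bottom first, from the cross-polarized
#' depolarization band around the flattening target depth; the ILM as the
#' strongest dark-to-bright edge above the RPE; then the interior
#' boundaries (INL-OPL, IPL-INL, RNFL/GCL-IPL, OPL-PRC) in per-column
#' bands bracketed by the boundaries already found, which enforces the
#' depth-ordering invariant by construction. Bands shrink to a 1-px
#' corridor where layers pinch (ONH), keeping the ordering strict.
#'
#' @param flat a `flat_volume`
#' @param smooth_sigma Gaussian smoothing (px) applied to each B-scan
#'   before graph construction, `c(depth, fast)`; the lateral SD is
#'   larger by default because the boundaries are near-horizontal after
#'   flattening, so lateral averaging suppresses speckle without blurring
#'   the axial edges
#' @param rpe_band half-width (px) of the RPE search band around the
#'   flattening target depth
#' @param rpe_max_th maximum RPE thickness searched (px)
#' @param median_k en-face median filter applied to every boundary map
#'   (odd; monotone, so ordering is preserved)
#' @param despike_q intensity quantile at which each B-scan is clipped
#'   before smoothing; tames fully developed speckle inside vessels,
#'   whose spikes would otherwise dominate the gradient normalization
#' @return a `boundary_set`: named list `depths` of `[slow, fast]` maps of
#'   0-based px, plus `dz`
#' @export
segment_all_layers <- function(flat, smooth_sigma = c(1, 2.5),
                               rpe_band = 12L, rpe_max_th = 10L,
                               median_k = 3L, despike_q = 0.995) {
  if (!inherits(flat, "flat_volume")) {
    rt_stop("ValidationError", "segment_all_layers expects a flattened volume")
  }
  co <- mean_copol(flat)
  d <- dim(co)
  nd <- d[1]; nf <- d[2]; ns <- d[3]
  cr <- flat$cross_pol[, , , 1L]
  if (dim(flat$cross_pol)[4] > 1L) {
    for (ri in 2:dim(flat$cross_pol)[4]) cr <- cr + flat$cross_pol[, , , ri]
    cr <- cr / dim(flat$cross_pol)[4]
  }
  dim(cr) <- d[1:3]
  tgt <- flat$rpe_depth_px + 1L  # 1-based

  maps <- lapply(oct_boundaries(), function(b) matrix(NA_real_, ns, nf))
  names(maps) <- oct_boundaries()

  for (si in seq_len(ns)) {
    bs <- co[, , si]
    bs <- pmin(bs, stats::quantile(bs, despike_q))
    bs <- smooth2d(bs, smooth_sigma)
    xs <- cr[, , si]
    xs <- pmin(xs, stats::quantile(xs, despike_q))
    xs <- smooth2d(xs, smooth_sigma)
    g_db <- build_weight_graph(bs, "dark-to-bright")
    g_bd <- build_weight_graph(bs, "bright-to-dark")
    gx_db <- build_weight_graph(xs, "dark-to-bright")
    gx_bd <- build_weight_graph(xs, "bright-to-dark")

    lo1 <- rep(max(2L, tgt - rpe_band), nf)
    hi1 <- rep(min(nd, tgt + rpe_band), nf)
    rpe_top <- shortest_path_band(gx_db$gn, gx_db$w_min, lo1, hi1)$rows
    rpe_bot <- shortest_path_band(gx_bd$gn, gx_bd$w_min,
                                  rpe_top + 1L,
                                  pmin(rpe_top + rpe_max_th, nd))$rows

    ilm <- shortest_path_band(g_db$gn, g_db$w_min,
                              rep(2L, nf), pmax(rpe_top - 8L, 3L))$rows
    inl_opl <- shortest_path_band(g_db$gn, g_db$w_min,
                                  ilm + 6L, clamp_lower(ilm + 6L,
                                                        rpe_top - 4L))$rows
    ipl_inl <- shortest_path_band(g_bd$gn, g_bd$w_min,
                                  ilm + 4L, clamp_lower(ilm + 4L,
                                                        inl_opl - 3L))$rows
    rnfl_ipl <- shortest_path_band(g_bd$gn, g_bd$w_min,
                                   ilm + 2L, clamp_lower(ilm + 2L,
                                                         ipl_inl - 2L))$rows
    opl_prc <- shortest_path_band(g_bd$gn, g_bd$w_min,
                                  inl_opl + 2L, clamp_lower(inl_opl + 2L,
                                                            rpe_top - 2L))$rows

    maps[["ILM"]][si, ] <- ilm - 1L
    maps[["RNFL/GCL-IPL"]][si, ] <- rnfl_ipl - 1L
    maps[["IPL-INL"]][si, ] <- ipl_inl - 1L
    maps[["INL-OPL"]][si, ] <- inl_opl - 1L
    maps[["OPL-PRC"]][si, ] <- opl_prc - 1L
    maps[["PRC-RPE"]][si, ] <- rpe_top - 1L
    maps[["RPE-bottom"]][si, ] <- rpe_bot - 1L
  }
  if (median_k > 1L) maps <- lapply(maps, medfilt2, k = median_k)
  boundary_set(maps, dz = flat$dz)
}

#' @noRd
clamp_lower <- function(upper, lower) pmax(lower, upper)

#' Construct and validate a boundary set
#'
#' @param depths named list of the seven `[slow, fast]` boundary depth
#'   maps (0-based px), inner to outer
#' @param dz axial spacing (µm/px)
#' @export
boundary_set <- function(depths, dz) {
  if (!setequal(names(depths), oct_boundaries())) {
    rt_stop("ValidationError", "boundary set must name all seven boundaries")
  }
  depths <- depths[oct_boundaries()]
  for (i in 2:length(depths)) {
    if (!all(depths[[i]] > depths[[i - 1L]])) {
      rt_stop("SegmentationOrderError",
              "boundary '%s' not strictly below '%s' at every column",
              names(depths)[i], names(depths)[i - 1L])
    }
  }
  structure(list(depths = depths, dz = dz), class = "boundary_set")
}

#' Per-layer and composite thickness maps
#'
#' Thickness (µm) = (lower boundary - upper boundary) x dz. Composites:
#' IRL = RNFL/GCL + IPL + INL, ORL = OPL + PRC + RPE, and TOTAL (the
#' ILM-to-RPE-bottom distance) = IRL + ORL pointwise by construction.
#'
#' @param bounds a `boundary_set`
#' @param dz axial µm/px (default from `bounds`)
#' @param onh_center_um ONH centre `c(x_fast, y_slow)` µm, attached to
#'   each map for region statistics
#' @param spacing_um en-face spacing `c(dx_slow, dx_fast)` µm/px
#' @return named list of `thickness_map` objects
#'   (RNFL/GCL, IPL, INL, OPL, PRC, RPE, IRL, ORL, TOTAL)
#' @export
thickness_maps <- function(bounds, dz = bounds$dz, onh_center_um = NULL,
                           spacing_um = NULL) {
  B <- bounds$depths
  mk <- function(layer, v) {
    structure(list(layer = layer, values_um = v,
                   onh_center_um = onh_center_um, spacing_um = spacing_um),
              class = "thickness_map")
  }
  maps <- list(
    `RNFL/GCL` = (B[["RNFL/GCL-IPL"]] - B[["ILM"]]) * dz,
    IPL = (B[["IPL-INL"]] - B[["RNFL/GCL-IPL"]]) * dz,
    INL = (B[["INL-OPL"]] - B[["IPL-INL"]]) * dz,
    OPL = (B[["OPL-PRC"]] - B[["INL-OPL"]]) * dz,
    PRC = (B[["PRC-RPE"]] - B[["OPL-PRC"]]) * dz,
    RPE = (B[["RPE-bottom"]] - B[["PRC-RPE"]]) * dz)
  maps$IRL <- maps$`RNFL/GCL` + maps$IPL + maps$INL
  maps$ORL <- maps$OPL + maps$PRC + maps$RPE
  maps$TOTAL <- (B[["RPE-bottom"]] - B[["ILM"]]) * dz
  Map(mk, names(maps), maps)
}

#' Annular-zone mean of an en-face map
#'
#' Mean of the map over pixels whose centre lies at physical distance
#' `r_in <= d < r_out` from the ONH centre (half-open interval; clipped to
#' the field of view).
#'
#' @param map a `thickness_map`, or a plain `[slow, fast]` matrix (then
#'   `onh_center_um` and `spacing_um` must be given)
#' @param r_in,r_out annulus radii (µm); defaults 200 and 600
#' @param onh_center_um,spacing_um overrides for plain matrices
#' @return list `mean`, `n_pixels`
#' @export
annular_mean <- function(map, r_in = 200, r_out = 600,
                         onh_center_um = NULL, spacing_um = NULL) {
  if (inherits(map, "thickness_map")) {
    if (is.null(onh_center_um)) onh_center_um <- map$onh_center_um
    if (is.null(spacing_um)) spacing_um <- map$spacing_um
    vals <- map$values_um
  } else {
    vals <- map
  }
  if (is.null(onh_center_um) || is.null(spacing_um)) {
    rt_stop("ValidationError",
            "annular_mean needs onh_center_um and spacing_um")
  }
  if (r_in >= r_out) {
    rt_stop("ValidationError", "need r_in < r_out")
  }
  d2 <- dist2_map(nrow(vals), ncol(vals), spacing_um[1], spacing_um[2],
                  onh_center_um)
  sel <- d2 >= r_in^2 & d2 < r_out^2
  if (!any(sel)) {
    rt_stop("EmptyROI", "annulus lies entirely outside the field of view")
  }
  list(mean = mean(vals[sel]), n_pixels = sum(sel))
}
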