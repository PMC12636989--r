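# Internal numerical helpers shared across modules.

#' Signal a classed pipeline error
#' @noRd
rt_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "retoct_error")))
}

#' @noRd
gauss_kernel <- function(sigma, order = 0L) {
  h <- max(1L, ceiling(3 * sigma))
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-x / sigma^2 * g)
  if (order == 2L) return((x^2 - sigma^2) / sigma^4 * g)
  stop("unsupported derivative order")
}

# Column-wise 1-D convolution with replicate padding; filters along the
# row (first) dimension of `m`.
#' @noRd
filter_cols <- function(m, k) {
  h <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  mp <- rbind(m[rep(1L, h), , drop = FALSE], m, m[rep(n, h), , drop = FALSE])
  out <- stats::filter(mp, k, method = "convolution", sides = 2L)
  matrix(out[(h + 1L):(h + n), ], nrow = n, ncol = ncol(m))
}

# Separable filtering: ky along rows, kx along columns.
#' @noRd
filter_sep <- function(m, ky, kx) {
  t(filter_cols(t(filter_cols(m, ky)), kx))
}

# sigma may be scalar (isotropic) or c(sigma_rows, sigma_cols).
#' @noRd
smooth2d <- function(m, sigma) {
  sigma <- rep(sigma, length.out = 2L)
  ky <- if (sigma[1] > 0) gauss_kernel(sigma[1]) else 1
  kx <- if (sigma[2] > 0) gauss_kernel(sigma[2]) else 1
  if (sigma[1] <= 0 && sigma[2] <= 0) return(m)
  filter_sep(m, ky, kx)
}

# Local mean over a square window (replicate padding); window clamped to
# the image size and forced odd.
#' @noRd
box_mean <- function(m, w) {
  w <- min(w, dim(m))
  if (w %% 2L == 0L) w <- w - 1L
  if (w < 1L) w <- 1L
  k <- rep(1 / w, w)
  filter_sep(m, k, k)
}

# Square median filter (k odd; k <= 1 is identity). Near the borders the
# median is taken over the in-bounds neighbors only, which avoids the
# bias replicate padding would add on sloped maps.
#' @noRd
medfilt2 <- function(m, k = 5L) {
  if (k <= 1L) return(m)
  h <- k %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  arr <- array(NA_real_, c(nr, nc, k * k))
  t <- 0L
  for (dy in -h:h) {
    rsrc <- seq_len(nr) + dy
    rok <- rsrc >= 1L & rsrc <= nr
    for (dx in -h:h) {
      t <- t + 1L
      csrc <- seq_len(nc) + dx
      cok <- csrc >= 1L & csrc <= nc
      arr[rok, cok, t] <- m[rsrc[rok], csrc[cok]]
    }
  }
  apply(arr, c(1L, 2L), stats::median, na.rm = TRUE)
}

# Shift a vector so that out[k] = v[k + s] (zero padding outside range).
#' @noRd
shift_vec <- function(v, s) {
  n <- length(v)
  out <- numeric(n)
  src <- seq_len(n) + s
  ok <- src >= 1L & src <= n
  out[ok] <- v[src[ok]]
  out
}

# Pixel-centre physical coordinates (µm) of an en-face [slow, fast] grid.
#' @noRd
enface_coords <- function(n_slow, n_fast, dx_slow, dx_fast) {
  list(
    y = (seq_len(n_slow) - 0.5) * dx_slow,  # slow axis
    x = (seq_len(n_fast) - 0.5) * dx_fast   # fast axis
  )
}

# Squared distance map [slow, fast] from a physical centre (x_fast, y_slow) µm.
#' @noRd
dist2_map <- function(n_slow, n_fast, dx_slow, dx_fast, center) {
  cc <- enface_coords(n_slow, n_fast, dx_slow, dx_fast)
  outer((cc$y - center[2])^2, (cc$x - center[1])^2, `+`)
}
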