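# Angiography: decorrelation estimator, slab projection, binarization,
# artifact removal, SNR confidence masking and vessel density.

make_flat <- function(co, nrep) {
  # wrap a [depth, fast, slow] template into a flat_volume with repeats
  arr <- array(rep(co, nrep), c(dim(co), nrep))
  structure(list(co_pol = arr, cross_pol = arr, rpe_depth_px = 0L,
                 shift_record = array(0L, c(dim(co)[3], dim(co)[2], nrep)),
                 dz = 2, dx_fast = 2, dx_slow = 2, meta = list()),
            class = c("flat_volume", "raw_volume"))
}

test_that("angiogram is 0 on static repeats and 1/2 on decorrelated speckle", {
  fl <- make_flat(array(stats::runif(6 * 5 * 4, 0.2, 1), c(6, 5, 4)), 3L)
  a <- compute_angiogram(fl)
  expect_true(all(a == 0))

  # i.i.d. exponential repeats: E |X-Y|/(X+Y) = E |2U-1| = 1/2
  set.seed(1)
  n <- 1e5
  fl2 <- make_flat(array(0, c(n, 1, 1)), 2L)
  fl2$co_pol[] <- stats::rexp(2 * n)
  a2 <- compute_angiogram(fl2)
  expect_true(all(a2 >= 0 & a2 <= 1))
  expect_lt(abs(mean(a2) - 0.5), 0.01)

  # invariance to a common global rescaling
  fl3 <- fl2
  fl3$co_pol <- fl3$co_pol * 37.5
  expect_equal(compute_angiogram(fl3), a2, tolerance = 1e-6)

  fl1 <- make_flat(array(1, c(4, 3, 2)), 1L)
  expect_error(compute_angiogram(fl1), class = "InsufficientRepeats")
})

test_that("slab projection assigns voxels to the right plexus", {
  nd <- 60L; nf <- 8L; ns <- 6L
  angio <- array(0, c(nd, nf, ns))
  B <- list(ILM = 10, `RNFL/GCL-IPL` = 14, `IPL-INL` = 20, `INL-OPL` = 26,
            `OPL-PRC` = 32, `PRC-RPE` = 40, `RPE-bottom` = 45)
  bounds <- boundary_set(lapply(B, function(b) matrix(b, ns, nf)), dz = 2)
  angio[16, 3, 2] <- 0.9   # 0-based depth 15: inside SVP slab [10, 20)
  svp <- slab_project(angio, bounds, "SVP")
  icp <- slab_project(angio, bounds, "ICP")
  dcp <- slab_project(angio, bounds, "DCP")
  expect_equal(svp[2, 3], 0.9)
  expect_true(all(icp == 0) && all(dcp == 0))

  const <- array(0.37, c(nd, nf, ns))
  expect_true(all(slab_project(const, bounds, "ICP") == 0.37))

  # empty slab: degenerate boundary pair
  B2 <- B; B2$`INL-OPL` <- 26; B2$`IPL-INL` <- 26 - 1e-9
  bounds2 <- boundary_set(lapply(B2, function(b) matrix(b, ns, nf)), dz = 2)
  expect_warning(out <- slab_project(const, bounds2, "ICP"), "empty")
  expect_true(all(out == 0))
})

test_that("majority vote equals the brute-force count on all 5-bit patterns", {
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 5L))
  bins <- lapply(1:5, function(k) matrix(patterns[[k]], 4L, 8L))
  vote <- majority_vote(bins)
  brute <- matrix(rowSums(as.matrix(patterns)) >= 3L, 4L, 8L)
  expect_identical(unname(vote), unname(brute))

  # even number of maps: ties are negative (strict majority)
  bins4 <- lapply(1:4, function(k) matrix(c(TRUE, TRUE, FALSE, FALSE)[k],
                                          2L, 2L))
  expect_true(all(!majority_vote(bins4)))  # 2 of 4 is not a majority
  expect_true(all(majority_vote(bins4[c(1, 1, 1, 2)])))  # 3 of 4 is
})

test_that("multi-scale binarization segments a synthetic vessel", {
  expect_true(all(!multiscale_binarize(matrix(0.5, 64, 64),
                                       spacing_um = 2)))

  # straight vessel, 8 um wide at 2 um/px, contrast 5:1, mild noise
  set.seed(2)
  img <- matrix(0.1, 96, 96)
  gt <- matrix(FALSE, 96, 96)
  gt[, 45:48] <- TRUE
  img[gt] <- 0.5
  img <- img * (1 + 0.1 * matrix(stats::rnorm(96 * 96), 96))
  bin <- multiscale_binarize(img, spacing_um = 2)
  dice <- 2 * sum(bin & gt) / (sum(bin) + sum(gt))
  expect_gte(dice, 0.8)

  expect_error(multiscale_binarize(matrix(-1, 4, 4)),
               class = "ValidationError")
})

test_that("line-artifact removal suppresses stripes and preserves vessels", {
  set.seed(3)
  n <- 96L
  # smooth vessel-like pattern: a few oriented Gaussian ridges
  cc <- seq_len(n)
  vessels <- matrix(0, n, n)
  for (k in 1:4) {
    ctr <- stats::runif(1, 20, 76)
    ang <- stats::runif(1, 0, pi)
    d <- abs(outer(cc - n / 2, cc - n / 2,
                   function(y, x) (x - n / 2 * 0) * sin(ang) -
                     (y - ctr) * cos(ang)))
    vessels <- vessels + 0.6 * exp(-d^2 / 8)
  }
  stripes <- 0.4 * matrix(sin(2 * pi * 12 * (cc - 1) / n), n, n)  # horizontal
  noisy <- vessels + stripes
  out <- remove_line_artifacts(noisy)

  stripe_bins <- c(13L, n - 11L)  # +-12 cycles along the slow axis
  en <- function(m) Mod(stats::fft(m))[stripe_bins, 1L]^2
  expect_lt(sum(en(out)), sum(en(noisy)) / 10)
  # vessel content essentially untouched
  v_en <- function(m) {
    M <- Mod(stats::fft(m))^2
    sum(M) - sum(M[stripe_bins, 1L])
  }
  expect_gt(v_en(out), 0.8 * v_en(vessels + 0 * stripes))

  # stripe-free input passes through nearly unchanged
  out2 <- remove_line_artifacts(vessels)
  expect_gte(stats::cor(c(vessels), c(out2)), 0.99)

  # pure stripes come out near-constant
  out3 <- remove_line_artifacts(stripes + 1)
  expect_lte(stats::sd(out3), 0.1 * stats::sd(stripes + 1))
})

test_that("projection-artifact removal is max(target - svp, 0)", {
  set.seed(4)
  t <- matrix(stats::runif(64) > 0.5, 8, 8)
  s <- matrix(stats::runif(64) > 0.5, 8, 8)
  out <- remove_projection_artifacts(t, s)
  expect_identical(out * 1, pmax(t - s, 0))   # counting oracle
  expect_true(all(out <= t))                  # never adds positives
  expect_true(all(!remove_projection_artifacts(t, matrix(TRUE, 8, 8))))
  expect_error(remove_projection_artifacts(t, s[1:4, ]),
               class = "ValidationError")
})

test_that("SNR masking switches at the printed thresholds", {
  enf <- matrix(2, 32, 32)
  bin <- matrix(FALSE, 32, 32)
  bin[10:20, 10:20] <- TRUE
  enf[bin] <- 40                           # SNR = 40 / 2 = 20
  sm <- snr_mask(enf, bin, subregion_px = 32L, threshold_snf = 20)
  expect_equal(sm$snr[1, 1], 20)
  expect_true(all(sm$inclusion_mask))
  sm2 <- snr_mask(enf, bin, 32L, 20 + 1e-9)
  expect_false(any(sm2$inclusion_mask))

  enf[bin] <- 30                           # SNR = 15
  expect_false(any(snr_mask(enf, bin, 32L, 20)$inclusion_mask))
  expect_true(all(snr_mask(enf, bin, 32L, 15)$inclusion_mask))

  # a tile without vessel pixels is excluded and flagged
  sm3 <- snr_mask(enf, matrix(FALSE, 32, 32), 32L, 15)
  expect_true(all(sm3$flagged))
  expect_false(any(sm3$inclusion_mask))

  # excluded pixels enter neither numerator nor noise floor
  excl <- matrix(FALSE, 32, 32); excl[1:5, ] <- TRUE
  enf[1:5, ] <- 1000
  sm4 <- snr_mask(enf, bin, 32L, 15, exclude = excl)
  expect_equal(sm4$snr[1, 1], 15)
})

test_that("vessel density is an exact pixel count", {
  bin <- matrix(FALSE, 20, 20)
  bin[1:10, 1:10] <- TRUE                  # exactly 25% positive
  d <- vessel_density(bin)
  expect_equal(d$density, 25)
  expect_equal(d$included_area_fraction, 1)

  # ONH disk covering only negatives: density rises to the recount
  onh <- matrix(FALSE, 20, 20)
  onh[15:20, 15:20] <- TRUE                # 36 negative pixels removed
  d2 <- vessel_density(bin, onh_mask = onh)
  expect_equal(d2$density, 100 * 100 / (400 - 36))

  expect_error(vessel_density(bin, inclusion_mask = matrix(FALSE, 20, 20)),
               class = "EmptyROI")
})

test_that("raising the SNF threshold only ever shrinks the confidence region", {
  ph <- cached("octa_small", function() {
    cfg <- octa_config(seed = 2L)
    ph <- generate_phantom(cfg)
    fl <- flatten_volume(ph$volume)
    bounds <- segment_all_layers(fl)
    list(cfg = cfg, truth = ph$truth, angio = compute_angiogram(fl),
         bounds = bounds, meta = ph$volume$meta)
  })
  enf <- slab_project(ph$angio, ph$bounds, "SVP")
  enf <- remove_line_artifacts(enf); enf[enf < 0] <- 0
  bin <- multiscale_binarize(enf, spacing_um = c(4, 4))
  onh <- onh_disk_mask(ph$cfg$n_slow, ph$cfg$n_fast, c(4, 4),
                       ph$meta$onh_center_um, 120)
  bin <- bin & !onh
  prev <- NULL
  for (thr in c(1, 5, 10, 20, 40)) {
    sm <- snr_mask(enf, bin, 64L, thr, exclude = onh)
    if (!is.null(prev)) expect_true(all(prev | !sm$inclusion_mask))
    prev <- sm$inclusion_mask
  }
  # on the phantom, moderate thresholds keep a usable confidence region
  sm20 <- snr_mask(enf, bin, 64L, 20, exclude = onh)
  expect_gt(sum(sm20$inclusion_mask & !onh), 0)
})
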