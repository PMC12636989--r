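# Volume archive formats (multi-page TIFF or NIfTI, one file per channel,
# with a JSON metadata sidecar), cohort measurement bookkeeping, and the
# run configuration that carries every stage's parameters.

#' Default run configuration
#'
#' All pipeline parameters in one serializable list. Defaults follow the
#' printed protocol values where they exist: annulus radii 200/600 µm,
#' Frangi scales 4-12 µm in 2 µm steps, subregion SNR thresholds
#' SVP/ICP/DCP = 20/20/15 x noise floor (the low-quality profile 20/15/10
#' is available as `snf_low_quality`).
#'
#' @param seed RNG seed recorded with every run
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    qc = list(snr_min = 3, v_max = 0.25),
    rpe = list(sigma = 2, median_k = 5L, noise_factor = 5),
    layers = list(smooth_sigma = 1, median_k = 3L),
    annulus_um = list(r_in = 200, r_out = 600),
    spacing_um = c(1000 / 400, 1000 / 512),   # (dx_slow, dx_fast)
    slabs = default_slabs(),
    frangi = list(scales_um = c(4, 6, 8, 10, 12), window_px = 64L,
                  offset = -0.04, beta = 0.5),
    snf = list(SVP = 20, ICP = 20, DCP = 15),
    snf_low_quality = list(SVP = 20, ICP = 15, DCP = 10),
    subregion_px = 64L,
    onh_exclusion_um = 200,
    stats = list(alpha = 0.05)
  )
}

#' Write / read a run configuration (YAML)
#' @param config a run-config list
#' @param path file path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  utils::modifyList(base, cfg)
}

#' Stable hash of a configuration
#' @param config any serializable object
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# Smallest power of two >= x (for lossless float32 TIFF scaling:
# integer-valued data divided by a power of two stays exact).
#' @noRd
pow2_scale <- function(x) 2^ceiling(log2(max(x, 1)))

#' Write a volume archive
#'
#' One file per channel plus a `meta.json` sidecar. TIFF channels are
#' stored as 32-bit pages (one `[depth, fast]` page per (repeat, slow)
#' frame, repeat-major), scaled into \[0, 1\] by a power of two recorded
#' in the metadata (quantization ~2e-10 of the range); integer-valued
#' channels are flagged in the metadata and snapped back on read, so
#' integer data round-trips bit-exactly. NIfTI channels are stored as
#' native (lossless) 4-d arrays.
#'
#' @param volume a `raw_volume`
#' @param path directory to create
#' @param format `"tiff"` or `"nifti"`
#' @export
write_volume <- function(volume, path, format = c("tiff", "nifti")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$co_pol)
  scale <- pow2_scale(max(volume$co_pol, volume$cross_pol))
  meta <- c(volume$meta,
            list(n_depth = d[1], n_fast = d[2], n_slow = d[3],
                 n_repeats = d[4], dz = volume$dz,
                 dx_fast = volume$dx_fast, dx_slow = volume$dx_slow,
                 format = format, intensity_scale = scale,
                 integer_data = as.list(vapply(
                   c(co_pol = "co_pol", cross_pol = "cross_pol"),
                   function(ch) all(volume[[ch]] == round(volume[[ch]])),
                   logical(1)))))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ch in c("co_pol", "cross_pol")) {
    arr <- volume[[ch]]
    if (format == "tiff") {
      pages <- vector("list", d[3] * d[4])
      k <- 0L
      for (ri in seq_len(d[4])) {
        for (si in seq_len(d[3])) {
          k <- k + 1L
          pages[[k]] <- arr[, , si, ri] / scale
        }
      }
      tiff::writeTIFF(pages, file.path(path, paste0(ch, ".tif")),
                      bits.per.sample = 32L)
    } else {
      RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"),
                         file.path(path, paste0(ch, ".nii.gz")))
    }
  }
  invisible(path)
}

#' Read a volume archive written by [write_volume()]
#'
#' @param path archive directory
#' @return a `raw_volume`
#' @export
read_volume <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) {
    rt_stop("FormatError", "missing metadata sidecar: %s", mf)
  }
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in c("n_depth", "n_fast", "n_slow", "n_repeats", "dz", "dx_fast",
              "dx_slow", "format", "intensity_scale")) {
    if (is.null(meta[[f]])) {
      rt_stop("FormatError", "metadata field '%s' missing", f)
    }
  }
  d <- c(meta$n_depth, meta$n_fast, meta$n_slow, meta$n_repeats)
  read_ch <- function(ch) {
    if (meta$format == "tiff") {
      fp <- file.path(path, paste0(ch, ".tif"))
      pages <- tiff::readTIFF(fp, all = TRUE)
      if (length(pages) != d[3] * d[4]) {
        rt_stop("FormatError",
                "field 'n_slow x n_repeats' (%d) does not match %d pages",
                d[3] * d[4], length(pages))
      }
      arr <- array(0, d)
      k <- 0L
      for (ri in seq_len(d[4])) {
        for (si in seq_len(d[3])) {
          k <- k + 1L
          pg <- pages[[k]] * meta$intensity_scale
          if (!identical(dim(pg), as.integer(d[1:2]))) {
            rt_stop("FormatError",
                    "field 'n_depth x n_fast' does not match page shape")
          }
          arr[, , si, ri] <- pg
        }
      }
      if (isTRUE(meta$integer_data[[ch]])) arr <- round(arr)
      arr
    } else {
      nii <- RNifti::readNifti(file.path(path, paste0(ch, ".nii.gz")))
      if (!identical(as.integer(dim(nii)), as.integer(d))) {
        rt_stop("FormatError", "field shape metadata does not match array")
      }
      array(as.vector(nii), dim = dim(nii))
    }
  }
  keep <- setdiff(names(meta),
                  c("n_depth", "n_fast", "n_slow", "n_repeats", "dz",
                    "dx_fast", "dx_slow", "format", "intensity_scale",
                    "integer_data"))
  raw_volume(read_ch("co_pol"), read_ch("cross_pol"), dz = meta$dz,
             dx_fast = meta$dx_fast, dx_slow = meta$dx_slow,
             meta = meta[keep])
}

#' Assemble per-scan results into a measurement table
#'
#' Input is either a data.frame of per-scan rows (`scan_id`, `mouse_id`,
#' `group` or `model`+`genotype`, `sex`, `eye`, `outcome_name`, `value`,
#' `include`) or a directory of per-scan JSON files each holding such
#' rows. QC-excluded scans are dropped (kept in the `exclusions`
#' attribute); repeated scans of the same eye are averaged; a duplicated
#' `scan_id` for the same outcome is an error.
#'
#' @param x data.frame or directory path
#' @return measurement table: one row per (mouse, eye, outcome), with an
#'   `exclusions` attribute and a `scan_counts` attribute (scans per group)
#' @export
assemble_measurements <- function(x) {
  if (is.character(x)) {
    files <- list.files(x, pattern = "\\.json$", full.names = TRUE)
    rows <- lapply(files, function(f) {
      as.data.frame(jsonlite::read_json(f, simplifyVector = TRUE))
    })
    x <- do.call(rbind, rows)
  }
  if (!"group" %in% names(x) && all(c("model", "genotype") %in% names(x))) {
    x$group <- paste(x$model, x$genotype, sep = ":")
  }
  if (!"include" %in% names(x)) x$include <- TRUE
  if (!"outcome_name" %in% names(x)) x$outcome_name <- "value"
  dup <- duplicated(x[c("scan_id", "outcome_name")])
  if (any(dup)) {
    rt_stop("ValidationError", "duplicate scan_id '%s' for outcome '%s'",
            x$scan_id[dup][1], x$outcome_name[dup][1])
  }
  excl <- x[!x$include, , drop = FALSE]
  x <- x[x$include, , drop = FALSE]
  key_cols <- intersect(c("mouse_id", "group", "model", "genotype", "sex",
                          "eye", "outcome_name"), names(x))
  agg <- stats::aggregate(x["value"], x[key_cols], mean)
  counts <- stats::aggregate(list(n_scans = x$value),
                             x[intersect(c("group", "outcome_name"),
                                         names(x))], length)
  attr(agg, "exclusions") <- excl
  attr(agg, "scan_counts") <- counts
  agg
}
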