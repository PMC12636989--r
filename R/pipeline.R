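# End-to-end convenience driver: QC -> RPE flattening -> layer
# segmentation -> annular thickness means -> angiography densities for
# one volume. The numbered scripts under analysis/ and the acceptance
# script are thin wrappers over this function and the per-stage
# operations it calls.

#' Analyze one PS-OCT volume end to end
#'
#' @param volume a `raw_volume`
#' @param config a [default_run_config()]-style list
#' @param angiography also run the angiography chain (needs >= 2 repeats)
#' @return list `qc`, `flat`, `bounds`, `thickness` (data.frame of annular
#'   means per layer), `density` (data.frame per plexus, when requested),
#'   `slabs` (per-plexus chain outputs)
#' @export
analyze_volume <- function(volume, config = default_run_config(),
                           angiography = TRUE) {
  qc <- qc_screen(volume, config$qc$snr_min, config$qc$v_max)
  out <- list(qc = qc)
  if (!qc$include) return(out)

  rpe <- segment_rpe_crosspol(volume, sigma = config$rpe$sigma,
                              median_k = config$rpe$median_k,
                              noise_factor = config$rpe$noise_factor)
  flat <- flatten_volume(volume, rpe)
  bounds <- segment_all_layers(flat,
                               smooth_sigma = config$layers$smooth_sigma,
                               median_k = config$layers$median_k)
  spacing <- c(volume$dx_slow, volume$dx_fast)
  onh <- volume$meta$onh_center_um
  tmaps <- thickness_maps(bounds, dz = volume$dz, onh_center_um = onh,
                          spacing_um = spacing)
  th <- do.call(rbind, lapply(names(tmaps), function(ly) {
    am <- annular_mean(tmaps[[ly]], config$annulus_um[["r_in"]],
                       config$annulus_um[["r_out"]])
    data.frame(layer = ly, mean_um = am$mean, n_pixels = am$n_pixels,
               stringsAsFactors = FALSE)
  }))
  out$flat <- flat
  out$bounds <- bounds
  out$thickness <- th

  if (angiography && dim(volume$co_pol)[4] >= 2L) {
    cfg <- config
    cfg$spacing_um <- spacing
    angio <- compute_angiogram(flat)
    svp <- quantify_plexus(angio, bounds, "SVP", config = cfg,
                           onh_center_um = onh)
    icp <- quantify_plexus(angio, bounds, "ICP", svp_binary = svp$binary,
                           config = cfg, onh_center_um = onh)
    dcp <- quantify_plexus(angio, bounds, "DCP", svp_binary = svp$binary,
                           config = cfg, onh_center_um = onh)
    slabs <- list(SVP = svp, ICP = icp, DCP = dcp)
    out$slabs <- slabs
    out$density <- do.call(rbind, lapply(slabs, function(s) {
      data.frame(plexus = s$plexus, density = s$density$density,
                 included_area_fraction = s$density$included_area_fraction,
                 threshold_snf = s$threshold_snf, stringsAsFactors = FALSE)
    }))
    rownames(out$density) <- NULL
  }
  out
}
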