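#!/usr/bin/env Rscript
# Quality-control pass over every archived scan: mean SNR, vignetting
# fraction and the include/exclude decision, written to results/qc.csv.

suppressPackageStartupMessages(library(retoct))

manifest <- utils::read.csv("results/cohort_manifest.csv")
rc <- read_run_config("results/run_config.yaml")

qc <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  v <- read_volume(manifest$path[i])
  q <- qc_screen(v, rc$qc$snr_min, rc$qc$v_max)
  data.frame(scan_id = manifest$scan_id[i], mean_snr = q$mean_snr,
             vignetting_fraction = q$vignetting_fraction,
             include = q$include)
}))
utils::write.csv(qc, "results/qc.csv", row.names = FALSE)
cat(sprintf("QC: %d/%d scans pass (snr >= %.1f, vignetting <= %.2f)\n",
            sum(qc$include), nrow(qc), rc$qc$snr_min, rc$qc$v_max))
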