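#!/usr/bin/env Rscript
# Group comparison: assemble per-scan measurements into one row per
# (mouse, eye, outcome), fit the random-intercept mixed model per outcome
# and report group means +/- SD plus the Bonferroni-corrected pairwise
# p-value matrix. Tables: results/group_means.csv, results/pairwise.csv.

suppressPackageStartupMessages(library(retoct))

thick <- utils::read.csv("results/thickness_per_scan.csv")
dens <- utils::read.csv("results/density_per_scan.csv")
tab <- rbind(thick[c("scan_id", "mouse_id", "model", "genotype", "eye",
                     "outcome_name", "value", "include")],
             dens[c("scan_id", "mouse_id", "model", "genotype", "eye",
                    "outcome_name", "value", "include")])
meas <- assemble_measurements(tab)

means <- list(); pw <- list()
for (oc in unique(meas$outcome_name)) {
  cmp <- pairwise_compare(meas, outcome = oc)
  means[[oc]] <- data.frame(outcome = oc, group = names(cmp$group_means),
                            mean = unname(cmp$group_means),
                            sd = unname(cmp$group_sds),
                            n_mice = unname(cmp$group_n_mice))
  pw[[oc]] <- cbind(outcome = oc, cmp$pairwise)
  sig <- cmp$pairwise[cmp$pairwise$significant, , drop = FALSE]
  cat(sprintf("%-14s %s\n", oc, if (nrow(sig)) {
    paste(sprintf("%s vs %s: delta %+.2f, p_bonf %.3g", sig$group1,
                  sig$group2, sig$estimate, sig$p_bonferroni),
          collapse = "; ")
  } else "no significant pairwise differences"))
}
means <- do.call(rbind, means)
pw <- do.call(rbind, pw)
utils::write.csv(means, "results/group_means.csv", row.names = FALSE)
utils::write.csv(pw, "results/pairwise.csv", row.names = FALSE)
cat(sprintf("wrote %d group summaries and %d pairwise tests\n",
            nrow(means), nrow(pw)))
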