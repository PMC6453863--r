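#!/usr/bin/env Rscript
# Stage 5: ESS sectorization and classification.
# The WSS profiles from stage 4 are spread over 5-degree sectors x 200 um
# intervals, classified against the low (< 1.0 Pa) and very-low (< 0.5 Pa)
# thresholds, and summarized per segment and device. The directional
# expectation: the thin-strut design shows higher in-scaffold ESS and
# smaller low/very-low fractions.

library(strutflow)
phantom <- vessel_phantom(14, 1.5, curvature = 0, seed = 1)

summary_rows <- list()
for (nm in c("thick", "thin")) {
  w <- read.csv(sprintf("results/wss_%s.csv", nm))
  el <- axisym_wss_elements(w, phantom$segment_bounds)
  map <- sectorize(el)
  write.csv(ess_map_long(map, scaffold_id = nm),
            sprintf("results/ess_map_%s.csv", nm), row.names = FALSE)
  seg <- ess_summary(map, "segment")
  write.csv(seg, sprintf("results/ess_segments_%s.csv", nm), row.names = FALSE)
  scaf <- sectorize(el[el$segment == "scaffolded", ])
  cl <- classify_ess(scaf)
  summary_rows[[nm]] <- cbind(design = nm, ess_summary(scaf, "device"))
  cat(sprintf("%s: in-scaffold mean ESS %.3f Pa, frac_low %.2f, frac_very_low %.2f\n",
              nm, summary_rows[[nm]]$mean_pa, cl$frac_low, cl$frac_very_low))
}
tab <- do.call(rbind, summary_rows)
write.csv(tab, "results/ess_device_summary.csv", row.names = FALSE)
stopifnot(tab$mean_pa[tab$design == "thin"] > tab$mean_pa[tab$design == "thick"],
          tab$frac_low[tab$design == "thin"] < tab$frac_low[tab$design == "thick"])
cat("directional reproduction of the in-vivo contrast: confirmed\n")
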