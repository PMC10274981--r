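#!/usr/bin/env Rscript
# Binarize baseline scans, compute the spatial extent index, export the
# heatmap table (rows sorted by diagnosis then extent), quantify
# cross-sectional Braak conformance in the amyloid-positive subsample, and
# fit the logistic link between centiloid and any tau positivity.

library(tauextent)

registry <- region_registry()
suvr <- load_suvr_table("results/cohort/suvr.csv", registry)
md <- load_metadata("results/cohort/metadata.csv")
th <- load_thresholds("results/thresholds.json", registry)

abpos <- md$subject_id[md$abeta_positive]
ana <- suvr[suvr$subject_id %in% abpos, ]

pat0 <- binarize(ana, th, visit_index = 0L)
write.csv(pat0[c("subject_id", "spatial_extent")], "results/extent.csv",
          row.names = FALSE)
write.csv(heatmap_table(pat0, md, registry), "results/heatmap.csv",
          row.names = FALSE)

for (g in c("CU", "MCI", "AD")) {
  ids <- md$subject_id[md$diagnosis == g & md$abeta_positive]
  e <- pat0$spatial_extent[pat0$subject_id %in% ids]
  message(sprintf("%s (ab+): %.1f%% with >=1 positive region, median extent %d",
                  g, 100 * mean(e >= 1), median(e)))
}

comps <- stage_composite_suvr(ana, registry)
sp0 <- stage_positivity(comps, th, visit_index = 0L)
cc <- braak_conformance_cross(sp0)
write.csv(cc$per_stage, "results/conformance.csv", row.names = FALSE)
message(sprintf("cross-sectional Braak conformance: %.1f%% of %d tau-positive subjects",
                cc$overall_pct, cc$n_positive))

# centiloid -> any-positivity on the full (ab+/-) sample
pat_all <- binarize(suvr, th, visit_index = 0L)
lg <- extent_logistic(md$centiloid[match(pat_all$subject_id,
                                         md$subject_id)],
                      pat_all$spatial_extent)
jsonlite::write_json(unclass(lg)[c("or", "ci", "n", "separation_flag")],
                     "results/extent_logistic.json", auto_unbox = TRUE,
                     digits = NA)
message(sprintf("odds of >=1 positive region: %.3f per centiloid (95%% CI %.3f-%.3f)",
                lg$or, lg$ci[1], lg$ci[2]))
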