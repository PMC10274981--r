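#!/usr/bin/env Rscript
# Head-to-head comparison of the spatial extent index vs the temporal
# meta-ROI SUVR as predictors of cognitive performance and decline:
# adjusted linear models (age, sex, education), standardized betas,
# Vuong's closeness test, BH-FDR within diagnostic group.

library(tauextent)

registry <- region_registry()
suvr <- load_suvr_table("results/cohort/suvr.csv", registry)
md <- load_metadata("results/cohort/metadata.csv")
cg <- load_cognition("results/cohort/cognition.csv")
th <- load_thresholds("results/thresholds.json", registry)

ana <- suvr[suvr$subject_id %in% md$subject_id[md$abeta_positive], ]
pat0 <- binarize(ana, th, visit_index = 0L)
comps <- stage_composite_suvr(ana, registry)

perf <- cognition_associations(pat0, comps, cg, md, mode = "performance")
write.csv(perf, "results/cognition_associations.csv", row.names = FALSE)
decl <- cognition_associations(pat0, comps, cg, md, mode = "decline")
write.csv(decl, "results/cognition_decline_associations.csv",
          row.names = FALSE)

show <- perf[perf$composite == "memory", ]
for (i in seq_len(nrow(show)))
  message(sprintf(
    "%s memory ~ %s: std beta %.2f (p=%.3g, R2adj=%.2f, AIC=%.1f), Vuong z=%.2f p=%.3f",
    show$group[i], show$predictor[i], show$std_beta[i], show$p[i],
    show$r2_adj[i], show$aic[i], show$vuong_z[i], show$vuong_p[i]))
message(sprintf("models surviving FDR (performance): %d of %d",
                sum(perf$p_fdr < 0.05), nrow(perf)))
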