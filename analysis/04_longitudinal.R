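#!/usr/bin/env Rscript
# Classify per-region progression between first and last scan, quantify
# longitudinal Braak conformance, and estimate annual rates of change in
# the spatial extent index by diagnosis (mixed models with random slopes
# and intercepts), in the amyloid-positive subsample.

library(tauextent)

registry <- region_registry()
suvr <- load_suvr_table("results/cohort/suvr.csv", registry)
md <- load_metadata("results/cohort/metadata.csv")
th <- load_thresholds("results/thresholds.json", registry)

ana <- suvr[suvr$subject_id %in% md$subject_id[md$abeta_positive], ]

fl <- first_last_patterns(ana, th, min_scans = 2L)
prog <- progression_states(fl$first, fl$last)
write.csv(data.frame(subject_id = rownames(prog),
                     as.data.frame(unclass(prog)), check.names = FALSE),
          "results/progression_states.csv", row.names = FALSE)
tab <- table(unclass(prog))
message("regional states: ",
        paste(names(tab), tab, sep = "=", collapse = ", "))
message(sprintf("subjects with >=1 regressing region: %.1f%%",
                100 * mean(apply(unclass(prog) == "regressor", 1, any))))

comps <- stage_composite_suvr(ana, registry)
keep <- rownames(prog)
sp <- stage_positivity(comps[comps$subject_id %in% keep, ], th)
last_idx <- tapply(sp$visit_index, sp$subject_id, max)
cl <- braak_conformance_long(
  sp[sp$visit_index == 0L, ],
  sp[sp$visit_index == last_idx[as.character(sp$subject_id)], ])
write.csv(cl$per_stage, "results/conformance_longitudinal.csv",
          row.names = FALSE)
message(sprintf("longitudinal Braak conformance: %.1f%% of %d stage-progressors",
                cl$overall_pct, cl$n_progressed))

pat <- binarize(ana, th)
rates <- vapply(c("CU", "MCI", "AD"), function(g) {
  ids <- md$subject_id[md$diagnosis == g]
  d <- pat[pat$subject_id %in% ids, ]
  annual_change(data.frame(subject_id = d$subject_id,
                           years = d$years_from_first_scan,
                           value = d$spatial_extent), g)$slope
}, numeric(1))
write.csv(data.frame(group = names(rates),
                     extent_change_per_year = rates),
          "results/rates.csv", row.names = FALSE)
message(sprintf("newly abnormal regions per year: CU %.2f, MCI %.2f, AD %.2f",
                rates["CU"], rates["MCI"], rates["AD"]))
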