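#!/usr/bin/env Rscript
# Between-subject overlap of tau positivity patterns (baseline) and of
# progression-state patterns (first vs last scan) via Jaccard similarity,
# averaged within diagnostic groups (amyloid-positive subsample).

library(tauextent)

registry <- region_registry()
suvr <- load_suvr_table("results/cohort/suvr.csv", registry)
md <- load_metadata("results/cohort/metadata.csv")
th <- load_thresholds("results/thresholds.json", registry)

ana <- suvr[suvr$subject_id %in% md$subject_id[md$abeta_positive], ]
groups <- md[c("subject_id", "diagnosis")]

pat0 <- binarize(ana, th, visit_index = 0L)
ovl <- mean_group_overlap(pat0, groups, mode = "binary")
write.csv(ovl$per_group, "results/overlap.csv", row.names = FALSE)
for (i in seq_len(nrow(ovl$per_group)))
  message(sprintf("baseline overlap %s: %.2f +/- %.2f (n=%d)",
                  ovl$per_group$group[i], ovl$per_group$mean[i],
                  ovl$per_group$sd[i], ovl$per_group$n[i]))

fl <- first_last_patterns(ana, th, min_scans = 2L)
prog <- progression_states(fl$first, fl$last)
ovp <- mean_group_overlap(prog, groups, mode = "progression")
write.csv(ovp$per_group, "results/overlap_progression.csv",
          row.names = FALSE)
for (i in seq_len(nrow(ovp$per_group)))
  message(sprintf("progression overlap %s: %.2f +/- %.2f (n=%d)",
                  ovp$per_group$group[i], ovp$per_group$mean[i],
                  ovp$per_group$sd[i], ovp$per_group$n[i]))
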