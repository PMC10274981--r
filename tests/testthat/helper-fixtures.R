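# shared fixtures built in code

REG <- region_registry()

# minimal valid long-format SUVR table: all regions at given values
toy_suvr <- function(values, subject_ids = names(values),
                     visit_years = 0) {
  rows <- list()
  for (i in seq_along(subject_ids)) {
    for (v in seq_along(visit_years)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_ids[i],
        visit_index = v - 1L,
        years_from_first_scan = visit_years[v],
        region_id = REG$region_id,
        suvr = values[[i]],
        stringsAsFactors = FALSE)
    }
  }
  as_suvr_table(do.call(rbind, rows), REG)
}

# threshold_set with constant cutoffs, bypassing mixture fitting
flat_thresholds <- function(region_cutoff = 1.3, stage_cutoff = 1.3) {
  out <- list(
    region_cutoffs = stats::setNames(rep(region_cutoff, nrow(REG)),
                                     REG$region_id),
    stage_cutoffs = stats::setNames(
      rep(stage_cutoff, 6L),
      c(paste0("stage_", braak_stage_order()), "meta_roi")),
    region_fits = list(), stage_fits = list(), flags = list())
  class(out) <- "threshold_set"
  out
}

# binary_pattern from a 0/1 matrix (rows = subjects)
pattern_from_matrix <- function(m, subject_ids = rownames(m),
                                visit_index = 0L, years = visit_index) {
  stopifnot(ncol(m) == nrow(REG))
  colnames(m) <- REG$region_id
  df <- data.frame(subject_id = subject_ids, visit_index = visit_index,
                   years_from_first_scan = years,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m))
  df$spatial_extent <- as.integer(rowSums(m))
  attr(df, "region_cols") <- REG$region_id
  class(df) <- c("binary_pattern", "data.frame")
  df
}

# staging-enriched property cohort: all amyloid-positive, uniform latent
# stages given positivity, ~95% tau-positive
property_config <- function(h, seed, n = c(CU = 200L, MCI = 200L,
                                           AD = 100L), ...) {
  u <- c(I = .2, III = .2, IV = .2, V = .2, VI = .2)
  synth_config(n = n, abeta_prob = c(CU = 1, MCI = 1, AD = 1),
               tau_link = list(intercept = 1.0),
               stage_dist = list(CU = u, MCI = u, AD = u),
               heterogeneity = h, seed = seed, ...)
}

# stage_positivity data.frame from a 0/1 matrix over stages
stage_pos_df <- function(m, subject_ids = rownames(m), visit_index = 0L) {
  colnames(m) <- paste0("stage_", braak_stage_order())
  df <- cbind(data.frame(subject_id = subject_ids,
                         visit_index = visit_index,
                         stringsAsFactors = FALSE),
              as.data.frame(m))
  class(df) <- c("stage_positivity", "data.frame")
  df
}
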