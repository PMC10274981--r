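# Longitudinal classification and annual change estimation.

#' Classify per-region change between first and last scan
#'
#' Regions are labelled from their baseline and last-visit binary states
#' only (intermediate visits do not affect the label): 0->0
#' \code{stable_negative}, 1->1 \code{stable_positive}, 0->1
#' \code{progressor}, 1->0 \code{regressor}.
#'
#' @param first,last \code{binary_pattern} data.frames for the first and
#'   last available scan of each subject (same subjects, same regions).
#'   Subjects present in only one of the two are dropped with a message.
#' @return Object of class \code{progression_matrix}: a character matrix
#'   (subjects x regions) of state labels, with \code{baseline_extent}
#'   attribute.
#' @export
progression_states <- function(first, last) {
  region_cols <- attr(first, "region_cols")
  stopifnot(identical(region_cols, attr(last, "region_cols")))
  common <- intersect(first$subject_id, last$subject_id)
  dropped <- setdiff(union(first$subject_id, last$subject_id), common)
  if (length(dropped))
    message("dropping ", length(dropped),
            " subject(s) without both scans: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  f <- as.matrix(first[match(common, first$subject_id), region_cols])
  l <- as.matrix(last[match(common, last$subject_id), region_cols])
  lab <- matrix(NA_character_, nrow = length(common),
                ncol = length(region_cols),
                dimnames = list(common, region_cols))
  lab[f == 0L & l == 0L] <- "stable_negative"
  lab[f == 1L & l == 1L] <- "stable_positive"
  lab[f == 0L & l == 1L] <- "progressor"
  lab[f == 1L & l == 0L] <- "regressor"
  attr(lab, "baseline_extent") <- rowSums(f)
  class(lab) <- c("progression_matrix", class(lab))
  lab
}

#' First/last visit binary patterns per subject
#'
#' Convenience extractor: binarizes the table and returns the baseline and
#' last-scan patterns for subjects with at least \code{min_scans} visits.
#'
#' @param table A \code{suvr_table}.
#' @param thresholds A \code{threshold_set}.
#' @param min_scans Minimum number of scans to include a subject (2 for the
#'   full longitudinal sample; 3 for constant-sample regional rate maps).
#' @return List with \code{first} and \code{last} \code{binary_pattern}s.
#' @export
first_last_patterns <- function(table, thresholds, min_scans = 2L) {
  nvis <- tapply(table$visit_index, table$subject_id,
                 function(v) length(unique(v)))
  keep <- names(nvis)[nvis >= min_scans]
  tab <- table[table$subject_id %in% keep, ]
  if (!nrow(tab)) stop("no subjects with at least ", min_scans, " scans")
  pat <- binarize(tab, thresholds)
  last_idx <- tapply(pat$visit_index, pat$subject_id, max)
  list(first = pat[pat$visit_index == 0L, ],
       last  = pat[pat$visit_index ==
                     last_idx[as.character(pat$subject_id)], ])
}

#' Longitudinal Braak-staging conformance
#'
#' For each stage that newly becomes positive at the last visit, conformance
#' requires every earlier stage in the chain I < III < IV < V < VI to be
#' positive at baseline or to have become positive during follow-up. The
#' percentage is computed over subjects who progressed on at least one
#' stage.
#'
#' @param stage_first,stage_last \code{stage_positivity} data.frames at the
#'   first and last scan (same subjects).
#' @return List with \code{per_subject} (subject_id, progressed_stages,
#'   conforms), \code{per_stage} (stage, n_newly_positive, pct_conforming),
#'   \code{overall_pct} and \code{n_progressed}.
#' @export
braak_conformance_long <- function(stage_first, stage_last) {
  stages <- braak_stage_order()
  cols <- paste0("stage_", stages)
  common <- intersect(stage_first$subject_id, stage_last$subject_id)
  f <- as.matrix(stage_first[match(common, stage_first$subject_id), cols])
  l <- as.matrix(stage_last[match(common, stage_last$subject_id), cols])
  newly <- f == 0L & l == 1L
  # "already positive or progressed": positive at baseline or at last visit
  ever <- (f == 1L) | (l == 1L)
  progressed <- rowSums(newly) > 0

  conf_stage <- function(i, s) {
    if (s == 1L) return(TRUE)
    all(ever[i, seq_len(s - 1L)])
  }
  conforms <- vapply(seq_along(common), function(i) {
    if (!progressed[i]) return(NA)
    ss <- which(newly[i, ])
    all(vapply(ss, function(s) conf_stage(i, s), logical(1)))
  }, logical(1))

  per_stage <- do.call(rbind, lapply(seq_along(stages), function(s) {
    idx <- which(newly[, s])
    ok <- vapply(idx, function(i) conf_stage(i, s), logical(1))
    data.frame(stage = stages[s], n_newly_positive = length(idx),
               pct_conforming = if (length(idx)) 100 * mean(ok) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  list(per_subject = data.frame(
         subject_id = common,
         n_progressed_stages = rowSums(newly),
         conforms = conforms, stringsAsFactors = FALSE),
       per_stage = per_stage,
       overall_pct = if (any(progressed)) 100 * mean(conforms[progressed])
         else NA_real_,
       n_progressed = sum(progressed))
}

#' Annual rate of change via a linear mixed model
#'
#' Fits \code{value ~ years + (1 + years | subject)} by REML; the fixed
#' slope is the population annual change and per-subject slopes are the
#' fixed effect plus the predicted (BLUP) random deviation. When the
#' random-slope variance is estimated at the boundary (singular fit), the
#' model falls back to a random intercept only, with a flag. Subjects with
#' fewer than two visits are dropped with a message. A 0/1 positivity
#' outcome is handled as a linear probability model.
#'
#' @param data data.frame with columns \code{subject_id}, \code{years} and
#'   \code{value} (one row per subject-visit).
#' @param measure Name of the measure (carried through to the result).
#' @return Object of class \code{annual_change}: \code{measure},
#'   \code{slope} (fixed effect, per year), \code{se}, \code{ci} (Wald 95%),
#'   \code{subject_slopes} (named vector), \code{random_slope_sd},
#'   \code{fallback_intercept_only}, \code{n_subjects}, \code{n_obs}.
#' @export
annual_change <- function(data, measure = "measure") {
  stopifnot(all(c("subject_id", "years", "value") %in% names(data)))
  data <- data[is.finite(data$value) & is.finite(data$years), ]
  nvis <- tapply(data$years, data$subject_id, function(y) length(unique(y)))
  drop <- names(nvis)[nvis < 2L]
  if (length(drop)) {
    message("annual_change(", measure, "): dropping ", length(drop),
            " subject(s) with a single visit")
    data <- data[!data$subject_id %in% drop, ]
  }
  if (length(unique(data$subject_id)) < 10L)
    stop("need at least 10 subjects with >=2 visits")
  data$subject_id <- factor(data$subject_id)

  # with exactly two visits per subject the slope+intercept model is
  # unidentifiable; treat that like a boundary fit and fall back
  fit <- tryCatch(suppressWarnings(suppressMessages(
    lme4::lmer(value ~ years + (1 + years | subject_id), data = data,
               REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 check.nobs.vs.nRE = "warning")))),
    error = function(e) NULL)
  fallback <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (fallback) {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ years + (1 | subject_id), data = data,
                 REML = TRUE)))
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))["years"]
  re <- lme4::ranef(fit)$subject_id
  rand_slope <- if (!fallback && "years" %in% colnames(re))
    stats::setNames(re[["years"]], rownames(re))
  else stats::setNames(rep(0, nrow(re)), rownames(re))
  vc <- as.data.frame(lme4::VarCorr(fit))
  rs_sd <- if (!fallback)
    vc$sdcor[vc$grp == "subject_id" & vc$var1 == "years" & is.na(vc$var2)]
  else 0

  out <- list(measure = measure,
              slope = unname(beta["years"]),
              se = unname(se),
              ci = unname(beta["years"] + c(-1, 1) * 1.96 * se),
              subject_slopes = beta["years"] + rand_slope,
              random_slope_sd = rs_sd,
              fallback_intercept_only = fallback,
              n_subjects = nlevels(data$subject_id),
              n_obs = nrow(data),
              model = fit)
  class(out) <- "annual_change"
  out
}

#' @export
print.annual_change <- function(x, ...) {
  cat(sprintf("Annual change in %s: %.3f/yr (95%% CI %.3f to %.3f), n=%d%s\n",
              x$measure, x$slope, x$ci[1], x$ci[2], x$n_subjects,
              if (x$fallback_intercept_only) " [random intercept only]"
              else ""))
  invisible(x)
}

#' Region-wise annual change in SUVR and positivity
#'
#' Fits \code{\link{annual_change}} per region for the region's SUVR and
#' for its 0/1 positivity (linear probability model), over subjects with at
#' least \code{min_scans} scans.
#'
#' @param table A \code{suvr_table}.
#' @param thresholds A \code{threshold_set}.
#' @param registry A \code{region_registry}.
#' @param min_scans Minimum scans per subject (default 3, giving a constant
#'   sample across follow-up as in regional rate maps).
#' @return data.frame: region_id, suvr_change_per_year,
#'   positivity_change_per_year, n_subjects, flags.
#' @export
regional_rates <- function(table, thresholds,
                           registry = region_registry(), min_scans = 3L) {
  nvis <- tapply(table$visit_index, table$subject_id,
                 function(v) length(unique(v)))
  keep <- names(nvis)[nvis >= min_scans]
  tab <- table[table$subject_id %in% keep, ]
  if (!nrow(tab)) stop("no subjects with at least ", min_scans, " scans")
  pat <- binarize(tab, thresholds)
  region_cols <- attr(pat, "region_cols")
  rows <- lapply(region_cols, function(rid) {
    sub <- tab[tab$region_id == rid, ]
    d_suvr <- data.frame(subject_id = sub$subject_id,
                         years = sub$years_from_first_scan,
                         value = sub$suvr)
    d_pos <- data.frame(subject_id = pat$subject_id,
                        years = pat$years_from_first_scan,
                        value = pat[[rid]])
    a1 <- suppressMessages(annual_change(d_suvr, paste0(rid, "_suvr")))
    a2 <- suppressMessages(annual_change(d_pos, paste0(rid, "_positivity")))
    data.frame(region_id = rid,
               suvr_change_per_year = a1$slope,
               positivity_change_per_year = a2$slope,
               n_subjects = a1$n_subjects,
               flags = paste(c(if (a1$fallback_intercept_only)
                 "suvr_intercept_only",
                 if (a2$fallback_intercept_only) "pos_intercept_only"),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
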