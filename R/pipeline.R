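# End-to-end pipeline driver: simulate (optional) -> thresholds ->
# extent/staging -> progression -> overlap -> cognition, with a
# reproducibility manifest.

#' Run the full spatial-extent pipeline from a configuration
#'
#' Stages: optional simulation (a \code{simulate} block), threshold
#' fitting, binarization + spatial extent + cross-sectional conformance,
#' longitudinal progression + conformance + annual rates (when several
#' visits exist), Jaccard overlap, and cognition associations (skipped with
#' a notice when no cognition inputs are available). All main analyses are
#' restricted to the amyloid-positive subsample by default
#' (\code{abeta = "pos"}); set \code{abeta} to \code{"all"} or \code{"neg"}
#' to override. Every output is a CSV/JSON table under \code{out_dir}, plus
#' \code{manifest.json} recording the config, seed, input digests, package
#' version and per-stage row counts and warnings.
#'
#' @param config Path to a YAML file or a list. Recognized fields:
#'   \code{seed}, \code{abeta}, \code{min_scans_rates}, \code{simulate}
#'   (logical or a list of \code{\link{synth_config}} overrides), or
#'   \code{inputs} (paths \code{suvr}, \code{metadata}, \code{cognition}).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  abeta <- config$abeta %||% "pos"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- region_registry()
  manifest <- list(seed = seed, abeta = abeta,
                   package_version =
                     as.character(utils::packageVersion("tauextent")),
                   config = config, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], list(...))
  }
  stage_fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate) && !isFALSE(config$simulate)) {
    overrides <- if (is.list(config$simulate)) config$simulate else list()
    cfg <- do.call(synth_config, c(overrides, list(seed = seed)))
    sim <- tryCatch(generate_cohort(cfg, registry),
                    error = function(e) stage_fail("simulate", e))
    suvr <- sim$suvr; metadata <- sim$metadata; cognition <- sim$cognition
    utils::write.csv(suvr, file.path(out_dir, "suvr.csv"),
                     row.names = FALSE)
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(cognition, file.path(out_dir, "cognition.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(region_params = sim$truth$region_params,
           stage_params = sim$truth$stage_params,
           log_or = sim$truth$log_or),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    note("simulate", n_subjects = nrow(metadata), n_rows = nrow(suvr))
  } else {
    inp <- config$inputs
    if (is.null(inp$suvr)) stop("config needs a simulate block or inputs$suvr")
    suvr <- tryCatch(load_suvr_table(inp$suvr, registry),
                     error = function(e) stage_fail("load", e))
    metadata <- tryCatch(load_metadata(inp$metadata),
                         error = function(e) stage_fail("load", e))
    cognition <- if (!is.null(inp$cognition))
      tryCatch(load_cognition(inp$cognition),
               error = function(e) stage_fail("load", e)) else NULL
    digests <- vapply(unlist(inp), function(p)
      unname(tools::md5sum(p)), character(1))
    manifest$input_digests <- as.list(digests)
    note("load", n_subjects = length(unique(suvr$subject_id)),
         n_rows = nrow(suvr))
  }

  keep <- switch(abeta,
                 all = metadata$subject_id,
                 pos = metadata$subject_id[metadata$abeta_positive],
                 neg = metadata$subject_id[!metadata$abeta_positive],
                 stop("abeta must be all, pos or neg"))

  # --- thresholds (fitted on the entire cross-sectional sample) ----------
  thresholds <- tryCatch(fit_all_thresholds(suvr, registry, seed = seed),
                         error = function(e) stage_fail("thresholds", e))
  write_thresholds(thresholds, file.path(out_dir, "thresholds.json"))
  note("thresholds", n_flagged = length(thresholds$flags),
       flagged = names(thresholds$flags))

  # --- extent / staging (analysis subsample) ------------------------------
  ana <- suvr[suvr$subject_id %in% keep, ]
  pat0 <- tryCatch(binarize(ana, thresholds, visit_index = 0L),
                   error = function(e) stage_fail("extent", e))
  utils::write.csv(pat0[c("subject_id", "spatial_extent")],
                   file.path(out_dir, "extent.csv"), row.names = FALSE)
  utils::write.csv(heatmap_table(pat0, metadata, registry),
                   file.path(out_dir, "heatmap.csv"), row.names = FALSE)
  comps <- stage_composite_suvr(ana, registry)
  spos0 <- stage_positivity(comps, thresholds, visit_index = 0L)
  utils::write.csv(spos0, file.path(out_dir, "stage_positivity.csv"),
                   row.names = FALSE)
  conf <- braak_conformance_cross(spos0)
  utils::write.csv(conf$per_stage, file.path(out_dir, "conformance.csv"),
                   row.names = FALSE)
  note("extent", n_subjects = nrow(pat0),
       overall_conformance_pct = conf$overall_pct)

  # logistic link on the full (unstratified) sample
  pat_all0 <- binarize(suvr, thresholds, visit_index = 0L)
  lg <- tryCatch(extent_logistic(
    metadata$centiloid[match(pat_all0$subject_id, metadata$subject_id)],
    pat_all0$spatial_extent), error = function(e) NULL)
  if (!is.null(lg))
    jsonlite::write_json(unclass(lg)[c("or", "ci", "n",
                                       "separation_flag")],
                         file.path(out_dir, "extent_logistic.json"),
                         auto_unbox = TRUE, digits = NA)

  # --- longitudinal -------------------------------------------------------
  nvis <- tapply(ana$visit_index, ana$subject_id,
                 function(v) length(unique(v)))
  overlap_prog <- NULL
  if (any(nvis >= 2L)) {
    fl <- first_last_patterns(ana, thresholds, min_scans = 2L)
    prog <- progression_states(fl$first, fl$last)
    states_df <- data.frame(subject_id = rownames(prog),
                            as.data.frame(unclass(prog)),
                            check.names = FALSE)
    utils::write.csv(states_df, file.path(out_dir,
                                          "progression_states.csv"),
                     row.names = FALSE)
    long_sub <- ana[ana$subject_id %in% rownames(prog), ]
    comps_l <- stage_composite_suvr(long_sub, registry)
    last_idx <- tapply(comps_l$visit_index, comps_l$subject_id, max)
    sp_first <- stage_positivity(comps_l, thresholds, visit_index = 0L)
    sp_all <- stage_positivity(comps_l, thresholds)
    sp_last <- sp_all[sp_all$visit_index ==
                        last_idx[as.character(sp_all$subject_id)], ]
    confl <- braak_conformance_long(sp_first, sp_last)
    utils::write.csv(confl$per_stage,
                     file.path(out_dir, "conformance_longitudinal.csv"),
                     row.names = FALSE)
    ext_long <- binarize(long_sub, thresholds)
    rate_ext <- annual_change(
      data.frame(subject_id = ext_long$subject_id,
                 years = ext_long$years_from_first_scan,
                 value = ext_long$spatial_extent),
      measure = "spatial_extent")
    dx <- metadata$diagnosis[match(ext_long$subject_id,
                                   metadata$subject_id)]
    rates_dx <- lapply(split(seq_len(nrow(ext_long)), dx), function(ii) {
      tryCatch(annual_change(
        data.frame(subject_id = ext_long$subject_id[ii],
                   years = ext_long$years_from_first_scan[ii],
                   value = ext_long$spatial_extent[ii]))$slope,
        error = function(e) NA_real_)
    })
    utils::write.csv(
      data.frame(group = c("all", names(rates_dx)),
                 extent_change_per_year = c(rate_ext$slope,
                                            unlist(rates_dx))),
      file.path(out_dir, "rates.csv"), row.names = FALSE)
    note("longitudinal", n_subjects = nrow(prog),
         overall_long_conformance_pct = confl$overall_pct,
         extent_rate = rate_ext$slope)
    overlap_prog <- prog
  } else {
    message("longitudinal stage skipped: no subject has >= 2 visits")
  }

  # --- heterogeneity ------------------------------------------------------
  groups <- metadata[metadata$subject_id %in% pat0$subject_id,
                     c("subject_id", "diagnosis")]
  ovl <- tryCatch(
    suppressMessages(mean_group_overlap(pat0, groups, mode = "binary")),
    error = function(e) NULL)
  if (!is.null(ovl))
    utils::write.csv(ovl$per_group, file.path(out_dir, "overlap.csv"),
                     row.names = FALSE)
  if (!is.null(overlap_prog)) {
    ovp <- tryCatch(
      suppressMessages(mean_group_overlap(overlap_prog, groups,
                                          mode = "progression")),
      error = function(e) NULL)
    if (!is.null(ovp))
      utils::write.csv(ovp$per_group,
                       file.path(out_dir, "overlap_progression.csv"),
                       row.names = FALSE)
  }

  # --- cognition ----------------------------------------------------------
  if (is.null(cognition)) {
    message("cognition stage skipped: no cognition inputs")
    note("cognition", skipped = TRUE)
  } else {
    res <- tryCatch(
      cognition_associations(pat0, comps, cognition, metadata),
      error = function(e) stage_fail("cognition", e))
    utils::write.csv(res, file.path(out_dir,
                                    "cognition_associations.csv"),
                     row.names = FALSE)
    note("cognition", n_models = nrow(res))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Tau-measure vs cognition association table
#'
#' For each diagnostic group and composite, fits the adjusted linear model
#' of baseline cognitive performance on the spatial extent index and on
#' the temporal meta-ROI SUVR, compares the two by Vuong's closeness test,
#' and applies BH-FDR within group across the fitted models.
#'
#' @param pattern Baseline \code{binary_pattern} (for the extent index).
#' @param composites Output of \code{\link{stage_composite_suvr}} (for the
#'   meta-ROI SUVR).
#' @param cognition Cognition table; the score closest in time to the
#'   baseline scan (within \code{match_window} years) is the performance
#'   outcome.
#' @param metadata Subject metadata (covariates and grouping).
#' @param match_window Years allowed between scan and cognitive visit
#'   (default 2).
#' @param mode \code{"performance"} (baseline score) or \code{"decline"}
#'   (per-subject mixed-model slope over all cognitive visits).
#' @return data.frame: group, composite, predictor, beta, std_beta, p,
#'   p_fdr, r2_adj, aic, vuong_z, vuong_p, n.
#' @export
cognition_associations <- function(pattern, composites, cognition,
                                   metadata, match_window = 2,
                                   mode = c("performance", "decline")) {
  mode <- match.arg(mode)
  base <- merge(pattern[c("subject_id", "spatial_extent")],
                composites[composites$visit_index == 0L,
                           c("subject_id", "meta_roi")],
                by = "subject_id")
  base <- merge(base, metadata[c("subject_id", "diagnosis", "age", "sex",
                                 "education")], by = "subject_id")

  if (mode == "decline") {
    sl <- cognitive_slopes(cognition)
    outcome_of <- function(comp) {
      d <- sl[sl$composite == comp, c("subject_id", "slope")]
      names(d)[2L] <- "outcome"
      d
    }
  } else {
    outcome_of <- function(comp) {
      d <- cognition[cognition$composite == comp, ]
      # score closest in time to the baseline scan (time 0)
      d <- d[order(d$subject_id,
                   abs(d$years_from_first_cognitive_visit)), ]
      d <- d[!duplicated(d$subject_id), ]
      d <- d[abs(d$years_from_first_cognitive_visit) <= match_window, ]
      data.frame(subject_id = d$subject_id, outcome = d$score,
                 stringsAsFactors = FALSE)
    }
  }

  rows <- NULL
  for (g in intersect(c("CU", "MCI", "AD"), unique(base$diagnosis))) {
    bg <- base[base$diagnosis == g, ]
    for (comp in unique(cognition$composite)) {
      d <- merge(bg, outcome_of(comp), by = "subject_id")
      pair <- lapply(c(extent = "spatial_extent", metaroi = "meta_roi"),
                     function(pr)
                       tryCatch(fit_association(d, "outcome", pr),
                                error = function(e) NULL))
      if (any(vapply(pair, is.null, logical(1)))) next
      # meta-ROI first: negative z then favors the spatial extent index
      vu <- vuong_test(pair$metaroi, pair$extent)
      for (nm in names(pair)) {
        m <- pair[[nm]]
        rows <- rbind(rows, data.frame(
          group = g, composite = comp, predictor = nm,
          beta = m$beta, std_beta = m$std_beta, p = m$p,
          r2_adj = m$r2_adj, aic = m$aic,
          vuong_z = vu$z, vuong_p = vu$p, n = m$n,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(rows)) stop("no group/composite with enough complete cases")
  # FDR within diagnostic group across the fitted models
  rows$p_fdr <- NA_real_
  for (g in unique(rows$group))
    rows$p_fdr[rows$group == g] <- fdr_adjust(rows$p[rows$group == g])
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a
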