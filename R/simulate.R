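# Synthetic tau-PET cohort generator with exposed ground truth.
#
# Emulates the statistical structure the pipeline assumes: per-region
# two-component (normal/abnormal) SUVR mixtures, Braak-ordered accumulation
# with tunable between-subject heterogeneity (stage-membership swapping
# between adjacent stages), diagnosis-dependent longitudinal spread rates,
# centiloid-linked tau-positivity odds, and cognition composites linearly
# degraded by tau burden.

#' Generator configuration with validated defaults
#'
#' Defaults describe an ADNI-like cohort: 463 CU / 277 MCI / 92 AD
#' subjects, amyloid-positive fractions 0.351 / 0.477 / 0.837, centiloid
#' distributions per diagnosis and amyloid status, a logistic link from
#' centiloid to any tau positivity with odds ratio 1.04 per centiloid,
#' regional SUVR mixtures N(1.10, 0.07^2) (normal) vs N(1.60, 0.15^2)
#' (abnormal) with small per-region jitter, heterogeneity h = 0.1, and
#' longitudinal spread rates of 2.5 (MCI), 0.968 (CU) and 0.865 (AD) newly
#' abnormal regions per year with a small nonzero regression probability.
#'
#' @param ... Named overrides for any top-level field; list-valued fields
#'   (\code{mixture}, \code{centiloid}, \code{tau_link},
#'   \code{longitudinal}, \code{cognition}, \code{stage_dist},
#'   \code{demographics}) are merged element-wise.
#' @param seed Master seed; fully determines the generated cohort.
#' @return A validated list of class \code{synth_config}.
#' @export
synth_config <- function(..., seed = 42L) {
  cfg <- list(
    n = c(CU = 463L, MCI = 277L, AD = 92L),
    abeta_prob = c(CU = 0.351, MCI = 0.477, AD = 0.837),
    heterogeneity = 0.1,
    abneg_stage_cap_prob = 0.97,
    mixture = list(mean_lo = 1.10, sd_lo = 0.07, delta = 0.50,
                   sd_hi = 0.15, jitter_mean = 0.02, jitter_delta = 0.03),
    stage_dist = list(  # latent stage distribution given any positivity
      CU  = c(I = 0.65, III = 0.20, IV = 0.10, V = 0.04, VI = 0.01),
      MCI = c(I = 0.25, III = 0.25, IV = 0.25, V = 0.15, VI = 0.10),
      AD  = c(I = 0.05, III = 0.15, IV = 0.25, V = 0.35, VI = 0.20)),
    centiloid = list(
      mean_pos = c(CU = 53.47, MCI = 75.78, AD = 90.14),
      sd_pos   = c(CU = 30.83, MCI = 35.15, AD = 32.86),
      mean_neg = c(CU = 4.09, MCI = 1.18, AD = 1.63),
      sd_neg   = c(CU = 8.11, MCI = 10.53, AD = 11.27)),
    tau_link = list(intercept = -3.0, log_or = log(1.04)),
    demographics = list(
      age_mean = c(CU = 74.8, MCI = 74.4, AD = 77.4), age_sd = 7.9,
      female_prob = c(CU = 0.59, MCI = 0.49, AD = 0.42),
      edu_mean = c(CU = 16.6, MCI = 16.0, AD = 15.6), edu_sd = 2.5),
    longitudinal = list(n_visits = 1L, spacing = 1.0,
                        rates = c(CU = 0.968, MCI = 2.5, AD = 0.865),
                        rate_abneg = 0.1, drift = 0.02,
                        regression_prob = 0.01),
    cognition = list(
      n_visits = 4L, spacing = 1.0,
      intercept = c(memory = 1.0, executive = 0.9, language = 0.75,
                    visuospatial = 0.06),
      extent_effect = c(memory = -0.03, executive = -0.03,
                        language = -0.02, visuospatial = -0.01),
      age_effect = -0.01, education_effect = 0.02, sex_effect = 0.05,
      decline_base = c(memory = -0.02, executive = -0.02,
                       language = -0.01, visuospatial = -0.005),
      decline_per_extent = -0.005, slope_sd = 0.05, residual_sd = 0.4),
    seed = as.integer(seed))
  dots <- list(...)
  # YAML deserializes named vectors as lists; coerce back to the default's
  # shape before merging
  coerce_like <- function(value, template) {
    if (is.atomic(template) && is.list(value)) unlist(value)
    else value
  }
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    if (is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]]))) {
      incoming <- dots[[nm]]
      if (!is.list(incoming)) stop(nm, " must be a named list")
      bad <- setdiff(names(incoming), names(cfg[[nm]]))
      if (length(bad)) stop("unknown ", nm, " field(s): ",
                            paste(bad, collapse = ", "))
      for (k in names(incoming))
        cfg[[nm]][[k]] <- coerce_like(incoming[[k]], cfg[[nm]][[k]])
    } else cfg[[nm]] <- coerce_like(dots[[nm]], cfg[[nm]])
  }
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  h <- cfg$heterogeneity
  if (!is.numeric(h) || h < 0 || h > 1)
    stop("heterogeneity must lie in [0, 1]")
  if (any(cfg$n < 0)) stop("group sizes must be non-negative")
  mx <- cfg$mixture
  if (mx$sd_lo <= 0 || mx$sd_hi <= 0) stop("mixture sds must be positive")
  if (mx$delta <= 0) stop("mixture delta (mean_hi - mean_lo) must be > 0")
  lg <- cfg$longitudinal
  if (any(lg$rates < 0) || lg$rate_abneg < 0)
    stop("spread rates must be >= 0")
  if (lg$regression_prob < 0 || lg$regression_prob > 1)
    stop("regression_prob must lie in [0, 1]")
  if (lg$n_visits < 1L) stop("n_visits must be >= 1")
  for (g in names(cfg$stage_dist)) {
    p <- cfg$stage_dist[[g]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("stage_dist[", g, "] must be a probability vector over stages")
    if (!identical(names(p), braak_stage_order()))
      stop("stage_dist[", g, "] must be named over stages ",
           paste(braak_stage_order(), collapse = ", "))
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Analytic posterior-0.5 cutoff of a two-component Gaussian mixture
#'
#' Root of w_hi * phi(x; mean_hi, sd_hi) = w_lo * phi(x; mean_lo, sd_lo)
#' inside (mean_lo, mean_hi), by high-precision bisection. This is the
#' ground-truth twin of \code{\link{cutoff_from_fit}} and the oracle for
#' all threshold-recovery checks.
#'
#' @param weight_hi Mixing proportion of the abnormal component (in (0,1)).
#' @param mean_lo,mean_hi Component means (distinct, mean_lo < mean_hi).
#' @param sd_lo,sd_hi Component standard deviations (> 0).
#' @return Cutoff SUVR.
#' @export
analytic_cutoff <- function(weight_hi, mean_lo, mean_hi, sd_lo, sd_hi) {
  stopifnot(weight_hi > 0, weight_hi < 1, sd_lo > 0, sd_hi > 0,
            mean_lo < mean_hi)
  fit <- list(weight_lo = 1 - weight_hi, weight_hi = weight_hi,
              mean_lo = mean_lo, mean_hi = mean_hi,
              sd_lo = sd_lo, sd_hi = sd_hi)
  g <- function(x) log_posterior_odds(x, fit)
  eps <- (mean_hi - mean_lo) * 1e-12
  lo <- mean_lo + eps; hi <- mean_hi - eps
  if (g(lo) * g(hi) > 0)
    stop("no posterior-0.5 crossing inside (mean_lo, mean_hi)")
  stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
}

stage_index <- function(stage) match(stage, braak_stage_order())

# swap stage memberships between adjacent stages, per subject
swap_stage_map <- function(canonical_idx, h) {
  idx <- canonical_idx
  if (h <= 0) return(idx)
  req <- which(stats::runif(length(idx)) < h & !is.na(idx))
  for (r in req) {
    s <- idx[r]
    nbr <- intersect(c(s - 1L, s + 1L), seq_len(5L))
    if (!length(nbr)) next
    s2 <- if (length(nbr) == 1L) nbr else
      nbr[1L + (stats::runif(1) < 0.5)]
    cand <- which(idx == s2)
    if (!length(cand)) next
    partner <- cand[sample.int(length(cand), 1L)]
    idx[r] <- s2
    idx[partner] <- s
  }
  idx
}

#' Generate a synthetic tau-PET cohort with ground truth
#'
#' Each subject draws a latent Braak stage from the diagnosis-specific
#' distribution conditional on any tau positivity; any-positivity follows a
#' logistic link on centiloid; amyloid-negative positive subjects are
#' capped at stage I with high probability. Regions whose (possibly
#' h-swapped) stage is at or below the latent stage are abnormal and draw
#' SUVR from the high component; others from the low component. With
#' multiple visits, still-negative regions cross to abnormal at the
#' diagnosis spread rate (Poisson per interval) in the subject's stage
#' order, abnormal SUVR drifts upward, and abnormal regions regress with a
#' small configurable probability. Cognition composites are generated
#' linearly from true baseline extent, demographics, and a per-subject
#' decline slope linked to extent.
#'
#' @param config A \code{synth_config}.
#' @param registry A \code{region_registry}.
#' @return List with \code{suvr} (\code{suvr_table}), \code{metadata},
#'   \code{cognition}, and \code{truth} (region/stage generating parameters
#'   with analytic cutoffs, per-visit true binary matrices, latent stages,
#'   true extent, true cognitive slopes, true log odds ratio, config).
#' @export
generate_cohort <- function(config = synth_config(),
                            registry = region_registry()) {
  stopifnot(inherits(config, "synth_config"))
  res <- NULL
  with_preserved_rng(config$seed, {
    res <- generate_cohort_impl(config, registry)
  })
  res
}

generate_cohort_impl <- function(cfg, registry) {
  stages <- braak_stage_order()
  R <- nrow(registry)
  canon_idx <- stage_index(registry$braak_stage)

  # per-region generating mixtures
  mx <- cfg$mixture
  mean_lo_r <- mx$mean_lo + stats::rnorm(R, 0, mx$jitter_mean)
  delta_r <- pmax(mx$delta + stats::rnorm(R, 0, mx$jitter_delta),
                  mx$delta / 2)
  mean_hi_r <- mean_lo_r + delta_r

  # subjects
  dx <- rep(names(cfg$n), times = cfg$n)
  n <- length(dx)
  if (n == 0L) stop("empty cohort")
  ids <- sprintf("S%04d", seq_len(n))
  abeta <- stats::runif(n) < cfg$abeta_prob[dx]
  cl <- ifelse(abeta,
               stats::rnorm(n, cfg$centiloid$mean_pos[dx],
                            cfg$centiloid$sd_pos[dx]),
               stats::rnorm(n, cfg$centiloid$mean_neg[dx],
                            cfg$centiloid$sd_neg[dx]))
  dm <- cfg$demographics
  age <- stats::rnorm(n, dm$age_mean[dx], dm$age_sd)
  sex <- ifelse(stats::runif(n) < dm$female_prob[dx], "F", "M")
  edu <- round(pmin(pmax(stats::rnorm(n, dm$edu_mean[dx], dm$edu_sd), 8),
                    22))

  # latent stage via centiloid-linked any-positivity
  p_pos <- stats::plogis(cfg$tau_link$intercept + cfg$tau_link$log_or * cl)
  any_pos <- stats::runif(n) < p_pos
  latent <- integer(n)  # 0 = no positive stage
  for (i in which(any_pos)) {
    s <- sample.int(5L, 1L, prob = cfg$stage_dist[[dx[i]]])
    if (!abeta[i] && stats::runif(1) < cfg$abneg_stage_cap_prob)
      s <- 1L
    latent[i] <- s
  }

  # subject-specific stage maps (h-swaps) and baseline truth
  h <- cfg$heterogeneity
  subj_idx <- matrix(0L, n, R, dimnames = list(ids, registry$region_id))
  for (i in seq_len(n)) subj_idx[i, ] <- swap_stage_map(canon_idx, h)
  truth0 <- (subj_idx <= latent) * 1L  # latent 0 -> all zero
  storage.mode(truth0) <- "integer"

  # longitudinal truth trajectories
  lg <- cfg$longitudinal
  V <- as.integer(lg$n_visits)
  visit_years <- (seq_len(V) - 1L) * lg$spacing
  truth_by_visit <- vector("list", V)
  truth_by_visit[[1L]] <- truth0
  if (V > 1L) {
    # per-subject accumulation order: stage, then random within stage
    order_r <- t(vapply(seq_len(n), function(i)
      order(subj_idx[i, ], stats::runif(R)), integer(R)))
    cur <- truth0
    for (v in 2L:V) {
      dt <- visit_years[v] - visit_years[v - 1L]
      rate <- ifelse(abeta, lg$rates[dx], lg$rate_abneg)
      nxt <- cur
      for (i in seq_len(n)) {
        k <- stats::rpois(1L, rate[i] * dt)
        if (k > 0L) {
          neg_in_order <- order_r[i, ][nxt[i, order_r[i, ]] == 0L]
          if (length(neg_in_order))
            nxt[i, utils::head(neg_in_order, k)] <- 1L
        }
        if (lg$regression_prob > 0) {
          pos <- which(nxt[i, ] == 1L)
          flip <- pos[stats::runif(length(pos)) < lg$regression_prob]
          if (length(flip)) nxt[i, flip] <- 0L
        }
      }
      truth_by_visit[[v]] <- nxt
      cur <- nxt
    }
  }

  # emitted SUVR per visit
  suvr_rows <- vector("list", V)
  for (v in seq_len(V)) {
    tv <- truth_by_visit[[v]]
    mu <- matrix(rep(mean_lo_r, each = n), n, R)
    mu[tv == 1L] <- (matrix(rep(mean_hi_r, each = n), n, R) +
                       lg$drift * visit_years[v])[tv == 1L]
    sdm <- ifelse(tv == 1L, mx$sd_hi, mx$sd_lo)
    vals <- matrix(stats::rnorm(n * R, as.vector(mu), as.vector(sdm)),
                   n, R)
    vals[vals < 0.3] <- 0.3
    suvr_rows[[v]] <- data.frame(
      subject_id = rep(ids, times = R),
      visit_index = v - 1L,
      years_from_first_scan = visit_years[v],
      region_id = rep(registry$region_id, each = n),
      suvr = as.vector(vals),
      stringsAsFactors = FALSE)
  }
  suvr <- do.call(rbind, suvr_rows)

  metadata <- data.frame(subject_id = ids, diagnosis = dx,
                         abeta_positive = abeta, centiloid = cl,
                         age = age, sex = sex, education = edu,
                         stringsAsFactors = FALSE)

  # cognition linearly degraded by true baseline extent
  cg <- cfg$cognition
  extent0 <- rowSums(truth0)
  cog_rows <- list()
  true_slopes <- list()
  cg_years <- (seq_len(cg$n_visits) - 1L) * cg$spacing
  for (comp in names(cg$intercept)) {
    slope_i <- cg$decline_base[comp] + cg$decline_per_extent * extent0 +
      stats::rnorm(n, 0, cg$slope_sd)
    base_i <- cg$intercept[comp] + cg$extent_effect[comp] * extent0 +
      cg$age_effect * (age - 74) + cg$education_effect * (edu - 16) +
      cg$sex_effect * (sex == "F")
    for (v in seq_along(cg_years)) {
      cog_rows[[length(cog_rows) + 1L]] <- data.frame(
        subject_id = ids,
        years_from_first_cognitive_visit = cg_years[v],
        composite = comp,
        score = base_i + slope_i * cg_years[v] +
          stats::rnorm(n, 0, cg$residual_sd),
        stringsAsFactors = FALSE)
    }
    true_slopes[[comp]] <- data.frame(subject_id = ids, composite = comp,
                                      slope = slope_i,
                                      stringsAsFactors = FALSE)
  }
  cognition <- do.call(rbind, cog_rows)

  # ground-truth cutoffs (analytic posterior-0.5 of generating mixtures,
  # empirical abnormal weights clamped away from degeneracy)
  w_r <- pmin(pmax(colMeans(truth0), 0.01), 0.99)
  cut_r <- vapply(seq_len(R), function(r)
    analytic_cutoff(w_r[r], mean_lo_r[r], mean_hi_r[r], mx$sd_lo,
                    mx$sd_hi), numeric(1))
  region_params <- data.frame(
    region_id = registry$region_id, braak_stage = registry$braak_stage,
    mean_lo = mean_lo_r, mean_hi = mean_hi_r,
    sd_lo = mx$sd_lo, sd_hi = mx$sd_hi,
    weight_hi = colMeans(truth0), cutoff = cut_r,
    stringsAsFactors = FALSE)

  stage_params <- do.call(rbind, lapply(stages, function(s) {
    members <- which(registry$braak_stage == s)
    m <- length(members)
    mlo <- mean(mean_lo_r[members]); mhi <- mean(mean_hi_r[members])
    slo <- sqrt(m * mx$sd_lo^2) / m; shi <- sqrt(m * mx$sd_hi^2) / m
    w <- mean(latent >= stage_index(s))
    w <- pmin(pmax(w, 0.01), 0.99)
    data.frame(stage = s, mean_lo = mlo, mean_hi = mhi,
               sd_lo = slo, sd_hi = shi, weight_hi = w,
               cutoff = analytic_cutoff(w, mlo, mhi, slo, shi),
               stringsAsFactors = FALSE)
  }))

  # noise-free (expected-SUVR) stage positivity per visit: the
  # by-construction stage status, free of sampling tails
  stage_binary_by_visit <- lapply(seq_len(V), function(v) {
    tv <- truth_by_visit[[v]]
    mu <- matrix(rep(mean_lo_r, each = n), n, R)
    mh <- matrix(rep(mean_hi_r, each = n), n, R) +
      lg$drift * visit_years[v]
    mu[tv == 1L] <- mh[tv == 1L]
    sb <- vapply(stages, function(s) {
      members <- which(registry$braak_stage == s)
      as.integer(rowMeans(mu[, members, drop = FALSE]) >=
                   stage_params$cutoff[stage_params$stage == s])
    }, integer(n))
    colnames(sb) <- paste0("stage_", stages)
    rownames(sb) <- ids
    sb
  })

  truth <- list(region_params = region_params,
                stage_params = stage_params,
                stage_binary_by_visit = stage_binary_by_visit,
                stage_cutoffs = stats::setNames(stage_params$cutoff,
                                                paste0("stage_",
                                                       stage_params$stage)),
                binary_by_visit = truth_by_visit,
                visit_years = visit_years,
                latent_stage = stats::setNames(
                  ifelse(latent == 0L, "none", stages[pmax(latent, 1L)]),
                  ids),
                true_extent = stats::setNames(extent0, ids),
                cognitive_slopes = do.call(rbind, true_slopes),
                log_or = cfg$tau_link$log_or,
                config = cfg)

  list(suvr = as_suvr_table(suvr, registry), metadata = metadata,
       cognition = cognition, truth = truth)
}

#' Generate a longitudinal synthetic cohort
#'
#' \code{\link{generate_cohort}} with at least two visits (default 3 visits
#' spaced one year apart).
#'
#' @param config A \code{synth_config}; its \code{longitudinal$n_visits}
#'   is raised to \code{n_visits} if smaller.
#' @param n_visits Number of tau-PET visits (>= 2).
#' @param registry A \code{region_registry}.
#' @return As \code{\link{generate_cohort}}.
#' @export
generate_longitudinal <- function(config = synth_config(), n_visits = 3L,
                                  registry = region_registry()) {
  if (n_visits < 2L) stop("longitudinal generation needs >= 2 visits")
  config$longitudinal$n_visits <-
    max(as.integer(n_visits), as.integer(config$longitudinal$n_visits))
  generate_cohort(config, registry)
}
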