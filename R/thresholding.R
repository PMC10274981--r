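# Two-component Gaussian mixture thresholding.
#
# The regional cutoff is the SUVR at which the posterior probability of
# belonging to the higher-mean ("abnormal") component equals 0.5 — the
# weight-adjusted posterior, not the equal-weight density intersection.

#' Fit a univariate two-component Gaussian mixture by EM
#'
#' Maximum-likelihood fit with free component variances, best of
#' \code{n_restarts} by log-likelihood. The first start splits the sample at
#' the two k-means-style cluster centers (extreme quantiles); subsequent
#' starts perturb randomly. Components are sorted so the higher-mean
#' component is the "abnormal" one. The caller's RNG state is preserved.
#'
#' @param values Numeric vector of SUVR values (finite; at least
#'   \code{min_n}).
#' @param seed Integer seed controlling restarts (deterministic fit).
#' @param n_restarts Number of EM restarts (default 10).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param min_n Minimum sample size (default 50).
#' @return Object of class \code{mixture_fit}: \code{weight_lo},
#'   \code{weight_hi}, \code{mean_lo}, \code{mean_hi}, \code{sd_lo},
#'   \code{sd_hi}, \code{n_obs}, \code{loglik}, \code{converged},
#'   \code{separation} ((mean_hi - mean_lo) / pooled sd), and the observed
#'   \code{range}.
#' @export
fit_two_component_mixture <- function(values, seed = 1L, n_restarts = 10L,
                                      tol = 1e-6, max_iter = 500L,
                                      min_n = 50L) {
  x <- values[is.finite(values)]
  if (length(x) < min_n)
    stop("need at least ", min_n, " finite values, got ", length(x))
  if (stats::sd(x) == 0)
    stop("zero-variance input: all values identical, mixture undefined")

  n <- length(x)
  var_floor <- 1e-6

  em_once <- function(mu1, mu2, s1, s2, w) {
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- (1 - w) * stats::dnorm(x, mu1, s1)
      d2 <- w * stats::dnorm(x, mu2, s2)
      tot <- d1 + d2
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      r <- d2 / tot
      ll <- sum(log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      w  <- mean(r)
      w  <- min(max(w, 1e-6), 1 - 1e-6)
      mu1 <- sum((1 - r) * x) / sum(1 - r)
      mu2 <- sum(r * x) / sum(r)
      s1 <- sqrt(max(sum((1 - r) * (x - mu1)^2) / sum(1 - r), var_floor))
      s2 <- sqrt(max(sum(r * (x - mu2)^2) / sum(r), var_floor))
    }
    list(mu1 = mu1, mu2 = mu2, s1 = s1, s2 = s2, w = w, loglik = ll,
         converged = converged)
  }

  best <- NULL
  with_preserved_rng(seed, {
    for (k in seq_len(n_restarts)) {
      if (k == 1L) {
        qs <- stats::quantile(x, c(0.25, 0.85), names = FALSE)
        init <- list(mu1 = qs[1L], mu2 = qs[2L],
                     s1 = stats::sd(x) / 2, s2 = stats::sd(x) / 2, w = 0.3)
      } else {
        qq <- sort(stats::runif(2, min(x), max(x)))
        if (diff(qq) < 1e-3 * (max(x) - min(x)))
          qq <- qq + c(-1, 1) * stats::sd(x) / 4
        init <- list(mu1 = qq[1L], mu2 = qq[2L],
                     s1 = stats::sd(x) / 2, s2 = stats::sd(x) / 2,
                     w = stats::runif(1, 0.1, 0.9))
      }
      fit <- em_once(init$mu1, init$mu2, init$s1, init$s2, init$w)
      if (is.null(best) ||
          (is.finite(fit$loglik) && fit$loglik > best$loglik))
        best <- fit
    }
  })

  # enforce mean_lo <= mean_hi labeling
  if (best$mu1 > best$mu2) {
    best <- list(mu1 = best$mu2, mu2 = best$mu1, s1 = best$s2, s2 = best$s1,
                 w = 1 - best$w, loglik = best$loglik,
                 converged = best$converged)
  }
  pooled <- sqrt(((1 - best$w) * best$s1^2 + best$w * best$s2^2))
  out <- list(weight_lo = 1 - best$w, weight_hi = best$w,
              mean_lo = best$mu1, mean_hi = best$mu2,
              sd_lo = best$s1, sd_hi = best$s2,
              n_obs = n, loglik = best$loglik, converged = best$converged,
              separation = (best$mu2 - best$mu1) / pooled,
              range = range(x))
  class(out) <- "mixture_fit"
  out
}

#' Posterior probability of the abnormal (high) component
#'
#' @param x SUVR values.
#' @param fit A \code{mixture_fit} (or any list with the same fields).
#' @return Posterior probabilities in [0, 1].
#' @export
posterior_abnormal <- function(x, fit) {
  lo <- fit$weight_lo * stats::dnorm(x, fit$mean_lo, fit$sd_lo)
  hi <- fit$weight_hi * stats::dnorm(x, fit$mean_hi, fit$sd_hi)
  hi / (lo + hi)
}

# signed log posterior odds of the abnormal component; root <=> posterior 0.5
log_posterior_odds <- function(x, fit) {
  log(fit$weight_hi) + stats::dnorm(x, fit$mean_hi, fit$sd_hi, log = TRUE) -
    log(fit$weight_lo) - stats::dnorm(x, fit$mean_lo, fit$sd_lo, log = TRUE)
}

#' SUVR cutoff at 50% posterior probability of abnormality
#'
#' Locates the SUVR where the posterior probability of the abnormal
#' component crosses 0.5, by sign-change bracketing on a dense grid over
#' (mean_lo, mean_hi) followed by bisection to |posterior - 0.5| < 1e-8.
#' If no crossing exists inside the interval (possible under extreme
#' weight/variance asymmetry) the global argmin of |posterior - 0.5| over
#' the observed range is returned with attribute \code{flag =
#' "no_interior_crossing"}.
#'
#' @param fit A \code{mixture_fit} with distinct means.
#' @param grid_points Grid resolution for bracketing (default 2000).
#' @return Cutoff SUVR (scalar), possibly with a \code{flag} attribute.
#' @export
cutoff_from_fit <- function(fit, grid_points = 2000L) {
  if (!(fit$mean_lo < fit$mean_hi))
    stop("mixture means must be distinct (mean_lo < mean_hi)")
  eps <- (fit$mean_hi - fit$mean_lo) * 1e-9
  grid <- seq(fit$mean_lo + eps, fit$mean_hi - eps, length.out = grid_points)
  g <- log_posterior_odds(grid, fit)
  sgn <- sign(g)
  cross <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (length(cross) == 0L && any(sgn == 0))
    return(grid[which(sgn == 0)[1L]])
  if (length(cross)) {
    i <- cross[1L]  # all crossings are interior; take the first
    root <- stats::uniroot(function(z) log_posterior_odds(z, fit),
                           lower = grid[i], upper = grid[i + 1L],
                           tol = .Machine$double.eps^0.75)$root
    stopifnot(abs(posterior_abnormal(root, fit) - 0.5) < 1e-8)
    return(root)
  }
  rng <- if (!is.null(fit$range)) fit$range else
    c(fit$mean_lo - 4 * fit$sd_lo, fit$mean_hi + 4 * fit$sd_hi)
  wide <- seq(rng[1L], rng[2L], length.out = max(grid_points, 10000L))
  cutoff <- wide[which.min(abs(posterior_abnormal(wide, fit) - 0.5))]
  attr(cutoff, "flag") <- "no_interior_crossing"
  cutoff
}

#' Per-visit Braak-stage and meta-ROI composite SUVR
#'
#' Unweighted mean SUVR over the member regions (both hemispheres) of each
#' Braak stage (I, III, IV, V, VI) and of the temporal meta-ROI, per
#' (subject, visit).
#'
#' @param table A \code{suvr_table}.
#' @param registry A \code{region_registry}.
#' @return data.frame with \code{subject_id}, \code{visit_index},
#'   \code{years_from_first_scan}, \code{stage_I}, \code{stage_III},
#'   \code{stage_IV}, \code{stage_V}, \code{stage_VI}, \code{meta_roi}.
#' @export
stage_composite_suvr <- function(table, registry = region_registry()) {
  groups <- c(as.list(stats::setNames(braak_stage_order(),
                                      paste0("stage_", braak_stage_order()))),
              list(meta_roi = "meta_roi"))
  sv <- unique(table[c("subject_id", "visit_index",
                       "years_from_first_scan")])
  sv <- sv[order(sv$subject_id, sv$visit_index), ]
  key <- paste(table$subject_id, table$visit_index, sep = "\r")
  skey <- paste(sv$subject_id, sv$visit_index, sep = "\r")
  for (nm in names(groups)) {
    members <- stage_members(registry, groups[[nm]])
    sub <- table[table$region_id %in% members, ]
    have <- table(paste(sub$subject_id, sub$visit_index, sep = "\r"))
    if (any(have[skey] != length(members)) || anyNA(have[skey])) {
      bad <- skey[which(is.na(have[skey]) | have[skey] != length(members))[1L]]
      present <- sub$region_id[paste(sub$subject_id, sub$visit_index,
                                     sep = "\r") == bad]
      stop("incomplete coverage for ", nm, ": missing region(s) ",
           paste(setdiff(members, present), collapse = ", "),
           " at subject/visit ", gsub("\r", "/", bad))
    }
    agg <- tapply(sub$suvr, paste(sub$subject_id, sub$visit_index,
                                  sep = "\r"), mean)
    sv[[nm]] <- unname(agg[skey])
  }
  rownames(sv) <- NULL
  sv
}

#' Fit data-driven abnormality thresholds for all regions and stages
#'
#' Fits a two-component Gaussian mixture to each region's baseline SUVR
#' distribution (each subject's first scan; follow-up visits are excluded
#' from fitting but are binarized with the same cutoffs) and extracts the
#' posterior-0.5 cutoff. The same procedure is applied to the Braak-stage
#' and meta-ROI composite SUVR. Deterministic given \code{seed}.
#'
#' Quality flags per region/stage: \code{low_separation} when the fitted
#' separation is below 1, \code{not_converged} when no EM restart converged,
#' \code{no_interior_crossing} when the posterior-0.5 point had to be taken
#' as an argmin over the observed range, and \code{fit_error} (with the
#' cutoff set to NA) when the mixture could not be fitted at all. Regions
#' are never silently dropped.
#'
#' @param table A \code{suvr_table} (all visits; baseline is selected
#'   internally).
#' @param registry A \code{region_registry}.
#' @param seed Integer master seed; each region gets a derived sub-seed.
#' @param min_n Minimum baseline sample size per region (default 50).
#' @return Object of class \code{threshold_set}: named numeric
#'   \code{region_cutoffs}, \code{stage_cutoffs} (stages I..VI plus
#'   \code{meta_roi}), lists \code{region_fits} and \code{stage_fits}, and a
#'   named list \code{flags}.
#' @export
fit_all_thresholds <- function(table, registry = region_registry(),
                               seed = 1L, min_n = 50L) {
  baseline <- table[table$visit_index == 0L, ]
  flags <- list()
  fit_one <- function(values, sub_seed, label) {
    res <- tryCatch(
      fit_two_component_mixture(values, seed = sub_seed, min_n = min_n),
      error = function(e) e)
    if (inherits(res, "error")) {
      flags[[label]] <<- c(flags[[label]], "fit_error")
      return(list(fit = NULL, cutoff = NA_real_))
    }
    if (!res$converged)
      flags[[label]] <<- c(flags[[label]], "not_converged")
    if (res$separation < 1)
      flags[[label]] <<- c(flags[[label]], "low_separation")
    cutoff <- cutoff_from_fit(res)
    if (!is.null(attr(cutoff, "flag"))) {
      flags[[label]] <<- c(flags[[label]], attr(cutoff, "flag"))
      cutoff <- as.numeric(cutoff)
    }
    list(fit = res, cutoff = cutoff)
  }

  region_fits <- list(); region_cutoffs <- numeric(0)
  for (i in seq_len(nrow(registry))) {
    rid <- registry$region_id[i]
    r <- fit_one(baseline$suvr[baseline$region_id == rid],
                 sub_seed = (seed + i) %% .Machine$integer.max, label = rid)
    region_fits[[rid]] <- r$fit
    region_cutoffs[rid] <- r$cutoff
  }

  comp <- stage_composite_suvr(table, registry)
  comp <- comp[comp$visit_index == 0L, ]
  stage_cols <- c(paste0("stage_", braak_stage_order()), "meta_roi")
  stage_fits <- list(); stage_cutoffs <- numeric(0)
  for (j in seq_along(stage_cols)) {
    sc <- stage_cols[j]
    r <- fit_one(comp[[sc]],
                 sub_seed = (seed + 1000L + j) %% .Machine$integer.max,
                 label = sc)
    stage_fits[[sc]] <- r$fit
    stage_cutoffs[sc] <- r$cutoff
  }

  out <- list(region_cutoffs = region_cutoffs,
              stage_cutoffs  = stage_cutoffs,
              region_fits    = region_fits,
              stage_fits     = stage_fits,
              flags          = flags)
  class(out) <- "threshold_set"
  out
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Threshold set over", length(x$region_cutoffs), "regions and",
      length(x$stage_cutoffs), "composites\n")
  cat("  regional cutoffs:",
      paste(round(range(x$region_cutoffs, na.rm = TRUE), 3),
            collapse = " - "), "SUVR\n")
  if (length(x$flags))
    cat("  flagged:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}

# run expr under a fixed seed, restoring the caller's RNG state afterwards
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
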