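# Associations between tau measures and cognition; non-nested model
# comparison; FDR control; amyloid-tau logistic link.

#' Per-subject cognitive decline slopes
#'
#' Per composite, fits score ~ years with random slopes and intercepts per
#' subject (REML) over all cognitive visits and returns each subject's
#' slope as fixed effect + predicted (BLUP) random deviation. Subjects with
#' fewer than \code{min_visits} visits are excluded.
#'
#' @param cognition Cognition table (see \code{\link{load_cognition}}).
#' @param min_visits Minimum cognitive visits per subject (default 3,
#'   i.e. more than two timepoints).
#' @return data.frame: subject_id, composite, slope.
#' @export
cognitive_slopes <- function(cognition, min_visits = 3L) {
  out <- NULL
  for (comp in unique(cognition$composite)) {
    d <- cognition[cognition$composite == comp, ]
    nvis <- tapply(d$years_from_first_cognitive_visit, d$subject_id,
                   function(y) length(unique(y)))
    keep <- names(nvis)[nvis >= min_visits]
    d <- d[d$subject_id %in% keep, ]
    if (length(unique(d$subject_id)) < 10L)
      stop("composite ", comp, ": fewer than 10 subjects with >=",
           min_visits, " visits")
    ac <- suppressMessages(annual_change(
      data.frame(subject_id = d$subject_id,
                 years = d$years_from_first_cognitive_visit,
                 value = d$score),
      measure = comp))
    out <- rbind(out, data.frame(subject_id = names(ac$subject_slopes),
                                 composite = comp,
                                 slope = unname(ac$subject_slopes),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Linear association between a tau measure and a cognitive outcome
#'
#' Ordinary least squares of outcome on predictor, adjusted for age, sex
#' and education. The standardized beta is the coefficient after z-scoring
#' outcome and predictor on the analysis subsample (covariates left raw).
#' Pointwise Gaussian log-likelihood contributions (at the ML variance) are
#' retained for Vuong's closeness test; they sum to the model
#' log-likelihood.
#'
#' @param data data.frame with the outcome, predictor and covariate
#'   columns; complete cases only are used.
#' @param outcome,predictor Column names.
#' @param covariates Covariate column names (default age, sex, education).
#' @param min_n Minimum complete cases (default 20).
#' @return Object of class \code{association_result}: \code{beta},
#'   \code{std_beta}, \code{p}, \code{r2_adj}, \code{aic}, \code{n},
#'   \code{pointwise_ll}, \code{loglik}, names and the \code{lm} fit.
#' @export
fit_association <- function(data, outcome, predictor,
                            covariates = c("age", "sex", "education"),
                            min_n = 20L) {
  cols <- c(outcome, predictor, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(d) < min_n)
    stop("fewer than ", min_n, " complete cases (", nrow(d), ")")
  if (stats::sd(d[[predictor]]) == 0)
    stop("zero-variance predictor: ", predictor)
  if (stats::sd(d[[outcome]]) == 0)
    stop("zero-variance outcome: ", outcome)

  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  cf <- stats::coef(sm)
  # z-scoring outcome by 1/sd(y) and predictor by sd(x) rescales the
  # coefficient exactly; no refit needed
  std_beta <- cf[predictor, "Estimate"] *
    stats::sd(d[[predictor]]) / stats::sd(d[[outcome]])
  n <- nrow(d)
  r <- stats::residuals(fit)
  sigma_ml <- sqrt(sum(r^2) / n)
  pll <- stats::dnorm(r, 0, sigma_ml, log = TRUE)

  out <- list(outcome = outcome, predictor = predictor,
              covariates = covariates,
              beta = unname(cf[predictor, "Estimate"]),
              std_beta = unname(std_beta),
              p = unname(cf[predictor, "Pr(>|t|)"]),
              r2_adj = sm$adj.r.squared,
              aic = stats::AIC(fit),
              n = n,
              pointwise_ll = unname(pll),
              loglik = sum(pll),
              fit = fit)
  class(out) <- "association_result"
  out
}

#' Vuong's closeness test for non-nested models of the same outcome
#'
#' z = sum(d_i) / (sqrt(n) * sd(d_i)) where d_i is the pointwise
#' log-likelihood difference (m1 - m2). Negative z favors m2. The one-sided
#' p-value is the standard normal tail in the observed direction,
#' pnorm(-|z|). No AIC-style parameter-count correction is applied: the
#' compared models here have identical parameter counts, so the correction
#' cancels.
#'
#' @param m1,m2 \code{association_result}s fitted to the same observations.
#' @return Object of class \code{vuong_result}: \code{z}, \code{p}
#'   (one-sided), \code{n}, \code{direction} ("m1", "m2" or "tie"),
#'   \code{degenerate} (TRUE when the pointwise log-likelihoods are
#'   identical and z is undefined).
#' @export
vuong_test <- function(m1, m2) {
  if (m1$n != m2$n)
    stop("models fitted on different observation counts (", m1$n, " vs ",
         m2$n, ")")
  if (!identical(m1$outcome, m2$outcome))
    stop("models must share the same outcome")
  d <- m1$pointwise_ll - m2$pointwise_ll
  n <- m1$n
  sdd <- stats::sd(d)
  if (sdd == 0) {
    out <- list(z = NA_real_, p = NA_real_, n = n, direction = "tie",
                degenerate = TRUE)
    class(out) <- "vuong_result"
    return(out)
  }
  z <- sum(d) / (sqrt(n) * sdd)
  out <- list(z = z, p = stats::pnorm(-abs(z)), n = n,
              direction = if (z < 0) "m2" else "m1",
              degenerate = FALSE)
  class(out) <- "vuong_result"
  out
}

#' @export
print.vuong_result <- function(x, ...) {
  if (x$degenerate) cat("Vuong test degenerate: identical pointwise",
                        "log-likelihoods\n")
  else cat(sprintf("Vuong z = %.3f, one-sided p = %.4f (favors %s), n = %d\n",
                   x$z, x$p, x$direction, x$n))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals Numeric p-values in [0, 1].
#' @return Adjusted p-values (step-up).
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Region-wise tau-cognition association maps
#'
#' One adjusted linear model per region (outcome ~ region SUVR + age + sex
#' + education); BH-FDR applied across the regions within the call (i.e.
#' within one group x composite family). Regions whose model cannot be
#' fitted (e.g. constant SUVR) are flagged and do not affect the others.
#'
#' @param suvr_wide data.frame with \code{subject_id} and one SUVR column
#'   per region (baseline visit).
#' @param outcome_df data.frame with \code{subject_id}, the outcome column
#'   and covariates.
#' @param outcome Outcome column name.
#' @param covariates Covariate names.
#' @param alpha FDR level for the survival mask (default 0.05).
#' @return data.frame: region_id, beta, std_beta, p, p_fdr, survives,
#'   flag.
#' @export
regionwise_associations <- function(suvr_wide, outcome_df, outcome,
                                    covariates = c("age", "sex",
                                                   "education"),
                                    alpha = 0.05) {
  regions <- setdiff(names(suvr_wide),
                     c("subject_id", "visit_index",
                       "years_from_first_scan"))
  d <- merge(suvr_wide, outcome_df, by = "subject_id")
  rows <- lapply(regions, function(rid) {
    res <- tryCatch(fit_association(d, outcome, rid, covariates),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(region_id = rid, beta = NA_real_, std_beta = NA_real_,
                 p = NA_real_, flag = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(region_id = rid, beta = res$beta, std_beta = res$std_beta,
                 p = res$p, flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  out$survives <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out
}

#' Logistic model of any tau positivity on amyloid burden
#'
#' P(spatial extent >= 1) as a function of centiloid, by maximum-likelihood
#' logistic regression. Returns the odds ratio per centiloid with a Wald
#' 95% CI. Complete or quasi-complete separation is detected (non-converged
#' fit or extreme coefficients) and flagged; no estimate is reported
#' silently in that case.
#'
#' @param centiloid Per-subject centiloid values.
#' @param extent Per-subject spatial extent index.
#' @param min_n Minimum sample size (default 50).
#' @return List of class \code{extent_logistic}: \code{or}, \code{ci},
#'   \code{log_or}, \code{se}, \code{n}, \code{separation_flag}.
#' @export
extent_logistic <- function(centiloid, extent, min_n = 50L) {
  stopifnot(length(centiloid) == length(extent))
  ok <- is.finite(centiloid) & is.finite(extent)
  y <- as.integer(extent[ok] >= 1L)
  x <- centiloid[ok]
  if (length(y) < min_n) stop("need at least ", min_n, " subjects")
  if (length(unique(y)) < 2L) stop("outcome has no variation")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  b <- stats::coef(fit)["x"]
  se <- sqrt(diag(stats::vcov(fit)))["x"]
  sep <- !fit$converged || abs(b) > 10 || se > 10 ||
    all(abs(fit$fitted.values - 0.5) > 0.4999)
  out <- list(or = if (sep) NA_real_ else unname(exp(b)),
              ci = if (sep) c(NA_real_, NA_real_) else
                unname(exp(b + c(-1, 1) * 1.96 * se)),
              log_or = if (sep) NA_real_ else unname(b),
              se = unname(se), n = length(y), separation_flag = sep)
  class(out) <- "extent_logistic"
  out
}
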