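# grid-scan oracle for the posterior-0.5 point, independent of the
# bracketing/bisection path in cutoff_from_fit
grid_cutoff_oracle <- function(fit, n_grid = 1e6) {
  grid <- seq(fit$mean_lo, fit$mean_hi, length.out = n_grid)
  grid[which.min(abs(posterior_abnormal(grid, fit) - 0.5))]
}

mixfit <- function(w_hi, m_lo, m_hi, s_lo, s_hi) {
  structure(list(weight_lo = 1 - w_hi, weight_hi = w_hi, mean_lo = m_lo,
                 mean_hi = m_hi, sd_lo = s_lo, sd_hi = s_hi),
            class = "mixture_fit")
}

test_that("EM recovers well-separated mixture parameters", {
  set.seed(2024)
  x <- c(rnorm(1400, 1.10, 0.07), rnorm(600, 1.60, 0.15))
  fit <- fit_two_component_mixture(x, seed = 1L)
  expect_true(fit$converged)
  expect_lt(abs(fit$mean_lo - 1.10), 0.02)
  expect_lt(abs(fit$mean_hi - 1.60), 0.02)
  expect_lt(abs(fit$weight_hi - 0.30), 0.05)
  expect_equal(fit$weight_lo + fit$weight_hi, 1)
  expect_gt(fit$sd_lo, 0); expect_gt(fit$sd_hi, 0)
})

test_that("EM agrees with an independent mixture fitter", {
  set.seed(99)
  x <- c(rnorm(1000, 1.12, 0.08), rnorm(500, 1.55, 0.12))
  fit <- fit_two_component_mixture(x, seed = 3L)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this by name
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mc_means <- sort(mc$parameters$mean)
  expect_lt(abs(fit$mean_lo - mc_means[1]), 0.01)
  expect_lt(abs(fit$mean_hi - mc_means[2]), 0.01)
  expect_lt(abs(fit$loglik - mc$loglik), 0.5)
})

test_that("degenerate and mirrored inputs respect the labeling contract", {
  expect_error(fit_two_component_mixture(rep(1.2, 100)), "zero-variance")
  expect_error(fit_two_component_mixture(rnorm(10)), "at least 50")
  set.seed(5)
  x <- c(rnorm(800, 1.1, 0.07), rnorm(400, 1.6, 0.15))
  xm <- 2 * median(x) - x  # mirror: components swap roles
  f1 <- fit_two_component_mixture(x, seed = 2L)
  f2 <- fit_two_component_mixture(xm, seed = 2L)
  expect_lte(f1$mean_lo, f1$mean_hi)
  expect_lte(f2$mean_lo, f2$mean_hi)
  expect_equal(f2$mean_hi, 2 * median(x) - f1$mean_lo, tolerance = 0.02)
})

test_that("symmetric mixtures cut exactly at the midpoint", {
  fit <- mixfit(0.5, 1.2, 1.6, 0.1, 0.1)
  expect_equal(cutoff_from_fit(fit), 1.4, tolerance = 1e-9)
  expect_equal(analytic_cutoff(0.5, 1.2, 1.6, 0.1, 0.1), 1.4,
               tolerance = 1e-9)
})

test_that("asymmetric cutoff matches the brute-force grid oracle", {
  fit <- mixfit(0.3, 1.10, 1.60, 0.07, 0.15)
  cut <- cutoff_from_fit(fit)
  expect_equal(cut, grid_cutoff_oracle(fit), tolerance = 1e-5)
  expect_equal(cut, analytic_cutoff(0.3, 1.10, 1.60, 0.07, 0.15),
               tolerance = 1e-9)
  expect_lt(abs(posterior_abnormal(cut, fit) - 0.5), 1e-8)
  expect_gt(cut, fit$mean_lo); expect_lt(cut, fit$mean_hi)
})

test_that("cutoff decreases monotonically in the abnormal weight", {
  cuts <- vapply(seq(0.1, 0.9, by = 0.1), function(w)
    cutoff_from_fit(mixfit(w, 1.10, 1.60, 0.07, 0.15)), numeric(1))
  expect_true(all(diff(cuts) < 0))
})

test_that("threshold fitting covers all regions deterministically", {
  cfg <- property_config(h = 0, seed = 31L,
                         n = c(CU = 100L, MCI = 100L, AD = 50L))
  sim <- generate_cohort(cfg)
  th1 <- fit_all_thresholds(sim$suvr, REG, seed = 7L)
  th2 <- fit_all_thresholds(sim$suvr, REG, seed = 7L)
  expect_identical(th1, th2)   # bitwise determinism
  expect_setequal(names(th1$region_cutoffs), REG$region_id)
  expect_true(all(is.finite(th1$region_cutoffs)))
  # recovered cutoffs near the analytic posterior-0.5 points
  err <- abs(th1$region_cutoffs[sim$truth$region_params$region_id] -
               sim$truth$region_params$cutoff)
  expect_lt(median(err), 0.02)
  # cutoffs inside the observed range
  rng <- range(sim$suvr$suvr)
  expect_true(all(th1$region_cutoffs > rng[1] &
                    th1$region_cutoffs < rng[2]))
})

test_that("a unimodal region is flagged but still gets a cutoff", {
  cfg <- property_config(h = 0, seed = 77L,
                         n = c(CU = 100L, MCI = 100L, AD = 50L))
  sim <- generate_cohort(cfg)
  # overwrite one region with unimodal draws
  set.seed(1)
  i <- sim$suvr$region_id == "cuneus_left"
  sim$suvr$suvr[i] <- rnorm(sum(i), 1.2, 0.05)
  th <- fit_all_thresholds(sim$suvr, REG, seed = 7L)
  expect_true("cuneus_left" %in% names(th$flags))
  expect_true(is.finite(th$region_cutoffs["cuneus_left"]))
})

test_that("stage composites are unweighted bilateral means", {
  tab <- toy_suvr(list(rep(1.3, 70)), subject_ids = "A")
  comp <- stage_composite_suvr(tab, REG)
  for (col in c(paste0("stage_", braak_stage_order()), "meta_roi"))
    expect_equal(comp[[col]], 1.3)

  # meta-ROI over 12 regions valued 0.1..1.2 -> mean 0.65
  vals <- rep(2, 70)
  meta_ids <- stage_members(REG, "meta_roi")
  vals[match(sort(meta_ids), REG$region_id)] <- (1:12) / 10
  tab2 <- toy_suvr(list(vals), subject_ids = "A")
  expect_equal(stage_composite_suvr(tab2, REG)$meta_roi, 0.65)

  # stage I composite is the mean of the two entorhinal values only
  vals3 <- rep(1.0, 70)
  vals3[match(c("entorhinal_left", "entorhinal_right"),
              REG$region_id)] <- c(1.2, 1.6)
  tab3 <- toy_suvr(list(vals3), subject_ids = "A")
  expect_equal(stage_composite_suvr(tab3, REG)$stage_I, 1.4)
})

test_that("missing member regions abort composite construction", {
  tab <- toy_suvr(list(rep(1.3, 70)), subject_ids = "A")
  broken <- tab[tab$region_id != "entorhinal_left", ]
  expect_error(stage_composite_suvr(broken, REG), "entorhinal_left")
})
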