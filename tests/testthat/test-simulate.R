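test_that("configuration is validated before any sampling", {
  expect_error(synth_config(heterogeneity = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(longitudinal = list(regression_prob = -0.1)),
               "regression_prob")
  expect_error(synth_config(mixture = list(sd_lo = 0)), "positive")
  expect_error(synth_config(nonsense = 1), "unknown config field")
  cfg <- synth_config(seed = 1L)
  expect_s3_class(cfg, "synth_config")
  expect_equal(unname(cfg$longitudinal$rates["MCI"]), 2.5)
})

test_that("the generator is bitwise deterministic under a seed", {
  cfg <- property_config(h = 0.2, seed = 303L,
                         n = c(CU = 30L, MCI = 30L, AD = 15L))
  cfg$longitudinal$n_visits <- 2L
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$suvr, b$suvr)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$cognition, b$cognition)
  expect_identical(a$truth$binary_by_visit, b$truth$binary_by_visit)
  # and does not disturb the caller's RNG stream
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(generate_cohort(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a degenerate stage distribution yields a null cohort", {
  cfg <- synth_config(n = c(CU = 40L, MCI = 0L, AD = 0L),
                      tau_link = list(intercept = -30),  # nobody positive
                      seed = 2L)
  sim <- generate_cohort(cfg)
  expect_true(all(sim$truth$binary_by_visit[[1L]] == 0L))
  expect_true(all(sim$truth$true_extent == 0L))
  expect_true(all(sim$truth$latent_stage == "none"))
})

test_that("analytic cutoff matches a fine grid scan and closed forms", {
  expect_equal(analytic_cutoff(0.5, 1.2, 1.6, 0.1, 0.1), 1.4,
               tolerance = 1e-10)
  # equal weights and sds: midpoint for any means
  expect_equal(analytic_cutoff(0.5, 0.8, 2.1, 0.2, 0.2), 1.45,
               tolerance = 1e-10)
  fit <- structure(list(weight_lo = 0.7, weight_hi = 0.3, mean_lo = 1.10,
                        mean_hi = 1.60, sd_lo = 0.07, sd_hi = 0.15),
                   class = "mixture_fit")
  grid <- seq(1.10, 1.60, length.out = 1e6)
  oracle <- grid[which.min(abs(posterior_abnormal(grid, fit) - 0.5))]
  expect_equal(analytic_cutoff(0.3, 1.10, 1.60, 0.07, 0.15), oracle,
               tolerance = 1e-6)
  expect_error(analytic_cutoff(0.5, 1.6, 1.2, 0.1, 0.1))
})

test_that("emitted SUVR binarized at analytic cutoffs matches the truth", {
  # separation >= 6 pooled sd: shrink the component sds
  cfg <- property_config(h = 0.1, seed = 19L,
                         n = c(CU = 100L, MCI = 100L, AD = 50L),
                         mixture = list(sd_lo = 0.05, sd_hi = 0.07,
                                        jitter_mean = 0.01,
                                        jitter_delta = 0.01))
  sim <- generate_cohort(cfg)
  ts <- flat_thresholds()
  ts$region_cutoffs[sim$truth$region_params$region_id] <-
    sim$truth$region_params$cutoff
  pat <- binarize(sim$suvr, ts, visit_index = 0L)
  got <- as.matrix(pat[attr(pat, "region_cols")])
  want <- sim$truth$binary_by_visit[[1L]][pat$subject_id, ]
  expect_gte(mean(got == want), 0.999)
  # spatial extent equals the cardinality of the positive-region set
  sets <- apply(got, 1, sum)
  expect_equal(unname(pat$spatial_extent), unname(sets))
})

test_that("longitudinal generation respects rates, order and drift", {
  cfg <- property_config(h = 0, seed = 55L,
                         n = c(CU = 50L, MCI = 50L, AD = 25L),
                         longitudinal = list(n_visits = 3L, drift = 0.05,
                                             regression_prob = 0))
  sim <- generate_longitudinal(cfg)
  tb <- sim$truth$binary_by_visit
  # monotone accumulation without regression
  expect_true(all(tb[[2L]] >= tb[[1L]]))
  expect_true(all(tb[[3L]] >= tb[[2L]]))
  # positive regions drift upward in SUVR on average
  always_pos <- tb[[1L]] == 1L & tb[[3L]] == 1L
  s0 <- sim$suvr[sim$suvr$visit_index == 0L, ]
  s2 <- sim$suvr[sim$suvr$visit_index == 2L, ]
  # mean SUVR among always-positive cells rises by ~drift * 2 years
  key0 <- paste(s0$subject_id, s0$region_id)
  key2 <- paste(s2$subject_id, s2$region_id)
  cells <- paste(rep(rownames(always_pos), times = ncol(always_pos)),
                 rep(colnames(always_pos), each = nrow(always_pos)))
  pos_cells <- cells[as.vector(always_pos)]
  expect_gt(mean(s2$suvr[match(pos_cells, key2)]) -
              mean(s0$suvr[match(pos_cells, key0)]), 0.05)
  # frozen cohort: zero hazard and drift
  cfg2 <- property_config(h = 0, seed = 56L,
                          n = c(CU = 30L, MCI = 30L, AD = 15L),
                          longitudinal = list(n_visits = 3L, drift = 0,
                                              regression_prob = 0,
                                              rates = c(CU = 0, MCI = 0,
                                                        AD = 0)))
  sim2 <- generate_cohort(cfg2)
  expect_identical(sim2$truth$binary_by_visit[[1L]],
                   sim2$truth$binary_by_visit[[3L]])
  expect_error(generate_longitudinal(cfg2, n_visits = 1L), ">= 2")
})

test_that("diagnosis spread-rate ordering is recoverable end to end", {
  cfg <- property_config(h = 0.1, seed = 23L,
                         n = c(CU = 60L, MCI = 60L, AD = 40L))
  sim <- generate_longitudinal(cfg, n_visits = 3L)
  ts <- flat_thresholds()
  ts$region_cutoffs[sim$truth$region_params$region_id] <-
    sim$truth$region_params$cutoff
  pat <- binarize(sim$suvr, ts)
  slopes <- vapply(c("CU", "MCI", "AD"), function(g) {
    ids <- sim$metadata$subject_id[sim$metadata$diagnosis == g]
    d <- pat[pat$subject_id %in% ids, ]
    annual_change(data.frame(subject_id = d$subject_id,
                             years = d$years_from_first_scan,
                             value = d$spatial_extent), g)$slope
  }, numeric(1))
  expect_gt(slopes["MCI"], slopes["CU"])
  expect_gt(slopes["MCI"], slopes["AD"])
})

test_that("ground-truth extent drives the cognition composites", {
  cfg <- property_config(h = 0, seed = 67L,
                         n = c(CU = 150L, MCI = 150L, AD = 100L))
  sim <- generate_cohort(cfg)
  base <- sim$cognition[
    sim$cognition$years_from_first_cognitive_visit == 0 &
      sim$cognition$composite == "memory", ]
  ext <- sim$truth$true_extent[base$subject_id]
  expect_lt(cor(base$score, ext), -0.3)  # tau burden degrades cognition
  # true decline slopes steepen with extent
  ts <- sim$truth$cognitive_slopes
  tm <- ts[ts$composite == "memory", ]
  expect_lt(cor(tm$slope, sim$truth$true_extent[tm$subject_id]), -0.3)
})
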