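test_that("progression labels implement the 2x2 state mapping", {
  f <- matrix(c(0L, 1L, 0L, 1L), 1, 4)
  l <- matrix(c(0L, 1L, 1L, 0L), 1, 4)
  first <- pattern_from_matrix(cbind(f, matrix(0L, 1, 66)),
                               subject_ids = "A")
  last <- pattern_from_matrix(cbind(l, matrix(0L, 1, 66)),
                              subject_ids = "A", visit_index = 1L)
  pm <- progression_states(first, last)
  expect_equal(unname(pm[1, 1:4]),
               c("stable_negative", "stable_positive", "progressor",
                 "regressor"))
})

test_that("state counts match independent 2x2 tabulation on random data", {
  set.seed(21)
  n <- 40
  fm <- matrix(rbinom(n * 70, 1, 0.3), n, 70)
  lm_ <- matrix(rbinom(n * 70, 1, 0.5), n, 70)
  rownames(fm) <- rownames(lm_) <- sprintf("S%02d", 1:n)
  pm <- progression_states(pattern_from_matrix(fm),
                           pattern_from_matrix(lm_, visit_index = 1L))
  counts <- table(factor(unclass(pm),
                         levels = c("stable_negative", "stable_positive",
                                    "progressor", "regressor")))
  # oracle: direct cell-by-cell tabulation
  oracle <- c(sum(fm == 0 & lm_ == 0), sum(fm == 1 & lm_ == 1),
              sum(fm == 0 & lm_ == 1), sum(fm == 1 & lm_ == 0))
  expect_equal(unname(as.vector(counts)), oracle)
  # identity pair -> everything stable
  pm2 <- progression_states(pattern_from_matrix(fm),
                            pattern_from_matrix(fm, visit_index = 1L))
  expect_false(any(unclass(pm2) %in% c("progressor", "regressor")))
  # label frequencies invariant under region permutation
  perm <- sample(70)
  pm3 <- progression_states(pattern_from_matrix(fm[, perm]),
                            pattern_from_matrix(lm_[, perm],
                                                visit_index = 1L))
  expect_equal(table(unclass(pm3)), table(unclass(pm)))
})

test_that("single-visit subjects are excluded from progression", {
  sim <- generate_longitudinal(property_config(h = 0.1, seed = 9L,
                                               n = c(CU = 30L, MCI = 30L,
                                                     AD = 15L)))
  tab <- sim$suvr
  # truncate one subject to a single visit
  solo <- tab$subject_id[1L]
  tab <- tab[!(tab$subject_id == solo & tab$visit_index > 0L), ]
  ts <- flat_thresholds()
  ts$region_cutoffs[sim$truth$region_params$region_id] <-
    sim$truth$region_params$cutoff
  fl <- first_last_patterns(tab, ts, min_scans = 2L)
  expect_false(solo %in% fl$first$subject_id)
  expect_setequal(fl$first$subject_id, fl$last$subject_id)
})

test_that("longitudinal conformance requires the chain below new stages", {
  mk <- function(first, last) {
    braak_conformance_long(stage_pos_df(rbind(first),
                                        subject_ids = "s"),
                           stage_pos_df(rbind(last), subject_ids = "s",
                                        visit_index = 1L))
  }
  # became positive on IV; III and I already positive -> conforming
  ok <- mk(c(1, 1, 0, 0, 0), c(1, 1, 1, 0, 0))
  expect_true(ok$per_subject$conforms)
  # became positive on V while III never positive -> gap in the chain
  bad <- mk(c(1, 0, 1, 0, 0), c(1, 0, 1, 1, 0))
  expect_false(bad$per_subject$conforms)
  # progressed on an earlier stage during follow-up also satisfies chain
  both <- mk(c(1, 0, 1, 0, 0), c(1, 1, 1, 1, 0))
  expect_true(both$per_subject$conforms)
  # no stage change -> excluded from the denominator
  none <- mk(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0))
  expect_equal(none$n_progressed, 0L)
  expect_true(is.na(none$per_subject$conforms))
})

test_that("longitudinal conformance on a three-subject toy cohort", {
  f <- rbind(a = c(1, 0, 0, 0, 0),
             b = c(0, 0, 0, 0, 0),
             c = c(1, 1, 1, 0, 0))
  l <- rbind(a = c(1, 1, 0, 0, 0),   # progressed III, chain ok
             b = c(0, 0, 1, 0, 0),   # progressed IV, I and III missing
             c = c(1, 1, 1, 0, 0))   # no change, excluded
  cl <- braak_conformance_long(stage_pos_df(f),
                               stage_pos_df(l, visit_index = 1L))
  expect_equal(cl$n_progressed, 2L)
  expect_equal(cl$overall_pct, 50)
  expect_equal(cl$per_stage$pct_conforming[cl$per_stage$stage == "III"],
               100)
  expect_equal(cl$per_stage$pct_conforming[cl$per_stage$stage == "IV"], 0)
})

test_that("noise-free linear trajectories recover the exact slope", {
  d <- expand.grid(subject_id = sprintf("S%02d", 1:15), years = 0:2)
  d$value <- 1 + 2.5 * d$years  # identical perfect lines
  ac <- annual_change(d, "toy")
  expect_equal(ac$slope, 2.5, tolerance = 1e-6)
  expect_lt(ac$random_slope_sd, 1e-3)
  expect_equal(unname(ac$subject_slopes), rep(2.5, 15), tolerance = 1e-6)
  # mixed-model slope equals per-subject OLS slope on noise-free data
  ols <- unname(coef(lm(value ~ years, d[d$subject_id == "S01", ]))[2])
  expect_equal(ac$slope, ols, tolerance = 1e-6)
})

test_that("mixed model recovers heterogeneous subject slopes", {
  set.seed(314)
  n <- 60
  slopes <- rnorm(n, 2.5, 0.5)
  d <- do.call(rbind, lapply(1:n, function(i)
    data.frame(subject_id = sprintf("S%03d", i), years = 0:2,
               value = 10 + slopes[i] * (0:2) + rnorm(3, 0, 1))))
  ac <- annual_change(d, "extent")
  expect_gt(ac$ci[1], 2.0); expect_lt(ac$ci[2], 3.0)
  expect_true(ac$ci[1] <= 2.5 && 2.5 <= ac$ci[2])
  # per-subject slopes track the generating slopes
  expect_gt(cor(slopes, unname(ac$subject_slopes)), 0.5)
})

test_that("single-visit subjects drop without changing the estimate", {
  set.seed(27)
  d <- do.call(rbind, lapply(1:20, function(i)
    data.frame(subject_id = sprintf("S%02d", i), years = 0:2,
               value = 5 + 1.2 * (0:2) + rnorm(3, 0, 0.5))))
  extra <- data.frame(subject_id = "LONE", years = 0, value = 99)
  a1 <- suppressMessages(annual_change(rbind(d, extra), "m"))
  a2 <- annual_change(d, "m")
  expect_equal(a1$slope, a2$slope)
  expect_equal(a1$n_subjects, a2$n_subjects)
})

test_that("zero regression probability yields zero regressors", {
  cfg <- property_config(h = 0.1, seed = 41L,
                         n = c(CU = 40L, MCI = 40L, AD = 20L),
                         longitudinal = list(n_visits = 3L,
                                             regression_prob = 0))
  sim <- generate_cohort(cfg)
  tb <- sim$truth$binary_by_visit
  expect_false(any(tb[[1L]] == 1L & tb[[3L]] == 0L))
  ts <- flat_thresholds()
  ts$region_cutoffs[sim$truth$region_params$region_id] <-
    sim$truth$region_params$cutoff
  # truth-level states: monotone trajectories, no regressor
  pm <- progression_states(
    pattern_from_matrix(tb[[1L]]),
    pattern_from_matrix(tb[[3L]], visit_index = 2L))
  expect_equal(sum(unclass(pm) == "regressor"), 0L)
})
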