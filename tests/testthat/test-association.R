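make_assoc_data <- function(n = 300, beta = -0.03, seed = 1) {
  set.seed(seed)
  d <- data.frame(extent = rpois(n, 8),
                  age = rnorm(n, 74, 8),
                  sex = sample(c("F", "M"), n, replace = TRUE),
                  education = round(rnorm(n, 16, 2.5)))
  d$memory <- 1 - 0.01 * (d$age - 74) + 0.02 * (d$education - 16) +
    beta * d$extent + rnorm(n, 0, 0.4)
  d
}

test_that("a perfect predictor yields standardized beta and R2 of one", {
  d <- data.frame(y = rnorm(50))
  d$x <- d$y
  res <- fit_association(d, "y", "x", covariates = character(0))
  expect_equal(res$std_beta, 1, tolerance = 1e-10)
  expect_equal(res$r2_adj, 1, tolerance = 1e-10)
})

test_that("adjusted OLS recovers a planted effect within its CI", {
  d <- make_assoc_data(n = 300, beta = -0.03, seed = 42)
  res <- fit_association(d, "memory", "extent")
  se <- summary(res$fit)$coefficients["extent", "Std. Error"]
  expect_true(abs(res$beta - (-0.03)) < 1.96 * se)
  expect_lt(res$p, 0.05)
  # standardized beta equals the z-scored refit coefficient
  d2 <- d; d2$memory <- scale(d$memory)[, 1]; d2$extent <- scale(d$extent)[, 1]
  ref <- lm(memory ~ extent + age + sex + education, d2)
  expect_equal(res$std_beta, unname(coef(ref)["extent"]), tolerance = 1e-10)
  # pointwise log-likelihoods sum to the model log-likelihood
  expect_equal(sum(res$pointwise_ll), as.numeric(logLik(res$fit)),
               tolerance = 1e-8)
  # error contracts
  d$flat <- 1
  expect_error(fit_association(d, "memory", "flat"), "zero-variance")
  expect_error(fit_association(d[1:5, ], "memory", "extent"), "fewer than")
})

test_that("p-values are uniform under a permuted (null) outcome", {
  d <- make_assoc_data(n = 120, beta = 0, seed = 7)
  set.seed(99)
  ps <- replicate(500, {
    d$mem_perm <- sample(d$memory)
    fit_association(d, "mem_perm", "extent")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Vuong statistic is antisymmetric and matches printed tails", {
  d <- make_assoc_data(n = 200, seed = 3)
  d$metaroi <- 1.2 + 0.03 * d$extent + rnorm(200, 0, 0.1)
  m1 <- fit_association(d, "memory", "extent")
  m2 <- fit_association(d, "memory", "metaroi")
  v12 <- vuong_test(m1, m2); v21 <- vuong_test(m2, m1)
  expect_equal(v12$z, -v21$z, tolerance = 1e-12)
  expect_equal(v12$p, v21$p, tolerance = 1e-12)
  # identical models degenerate with an explicit flag
  vid <- vuong_test(m1, m1)
  expect_true(vid$degenerate)
  expect_true(is.na(vid$z))
  # one-sided normal tail reproduces the printed (z, p) pairs
  expect_equal(round(pnorm(-abs(-1.92)), 3), 0.027)
  expect_equal(round(pnorm(-abs(-1.13)), 2), 0.13)
  expect_equal(round(pnorm(-abs(0.01)), 2), 0.50)
  # AIC difference and Vuong direction agree in sign for equal
  # parameter counts
  expect_equal(v12$direction == "m1", m1$aic < m2$aic)
})

test_that("BH adjustment matches the step-up formula oracle", {
  # independent oracle: cummin of sorted p * m / i, mapped back
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m:1)))[ro]
  }
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(15)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))^2
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("region-wise maps recover a planted signal and isolate errors", {
  set.seed(123)
  n <- 150
  suvr_wide <- data.frame(subject_id = sprintf("S%03d", 1:n))
  for (r in REG$region_id) suvr_wide[[r]] <- rnorm(n, 1.2, 0.1)
  planted <- REG$region_id[7]
  out_df <- data.frame(subject_id = suvr_wide$subject_id,
                       age = rnorm(n, 74, 8),
                       sex = sample(c("F", "M"), n, TRUE),
                       education = round(rnorm(n, 16, 2)))
  out_df$y <- -0.5 * scale(suvr_wide[[planted]])[, 1] + rnorm(n, 0, 0.5)
  suvr_wide[[REG$region_id[9]]] <- 1.0  # constant region
  res <- regionwise_associations(suvr_wide, out_df, "y")
  expect_equal(nrow(res), 70L)
  expect_true(res$survives[res$region_id == planted])
  expect_equal(which.max(abs(res$std_beta)),
               which(res$region_id == planted))
  flagged <- res[res$region_id == REG$region_id[9], ]
  expect_false(flagged$flag == "")
  expect_true(is.na(flagged$p))
  expect_equal(sum(res$flag != ""), 1L)
})

test_that("logistic extent model recovers the generating odds ratio", {
  set.seed(31)
  n <- 800
  cl <- rnorm(n, 40, 30)
  p <- plogis(-2.5 + log(1.04) * cl)
  ext <- rbinom(n, 1, p) * rpois(n, 3)
  res <- extent_logistic(cl, ext)
  expect_false(res$separation_flag)
  expect_true(res$ci[1] < 1.04 && 1.04 < res$ci[2])
  # perfectly separated data are flagged, never silently estimated
  sep <- extent_logistic(c(rnorm(100, -50, 1), rnorm(100, 50, 1)),
                         rep(c(0L, 5L), each = 100))
  expect_true(sep$separation_flag)
  expect_true(is.na(sep$or))
  expect_error(extent_logistic(1:30, rep(1, 30)), "at least 50")
})

test_that("cognitive slopes come from mixed models per composite", {
  # noise-free decline: every subject slope exactly -0.1
  cg <- do.call(rbind, lapply(1:15, function(i)
    data.frame(subject_id = sprintf("S%02d", i),
               years_from_first_cognitive_visit = 0:3,
               composite = "memory",
               score = 1 - 0.1 * (0:3))))
  sl <- cognitive_slopes(cg)
  expect_equal(sl$slope, rep(-0.1, 15), tolerance = 1e-6)
  # single-visit subjects are excluded
  cg2 <- rbind(cg, data.frame(subject_id = "LONE",
                              years_from_first_cognitive_visit = 0,
                              composite = "memory", score = 0))
  sl2 <- suppressMessages(cognitive_slopes(cg2))
  expect_false("LONE" %in% sl2$subject_id)
  # recovery of heterogeneous slopes on generator output, where the
  # extent-linked decline dominates the slope variance
  cfg <- property_config(h = 0, seed = 131L,
                         n = c(CU = 60L, MCI = 60L, AD = 40L),
                         cognition = list(n_visits = 5L))
  sim <- generate_cohort(cfg)
  sl3 <- cognitive_slopes(sim$cognition)
  truth3 <- sim$truth$cognitive_slopes
  j <- merge(sl3, truth3, by = c("subject_id", "composite"))
  expect_gt(cor(j$slope.x, j$slope.y), 0.8)
})
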