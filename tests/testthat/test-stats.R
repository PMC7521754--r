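test_that("one-factor engine reproduces the hand-computed ANOVA", {
  d <- data.frame(length = c(1, 2, 3, 2, 3, 4),
                  status = rep(c("MR", "FR"), each = 3))
  an <- mfbc:::factorial_anova(d, "status", ss_type = 2)
  expect_equal(an$F[1], 1.5)
  expect_equal(an$Df[1], 1)
  expect_equal(an$Df_res, 4)
  # same groups with a constant year are gated by the two-way analysis
  d$year_label <- 2014
  res <- two_way_anova(d)
  expect_equal(res$gate, "skipped_single_year")
  expect_true(is.na(res$status_F))
})

test_that("identical MR and FR samples give a zero status F", {
  base <- data.frame(length = c(10, 12, 14, 11, 13, 15),
                     year_label = rep(2012:2014, 2))
  d <- rbind(cbind(base, status = "MR"), cbind(base, status = "FR"))
  res <- two_way_anova(d)
  expect_equal(res$gate, "analyzed")
  expect_equal(res$status_F, 0, tolerance = 1e-12)
  expect_equal(res$partial_eta_sq_status, 0, tolerance = 1e-12)
})

test_that("balanced two-way design matches the closed form for all SS types", {
  set.seed(6)
  cells <- expand.grid(status = c("MR", "FR"), year_label = 2012:2014)
  d <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(status = cells$status[i], year_label = cells$year_label[i],
               length = rnorm(4, mean = 50 +
                                3 * (cells$status[i] == "MR") +
                                2 * (cells$year_label[i] - 2012)))
  }))
  # closed-form balanced two-way ANOVA (additive model): residual pools the
  # within-cell and interaction sums of squares
  n <- 4; a <- 2; b <- 3; N <- n * a * b
  grand <- mean(d$length)
  am <- tapply(d$length, d$status, mean)
  bm <- tapply(d$length, d$year_label, mean)
  cm <- tapply(d$length, interaction(d$status, d$year_label), mean)
  ss_a <- n * b * sum((am - grand)^2)
  ss_b <- n * a * sum((bm - grand)^2)
  cell_of <- interaction(d$status, d$year_label)
  ss_w <- sum((d$length - cm[cell_of])^2)
  ss_ab <- n * sum((as.vector(cm) -
                      as.vector(outer(am - grand, bm - grand, "+")) -
                      grand)^2)
  df_res <- N - a - b + 1
  f_a <- (ss_a / (a - 1)) / ((ss_w + ss_ab) / df_res)
  f_b <- (ss_b / (b - 1)) / ((ss_w + ss_ab) / df_res)
  for (type in 1:3) {
    res <- two_way_anova(d, ss_type = type)
    expect_equal(res$status_F, f_a, tolerance = 1e-10)
    expect_equal(res$year_F, f_b, tolerance = 1e-10)
    expect_equal(res$residual_DF, df_res)
  }
})

test_that("degenerate cohorts are gated, not fitted", {
  one_status <- data.frame(length = rnorm(10), status = "MR",
                           year_label = rep(2013:2014, 5))
  expect_equal(two_way_anova(one_status)$gate, "skipped_single_status")
  confounded <- data.frame(
    length = rnorm(8),
    status = rep(c("MR", "FR"), each = 4),
    year_label = rep(c(2013, 2014), each = 4))
  expect_equal(two_way_anova(confounded)$gate, "skipped_collinear")
})

test_that("a posteriori power follows the noncentral-F convention", {
  # zero effect: power equals the test size exactly
  expect_equal(posthoc_power(0, 1, 50, alpha = 0.05), 0.05, tolerance = 1e-12)
  expect_equal(posthoc_power(0, 3, 11, alpha = 0.10), 0.10, tolerance = 1e-12)
  # strictly increasing in effect size and in residual df
  f2 <- seq(0, 1, by = 0.1)
  eta <- f2 / (1 + f2)
  pw <- vapply(eta, posthoc_power, 0, u = 1, v = 30)
  expect_true(all(diff(pw) > 0))
  pv <- vapply(c(5, 10, 20, 50, 100), function(v) {
    posthoc_power(0.2, 1, v)
  }, 0)
  expect_true(all(diff(pv) > 0))
  expect_error(posthoc_power(1, 1, 10), "\\[0, 1\\)")
  expect_error(posthoc_power(-0.1, 1, 10), "\\[0, 1\\)")
})

test_that("noncentral-F power matches a Monte-Carlo rejection rate", {
  # two groups of 51 (u = 1, v = 100), true difference d = 1, sigma = 1:
  # lambda = n*d^2/2 = 25.5 = f2*(u+v+1) with f2 = 0.25.
  set.seed(123)
  nrep <- 200000
  n <- 51; d <- 1
  xb1 <- rnorm(nrep, 0, sqrt(1 / n))
  xb2 <- rnorm(nrep, d, sqrt(1 / n))
  s2 <- rchisq(nrep, df = 2 * n - 2) / (2 * n - 2)
  fstat <- (xb2 - xb1)^2 / (s2 * 2 / n)
  rej <- mean(fstat > qf(0.95, 1, 100))
  pw <- posthoc_power(0.25 / 1.25, u = 1, v = 100, alpha = 0.05)
  expect_lt(abs(rej - pw), 0.005)
})

test_that("summary table applies the midpoint percent-difference convention", {
  obs <- data.frame(
    fish_id = letters[1:8],
    status = rep(c("MR", "FR"), each = 4),
    age = rep(1L, 8), year_label = rep(2011:2014, 2),
    length = c(80, 82, 78, 80, 70, 72, 68, 70))
  tab <- cohort_summary_table(obs)
  expect_equal(tab$mr_mean, 80)
  expect_equal(tab$fr_mean, 70)
  expect_equal(tab$absolute_diff, 10)
  expect_equal(tab$percent_diff, 100 * 10 / 75)
  expect_equal(tab$mr_se, sd(c(80, 82, 78, 80)) / 2)
  # equal means: zero differences
  expect_equal(unname(mean_difference(55, 55)), c(0, 0))
  # a status absent at an age leaves difference cells empty
  solo <- obs[obs$status == "MR", ]
  solo$age <- 2L
  tab2 <- cohort_summary_table(rbind(obs, solo))
  expect_true(is.na(tab2$fr_mean[tab2$age == 2]))
  expect_true(is.na(tab2$absolute_diff[tab2$age == 2]))
})

test_that("cohort-level ANOVA table carries gates and Holm column", {
  sim <- simulate_population(sim_config(rng_seed = 77))
  obs <- suppressWarnings(predict(mfbc(sim$fish)))
  res <- cohort_anova(obs)
  expect_s3_class(res, "cohort_anova")
  expect_equal(res$age, 1:12)
  # the oldest age has a single year class and is gated
  expect_equal(res$gate[res$age == 12], "skipped_single_year")
  ok <- res$gate == "analyzed"
  expect_true(all(res$status_DF[ok] == 1))
  expect_equal(res$year_DF[ok], (12 - res$age - 1)[ok] + 1)
  expect_true(all(res$power[ok] >= 0 & res$power[ok] <= 1))
  expect_true(all(res$status_p_holm[ok] >= res$status_p[ok] - 1e-12))
})
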