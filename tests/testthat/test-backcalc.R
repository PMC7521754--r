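test_that("allometric fit recovers generating constants on exact data", {
  set.seed(7)
  R <- runif(50, 0.2, 2.5)
  rec <- records_on_curve(R, a = 10, b = 20, cc = 2)
  fit <- mfbc(rec)
  co <- coef(fit)
  expect_equal(co[["a"]], 10, tolerance = 1e-6)
  expect_equal(co[["b"]], 20, tolerance = 1e-6)
  expect_equal(co[["c"]], 2, tolerance = 1e-6)
})

test_that("allometric fit handles the linear special case", {
  set.seed(8)
  R <- runif(40, 0.5, 3)
  rec <- records_on_curve(R, a = 5, b = 3, cc = 1)
  co <- coef(mfbc(rec))
  expect_equal(co[["a"]], 5, tolerance = 1e-4)
  expect_equal(co[["b"]], 3, tolerance = 1e-4)
  expect_equal(co[["c"]], 1, tolerance = 1e-4)
})

test_that("degenerate designs are rejected", {
  rec <- records_on_curve(rep(1.4, 6), a = 10, b = 20, cc = 2)
  expect_error(mfbc(rec), "degenerate")
  rec4 <- records_on_curve(c(0.5, 0.9, 1.4, 2.1), a = 10, b = 20, cc = 2)
  expect_error(mfbc(rec4), "at least 5")
})

test_that("anchors follow the mean-first-annulus rule and overrides", {
  R <- c(0.4, 0.8, 1.2, 1.6, 2.0)
  rec <- fish_records(
    fish_id = paste0("f", 1:5), status = "MR", site = "s",
    capture_year = 2015, age_at_capture = 2,
    length_capture = 10 + 20 * R^2, radius_capture = R,
    radii = lapply(R, function(r) c(ifelse(r == 0.4, 0.2, 0.4), r * 0.9))
  )
  fit <- mfbc(rec)
  # four fish have r1 = 0.4, one has 0.2
  expect_equal(coef(fit)[["R0p"]], mean(c(0.2, rep(0.4, 4))))
  # L0p is the allometric prediction at R0p
  co <- coef(fit)
  expect_equal(co[["L0p"]],
               co[["a"]] + co[["b"]] * co[["R0p"]]^co[["c"]])
  # overrides are honoured verbatim
  fit2 <- mfbc(rec, R0p_override = 1, L0p_override = 30)
  expect_equal(coef(fit2)[["R0p"]], 1)
  expect_equal(coef(fit2)[["L0p"]], 30)
  expect_equal(unname(fit2$provenance[c("R0p", "L0p")]),
               c("override", "override"))
})

test_that("anchor arithmetic: params (10,20,2) at R0p = 1 give L0p = 30", {
  expect_equal(length_from_radius(1, 10, 20, 2), 30)
})

test_that("modified Fry formula reproduces the hand-computed log-midpoint", {
  li <- mfbc_length(sqrt(10), L_cpt = 100, R_cpt = 10, a = 10,
                    L0p = 20, R0p = 1)
  expect_equal(li, 40, tolerance = 1e-12)
})

test_that("endpoint identities and monotonicity hold on random valid inputs", {
  set.seed(42)
  for (k in 1:200) {
    p <- random_mfbc_params()
    expect_equal(
      mfbc_length(p$R_cpt, p$L_cpt, p$R_cpt, p$a, p$L0p, p$R0p),
      p$L_cpt, tolerance = 1e-9)
    expect_equal(
      mfbc_length(p$R0p, p$L_cpt, p$R_cpt, p$a, p$L0p, p$R0p),
      p$L0p, tolerance = 1e-9)
    ri <- sort(runif(5, 0.5 * p$R0p, 1.2 * p$R_cpt))
    li <- mfbc_length(ri, p$L_cpt, p$R_cpt, p$a, p$L0p, p$R0p)
    expect_true(all(diff(li) > 0))
    # interior radii give lengths between the anchors
    mid <- runif(1, p$R0p, p$R_cpt)
    lm_ <- mfbc_length(mid, p$L_cpt, p$R_cpt, p$a, p$L0p, p$R0p)
    expect_gte(lm_, p$L0p)
    expect_lte(lm_, p$L_cpt)
  }
})

test_that("formula domain errors name the offending quantity", {
  expect_error(mfbc_length(1, 5, 10, a = 10, L0p = 20, R0p = 0.5), "L_cpt")
  expect_error(mfbc_length(1, 100, 10, a = 10, L0p = 8, R0p = 0.5), "L0p")
  expect_error(mfbc_length(-1, 100, 10, a = 10, L0p = 20, R0p = 0.5), "Ri")
  expect_error(mfbc_length(1, 100, 10, a = 10, L0p = 20, R0p = 10),
               "degenerate anchors")
})

test_that("noise-free generative recovery: back-calculation is exact", {
  sim <- simulate_exact_quota(seed = 13)
  fit <- mfbc(sim$fish)
  obs <- predict(fit)
  truth <- sim$truth
  key_o <- paste(obs$fish_id, obs$age)
  key_t <- paste(truth$fish_id, truth$annulus)
  m <- match(key_o, key_t)
  expect_false(anyNA(m))
  rel <- abs(obs$length - truth$true_length[m]) / truth$true_length[m]
  expect_lt(max(rel), 1e-6)
})

test_that("capture-radius mode returns the capture length at the capture age", {
  sim <- simulate_population(sim_config(n_fish = c(MR = 20, FR = 20),
                                        rng_seed = 31))
  fit <- mfbc(sim$fish)
  obs <- suppressWarnings(predict(fit, capture_age = "capture_radius"))
  f <- as.data.frame(sim$fish)
  f <- f[!duplicated(f$fish_id), ]
  cap <- obs[obs$age == obs$age_at_capture, ]
  m <- match(cap$fish_id, f$fish_id)
  expect_equal(cap$length, f$length_capture[m], tolerance = 1e-12)
})

test_that("per-fish anchor mode pins each fish's first annulus to the curve", {
  sim <- simulate_exact_quota(seed = 17)
  fit <- mfbc(sim$fish, r0p_mode = "per_fish")
  expect_null(fit$anchors)
  obs <- predict(fit)
  truth <- sim$truth
  m <- match(paste(obs$fish_id, obs$age),
             paste(truth$fish_id, truth$annulus))
  rel <- abs(obs$length - truth$true_length[m]) / truth$true_length[m]
  expect_lt(max(rel), 1e-6)
})

test_that("each fish of age A contributes exactly A observations", {
  sim <- simulate_exact_quota(seed = 19)
  obs <- predict(mfbc(sim$fish))
  per_fish <- table(obs$fish_id)
  f <- as.data.frame(sim$fish)
  f <- f[!duplicated(f$fish_id), ]
  expect_equal(as.integer(per_fish[f$fish_id]), f$age_at_capture)
  # pooled per-age counts are the cumulative tails of the original counts
  mr_pool <- vapply(1:12, function(a) {
    sum(obs$status == "MR" & obs$age == a)
  }, 0L)
  fr_pool <- vapply(1:12, function(a) {
    sum(obs$status == "FR" & obs$age == a)
  }, 0L)
  expect_equal(mr_pool, pooled_counts(mr_age_counts))
  expect_equal(fr_pool, pooled_counts(fr_age_counts))
  expect_true(all(diff(mr_pool) <= 0))
})

test_that("a single age-1 fish yields exactly one observation", {
  R <- c(0.5, 0.8, 1.1, 1.5, 2.0)
  rec <- records_on_curve(R, a = 10, b = 20, cc = 2, ages = 1L)
  obs <- predict(mfbc(rec))
  expect_equal(nrow(obs), 5)
  expect_true(all(obs$age == 1))
})

test_that("model methods are coherent", {
  sim <- simulate_population(sim_config(n_fish = c(MR = 30, FR = 30),
                                        rng_seed = 23))
  fit <- mfbc(sim$fish)
  expect_output(print(fit), "Modified Fry")
  expect_output(print(summary(fit)), "provenance")
  expect_equal(length(residuals(fit)), fit$n_fish)
  expect_equal(fitted(fit) + residuals(fit), fit$fish$length_capture)
  s <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(s), c(fit$n_fish, 3L))
})
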