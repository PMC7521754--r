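test_that("wide-format reader builds one record per fish with all annuli", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_wide_fish_csv(path, radii = c(0.2, 0.35, 0.5), radius_capture = 0.55)
  rec <- read_fish_table(path)
  expect_s3_class(rec, "fish_records")
  expect_equal(length(unique(rec$fish_id)), 1)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$radius, c(0.2, 0.35, 0.5))
  expect_equal(rec$annulus, 1:3)
})

test_that("non-monotonic radii are rejected, naming the fish", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_wide_fish_csv(path, radii = c(0.2, 0.5, 0.35))
  expect_error(read_fish_table(path), "f1.*strictly increasing")
})

test_that("missing required columns give a schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(fish_id = "f1", status = "MR", site = "s",
                   capture_year = 2015, age_at_capture = 1,
                   length_capture = 40)
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_fish_table(path), "radius_capture")
})

test_that("long format round-trips and equals the wide reading", {
  path_w <- withr::local_tempfile(fileext = ".csv")
  path_l <- withr::local_tempfile(fileext = ".csv")
  write_wide_fish_csv(path_w)
  rec <- read_fish_table(path_w)
  utils::write.csv(as.data.frame(rec), path_l, row.names = FALSE)
  rec2 <- read_fish_table(path_l)
  expect_equal(as.data.frame(rec2), as.data.frame(rec))
})

test_that("validation enforces every per-fish invariant", {
  ok <- fish_records("a", "MR", "s", 2015, 3, 50, 0.6,
                     list(c(0.2, 0.3, 0.5)))
  expect_s3_class(ok, "fish_records")
  # radii exceeding capture radius
  expect_error(
    fish_records("a", "MR", "s", 2015, 2, 50, 0.25, list(c(0.2, 0.3))),
    "exceeds radius at capture")
  # non-positive radius
  expect_error(
    fish_records("a", "MR", "s", 2015, 2, 50, 0.5, list(c(-0.1, 0.3))),
    "positive")
  # wrong annulus count vs age
  bad <- as.data.frame(ok)
  bad <- bad[bad$annulus < 3, ]
  expect_error(validate_fish_records(bad), "one radius per annulus")
  # bad status
  expect_error(
    fish_records("a", "XX", "s", 2015, 1, 50, 0.5, list(0.2)),
    "MR or FR")
  # non-positive capture length
  expect_error(
    fish_records("a", "FR", "s", 2015, 1, -3, 0.5, list(0.2)),
    "length at capture")
})

test_that("mixed capture years warn but validate", {
  rec <- fish_records(c("a", "b"), c("MR", "FR"), "s", c(2014, 2015),
                      c(1, 1), c(40, 41), c(0.5, 0.5),
                      list(0.3, 0.3), validate = FALSE)
  expect_warning(validate_fish_records(rec), "several capture years")
})

test_that("validation accepts all generated records and rejects perturbations", {
  set.seed(11)
  for (k in 1:10) {
    sim <- simulate_population(sim_config(
      n_fish = c(MR = 8, FR = 8), max_age = 6,
      age_weights = list(MR = rep(1, 6), FR = rep(1, 6)),
      sampling = "multinomial", rng_seed = 1000 + k))
    expect_silent(validate_fish_records(sim$fish))
    bad <- as.data.frame(sim$fish)
    mode <- k %% 3
    if (mode == 0) {
      i <- which(bad$annulus == 2)[1]
      bad$radius[i] <- -bad$radius[i]          # negative radius
    } else if (mode == 1) {
      i <- which(bad$annulus == bad$age_at_capture)[1]
      bad$radius[i] <- bad$radius_capture[i] * 2  # radius beyond capture
    } else {
      id <- bad$fish_id[bad$annulus == 3][1]
      f <- bad$fish_id == id & bad$annulus %in% 2:3
      bad$radius[f] <- rev(bad$radius[f])      # non-monotonic
    }
    expect_error(validate_fish_records(bad))
  }
})

test_that("reference MR age quota yields 111 fish", {
  sim <- simulate_exact_quota(seed = 3)
  fish <- sim$fish
  mr_ids <- unique(fish$fish_id[fish$status == "MR"])
  expect_equal(length(mr_ids), 111)
})

test_that("observations round-trip through CSV at full precision", {
  sim <- simulate_exact_quota(seed = 5)
  obs <- predict(mfbc(sim$fish))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_identical(back$length, obs$length)
  expect_identical(back$year_label, obs$year_label)
  expect_identical(back$fish_id, obs$fish_id)
  expect_equal(nrow(back), nrow(obs))
})

test_that("writing an empty observation set is an error", {
  expect_error(write_observations(data.frame(), tempfile()), "no observations")
})
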