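# Reference per-status age-frequency of the 2015 field collection the
# default simulation emulates (ages 1..12).
mr_age_counts <- c(30L, 24L, 11L, 10L, 9L, 9L, 5L, 3L, 4L, 3L, 1L, 2L)
fr_age_counts <- c(31L, 25L, 28L, 21L, 20L, 18L, 5L, 1L, 1L, 6L, 2L, 1L)

# Cumulative-tail ("pooled") counts implied by an original age frequency.
pooled_counts <- function(orig) rev(cumsum(rev(orig)))

# Noise-free population with the reference age quota; every fish lies exactly
# on the true allometric curve, so back-calculation must be exact.
simulate_exact_quota <- function(seed = 1,
                                 mr = mr_age_counts, fr = fr_age_counts) {
  simulate_population(sim_config(
    n_fish = c(MR = sum(mr), FR = sum(fr)),
    age_weights = list(MR = mr, FR = fr), sampling = "quota",
    noise_sd_radius = 0, noise_sd_length = 0, rng_seed = seed
  ))
}

# One hand-built fish as a wide-format CSV row.
write_wide_fish_csv <- function(path, radii = c(0.2, 0.35, 0.5),
                                radius_capture = 0.55) {
  df <- data.frame(
    fish_id = "f1", status = "MR", site = "MR1", capture_year = 2015,
    age_at_capture = length(radii), length_capture = 45,
    radius_capture = radius_capture
  )
  for (i in seq_along(radii)) df[[paste0("r", i)]] <- radii[i]
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Random valid parameter set for the modified Fry formula.
random_mfbc_params <- function() {
  a <- stats::runif(1, -5, 15)
  R0p <- stats::runif(1, 0.1, 1)
  R_cpt <- R0p * stats::runif(1, 1.5, 10)
  L0p <- a + stats::runif(1, 1, 30)
  L_cpt <- L0p + stats::runif(1, 1, 100)
  list(a = a, R0p = R0p, R_cpt = R_cpt, L0p = L0p, L_cpt = L_cpt)
}

# Minimal fish_records table built directly from capture measurements lying
# exactly on L = a + b R^c, one annulus per fish at half the capture radius.
records_on_curve <- function(R, a, b, cc, ages = 1L) {
  L <- a + b * R^cc
  fish_records(
    fish_id = sprintf("c%03d", seq_along(R)), status = "MR", site = "MR1",
    capture_year = 2015, age_at_capture = rep_len(ages, length(R)),
    length_capture = L, radius_capture = R,
    radii = lapply(R, function(r) r * 0.5)
  )
}
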