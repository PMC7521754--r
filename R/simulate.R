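#' von Bertalanffy length at age
#'
#' Standard growth kernel used by the population simulator:
#' `L(t) = Linf * (1 - exp(-K * (t - t0)))`.
#'
#' @param age age in years; must exceed `t0`.
#' @param Linf asymptotic length (mm).
#' @param K growth coefficient (1/yr).
#' @param t0 theoretical age at length zero (yr).
#' @return Length in mm, increasing in `age` and approaching `Linf`.
#' @export
vbgf_length <- function(age, Linf, K, t0) {
  stopifnot(Linf > 0, K > 0)
  if (any(age <= t0)) stop("age must exceed t0")
  Linf * (1 - exp(-K * (age - t0)))
}

#' Allometric body-otolith relation and its inverse
#'
#' The back-calculation model assumes standard length follows
#' `L = a + b * R^c` in otolith radius `R`, with `a` the biological intercept.
#' `length_from_radius()` evaluates the relation; `radius_from_length()`
#' inverts it.
#'
#' @param L standard length (mm), must exceed `a` for the inverse.
#' @param R otolith radius (> 0).
#' @param a biological intercept (mm).
#' @param b,c allometric coefficients (`b > 0`, `c > 0`).
#' @return Radius, or length, respectively.
#' @export
radius_from_length <- function(L, a, b, c) {
  stopifnot(b > 0, c > 0)
  if (any(L <= a)) stop("length must exceed the biological intercept a")
  ((L - a) / b)^(1 / c)
}

#' @rdname radius_from_length
#' @export
length_from_radius <- function(R, a, b, c) {
  stopifnot(b > 0, c > 0)
  if (any(R <= 0)) stop("radius must be positive")
  a + b * R^c
}

#' Reference per-age sample counts
#'
#' Per-status age-frequency of the 2015 brown surgeonfish collection the
#' package's default simulation emulates: 111 marine-reserve and 159
#' fished-reef fish across ages 1-12.  Used as the default age-distribution
#' weights and as the quota in reproduction tests of the pooled
#' (back-calculated) sample sizes.
#'
#' @return Named list with integer vectors `MR` and `FR` of length 12.
#' @export
default_age_counts <- function() {
  list(
    MR = c(30L, 24L, 11L, 10L, 9L, 9L, 5L, 3L, 4L, 3L, 1L, 2L),
    FR = c(31L, 25L, 28L, 21L, 20L, 18L, 5L, 1L, 1L, 6L, 2L, 1L)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic fish population generator.  The defaults
#' emulate the sampled system the package targets: a single 2015 collection of
#' ages 1-12 from five marine-reserve (MR) and five fished-reef (FR) sites,
#' with MR fish growing faster over a mid-life age window and a positive
#' year-class trend in asymptotic length.
#'
#' @param n_fish named vector `c(MR = ..., FR = ...)`: fish per status.
#' @param capture_year calendar year of the (single) sampling campaign.
#' @param max_age oldest age sampled.
#' @param age_weights named list of per-age weights per status (default: the
#'   reference counts from [default_age_counts()]).
#' @param sampling `"quota"` draws exact per-age counts by scaling the weights
#'   to `n_fish` (largest-remainder rounding); `"multinomial"` samples ages
#'   independently with probability proportional to the weights.
#' @param Linf_mean mean asymptotic standard length (mm).
#' @param K von Bertalanffy growth coefficient (1/yr).
#' @param t0 von Bertalanffy age at length zero (yr).
#' @param cv_Linf coefficient of variation of individual `Linf`.
#' @param status_effect multiplicative factor applied to the annual growth
#'   increments of MR fish over `status_age_window` (1 = no protection
#'   effect).
#' @param status_age_window integer ages (inclusive range) over which the
#'   status effect acts; default ages 3-6, the mid-life window in which
#'   protection effects on this species emerge.
#' @param year_trend additive change in `Linf` (mm) per birth year, so later
#'   year classes grow larger when positive.
#' @param a_true,b_true,c_true true allometric constants linking length to
#'   otolith radius (`L = a + b R^c`).
#' @param noise_sd_radius lognormal sd applied to otolith radius increments
#'   (0 = noise free; increments are re-cumulated so radii stay monotone).
#' @param noise_sd_length additive Gaussian sd (mm) on measured capture
#'   length.
#' @param marginal_growth fraction by which the capture radius exceeds the
#'   last annulus radius (post-annulus growth before capture).
#' @param n_sites number of sites per status.
#' @param rng_seed optional integer seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_fish = c(MR = 111, FR = 159),
                       capture_year = 2015, max_age = 12,
                       age_weights = default_age_counts(),
                       sampling = c("quota", "multinomial"),
                       Linf_mean = 92, K = 0.23, t0 = -1.0,
                       cv_Linf = 0.10,
                       status_effect = 1.2, status_age_window = c(3, 6),
                       year_trend = 2.0,
                       a_true = 8, b_true = 55, c_true = 0.9,
                       noise_sd_radius = 0.04, noise_sd_length = 1.5,
                       marginal_growth = 0.05, n_sites = 5,
                       rng_seed = NULL) {
  n_fish <- unlist(n_fish)
  stopifnot(Linf_mean > a_true, a_true >= 0, K > 0, cv_Linf >= 0,
            b_true > 0, c_true > 0, max_age >= 1, t0 < 0,
            status_effect > 0,
            noise_sd_radius >= 0, noise_sd_length >= 0,
            marginal_growth >= 0, all(n_fish >= 1))
  if (is.null(names(n_fish))) names(n_fish) <- c("MR", "FR")
  cfg <- list(
    n_fish = n_fish, capture_year = as.integer(capture_year),
    max_age = as.integer(max_age), age_weights = age_weights,
    sampling = match.arg(sampling),
    Linf_mean = Linf_mean, K = K, t0 = t0, cv_Linf = cv_Linf,
    status_effect = status_effect,
    status_age_window = as.integer(status_age_window),
    year_trend = year_trend,
    a_true = a_true, b_true = b_true, c_true = c_true,
    noise_sd_radius = noise_sd_radius, noise_sd_length = noise_sd_length,
    marginal_growth = marginal_growth, n_sites = as.integer(n_sites),
    rng_seed = rng_seed
  )
  class(cfg) <- "sim_config"
  cfg
}

# Largest-remainder allocation of n among weights (deterministic).
quota_counts <- function(weights, n) {
  w <- weights / sum(weights)
  raw <- w * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by_frac <- order(raw - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Annual growth increments for one fish; the status factor scales the
# increments accrued over the protection window only.
growth_increments <- function(ages, Linf, K, t0, factor_by_age) {
  inc <- Linf * (exp(-K * (ages - 1 - t0)) - exp(-K * (ages - t0)))
  inc * factor_by_age
}

#' Simulate a fish population with known ground truth
#'
#' Generates individual fish under a von Bertalanffy growth model with
#' individual variability in asymptotic length, a year-class trend, and a
#' mid-life protection effect on marine-reserve fish, then converts true
#' lengths-at-age to otolith annulus radii through the true allometric
#' relation.  Optional lognormal noise perturbs the radius increments (and is
#' re-cumulated, so radii remain strictly increasing); optional Gaussian noise
#' perturbs the measured capture length.
#'
#' @param cfg a [sim_config()].
#' @return List with `fish` (a validated `"fish_records"` table) and `truth`
#'   (one row per fish-annulus: `fish_id`, `status`, `site`, `birth_year`,
#'   `annulus`, `true_length`, `Linf_individual`).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  ref_year <- cfg$capture_year - cfg$max_age
  win <- cfg$status_age_window

  all_fish <- list()
  all_truth <- list()
  counter <- 0L
  for (st in names(cfg$n_fish)) {
    n <- as.integer(cfg$n_fish[[st]])
    w <- cfg$age_weights[[st]]
    if (is.null(w)) w <- rep(1, cfg$max_age)
    w <- rep_len(as.numeric(w), cfg$max_age)
    ages <- if (cfg$sampling == "quota") {
      rep(seq_len(cfg$max_age), quota_counts(w, n))
    } else {
      sample(seq_len(cfg$max_age), n, replace = TRUE, prob = w / sum(w))
    }
    sites <- paste0(st, rep_len(seq_len(cfg$n_sites), n))
    for (k in seq_len(n)) {
      counter <- counter + 1L
      A <- ages[k]
      birth <- cfg$capture_year - A
      Linf_i <- (cfg$Linf_mean + cfg$year_trend * (birth - ref_year)) *
        (1 + if (cfg$cv_Linf > 0) stats::rnorm(1, 0, cfg$cv_Linf) else 0)
      Linf_i <- max(Linf_i, cfg$a_true + 1)
      fac <- rep(1, A)
      if (st == "MR" && cfg$status_effect != 1) {
        in_win <- seq_len(A) >= win[1] & seq_len(A) <= win[2]
        fac[in_win] <- cfg$status_effect
      }
      L0 <- vbgf_length(0, Linf_i, cfg$K, cfg$t0)
      true_len <- L0 + cumsum(
        growth_increments(seq_len(A), Linf_i, cfg$K, cfg$t0, fac)
      )
      r_true <- radius_from_length(true_len, cfg$a_true, cfg$b_true,
                                   cfg$c_true)
      if (cfg$noise_sd_radius > 0) {
        d <- diff(c(0, r_true))
        d <- d * exp(stats::rnorm(A, 0, cfg$noise_sd_radius) -
                       cfg$noise_sd_radius^2 / 2)
        radii <- cumsum(d)
      } else {
        radii <- r_true
      }
      R_cpt <- radii[A] * (1 + cfg$marginal_growth)
      L_cpt <- length_from_radius(R_cpt, cfg$a_true, cfg$b_true, cfg$c_true)
      if (cfg$noise_sd_length > 0) {
        L_cpt <- max(L_cpt + stats::rnorm(1, 0, cfg$noise_sd_length),
                     cfg$a_true + 1e-3)
      }
      id <- sprintf("%s%04d", st, counter)
      all_fish[[counter]] <- list(
        fish_id = id, status = st, site = sites[k],
        age = A, L_cpt = L_cpt, R_cpt = R_cpt, radii = radii
      )
      all_truth[[counter]] <- data.frame(
        fish_id = id, status = st, site = sites[k],
        birth_year = birth, annulus = seq_len(A),
        true_length = true_len, Linf_individual = Linf_i,
        stringsAsFactors = FALSE
      )
    }
  }
  fish <- fish_records(
    fish_id = vapply(all_fish, `[[`, "", "fish_id"),
    status = vapply(all_fish, `[[`, "", "status"),
    site = vapply(all_fish, `[[`, "", "site"),
    capture_year = cfg$capture_year,
    age_at_capture = vapply(all_fish, `[[`, 0L, "age"),
    length_capture = vapply(all_fish, `[[`, 0, "L_cpt"),
    radius_capture = vapply(all_fish, `[[`, 0, "R_cpt"),
    radii = lapply(all_fish, `[[`, "radii")
  )
  truth <- do.call(rbind, all_truth)
  rownames(truth) <- NULL
  list(fish = fish, truth = truth)
}
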