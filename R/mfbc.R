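#' Modified Fry back-calculation of length-at-age
#'
#' The back-calculation interpolates log body size linearly in log otolith
#' radius between two anchors: the formation anchor `(R0p, L0p)` (mean radius
#' of the first annulus and the length at increment formation) and the capture
#' anchor `(R_cpt, L_cpt)`, after shifting lengths by the biological intercept
#' `a` of the allometric body-otolith relation `L = a + b * R^c`:
#'
#' \deqn{L_i = a + \exp\!\Big(\ln(L_{0P}-a) +
#'   \big[\ln(L_{cpt}-a)-\ln(L_{0P}-a)\big]
#'   \frac{\ln R_i - \ln R_{0P}}{\ln R_{cpt} - \ln R_{0P}}\Big)}
#'
#' `mfbc()` estimates the allometric constants `(a, b, c)` by nonlinear least
#' squares of capture length on capture radius across the whole sample
#' (statuses pooled), computes the anchors, and returns a fitted model object;
#' `predict()` (or [back_calculate()]) then yields one back-calculated length
#' per fish-annulus.
#'
#' The least-squares fit is initialised from a log-linear regression of
#' `log(L)` on `log(R)` and refined with `nls` (port algorithm) under the
#' constraint `a < min(L_cpt)`; if that fails, `a` is profiled out on a grid
#' (for fixed `a` the model is log-linear); if no nonlinear fit converges the
#' model falls back, with a warning, to the linear relation `L = a + b R`
#' (`c = 1`).  Any of the three anchors can be overridden with values from the
#' literature (e.g. a settlement-size prior for `L0p`).
#'
#' @param records a `"fish_records"` table ([read_fish_table()],
#'   [fish_records()], [simulate_population()]).
#' @param a_override,L0p_override,R0p_override optional fixed values replacing
#'   the fitted biological intercept, formation length, or formation radius.
#' @param r0p_mode `"population_mean"` (default) anchors every fish at the
#'   sample mean first-annulus radius, the convention used for field samples;
#'   `"per_fish"` anchors each fish at its own first-annulus radius, as in the
#'   original formulation of the model.
#' @return An object of class `"mfbc"`: a list with `coefficients` (a, b, c),
#'   `anchors` (R0p, L0p; `NULL` in per-fish mode), `r0p_mode`, `provenance`
#'   (per quantity: `"fitted"`, `"derived"` or `"override"`), `fit` (the
#'   underlying `nls`/`lm` object, when one exists), `method` (fitting route),
#'   `fish` (per-fish capture data), `records`, `sigma` (residual sd of the
#'   allometric fit) and `call`.
#' @examples
#' sim <- simulate_population(sim_config(n_fish = c(MR = 40, FR = 40),
#'                                       rng_seed = 1))
#' fit <- mfbc(sim$fish)
#' coef(fit)
#' obs <- predict(fit)
#' head(obs)
#' @export
mfbc <- function(records, a_override = NULL, L0p_override = NULL,
                 R0p_override = NULL,
                 r0p_mode = c("population_mean", "per_fish")) {
  r0p_mode <- match.arg(r0p_mode)
  records <- validate_fish_records(records)
  fish <- fish_capture_table(records)

  al <- fit_allometry(fish$length_capture, fish$radius_capture,
                      a_fixed = a_override)
  a <- al$coef[["a"]]; b <- al$coef[["b"]]; cc <- al$coef[["c"]]

  r1 <- records$radius[records$annulus == 1L]
  if (length(r1) == 0) stop("no first-annulus radii in records")
  R0p <- if (!is.null(R0p_override)) R0p_override else mean(r1)
  L0p <- if (!is.null(L0p_override)) L0p_override else
    length_from_radius(R0p, a, b, cc)
  if (L0p <= a) stop("length at increment formation L0p must exceed a")

  provenance <- c(
    a = if (is.null(a_override)) "fitted" else "override",
    b = "fitted", c = "fitted",
    R0p = if (!is.null(R0p_override)) "override" else
      if (r0p_mode == "per_fish") "per-fish" else "fitted",
    L0p = if (!is.null(L0p_override)) "override" else "derived"
  )
  out <- list(
    coefficients = c(a = a, b = b, c = cc),
    anchors = if (r0p_mode == "population_mean") c(R0p = R0p, L0p = L0p)
              else NULL,
    r0p_mode = r0p_mode,
    overrides = list(a = a_override, L0p = L0p_override, R0p = R0p_override),
    provenance = provenance,
    fit = al$fit, method = al$method, sigma = al$sigma,
    fish = fish, records = records,
    n_fish = nrow(fish),
    call = match.call()
  )
  class(out) <- "mfbc"
  out
}

# Per-fish capture measurements (one row per fish) from the long table.
fish_capture_table <- function(records) {
  first <- !duplicated(records$fish_id)
  fish <- records[first, c("fish_id", "status", "site", "capture_year",
                           "age_at_capture", "length_capture",
                           "radius_capture")]
  rownames(fish) <- NULL
  fish
}

# Pooled nonlinear least squares of L = a + b R^c with a < min(L).
fit_allometry <- function(L, R, a_fixed = NULL) {
  if (length(L) < 5) stop("allometric fit needs at least 5 fish")
  if (diff(range(R)) < 1e-12) {
    stop("degenerate design: all capture radii are equal")
  }
  eps <- 1e-6 * diff(range(L)) + 1e-9
  a_max <- min(L) - eps

  loglin_bc <- function(a) {
    co <- stats::coef(stats::lm(log(L - a) ~ log(R)))
    c(b = exp(unname(co[1])), c = max(unname(co[2]), 1e-3))
  }

  if (!is.null(a_fixed)) {
    if (a_fixed >= min(L)) {
      stop("a_override must be below the smallest capture length")
    }
    st <- loglin_bc(a_fixed)
    fit <- try(stats::nls(L ~ a_fixed + b * R^c,
                          data = data.frame(L = L, R = R),
                          start = list(b = st[["b"]], c = st[["c"]]),
                          algorithm = "port",
                          lower = c(b = 1e-9, c = 1e-3),
                          control = stats::nls.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      fit <- stats::lm(L ~ R)
      co <- stats::coef(fit)
      warning("allometric fit did not converge; ",
              "falling back to linear relation (c = 1)")
      return(list(coef = c(a = a_fixed, b = unname(co[2]), c = 1),
                  fit = fit, method = "linear-fallback",
                  sigma = stats::sigma(fit)))
    }
    co <- stats::coef(fit)
    return(list(coef = c(a = a_fixed, b = unname(co[["b"]]),
                         c = unname(co[["c"]])),
                fit = fit, method = "nls-fixed-a", sigma = stats::sigma(fit)))
  }

  st <- loglin_bc(0)
  fit <- try(stats::nls(L ~ a + b * R^c, data = data.frame(L = L, R = R),
                        start = list(a = 0, b = st[["b"]], c = st[["c"]]),
                        algorithm = "port",
                        lower = c(a = -Inf, b = 1e-9, c = 1e-3),
                        upper = c(a = a_max, b = Inf, c = Inf),
                        control = stats::nls.control(maxiter = 200)),
             silent = TRUE)
  if (!inherits(fit, "try-error")) {
    co <- stats::coef(fit)
    return(list(coef = c(a = unname(co[["a"]]), b = unname(co[["b"]]),
                         c = unname(co[["c"]])),
                fit = fit, method = "nls", sigma = stats::sigma(fit)))
  }

  # Profile a out: for fixed a the model is linear in log space, so a 1-D
  # search over a is a robust concentrated least-squares route.
  rss <- function(a) {
    bc <- loglin_bc(a)
    sum((L - (a + bc[["b"]] * R^bc[["c"]]))^2)
  }
  opt <- try(stats::optimize(rss, interval = c(min(L) - diff(range(L)) * 10,
                                               a_max)),
             silent = TRUE)
  if (!inherits(opt, "try-error")) {
    a_hat <- opt$minimum
    bc <- loglin_bc(a_hat)
    n <- length(L)
    sig <- sqrt(opt$objective / max(n - 3, 1))
    return(list(coef = c(a = a_hat, b = bc[["b"]], c = bc[["c"]]),
                fit = NULL, method = "profile", sigma = sig))
  }
  fit <- stats::lm(L ~ R)
  co <- stats::coef(fit)
  warning("allometric fit did not converge; ",
          "falling back to linear relation (c = 1)")
  list(coef = c(a = unname(co[1]), b = unname(co[2]), c = 1),
       fit = fit, method = "linear-fallback", sigma = stats::sigma(fit))
}

#' Back-calculated length at one otolith radius
#'
#' Vectorised evaluation of the modified Fry formula (see [mfbc()]).  The
#' formula interpolates `log(L - a)` linearly in `log(R)` between the
#' formation anchor `(R0p, L0p)` and the capture anchor `(R_cpt, L_cpt)`, so
#' `Ri = R0p` returns `L0p` and `Ri = R_cpt` returns `L_cpt` exactly.
#'
#' @param Ri otolith radius at the annulus of interest (> 0).
#' @param L_cpt,R_cpt length and otolith radius at capture.
#' @param a biological intercept; must lie below `L_cpt` and `L0p`.
#' @param L0p length at increment formation.
#' @param R0p radius anchor at increment formation; must differ from `R_cpt`.
#' @return Back-calculated length(s) in the units of `L_cpt`.
#' @examples
#' mfbc_length(sqrt(10), L_cpt = 100, R_cpt = 10, a = 10, L0p = 20, R0p = 1)
#' @export
mfbc_length <- function(Ri, L_cpt, R_cpt, a, L0p, R0p) {
  if (any(L_cpt <= a)) stop("domain error: L_cpt - a must be positive")
  if (any(L0p <= a))   stop("domain error: L0p - a must be positive")
  if (any(Ri <= 0))    stop("domain error: Ri must be positive")
  if (any(R0p <= 0))   stop("domain error: R0p must be positive")
  if (any(R_cpt <= 0)) stop("domain error: R_cpt must be positive")
  if (any(abs(log(R_cpt) - log(R0p)) < 1e-12)) {
    stop("degenerate anchors: R_cpt equals R0p")
  }
  a + exp(log(L0p - a) +
            (log(L_cpt - a) - log(L0p - a)) *
            (log(Ri) - log(R0p)) / (log(R_cpt) - log(R0p)))
}

#' Back-calculate length-at-age for every fish
#'
#' Applies the fitted modified Fry model to every annulus of every fish,
#' producing one observation per fish-annulus.  A fish of age `A` contributes
#' exactly `A` observations, so the pooled per-age sample sizes equal the
#' cumulative tails of the original age frequency.  Each observation carries a
#' calendar-year label from [assign_year_label()]: the last annulus formed the
#' year before capture, earlier annuli one year earlier each.
#'
#' Fish for which the formula is undefined (capture length at or below the
#' biological intercept, or capture radius equal to the anchor radius) are
#' skipped, not clamped, and reported in a warning.  The same applies to fish
#' whose implied log-log interpolation slope is biologically implausible (see
#' `slope_limits`): when a fish's capture radius falls near the anchor radius,
#' the slope ratio divides by almost zero and measurement noise is amplified
#' without bound, so such fish are excluded rather than contributing unbounded
#' artefacts.  On measurements exactly consistent with the allometry the slope
#' equals the fitted exponent and no fish is ever skipped.
#'
#' @param object a fitted `"mfbc"` model.
#' @param newdata optional `"fish_records"` table to back-calculate instead of
#'   the training records.
#' @param capture_age radius used for the capture-age observation:
#'   `"last_annulus"` (default) uses `r[A]`, the radius at that annulus's
#'   formation; `"capture_radius"` uses `R_cpt`, at which the formula returns
#'   the capture length exactly.
#' @param year_rule `"formation"` labels annulus `i` of a fish of age `A`
#'   captured in year `Y` with `(Y - 1) - (A - i)`; `"birth"` labels all of a
#'   fish's annuli with its birth year `Y - A` (sensitivity alternative).
#' @param slope_limits admissible range of the per-fish log-log slope,
#'   expressed as multiples of the fitted allometric exponent `c`; fish
#'   outside it are skipped with a warning.
#' @param ... unused.
#' @return Data frame of class `"length_at_age"`: `fish_id`, `status`, `site`,
#'   `capture_year`, `age_at_capture`, `age`, `year_label`, `length`.
#' @export
predict.mfbc <- function(object, newdata = NULL,
                         capture_age = c("last_annulus", "capture_radius"),
                         year_rule = c("formation", "birth"),
                         slope_limits = c(0.2, 5), ...) {
  capture_age <- match.arg(capture_age)
  year_rule <- match.arg(year_rule)
  rec <- if (is.null(newdata)) object$records else
    validate_fish_records(newdata)
  rec <- rec[order(rec$fish_id, rec$annulus), , drop = FALSE]
  a <- object$coefficients[["a"]]
  b <- object$coefficients[["b"]]
  cc <- object$coefficients[["c"]]

  # per-row anchors (constant within fish)
  if (object$r0p_mode == "per_fish") {
    first <- rec$annulus == 1L
    r1 <- rec$radius[first]
    names(r1) <- rec$fish_id[first]
    R0p <- unname(r1[rec$fish_id])
    L0p <- if (!is.null(object$overrides$L0p)) {
      rep(object$overrides$L0p, nrow(rec))
    } else {
      length_from_radius(R0p, a, b, cc)
    }
  } else {
    R0p <- rep(object$anchors[["R0p"]], nrow(rec))
    L0p <- rep(object$anchors[["L0p"]], nrow(rec))
  }
  L_cpt <- rec$length_capture
  R_cpt <- rec$radius_capture
  Ri <- rec$radius
  if (capture_age == "capture_radius") {
    at_cap <- rec$annulus == rec$age_at_capture
    Ri[at_cap] <- R_cpt[at_cap]
  }

  # the within-fish interpolation slope in log space; on data consistent with
  # the allometry it equals c, so a wildly different value flags a fish whose
  # anchors are degenerate (e.g. capture radius at the population anchor) and
  # whose back-calculation would amplify measurement noise without bound
  denom <- log(R_cpt) - log(R0p)
  slope <- (log(L_cpt - a) - log(L0p - a)) / denom
  valid <- L_cpt > a & L0p > a & Ri > 0 & R0p > 0 & R_cpt > 0 &
    abs(denom) > 1e-12 & is.finite(slope) &
    slope >= slope_limits[1] * cc & slope <= slope_limits[2] * cc
  fish_ok <- !(rec$fish_id %in% unique(rec$fish_id[!valid]))
  if (any(!fish_ok)) {
    bad <- unique(rec$fish_id[!fish_ok])
    warning("skipped ", length(bad),
            " fish with undefined or unstable back-calculation: ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) " ..." else "")
  }
  r <- rec[fish_ok, , drop = FALSE]
  out <- data.frame(
    fish_id = r$fish_id, status = r$status, site = r$site,
    capture_year = r$capture_year, age_at_capture = r$age_at_capture,
    age = r$annulus,
    year_label = if (year_rule == "formation") {
      assign_year_label(r$capture_year, r$age_at_capture, r$annulus)
    } else {
      as.integer(r$capture_year - r$age_at_capture)
    },
    length = a + exp(log(L0p[fish_ok] - a) +
                       slope[fish_ok] * (log(Ri[fish_ok]) -
                                           log(R0p[fish_ok]))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("length_at_age", "data.frame")
  out
}

#' @rdname predict.mfbc
#' @param records passed as `newdata`.
#' @export
back_calculate <- function(object, records = NULL, ...) {
  stopifnot(inherits(object, "mfbc"))
  predict(object, newdata = records, ...)
}

#' @export
print.mfbc <- function(x, digits = 4, ...) {
  cat("Modified Fry back-calculation model\n")
  cat("  fish:", x$n_fish, " (", sum(x$records$annulus >= 1),
      "annulus readings )\n")
  cat("  allometry  L = a + b * R^c   [", x$method, "]\n")
  print(round(x$coefficients, digits))
  if (!is.null(x$anchors)) {
    cat("  anchors: R0p =", signif(x$anchors[["R0p"]], digits),
        " L0p =", signif(x$anchors[["L0p"]], digits), "\n")
  } else {
    cat("  anchors: per-fish first-annulus radii\n")
  }
  invisible(x)
}

#' @export
coef.mfbc <- function(object, ...) {
  c(object$coefficients, object$anchors)
}

#' @export
fitted.mfbc <- function(object, ...) {
  co <- object$coefficients
  length_from_radius(object$fish$radius_capture, co[["a"]], co[["b"]],
                     co[["c"]])
}

#' @export
residuals.mfbc <- function(object, ...) {
  object$fish$length_capture - fitted(object)
}

#' @export
summary.mfbc <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    coefficients = object$coefficients, anchors = object$anchors,
    provenance = object$provenance, method = object$method,
    sigma = object$sigma, n_fish = object$n_fish,
    resid_summary = summary(res),
    age_range = range(object$fish$age_at_capture),
    call = object$call
  )
  class(out) <- "summary.mfbc"
  out
}

#' @export
print.summary.mfbc <- function(x, digits = 4, ...) {
  cat("Modified Fry back-calculation model\n\nCall:\n  ")
  print(x$call)
  cat("\nAllometry L = a + b * R^c (", x$method, "), n =", x$n_fish,
      "fish, ages", x$age_range[1], "-", x$age_range[2], "\n")
  print(round(x$coefficients, digits))
  cat("provenance:", paste(names(x$provenance), x$provenance, sep = "=",
                           collapse = "  "), "\n")
  if (!is.null(x$anchors)) print(signif(x$anchors, digits))
  cat("residual sd:", signif(x$sigma, digits), "\n")
  cat("capture-length residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

#' Plot the fitted allometric relation
#'
#' Scatter of capture length against capture otolith radius with the fitted
#' curve `L = a + b R^c` and the formation anchor.
#'
#' @param x a fitted `"mfbc"` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mfbc <- function(x, ...) {
  co <- x$coefficients
  R <- x$fish$radius_capture
  L <- x$fish$length_capture
  graphics::plot(R, L, xlab = "otolith radius at capture",
                 ylab = "standard length at capture (mm)",
                 main = "Allometric body-otolith relation", ...)
  rr <- seq(min(R) * 0.9, max(R) * 1.05, length.out = 200)
  graphics::lines(rr, length_from_radius(rr, co[["a"]], co[["b"]], co[["c"]]),
                  col = "steelblue", lwd = 2)
  if (!is.null(x$anchors)) {
    graphics::points(x$anchors[["R0p"]], x$anchors[["L0p"]], pch = 17,
                     col = "firebrick", cex = 1.3)
  }
  invisible(x)
}

#' Simulate capture lengths from the fitted allometry
#'
#' Draws new capture lengths at the observed capture radii from the fitted
#' relation plus Gaussian residual noise; useful for parametric-bootstrap
#' checks of the allometric fit.
#'
#' @param object a fitted `"mfbc"` model.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return Data frame with `nsim` columns, one row per fish.
#' @export
simulate.mfbc <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                         object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
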