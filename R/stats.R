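# Linear-model ANOVA engine shared by the one- and two-factor analyses.
# Returns per-term F/Df/p plus residual Df and sums of squares.  Type II is
# the default for the unbalanced designs produced by back-calculation; types
# 1 and 3 are available for sensitivity analysis.
factorial_anova <- function(d, terms, ss_type = 2) {
  stopifnot(ss_type %in% 1:3, "length" %in% names(d))
  for (tm in terms) d[[tm]] <- factor(d[[tm]])
  form <- stats::reformulate(terms, response = "length")
  if (ss_type == 3) {
    ctr <- lapply(terms, function(.) "contr.sum")
    names(ctr) <- terms
    fit <- stats::lm(form, data = d, contrasts = ctr)
  } else {
    fit <- stats::lm(form, data = d)
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("aliased coefficients: factors are collinear in this cohort")
  }
  if (ss_type == 1) {
    tab <- stats::anova(fit)
  } else {
    tab <- car::Anova(fit, type = ss_type)
  }
  tt <- as.data.frame(tab)
  rn <- rownames(tt)
  res_row <- which(rn == "Residuals")
  keep <- match(terms, rn)
  list(
    term = terms,
    SS = tt[keep, "Sum Sq"], Df = tt[keep, "Df"],
    F = tt[keep, "F value"], p = tt[keep, "Pr(>F)"],
    SS_res = tt[res_row, "Sum Sq"], Df_res = tt[res_row, "Df"],
    fit = fit
  )
}

#' Two-way ANOVA for one age cohort
#'
#' Fits the additive linear model `length ~ status + year` (both categorical)
#' to one back-calculated age cohort and reports F, degrees of freedom and p
#' for both effects, using Type II sums of squares by default since the
#' designs are unbalanced.  No status-by-year interaction is fitted: many
#' status-year cells contain at most one observation.  The status effect size
#' is reported as partial eta squared `SS_status / (SS_status + SS_residual)`
#' and Cohen's f-squared, and an a posteriori power for the status test is
#' computed with [posthoc_power()].
#'
#' Cohorts that cannot support the model are gated rather than fitted: a
#' single year class (`gate = "skipped_single_year"`, as happens at the oldest
#' age where all observations belong to one cohort), a single status level
#' (`"skipped_single_status"`), too few residual degrees of freedom
#' (`"skipped_insufficient_df"`), or collinear factors
#' (`"skipped_collinear"`).
#'
#' @param d data frame with columns `length`, `status`, `year_label` (one age
#'   cohort, e.g. one element of [pool_by_age()]).
#' @param alpha significance level used for the power computation.
#' @param ss_type sums-of-squares type: 2 (default), 1 or 3.
#' @return One-row data frame: `age`, `n`, `gate`, `status_F`, `status_DF`,
#'   `status_p`, `year_F`, `year_DF`, `year_p`, `residual_DF`,
#'   `partial_eta_sq_status`, `cohens_f2`, `power`.
#' @export
two_way_anova <- function(d, alpha = 0.05, ss_type = 2) {
  age <- if (!is.null(attr(d, "age"))) attr(d, "age") else
    if ("age" %in% names(d)) d$age[1] else NA_integer_
  empty <- data.frame(
    age = age, n = nrow(d), gate = NA_character_,
    status_F = NA_real_, status_DF = NA_integer_, status_p = NA_real_,
    year_F = NA_real_, year_DF = NA_integer_, year_p = NA_real_,
    residual_DF = NA_integer_, partial_eta_sq_status = NA_real_,
    cohens_f2 = NA_real_, power = NA_real_, stringsAsFactors = FALSE
  )
  n_status <- length(unique(d$status))
  n_year <- length(unique(d$year_label))
  if (n_year < 2) { empty$gate <- "skipped_single_year"; return(empty) }
  if (n_status < 2) { empty$gate <- "skipped_single_status"; return(empty) }
  df_model <- (n_status - 1) + (n_year - 1)
  if (nrow(d) - 1 - df_model < 1) {
    empty$gate <- "skipped_insufficient_df"
    return(empty)
  }
  an <- try(factorial_anova(d, c("status", "year_label"), ss_type),
            silent = TRUE)
  if (inherits(an, "try-error")) {
    empty$gate <- "skipped_collinear"
    return(empty)
  }
  eta <- an$SS[1] / (an$SS[1] + an$SS_res)
  f2 <- eta / (1 - eta)
  data.frame(
    age = age, n = nrow(d), gate = "analyzed",
    status_F = an$F[1], status_DF = an$Df[1], status_p = an$p[1],
    year_F = an$F[2], year_DF = an$Df[2], year_p = an$p[2],
    residual_DF = an$Df_res,
    partial_eta_sq_status = eta, cohens_f2 = f2,
    power = posthoc_power(eta, an$Df[1], an$Df_res, alpha),
    stringsAsFactors = FALSE
  )
}

#' Per-age two-way ANOVA across all cohorts
#'
#' Runs [two_way_anova()] on every age cohort of a back-calculated
#' length-at-age table and stacks the results, adding a Holm-adjusted status
#' p-value column (`status_p_holm`) across the analyzed ages as a clearly
#' labelled extension — the per-age p-values themselves are reported
#' unadjusted.
#'
#' @param obs a `"length_at_age"` table, or an `"age_cohorts"` list.
#' @param alpha significance level for power computations.
#' @param ss_type sums-of-squares type (2 default).
#' @return Data frame of class `"cohort_anova"`, one row per age.
#' @export
cohort_anova <- function(obs, alpha = 0.05, ss_type = 2) {
  cohorts <- if (inherits(obs, "age_cohorts")) obs else pool_by_age(obs)
  res <- do.call(rbind, lapply(cohorts, two_way_anova, alpha = alpha,
                               ss_type = ss_type))
  rownames(res) <- NULL
  res$status_p_holm <- NA_real_
  ok <- res$gate == "analyzed"
  res$status_p_holm[ok] <- stats::p.adjust(res$status_p[ok],
                                           method = "holm")
  attr(res, "alpha") <- alpha
  attr(res, "ss_type") <- ss_type
  class(res) <- c("cohort_anova", "data.frame")
  res
}

#' @export
print.cohort_anova <- function(x, digits = 3, ...) {
  hdr <- "Per-age two-way ANOVA (length ~ status + year"
  if (!is.null(attr(x, "ss_type"))) {
    hdr <- paste0(hdr, ", type ", attr(x, "ss_type"), " SS, alpha = ",
                  attr(x, "alpha"))
  }
  cat(hdr, ")\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) signif(v, digits))
  print(y, row.names = FALSE)
  invisible(x)
}

#' A posteriori power of an F test
#'
#' Power of a completed fixed-effects F test, computed from its observed
#' partial eta squared via Cohen's effect size `f2 = eta2 / (1 - eta2)` and
#' the noncentral F distribution with noncentrality
#' `lambda = f2 * (u + v + 1)`:
#' `power = P( F(u, v, lambda) > F_crit(alpha, u, v) )`.
#' At `f2 = 0` the power equals `alpha` exactly.
#'
#' @param partial_eta_sq observed partial eta squared, in `[0, 1)`.
#' @param u numerator (effect) degrees of freedom.
#' @param v denominator (residual) degrees of freedom.
#' @param alpha significance level of the test.
#' @return Power in `[0, 1]`.
#' @examples
#' posthoc_power(0.2, u = 1, v = 30)
#' @export
posthoc_power <- function(partial_eta_sq, u, v, alpha = 0.05) {
  if (any(partial_eta_sq < 0) || any(partial_eta_sq >= 1)) {
    stop("partial_eta_sq must lie in [0, 1)")
  }
  stopifnot(u >= 1, v >= 1, alpha > 0, alpha < 1)
  f2 <- partial_eta_sq / (1 - partial_eta_sq)
  lambda <- f2 * (u + v + 1)
  fcrit <- stats::qf(1 - alpha, u, v)
  stats::pf(fcrit, u, v, ncp = lambda, lower.tail = FALSE)
}

#' Absolute and percent difference between two means
#'
#' The descriptive convention of the per-age summary table: the absolute
#' difference `|m1 - m2|` and the percent difference relative to the midpoint
#' of the two means, `100 * |m1 - m2| / ((m1 + m2) / 2)`.
#'
#' @param m1,m2 the two group means (e.g. MR and FR mean length at one age).
#' @return Named vector `c(absolute = ..., percent = ...)`.
#' @export
mean_difference <- function(m1, m2) {
  c(absolute = abs(m1 - m2),
    percent = 100 * abs(m1 - m2) / ((m1 + m2) / 2))
}

#' Per-age descriptive summary by status
#'
#' Means and standard errors of back-calculated length per age and status,
#' with the absolute and percent (midpoint-denominator) differences between
#' the two statuses.  Values are stored at full precision; the print method
#' rounds for display.
#'
#' @param obs a `"length_at_age"` table or `"age_cohorts"` list.
#' @param decimals decimals used by the print method.
#' @return Data frame of class `"cohort_summary"`: `age`, `mr_n`, `mr_mean`,
#'   `mr_se`, `fr_n`, `fr_mean`, `fr_se`, `absolute_diff`, `percent_diff`.
#' @export
cohort_summary_table <- function(obs, decimals = 2) {
  cohorts <- if (inherits(obs, "age_cohorts")) obs else pool_by_age(obs)
  one <- function(d) {
    age <- attr(d, "age")
    stat <- function(st) {
      x <- d$length[d$status == st]
      n <- length(x)
      c(n = n, mean = if (n > 0) mean(x) else NA_real_,
        se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_)
    }
    mr <- stat("MR"); fr <- stat("FR")
    diff <- if (!is.na(mr[["mean"]]) && !is.na(fr[["mean"]])) {
      mean_difference(mr[["mean"]], fr[["mean"]])
    } else c(absolute = NA_real_, percent = NA_real_)
    data.frame(
      age = age, mr_n = mr[["n"]], mr_mean = mr[["mean"]],
      mr_se = mr[["se"]], fr_n = fr[["n"]], fr_mean = fr[["mean"]],
      fr_se = fr[["se"]], absolute_diff = diff[["absolute"]],
      percent_diff = diff[["percent"]], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(cohorts, one))
  rownames(out) <- NULL
  attr(out, "decimals") <- decimals
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  dec <- attr(x, "decimals")
  y <- as.data.frame(x)
  num <- vapply(y, is.double, TRUE)
  y[num] <- lapply(y[num], round, digits = dec)
  cat("Mean back-calculated length (mm) per age by status\n")
  print(y, row.names = FALSE)
  invisible(x)
}
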