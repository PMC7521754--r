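#' LOESS year trend for one set of observations
#'
#' Locally weighted regression of back-calculated length on calendar year
#' label, with an approximate 95% pointwise confidence band.  The default is a
#' local quadratic with tricube weights at span 0.95 — a heavy smooth that
#' emphasises large-scale temporal shifts over year-to-year wiggles.  The fit
#' is gated (no curve returned) when fewer than `min_year_levels` distinct
#' years are available, since a smoother over one or two temporal cohorts is
#' meaningless.
#'
#' @param x year labels (numeric).
#' @param y lengths (mm).
#' @param span LOESS span in (0, 1] (larger = smoother).
#' @param degree local polynomial degree, 2 (default) or 1.
#' @param min_year_levels minimum distinct `x` values required.
#' @param conf confidence level of the pointwise band.
#' @param grid evaluation points (default: the distinct year labels).
#' @return List of class `"loess_trend"`: `gated`, `reason`, `x`, `fit`,
#'   `se`, `lower`, `upper`, `n`, `span`, `degree`, `model`.
#' @export
loess_trend <- function(x, y, span = 0.95, degree = 2, min_year_levels = 3,
                        conf = 0.95, grid = NULL) {
  stopifnot(length(x) == length(y), span > 0, degree %in% 1:2)
  ux <- sort(unique(x))
  if (length(ux) < min_year_levels) {
    return(structure(list(
      gated = TRUE,
      reason = sprintf("insufficient temporal cohorts (%d < %d)",
                       length(ux), min_year_levels),
      n = length(y), span = span, degree = degree
    ), class = "loess_trend"))
  }
  if (is.null(grid)) grid <- ux
  # sparse cohorts make the local quadratic rank-deficient; loess falls back
  # to a pseudoinverse, which is fine for these diagnostic curves
  muffle_loess <- function(w) {
    if (grepl(paste0("pseudoinverse|reciprocal condition|neighborhood|",
                     "far away|near singularities"),
              conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  }
  withCallingHandlers({
    lo <- stats::loess(y ~ x, span = span, degree = degree,
                       family = "gaussian",
                       control = stats::loess.control(surface = "direct"))
    pr <- stats::predict(lo, newdata = data.frame(x = grid), se = TRUE)
  }, warning = muffle_loess)
  tq <- stats::qt(1 - (1 - conf) / 2, pr$df)
  structure(list(
    gated = FALSE, reason = NULL,
    x = grid, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
    lower = as.numeric(pr$fit - tq * pr$se.fit),
    upper = as.numeric(pr$fit + tq * pr$se.fit),
    n = length(y), span = span, degree = degree, model = lo
  ), class = "loess_trend")
}

#' @export
print.loess_trend <- function(x, ...) {
  if (x$gated) {
    cat("LOESS trend: gated -", x$reason, "\n")
  } else {
    cat(sprintf(
      "LOESS trend (span %.2f, degree %d, n = %d): fit %.2f -> %.2f over %d-%d\n",
      x$span, x$degree, x$n, x$fit[1], x$fit[length(x$fit)],
      min(x$x), max(x$x)))
  }
  invisible(x)
}

status_colours <- c(MR = "#1b6ca8", FR = "#c1572a")

#' Plot one age cohort with LOESS trends by status
#'
#' Scatter of back-calculated length against year class for one age cohort,
#' with a LOESS curve and 95% pointwise band per status, the two-way ANOVA
#' results annotated in the lower left, and (when the year effect is
#' significant) the year-class labels printed above the curves.  Panels are
#' gated — nothing is drawn and `NULL` is returned — when the cohort has fewer
#' distinct year classes than `min_year_levels`.
#'
#' @param d one age-cohort data frame (element of [pool_by_age()]).
#' @param anova_row optional matching row of a [cohort_anova()] table, used
#'   for the annotation.
#' @param span,degree,min_year_levels see [loess_trend()].
#' @param alpha significance level used for the year-label annotation.
#' @return Invisibly, a named list of `"loess_trend"` fits per status, or
#'   `NULL` if the panel was gated.
#' @export
plot_age_cohort <- function(d, anova_row = NULL, span = 0.95, degree = 2,
                            min_year_levels = 3, alpha = 0.05) {
  age <- attr(d, "age")
  if (is.null(age) && "age" %in% names(d)) age <- d$age[1]
  if (length(unique(d$year_label)) < min_year_levels) {
    return(invisible(NULL))
  }
  fits <- lapply(split(d, d$status), function(s) {
    loess_trend(s$year_label, s$length, span = span, degree = degree,
                min_year_levels = min_year_levels)
  })
  xr <- range(d$year_label)
  yr <- range(c(d$length,
                unlist(lapply(fits, function(f) {
                  if (!f$gated) c(f$lower, f$upper) else NULL
                }))))
  graphics::plot(d$year_label, d$length, type = "n", xlab = "year class",
                 ylab = "back-calculated length (mm)",
                 main = paste("Age", age), xlim = xr,
                 ylim = yr + c(-0.12, 0.08) * diff(yr))
  for (st in names(fits)) {
    f <- fits[[st]]
    col <- if (st %in% names(status_colours)) status_colours[[st]] else "grey40"
    s <- d[d$status == st, ]
    graphics::points(s$year_label, s$length, col = grDevices::adjustcolor(col, 0.45),
                     pch = 16, cex = 0.6)
    if (!f$gated) {
      graphics::polygon(c(f$x, rev(f$x)), c(f$lower, rev(f$upper)),
                        col = grDevices::adjustcolor(col, 0.2), border = NA)
      graphics::lines(f$x, f$fit, col = col, lwd = 2)
    }
  }
  graphics::legend("topleft", legend = names(fits), bty = "n",
                   col = vapply(names(fits), function(s)
                     if (s %in% names(status_colours)) status_colours[[s]]
                     else "grey40", ""),
                   lwd = 2, cex = 0.8)
  if (!is.null(anova_row) && identical(anova_row$gate, "analyzed")) {
    txt <- sprintf("status: F=%.2f, p=%.3f\nyear: F=%.2f, p=%.3f",
                   anova_row$status_F, anova_row$status_p,
                   anova_row$year_F, anova_row$year_p)
    graphics::text(xr[1], yr[1] - 0.1 * diff(yr), txt, adj = c(0, 0),
                   cex = 0.7)
    if (!is.na(anova_row$year_p) && anova_row$year_p < alpha) {
      ytop <- yr[2] + 0.06 * diff(yr)
      yrs <- sort(unique(d$year_label))
      graphics::text(yrs, ytop, labels = yrs, cex = 0.55, srt = 90)
    }
  }
  invisible(fits)
}

#' Plot all age-cohort panels
#'
#' Draws one [plot_age_cohort()] panel per (non-gated) age.  If `file` is
#' given a device is opened for it (`.pdf` or `.png` by extension); otherwise
#' the current device is used.
#'
#' @param obs a `"length_at_age"` table or `"age_cohorts"` list.
#' @param results optional [cohort_anova()] table for annotations.
#' @param file optional output file.
#' @param ages ages to plot (default: all present).
#' @param ... passed to [plot_age_cohort()].
#' @return Invisibly, the integer ages actually drawn.
#' @export
plot_cohorts <- function(obs, results = NULL, file = NULL, ages = NULL, ...) {
  cohorts <- if (inherits(obs, "age_cohorts")) obs else pool_by_age(obs)
  if (!is.null(ages)) cohorts <- cohorts[names(cohorts) %in% as.character(ages)]
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           pdf = grDevices::pdf(file, width = 10, height = 7),
           png = grDevices::png(file, width = 1400, height = 1000, res = 130),
           stop("unsupported figure format: ", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  k <- length(cohorts)
  nc <- ceiling(sqrt(k)); nr <- ceiling(k / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  drawn <- integer(0)
  for (d in cohorts) {
    age <- attr(d, "age")
    row <- if (!is.null(results)) results[results$age == age, , drop = FALSE]
           else NULL
    if (!is.null(row) && nrow(row) == 0) row <- NULL
    got <- plot_age_cohort(d, anova_row = row, ...)
    if (!is.null(got)) drawn <- c(drawn, age)
  }
  invisible(drawn)
}
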