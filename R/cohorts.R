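#' Calendar-year label of a back-calculated observation
#'
#' The last annulus of a fish was laid down in the year before capture, and
#' each earlier annulus one year earlier, so annulus `i` of a fish of age `A`
#' captured in year `Y` carries the label `(Y - 1) - (A - i)`.  With a single
#' 2015 campaign and ages 1-12 this places age-1 observations in 2003-2014 and
#' age-10 observations in 2012-2014.
#'
#' @param capture_year calendar year of capture.
#' @param A age at capture (annulus count).
#' @param i annulus index, `1 <= i <= A` (vectorised).
#' @return Integer calendar year(s).
#' @examples
#' assign_year_label(2015, 12, 1)   # 2003
#' assign_year_label(2015, 10, 10)  # 2014
#' @export
assign_year_label <- function(capture_year, A, i) {
  if (any(i < 1 | i > A)) stop("annulus index i must lie in 1..A")
  as.integer((capture_year - 1) - (A - i))
}

#' Split observations into per-age cohort datasets
#'
#' Partitions a back-calculated length-at-age table into one dataset per age,
#' each carrying its status and year-label level counts; ages with no
#' observations are omitted.  These per-age datasets are the unit of the
#' downstream two-way ANOVA and LOESS stages.
#'
#' @param obs a `"length_at_age"` table from [back_calculate()].
#' @return Named list (class `"age_cohorts"`) of data frames, names `"1"`,
#'   `"2"`, ...; each element has attributes `age`, `n_status_levels`,
#'   `n_year_levels`.
#' @export
pool_by_age <- function(obs) {
  stopifnot(all(c("age", "status", "year_label", "length") %in% names(obs)))
  ages <- sort(unique(obs$age))
  out <- lapply(ages, function(a) {
    d <- obs[obs$age == a, , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "age") <- a
    attr(d, "n_status_levels") <- length(unique(d$status))
    attr(d, "n_year_levels") <- length(unique(d$year_label))
    d
  })
  names(out) <- ages
  class(out) <- "age_cohorts"
  out
}

#' @export
print.age_cohorts <- function(x, ...) {
  cat("Age-cohort datasets:", length(x), "ages\n")
  for (d in x) {
    cat(sprintf("  age %2d: n = %4d, %d status level(s), %d year class(es)\n",
                attr(d, "age"), nrow(d), attr(d, "n_status_levels"),
                attr(d, "n_year_levels")))
  }
  invisible(x)
}

#' Original versus back-calculated sample sizes
#'
#' Tabulates, per status and age, the number of fish captured at that age
#' (original sample size) and the number of back-calculated observations at
#' that age (pooled sample size).  Because every fish of age `A` contributes
#' one observation at each age `1..A`, the back-calculated count at age `i` is
#' the cumulative tail of the original counts from `i` upwards, and each row
#' is non-increasing in age.
#'
#' @param records the `"fish_records"` table that was back-calculated.
#' @param obs the corresponding `"length_at_age"` table.
#' @return Data frame with columns `data` (`"original"`/`"back_calculated"`),
#'   `status`, and one column per age.
#' @export
sample_size_table <- function(records, obs) {
  if ((is.null(records) || nrow(records) == 0) &&
      (is.null(obs) || nrow(obs) == 0)) {
    return(data.frame(data = character(0), status = character(0)))
  }
  ages <- sort(unique(c(records$annulus, obs$age)))
  statuses <- unique(c(records$status, obs$status))
  fish <- fish_capture_table(records)
  orig <- t(vapply(statuses, function(st) {
    vapply(ages, function(a) {
      sum(fish$status == st & fish$age_at_capture == a)
    }, 0L)
  }, integer(length(ages))))
  bc <- t(vapply(statuses, function(st) {
    vapply(ages, function(a) sum(obs$status == st & obs$age == a), 0L)
  }, integer(length(ages))))
  counts <- rbind(orig, bc)
  colnames(counts) <- paste0("age_", ages)
  out <- data.frame(
    data = rep(c("original", "back_calculated"), each = length(statuses)),
    status = rep(statuses, 2),
    counts, stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(out) <- NULL
  out
}
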