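#' Construct a table of fish records
#'
#' Builds the canonical long-format table of per-fish otolith readings used by
#' the whole package: one row per fish-annulus, with the per-fish capture
#' measurements repeated on every row.  This is the in-memory analogue of the
#' on-disk CSV accepted by [read_fish_table()].
#'
#' @param fish_id vector of fish identifiers (one per fish).
#' @param status protection status of the site each fish came from, `"MR"`
#'   (marine reserve) or `"FR"` (fished reef).
#' @param site site label.
#' @param capture_year calendar year of capture (a single sampling campaign is
#'   the expected design).
#' @param age_at_capture integer age in years (annulus count), one per fish.
#' @param length_capture standard length at capture in mm.
#' @param radius_capture otolith radius at capture, same length unit as the
#'   annulus radii.
#' @param radii list with one numeric vector per fish: the otolith radius at
#'   each annulus 1..age, strictly increasing and not exceeding
#'   `radius_capture`.
#' @param validate run [validate_fish_records()] on the result (default TRUE).
#'
#' @return A data frame of class `"fish_records"` with columns `fish_id`,
#'   `status`, `site`, `capture_year`, `age_at_capture`, `length_capture`,
#'   `radius_capture`, `annulus`, `radius`.
#' @seealso [read_fish_table()], [validate_fish_records()]
#' @export
fish_records <- function(fish_id, status, site, capture_year, age_at_capture,
                         length_capture, radius_capture, radii,
                         validate = TRUE) {
  n <- length(fish_id)
  stopifnot(length(radii) == n)
  status <- rep_len(as.character(status), n)
  site <- rep_len(as.character(site), n)
  capture_year <- rep_len(as.integer(capture_year), n)
  age_at_capture <- rep_len(as.integer(age_at_capture), n)
  length_capture <- rep_len(as.numeric(length_capture), n)
  radius_capture <- rep_len(as.numeric(radius_capture), n)
  reps <- lengths(radii)
  out <- data.frame(
    fish_id        = rep(as.character(fish_id), reps),
    status         = rep(status, reps),
    site           = rep(site, reps),
    capture_year   = rep(capture_year, reps),
    age_at_capture = rep(age_at_capture, reps),
    length_capture = rep(length_capture, reps),
    radius_capture = rep(radius_capture, reps),
    annulus        = unlist(lapply(reps, seq_len), use.names = FALSE),
    radius         = unlist(radii, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fish_records", "data.frame")
  if (validate) validate_fish_records(out) else out
}

required_fish_columns <- c(
  "fish_id", "status", "site", "capture_year", "age_at_capture",
  "length_capture", "radius_capture"
)

#' Validate fish records
#'
#' Checks every per-fish invariant the downstream back-calculation relies on:
#' status is MR or FR; age at capture is a positive integer; the fish has
#' exactly one radius per annulus `1..age`; radii are positive, strictly
#' increasing, and do not exceed the otolith radius at capture; capture length
#' is positive.  Violations are collected and reported together, each naming
#' the offending `fish_id`.  A file mixing several capture years triggers a
#' warning (year labels are still computed per fish), not an error.
#'
#' @param records long-format data frame as returned by [fish_records()] or
#'   [read_fish_table()].
#' @return `records` (invisibly classed as `"fish_records"`), if valid.
#' @export
validate_fish_records <- function(records) {
  miss <- setdiff(c(required_fish_columns, "annulus", "radius"),
                  names(records))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  problems <- character(0)
  note <- function(what, ids) {
    ids <- unique(ids)
    problems[[length(problems) + 1L]] <<- paste0(
      "fish ", paste(utils::head(ids, 5), collapse = ", "),
      if (length(ids) > 5) sprintf(" (and %d more)", length(ids) - 5) else "",
      ": ", what)
  }
  r <- records[order(records$fish_id, records$annulus), , drop = FALSE]
  id <- r$fish_id

  bad <- !r$status %in% c("MR", "FR")
  if (any(bad)) note("status must be MR or FR", id[bad])
  bad <- is.na(r$age_at_capture) | r$age_at_capture < 1 |
    r$age_at_capture != round(r$age_at_capture)
  if (any(bad)) note("age_at_capture must be an integer >= 1", id[bad])

  # annuli must be exactly 1..A within each fish
  pos_in_fish <- stats::ave(seq_along(id), id, FUN = seq_along)
  n_in_fish <- stats::ave(seq_along(id), id, FUN = length)
  bad <- r$annulus != pos_in_fish | n_in_fish != r$age_at_capture
  if (any(bad)) note("annuli must be exactly 1..A (one radius per annulus)",
                     id[bad])

  bad <- is.na(r$radius) | r$radius <= 0
  if (any(bad)) note("annulus radii must all be positive", id[bad])
  same_fish <- c(FALSE, id[-1] == id[-length(id)])
  bad <- same_fish & c(TRUE, diff(r$radius) <= 0)
  if (any(bad, na.rm = TRUE)) {
    note("annulus radii must be strictly increasing", id[bad])
  }
  last <- c(id[-1] != id[-length(id)], TRUE)
  bad <- last & r$radius > r$radius_capture + 1e-12
  if (any(bad, na.rm = TRUE)) {
    note("last annulus radius exceeds radius at capture", id[bad])
  }
  bad <- is.na(r$length_capture) | r$length_capture <= 0
  if (any(bad)) note("length at capture must be positive", id[bad])
  for (col in c("capture_year", "age_at_capture", "length_capture",
                "radius_capture", "status")) {
    bad <- stats::ave(as.numeric(factor(r[[col]])), id,
                      FUN = function(x) length(unique(x))) > 1
    if (any(bad)) note(paste0(col, " differs across annulus rows"), id[bad])
  }
  if (length(problems) > 0) {
    stop("invalid fish records:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  if (length(unique(records$capture_year)) > 1) {
    warning("records mix several capture years; ",
            "year labels will be computed per fish", call. = FALSE)
  }
  if (!inherits(records, "fish_records")) {
    class(records) <- c("fish_records", class(records))
  }
  invisible(records)
}

#' Read a fish table from CSV
#'
#' Accepts both on-disk dialects: the canonical long format (columns
#' `fish_id`, `status`, `site`, `capture_year`, `age_at_capture`,
#' `length_capture`, `radius_capture`, `annulus`, `radius`; one row per
#' fish-annulus) and a wide format where each fish is one row and the annulus
#' radii sit in columns `r1`, `r2`, ... with cells beyond the fish's age left
#' empty.  The result is always long format and is validated on the way in.
#'
#' @param path path to a CSV file with a header row, UTF-8.
#' @return A validated `"fish_records"` data frame (long format).
#' @examples
#' path <- system.file("extdata", "synthetic_fish_wide.csv", package = "mfbc")
#' fish <- read_fish_table(path)
#' head(fish)
#' @export
read_fish_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_fish_columns, names(raw))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (all(c("annulus", "radius") %in% names(raw))) {
    rec <- raw[c(required_fish_columns, "annulus", "radius")]
  } else {
    rcols <- grep("^r[0-9]+$", names(raw), value = TRUE)
    if (length(rcols) == 0) {
      stop("missing required column(s): either annulus/radius (long format) ",
           "or r1..rN (wide format)")
    }
    rcols <- rcols[order(as.integer(sub("^r", "", rcols)))]
    radii <- lapply(seq_len(nrow(raw)), function(i) {
      r <- as.numeric(raw[i, rcols])
      r[!is.na(r)]
    })
    rec <- fish_records(
      fish_id = raw$fish_id, status = raw$status, site = raw$site,
      capture_year = raw$capture_year, age_at_capture = raw$age_at_capture,
      length_capture = raw$length_capture,
      radius_capture = raw$radius_capture,
      radii = radii, validate = FALSE
    )
  }
  validate_fish_records(rec)
  class(rec) <- c("fish_records", "data.frame")
  rec
}

# Format doubles so that read-back is bit-identical (17 significant digits
# round-trips IEEE doubles).
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

#' Write back-calculated observations to CSV
#'
#' Writes a length-at-age observation table (as produced by
#' [back_calculate()]) with numeric fields at full double precision, so that
#' [read_observations()] returns identical values.
#'
#' @param obs data frame of observations; must be non-empty and contain at
#'   least `fish_id`, `status`, `age`, `year_label`, `length`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  if (is.null(obs) || nrow(obs) == 0) {
    stop("no observations to write")
  }
  need <- c("fish_id", "status", "age", "year_label", "length")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0) {
    stop("observations missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- as.data.frame(lapply(obs, format_full), stringsAsFactors = FALSE)
  names(out) <- names(obs)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back-calculated observations from CSV
#'
#' Inverse of [write_observations()].
#'
#' @param path CSV path.
#' @return Data frame of observations.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("age", "year_label", "capture_year", "age_at_capture")) {
    if (col %in% names(obs)) obs[[col]] <- as.integer(obs[[col]])
  }
  obs
}

#' Analysis configuration
#'
#' Bundles the tunable settings of the statistical stages with their defaults:
#' significance level 0.05, LOESS span 0.95 (heavy smoothing, emphasising
#' large-scale trends over local wiggles), a minimum of 3 distinct year
#' classes before a LOESS panel is drawn, and anchor overrides for the
#' back-calculation (see [mfbc()]).
#'
#' @param alpha significance level, in (0, 1).
#' @param loess_span LOESS smoothing span, in (0, 1].
#' @param min_year_levels_for_loess minimum number of distinct year labels an
#'   age cohort needs before a LOESS fit is attempted.
#' @param rng_seed optional integer seed recorded with the configuration.
#' @param a_override,L0p_override,R0p_override optional fixed anchors passed
#'   through to [mfbc()]; `NULL` means estimate from the data.
#' @param r0p_mode `"population_mean"` (default) anchors every fish at the
#'   sample mean first-annulus radius; `"per_fish"` uses each fish's own
#'   first-annulus radius.
#' @param ss_type sums-of-squares type for the unbalanced two-way ANOVA
#'   (2 default; 1 and 3 available for sensitivity checks).
#' @param report_decimals decimals used when formatting summary tables.
#' @return A list of class `"mfbc_config"`.
#' @export
analysis_config <- function(alpha = 0.05, loess_span = 0.95,
                            min_year_levels_for_loess = 3, rng_seed = NULL,
                            a_override = NULL, L0p_override = NULL,
                            R0p_override = NULL,
                            r0p_mode = c("population_mean", "per_fish"),
                            ss_type = 2, report_decimals = 2) {
  stopifnot(alpha > 0, alpha < 1, loess_span > 0, loess_span <= 1,
            min_year_levels_for_loess >= 2, ss_type %in% 1:3)
  cfg <- list(
    alpha = alpha, loess_span = loess_span,
    min_year_levels_for_loess = as.integer(min_year_levels_for_loess),
    rng_seed = rng_seed, a_override = a_override,
    L0p_override = L0p_override, R0p_override = R0p_override,
    r0p_mode = match.arg(r0p_mode), ss_type = as.integer(ss_type),
    report_decimals = as.integer(report_decimals)
  )
  class(cfg) <- "mfbc_config"
  cfg
}
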