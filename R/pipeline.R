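#' Run the full back-calculation pipeline
#'
#' Orchestrates one reproducible run: simulate a population (or read one from
#' CSV), fit the modified Fry model, back-calculate all lengths-at-age, pool
#' into age cohorts, run the per-age two-way ANOVAs with power, build the
#' descriptive summary, and draw the LOESS panels.  All artefacts are written
#' to `out_dir`: `fish.csv`, `truth.csv` (when simulated), `params.json`,
#' `obs.csv`, `counts.csv`, `results.csv`, `table2.csv`, `figs/cohorts.pdf`,
#' and `run_log.txt` recording seed, configuration hash and gating decisions.
#'
#' The configuration is a nested list (or a YAML file with the same shape):
#' `sim` — arguments for [sim_config()] (ignored when `fish_csv` points at an
#' input file); `analysis` — arguments for [analysis_config()]; plus optional
#' scalar keys `capture_age`, `year_rule`, `make_figures`.  Unknown keys are
#' an error, so a typo cannot silently fall back to a default.  A single seed
#' fans out to per-stage substreams so stages can be re-run in isolation.
#'
#' @param config list or path to a YAML file; `NULL` means all defaults.
#' @param out_dir output directory (created if needed); required here or as
#'   `config$out_dir`.
#' @param seed integer seed for the run; required here or as `config$seed`.
#' @param fish_csv optional path to an existing fish table; skips simulation.
#' @param verbose print stage progress to stderr.
#' @return Invisibly, a list with the in-memory artefacts: `fish`, `truth`,
#'   `fit`, `obs`, `cohorts`, `counts`, `results`, `summary`, `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL,
                         fish_csv = NULL, verbose = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  allowed <- c("sim", "analysis", "capture_age", "year_rule", "out_dir",
               "seed", "fish_csv", "make_figures")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("missing required config key: out_dir")
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("missing required config key: seed")
  if (is.null(fish_csv)) fish_csv <- config$fish_csv
  make_figures <- if (is.null(config$make_figures)) TRUE else
    isTRUE(config$make_figures)
  capture_age <- if (is.null(config$capture_age)) "last_annulus" else
    config$capture_age
  year_rule <- if (is.null(config$year_rule)) "formation" else
    config$year_rule

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines[[length(log_lines) + 1L]] <<- msg
    if (verbose) message(msg)
  }
  # Per-stage substreams derived from the single run seed.
  stage_seed <- function(k) (as.integer(seed) * 101L + k * 7919L) %% 2147483647L

  say("seed: ", seed)
  say("config hash: ", config_hash(config))

  acfg <- do.call(analysis_config, c(config$analysis,
                                     list(rng_seed = as.integer(seed))))

  if (is.null(fish_csv)) {
    scfg <- do.call(sim_config, c(config$sim,
                                  list(rng_seed = stage_seed(1L))))
    say("stage simulate: n_fish = ",
        paste(names(scfg$n_fish), scfg$n_fish, sep = "=", collapse = ", "),
        ", sampling = ", scfg$sampling)
    sim <- simulate_population(scfg)
    fish <- sim$fish
    truth <- sim$truth
    write_table_full(truth, file.path(out_dir, "truth.csv"))
  } else {
    say("stage read: ", fish_csv)
    fish <- read_fish_table(fish_csv)
    truth <- NULL
  }
  write_table_full(as.data.frame(fish), file.path(out_dir, "fish.csv"))

  say("stage backcalc: fitting allometry and anchors")
  fit <- mfbc(fish, a_override = acfg$a_override,
              L0p_override = acfg$L0p_override,
              R0p_override = acfg$R0p_override, r0p_mode = acfg$r0p_mode)
  say("  allometry (", fit$method, "): a=", signif(coef(fit)[["a"]], 6),
      " b=", signif(coef(fit)[["b"]], 6), " c=", signif(coef(fit)[["c"]], 6))
  params <- c(as.list(fit$coefficients),
              as.list(if (is.null(fit$anchors)) list() else fit$anchors),
              list(method = fit$method, sigma = fit$sigma,
                   r0p_mode = fit$r0p_mode,
                   provenance = as.list(fit$provenance)))
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)

  obs <- withCallingHandlers(
    predict(fit, capture_age = capture_age, year_rule = year_rule),
    warning = function(w) {
      if (grepl("skipped", conditionMessage(w))) {
        say("  ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  write_observations(obs, file.path(out_dir, "obs.csv"))

  say("stage cohorts: ", length(unique(obs$age)), " age cohorts")
  cohorts <- pool_by_age(obs)
  counts <- sample_size_table(fish, obs)
  write_table_full(counts, file.path(out_dir, "counts.csv"))

  say("stage analyze: two-way ANOVA, type ", acfg$ss_type, " SS, alpha ",
      acfg$alpha)
  results <- cohort_anova(obs, alpha = acfg$alpha, ss_type = acfg$ss_type)
  for (i in seq_len(nrow(results))) {
    if (results$gate[i] != "analyzed") {
      say("  gate: age ", results$age[i], " -> ", results$gate[i])
    }
  }
  write_table_full(as.data.frame(results), file.path(out_dir, "results.csv"))
  summ <- cohort_summary_table(obs, decimals = acfg$report_decimals)
  write_table_full(as.data.frame(summ), file.path(out_dir, "table2.csv"))

  if (make_figures) {
    dir.create(file.path(out_dir, "figs"), showWarnings = FALSE)
    drawn <- plot_cohorts(cohorts, results,
                          file = file.path(out_dir, "figs", "cohorts.pdf"),
                          span = acfg$loess_span,
                          min_year_levels = acfg$min_year_levels_for_loess,
                          alpha = acfg$alpha)
    say("stage plot: panels drawn for ages ",
        paste(drawn, collapse = ", "))
  }
  writeLines(log_lines, log_path)
  invisible(list(fish = fish, truth = truth, fit = fit, obs = obs,
                 cohorts = cohorts, counts = counts, results = results,
                 summary = summ, out_dir = out_dir))
}

# Write a data frame with doubles at full precision (deterministic,
# round-trippable output).
write_table_full <- function(df, path) {
  out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Stable hash of the configuration (via its canonical YAML serialisation).
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}
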