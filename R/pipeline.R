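#' Pipeline configuration
#'
#' Bundles the data-generating configuration with regimen and estimation
#' settings and the output directory.  Serializable to YAML via
#' [write_pipeline_config()] / [read_pipeline_config()] (round-trips
#' unchanged).
#'
#' @param dgp a [dgp_config()].
#' @param out_dir output directory for pipeline artifacts.
#' @param p_never longer-term arm "never discontinue" atom mass
#'   (`NULL` = equal to each quarter's mass, 1/29).
#' @param B bootstrap replicates.
#' @param seed estimation seed (the data-generating seed lives in `dgp`).
#' @param truncation weight truncation bound.
#' @param floor propensity floor.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(dgp, out_dir, p_never = NULL, B = 200L, seed,
                            truncation = 50, floor = 1e-4) {
  stopifnot(inherits(dgp, "dgp_config"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(dgp = dgp, out_dir = out_dir, p_never = p_never,
              B = as.integer(B), seed = as.integer(seed),
              truncation = truncation, floor = floor)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$dgp <- unclass(x$dgp)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  d <- x$dgp
  dgp <- dgp_config(n_subjects = d$n_subjects, n_quarters = d$n_quarters,
                    baseline = d$baseline, treatment = d$treatment,
                    covariate = d$covariate, event = d$event,
                    censoring = d$censoring, dispensing = d$dispensing,
                    seed = d$seed)
  pipeline_config(dgp = dgp, out_dir = x$out_dir, p_never = x$p_never,
                  B = x$B, seed = x$seed, truncation = x$truncation,
                  floor = x$floor)
}

#' Write the raw cohort input files
#'
#' Writes `subjects.csv`, `covariates.csv` (the measurement stream),
#' `terminal.csv`, `dispensings.csv` and the simulator's own `panel.csv`
#' (one row per subject-quarter: `t`, `on_treatment`, `L`, `event`,
#' `censor_cause`).  Day 0 is the index date; quarters are 1-based.
#'
#' @param cohort a `cohort_panel`.
#' @param dispensings dispensing records from [emit_dispensings()].
#' @param dir target directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_csvs <- function(cohort, dispensings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(cohort$subjects, file.path(dir, "subjects.csv"))
  fwrite(cohort$measurements, file.path(dir, "covariates.csv"))
  fwrite(cohort$subjects[, .(subject_id, terminal_t, terminal_cause)],
         file.path(dir, "terminal.csv"))
  fwrite(dispensings, file.path(dir, "dispensings.csv"))
  fwrite(cohort$panel[, .(subject_id, t, on_treatment, L = L_obs, event,
                          censor_cause)],
         file.path(dir, "panel.csv"))
  invisible(dir)
}

#' Run the full pipeline: simulate, build panel, weight, estimate, report
#'
#' Executes all stages in order: cohort simulation, dispensing emission,
#' input CSV writing, panel reconstruction from the written inputs (the
#' analysis path never sees the simulator's internal state), compliance,
#' propensity models, weights, estimation with bootstrap inference, and
#' report writing (`survival.csv`, `risk_differences.csv`,
#' `auc_test.json`, `manifest.json`).  Every artifact records the
#' configuration hash; re-running with an identical configuration
#' reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @return a `run_manifest` (invisibly also written to `manifest.json`):
#'   configuration hash, package version, per-arm per-quarter compatible
#'   at-risk counts, and warnings (truncation fraction, dropped bootstrap
#'   replicates, empty risk sets).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  manifest <- NULL
  tryCatch({
    cohort <- simulate_cohort(config$dgp)
    disp <- emit_dispensings(cohort)
    stage <- "write-inputs"
    ind <- file.path(config$out_dir, "inputs")
    write_cohort_csvs(cohort, disp, ind)
    stage <- "build-panel"
    panel <- build_person_quarters(
      records = fread(file.path(ind, "dispensings.csv")),
      covariates = fread(file.path(ind, "covariates.csv")),
      terminal = fread(file.path(ind, "terminal.csv")),
      subjects = fread(file.path(ind, "subjects.csv")),
      L_fill = config$dgp$baseline$L_fill
    )
    stage <- "estimate"
    fit <- msm_fit(panel, B = config$B, seed = config$seed,
                   p_never = config$p_never,
                   truncation = config$truncation, floor = config$floor,
                   n_quarters = config$dgp$n_quarters)
    stage <- "report"
    ## hash covers the scientific configuration, not the output location
    hash <- object_hash(unclass(config)[setdiff(names(config), "out_dir")])
    surv <- rbindlist(lapply(names(fit$curves), function(a) {
      cv <- fit$curves[[a]]
      data.table(arm = a, t = cv$t, S = cv$S, risk = cv$risk,
                 ci_low = cv$ci_low, ci_high = cv$ci_high)
    }))
    fwrite(surv, file.path(config$out_dir, "survival.csv"))
    fwrite(fit$rd, file.path(config$out_dir, "risk_differences.csv"))
    at <- fit$auc_test
    jsonlite::write_json(
      list(config_hash = hash,
           area_short_term = at$areas[["short_term"]],
           area_longer_term = at$areas[["longer_term"]],
           difference = at$difference, se = at$se, p_value = at$p_value,
           B = at$B, seed = at$seed),
      file.path(config$out_dir, "auc_test.json"), auto_unbox = TRUE,
      digits = NA)

    prep_counts <- lapply(names(fit$curves), function(a) {
      cmp <- evaluate_compliance(panel, discontinuation_law(
        a, p_never = if (a == "longer_term") config$p_never,
        n_quarters = config$dgp$n_quarters))
      as.integer(sum_by_quarter(as.numeric(cmp$compatible), cmp$t,
                                config$dgp$n_quarters))
    })
    names(prep_counts) <- names(fit$curves)
    manifest <- list(
      config_hash = hash,
      package_version = as.character(utils::packageVersion("stochmsm")),
      n_subjects = config$dgp$n_subjects,
      n_events = sum(panel$event),
      entering_by_quarter = prep_counts,
      warnings = list(
        frac_truncated = lapply(fit$weights, `[[`, "frac_truncated"),
        bootstrap_dropped = fit$boot$n_dropped,
        any_empty_risk_set = fit$boot$point$empty
      )
    )
    class(manifest) <- "run_manifest"
    jsonlite::write_json(unclass(manifest),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) {
    ## abort with the failing stage; clean partial top-level outputs
    for (f in c("survival.csv", "risk_differences.csv", "auc_test.json",
                "manifest.json")) {
      unlink(file.path(config$out_dir, f))
    }
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$fit <- fit
  invisible(manifest)
}

#' Built-in fixtures at three scales
#'
#' * `"tiny"`: a deterministic, hand-written 12-subject, 8-quarter cohort
#'   (no randomness; `seed` ignored) whose treatment patterns, events and
#'   censoring layout are fixed in code, with dispensing records that
#'   reproduce the on/off patterns exactly.  Used by the
#'   exhaustive-enumeration tests.
#' * `"small"`: 2,000 subjects from the `"reduced"` preset.
#' * `"default"`: 20,000 subjects from the `"default"` preset.
#'
#' @param scale fixture scale.
#' @param seed integer seed (used by the simulated scales).
#' @param dir optional directory to write the input CSVs to.
#' @return a list with `records`, `covariates`, `terminal`, `subjects`,
#'   `panel` (built via [build_person_quarters()]), and for simulated
#'   scales the `cohort` and `config`.
#' @export
make_fixture <- function(scale = c("tiny", "small", "default"), seed = 1L,
                         dir = NULL) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    fx <- tiny_fixture_tables()
  } else {
    n <- if (scale == "small") 2000L else 20000L
    preset <- if (scale == "small") "reduced" else "default"
    cfg <- dgp_preset(preset, n_subjects = n, seed = seed)
    cohort <- simulate_cohort(cfg)
    disp <- emit_dispensings(cohort)
    fx <- list(
      records = disp,
      covariates = cohort$measurements,
      terminal = cohort$subjects[, .(subject_id, terminal_t, terminal_cause)],
      subjects = cohort$subjects,
      cohort = cohort, config = cfg
    )
  }
  fx$panel <- build_person_quarters(fx$records, fx$covariates, fx$terminal,
                                    fx$subjects)
  fx$scale <- scale
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(fx$records, file.path(dir, "dispensings.csv"))
    fwrite(fx$covariates, file.path(dir, "covariates.csv"))
    fwrite(fx$terminal, file.path(dir, "terminal.csv"))
    fwrite(fx$subjects, file.path(dir, "subjects.csv"))
  }
  fx
}

## Hand-written 12-subject / 8-quarter truth table.  `pattern` gives the
## on/off sequence up to the terminal quarter; terminal causes: admin at
## quarter 8 unless stated.
tiny_fixture_tables <- function() {
  spec <- list(
    list(id = 1L,  pat = c(1, 1, 1, 1, 1, 1, 1, 1), cause = "admin"),
    list(id = 2L,  pat = c(1, 1, 1, 0, 0, 0, 0, 0), cause = "admin"),
    list(id = 3L,  pat = c(1, 1, 0, 0, 0),          cause = "event"),
    list(id = 4L,  pat = c(1, 1, 1, 1, 1, 1, 1, 1), cause = "admin"),
    list(id = 5L,  pat = c(1, 0, 0, 0, 0, 0, 0, 0), cause = "admin"),
    list(id = 6L,  pat = c(1, 1, 1, 1),             cause = "death"),
    list(id = 7L,  pat = c(1, 1, 1, 1, 1, 1),       cause = "event"),
    list(id = 8L,  pat = c(1, 1, 0, 1, 1, 1, 1, 1), cause = "admin"),
    list(id = 9L,  pat = c(0, 0, 0, 0, 0, 0, 0, 0), cause = "admin"),
    list(id = 10L, pat = c(1, 1, 1, 1, 1),          cause = "disenroll"),
    list(id = 11L, pat = c(1, 1, 1, 1, 1, 1, 1, 0), cause = "admin"),
    list(id = 12L, pat = c(1, 1, 1, 0),             cause = "event")
  )
  recs <- rbindlist(lapply(spec, function(s) {
    on_q <- which(s$pat == 1)
    if (!length(on_q)) return(NULL)
    data.table(subject_id = s$id, start_day = 90L * (on_q - 1L),
               days_supply = 90L)
  }))
  covs <- rbindlist(lapply(spec, function(s)
    data.table(subject_id = s$id, t = 1L, L = -2.6)))
  term <- rbindlist(lapply(spec, function(s)
    data.table(subject_id = s$id, terminal_t = length(s$pat),
               terminal_cause = s$cause)))
  subj <- rbindlist(lapply(spec, function(s)
    data.table(subject_id = s$id, age = 68.6, agec = 0, frailty = 0L,
               L0 = -2.6)))
  list(records = recs, covariates = covs, terminal = term, subjects = subj)
}
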