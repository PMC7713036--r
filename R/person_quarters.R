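#' Mean imputation with a paired indicator
#'
#' Replaces missing values of a declared covariate by a fill value and adds
#' (or overwrites) a paired `<field>_imputed` indicator equal to 1 exactly
#' where imputation occurred.
#'
#' @param panel a `data.frame`/`data.table`.
#' @param field name of the column to impute (must exist).
#' @param fill_value value substituted for missing entries.
#' @return a `data.table` copy of `panel` with `field` filled and the
#'   indicator column added.
#' @export
#' @examples
#' impute_with_indicator(data.frame(L = c(-2.1, NA)), "L", -2.5)
impute_with_indicator <- function(panel, field, fill_value) {
  if (!is.character(field) || length(field) != 1L ||
      !field %in% names(panel)) {
    stop("unknown field: ", field, call. = FALSE)
  }
  dt <- as.data.table(panel)
  ind <- paste0(field, "_imputed")
  miss <- is.na(dt[[field]])
  dt[, (ind) := as.integer(miss)]
  if (any(miss)) set(dt, which(miss), field, fill_value)
  dt[]
}

#' Build the quarterly analysis panel from raw inputs
#'
#' Converts dispensing records, a covariate measurement stream and terminal
#' events into one row per subject-quarter through the terminal quarter:
#' day-level coverage with stockpiling is summarised into a per-quarter PDC
#' and on/off classification (PDC >= `pdc_threshold`); the bone-density
#' score is updated in quarters with a new measurement and otherwise carried
#' forward without expiry; subjects with no measurement at or before a
#' quarter have the score mean-imputed (`L_fill`) with a paired indicator;
#' `tslm` counts quarters since the most recent measurement (entry counts as
#' quarter 1 for never-measured subjects, so `tslm = t - 1` under
#' imputation); `cum_on` accumulates on-treatment quarters.
#'
#' @param records dispensing records: `subject_id`, `start_day`,
#'   `days_supply`.
#' @param covariates measurement stream: `subject_id`, `t` (quarter the
#'   measurement falls in), `L` (measured score).
#' @param terminal one row per subject: `subject_id`, `terminal_t`,
#'   `terminal_cause` (one of `"event"`, `"death"`, `"disenroll"`,
#'   `"exclusion"`, `"admin"`).
#' @param subjects baseline table: `subject_id`, `agec` (standardised age),
#'   `frailty`.
#' @param pdc_threshold on-treatment threshold (default 0.5).
#' @param L_fill imputation value for the score (default -2.5).
#' @return a `data.table` with columns `subject_id`, `t`, `pdc`,
#'   `on_treatment`, `on_prev`, `cum_on`, `L_obs`, `L_cat`, `L_imputed`,
#'   `tslm`, `agec`, `frailty`, `event`, `censor_cause`, keyed by subject
#'   and quarter.  `on_prev` at quarter 1 is 1 (cohort entry is treatment
#'   initiation).
#' @export
build_person_quarters <- function(records, covariates, terminal, subjects,
                                  pdc_threshold = 0.5, L_fill = -2.5) {
  records <- as.data.table(records)
  covariates <- as.data.table(covariates)
  terminal <- as.data.table(terminal)
  subjects <- as.data.table(subjects)

  if (anyDuplicated(terminal$subject_id)) {
    stop("data consistency: multiple terminal events for a subject",
         call. = FALSE)
  }
  bad <- setdiff(unique(records$subject_id), terminal$subject_id)
  if (length(bad)) {
    stop("data consistency: dispensing records for unknown subjects",
         call. = FALSE)
  }

  panel <- terminal[, .(t = seq_len(terminal_t)), by = subject_id]

  ## per-quarter covered days from the coverage-block algorithm
  if (nrow(records)) {
    recs <- terminal[, .(subject_id, terminal_t)][records, on = "subject_id"]
    cov <- recs[, {
      nq <- terminal_t[1L]
      .(t = seq_len(nq),
        covered = quarter_covered_days(coverage_blocks(start_day, days_supply),
                                       nq))
    }, by = subject_id]
    panel <- cov[panel, on = c("subject_id", "t")]
    panel[is.na(covered), covered := 0]
  } else {
    panel[, covered := 0]
  }
  panel[, pdc := covered / 90]
  panel[, covered := NULL]
  panel[, on_treatment := as.integer(pdc >= pdc_threshold)]
  panel[, on_prev := shift(on_treatment, fill = 1L), by = subject_id]
  panel[, cum_on := cumsum(on_treatment), by = subject_id]

  ## carry-forward covariate: most recent measurement at or before t
  setkey(panel, subject_id, t)
  if (nrow(covariates)) {
    cv <- covariates[, .(subject_id, meas_t = t, meas_q = t, L_obs = L)]
    setkey(cv, subject_id, meas_t)
    rolled <- cv[panel[, .(subject_id, meas_t = t)],
                 on = c("subject_id", "meas_t"), roll = Inf]
    panel[, L_obs := rolled$L_obs]
    ## quarters since last measurement; never-measured counts entry
    ## (quarter 1) as the imputed value's origin
    panel[, tslm := as.integer(t - fifelse(is.na(rolled$meas_q), 1,
                                           rolled$meas_q))]
  } else {
    panel[, L_obs := NA_real_]
    panel[, tslm := as.integer(t - 1L)]
  }

  panel <- impute_with_indicator(panel, "L_obs", L_fill)
  setnames(panel, "L_obs_imputed", "L_imputed")
  panel[, L_cat := bmd_category(L_obs)]

  panel <- subjects[, .(subject_id, agec, frailty)][panel, on = "subject_id"]

  term2 <- terminal[, .(subject_id, terminal_t, terminal_cause)]
  panel <- term2[panel, on = "subject_id"]
  panel[, event := as.integer(t == terminal_t & terminal_cause == "event")]
  panel[, censor_cause := fifelse(t == terminal_t & terminal_cause != "event",
                                  terminal_cause, NA_character_)]
  panel[, c("terminal_t", "terminal_cause") := NULL]
  setcolorder(panel, c("subject_id", "t", "pdc", "on_treatment", "on_prev",
                       "cum_on", "L_obs", "L_cat", "L_imputed", "tslm",
                       "agec", "frailty", "event", "censor_cause"))
  setkey(panel, subject_id, t)
  panel[]
}
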