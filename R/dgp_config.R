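#' Configuration of the synthetic cohort data-generating process
#'
#' Builds and validates the full parameter set of the synthetic longitudinal
#' cohort: baseline covariate distributions, the on/off treatment process,
#' the treatment-affected bone-density-like score `L`, the rare terminal
#' event hazard, the censoring hazards, and the dispensing emission process.
#'
#' The cohort follows subjects over `n_quarters` 90-day quarters (day 0 is
#' the index date; quarter `t` spans days `[90(t-1), 90t)`).  All subjects
#' enter on treatment (the index dispensing).  Each quarter, treatment is
#' drawn from a logistic continuation model (if on in the previous quarter)
#' or a logistic re-initiation model (if off), both driven by the *measured*
#' bone-density category, frailty, age, and (continuation only) cumulative
#' exposure.  The latent score `L` evolves as
#' `L(t) = L(t-1) + drift + treat_effect * on(t) + noise`, so past treatment
#' feeds back into the confounder.  The event hazard is a per-quarter
#' logistic hazard in cumulative exposure, the latent score and frailty.
#' Death, disenrollment and exclusion act as competing censoring processes;
#' administrative censoring occurs at `n_quarters`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_quarters follow-up horizon in quarters (default 40, i.e. 10 years).
#' @param baseline list: `age_mean`, `age_sd` (years), `frailty_prev`
#'   (prevalence of the binary frailty covariate), `L0_mean`, `L0_sd`
#'   (initial bone-density score, T-score scale), `p_L0_measured`
#'   (probability the baseline score is measured), `L_fill` (imputation value
#'   used when unmeasured, default -2.5).
#' @param treatment list of logistic coefficients for the treatment process:
#'   `cont_intercept`, `cont_cat` (length-4 offsets for bone-density
#'   categories 1-4), `cont_cum` (per cumulative on-quarter), `cont_frailty`,
#'   `cont_age` (per SD of age); and `init_intercept`, `init_cat`,
#'   `init_frailty`, `init_age` for off-to-on re-initiation.
#' @param covariate list: `drift` (score change per quarter off treatment),
#'   `treat_effect` (additional change per quarter on treatment), `noise_sd`,
#'   `p_measure` (per-quarter probability the score is re-measured).
#' @param event list of per-quarter logistic hazard coefficients:
#'   `intercept`, `cum` (per cumulative on-quarter), `L` (per unit of the
#'   centred latent score), `frailty`.
#' @param censoring list with elements `death`, `disenroll`, `exclusion`,
#'   each a list of logistic hazard coefficients (`intercept`, `age`,
#'   `frailty`, `cat` length-4), and logical `model_admin` (whether the
#'   administrative end should be treated as a modellable cause; default
#'   `FALSE`, i.e. deterministic at `n_quarters`).
#' @param dispensing list: `days_supply` (days per dispensing), `delay_max`
#'   (maximum uniform refill delay in days, < 45), `p_overlap` (probability a
#'   refill is emitted early, overlapping the prior supply by 1-30 days).
#' @param seed integer seed; mandatory for reproducibility.
#'
#' @return an object of class `dgp_config` (a validated named list).
#' @export
#' @examples
#' cfg <- dgp_config(n_subjects = 100, seed = 1)
#' cfg$event$intercept
dgp_config <- function(n_subjects,
                       n_quarters = 40L,
                       baseline = list(),
                       treatment = list(),
                       covariate = list(),
                       event = list(),
                       censoring = list(),
                       dispensing = list(),
                       seed) {
  if (missing(n_subjects) || length(n_subjects) != 1L || is.na(n_subjects) ||
      n_subjects < 1) {
    stop("invalid config: `n_subjects` must be a single integer >= 1",
         call. = FALSE)
  }
  if (length(n_quarters) != 1L || is.na(n_quarters) || n_quarters < 1) {
    stop("invalid config: `n_quarters` must be a single integer >= 1",
         call. = FALSE)
  }
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("invalid config: `seed` is mandatory", call. = FALSE)
  }

  defaults <- dgp_defaults()
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_quarters = as.integer(n_quarters),
    baseline   = utils::modifyList(defaults$baseline,   baseline),
    treatment  = utils::modifyList(defaults$treatment,  treatment),
    covariate  = utils::modifyList(defaults$covariate,  covariate),
    event      = utils::modifyList(defaults$event,      event),
    censoring  = utils::modifyList(defaults$censoring,  censoring),
    dispensing = utils::modifyList(defaults$dispensing, dispensing),
    seed       = as.integer(seed)
  )
  class(cfg) <- "dgp_config"
  validate_dgp_config(cfg)
  cfg
}

## Default coefficient sets: a 20,000-subject cohort yields on the order of
## tens of events over 40 quarters (rare-event regime, per-quarter hazard
## well below 1e-3), treatment prevalence declines over follow-up, and the
## bone-density score both responds to treatment and drives subsequent
## treatment and outcome (treatment-confounder feedback).
dgp_defaults <- function() {
  list(
    baseline = list(
      age_mean = 68.6, age_sd = 9.1, frailty_prev = 0.14,
      L0_mean = -2.6, L0_sd = 0.7, p_L0_measured = 0.72, L_fill = -2.5
    ),
    treatment = list(
      cont_intercept = 3.0,
      cont_cat = c(-1.6, -0.6, 0, 1.0),
      cont_cum = -0.12,
      cont_frailty = 0.9,
      cont_age = 0.10,
      init_intercept = -3.4,
      init_cat = c(-1.2, -0.5, 0, 1.0),
      init_frailty = 0.9,
      init_age = 0
    ),
    covariate = list(
      drift = -0.01, treat_effect = 0.05, noise_sd = 0.10, p_measure = 0.10
    ),
    event = list(
      intercept = qlogis(8e-5), cum = 0.10, L = -1.4, frailty = 0.9
    ),
    censoring = list(
      death = list(intercept = qlogis(0.0055), age = 0.5, frailty = 0.8,
                   cat = c(0, 0, 0, 0)),
      disenroll = list(intercept = qlogis(0.015), age = -0.15, frailty = -0.4,
                       cat = c(0.8, 0.3, 0, -0.6)),
      exclusion = list(intercept = qlogis(0.0025), age = 0.3, frailty = 0.8,
                       cat = c(0, 0, 0, 0)),
      model_admin = FALSE
    ),
    dispensing = list(days_supply = 90L, delay_max = 10L, p_overlap = 0.25)
  )
}

validate_dgp_config <- function(cfg) {
  stopifnot(inherits(cfg, "dgp_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  ## intercepts may be infinite (degenerate always/never processes used in
  ## edge-case analyses); slopes must be finite
  num1i <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)

  b <- cfg$baseline
  chk(num1(b$age_sd) && b$age_sd > 0, "baseline age_sd must be > 0")
  chk(num1(b$frailty_prev) && b$frailty_prev >= 0 && b$frailty_prev <= 1,
      "frailty_prev must be a probability")
  chk(num1(b$p_L0_measured) && b$p_L0_measured >= 0 && b$p_L0_measured <= 1,
      "p_L0_measured must be a probability")
  chk(num1(b$L0_sd) && b$L0_sd >= 0, "L0_sd must be >= 0")

  tr <- cfg$treatment
  chk(length(tr$cont_cat) == 4L && length(tr$init_cat) == 4L,
      "treatment category offsets must have length 4")
  for (nm in c("cont_cum", "cont_frailty", "cont_age",
               "init_frailty", "init_age")) {
    chk(num1(tr[[nm]]), paste0("treatment$", nm, " must be a finite scalar"))
  }
  for (nm in c("cont_intercept", "init_intercept")) {
    chk(num1i(tr[[nm]]), paste0("treatment$", nm, " must be a scalar"))
  }

  cv <- cfg$covariate
  chk(num1(cv$noise_sd) && cv$noise_sd >= 0, "noise_sd must be >= 0")
  chk(num1(cv$p_measure) && cv$p_measure >= 0 && cv$p_measure <= 1,
      "p_measure must be a probability")

  ev <- cfg$event
  chk(num1i(ev$intercept), "event$intercept must be a scalar")
  for (nm in c("cum", "L", "frailty")) {
    chk(num1(ev[[nm]]), paste0("event$", nm, " must be a finite scalar"))
  }

  cs <- cfg$censoring
  for (cause in c("death", "disenroll", "exclusion")) {
    cc <- cs[[cause]]
    chk(is.list(cc) && num1i(cc$intercept) && num1(cc$age) && num1(cc$frailty),
        paste0("censoring$", cause, " coefficients malformed"))
    chk(length(cc$cat) == 4L, paste0("censoring$", cause, "$cat length 4"))
  }

  dp <- cfg$dispensing
  chk(num1(dp$days_supply) && dp$days_supply >= 1, "days_supply must be >= 1")
  chk(num1(dp$delay_max) && dp$delay_max >= 0 && dp$delay_max < 45,
      "delay_max must be in [0, 45) days")
  chk(num1(dp$p_overlap) && dp$p_overlap >= 0 && dp$p_overlap <= 1,
      "p_overlap must be a probability")

  ## Probability range check over the covariate support: logistic link keeps
  ## every hazard in (0, 1); verify the default-support linear predictors do
  ## not produce degenerate (non-finite) probabilities.
  probe_cat <- 1:4
  probe <- expand.grid(cat = probe_cat, fr = c(0, 1), agec = c(-3, 3),
                       cum = c(0, cfg$n_quarters))
  lp_cont <- tr$cont_intercept + tr$cont_cat[probe$cat] +
    tr$cont_cum * probe$cum + tr$cont_frailty * probe$fr +
    tr$cont_age * probe$agec
  chk(all(is.finite(plogis(lp_cont))), "continuation probabilities degenerate")
  invisible(cfg)
}

#' Preset data-generating configurations used across the package
#'
#' * `"default"`: the confounded study-scale configuration (rare events; a
#'   20,000-subject cohort yields on the order of 20-60 events).
#' * `"null"`: event hazard independent of treatment and of the
#'   treatment-affected score (both counterfactual arms share the same true
#'   risk); event rate elevated so cohorts of ~2,000 subjects carry enough
#'   events for inference.
#' * `"strong"`: a pronounced cumulative-exposure effect (0.15 on the
#'   log-odds per on-quarter) with an elevated event rate; used for power
#'   assessment at reduced cohort sizes.
#' * `"reduced"`: the default confounding structure with an elevated event
#'   rate, for coverage studies at ~2,000 subjects.
#'
#' @param name preset name.
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @param ... further overrides passed to [dgp_config()].
#' @return a `dgp_config`.
#' @export
dgp_preset <- function(name = c("default", "null", "strong", "reduced"),
                       n_subjects, seed, ...) {
  name <- match.arg(name)
  ev <- switch(
    name,
    default = list(),
    null    = list(intercept = qlogis(8e-4), cum = 0, L = 0, frailty = 0.3),
    strong  = list(intercept = qlogis(6e-4), cum = 0.22, L = -1.4,
                   frailty = 0.9),
    reduced = list(intercept = qlogis(1.5e-3), cum = 0.10, L = -1.4,
                   frailty = 0.9)
  )
  dgp_config(n_subjects = n_subjects, event = ev, seed = seed, ...)
}

#' @export
print.dgp_config <- function(x, ...) {
  cat("<dgp_config>\n")
  cat("  subjects:", x$n_subjects, " quarters:", x$n_quarters,
      " seed:", x$seed, "\n")
  cat("  event hazard: logit =", signif(x$event$intercept, 4), "+",
      x$event$cum, "* cum +", x$event$L, "* (L + 2.6) +",
      x$event$frailty, "* frailty\n")
  invisible(x)
}
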