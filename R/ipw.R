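## ---- model specification ---------------------------------------------

## Design matrices and risk sets for the six propensity models.  Built once
## per panel; refits (e.g. bootstrap replicates) only change case weights.
build_model_specs <- function(panel) {
  stopifnot(is.data.table(panel))
  n <- nrow(panel)
  cat1 <- as.numeric(panel$L_cat == 1L)
  cat2 <- as.numeric(panel$L_cat == 2L)
  cat4 <- as.numeric(panel$L_cat == 4L)
  base <- cbind(`(Intercept)` = 1, cat1 = cat1, cat2 = cat2, cat4 = cat4,
                L_imputed = panel$L_imputed, tslm = panel$tslm,
                frailty = panel$frailty, agec = panel$agec, t = panel$t)
  cum_prev <- panel$cum_on - panel$on_treatment

  idx_cont <- which(panel$on_prev == 1L)
  idx_init <- which(panel$on_prev == 0L)
  is_event <- panel$event == 1L
  cc <- panel$censor_cause
  idx_death <- which(!is_event)
  idx_excl  <- which(!is_event & (is.na(cc) | cc != "death"))
  idx_disen <- which(!is_event & (is.na(cc) | !cc %in% c("death", "exclusion")))

  Xcens <- cbind(base, on_treatment = panel$on_treatment)

  specs <- list(
    continuation = list(idx = idx_cont,
                        X = cbind(base, cum = cum_prev)[idx_cont, , drop = FALSE],
                        y = panel$on_treatment[idx_cont]),
    initiation   = list(idx = idx_init,
                        X = base[idx_init, , drop = FALSE],
                        y = panel$on_treatment[idx_init]),
    death        = list(idx = idx_death,
                        X = Xcens[idx_death, , drop = FALSE],
                        y = as.numeric(!is.na(cc[idx_death]) &
                                         cc[idx_death] == "death")),
    exclusion    = list(idx = idx_excl,
                        X = Xcens[idx_excl, , drop = FALSE],
                        y = as.numeric(!is.na(cc[idx_excl]) &
                                         cc[idx_excl] == "exclusion")),
    disenroll    = list(idx = idx_disen,
                        X = Xcens[idx_disen, , drop = FALSE],
                        y = as.numeric(!is.na(cc[idx_disen]) &
                                         cc[idx_disen] == "disenroll"))
  )
  attr(specs, "n_rows") <- n
  specs
}

refit_models <- function(specs, row_w = NULL, warm = NULL, tol = 1e-6) {
  fits <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    w <- if (is.null(row_w)) NULL else row_w[sp$idx]
    f <- fit_logit(sp$X, sp$y, w = w, tol = tol,
                   start = if (!is.null(warm)) warm[[nm]]$coef else NULL)
    if (!f$converged && !f$degenerate) {
      stop("propensity model failed to converge: ", nm, call. = FALSE)
    }
    f
  })
  names(fits) <- names(specs)
  fits
}

#' Fit the propensity models for treatment and censoring
#'
#' Fits, by weighted logistic regression, (1) the treatment continuation
#' model (probability of being on treatment given on in the previous
#' quarter), which includes a main term for cumulative exposure to date;
#' (2) the treatment (re-)initiation model (probability of being on given
#' off in the previous quarter); and (3-5) one per-quarter hazard model for
#' each stochastic censoring cause (death, exclusion, disenrollment), each
#' fit only on person-quarters at risk of that cause (events excluded;
#' causes ordered death > exclusion > disenrollment).  Administrative end
#' of follow-up is deterministic at the horizon and reported as a
#' degenerate cause rather than modelled.  All models adjust for the
#' bone-density category, its imputation indicator, time since the last
#' measurement, frailty, standardised age, and follow-up time; the
#' censoring models additionally adjust for current treatment.
#'
#' A cause with no transitions is flagged degenerate and contributes
#' probability 0 (hence weight component 1) downstream.
#'
#' @param panel a person-quarter `data.table` (from [simulate_cohort()]'s
#'   `$panel` or [build_person_quarters()]), sorted by subject and quarter.
#' @param weights optional nonnegative per-row case weights (e.g. bootstrap
#'   frequency weights).
#' @return an object of class `propensity_models`: the fitted models with
#'   coefficients, fitted probabilities, risk-set sizes and event counts.
#' @export
fit_propensity_models <- function(panel, weights = NULL) {
  if (inherits(panel, "cohort_panel")) panel <- panel$panel
  specs <- build_model_specs(panel)
  fits <- refit_models(specs, row_w = weights)
  out <- list(specs = specs, fits = fits, n_rows = attr(specs, "n_rows"))
  class(out) <- "propensity_models"
  out
}

#' @export
print.propensity_models <- function(x, ...) {
  cat("<propensity_models>\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-12s n=%8.0f events=%8.0f %s\n", nm, f$n, f$events,
                if (f$degenerate) "(degenerate)" else ""))
  }
  invisible(x)
}

## Fitted probability of being ON treatment, one entry per panel row.
prob_on_vector <- function(specs, fits) {
  p <- numeric(attr(specs, "n_rows"))
  for (nm in c("continuation", "initiation")) {
    p[specs[[nm]]$idx] <- fits[[nm]]$fitted
  }
  p
}

## Per-row probability of remaining uncensored (all stochastic causes),
## and the pooled marginal per-quarter analogue used as the stabilization
## numerator.  Returns num/den ratio per row.
censoring_ratio_vector <- function(specs, fits, tq, Tq, row_w = NULL,
                                   floor = 1e-4) {
  n <- attr(specs, "n_rows")
  if (is.null(row_w)) row_w <- rep(1, n)
  num <- rep(1, n); den <- rep(1, n)
  for (nm in c("death", "exclusion", "disenroll")) {
    sp <- specs[[nm]]; f <- fits[[nm]]
    mu <- if (f$degenerate && f$events == 0) rep(0, length(sp$idx)) else f$fitted
    ## pooled marginal per-quarter cause hazard on the same risk set
    wset <- row_w[sp$idx]
    m_t <- sum_by_quarter(wset * sp$y, tq[sp$idx], Tq) /
      pmax(sum_by_quarter(wset, tq[sp$idx], Tq), .Machine$double.eps)
    num[sp$idx] <- num[sp$idx] * (1 - m_t[tq[sp$idx]])
    den[sp$idx] <- den[sp$idx] * pmax(1 - mu, floor)
  }
  num / den
}

#' Treatment component of the inverse-probability weights
#'
#' For each subject-quarter compatible with the regimen, the cumulative
#' product over quarters `k <= t` of the ratio between the regimen's
#' intervention probability of the observed treatment value at `k`
#' (the stabilization numerator of a stochastic intervention) and the
#' fitted probability of that observed value from the continuation or
#' initiation model.  Incompatible quarters carry weight 0.
#'
#' @param panel person-quarter `data.table`.
#' @param models a `propensity_models` fit on `panel`.
#' @param compliance output of [evaluate_compliance()] for one arm on the
#'   same panel (row-aligned by subject and quarter).
#' @param floor lower bound applied to fitted denominators before division
#'   (default `1e-4`); the number of floored probabilities is recorded in
#'   attribute `n_floored`.
#' @return a `data.table` `subject_id`, `t`, `arm`, `tw` (cumulative
#'   treatment weight component).
#' @export
treatment_weights <- function(panel, models, compliance, floor = 1e-4) {
  if (inherits(panel, "cohort_panel")) panel <- panel$panel
  stopifnot(inherits(models, "propensity_models"),
            nrow(compliance) == nrow(panel))
  g <- panel_groups(panel)
  p_on <- prob_on_vector(models$specs, models$fits)
  p_obs <- ifelse(panel$on_treatment == 1L, p_on, 1 - p_on)
  n_floored <- sum(p_obs < floor)
  p_obs <- pmax(p_obs, floor)
  ratio <- ifelse(compliance$compatible, compliance$intervention_prob / p_obs, 0)
  tw <- grp_cumprod(ratio, g$gstart, g$glen)
  out <- data.table(subject_id = panel$subject_id, t = panel$t,
                    arm = compliance$arm[1L], tw = tw)
  setattr(out, "n_floored", n_floored)
  out[]
}

#' Censoring component of the inverse-probability weights
#'
#' The cumulative product, over quarters strictly before `t`, of the ratio
#' between the pooled marginal per-quarter probability of remaining
#' uncensored from all stochastic causes (the stabilization numerator) and
#' the subject's fitted conditional probability of remaining uncensored.
#' Quarters strictly before `t` enter because a subject observed at risk in
#' quarter `t` has, by construction, escaped censoring in quarters
#' `1, ..., t - 1`.
#'
#' @inheritParams treatment_weights
#' @return a `data.table` `subject_id`, `t`, `cw`.
#' @export
censoring_weights <- function(panel, models, floor = 1e-4) {
  if (inherits(panel, "cohort_panel")) panel <- panel$panel
  stopifnot(inherits(models, "propensity_models"))
  g <- panel_groups(panel)
  Tq <- max(panel$t)
  ratio <- censoring_ratio_vector(models$specs, models$fits, panel$t, Tq,
                                  floor = floor)
  cw <- grp_lag(grp_cumprod(ratio, g$gstart, g$glen), g$gstart, fill = 1)
  data.table(subject_id = panel$subject_id, t = panel$t, cw = cw)
}

#' Combine and truncate stabilized weights
#'
#' Multiplies the treatment and censoring components and truncates the
#' combined stabilized weight at `bound` (default 50), flagging truncated
#' person-quarters.  Summary statistics (fraction truncated among
#' regimen-compatible person-quarters, per-arm median and IQR) are attached
#' as the `"summary"` attribute.
#'
#' @param tw output of [treatment_weights()].
#' @param cw output of [censoring_weights()].
#' @param bound truncation bound (default 50).
#' @return a `data.table` `subject_id`, `t`, `arm`, `w`, `truncated`.
#' @export
combine_weights <- function(tw, cw, bound = 50) {
  if (nrow(tw) != nrow(cw) || !all(tw$subject_id == cw$subject_id) ||
      !all(tw$t == cw$t)) {
    stop("weight components are not aligned on subject-quarter", call. = FALSE)
  }
  w_raw <- tw$tw * cw$cw
  out <- data.table(subject_id = tw$subject_id, t = tw$t, arm = tw$arm,
                    w = pmin(w_raw, bound), truncated = w_raw > bound)
  compat <- out$w > 0
  smry <- list(
    frac_truncated = if (any(compat)) mean(out$truncated[compat]) else 0,
    median = if (any(compat)) stats::median(out$w[compat]) else NA_real_,
    iqr = if (any(compat)) unname(quantile(out$w[compat], c(0.25, 0.75)))
          else c(NA_real_, NA_real_)
  )
  setattr(out, "summary", smry)
  out[]
}

## Row-group structure of a panel sorted by (subject_id, t).
panel_groups <- function(panel) {
  n <- nrow(panel)
  newg <- c(TRUE, panel$subject_id[-1L] != panel$subject_id[-n])
  gstart <- which(newg)
  glen <- diff(c(gstart, n + 1L))
  list(gstart = gstart, glen = glen, n_subjects = length(gstart))
}
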