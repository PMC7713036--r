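#' Bone-density category coding
#'
#' Categorises a T-score-like value into the four ordinal categories used
#' throughout the package: 1 = above -2.0, 2 = -2.5 (exclusive) to -2.0,
#' 3 = -3.0 (exclusive) to -2.5, 4 = -3.0 and below.
#'
#' @param L numeric vector of scores.
#' @return integer vector of category codes 1-4 (`NA` passed through).
#' @export
#' @examples
#' bmd_category(c(-1.5, -2.0, -2.6, -3.0))
bmd_category <- function(L) {
  out <- 4L - findInterval(L, c(-3.0, -2.5, -2.0), left.open = TRUE)
  out[is.na(L)] <- NA_integer_
  as.integer(out)
}

#' Simulate a longitudinal cohort with treatment-confounder feedback
#'
#' Generates the quarterly panel of a synthetic cohort under the
#' data-generating process described in [dgp_config()].  All subjects enter
#' on treatment at quarter 1 (the index dispensing).  Each quarter, for
#' subjects still under follow-up: the bone-density score may be re-measured;
#' treatment is drawn from the continuation or re-initiation model given the
#' measured (carried-forward, possibly imputed) category; the terminal event
#' is drawn from a rare per-quarter logistic hazard in cumulative exposure
#' and the latent score; non-events are exposed to death, exclusion and
#' disenrollment censoring (in that order of precedence); survivors' latent
#' scores are updated with drift, a treatment effect, and noise.  Subjects
#' completing quarter `n_quarters` without event or censoring are
#' administratively censored.
#'
#' Treatment and censoring depend only on *measured* quantities, so the
#' sequential-randomization condition required by inverse-probability
#' weighting holds by construction with respect to the observed covariate
#' history, while the event hazard is driven by the latent score.
#'
#' @param config a [dgp_config()].
#' @return an object of class `cohort_panel`: a list with elements
#'   `panel` (one row per subject-quarter; columns `subject_id`, `t`,
#'   `on_treatment`, `on_prev`, `cum_on`, `L_true`, `L_obs`, `L_cat`,
#'   `L_imputed`, `tslm`, `agec`, `frailty`, `event`, `censor_cause`),
#'   `subjects` (baseline covariates and terminal state), `measurements`
#'   (quarters in which the score was measured, including quarter 1 when the
#'   baseline value was available), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  n <- config$n_subjects
  Tq <- config$n_quarters
  b <- config$baseline; tr <- config$treatment; cv <- config$covariate
  ev <- config$event; cs <- config$censoring

  set.seed(config$seed)

  age <- rnorm(n, b$age_mean, b$age_sd)
  agec <- (age - b$age_mean) / b$age_sd
  frailty <- rbinom(n, 1L, b$frailty_prev)
  L_true <- rnorm(n, b$L0_mean, b$L0_sd)
  L0_draw <- L_true
  measured0 <- runif(n) < b$p_L0_measured
  L_obs <- ifelse(measured0, L_true, b$L_fill)
  L_imp <- as.integer(!measured0)
  last_meas <- rep(1L, n)          # imputed baseline counts as quarter 1

  active <- rep(TRUE, n)
  on_prev <- rep(1L, n)            # index dispensing: everyone enters on
  cum <- rep(0L, n)

  meas_list <- vector("list", Tq)
  meas_list[[1L]] <- data.table(subject_id = which(measured0), t = 1L,
                                L = L_true[measured0])
  rows <- vector("list", Tq)

  for (t in seq_len(Tq)) {
    idx <- which(active)
    if (!length(idx)) break

    if (t > 1L) {
      meas <- idx[runif(length(idx)) < cv$p_measure]
      if (length(meas)) {
        L_obs[meas] <- L_true[meas]
        last_meas[meas] <- t
        L_imp[meas] <- 0L
        meas_list[[t]] <- data.table(subject_id = meas, t = t,
                                     L = L_true[meas])
      }
    }

    cat_i <- bmd_category(L_obs[idx])
    tslm_i <- t - last_meas[idx]
    fr_i <- frailty[idx]; ag_i <- agec[idx]
    onp_i <- on_prev[idx]

    lp <- ifelse(
      onp_i == 1L,
      tr$cont_intercept + tr$cont_cat[cat_i] + tr$cont_cum * cum[idx] +
        tr$cont_frailty * fr_i + tr$cont_age * ag_i,
      tr$init_intercept + tr$init_cat[cat_i] +
        tr$init_frailty * fr_i + tr$init_age * ag_i
    )
    A <- rbinom(length(idx), 1L, plogis(lp))
    cum_i <- cum[idx] + A

    p_ev <- plogis(ev$intercept + ev$cum * cum_i +
                     ev$L * (L_true[idx] - b$L0_mean) + ev$frailty * fr_i)
    e_i <- rbinom(length(idx), 1L, p_ev)

    cause <- rep(NA_character_, length(idx))
    alive <- e_i == 0L
    for (cz in c("death", "exclusion", "disenroll")) {
      cc <- cs[[if (cz == "exclusion") "exclusion" else cz]]
      atr <- which(alive & is.na(cause))
      if (!length(atr)) break
      p_c <- plogis(cc$intercept + cc$age * ag_i[atr] +
                      cc$frailty * fr_i[atr] + cc$cat[cat_i[atr]])
      hit <- rbinom(length(atr), 1L, p_c) == 1L
      cause[atr[hit]] <- cz
    }
    if (t == Tq) cause[alive & is.na(cause)] <- "admin"

    rows[[t]] <- data.table(
      subject_id = idx, t = t, on_treatment = A, on_prev = onp_i,
      cum_on = cum_i, L_true = L_true[idx], L_obs = L_obs[idx],
      L_cat = cat_i, L_imputed = L_imp[idx], tslm = tslm_i,
      agec = ag_i, frailty = fr_i, event = e_i, censor_cause = cause
    )

    terminal <- e_i == 1L | !is.na(cause)
    cum[idx] <- cum_i
    on_prev[idx] <- A
    surv <- idx[!terminal]
    active[idx[terminal]] <- FALSE
    if (length(surv)) {
      A_s <- A[!terminal]
      L_true[surv] <- L_true[surv] + cv$drift + cv$treat_effect * A_s +
        rnorm(length(surv), 0, cv$noise_sd)
    }
  }

  panel <- rbindlist(rows)
  setkey(panel, subject_id, t)

  term <- panel[, .(terminal_t = t[.N],
                    terminal_cause = if (event[.N] == 1L) "event"
                                     else censor_cause[.N]),
                by = subject_id]
  subjects <- data.table(
    subject_id = seq_len(n), age = age, agec = agec, frailty = frailty,
    L0 = ifelse(measured0, L0_draw, NA_real_)
  )
  subjects <- merge(subjects, term, by = "subject_id", all.x = TRUE)

  out <- list(panel = panel, subjects = subjects,
              measurements = rbindlist(meas_list), config = config)
  class(out) <- "cohort_panel"
  validate_cohort_panel(out)
  out
}

validate_cohort_panel <- function(x) {
  p <- x$panel
  ## exactly one terminal state, no rows after it, event and censoring
  ## mutually exclusive
  bad <- p[event == 1L & !is.na(censor_cause)]
  if (nrow(bad)) stop("panel integrity: event and censoring in same quarter")
  chk <- p[, .(n_term = sum(event == 1L | !is.na(censor_cause)),
               last_ok = all(t == seq_len(.N)) &&
                 all(which(event == 1L | !is.na(censor_cause)) %in% .N)),
           by = subject_id]
  if (any(chk$n_term > 1L) || !all(chk$last_ok)) {
    stop("panel integrity: rows after terminal quarter or multiple terminals")
  }
  invisible(x)
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("<cohort_panel>", nrow(x$subjects), "subjects,",
      nrow(x$panel), "person-quarters,",
      sum(x$panel$event), "events\n")
  tb <- table(x$subjects$terminal_cause, useNA = "ifany")
  cat("  terminal causes:",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Emit dispensing records consistent with a simulated treatment path
#'
#' For every subject-quarter flagged on treatment, emits dispensing records
#' (start day, days supplied) whose day-level coverage re-classifies the
#' quarter as on treatment (PDC >= 0.50) under the stockpiling and
#' precedence rules of [expand_daily_coverage()]; quarters off treatment
#' receive no records and remain below the threshold (round-trip property).
#' Refills are jittered by a uniform delay of up to `delay_max` days, and
#' with probability `p_overlap` a refill within a continuous run of
#' on-quarters is emitted early so that it overlaps the prior supply by 1-30
#' days, exercising stockpiling.
#'
#' The round-trip guarantee requires `68 <= days_supply <= 90` and
#' `delay_max <= 20` (enforced at emission).
#'
#' @param cohort a `cohort_panel` from [simulate_cohort()].
#' @param config the generating [dgp_config()] (defaults to the one stored
#'   in `cohort`).
#' @param seed integer seed for the emission draws (defaults to the cohort
#'   seed plus one).
#' @return a `data.table` of dispensing records: `subject_id`, `start_day`
#'   (days since index, day 0 = index date), `days_supply`.
#' @export
emit_dispensings <- function(cohort, config = cohort$config,
                             seed = config$seed + 1L) {
  stopifnot(inherits(cohort, "cohort_panel"))
  dp <- config$dispensing
  s <- as.integer(dp$days_supply)
  dmax <- as.integer(dp$delay_max)
  if (s < 68L || s > 90L || dmax > 20L) {
    stop("emit_dispensings: round-trip guarantee requires ",
         "68 <= days_supply <= 90 and delay_max <= 20", call. = FALSE)
  }
  set.seed(seed)

  on_rows <- cohort$panel[on_treatment == 1L, .(subject_id, t)]
  if (!nrow(on_rows)) {
    return(data.table(subject_id = integer(), start_day = integer(),
                      days_supply = integer()))
  }
  setkey(on_rows, subject_id, t)

  emit_one <- function(ts) {
    k <- length(ts)
    start <- integer(k)
    cov_end <- -1e9
    prev_t <- -10L
    for (j in seq_len(k)) {
      t <- ts[j]
      qstart <- 90L * (t - 1L)
      chained <- (t - prev_t) == 1L
      if (chained && runif(1) < dp$p_overlap) {
        o <- sample.int(30L, 1L)
        start[j] <- as.integer(cov_end - o)
        cov_end <- cov_end + s
      } else {
        d <- sample.int(dmax + 1L, 1L) - 1L
        start[j] <- qstart + d
        if (chained && start[j] < cov_end) {
          ## refill before prior supply ran out (<= 30 days remain):
          ## stockpiling appends the new supply
          cov_end <- cov_end + s
        } else {
          cov_end <- start[j] + s
        }
      }
      prev_t <- t
    }
    start
  }

  recs <- on_rows[, .(start_day = emit_one(t)), by = subject_id]
  recs[, days_supply := s]
  recs[]
}

#' True counterfactual risk under a regimen by direct intervention
#'
#' Simulates `n_mc` subjects from the data-generating process with treatment
#' assigned by the regimen's intervention law instead of the observational
#' treatment model: within the admissible window the discontinuation time is
#' drawn from the regimen's conditional per-quarter discontinuation
#' probabilities, and treatment is otherwise deterministic (on before
#' discontinuation, off after; no restart).  Covariate dynamics and the
#' event hazard are unchanged.  Disenrollment and exclusion censoring are
#' disabled (the estimand removes them via censoring weights); death is
#' retained and treated as censoring: the reported risk is the complement of
#' the product of per-quarter at-risk-averaged event hazards, the same
#' functional targeted by the inverse-probability-weighted estimator.
#'
#' @param config a [dgp_config()].
#' @param regimen a `regimen_spec` (see [discontinuation_law()]) or an arm
#'   label `"short_term"` / `"longer_term"`.
#' @param n_mc number of Monte-Carlo subjects (a warning is issued below
#'   1000, where the truth is unstable).
#' @param seed integer seed.
#' @return a `data.table` of class `survival_curve` with columns `t`, `h`,
#'   `S`, `risk` and `se` (Greenwood Monte-Carlo standard error of `risk`),
#'   and attributes `arm` and `n_mc`.
#' @export
oracle_counterfactual_risk <- function(config, regimen, n_mc, seed) {
  stopifnot(inherits(config, "dgp_config"))
  if (is.character(regimen)) regimen <- discontinuation_law(regimen)
  stopifnot(inherits(regimen, "regimen_spec"))
  if (n_mc < 1000) {
    warning("oracle_counterfactual_risk: n_mc < 1000 gives an unstable truth")
  }
  n <- as.integer(n_mc)
  Tq <- config$n_quarters
  b <- config$baseline; cv <- config$covariate; ev <- config$event
  dcf <- config$censoring$death

  set.seed(seed)
  agec <- (rnorm(n, b$age_mean, b$age_sd) - b$age_mean) / b$age_sd
  frailty <- rbinom(n, 1L, b$frailty_prev)
  L_true <- rnorm(n, b$L0_mean, b$L0_sd)
  ## measured category still drives the death hazard's cat term
  measured0 <- runif(n) < b$p_L0_measured
  L_obs <- ifelse(measured0, L_true, b$L_fill)

  active <- rep(TRUE, n)
  still_on <- rep(TRUE, n)   # discontinuation not yet drawn
  cum <- rep(0L, n)

  d_t <- integer(Tq); n_t <- integer(Tq)

  for (t in seq_len(Tq)) {
    idx <- which(active)
    if (!length(idx)) break
    n_t[t] <- length(idx)

    if (t > 1L) {
      meas <- idx[runif(length(idx)) < cv$p_measure]
      L_obs[meas] <- L_true[meas]
    }

    q <- conditional_discontinuation_prob(regimen, t)
    so_i <- still_on[idx]
    disc <- logical(length(idx))
    if (q > 0 && any(so_i)) disc[so_i] <- runif(sum(so_i)) < q
    A <- as.integer(so_i & !disc)
    still_on[idx[disc]] <- FALSE
    cum_i <- cum[idx] + A

    p_ev <- plogis(ev$intercept + ev$cum * cum_i +
                     ev$L * (L_true[idx] - b$L0_mean) + ev$frailty * frailty[idx])
    e_i <- rbinom(length(idx), 1L, p_ev)
    d_t[t] <- sum(e_i)

    alive <- e_i == 0L
    p_d <- plogis(dcf$intercept + dcf$age * agec[idx] +
                    dcf$frailty * frailty[idx] +
                    dcf$cat[bmd_category(L_obs[idx])])
    dead <- rbinom(length(idx), 1L, p_d) == 1L & alive

    term <- !alive | dead | t == Tq
    cum[idx] <- cum_i
    surv <- idx[!term]
    active[idx[term]] <- FALSE
    if (length(surv)) {
      A_s <- A[!term]
      L_true[surv] <- L_true[surv] + cv$drift + cv$treat_effect * A_s +
        rnorm(length(surv), 0, cv$noise_sd)
    }
  }

  n_t <- as.numeric(n_t); d_t <- as.numeric(d_t)
  h <- ifelse(n_t > 0, d_t / n_t, 0)
  S <- cumprod(1 - h)
  gw <- cumsum(ifelse(n_t > 0 & n_t > d_t, d_t / (n_t * (n_t - d_t)), 0))
  out <- data.table(t = seq_len(Tq), h = h, S = S, risk = 1 - S,
                    se = S * sqrt(gw))
  setattr(out, "class", c("survival_curve", class(out)))
  setattr(out, "arm", regimen$arm_label)
  setattr(out, "n_mc", n)
  out[]
}
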