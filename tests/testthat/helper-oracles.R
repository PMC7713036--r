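## Independent brute-force oracles used across the suite.

## Day-by-day coverage oracle: marks a literal day vector, applying the
## stockpiling (<= 30 covered days remaining -> append) and precedence
## (> 30 remaining -> run from the new start, discard the earlier surplus)
## rules one day at a time.  Day d maps to covered[d + 1].
oracle_coverage_days <- function(start_day, days_supply, horizon) {
  covered <- rep(FALSE, horizon)
  if (!length(start_day)) return(covered)
  o <- order(start_day)
  start_day <- start_day[o]; days_supply <- days_supply[o]
  E <- -1  # day after the last day of the current supply run
  for (i in seq_along(start_day)) {
    s <- start_day[i]; d <- days_supply[i]
    if (s >= E) {
      days <- s:(s + d - 1)
      E <- s + d
    } else if (E - s <= 30) {
      days <- E:(E + d - 1)
      E <- E + d
    } else {
      if (s + d < E) {
        for (dd in (s + d):(E - 1)) if (dd < horizon) covered[dd + 1] <- FALSE
      }
      days <- s:(s + d - 1)
      E <- s + d
    }
    for (dd in days) if (dd >= 0 && dd < horizon) covered[dd + 1] <- TRUE
  }
  covered
}

oracle_quarter_pdc <- function(covered, t) {
  sum(covered[(90 * (t - 1) + 1):(90 * t)]) / 90
}

## Closed-form counterfactual risk for a degenerate (noise-free,
## homogeneous-baseline, no-death) configuration: enumerate the
## discontinuation-time paths of the regimen, compute each path's exact
## per-quarter hazards, and combine them into the at-risk-averaged hazard
## product that the Monte-Carlo oracle estimates.
enumeration_counterfactual_risk <- function(config, spec) {
  b <- config$baseline; cv <- config$covariate; ev <- config$event
  Tq <- config$n_quarters
  stopifnot(b$L0_sd == 0, cv$noise_sd == 0, b$frailty_prev == 0)
  q <- vapply(seq_len(Tq),
              function(k) conditional_discontinuation_prob(spec, k),
              numeric(1))
  ## discontinuation quarter d (off from d); Tq + 1 encodes "never"
  ds <- c(spec$d_quarters, Tq + 1L)
  pd <- numeric(length(ds))
  for (j in seq_along(ds)) {
    d <- ds[j]
    p <- 1
    for (k in seq_len(min(d - 1, Tq))) p <- p * (1 - q[k])
    if (d <= Tq) p <- p * q[d]
    pd[j] <- p
  }
  stopifnot(abs(sum(pd) - 1) < 1e-12)

  h_path <- matrix(0, length(ds), Tq)
  for (j in seq_along(ds)) {
    d <- ds[j]
    L <- b$L0_mean; cum <- 0
    for (k in seq_len(Tq)) {
      A <- as.integer(k < d)
      cum <- cum + A
      h_path[j, k] <- plogis(ev$intercept + ev$cum * cum +
                               ev$L * (L - b$L0_mean))
      L <- L + cv$drift + cv$treat_effect * A
    }
  }
  Spath <- t(apply(1 - h_path, 1, cumprod))
  hbar <- numeric(Tq)
  for (k in seq_len(Tq)) {
    atrisk <- if (k == 1) rep(1, length(ds)) else Spath[, k - 1]
    hbar[k] <- sum(pd * atrisk * h_path[, k]) / sum(pd * atrisk)
  }
  1 - cumprod(1 - hbar)
}

## Exhaustive enumeration of hazards/survival/risks/area for a small panel
## with all weights equal to 1, using plain loops over a list of per-subject
## on/off patterns with terminal causes (the tiny fixture's truth table).
enumerate_tiny <- function(patterns, causes, arm, n_quarters = 8L) {
  nsub <- length(patterns)
  ## per-subject compatibility horizon and risk-set membership
  compat_until <- integer(nsub)
  for (i in seq_len(nsub)) {
    pat <- patterns[[i]]
    state <- "on"        # on-history so far all on
    lastq <- 0L
    for (tt in seq_along(pat)) {
      ok <- TRUE
      if (state == "on") {
        if (pat[tt] == 1) {
          if (arm == "short_term" && tt >= 12) ok <- FALSE
        } else {
          if (arm == "longer_term" && tt <= 12) ok <- FALSE
          if (ok) state <- "off"
        }
      } else {
        if (pat[tt] == 1) ok <- FALSE   # restart
      }
      if (!ok) break
      lastq <- tt
    }
    compat_until[i] <- lastq
  }
  h <- numeric(n_quarters)
  atr <- ev <- numeric(n_quarters)
  for (tt in seq_len(n_quarters)) {
    for (i in seq_len(nsub)) {
      if (compat_until[i] >= tt) {
        atr[tt] <- atr[tt] + 1
        if (length(patterns[[i]]) == tt && causes[i] == "event") {
          ev[tt] <- ev[tt] + 1
        }
      }
    }
    h[tt] <- if (atr[tt] > 0) ev[tt] / atr[tt] else 0
  }
  S <- cumprod(1 - h)
  list(h = h, S = S, risk = 1 - S, area = sum(S),
       atrisk = atr, events = ev, compat_until = compat_until)
}

## Small deterministic panel builder for weight/hazard unit tests.
panel_from_patterns <- function(patterns, causes) {
  rows <- lapply(seq_along(patterns), function(i) {
    pat <- patterns[[i]]
    nq <- length(pat)
    data.table::data.table(
      subject_id = i, t = seq_len(nq), pdc = as.numeric(pat),
      on_treatment = as.integer(pat),
      on_prev = c(1L, pat[-nq]),
      cum_on = cumsum(pat),
      L_obs = -2.6, L_cat = 3L, L_imputed = 0L, tslm = seq_len(nq) - 1L,
      agec = 0, frailty = 0L,
      event = as.integer(seq_len(nq) == nq & causes[i] == "event"),
      censor_cause = c(rep(NA_character_, nq - 1L),
                       if (causes[i] == "event") NA_character_ else causes[i])
    )
  })
  out <- data.table::rbindlist(rows)
  data.table::setkey(out, subject_id, t)
  out
}
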