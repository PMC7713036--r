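#' Stochastic discontinuation regimens
#'
#' The two treatment regimens compared by the pipeline are stochastic
#' interventions on the timing of treatment discontinuation, expressed as a
#' marginal probability law over the discontinuation quarter `d`
#' ("discontinue at `d`" means on treatment for quarters `< d`, off from `d`
#' onward, with no restart):
#'
#' * `short_term`: discontinuation within the first 3 years — uniform mass
#'   `1/12` on each quarter `d = 1, ..., 12`.
#' * `longer_term`: continuous treatment for the first 3 years, then either
#'   discontinuation in one of quarters `13, ..., 40` or continued treatment
#'   through the horizon ("never"), each outcome weighted equally by default
#'   (mass `1/29`); the mass of the "never" atom is configurable via
#'   `p_never`.
#'
#' @param arm_label `"short_term"` or `"longer_term"`.
#' @param p_never probability mass on "never discontinue" for the
#'   longer-term arm (default `1/29`, equal to each quarter's mass); the
#'   remaining mass is spread uniformly over quarters 13-40.  Ignored for
#'   the short-term arm.
#' @param n_quarters follow-up horizon (default 40).
#' @return an object of class `regimen_spec`: a list with `arm_label`,
#'   `d_quarters` (admissible discontinuation quarters), `d_mass` (their
#'   probability masses), `p_never`, and `n_quarters`.
#' @export
#' @examples
#' sp <- discontinuation_law("short_term")
#' sum(sp$d_mass)  # 1
discontinuation_law <- function(arm_label, p_never = NULL, n_quarters = 40L) {
  if (length(arm_label) != 1L ||
      !arm_label %in% c("short_term", "longer_term")) {
    stop("unknown arm: ", paste(arm_label, collapse = ", "), call. = FALSE)
  }
  if (arm_label == "short_term") {
    spec <- list(arm_label = arm_label, d_quarters = 1:12,
                 d_mass = rep(1 / 12, 12), p_never = 0,
                 n_quarters = as.integer(n_quarters))
  } else {
    dq <- 13:n_quarters
    if (is.null(p_never)) p_never <- 1 / (length(dq) + 1)
    stopifnot(p_never >= 0, p_never < 1)
    spec <- list(arm_label = arm_label, d_quarters = dq,
                 d_mass = rep((1 - p_never) / length(dq), length(dq)),
                 p_never = p_never, n_quarters = as.integer(n_quarters))
  }
  class(spec) <- "regimen_spec"
  stopifnot(abs(sum(spec$d_mass) + spec$p_never - 1) < 1e-12,
            all(spec$d_mass >= 0))
  spec
}

#' @export
print.regimen_spec <- function(x, ...) {
  cat("<regimen_spec>", x$arm_label, "\n")
  cat("  discontinuation quarters:", min(x$d_quarters), "-",
      max(x$d_quarters), " (mass", signif(x$d_mass[1], 4), "each)\n")
  if (x$p_never > 0) cat("  P(never discontinue) =", signif(x$p_never, 4), "\n")
  invisible(x)
}

#' Per-quarter conditional discontinuation probability
#'
#' Converts a regimen's marginal discontinuation law into the conditional
#' probability of discontinuing at quarter `t` given treatment has continued
#' through quarter `t - 1` (and the history is regimen-compatible).  Under
#' the default uniform laws this is `1 / (13 - t)` for the short-term arm
#' (quarters 1-12, reaching 1 at quarter 12) and, for the longer-term arm,
#' 0 during the forced-continuation window (quarters 1-12) and
#' `1 / (42 - t)` for quarters 13-40.
#'
#' @param spec a `regimen_spec`.
#' @param t quarter index (1-based).
#' @return conditional discontinuation probability at `t`.
#' @export
conditional_discontinuation_prob <- function(spec, t) {
  stopifnot(inherits(spec, "regimen_spec"))
  if (length(t) != 1L || is.na(t) || t < 1L || t > spec$n_quarters) {
    stop("quarter out of range: t = ", t, call. = FALSE)
  }
  if (!t %in% spec$d_quarters) return(0)
  j <- match(t, spec$d_quarters)
  tail_mass <- sum(spec$d_mass[j:length(spec$d_mass)]) + spec$p_never
  spec$d_mass[j] / tail_mass
}

#' Regimen compatibility and intervention probabilities for observed paths
#'
#' For every subject-quarter of an observed panel, determines whether the
#' observed treatment history up to that quarter has positive probability
#' under the regimen's law (`compatible`), and the law's probability of the
#' observed on/off value at that quarter given the compatible history
#' (`intervention_prob`).  Compatibility is absorbing: once a history
#' diverges from the regimen (treatment during a quarter the law forbids,
#' e.g. still on at quarter 12 under the short-term arm or off during the
#' longer-term arm's forced window, or any restart after discontinuation),
#' the subject's remaining person-time is incompatible and carries
#' probability 0.  While continuously on treatment during the first 3 years
#' a subject is compatible with both arms and contributes person-time to
#' both.
#'
#' @param panel a person-quarter `data.table` with columns `subject_id`,
#'   `t` (consecutive from 1 within subject) and `on_treatment`, ordered by
#'   subject and quarter, or a `cohort_panel`.
#' @param spec a `regimen_spec`.
#' @return a `data.table` with columns `subject_id`, `t`, `arm`,
#'   `compatible` (logical) and `intervention_prob`.
#' @export
evaluate_compliance <- function(panel, spec) {
  stopifnot(inherits(spec, "regimen_spec"))
  if (inherits(panel, "cohort_panel")) panel <- panel$panel
  dt <- panel[, .(subject_id, t, on_treatment)]
  setkey(dt, subject_id, t)
  if (dt[, any(t != seq_len(.N)), by = subject_id][, any(V1)]) {
    stop("panel integrity: quarter sequence has gaps", call. = FALSE)
  }

  ## per subject: first off quarter and first restart quarter (Inf if none)
  fo_dt <- dt[on_treatment == 0L, .(first_off = as.numeric(t[1L])),
              by = subject_id]
  dt <- fo_dt[dt, on = "subject_id"]
  dt[is.na(first_off), first_off := Inf]
  rs_dt <- dt[on_treatment == 1L & t > first_off,
              .(restart = as.numeric(t[1L])), by = subject_id]
  dt <- rs_dt[dt, on = "subject_id"]
  dt[is.na(restart), restart := Inf]

  tq <- dt$t
  fo <- dt$first_off
  rs <- dt$restart
  A <- dt$on_treatment

  if (spec$arm_label == "short_term") {
    q <- vapply(seq_len(spec$n_quarters),
                function(k) conditional_discontinuation_prob(spec, k),
                numeric(1))
    p <- numeric(nrow(dt))
    on_phase <- tq < fo
    p[on_phase] <- 1 - q[tq[on_phase]]          # 0 at quarter 12 while on
    at_disc <- tq == fo & is.finite(fo)
    p[at_disc] <- q[pmin(tq[at_disc], spec$n_quarters)]
    p[tq == fo & tq > max(spec$d_quarters)] <- 0 # discontinuation too late
    off_phase <- tq > fo & tq < rs
    p[off_phase] <- 1
    p[tq >= rs] <- 0
  } else {
    q <- vapply(seq_len(spec$n_quarters),
                function(k) conditional_discontinuation_prob(spec, k),
                numeric(1))
    forced <- max(setdiff(seq_len(spec$n_quarters), spec$d_quarters))
    p <- numeric(nrow(dt))
    on_phase <- tq < fo
    p[on_phase] <- 1 - q[tq[on_phase]]          # 1 during forced window
    at_disc <- tq == fo & is.finite(fo)
    p[at_disc] <- ifelse(tq[at_disc] <= forced, 0, q[pmin(tq[at_disc], spec$n_quarters)])
    off_phase <- tq > fo & tq < rs
    p[off_phase] <- 1
    p[tq >= rs] <- 0
  }

  out <- dt[, .(subject_id, t)]
  out[, arm := spec$arm_label]
  out[, intervention_prob := p]
  ## absorbing incompatibility: zero probability propagates forward
  out[, compatible := cumprod(intervention_prob > 0) > 0, by = subject_id]
  out[compatible == FALSE, intervention_prob := 0]
  out[]
}
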