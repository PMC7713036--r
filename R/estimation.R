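#' Weighted discrete-time hazard curve (saturated marginal structural model)
#'
#' The stochastic-intervention analogue of a saturated marginal structural
#' model has one free hazard parameter per arm-quarter, so the
#' inverse-probability-weighted hazard estimate is the weighted empirical
#' hazard: `h(t) = sum(w_i(t) * event_i(t)) / sum(w_i(t))` over the
#' regimen-compatible person-quarters at `t`.  Quarters whose weighted risk
#' set is empty contribute `h = 0` and are flagged.
#'
#' @param panel person-quarter `data.table`.
#' @param weights combined weights from [combine_weights()] (or any
#'   `data.table` row-aligned with `panel` carrying a `w` column); weight 0
#'   removes a person-quarter from the risk set.
#' @param n_quarters hazard grid length (default: maximum quarter in
#'   `panel`).
#' @return a `data.table` of class `hazard_curve`: `t`, `h`,
#'   `w_events`, `w_atrisk`, `empty`.
#' @export
weighted_hazard <- function(panel, weights, n_quarters = max(panel$t)) {
  if (inherits(panel, "cohort_panel")) panel <- panel$panel
  if (nrow(weights) != nrow(panel)) {
    stop("weights are not row-aligned with the panel", call. = FALSE)
  }
  w <- weights$w
  we <- sum_by_quarter(w * panel$event, panel$t, n_quarters)
  wr <- sum_by_quarter(w, panel$t, n_quarters)
  out <- data.table(t = seq_len(n_quarters),
                    h = ifelse(wr > 0, we / wr, 0),
                    w_events = we, w_atrisk = wr, empty = wr <= 0)
  setattr(out, "class", c("hazard_curve", class(out)))
  if (!is.null(weights$arm)) setattr(out, "arm", weights$arm[1L])
  out[]
}

#' Map a hazard curve to survival and cumulative risk
#'
#' `S(t) = prod_{k <= t} (1 - h(k))`, `risk(t) = 1 - S(t)`; `S(0) = 1`
#' implicitly.  A Greenwood-style standard error of the risk is attached
#' when the hazard curve carries weighted risk-set sizes.
#'
#' @param hz a `hazard_curve` from [weighted_hazard()], or a numeric vector
#'   of per-quarter hazards.
#' @return a `data.table` of class `survival_curve`: `t`, `h`, `S`, `risk`
#'   (plus `se` when available).
#' @export
survival_from_hazard <- function(hz) {
  if (is.numeric(hz)) hz <- data.table(t = seq_along(hz), h = hz)
  stopifnot(all(hz$h >= 0 & hz$h <= 1))
  out <- data.table(t = hz$t, h = hz$h, S = cumprod(1 - hz$h))
  out[, risk := 1 - S]
  if (!is.null(hz$w_atrisk)) {
    term <- ifelse(hz$w_atrisk > 0 & hz$h < 1,
                   hz$h / (hz$w_atrisk * (1 - hz$h)), 0)
    out[, se := S * sqrt(cumsum(term))]
    out[, empty := hz$empty]
  }
  setattr(out, "class", c("survival_curve", class(out)))
  if (!is.null(attr(hz, "arm"))) setattr(out, "arm", attr(hz, "arm"))
  out[]
}

#' @export
print.survival_curve <- function(x, ...) {
  arm <- attr(x, "arm")
  cat("<survival_curve>", if (!is.null(arm)) arm else "", "\n")
  show_t <- unique(pmin(c(4, 8, 12, 16, 20, 40), max(x$t)))
  print(as.data.frame(x[t %in% show_t,
                        .(t, S = signif(S, 6),
                          risk_per_100k = round(risk * 1e5, 1))]),
        row.names = FALSE)
  invisible(x)
}

#' Risk difference between two counterfactual curves at a horizon
#'
#' `RD(t) = risk_longer(t) - risk_short(t)`, with a percentile bootstrap
#' confidence interval when bootstrap replicates are supplied.
#'
#' @param curves named list with `survival_curve` elements `short_term` and
#'   `longer_term`.
#' @param t quarter at which to evaluate the contrast.
#' @param boot optional bootstrap object from [bootstrap_inference()].
#' @param level confidence level (default 0.95).
#' @return a one-row `data.table`: `t`, `rd`, and (with `boot`) `se`,
#'   `ci_low`, `ci_high`, `n_replicates`.
#' @export
risk_difference <- function(curves, t, boot = NULL, level = 0.95) {
  stopifnot(all(c("short_term", "longer_term") %in% names(curves)))
  if (t > max(curves$short_term$t) || t > max(curves$longer_term$t) || t < 1) {
    stop("quarter out of range: t = ", t, call. = FALSE)
  }
  rd <- curves$longer_term$risk[t] - curves$short_term$risk[t]
  out <- data.table(t = as.integer(t), rd = rd)
  if (!is.null(boot)) {
    d <- boot$risk[, t, "longer_term"] - boot$risk[, t, "short_term"]
    a <- (1 - level) / 2
    out[, `:=`(se = sd(d),
               ci_low = unname(quantile(d, a, type = 6)),
               ci_high = unname(quantile(d, 1 - a, type = 6)),
               n_replicates = length(d))]
  }
  out[]
}

## ---- one-pass estimation shared by point estimates and the bootstrap ----

#' Prepare a panel for repeated regimen estimation
#'
#' Precomputes everything that does not change across bootstrap replicates:
#' design matrices and risk sets of the six propensity models, group
#' structure, and per-arm compliance indicators and intervention
#' probabilities.  [estimate_curves()] then turns a vector of per-subject
#' frequency weights into per-arm hazard, survival and risk curves.
#'
#' @param panel person-quarter `data.table` (or `cohort_panel`).
#' @param p_never optional mass of the longer-term arm's "never
#'   discontinue" atom (see [discontinuation_law()]).
#' @param n_quarters horizon (default: maximum quarter observed).
#' @param truncation combined-weight truncation bound (default 50).
#' @param floor propensity floor before division (default 1e-4).
#' @return an opaque list consumed by [estimate_curves()].
#' @export
prepare_estimation <- function(panel, p_never = NULL,
                               n_quarters = max(panel$t),
                               truncation = 50, floor = 1e-4) {
  if (inherits(panel, "cohort_panel")) panel <- panel$panel
  setkey(panel, subject_id, t)
  g <- panel_groups(panel)
  specs <- build_model_specs(panel)
  arms <- list(
    short_term = discontinuation_law("short_term", n_quarters = n_quarters),
    longer_term = discontinuation_law("longer_term", p_never = p_never,
                                      n_quarters = n_quarters)
  )
  comp <- lapply(arms, function(sp) evaluate_compliance(panel, sp))
  list(panel = panel, groups = g, specs = specs, arms = arms,
       compliance = comp,
       ipnum = lapply(comp, `[[`, "intervention_prob"),
       compat = lapply(comp, function(x) as.numeric(x$compatible)),
       n_quarters = as.integer(n_quarters),
       truncation = truncation, floor = floor,
       tq = as.integer(panel$t), event = as.numeric(panel$event),
       on = panel$on_treatment, warm = NULL)
}

#' Estimate counterfactual curves for both arms from one weighted pass
#'
#' Re-fits the six propensity models under the supplied per-subject
#' frequency weights (all ones for the point estimate; multinomial counts
#' for a bootstrap replicate), rebuilds the stabilized truncated weights,
#' and returns weighted and crude (unweighted, compatible-person-time)
#' hazard/survival/risk curves per arm plus the area under each survival
#' curve.
#'
#' @param prep output of [prepare_estimation()].
#' @param freq per-subject frequency weights in panel subject order
#'   (default all 1).
#' @param weight_summary compute per-arm weight medians/IQR/truncation
#'   fractions (skipped inside bootstrap replicates for speed).
#' @param light return only per-arm risk vectors and areas (the bootstrap
#'   path).
#' @param tol Newton-step max-norm tolerance for the model refits
#'   (bootstrap replicates use a looser tolerance than the point estimate;
#'   resampling noise dominates far earlier).
#' @return list with `curves` (per arm, `survival_curve`), `crude` (per
#'   arm), `auc` (named per-arm vector), `weights` (per-arm summary), and
#'   `empty` (TRUE if any weighted risk set up to the horizon was empty).
#' @export
estimate_curves <- function(prep, freq = NULL, weight_summary = TRUE,
                            light = FALSE, tol = 1e-6) {
  g <- prep$groups
  row_w <- if (is.null(freq)) NULL else rep(freq, g$glen)
  fits <- refit_models(prep$specs, row_w = row_w, warm = prep$warm,
                       tol = tol)
  specs <- prep$specs
  n <- attr(specs, "n_rows")

  p_on <- prob_on_vector(specs, fits)
  ## probability of the observed treatment value
  p_obs <- pmax((1 - p_on) + prep$on * (2 * p_on - 1), prep$floor)
  rw <- if (is.null(row_w)) rep(1, n) else row_w
  causes <- c("death", "exclusion", "disenroll")
  mu_list <- lapply(causes, function(nm) {
    f <- fits[[nm]]
    if (f$degenerate && f$events == 0) rep(0, length(specs[[nm]]$idx))
    else f$fitted
  })
  cens_ratio <- .censoring_ratio_cpp(
    n, lapply(specs[causes], `[[`, "idx"), lapply(specs[causes], `[[`, "y"),
    mu_list, rw, prep$tq, prep$n_quarters, prep$floor)
  cw <- grp_cumprod_lag(cens_ratio, g$gstart, g$glen)

  out_curves <- list(); out_crude <- list(); auc <- c(); wsum <- list()
  risk_light <- list()
  any_empty <- FALSE
  for (arm in names(prep$arms)) {
    ## intervention_prob is 0 exactly on incompatible person-quarters, and
    ## zeros are absorbing in the cumulative treatment-ratio product
    hh <- .arm_hazard_cpp(prep$ipnum[[arm]], p_obs, cw, rw, prep$event,
                          prep$tq, g$gstart, prep$n_quarters,
                          prep$truncation)
    we <- hh$we; wr <- hh$wr
    empty <- wr <= 0
    any_empty <- any_empty || any(empty)
    h <- numeric(prep$n_quarters)
    h[!empty] <- we[!empty] / wr[!empty]
    if (light) {
      S <- cumprod(1 - h)
      risk_light[[arm]] <- 1 - S
      auc[arm] <- sum(S)
      next
    }
    hz <- data.table(t = seq_len(prep$n_quarters), h = h,
                     w_events = we, w_atrisk = wr, empty = empty)
    setattr(hz, "class", c("hazard_curve", class(hz)))
    setattr(hz, "arm", arm)
    sc <- survival_from_hazard(hz)
    out_curves[[arm]] <- sc
    auc[arm] <- sum(sc$S)

    ch <- numeric(prep$n_quarters)
    ch[hh$cr > 0] <- hh$ce[hh$cr > 0] / hh$cr[hh$cr > 0]
    chz <- data.table(t = seq_len(prep$n_quarters), h = ch,
                      w_events = hh$ce, w_atrisk = hh$cr, empty = hh$cr <= 0)
    setattr(chz, "class", c("hazard_curve", class(chz)))
    setattr(chz, "arm", arm)
    out_crude[[arm]] <- survival_from_hazard(chz)

    if (!weight_summary) next
    tw <- grp_cumprod(prep$ipnum[[arm]] / p_obs, g$gstart, g$glen)
    w <- pmin(tw * cw, prep$truncation)
    compat <- prep$compat[[arm]]
    active <- compat > 0 & w > 0 & rw > 0
    wsum[[arm]] <- list(
      median = if (any(active)) stats::median(rep(w[active], rw[active]))
               else NA_real_,
      iqr = if (any(active))
        unname(quantile(rep(w[active], rw[active]), c(0.25, 0.75)))
        else c(NA_real_, NA_real_),
      frac_truncated = if (any(active))
        sum(rw[active] * (tw[active] * cw[active] > prep$truncation)) /
          sum(rw[active])
        else 0
    )
  }
  if (light) {
    return(list(risk = risk_light, auc = auc, empty = any_empty))
  }
  list(curves = out_curves, crude = out_crude, auc = auc,
       weights = wsum, fits = fits, empty = any_empty)
}
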