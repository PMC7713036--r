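fake_models <- function(panel, p_on) {
  n <- nrow(panel)
  idx_cont <- which(panel$on_prev == 1L)
  idx_init <- which(panel$on_prev == 0L)
  specs <- list(continuation = list(idx = idx_cont),
                initiation = list(idx = idx_init))
  attr(specs, "n_rows") <- n
  fits <- list(continuation = list(fitted = p_on[idx_cont]),
               initiation = list(fitted = p_on[idx_init]))
  structure(list(specs = specs, fits = fits), class = "propensity_models")
}

test_that("continuation model recovers the generating coefficients", {
  cfg <- dgp_preset("default", n_subjects = 20000, seed = 41)
  co <- simulate_cohort(cfg)
  models <- fit_propensity_models(co$panel)
  f <- models$fits$continuation
  truth <- c(3.0, -1.6, -0.6, 1.0, 0, 0, 0.9, 0.10, 0, -0.12)
  ## independent route: stats::glm on the same risk set provides both a
  ## coefficient cross-check and the standard errors
  sp <- models$specs$continuation
  g <- suppressWarnings(glm.fit(sp$X, sp$y, family = binomial()))
  expect_equal(unname(f$coef), unname(g$coefficients), tolerance = 1e-6)
  se <- sqrt(diag(chol2inv(g$qr$qr[1:10, 1:10])))
  expect_true(all(abs(f$coef - truth) < 3 * se))
})

test_that("a cause without events is degenerate and weightless", {
  cfg <- dgp_config(n_subjects = 2000, seed = 43,
                    censoring = list(disenroll = list(intercept = -Inf,
                                                      age = 0, frailty = 0,
                                                      cat = c(0, 0, 0, 0))))
  co <- simulate_cohort(cfg)
  models <- fit_propensity_models(co$panel)
  expect_true(models$fits$disenroll$degenerate)
  expect_identical(models$fits$disenroll$events, 0)
  ## with all stochastic causes silenced the censoring component is 1
  cfg2 <- dgp_config(n_subjects = 500, seed = 43, censoring = list(
    death = list(intercept = -Inf, age = 0, frailty = 0, cat = c(0, 0, 0, 0)),
    disenroll = list(intercept = -Inf, age = 0, frailty = 0,
                     cat = c(0, 0, 0, 0)),
    exclusion = list(intercept = -Inf, age = 0, frailty = 0,
                     cat = c(0, 0, 0, 0))))
  co2 <- simulate_cohort(cfg2)
  m2 <- fit_propensity_models(co2$panel)
  cw <- censoring_weights(co2$panel, m2)
  expect_true(all(cw$cw == 1))
})

test_that("coin-flip treatment yields fitted probabilities near one half", {
  cfg <- dgp_config(n_subjects = 20000, seed = 47,
                    treatment = list(cont_intercept = 0,
                                     cont_cat = c(0, 0, 0, 0), cont_cum = 0,
                                     cont_frailty = 0, cont_age = 0,
                                     init_intercept = 0,
                                     init_cat = c(0, 0, 0, 0),
                                     init_frailty = 0, init_age = 0))
  co <- simulate_cohort(cfg)
  models <- fit_propensity_models(co$panel)
  expect_lt(abs(mean(models$fits$continuation$fitted) - 0.5), 0.01)
  expect_lt(abs(mean(models$fits$initiation$fitted) - 0.5), 0.01)
})

test_that("treatment weights are 1 when fitted equals the intervention law", {
  pats <- list(c(rep(1L, 6), rep(0L, 2)), c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  panel <- panel_from_patterns(pats, c("admin", "admin"))
  comp <- evaluate_compliance(panel, discontinuation_law("short_term"))
  p_on <- ifelse(panel$on_treatment == 1L, comp$intervention_prob,
                 1 - comp$intervention_prob)
  tw <- treatment_weights(panel, fake_models(panel, p_on), comp)
  expect_equal(tw$tw[comp$compatible], rep(1, sum(comp$compatible)))
})

test_that("treatment weight equals the hand-computed product of ratios", {
  ## one subject observed off in both quarters: intervention numerators are
  ## 1/12 (discontinue at quarter 1) then 1 (stay off); fitted
  ## probabilities of being on are 0.2 and 0.5
  panel <- panel_from_patterns(list(c(0L, 0L)), "admin")
  comp <- evaluate_compliance(panel, discontinuation_law("short_term"))
  expect_equal(comp$intervention_prob, c(1 / 12, 1))
  tw <- treatment_weights(panel, fake_models(panel, c(0.2, 0.5)), comp)
  expect_equal(tw$tw, c((1 / 12) / 0.8, (1 / 12) / 0.8 * 1 / 0.5))
})

test_that("restarting treatment zeroes the weight from that quarter on", {
  panel <- panel_from_patterns(list(c(1L, 0L, 0L, 1L, 1L, 0L)), "admin")
  comp <- evaluate_compliance(panel, discontinuation_law("short_term"))
  p_on <- rep(0.5, nrow(panel))
  tw <- treatment_weights(panel, fake_models(panel, p_on), comp)
  expect_true(all(tw$tw[1:3] > 0))
  expect_true(all(tw$tw[4:6] == 0))
})

test_that("stabilized censoring weights center at one when non-informative", {
  cfg <- dgp_config(n_subjects = 20000, seed = 53, censoring = list(
    death = list(intercept = qlogis(0.005), age = 0, frailty = 0,
                 cat = c(0, 0, 0, 0)),
    disenroll = list(intercept = qlogis(0.015), age = 0, frailty = 0,
                     cat = c(0, 0, 0, 0)),
    exclusion = list(intercept = qlogis(0.002), age = 0, frailty = 0,
                     cat = c(0, 0, 0, 0))))
  co <- simulate_cohort(cfg)
  models <- fit_propensity_models(co$panel)
  cw <- censoring_weights(co$panel, models)
  expect_lt(abs(mean(cw$cw) - 1), 0.02)
})

test_that("censoring weights restore the uncensored covariate distribution", {
  ## single informative cause: frail subjects disenroll far more often;
  ## no events or competing censoring, everyone stays on treatment
  cfg <- dgp_config(
    n_subjects = 20000, seed = 59,
    treatment = list(cont_intercept = Inf, cont_cat = c(0, 0, 0, 0),
                     cont_cum = 0, cont_frailty = 0, cont_age = 0),
    event = list(intercept = -Inf),
    censoring = list(
      death = list(intercept = -Inf, age = 0, frailty = 0, cat = c(0, 0, 0, 0)),
      exclusion = list(intercept = -Inf, age = 0, frailty = 0,
                       cat = c(0, 0, 0, 0)),
      disenroll = list(intercept = qlogis(0.03), age = 0, frailty = 1.5,
                       cat = c(0, 0, 0, 0))))
  co <- simulate_cohort(cfg)
  models <- fit_propensity_models(co$panel)
  cw <- censoring_weights(co$panel, models)
  rows <- which(co$panel$t == 20L)
  w <- cw$cw[rows]; x <- co$panel$frailty[rows]
  wm <- sum(w * x) / sum(w)
  target <- mean(co$subjects$frailty)       # uncensored population mean
  crude <- mean(x)
  se <- sqrt(sum((w * (x - wm))^2)) / sum(w)
  expect_lt(abs(wm - target), 3 * se)
  expect_gt(abs(crude - target), 3 * se)    # without weights it is shifted
})

test_that("combining truncates at the bound and summarizes", {
  tw <- data.table(subject_id = 1:3, t = 1L, arm = "short_term",
                   tw = c(1, 60, 2))
  cw <- data.table(subject_id = 1:3, t = 1L, cw = c(1, 2, 1))
  w <- combine_weights(tw, cw, bound = 50)
  expect_equal(w$w, c(1, 50, 2))
  expect_identical(w$truncated, c(FALSE, TRUE, FALSE))
  smry <- attr(w, "summary")
  expect_equal(smry$frac_truncated, 1 / 3)
  cw_bad <- data.table(subject_id = c(1L, 3L), t = 1L, cw = 1)
  expect_error(combine_weights(tw, cw_bad), "aligned")
})
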