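unit_weights <- function(panel, comp) {
  data.table(subject_id = panel$subject_id, t = panel$t,
             arm = comp$arm[1L], w = as.numeric(comp$compatible))
}

test_that("weighted hazard matches hand enumeration on a tiny panel", {
  ## ten subjects, everyone discontinues at quarter 2 (short-compatible);
  ## one event at quarter 3 with eight subjects still at risk
  pats <- c(
    lapply(1:7, function(i) c(1L, rep(0L, 7))),   # full follow-up
    list(c(1L, 0L, 0L)),                          # event at quarter 3
    list(c(1L, 0L)),                              # censored at quarter 2
    list(c(1L, 0L))                               # censored at quarter 2
  )
  causes <- c(rep("admin", 7), "event", "death", "disenroll")
  panel <- panel_from_patterns(pats, causes)
  comp <- evaluate_compliance(panel, discontinuation_law("short_term"))
  hz <- weighted_hazard(panel, unit_weights(panel, comp), n_quarters = 8L)
  expect_equal(hz$w_atrisk, c(10, 10, 8, 7, 7, 7, 7, 7))
  expect_equal(hz$h[3], 1 / 8)
  expect_equal(hz$h[-3], rep(0, 7))
  expect_false(any(hz$empty))
})

test_that("zero events give flat survival", {
  pats <- lapply(1:5, function(i) c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  panel <- panel_from_patterns(pats, rep("admin", 5))
  comp <- evaluate_compliance(panel, discontinuation_law("short_term"))
  sc <- survival_from_hazard(
    weighted_hazard(panel, unit_weights(panel, comp), 8L))
  expect_true(all(sc$S == 1))
  expect_true(all(sc$risk == 0))
})

test_that("survival mapping follows the product formula", {
  sc <- survival_from_hazard(c(0.01, 0.02))
  expect_equal(sc$S, c(0.99, 0.9702))
  expect_equal(sc$risk[2], 0.0298)
  ## absorbing hazard
  sc2 <- survival_from_hazard(c(1, 0.5, 0))
  expect_true(all(sc2$S == 0))
  expect_error(survival_from_hazard(c(0.5, 1.2)))
})

test_that("with unit weights and no censoring risk equals the event share", {
  ## Kaplan-Meier coincidence on complete data: everyone followed to the
  ## horizon or to their event, no censoring of any kind
  set.seed(61)
  nsub <- 40
  pats <- list(); causes <- character(nsub)
  for (i in seq_len(nsub)) {
    ev_q <- sample(c(NA, 3:8), 1, prob = c(0.5, rep(0.5 / 6, 6)))
    if (is.na(ev_q)) {
      pats[[i]] <- c(1L, rep(0L, 7)); causes[i] <- "admin"
    } else {
      pats[[i]] <- c(1L, rep(0L, ev_q - 1L)); causes[i] <- "event"
    }
  }
  panel <- panel_from_patterns(pats, causes)
  comp <- evaluate_compliance(panel, discontinuation_law("short_term"))
  expect_true(all(comp$compatible))
  sc <- survival_from_hazard(
    weighted_hazard(panel, unit_weights(panel, comp), 8L))
  expect_equal(sc$risk[8], mean(causes == "event"))
})

test_that("risk differences subtract curves with bounds checks", {
  a <- survival_from_hazard(rep(0.001, 40))
  b <- survival_from_hazard(rep(0.003, 40))
  curves <- list(short_term = a, longer_term = b)
  rd <- risk_difference(curves, 40L)
  expect_equal(rd$rd, b$risk[40] - a$risk[40])
  expect_equal(risk_difference(list(short_term = a, longer_term = a), 20L)$rd,
               0)
  expect_error(risk_difference(curves, 41L), "out of range")
})

test_that("area difference is hand-computable for one-event toy curves", {
  S_a <- rep(1, 8)
  h_b <- c(0, 0, 0.25, 0, 0, 0, 0, 0)
  S_b <- cumprod(1 - h_b)
  expect_equal(sum(S_a) - sum(S_b), sum(1 - S_b))
  expect_equal(sum(1 - S_b), 6 * 0.25)
})

test_that("bootstrap inference is seed-deterministic", {
  cfg <- dgp_preset("reduced", n_subjects = 600, seed = 67)
  co <- simulate_cohort(cfg)
  b1 <- bootstrap_inference(co$panel, B = 60, seed = 5)
  b2 <- bootstrap_inference(co$panel, B = 60, seed = 5)
  expect_identical(b1$risk, b2$risk)
  expect_identical(b1$auc_diff, b2$auc_diff)
  b3 <- bootstrap_inference(co$panel, B = 60, seed = 6)
  expect_false(identical(b1$risk, b3$risk))
  expect_error(bootstrap_inference(co$panel, B = 10, seed = 1), "at least 50")
})

test_that("a deterministic outcome collapses the bootstrap interval", {
  ## no events at all: every replicate estimates risk exactly zero
  cfg <- dgp_config(n_subjects = 300, seed = 71,
                    event = list(intercept = -Inf))
  co <- simulate_cohort(cfg)
  boot <- bootstrap_inference(co$panel, B = 60, seed = 7)
  expect_true(all(boot$risk == 0))
  at <- auc_difference_test(NULL, boot = boot)
  expect_equal(at$p_value, 1)
  expect_equal(at$difference, 0)
})

test_that("the weighted estimator is invariant to the panel construction path", {
  ## modular route (public weight functions) equals the fused estimation path
  cfg <- dgp_preset("reduced", n_subjects = 800, seed = 73)
  co <- simulate_cohort(cfg)
  prep <- prepare_estimation(co$panel)
  res <- estimate_curves(prep)

  models <- fit_propensity_models(co$panel)
  for (arm in c("short_term", "longer_term")) {
    comp <- evaluate_compliance(co$panel, discontinuation_law(arm))
    tw <- treatment_weights(co$panel, models, comp)
    cw <- censoring_weights(co$panel, models)
    w <- combine_weights(tw, cw)
    hz <- weighted_hazard(co$panel, w, n_quarters = 40L)
    sc <- survival_from_hazard(hz)
    expect_equal(sc$risk, res$curves[[arm]]$risk, tolerance = 1e-12)
  }
})
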