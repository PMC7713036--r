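## Weighted logistic regression by Newton-Raphson with step-halving.
##
## A minimal IRLS kept inside the package because bootstrap inference
## re-fits all six propensity models in every replicate (tens of thousands
## of fits across the calibration studies); model matrices are built once
## and only the case weights change between replicates, so the fit reduces
## to a handful of BLAS calls.  Agreement with stats::glm is enforced by a
## unit test.
##
## X: numeric matrix (first column the intercept); y in {0,1};
## w: nonnegative case weights; start: warm-start coefficients.
fit_logit <- function(X, y, w = NULL, start = NULL,
                      tol = 1e-6, maxit = 40L) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  keep <- w > 0
  sw1 <- sum(w * y); sw0 <- sum(w) - sw1
  if (n == 0L || sw1 == 0 || sw0 == 0) {
    p <- if (n == 0L || sum(w) == 0) 0 else sw1 / sum(w)
    return(list(coef = rep(NA_real_, ncol(X)), fitted = rep(p, n),
                converged = TRUE, degenerate = TRUE, iter = 0L,
                n = sum(keep), events = sw1))
  }

  beta <- if (!is.null(start) && all(is.finite(start))) start else {
    c(qlogis(sw1 / sum(w)), rep(0, ncol(X) - 1L))
  }
  fit <- .irls_logit(X, y, w, beta, maxit, tol)
  list(coef = drop(fit$coef), fitted = drop(fit$fitted),
       converged = fit$converged, degenerate = FALSE, iter = fit$iter,
       n = sum(keep), events = sw1, deviance = fit$deviance)
}
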