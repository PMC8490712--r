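# Convex QP backend. Both calibration subproblems are weighted least squares
# with linear inequality constraints:
#   minimize  sum_i w_i (y_i - x_i' b)^2   s.t.  t(A) b >= b0
# solved by the dual active-set method (quadprog). The Hessian 2 X'WX can be
# rank-deficient on degenerate instances (collinear features, districts with
# few years); a relative ridge is then added in escalating steps, starting
# from none so that well-posed instances are solved exactly.

solve_qp_wls <- function(X, y, w, Amat = NULL, bvec = NULL, tol = 1e-8) {
  X <- as.matrix(X)
  w <- w / mean(w)  # conditioning only; rescaling weights leaves the argmin unchanged
  Dmat <- 2 * crossprod(X, X * w)
  dvec <- 2 * as.numeric(crossprod(X, w * y))
  if (is.null(Amat)) {
    Amat <- matrix(0, ncol(X), 0)
    bvec <- numeric(0)
  }
  scale_d <- mean(diag(Dmat))
  if (!is.finite(scale_d) || scale_d <= 0) scale_d <- 1
  ridges <- c(0, scale_d * 10^c(-12, -10, -8, -6))
  last_err <- NULL
  for (r in ridges) {
    fit <- tryCatch(
      quadprog::solve.QP(Dmat + diag(r, ncol(X)), dvec, Amat, bvec, meq = 0),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      return(list(solution = fit$solution, value = fit$value, ridge = r,
                  active = fit$iact[fit$iact > 0]))
    }
    last_err <- fit
    if (grepl("constraints are inconsistent", conditionMessage(fit))) break
  }
  abort(sprintf("QP solver failed: %s", conditionMessage(last_err)))
}
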