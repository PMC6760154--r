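# Independent oracles used to check the LP engine and the controller
# arithmetic. These deliberately avoid the package's solver path.

# Exhaustive vertex enumeration for min/max c'v over {v : S v = 0,
# lb <= v <= ub}. Every vertex has n linearly independent active
# constraints; the equalities are always active, so vertices are found by
# pinning subsets of variables to a bound and solving the stacked square
# system. Returns the optimal objective value (NA if infeasible).
vertex_lp_optimum <- function(S, lb, ub, c_obj, sense = "min", tol = 1e-8) {
  n <- ncol(S)
  r <- if (nrow(S)) qr(S)$rank else 0
  k <- n - r                       # bound constraints needed per vertex
  best <- NA_real_
  consider <- function(v) {
    if (any(!is.finite(v))) return()
    if (max(abs(S %*% v)) > tol) return()
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    val <- sum(c_obj * v)
    if (is.na(best) || (sense == "min" && val < best) ||
        (sense == "max" && val > best)) best <<- val
  }
  if (k == 0) {
    # unique candidate: v solving S v = 0 -> v = 0 if S full column rank
    consider(rep(0, n))
    return(best)
  }
  subsets <- utils::combn(n, k, simplify = FALSE)
  for (J in subsets) {
    E <- matrix(0, k, n)
    E[cbind(seq_len(k), J)] <- 1
    A <- rbind(S, E)
    for (mask in 0:(2^k - 1)) {
      vals <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0, ub[J], lb[J])
      rhs <- c(rep(0, nrow(S)), vals)
      qa <- qr(A)
      if (qa$rank < n) next
      v <- tryCatch(qr.coef(qr(A), rhs), error = function(e) NULL)
      if (is.null(v)) next
      if (max(abs(A %*% v - rhs)) > tol) next   # inconsistent overdetermined
      consider(as.numeric(v))
    }
  }
  best
}

# High-resolution numerical integration of the feed-mass integral
# mass = integral_0^dt flux * MW * X0 * exp(mu t) dt
feed_mass_oracle <- function(flux, mw, X0, mu, dt) {
  stats::integrate(function(t) flux * mw * X0 * exp(mu * t), 0, dt,
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# Closed-form OLS for a raw polynomial fit: coefficients and standard errors
# from the normal equations, independent of lm().
ols_poly_oracle <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - degree - 1)
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(coef = as.numeric(beta), se = se)
}
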