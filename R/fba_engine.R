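# Linear-programming layer: steady-state flux balance S v = 0, lb <= v <= ub,
# with switchable objectives. The feed controller only ever consumes objective
# values (growth flux, minimized uptake fluxes), never individual fluxes, so
# no flux-uniqueness post-processing is applied.

BIG_BOUND <- 1000  # stand-in for +/-Inf bounds, COBRA convention

# Dense two-phase primal simplex with Bland's anti-cycling rule.
# Solves: min c'v  s.t.  A v = b,  lb <= v <= ub  (all finite).
# Variables are shifted (x = v - lb) and upper bounds written as slack rows
# (x_j + s_j = ub_j - lb_j), so every variable is bounded and phase-2 pivots
# can never be unbounded. Returns list(status, v, objective).
lp_simplex <- function(c_obj, A, b, lb, ub, tol = 1e-9, max_iter = 20000) {
  n <- length(c_obj)
  m <- nrow(A)
  w <- ub - lb                     # slack-row rhs, >= 0
  b2 <- b - as.numeric(A %*% lb)   # shifted equality rhs
  # rows: m equalities over x, then n slack rows x_j + s_j = w_j
  M <- m + n
  N <- 2L * n
  Tm <- matrix(0, M, N + 1L)
  if (m > 0) {
    Tm[seq_len(m), seq_len(n)] <- A
    Tm[seq_len(m), N + 1L] <- b2
  }
  Tm[m + seq_len(n), seq_len(n)] <- diag(n)
  Tm[m + seq_len(n), n + seq_len(n)] <- diag(n)
  Tm[m + seq_len(n), N + 1L] <- w
  neg <- Tm[, N + 1L] < 0
  Tm[neg, ] <- -Tm[neg, , drop = FALSE]

  # initial basis: slacks for slack rows, artificials for equality rows.
  # Artificial columns appended for the first m rows only.
  n_art <- m
  if (n_art > 0) {
    art <- matrix(0, M, n_art)
    art[cbind(seq_len(m), seq_len(m))] <- 1
    Tm <- cbind(Tm[, seq_len(N), drop = FALSE], art,
                Tm[, N + 1L, drop = FALSE])
  }
  rhs_col <- ncol(Tm)
  basis <- c(if (m > 0) N + seq_len(m) else integer(0), n + seq_len(n))

  # slack rows that were sign-flipped have -1 on their slack column; re-derive
  # a valid starting basis for them: if w_j >= 0 the row was not flipped, so
  # flipping only happens for equality rows (w >= 0 always). Safe.

  pivot <- function(Tm, r, j) {
    Tm[r, ] <- Tm[r, ] / Tm[r, j]
    for (i in seq_len(nrow(Tm))) {
      if (i != r && abs(Tm[i, j]) > 0) Tm[i, ] <- Tm[i, ] - Tm[i, j] * Tm[r, ]
    }
    Tm
  }

  run_phase <- function(Tm, basis, cost, allowed) {
    # canonicalize cost row against current basis
    z <- cost
    for (i in seq_along(basis)) {
      cb <- cost[basis[i]]
      if (cb != 0) z <- z - cb * Tm[i, seq_along(cost)]
    }
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(Tm = Tm, basis = basis, ok = FALSE))
      enter <- 0L
      for (j in allowed) {           # Bland: smallest eligible index
        if (z[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) return(list(Tm = Tm, basis = basis, ok = TRUE, z = z))
      ratios <- ifelse(Tm[, enter] > tol, Tm[, rhs_col] / Tm[, enter], Inf)
      if (all(!is.finite(ratios))) {
        return(list(Tm = Tm, basis = basis, ok = FALSE, unbounded = TRUE))
      }
      rmin <- min(ratios)
      cand <- which(ratios <= rmin + tol & is.finite(ratios))
      r <- cand[which.min(basis[cand])]  # Bland tie-break on basis index
      z <- z - z[enter] / Tm[r, enter] * Tm[r, seq_along(z)]
      Tm <- pivot(Tm, r, enter)
      basis[r] <- enter
    }
  }

  # phase 1: minimize sum of artificials
  if (n_art > 0) {
    cost1 <- c(rep(0, N), rep(1, n_art))
    ph1 <- run_phase(Tm, basis, cost1, seq_len(N + n_art))
    if (!ph1$ok) return(list(status = "failed"))
    Tm <- ph1$Tm; basis <- ph1$basis
    obj1 <- sum(cost1[basis] * Tm[, rhs_col])
    if (obj1 > 1e-7) return(list(status = "infeasible"))
    # drive residual artificials out of the basis
    for (i in which(basis > N)) {
      j <- which(abs(Tm[i, seq_len(N)]) > tol)[1]
      if (!is.na(j)) {
        Tm <- pivot(Tm, i, j)
        basis[i] <- j
      }
    }
    keep_rows <- basis <= N
    Tm <- Tm[keep_rows, c(seq_len(N), rhs_col), drop = FALSE]
    basis <- basis[keep_rows]
    rhs_col <- N + 1L
  }

  # phase 2
  cost2 <- c(c_obj, rep(0, n))
  ph2 <- run_phase(Tm, basis, cost2, seq_len(N))
  if (!ph2$ok) return(list(status = "failed"))
  Tm <- ph2$Tm; basis <- ph2$basis
  x <- numeric(N)
  x[basis] <- Tm[, rhs_col]
  v <- x[seq_len(n)] + lb
  list(status = "optimal", v = v, objective = sum(c_obj * v))
}

#' Solve a flux balance analysis linear program
#'
#' Optimizes a single reaction flux subject to `S v = 0` and the network's
#' flux bounds. Non-finite bounds are clipped to +/-1000 before solving; if
#' the optimum then sits on a clipped bound of the objective reaction the
#' status is reported as `"unbounded"`.
#'
#' @param network a [metabolic_network()].
#' @param reaction objective reaction identifier.
#' @param sense `"maximize"` or `"minimize"`.
#' @return a `flux_solution`: list with `v` (named fluxes), `objective_id`,
#'   `objective_value`, `status` (one of optimal/infeasible/unbounded).
#' @export
solve_fba <- function(network, reaction, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  stopifnot(inherits(network, "metabolic_network"))
  if (!reaction %in% network$reaction_ids) {
    stop("objective reaction not in network: ", reaction)
  }
  rids <- network$reaction_ids
  n <- length(rids)
  lb <- pmax(network$lb, -BIG_BOUND)
  ub <- pmin(network$ub, BIG_BOUND)
  clipped <- (network$lb < -BIG_BOUND + 1e-9) | (network$ub > BIG_BOUND - 1e-9) |
    !is.finite(network$lb) | !is.finite(network$ub)
  lb[!is.finite(lb)] <- -BIG_BOUND
  ub[!is.finite(ub)] <- BIG_BOUND

  # shift x = v - lb >= 0; S x = -S lb; x <= ub - lb
  S <- network$S
  keep <- rowSums(S != 0) > 0
  S <- S[keep, , drop = FALSE]
  a <- stats::setNames(numeric(n), rids)
  a[reaction] <- 1

  if (nrow(S) == 0) {
    v <- ifelse(a > 0, if (sense == "maximize") ub else lb, 0)
    v <- stats::setNames(pmax(lb, pmin(ub, v)), rids)
    return(new_flux_solution(v, reaction, v[[reaction]], "optimal", network))
  }

  c_obj <- if (sense == "maximize") -a else a
  res <- lp_simplex(c_obj, S, rep(0, nrow(S)), lb, ub)

  if (res$status == "infeasible") {
    sol <- new_flux_solution(stats::setNames(rep(NA_real_, n), rids),
                             reaction, NA_real_, "infeasible", network)
    log_lp(network, reaction, sense, sol)
    return(sol)
  }
  if (res$status != "optimal") {
    stop("LP solver did not converge for objective ", reaction)
  }
  v <- stats::setNames(res$v, rids)
  status <- "optimal"
  # clipped-bound diagnostics: optimum pinned to an artificial bound
  if (clipped[[reaction]] &&
      (abs(v[[reaction]] - BIG_BOUND) < 1e-6 ||
       abs(v[[reaction]] + BIG_BOUND) < 1e-6)) {
    status <- "unbounded"
  }
  sol <- new_flux_solution(v, reaction, v[[reaction]], status, network)
  log_lp(network, reaction, sense, sol)
  sol
}

new_flux_solution <- function(v, objective_id, objective_value, status,
                              network) {
  structure(list(v = v, objective_id = objective_id,
                 objective_value = objective_value, status = status,
                 steady_state_norm =
                   if (status == "optimal")
                     max(abs(network$S %*% v)) else NA_real_),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> ", x$status, ": ", x$objective_id, " = ",
      format(x$objective_value, digits = 8), "\n", sep = "")
  invisible(x)
}

log_lp <- function(network, reaction, sense, sol) {
  if (!isTRUE(getOption("mmcontrol.log_lp", FALSE))) return(invisible())
  message(jsonlite::toJSON(list(event = "lp_solve", objective = reaction,
                                sense = sense, status = sol$status,
                                value = sol$objective_value),
                           auto_unbox = TRUE, digits = NA, null = "null"))
}

as_network <- function(x) {
  if (inherits(x, "model_variant")) x$network
  else if (inherits(x, "metabolic_network")) x
  else stop("expected a model_variant or metabolic_network")
}

#' Maximize the growth (biomass) flux
#'
#' @param variant a [model_variant()] or [metabolic_network()].
#' @return a `flux_solution` for the biomass reaction.
#' @export
maximize_growth <- function(variant) {
  net <- as_network(variant)
  solve_fba(net, net$biomass_rxn, "maximize")
}

#' Minimize a nutrient uptake at a fixed growth rate
#'
#' The growth inversion at the core of metabolic model control: the biomass
#' flux is fixed to the observed growth rate (`lb = ub = mu`) and the uptake
#' flux of the named nutrient becomes the minimization objective, yielding
#' the smallest nutrient supply able to sustain that growth.
#'
#' @param variant a [model_variant()] or [metabolic_network()].
#' @param nutrient a name present in the network's `uptake_rxns` map
#'   (e.g. `"nitrate"`, `"glucose"`).
#' @param mu growth rate to impose (1/h), `mu >= 0`.
#' @return a `flux_solution` for the uptake reaction; on infeasibility the
#'   field `max_growth` carries the largest achievable growth rate.
#' @export
minimize_uptake_at_growth <- function(variant, nutrient, mu) {
  net <- as_network(variant)
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0) {
    stop("mu must be a single non-negative growth rate")
  }
  rxn <- uptake_reaction(net, nutrient)
  net2 <- set_bounds(net, net$biomass_rxn, lb = mu, ub = mu)
  sol <- solve_fba(net2, rxn, "minimize")
  if (sol$status == "infeasible") {
    sol$max_growth <- maximize_growth(net)$objective_value
  }
  sol
}

uptake_reaction <- function(network, nutrient) {
  if (!nutrient %in% names(network$uptake_rxns)) {
    stop("nutrient '", nutrient, "' has no mapped uptake reaction; available: ",
         paste(names(network$uptake_rxns), collapse = ", "))
  }
  network$uptake_rxns[[nutrient]]
}

#' Lexicographic minimization of several uptakes at fixed growth
#'
#' Sequential uptake minimization used under heterotrophy: each nutrient in
#' `order` is minimized with every previously minimized uptake fixed (as an
#' equality within `fix_tol`) at its optimum, so later stages cannot degrade
#' earlier optima. `order = c("glucose", "nitrate")` reproduces the two-stage
#' glucose-then-nitrate procedure; a single-element order reduces to
#' [minimize_uptake_at_growth()].
#'
#' @param variant a [model_variant()] or [metabolic_network()].
#' @param mu growth rate to impose (1/h).
#' @param order character vector of nutrient names, minimized in order.
#' @param fix_tol half-width of the equality window used to fix earlier
#'   optima (default 1e-9).
#' @return named numeric of minimized uptake fluxes, with attribute
#'   `solutions` (list of `flux_solution`s). Infeasibility at any stage
#'   raises an error naming the stage.
#' @export
lexicographic_minimize <- function(variant, mu,
                                   order = c("glucose", "nitrate"),
                                   fix_tol = 1e-12) {
  net <- as_network(variant)
  if (!length(order)) stop("order must name at least one nutrient")
  net <- set_bounds(net, net$biomass_rxn, lb = mu, ub = mu)
  out <- stats::setNames(numeric(length(order)), order)
  sols <- vector("list", length(order))
  for (i in seq_along(order)) {
    rxn <- uptake_reaction(net, order[[i]])
    sol <- solve_fba(net, rxn, "minimize")
    if (sol$status != "optimal") {
      stop("lexicographic stage '", order[[i]], "' is ", sol$status,
           " at mu = ", format(mu))
    }
    out[[i]] <- sol$objective_value
    sols[[i]] <- sol
    net <- set_bounds(net, rxn,
                      lb = sol$objective_value - fix_tol,
                      ub = sol$objective_value + fix_tol)
  }
  attr(out, "solutions") <- sols
  out
}
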