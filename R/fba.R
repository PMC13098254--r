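# Flux balance analysis: maximize the biomass objective subject to
# steady-state mass balance S v = 0 and reaction bounds, as a linear program.

BOUND_CAP <- 1000 # conventional |bound| cap for "unconstrained" reactions

#' Flux balance analysis on a metabolic network
#'
#' Exchanges are closed (lower bound 0) except those opened by `medium`
#' (lower bound `-rate`) and the carbon source of interest, opened at
#' `-uptake`. Only the carbon exchange of interest is toggled; inorganic /
#' non-carbon exchanges belong in `medium`. Growth is declared when the
#' optimal objective exceeds `growth_tol`.
#'
#' @param network a `metabolic_network`.
#' @param medium named numeric vector, exchange reaction id -> allowed uptake
#'   rate (mmol/h/gCDW, non-negative); `NULL` for none.
#' @param carbon_source exchange reaction id of the sole carbon source, or
#'   `NULL` to use the bounds as stored.
#' @param uptake uptake rate for the carbon source (default 10 mmol/h/gCDW).
#' @param growth_tol objective threshold above which growth is called.
#' @return an `fba_solution`: list with `objective` (1/h scale, `NA` if not
#'   optimal), `fluxes` (named vector), `status` (`"optimal"`,
#'   `"infeasible"` or `"unsolved"`), and `growth` (logical).
#' @export
fba <- function(network, medium = NULL, carbon_source = NULL, uptake = 10,
                growth_tol = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  rx <- network$reactions
  lb <- pmax(rx$lower_bound, -BOUND_CAP)
  ub <- pmin(rx$upper_bound, BOUND_CAP)
  ex <- startsWith(rx$id, "EX_")
  if (!is.null(carbon_source) || !is.null(medium)) {
    lb[ex] <- pmax(lb[ex], 0) # close all exchanges, then reopen
    if (!is.null(medium)) {
      stopifnot(is.numeric(medium), !is.null(names(medium)), all(medium >= 0))
      unknown <- setdiff(names(medium), rx$id)
      if (length(unknown)) {
        abort(paste0("medium references unknown exchange(s): ",
                     toString(unknown)))
      }
      lb[match(names(medium), rx$id)] <- -abs(medium)
    }
    if (!is.null(carbon_source)) {
      j <- match(carbon_source, rx$id)
      if (is.na(j)) abort(sprintf("unknown exchange reaction '%s'", carbon_source))
      if (!ex[j]) abort(sprintf("'%s' is not an exchange reaction", carbon_source))
      lb[j] <- -abs(uptake)
    }
  }
  sol <- solve_lp_max(stoichiometry_matrix(network),
                      lb, ub,
                      objective = as.numeric(rx$id == network$objective))
  fluxes <- setNames(sol$x, rx$id)
  obj <- if (sol$status == "optimal") sol$value else NA_real_
  structure(
    list(objective = obj, fluxes = fluxes, status = sol$status,
         growth = isTRUE(obj > growth_tol)),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution> status: %s; objective: %s; growth: %s\n",
              x$status,
              if (is.na(x$objective)) "NA" else format(x$objective),
              x$growth))
  invisible(x)
}

#' Dense stoichiometric matrix of a network
#'
#' @param network a `metabolic_network`.
#' @return numeric matrix, metabolites x reactions.
#' @export
stoichiometry_matrix <- function(network) {
  mets <- network$metabolites$id
  rx <- network$reactions
  S <- matrix(0, nrow = length(mets), ncol = nrow(rx),
              dimnames = list(mets, rx$id))
  for (j in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

# maximize c'v subject to S v = 0, lb <= v <= ub.
# Shifted to x = v - lb >= 0; upper bounds become slack rows, giving the
# standard form max c'x, A x = b, x >= 0 solved by a dense two-phase simplex.
solve_lp_max <- function(S, lb, ub, objective) {
  n <- length(lb)
  stopifnot(ncol(S) == n, length(ub) == n, length(objective) == n)
  m <- nrow(S)
  A <- rbind(cbind(S, matrix(0, m, n)),
             cbind(diag(n), diag(n)))
  b <- c(as.numeric(-S %*% lb), ub - lb)
  sol <- simplex_bland(c(objective, rep(0, n)), A, b)
  if (sol$status != "optimal") {
    return(list(status = sol$status, x = rep(NA_real_, n), value = NA_real_))
  }
  x <- sol$x[seq_len(n)] + lb
  list(status = "optimal", x = x, value = sum(objective * x))
}

# Dense two-phase primal simplex maximizing c'x s.t. A x = b, x >= 0.
# Bland's anti-cycling rule (smallest-index entering column; smallest basis
# index on ratio ties) guarantees termination; adequate and exact at the
# desk scale of these networks.
simplex_bland <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  run_phase <- function(Tab, rhs, basis, cost, allowed) {
    repeat {
      cb <- cost[basis]
      red <- cost - as.numeric(crossprod(cb, Tab))
      red[basis] <- 0
      enter <- which(red < -tol & allowed)
      if (!length(enter)) {
        return(list(Tab = Tab, rhs = rhs, basis = basis, unbounded = FALSE))
      }
      pc <- min(enter) # Bland: smallest eligible index
      col <- Tab[, pc]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(Tab = Tab, rhs = rhs, basis = basis, unbounded = TRUE))
      }
      ratios <- pmax(rhs[pos], 0) / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      pr <- cand[which.min(basis[cand])] # Bland tie-break
      piv <- Tab[pr, pc]
      Tab[pr, ] <- Tab[pr, ] / piv
      rhs[pr] <- rhs[pr] / piv
      for (i in seq_len(m)) {
        if (i != pr && abs(Tab[i, pc]) > tol * 1e-3) {
          f <- Tab[i, pc]
          Tab[i, ] <- Tab[i, ] - f * Tab[pr, ]
          rhs[i] <- rhs[i] - f * rhs[pr]
        }
      }
      basis[pr] <- pc
    }
  }

  # phase 1: artificial basis, minimize their sum (as max of the negative)
  Tab <- cbind(A, diag(m))
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  r1 <- run_phase(Tab, b, basis, cost1, allowed = rep(TRUE, n + m))
  if (r1$unbounded) return(list(status = "unsolved"))
  if (sum(cost1[r1$basis] * r1$rhs) > 1e-7) return(list(status = "infeasible"))
  Tab <- r1$Tab; rhs <- r1$rhs; basis <- r1$basis
  # pivot remaining artificials out where a structural column is available;
  # an all-zero structural row is redundant and its artificial stays at zero
  for (i in which(basis > n)) {
    j <- which(abs(Tab[i, seq_len(n)]) > tol)
    if (length(j)) {
      pc <- j[1]
      piv <- Tab[i, pc]
      Tab[i, ] <- Tab[i, ] / piv
      rhs[i] <- rhs[i] / piv
      for (k in seq_len(m)) {
        if (k != i && abs(Tab[k, pc]) > 0) {
          f <- Tab[k, pc]
          Tab[k, ] <- Tab[k, ] - f * Tab[i, ]
          rhs[k] <- rhs[k] - f * rhs[i]
        }
      }
      basis[i] <- pc
    }
  }
  # phase 2: maximize c'x over structural columns only
  cost2 <- c(-cvec, rep(0, m))
  r2 <- run_phase(Tab, rhs, basis, cost2,
                  allowed = c(rep(TRUE, n), rep(FALSE, m)))
  if (r2$unbounded) return(list(status = "unbounded"))
  x <- numeric(n)
  keep <- r2$basis <= n
  x[r2$basis[keep]] <- pmax(r2$rhs[keep], 0)
  list(status = "optimal", x = x, value = sum(cvec * x))
}
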