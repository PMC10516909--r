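# Brute-force dense LP used only by the test oracle (oracle_fba /
# oracle_scan): a textbook two-phase tableau simplex with Bland's
# anti-cycling rule. Deliberately independent of the production FBA code
# path (different formulation, different pivoting), deterministic, and
# intended for problems of a few dozen variables.
#
# Solves: optimize cc . x  subject to  Aeq x = beq,  0 <= x <= ub.
# Returns list(x, value) or NULL when infeasible.
bland_lp <- function(cc, Aeq, beq, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(cc)
  # standard form: append slacks for the upper bounds
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), n)),
             cbind(diag(n), diag(n)))
  b <- c(beq, ub)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  m <- nrow(A)
  N <- ncol(A)

  # phase 1: artificial basis, minimize sum of artificials
  T <- cbind(A, diag(m), b)
  basis <- N + seq_len(m)
  z <- c(rep(0, N), rep(1, m), 0)
  for (i in seq_len(m)) z <- z - T[i, ]
  res <- bland_iterate(T, z, basis, tol)
  if (is.null(res) || -res$z[length(res$z)] > 1e-7) return(NULL)
  T <- res$T; basis <- res$basis

  # pivot residual artificials out of the basis; drop redundant rows
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] <= N) next
    piv <- which(abs(T[i, seq_len(N)]) > tol)
    piv <- setdiff(piv, basis)
    if (length(piv)) {
      T <- pivot_row(T, i, piv[1])
      basis[i] <- piv[1]
    } else {
      keep[i] <- FALSE   # redundant constraint
    }
  }
  T <- T[keep, , drop = FALSE]
  basis <- basis[keep]

  # phase 2 on the original columns
  T <- T[, c(seq_len(N), N + m + 1), drop = FALSE]
  cost <- c(if (maximize) -cc else cc, rep(0, N - n), 0)
  z <- cost
  for (i in seq_along(basis)) {
    if (abs(z[basis[i]]) > 0) z <- z - z[basis[i]] * T[i, ]
  }
  res <- bland_iterate(T, z, basis, tol)
  if (is.null(res)) return(NULL)   # unbounded cannot occur with finite ub
  x <- numeric(N)
  x[res$basis] <- res$T[, ncol(res$T)]
  x <- x[seq_len(n)]
  list(x = x, value = sum(cc * x))
}

# minimize, entering = lowest-index negative reduced cost, leaving =
# lowest-index basic variable among the minimum ratios (Bland's rule)
bland_iterate <- function(T, z, basis, tol, max_iter = 20000) {
  rhs <- ncol(T)
  for (iter in seq_len(max_iter)) {
    enter <- which(z[-rhs] < -tol)
    if (!length(enter)) return(list(T = T, z = z, basis = basis))
    j <- enter[1]
    col <- T[, j]
    rows <- which(col > tol)
    if (!length(rows)) return(NULL)   # unbounded direction
    ratio <- T[rows, rhs] / col[rows]
    cand <- rows[ratio <= min(ratio) + tol]
    r <- cand[which.min(basis[cand])]
    T <- pivot_row(T, r, j)
    z <- z - z[j] * T[r, ]
    basis[r] <- j
  }
  stop("oracle simplex exceeded the iteration limit")
}

pivot_row <- function(T, r, j) {
  T[r, ] <- T[r, ] / T[r, j]
  for (i in seq_len(nrow(T))) {
    if (i != r && abs(T[i, j]) > 0) T[i, ] <- T[i, ] - T[i, j] * T[r, ]
  }
  T
}

#' Independent dense-LP oracle for a single FBA objective
#'
#' Computes the optimal objective value of an FBA problem through the
#' oracle's brute-force dense simplex rather than the production solver;
#' used in tests to cross-check [fba()] on small fixtures.
#'
#' @param model a `gem` (small; the oracle is dense).
#' @param objective reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @return the optimal objective value, or `NA` if infeasible.
#' @export
oracle_fba <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  j <- match_reaction(model, objective)
  lb <- pmax(model$rxns$lb, -1e5)
  ub <- pmin(model$rxns$ub, 1e5)
  Sd <- as.matrix(model$S)
  # shifted variables x = v - lb in [0, ub - lb]
  cc <- numeric(nrow(model$rxns)); cc[j] <- 1
  res <- bland_lp(cc, Sd, as.numeric(-Sd %*% lb), ub - lb,
                  maximize = (sense == "max"))
  if (is.null(res)) return(NA_real_)
  res$value + lb[j]
}
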