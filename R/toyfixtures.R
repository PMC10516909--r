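#' The six-reaction reference toy model
#'
#' A deterministic linear-chain model whose scan outcome is known by
#' construction and which anchors most of the test suite:
#'
#' * `EX_A`: uptake of substrate A, bounds (-10, 0)
#' * `R1`:   A -> B
#' * `R2`:   B ->  (biomass drain; the objective)
#' * `R3`:   B -> P
#' * `EX_P`: P ->  (target sink)
#' * `R5`:   A -> W with `EX_W`: W ->  (never-profitable waste branch)
#'
#' Ground truth: maximal biomass and maximal target flux are both 10
#' (pinned by the uptake bound); enforcing target flux e forces biomass
#' 10 - e; `R3`/`EX_P` are flux-increasing, `R2` flux-decreasing,
#' `EX_A`/`R1` unaffected (saturated); `R1`, `R2` and `EX_A` are
#' essential, the waste branch is not.
#'
#' @return a `gem` with 4 internal metabolites and 7 reactions (6 named in
#'   the chain plus the waste exchange).
#' @export
build_toy1 <- function() {
  gem_from_reactions("TOY1", list(
    list(id = "EX_A", name = "A exchange", mets = c(A = -1),
         lb = -10, ub = 0, subsystem = "Exchange"),
    list(id = "R1", name = "A to B", mets = c(A = -1, B = 1),
         lb = 0, ub = 1000, subsystem = "Core"),
    list(id = "R2", name = "biomass drain", mets = c(B = -1),
         lb = 0, ub = 1000, subsystem = "Biomass", objective_coef = 1),
    list(id = "R3", name = "B to P", mets = c(B = -1, P = 1),
         lb = 0, ub = 1000, subsystem = "Target pathway"),
    list(id = "EX_P", name = "P sink", mets = c(P = -1),
         lb = 0, ub = 1000, subsystem = "Exchange"),
    list(id = "R5", name = "A to W", mets = c(A = -1, W = 1),
         lb = 0, ub = 1000, subsystem = "Waste branch"),
    list(id = "EX_W", name = "W exchange", mets = c(W = -1),
         lb = 0, ub = 1000, subsystem = "Exchange")))
}

#' Seeded random toy model
#'
#' Generates a small branched network with a known-by-construction scan
#' outcome: a linear chain from a bounded substrate uptake to a biomass
#' drain, a target branch leaving the chain at a random position with its
#' own sink, and up to three dead-end waste branches attached at random
#' chain metabolites. The topology is a tree, so for any fixed enforced
#' target flux the optimal flux distribution is unique — which is what
#' makes the fixtures sharp instruments for comparing the scan against the
#' oracle. Optionally a maintenance-style drain with a positive lower
#' bound is attached to the first chain metabolite.
#'
#' @param n_branch_reactions number of waste branches (capped at 3).
#' @param uptake_bound substrate uptake magnitude; must be positive.
#' @param include_maintenance attach a drain with lower bound 0.1.
#' @param seed integer seed; the same seed yields the identical model.
#' @return a `gem` with at most 15 reactions; biomass reaction `BIOMASS`,
#'   target sink `EX_P`.
#' @export
build_random_toy <- function(n_branch_reactions = 2, uptake_bound = 10,
                             include_maintenance = FALSE, seed = 1) {
  if (uptake_bound <= 0) stop("uptake_bound must be positive")
  nb <- min(n_branch_reactions, 3)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  L <- sample(2:4, 1)
  chain <- paste0("C", seq_len(L))
  rxns <- list(
    list(id = "EX_S", name = "substrate exchange",
         mets = stats::setNames(-1, chain[1]),
         lb = -uptake_bound, ub = 0, subsystem = "Exchange"))
  for (i in seq_len(L - 1)) {
    rxns[[length(rxns) + 1]] <- list(
      id = paste0("CH", i), name = paste("chain", i),
      mets = stats::setNames(c(-1, 1), chain[c(i, i + 1)]),
      lb = 0, ub = 1000, subsystem = "Core")
  }
  rxns[[length(rxns) + 1]] <- list(
    id = "BIOMASS", name = "biomass drain",
    mets = stats::setNames(-1, chain[L]),
    lb = 0, ub = 1000, subsystem = "Biomass", objective_coef = 1)
  tpos <- sample(seq_len(L), 1)
  rxns[[length(rxns) + 1]] <- list(
    id = "TGT", name = "target branch",
    mets = stats::setNames(c(-1, 1), c(chain[tpos], "P")),
    lb = 0, ub = 1000, subsystem = "Target pathway")
  rxns[[length(rxns) + 1]] <- list(
    id = "EX_P", name = "target sink", mets = c(P = -1),
    lb = 0, ub = 1000, subsystem = "Exchange")
  for (b in seq_len(nb)) {
    src <- chain[sample(seq_len(L), 1)]
    w <- paste0("W", b)
    rxns[[length(rxns) + 1]] <- list(
      id = paste0("BR", b), name = paste("waste branch", b),
      mets = stats::setNames(c(-1, 1), c(src, w)),
      lb = 0, ub = 1000, subsystem = "Waste branch")
    rxns[[length(rxns) + 1]] <- list(
      id = paste0("EX_W", b), name = paste("waste exchange", b),
      mets = stats::setNames(-1, w),
      lb = 0, ub = 1000, subsystem = "Exchange")
  }
  if (include_maintenance) {
    rxns[[length(rxns) + 1]] <- list(
      id = "ATPM", name = "maintenance drain",
      mets = stats::setNames(-1, chain[1]),
      lb = 0.1, ub = 1000, subsystem = "Maintenance")
  }
  gem_from_reactions(paste0("RTOY_seed", seed), rxns)
}

#' Brute-force oracle classification of a scan
#'
#' Independent ground-truth path used to validate [run_scan()] +
#' [classify_reactions()]: at each enforced target value it maximizes
#' biomass by the oracle's own dense tableau simplex (a different
#' formulation and a different solver code path from the production FBA),
#' then computes every reaction's attainable flux range at that optimum by
#' exhaustive min/max LP, and classifies each reaction on the trend of its
#' range midpoints. Classifying on midpoints rather than a single optimal
#' vertex makes the oracle insensitive to alternate optima.
#'
#' Only intended for models of at most ~20 reactions.
#'
#' @param model a `gem` (<= 20 reactions).
#' @param biomass_id biomass reaction id.
#' @param target_id target sink reaction id.
#' @param schedule a `step_schedule`.
#' @param change_tol classification tolerance, as in
#'   [classify_reactions()].
#' @param monotonicity_tol validity-filter tolerance, as in
#'   [filter_valid_profiles()].
#' @return data.frame `reaction_id`, `reaction_type`, as the subset of
#'   reactions an equivalent filter retains.
#' @export
oracle_scan <- function(model, biomass_id, target_id, schedule,
                        change_tol = 0.01, monotonicity_tol = 1e-4) {
  stopifnot(nrow(model$rxns) <= 20)
  nr <- nrow(model$rxns)
  lb <- pmax(model$rxns$lb, -1e5)
  ub <- pmin(model$rxns$ub, 1e5)
  bj <- match_reaction(model, biomass_id)
  tj <- match_reaction(model, target_id)
  Sd <- as.matrix(model$S)
  n <- schedule$n_steps
  mid <- matrix(NA_real_, nr, n, dimnames = list(model$rxns$id, NULL))

  # dense LP over x = v - lb >= 0:  S x = -S lb,  x <= ub - lb
  solve_lp <- function(cc, lbk, extra_Aeq = NULL, extra_beq = NULL,
                       maximize = TRUE) {
    Aeq <- rbind(Sd, extra_Aeq)
    beq <- c(as.numeric(-Sd %*% lbk),
             if (is.null(extra_Aeq)) NULL
             else extra_beq - as.numeric(extra_Aeq %*% lbk))
    out <- bland_lp(cc, Aeq, beq, ub - lbk, maximize = maximize)
    if (is.null(out)) return(NULL)
    out$x + lbk   # back to v
  }

  for (k in seq_len(n)) {
    lbk <- lb
    lbk[tj] <- schedule$enforced_values[k]
    if (lbk[tj] > ub[tj]) next
    e_b <- numeric(nr); e_b[bj] <- 1
    v <- solve_lp(e_b, lbk)
    if (is.null(v)) next
    bstar <- v[bj]
    brow <- matrix(e_b, 1)
    for (j in seq_len(nr)) {
      e_j <- numeric(nr); e_j[j] <- 1
      vmin <- solve_lp(e_j, lbk, brow, bstar, maximize = FALSE)
      vmax <- solve_lp(e_j, lbk, brow, bstar, maximize = TRUE)
      if (is.null(vmin) || is.null(vmax)) next
      mid[j, k] <- (vmin[j] + vmax[j]) / 2
    }
  }

  # independent re-statement of the validity filter and 3-way rule
  res <- lapply(seq_len(nr), function(j) {
    v <- abs(mid[j, ])
    if (anyNA(v)) return(NULL)
    tol_m <- max(monotonicity_tol * max(v), 1e-9)
    if (!(all(diff(v) >= -tol_m) || all(diff(v) <= tol_m))) return(NULL)
    tol_c <- max(change_tol * max(v[1], v[n]), 1e-9)
    d <- v[n] - v[1]
    type <- if (d > tol_c) "flux_increasing"
            else if (d < -tol_c) "flux_decreasing"
            else "unaffected"
    data.frame(reaction_id = model$rxns$id[j], reaction_type = type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res[!vapply(res, is.null, TRUE)],
                   list(make.row.names = FALSE)))
}
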