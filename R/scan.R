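#' Initialize a growth-coupled scan
#'
#' The scan's initiation stage establishes four numbers: the non-growth ATP
#' maintenance floor (the maintenance reaction's lower bound, or an
#' override — the model must sustain this ATP hydrolysis flux at any
#' growth rate), the minimal and the theoretical maximal biomass flux under
#' the current constraints, and the maximal attainable target flux with
#' biomass left free. The target maximum anchors the enforced-flux step
#' schedule.
#'
#' @param model a constrained `gem`.
#' @param biomass_id biomass reaction id.
#' @param target_id target sink reaction id (e.g. a heme demand reaction).
#' @param atp_maintenance_override optional maintenance floor replacing the
#'   value read from the model.
#' @return a `scan_init` list: `atp_maintenance_floor`, `biomass_min`,
#'   `biomass_max`, `target_max`.
#' @export
initialize_scan <- function(model, biomass_id, target_id,
                            atp_maintenance_override = NULL) {
  match_reaction(model, biomass_id)
  match_reaction(model, target_id)
  floor_ <- if (!is.null(atp_maintenance_override)) {
    atp_maintenance_override
  } else {
    j <- find_maintenance_reaction(model)
    if (is.na(j)) 0 else max(model$rxns$lb[j], 0)
  }
  bmax <- fba(model, biomass_id, "max", deterministic = FALSE)
  if (bmax$status != "optimal") {
    stop("scan initialization failed at max-biomass FBA: status ",
         bmax$status)
  }
  bmin <- fba(model, biomass_id, "min", deterministic = FALSE)
  if (bmin$status != "optimal") {
    stop("scan initialization failed at min-biomass FBA: status ",
         bmin$status)
  }
  tmax <- fba(model, target_id, "max", deterministic = FALSE)
  if (tmax$status != "optimal") {
    stop("scan initialization failed at max-target FBA: status ",
         tmax$status)
  }
  structure(list(atp_maintenance_floor = floor_,
                 biomass_min = max(bmin$objective_value, 0),
                 biomass_max = bmax$objective_value,
                 target_max = tmax$objective_value),
            class = "scan_init")
}

#' Build the enforced-flux step schedule
#'
#' The target flux axis from 0 to `cap_fraction * target_max` is divided
#' into `n_steps` equal steps; the enforced values are the step endpoints
#' `(k / n_steps) * cap_fraction * target_max`, k = 1..n_steps. The cap
#' (default 90% of the maximum) keeps the final step away from the
#' theoretical target maximum, where biomass formation collapses to zero
#' and growth-coupling cannot be read out.
#'
#' @param target_max maximal target flux from [initialize_scan()]; must be
#'   positive.
#' @param n_steps number of steps (default 5).
#' @param cap_fraction fraction of `target_max` reached at the last step
#'   (default 0.9).
#' @return a `step_schedule` list: `enforced_values`, `n_steps`,
#'   `cap_fraction`, `target_max`.
#' @examples
#' build_step_schedule(10)  # 1.8 3.6 5.4 7.2 9.0
#' @export
build_step_schedule <- function(target_max, n_steps = 5, cap_fraction = 0.9) {
  if (!is.numeric(target_max) || target_max <= 0) {
    stop("target cannot carry flux (target_max = ", target_max, ")")
  }
  stopifnot(n_steps >= 2, cap_fraction > 0, cap_fraction <= 1)
  vals <- seq_len(n_steps) * (cap_fraction * target_max / n_steps)
  structure(list(enforced_values = vals, n_steps = n_steps,
                 cap_fraction = cap_fraction, target_max = target_max),
            class = "step_schedule")
}

#' Run the enforced-flux scan
#'
#' For every scheduled step the target reaction's lower bound is raised to
#' the enforced value (its upper bound is kept, so the optimum may exceed
#' the enforced value if that benefits growth), biomass is re-maximized
#' with the deterministic parsimonious solve, and every reaction's flux is
#' recorded. The result is one five-value profile per reaction plus the
#' biomass trajectory. An infeasible step is flagged, not fatal: its column
#' is `NA` and every profile's `all_feasible` flag drops to `FALSE`.
#'
#' Asserts, as an invariant of the method, that the recorded biomass
#' trajectory is non-increasing in the enforced target flux (raising a
#' lower bound can only shrink the feasible region).
#'
#' @param model a constrained `gem`.
#' @param biomass_id biomass reaction id.
#' @param target_id target sink reaction id.
#' @param schedule a `step_schedule`.
#' @param deterministic use the minimal-total-absolute-flux secondary
#'   objective (default `TRUE`); `FALSE` records raw solver vertices.
#' @return a `scan_table`: list with `profiles` (data.frame: Reactions_ID,
#'   Reactions_name, FBA_results_1..n, Subsystem, Var10, all_feasible,
#'   direction_left_to_right), `biomass_per_step`, `init` fields carried
#'   through in `schedule`, and flags.
#' @export
run_scan <- function(model, biomass_id, target_id, schedule,
                     deterministic = TRUE) {
  stopifnot(inherits(schedule, "step_schedule"))
  match_reaction(model, biomass_id)
  tj <- match_reaction(model, target_id)
  n <- schedule$n_steps
  nr <- nrow(model$rxns)
  flux <- matrix(NA_real_, nr, n, dimnames = list(model$rxns$id, NULL))
  biomass <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    mk <- model
    mk$rxns$lb[tj] <- schedule$enforced_values[k]
    if (mk$rxns$lb[tj] > mk$rxns$ub[tj]) {
      next   # enforced value outside the target's own bounds: infeasible
    }
    sol <- fba(mk, biomass_id, "max", deterministic = deterministic)
    if (sol$status != "optimal") next
    flux[, k] <- sol$fluxes[model$rxns$id]
    biomass[k] <- sol$objective_value
  }
  ok <- !is.na(biomass)
  if (sum(ok) >= 2) {
    d <- diff(biomass[ok])
    if (any(d > 1e-6)) {
      stop("biomass per step increased with the enforced target flux; ",
           "scan invariant violated")
    }
  }
  profiles <- data.frame(
    Reactions_ID = model$rxns$id,
    Reactions_name = model$rxns$name,
    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    profiles[[paste0("FBA_results_", k)]] <- flux[, k]
  }
  profiles$Subsystem <- model$rxns$subsystem
  profiles$Var10 <- vapply(model$rxns$id, function(id)
    reaction_equation(model, id), character(1))
  profiles$all_feasible <- rep(all(ok), nr)
  profiles$steadily_changing <- NA
  # TRUE when every non-negligible recorded flux runs left to right
  profiles$direction_left_to_right <- apply(flux, 1, function(v) {
    v <- v[!is.na(v)]
    v <- v[abs(v) > 1e-9]
    if (!length(v)) return(TRUE)
    all(v > 0)
  })
  rownames(profiles) <- NULL
  structure(list(profiles = profiles, biomass_per_step = biomass,
                 schedule = schedule, biomass_id = biomass_id,
                 target_id = target_id, deterministic = deterministic),
            class = "scan_table")
}

#' @export
print.scan_table <- function(x, ...) {
  cat("<scan_table> ", nrow(x$profiles), " reactions x ",
      x$schedule$n_steps, " steps; target ", x$target_id,
      " enforced up to ", fmt_num(max(x$schedule$enforced_values)), "\n",
      sep = "")
  cat("  biomass per step:", paste(fmt_num(x$biomass_per_step),
                                   collapse = " "), "\n")
  invisible(x)
}

flux_matrix <- function(table) {
  cols <- grep("^FBA_results_", names(table$profiles))
  as.matrix(table$profiles[, cols, drop = FALSE])
}

#' Keep complete, steadily changing profiles
#'
#' Retains only reactions whose profile has a value at all steps
#' (`all_feasible`) and whose absolute flux sequence is monotone —
#' non-increasing or non-decreasing — within a relative tolerance.
#' Profiles that wobble reflect alternate-optima noise or non-steady
#' behaviour and are dropped before classification.
#'
#' @param table a `scan_table`.
#' @param monotonicity_tol relative tolerance for monotonicity (default
#'   1e-4 of the profile's largest magnitude, absolute floor 1e-9).
#' @return the filtered `scan_table`, with `steadily_changing` set on the
#'   survivors.
#' @export
filter_valid_profiles <- function(table, monotonicity_tol = 1e-4) {
  fm <- abs(flux_matrix(table))
  keep <- table$profiles$all_feasible & apply(fm, 1, function(v) {
    if (anyNA(v)) return(FALSE)
    tol <- max(monotonicity_tol * max(v), 1e-9)
    all(diff(v) >= -tol) || all(diff(v) <= tol)
  })
  table$profiles <- table$profiles[keep, , drop = FALSE]
  table$profiles$steadily_changing <- rep(TRUE, nrow(table$profiles))
  rownames(table$profiles) <- NULL
  table
}

#' Classify reactions by their response to enforced target flux
#'
#' Compares each retained reaction's absolute flux at the first and last
#' step: an increase beyond `change_tol` marks a flux-increasing reaction
#' (upregulation candidate), a decrease a flux-decreasing reaction
#' (downregulation/deletion candidate), anything else is unaffected. The
#' proportionality label combines the carried direction (positive = flux
#' runs left to right in the written stoichiometry) with the trend against
#' the enforced target flux: directly proportional (rising with the
#' target) or contra proportional (falling).
#'
#' @param table a filtered `scan_table`.
#' @param change_tol relative flux change between first and last step below
#'   which a reaction counts as unaffected (default 1%, absolute floor
#'   1e-9).
#' @return data.frame with `reaction_id`, `reaction_type`
#'   (`flux_increasing` / `flux_decreasing` / `unaffected`),
#'   `proportionality` (`positive_directly`, `positive_contra`,
#'   `negative_directly`, `negative_contra`, `none`),
#'   `direction_left_to_right`, `subsystem`.
#' @export
classify_reactions <- function(table, change_tol = 0.01) {
  fm <- abs(flux_matrix(table))
  p <- table$profiles
  n <- nrow(p)
  type <- character(n)
  prop <- character(n)
  for (i in seq_len(n)) {
    v <- fm[i, ]
    ref <- max(v[1], v[length(v)])
    tol <- max(change_tol * ref, 1e-9)
    delta <- v[length(v)] - v[1]
    if (delta > tol) {
      type[i] <- "flux_increasing"
    } else if (delta < -tol) {
      type[i] <- "flux_decreasing"
    } else {
      type[i] <- "unaffected"
    }
    prop[i] <- if (type[i] == "unaffected") {
      "none"
    } else {
      paste0(if (p$direction_left_to_right[i]) "positive" else "negative",
             if (type[i] == "flux_increasing") "_directly" else "_contra")
    }
  }
  data.frame(reaction_id = p$Reactions_ID,
             reaction_type = type,
             proportionality = prop,
             direction_left_to_right = p$direction_left_to_right,
             subsystem = p$Subsystem,
             stringsAsFactors = FALSE)
}
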