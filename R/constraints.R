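#' Build a constraint set from experimental rates
#'
#' A `constraint_set` captures the exchange-flux bounds measured in a
#' cultivation (exometabolomics): direct signed bounds, uptake rates given
#' as positive magnitudes, the measured specific growth rate, the carbon
#' substrate (used to pick the matching biomass reaction in models that
#' carry one composition per substrate), and an optional non-growth ATP
#' maintenance override.
#'
#' Sign convention: within a model, uptake is a negative exchange flux and
#' secretion positive. Published uptake rates are positive magnitudes, so an
#' `uptake` entry `c(2.17, 2.29)` (mmol gDW^-1 h^-1) becomes exchange
#' bounds `(-2.29, -2.17)`.
#'
#' @param bounds named list/vector of `c(lower, upper)` signed bounds per
#'   exchange reaction id.
#' @param uptake named list of `c(min_rate, max_rate)` positive uptake
#'   magnitudes per exchange reaction id.
#' @param measured_mu measured specific growth rate, h^-1 (optional).
#' @param substrate `"glycerol"`, `"methanol"` or `NA`.
#' @param atp_maintenance_override lower bound to impose on the ATP
#'   maintenance reaction, mmol gDW^-1 h^-1 (optional).
#' @return a `constraint_set`.
#' @export
constraint_set <- function(bounds = list(), uptake = list(),
                           measured_mu = NULL, substrate = NA_character_,
                           atp_maintenance_override = NULL) {
  norm <- function(x) lapply(x, function(b) {
    b <- as.numeric(b)
    if (length(b) == 1) b <- c(b, b)
    if (length(b) != 2) stop("each bound entry must have 1 or 2 values")
    b
  })
  bounds <- norm(bounds)
  uptake <- norm(uptake)
  for (id in names(uptake)) {
    u <- uptake[[id]]
    if (any(u < 0)) stop("uptake magnitudes must be non-negative (", id, ")")
    bounds[[id]] <- c(-max(u), -min(u))
  }
  bad <- names(bounds)[vapply(bounds, function(b) b[1] > b[2], TRUE)]
  if (length(bad)) {
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "))
  }
  structure(list(bounds = bounds, measured_mu = measured_mu,
                 substrate = substrate,
                 atp_maintenance_override = atp_maintenance_override),
            class = "constraint_set")
}

#' Read a constraint set from YAML
#'
#' Expected keys: `substrate`, `bounds: {reaction_id: [lower, upper]}`,
#' `uptake: {reaction_id: [min, max]}` (positive magnitudes),
#' `measured_mu`, `atp_maintenance_override`; all optional.
#'
#' @param path YAML file path.
#' @return a `constraint_set`.
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop("constraint file not found: ", path)
  y <- yaml::read_yaml(path)
  constraint_set(bounds = y$bounds %||% list(),
                 uptake = y$uptake %||% list(),
                 measured_mu = y$measured_mu,
                 substrate = y$substrate %||% NA_character_,
                 atp_maintenance_override = y$atp_maintenance_override)
}

#' Apply experimental constraints to a model
#'
#' Returns a modified copy (the input is untouched): each listed exchange
#' reaction's bounds are replaced; if `measured_mu` is set and a biomass
#' reaction id is supplied, growth is capped at the measured rate; an ATP
#' maintenance override replaces the maintenance reaction's lower bound.
#' Bounds that render the model infeasible are accepted here and surface as
#' `status = "infeasible"` at solve time.
#'
#' @param model a `gem`.
#' @param constraints a `constraint_set`.
#' @param biomass_id biomass reaction id; only needed when `measured_mu`
#'   is set.
#' @return a constrained copy of `model`.
#' @export
apply_constraints <- function(model, constraints, biomass_id = NULL) {
  stopifnot(inherits(constraints, "constraint_set"))
  for (id in names(constraints$bounds)) {
    j <- match(id, model$rxns$id)
    if (is.na(j)) stop("constraint on unknown reaction id: ", id)
    b <- constraints$bounds[[id]]
    model$rxns$lb[j] <- b[1]
    model$rxns$ub[j] <- b[2]
  }
  if (!is.null(constraints$measured_mu) && !is.null(biomass_id)) {
    j <- match_reaction(model, biomass_id)
    model$rxns$ub[j] <- constraints$measured_mu
  }
  if (!is.null(constraints$atp_maintenance_override)) {
    j <- find_maintenance_reaction(model)
    if (is.na(j)) stop("no ATP maintenance reaction found to override")
    model$rxns$lb[j] <- constraints$atp_maintenance_override
  }
  validate_gem(model)
  model
}

# index of the non-growth ATP maintenance reaction, NA if absent
find_maintenance_reaction <- function(model) {
  hit <- grepl("^ATPM$|maintenance", model$rxns$id, ignore.case = TRUE) |
    grepl("maintenance", model$rxns$name, ignore.case = TRUE)
  if (!any(hit)) NA_integer_ else which(hit)[1]
}

#' Pick the biomass reaction matching a substrate
#'
#' Models fitted with one biomass composition per carbon source carry
#' several biomass reactions; this selects the one whose id or name
#' mentions the requested substrate. With a single biomass reaction the
#' substrate is ignored.
#'
#' @param model a `gem`.
#' @param substrate substring to match (e.g. `"glycerol"`, `"methanol"`);
#'   `NA` allowed when the model has exactly one biomass reaction.
#' @return the selected biomass reaction id.
#' @export
select_biomass <- function(model, substrate = NA_character_) {
  cand <- which(grepl("biomass|growth", model$rxns$id, ignore.case = TRUE) |
                  grepl("biomass|growth", model$rxns$name, ignore.case = TRUE))
  if (!length(cand)) stop("no biomass reaction found in model ", model$id)
  if (length(cand) == 1) return(model$rxns$id[cand])
  if (is.na(substrate)) {
    stop("model has ", length(cand),
         " biomass reactions; a substrate is needed to choose: ",
         paste(model$rxns$id[cand], collapse = ", "))
  }
  sel <- cand[grepl(substrate, model$rxns$id[cand], ignore.case = TRUE) |
                grepl(substrate, model$rxns$name[cand], ignore.case = TRUE)]
  if (length(sel) != 1) {
    stop("substrate '", substrate, "' does not identify a unique biomass ",
         "reaction among: ", paste(model$rxns$id[cand], collapse = ", "))
  }
  model$rxns$id[sel]
}
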