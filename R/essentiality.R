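#' Maximal growth after deleting one reaction
#'
#' Sets the reaction's bounds to (0, 0) — the in-silico knockout — and
#' re-maximizes biomass. The input model is not modified. An infeasible
#' post-deletion model (e.g. a maintenance flux that can no longer be
#' sustained) returns growth 0 rather than an error.
#'
#' @param model a `gem`.
#' @param reaction_id reaction to delete.
#' @param biomass_id biomass reaction id.
#' @return maximal biomass flux after the deletion.
#' @export
delete_and_grow <- function(model, reaction_id, biomass_id) {
  j <- match_reaction(model, reaction_id)
  model$rxns$lb[j] <- 0
  model$rxns$ub[j] <- 0
  sol <- fba(model, biomass_id, "max", deterministic = FALSE)
  if (sol$status != "optimal") return(0)
  sol$objective_value
}

#' Single-reaction-deletion essentiality screen
#'
#' Deletes each candidate reaction in turn and compares the resulting
#' maximal growth with the wild type. A reaction is essential when growth
#' after its deletion falls below `essentiality_fraction` of wild-type
#' growth; the default fraction (0.001) separates numerically-zero growth
#' from LP round-off without crediting marginal growth as viability.
#'
#' @param model a `gem`.
#' @param candidate_ids reactions to screen; `NULL` screens every reaction.
#' @param biomass_id biomass reaction id.
#' @param essentiality_fraction fraction of wild-type growth below which a
#'   deletion counts as lethal.
#' @return data.frame `reaction_id`, `growth_after_deletion`,
#'   `wild_type_growth`, `essential`, in input order.
#' @export
screen_essentiality <- function(model, candidate_ids = NULL, biomass_id,
                                essentiality_fraction = 0.001) {
  wt <- fba(model, biomass_id, "max", deterministic = FALSE)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("essentiality screen requires positive wild-type growth (status ",
         wt$status, ")")
  }
  if (is.null(candidate_ids)) candidate_ids <- model$rxns$id
  growth <- vapply(candidate_ids, function(id)
    delete_and_grow(model, id, biomass_id), numeric(1))
  data.frame(
    reaction_id = candidate_ids,
    growth_after_deletion = unname(growth),
    wild_type_growth = rep(wt$objective_value, length(candidate_ids)),
    essential = unname(growth) < essentiality_fraction * wt$objective_value,
    stringsAsFactors = FALSE)
}

#' Drop essential reactions from a ranked candidate list
#'
#' Downregulation/deletion candidates must leave the cell viable; this
#' filters a ranked id list against an essentiality screen, preserving the
#' ranking order of the survivors.
#'
#' @param records output of [screen_essentiality()].
#' @param downregulation_list ranked reaction ids (see [rank_candidates()]).
#' @return the non-essential subset of `downregulation_list`, order kept.
#' @export
filter_nonessential <- function(records, downregulation_list) {
  idx <- match(downregulation_list, records$reaction_id)
  if (anyNA(idx)) {
    stop("no essentiality record for reaction(s): ",
         paste(downregulation_list[is.na(idx)], collapse = ", "))
  }
  downregulation_list[!records$essential[idx]]
}
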