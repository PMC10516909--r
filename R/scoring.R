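#' Step-weighted factor of a flux profile
#'
#' Scores how strongly a reaction's flux changes across the enforced-flux
#' steps relative to its mean flux. The default `"deviation"` variant sums
#' the absolute percent deviations of each step from the profile mean,
#'
#'   SWF = sum_k |v_k - mean(v)| / |mean(v)| * 100,
#'
#' which is zero exactly for constant profiles, grows with the coupling
#' strength and is invariant to rescaling the whole profile. The
#' `"literal"` variant sums the raw ratios `v_k / mean(v) * 100`; it is
#' retained for reference but is the algebraic identity `100 * n` for any
#' profile (the ratios to the arithmetic mean always sum to the number of
#' steps) and therefore cannot discriminate candidates.
#'
#' @param profile numeric flux values across the steps (typically 5).
#' @param variant `"deviation"` (default) or `"literal"`.
#' @param reaction_id optional id carried into the result.
#' @return an `swf_record` list: `reaction_id`, `swf_percent`, `variant`,
#'   `profile_mean`.
#' @examples
#' step_weighted_factor(c(1.8, 3.6, 5.4, 7.2, 9.0))        # 200
#' step_weighted_factor(rep(10, 5), variant = "literal")   # 500
#' @export
step_weighted_factor <- function(profile,
                                 variant = c("deviation", "literal"),
                                 reaction_id = NA_character_) {
  variant <- match.arg(variant)
  if (anyNA(profile) || any(!is.finite(profile))) {
    stop("profile contains missing or non-finite values")
  }
  m <- mean(profile)
  if (abs(m) < 1e-12) {
    stop("step-weighted factor undefined: profile mean is zero",
         if (!is.na(reaction_id)) paste0(" (", reaction_id, ")") else "")
  }
  swf <- switch(variant,
                deviation = sum(abs(profile - m)) / abs(m) * 100,
                literal = sum(profile / m) * 100)
  structure(list(reaction_id = reaction_id, swf_percent = swf,
                 variant = variant, profile_mean = m),
            class = "swf_record")
}

#' Score every retained scan profile
#'
#' Applies [step_weighted_factor()] to each reaction in a filtered scan
#' table. Reactions whose profile mean is zero have no defined score; they
#' are excluded and reported via a message rather than an error.
#'
#' @param table a filtered `scan_table`.
#' @param variant passed to [step_weighted_factor()].
#' @return data.frame `reaction_id`, `SWF_percent`, `SWF_variant`,
#'   `profile_mean`; one row per scorable reaction.
#' @export
score_scan <- function(table, variant = c("deviation", "literal")) {
  variant <- match.arg(variant)
  fm <- flux_matrix(table)
  ids <- table$profiles$Reactions_ID
  recs <- lapply(seq_along(ids), function(i) {
    tryCatch(step_weighted_factor(fm[i, ], variant, ids[i]),
             error = function(e) NULL)
  })
  dropped <- ids[vapply(recs, is.null, TRUE)]
  if (length(dropped)) {
    message("excluded from scoring (zero-mean profile): ",
            paste(dropped, collapse = ", "))
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  data.frame(
    reaction_id = vapply(recs, `[[`, "", "reaction_id"),
    SWF_percent = vapply(recs, `[[`, 0, "swf_percent"),
    SWF_variant = variant,
    profile_mean = vapply(recs, `[[`, 0, "profile_mean"),
    stringsAsFactors = FALSE)
}

#' Rank regulation candidates by step-weighted factor
#'
#' Upregulation candidates are the flux-increasing reactions, ranked by
#' descending score; downregulation/deletion candidates the flux-decreasing
#' ones (essentiality filtering is applied downstream, see
#' [filter_nonessential()]). Scores are compared after rounding away
#' LP-level noise (9 decimal places), and ties are broken lexicographically
#' by reaction id, so the ranking is deterministic.
#'
#' @param classifications output of [classify_reactions()].
#' @param swf_records output of [score_scan()].
#' @param direction `"upregulation"` or `"downregulation"`.
#' @return character vector of reaction ids, best candidate first.
#' @export
rank_candidates <- function(classifications, swf_records,
                            direction = c("upregulation", "downregulation")) {
  direction <- match.arg(direction)
  wanted <- switch(direction,
                   upregulation = "flux_increasing",
                   downregulation = "flux_decreasing")
  ids <- classifications$reaction_id[classifications$reaction_type == wanted]
  ids <- ids[ids %in% swf_records$reaction_id]
  if (!length(ids)) return(character(0))
  score <- round(swf_records$SWF_percent[match(ids, swf_records$reaction_id)], 9)
  ids[order(-score, ids)]
}
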