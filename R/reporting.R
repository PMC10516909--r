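#' Partition classified reactions into the four proportionality tables
#'
#' The affected reactions are split by carried flux direction and trend
#' against the enforced target flux:
#' * `positive_directly`: left-to-right flux, rises with the target
#' * `positive_contra`: left-to-right flux, falls with the target
#' * `negative_directly`: right-to-left flux, rises with the target
#' * `negative_contra`: right-to-left flux, falls with the target
#'
#' Unaffected reactions appear in no partition; the four lists are
#' disjoint and cover exactly the affected set.
#'
#' @param classifications output of [classify_reactions()].
#' @return named list of four character vectors of reaction ids.
#' @export
partition_proportionality <- function(classifications) {
  out <- lapply(c(positive_directly = "positive_directly",
                  positive_contra = "positive_contra",
                  negative_directly = "negative_directly",
                  negative_contra = "negative_contra"),
                function(p) {
                  classifications$reaction_id[
                    classifications$proportionality == p]
                })
  out
}

#' Subsystem composition of a candidate list
#'
#' Counts candidates per model subsystem and expresses each count as a
#' percentage of the scope total, mirroring the fractional-distribution
#' summaries used to interpret candidate lists pathway by pathway.
#' Records without a subsystem annotation are bucketed as `"unannotated"`.
#'
#' @param records data.frame with `reaction_id` and `subsystem` columns
#'   (e.g. classifications subset to one candidate list).
#' @return data.frame `subsystem`, `count`, `fraction_percent`, sorted by
#'   descending count; fractions sum to 100 within rounding.
#' @export
summarize_subsystems <- function(records) {
  if (!nrow(records)) {
    return(data.frame(subsystem = character(0), count = integer(0),
                      fraction_percent = numeric(0)))
  }
  ss <- records$subsystem
  ss[is.na(ss) | !nzchar(ss)] <- "unannotated"
  tab <- sort(table(ss), decreasing = TRUE)
  data.frame(subsystem = names(tab),
             count = as.integer(tab),
             fraction_percent = candidate_fraction(as.integer(tab),
                                                   nrow(records)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Candidate count as a percentage of a total
#'
#' The fraction routine used in all reported summaries, e.g. 33 candidate
#' reactions out of 2243 model reactions = 1.47%.
#'
#' @param count numerator (vectorised).
#' @param total denominator, > 0.
#' @return percentage value(s).
#' @examples
#' round(candidate_fraction(33, 2243), 2)  # 1.47
#' @export
candidate_fraction <- function(count, total) {
  stopifnot(total > 0)
  count / total * 100
}

#' Assemble a report bundle
#'
#' Gathers every output of a scan run — the full scan table, the four
#' proportionality partitions, the ranked candidate tables with scores and
#' essentiality, subsystem summaries, and run metadata — into one object
#' that [write_report()] serializes.
#'
#' @param table the filtered `scan_table`.
#' @param classifications output of [classify_reactions()].
#' @param swf output of [score_scan()].
#' @param essentiality output of [screen_essentiality()] (may be `NULL`
#'   when no downregulation candidates exist).
#' @param upregulation,downregulation ranked id vectors; `downregulation`
#'   should already be essentiality-filtered.
#' @param metadata named list recorded in the YAML sidecar (model id,
#'   schedule, tolerances, variant flags, ...).
#' @return a `report_bundle`.
#' @export
report_bundle <- function(table, classifications, swf, essentiality,
                          upregulation, downregulation, metadata = list()) {
  parts <- partition_proportionality(classifications)
  candidate_table <- function(ids) {
    df <- table$profiles[match(ids, table$profiles$Reactions_ID), ,
                         drop = FALSE]
    df$SWF_percent <- swf$SWF_percent[match(ids, swf$reaction_id)]
    df$SWF_variant <- swf$SWF_variant[match(ids, swf$reaction_id)]
    rownames(df) <- NULL
    df
  }
  structure(list(
    scan_table = table,
    partitions = parts,
    upregulation = candidate_table(upregulation),
    downregulation = candidate_table(downregulation),
    essentiality = essentiality,
    subsystem_summary = summarize_subsystems(
      classifications[classifications$reaction_type == "flux_decreasing", ,
                      drop = FALSE]),
    metadata = metadata), class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' Writes the seven canonical CSV tables — the scan table, the four
#' proportionality partitions, and the upregulation and downregulation
#' candidate tables — plus, when non-empty, the essentiality screen and
#' the subsystem summary, and a YAML metadata sidecar. CSV (UTF-8, `.`
#' decimal, header row) is the canonical format: numbers are serialized
#' with round-trip precision so a read-back reproduces the in-memory
#' values exactly, and re-running with identical inputs yields
#' byte-identical files (the timestamp lives only in the sidecar).
#' An XLSX mirror of the workbook layout is not supported on this
#' installation and `formats = "xlsx"` is rejected.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory (created if needed).
#' @param formats subset of `"csv"`.
#' @return named character vector of written file paths, invisibly.
#' @export
write_report <- function(bundle, out_dir, formats = "csv") {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!all(formats %in% "csv")) {
    stop("unsupported report format(s): ",
         paste(setdiff(formats, "csv"), collapse = ", "),
         " (CSV is the canonical output; no XLSX writer is available ",
         "on this installation)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- bundle$scan_table$profiles
  scan_cols <- c("Reactions_ID", "Reactions_name",
                 grep("^FBA_results_", names(profiles), value = TRUE),
                 "Subsystem", "Var10")
  paths <- c(scan_table = write_table_csv(
    profiles[, scan_cols], file.path(out_dir, "scan_table.csv")))
  for (p in names(bundle$partitions)) {
    ids <- bundle$partitions[[p]]
    df <- profiles[match(ids, profiles$Reactions_ID), scan_cols,
                   drop = FALSE]
    paths[[p]] <- write_table_csv(
      df, file.path(out_dir, paste0(partition_file_name(p), ".csv")))
  }
  for (side in c("upregulation", "downregulation")) {
    df <- bundle[[side]]
    keep <- c(scan_cols, "SWF_percent", "SWF_variant")
    paths[[side]] <- write_table_csv(
      df[, intersect(keep, names(df)), drop = FALSE],
      file.path(out_dir, paste0(side, ".csv")))
  }
  if (!is.null(bundle$essentiality) && nrow(bundle$essentiality)) {
    paths[["essentiality"]] <- write_table_csv(
      bundle$essentiality, file.path(out_dir, "essentiality.csv"))
  }
  if (nrow(bundle$subsystem_summary)) {
    paths[["subsystem_summary"]] <- write_table_csv(
      bundle$subsystem_summary, file.path(out_dir, "subsystem_summary.csv"))
  }
  meta <- bundle$metadata
  meta$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
  paths[["metadata"]] <- file.path(out_dir, "run_metadata.yaml")
  invisible(paths)
}

partition_file_name <- function(p) {
  switch(p,
         positive_directly = "Positive_directly_proportional",
         positive_contra = "Positive_contra_proportional",
         negative_directly = "Negative_directly_proportional",
         negative_contra = "Negative_contra_proportional",
         p)
}

#' Write a data.frame as round-trip-exact CSV
#'
#' Numeric columns are formatted with the shortest decimal representation
#' that parses back to the identical double, so
#' `read_table_csv(write_table_csv(df, p))` reproduces `df`'s values
#' bit for bit.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Read back a CSV written by [write_table_csv()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE,
                        colClasses = "character")
  for (col in names(df)) {
    v <- df[[col]]
    present <- v[v != "NA" & nzchar(v)]
    if (!length(present)) next
    if (all(present %in% c("TRUE", "FALSE"))) {
      df[[col]] <- as.logical(ifelse(v == "NA" | !nzchar(v), NA, v))
    } else if (all(grepl("^-?[0-9][0-9.eE+-]*$", present))) {
      suppressWarnings(num <- as.numeric(ifelse(v == "NA" | !nzchar(v),
                                                NA, v)))
      if (!any(is.na(num) & v != "NA" & nzchar(v))) df[[col]] <- num
    }
  }
  df
}
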