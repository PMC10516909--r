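toy1_bundle <- function() {
  a <- toy1_artifacts()
  up <- rank_candidates(a$classifications, a$swf, "upregulation")
  down <- rank_candidates(a$classifications, a$swf, "downregulation")
  ess <- screen_essentiality(a$model, down, "R2")
  report_bundle(a$filtered, a$classifications, a$swf, ess,
                up, filter_nonessential(ess, down),
                metadata = list(model_id = a$model$id))
}

test_that("proportionality partitions are disjoint and cover the affected set", {
  a <- toy1_artifacts()
  parts <- partition_proportionality(a$classifications)
  expect_named(parts, c("positive_directly", "positive_contra",
                        "negative_directly", "negative_contra"))
  expect_true("R3" %in% parts$positive_directly)
  expect_true("R2" %in% parts$positive_contra)
  expect_false("EX_A" %in% unlist(parts))

  all_ids <- unlist(parts, use.names = FALSE)
  expect_equal(anyDuplicated(all_ids), 0)
  affected <- a$classifications$reaction_id[
    a$classifications$reaction_type != "unaffected"]
  expect_setequal(all_ids, affected)
})

test_that("subsystem summaries report counts and percentages of scope", {
  rec <- data.frame(
    reaction_id = sprintf("R%03d", 1:66),
    subsystem = c(rep("Amino acid metabolism", 26),
                  rep("Nucleotide metabolism", 11),
                  rep("Other", 29)))
  s <- summarize_subsystems(rec)
  expect_equal(s$count[s$subsystem == "Amino acid metabolism"], 26)
  expect_equal(s$fraction_percent[s$subsystem == "Amino acid metabolism"],
               26 / 66 * 100, tolerance = 1e-12)
  expect_equal(round(s$fraction_percent[s$subsystem == "Amino acid metabolism"], 1),
               39.4)
  expect_equal(sum(s$fraction_percent), 100, tolerance = 1e-9)

  one <- summarize_subsystems(data.frame(reaction_id = "R1", subsystem = "X"))
  expect_equal(one$fraction_percent, 100)
  expect_equal(nrow(summarize_subsystems(data.frame(reaction_id = character(0),
                                                    subsystem = character(0)))),
               0)
  unann <- summarize_subsystems(data.frame(reaction_id = "R1", subsystem = ""))
  expect_equal(unann$subsystem, "unannotated")
})

test_that("the candidate fraction routine reproduces reported arithmetic", {
  expect_equal(round(candidate_fraction(33, 2243), 2), 1.47)
  expect_equal(candidate_fraction(0, 10), 0)
  expect_error(candidate_fraction(1, 0))
})

test_that("write_report emits the seven canonical tables with exact headers", {
  out <- withr::local_tempdir()
  paths <- write_report(toy1_bundle(), out)
  core <- c("scan_table.csv", "Positive_directly_proportional.csv",
            "Positive_contra_proportional.csv",
            "Negative_directly_proportional.csv",
            "Negative_contra_proportional.csv",
            "upregulation.csv", "downregulation.csv")
  expect_true(all(file.exists(file.path(out, core))))
  hdr <- strsplit(readLines(file.path(out, "scan_table.csv"), n = 1), ",")[[1]]
  expect_equal(gsub('"', "", hdr),
               c("Reactions_ID", "Reactions_name",
                 paste0("FBA_results_", 1:5), "Subsystem", "Var10"))
  expect_true(file.exists(file.path(out, "run_metadata.yaml")))
})

test_that("CSV round trips reproduce the in-memory values bit for bit", {
  out <- withr::local_tempdir()
  write_report(toy1_bundle(), out)
  a <- toy1_artifacts()
  back <- read_table_csv(file.path(out, "scan_table.csv"))
  for (k in 1:5) {
    col <- paste0("FBA_results_", k)
    expect_identical(back[[col]], a$filtered$profiles[[col]], label = col)
  }
  expect_identical(back$Reactions_ID, a$filtered$profiles$Reactions_ID)
})

test_that("re-running a report yields byte-identical CSVs", {
  b <- toy1_bundle()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  write_report(b, out1)
  write_report(b, out2)
  for (f in list.files(out1, pattern = "\\.csv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("unsupported report formats are rejected up front", {
  expect_error(write_report(toy1_bundle(), withr::local_tempdir(),
                            formats = c("csv", "xlsx")),
               "unsupported")
})
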