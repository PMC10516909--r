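test_that("the reference toy model matches its construction contract", {
  m <- build_toy1()
  expect_equal(nrow(m$rxns), 7)
  expect_equal(nrow(m$mets), 4)
  expect_equal(m$rxns$id[m$rxns$objective_coef != 0], "R2")
  expect_equal(fba(m, "R2")$objective_value, 10, tolerance = 1e-9)
  expect_equal(fba(m, "EX_P")$objective_value, 10, tolerance = 1e-9)
})

test_that("random toys are seed-deterministic, feasible and bounded in size", {
  m1 <- build_random_toy(seed = 1)
  m2 <- build_random_toy(seed = 1)
  expect_identical(as.matrix(m1$S), as.matrix(m2$S))
  expect_identical(m1$rxns, m2$rxns)

  for (seed in 1:10) {
    m <- random_toy_for_seed(seed)
    expect_lte(nrow(m$rxns), 15)
    expect_gt(fba(m, "BIOMASS")$objective_value, 0)
  }
  expect_error(build_random_toy(uptake_bound = 0), "positive")
})

test_that("random toy generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(build_random_toy(seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("scan classification equals the oracle on the reference toy", {
  a <- toy1_artifacts()
  orc <- oracle_scan(a$model, "R2", "EX_P", a$schedule)
  expect_identical(sorted_classes(a$classifications), sorted_classes(orc))
})

test_that("scan and oracle agree on seeded fixtures", {
  for (seed in c(1, 6, 17)) {
    m <- random_toy_for_seed(seed)
    init <- initialize_scan(m, "BIOMASS", "EX_P")
    sch <- build_step_schedule(init$target_max)
    cls <- classify_reactions(filter_valid_profiles(
      run_scan(m, "BIOMASS", "EX_P", sch)))
    orc <- oracle_scan(m, "BIOMASS", "EX_P", sch)
    expect_identical(sorted_classes(cls), sorted_classes(orc),
                     label = paste("seed", seed))
  }
})

test_that("the oracle stays defined for a two-step schedule", {
  m <- build_toy1()
  sch <- build_step_schedule(10, n_steps = 2)
  orc <- oracle_scan(m, "R2", "EX_P", sch)
  expect_true(all(c("R2", "R3", "EX_P") %in% orc$reaction_id))
  expect_equal(orc$reaction_type[orc$reaction_id == "EX_A"], "unaffected")
})

test_that("fixtures serialize and reload losslessly through model I/O", {
  m <- build_random_toy(seed = 8)
  for (fmt in c(".xml", ".json")) {
    path <- withr::local_tempfile(fileext = fmt)
    write_gem(m, path)
    m2 <- read_gem(path)
    expect_identical(as.matrix(m$S), as.matrix(m2$S))
    expect_identical(m$rxns$lb, m2$rxns$lb)
    expect_identical(m$rxns$ub, m2$rxns$ub)
  }
})
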