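test_that("scan initialization finds the four anchor values", {
  a <- toy1_artifacts()
  expect_equal(a$init$biomass_max, 10, tolerance = 1e-9)
  expect_equal(a$init$target_max, 10, tolerance = 1e-9)
  expect_equal(a$init$biomass_min, 0)
  expect_equal(a$init$atp_maintenance_floor, 0)

  # a maintenance reaction's lower bound becomes the floor
  m <- build_random_toy(include_maintenance = TRUE, seed = 4)
  init <- initialize_scan(m, "BIOMASS", "EX_P")
  expect_equal(init$atp_maintenance_floor, 0.1)
  expect_equal(init$biomass_max, oracle_fba(m, "BIOMASS"), tolerance = 1e-6)
  expect_equal(init$target_max, oracle_fba(m, "EX_P"), tolerance = 1e-6)

  expect_error(initialize_scan(build_toy1(), "R2", "nope"), "nope")
})

test_that("the step schedule divides the capped maximum into equal steps", {
  s <- build_step_schedule(10)
  expect_equal(s$enforced_values, c(1.8, 3.6, 5.4, 7.2, 9.0))
  expect_equal(build_step_schedule(10, n_steps = 2, cap_fraction = 1)$enforced_values,
               c(5, 10))
  expect_true(all(diff(s$enforced_values) > 0))
  expect_equal(s$enforced_values[5], 0.9 * 10)
  expect_error(build_step_schedule(0), "cannot carry flux")
  expect_error(build_step_schedule(-2), "cannot carry flux")
})

test_that("the scan records the forced trade-off between growth and target", {
  a <- toy1_artifacts()
  expect_equal(a$table$biomass_per_step, c(8.2, 6.4, 4.6, 2.8, 1.0),
               tolerance = 1e-7)
  fm <- as.matrix(a$table$profiles[, paste0("FBA_results_", 1:5)])
  rownames(fm) <- a$table$profiles$Reactions_ID
  expect_equal(unname(fm["R3", ]), c(1.8, 3.6, 5.4, 7.2, 9.0),
               tolerance = 1e-7)
  expect_equal(unname(fm["EX_A", ]), rep(-10, 5), tolerance = 1e-7)
  expect_equal(unname(fm["R2", ]), a$table$biomass_per_step)
})

test_that("biomass per step never increases with the enforced target flux", {
  for (seed in c(2, 7, 13)) {
    m <- random_toy_for_seed(seed)
    init <- initialize_scan(m, "BIOMASS", "EX_P")
    tab <- run_scan(m, "BIOMASS", "EX_P",
                    build_step_schedule(init$target_max))
    expect_true(all(diff(tab$biomass_per_step) <= 1e-6),
                label = paste("seed", seed))
  }
})

test_that("a zero enforced value reproduces the unconstrained optimum", {
  m <- build_toy1()
  base <- fba(m, "R2")
  sch <- build_step_schedule(10)
  sch$enforced_values <- c(0, sch$enforced_values[-1])
  tab <- run_scan(m, "R2", "EX_P", sch)
  fm <- as.matrix(tab$profiles[, paste0("FBA_results_", 1:5)])
  expect_equal(unname(fm[, 1]), unname(base$fluxes[tab$profiles$Reactions_ID]),
               tolerance = 1e-6)
})

test_that("an infeasible step is flagged rather than fatal", {
  m <- build_toy1()
  sch <- build_step_schedule(10)
  sch$enforced_values[5] <- 50   # beyond the target's feasible range
  tab <- run_scan(m, "R2", "EX_P", sch)
  expect_true(all(is.na(tab$profiles$FBA_results_5)))
  expect_false(any(tab$profiles$all_feasible))
  expect_equal(nrow(filter_valid_profiles(tab)$profiles), 0)
})

test_that("the validity filter keeps monotone complete profiles only", {
  a <- toy1_artifacts()
  tab <- a$table
  # inject a wobbling profile
  i <- match("R5", tab$profiles$Reactions_ID)
  tab$profiles[i, paste0("FBA_results_", 1:5)] <- c(1, 5, 2, 8, 3)
  kept <- filter_valid_profiles(tab)$profiles
  expect_false("R5" %in% kept$Reactions_ID)
  expect_true("R2" %in% kept$Reactions_ID)   # strictly decreasing
  expect_true(all(kept$steadily_changing))
})

test_that("classification splits reactions into three disjoint covering classes", {
  a <- toy1_artifacts()
  cls <- a$classifications
  get <- function(id) cls[cls$reaction_id == id, ]
  expect_equal(get("R3")$reaction_type, "flux_increasing")
  expect_equal(get("R3")$proportionality, "positive_directly")
  expect_equal(get("EX_P")$reaction_type, "flux_increasing")
  expect_equal(get("R2")$reaction_type, "flux_decreasing")
  expect_equal(get("R2")$proportionality, "positive_contra")
  expect_equal(get("EX_A")$reaction_type, "unaffected")
  expect_equal(get("EX_A")$proportionality, "none")

  # the three classes partition the retained set
  expect_setequal(cls$reaction_id, a$filtered$profiles$Reactions_ID)
  expect_true(all(cls$reaction_type %in%
                    c("flux_increasing", "flux_decreasing", "unaffected")))
  expect_true(all((cls$reaction_type == "unaffected") ==
                    (cls$proportionality == "none")))
})

test_that("every enforced value lies inside the target's feasible range", {
  a <- toy1_artifacts()
  rng <- flux_range(a$model, "EX_P")
  expect_true(all(a$schedule$enforced_values >= rng[1] - 1e-9))
  expect_true(all(a$schedule$enforced_values <= rng[2] + 1e-9))
})
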