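test_that("model construction enforces the structural invariants", {
  m <- build_toy1()
  expect_s3_class(m, "gem")
  expect_equal(dim(m$S), c(nrow(m$mets), nrow(m$rxns)))

  expect_error(
    gem_from_reactions("bad", list(
      list(id = "R1", mets = c(A = -1, ghost_met = 1), lb = 0, ub = 10))
      [c(1, 1)]),
    "duplicate reaction")
  expect_error(
    gem_from_reactions("bad", list(
      list(id = "R1", mets = c(A = -1, ghost_met = 1), lb = 0, ub = 10)),
      mets = data.frame(id = "A", name = "A", formula = "", charge = 0L,
                        compartment = "c")),
    "ghost_met")
  bad <- m
  bad$rxns$lb[2] <- 5
  bad$rxns$ub[2] <- 1
  expect_error(validate_gem(bad), "R1")
})

test_that("wet-to-dry cell weight conversion is the 0.3 factor", {
  expect_identical(dcw_from_wcw(10), 3)
  expect_identical(dcw_from_wcw(0), 0)
  expect_identical(dcw_from_wcw(7.5), 2.25)
  expect_error(dcw_from_wcw(-1), "non-negative")
})

test_that("uptake magnitudes become negative exchange bounds", {
  m <- build_toy1()
  cs <- constraint_set(uptake = list(EX_A = c(2.17, 2.29)))
  m2 <- apply_constraints(m, cs)
  j <- match("EX_A", m2$rxns$id)
  expect_equal(m2$rxns$lb[j], -2.29)
  expect_equal(m2$rxns$ub[j], -2.17)
  # original untouched
  expect_equal(m$rxns$lb[match("EX_A", m$rxns$id)], -10)

  # empty set is the identity
  m3 <- apply_constraints(m, constraint_set())
  expect_identical(m3$rxns, m$rxns)

  expect_error(
    apply_constraints(m, constraint_set(bounds = list(EX_xyz = c(0, 1)))),
    "EX_xyz")
})

test_that("measured growth rate caps the biomass reaction", {
  m <- build_toy1()
  cs <- constraint_set(measured_mu = 0.19)
  m2 <- apply_constraints(m, cs, biomass_id = "R2")
  expect_equal(m2$rxns$ub[match("R2", m2$rxns$id)], 0.19)
  sol <- fba(m2, "R2")
  expect_equal(sol$objective_value, 0.19, tolerance = 1e-9)
})

test_that("FBA solves TOY1 and respects mass balance and bounds", {
  m <- build_toy1()
  sol <- fba(m, "R2")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_true(check_solution(m, sol))
  expect_equal(unname(sol$fluxes["EX_A"]), -10, tolerance = 1e-9)

  tgt <- fba(m, "EX_P")
  expect_equal(tgt$objective_value, 10, tolerance = 1e-9)

  # infeasible bounds surface at solve time, not before
  m$rxns$lb[match("EX_P", m$rxns$id)] <- 50
  expect_equal(fba(m, "R2")$status, "infeasible")
})

test_that("deterministic FBA is idempotent and parsimonious", {
  m <- build_toy1()
  s1 <- fba(m, "R2", deterministic = TRUE)
  s2 <- fba(m, "R2", deterministic = TRUE)
  expect_true(all(abs(s1$fluxes - s2$fluxes) <= 1e-9))
  # the waste branch carries no flux in the minimal-total-flux optimum
  expect_equal(unname(s1$fluxes[c("R5", "EX_W")]), c(0, 0))
})

test_that("FBA matches the independent dense-LP oracle on random fixtures", {
  for (seed in 1:8) {
    m <- random_toy_for_seed(seed)
    for (obj in c("BIOMASS", "EX_P")) {
      sol <- fba(m, obj)
      expect_equal(sol$objective_value, oracle_fba(m, obj),
                   tolerance = 1e-6,
                   label = sprintf("seed %d objective %s", seed, obj))
      expect_true(check_solution(m, sol))
    }
  }
})

test_that("biomass selection honours the substrate field", {
  m <- gem_from_reactions("two_biomass", list(
    list(id = "EX_S", mets = c(S = -1), lb = -10, ub = 0),
    list(id = "BIOMASS_glycerol", name = "biomass glycerol",
         mets = c(S = -1), lb = 0, ub = 1000),
    list(id = "BIOMASS_methanol", name = "biomass methanol",
         mets = c(S = -1), lb = 0, ub = 1000)))
  expect_equal(select_biomass(m, "methanol"), "BIOMASS_methanol")
  expect_equal(select_biomass(m, "glycerol"), "BIOMASS_glycerol")
  expect_error(select_biomass(m), "substrate")
  expect_equal(select_biomass(build_toy1()), "R2")
})
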