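test_that("single deletions on TOY1 give the known growth outcomes", {
  m <- build_toy1()
  expect_equal(delete_and_grow(m, "R1", "R2"), 0)     # sole biomass route
  expect_equal(delete_and_grow(m, "EX_A", "R2"), 0)   # sole carbon source
  expect_equal(delete_and_grow(m, "R5", "R2"), 10, tolerance = 1e-9)
  # the input model is untouched
  expect_equal(m$rxns$ub[match("R1", m$rxns$id)], 1000)
})

test_that("the essentiality screen identifies exactly the lethal deletions", {
  m <- build_toy1()
  rec <- screen_essentiality(m, NULL, "R2", essentiality_fraction = 1e-3)
  expect_equal(rec$reaction_id, m$rxns$id)   # input order preserved
  expect_setequal(rec$reaction_id[rec$essential], c("R1", "R2", "EX_A"))
  expect_equal(unique(rec$wild_type_growth), 10, tolerance = 1e-9)

  expect_equal(nrow(screen_essentiality(m, character(0), "R2")), 0)
})

test_that("deleting a reaction never increases the growth optimum", {
  for (m in list(build_toy1(), random_toy_for_seed(5))) {
    bio <- if (m$id == "TOY1") "R2" else "BIOMASS"
    wt <- fba(m, bio)$objective_value
    rec <- screen_essentiality(m, NULL, bio)
    expect_true(all(rec$growth_after_deletion <= wt + 1e-6),
                label = m$id)
  }
})

test_that("deleting an always-zero-flux reaction leaves growth unchanged", {
  m <- build_toy1()
  wt <- fba(m, "R2")$objective_value
  # pin biomass at the optimum; the waste branch range must collapse to 0
  rng <- flux_range(m, "R5", fixed = c(R2 = wt))
  expect_equal(rng, c(0, 0), tolerance = 1e-9)
  expect_equal(delete_and_grow(m, "R5", "R2"), wt, tolerance = 1e-6)
})

test_that("the non-essential filter preserves rank order and flags gaps", {
  m <- build_toy1()
  rec <- screen_essentiality(m, c("R2", "R5", "R3"), "R2")
  expect_equal(filter_nonessential(rec, c("R2")), character(0))
  expect_equal(filter_nonessential(rec, c("R3", "R5")), c("R3", "R5"))
  expect_error(filter_nonessential(rec, c("R3", "EX_W")), "EX_W")
})

test_that("screening requires viable wild-type growth", {
  m <- build_toy1()
  m$rxns$ub[match("R2", m$rxns$id)] <- 0
  expect_error(screen_essentiality(m, NULL, "R2"), "wild-type")
})
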