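test_that("step-weighted factor matches hand-computed values", {
  expect_equal(step_weighted_factor(rep(10, 5), "literal")$swf_percent, 500)
  expect_equal(step_weighted_factor(rep(10, 5), "deviation")$swf_percent, 0)
  expect_equal(step_weighted_factor(c(1.8, 3.6, 5.4, 7.2, 9.0))$swf_percent,
               200)
  # mean 4.6, summed absolute deviations 10.8 -> 10.8 / 4.6 * 100
  expect_equal(step_weighted_factor(c(8.2, 6.4, 4.6, 2.8, 1.0))$swf_percent,
               234.7826086956522, tolerance = 1e-12)
  expect_error(step_weighted_factor(c(-1, 1, -1, 1, 0)), "mean is zero")
  expect_error(step_weighted_factor(c(1, NA, 3, 4, 5)), "missing")
})

test_that("the literal variant is the 100 * n identity, whatever the profile", {
  set.seed(42)
  for (i in 1:25) {
    v <- rnorm(5, mean = 5, sd = 2)
    if (abs(mean(v)) < 1e-6) next
    expect_equal(step_weighted_factor(v, "literal")$swf_percent, 500,
                 tolerance = 1e-9)
  }
})

test_that("the deviation variant is scale-invariant and zero iff constant", {
  set.seed(7)
  for (i in 1:100) {
    v <- rnorm(5, mean = 10, sd = 3)
    c_ <- runif(1, 0.1, 50) * sample(c(-1, 1), 1)
    s0 <- step_weighted_factor(v)$swf_percent
    s1 <- step_weighted_factor(c_ * v)$swf_percent
    expect_equal(s1, s0, tolerance = 1e-9)
    expect_gt(s0, 0)
  }
  expect_equal(step_weighted_factor(rep(3.7, 5))$swf_percent, 0)
})

test_that("candidate ranking is a deterministic permutation with tie-breaks", {
  a <- toy1_artifacts()
  up <- rank_candidates(a$classifications, a$swf, "upregulation")
  expect_equal(up, c("EX_P", "R3"))   # equal scores, lexicographic order
  down <- rank_candidates(a$classifications, a$swf, "downregulation")
  expect_equal(down, "R2")

  incr <- a$classifications$reaction_id[
    a$classifications$reaction_type == "flux_increasing"]
  expect_setequal(up, intersect(incr, a$swf$reaction_id))

  empty <- a$classifications[0, ]
  expect_equal(rank_candidates(empty, a$swf, "upregulation"), character(0))
})

test_that("zero-mean profiles are excluded from scoring, not fatal", {
  a <- toy1_artifacts()
  expect_message(swf <- score_scan(a$filtered), "R5")
  expect_false("R5" %in% swf$reaction_id)
  expect_true(all(c("R2", "R3", "EX_P") %in% swf$reaction_id))
})
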