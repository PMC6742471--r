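test_that("discount factors follow (1 + r)^-k with year one undiscounted", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 0:7), rep(1, 8))
  expect_equal(discount_factor(0.03, 2), 1 / 1.03^2)
  expect_error(discount_factor(0.03, -1), ">= 0")
  expect_error(discount_factor(-0.01, 1), ">= 0")
})

test_that("decision tree certifies the product of the three pass rates", {
  ps <- make_test_ps(p_minor = 0.8, p_major = 0.75, p_exam = 0.9)
  split <- decision_tree_split(ps$transitions)
  expect_equal(sum(split), 1)
  expect_equal(unname(split["certified_dog"]), 0.8 * 0.75 * 0.9) # 0.54
  expect_equal(unname(split["dog_not_certified"]), 0.46)
  one <- make_test_ps(p_minor = 1, p_major = 1, p_exam = 1)
  expect_equal(unname(decision_tree_split(one$transitions)["certified_dog"]), 1)
  zero <- make_test_ps(p_minor = 0, p_major = 0.5, p_exam = 0.7)
  expect_equal(unname(decision_tree_split(zero$transitions)["certified_dog"]), 0)
})

test_that("transition rows apply sequential risks and sum to one", {
  ps <- make_test_ps(owner_q = 0.01, dog_q = 0.05, p_decert = 0.02)
  t <- ps$transitions
  row <- build_transition_row("certified_dog", 45, 3, t, retirement_age = 10)
  expect_equal(unname(row["owner_dead"]), 0.01)
  expect_equal(unname(row["dog_dead"]), 0.99 * 0.05)
  expect_equal(unname(row["dog_not_certified"]), 0.99 * 0.95 * 0.02)
  expect_equal(unname(row["certified_dog"]), 0.99 * 0.95 * 0.98)
  expect_equal(sum(row), 1)
  # forced retirement at the retirement age
  ret <- build_transition_row("certified_dog", 45, 10, t, retirement_age = 10)
  expect_equal(unname(ret["dog_retired"]), 0.99 * 0.95)
  expect_equal(unname(ret["certified_dog"]), 0)
  # absorbing states map to themselves
  expect_equal(unname(build_transition_row("owner_dead", 45, 3, t, 10)["owner_dead"]), 1)
  expect_equal(unname(build_transition_row("dog_dead", 45, 3, t, 10)["dog_dead"]), 1)
  # uncovered age names the age
  expect_error(build_transition_row("certified_dog", 200, 3, t, 10), "200")
  # property: sums to one for 1,000 randomised inputs
  set.seed(41)
  for (i in 1:1000) {
    qo <- runif(1); qd <- runif(1); pd <- runif(1)
    tt <- transition_inputs(0.9, 0.9, 0.9, pd,
                            data.frame(age = 45, q_annual = qo),
                            data.frame(dog_age = 3, q_annual = qd))
    st <- sample(c("certified_dog", "dog_retired", "dog_not_certified"), 1)
    r <- build_transition_row(st, 45, 3, tt, sample(c(3, 10), 1))
    expect_equal(sum(r), 1, tolerance = 1e-12)
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("traces conserve mass and keep owner death monotone", {
  set.seed(42)
  for (i in 1:60) {
    ps <- random_ps()
    for (arm in c("certified_track", "companion_track")) {
      tr <- run_trace(ps, arm)
      expect_equal(rowSums(tr$occupancy), rep(1, ps$settings$horizon_years),
                   tolerance = 1e-12)
      expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1))
      expect_true(all(diff(tr$occupancy[, "owner_dead"]) >= -1e-15))
    }
  }
})

test_that("a no-exit cohort stays certified and accrues the plain annuity", {
  ps <- make_test_ps(owner_q = 0, dog_q = 0, p_minor = 1, p_major = 1,
                     p_exam = 1, p_decert = 0, retirement = 20L, discount = 0)
  tr <- run_trace(ps, "certified_track")
  expect_equal(unname(tr$occupancy[-1, "certified_dog"]), rep(1, 9))
  # companion arm, zero mortality, no discounting: horizon x weight
  comp <- run_trace(ps, "companion_track")
  expect_equal(comp$total_qaly, 10 * 0.3)
  ps_fix <- fixture_ps("physical_service",
                       overrides = list(discount_rate = 0))
  ps_fix$transitions$owner_mortality$q_annual <- 0
  ps_fix$transitions$dog_mortality$q_annual <- 0
  expect_equal(run_trace(ps_fix, "companion_track")$total_qaly, 10 * 0.226)
})

test_that("engine matches the path-enumeration oracle", {
  set.seed(7)
  for (i in 1:25) {
    ps <- random_ps()
    ps$settings$horizon_years <- 3L
    for (arm in c("certified_track", "companion_track")) {
      tr <- run_trace(ps, arm)
      oc <- oracle_totals(ps, arm)
      expect_equal(tr$total_cost, oc$cost, tolerance = 1e-9)
      expect_equal(tr$total_qaly, oc$qaly, tolerance = 1e-9)
    }
  }
  # including the packaged base case at a short horizon
  ps <- fixture_ps("physical_service", overrides = list(horizon_years = 4))
  for (arm in c("certified_track", "companion_track")) {
    tr <- run_trace(ps, arm)
    oc <- oracle_totals(ps, arm)
    expect_equal(tr$total_cost, oc$cost, tolerance = 1e-9)
    expect_equal(tr$total_qaly, oc$qaly, tolerance = 1e-9)
  }
})

test_that("owner death accrues nothing", {
  ps <- make_test_ps(owner_q = 1, dog_q = 0)
  tr <- run_trace(ps, "companion_track")
  expect_equal(unname(tr$occupancy[-1, "owner_dead"]), rep(1, 9))
  # only cycle 0 accrues anything
  expect_equal(sum(tr$cycle_costs[-1, ]), 0)
  expect_equal(sum(tr$cycle_qalys[-1]), 0)
})

test_that("raising the discount rate never raises totals", {
  set.seed(11)
  for (i in 1:10) {
    ps <- random_ps()
    lo <- ps; lo$settings$discount_rate <- 0
    hi <- ps; hi$settings$discount_rate <- 0.08
    for (arm in c("certified_track", "companion_track")) {
      expect_gte(run_trace(lo, arm)$total_cost, run_trace(hi, arm)$total_cost)
      expect_gte(run_trace(lo, arm)$total_qaly, run_trace(hi, arm)$total_qaly)
    }
  }
})

test_that("with zero pass rates the arms differ only in year-1 dog costs", {
  ps <- make_test_ps(p_minor = 0, p_major = 0, p_exam = 0)
  cert <- run_trace(ps, "certified_track")
  comp <- run_trace(ps, "companion_track")
  expect_equal(cert$occupancy, comp$occupancy)
  expect_equal(cert$cycle_qalys, comp$cycle_qalys)
  diff <- cert$cycle_costs - comp$cycle_costs
  expect_equal(unname(diff[1, "dog"]),
               ps$dog_costs$totals["year1", "certified"] -
                 ps$dog_costs$totals["year1", "companion"])
  diff[1, "dog"] <- 0
  expect_equal(max(abs(diff)), 0)
})

test_that("arm comparison classifies quadrants and forms the ICER", {
  dom <- compare_totals(994041, 1e6, 2.79, 2.51)
  expect_equal(dom$delta_cost, -5959)
  expect_equal(dom$dominance, "dominant")
  expect_equal(dom$icer_label, "Dominant")
  expect_true(is.na(dom$icer))
  ne <- compare_totals(101000, 100000, 2.05, 2.00)
  expect_equal(ne$icer, 20000)
  expect_equal(ne$dominance, "tradeoff_ne")
  sw <- compare_totals(99000, 100000, 1.95, 2.00)
  expect_equal(sw$dominance, "tradeoff_sw")
  expect_equal(sw$icer, 20000)
  expect_equal(compare_totals(2, 1, 1.9, 2)$dominance, "dominated")
  none <- compare_totals(1, 1, 2, 2)
  expect_equal(none$dominance, "no_difference")
  expect_true(is.na(none$icer))
  halfdom <- compare_totals(0, 1, 2, 2)   # cheaper, equal QALYs
  expect_equal(halfdom$dominance, "dominant")
  expect_true(is.na(halfdom$icer))
  # end-to-end: fit object wires traces into the comparison
  fit <- dog_cea(make_test_ps())
  expect_s3_class(fit, "dog_cea")
  expect_equal(fit$result$delta_cost,
               fit$traces$certified_track$total_cost -
                 fit$traces$companion_track$total_cost)
})
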