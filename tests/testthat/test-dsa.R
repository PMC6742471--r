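test_that("the built-in scenario set is complete and well formed", {
  sc <- builtin_scenarios()
  expect_length(sc, 11)
  expect_equal(vapply(sc, `[[`, integer(1), "scenario_id"), 1:11)
  expect_equal(sc[[1]]$transform$settings$discount_rate, 0)
  expect_equal(sc[[2]]$transform$settings$discount_rate, 0.05)
  expect_equal(sc[[3]]$transform$dog_lifetable_cum11, 0.30)
  expect_equal(sc[[4]]$transform$dog_lifetable_cum11, 0.10)
  expect_equal(sc[[5]]$transform$settings$dog_retirement_age, 8)
  expect_equal(sc[[6]]$transform$settings$dog_retirement_age, 12)
  expect_equal(sc[[9]]$transform$purchase_trained_usd, 17569)
  expect_equal(sc[[10]]$transform$perspective, "healthcare")
  expect_equal(sc[[11]]$transform$perspective, "societal_no_productivity")
})

test_that("scenario application is side-effect-free and composable", {
  ps <- fixture_ps("physical_service")
  before <- ps
  out <- apply_scenario(ps, list())                     # identity
  expect_equal(out, ps)
  expect_equal(ps, before)                              # base untouched
  twice <- apply_scenario(apply_scenario(ps, list()), list())
  expect_equal(twice, ps)
  ret8 <- apply_scenario(ps, builtin_scenarios()[[5]])
  expect_equal(ret8$settings$dog_retirement_age, 8L)
  ret8$settings$dog_retirement_age <- ps$settings$dog_retirement_age
  expect_equal(ret8, ps)                                # nothing else moved
  nop <- apply_scenario(ps, builtin_scenarios()[[11]])
  for (st in names(nop$profiles))
    expect_equal(nop$profiles[[st]]$annual_cost$productivity_loss$point_value, 0)
  expect_error(apply_scenario(ps, list(nonsense = 1)), "nonsense")
  expect_error(apply_scenario(ps, list(settings = list(bogus_field = 1))),
               "bogus_field")
})

test_that("the trained-dog scenario rewires costs and certification", {
  ps <- fixture_ps("physical_service")
  out <- apply_scenario(ps, builtin_scenarios()[[9]])
  comp <- out$dog_costs$components
  expect_equal(comp$certified[comp$component == "purchase"], 17569)
  expect_equal(sum(comp$certified[comp$component %in%
                                    c("suitability_tests", "training", "capes")]), 0)
  expect_equal(out$transitions$p_pass_exam, 1)
  expect_equal(out$settings$benefit_start_cycle, 0L)
  tr <- run_trace(out, "certified_track")
  expect_equal(unname(tr$occupancy[1, "certified_dog"]), 1)
})

test_that("all eleven scenarios run and ordering properties hold", {
  ps <- fixture_ps("diabetes_alert")
  res <- suppressWarnings(run_dsa(ps))
  expect_equal(nrow(res), 11)
  expect_equal(res$scenario_id, 1:11)
  expect_true(all(is.finite(res$incremental_cost)))
  # undiscounted per-arm totals weakly dominate 5%-discounted totals
  ps0 <- apply_scenario(ps, builtin_scenarios()[[1]])
  ps5 <- apply_scenario(ps, builtin_scenarios()[[2]])
  for (arm in c("certified_track", "companion_track")) {
    expect_gte(run_trace(ps0, arm)$total_qaly, run_trace(ps5, arm)$total_qaly)
    expect_gte(run_trace(ps0, arm)$total_cost, run_trace(ps5, arm)$total_cost)
  }
  # longer-lived dogs yield at least as many certified-arm QALYs
  short <- apply_scenario(ps, builtin_scenarios()[[3]])
  long <- apply_scenario(ps, builtin_scenarios()[[4]])
  expect_lte(run_trace(short, "certified_track")$total_qaly,
             run_trace(long, "certified_track")$total_qaly)
  # the all-costs scenario with a zero add-on table equals the base case
  base <- dog_cea(ps)$result
  all_costs <- dog_cea(apply_scenario(ps, builtin_scenarios()[[8]]))$result
  expect_equal(all_costs$delta_cost, base$delta_cost)
  expect_equal(all_costs$delta_qaly, base$delta_qaly)
})

test_that("retired-state drift moves costs up and utilities down", {
  ps <- make_test_ps(retirement = 5L, p_decert = 0, owner_q = 0, dog_q = 0,
                     retired = simple_profile(7000, 4250, 1750, 5750, 0.375))
  drifted <- apply_scenario(ps, builtin_scenarios()[[7]])
  base_cert <- run_trace(ps, "certified_track")
  drift_cert <- run_trace(drifted, "certified_track")
  expect_gt(drift_cert$total_cost, base_cert$total_cost)
  expect_lt(drift_cert$total_qaly, base_cert$total_qaly)
  # companion arm never retires, so it is untouched
  expect_equal(run_trace(drifted, "companion_track")$total_cost,
               run_trace(ps, "companion_track")$total_cost)
})
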