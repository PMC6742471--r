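test_that("distribution specs validate their parameter space", {
  expect_error(dist_spec("gamma", -1, 2, 10), "alfa > 0")
  expect_error(dist_spec("beta", 2, 0, 0.5), "alfa > 0")
  expect_error(dist_spec("gamma", 2, 2, -5), ">= 0")
  expect_error(dist_spec("beta", 2, 2, 1.4), "point_value")
  expect_silent(dist_spec("beta", 2, 2, -0.5))   # tariff allows negative utility
  expect_error(dist_spec("beta", 2, 2, -0.7), "point_value")
  expect_equal(dist_spec("point", point_value = 3)$point_value, 3)
})

test_that("packaged fixtures carry the published per-category values", {
  published <- list(
    physical_service = list(
      companion = c(healthcare = 8928, municipal = 44588, informal_care = 4768,
                    productivity_loss = 66901, qaly = 0.226),
      certified = c(healthcare = 7530, municipal = 47630, informal_care = 3503,
                    productivity_loss = 63859, qaly = 0.351),
      retired_or_decert = c(healthcare = 8229, municipal = 46109,
                            informal_care = 4135, productivity_loss = 65380,
                            qaly = 0.309)),
    diabetes_alert = list(
      companion = c(healthcare = 9475, municipal = 3528, informal_care = 2414,
                    productivity_loss = 28900, qaly = 0.656),
      certified = c(healthcare = 10001, municipal = 3095, informal_care = 1168,
                    productivity_loss = 27829, qaly = 0.674),
      retired_or_decert = c(healthcare = 9738, municipal = 3312,
                            informal_care = 1791, productivity_loss = 28364,
                            qaly = 0.665)))
  for (dt in names(published)) {
    ps <- fixture_ps(dt)
    for (st in names(published[[dt]])) {
      want <- published[[dt]][[st]]
      p <- ps$profiles[[st]]
      for (ct in setdiff(names(want), "qaly"))
        expect_equal(p$annual_cost[[ct]]$point_value, unname(want[ct]),
                     info = paste(dt, st, ct))
      expect_equal(p$qaly_weight$point_value, unname(want["qaly"]),
                   info = paste(dt, st, "qaly"))
    }
    # dog-dead state reverts to baseline; band totals match print within 1 USD
    expect_identical(ps$profiles$dog_dead, ps$profiles$companion)
    comp_sums <- with(ps$dog_costs$components,
                      tapply(certified, band, sum)[rownames(ps$dog_costs$totals)])
    expect_true(all(abs(comp_sums - ps$dog_costs$totals[, "certified"]) <= 1))
  }
  # spot-check the published gamma/beta pairs made it into the specs
  ps <- fixture_ps("physical_service")
  expect_equal(ps$profiles$companion$annual_cost$healthcare$alfa, 27)
  expect_equal(ps$profiles$companion$annual_cost$healthcare$beta, 704)
  expect_equal(ps$profiles$certified$qaly_weight$alfa, 29)
  expect_equal(ps$profiles$certified$qaly_weight$beta, 53)
  # physical retired weight has no published pair: point spec, not 0.2885
  expect_equal(ps$profiles$retired_or_decert$qaly_weight$family, "point")
})

test_that("loading rejects invalid probabilities and malformed files", {
  dir <- withr::local_tempdir()
  file.copy(list.files(default_bundle(), full.names = TRUE), dir)
  writeLines(c("p_pass_minor: 1.2", "p_pass_major: 0.9",
               "p_pass_exam: 0.9", "p_annual_decert: 0.02"),
             file.path(dir, "transitions.cfg"))
  expect_error(load_parameter_set(dir, "physical_service"),
               "p_pass_minor")
  writeLines("not,a,valid\nheader", file.path(dir, "costs_physical_service.csv"))
  expect_error(load_parameter_set(dir, "physical_service"),
               "costs_physical_service")
})

test_that("write_parameter_set round-trips through the bundle dialect", {
  for (dt in c("physical_service", "diabetes_alert")) {
    ps <- fixture_ps(dt)
    dir <- withr::local_tempdir()
    write_parameter_set(ps, dir)
    ps2 <- load_parameter_set(dir, dt)
    expect_equal(ps2, ps, tolerance = 1e-12)
  }
})

test_that("retired-state derivation is the truncated category midpoint", {
  comp <- simple_profile(100, 200, 301, 400, 0.2)
  cert <- simple_profile(200, 250, 302, 500, 0.4)
  mid <- derive_retired_profile(comp, cert)
  expect_equal(mid$annual_cost$healthcare$point_value, 150)
  expect_equal(mid$annual_cost$informal_care$point_value, 301) # 301.5 truncated
  expect_equal(mid$qaly_weight$point_value, 0.3)               # utilities not truncated
  # idempotent midpoint and category-wise bounds
  expect_equal(derive_retired_profile(comp, comp)$annual_cost$municipal$point_value, 200)
  for (ct in c("healthcare", "municipal", "informal_care", "productivity_loss")) {
    v <- mid$annual_cost[[ct]]$point_value
    lo <- min(comp$annual_cost[[ct]]$point_value, cert$annual_cost[[ct]]$point_value)
    hi <- max(comp$annual_cost[[ct]]$point_value, cert$annual_cost[[ct]]$point_value)
    expect_true(v >= lo - 1 && v <= hi)
  }
})

test_that("perspective filters only ever remove costs", {
  ps <- fixture_ps("physical_service")
  expect_equal(apply_perspective(ps, "societal")$profiles, ps$profiles)
  nop <- apply_perspective(ps, "societal_no_productivity")
  expect_equal(nop$profiles$companion$annual_cost$productivity_loss$point_value, 0)
  expect_equal(nop$profiles$companion$annual_cost$healthcare$point_value, 8928)
  hc <- apply_perspective(fixture_ps("diabetes_alert"), "healthcare")
  for (st in names(hc$profiles)) {
    for (ct in c("municipal", "informal_care", "productivity_loss"))
      expect_equal(hc$profiles[[st]]$annual_cost[[ct]]$point_value, 0)
  }
  # never increases any category, any perspective
  for (persp in c("societal", "healthcare", "societal_no_productivity")) {
    out <- apply_perspective(ps, persp)
    for (st in names(out$profiles))
      for (ct in names(out$profiles[[st]]$annual_cost))
        expect_lte(out$profiles[[st]]$annual_cost[[ct]]$point_value,
                   ps$profiles[[st]]$annual_cost[[ct]]$point_value)
    expect_true(all(out$dog_costs$totals <= ps$dog_costs$totals))
  }
})

test_that("currency conversion divides by the exchange rate", {
  expect_equal(convert_currency(8538, 8.538), 1000)
  expect_equal(convert_currency(853.8, 8.538), 100)
  expect_equal(convert_currency(0), 0)
  expect_error(convert_currency(100, 0), "positive")
  # a SEK-denominated bundle loads to the same USD parameter set
  ps <- fixture_ps("physical_service")
  dir <- withr::local_tempdir()
  write_parameter_set(ps, dir)
  tab <- read.csv(file.path(dir, "costs_physical_service.csv"))
  num <- tab$category != "qaly_weight"
  for (cn in c("companion", "certified", "retired")) {
    tab[[cn]][num] <- tab[[cn]][num] * 8.538
    tab[[paste0("beta_", cn)]][num] <- tab[[paste0("beta_", cn)]][num] * 8.538
  }
  write.csv(tab, file.path(dir, "costs_physical_service.csv"), row.names = FALSE)
  dc <- read.csv(file.path(dir, "dog_costs.csv"))
  dc$companion <- dc$companion * 8.538
  dc$certified <- dc$certified * 8.538
  write.csv(dc, file.path(dir, "dog_costs.csv"), row.names = FALSE)
  cfg <- readLines(file.path(dir, "settings.cfg"))
  writeLines(sub("^currency: USD", "currency: SEK", cfg),
             file.path(dir, "settings.cfg"))
  ps_sek <- load_parameter_set(dir, "physical_service")
  expect_equal(ps_sek$profiles$companion$annual_cost$healthcare$point_value,
               8928, tolerance = 1e-9)
  expect_equal(ps_sek$dog_costs$totals, ps$dog_costs$totals, tolerance = 1e-9)
})

test_that("schedule validation flags component/total disagreement", {
  comp <- simple_schedule()$components
  bad_tot <- matrix(c(9999, 9999, 9999, 9999, 9999, 9999), 3, 2)
  expect_error(dog_cost_schedule(comp, bad_tot), "1 USD")
})
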