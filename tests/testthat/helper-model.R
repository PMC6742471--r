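# Shared fixtures: hand-built parameter sets, a randomised-parameter
# generator for property tests, and an independent path-enumeration
# oracle for the cohort engine.

simple_profile <- function(health, municipal, informal, productivity, qaly,
                           gamma_pars = NULL) {
  mk <- function(v) {
    if (is.null(gamma_pars)) dist_spec("point", point_value = v)
    else dist_spec("gamma", gamma_pars[1], gamma_pars[2], v)
  }
  state_profile(list(healthcare = mk(health), municipal = mk(municipal),
                     informal_care = mk(informal), productivity_loss = mk(productivity)),
                dist_spec("point", point_value = qaly))
}

simple_schedule <- function(purchase = 1000, upkeep = 500, tests = 200,
                            training = 5000, capes = 100, maint = 80, health = 50) {
  dog_cost_schedule(data.frame(
    component = c("purchase", "annual_upkeep", "suitability_tests",
                  "annual_upkeep", "training", "capes",
                  "annual_upkeep", "maintenance_test", "health_declaration"),
    band = c("year1", "year1", "year1", "year2", "year2", "year2",
             "subsequent", "subsequent", "subsequent"),
    companion = c(purchase, upkeep, 0, upkeep, 0, 0, upkeep, 0, 0),
    certified = c(purchase, upkeep, tests, upkeep, training, capes,
                  upkeep, maint, health)))
}

# small hand-built parameter set with flat mortality
make_test_ps <- function(horizon = 10L, discount = 0.03, owner_q = 0.01,
                         dog_q = 0.05, p_minor = 0.9, p_major = 0.9,
                         p_exam = 0.9, p_decert = 0.02, retirement = 10L,
                         owner_start = 44L, dog_start = 2L,
                         benefit_start_cycle = 1L,
                         retired_cost_growth = 1, retired_qaly_decay = 1,
                         companion = simple_profile(8000, 4000, 2000, 6000, 0.3),
                         certified = simple_profile(6000, 4500, 1500, 5500, 0.45),
                         retired = NULL,
                         dog_costs = simple_schedule()) {
  owner_lt <- data.frame(age = seq(owner_start, owner_start + horizon + 2L),
                         q_annual = owner_q)
  dog_lt <- data.frame(dog_age = seq(dog_start, dog_start + horizon + 2L),
                       q_annual = dog_q)
  parameter_set("physical_service",
                list(companion = companion, certified = certified,
                     retired_or_decert = retired),
                dog_costs,
                transition_inputs(p_minor, p_major, p_exam, p_decert,
                                  owner_lt, dog_lt),
                economic_settings(discount_rate = discount,
                                  horizon_years = horizon,
                                  owner_start_age = owner_start,
                                  dog_start_age = dog_start,
                                  dog_retirement_age = retirement,
                                  benefit_start_cycle = benefit_start_cycle,
                                  retired_cost_growth = retired_cost_growth,
                                  retired_qaly_decay = retired_qaly_decay))
}

# randomised valid parameter set for property tests
random_ps <- function() {
  horizon <- sample(3:10, 1)
  dog_start <- 2L
  make_test_ps(horizon = horizon,
               discount = stats::runif(1, 0, 0.08),
               owner_q = stats::runif(1, 0, 0.3),
               dog_q = stats::runif(1, 0, 0.4),
               p_minor = stats::runif(1), p_major = stats::runif(1),
               p_exam = stats::runif(1), p_decert = stats::runif(1, 0, 0.5),
               retirement = sample((dog_start + 1):(dog_start + horizon + 1), 1),
               benefit_start_cycle = sample(0:2, 1),
               retired_cost_growth = stats::runif(1, 0.8, 1.2),
               retired_qaly_decay = stats::runif(1, 0.8, 1.2),
               companion = simple_profile(stats::runif(1, 0, 1e4),
                                          stats::runif(1, 0, 1e4),
                                          stats::runif(1, 0, 1e4),
                                          stats::runif(1, 0, 1e4),
                                          stats::runif(1, 0.05, 0.95)),
               certified = simple_profile(stats::runif(1, 0, 1e4),
                                          stats::runif(1, 0, 1e4),
                                          stats::runif(1, 0, 1e4),
                                          stats::runif(1, 0, 1e4),
                                          stats::runif(1, 0.05, 0.95)))
}

# ---------------------------------------------------------------------
# Independent oracle: expected discounted cost/QALY by explicit
# enumeration of every state path through the model. Deliberately
# written as a branch-by-branch recursion, sharing no code with the
# engine's matrix implementation.
oracle_totals <- function(ps, arm) {
  s <- ps$settings
  t <- ps$transitions
  H <- s$horizon_years
  retire_cycle <- s$dog_retirement_age - s$dog_start_age
  q_o <- function(k) t$owner_mortality$q_annual[
    match(s$owner_start_age + k, t$owner_mortality$age)]
  q_d <- function(k) t$dog_mortality$q_annual[
    match(s$dog_start_age + k, t$dog_mortality$dog_age)]
  p_cert <- t$p_pass_minor * t$p_pass_major * t$p_pass_exam
  if (arm == "companion_track") p_cert <- 0

  pv <- function(p) vapply(p$annual_cost, function(d) d$point_value, numeric(1))
  add_un <- function(p, v) if (s$include_unrelated) v + p$unrelated_addon else v
  cost_profile <- function(state, k) {
    p <- switch(state,
                presplit = ps$profiles$companion,
                cert = if (k >= s$benefit_start_cycle) ps$profiles$certified
                       else ps$profiles$companion,
                retired = ps$profiles$retired_or_decert,
                nc_never = ps$profiles$companion,
                nc_decert = ps$profiles$retired_or_decert,
                dog_dead = ps$profiles$dog_dead,
                owner_dead = NULL)
    if (is.null(p)) return(0)
    v <- sum(add_un(p, pv(p)))
    if (state == "retired") v <- v * s$retired_cost_growth^max(0, k - retire_cycle)
    v
  }
  qaly_of <- function(state, k) {
    w <- switch(state,
                presplit = ps$profiles$companion$qaly_weight$point_value,
                cert = if (k >= s$benefit_start_cycle)
                         ps$profiles$certified$qaly_weight$point_value
                       else ps$profiles$companion$qaly_weight$point_value,
                retired = ps$profiles$retired_or_decert$qaly_weight$point_value *
                  s$retired_qaly_decay^max(0, k - retire_cycle),
                nc_never = ps$profiles$companion$qaly_weight$point_value,
                nc_decert = ps$profiles$retired_or_decert$qaly_weight$point_value,
                dog_dead = ps$profiles$dog_dead$qaly_weight$point_value,
                owner_dead = 0)
    w
  }
  band_of <- function(k) if (k == 0) "year1" else if (k == 1) "year2" else "subsequent"
  dog_cost <- function(state, k) {
    tt <- ps$dog_costs$totals
    switch(state,
           presplit = tt[band_of(k), "certified"],
           cert = tt[band_of(k), "certified"],
           retired = tt[band_of(k), "companion"],
           nc_never = tt[band_of(k), "companion"],
           nc_decert = tt[band_of(k), "companion"],
           0)
  }
  branches <- function(state, k) {
    # transition INTO cycle k; ages attained in cycle k
    if (state %in% c("dog_dead", "owner_dead"))
      return(list(list(state, 1)))
    qo <- q_o(k); qd <- q_d(k)
    alive <- (1 - qo) * (1 - qd)
    base <- list(list("owner_dead", qo), list("dog_dead", (1 - qo) * qd))
    rest <- if (state == "presplit") {
      list(list("cert", alive * p_cert), list("nc_never", alive * (1 - p_cert)))
    } else if (state == "cert") {
      if (s$dog_start_age + k >= s$dog_retirement_age)
        list(list("retired", alive))
      else list(list("nc_decert", alive * t$p_annual_decert),
                list("cert", alive * (1 - t$p_annual_decert)))
    } else list(list(state, alive))
    c(base, rest)
  }
  total_cost <- 0; total_qaly <- 0
  walk <- function(state, k, prob) {
    if (prob == 0 || k >= H) return()
    disc <- (1 + s$discount_rate)^(-k)
    total_cost <<- total_cost +
      prob * disc * (cost_profile(state, k) + dog_cost(state, k))
    total_qaly <<- total_qaly + prob * disc * qaly_of(state, k)
    for (b in branches(state, k + 1))
      walk(b[[1]], k + 1, prob * b[[2]])
  }
  start <- if (arm == "certified_track" && s$benefit_start_cycle == 0L) {
    list(list("cert", p_cert), list("nc_never", 1 - p_cert))
  } else if (arm == "certified_track") {
    list(list("presplit", 1))
  } else {
    list(list("nc_never", 1))
  }
  for (b in start) walk(b[[1]], 0, b[[2]])
  list(cost = total_cost, qaly = total_qaly)
}

fixture_ps <- function(dog_type = "physical_service", ...) {
  load_parameter_set(default_bundle(), dog_type, ...)
}

# strip every sampling distribution down to its point value
point_only <- function(ps) {
  for (st in names(ps$profiles)) {
    for (ct in names(ps$profiles[[st]]$annual_cost)) {
      v <- ps$profiles[[st]]$annual_cost[[ct]]$point_value
      ps$profiles[[st]]$annual_cost[[ct]] <- dist_spec("point", point_value = v)
    }
    w <- ps$profiles[[st]]$qaly_weight$point_value
    ps$profiles[[st]]$qaly_weight <- dist_spec("point", point_value = w)
  }
  ps$dog_costs$components$alfa <- NA_real_
  ps$dog_costs$components$beta <- NA_real_
  ps
}
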