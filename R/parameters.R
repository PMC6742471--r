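# Parameter containers, validation, bundle IO, and the input-side
# transforms (retired-state midpoint, perspective filters, currency).

#' Cost categories used throughout the model
#'
#' Five categories partition total cost: health care, municipal services,
#' informal care, productivity loss (sick leave) and dog-related costs.
#' The first four are carried by state profiles; dog costs follow their
#' own year-by-year schedule.
#' @export
cost_categories <- function() c("healthcare", "municipal", "informal_care",
                                "productivity_loss", "dog")

# categories carried by a state profile (dog costs live in the schedule)
profile_categories <- function() cost_categories()[1:4]

model_states <- function() c("certified_dog", "dog_retired", "dog_not_certified",
                             "dog_dead", "owner_dead")

dog_types <- function() c("physical_service", "diabetes_alert")

chk <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

is_prob <- function(p) is.numeric(p) && length(p) == 1L && is.finite(p) && p >= 0 && p <= 1

#' Economic settings for a model run
#'
#' @param discount_rate annual discount rate applied to both costs and
#'   QALYs (fraction, default 0.03).
#' @param horizon_years model horizon in years (decision-tree year plus
#'   Markov years; default 10).
#' @param cycle_length cycle length in years; the model is annual (1).
#' @param owner_start_age cohort starting age in years (default 44).
#' @param dog_start_age dog age at entry in years (default 2).
#' @param dog_retirement_age dog age at which retirement is certain
#'   (default 10).
#' @param perspective costing perspective: `"societal"` (all categories),
#'   `"healthcare"` (health-care plus dog costs) or
#'   `"societal_no_productivity"`.
#' @param sek_per_usd SEK per USD exchange rate used when inputs arrive
#'   in SEK (default 8.538, the 2017 mean).
#' @param threshold_grid strictly increasing willingness-to-pay grid in
#'   USD/QALY for acceptability curves.
#' @param rng_seed default seed for stochastic operations.
#' @param psa_anchor how PSA draws are anchored, see [sample_dist()].
#' @param benefit_start_cycle first cycle in which the certified-state
#'   cost/utility profile applies to certified owners (default 1: the
#'   decision-tree year accrues baseline values).
#' @param retired_cost_growth per-cycle exponential growth factor on
#'   retired-state costs, counted from the retirement cycle (default 1).
#' @param retired_qaly_decay per-cycle exponential decay factor on the
#'   retired-state QALY weight (default 1).
#' @param include_unrelated include care unrelated to the certified-dog
#'   indication (adds each profile's `unrelated_addon`; default FALSE).
#' @return an object of class `"economic_settings"`.
#' @export
economic_settings <- function(discount_rate = 0.03, horizon_years = 10L,
                              cycle_length = 1, owner_start_age = 44L,
                              dog_start_age = 2L, dog_retirement_age = 10L,
                              perspective = c("societal", "healthcare",
                                              "societal_no_productivity"),
                              sek_per_usd = 8.538,
                              threshold_grid = seq(0, 150000, by = 2500),
                              rng_seed = 1L,
                              psa_anchor = c("moment_matched", "printed_params"),
                              benefit_start_cycle = 1L,
                              retired_cost_growth = 1,
                              retired_qaly_decay = 1,
                              include_unrelated = FALSE) {
  perspective <- match.arg(perspective)
  psa_anchor <- match.arg(psa_anchor)
  chk(is.numeric(discount_rate) && discount_rate >= 0,
      "economic_settings: discount_rate must be >= 0")
  chk(horizon_years >= 1, "economic_settings: horizon_years must be >= 1")
  chk(cycle_length == 1, "economic_settings: only annual cycles are supported")
  chk(dog_retirement_age > dog_start_age,
      "economic_settings: dog_retirement_age must exceed dog_start_age")
  chk(length(threshold_grid) >= 1 && all(diff(threshold_grid) > 0),
      "economic_settings: threshold_grid must be strictly increasing")
  chk(retired_cost_growth > 0 && retired_qaly_decay > 0,
      "economic_settings: retired-state growth/decay factors must be positive")
  structure(list(discount_rate = discount_rate,
                 horizon_years = as.integer(horizon_years),
                 cycle_length = 1,
                 owner_start_age = as.integer(owner_start_age),
                 dog_start_age = as.integer(dog_start_age),
                 dog_retirement_age = as.integer(dog_retirement_age),
                 perspective = perspective,
                 sek_per_usd = sek_per_usd,
                 threshold_grid = as.numeric(threshold_grid),
                 rng_seed = as.integer(rng_seed),
                 psa_anchor = psa_anchor,
                 benefit_start_cycle = as.integer(benefit_start_cycle),
                 retired_cost_growth = retired_cost_growth,
                 retired_qaly_decay = retired_qaly_decay,
                 include_unrelated = isTRUE(include_unrelated)),
            class = "economic_settings")
}

#' Annual cost/utility profile attached to one model state
#'
#' @param annual_cost named list of [dist_spec()]s over the four
#'   non-dog cost categories (USD per owner-year). Absent categories are
#'   filled with zero point specs.
#' @param qaly_weight a [dist_spec()] for the state's utility weight.
#' @param unrelated_addon named numeric vector of annual costs for care
#'   unrelated to the certified-dog indication, added per category when
#'   the all-costs switch is on. Defaults to zero.
#' @return an object of class `"state_profile"`.
#' @export
state_profile <- function(annual_cost, qaly_weight, unrelated_addon = NULL) {
  cats <- profile_categories()
  chk(is.list(annual_cost), "state_profile: annual_cost must be a named list")
  chk(all(names(annual_cost) %in% cats),
      "state_profile: unknown cost category: ",
      paste(setdiff(names(annual_cost), cats), collapse = ", "))
  full <- stats::setNames(vector("list", length(cats)), cats)
  for (ct in cats) {
    full[[ct]] <- if (ct %in% names(annual_cost)) annual_cost[[ct]]
                  else dist_spec("point", point_value = 0)
    chk(is_dist_spec(full[[ct]]), "state_profile: '", ct, "' is not a dist_spec")
    chk(full[[ct]]$point_value >= 0, "state_profile: '", ct, "' cost must be >= 0")
  }
  chk(is_dist_spec(qaly_weight), "state_profile: qaly_weight must be a dist_spec")
  chk(qaly_weight$point_value >= UTILITY_MIN && qaly_weight$point_value <= 1,
      "state_profile: qaly_weight outside the tariff range [", UTILITY_MIN, ", 1]")
  addon <- stats::setNames(rep(0, length(cats)), cats)
  if (!is.null(unrelated_addon)) {
    chk(all(names(unrelated_addon) %in% cats) && all(unrelated_addon >= 0),
        "state_profile: invalid unrelated_addon")
    addon[names(unrelated_addon)] <- unrelated_addon
  }
  structure(list(annual_cost = full, qaly_weight = qaly_weight,
                 unrelated_addon = addon),
            class = "state_profile")
}

#' Dog-cost schedule by year band and track
#'
#' Holds the component-level dog costs (purchase, upkeep, tests,
#' training, capes, certification maintenance, health declaration) in
#' three year bands — year 1, year 2, and all following years — for the
#' companion track and the certified track, together with the published
#' per-band totals. Component sums must agree with the totals within
#' 1 USD (printed totals carry rounding).
#'
#' @param components data frame with columns `component`, `band`
#'   (`"year1"`, `"year2"`, `"subsequent"`), `companion`, `certified`
#'   (USD), and optional `alfa`, `beta` gamma parameters for components
#'   sampled in PSA.
#' @param totals optional 3x2 matrix of published band totals
#'   (rows year1/year2/subsequent, columns companion/certified). When
#'   omitted, component sums are used.
#' @return an object of class `"dog_cost_schedule"`.
#' @export
dog_cost_schedule <- function(components, totals = NULL) {
  bands <- c("year1", "year2", "subsequent")
  chk(is.data.frame(components) &&
        all(c("component", "band", "companion", "certified") %in% names(components)),
      "dog_cost_schedule: malformed components table")
  chk(all(components$band %in% bands), "dog_cost_schedule: unknown year band")
  chk(all(components$companion >= 0) && all(components$certified >= 0),
      "dog_cost_schedule: negative component cost")
  if (!("alfa" %in% names(components))) components$alfa <- NA_real_
  if (!("beta" %in% names(components))) components$beta <- NA_real_
  sums <- sapply(bands, function(b) {
    i <- components$band == b
    c(companion = sum(components$companion[i]), certified = sum(components$certified[i]))
  })
  sums <- t(sums) # bands x tracks
  if (is.null(totals)) {
    totals <- sums
  } else {
    totals <- as.matrix(totals)
    dimnames(totals) <- list(bands, c("companion", "certified"))
    chk(all(abs(totals - sums) <= 1 + 1e-9),
        "dog_cost_schedule: band totals differ from component sums by more than 1 USD")
  }
  structure(list(components = components, totals = totals), class = "dog_cost_schedule")
}

#' Transition probabilities and mortality tables
#'
#' @param p_pass_minor,p_pass_major,p_pass_exam probabilities of passing
#'   the minor suitability test, the major suitability test and the
#'   final certification exam. Not published; the defaults (0.9 each)
#'   are package assumptions and should be overridden when data exist.
#' @param p_annual_decert annual probability of failing the certification
#'   maintenance test (assumption, default 0.02).
#' @param owner_mortality data frame `age`, `q_annual` of annual owner
#'   death probabilities.
#' @param dog_mortality data frame `dog_age`, `q_annual` of annual dog
#'   death probabilities (applied identically in both arms).
#' @return an object of class `"transition_inputs"`.
#' @export
transition_inputs <- function(p_pass_minor = 0.9, p_pass_major = 0.9,
                              p_pass_exam = 0.9, p_annual_decert = 0.02,
                              owner_mortality, dog_mortality) {
  for (nm in c("p_pass_minor", "p_pass_major", "p_pass_exam", "p_annual_decert")) {
    v <- get(nm)
    chk(is_prob(v), "transition_inputs: ", nm, " must be a probability in [0, 1]")
  }
  chk(is.data.frame(owner_mortality) &&
        all(c("age", "q_annual") %in% names(owner_mortality)) &&
        all(is_prob_vec(owner_mortality$q_annual)),
      "transition_inputs: malformed owner_mortality table")
  chk(is.data.frame(dog_mortality) &&
        all(c("dog_age", "q_annual") %in% names(dog_mortality)) &&
        all(is_prob_vec(dog_mortality$q_annual)),
      "transition_inputs: malformed dog_mortality table")
  structure(list(p_pass_minor = p_pass_minor, p_pass_major = p_pass_major,
                 p_pass_exam = p_pass_exam, p_annual_decert = p_annual_decert,
                 owner_mortality = owner_mortality, dog_mortality = dog_mortality),
            class = "transition_inputs")
}

is_prob_vec <- function(p) is.numeric(p) & is.finite(p) & p >= 0 & p <= 1

lookup_q <- function(table, key_col, key, what) {
  i <- match(key, table[[key_col]])
  if (anyNA(i))
    stop(what, " mortality table does not cover age ",
         paste(key[is.na(i)], collapse = ", "), call. = FALSE)
  table$q_annual[i]
}

#' Assemble and validate a complete parameter set
#'
#' Binds state profiles, the dog-cost schedule, transition inputs and
#' settings for one dog type. The dog-dead state reuses the companion
#' (baseline) profile; owner death accrues nothing.
#'
#' @param dog_type `"physical_service"` or `"diabetes_alert"`.
#' @param profiles named list of [state_profile()]s for `companion`,
#'   `certified` and `retired_or_decert`. A missing retired profile is
#'   derived with [derive_retired_profile()].
#' @param dog_costs a [dog_cost_schedule()].
#' @param transitions a [transition_inputs()].
#' @param settings an [economic_settings()].
#' @return an object of class `"parameter_set"`.
#' @export
parameter_set <- function(dog_type, profiles, dog_costs, transitions, settings) {
  chk(dog_type %in% dog_types(), "parameter_set: unknown dog_type '", dog_type, "'")
  chk(inherits(dog_costs, "dog_cost_schedule"), "parameter_set: dog_costs invalid")
  chk(inherits(transitions, "transition_inputs"), "parameter_set: transitions invalid")
  chk(inherits(settings, "economic_settings"), "parameter_set: settings invalid")
  chk(all(c("companion", "certified") %in% names(profiles)),
      "parameter_set: profiles must include 'companion' and 'certified'")
  if (is.null(profiles$retired_or_decert))
    profiles$retired_or_decert <- derive_retired_profile(profiles$companion,
                                                         profiles$certified)
  for (p in profiles[c("companion", "certified", "retired_or_decert")])
    chk(inherits(p, "state_profile"), "parameter_set: profiles must be state_profiles")
  profiles$dog_dead <- profiles$companion # baseline values apply after dog death
  s <- settings
  ages_needed <- seq(s$owner_start_age, s$owner_start_age + s$horizon_years)
  chk(all(ages_needed %in% transitions$owner_mortality$age),
      "parameter_set: owner mortality table must cover ages ",
      min(ages_needed), "-", max(ages_needed))
  dog_ages_needed <- seq(s$dog_start_age, s$dog_start_age + s$horizon_years - 1L)
  chk(all(dog_ages_needed %in% transitions$dog_mortality$dog_age),
      "parameter_set: dog mortality table must cover ages ",
      min(dog_ages_needed), "-", max(dog_ages_needed))
  structure(list(dog_type = dog_type,
                 profiles = profiles[c("companion", "certified",
                                       "retired_or_decert", "dog_dead")],
                 dog_costs = dog_costs, transitions = transitions,
                 settings = s),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  s <- x$settings
  cat("Parameter set:", x$dog_type, "\n")
  cat(sprintf("  horizon %d y, discount %.1f%%, owner age %d, dog age %d (retires at %d)\n",
              s$horizon_years, 100 * s$discount_rate, s$owner_start_age,
              s$dog_start_age, s$dog_retirement_age))
  cat("  perspective:", s$perspective, "\n")
  w <- vapply(x$profiles, function(p) p$qaly_weight$point_value, numeric(1))
  cat("  QALY weights:",
      paste(sprintf("%s %.3f", names(w), w), collapse = ", "), "\n")
  invisible(x)
}

#' Midpoint profile for a retired or decertified dog
#'
#' The retired/decertified state takes, per category, the arithmetic
#' mean of the companion and certified annual costs (truncated to whole
#' USD, matching the published tables) and the mean of the two utility
#' weights. Gamma/beta parameters are interpolated as the mean of the
#' parents' parameters; mixed or point parents yield a point spec.
#'
#' @param companion,certified validated [state_profile()]s.
#' @return a [state_profile()] for the retired/decertified state.
#' @export
derive_retired_profile <- function(companion, certified) {
  chk(inherits(companion, "state_profile") && inherits(certified, "state_profile"),
      "derive_retired_profile: inputs must be state_profiles")
  mid_spec <- function(a, b, cost = TRUE) {
    mid <- (a$point_value + b$point_value) / 2
    if (cost) mid <- trunc(mid)
    if (a$family == b$family && a$family != "point")
      dist_spec(a$family, (a$alfa + b$alfa) / 2, (a$beta + b$beta) / 2, mid)
    else dist_spec("point", point_value = mid)
  }
  costs <- lapply(profile_categories(), function(ct)
    mid_spec(companion$annual_cost[[ct]], certified$annual_cost[[ct]]))
  names(costs) <- profile_categories()
  state_profile(costs,
                mid_spec(companion$qaly_weight, certified$qaly_weight, cost = FALSE),
                unrelated_addon = (companion$unrelated_addon + certified$unrelated_addon) / 2)
}

#' Restrict a parameter set to a costing perspective
#'
#' `societal` keeps all categories; `societal_no_productivity` zeroes
#' productivity losses; `healthcare` keeps only the categories in
#' `keep` (default health care plus dog costs — the intervention cost
#' stays in any payer perspective).
#'
#' @param ps a [parameter_set()].
#' @param perspective target perspective.
#' @param keep categories retained under the healthcare perspective.
#' @return a new [parameter_set()]; the input is not modified.
#' @export
apply_perspective <- function(ps, perspective = c("societal", "healthcare",
                                                  "societal_no_productivity"),
                              keep = c("healthcare", "dog")) {
  chk(inherits(ps, "parameter_set"), "apply_perspective: ps must be a parameter_set")
  perspective <- match.arg(perspective)
  chk(all(keep %in% cost_categories()), "apply_perspective: unknown category in keep")
  drop <- switch(perspective,
                 societal = character(0),
                 societal_no_productivity = "productivity_loss",
                 healthcare = setdiff(cost_categories(), keep))
  out <- ps
  for (st in names(out$profiles)) {
    for (ct in intersect(drop, profile_categories())) {
      out$profiles[[st]]$annual_cost[[ct]] <- dist_spec("point", point_value = 0)
      out$profiles[[st]]$unrelated_addon[[ct]] <- 0
    }
  }
  if ("dog" %in% drop) {
    out$dog_costs$components$companion <- 0
    out$dog_costs$components$certified <- 0
    out$dog_costs$totals[] <- 0
  }
  out$settings$perspective <- perspective
  out
}

#' Convert Swedish kronor to US dollars
#'
#' @param amount_sek amount in SEK.
#' @param rate SEK per USD (default 8.538, the 2017 mean rate).
#' @return amount in USD.
#' @examples
#' convert_currency(8538)      # 1000
#' @export
convert_currency <- function(amount_sek, rate = 8.538) {
  chk(is.numeric(rate) && length(rate) == 1L && is.finite(rate) && rate > 0,
      "convert_currency: rate must be positive")
  amount_sek / rate
}
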