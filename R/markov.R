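# Decision tree (year 1) + Markov cohort (years 2-10) engine.
#
# Reported states: certified_dog, dog_retired, dog_not_certified,
# dog_dead, owner_dead. Internally dog_not_certified is split into
# owners who never certified (baseline profile) and owners whose dog
# lost certification (retired/decertified profile); the reported trace
# merges the two.
#
# run_trace() = markov_occupancy() + accrue_trace(); the probabilistic
# sensitivity analysis reuses accrue_trace() on fixed occupancies, so
# deterministic and probabilistic runs share one accrual code path.

INTERNAL_STATES <- c("certified", "retired", "nc_never", "nc_decert",
                     "dog_dead", "owner_dead")

#' Discount factor for an annual cycle
#'
#' Cycle 0 (the first model year) is undiscounted; cycle `k` is
#' discounted by `(1 + rate)^-k`.
#'
#' @param rate annual discount rate (fraction, `>= 0`).
#' @param cycle_index cycle number, 0-based.
#' @return numeric discount factor(s).
#' @examples
#' discount_factor(0.03, 0:9)
#' @export
discount_factor <- function(rate, cycle_index) {
  chk(is.numeric(rate) && all(rate >= 0), "discount_factor: rate must be >= 0")
  chk(all(cycle_index >= 0), "discount_factor: cycle_index must be >= 0")
  (1 + rate)^(-cycle_index)
}

#' First-year decision-tree split
#'
#' Owners on the certified track must pass a minor suitability test, a
#' major suitability test and (after training) a final exam. The
#' certified fraction is the product of the three pass probabilities;
#' the remainder stays with an uncertified dog.
#'
#' @param t a [transition_inputs()].
#' @return named probability vector over the five model states (sums to 1).
#' @export
decision_tree_split <- function(t) {
  chk(inherits(t, "transition_inputs"), "decision_tree_split: t must be transition_inputs")
  p_cert <- t$p_pass_minor * t$p_pass_major * t$p_pass_exam
  out <- stats::setNames(numeric(5), model_states())
  out["certified_dog"] <- p_cert
  out["dog_not_certified"] <- 1 - p_cert
  out
}

#' One row of the annual transition matrix
#'
#' Competing risks are applied as sequential conditional risks — owner
#' death, then dog death, then (certified owners) forced retirement when
#' the dog has reached retirement age, then decertification — so each
#' row sums to one by construction. `owner_age` and `dog_age` are the
#' ages attained in the destination cycle. Owner-dead and dog-dead are
#' absorbing.
#'
#' @param state origin state (one of the five model states).
#' @param owner_age,dog_age ages in years; must be covered by the
#'   mortality tables.
#' @param t a [transition_inputs()].
#' @param retirement_age dog age at which retirement is certain.
#' @return named probability vector over the five model states.
#' @export
build_transition_row <- function(state, owner_age, dog_age, t, retirement_age) {
  chk(state %in% model_states(), "build_transition_row: unknown state '", state, "'")
  out <- stats::setNames(numeric(5), model_states())
  if (state %in% c("owner_dead", "dog_dead")) {
    out[state] <- 1
    return(out)
  }
  q_o <- lookup_q(t$owner_mortality, "age", owner_age, "owner")
  q_d <- lookup_q(t$dog_mortality, "dog_age", dog_age, "dog")
  out["owner_dead"] <- q_o
  out["dog_dead"] <- (1 - q_o) * q_d
  alive <- (1 - q_o) * (1 - q_d)
  if (state == "certified_dog") {
    if (dog_age >= retirement_age) {
      out["dog_retired"] <- alive
    } else {
      out["dog_not_certified"] <- alive * t$p_annual_decert
      out["certified_dog"] <- alive * (1 - t$p_annual_decert)
    }
  } else {
    out[state] <- alive
  }
  out
}

# internal 6x6 transition matrix for the transition *into* a cycle
transition_matrix_internal <- function(t, owner_age, dog_age, retirement_age) {
  q_o <- lookup_q(t$owner_mortality, "age", owner_age, "owner")
  q_d <- lookup_q(t$dog_mortality, "dog_age", dog_age, "dog")
  alive <- (1 - q_o) * (1 - q_d)
  P <- matrix(0, 6, 6, dimnames = list(INTERNAL_STATES, INTERNAL_STATES))
  for (s in c("certified", "retired", "nc_never", "nc_decert")) {
    P[s, "owner_dead"] <- q_o
    P[s, "dog_dead"] <- (1 - q_o) * q_d
  }
  if (dog_age >= retirement_age) {
    P["certified", "retired"] <- alive
  } else {
    P["certified", "nc_decert"] <- alive * t$p_annual_decert
    P["certified", "certified"] <- alive * (1 - t$p_annual_decert)
  }
  P["retired", "retired"] <- alive
  P["nc_never", "nc_never"] <- alive
  P["nc_decert", "nc_decert"] <- alive
  P["dog_dead", "dog_dead"] <- 1
  P["owner_dead", "owner_dead"] <- 1
  P
}

dog_band <- function(cycle) if (cycle == 0L) "year1" else if (cycle == 1L) "year2" else "subsequent"

# cycle-by-cycle occupancy of the six internal compartments
markov_occupancy <- function(ps, arm) {
  s <- ps$settings
  t <- ps$transitions
  H <- s$horizon_years
  p_cert <- if (arm == "certified_track")
    t$p_pass_minor * t$p_pass_major * t$p_pass_exam else 0
  occ <- matrix(0, H, 6, dimnames = list(NULL, INTERNAL_STATES))
  if (s$benefit_start_cycle == 0L && arm == "certified_track") {
    # immediate certification (e.g. purchase of a fully trained dog)
    occ[1, "certified"] <- p_cert
    occ[1, "nc_never"] <- 1 - p_cert
  } else {
    occ[1, "nc_never"] <- 1
  }
  if (H >= 2) {
    if (occ[1, "certified"] > 0) {
      occ[2, ] <- occ[1, ] %*% transition_matrix_internal(
        t, s$owner_start_age + 1L, s$dog_start_age + 1L, s$dog_retirement_age)
    } else {
      # decision-tree split combined with the first Markov year's mortality
      q_o <- lookup_q(t$owner_mortality, "age", s$owner_start_age + 1L, "owner")
      q_d <- lookup_q(t$dog_mortality, "dog_age", s$dog_start_age + 1L, "dog")
      alive <- (1 - q_o) * (1 - q_d)
      occ[2, "owner_dead"] <- q_o
      occ[2, "dog_dead"] <- (1 - q_o) * q_d
      occ[2, "certified"] <- alive * p_cert
      occ[2, "nc_never"] <- alive * (1 - p_cert)
    }
    if (H >= 3) for (k in 2:(H - 1)) {
      P <- transition_matrix_internal(t, s$owner_start_age + k,
                                      s$dog_start_age + k, s$dog_retirement_age)
      occ[k + 1, ] <- occ[k, ] %*% P
    }
  }
  occ
}

# numeric accrual inputs extracted from a parameter set
trace_values <- function(ps) {
  s <- ps$settings
  prof_cost <- function(p) {
    v <- vapply(p$annual_cost, function(d) d$point_value, numeric(1))
    if (s$include_unrelated) v <- v + p$unrelated_addon
    v
  }
  list(cost_of = list(companion = prof_cost(ps$profiles$companion),
                      certified = prof_cost(ps$profiles$certified),
                      retired = prof_cost(ps$profiles$retired_or_decert),
                      dog_dead = prof_cost(ps$profiles$dog_dead)),
       w_of = c(companion = ps$profiles$companion$qaly_weight$point_value,
                certified = ps$profiles$certified$qaly_weight$point_value,
                retired = ps$profiles$retired_or_decert$qaly_weight$point_value,
                dog_dead = ps$profiles$dog_dead$qaly_weight$point_value),
       totals = ps$dog_costs$totals)
}

# discounted per-cycle cost/QALY accrual on a fixed occupancy
accrue_trace <- function(occ, vals, s, arm) {
  H <- nrow(occ)
  retire_cycle <- s$dog_retirement_age - s$dog_start_age
  all_cats <- cost_categories()
  cats <- profile_categories()
  cycle_costs <- matrix(0, H, length(all_cats), dimnames = list(NULL, all_cats))
  cycle_qalys <- numeric(H)
  disc <- discount_factor(s$discount_rate, seq_len(H) - 1L)
  cost_of <- vals$cost_of
  w_of <- vals$w_of
  totals <- vals$totals
  for (k in seq_len(H) - 1L) {
    row <- occ[k + 1, ]
    cert_profile <- if (k >= s$benefit_start_cycle) "certified" else "companion"
    # retired-state exponential drift, counted from the retirement cycle
    t_ret <- max(0L, k - retire_cycle)
    gro <- s$retired_cost_growth^t_ret
    dec <- s$retired_qaly_decay^t_ret
    cvec <- row[["certified"]] * cost_of[[cert_profile]] +
      row[["retired"]] * cost_of$retired * gro +
      row[["nc_never"]] * cost_of$companion +
      row[["nc_decert"]] * cost_of$retired +
      row[["dog_dead"]] * cost_of$dog_dead
    band <- dog_band(k)
    if (k == 0L && arm == "certified_track" && s$benefit_start_cycle > 0L) {
      dog_cost <- totals[band, "certified"] # whole cohort takes the tests
    } else {
      dog_cost <- row[["certified"]] * totals[band, "certified"] +
        (row[["retired"]] + row[["nc_never"]] + row[["nc_decert"]]) *
          totals[band, "companion"]
    }
    cycle_costs[k + 1, cats] <- cvec * disc[k + 1]
    cycle_costs[k + 1, "dog"] <- dog_cost * disc[k + 1]
    cycle_qalys[k + 1] <- (row[["certified"]] * w_of[[cert_profile]] +
      row[["retired"]] * w_of[["retired"]] * dec +
      row[["nc_never"]] * w_of[["companion"]] +
      row[["nc_decert"]] * w_of[["retired"]] +
      row[["dog_dead"]] * w_of[["dog_dead"]]) * disc[k + 1]
  }
  list(cycle_costs = cycle_costs, cycle_qalys = cycle_qalys)
}

#' Run one arm of the model
#'
#' Cycle 0 is the decision-tree year: on the certified track the cohort
#' undergoes the suitability tests and training intake (certified-track
#' year-1 dog costs) while accruing the baseline cost/utility profile;
#' on the companion track it is an ordinary companion-dog year. The
#' decision-tree split, combined with the first year's mortality, feeds
#' cycle 1; cycles 1 to `horizon - 1` follow the annual transition
#' matrix. Each cycle accrues state costs, dog costs (year-1 / year-2 /
#' subsequent schedule) and QALY weights, multiplied by occupancy and
#' the discount factor.
#'
#' @param ps a [parameter_set()].
#' @param arm `"certified_track"` or `"companion_track"`.
#' @return an object of class `"cohort_trace"` with occupancy (cycles x
#'   five states), discounted per-cycle costs by category, discounted
#'   per-cycle QALYs, and their totals.
#' @export
run_trace <- function(ps, arm = c("certified_track", "companion_track")) {
  arm <- match.arg(arm)
  chk(inherits(ps, "parameter_set"), "run_trace: ps must be a parameter_set")
  occ <- markov_occupancy(ps, arm)
  acc <- accrue_trace(occ, trace_values(ps), ps$settings, arm)
  reported <- cbind(certified_dog = occ[, "certified"],
                    dog_retired = occ[, "retired"],
                    dog_not_certified = occ[, "nc_never"] + occ[, "nc_decert"],
                    dog_dead = occ[, "dog_dead"],
                    owner_dead = occ[, "owner_dead"])
  structure(list(arm = arm, dog_type = ps$dog_type,
                 occupancy = reported, occupancy_internal = occ,
                 cycle_costs = acc$cycle_costs, cycle_qalys = acc$cycle_qalys,
                 cost_by_category = colSums(acc$cycle_costs),
                 total_cost = sum(acc$cycle_costs),
                 total_qaly = sum(acc$cycle_qalys),
                 settings = ps$settings),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: %s arm, %s, %d cycles\n", x$arm, x$dog_type,
              nrow(x$occupancy)))
  cat(sprintf("  discounted totals: %.0f USD, %.3f QALYs\n",
              x$total_cost, x$total_qaly))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = seq_len(nrow(x$occupancy)) - 1L,
             x$occupancy,
             cost = x$cycle_costs,
             qalys = x$cycle_qalys, check.names = FALSE)
}

#' Incremental comparison of per-arm totals
#'
#' Computes incremental cost and QALYs (certified minus companion),
#' classifies the cost-effectiveness quadrant, and forms the ICER where
#' a ratio is meaningful. In dominance quadrants the ICER is reported as
#' a label, never a negative number.
#'
#' @param cost_certified,cost_companion discounted total costs (USD).
#' @param qaly_certified,qaly_companion discounted total QALYs.
#' @return an object of class `"ce_result"` with elements
#'   `cost_by_arm`, `qaly_by_arm`, `delta_cost`, `delta_qaly`, `icer`
#'   (numeric or `NA`), `icer_label`, `dominance`.
#' @examples
#' compare_totals(1191121, 1197080, 2.79, 2.51)  # dominant
#' @export
compare_totals <- function(cost_certified, cost_companion,
                           qaly_certified, qaly_companion) {
  dc <- cost_certified - cost_companion
  de <- qaly_certified - qaly_companion
  if (dc < 0 && de > 0) {
    dominance <- "dominant"; icer <- NA_real_; label <- "Dominant"
  } else if (dc > 0 && de < 0) {
    dominance <- "dominated"; icer <- NA_real_; label <- "Dominated"
  } else if (de == 0) {
    if (dc == 0) { dominance <- "no_difference"; label <- "undefined (no difference)" }
    else if (dc < 0) { dominance <- "dominant"; label <- "Dominant" }
    else { dominance <- "dominated"; label <- "Dominated" }
    icer <- NA_real_
  } else {
    dominance <- if (de > 0) "tradeoff_ne" else "tradeoff_sw"
    icer <- dc / de
    label <- sprintf("%.0f", icer)
  }
  structure(list(cost_by_arm = c(certified = cost_certified,
                                 companion = cost_companion),
                 qaly_by_arm = c(certified = qaly_certified,
                                 companion = qaly_companion),
                 delta_cost = dc, delta_qaly = de,
                 icer = icer, icer_label = label, dominance = dominance),
            class = "ce_result")
}

#' Compare two cohort traces
#'
#' @param cert,comp `cohort_trace` objects from [run_trace()] for the
#'   certified and companion arms of the same parameter set.
#' @return a `ce_result`, see [compare_totals()].
#' @export
compare_arms <- function(cert, comp) {
  chk(inherits(cert, "cohort_trace") && inherits(comp, "cohort_trace"),
      "compare_arms: inputs must be cohort_traces")
  out <- compare_totals(cert$total_cost, comp$total_cost,
                        cert$total_qaly, comp$total_qaly)
  out$cost_category_by_arm <- rbind(certified = cert$cost_by_category,
                                    companion = comp$cost_by_category)
  out
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Incremental cost-effectiveness (certified vs companion)\n")
  cat(sprintf("  cost:  %.0f vs %.0f USD (delta %+.0f)\n",
              x$cost_by_arm[["certified"]], x$cost_by_arm[["companion"]], x$delta_cost))
  cat(sprintf("  QALYs: %.2f vs %.2f (delta %+.2f)\n",
              x$qaly_by_arm[["certified"]], x$qaly_by_arm[["companion"]], x$delta_qaly))
  cat("  ICER:", x$icer_label, if (!is.na(x$icer)) "USD/QALY" else "", "\n")
  invisible(x)
}
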