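# Deterministic one-way sensitivity analysis: eleven named scenarios,
# each a declarative transform of a parameter set.

#' The eleven built-in sensitivity scenarios
#'
#' Returns the scenario set of the source analysis: discounting at 0%
#' and 5%, short/long dog life span (30% / 10% cumulative mortality by
#' dog age 11), retirement at 8 and at 12, exponential cost increase
#' with HRQoL decrease for owners of a retired dog, inclusion of
#' unrelated care ("all costs"), purchase of a fully trained dog
#' (17,569 USD), a health-care perspective, and a societal perspective
#' without productivity losses.
#'
#' The exponential rates of scenario 7 (cost growth 1.05, utility decay
#' 0.95 per cycle in retirement) and the zero unrelated-cost add-on of
#' scenario 8 are package assumptions — the source prints neither — and
#' can be overridden through the transform.
#'
#' @return list of `scenario_spec` objects (length 11).
#' @export
builtin_scenarios <- function() {
  sc <- function(id, name, transform)
    structure(list(scenario_id = id, name = name, transform = transform),
              class = "scenario_spec")
  list(
    sc(1L, "Discount rate (cost and QALYs): 0%",
       list(settings = list(discount_rate = 0))),
    sc(2L, "Discount rate (cost and QALYs): 5%",
       list(settings = list(discount_rate = 0.05))),
    sc(3L, "Short life span of the dog",
       list(dog_lifetable_cum11 = 0.30)),
    sc(4L, "Long life-span of the dog",
       list(dog_lifetable_cum11 = 0.10)),
    sc(5L, "Dogs retires at the age of 8",
       list(settings = list(dog_retirement_age = 8L))),
    sc(6L, "Dogs retires at the age of 12",
       list(settings = list(dog_retirement_age = 12L))),
    sc(7L, "Cost increase and HRQoL decrease for owners with a retired dog",
       list(settings = list(retired_cost_growth = 1.05,
                            retired_qaly_decay = 0.95))),
    sc(8L, "Analysis including related and unrelated costs (all costs)",
       list(settings = list(include_unrelated = TRUE))),
    sc(9L, "Purchasing a fully trained dog (17,569 USD)",
       list(purchase_trained_usd = 17569)),
    sc(10L, "Health-care perspective",
       list(perspective = "healthcare")),
    sc(11L, "Societal perspective without productivity losses",
       list(perspective = "societal_no_productivity"))
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario %d: %s>\n", x$scenario_id, x$name))
  invisible(x)
}

#' Apply a scenario transform to a parameter set
#'
#' Recognised override points: `settings = list(...)` (any
#' [economic_settings()] field), `transitions = list(...)` (pass /
#' decertification probabilities), `perspective` (see
#' [apply_perspective()]), `dog_lifetable_cum11` (replace the dog life
#' table with [make_dog_lifetable()] calibrated to that cumulative
#' mortality at age 11), and `purchase_trained_usd` (fully trained dog:
#' certified-track purchase replaced, suitability/training/cape
#' components removed, certification immediate). Anything else is an
#' error naming the path. The input set is never modified.
#'
#' @param ps a [parameter_set()].
#' @param spec a `scenario_spec` from [builtin_scenarios()], or a bare
#'   transform list.
#' @return a new [parameter_set()].
#' @export
apply_scenario <- function(ps, spec) {
  chk(inherits(ps, "parameter_set"), "apply_scenario: ps must be a parameter_set")
  transform <- if (inherits(spec, "scenario_spec")) spec$transform else spec
  chk(is.list(transform), "apply_scenario: transform must be a list")
  known <- c("settings", "transitions", "perspective", "dog_lifetable_cum11",
             "purchase_trained_usd")
  bad <- setdiff(names(transform), known)
  chk(length(bad) == 0, "apply_scenario: unknown override path: ",
      paste(bad, collapse = ", "))
  out <- ps
  if (!is.null(transform$settings)) {
    st <- transform$settings
    bad <- setdiff(names(st), names(out$settings))
    chk(length(bad) == 0, "apply_scenario: unknown settings field: ",
        paste(bad, collapse = ", "))
    args <- unclass(out$settings)
    args[names(st)] <- st
    out$settings <- do.call(economic_settings, args)
  }
  if (!is.null(transform$transitions)) {
    tr <- transform$transitions
    ok <- c("p_pass_minor", "p_pass_major", "p_pass_exam", "p_annual_decert")
    bad <- setdiff(names(tr), ok)
    chk(length(bad) == 0, "apply_scenario: unknown transitions field: ",
        paste(bad, collapse = ", "))
    for (nm in names(tr)) out$transitions[[nm]] <- tr[[nm]]
    out$transitions <- do.call(transition_inputs, unclass(out$transitions))
  }
  if (!is.null(transform$dog_lifetable_cum11)) {
    lt <- make_dog_lifetable(transform$dog_lifetable_cum11,
                             start_age = out$settings$dog_start_age,
                             end_age = max(out$transitions$dog_mortality$dog_age))
    out$transitions$dog_mortality <- lt
  }
  if (!is.null(transform$purchase_trained_usd)) {
    price <- transform$purchase_trained_usd
    chk(is.numeric(price) && price > 0, "apply_scenario: invalid trained-dog price")
    comp <- out$dog_costs$components
    drop <- comp$component %in% c("suitability_tests", "training", "capes")
    comp$certified[drop] <- 0
    comp$certified[comp$component == "purchase"] <- price
    out$dog_costs <- dog_cost_schedule(comp) # totals re-derived from components
    # a trained dog certifies immediately: no tests, benefits from cycle 0
    out$transitions$p_pass_minor <- 1
    out$transitions$p_pass_major <- 1
    out$transitions$p_pass_exam <- 1
    out$settings$benefit_start_cycle <- 0L
  }
  # rebuild to re-check every invariant after the overrides
  out <- parameter_set(out$dog_type,
                       out$profiles[c("companion", "certified", "retired_or_decert")],
                       out$dog_costs, out$transitions, out$settings)
  if (!is.null(transform$perspective))
    out <- apply_perspective(out, transform$perspective)
  out
}

#' Run the deterministic sensitivity analysis
#'
#' Applies each scenario to the base parameter set, reruns the
#' deterministic model, and tabulates incremental cost, incremental
#' QALYs and the ICER or dominance label, in scenario order.
#'
#' @param ps the base-case [parameter_set()].
#' @param specs list of scenarios, by default [builtin_scenarios()].
#' @return data frame of class `"dog_cea_dsa"` with columns
#'   `scenario_id`, `name`, `incremental_cost`, `incremental_qaly`,
#'   `icer` (label), `dominance`.
#' @export
run_dsa <- function(ps, specs = builtin_scenarios()) {
  chk(inherits(ps, "parameter_set"), "run_dsa: ps must be a parameter_set")
  chk(length(specs) >= 1, "run_dsa: specs must be non-empty")
  rows <- lapply(specs, function(spec) {
    fit <- dog_cea(apply_scenario(ps, spec))
    r <- fit$result
    data.frame(scenario_id = if (inherits(spec, "scenario_spec"))
                 spec$scenario_id else NA_integer_,
               name = if (inherits(spec, "scenario_spec")) spec$name else "custom",
               incremental_cost = r$delta_cost,
               incremental_qaly = r$delta_qaly,
               icer = r$icer_label,
               dominance = r$dominance)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dog_cea_dsa", "data.frame")
  out
}

#' @export
print.dog_cea_dsa <- function(x, ...) {
  cat("Deterministic sensitivity analysis\n")
  y <- as.data.frame(x)
  y$incremental_cost <- round(y$incremental_cost)
  y$incremental_qaly <- round(y$incremental_qaly, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
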