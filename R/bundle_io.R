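# Reading and writing parameter bundles.
#
# A bundle is a directory holding:
#   costs_<dogtype>.csv   state cost/QALY table (category rows, per-state
#                         values and gamma/beta parameters)
#   dog_costs.csv         dog-cost components by year band, plus
#                         published band totals ("printed_total" rows)
#   transitions.cfg       YAML: test-pass and decertification probabilities
#   settings.cfg          YAML: economic settings
#   owner_lifetable.csv   columns age, q_annual
#   dog_lifetable.csv     columns dog_age, q_annual

#' Path to the packaged base-case parameter bundle
#'
#' The bundle carries the published annual costs, gamma/beta parameters
#' and QALY weights for both dog types, the dog-cost schedule, assumed
#' transition probabilities, and synthetic owner/dog life tables (the
#' original national life table and veterinary mortality data are not
#' redistributable; the packaged tables are generated by
#' [make_owner_lifetable()] / [make_dog_lifetable()] with documented
#' anchors).
#' @return directory path.
#' @export
default_bundle <- function() {
  system.file("extdata", "base_bundle", package = "dogcea", mustWork = TRUE)
}

read_csv_strict <- function(path) {
  tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
           error = function(e) stop("failed to parse '", basename(path), "': ",
                                    conditionMessage(e), call. = FALSE),
           warning = function(w) stop("failed to parse '", basename(path), "': ",
                                      conditionMessage(w), call. = FALSE))
}

read_cfg <- function(path) {
  tryCatch(yaml::read_yaml(path),
           error = function(e) stop("failed to parse '", basename(path), "': ",
                                    conditionMessage(e), call. = FALSE))
}

num_or_na <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)

spec_from_row <- function(value, alfa, beta, family, file, row) {
  if (!is.finite(value))
    stop("'", file, "' row ", row, ": missing value", call. = FALSE)
  if (is.finite(alfa) && is.finite(beta)) dist_spec(family, alfa, beta, value)
  else dist_spec("point", point_value = value)
}

profile_from_costs <- function(tab, col, file, usd_scale) {
  cats <- profile_categories()
  costs <- list(); addon <- c()
  for (ct in cats) {
    i <- which(tab$category == ct)
    if (length(i) != 1L)
      stop("'", file, "': expected exactly one row for category '", ct, "'",
           call. = FALSE)
    costs[[ct]] <- spec_from_row(tab[[col]][i] * usd_scale,
                                 num_or_na(tab[[paste0("alfa_", col)]][i]),
                                 num_or_na(tab[[paste0("beta_", col)]][i]) * usd_scale,
                                 "gamma", file, i)
    un_col <- paste0("unrelated_", col)
    addon[ct] <- if (un_col %in% names(tab) && is.finite(tab[[un_col]][i]))
      tab[[un_col]][i] * usd_scale else 0
  }
  i <- which(tab$category == "qaly_weight")
  if (length(i) != 1L)
    stop("'", file, "': expected exactly one 'qaly_weight' row", call. = FALSE)
  qw <- spec_from_row(tab[[col]][i], num_or_na(tab[[paste0("alfa_", col)]][i]),
                      num_or_na(tab[[paste0("beta_", col)]][i]), "beta", file, i)
  state_profile(costs, qw, unrelated_addon = addon)
}

#' Load a validated parameter set from a bundle directory
#'
#' @param path bundle directory (see [default_bundle()] for the packaged
#'   base case).
#' @param dog_type `"physical_service"` or `"diabetes_alert"`.
#' @param overrides optional named list of settings overrides applied on
#'   top of `settings.cfg` (e.g. `list(discount_rate = 0)`).
#' @return a [parameter_set()].
#' @export
load_parameter_set <- function(path, dog_type = dog_types(), overrides = NULL) {
  dog_type <- match.arg(dog_type)
  chk(dir.exists(path), "load_parameter_set: no such bundle directory '", path, "'")
  f <- function(name) {
    p <- file.path(path, name)
    chk(file.exists(p), "load_parameter_set: bundle is missing '", name, "'")
    p
  }
  raw_settings <- read_cfg(f("settings.cfg"))
  if (!is.null(overrides)) raw_settings[names(overrides)] <- overrides
  currency <- raw_settings$currency %||% "USD"
  chk(currency %in% c("USD", "SEK"), "settings.cfg: currency must be USD or SEK")
  sek_per_usd <- raw_settings$sek_per_usd %||% 8.538
  usd_scale <- if (currency == "SEK") convert_currency(1, sek_per_usd) else 1
  grid <- seq(raw_settings$threshold_min %||% 0,
              raw_settings$threshold_max %||% 150000,
              by = raw_settings$threshold_step %||% 2500)
  keys <- setdiff(intersect(names(raw_settings), names(formals(economic_settings))),
                  c("sek_per_usd", "threshold_grid"))
  settings <- do.call(economic_settings,
                      c(raw_settings[keys], list(sek_per_usd = sek_per_usd,
                                                 threshold_grid = grid)))

  costs <- read_csv_strict(f(paste0("costs_", dog_type, ".csv")))
  chk(all(c("category", "companion", "certified") %in% names(costs)),
      "'costs_", dog_type, ".csv' must have columns category, companion, certified")
  profiles <- list(companion = profile_from_costs(costs, "companion",
                                                  paste0("costs_", dog_type, ".csv"),
                                                  usd_scale),
                   certified = profile_from_costs(costs, "certified",
                                                  paste0("costs_", dog_type, ".csv"),
                                                  usd_scale))
  if ("retired" %in% names(costs) && all(is.finite(costs$retired)))
    profiles$retired_or_decert <- profile_from_costs(costs, "retired",
                                                     paste0("costs_", dog_type, ".csv"),
                                                     usd_scale)

  dc <- read_csv_strict(f("dog_costs.csv"))
  tot_rows <- dc$component == "printed_total"
  totals <- NULL
  if (any(tot_rows)) {
    tt <- dc[tot_rows, ]
    totals <- rbind(year1 = c(tt$companion[tt$band == "year1"],
                              tt$certified[tt$band == "year1"]),
                    year2 = c(tt$companion[tt$band == "year2"],
                              tt$certified[tt$band == "year2"]),
                    subsequent = c(tt$companion[tt$band == "subsequent"],
                                   tt$certified[tt$band == "subsequent"])) * usd_scale
  }
  comp <- dc[!tot_rows, ]
  comp$companion <- comp$companion * usd_scale
  comp$certified <- comp$certified * usd_scale
  dog_costs <- dog_cost_schedule(comp, totals)

  tr <- read_cfg(f("transitions.cfg"))
  transitions <- transition_inputs(
    p_pass_minor = tr$p_pass_minor %||% 0.9,
    p_pass_major = tr$p_pass_major %||% 0.9,
    p_pass_exam = tr$p_pass_exam %||% 0.9,
    p_annual_decert = tr$p_annual_decert %||% 0.02,
    owner_mortality = read_csv_strict(f("owner_lifetable.csv")),
    dog_mortality = read_csv_strict(f("dog_lifetable.csv")))

  ps <- parameter_set(dog_type, profiles, dog_costs, transitions, settings)
  if (settings$perspective != "societal")
    ps <- apply_perspective(ps, settings$perspective)
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter set back out as a bundle directory
#'
#' Inverse of [load_parameter_set()]: writing then re-loading reproduces
#' the parameter set (up to floating-point printing precision).
#'
#' @param ps a [parameter_set()].
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  chk(inherits(ps, "parameter_set"), "write_parameter_set: ps must be a parameter_set")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cats <- c(profile_categories(), "qaly_weight")
  cols <- c(companion = "companion", certified = "certified",
            retired = "retired_or_decert")
  tab <- data.frame(category = cats)
  for (cn in names(cols)) {
    p <- ps$profiles[[cols[[cn]]]]
    specs <- c(p$annual_cost, list(qaly_weight = p$qaly_weight))
    tab[[cn]] <- vapply(specs, function(s) s$point_value, numeric(1))
    tab[[paste0("alfa_", cn)]] <- vapply(specs, function(s) s$alfa, numeric(1))
    tab[[paste0("beta_", cn)]] <- vapply(specs, function(s) s$beta, numeric(1))
    tab[[paste0("unrelated_", cn)]] <- c(p$unrelated_addon, qaly_weight = 0)
  }
  utils::write.csv(tab, file.path(path, paste0("costs_", ps$dog_type, ".csv")),
                   row.names = FALSE)

  dc <- ps$dog_costs$components[, c("component", "band", "companion",
                                    "certified", "alfa", "beta")]
  tot <- data.frame(component = "printed_total",
                    band = rownames(ps$dog_costs$totals),
                    companion = ps$dog_costs$totals[, "companion"],
                    certified = ps$dog_costs$totals[, "certified"],
                    alfa = NA_real_, beta = NA_real_)
  utils::write.csv(rbind(dc, tot), file.path(path, "dog_costs.csv"),
                   row.names = FALSE)

  tr <- ps$transitions
  yaml::write_yaml(list(p_pass_minor = tr$p_pass_minor,
                        p_pass_major = tr$p_pass_major,
                        p_pass_exam = tr$p_pass_exam,
                        p_annual_decert = tr$p_annual_decert),
                   file.path(path, "transitions.cfg"))
  utils::write.csv(tr$owner_mortality[, c("age", "q_annual")],
                   file.path(path, "owner_lifetable.csv"), row.names = FALSE)
  utils::write.csv(tr$dog_mortality[, c("dog_age", "q_annual")],
                   file.path(path, "dog_lifetable.csv"), row.names = FALSE)

  s <- ps$settings
  yaml::write_yaml(list(currency = "USD",
                        discount_rate = s$discount_rate,
                        horizon_years = s$horizon_years,
                        owner_start_age = s$owner_start_age,
                        dog_start_age = s$dog_start_age,
                        dog_retirement_age = s$dog_retirement_age,
                        perspective = s$perspective,
                        sek_per_usd = s$sek_per_usd,
                        threshold_min = min(s$threshold_grid),
                        threshold_max = max(s$threshold_grid),
                        threshold_step = if (length(s$threshold_grid) > 1)
                          diff(s$threshold_grid)[1] else 2500,
                        rng_seed = s$rng_seed,
                        psa_anchor = s$psa_anchor,
                        benefit_start_cycle = s$benefit_start_cycle,
                        retired_cost_growth = s$retired_cost_growth,
                        retired_qaly_decay = s$retired_qaly_decay,
                        include_unrelated = s$include_unrelated),
                   file.path(path, "settings.cfg"))
  invisible(path)
}

#' Published headline results shipped for worked-example checks
#'
#' Returns the published 10-year results as data frames:
#' `"headline"` gives per-arm discounted total cost (USD) and QALYs per
#' dog type; `"decomposition"` gives the per-category 10-year cost
#' totals per arm with the published difference column. These are
#' *outputs* of the original analysis, shipped only so that
#' incremental-assembly arithmetic can be checked against print; the
#' model never reads them.
#'
#' @param which `"headline"` or `"decomposition"`.
#' @return a data frame.
#' @export
reported_results <- function(which = c("headline", "decomposition")) {
  which <- match.arg(which)
  f <- switch(which, headline = "headline_totals.csv",
              decomposition = "cost_decomposition.csv")
  read_csv_strict(system.file("extdata", "reported", f,
                              package = "dogcea", mustWork = TRUE))
}
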