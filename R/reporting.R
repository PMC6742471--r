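# File-producing entry points (also served by the thin command-line
# front-end in inst/exec/dogcea). Each writes its outputs plus a YAML
# run manifest sufficient to reproduce the run: command, bundle path
# and per-file checksums, seed, package version, timestamp, outputs.
# Numeric CSVs keep full precision; rounding happens only in printed
# summaries.

write_manifest <- function(command, bundle, seed, out_dir, outputs) {
  files <- list.files(bundle, full.names = TRUE)
  manifest <- list(command = command,
                   bundle = normalizePath(bundle),
                   bundle_md5 = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("dogcea")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   outputs = outputs)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}

warn_assumptions <- function(ps) {
  t <- ps$transitions
  warning(sprintf(paste0("assumed (unpublished) probabilities in use: ",
                         "p_pass_minor=%.2f, p_pass_major=%.2f, p_pass_exam=%.2f, ",
                         "p_annual_decert=%.2f"),
                  t$p_pass_minor, t$p_pass_major, t$p_pass_exam,
                  t$p_annual_decert), call. = FALSE)
  s <- ps$settings
  if (s$retired_cost_growth != 1 || s$retired_qaly_decay != 1)
    warning(sprintf("assumed retired-state drift in use: cost growth %.2f, QALY decay %.2f",
                    s$retired_cost_growth, s$retired_qaly_decay), call. = FALSE)
}

#' Run the base-case model and write its tables
#'
#' Writes the per-category cost decomposition, the headline
#' cost-effectiveness table, both cycle-by-cycle trace CSVs, and a run
#' manifest.
#'
#' @param bundle parameter-bundle directory.
#' @param dog_type `"physical_service"` or `"diabetes_alert"`.
#' @param perspective optional perspective override.
#' @param out output directory (created if needed).
#' @param overrides optional settings overrides.
#' @return the `dog_cea` fit, invisibly.
#' @export
cea_run <- function(bundle = default_bundle(), dog_type = dog_types(),
                    perspective = NULL, out = ".", overrides = NULL) {
  dog_type <- match.arg(dog_type)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ps <- load_parameter_set(bundle, dog_type, overrides = overrides)
  warn_assumptions(ps)
  fit <- dog_cea(ps, perspective = perspective)
  outputs <- c("cost_decomposition.csv", "ce_table.csv",
               "trace_certified.csv", "trace_companion.csv")
  utils::write.csv(cost_decomposition(fit),
                   file.path(out, outputs[1]), row.names = FALSE)
  utils::write.csv(ce_table(fit), file.path(out, outputs[2]), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$traces$certified_track),
                   file.path(out, outputs[3]), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$traces$companion_track),
                   file.path(out, outputs[4]), row.names = FALSE)
  write_manifest(paste("run", dog_type), bundle, ps$settings$rng_seed, out,
                 as.list(outputs))
  invisible(fit)
}

#' Run the probabilistic sensitivity analysis and write its outputs
#'
#' Writes the cost-effectiveness plane draws, the acceptability curve,
#' a one-row summary (probability of cost saving / QALY gain and
#' quadrant proportions) and a run manifest.
#'
#' @inheritParams cea_run
#' @param n number of simulations.
#' @param seed RNG seed (defaults to the bundle's `rng_seed`).
#' @return the `dog_cea_psa` object, invisibly.
#' @export
cea_psa <- function(bundle = default_bundle(), dog_type = dog_types(),
                    n = 10000L, seed = NULL, out = ".", overrides = NULL) {
  dog_type <- match.arg(dog_type)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ps <- load_parameter_set(bundle, dog_type, overrides = overrides)
  warn_assumptions(ps)
  psa <- run_psa(ps, n = n, seed = seed)
  outputs <- c("ce_plane.csv", "ceac.csv", "psa_summary.csv")
  utils::write.csv(psa$draws, file.path(out, outputs[1]), row.names = FALSE)
  utils::write.csv(psa$ceac, file.path(out, outputs[2]), row.names = FALSE)
  utils::write.csv(data.frame(n_draws = psa$n_draws, seed = psa$seed,
                              p_cost_saving = psa$p_cost_saving,
                              p_qaly_gain = psa$p_qaly_gain,
                              t(psa$quadrants)),
                   file.path(out, outputs[3]), row.names = FALSE)
  write_manifest(paste("psa", dog_type, n), bundle, psa$seed, out,
                 as.list(outputs))
  invisible(psa)
}

#' Run the deterministic sensitivity analysis and write its table
#'
#' @inheritParams cea_run
#' @param specs scenario list, by default [builtin_scenarios()].
#' @return the scenario results data frame, invisibly.
#' @export
cea_dsa <- function(bundle = default_bundle(), dog_type = dog_types(),
                    out = ".", specs = builtin_scenarios(), overrides = NULL) {
  dog_type <- match.arg(dog_type)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ps <- load_parameter_set(bundle, dog_type, overrides = overrides)
  warn_assumptions(ps)
  res <- run_dsa(ps, specs)
  utils::write.csv(as.data.frame(res), file.path(out, "dsa_results.csv"),
                   row.names = FALSE)
  write_manifest(paste("dsa", dog_type), bundle, ps$settings$rng_seed, out,
                 list("dsa_results.csv"))
  invisible(res)
}

#' Generate synthetic inputs and write them as a bundle plus study CSV
#'
#' Writes the synthetic owner and dog life tables in the bundle dialect
#' and a tidy pseudo-study sample (`subject`, `arm`, `category`,
#' `quarterly_value`), plus a run manifest.
#'
#' @inheritParams cea_run
#' @param n_subjects pseudo-study size.
#' @param seed RNG seed.
#' @return the pseudo-study data frame, invisibly.
#' @export
cea_simulate <- function(bundle = default_bundle(), dog_type = dog_types(),
                         n_subjects = 100L, seed = 1L, out = ".") {
  dog_type <- match.arg(dog_type)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ps <- load_parameter_set(bundle, dog_type)
  study <- simulate_pseudo_study(ps, n_subjects, seed = seed)
  tidy <- stats::reshape(study, direction = "long",
                         varying = c(profile_categories(), "utility"),
                         v.names = "quarterly_value",
                         times = c(profile_categories(), "utility"),
                         timevar = "category", idvar = c("subject_id", "arm"))
  tidy <- tidy[order(tidy$subject_id, tidy$arm, tidy$category),
               c("subject_id", "arm", "category", "quarterly_value")]
  names(tidy)[1] <- "subject"
  outputs <- c("pseudo_study.csv", "owner_lifetable.csv", "dog_lifetable.csv")
  utils::write.csv(tidy, file.path(out, outputs[1]), row.names = FALSE)
  utils::write.csv(make_owner_lifetable(),
                   file.path(out, outputs[2]), row.names = FALSE)
  utils::write.csv(make_dog_lifetable(0.20),
                   file.path(out, outputs[3]), row.names = FALSE)
  write_manifest(paste("simulate", dog_type, n_subjects), bundle, seed, out,
                 as.list(outputs))
  invisible(study)
}
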