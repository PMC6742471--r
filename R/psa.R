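# Probabilistic sensitivity analysis.
#
# Sampled parameters, in the fixed canonical order used for every run
# (parameter-major: all n draws of the first parameter, then all n of
# the second, ... from one shared RNG stream, so seeds are portable):
#   for each state in (companion, certified, retired_or_decert):
#     healthcare, municipal, informal_care, productivity_loss costs
#     (gamma), then the state's QALY weight (beta);
#   then each distinct dog-cost component carrying gamma parameters, in
#   the order they appear in the schedule (purchase, annual upkeep).
# Point specs pass through unsampled. The dog-dead state mirrors the
# sampled companion profile; transition and test probabilities are not
# sampled (the source analysis attaches distributions only to costs and
# QALY weights).

psa_param_table <- function(ps) {
  out <- list()
  for (st in c("companion", "certified", "retired_or_decert")) {
    p <- ps$profiles[[st]]
    for (ct in profile_categories())
      out[[paste(st, ct, sep = ".")]] <- p$annual_cost[[ct]]
    out[[paste(st, "qaly_weight", sep = ".")]] <- p$qaly_weight
  }
  comp <- ps$dog_costs$components
  seen <- character(0)
  for (i in seq_len(nrow(comp))) {
    nm <- comp$component[i]
    if (nm %in% seen) next
    if (is.finite(comp$alfa[i]) && is.finite(comp$beta[i])) {
      out[[paste("dog", nm, sep = ".")]] <-
        dist_spec("gamma", comp$alfa[i], comp$beta[i], comp$certified[i])
      seen <- c(seen, nm)
    }
  }
  out
}

# apply a named draw vector to the numeric accrual inputs; dog-cost band
# totals are shifted by the sampled component deltas so the published
# band totals stay the anchor.
apply_draw_values <- function(vals, draw, ps) {
  for (nm in names(draw)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    scope <- parts[1]; field <- parts[2]
    if (scope == "dog") next
    key <- switch(scope, companion = "companion", certified = "certified",
                  retired_or_decert = "retired")
    if (field == "qaly_weight") {
      vals$w_of[[key]] <- draw[[nm]]
      if (key == "companion") vals$w_of[["dog_dead"]] <- draw[[nm]]
    } else {
      vals$cost_of[[key]][[field]] <- draw[[nm]]
      if (key == "companion") vals$cost_of$dog_dead[[field]] <- draw[[nm]]
    }
  }
  comp <- ps$dog_costs$components
  dog_draws <- grep("^dog\\.", names(draw), value = TRUE)
  if (length(dog_draws)) {
    shift <- matrix(0, 3, 2, dimnames = dimnames(ps$dog_costs$totals))
    for (nm in dog_draws) {
      cname <- sub("^dog\\.", "", nm)
      rows <- which(comp$component == cname)
      for (i in rows) {
        b <- comp$band[i]
        if (comp$companion[i] > 0)
          shift[b, "companion"] <- shift[b, "companion"] + draw[[nm]] - comp$companion[i]
        if (comp$certified[i] > 0)
          shift[b, "certified"] <- shift[b, "certified"] + draw[[nm]] - comp$certified[i]
      }
    }
    vals$totals <- pmax(vals$totals + shift, 0)
  }
  vals
}

#' Draw one probabilistic parameter set
#'
#' Samples every gamma/beta-distributed cost and QALY weight once from
#' the current RNG stream (see [sample_dist()] for the anchoring rule
#' chosen by `settings$psa_anchor`) and returns a parameter set with the
#' base-case values replaced by the draw. Point specs pass through
#' unchanged; draws are independent across parameters.
#'
#' @param ps a [parameter_set()].
#' @return a [parameter_set()] carrying the drawn values.
#' @export
sample_parameter_set <- function(ps) {
  chk(inherits(ps, "parameter_set"), "sample_parameter_set: ps must be a parameter_set")
  specs <- psa_param_table(ps)
  anchor <- ps$settings$psa_anchor
  draw <- vapply(names(specs), function(nm)
    sample_dist(specs[[nm]], 1L, anchor = anchor, label = nm), numeric(1))
  out <- ps
  for (nm in names(draw)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    scope <- parts[1]; field <- parts[2]
    if (scope == "dog") {
      rows <- which(out$dog_costs$components$component == field)
      for (i in rows) {
        delta_c <- draw[[nm]] - out$dog_costs$components$companion[i]
        delta_t <- draw[[nm]] - out$dog_costs$components$certified[i]
        b <- out$dog_costs$components$band[i]
        if (out$dog_costs$components$companion[i] > 0) {
          out$dog_costs$components$companion[i] <- draw[[nm]]
          out$dog_costs$totals[b, "companion"] <-
            max(0, out$dog_costs$totals[b, "companion"] + delta_c)
        }
        if (out$dog_costs$components$certified[i] > 0) {
          out$dog_costs$components$certified[i] <- draw[[nm]]
          out$dog_costs$totals[b, "certified"] <-
            max(0, out$dog_costs$totals[b, "certified"] + delta_t)
        }
      }
    } else if (field == "qaly_weight") {
      out$profiles[[scope]]$qaly_weight$point_value <- draw[[nm]]
    } else {
      out$profiles[[scope]]$annual_cost[[field]]$point_value <- draw[[nm]]
    }
  }
  out$profiles$dog_dead <- out$profiles$companion
  out
}

#' Probabilistic sensitivity analysis
#'
#' Repeatedly samples the cost and QALY-weight distributions, reruns
#' both arms on each draw (state-transition structure and mortality are
#' held fixed), and summarises decision uncertainty as cost-effectiveness
#' plane draws, quadrant proportions and an acceptability curve over the
#' settings' willingness-to-pay grid. Reproducible for a fixed seed.
#'
#' @param ps a [parameter_set()].
#' @param n number of simulations (the source analysis used 10,000).
#' @param seed RNG seed; defaults to `settings$rng_seed`.
#' @return an object of class `"dog_cea_psa"` with `draws` (data frame
#'   `draw_index`, `delta_cost`, `delta_qaly`), `n_draws`,
#'   `p_cost_saving`, `p_qaly_gain`, `quadrants`, `ceac`, `seed`.
#' @export
run_psa <- function(ps, n = 10000L, seed = NULL) {
  chk(inherits(ps, "parameter_set"), "run_psa: ps must be a parameter_set")
  chk(is.numeric(n) && n >= 1, "run_psa: n must be >= 1")
  n <- as.integer(n)
  seed <- as.integer(seed %||% ps$settings$rng_seed)
  specs <- psa_param_table(ps)
  anchor <- ps$settings$psa_anchor
  set.seed(seed)
  # parameter-major: one block of n draws per parameter
  draw_mat <- vapply(names(specs), function(nm)
    sample_dist(specs[[nm]], n, anchor = anchor, label = nm), numeric(n))
  if (n == 1L) draw_mat <- matrix(draw_mat, nrow = 1L,
                                  dimnames = list(NULL, names(specs)))
  occ_cert <- markov_occupancy(ps, "certified_track")
  occ_comp <- markov_occupancy(ps, "companion_track")
  base_vals <- trace_values(ps)
  s <- ps$settings
  dc <- de <- numeric(n)
  for (i in seq_len(n)) {
    vals <- apply_draw_values(base_vals, draw_mat[i, ], ps)
    a_cert <- accrue_trace(occ_cert, vals, s, "certified_track")
    a_comp <- accrue_trace(occ_comp, vals, s, "companion_track")
    dc[i] <- sum(a_cert$cycle_costs) - sum(a_comp$cycle_costs)
    de[i] <- sum(a_cert$cycle_qalys) - sum(a_comp$cycle_qalys)
  }
  if (any(!is.finite(dc)) || any(!is.finite(de)))
    stop("run_psa: non-finite result at draw ",
         which(!is.finite(dc) | !is.finite(de))[1], call. = FALSE)
  draws <- data.frame(draw_index = seq_len(n), delta_cost = dc, delta_qaly = de)
  quadrants <- c(dominant = mean(dc < 0 & de > 0),
                 tradeoff_ne = mean(dc >= 0 & de > 0),
                 dominated = mean(dc >= 0 & de <= 0),
                 tradeoff_sw = mean(dc < 0 & de <= 0))
  structure(list(draws = draws, n_draws = n,
                 p_cost_saving = mean(dc < 0),
                 p_qaly_gain = mean(de > 0),
                 quadrants = quadrants,
                 ceac = compute_ceac(draws, s$threshold_grid),
                 seed = seed, dog_type = ps$dog_type),
            class = "dog_cea_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold `lambda`, the fraction of draws
#' with positive net monetary benefit `lambda * delta_qaly - delta_cost`
#' (a tie counts as not cost-effective). At `lambda = 0` this equals the
#' probability of cost saving; as `lambda` grows it approaches the
#' probability of a QALY gain.
#'
#' @param draws data frame with columns `delta_cost`, `delta_qaly`.
#' @param thresholds numeric vector of thresholds (USD/QALY).
#' @return data frame `threshold`, `probability`.
#' @export
compute_ceac <- function(draws, thresholds) {
  chk(is.data.frame(draws) && nrow(draws) >= 1,
      "compute_ceac: draws must be a non-empty data frame")
  chk(all(c("delta_cost", "delta_qaly") %in% names(draws)),
      "compute_ceac: draws needs delta_cost and delta_qaly columns")
  prob <- vapply(thresholds, function(lam)
    mean(lam * draws$delta_qaly - draws$delta_cost > 0), numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Probabilistic sensitivity analysis of a fitted model
#'
#' `simulate()` on a `dog_cea` fit runs [run_psa()] on its parameter
#' set.
#'
#' @param object a `dog_cea` fit.
#' @param nsim number of simulations.
#' @param seed RNG seed (defaults to the settings' seed).
#' @param ... unused.
#' @return a `dog_cea_psa` object.
#' @examples
#' fit <- dog_cea(dog_type = "diabetes_alert")
#' psa <- simulate(fit, nsim = 100, seed = 7)
#' psa
#' @export
simulate.dog_cea <- function(object, nsim = 10000L, seed = NULL, ...) {
  run_psa(object$params, n = nsim, seed = seed)
}

#' @export
print.dog_cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %s, %d draws (seed %d)\n",
              x$dog_type, x$n_draws, x$seed))
  cat(sprintf("  P(cost saving)       = %.3f\n", x$p_cost_saving))
  cat(sprintf("  P(QALY gain)         = %.3f\n", x$p_qaly_gain))
  cat(sprintf("  P(dominant)          = %.3f\n", x$quadrants[["dominant"]]))
  mid <- x$ceac[which.min(abs(x$ceac$threshold - 50000)), ]
  cat(sprintf("  P(cost-effective at %d USD/QALY) = %.3f\n",
              mid$threshold, mid$probability))
  invisible(x)
}

#' Plot PSA results
#'
#' `which = "plane"` draws the cost-effectiveness plane (incremental
#' QALYs vs incremental cost per draw); `which = "ceac"` draws the
#' acceptability curve; `"both"` draws the two side by side.
#'
#' @param x a `dog_cea_psa` object.
#' @param which `"plane"`, `"ceac"` or `"both"`.
#' @param ... passed on to the plotting functions.
#' @return `x`, invisibly.
#' @export
plot.dog_cea_psa <- function(x, which = c("both", "plane", "ceac"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "plane")) {
    graphics::plot(x$draws$delta_qaly, x$draws$delta_cost, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.3),
                   xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, lty = 2)
  }
  if (which %in% c("both", "ceac")) {
    graphics::plot(x$ceac$threshold, x$ceac$probability, type = "l", lwd = 2,
                   ylim = c(0, 1), xlab = "Willingness to pay (USD/QALY)",
                   ylab = "P(cost-effective)",
                   main = "Acceptability curve", ...)
  }
  invisible(x)
}
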