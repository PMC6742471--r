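#' Fit the certified-dog cost-effectiveness model
#'
#' The central entry point: runs both arms of the decision-analytic
#' model — a certified-dog track (year-1 decision tree with suitability
#' tests, training and final exam, then a nine-year Markov cohort over
#' the states certified / retired / not certified / dog dead / owner
#' dead) and a regular-companion-dog track — and compares discounted
#' costs and QALYs.
#'
#' @param params a [parameter_set()], or a bundle directory path to load
#'   with [load_parameter_set()]. Defaults to the packaged base case.
#' @param dog_type dog type used when `params` is a path.
#' @param perspective optional perspective override, see
#'   [apply_perspective()].
#' @param overrides optional settings overrides passed to
#'   [load_parameter_set()] (ignored when `params` is a parameter set).
#' @return an object of class `"dog_cea"`: the two `cohort_trace`s, the
#'   `ce_result`, and the parameter set used. Methods: `print`,
#'   `summary`, `coef`, `plot`, `simulate` (probabilistic sensitivity
#'   analysis), `as.data.frame`.
#' @examples
#' fit <- dog_cea(dog_type = "physical_service")
#' fit
#' summary(fit)
#' @export
dog_cea <- function(params = default_bundle(), dog_type = dog_types(),
                    perspective = NULL, overrides = NULL) {
  if (is.character(params)) {
    dog_type <- match.arg(dog_type)
    params <- load_parameter_set(params, dog_type, overrides = overrides)
  }
  chk(inherits(params, "parameter_set"), "dog_cea: params must be a parameter_set or path")
  if (!is.null(perspective)) params <- apply_perspective(params, perspective)
  cert <- run_trace(params, "certified_track")
  comp <- run_trace(params, "companion_track")
  structure(list(params = params,
                 traces = list(certified_track = cert, companion_track = comp),
                 result = compare_arms(cert, comp)),
            class = "dog_cea")
}

#' @export
print.dog_cea <- function(x, ...) {
  s <- x$params$settings
  cat(sprintf("Certified-dog cost-effectiveness model (%s)\n", x$params$dog_type))
  cat(sprintf("  %d-year horizon, %.0f%% discount, %s perspective\n",
              s$horizon_years, 100 * s$discount_rate, s$perspective))
  print(x$result)
  invisible(x)
}

#' Base-case parameter vector of a fitted model
#'
#' Returns the point values the deterministic run used: per-state annual
#' costs by category, per-state utility weights, dog-cost band totals
#' and transition probabilities.
#' @param object a `dog_cea` fit.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.dog_cea <- function(object, ...) {
  ps <- object$params
  out <- c()
  for (st in c("companion", "certified", "retired_or_decert")) {
    p <- ps$profiles[[st]]
    v <- vapply(p$annual_cost, function(d) d$point_value, numeric(1))
    names(v) <- paste(st, names(v), sep = ".")
    out <- c(out, v, stats::setNames(p$qaly_weight$point_value,
                                     paste0(st, ".qaly_weight")))
  }
  tot <- ps$dog_costs$totals
  out <- c(out,
           stats::setNames(as.vector(tot),
                           paste("dog", rep(rownames(tot), ncol(tot)),
                                 rep(colnames(tot), each = nrow(tot)), sep = ".")),
           p_pass_minor = ps$transitions$p_pass_minor,
           p_pass_major = ps$transitions$p_pass_major,
           p_pass_exam = ps$transitions$p_pass_exam,
           p_annual_decert = ps$transitions$p_annual_decert)
  out
}

#' Ten-year cost decomposition by category
#'
#' Discounted total cost per category and arm over the horizon, with
#' the certified-minus-companion difference column — the shape of the
#' published category table.
#'
#' @param x a `dog_cea` fit.
#' @return data frame with columns `category`, `certified`, `companion`,
#'   `difference`, closed by a `total` row.
#' @export
cost_decomposition <- function(x) {
  chk(inherits(x, "dog_cea"), "cost_decomposition: x must be a dog_cea fit")
  cert <- x$traces$certified_track$cost_by_category
  comp <- x$traces$companion_track$cost_by_category
  out <- data.frame(category = c(cost_categories(), "total"),
                    certified = c(cert, sum(cert)),
                    companion = c(comp, sum(comp)),
                    row.names = NULL)
  out$difference <- out$certified - out$companion
  out
}

#' Headline cost-effectiveness table
#'
#' @param x a `dog_cea` fit.
#' @return data frame with one row per arm (discounted cost, QALYs) and
#'   the incremental columns, plus the ICER label.
#' @export
ce_table <- function(x) {
  chk(inherits(x, "dog_cea"), "ce_table: x must be a dog_cea fit")
  r <- x$result
  data.frame(arm = c("certified", "companion"),
             cost_usd = as.numeric(r$cost_by_arm),
             delta_cost = c(r$delta_cost, NA),
             qaly = as.numeric(r$qaly_by_arm),
             delta_qaly = c(r$delta_qaly, NA),
             icer = c(r$icer_label, NA))
}

#' @export
summary.dog_cea <- function(object, ...) {
  structure(list(dog_type = object$params$dog_type,
                 settings = object$params$settings,
                 decomposition = cost_decomposition(object),
                 ce = ce_table(object),
                 result = object$result),
            class = "summary.dog_cea")
}

#' @export
print.summary.dog_cea <- function(x, ...) {
  cat(sprintf("=== %s vs regular companion dog (%d-year horizon) ===\n",
              x$dog_type, x$settings$horizon_years))
  cat("\nDiscounted costs by category (USD):\n")
  d <- x$decomposition
  d[-1] <- lapply(d[-1], round)
  print(d, row.names = FALSE)
  cat("\nCost effectiveness:\n")
  ce <- x$ce
  ce$cost_usd <- round(ce$cost_usd)
  ce$delta_cost <- round(ce$delta_cost)
  ce$qaly <- round(ce$qaly, 2)
  ce$delta_qaly <- round(ce$delta_qaly, 2)
  print(ce, row.names = FALSE)
  invisible(x)
}

#' Plot a fitted model
#'
#' `which = "trace"` shows state occupancy over the model cycles for the
#' certified track; `which = "costs"` shows the per-category discounted
#' cost totals for both arms.
#'
#' @param x a `dog_cea` fit.
#' @param which `"trace"` or `"costs"`.
#' @param ... passed to the underlying plotting functions.
#' @return `x`, invisibly.
#' @export
plot.dog_cea <- function(x, which = c("trace", "costs"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    occ <- x$traces$certified_track$occupancy
    graphics::matplot(seq_len(nrow(occ)) - 1L, occ, type = "l", lty = 1,
                      lwd = 2, col = seq_len(ncol(occ)),
                      xlab = "Model cycle (year)", ylab = "Occupancy",
                      main = paste("Certified-track cohort trace:", x$params$dog_type),
                      ...)
    graphics::legend("right", legend = colnames(occ), lty = 1, lwd = 2,
                     col = seq_len(ncol(occ)), bty = "n", cex = 0.8)
  } else {
    d <- cost_decomposition(x)
    d <- d[d$category != "total", ]
    graphics::barplot(t(as.matrix(d[, c("certified", "companion")])),
                      beside = TRUE, names.arg = d$category,
                      legend.text = c("certified", "companion"),
                      ylab = "Discounted 10-year cost (USD)",
                      main = paste("Cost decomposition:", x$params$dog_type), ...)
  }
  invisible(x)
}

#' @export
as.data.frame.dog_cea <- function(x, ...) {
  rbind(cbind(arm = "certified_track",
              as.data.frame(x$traces$certified_track)),
        cbind(arm = "companion_track",
              as.data.frame(x$traces$companion_track)))
}
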