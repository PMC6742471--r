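#' Distribution specification for a model input
#'
#' A `dist_spec` couples a base-case (point) value with the sampling
#' distribution used in probabilistic sensitivity analysis. Costs are
#' gamma distributed with `(alfa, beta)` read as (shape, scale); utility
#' weights are beta distributed with `(alfa, beta)` as the standard shape
#' parameters. A `point` spec is never sampled.
#'
#' The printed `(alfa, beta)` pairs in the source tables do not, in
#' general, have a mean equal to the printed base-case value, so by
#' default sampling is *moment matched*: the distribution is re-anchored
#' so that its mean equals `point_value` while keeping its relative
#' spread (gamma: shape kept, scale rescaled; beta: precision
#' `alfa + beta` kept, mean set to the point value). Set
#' `psa_anchor = "printed_params"` in the settings to sample the printed
#' pair verbatim.
#'
#' @param family one of `"gamma"`, `"beta"`, `"point"`.
#' @param alfa shape-like parameter (`> 0` for gamma/beta; `NA` for point).
#' @param beta second parameter (scale for gamma, second shape for beta).
#' @param point_value base-case value in USD (gamma/point) or on the
#'   utility scale (beta; must lie in `[-0.594, 1]`, the tariff range).
#' @return an object of class `"dist_spec"`.
#' @examples
#' dist_spec("gamma", 27, 704, 8928)
#' dist_spec("beta", 29, 53, 0.351)
#' dist_spec("point", point_value = 0.309)
#' @export
dist_spec <- function(family = c("gamma", "beta", "point"),
                      alfa = NA_real_, beta = NA_real_, point_value) {
  family <- match.arg(family)
  stopifnot(is.numeric(point_value), length(point_value) == 1L, is.finite(point_value))
  if (family %in% c("gamma", "beta")) {
    if (!is.finite(alfa) || !is.finite(beta) || alfa <= 0 || beta <= 0)
      stop("dist_spec: family '", family, "' requires alfa > 0 and beta > 0", call. = FALSE)
  }
  if (family == "gamma" && point_value < 0)
    stop("dist_spec: gamma-family point_value must be >= 0", call. = FALSE)
  if (family == "beta" && (point_value < UTILITY_MIN || point_value > 1))
    stop("dist_spec: beta-family point_value must lie in [", UTILITY_MIN, ", 1]",
         call. = FALSE)
  structure(list(family = family, alfa = as.numeric(alfa),
                 beta = as.numeric(beta), point_value = as.numeric(point_value)),
            class = "dist_spec")
}

# Lower bound of the EQ-5D UK tariff; utilities cannot fall below it.
UTILITY_MIN <- -0.594

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' @export
print.dist_spec <- function(x, ...) {
  if (x$family == "point") {
    cat(sprintf("<dist_spec point: %g>\n", x$point_value))
  } else {
    cat(sprintf("<dist_spec %s(alfa = %g, beta = %g), base case %g>\n",
                x$family, x$alfa, x$beta, x$point_value))
  }
  invisible(x)
}

#' Draw from a distribution specification
#'
#' Samples `n` values from the spec using the current RNG stream. With
#' `anchor = "moment_matched"` (the default) the distribution is
#' re-centred so its mean equals the base-case `point_value`; with
#' `"printed_params"` the stored `(alfa, beta)` pair is used unchanged.
#' Point specs return the base-case value for every draw.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @param anchor `"moment_matched"` or `"printed_params"`.
#' @param label parameter name used in error messages.
#' @return numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1L,
                        anchor = c("moment_matched", "printed_params"),
                        label = "parameter") {
  anchor <- match.arg(anchor)
  if (!is_dist_spec(spec))
    stop("sample_dist: '", label, "' is not a dist_spec", call. = FALSE)
  if (spec$family == "point") return(rep(spec$point_value, n))
  if (!is.finite(spec$alfa) || !is.finite(spec$beta) || spec$alfa <= 0 || spec$beta <= 0)
    stop("sample_dist: invalid (alfa, beta) for '", label, "'", call. = FALSE)
  if (spec$family == "gamma") {
    scale <- if (anchor == "moment_matched") spec$point_value / spec$alfa else spec$beta
    stats::rgamma(n, shape = spec$alfa, scale = scale)
  } else {
    if (anchor == "moment_matched") {
      # keep the precision alfa + beta, move the mean to the base case
      m <- spec$point_value
      if (m <= 0 || m >= 1)
        stop("sample_dist: cannot moment-match beta for '", label,
             "' with base-case value ", m, " outside (0, 1)", call. = FALSE)
      prec <- spec$alfa + spec$beta
      stats::rbeta(n, shape1 = m * prec, shape2 = (1 - m) * prec)
    } else {
      stats::rbeta(n, shape1 = spec$alfa, shape2 = spec$beta)
    }
  }
}
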