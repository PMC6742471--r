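# Synthetic-data generators: owner life tables, dog survival schedules
# calibrated to cumulative-mortality anchors, and individual-level
# pseudo-study samples with the gamma/beta structure of the cost and
# QALY tables — enabling parameter-recovery tests without any external
# data. These stand in for national life tables and veterinary
# mortality estimates, which are not redistributable; all packaged
# mortality inputs are synthetic and labelled as such.

#' Generate an owner life table
#'
#' Annual death probabilities over an age range, either constant or
#' Gompertz (`q(age) = level * exp(slope * (age - anchor_age))`, capped
#' at 1). The default anchors q(44) = 0.002 doubling every 10 years — a
#' plausible general-population magnitude for a middle-aged cohort. Any
#' real life table can replace the generated one through the bundle CSV
#' interface (columns `age`, `q_annual`).
#'
#' @param start_age,end_age age range covered (inclusive).
#' @param model `"gompertz"` or `"constant"`.
#' @param level annual death probability at `anchor_age` (constant
#'   model: at every age).
#' @param slope log-linear increase per year of age (gompertz only).
#' @param anchor_age age at which `q = level`.
#' @param jitter_sd optional lognormal jitter (sd on the log scale) for
#'   stress-testing; 0 keeps the table deterministic.
#' @param seed RNG seed, used only when `jitter_sd > 0`.
#' @return data frame `age`, `q_annual`.
#' @examples
#' lt <- make_owner_lifetable(40, 70)
#' stopifnot(all(diff(lt$q_annual) > 0))
#' @export
make_owner_lifetable <- function(start_age = 40L, end_age = 70L,
                                 model = c("gompertz", "constant"),
                                 level = 0.002, slope = log(2) / 10,
                                 anchor_age = 44L, jitter_sd = 0, seed = NULL) {
  model <- match.arg(model)
  chk(end_age >= start_age, "make_owner_lifetable: end_age must be >= start_age")
  chk(level >= 0 && level <= 1, "make_owner_lifetable: level must be in [0, 1]")
  age <- seq(start_age, end_age)
  q <- if (model == "constant") rep(level, length(age))
       else pmin(1, level * exp(slope * (age - anchor_age)))
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- pmin(1, q * exp(stats::rnorm(length(q), 0, jitter_sd)))
  }
  data.frame(age = age, q_annual = q)
}

# cumulative mortality from start_age through age 11 (inclusive)
cum_mortality_to_11 <- function(lifetable, start_age) {
  i <- lifetable$dog_age >= start_age & lifetable$dog_age <= 11
  1 - prod(1 - lifetable$q_annual[i])
}

#' Generate a dog life table calibrated to a cumulative-mortality anchor
#'
#' Builds an age-increasing baseline hazard
#' `q(a) = 0.02 * exp(0.35 * (a - start_age))` and scales it by a single
#' multiplier, solved by bisection to 1e-10, so that the cumulative
#' mortality from `start_age` through age 11 (inclusive) equals
#' `cum_mortality_at_11`. The short and long life-span scenarios use
#' anchors 0.30 and 0.10; the packaged base case uses the 0.20 midpoint.
#'
#' @param cum_mortality_at_11 target cumulative mortality, in (0, 1).
#' @param start_age first dog age covered (default 2).
#' @param end_age last dog age covered (default 13).
#' @param base_level,base_slope baseline hazard shape parameters.
#' @return data frame `dog_age`, `q_annual`.
#' @examples
#' lt <- make_dog_lifetable(0.30)
#' prod(1 - lt$q_annual[lt$dog_age <= 11])  # 0.70
#' @export
make_dog_lifetable <- function(cum_mortality_at_11, start_age = 2L,
                               end_age = 13L, base_level = 0.02,
                               base_slope = 0.35) {
  chk(is.numeric(cum_mortality_at_11) && cum_mortality_at_11 > 0 &&
        cum_mortality_at_11 < 1,
      "make_dog_lifetable: cum_mortality_at_11 must be in (0, 1)")
  chk(start_age <= 11, "make_dog_lifetable: start_age must be <= 11")
  chk(end_age >= 11, "make_dog_lifetable: end_age must be >= 11")
  age <- seq(start_age, end_age)
  q_base <- base_level * exp(base_slope * (age - start_age))
  cum_at <- function(m) {
    q <- pmin(1, m * q_base)
    1 - prod(1 - q[age <= 11])
  }
  lo <- 0; hi <- 1
  while (cum_at(hi) < cum_mortality_at_11) {
    hi <- hi * 2
    if (hi > 1e8) stop("make_dog_lifetable: target not attainable", call. = FALSE)
  }
  for (i in 1:200) { # bisection to ~1e-10 on the multiplier
    mid <- (lo + hi) / 2
    if (cum_at(mid) < cum_mortality_at_11) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  m <- (lo + hi) / 2
  data.frame(dog_age = age, q_annual = pmin(1, m * q_base))
}

#' Simulate an individual-level pseudo-study
#'
#' Emulates the pre-post design behind the cost and utility tables:
#' each subject contributes a baseline observation (regular companion
#' dog: quarterly costs drawn as one quarter of an annual draw from the
#' companion-state gamma distributions, utility from the companion
#' beta) and a follow-up observation (certified-state distributions).
#' Utilities are clipped to the EQ-5D tariff range; clips are counted
#' in the `clipped` attribute. Reproducible by seed.
#'
#' @param ps a [parameter_set()] supplying the distributions.
#' @param n_subjects number of subjects (`>= 1`).
#' @param seed RNG seed.
#' @return data frame with columns `subject_id`, `arm`
#'   (`baseline` / `followup`), one quarterly-cost column per category,
#'   and `utility`.
#' @export
simulate_pseudo_study <- function(ps, n_subjects, seed = NULL) {
  chk(inherits(ps, "parameter_set"), "simulate_pseudo_study: ps must be a parameter_set")
  chk(is.numeric(n_subjects) && n_subjects >= 1,
      "simulate_pseudo_study: n_subjects must be >= 1")
  n <- as.integer(n_subjects)
  if (!is.null(seed)) set.seed(seed)
  anchor <- ps$settings$psa_anchor
  arms <- c(baseline = "companion", followup = "certified")
  clipped <- 0L
  rows <- lapply(names(arms), function(arm) {
    p <- ps$profiles[[arms[[arm]]]]
    out <- data.frame(subject_id = seq_len(n), arm = arm)
    for (ct in profile_categories())
      out[[ct]] <- sample_dist(p$annual_cost[[ct]], n, anchor = anchor,
                               label = paste(arms[[arm]], ct, sep = ".")) / 4
    u <- sample_dist(p$qaly_weight, n, anchor = anchor,
                     label = paste0(arms[[arm]], ".qaly_weight"))
    clipped <<- clipped + sum(u < UTILITY_MIN | u > 1)
    out$utility <- pmin(1, pmax(UTILITY_MIN, u))
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "clipped") <- clipped
  out
}

mom_gamma <- function(m, v) {
  if (!is.finite(v) || v <= 0 || m <= 0) return(NULL)
  dist_spec("gamma", alfa = m^2 / v, beta = v / m, point_value = m)
}

mom_beta <- function(m, v) {
  if (!is.finite(v) || v <= 0 || m <= 0 || m >= 1 || v >= m * (1 - m)) return(NULL)
  common <- m * (1 - m) / v - 1
  dist_spec("beta", alfa = m * common, beta = (1 - m) * common, point_value = m)
}

#' Estimate state profiles from pseudo-study samples
#'
#' Annualises the quarterly costs (multiplied by four, as in the source
#' costing), takes per-arm means, and fits gamma (costs) and beta
#' (utility) distributions by the method of moments. Arms with
#' degenerate variance fall back to point specs with a warning.
#'
#' @param samples a data frame from [simulate_pseudo_study()].
#' @return list with [state_profile()]s `companion` (baseline arm) and
#'   `certified` (follow-up arm).
#' @export
estimate_parameters <- function(samples) {
  chk(is.data.frame(samples) && all(c("arm", "utility") %in% names(samples)),
      "estimate_parameters: malformed samples")
  arms <- c(companion = "baseline", certified = "followup")
  out <- lapply(arms, function(arm) {
    d <- samples[samples$arm == arm, ]
    chk(nrow(d) >= 2, "estimate_parameters: need >= 2 subjects per arm")
    costs <- list()
    for (ct in profile_categories()) {
      annual <- 4 * d[[ct]]
      spec <- mom_gamma(mean(annual), stats::var(annual))
      if (is.null(spec)) {
        warning("degenerate variance for ", arm, " ", ct,
                "; falling back to a point value", call. = FALSE)
        spec <- dist_spec("point", point_value = max(0, mean(annual)))
      }
      costs[[ct]] <- spec
    }
    u <- d$utility
    uspec <- mom_beta(mean(u), stats::var(u))
    if (is.null(uspec)) {
      warning("degenerate utility variance for ", arm,
              "; falling back to a point value", call. = FALSE)
      uspec <- dist_spec("point", point_value = min(1, max(UTILITY_MIN, mean(u))))
    }
    state_profile(costs, uspec)
  })
  names(out) <- names(arms)
  out
}
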