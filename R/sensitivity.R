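#' Define a one-way parameter perturbation
#'
#' Bounds default to +/- one standard deviation when one is supplied, else
#' +/- 20% of the base value, truncated to the parameter's valid domain.
#'
#' @param parameter Parameter name (a scalar field of the transition
#'   bundle, or `mean_los_days`/`dispersion` for the discharge schedule).
#' @param base Base (point) value.
#' @param sd Optional standard deviation; when given, bounds are
#'   `base +/- sd`.
#' @param rel Relative half-width used when `sd` is absent (default 0.2).
#' @param lower,upper Domain truncation bounds.
#' @return List of class `parameter_perturbation` with `low`/`high`.
#' @export
perturbation <- function(parameter, base, sd = NULL, rel = 0.2,
                         lower = -Inf, upper = Inf) {
  hw <- if (!is.null(sd)) sd else rel * abs(base)
  low <- max(base - hw, lower)
  high <- min(base + hw, upper)
  if (low > base || high < base)
    stop("perturbation bounds do not bracket the base value for ",
         parameter, call. = FALSE)
  structure(list(parameter = parameter, base = base, low = low, high = high,
                 half_width = hw),
            class = "parameter_perturbation")
}

#' Default perturbation set for a scenario
#'
#' The transition probabilities, SMRs and relapse duration of the
#' scenario's parameter bundle, each varied by +/- 20% (standard
#' deviations are not published) and truncated to valid ranges.
#'
#' @param params A [make_default_parameters()] bundle.
#' @return List of [perturbation()]s.
#' @export
default_perturbations <- function(params) {
  pr <- function(nm) perturbation(nm, params[[nm]], lower = 0, upper = 1)
  out <- list(pr("p_relapse_adherent"), pr("p_relapse_nonadherent"),
              pr("hosp_fraction"), pr("p_return_adherent"), pr("p_restart"),
              perturbation("smr_stable", params$smr_stable, lower = 1),
              perturbation("smr_relapse", params$smr_relapse, lower = 1),
              perturbation("mean_los_days",
                           params$discharge_schedule$target_mean_days,
                           lower = 1))
  if (!params$ti_mode) out <- c(out, list(pr("p_discontinue")))
  out
}

extract_outcome <- function(res, outcome) {
  v <- res$result[[outcome]]
  if (is.null(v)) stop("unknown outcome metric: ", outcome, call. = FALSE)
  v
}

#' One-way (tornado) sensitivity sweep
#'
#' Reruns the entire pipeline (engine, outcomes, consumption, environment,
#' net score) at the low and high bound of each perturbation, all other
#' parameters at base, and records the outcome spread. A zero-width
#' perturbation reproduces the base outcome at both bounds.
#'
#' @param params Base parameter bundle.
#' @param perturbations List of [perturbation()]s; default
#'   [default_perturbations()].
#' @param outcome Metric to track (a [scenario_result()] field, default
#'   `"daly_net"`).
#' @param T Cycles.
#' @param factors Environmental factor table (derived from fixtures when
#'   omitted).
#' @return An object of class `sensitivity_result`: data frame sorted by
#'   decreasing |spread| with columns `parameter`, `low`, `high`,
#'   `outcome_low`, `outcome_high`, `spread`, plus the base outcome as an
#'   attribute.
#' @export
one_way_sweep <- function(params, perturbations = default_perturbations(params),
                          outcome = "daly_net", T = 12, factors = NULL) {
  if (is.null(factors)) factors <- derive_unit_factors(load_env_burden_table())
  base_res <- run_scenario(params = params, T = T, factors = factors)
  base_out <- extract_outcome(base_res, outcome)
  rows <- lapply(perturbations, function(pt) {
    at <- function(v) {
      p2 <- apply_overrides(params, stats::setNames(list(v), pt$parameter))
      extract_outcome(run_scenario(params = p2, T = T, factors = factors), outcome)
    }
    lo <- if (pt$low == pt$base) base_out else at(pt$low)
    hi <- if (pt$high == pt$base) base_out else at(pt$high)
    data.frame(parameter = pt$parameter, low = pt$low, high = pt$high,
               outcome_low = lo, outcome_high = hi, spread = hi - lo)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-abs(df$spread)), ]
  rownames(df) <- NULL
  structure(df, class = c("sensitivity_result", "data.frame"),
            outcome = outcome, base_outcome = base_out,
            scenario = params$scenario)
}

#' Distribution specifications for the probabilistic analysis
#'
#' Conventional families for bounded health-economic parameters: beta for
#' probabilities (method of moments), gamma for durations, normal
#' truncated to the valid range for ratios. Standard deviations default to
#' `(high - low) / (2 * 1.96)` of the +/- 20% range, i.e. the range is
#' read as a 95% interval.
#'
#' @param params A parameter bundle.
#' @return Named list of distribution specs (`family`, `mean`, `sd`,
#'   `lower`, `upper`).
#' @export
default_psa_distributions <- function(params) {
  spec <- function(nm, family, lower = 0, upper = 1, mean = params[[nm]]) {
    sd <- (min(mean * 1.2, upper) - max(mean * 0.8, lower)) / (2 * 1.96)
    list(parameter = nm, family = family, mean = mean, sd = sd,
         lower = lower, upper = upper)
  }
  out <- list(
    spec("p_relapse_adherent", "beta"),
    spec("p_relapse_nonadherent", "beta"),
    spec("hosp_fraction", "beta"),
    spec("p_return_adherent", "beta"),
    spec("p_restart", "beta"),
    spec("smr_stable", "truncnorm", lower = 1, upper = Inf),
    spec("smr_relapse", "truncnorm", lower = 1, upper = Inf),
    spec("mean_los_days", "gamma", lower = 1, upper = Inf,
         mean = params$discharge_schedule$target_mean_days))
  if (!params$ti_mode) out <- c(out, list(spec("p_discontinue", "beta")))
  names(out) <- vapply(out, `[[`, "", "parameter")
  out
}

# inverse-CDF draw of one parameter from its spec, given a uniform quantile
draw_from_spec <- function(spec, u) {
  m <- spec$mean; s <- spec$sd
  if (s == 0) return(m)
  switch(spec$family,
    beta = {
      if (m <= 0 || m >= 1) return(m)
      v <- s^2
      if (v >= m * (1 - m)) v <- 0.99 * m * (1 - m)
      a <- m * (m * (1 - m) / v - 1)
      b <- (1 - m) * (m * (1 - m) / v - 1)
      stats::qbeta(u, a, b)
    },
    gamma = stats::qgamma(u, shape = (m / s)^2, rate = m / s^2),
    truncnorm = {
      plo <- stats::pnorm((spec$lower - m) / s)
      phi <- stats::pnorm((spec$upper - m) / s)
      m + s * stats::qnorm(plo + u * (phi - plo))
    },
    stop("unknown distribution family: ", spec$family, call. = FALSE))
}

#' Sample one transition-parameter set from distribution specs
#'
#' Deterministic under the seed; zero-variance specs return the base
#' values unchanged. Sampled probabilities are truncated to \[0, 1\].
#'
#' @param params Base bundle.
#' @param distributions A [default_psa_distributions()] list.
#' @param seed Integer seed.
#' @return A `transition_parameters` bundle.
#' @export
sample_parameter_set <- function(params, distributions = default_psa_distributions(params),
                                 seed) {
  if (!missing(seed)) set.seed(seed)
  u <- stats::runif(length(distributions))
  draws <- mapply(function(spec, ui) {
    v <- draw_from_spec(spec, ui)
    min(max(v, spec$lower), spec$upper)
  }, distributions, u)
  apply_overrides(params, as.list(draws))
}

#' Probabilistic sensitivity analysis over the full pipeline
#'
#' Draws `n` parameter sets and runs every scenario through the entire
#' pipeline per draw. Common random numbers: within a draw, every scenario
#' uses the same uniform quantile for each parameter, so scenario deltas
#' are stabilized. Identical seeds give identical draw tables.
#'
#' @param scenarios Character vector of scenario ids.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @param distributions Optional named list per scenario; default
#'   [default_psa_distributions()] of each scenario's bundle.
#' @param T Cycles.
#' @param factors Environmental factor table.
#' @return An object of class `psa_result`: data frame with one row per
#'   draw x scenario and columns `draw`, `scenario`, `yld`, `yll`,
#'   `daly_patient`, `qaly`, `daly_env`, `daly_net`.
#' @export
probabilistic_sa <- function(scenarios = c("pp1m", "ti"), n = 200, seed = 1,
                             distributions = NULL, T = 12, factors = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(factors)) factors <- derive_unit_factors(load_env_burden_table())
  bases <- lapply(scenarios, make_default_parameters)
  names(bases) <- scenarios
  dists <- lapply(bases, function(p)
    if (is.null(distributions)) default_psa_distributions(p) else distributions)
  # all scenarios share the parameter axes of the first for CRN alignment
  axes <- names(dists[[1]])
  set.seed(seed)
  U <- matrix(stats::runif(n * length(axes)), nrow = n,
              dimnames = list(NULL, axes))
  rows <- list()
  for (i in seq_len(n)) {
    for (sc in scenarios) {
      dspec <- dists[[sc]]
      draws <- lapply(names(dspec), function(nm) {
        ui <- if (nm %in% axes) U[i, nm] else stats::runif(1)
        v <- draw_from_spec(dspec[[nm]], ui)
        min(max(v, dspec[[nm]]$lower), dspec[[nm]]$upper)
      })
      names(draws) <- names(dspec)
      p2 <- apply_overrides(bases[[sc]], draws)
      res <- run_scenario(params = p2, T = T, factors = factors)
      rows[[length(rows) + 1]] <- data.frame(
        draw = i, scenario = sc,
        yld = res$result$yld, yll = res$result$yll,
        daly_patient = res$result$daly_patient, qaly = res$result$qaly,
        daly_env = res$result$daly_env, daly_net = res$result$daly_net)
    }
  }
  structure(do.call(rbind, rows), class = c("psa_result", "data.frame"),
            seed = seed, n = n, scenarios = scenarios)
}

#' Robustness of the net-DALY conclusion
#'
#' Fraction of paired draws in which the treatment's net DALYs are lower
#' than the reference's (i.e. the treatment remains favourable).
#'
#' @param psa A [probabilistic_sa()] result containing both scenarios.
#' @param treatment Treatment scenario id.
#' @param reference Reference scenario id (default `"ti"`).
#' @return Fraction in \[0, 1\].
#' @export
conclusion_robustness <- function(psa, treatment, reference = "ti") {
  stopifnot(inherits(psa, "psa_result") || is.data.frame(psa))
  tr <- psa[psa$scenario == treatment, c("draw", "daly_net")]
  rf <- psa[psa$scenario == reference, c("draw", "daly_net")]
  if (!nrow(tr) || !nrow(rf) || !setequal(tr$draw, rf$draw))
    stop("PSA must contain paired draws for both scenarios", call. = FALSE)
  m <- merge(tr, rf, by = "draw", suffixes = c("_tr", "_rf"))
  mean(m$daly_net_tr - m$daly_net_rf < 0)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> ", attr(x, "scenario"), ", outcome ",
      attr(x, "outcome"), " (base ", round(attr(x, "base_outcome"), 2), ")\n",
      sep = "")
  print.data.frame(cbind(x[, c("parameter", "low", "high")],
                         round(x[, c("outcome_low", "outcome_high", "spread")], 3)))
  invisible(x)
}
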