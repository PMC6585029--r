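#' Rescale a transition probability to a different cycle length
#'
#' Converts a probability defined over `from_cycles` cycles into the
#' equivalent probability over `to_cycles` cycles under a constant-hazard
#' assumption: `1 - (1 - p)^(to/from)`. Used to turn annual mortality rates
#' into monthly probabilities and to move between monthly and 3-monthly
#' discontinuation probabilities.
#'
#' @param p Probability in \[0, 1\].
#' @param from_cycles Number of cycles `p` refers to (> 0).
#' @param to_cycles Number of cycles the result should refer to (> 0).
#' @return Rescaled probability.
#' @examples
#' convert_cycle_probability(0.12, 12, 1)  # annual -> monthly
#' @export
convert_cycle_probability <- function(p, from_cycles, to_cycles) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must be in [0, 1]", call. = FALSE)
  if (from_cycles <= 0 || to_cycles <= 0)
    stop("cycle counts must be > 0", call. = FALSE)
  1 - (1 - p)^(to_cycles / from_cycles)
}

#' Monthly mortality probability at a given age
#'
#' Looks up the annual mortality probability at the attained (fractional)
#' age, converts it to a monthly probability under constant hazard, and
#' multiplies by the standardized mortality ratio (SMR) of the health state.
#' The product is clamped to \[0, 1\].
#'
#' @param age Attained age in years; must lie within the life-table support.
#' @param life_table A [make_life_table()] object (or any data frame with
#'   columns `age` and `qx`).
#' @param smr Standardized mortality ratio (> 0); 2.58 for stable
#'   schizophrenia, 6.2 during relapse in the default parameter sets.
#' @return Monthly death probability in \[0, 1\].
#' @export
monthly_mortality <- function(age, life_table, smr) {
  if (smr <= 0) stop("smr must be > 0", call. = FALSE)
  q_annual <- annual_mortality(life_table, age)
  pmin(1, smr * convert_cycle_probability(q_annual, 12, 1))
}
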