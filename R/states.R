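#' Tunnel-expanded state space for the relapse cohort model
#'
#' Expands the five-state diagram (stable adherent, stable non-adherent,
#' relapse treated in hospital, relapse treated in ambulatory care, death)
#' into a tunnel-state space in which each relapse month is its own state, so
#' that the probability of discharge can depend on how long a patient has
#' already been in relapse. With tunnel depth `K` the space has `2K + 3`
#' states; the last tunnel month self-loops so stays longer than `K` months
#' are possible.
#'
#' @param K Tunnel depth in months (number of distinct relapse months).
#'   Default 8.
#' @return An object of class `state_space`: a list with `states` (ordered
#'   character vector), `K`, and index helpers.
#' @examples
#' expand_tunnel_states(8)   # 19 states
#' expand_tunnel_states(1)   # degenerate: the 5-state diagram
#' @export
expand_tunnel_states <- function(K = 8) {
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K < 1 || K != floor(K))
    stop("K must be a single integer >= 1", call. = FALSE)
  K <- as.integer(K)
  states <- c("StableAdherent", "StableNonAdherent",
              paste0("RelapseHosp", seq_len(K)),
              paste0("RelapseAmb", seq_len(K)),
              "Death")
  structure(
    list(states = states,
         K = K,
         n = length(states),
         stable = c("StableAdherent", "StableNonAdherent"),
         hosp = paste0("RelapseHosp", seq_len(K)),
         amb = paste0("RelapseAmb", seq_len(K)),
         relapse = c(paste0("RelapseHosp", seq_len(K)),
                     paste0("RelapseAmb", seq_len(K))),
         death = "Death"),
    class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", x$n, " states (tunnel depth K = ", x$K, ")\n", sep = "")
  cat(" ", paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

is_state_space <- function(x) inherits(x, "state_space")
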