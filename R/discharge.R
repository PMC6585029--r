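#' Monthly discharge hazards from a right-skewed length-of-stay distribution
#'
#' Discretizes a right-skewed relapse-duration distribution (lognormal by
#' default) into monthly discharge hazards `d_1..d_K` for the tunnel states:
#' `d_k` is the probability of leaving relapse at the end of tunnel month
#' `k`, given the patient is still in relapse. Mass beyond month `K` is
#' handled by the month-`K` self-loop, which keeps discharging at hazard
#' `d_K` (a geometric tail). The hospital distribution this emulates is
#' right-skewed — most patients leave before the mean stay, a few stay much
#' longer — which is the reason the model uses tunnel states at all.
#'
#' The schedule stores, next to the hazards, the conditional mean stay (in
#' days) of each monthly bin and of the tail, so that sampled stays
#' reproduce the continuous distribution's mean.
#'
#' @param mean_los_days Target mean length of stay in days (> 0). The
#'   default of 60 days is a configurable placeholder, not a published
#'   value.
#' @param dispersion Lognormal `sdlog`; 0 gives a degenerate (point-mass)
#'   stay at the mean.
#' @param K Tunnel depth in months.
#' @param cycle_days Days per model cycle (month), default 30.
#' @return An object of class `discharge_schedule`: list with `d` (length
#'   `K`), `bin_mean_days`, `tail_mean_days`, `mean_los_days` (realized,
#'   analytic), and the generating parameters.
#' @examples
#' ds <- make_discharge_schedule(60, 0.8)
#' ds$d
#' @export
make_discharge_schedule <- function(mean_los_days = 60, dispersion = 0.8,
                                    K = 8, cycle_days = 30) {
  if (mean_los_days <= 0) stop("mean_los_days must be > 0", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  edges <- cycle_days * (0:K)

  if (dispersion == 0) {
    # degenerate: everyone discharged at the end of the month containing the mean
    bin <- min(max(ceiling(mean_los_days / cycle_days), 1), K)
    d <- rep(0, K); d[bin] <- 1
    bm <- rep(NA_real_, K); bm[bin] <- mean_los_days
    sched <- list(d = d, bin_mean_days = bm, tail_mean_days = NA_real_,
                  mean_los_days = mean_los_days)
  } else {
    sdlog <- dispersion
    meanlog <- log(mean_los_days) - sdlog^2 / 2
    F <- stats::plnorm(edges, meanlog, sdlog)
    p_bin <- diff(F)                      # P(stay in month k), k = 1..K
    surv <- 1 - F[-length(F)]             # P(stay > 30(k-1))
    d <- ifelse(surv > 0, p_bin / surv, 1)
    # conditional mean of the lognormal within each bin (partial expectation)
    pe <- function(x) stats::pnorm((log(pmax(x, .Machine$double.xmin)) -
                                      meanlog - sdlog^2) / sdlog)
    pe0 <- c(0, pe(edges[-1]))
    mass <- exp(meanlog + sdlog^2 / 2) * diff(pe0)
    bm <- ifelse(p_bin > 0, mass / p_bin, NA_real_)
    p_tail <- 1 - F[K + 1]
    tail_mean <- if (p_tail > 0)
      exp(meanlog + sdlog^2 / 2) * (1 - pe(edges[K + 1])) / p_tail else NA_real_
    realized <- sum(p_bin * bm, na.rm = TRUE) +
      if (p_tail > 0) p_tail * tail_mean else 0
    if (abs(realized - mean_los_days) / mean_los_days > 0.02)
      stop("discharge schedule cannot realize the target mean within 2% ",
           "with K = ", K, " months of support", call. = FALSE)
    sched <- list(d = d, bin_mean_days = bm, tail_mean_days = tail_mean,
                  mean_los_days = realized)
  }
  structure(c(sched, list(target_mean_days = mean_los_days,
                          dispersion = dispersion, K = K,
                          cycle_days = cycle_days)),
            class = "discharge_schedule")
}

#' Sample lengths of stay from a discharge schedule
#'
#' Draws the discharge month from the monthly hazards (with the geometric
#' month-`K` tail) and maps it to days through the stored conditional bin
#' means, so the sample mean estimates the continuous distribution's mean.
#'
#' @param schedule A [make_discharge_schedule()] object.
#' @param n Number of stays to sample.
#' @return Numeric vector of `n` stays in days.
#' @export
sample_los <- function(schedule, n) {
  stopifnot(inherits(schedule, "discharge_schedule"), n >= 1)
  K <- schedule$K
  d <- schedule$d
  out <- numeric(n)
  month <- integer(n)
  alive <- rep(TRUE, n)
  k <- 1L
  while (any(alive)) {
    hz <- d[min(k, K)]
    exit <- alive & (stats::runif(n) < hz)
    month[exit] <- k
    alive <- alive & !exit
    k <- k + 1L
    if (k > 1000L) { month[alive] <- k; break }  # guard: hazard ~ 0
  }
  inK <- month <= K
  out[inK] <- schedule$bin_mean_days[month[inK]]
  out[!inK] <- schedule$tail_mean_days
  out
}

#' @export
print.discharge_schedule <- function(x, ...) {
  cat("<discharge_schedule> K = ", x$K, " months, mean LOS = ",
      round(x$mean_los_days, 1), " days (target ", x$target_mean_days,
      ", dispersion ", x$dispersion, ")\n", sep = "")
  cat("  d_k:", paste(round(x$d, 4), collapse = " "), "\n")
  invisible(x)
}
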