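#' Ground truth for a cycloheximide chase
#'
#' Protein abundance decays as `N(t) = n0 * exp(-rate_k * t)` once
#' synthesis is blocked; the half-life is `log(2)/rate_k`. The default
#' sampling grid is 0, 2, 4 and 6 h after cycloheximide addition.
#'
#' @param condition label for the experimental condition.
#' @param n0 initial abundance (AU).
#' @param rate_k first-order decay rate (per hour), >= 0.
#' @param times sampling times (hours), sorted ascending from 0.
#' @param noise_cv multiplicative measurement noise CV (fraction), >= 0.
#' @return list of class `chase_truth`.
#' @export
chase_truth <- function(condition = "control", n0 = 100,
                        rate_k = log(2) / 4, times = c(0, 2, 4, 6),
                        noise_cv = 0.05) {
  if (rate_k < 0) stop("rate_k must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly increasing and start at 0")
  structure(list(condition = condition, n0 = n0, rate_k = rate_k,
                 times = times, noise_cv = noise_cv),
            class = "chase_truth")
}

#' Simulate a cycloheximide-chase time course
#'
#' Values are `n0 * exp(-rate_k * t) * (1 + eps)` with
#' `eps ~ N(0, noise_cv)`, floored just above zero so downstream
#' log-space fitting is always defined.
#'
#' @param truth a [chase_truth()].
#' @param seed integer seed.
#' @return data.frame: `condition`, `time_h`, `value`, `truth_value`.
#' @export
simulate_chase <- function(truth = chase_truth(), seed = 1L) {
  mu <- truth$n0 * exp(-truth$rate_k * truth$times)
  with_seed(seed, {
    eps <- if (truth$noise_cv > 0)
      stats::rnorm(length(mu), 0, truth$noise_cv) else 0
    data.frame(condition = truth$condition, time_h = truth$times,
               value = pmax(mu * (1 + eps), 1e-12), truth_value = mu)
  })
}

#' Simulate bio-layer interferometry sensorgrams (1:1 Langmuir)
#'
#' For analyte concentration C the association phase follows
#' `R(t) = Req * (1 - exp(-(kon*C + koff) * t))` with
#' `Req = rmax * C / (C + koff/kon)`, and the dissociation phase decays
#' from the end-of-association response as `exp(-koff * (t - t_assoc))`.
#' Default timing is 5 min association and 10 min dissociation.
#'
#' @param kon association rate constant (1/M/s), > 0.
#' @param koff dissociation rate constant (1/s), > 0.
#' @param concentrations analyte concentrations (M), at least one.
#' @param t_assoc,t_dissoc phase durations (s).
#' @param rmax saturating response (response units), > 0.
#' @param noise_sd additive Gaussian noise sd (response units).
#' @param seed integer seed.
#' @param dt sampling interval (s).
#' @return data.frame: `conc_M`, `time_s` (global, association starts at
#'   0), `response`, `phase` ("assoc"/"dissoc"); attribute `t_assoc`
#'   carries the phase split.
#' @export
simulate_sensorgrams <- function(kon, koff, concentrations,
                                 t_assoc = 300, t_dissoc = 600,
                                 rmax = 1, noise_sd = 0, seed = 1L,
                                 dt = 1) {
  if (kon <= 0 || koff <= 0 || rmax <= 0)
    stop("kon, koff and rmax must be positive")
  if (length(concentrations) < 1L) stop("need at least one concentration")
  kd <- koff / kon
  out <- do.call(rbind, lapply(concentrations, function(C) {
    ta <- seq(0, t_assoc, by = dt)
    td <- seq(dt, t_dissoc, by = dt) + t_assoc
    req <- rmax * C / (C + kd)
    ra <- req * (1 - exp(-(kon * C + koff) * ta))
    r_end <- req * (1 - exp(-(kon * C + koff) * t_assoc))
    rd <- r_end * exp(-koff * (td - t_assoc))
    data.frame(conc_M = C, time_s = c(ta, td), response = c(ra, rd),
               phase = rep(c("assoc", "dissoc"), c(length(ta), length(td))))
  }))
  if (noise_sd > 0)
    out$response <- with_seed(seed, out$response +
                                stats::rnorm(nrow(out), 0, noise_sd))
  attr(out, "t_assoc") <- t_assoc
  out
}
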