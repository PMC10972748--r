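#' Predicted 1:1 Langmuir sensorgram response
#'
#' @param times global times (s).
#' @param conc analyte concentration (M), one per row of `times`.
#' @param phase "assoc" / "dissoc" per row.
#' @param kon,koff,rmax model parameters.
#' @param t_assoc association/dissociation split (s).
#' @return predicted response.
#' @keywords internal
bli_predict <- function(times, conc, phase, kon, koff, rmax, t_assoc) {
  kd <- koff / kon
  req <- rmax * conc / (conc + kd)
  kobs <- kon * conc + koff
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(phase == "assoc",
         req * (1 - exp(-kobs * times)),
         r_end * exp(-koff * (times - t_assoc)))
}

#' Global 1:1 binding fit of BLI sensorgrams
#'
#' Nonlinear least squares over all concentrations jointly with shared
#' `kon`, `koff` and `rmax` (the standard 1:1 Langmuir model), on log
#' parameters with a multi-start grid over log-spaced `kon`/`koff`; the
#' start with the lowest residual sum of squares wins. Rows with negative
#' `time_s` are treated as pre-association baseline and their mean
#' response is subtracted first.
#'
#' With dissociation-phase data only, `koff` is fitted from the single
#' exponential decay and `kon` (hence Kd) is reported as NA with a
#' warning.
#'
#' @param sensorgrams data.frame with `conc_M`, `time_s`, `response`,
#'   `phase` (see [simulate_sensorgrams()]).
#' @param t_assoc phase split (s); taken from the `t_assoc` attribute or
#'   the largest association time when missing.
#' @param kon_starts,koff_starts multi-start grids.
#' @return object of class `binding_fit`: `kon` (1/M/s), `koff` (1/s),
#'   `rmax`, `kd` (M, `= koff/kon` exactly), `rss`, `req` (per-curve
#'   plateau), `n_obs`.
#' @export
fit_1to1 <- function(sensorgrams, t_assoc = NULL,
                     kon_starts = 10^c(4, 5, 6),
                     koff_starts = 10^c(-3, -2, -1)) {
  d <- sensorgrams
  stopifnot(all(c("conc_M", "time_s", "response", "phase") %in% names(d)))
  base <- d$time_s < 0
  if (any(base)) {
    d$response <- d$response - mean(d$response[base])
    d <- d[!base, ]
  }
  if (is.null(t_assoc))
    t_assoc <- attr(sensorgrams, "t_assoc")
  if (is.null(t_assoc)) {
    at <- d$time_s[d$phase == "assoc"]
    t_assoc <- if (length(at)) max(at) else NA_real_
  }
  concs <- sort(unique(d$conc_M))

  if (!any(d$phase == "assoc")) {
    warning("dissociation-only data: koff fitted alone, kon unreliable (NA)")
    fit <- stats::lm(log(pmax(d$response, 1e-12)) ~ d$time_s)
    koff <- -unname(stats::coef(fit)[2])
    return(structure(list(kon = NA_real_, koff = koff, rmax = NA_real_,
                          kd = NA_real_, rss = sum(stats::resid(fit)^2),
                          req = NULL, n_obs = nrow(d),
                          t_assoc = t_assoc),
                     class = "binding_fit"))
  }

  rmax0 <- max(d$response) / 0.9
  resid_fn <- function(p) {
    d$response - bli_predict(d$time_s, d$conc_M, d$phase,
                             exp(p[1]), exp(p[2]), exp(p[3]), t_assoc)
  }
  best <- NULL
  for (k1 in kon_starts) for (k2 in koff_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(c(k1, k2, rmax0)), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best))
    stop("1:1 fit failed to converge from any start")
  kon <- exp(best$par[1]); koff <- exp(best$par[2]); rmax <- exp(best$par[3])
  kd <- koff / kon
  structure(list(kon = kon, koff = koff, rmax = rmax, kd = kd,
                 rss = best$rss,
                 req = stats::setNames(rmax * concs / (concs + kd),
                                       format(concs, digits = 3)),
                 n_obs = nrow(d), t_assoc = t_assoc),
            class = "binding_fit")
}

#' Equilibrium dissociation constant from rate constants
#'
#' `Kd = koff / kon`; `koff = 0` gives 0 (covalent limit).
#'
#' @param kon association rate constant (1/M/s), > 0.
#' @param koff dissociation rate constant (1/s), >= 0.
#' @return Kd in molar.
#' @export
kd_from_rates <- function(kon, koff) {
  if (kon <= 0) stop("kon must be positive")
  koff / kon
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 Langmuir binding fit (%d observations)\n", x$n_obs))
  cat(sprintf("  kon  = %.4g /M/s\n", x$kon))
  cat(sprintf("  koff = %.4g /s\n", x$koff))
  cat(sprintf("  Kd   = %.4g M (%.3g nM)\n", x$kd, x$kd * 1e9))
  cat(sprintf("  rmax = %.4g RU, rss = %.4g\n", x$rmax, x$rss))
  invisible(x)
}
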