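# internal: EM for log DNA content -- two Gaussian peaks (2N, 4N) plus a
# uniform S-phase bridge supported on (mu1, mu2). The bridge term keeps
# the replicating population from dragging the peak means inward; with no
# cells between the peaks its weight goes to ~0 and the model reduces to
# a plain two-component Gaussian mixture.
dna_peak_em <- function(x, mu, sigma0 = 0.06, max_iter = 200L,
                        tol = 1e-8) {
  sg <- rep(sigma0, 2)
  pw <- c(0.4, 0.25, 0.35)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu[2] - mu[1]
    f1 <- stats::dnorm(x, mu[1], sg[1])
    f2 <- stats::dnorm(x, mu[2], sg[2])
    fu <- if (w > 0.02) ifelse(x > mu[1] & x < mu[2], 1 / w, 0) else 0
    num <- cbind(pw[1] * f1, pw[2] * f2, pw[3] * fu)
    den <- rowSums(num)
    den[den <= 0] <- 1e-300
    r <- num / den
    ll <- sum(log(den))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    pw <- colMeans(r)
    mu[1] <- sum(r[, 1] * x) / sum(r[, 1])
    mu[2] <- sum(r[, 2] * x) / sum(r[, 2])
    sg[1] <- sqrt(sum(r[, 1] * (x - mu[1])^2) / sum(r[, 1]))
    sg[2] <- sqrt(sum(r[, 2] * (x - mu[2])^2) / sum(r[, 2]))
    sg <- pmax(sg, 1e-4)
    if (mu[2] < mu[1]) { mu <- rev(mu); sg <- rev(sg) }
  }
  list(mu = mu, sigma = sg, weights = pw, converged = converged,
       iterations = it)
}

#' Fit 2N/4N DNA-content gates
#'
#' Two Gaussian components (the 2N and 4N peaks) plus a uniform S-phase
#' bridge between them are fitted to log DNA content (integrated DAPI)
#' by EM, initialized at the two strongest kernel-density modes -- the
#' standard structure of a DNA-content histogram. Windows are placed at
#' peak +/- `window_sd` component-sd in log space. Populations whose
#' 4N/2N peak ratio falls outside [1.7, 2.3] are flagged
#' `quality = "degraded"`; effectively unimodal inputs duplicate the
#' single peak. If EM does not converge the KDE modes themselves are
#' reported, with a warning.
#'
#' @param dna_values DNA content per cell (integrated DAPI, AU); >= 50
#'   cells required, >= 200 recommended.
#' @param window_sd half-width of the 2N/4N windows in component-sd.
#' @return object of class `phase_gates`: `g1_peak`, `g2_peak`,
#'   `g1_window`, `g2_window` (AU), log-space sds, `peak_ratio`,
#'   `quality`.
#' @export
fit_dna_gates <- function(dna_values, window_sd = 2.5) {
  dna_values <- dna_values[is.finite(dna_values) & dna_values > 0]
  if (length(dna_values) < 50L)
    stop("need at least 50 cells to fit DNA gates")
  x <- log(dna_values)

  dens <- stats::density(x, n = 512)
  im <- which(diff(sign(diff(dens$y))) == -2) + 1L
  modes <- dens$x[im]
  mu0 <- if (length(modes) >= 2L)
    sort(modes[order(-dens$y[im])][1:2])
  else as.numeric(stats::quantile(x, c(0.25, 0.75)))

  fit <- dna_peak_em(x, mu0)
  mu <- fit$mu
  sig <- fit$sigma
  if (!fit$converged) {
    warning("DNA-gate EM did not converge; reporting KDE peak positions")
    if (length(modes) >= 2L) mu <- mu0
  }

  ratio <- exp(mu[2]) / exp(mu[1])
  quality <- "ok"
  if (!is.finite(ratio) || ratio < 1.7 || ratio > 2.3) {
    quality <- "degraded"
    if (ratio < 1.2) {  # effectively unimodal: duplicate the single peak
      mu <- rep(mean(mu), 2)
      sig <- rep(max(sig), 2)
    }
  }
  structure(list(
    g1_peak = exp(mu[1]), g2_peak = exp(mu[2]),
    g1_sdlog = sig[1], g2_sdlog = sig[2],
    g1_window = exp(mu[1] + c(-1, 1) * window_sd * sig[1]),
    g2_window = exp(mu[2] + c(-1, 1) * window_sd * sig[2]),
    peak_ratio = exp(mu[2]) / exp(mu[1]),
    edu_threshold = NA_real_, m_dapi_mfi_threshold = NA_real_,
    quality = quality, n_cells = length(dna_values)
  ), class = "phase_gates")
}

#' Fit the full set of phase gates
#'
#' DNA gates via [fit_dna_gates()], an EdU S-phase threshold (Otsu on
#' log EdU), and an M-phase DAPI-MFI threshold (Otsu on DAPI MFI
#' restricted to cells inside the 4N window).
#'
#' @param records per-cell feature table.
#' @param dna,edu,dapi_mfi column names of DNA content (integrated DAPI),
#'   EdU MFI and DAPI MFI.
#' @inheritParams fit_dna_gates
#' @return `phase_gates` with `edu_threshold` and
#'   `m_dapi_mfi_threshold` filled in.
#' @export
fit_phase_gates <- function(records, dna = "dapi_integrated",
                            edu = "edu_mfi", dapi_mfi = "dapi_mfi",
                            window_sd = 2.5) {
  gates <- fit_dna_gates(records[[dna]], window_sd = window_sd)
  ev <- records[[edu]]
  gates$edu_threshold <- exp(otsu_threshold(log(pmax(ev, 1e-9))))
  in_4n <- records[[dna]] >= gates$g2_window[1] &
    records[[dna]] <= gates$g2_window[2]
  mv <- records[[dapi_mfi]][in_4n]
  gates$m_dapi_mfi_threshold <- if (length(mv) >= 2L && diff(range(mv)) > 0)
    otsu_threshold(mv) else Inf
  gates
}

#' Assign cell-cycle phases from fitted gates
#'
#' Rule order: S if EdU MFI exceeds the EdU threshold (S takes precedence
#' over the DNA windows, so early-S cells near 2N are called S); else G1
#' if DNA content is inside the 2N window; else, inside the 4N window, M
#' if DAPI MFI exceeds the mitotic threshold (or the cell is
#' H3pS10-positive when that channel is supplied), otherwise G2; else
#' unclassified.
#'
#' @param records per-cell feature table.
#' @param gates a `phase_gates` object.
#' @inheritParams fit_phase_gates
#' @param h3ps10 optional column of H3pS10 MFI; when given, M within the
#'   4N window is called by `h3ps10 > h3ps10_threshold` instead of DAPI
#'   MFI.
#' @param h3ps10_threshold threshold for H3pS10 positivity.
#' @return factor with levels G1, S, G2, M, unclassified -- exactly one
#'   per cell.
#' @export
call_phases <- function(records, gates, dna = "dapi_integrated",
                        edu = "edu_mfi", dapi_mfi = "dapi_mfi",
                        h3ps10 = NULL, h3ps10_threshold = NULL) {
  for (col in c(dna, edu, dapi_mfi))
    if (is.null(records[[col]]))
      stop("required channel column missing: ", col)
  if (is.na(gates$edu_threshold))
    stop("gates lack an EdU threshold; use fit_phase_gates()")
  d <- records[[dna]]
  phase <- rep("unclassified", nrow(records))
  in_2n <- d >= gates$g1_window[1] & d <= gates$g1_window[2]
  in_4n <- d >= gates$g2_window[1] & d <= gates$g2_window[2]
  mitotic <- if (!is.null(h3ps10)) {
    thr <- if (is.null(h3ps10_threshold))
      otsu_threshold(records[[h3ps10]]) else h3ps10_threshold
    records[[h3ps10]] > thr
  } else records[[dapi_mfi]] > gates$m_dapi_mfi_threshold
  is_s <- records[[edu]] > gates$edu_threshold
  phase[in_4n & !is_s] <- ifelse(mitotic[in_4n & !is_s], "M", "G2")
  phase[in_2n & !is_s] <- "G1"
  phase[is_s] <- "S"
  factor(phase, levels = c("G1", "S", "G2", "M", "unclassified"))
}

#' Summarize a channel by cell-cycle phase
#'
#' Mean and sd of (background-corrected) MFI per phase, plus the mean
#' relative to a reference phase. Unclassified cells are excluded; empty
#' phases are reported with `n_cells = 0` and NA statistics.
#'
#' @param values per-cell channel values.
#' @param phases factor from [call_phases()].
#' @param reference reference phase (relative_mfi = 1).
#' @return data.frame: `phase`, `n_cells`, `mean_mfi`, `sd_mfi`,
#'   `relative_mfi`.
#' @export
phase_summaries <- function(values, phases, reference = "G1") {
  lev <- setdiff(levels(phases), "unclassified")
  keep <- phases != "unclassified"
  values <- values[keep]; phases <- droplevels(phases[keep])
  ref_vals <- values[phases == reference]
  if (length(ref_vals) == 0L)
    stop("reference phase '", reference, "' has no cells")
  ref_mean <- mean(ref_vals)
  do.call(rbind, lapply(lev, function(p) {
    v <- values[phases == p]
    data.frame(phase = p, n_cells = length(v),
               mean_mfi = if (length(v)) mean(v) else NA_real_,
               sd_mfi = if (length(v) > 1) stats::sd(v) else NA_real_,
               relative_mfi = if (length(v)) mean(v) / ref_mean else NA_real_)
  }))
}

#' Per-phase contrast between conditions
#'
#' For each phase: ratio of condition means to the reference condition
#' with a seeded bootstrap CI, a one-way ANOVA p-value across conditions,
#' and Sidak-adjusted pairwise Welch p-values (adjusted over the pairwise
#' family within the phase).
#'
#' @param values per-cell channel values (all conditions pooled).
#' @param condition factor of condition labels; the first level is the
#'   reference.
#' @param phases factor of phase calls (same length).
#' @param n_boot bootstrap resamples for the ratio CI.
#' @param conf CI level.
#' @param seed integer seed for the bootstrap.
#' @return data.frame: `phase`, `comparison`, `ratio`, `ci_lo`, `ci_hi`,
#'   `p_anova`, `p_pairwise`, `p_sidak`.
#' @export
condition_contrast <- function(values, condition, phases, n_boot = 2000L,
                               conf = 0.95, seed = 1L) {
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) < 2L) stop("need at least two conditions")
  ref <- levels(condition)[1]
  ph_common <- Reduce(intersect,
                      lapply(levels(condition),
                             function(cc) unique(as.character(
                               phases[condition == cc & phases != "unclassified"]))))
  if (length(ph_common) == 0L) stop("no phase present in all conditions")
  alpha <- 1 - conf
  pairs <- utils::combn(levels(condition), 2, simplify = FALSE)

  with_seed(seed, {
    do.call(rbind, lapply(ph_common, function(p) {
      sel <- phases == p
      v <- values[sel]; g <- droplevels(condition[sel])
      p_anova <- stats::anova(stats::lm(v ~ g))[["Pr(>F)"]][1]
      do.call(rbind, lapply(pairs, function(pr) {
        va <- v[g == pr[1]]; vb <- v[g == pr[2]]
        ratio <- mean(vb) / mean(va)
        bs <- replicate(n_boot, mean(sample(vb, replace = TRUE)) /
                          mean(sample(va, replace = TRUE)))
        ci <- stats::quantile(bs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
        pw <- stats::t.test(vb, va)$p.value
        data.frame(phase = p,
                   comparison = paste(pr[2], "vs", pr[1]),
                   ratio = ratio, ci_lo = ci[1], ci_hi = ci[2],
                   p_anova = p_anova, p_pairwise = pw,
                   p_sidak = 1 - (1 - pw)^length(pairs))
      }))
    }))
  })
}
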