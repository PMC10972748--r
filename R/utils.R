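#' Otsu threshold for a numeric vector
#'
#' Between-class-variance maximization on a fixed-width histogram, applied
#' to arbitrary feature vectors (log-EdU, DAPI MFI) rather than images.
#' The returned cut is the upper edge of the chosen bin, so it is
#' equivariant under positive affine rescaling of the input.
#'
#' @param x numeric vector, length >= 2 with non-zero range.
#' @param levels number of histogram bins.
#' @return threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least two finite values")
  r <- range(x)
  if (diff(r) == 0) return(r[1L])
  breaks <- seq(r[1L], r[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA_real_)
  k <- which.max(sigma_b)
  breaks[k + 1L]
}

# internal: checked seed handling -- every stochastic entry point takes an
# integer seed so pipelines are bit-reproducible
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# internal: label matrix -> data.frame of centroids (1-based pixel centers)
label_centroids <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), x = numeric(), y = numeric()))
  lab <- labels[idx]
  nr <- nrow(labels)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  cx <- tapply(col, lab, mean)
  cy <- tapply(row, lab, mean)
  data.frame(label = as.integer(names(cx)), x = as.numeric(cx),
             y = as.numeric(cy))
}
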