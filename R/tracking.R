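#' Link per-frame detections into nucleus tracks
#'
#' Greedy nearest-centroid linking: candidate matches between open tracks
#' and the next frame's detections are taken in order of increasing
#' distance (ties by lower track id, then lower detection label);
#' assignments beyond `max_disp` are refused, unmatched detections open
#' new tracks, and unmatched tracks terminate. Suited to near-stationary
#' nuclei in time-lapse imaging.
#'
#' @param detections long-format data.frame with columns `frame`,
#'   `cell_id`, `centroid_x`, `centroid_y`; any further columns (e.g.
#'   `mfi`) are carried through.
#' @param max_disp maximum frame-to-frame displacement (px).
#' @return `detections` with a `track_id` column; every detection belongs
#'   to exactly one track.
#' @export
link_tracks <- function(detections, max_disp = 20) {
  stopifnot(all(c("frame", "cell_id", "centroid_x", "centroid_y") %in%
                  names(detections)))
  if (nrow(detections) == 0L) {
    detections$track_id <- integer(0)
    return(detections)
  }
  frames <- sort(unique(detections$frame))
  detections$track_id <- NA_integer_
  det <- split(seq_len(nrow(detections)), detections$frame)
  next_id <- 1L
  open <- data.frame(track_id = integer(), x = numeric(), y = numeric())
  for (f in as.character(frames)) {
    idx <- det[[f]]
    ord <- idx[order(detections$cell_id[idx])]
    n <- length(ord)
    assigned <- rep(FALSE, n)
    if (nrow(open) && n) {
      dx <- outer(open$x, detections$centroid_x[ord], "-")
      dy <- outer(open$y, detections$centroid_y[ord], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_disp, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dist[cand], open$track_id[cand[, 1]],
                           cand[, 2]), , drop = FALSE]
        used_track <- rep(FALSE, nrow(open))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_track[i] && !assigned[j]) {
            used_track[i] <- TRUE; assigned[j] <- TRUE
            detections$track_id[ord[j]] <- open$track_id[i]
          }
        }
      }
    }
    for (j in which(!assigned)) {
      detections$track_id[ord[j]] <- next_id
      next_id <- next_id + 1L
    }
    here <- detections[ord, ]
    open <- data.frame(track_id = here$track_id, x = here$centroid_x,
                       y = here$centroid_y)
  }
  detections
}

#' Normalize a track to a reference frame
#'
#' `relative_mfi[i] = mfi[i] / mfi[reference_index]`, the first
#' post-mitotic frame by default -- so the reference frame reads exactly
#' 1 and the series is invariant to any rescaling of raw intensities.
#'
#' @param track data.frame with an `mfi` column ordered by time.
#' @param reference_index frame index (1-based) used as reference.
#' @return `track` with a `relative_mfi` column.
#' @export
normalize_track <- function(track, reference_index = 1L) {
  stopifnot("mfi" %in% names(track),
            reference_index >= 1L, reference_index <= nrow(track))
  ref <- track$mfi[reference_index]
  if (!is.finite(ref) || ref <= 0)
    stop("reference MFI must be positive")
  track$relative_mfi <- track$mfi / ref
  track
}

#' Classify a PCNA crop as diffuse or punctate
#'
#' Replication foci make PCNA punctate in S phase. After light Gaussian
#' smoothing, the granularity score is `(P99 - median)/median` of in-mask
#' intensities; the crop is punctate iff the score strictly exceeds
#' `threshold`.
#'
#' @param crop 2-D intensity matrix.
#' @param mask optional logical matrix restricting to the nucleus.
#' @param threshold granularity cut (dimensionless).
#' @param min_area minimum in-mask pixels.
#' @param smooth_sigma Gaussian smoothing sigma (px); 0 disables.
#' @return list: `pattern` ("diffuse"/"punctate") and `score`.
#' @export
classify_pcna_pattern <- function(crop, mask = NULL, threshold = 1.0,
                                  min_area = 50L, smooth_sigma = 1) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(crop), ncol(crop))
  if (sum(mask) < min_area)
    stop("crop smaller than min_area (", min_area, " px)")
  if (smooth_sigma > 0)
    crop <- EBImage::imageData(EBImage::gblur(crop, sigma = smooth_sigma))
  v <- crop[mask]
  med <- stats::median(v)
  score <- if (med > 0)
    (stats::quantile(v, 0.99, names = FALSE) - med) / med else 0
  list(pattern = if (score > threshold) "punctate" else "diffuse",
       score = score)
}

#' Detect G1->S and S->G2 transitions from PCNA patterns
#'
#' G1->S is the first frame opening a run of at least `min_run` punctate
#' labels; S->G2 is the first frame of the subsequent run of at least
#' `min_run` diffuse labels. Runs shorter than `min_run` (flickers) are
#' ignored.
#'
#' @param patterns character vector of "diffuse"/"punctate" per frame.
#' @param min_run minimum run length (frames).
#' @return list with 1-based frame indices `g1_s` and `s_g2` (NA when the
#'   transition is absent).
#' @export
detect_phase_transitions <- function(patterns, min_run = 3L) {
  stopifnot(all(patterns %in% c("diffuse", "punctate")))
  r <- rle(patterns)
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  p_run <- which(r$values == "punctate" & r$lengths >= min_run)
  if (!length(p_run)) return(list(g1_s = NA_integer_, s_g2 = NA_integer_))
  g1_s <- starts[p_run[1]]
  d_run <- which(r$values == "diffuse" & r$lengths >= min_run &
                   seq_along(r$values) > p_run[1])
  s_g2 <- if (length(d_run)) starts[d_run[1]] else NA_integer_
  list(g1_s = g1_s, s_g2 = s_g2)
}
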