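#' Segment nuclei from a DAPI image
#'
#' Global Otsu threshold, hole filling, then distance-transform watershed
#' to split touching nuclei; components outside the area window (or
#' touching the field border, by default) are dropped and labels
#' renumbered 1..K.
#'
#' @param dapi 2-D numeric intensity matrix (rows = y).
#' @param min_area,max_area nucleus area window in pixels.
#' @param exclude_border drop nuclei touching the image border.
#' @param ws_tolerance watershed minimum object depth; raise to suppress
#'   over-splitting of noisy nuclei.
#' @return integer label matrix (0 = background); attribute `n_dropped`
#'   counts filtered components. A constant image yields zero labels.
#' @export
segment_nuclei <- function(dapi, min_area = 80, max_area = 5000,
                           exclude_border = TRUE, ws_tolerance = 1) {
  if (length(dapi) == 0L) stop("empty image")
  if (diff(range(dapi)) == 0)
    return(structure(matrix(0L, nrow(dapi), ncol(dapi)), n_dropped = 0L))
  thr <- otsu_threshold(as.vector(dapi))
  bw <- EBImage::fillHull(dapi > thr)
  dm <- EBImage::distmap(bw)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = ws_tolerance,
                                               ext = 1))
  # area / border filters
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border[border > 0])
  }
  n_dropped <- sum(areas > 0) - length(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    remap <- integer(max(lab))
    remap[sort(keep)] <- seq_along(keep)
    pos <- lab > 0 & lab %in% keep
    out[pos] <- remap[lab[pos]]
  }
  structure(out, n_dropped = as.integer(n_dropped))
}

#' Build cytoplasmic ring masks around nuclei
#'
#' The ring for nucleus k is the set of background pixels whose distance
#' to the nearest nucleus lies in `(gap, gap + width]`, assigned to the
#' nucleus with the nearest centroid (ties to the lower label). Rings
#' share their nucleus labels, never overlap any nucleus or each other,
#' and are clipped at the field border.
#'
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param gap clearance between nucleus and ring (px), >= 0.
#' @param width ring thickness (px), >= 1.
#' @return integer label matrix of rings.
#' @export
ring_mask <- function(nuclei, gap = 1, width = 5) {
  stopifnot(gap >= 0, width >= 1)
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  cen <- label_centroids(nuclei)
  if (nrow(cen) == 0L) return(out)
  d <- EBImage::imageData(EBImage::distmap(nuclei == 0))
  band <- which(d > gap & d <= gap + width)
  if (length(band) == 0L) return(out)
  nr <- nrow(nuclei)
  px <- (band - 1L) %/% nr + 1L
  py <- (band - 1L) %% nr + 1L
  # nearest-centroid ownership; ties broken by lower label (column order)
  d2 <- outer(px, cen$x, "-")^2 + outer(py, cen$y, "-")^2
  out[band] <- cen$label[max.col(-d2, ties.method = "first")]
  out
}

#' Lower-quartile background of a field
#'
#' The 25th percentile (linear-interpolation definition) of all pixel
#' intensities in the image -- the per-image background estimate
#' subtracted from per-cell mean intensities.
#'
#' @param image 2-D numeric matrix.
#' @return background level (AU).
#' @export
lower_quartile_background <- function(image) {
  if (length(image) == 0L) stop("empty image")
  unname(stats::quantile(as.vector(image), 0.25, type = 7))
}

#' Extract per-cell intensity features
#'
#' Per nucleus and channel: nuclear MFI (mean over nucleus pixels),
#' integrated intensity (sum; equals MFI x area exactly), cytoplasmic
#' ring MFI, per-field lower-quartile background, and background-
#' corrected means floored at zero.
#'
#' @param channels named list of 2-D intensity matrices.
#' @param nuclei nucleus label matrix.
#' @param rings ring label matrix (optional); ring labels must be a
#'   subset of nucleus labels.
#' @param field_id label recorded per row.
#' @return data.frame with one row per nucleus: `cell_id`, `field_id`,
#'   `area`, `centroid_x`, `centroid_y`, and per channel `<ch>_mfi`,
#'   `<ch>_integrated`, `<ch>_ring_mfi`, `<ch>_bg`, `<ch>_mfi_corrected`,
#'   `<ch>_ring_mfi_corrected`.
#' @export
extract_cell_features <- function(channels, nuclei, rings = NULL,
                                  field_id = "field1") {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)))
  for (ch in names(channels))
    if (!identical(dim(channels[[ch]]), dim(nuclei)))
      stop("channel '", ch, "' shape does not match the nucleus mask")
  ids <- sort(unique(nuclei[nuclei > 0]))
  if (!is.null(rings)) {
    if (!identical(dim(rings), dim(nuclei)))
      stop("ring mask shape does not match the nucleus mask")
    extra <- setdiff(unique(rings[rings > 0]), ids)
    if (length(extra))
      stop("ring label(s) not present in nuclei: ",
           paste(extra, collapse = ", "))
  }
  cen <- label_centroids(nuclei)
  nuc_idx <- which(nuclei > 0)
  nuc_lab <- factor(nuclei[nuc_idx], levels = ids)
  area <- as.integer(table(nuc_lab))
  out <- data.frame(cell_id = ids, field_id = field_id, area = area,
                    centroid_x = cen$x[match(ids, cen$label)],
                    centroid_y = cen$y[match(ids, cen$label)])
  if (!is.null(rings)) {
    ring_idx <- which(rings > 0)
    ring_lab <- factor(rings[ring_idx], levels = ids)
  }
  for (ch in names(channels)) {
    img <- channels[[ch]]
    bg <- lower_quartile_background(img)
    v <- img[nuc_idx]
    mfi <- as.numeric(tapply(v, nuc_lab, mean))
    integ <- as.numeric(tapply(v, nuc_lab, sum))
    ring_mfi <- rep(NA_real_, length(ids))
    if (!is.null(rings) && length(ring_idx))
      ring_mfi <- as.numeric(tapply(img[ring_idx], ring_lab, mean))
    out[[paste0(ch, "_mfi")]] <- mfi
    out[[paste0(ch, "_integrated")]] <- integ
    out[[paste0(ch, "_ring_mfi")]] <- ring_mfi
    out[[paste0(ch, "_bg")]] <- bg
    out[[paste0(ch, "_mfi_corrected")]] <- pmax(mfi - bg, 0)
    out[[paste0(ch, "_ring_mfi_corrected")]] <- pmax(ring_mfi - bg, 0)
  }
  out
}
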