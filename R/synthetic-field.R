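#' Field rendering specification
#'
#' @param width,height field size in pixels.
#' @param background per-channel background level (AU); a single value is
#'   recycled to all channels.
#' @param noise_sd per-channel additive Gaussian noise sd (AU).
#' @param bit_depth pixel depth in bits; values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param shading optional linear illumination gradient: total AU added
#'   left-to-right across the field (0 = flat illumination). Used to
#'   stress-test background correction.
#' @param seed integer seed for the noise draw.
#' @return list of class `field_spec`.
#' @export
field_spec <- function(width = 1024L, height = 1024L, background = 100,
                       noise_sd = 5, bit_depth = 16L, shading = 0,
                       seed = 1L) {
  stopifnot(all(background >= 0), all(noise_sd >= 0), width > 0, height > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background, noise_sd = noise_sd,
                 bit_depth = as.integer(bit_depth), shading = shading,
                 seed = seed),
            class = "field_spec")
}

#' Render a multichannel field from cell truth
#'
#' Paints each nucleus as a hard disk of its true channel level on a
#' uniform background, adds Gaussian read noise, and clips to the pixel
#' depth. For channels named in `cytosol_channels` a larger concentric
#' disk at the cell's `cytosol_level` is painted first, so the
#' cytoplasmic ring around each nucleus reports cytosolic signal. The
#' true label mask (pixel label = `cell_id`) is returned alongside.
#'
#' @param cells `cell_truth` table with centroids (see [place_cells()]).
#' @param spec a [field_spec()].
#' @param cytosol_channels channels that receive a cytosolic disk.
#' @param cytosol_factor cytosol disk radius as a multiple of the nuclear
#'   radius.
#' @return list with `channels` (named list of numeric matrices, rows =
#'   y), `mask` (integer label matrix) and `cells` (the truth table).
#' @export
render_field <- function(cells, spec = field_spec(),
                         cytosol_channels = "cgas_gfp",
                         cytosol_factor = 2.5) {
  chans <- sub("^level_", "", grep("^level_", names(cells), value = TRUE))
  w <- spec$width; h <- spec$height
  if (nrow(cells) > 0) {
    if (anyNA(cells$centroid_x))
      stop("cells have no centroids; run place_cells() first")
    if (any(cells$centroid_x - cells$radius < 0.5 |
            cells$centroid_x + cells$radius > w + 0.5 |
            cells$centroid_y - cells$radius < 0.5 |
            cells$centroid_y + cells$radius > h + 0.5))
      stop("nucleus out of field bounds")
  }
  bg <- rep_len(spec$background, length(chans)); names(bg) <- chans
  nsd <- rep_len(spec$noise_sd, length(chans)); names(nsd) <- chans
  maxval <- 2^spec$bit_depth - 1

  base <- matrix(0, nrow = h, ncol = w)
  shade <- if (spec$shading != 0)
    matrix(rep(seq(0, spec$shading, length.out = w), each = h), nrow = h)
  else 0
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)

  mask <- matrix(0L, nrow = h, ncol = w)
  imgs <- lapply(chans, function(ch) base)
  names(imgs) <- chans

  for (i in seq_len(nrow(cells))) {
    cx <- cells$centroid_x[i]; cy <- cells$centroid_y[i]
    r <- cells$radius[i]
    rc <- r * cytosol_factor
    x0 <- max(1L, floor(cx - rc)); x1 <- min(w, ceiling(cx + rc))
    y0 <- max(1L, floor(cy - rc)); y1 <- min(h, ceiling(cy + rc))
    sub_d2 <- (xs[y0:y1, x0:x1] - cx)^2 + (ys[y0:y1, x0:x1] - cy)^2
    in_nuc <- sub_d2 <= r^2
    in_cyt <- sub_d2 <= rc^2 & !in_nuc
    mm <- mask[y0:y1, x0:x1]
    mm[in_nuc] <- cells$cell_id[i]
    mask[y0:y1, x0:x1] <- mm
    for (ch in chans) {
      im <- imgs[[ch]][y0:y1, x0:x1]
      if (ch %in% cytosol_channels)
        im[in_cyt] <- pmax(im[in_cyt], cells$cytosol_level[i])
      im[in_nuc] <- cells[[paste0("level_", ch)]][i]
      imgs[[ch]][y0:y1, x0:x1] <- im
    }
  }

  imgs <- with_seed(spec$seed, {
    lapply(setNames(chans, chans), function(ch) {
      im <- imgs[[ch]] + bg[[ch]] + shade
      if (nsd[[ch]] > 0)
        im <- im + matrix(stats::rnorm(h * w, 0, nsd[[ch]]), nrow = h)
      pmin(pmax(im, 0), maxval)
    })
  })
  list(channels = imgs, mask = mask, cells = cells)
}

#' Write/read a rendered field as 16-bit greyscale TIFFs
#'
#' One file per channel, `<field>_<channel>.tif`, plus the truth label
#' mask as `<field>_mask.tif`. Intensities are stored as raw 16-bit
#' counts.
#'
#' @param field result of [render_field()].
#' @param dir output directory (created if needed).
#' @param field_id filename stem.
#' @return invisibly, the written file paths.
#' @export
write_field_tiff <- function(field, dir, field_id = "field1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(field$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", field_id, ch))
    tiff::writeTIFF(field$channels[[ch]] / 65535, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  p <- file.path(dir, sprintf("%s_mask.tif", field_id))
  tiff::writeTIFF(field$mask / 65535, p, bits.per.sample = 16L)
  invisible(c(paths, p))
}

#' @rdname write_field_tiff
#' @param path a TIFF written by [write_field_tiff()].
#' @param integer_labels round back to integer labels (for masks).
#' @export
read_field_tiff <- function(path, integer_labels = FALSE) {
  m <- tiff::readTIFF(path) * 65535
  if (integer_labels) {
    m <- round(m)
    mode(m) <- "integer"
  }
  m
}
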