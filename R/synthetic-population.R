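#' Default phase-dependent channel level model
#'
#' True mean nuclear signal (AU) per channel in each cell-cycle phase.
#' DAPI mean intensity is constant through interphase -- DNA content is
#' carried by nuclear *area* so that integrated DAPI is proportional to
#' genome equivalents -- while mitotic chromatin condensation shrinks the
#' nucleus (radius factor `m_shrink`) and raises DAPI MFI by the matching
#' `1/m_shrink^2`, keeping integrated DAPI at 4N. EdU is high only in S
#' phase; nuclear cGAS-GFP declines as cells progress from G1 to mitosis.
#'
#' @param dapi interphase DAPI mean level (AU).
#' @param m_shrink mitotic radius shrink factor.
#' @return named list `G1`, `S`, `G2`, `M` of named channel-mean vectors.
#' @export
default_level_model <- function(dapi = 300, m_shrink = 0.7) {
  list(
    G1 = c(dapi = dapi, edu = 40,  cgas_gfp = 500),
    S  = c(dapi = dapi, edu = 600, cgas_gfp = 350),
    G2 = c(dapi = dapi, edu = 40,  cgas_gfp = 250),
    M  = c(dapi = dapi / m_shrink^2, edu = 40, cgas_gfp = 200)
  )
}

#' Generate a synthetic cell population with known cell-cycle truth
#'
#' Draws `n` cells across the cell cycle by a seeded multinomial, assigns
#' each a DNA content (genome equivalents: 2N in G1, 4N in G2/M, uniform
#' in between for S), a nuclear radius scaling as `sqrt(dna/2)` so that
#' integrated DAPI tracks DNA content, and true per-channel mean signals
#' with lognormal cell-to-cell variability.
#'
#' @param n number of cells (>= 1).
#' @param phase_fractions named fractions over `G1`,`S`,`G2`,`M`; must sum
#'   to 1 (tolerance 1e-9).
#' @param level_model phase -> channel-mean map; see [default_level_model()].
#' @param seed integer seed; fixed seed gives a bit-identical table.
#' @param radius_2n nuclear radius (px) of a 2N interphase nucleus.
#' @param dna_sdlog lognormal sd of DNA content around the 2N/4N modes.
#' @param s_dna_range open DNA-content interval sampled uniformly in S.
#' @param m_shrink mitotic radius shrink factor (condensed chromatin).
#' @param level_sdlog named per-channel lognormal sd of cell-to-cell true
#'   signal variability.
#' @param cytosol_level true cytosolic cGAS-GFP level (AU).
#' @return data.frame (class `cell_truth`): `cell_id`, `phase`,
#'   `dna_content`, `radius`, `cytosol_level` and one `level_<channel>`
#'   column per channel. Centroids are assigned later by [place_cells()].
#' @export
make_cell_population <- function(n,
                                 phase_fractions = c(G1 = 0.5, S = 0.3,
                                                     G2 = 0.15, M = 0.05),
                                 level_model = default_level_model(),
                                 seed = 1L,
                                 radius_2n = 12,
                                 dna_sdlog = 0.05,
                                 s_dna_range = c(2.1, 3.9),
                                 m_shrink = 0.7,
                                 level_sdlog = c(dapi = 0, edu = 0.3,
                                                 cgas_gfp = 0.1),
                                 cytosol_level = 150) {
  stopifnot(n >= 1)
  phases <- c("G1", "S", "G2", "M")
  if (!all(names(phase_fractions) %in% phases))
    stop("unknown phase name: ",
         paste(setdiff(names(phase_fractions), phases), collapse = ", "))
  if (abs(sum(phase_fractions) - 1) > 1e-9)
    stop("phase fractions must sum to 1")
  frac <- setNames(numeric(4), phases)
  frac[names(phase_fractions)] <- phase_fractions

  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, frac))
    phase <- factor(rep(phases, counts), levels = phases)
    nn <- length(phase)
    dna <- numeric(nn)
    g1 <- phase == "G1"; s <- phase == "S"; g2m <- phase %in% c("G2", "M")
    dna[g1] <- 2 * exp(stats::rnorm(sum(g1), 0, dna_sdlog))
    dna[g2m] <- 4 * exp(stats::rnorm(sum(g2m), 0, dna_sdlog))
    dna[s] <- stats::runif(sum(s), s_dna_range[1], s_dna_range[2])

    radius <- radius_2n * sqrt(dna / 2)
    radius[phase == "M"] <- radius[phase == "M"] * m_shrink

    channels <- names(level_model[[1]])
    out <- data.frame(cell_id = seq_len(nn), phase = phase,
                      dna_content = dna, radius = radius,
                      centroid_x = NA_real_, centroid_y = NA_real_,
                      cytosol_level = cytosol_level)
    for (ch in channels) {
      base <- vapply(as.character(phase),
                     function(p) level_model[[p]][[ch]], numeric(1))
      sdl <- if (ch %in% names(level_sdlog)) level_sdlog[[ch]] else 0
      lev <- if (sdl > 0) base * exp(stats::rnorm(nn, 0, sdl)) else base
      out[[paste0("level_", ch)]] <- lev
    }
    class(out) <- c("cell_truth", "data.frame")
    out
  })
}

#' Place nuclei in a field without overlap
#'
#' Seeded dart throwing: centroids are drawn uniformly and accepted when
#' every pairwise centre distance exceeds the sum of nuclear radii plus
#' `margin`, so nuclei are hard disks that never overlap.
#'
#' @param cells `cell_truth` table from [make_cell_population()].
#' @param width,height field size in pixels.
#' @param margin minimum clearance (px) between disk boundaries and to the
#'   field border.
#' @param seed integer seed.
#' @param max_tries placement attempts per nucleus before giving up.
#' @return `cells` with `centroid_x`, `centroid_y` filled in.
#' @export
place_cells <- function(cells, width, height, margin = 4, seed = 1L,
                        max_tries = 5000L) {
  n <- nrow(cells)
  r <- cells$radius
  with_seed(seed, {
    cx <- numeric(n); cy <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- stats::runif(1, r[i] + margin, width - r[i] - margin)
        y <- stats::runif(1, r[i] + margin, height - r[i] - margin)
        if (i == 1L ||
            all((x - cx[seq_len(i - 1L)])^2 + (y - cy[seq_len(i - 1L)])^2 >
                (r[i] + r[seq_len(i - 1L)] + margin)^2)) {
          cx[i] <- x; cy[i] <- y; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place nucleus ", i,
                    " without overlap; field too crowded")
    }
    cells$centroid_x <- cx
    cells$centroid_y <- cy
    cells
  })
}

#' Simulate per-cell feature measurements from population truth
#'
#' Emulates the output of the segmentation/feature-extraction stage
#' directly from ground truth, bypassing image rendering: each nuclear MFI
#' is the true level times multiplicative measurement noise, and
#' integrated intensity is MFI times the true nuclear area. Values are
#' background-free, i.e. comparable to the `_corrected` columns of
#' [extract_cell_features()].
#'
#' @param cells `cell_truth` table.
#' @param noise_cv multiplicative measurement noise CV (fraction).
#' @param seed integer seed.
#' @return data.frame with `cell_id`, `truth_phase`, `area`, one
#'   `<channel>_mfi` per channel, and `dapi_integrated`.
#' @export
measure_population <- function(cells, noise_cv = 0.05, seed = 1L) {
  stopifnot(noise_cv >= 0)
  chans <- sub("^level_", "", grep("^level_", names(cells), value = TRUE))
  area <- pi * cells$radius^2
  with_seed(seed, {
    out <- data.frame(cell_id = cells$cell_id,
                      truth_phase = cells$phase, area = area)
    for (ch in chans) {
      eps <- if (noise_cv > 0) stats::rnorm(nrow(cells), 0, noise_cv) else 0
      out[[paste0(ch, "_mfi")]] <- cells[[paste0("level_", ch)]] * (1 + eps)
    }
    out$dapi_integrated <- out$dapi_mfi * area
    out
  })
}
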