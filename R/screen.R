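#' Aggregate per-cell features to wells
#'
#' Per well: mean background-corrected nuclear MFI and mean integrated
#' intensity of the scored channel, with a low-count flag for wells under
#' `min_cells` (those are excluded from anchor estimation downstream but
#' kept in reports).
#'
#' @param cells per-cell feature table with `well_id` and `plate_id`.
#' @param layout well table: `well_id`, `plate_id`, `role`, `gene`,
#'   `sirna_id`.
#' @param channel channel whose `<channel>_mfi_corrected` and
#'   `<channel>_integrated` columns are aggregated.
#' @param min_cells minimum cells for a well to be considered usable.
#' @return data.frame: layout columns plus `raw_mfi`, `raw_integrated`,
#'   `n_cells`, `low_count`.
#' @export
aggregate_wells <- function(cells, layout, channel = "cgas_gfp",
                            min_cells = 50L) {
  key <- function(d) paste(d$plate_id, d$well_id, sep = "/")
  unknown <- setdiff(key(cells), key(layout))
  if (length(unknown))
    stop("cell(s) mapped to unknown well(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  mfi_col <- paste0(channel, "_mfi_corrected")
  int_col <- paste0(channel, "_integrated")
  stopifnot(mfi_col %in% names(cells), int_col %in% names(cells))
  ck <- key(cells); lk <- key(layout)
  empty <- setdiff(lk, ck)
  if (length(empty))
    stop("well(s) with no cells: ", paste(utils::head(empty, 3),
                                          collapse = ", "))
  f <- factor(ck, levels = lk)
  out <- layout
  out$raw_mfi <- as.numeric(tapply(cells[[mfi_col]], f, mean))
  out$raw_integrated <- as.numeric(tapply(cells[[int_col]], f, mean))
  out$n_cells <- as.integer(table(f))
  out$low_count <- out$n_cells < min_cells
  out
}

#' Three-anchor plate normalization
#'
#' Raw well intensities are mapped through the plate controls so that the
#' reporter-targeting siRNA lands at -1, the negative control at 0 and
#' the proteasome-inhibitor control at +1. With control means `c_minus`,
#' `c_zero`, `c_plus` the score is piecewise linear and continuous at 0:
#' `(x - c_zero)/(c_zero - c_minus)` below the negative-control mean,
#' `(x - c_zero)/(c_plus - c_zero)` above it.
#'
#' Anchors are estimated from usable (non-low-count) control wells,
#' pooled across the whole experiment by default: with only two negative
#' wells per plate, per-plate anchors inject substantial estimation noise
#' into every score and distort the null tail, whereas experiment-wide
#' anchors keep scores an affine map of raw intensity. Use
#' `per = "plate"` when plates drift relative to one another.
#'
#' @param wells well table from [aggregate_wells()] or
#'   [simulate_screen_plates()], with `raw_mfi`/`raw_integrated` and
#'   `role` columns.
#' @param per anchor pooling: `"experiment"` (default) or `"plate"`.
#' @return `wells` plus `score_mfi`, `score_integrated` and a logical
#'   `plate_valid`; anchor means are attached as attribute `anchors`.
#'   Plates whose anchors violate `c_minus < c_zero < c_plus` are flagged
#'   invalid and their scores set to NA.
#' @export
anchor_normalize <- function(wells, per = c("experiment", "plate")) {
  per <- match.arg(per)
  stopifnot(all(c("role", "raw_mfi", "raw_integrated") %in% names(wells)))
  usable <- if ("low_count" %in% names(wells)) !wells$low_count
            else rep(TRUE, nrow(wells))
  groups <- if (per == "plate") split(seq_len(nrow(wells)), wells$plate_id)
            else list(experiment = seq_len(nrow(wells)))
  wells$score_mfi <- NA_real_
  wells$score_integrated <- NA_real_
  wells$plate_valid <- TRUE
  anchors <- list()
  score1 <- function(x, cm, c0, cp)
    ifelse(x < c0, (x - c0) / (c0 - cm), (x - c0) / (cp - c0))
  for (g in names(groups)) {
    idx <- groups[[g]]
    role <- wells$role[idx]
    for (col in c("raw_mfi", "raw_integrated")) {
      u <- usable[idx]
      cm <- mean(wells[[col]][idx][role == "cgas" & u])
      c0 <- mean(wells[[col]][idx][role == "negative" & u])
      cp <- mean(wells[[col]][idx][role == "epoxomicin" & u])
      if (!all(is.finite(c(cm, c0, cp))))
        stop("missing control role in group '", g, "'")
      sc <- paste0("score_", sub("^raw_", "", col))
      if (cm >= c0 || cp <= c0) {
        wells$plate_valid[idx] <- FALSE
        warning("anchor ordering violated in group '", g,
                "'; wells flagged invalid")
      } else {
        wells[[sc]][idx] <- score1(wells[[col]][idx], cm, c0, cp)
      }
      anchors[[g]][[col]] <- c(cgas = cm, negative = c0, epoxomicin = cp)
    }
  }
  wells$score_mfi[!wells$plate_valid] <- NA_real_
  wells$score_integrated[!wells$plate_valid] <- NA_real_
  attr(wells, "anchors") <- anchors
  wells
}

#' Call screen hits at a k-s.d. threshold
#'
#' A well is a hit when its score deviates from the mean negative-control
#' score by strictly more than `k_sd` standard deviations. The scale is,
#' by default, a robust (MAD-based) s.d. of the sample-well scores: in an
#' arrayed screen almost all siRNAs are inert, so the sample-well MAD
#' estimates the null spread precisely and robustly, whereas the handful
#' of negative-control wells per plate both under-represents that spread
#' (each contributes to its own anchor) and estimates it noisily.
#' `scale_from = "negative"` applies the literal negative-control s.d.
#'
#' @param wells scored well table from [anchor_normalize()].
#' @param k_sd hit threshold in s.d. units.
#' @param statistic score column to gate on (`score_integrated` is
#'   reported but not gated by default).
#' @param scale_from `"samples"` (robust MAD of sample scores) or
#'   `"negative"` (s.d. of negative-control scores).
#' @param hits_required gene-level rule: minimum siRNA wells flagged in a
#'   consistent direction for the gene to be called.
#' @return list: `wells` (with `z`, `hit`, `direction`) and `genes`
#'   (per-gene `n_wells`, `n_hits_up`, `n_hits_down`, `mean_score`,
#'   `hit`, `direction`).
#' @export
call_hits <- function(wells, k_sd = 3, statistic = "score_mfi",
                      scale_from = c("samples", "negative"),
                      hits_required = 1L) {
  scale_from <- match.arg(scale_from)
  ok <- wells$plate_valid & is.finite(wells[[statistic]])
  usable <- ok & !(if ("low_count" %in% names(wells)) wells$low_count
                   else FALSE)
  neg <- wells[[statistic]][usable & wells$role == "negative"]
  if (length(neg) < 4L)
    stop("need at least 4 usable negative-control wells")
  center <- mean(neg)
  samp <- wells[[statistic]][usable & wells$role == "sample"]
  s <- if (scale_from == "samples")
    stats::mad(samp, center = stats::median(samp))
  else stats::sd(neg)
  if (!is.finite(s) || s == 0)
    stop("degenerate (zero) score spread; cannot calibrate hits")
  wells$z <- (wells[[statistic]] - center) / s
  wells$hit <- ok & abs(wells$z) > k_sd & wells$role == "sample"
  wells$direction <- ifelse(!wells$hit, "none",
                            ifelse(wells$z > 0, "up", "down"))
  sw <- wells[wells$role == "sample" & ok, ]
  genes <- do.call(rbind, lapply(split(sw, sw$gene), function(d) {
    up <- sum(d$direction == "up"); down <- sum(d$direction == "down")
    data.frame(gene = d$gene[1], n_wells = nrow(d),
               n_hits_up = up, n_hits_down = down,
               mean_score = mean(d[[statistic]]),
               hit = max(up, down) >= hits_required,
               direction = if (up > down) "up"
                           else if (down > up) "down" else "none")
  }))
  genes <- genes[order(-genes$mean_score), ]
  rownames(genes) <- NULL
  list(wells = wells, genes = genes)
}

#' Plot-ready screen report
#'
#' Scatter table of MFI score against integrated-intensity score for
#' every scored well, plus a gene list ranked by mean MFI score across
#' siRNAs (largest increase first).
#'
#' @param wells scored well table (optionally after [call_hits()]).
#' @return list: `scatter` (well_id, plate_id, role, gene, score_mfi,
#'   score_integrated, and hit/direction when present) and `genes`.
#' @export
screen_report <- function(wells) {
  cols <- intersect(c("well_id", "plate_id", "role", "gene", "sirna_id",
                      "score_mfi", "score_integrated", "z", "hit",
                      "direction"), names(wells))
  scatter <- wells[, cols]
  sw <- wells[wells$role == "sample" & is.finite(wells$score_mfi), ]
  genes <- if (nrow(sw)) {
    g <- stats::aggregate(cbind(score_mfi, score_integrated) ~ gene,
                          data = sw, FUN = mean)
    g[order(-g$score_mfi), ]
  } else data.frame(gene = character(), score_mfi = numeric(),
                    score_integrated = numeric())
  rownames(genes) <- NULL
  list(scatter = scatter, genes = genes)
}
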