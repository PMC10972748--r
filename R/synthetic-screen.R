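#' Arrayed RNAi screen design
#'
#' Defaults mirror a genome-subset ubiquitin-proteasome-system screen:
#' 972 gene targets with three independent siRNAs each, arrayed on
#' 96-well plates that carry 8 control wells apiece -- 2 negative-control
#' siRNA wells (anchor 0), 2 wells of siRNA against the reporter itself
#' (anchor -1) and 4 proteasome-inhibitor (epoxomicin) wells (anchor +1).
#'
#' @param n_genes number of gene targets in the library.
#' @param sirnas_per_gene independent siRNAs per target (one well each).
#' @param controls_per_plate named counts of control wells per plate.
#' @param effect_map named numeric: true effect of a gene on the
#'   anchor-normalized score scale (0 = inert). Genes not listed are
#'   inert.
#' @param well_noise_sd well-to-well technical noise sd, in anchor units.
#'   A well averages >1000 cells, so the CV of its mean is small; 0.05
#'   anchor units corresponds to a raw well-mean CV of a few percent.
#' @param anchor_raw true raw MFI levels (AU) of the three anchors. The
#'   defaults are equidistant (reporter knockdown halves the baseline
#'   well MFI, proteasome block raises it by half), so the two
#'   normalization slopes coincide and null well scores stay Gaussian;
#'   with strongly asymmetric anchors the piecewise map scales the two
#'   sides of the null differently.
#' @param integrated_scale mean nuclear area (px) linking MFI to
#'   integrated-intensity anchors.
#' @param mean_cells Poisson mean of cells imaged per well.
#' @return list of class `screen_design`.
#' @export
screen_design <- function(n_genes = 972L, sirnas_per_gene = 3L,
                          controls_per_plate = c(negative = 2L, cgas = 2L,
                                                 epoxomicin = 4L),
                          effect_map = NULL,
                          well_noise_sd = 0.05,
                          anchor_raw = c(cgas = 120, negative = 240,
                                         epoxomicin = 360),
                          integrated_scale = 600,
                          mean_cells = 900) {
  stopifnot(sum(controls_per_plate) == 8L,
            all(c("negative", "cgas", "epoxomicin") %in%
                  names(controls_per_plate)),
            well_noise_sd >= 0,
            anchor_raw[["cgas"]] < anchor_raw[["negative"]],
            anchor_raw[["negative"]] < anchor_raw[["epoxomicin"]])
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (!is.null(effect_map)) {
    bad <- setdiff(names(effect_map), genes)
    if (length(bad))
      stop("effect requested for gene(s) not in library: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes),
                 sirnas_per_gene = as.integer(sirnas_per_gene),
                 genes = genes,
                 controls_per_plate = controls_per_plate,
                 effect_map = effect_map,
                 well_noise_sd = well_noise_sd,
                 anchor_raw = anchor_raw,
                 integrated_scale = integrated_scale,
                 mean_cells = mean_cells),
            class = "screen_design")
}

# internal: piecewise inverse of the anchor normalization -- maps a score
# back to raw intensity given the three true anchor levels, so generated
# plates are consistent with anchor_normalize() by construction
anchor_inverse <- function(score, a_minus, a_zero, a_plus) {
  ifelse(score < 0,
         a_zero + score * (a_zero - a_minus),
         a_zero + score * (a_plus - a_zero))
}

#' Simulate an arrayed screen as per-well intensity tables
#'
#' Wells are generated in anchor-score space (true effect + Gaussian
#' well noise, controls around their anchors) and mapped to raw MFI /
#' integrated intensity through the inverse of the anchor normalization,
#' so that after [anchor_normalize()] a gene's expected score equals its
#' entry in `effect_map`.
#'
#' @param design a [screen_design()].
#' @param seed integer seed.
#' @return list with `wells` (well_id, plate_id, role, gene, sirna_id,
#'   raw_mfi, raw_integrated, n_cells) and `truth` (per sample well:
#'   truth_effect).
#' @export
simulate_screen_plates <- function(design = screen_design(), seed = 1L) {
  rows <- LETTERS[1:8]
  all_wells <- as.vector(outer(rows, sprintf("%02d", 1:12), paste0))
  ctrl_wells <- c(negative = list(c("A01", "B01")),
                  cgas = list(c("C01", "D01")),
                  epoxomicin = list(c("E01", "F01", "G01", "H01")))
  sample_pos <- setdiff(all_wells, unlist(ctrl_wells))

  gene <- rep(design$genes, each = design$sirnas_per_gene)
  sirna <- paste0(gene, "_s", rep(seq_len(design$sirnas_per_gene),
                                  times = design$n_genes))
  n_samp <- length(gene)
  n_per_plate <- length(sample_pos)
  n_plates <- ceiling(n_samp / n_per_plate)

  plate_of <- rep(seq_len(n_plates), each = n_per_plate)[seq_len(n_samp)]
  well_of <- rep(sample_pos, times = n_plates)[seq_len(n_samp)]
  samp <- data.frame(well_id = well_of,
                     plate_id = sprintf("P%03d", plate_of),
                     role = "sample", gene = gene, sirna_id = sirna)

  ctrl <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    do.call(rbind, lapply(names(ctrl_wells), function(role) {
      data.frame(well_id = ctrl_wells[[role]],
                 plate_id = sprintf("P%03d", p), role = role,
                 gene = NA_character_, sirna_id = NA_character_)
    }))
  }))
  wells <- rbind(samp, ctrl)

  eff <- numeric(nrow(wells))
  if (!is.null(design$effect_map)) {
    m <- match(wells$gene, names(design$effect_map))
    eff[!is.na(m)] <- design$effect_map[m[!is.na(m)]]
  }
  eff[wells$role == "cgas"] <- -1
  eff[wells$role == "epoxomicin"] <- 1

  a <- design$anchor_raw
  with_seed(seed, {
    s_mfi <- eff + stats::rnorm(nrow(wells), 0, design$well_noise_sd)
    s_int <- eff + stats::rnorm(nrow(wells), 0, design$well_noise_sd)
    wells$raw_mfi <- anchor_inverse(s_mfi, a[["cgas"]], a[["negative"]],
                                    a[["epoxomicin"]])
    sc <- design$integrated_scale
    wells$raw_integrated <- anchor_inverse(s_int, a[["cgas"]] * sc,
                                           a[["negative"]] * sc,
                                           a[["epoxomicin"]] * sc)
    wells$n_cells <- stats::rpois(nrow(wells), design$mean_cells)
  })

  truth <- wells[wells$role == "sample",
                 c("well_id", "plate_id", "gene", "sirna_id")]
  truth$truth_effect <- eff[wells$role == "sample"]
  list(wells = wells, truth = truth)
}
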