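test_that("well aggregation averages cells per well", {
  layout <- data.frame(well_id = c("A01", "A02"), plate_id = "P1",
                       role = c("negative", "sample"),
                       gene = c(NA, "g1"), sirna_id = c(NA, "g1_s1"))
  cells <- data.frame(
    well_id = c("A01", "A01", "A02", "A02"), plate_id = "P1",
    cgas_gfp_mfi_corrected = c(100, 200, 300, 300),
    cgas_gfp_integrated = c(1000, 2000, 3000, 3000))
  w <- aggregate_wells(cells, layout, min_cells = 1)
  expect_equal(w$raw_mfi, c(150, 300))
  expect_equal(w$raw_integrated, c(1500, 3000))
  expect_equal(w$n_cells, c(2L, 2L))

  bad <- cells; bad$well_id[1] <- "Z99"
  expect_error(aggregate_wells(bad, layout, min_cells = 1), "unknown")
  expect_error(aggregate_wells(cells[1:2, ], layout, min_cells = 1),
               "no cells")
  # low-count flag
  w2 <- aggregate_wells(cells, layout, min_cells = 3)
  expect_true(all(w2$low_count))
})

test_that("anchor normalization maps control means to -1/0/+1 exactly", {
  # probe wells placed exactly at the realized control means must score
  # exactly -1, 0, +1 -- the defining property of the normalization
  scr <- simulate_screen_plates(screen_design(n_genes = 88), seed = 6)
  for (per in c("experiment", "plate")) {
    sc <- anchor_normalize(scr$wells, per = per)
    anchors <- attr(sc, "anchors")
    probes <- do.call(rbind, lapply(names(anchors), function(g) {
      a <- anchors[[g]][["raw_mfi"]]
      data.frame(well_id = paste0("probe", 1:3),
                 plate_id = if (per == "plate") g else sc$plate_id[1],
                 role = "sample", gene = "probe", sirna_id = "probe",
                 raw_mfi = unname(a),
                 raw_integrated = unname(anchors[[g]][["raw_integrated"]]),
                 n_cells = 1000L)
    }))
    sc2 <- anchor_normalize(rbind(scr$wells, probes), per = per)
    pr <- sc2[sc2$gene %in% "probe", ]
    expect_equal(pr$score_mfi, rep(c(-1, 0, 1), nrow(pr) / 3),
                 tolerance = 1e-12)
    expect_equal(pr$score_integrated, rep(c(-1, 0, 1), nrow(pr) / 3),
                 tolerance = 1e-12)
  }
})

test_that("the piecewise score matches hand evaluation and is affine-invariant", {
  wells <- data.frame(
    well_id = sprintf("W%d", 1:9), plate_id = "P1",
    role = c("cgas", "cgas", "negative", "negative",
             "epoxomicin", "epoxomicin", "epoxomicin", "epoxomicin",
             "sample"),
    gene = c(rep(NA, 8), "g1"), sirna_id = c(rep(NA, 8), "g1_s1"),
    raw_mfi = c(50, 50, 100, 100, 200, 200, 200, 200, 150),
    raw_integrated = c(50, 50, 100, 100, 200, 200, 200, 200, 150))
  sc <- anchor_normalize(wells, per = "plate")
  expect_equal(sc$score_mfi[9], 0.5)              # (150-100)/(200-100)
  expect_equal(sc$score_mfi[1], -1)
  below <- wells; below$raw_mfi[9] <- 75
  expect_equal(anchor_normalize(below, per = "plate")$score_mfi[9], -0.5)

  # translation and positive affine invariance of raw intensities
  aff <- wells
  aff$raw_mfi <- 3.7 * aff$raw_mfi + 220
  aff$raw_integrated <- 0.4 * aff$raw_integrated + 11
  expect_equal(anchor_normalize(aff, per = "plate")$score_mfi,
               sc$score_mfi)
  expect_equal(anchor_normalize(aff, per = "plate")$score_integrated,
               sc$score_integrated)

  # violated anchor ordering flags the plate invalid
  badw <- wells; badw$raw_mfi[1:2] <- 500
  expect_warning(scb <- anchor_normalize(badw, per = "plate"), "ordering")
  expect_true(all(!scb$plate_valid))
  expect_true(all(is.na(scb$score_mfi)))
})

test_that("hit calling is strict at the threshold and finds planted genes", {
  scr <- simulate_screen_plates(screen_design(n_genes = 352), seed = 8)
  sc <- anchor_normalize(scr$wells)
  h <- call_hits(sc)

  # boundary convention: a score exactly at k_sd s.d. is not a hit.
  # Constructed so the robust scale is exactly 1 and the negative mean
  # exactly 0: 50 samples at +/- qnorm(0.75) (MAD = 1) plus two probes.
  q <- qnorm(0.75)
  s_exp <- mad(rep(c(-q, q), 25), center = 0)  # the scale call_hits sees
  probe_scores <- c(rep(c(-q, q), 25), -3 * s_exp, 3 * s_exp)
  toy <- data.frame(
    well_id = sprintf("W%03d", seq_len(length(probe_scores) + 4)),
    plate_id = "P1",
    role = c(rep("sample", length(probe_scores)), rep("negative", 4)),
    gene = c(sprintf("g%03d", seq_along(probe_scores)), rep(NA, 4)),
    score_mfi = c(probe_scores, 0, 0, 0, 0),
    plate_valid = TRUE)
  ht <- call_hits(toy)
  at3 <- abs(toy$score_mfi) == 3 * s_exp
  expect_false(any(ht$wells$hit[at3]))
  toy$score_mfi[at3] <- sign(toy$score_mfi[at3]) * 3.01 * s_exp
  ht2 <- call_hits(toy)
  over <- abs(toy$score_mfi) > 3 * s_exp
  expect_true(all(ht2$wells$hit[over]))
  expect_identical(sort(ht2$wells$direction[over]), c("down", "up"))

  # planted strong effects: all three wells flagged in the right direction
  samp <- sc$score_mfi[sc$role == "sample"]
  sd_null <- mad(samp, center = median(samp))
  des <- screen_design(n_genes = 352,
                       effect_map = c(gene0010 = 6 * sd_null,
                                      gene0020 = -6 * sd_null))
  scr6 <- simulate_screen_plates(des, seed = 9)
  h6 <- call_hits(anchor_normalize(scr6$wells))
  up <- h6$wells[h6$wells$gene %in% "gene0010", ]
  dn <- h6$wells[h6$wells$gene %in% "gene0020", ]
  expect_true(all(up$hit) && all(up$direction == "up"))
  expect_true(all(dn$hit) && all(dn$direction == "down"))
  g <- h6$genes
  expect_true(g$hit[g$gene == "gene0010"])
  expect_identical(g$direction[g$gene == "gene0020"], "down")

  # ranked report puts the largest planted effect first
  rep6 <- screen_report(h6$wells)
  expect_identical(rep6$genes$gene[1], "gene0010")
  # anchors sit at -1 / 0 / +1 on the scatter axes
  expect_equal(mean(rep6$scatter$score_mfi[rep6$scatter$role == "cgas"]),
               -1, tolerance = 1e-12)

  # degenerate zero spread
  sc0 <- anchor_normalize(
    simulate_screen_plates(screen_design(n_genes = 88,
                                         well_noise_sd = 0), seed = 1)$wells)
  expect_error(call_hits(sc0), "degenerate")
})

test_that("a null screen is calibrated to the Gaussian 3-s.d. tail", {
  # ~3,000 inert sample wells; tail fraction within its binomial envelope
  scr <- simulate_screen_plates(screen_design(), seed = 10)
  h <- call_hits(anchor_normalize(scr$wells))
  sw <- h$wells[h$wells$role == "sample", ]
  p0 <- 2 * pnorm(-3)
  ci <- 1.96 * sqrt(p0 * (1 - p0) / nrow(sw))
  expect_lt(abs(mean(sw$hit) - p0), ci + 1e-9)
})

test_that("empty sample sets produce header-only reports", {
  scr <- simulate_screen_plates(screen_design(n_genes = 88), seed = 2)
  ctrl_only <- scr$wells[scr$wells$role != "sample", ]
  sc <- anchor_normalize(ctrl_only)
  rep0 <- screen_report(sc)
  expect_equal(nrow(rep0$genes), 0)
  expect_true(all(c("score_mfi", "score_integrated") %in%
                    names(rep0$scatter)))
})
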