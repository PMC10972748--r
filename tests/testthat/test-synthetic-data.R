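test_that("cell population honours phase fractions and DNA rules", {
  # single-phase population
  pop <- make_cell_population(1000, phase_fractions = c(G1 = 1), seed = 3)
  expect_equal(nrow(pop), 1000)
  expect_true(all(pop$phase == "G1"))
  expect_true(all(abs(pop$dna_content - 2) < 2 * 4 * 0.05))

  # seed determinism: identical tables for identical seeds
  a <- make_cell_population(4, c(G1 = .25, S = .25, G2 = .25, M = .25),
                            seed = 7)
  b <- make_cell_population(4, c(G1 = .25, S = .25, G2 = .25, M = .25),
                            seed = 7)
  expect_identical(a, b)

  # realized fractions close to targets at n = 5000 (~3 binomial s.e.)
  pop <- make_cell_population(5000, seed = 1)
  frac <- prop.table(table(pop$phase))
  expect_true(all(abs(frac - c(0.5, 0.3, 0.15, 0.05)) < 0.02))

  # per-phase DNA content invariants
  expect_true(all(abs(pop$dna_content[pop$phase == "G1"] - 2) < 0.5))
  expect_true(all(abs(pop$dna_content[pop$phase %in% c("G2", "M")] - 4) < 1))
  s_dna <- pop$dna_content[pop$phase == "S"]
  expect_true(all(s_dna > 2 & s_dna < 4))
  expect_true(all(pop$radius > 0))

  expect_error(make_cell_population(10, c(G1 = .5, S = .4)), "sum to 1")
  expect_error(make_cell_population(10, c(G1 = .5, XX = .5)),
               "unknown phase")
})

test_that("rendering is exact without noise and unbiased with noise", {
  # one cell, zero noise: pixels are exactly background or level
  pop <- make_cell_population(1, c(G1 = 1), seed = 1,
                              level_sdlog = c(dapi = 0, edu = 0,
                                              cgas_gfp = 0))
  pop$centroid_x <- 60; pop$centroid_y <- 60
  pop$level_dapi <- 200
  fld <- render_field(pop, field_spec(120, 120, background = 100,
                                      noise_sd = 0),
                      cytosol_channels = character())
  dapi <- fld$channels$dapi
  expect_setequal(unique(as.vector(dapi)), c(100, 300))
  expect_equal(sort(unique(as.vector(fld$mask))), c(0L, 1L))
  expect_identical(which(dapi == 300), which(fld$mask == 1L))

  # zero cells: pure background, empty mask
  fld0 <- render_field(make_cell_population(1, c(G1 = 1))[0, ],
                       field_spec(50, 50, noise_sd = 2, seed = 9))
  expect_true(all(fld0$mask == 0L))
  expect_equal(mean(fld0$channels$dapi), 100, tolerance = 0.01)

  # truth conservation: mask labels biject with cell ids
  fld <- make_test_field(n = 15, seed = 21, noise_sd = 3)
  expect_setequal(unique(fld$mask[fld$mask > 0]), fld$cells$cell_id)

  # in-mask DAPI means match truth within 3 noise s.e. per cell
  for (i in seq_len(nrow(fld$cells))) {
    px <- which(fld$mask == fld$cells$cell_id[i])
    se <- 3 / sqrt(length(px))
    expect_lt(abs(mean(fld$channels$dapi[px]) -
                    (fld$cells$level_dapi[i] + 100)), 3 * se + 0.5)
  }

  # out-of-bounds nucleus is an error
  popb <- make_cell_population(1, c(G1 = 1), seed = 1)
  popb$centroid_x <- 3; popb$centroid_y <- 50
  expect_error(render_field(popb, field_spec(100, 100)), "out of field")
})

test_that("field TIFF round-trip preserves pixel counts and labels", {
  fld <- make_test_field(n = 4, seed = 5, noise_sd = 0, size = 200)
  dir <- withr::local_tempdir()
  write_field_tiff(fld, dir, "f1")
  dapi <- read_field_tiff(file.path(dir, "f1_dapi.tif"))
  # 16-bit storage quantizes to unit steps
  expect_lt(max(abs(dapi - fld$channels$dapi)), 0.51)
  mask <- read_field_tiff(file.path(dir, "f1_mask.tif"),
                          integer_labels = TRUE)
  expect_identical(mask, fld$mask)
})

test_that("simulated screen matches the library design", {
  scr <- simulate_screen_plates(screen_design(), seed = 2)
  w <- scr$wells
  samp <- w[w$role == "sample", ]
  expect_equal(length(unique(samp$gene)), 972)
  expect_true(all(table(samp$gene) == 3))
  ctrl <- table(w$plate_id[w$role != "sample"])
  expect_true(all(ctrl == 8))
  per_role <- table(w$role[w$role != "sample"], w$plate_id[w$role != "sample"])
  expect_true(all(per_role["negative", ] == 2))
  expect_true(all(per_role["cgas", ] == 2))
  expect_true(all(per_role["epoxomicin", ] == 4))

  # zero noise, no effects: every sample well sits at the negative level
  scr0 <- simulate_screen_plates(screen_design(well_noise_sd = 0), seed = 1)
  expect_true(all(scr0$wells$raw_mfi[scr0$wells$role == "sample"] == 240))

  # a planted +6 effect appears ~6 anchor units above negative controls
  des <- screen_design(effect_map = c(gene0100 = 6))
  scr6 <- simulate_screen_plates(des, seed = 3)
  sc <- anchor_normalize(scr6$wells)
  g <- sc$score_mfi[sc$gene %in% "gene0100"]
  expect_equal(mean(g), 6, tolerance = 0.15)

  expect_error(screen_design(effect_map = c(nosuchgene = 2)),
               "not in library")
})

test_that("chase simulation follows first-order decay", {
  # half-life identity at zero noise
  cd <- simulate_chase(chase_truth(rate_k = log(2) / 4, noise_cv = 0),
                       seed = 1)
  expect_equal(cd$value[cd$time_h == 4], cd$value[cd$time_h == 0] / 2)
  # zero rate: flat
  cd0 <- simulate_chase(chase_truth(rate_k = 0, noise_cv = 0), seed = 1)
  expect_true(all(cd0$value == cd0$value[1]))
  # seeded noisy chase is recovered by the decay fit within 10%
  cdn <- simulate_chase(chase_truth(rate_k = 0.2, noise_cv = 0.05),
                        seed = 3)
  f <- fit_exponential_decay(cdn$time_h, cdn$value)
  expect_lt(abs(f$rate_k - 0.2) / 0.2, 0.10)
  expect_error(chase_truth(noise_cv = -1), "noise_cv")
  expect_error(chase_truth(times = c(0, 2, 2)), "increasing")
})

test_that("sensorgram generator obeys Langmuir identities", {
  # near-saturating concentration plateaus at rmax
  sg <- simulate_sensorgrams(1e5, 1e-2, 1e-3, rmax = 2, noise_sd = 0)
  expect_equal(max(sg$response), 2, tolerance = 1e-3)
  # C = Kd: association plateau is rmax/2
  kd <- 1e-2 / 1e5
  sg2 <- simulate_sensorgrams(1e5, 1e-2, kd, t_assoc = 3000, rmax = 2,
                              noise_sd = 0)
  expect_equal(max(sg2$response), 1, tolerance = 1e-3)
  expect_error(simulate_sensorgrams(-1, 1e-2, 1e-6), "positive")
})
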