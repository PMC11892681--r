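test_that("region fields hit the requested prevalence up to one pixel", {
  rf <- generate_tissue_regions(c(64, 64), 0.4, 6, seed = 2)
  expect_equal(sum(rf), round(0.4 * 64 * 64))
  expect_true(abs(mean(rf) - 0.4) <= 1 / (64 * 64))
  expect_equal(sum(generate_tissue_regions(c(8, 8), 1.0, 3, 1)), 64)
  expect_equal(sum(generate_tissue_regions(c(8, 8), 0.0, 3, 1)), 0)
  expect_error(generate_tissue_regions(c(0, 4), 0.5, 3, 1), "positive")
  expect_error(generate_tissue_regions(c(4, 4), 1.5, 3, 1), "\\[0, 1\\]")
  # determinism and spatial coherence (smoothing gives few label changes)
  expect_identical(rf, generate_tissue_regions(c(64, 64), 0.4, 6, seed = 2))
  flips <- sum(abs(diff(rf))) + sum(abs(diff(t(rf))))
  expect_lt(flips / (2 * 64 * 63), 0.25)  # far below the 0.48 of white noise
})

test_that("zero-noise spectra equal their programmed closed form", {
  arms <- c("vehicle", "drugA")
  cfg <- tiny_config(noise_cv = 0, jitter_ppm = 0, grid = c(4, 4))
  rf <- matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4)
  d <- generate_msi_dataset(cfg, 1, "drugA", rf, seed = 9, mode = "centroid")
  panel <- cfg$metabolite_panel
  expected <- function(j, inA)
    2^(panel$baseline_log2[j] + cfg$batch_log2_scale[1] +
       panel$region_effect_log2[j] * inA + panel$effect_drugA[j])
  inA <- as.vector(rf) == 1
  for (p in c(1, 9, 16)) {
    got <- d$spectra[[p]]$intensity
    want <- vapply(seq_len(nrow(panel)), expected, numeric(1), inA = inA[p])
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(d$spectra[[p]]$mz,
                 adduct_mz(panel$neutral_mass, "[M+H]+")[seq_len(nrow(panel))] * 1,
                 tolerance = 1e-12)
  }
  # same seed twice: identical datasets
  d2 <- generate_msi_dataset(cfg, 1, "drugA", rf, seed = 9, mode = "centroid")
  expect_identical(d, d2)
  expect_error(generate_msi_dataset(cfg, 1, "mystery", rf, 1), "unknown arm")
})

test_that("drug ion is at background in vehicle and full level in treated arms", {
  cfg <- tiny_config(noise_cv = 0, jitter_ppm = 0, grid = c(3, 3))
  rf <- matrix(0L, 3, 3)
  panel <- cfg$metabolite_panel
  j <- which(panel$is_drug_ion)
  dv <- generate_msi_dataset(cfg, 1, "vehicle", rf, 1, mode = "centroid")
  dt <- generate_msi_dataset(cfg, 1, "drugA", rf, 1, mode = "centroid")
  expect_equal(log2(dt$spectra[[1]]$intensity[j]) -
               log2(dv$spectra[[1]]$intensity[j]), 8)
  # spatially uniform at zero noise
  expect_equal(length(unique(vapply(dt$spectra, function(s) s$intensity[j],
                                    numeric(1)))), 1L)
})

test_that("noisy per-metabolite mean log2 intensity matches the programmed value", {
  # median-one lognormal noise leaves E[log2 intensity] at the programmed
  # value; Monte-Carlo over ~1000 pixels
  cfg <- tiny_config(noise_cv = 0.2, jitter_ppm = 0, grid = c(32, 32))
  rf <- matrix(1L, 32, 32)  # all Region A
  d <- generate_msi_dataset(cfg, 1, "vehicle", rf, seed = 4, mode = "centroid")
  panel <- cfg$metabolite_panel
  obs <- rowMeans(log2(vapply(d$spectra, `[[`, numeric(nrow(panel)), "intensity")))
  want <- panel$baseline_log2 + cfg$batch_log2_scale[1] + panel$region_effect_log2
  want[panel$is_drug_ion] <- want[panel$is_drug_ion] - 8  # vehicle background
  expect_true(all(abs(obs - want) < 0.05))
  # lognormal CV: spatial CV of the uniform drug field in a treated arm
  dt <- generate_msi_dataset(cfg, 1, "drugA", rf, seed = 4, mode = "centroid")
  j <- which(panel$is_drug_ion)
  v <- vapply(dt$spectra, function(s) s$intensity[j], numeric(1))
  expect_equal(sd(v) / mean(v), 0.2, tolerance = 0.03)
})

test_that("IMC phantom respects geometry and zero-noise marker means", {
  rf <- matrix(1L, 8, 8)          # all Region A
  rf[, 5:8] <- 0L                 # right half Region B
  aff <- affine_transform(diag(2), c(0, 0))
  rules <- default_marker_rules(c("vehicle", "drugA"))
  imc <- generate_imc_images(rf, aff, rules, "vehicle", cell_density = 400,
                             seed = 2, roi_um = 300, noise_sd = 0)
  expect_equal(dim(imc$images$DNA), c(300, 300))
  # nucleus areas from the DNA raster match pi r^2 within rasterisation error
  total_px <- sum(imc$images$DNA == 1)
  expect_equal(total_px, sum(round(pi * imc$cells$radius_um^2)),
               tolerance = 0.05)
  # programmed means recovered exactly inside nuclei at zero noise
  glut <- imc$images$GLUT1
  for (i in seq_len(nrow(imc$cells))) {
    cx <- imc$cells$x_um[i]; cy <- imc$cells$y_um[i]
    val <- glut[ceiling(cy), ceiling(cx)]
    want <- rules$mean_intensity[rules$marker == "GLUT1" &
                                 rules$region == imc$cells$region[i] &
                                 rules$arm == "vehicle"]
    expect_equal(val, want)
  }
  # zero cell density: background everywhere
  imc0 <- generate_imc_images(rf, aff, rules, "vehicle", cell_density = 0,
                              seed = 2, roi_um = 100)
  expect_true(all(imc0$images$pS6 == 0.02))
  # packing limit
  expect_error(generate_imc_images(rf, aff, rules, "vehicle",
                                   cell_density = 40000, seed = 2,
                                   roi_um = 100), "packing")
})

test_that("generate_study writes a complete, deterministic study", {
  cfg <- study_config(n_experiments = 2, arms = c("vehicle", "drugA"),
                      tissues_per_arm = 1, grid_shape = c(8, 8),
                      region_prevalence = c(vehicle = 0.8, drugA = 0.3),
                      metabolite_panel = default_metabolite_panel(
                        c("vehicle", "drugA"), 26),
                      seed = 7)
  dir1 <- withr::local_tempdir()
  st <- generate_study(cfg, dir1, imc_experiments = 2, roi_um = 120)
  expect_equal(nrow(st$manifest), 2 * 2 * 1)
  expect_true(all(file.exists(st$manifest$imzml)))
  expect_true(all(file.exists(sub("\\.imzML$", ".ibd", st$manifest$imzml))))
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_true(file.exists(file.path(dir1, "ground_truth.json")))
  # programmed prevalence ordering survives in the emitted ground truth
  fr <- vapply(st$ground_truth$region_field, mean, numeric(1))
  arms <- st$manifest$arm[match(names(fr), st$manifest$tissue_id)]
  expect_true(min(fr[arms == "vehicle"]) > max(fr[arms == "drugA"]))
  # identical seed, identical bytes
  dir2 <- withr::local_tempdir()
  generate_study(cfg, dir2, imc_experiments = 2, roi_um = 120)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_identical(f1, list.files(dir2, recursive = TRUE))
  sum1 <- tools::md5sum(file.path(dir1, f1))
  sum2 <- tools::md5sum(file.path(dir2, f1))
  expect_true(all(unname(sum1) == unname(sum2)))
  # written study reads back to the in-memory generation
  d <- read_imzml(st$manifest$imzml[1])
  expect_equal(nrow(d$coords), 64)
  expect_equal(d$arm, st$manifest$arm[1])
})
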