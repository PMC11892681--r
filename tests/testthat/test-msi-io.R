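test_that("rebinning is linear interpolation, zero outside support", {
  # constant intensity stays constant at interior bins
  s <- new_spectrum(c(100, 100.5, 101), c(3, 3, 3))
  r <- rebin_spectrum(s, 0.1, mass_range = c(100, 101))
  inside <- r$mz > 100 & r$mz < 101
  expect_true(all(abs(r$intensity[inside] - 3) < 1e-12))
  # hand-computed midpoint: (100.000, 0) -> (100.002, 10) gives 5 at 100.001
  s2 <- new_spectrum(c(100.000, 100.002), c(0, 10))
  r2 <- rebin_spectrum(s2, 0.001, mass_range = c(100 - 0.0005, 100.0025))
  expect_equal(r2$intensity[which.min(abs(r2$mz - 100.001))], 5,
               tolerance = 1e-9)
  # points on bin centres are reproduced exactly
  ax <- mass_axis(c(100, 101), 0.1)
  ctr <- axis_centres(ax)
  s3 <- new_spectrum(ctr, seq_along(ctr))
  r3 <- rebin_spectrum(s3, axis = ax)
  expect_equal(r3$intensity, as.numeric(seq_along(ctr)))
  # zero outside support
  s4 <- new_spectrum(c(100.4, 100.6), c(2, 2))
  r4 <- rebin_spectrum(s4, axis = ax)
  expect_true(all(r4$intensity[r4$mz < 100.4 | r4$mz > 100.6] == 0))
  expect_error(rebin_spectrum(new_spectrum(100, 1), 0.1), "< 2 points")
})

test_that("rebinning at the same width is the identity on bin centres", {
  ax <- mass_axis(c(200, 210), 0.05)
  s <- new_spectrum(axis_centres(ax), runif(length(axis_centres(ax))))
  r1 <- rebin_spectrum(s, axis = ax)
  r2 <- rebin_spectrum(r1, axis = ax)
  expect_equal(r1$intensity, r2$intensity, tolerance = 1e-12)
})

test_that("RMS normalisation: unit RMS, scale invariance, idempotence", {
  # [3, 4]: RMS = sqrt((9 + 16)/2) = sqrt(12.5)
  r <- rms_normalise(new_spectrum(c(1, 2), c(3, 4)))
  expect_equal(r$intensity, c(3, 4) / sqrt(12.5), tolerance = 1e-10)
  expect_equal(r$intensity, c(0.8485, 1.1314), tolerance = 1e-4)
  expect_equal(rms_normalise(new_spectrum(c(1, 2, 3), c(1, 1, 1)))$intensity,
               c(1, 1, 1))
  s <- new_spectrum(1:5, c(0, 2, 5, 1, 0))
  expect_equal(rms_normalise(s)$intensity,
               rms_normalise(new_spectrum(1:5, 7.3 * s$intensity))$intensity)
  expect_equal(rms_normalise(rms_normalise(s))$intensity,
               rms_normalise(s)$intensity)
  expect_equal(sqrt(mean(rms_normalise(s)$intensity^2)), 1)
  expect_error(rms_normalise(new_spectrum(1:3, c(0, 0, 0))), "all-zero")
})

test_that("mean spectrum is the pixel-wise arithmetic mean", {
  ax <- mass_axis(c(89.5, 310.5), 1)  # bin centres on integers
  sp <- list(new_spectrum(c(100, 200, 300), c(0, 2, 0)),
             new_spectrum(c(100, 200, 300), c(2, 0, 2)))
  d <- msi_dataset(data.frame(x = 0:1, y = c(0L, 0L)), sp, 50,
                   mass_range = c(90, 310))
  m <- mean_spectrum(d, axis = ax, normalise = FALSE)
  at <- function(mz) m$intensity[which.min(abs(m$mz - mz))]
  expect_equal(at(200), mean(c(2, 0)))  # pixel-wise mean at the sample point
  # single pixel: identity
  d1 <- msi_dataset(data.frame(x = 0L, y = 0L), sp[1], 50,
                    mass_range = c(90, 310))
  m1 <- mean_spectrum(d1, axis = ax, normalise = FALSE)
  r1 <- rebin_spectrum(sp[[1]], axis = ax)
  expect_equal(m1$intensity, r1$intensity)
  # commutes with pixel ordering
  d2 <- msi_dataset(data.frame(x = 1:0, y = c(0L, 0L)), rev(sp), 50,
                    mass_range = c(90, 310))
  expect_equal(mean_spectrum(d2, axis = ax, normalise = FALSE)$intensity,
               m$intensity)
})

test_that("imzML round-trip is the identity within float32", {
  d <- three_pixel_dataset()
  stem <- file.path(withr::local_tempdir(), "t1")
  write_imzml(d, stem)
  expect_true(file.exists(paste0(stem, ".imzML")))
  expect_true(file.exists(paste0(stem, ".ibd")))
  d2 <- read_imzml(paste0(stem, ".imzML"))
  expect_equal(d2$coords, d$coords)
  expect_equal(d2$tissue_id, "T1")
  expect_equal(d2$arm, "vehicle")
  expect_equal(d2$pixel_pitch, 50)
  for (i in seq_along(d$spectra)) {
    expect_equal(d2$spectra[[i]]$mz, d$spectra[[i]]$mz)  # float64 exact
    expect_equal(d2$spectra[[i]]$intensity, d$spectra[[i]]$intensity,
                 tolerance = 1e-6)
  }
  # zero-intensity points are preserved, not dropped
  expect_equal(length(d2$spectra[[2]]$intensity), 3L)
  expect_equal(d2$spectra[[2]]$intensity[c(1, 3)], c(0, 0))
})

test_that("imzML files follow the 1-based on-disk coordinate convention", {
  d <- three_pixel_dataset()
  stem <- file.path(withr::local_tempdir(), "conv")
  write_imzml(d, stem)
  doc <- xml2::read_xml(paste0(stem, ".imzML"))
  ns <- c(d = "http://psi.hupo.org/ms/mzml")
  xs <- as.integer(xml2::xml_attr(xml2::xml_find_all(
    doc, ".//d:cvParam[@accession='IMS:1000050']", ns), "value"))
  expect_equal(sort(unique(xs)), c(1L, 2L))  # memory holds 0-based 0,1
})

test_that("imzML error paths: empty pixel set, missing ibd, bad offsets", {
  d <- three_pixel_dataset()
  expect_error(msi_dataset(data.frame(x = integer(0), y = integer(0)),
                           list(), 50), "empty pixel")
  stem <- file.path(withr::local_tempdir(), "bad")
  write_imzml(d, stem)
  file.remove(paste0(stem, ".ibd"))
  expect_error(read_imzml(paste0(stem, ".imzML")), "missing .ibd")
  # truncate the ibd: offsets point beyond the file, error names a pixel
  stem2 <- file.path(withr::local_tempdir(), "trunc")
  write_imzml(d, stem2)
  sz <- file.info(paste0(stem2, ".ibd"))$size
  con <- file(paste0(stem2, ".ibd"), "r+b")
  truncate_ok <- tryCatch({ seek(con, sz - 20, rw = "write"); truncate(con); TRUE },
                          error = function(e) FALSE, finally = close(con))
  if (truncate_ok)
    expect_error(read_imzml(paste0(stem2, ".imzML")), "pixel")
})

test_that("written imzML parses with an independent reader", {
  d <- three_pixel_dataset()
  stem <- file.path(withr::local_tempdir(), "oracle")
  write_imzml(d, stem)
  script <- sprintf(paste0(
    "from pyimzml.ImzMLParser import ImzMLParser\n",
    "p = ImzMLParser(r'%s.imzML')\n",
    "for i, (x, y, z) in enumerate(p.coordinates):\n",
    "    mz, ii = p.getspectrum(i)\n",
    "    print(x, y, len(mz), round(float(sum(ii)), 4))\n"), stem)
  sf <- file.path(withr::local_tempdir(), "read_imzml.py")
  writeLines(script, sf)
  out <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  got <- read.table(text = paste(out, collapse = "\n"))
  expect_equal(got$V1, d$coords$x + 1L)
  expect_equal(got$V2, d$coords$y + 1L)
  expect_equal(got$V3, rep(3L, 3))
  expect_equal(got$V4,
               sapply(d$spectra, function(s) round(sum(s$intensity), 4)))
})
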