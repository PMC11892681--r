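uniform_spectrum <- function(y, lo = 100, w = 0.001) {
  ax <- mass_axis(c(lo, lo + length(y) * w), w)
  s <- new_spectrum(axis_centres(ax), y)
  attr(s, "axis") <- ax
  s
}

test_that("gradient detection finds apexes and bounds", {
  s <- uniform_spectrum(c(0, 1, 3, 1, 0))
  pt <- detect_peaks_gradient(s, min_apex = 0)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$left_idx, 1L)       # support edge
  expect_equal(pt$right_idx, 5L)
  expect_equal(pt$apex_mz, s$mz[3])
  # monotone ramp: no sign change, no peaks
  expect_equal(nrow(detect_peaks_gradient(uniform_spectrum(1:10), 0)), 0L)
  # non-uniform axis rejected
  bad <- new_spectrum(c(1, 2, 4), c(0, 1, 0))
  expect_error(detect_peaks_gradient(bad), "uniform axis")
})

test_that("two Gaussians are recovered within one bin of their means", {
  ax <- mass_axis(c(199, 301), 0.001)
  mz <- axis_centres(ax)
  mu <- c(mz[1000], mz[99000])   # true means on bin centres
  y <- 10 * exp(-(mz - mu[1])^2 / (2 * 0.05^2)) +
       4 * exp(-(mz - mu[2])^2 / (2 * 0.05^2))
  s <- new_spectrum(mz, y); attr(s, "axis") <- ax
  pt <- detect_peaks_gradient(s, min_apex = 0.5)
  expect_equal(nrow(pt), 2L)
  expect_true(all(abs(pt$apex_mz - mu) <= 0.001))
  expect_true(all(abs(pt$center_mz - mu) <= 0.001))
  # oracle: brute-force strict local maxima above the floor
  brute <- which(y > 0.5 & y > c(-Inf, y[-length(y)]) & y > c(y[-1], Inf))
  apex_idx <- match(pt$apex_intensity, y)
  expect_equal(apex_idx, brute)
})

test_that("every detected apex is a strict local maximum (property)", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      y <- abs(stats::filter(rnorm(400), rep(1, 5), sides = 2))
      y[is.na(y)] <- 0
      s <- uniform_spectrum(as.numeric(y))
      pt <- detect_peaks_gradient(s, min_apex = 0)
      idx <- match(pt$apex_intensity, s$intensity)
      for (k in seq_len(nrow(pt))) {
        i <- pt$left_idx[k]:pt$right_idx[k]
        a <- which.max(s$intensity[i]) + pt$left_idx[k] - 1L
        expect_gt(s$intensity[a], s$intensity[a - 1])
        expect_gt(s$intensity[a], s$intensity[a + 1])
      }
      # windows partition disjoint index ranges
      if (nrow(pt) > 1)
        expect_true(all(pt$left_idx[-1] > pt$right_idx[-nrow(pt)]))
    }
  })
})

test_that("integration sums window bins of the normalised pixel spectrum", {
  ax <- mass_axis(c(100, 100.005), 0.001)
  ctr <- axis_centres(ax)
  d <- msi_dataset(data.frame(x = 0L, y = 0L),
                   list(new_spectrum(ctr, c(0, 1, 3, 1, 0))), 50,
                   mass_range = c(100, 100.005))
  pt <- structure(data.frame(center_mz = ctr[3], left_mz = ctr[2],
                             right_mz = ctr[4], apex_mz = ctr[3],
                             apex_intensity = 3, left_idx = 2L, right_idx = 4L),
                  class = c("peak_table", "data.frame"), axis = ax)
  pm_raw <- integrate_peaks(d, pt, axis = ax, normalise = FALSE)
  expect_equal(unname(pm_raw$intensity[1, 1]), 5)  # 1 + 3 + 1
  pm <- integrate_peaks(d, pt, axis = ax, normalise = TRUE)
  rms <- sqrt(mean(c(0, 1, 3, 1, 0)^2))
  expect_equal(unname(pm$intensity[1, 1]), 5 / rms)
  # widening the bounds into flat zero baseline changes nothing
  pt2 <- pt; pt2$left_idx <- 1L; pt2$right_idx <- 5L
  expect_equal(integrate_peaks(d, pt2, axis = ax, normalise = FALSE)$intensity[1, 1],
               pm_raw$intensity[1, 1])
  # zero-signal pixel integrates to zero
  d0 <- msi_dataset(data.frame(x = 0L, y = 0L),
                    list(new_spectrum(ctr, rep(0, 5))), 50,
                    mass_range = c(100, 100.005))
  expect_equal(unname(integrate_peaks(d0, pt, axis = ax,
                                      normalise = FALSE)$intensity[1, 1]), 0)
})

test_that("ion images clip at the pooled 95th percentile, idempotently", {
  m <- two_population_matrix()
  m$intensity[, 1] <- 1:120
  m$pixels$x <- rep(0:11, 10); m$pixels$y <- rep(0:9, each = 12)
  img <- render_ion_image(m, 1)
  cap <- quantile(1:120, 0.95, names = FALSE)
  expect_equal(max(unlist(img), na.rm = TRUE), cap)
  # all-equal pixels are untouched
  m$intensity[, 2] <- 7
  expect_true(all(unlist(render_ion_image(m, 2)) == 7))
  # clipping an already-clipped image at the same cap changes nothing
  expect_identical(lapply(img, function(x) pmin(x, cap)), img)
})

test_that("annotation applies nested inclusion/accuracy windows", {
  db <- data.frame(name = c("AZD2014", "other"),
                   formula = c("C25H30N6O3", "C6H12O6"))
  cfg <- annotation_config(db, default_adducts("positive"),
                           inclusion_ppm = 10, accuracy_ppm = 10)
  pt <- structure(data.frame(center_mz = c(463.2452, 463.3000)),
                  class = c("peak_table", "data.frame"))
  ann <- annotate_peaks(pt, cfg)
  expect_equal(ann$name[ann$peak_idx == 1][1], "AZD2014")
  expect_equal(ann$adduct[ann$peak_idx == 1][1], "[M+H]+")
  expect_lt(abs(ann$ppm_error[ann$peak_idx == 1][1]), 0.2)
  # 463.3000 is ~118 ppm off: rejected at 10 ppm
  expect_false(2 %in% ann$peak_idx)
  # monotonicity: shrinking accuracy_ppm never adds assignments
  wide <- annotate_peaks(pt, annotation_config(db, default_adducts("positive"),
                                               300, 150))
  narrow <- annotate_peaks(pt, annotation_config(db, default_adducts("positive"),
                                                 300, 50))
  key <- function(a) paste(a$peak_idx, a$name, a$adduct)
  expect_true(all(key(narrow) %in% key(wide)))
  expect_error(annotation_config(db, "[M+H]+", 10, 70), "<=")
})

test_that("consensus matching keeps only peaks common to all experiments", {
  mk <- function(mzs) structure(data.frame(center_mz = mzs),
                                class = c("peak_table", "data.frame"))
  tabs <- list(A = mk(c(200.0000, 463.2452)),
               B = mk(c(200.0001, 463.2455)),
               C = mk(c(463.2449, 900.1)))
  ms <- match_peaks_across_experiments(tabs, match_ppm = 10)
  expect_equal(nrow(ms), 1L)  # 200 only in A,B; 900.1 only in C
  expect_equal(ms$consensus_mz, mean(c(463.2452, 463.2455, 463.2449)))
  expect_equal(ms$idx_A, 2L); expect_equal(ms$idx_C, 1L)
  # symmetric in table order
  ms2 <- match_peaks_across_experiments(rev(tabs), match_ppm = 10)
  expect_equal(ms2$consensus_mz, ms$consensus_mz)
  # empty intersection
  ms0 <- match_peaks_across_experiments(list(A = mk(100), B = mk(200)), 10)
  expect_equal(nrow(ms0), 0L)
  # ambiguous table: duplicate centres within tolerance
  expect_error(match_peaks_across_experiments(
    list(A = mk(c(300.0000, 300.0005)), B = mk(300.0000)), match_ppm = 10),
    "ambiguous")
  expect_error(match_peaks_across_experiments(list(A = mk(100)), 10), "at least 2")
})
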