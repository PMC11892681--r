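test_that("affine fitting recovers known transforms exactly", {
  # already-aligned landmarks: identity, zero residual
  P <- cbind(c(0, 100, 0, 100), c(0, 0, 100, 100))
  tr0 <- fit_affine(P, P)
  expect_equal(tr0$A, diag(2), tolerance = 1e-12)
  expect_equal(tr0$b, c(0, 0), tolerance = 1e-12)
  expect_lt(max(attr(tr0, "residuals")), 1e-9)
  # rotation 30 deg, scale 50, translation (120, -40): exact recovery
  th <- 30 * pi / 180
  A <- 50 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- c(120, -40)
  Q <- t(A %*% t(P) + b)
  tr <- fit_affine(P, Q)
  expect_equal(tr$A, A, tolerance = 1e-9)
  expect_equal(tr$b, b, tolerance = 1e-9)
  expect_lt(max(attr(tr, "residuals")), 1e-6)
  # inverse composes to identity
  rt <- apply_affine(invert_affine(tr), apply_affine(tr, P))
  expect_equal(rt, P, tolerance = 1e-9)
  expect_error(fit_affine(P[1:2, ], Q[1:2, ]), ">= 3")
  coll <- cbind(1:4, 2 * (1:4) + 3)
  expect_error(fit_affine(coll, coll), "collinear")
})

test_that("perturbed landmarks reproduce the normal-equations solution", {
  P <- cbind(c(0, 100, 0, 100), c(0, 0, 100, 100))
  Q <- t(2 * diag(2) %*% t(P) + c(10, 5))
  Q[4, ] <- Q[4, ] + c(1, 0)   # 1 µm perturbation
  tr <- fit_affine(P, Q)
  expect_gt(attr(tr, "rmse"), 0)
  # oracle: closed-form least squares via the normal equations
  X <- cbind(1, P)
  beta <- solve(t(X) %*% X, t(X) %*% Q)
  expect_equal(tr$b, unname(beta[1, ]), tolerance = 1e-9)
  expect_equal(tr$A, unname(t(beta[2:3, ])), tolerance = 1e-9)
})

test_that("label transfer maps MSI pixels to 50x50 IMC blocks under identity", {
  seg <- make_seg("t1", c(0, 1, 0, 1), c(0, 0, 1, 1), c("A", "B", "B", "A"))
  lab <- transfer_labels(seg, msi_pixel_pitch = 50,
                         affine = affine_transform(diag(2)),
                         imc_shape = c(100, 100), imc_pixel_pitch = 1)
  # exhaustive per-pixel check on the 2x2 MSI map
  for (r in 1:100) for (cl in c(1, 60)) {
    want <- seg$region[seg$x == (cl > 50) * 1 & seg$y == (r > 50) * 1]
    expect_identical(lab[r, cl], want)
  }
  expect_true(all(lab[1:50, 1:50] == "A"))
  expect_true(all(lab[51:100, 51:100] == "A"))
  expect_true(all(lab[1:50, 51:100] == "B"))
  # label areas conserved exactly for the identity transform
  expect_equal(sum(lab == "A") / 2500, sum(seg$region == "A"))
  # field entirely outside the MSI footprint: all unassigned
  far <- transfer_labels(seg, 50, affine_transform(diag(2), c(1e5, 1e5)),
                         c(20, 20), 1)
  expect_true(all(far == "unassigned"))
  expect_error(transfer_labels(seg[0, ], 50, affine_transform(diag(2)),
                               c(10, 10), 1), "empty")
})

test_that("identity transfer at equal pitches reproduces the label map", {
  seg <- make_seg("t1", rep(0:3, 4), rep(0:3, each = 4),
                  withr::with_seed(8, sample(c("A", "B"), 16, replace = TRUE)))
  lab <- transfer_labels(seg, 1, affine_transform(diag(2)), c(4, 4), 1)
  want <- matrix(NA_character_, 4, 4)
  want[cbind(seg$y + 1, seg$x + 1)] <- seg$region
  expect_identical(lab, want)
})

test_that("cell segmentation applies the nuclear and cell size gates", {
  # one disk nucleus, radius 5 µm, on a 40x40 µm field
  img <- matrix(0, 40, 40)
  ctr <- c(20, 20)
  for (r in 1:40) for (cl in 1:40)
    if ((r - 0.5 - ctr[1])^2 + (cl - 0.5 - ctr[2])^2 <= 25) img[r, cl] <- 1
  marker <- matrix(2, 40, 40)
  cs <- segment_cells(img, list(m = marker), pixel_pitch = 1,
                      dna_threshold = 0.5)
  expect_equal(nrow(cs$cells), 1L)
  expect_equal(cs$cells$nucleus_area_um2, pi * 25, tolerance = 0.05)
  # cytoplasm expansion <= 4 µm: cell within radius 9 disk, area <= pi*81
  expect_lte(cs$cells$cell_area_um2, pi * 81 * 1.05)
  expect_gt(cs$cells$cell_area_um2, cs$cells$nucleus_area_um2)
  expect_lte(cs$cells$cell_area_um2, 600)
  expect_equal(cs$cells$mean_m, 2)
  expect_equal(cs$cells$centroid_x_um, 20, tolerance = 0.1)
  # a 10 µm² speck is rejected by the 20 µm² gate
  small <- matrix(0, 20, 20); small[5:6, 5:9] <- 1
  expect_warning(cs2 <- segment_cells(small, pixel_pitch = 1), "size gates")
  expect_equal(nrow(cs2$cells), 0L)
  expect_warning(segment_cells(matrix(0, 5, 5)), "zero nuclei")
})

test_that("competing nuclei split the cytoplasm at the equidistant boundary", {
  img <- matrix(0, 30, 40)
  for (r in 1:30) for (cl in 1:40) {
    if ((r - 15)^2 + (cl - 12)^2 <= 4) img[r, cl] <- 1
    if ((r - 15)^2 + (cl - 18)^2 <= 4) img[r, cl] <- 1   # centres 6 µm apart
  }
  cs <- segment_cells(img, pixel_pitch = 1, nucleus_area_range = c(5, 571))
  expect_equal(nrow(cs$cells), 2L)
  ids <- sort(unique(as.vector(cs$cell_map))); ids <- ids[ids > 0]
  expect_equal(length(ids), 2L)
  # footprints disjoint by construction of cell_map; check nearest-nucleus rule
  own <- which(cs$cell_map > 0, arr.ind = TRUE)
  d1 <- sqrt((own[, 1] - 15)^2 + (own[, 2] - 12)^2)
  d2 <- sqrt((own[, 1] - 15)^2 + (own[, 2] - 18)^2)
  lab <- cs$cell_map[own]
  near1 <- cs$cells$centroid_x_um[1] < cs$cells$centroid_x_um[2]
  left_id <- if (near1) 1L else 2L
  strictly_left <- d1 < d2 - 1
  strictly_right <- d2 < d1 - 1
  expect_true(all(lab[strictly_left] == left_id))
  expect_true(all(lab[strictly_right] == (3L - left_id)))
})

test_that("region quantification matches a brute-force group-by", {
  lab <- matrix(c("A", "A", "B", "B"), 2, 2)
  lab <- lab[rep(1:2, each = 10), rep(1:2, each = 10)]  # 20x20, left A right B
  marker <- matrix(2, 20, 20); marker[, 11:20] <- 10
  cells <- data.frame(cell_id = 1:2, centroid_x_um = c(5, 15),
                      centroid_y_um = c(10, 10), nucleus_area_um2 = 30,
                      cell_area_um2 = 60, mean_m = c(2, 10))
  st <- quantify_by_region(list(m = marker), cells, lab,
                           c(m = 5), pixel_pitch = 1, arm = "vehicle")
  expect_equal(st$mean_pixel_intensity[st$region == "A"], 2)
  expect_equal(st$mean_pixel_intensity[st$region == "B"], 10)
  expect_equal(st$total_cells, c(1L, 1L))
  expect_equal(st$positive_cells[st$region == "A"], 0L)
  expect_equal(st$positive_cells[st$region == "B"], 1L)
  # threshold 0: every cell positive
  st0 <- quantify_by_region(list(m = marker), cells, lab, c(m = 0),
                            pixel_pitch = 1)
  expect_true(all(st0$positive_fraction == 1))
  # cells on unassigned labels are excluded and reported
  lab2 <- lab; lab2[, 1:10] <- "unassigned"
  st2 <- quantify_by_region(list(m = marker), cells, lab2, c(m = 5),
                            pixel_pitch = 1)
  expect_equal(attr(st2, "excluded_cells"), 1L)
  expect_equal(sum(st2$total_cells), 1L)
  expect_error(quantify_by_region(list(m = marker), cells, lab,
                                  c(other = 1), pixel_pitch = 1),
               "no positivity threshold")
})
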