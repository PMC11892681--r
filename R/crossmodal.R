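# MSI -> IMC registration and per-region protein-marker quantification:
# landmark least-squares affine fitting, label transfer onto the 1-µm IMC
# grid, simplified nuclear/cytoplasm cell segmentation with explicit size
# gates (nucleus 20-571 µm², cytoplasm expansion <= 4 µm, cell <= 600 µm²),
# and region-wise marker statistics.

#' Construct a planar affine transform
#'
#' Maps MSI µm-coordinates to IMC µm-coordinates: y = A x + b.
#' @param A 2x2 linear part (must be invertible)
#' @param b length-2 translation
#' @return object of class `affine_transform`
#' @export
affine_transform <- function(A, b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < 1e-12) stopf("affine linear part is singular")
  structure(list(A = A, b = as.numeric(b)), class = "affine_transform")
}

#' Apply an affine transform to points
#' @param transform an [affine_transform()]
#' @param xy n x 2 matrix of points
#' @return n x 2 matrix of transformed points
#' @export
apply_affine <- function(transform, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  t(transform$A %*% t(xy) + transform$b)
}

#' Invert an affine transform
#' @param transform an [affine_transform()]
#' @return the inverse `affine_transform`
#' @export
invert_affine <- function(transform) {
  Ai <- solve(transform$A)
  affine_transform(Ai, -as.vector(Ai %*% transform$b))
}

#' Fit an affine transform from landmark pairs
#'
#' Least squares on >= 3 non-collinear landmark pairs, minimising the sum of
#' squared residuals in the IMC frame.
#'
#' @param landmarks_msi n x 2 matrix (or data.frame) of MSI µm coordinates
#' @param landmarks_imc n x 2 matrix of corresponding IMC µm coordinates
#' @return an `affine_transform` with attributes `"residuals"` (per-landmark
#'   Euclidean residual, µm) and `"rmse"`
#' @export
fit_affine <- function(landmarks_msi, landmarks_imc) {
  P <- as.matrix(landmarks_msi); Q <- as.matrix(landmarks_imc)
  if (nrow(P) < 3) stopf("need >= 3 landmark pairs, got %d", nrow(P))
  if (nrow(P) != nrow(Q)) stopf("landmark tables differ in length")
  X <- cbind(1, P)
  if (qr(X)$rank < 3) stopf("landmarks are collinear; affine is not identifiable")
  beta <- qr.solve(X, Q)           # 3 x 2: intercept then linear part
  tr <- affine_transform(t(beta[2:3, ]), beta[1, ])
  res <- sqrt(rowSums((apply_affine(tr, P) - Q)^2))
  attr(tr, "residuals") <- res
  attr(tr, "rmse") <- sqrt(mean(res^2))
  tr
}

#' Transfer MSI region labels onto the IMC pixel grid
#'
#' Each IMC pixel centre ((i - 0.5) * pitch) is mapped through the inverse
#' affine into MSI µm space and converted to an MSI grid index
#' (floor(coordinate / pitch)); the pixel inherits that MSI pixel's region.
#' IMC pixels falling outside the MSI footprint (or on MSI pixels absent
#' from the segmentation) are labelled "unassigned".
#'
#' @param segmentation matched `segmentation_map` rows for one tissue
#' @param msi_pixel_pitch MSI pixel pitch, µm
#' @param affine `affine_transform` mapping MSI µm to IMC µm
#' @param imc_shape IMC image (rows, cols) in pixels
#' @param imc_pixel_pitch IMC pixel pitch, µm
#' @return character matrix (rows x cols) of labels "A"/"B"/"unassigned"
#' @export
transfer_labels <- function(segmentation, msi_pixel_pitch, affine, imc_shape,
                            imc_pixel_pitch = 1) {
  if (!nrow(segmentation)) stopf("empty segmentation")
  if (any(is.na(segmentation$region))) stopf("segmentation is not region-matched")
  inv <- invert_affine(affine)
  nr <- imc_shape[1]; nc <- imc_shape[2]
  cx <- (seq_len(nc) - 0.5) * imc_pixel_pitch
  cy <- (seq_len(nr) - 0.5) * imc_pixel_pitch
  pts <- cbind(rep(cx, each = nr), rep(cy, times = nc))
  msi_um <- apply_affine(inv, pts)
  ix <- floor(msi_um[, 1] / msi_pixel_pitch)
  iy <- floor(msi_um[, 2] / msi_pixel_pitch)
  key <- paste(segmentation$x, segmentation$y)
  lab <- segmentation$region[match(paste(ix, iy), key)]
  lab[is.na(lab)] <- "unassigned"
  matrix(lab, nr, nc)
}

#' Segment cells from a DNA channel (simplified nuclear/cytoplasm model)
#'
#' Nuclei are connected components of the thresholded DNA channel filtered
#' to area in [`nucleus_area_range`] µm². The cell footprint is the nucleus
#' expanded by up to `cyto_radius` µm, with contested pixels split at the
#' equidistant boundary between competing nuclei, then truncated (pixels
#' farthest from the nucleus dropped first) so the cell area does not exceed
#' `max_cell_area` µm².
#'
#' @param dna_image numeric matrix (DNA intercalator channel)
#' @param marker_images named list of marker matrices on the same grid
#' @param pixel_pitch pixel size, µm
#' @param dna_threshold nuclei = pixels with DNA > this value
#' @param nucleus_area_range nucleus area gates, µm²
#' @param cyto_radius maximum cytoplasm expansion, µm
#' @param max_cell_area maximum cell area, µm²
#' @return list with `cells` (data.frame: cell_id, centroid_x_um,
#'   centroid_y_um, nucleus_area_um2, cell_area_um2, mean_<marker> columns)
#'   and `cell_map` (integer matrix of cell ids, 0 = background)
#' @export
segment_cells <- function(dna_image, marker_images = list(), pixel_pitch = 1,
                          dna_threshold = 0.5,
                          nucleus_area_range = c(20, 571),
                          cyto_radius = 4, max_cell_area = 600) {
  if (!length(dna_image)) stopf("empty DNA channel")
  px_area <- pixel_pitch^2
  mask <- dna_image > dna_threshold
  labels <- EBImage::bwlabel(mask)
  nlab <- max(labels)
  empty <- list(cells = data.frame(cell_id = integer(0)),
                cell_map = matrix(0L, nrow(dna_image), ncol(dna_image)))
  if (nlab == 0) {
    warning("DNA threshold yielded zero nuclei")
    return(empty)
  }
  areas <- tabulate(labels[labels > 0], nbins = nlab) * px_area
  keep <- which(areas >= nucleus_area_range[1] & areas <= nucleus_area_range[2])
  if (!length(keep)) {
    warning("no nuclei within the size gates")
    return(empty)
  }
  # distance (in µm) from every pixel to each retained nucleus
  nr <- nrow(dna_image); nc <- ncol(dna_image)
  dist_to <- function(lab) {
    comp <- matrix(1L, nr, nc)
    comp[labels == lab] <- 0L
    as.matrix(EBImage::distmap(comp)) * pixel_pitch
  }
  dmin <- matrix(Inf, nr, nc)
  owner <- matrix(0L, nr, nc)
  for (j in seq_along(keep)) {
    d <- dist_to(keep[j])
    better <- d < dmin
    owner[better] <- j
    dmin[better] <- d[better]
  }
  cell_map <- matrix(0L, nr, nc)
  within <- dmin <= cyto_radius & owner > 0
  cell_map[within] <- owner[within]
  max_px <- floor(max_cell_area / px_area)
  for (j in seq_along(keep)) {
    idx <- which(cell_map == j)
    if (length(idx) > max_px) {
      drop <- idx[order(dmin[idx], idx)][(max_px + 1):length(idx)]
      cell_map[drop] <- 0L
    }
  }
  cells <- do.call(rbind, lapply(seq_along(keep), function(j) {
    nuc_idx <- which(labels == keep[j])
    cell_idx <- which(cell_map == j)
    rc <- arrayInd(nuc_idx, dim(labels))
    row <- data.frame(cell_id = j,
                      centroid_x_um = mean(rc[, 2] - 0.5) * pixel_pitch,
                      centroid_y_um = mean(rc[, 1] - 0.5) * pixel_pitch,
                      nucleus_area_um2 = length(nuc_idx) * px_area,
                      cell_area_um2 = length(cell_idx) * px_area)
    for (m in names(marker_images))
      row[[paste0("mean_", m)]] <- mean(marker_images[[m]][cell_idx])
    row
  }))
  rownames(cells) <- NULL
  list(cells = cells, cell_map = cell_map)
}

#' Region-wise marker quantification
#'
#' Per region: mean marker intensity over the region's labelled pixels
#' (pixel-level) and, at cell level, the number of positive cells among the
#' cells whose nucleus centroid falls in the region. A cell is positive for
#' a marker iff its per-cell mean intensity is at or above that marker's
#' threshold. Cells whose centroid lands on an "unassigned" label are
#' excluded and counted in attribute `"excluded_cells"`.
#'
#' @param marker_images named list of marker matrices (IMC grid)
#' @param cell_table `cells` from [segment_cells()]
#' @param label_image region label matrix from [transfer_labels()]
#' @param positive_thresholds named per-marker positivity thresholds
#' @param pixel_pitch IMC pixel pitch, µm
#' @param arm arm annotation carried into the output
#' @return data.frame (class `region_marker_stats`): arm, region, marker,
#'   mean_pixel_intensity, mean_cell_intensity, positive_cells, total_cells,
#'   positive_fraction
#' @export
quantify_by_region <- function(marker_images, cell_table, label_image,
                               positive_thresholds, pixel_pitch = 1,
                               arm = NA_character_) {
  regions <- setdiff(sort(unique(as.vector(label_image))), "unassigned")
  markers <- names(marker_images)
  if (nrow(cell_table)) {
    ci <- pmin(pmax(floor(cell_table$centroid_x_um / pixel_pitch) + 1L, 1L),
               ncol(label_image))
    ri <- pmin(pmax(floor(cell_table$centroid_y_um / pixel_pitch) + 1L, 1L),
               nrow(label_image))
    cell_region <- label_image[cbind(ri, ci)]
  } else cell_region <- character(0)
  excluded <- sum(cell_region == "unassigned")
  out <- do.call(rbind, lapply(regions, function(reg) {
    pix_sel <- label_image == reg
    cells_in <- which(cell_region == reg)
    do.call(rbind, lapply(markers, function(m) {
      cvals <- if (length(cells_in)) cell_table[[paste0("mean_", m)]][cells_in]
               else numeric(0)
      if (!m %in% names(positive_thresholds))
        stopf("no positivity threshold for marker %s", m)
      thr <- positive_thresholds[[m]]
      data.frame(arm = arm, region = reg, marker = m,
                 mean_pixel_intensity = mean(marker_images[[m]][pix_sel]),
                 mean_cell_intensity = if (length(cvals)) mean(cvals) else NA_real_,
                 positive_cells = sum(cvals >= thr),
                 total_cells = length(cvals),
                 positive_fraction = if (length(cvals)) mean(cvals >= thr) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  structure(out, class = c("region_marker_stats", "data.frame"),
            excluded_cells = excluded)
}
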