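# Seeded synthetic multi-experiment MSI + IMC phantom studies with full
# ground truth. The phantom emulates a three-batch xenograft design with four
# arms (vehicle, two single agents, combination), two latent metabolic
# regions per tissue whose prevalence depends on the arm, a metabolite panel
# with region- and treatment-specific log2 effects plus per-experiment batch
# scale factors and multiplicative lognormal noise, a drug ion present only
# in treated tissues, and IMC marker images tied to the MSI grid by a known
# affine transform.

#' Default synthetic metabolite panel
#'
#' Deterministic panel of `n` metabolites (including one drug ion):
#' six "nucleotide-like" ions elevated in Region A (+2 log2), six elevated in
#' Region B (-2 log2), six treatment-suppressed and six treatment-induced
#' ions (tissue-wide effects, disjoint from the region-defining set), the
#' rest inert high-abundance ions. Region-defining and treatment-responding
#' sets are disjoint so that the tissue-mean log2 fold change of a responder
#' equals its programmed treatment effect regardless of region prevalence.
#'
#' @param arms arm names; the first is the vehicle arm
#' @param n panel size (>= 26)
#' @return data.frame with columns name, neutral_mass, adduct, baseline_log2,
#'   region_effect_log2, is_drug_ion, and one `effect_<arm>` column per arm
#' @export
default_metabolite_panel <- function(arms = c("vehicle", "drugA", "drugB", "combo"),
                                     n = 50) {
  if (n < 26) stopf("panel needs at least 26 metabolites")
  nm <- n - 1L
  mass <- seq(120, 960, length.out = nm) + 0.37 * sin(seq_len(nm))
  panel <- data.frame(
    name = sprintf("met_%03d", seq_len(nm)),
    neutral_mass = mass,
    adduct = "[M+H]+",
    baseline_log2 = 12,
    region_effect_log2 = 0,
    is_drug_ion = FALSE,
    stringsAsFactors = FALSE
  )
  panel$region_effect_log2[1:6] <- 2    # Region-A-high (ATP-like)
  panel$region_effect_log2[7:12] <- -2  # Region-B-high
  panel$baseline_log2[1:24] <- 10       # effect-carrying ions kept modest
  eff <- matrix(0, nm, length(arms), dimnames = list(NULL, arms))
  treated <- setdiff(arms, arms[1])
  if (length(treated) >= 3) {
    down <- c(-1.0, -0.6, -1.6); up <- c(1.0, 0.6, 1.6)
  } else {
    down <- rep(-1.0, length(treated)); up <- rep(1.0, length(treated))
  }
  for (k in seq_along(treated)) {
    eff[13:18, treated[k]] <- down[k]   # nucleotide-like suppression
    eff[19:24, treated[k]] <- up[k]     # carnitine-like induction
  }
  for (a in arms) panel[[paste0("effect_", a)]] <- eff[, a]
  drug <- data.frame(
    name = "drugA_ion", neutral_mass = 462.2379, adduct = "[M+H]+",
    baseline_log2 = 9, region_effect_log2 = 0, is_drug_ion = TRUE,
    stringsAsFactors = FALSE
  )
  for (a in arms) drug[[paste0("effect_", a)]] <- 0
  panel <- rbind(panel, drug)
  panel[order(panel$neutral_mass), , drop = FALSE]
}

#' Synthetic study configuration
#'
#' @param n_experiments number of independent experiments (batches)
#' @param arms arm names; first entry is the vehicle arm
#' @param tissues_per_arm tissues per arm per experiment
#' @param grid_shape MSI grid (rows, cols) in pixels
#' @param msi_pixel_pitch MSI pixel pitch, µm
#' @param imc_pixel_pitch IMC pixel pitch, µm
#' @param metabolite_panel see [default_metabolite_panel()]
#' @param batch_log2_scale per-experiment global log2 intensity offset
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   intensity noise
#' @param jitter_ppm ppm scale of per-peak m/z jitter
#' @param region_prevalence named vector, arm -> expected Region-A fraction
#' @param region_smoothness Gaussian smoothing sd (pixels) of the latent
#'   region field
#' @param mass_range acquisition mass range (Da)
#' @param seed master seed; all per-tissue streams derive from it
#' @return object of class `study_config`
#' @export
study_config <- function(n_experiments = 3,
                         arms = c("vehicle", "drugA", "drugB", "combo"),
                         tissues_per_arm = 2,
                         grid_shape = c(64, 64),
                         msi_pixel_pitch = 50,
                         imc_pixel_pitch = 1,
                         metabolite_panel = default_metabolite_panel(arms),
                         batch_log2_scale = NULL,
                         noise_cv = 0.2,
                         jitter_ppm = 5,
                         region_prevalence = c(vehicle = 0.8, drugA = 0.3,
                                               drugB = 0.5, combo = 0.1),
                         region_smoothness = 6,
                         mass_range = c(70, 1000),
                         seed = 1L) {
  if (n_experiments < 1) stopf("n_experiments must be >= 1")
  if (any(grid_shape <= 0)) stopf("grid_shape must be positive")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  if (is.null(batch_log2_scale))
    batch_log2_scale <- c(0, 0.6, -0.4, 0.3, -0.2)[seq_len(n_experiments) %% 5 + 1]
  if (length(batch_log2_scale) != n_experiments)
    stopf("batch_log2_scale must have one entry per experiment")
  if (!all(arms %in% names(region_prevalence)))
    stopf("region_prevalence must name every arm")
  if (any(region_prevalence < 0 | region_prevalence > 1))
    stopf("region_prevalence values must lie in [0, 1]")
  if (any(panel_drug <- metabolite_panel$is_drug_ion))
    if (any(metabolite_panel$region_effect_log2[panel_drug] != 0))
      stopf("drug ions must have region_effect_log2 = 0")
  structure(list(
    n_experiments = as.integer(n_experiments), arms = arms,
    tissues_per_arm = as.integer(tissues_per_arm),
    grid_shape = as.integer(grid_shape),
    msi_pixel_pitch = msi_pixel_pitch, imc_pixel_pitch = imc_pixel_pitch,
    metabolite_panel = metabolite_panel,
    batch_log2_scale = batch_log2_scale, noise_cv = noise_cv,
    jitter_ppm = jitter_ppm, region_prevalence = region_prevalence,
    region_smoothness = region_smoothness, mass_range = mass_range,
    seed = as.integer(seed)
  ), class = "study_config")
}

.gauss_smooth <- function(m, sigma) {
  sm <- function(k) {
    W <- outer(seq_len(k), seq_len(k), function(i, j) dnorm(i - j, sd = sigma))
    W / rowSums(W)  # edge renormalisation
  }
  sm(nrow(m)) %*% m %*% t(sm(ncol(m)))
}

#' Generate a latent two-region tissue field
#'
#' Smoothed Gaussian white noise thresholded by rank so that exactly
#' `round(prevalence * n_pixels)` pixels are Region A, giving spatially
#' coherent regions with the requested prevalence up to one-pixel
#' quantisation.
#'
#' @param grid_shape (rows, cols)
#' @param prevalence expected Region-A fraction, in [0, 1]
#' @param smoothness Gaussian smoothing sd in pixels (> 0)
#' @param seed integer seed
#' @return integer matrix (rows x cols) with 1 = Region A, 0 = Region B
#' @export
generate_tissue_regions <- function(grid_shape, prevalence, smoothness = 6,
                                    seed = 1L) {
  if (any(grid_shape <= 0)) stopf("grid_shape must be positive")
  if (prevalence < 0 || prevalence > 1) stopf("prevalence must lie in [0, 1]")
  if (smoothness <= 0) stopf("smoothness must be > 0")
  nr <- grid_shape[1]; nc <- grid_shape[2]
  field <- with_seed(seed, matrix(rnorm(nr * nc), nr, nc))
  field <- .gauss_smooth(field, smoothness)
  k <- round(prevalence * nr * nc)
  out <- matrix(0L, nr, nc)
  if (k > 0) out[order(field, decreasing = TRUE)[seq_len(k)]] <- 1L
  out
}

#' Generate a synthetic MSI dataset for one tissue
#'
#' Per-pixel log2 apex intensity of metabolite j is
#' `baseline + batch + region_effect * [pixel in A] + effect_arm`, with a
#' drug ion emitted at background (baseline - 8) in the vehicle arm,
#' multiplied by median-one lognormal noise with coefficient of variation
#' `noise_cv`. Peak positions receive ppm-scale Gaussian jitter. In profile
#' mode each peak is rendered as a sampled Gaussian (sd `peak_sigma` Da) with
#' explicit zero baseline anchors; centroid mode emits bare sticks.
#'
#' @param config a [study_config()]
#' @param experiment experiment index (1-based)
#' @param arm arm name
#' @param region_field matrix from [generate_tissue_regions()]
#' @param seed integer seed for this tissue
#' @param tissue_id tissue identifier
#' @param mode "profile" (default) or "centroid"
#' @param peak_sigma Gaussian peak sd in Da (profile mode)
#' @return an [msi_dataset()]
#' @export
generate_msi_dataset <- function(config, experiment, arm, region_field,
                                 seed, tissue_id = NULL,
                                 mode = c("profile", "centroid"),
                                 peak_sigma = 0.08) {
  mode <- match.arg(mode)
  if (!arm %in% config$arms) stopf("unknown arm '%s'", arm)
  panel <- config$metabolite_panel
  for (ad in unique(panel$adduct))
    if (!ad %in% known_adducts()) stopf("unknown adduct '%s' in panel", ad)
  if (is.null(tissue_id))
    tissue_id <- sprintf("E%d_%s_t", experiment, arm)
  nr <- nrow(region_field); nc <- ncol(region_field)
  npx <- nr * nc
  nmet <- nrow(panel)
  centre_mz <- vapply(seq_len(nmet), function(j)
    adduct_mz(panel$neutral_mass[j], panel$adduct[j]), numeric(1))

  log2I <- panel$baseline_log2 + config$batch_log2_scale[experiment] +
    panel[[paste0("effect_", arm)]]
  if (any(panel$is_drug_ion) && arm == config$arms[1])
    log2I[panel$is_drug_ion] <- log2I[panel$is_drug_ion] - 8
  inA <- as.vector(region_field) == 1L   # column-major pixel order
  # npx x nmet programmed intensity
  base <- 2^(matrix(log2I, npx, nmet, byrow = TRUE) +
               outer(inA, panel$region_effect_log2))
  sigma <- sqrt(log(1 + config$noise_cv^2))

  res <- with_seed(seed, {
    noise <- if (sigma > 0) matrix(exp(sigma * rnorm(npx * nmet)), npx, nmet)
             else 1
    inten <- base * noise
    jit <- if (config$jitter_ppm > 0)
      matrix(rnorm(npx * nmet, sd = config$jitter_ppm), npx, nmet) else
      matrix(0, npx, nmet)
    list(inten = inten, jit = jit)
  })
  mzmat <- matrix(centre_mz, npx, nmet, byrow = TRUE)
  mzmat <- mzmat * (1 + res$jit * 1e-6)

  if (mode == "profile") {
    offs <- c(seq(-2, 2, by = 2 / 3) * peak_sigma)
    wts <- exp(-offs^2 / (2 * peak_sigma^2))
    anchor <- 2.4 * peak_sigma
    build <- function(ctrs, apex) {
      mz <- as.vector(rbind(ctrs - anchor,
                            outer(offs, ctrs, `+`),
                            ctrs + anchor))
      iv <- as.vector(rbind(0, outer(wts, apex), 0))
      new_spectrum(mz, iv)
    }
  } else {
    build <- function(ctrs, apex) new_spectrum(ctrs, apex)
  }
  spectra <- lapply(seq_len(npx), function(p)
    build(mzmat[p, ], res$inten[p, ]))

  # column-major pixel order: pixel p = (row, col) -> y = row-1, x = col-1
  coords <- data.frame(x = rep(seq_len(nc), each = nr) - 1L,
                       y = rep(seq_len(nr), times = nc) - 1L)
  msi_dataset(coords, spectra, pixel_pitch = config$msi_pixel_pitch,
              polarity = "positive", modality = "DESI",
              tissue_id = tissue_id,
              experiment_id = sprintf("Experiment-%d", experiment),
              arm = arm, mass_range = config$mass_range)
}

#' Default IMC marker rules emulating regional pharmacodynamic response
#'
#' Mean in-cell marker intensities (normalised 0-1 scale) per
#' (marker, region, arm class): pS6 is suppressed equally in both regions
#' under any treatment; GLUT1 and Ki67 are suppressed in Region B but
#' retained in Region A; CD31 and collagen I differ between regions
#' independently of treatment.
#'
#' @param arms arm names; first entry is the vehicle arm
#' @return data.frame with columns marker, region, arm, mean_intensity
#' @export
default_marker_rules <- function(arms = c("vehicle", "drugA", "drugB", "combo")) {
  vehicle <- arms[1]
  tab <- expand.grid(marker = c("pS6", "Ki67", "GLUT1", "CD31", "collagen1"),
                     region = c("A", "B"), arm = arms,
                     stringsAsFactors = FALSE)
  val <- function(marker, region, arm) {
    treated <- arm != vehicle
    switch(marker,
      pS6 = if (treated) 0.25 else 0.80,
      Ki67 = if (treated && region == "B") 0.15 else if (treated) 0.60 else 0.75,
      GLUT1 = if (treated && region == "B") 0.20 else if (region == "A") 0.80 else 0.70,
      CD31 = if (region == "A") 0.25 else 0.50,
      collagen1 = if (region == "A") 0.20 else 0.45)
  }
  tab$mean_intensity <- mapply(val, tab$marker, tab$region, tab$arm)
  tab
}

#' Generate synthetic IMC marker images for one tissue
#'
#' Places disk nuclei (DNA channel) on a 1-µm-class IMC grid covering a
#' square region of interest; marker channels take the region/arm-programmed
#' mean inside each cell footprint (nucleus dilated by `cyto_radius`) and
#' background elsewhere. The cell's region is the ground-truth region of the
#' MSI pixel its centre maps to under the inverse of `affine_true`.
#'
#' @param region_field ground-truth region matrix (MSI grid)
#' @param affine_true [affine_transform()] mapping MSI µm to IMC µm
#' @param marker_rules see [default_marker_rules()]
#' @param arm arm name
#' @param cell_density cells per mm^2
#' @param seed integer seed
#' @param roi_um side of the square IMC field of view, µm
#' @param imc_pixel_pitch IMC pixel pitch, µm
#' @param msi_pixel_pitch MSI pixel pitch, µm
#' @param nucleus_radius_range min/max nucleus radius, µm
#' @param cyto_radius cytoplasm expansion used when painting markers, µm
#' @param noise_sd additive Gaussian pixel noise sd
#' @param background background intensity of marker channels
#' @return list with `images` (named list of matrices, markers + DNA),
#'   `cells` (data.frame x_um, y_um, radius_um, region), `affine` and
#'   `pixel_pitch`
#' @export
generate_imc_images <- function(region_field, affine_true, marker_rules, arm,
                                cell_density = 600, seed = 1L, roi_um = 400,
                                imc_pixel_pitch = 1, msi_pixel_pitch = 50,
                                nucleus_radius_range = c(3, 5.5),
                                cyto_radius = 3, noise_sd = 0,
                                background = 0.02) {
  side <- as.integer(round(roi_um / imc_pixel_pitch))
  rmax <- nucleus_radius_range[2]
  n_cells <- round(cell_density * (roi_um / 1000)^2)
  if (n_cells * pi * (2 * rmax)^2 > 0.65 * roi_um^2)
    stopf("cell_density %g would overlap nuclei beyond the packing limit", cell_density)

  inv <- invert_affine(affine_true)
  cells <- with_seed(seed, {
    xs <- ys <- rs <- numeric(0)
    attempts <- 0
    while (length(xs) < n_cells && attempts < 200 * max(n_cells, 1)) {
      attempts <- attempts + 1
      r <- runif(1, nucleus_radius_range[1], nucleus_radius_range[2])
      x <- runif(1, r + cyto_radius, roi_um - r - cyto_radius)
      y <- runif(1, r + cyto_radius, roi_um - r - cyto_radius)
      if (!length(xs) || all((xs - x)^2 + (ys - y)^2 > (rs + r + 1)^2)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
      }
    }
    data.frame(x_um = xs, y_um = ys, radius_um = rs)
  })
  if (nrow(cells) < n_cells)
    stopf("could not place %d non-overlapping nuclei (placed %d)", n_cells, nrow(cells))

  if (nrow(cells)) {
    msi_um <- apply_affine(inv, cbind(cells$x_um, cells$y_um))
    ix <- floor(msi_um[, 1] / msi_pixel_pitch)  # MSI column index (x)
    iy <- floor(msi_um[, 2] / msi_pixel_pitch)  # MSI row index (y)
    ok <- ix >= 0 & ix < ncol(region_field) & iy >= 0 & iy < nrow(region_field)
    cells$region <- ifelse(ok,
      ifelse(region_field[cbind(pmax(iy, 0) + 1, pmax(ix, 0) + 1)] == 1L, "A", "B"),
      NA_character_)
  } else cells$region <- character(0)

  markers <- unique(marker_rules$marker)
  # pixel centres at (i - 0.5) * pitch
  px <- (seq_len(side) - 0.5) * imc_pixel_pitch
  images <- c(setNames(lapply(markers, function(m)
    matrix(background, side, side)), markers),
    list(DNA = matrix(0.02, side, side)))
  rule_mean <- function(marker, region) {
    v <- marker_rules$mean_intensity[marker_rules$marker == marker &
                                     marker_rules$region == region &
                                     marker_rules$arm == arm]
    if (!length(v)) stopf("no marker rule for (%s, %s, %s)", marker, region, arm)
    v[1]
  }
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i]; cy <- cells$y_um[i]; r <- cells$radius_um[i]
    reg <- cells$region[i]
    # bounding boxes in pixel index space; rows index y, cols index x
    sel <- function(radius) {
      jx <- which(abs(px - cx) <= radius + 1)
      jy <- which(abs(px - cy) <= radius + 1)
      d2 <- outer((px[jy] - cy)^2, (px[jx] - cx)^2, `+`)
      list(jy = jy, jx = jx, inside = d2 <= radius^2)
    }
    nuc <- sel(r)
    images$DNA[nuc$jy, nuc$jx][nuc$inside] <- 1
    if (!is.na(reg)) {
      cell <- sel(r + cyto_radius)
      for (m in markers)
        images[[m]][cell$jy, cell$jx][cell$inside] <- rule_mean(m, reg)
    }
  }
  if (noise_sd > 0)
    images <- with_seed(seed + 1L, lapply(images, function(im)
      pmin(pmax(im + matrix(rnorm(length(im), sd = noise_sd),
                            nrow(im)), 0), 1)))
  list(images = images, cells = cells, affine = affine_true,
       pixel_pitch = imc_pixel_pitch)
}

.true_affine_for_tissue <- function(config, seed, roi_um = 400) {
  # mild rotation/scale, translation placing the grid centre at the ROI centre
  th <- with_seed(seed, runif(1, -4, 4)) * pi / 180
  sc <- with_seed(seed + 1L, runif(1, 0.97, 1.03))
  A <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr_msi <- c(config$grid_shape[2], config$grid_shape[1]) / 2 * config$msi_pixel_pitch
  b <- c(roi_um / 2, roi_um / 2) - as.vector(A %*% ctr_msi)
  affine_transform(A, b)
}

#' Generate a full synthetic study on disk
#'
#' One imzML file pair per tissue, a CSV manifest, per-tissue landmark
#' tables, IMC marker TIFFs for the final experiment (mirroring a design in
#' which only one batch is taken forward to IMC), and a ground-truth JSON.
#'
#' @param config a [study_config()]
#' @param dir output directory (created if missing)
#' @param imc_experiments experiment indices for which IMC images are
#'   generated (default: the last experiment)
#' @param roi_um IMC field-of-view side, µm
#' @param mode spectrum rendering mode passed to [generate_msi_dataset()]
#' @return invisibly, list(manifest, ground_truth)
#' @export
generate_study <- function(config, dir,
                           imc_experiments = config$n_experiments,
                           roi_um = 400, mode = "profile") {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create output directory %s", dir)
  manifest <- list(); gt_regions <- list(); gt_affine <- list()
  gt_cells <- list()
  marker_rules <- default_marker_rules(config$arms)
  for (e in seq_len(config$n_experiments)) {
    for (arm in config$arms) {
      for (t in seq_len(config$tissues_per_arm)) {
        tissue_id <- sprintf("E%d_%s_%d", e, arm, t)
        tseed <- derive_seed(config$seed, "tissue", e, arm, t)
        rf <- generate_tissue_regions(config$grid_shape,
                                      config$region_prevalence[[arm]],
                                      config$region_smoothness,
                                      seed = derive_seed(tseed, "regions"))
        ds <- generate_msi_dataset(config, e, arm, rf,
                                   seed = derive_seed(tseed, "msi"),
                                   tissue_id = tissue_id, mode = mode)
        stem <- file.path(dir, tissue_id)
        write_imzml(ds, stem)
        aff <- .true_affine_for_tissue(config, derive_seed(tseed, "affine"), roi_um)
        corners_msi <- rbind(c(0, 0),
                             c(config$grid_shape[2] * config$msi_pixel_pitch, 0),
                             c(0, config$grid_shape[1] * config$msi_pixel_pitch),
                             config$grid_shape[c(2, 1)] * config$msi_pixel_pitch)
        corners_imc <- apply_affine(aff, corners_msi)
        lm <- data.frame(x_msi_um = corners_msi[, 1], y_msi_um = corners_msi[, 2],
                         x_imc_um = corners_imc[, 1], y_imc_um = corners_imc[, 2])
        write.csv(lm, paste0(stem, "_landmarks.csv"), row.names = FALSE)
        imc_dir <- NA_character_
        if (e %in% imc_experiments) {
          imc <- generate_imc_images(rf, aff, marker_rules, arm,
                                     seed = derive_seed(tseed, "imc"),
                                     roi_um = roi_um,
                                     imc_pixel_pitch = config$imc_pixel_pitch,
                                     msi_pixel_pitch = config$msi_pixel_pitch)
          imc_dir <- paste0(stem, "_imc")
          dir.create(imc_dir, showWarnings = FALSE)
          for (ch in names(imc$images))
            tiff::writeTIFF(imc$images[[ch]],
                            file.path(imc_dir, paste0(ch, ".tif")),
                            bits.per.sample = 32L)
          write.csv(imc$cells, file.path(imc_dir, "cells_truth.csv"),
                    row.names = FALSE)
          gt_cells[[tissue_id]] <- imc$cells
        }
        manifest[[length(manifest) + 1]] <- data.frame(
          tissue_id = tissue_id, experiment = sprintf("Experiment-%d", e),
          arm = arm, imzml = paste0(stem, ".imzML"),
          landmarks = paste0(stem, "_landmarks.csv"), imc_dir = imc_dir,
          stringsAsFactors = FALSE)
        gt_regions[[tissue_id]] <- rf
        gt_affine[[tissue_id]] <- aff
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  # CSV carries paths relative to the study directory so the study is
  # relocatable (and byte-identical across runs)
  manifest_rel <- manifest
  for (col in c("imzml", "landmarks", "imc_dir"))
    manifest_rel[[col]] <- sub(paste0("^", dir, "/?"), "", manifest_rel[[col]])
  write.csv(manifest_rel, file.path(dir, "manifest.csv"), row.names = FALSE)
  ground_truth <- list(
    region_field = gt_regions, affine_true = gt_affine,
    region_prevalence = as.list(config$region_prevalence),
    marker_rules = marker_rules, cells = gt_cells,
    panel = config$metabolite_panel, seed = config$seed)
  json <- list(
    region_prevalence = as.list(config$region_prevalence),
    region_field = lapply(gt_regions, function(m) unname(as.data.frame(m))),
    affine = lapply(gt_affine, function(a) list(A = a$A, b = a$b)),
    seed = config$seed)
  jsonlite::write_json(json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, ground_truth = ground_truth))
}

#' Tissue design table of a study configuration
#'
#' Enumerates every tissue (experiment x arm x replicate) with its
#' deterministically derived seed; the generation functions use the same
#' derivation, so ground truth can be reproduced without regenerating data.
#'
#' @param config a [study_config()]
#' @return data.frame with columns e, arm, t, tissue_id, seed
#' @export
study_tissues <- function(config) {
  g <- expand.grid(t = seq_len(config$tissues_per_arm), arm = config$arms,
                   e = seq_len(config$n_experiments), stringsAsFactors = FALSE)
  g$tissue_id <- sprintf("E%d_%s_%d", g$e, g$arm, g$t)
  g$seed <- mapply(function(e, arm, t)
    derive_seed(config$seed, "tissue", e, arm, t), g$e, g$arm, g$t)
  g[, c("e", "arm", "t", "tissue_id", "seed")]
}

#' Ground-truth region fields of a study configuration
#'
#' @param config a [study_config()]
#' @return named list (by tissue_id) of region matrices (1 = Region A)
#' @export
study_region_truth <- function(config) {
  tt <- study_tissues(config)
  out <- lapply(seq_len(nrow(tt)), function(i)
    generate_tissue_regions(config$grid_shape,
                            config$region_prevalence[[tt$arm[i]]],
                            config$region_smoothness,
                            seed = derive_seed(tt$seed[i], "regions")))
  names(out) <- tt$tissue_id
  out
}

#' Centre of the most region-balanced square window of a tissue
#'
#' IMC acquisitions cover small regions of interest chosen to contain
#' representative areas of both metabolic regions; this helper makes that
#' choice reproducible: it slides a `window_px` x `window_px` window over
#' the MSI region field and returns the µm centre of the window maximising
#' the smaller region's pixel count.
#'
#' @param region_field region matrix (1 = Region A)
#' @param window_px window side in MSI pixels
#' @param pixel_pitch MSI pixel pitch, µm
#' @return list with `centre_um` (x, y), `offset_px` (col, row, 0-based) and
#'   `balance` (minority-region fraction inside the window)
#' @export
balanced_roi_centre <- function(region_field, window_px, pixel_pitch = 50) {
  nr <- nrow(region_field); nc <- ncol(region_field)
  w <- min(window_px, nr, nc)
  cs <- rbind(0, apply(region_field, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum)))  # (nr+1) x (nc+1) integral image
  best <- c(-1, 1, 1)
  for (i0 in seq_len(nr - w + 1)) for (j0 in seq_len(nc - w + 1)) {
    a <- cs[i0 + w, j0 + w] - cs[i0, j0 + w] - cs[i0 + w, j0] + cs[i0, j0]
    m <- min(a, w * w - a)
    if (m > best[1]) best <- c(m, i0, j0)
  }
  i0 <- best[2]; j0 <- best[3]
  list(centre_um = c((j0 - 1 + w / 2) * pixel_pitch,
                     (i0 - 1 + w / 2) * pixel_pitch),
       offset_px = c(j0 - 1, i0 - 1),
       balance = best[1] / (w * w))
}
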