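# End-to-end orchestration: simulate -> preprocess -> peaks -> annotate ->
# respond -> segment -> register -> quantify -> report. Tissues are
# generated lazily (deterministically from the master seed) so no more than
# one tissue's spectra are held in memory at a time.

#' Pipeline run configuration
#'
#' @param study a [study_config()]
#' @param bin_width rebinning width, Da
#' @param min_apex peak detection floor (NULL = 3x MAD)
#' @param match_ppm cross-experiment consensus matching tolerance, ppm
#' @param inclusion_ppm,accuracy_ppm annotation windows, ppm
#' @param segmentation a [segmentation_config()]
#' @param subset_arms arms used for the reduced re-segmentation whose overlap
#'   with the full segmentation is reported (NULL to skip)
#' @param imc list: roi_um, cell_density, dna_threshold, noise_sd,
#'   positive_threshold (scalar applied to all markers)
#' @param mode spectrum rendering mode for simulation
#' @return object of class `run_config`
#' @export
run_config <- function(study = study_config(), bin_width = 0.05,
                       min_apex = NULL, match_ppm = 50,
                       inclusion_ppm = 300, accuracy_ppm = 150,
                       segmentation = segmentation_config(),
                       subset_arms = NULL,
                       imc = list(roi_um = 300, cell_density = 600,
                                  dna_threshold = 0.5, noise_sd = 0.01,
                                  positive_threshold = 0.5),
                       mode = "profile") {
  if (accuracy_ppm > inclusion_ppm) stopf("accuracy_ppm must be <= inclusion_ppm")
  if (is.null(subset_arms)) subset_arms <- study$arms[1:min(2, length(study$arms))]
  structure(list(study = study, bin_width = bin_width, min_apex = min_apex,
                 match_ppm = match_ppm, inclusion_ppm = inclusion_ppm,
                 accuracy_ppm = accuracy_ppm, segmentation = segmentation,
                 subset_arms = subset_arms, imc = imc, mode = mode),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys raise an error before any computation; nested blocks map
#' onto [study_config()], [segmentation_config()] and [run_config()]
#' arguments.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("study", "bin_width", "min_apex", "match_ppm", "inclusion_ppm",
             "accuracy_ppm", "segmentation", "subset_arms", "imc", "mode")
  bad <- setdiff(names(y), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  args <- y
  if (!is.null(y$study)) {
    if (!is.null(y$study$region_prevalence))
      y$study$region_prevalence <- unlist(y$study$region_prevalence)
    if (!is.null(y$study$arms)) y$study$arms <- unlist(y$study$arms)
    if (!is.null(y$study$grid_shape)) y$study$grid_shape <- unlist(y$study$grid_shape)
    if (!is.null(y$study$mass_range)) y$study$mass_range <- unlist(y$study$mass_range)
    args$study <- do.call(study_config, y$study)
  }
  if (!is.null(y$segmentation))
    args$segmentation <- do.call(segmentation_config, y$segmentation)
  do.call(run_config, args)
}

.tissue_table <- function(config) study_tissues(config)

.tissue_regions_for <- function(config, row) {
  generate_tissue_regions(config$grid_shape,
                          config$region_prevalence[[row$arm]],
                          config$region_smoothness,
                          seed = derive_seed(row$seed, "regions"))
}

.tissue_dataset_for <- function(config, row, mode) {
  rf <- .tissue_regions_for(config, row)
  generate_msi_dataset(config, row$e, row$arm, rf,
                       seed = derive_seed(row$seed, "msi"),
                       tissue_id = row$tissue_id, mode = mode)
}

# Per-experiment RMS-normalised mean spectrum with lazy tissue generation.
.experiment_mean_lazy <- function(config, e, axis, mode) {
  tt <- .tissue_table(config)
  tt <- tt[tt$e == e, , drop = FALSE]
  acc <- numeric(axis$n); total <- 0
  for (i in seq_len(nrow(tt))) {
    d <- .tissue_dataset_for(config, tt[i, ], mode)
    ms <- mean_spectrum(d, axis = axis, normalise = TRUE)
    k <- attr(ms, "n_pixels")
    acc <- acc + ms$intensity * k
    total <- total + k
  }
  out <- new_spectrum(axis_centres(axis), acc / total)
  attr(out, "axis") <- axis
  attr(out, "n_pixels") <- total
  out
}

#' Build the consensus peak matrix of a synthetic study
#'
#' Runs the MSI front end: per-experiment RMS-normalised mean spectra,
#' gradient peak detection, cross-experiment consensus matching, and
#' per-pixel integration with each experiment's own member bounds. Tissues
#' are generated lazily from the study seed.
#'
#' @param study a [study_config()]
#' @param bin_width rebin width, Da
#' @param match_ppm consensus matching tolerance, ppm
#' @param min_apex detection floor (NULL = 3x MAD)
#' @param mode spectrum rendering mode
#' @return list: peak_tables (per experiment), consensus
#'   ([match_peaks_across_experiments()] result or NULL for one experiment),
#'   peak_matrix (a `peak_matrix` over all pixels)
#' @export
study_peak_matrix <- function(study, bin_width = 0.05, match_ppm = 50,
                              min_apex = NULL, mode = "profile") {
  axis <- mass_axis(study$mass_range, bin_width)
  exps <- sprintf("Experiment-%d", seq_len(study$n_experiments))
  peak_tables <- lapply(seq_len(study$n_experiments), function(e)
    detect_peaks_gradient(.experiment_mean_lazy(study, e, axis, mode),
                          min_apex = min_apex))
  names(peak_tables) <- exps
  matched <- if (study$n_experiments >= 2)
    match_peaks_across_experiments(peak_tables, match_ppm)
  else NULL
  if (!is.null(matched) && nrow(matched) == 0)
    stopf("empty consensus peak set; downstream stages cannot run")
  tt <- study_tissues(study)
  parts <- lapply(seq_len(nrow(tt)), function(i) {
    row <- tt[i, ]
    ptab <- peak_tables[[row$e]]
    if (!is.null(matched))
      ptab <- ptab[matched[[paste0("idx_", exps[row$e])]], , drop = FALSE]
    d <- .tissue_dataset_for(study, row, mode)
    pm <- integrate_peaks(d, ptab, axis = axis)
    if (!is.null(matched))
      colnames(pm$intensity) <- sprintf("mz_%.4f", matched$consensus_mz)
    pm
  })
  peak_matrix <- structure(list(
    intensity = do.call(rbind, lapply(parts, `[[`, "intensity")),
    pixels = do.call(rbind, lapply(parts, `[[`, "pixels")),
    peaks = data.frame(center_mz = if (is.null(matched))
      peak_tables[[1]]$center_mz else matched$consensus_mz)),
    class = "peak_matrix")
  list(peak_tables = peak_tables, consensus = matched,
       peak_matrix = peak_matrix, axis = axis)
}

#' Run the full study analysis
#'
#' Executes the whole workflow on a (simulated) study and returns a report
#' bundle; identical configuration and seeds give identical summaries. When
#' `out_dir` is given, tables are written as CSV and the machine-readable
#' summary as JSON.
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory
#' @param quiet suppress progress messages
#' @return list with elements peaks, consensus, annotation, peak_matrix,
#'   response, drug, segmentation, imc, summary
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$study
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  # --- peaks, consensus, integration
  say("detecting, matching and integrating peaks")
  front <- study_peak_matrix(sc, config$bin_width, config$match_ppm,
                             config$min_apex, config$mode)
  peak_tables <- front$peak_tables
  matched <- front$consensus
  peak_matrix <- front$peak_matrix
  tt <- .tissue_table(sc)
  tick("peaks")

  # --- annotation against the configured metabolite database
  db <- data.frame(name = sc$metabolite_panel$name,
                   neutral_mass = sc$metabolite_panel$neutral_mass)
  acfg <- annotation_config(db, default_adducts("positive"),
                            config$inclusion_ppm, config$accuracy_ppm)
  ann_input <- if (is.null(matched)) peak_tables[[1]] else
    structure(data.frame(center_mz = matched$consensus_mz),
              class = c("peak_table", "data.frame"))
  annotation <- annotate_peaks(ann_input, acfg)
  tick("annotate")

  # --- response statistics
  vehicle <- sc$arms[1]
  tm <- tissue_means(peak_matrix)
  fc <- log2fc_vs_vehicle(tm, vehicle)
  tests <- do.call(rbind, lapply(setdiff(sc$arms, vehicle), function(a) {
    r <- compare_arms(fc, a, vehicle, method = "two_sided_t")
    r$arm <- a
    r
  }))
  drug <- NULL
  if (any(sc$metabolite_panel$is_drug_ion)) {
    dmz <- adduct_mz(sc$metabolite_panel$neutral_mass[sc$metabolite_panel$is_drug_ion][1],
                     sc$metabolite_panel$adduct[sc$metabolite_panel$is_drug_ion][1])
    drug <- tryCatch(drug_ion_report(peak_matrix, tm, dmz, ppm = config$accuracy_ppm,
                                     vehicle_arm = vehicle),
                     error = function(e) NULL)
  }
  tick("respond")

  # --- segmentation (full study), region fractions, subset re-segmentation
  say("segmenting pixels (t-SNE + k-means)")
  segs <- segment_study(peak_matrix, config$segmentation, vehicle)
  fractions <- do.call(rbind, lapply(segs, function(s)
    do.call(rbind, lapply(unique(s$tissue_id), function(tid)
      data.frame(experiment_id = s$experiment_id[1], tissue_id = tid,
                 arm = s$arm[s$tissue_id == tid][1],
                 region_a_pct = region_fraction(s, tid))))))
  rownames(fractions) <- NULL
  overlap <- NULL
  if (!is.null(config$subset_arms) &&
      length(setdiff(sc$arms, config$subset_arms)) > 0) {
    sel <- peak_matrix$pixels$arm %in% config$subset_arms
    pm_sub <- structure(list(intensity = peak_matrix$intensity[sel, , drop = FALSE],
                             pixels = peak_matrix$pixels[sel, , drop = FALSE],
                             peaks = peak_matrix$peaks), class = "peak_matrix")
    segs_sub <- segment_study(pm_sub, config$segmentation, vehicle)
    overlap <- data.frame(
      experiment_id = names(segs),
      overlap_pct = vapply(names(segs), function(e)
        segmentation_overlap(segs[[e]], segs_sub[[e]]), numeric(1)))
    rownames(overlap) <- NULL
  }
  tick("segment")

  # --- registration + IMC quantification (last experiment, mirroring a
  #     design where one batch is taken to IMC)
  say("registering IMC and quantifying markers by region")
  rules <- default_marker_rules(sc$arms)
  imc_e <- sc$n_experiments
  tt_imc <- tt[tt$e == imc_e, , drop = FALSE]
  imc_stats <- list(); registration <- list()
  for (i in seq_len(nrow(tt_imc))) {
    row <- tt_imc[i, ]
    rf <- .tissue_regions_for(sc, row)
    aff_true <- .true_affine_for_tissue(sc, derive_seed(row$seed, "affine"),
                                        config$imc$roi_um)
    imc <- generate_imc_images(rf, aff_true, rules, row$arm,
                               cell_density = config$imc$cell_density,
                               seed = derive_seed(row$seed, "imc"),
                               roi_um = config$imc$roi_um,
                               imc_pixel_pitch = sc$imc_pixel_pitch,
                               msi_pixel_pitch = sc$msi_pixel_pitch,
                               noise_sd = config$imc$noise_sd %||% 0)
    corners <- rbind(c(0, 0), c(sc$grid_shape[2] * sc$msi_pixel_pitch, 0),
                     c(0, sc$grid_shape[1] * sc$msi_pixel_pitch),
                     sc$grid_shape[c(2, 1)] * sc$msi_pixel_pitch)
    fitted <- fit_affine(corners, apply_affine(aff_true, corners))
    registration[[row$tissue_id]] <- attr(fitted, "rmse")
    seg_t <- segs[[sprintf("Experiment-%d", imc_e)]]
    seg_t <- seg_t[seg_t$tissue_id == row$tissue_id, , drop = FALSE]
    side <- nrow(imc$images$DNA)
    labels <- transfer_labels(seg_t, sc$msi_pixel_pitch, fitted,
                              c(side, side), sc$imc_pixel_pitch)
    markers <- imc$images[setdiff(names(imc$images), "DNA")]
    cellseg <- segment_cells(imc$images$DNA, markers,
                             pixel_pitch = sc$imc_pixel_pitch,
                             dna_threshold = config$imc$dna_threshold)
    thr <- setNames(rep(config$imc$positive_threshold, length(markers)),
                    names(markers))
    imc_stats[[row$tissue_id]] <- quantify_by_region(
      markers, cellseg$cells, labels, thr,
      pixel_pitch = sc$imc_pixel_pitch, arm = row$arm)
  }
  imc_stats_all <- do.call(rbind, imc_stats)
  # aggregate across tissues: cell-count-weighted means per (arm, region, marker)
  region_marker_stats <- NULL
  if (!is.null(imc_stats_all) && nrow(imc_stats_all)) {
    sp <- split(imc_stats_all,
                list(imc_stats_all$arm, imc_stats_all$region,
                     imc_stats_all$marker), drop = TRUE)
    region_marker_stats <- do.call(rbind, lapply(sp, function(g) {
      data.frame(arm = g$arm[1], region = g$region[1], marker = g$marker[1],
                 mean_pixel_intensity = mean(g$mean_pixel_intensity),
                 mean_cell_intensity =
                   sum(g$mean_cell_intensity * g$total_cells) / sum(g$total_cells),
                 positive_cells = sum(g$positive_cells),
                 total_cells = sum(g$total_cells))
    }))
    region_marker_stats$positive_fraction <-
      region_marker_stats$positive_cells / region_marker_stats$total_cells
    rownames(region_marker_stats) <- NULL
  }
  tick("imc")

  summary <- list(
    simulate = list(n_experiments = sc$n_experiments, arms = sc$arms,
                    tissues_per_arm = sc$tissues_per_arm,
                    grid_shape = sc$grid_shape, noise_cv = sc$noise_cv,
                    seed = sc$seed),
    peaks = lapply(peak_tables, nrow),
    consensus = list(n_peaks = if (is.null(matched)) nrow(peak_tables[[1]])
                     else nrow(matched)),
    annotation = list(n_assigned_peaks = length(unique(annotation$peak_idx))),
    response = list(n_tests = if (is.null(tests)) 0 else nrow(tests),
                    n_significant_05 = if (is.null(tests)) 0 else
                      sum(tests$p_value < 0.05)),
    drug = if (!is.null(drug)) list(observed_mz = drug$observed_mz,
                                    ppm_error = drug$ppm_error) else NULL,
    segmentation = list(region_fractions = fractions,
                        overlap = overlap),
    imc = list(region_marker_stats = region_marker_stats,
               registration_rmse_um = unlist(registration)),
    provenance = list(seed = sc$seed)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stopf("cannot create %s", out_dir)
    write.csv(as.data.frame(tm), file.path(out_dir, "tissue_means.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(fc), file.path(out_dir, "log2fc.csv"),
              row.names = FALSE)
    if (!is.null(tests))
      write.csv(tests, file.path(out_dir, "arm_tests.csv"), row.names = FALSE)
    write.csv(fractions, file.path(out_dir, "region_fractions.csv"),
              row.names = FALSE)
    if (!is.null(region_marker_stats))
      write.csv(region_marker_stats,
                file.path(out_dir, "region_marker_stats.csv"), row.names = FALSE)
    write.csv(annotation, file.path(out_dir, "annotation.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  list(peak_tables = peak_tables, consensus = matched, annotation = annotation,
       peak_matrix = peak_matrix, tissue_means = tm, log2fc = fc,
       tests = tests, drug = drug, segmentation = segs,
       region_fractions = fractions, overlap = overlap,
       imc = list(per_tissue = imc_stats_all, aggregated = region_marker_stats,
                  registration_rmse_um = unlist(registration)),
       timings_s = timings, summary = summary)
}
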