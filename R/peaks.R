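# Gradient peak detection on experiment mean spectra, per-pixel peak
# integration into ion images, accurate-mass adduct annotation, and
# consensus peak matching across experiments.

#' Gradient peak detection on a uniform-axis spectrum
#'
#' Apexes are positions where the first difference of intensity changes sign
#' from positive to negative; integration bounds extend to the nearest
#' position where intensity stops decreasing (local minimum or support edge).
#' Apexes below `min_apex` are discarded. Peak centres are refined by the
#' intensity-weighted centroid of the window, which restores sub-bin mass
#' accuracy on coarse axes.
#'
#' @param mean_spectrum a rebinned `spectrum` (uniform axis)
#' @param min_apex minimum apex intensity; default 3x the median absolute
#'   deviation of the spectrum
#' @return a `peak_table`: data.frame with center_mz, left_mz, right_mz,
#'   apex_mz, apex_intensity, left_idx, right_idx (1-based bin indices),
#'   sorted by center_mz, with the axis attached as attribute `"axis"`
#' @export
detect_peaks_gradient <- function(mean_spectrum, min_apex = NULL) {
  axis <- attr(mean_spectrum, "axis")
  mz <- mean_spectrum$mz
  y <- mean_spectrum$intensity
  if (length(mz) >= 3) {
    dif <- diff(mz)
    if (max(abs(dif - dif[1])) > 1e-6 * dif[1])
      stopf("gradient detection requires a uniform axis")
  }
  if (is.null(min_apex)) min_apex <- 3 * mad(y)
  n <- length(y)
  d <- diff(y)
  # sign changes + -> - of the first difference; zero runs (plateaux, e.g. a
  # peak falling exactly between two bins) are crossed, the apex taken at the
  # first point of the plateau
  s <- sign(d)
  nz <- which(s != 0)
  apex <- integer(0)
  if (length(nz) > 1) {
    turn <- which(s[nz[-length(nz)]] > 0 & s[nz[-1]] < 0)
    apex <- nz[turn] + 1L
  }
  apex <- apex[y[apex] >= min_apex]
  if (!length(apex))
    return(structure(data.frame(center_mz = numeric(0), left_mz = numeric(0),
                                right_mz = numeric(0), apex_mz = numeric(0),
                                apex_intensity = numeric(0),
                                left_idx = integer(0), right_idx = integer(0)),
                     class = c("peak_table", "data.frame"), axis = axis))
  left <- vapply(apex, function(i) {
    while (i > 1 && y[i - 1] <= y[i]) i <- i - 1L
    i
  }, integer(1))
  right <- vapply(apex, function(i) {
    while (i < n && y[i + 1] <= y[i]) i <- i + 1L
    i
  }, integer(1))
  # adjacent windows may share the boundary minimum; give it to the left peak
  if (length(apex) > 1)
    for (k in 2:length(apex))
      if (left[k] <= right[k - 1]) left[k] <- right[k - 1] + 1L
  centroid <- vapply(seq_along(apex), function(k) {
    idx <- left[k]:right[k]
    w <- y[idx]
    if (sum(w) <= 0) mz[apex[k]] else sum(mz[idx] * w) / sum(w)
  }, numeric(1))
  out <- data.frame(center_mz = centroid, left_mz = mz[left],
                    right_mz = mz[right], apex_mz = mz[apex],
                    apex_intensity = y[apex],
                    left_idx = left, right_idx = right)
  out <- out[order(out$center_mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_table", "data.frame"), axis = axis)
}

#' Integrate detected peaks per pixel into a peak matrix
#'
#' Each entry is the sum of the pixel's RMS-normalised rebinned intensities
#' over the bins of the peak's integration window.
#'
#' @param datasets one `msi_dataset` or a list (one experiment)
#' @param peak_table a [detect_peaks_gradient()] result (with axis)
#' @param axis the shared [mass_axis()]; defaults to the peak table's
#' @param normalise RMS-normalise each pixel (default TRUE)
#' @return a `peak_matrix`: list with `intensity` (pixels x peaks),
#'   `pixels` (tissue_id, experiment_id, arm, x, y) and `peaks`
#' @export
integrate_peaks <- function(datasets, peak_table, axis = NULL,
                            normalise = TRUE) {
  if (inherits(datasets, "msi_dataset")) datasets <- list(datasets)
  if (is.null(axis)) axis <- attr(peak_table, "axis")
  if (is.null(axis)) stopf("no axis available for integration")
  pax <- attr(peak_table, "axis")
  if (!is.null(pax) && !.axis_equal(axis, pax))
    stopf("peak table axis does not match the integration axis")
  mzs <- ints <- list(); meta <- list()
  for (d in datasets) {
    mzs <- c(mzs, lapply(d$spectra, `[[`, "mz"))
    ints <- c(ints, lapply(d$spectra, `[[`, "intensity"))
    meta[[length(meta) + 1]] <- data.frame(
      tissue_id = d$tissue_id, experiment_id = d$experiment_id, arm = d$arm,
      x = d$coords$x, y = d$coords$y, stringsAsFactors = FALSE)
  }
  m <- cpp_integrate(mzs, ints, axis$lo, axis$bin_width, axis$n,
                     peak_table$left_idx - 1L, peak_table$right_idx - 1L,
                     normalise)
  colnames(m) <- sprintf("mz_%.4f", peak_table$center_mz)
  structure(list(intensity = m, pixels = do.call(rbind, meta),
                 peaks = as.data.frame(peak_table)),
            class = "peak_matrix")
}

#' Render an ion image with 95th-percentile display clipping
#'
#' Intensities of one peak are clipped at the 95th percentile of the pooled
#' pixel values across all tissues of the experiment (display convention;
#' statistics always use unclipped values).
#'
#' @param peak_matrix a [integrate_peaks()] result
#' @param peak peak index (column) or column name
#' @param tissues tissue ids to render; default all in the matrix
#' @param probs clipping quantile (default 0.95)
#' @return named list of numeric matrices (rows = y, cols = x), one per tissue
#' @export
render_ion_image <- function(peak_matrix, peak, tissues = NULL, probs = 0.95) {
  v <- peak_matrix$intensity[, peak]
  px <- peak_matrix$pixels
  if (is.null(tissues)) tissues <- unique(px$tissue_id)
  pool <- v[px$tissue_id %in% tissues]
  if (!length(pool)) stopf("no pixels to render")
  cap <- quantile(pool, probs, names = FALSE)
  vc <- pmin(v, cap)
  out <- lapply(tissues, function(tid) {
    sel <- px$tissue_id == tid
    im <- matrix(NA_real_, max(px$y[sel]) + 1L, max(px$x[sel]) + 1L)
    im[cbind(px$y[sel] + 1L, px$x[sel] + 1L)] <- vc[sel]
    im
  })
  names(out) <- tissues
  out
}

#' Annotation configuration
#'
#' @param database data.frame with columns `name` and either `neutral_mass`
#'   or `formula`
#' @param adducts adduct labels to consider
#' @param inclusion_ppm candidate search window (ppm)
#' @param accuracy_ppm retention window (ppm), must be <= inclusion_ppm
#' @return object of class `annotation_config`
#' @export
annotation_config <- function(database, adducts, inclusion_ppm,
                              accuracy_ppm) {
  if (accuracy_ppm > inclusion_ppm)
    stopf("accuracy_ppm (%g) must be <= inclusion_ppm (%g)",
          accuracy_ppm, inclusion_ppm)
  if (is.null(database$neutral_mass)) {
    if (is.null(database$formula)) stopf("database needs neutral_mass or formula")
    database$neutral_mass <- formula_mass(database$formula)
  }
  if (any(database$neutral_mass <= 0)) stopf("database masses must be > 0")
  structure(list(database = database, adducts = adducts,
                 inclusion_ppm = inclusion_ppm, accuracy_ppm = accuracy_ppm),
            class = "annotation_config")
}

#' Accurate-mass annotation of detected peaks
#'
#' For each peak, database entries whose theoretical adduct m/z lies within
#' the inclusion window are candidates; candidates within the (tighter)
#' accuracy window are retained, sorted by absolute ppm error.
#'
#' @param peak_table a `peak_table`
#' @param config an [annotation_config()]
#' @return data.frame: peak_idx, center_mz, name, adduct, theoretical_mz,
#'   ppm_error
#' @export
annotate_peaks <- function(peak_table, config) {
  db <- config$database
  theo <- do.call(rbind, lapply(config$adducts, function(ad)
    data.frame(name = db$name, adduct = ad,
               theoretical_mz = adduct_mz(db$neutral_mass, ad),
               stringsAsFactors = FALSE)))
  hits <- lapply(seq_len(nrow(peak_table)), function(i) {
    obs <- peak_table$center_mz[i]
    ppm <- ppm_error(obs, theo$theoretical_mz)
    keep <- abs(ppm) <= config$inclusion_ppm
    keep <- keep & abs(ppm) <= config$accuracy_ppm
    if (!any(keep)) return(NULL)
    h <- theo[keep, , drop = FALSE]
    h$ppm_error <- ppm[keep]
    h$peak_idx <- i
    h$center_mz <- obs
    h[order(abs(h$ppm_error)), ]
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(peak_idx = integer(0), center_mz = numeric(0),
                      name = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0))
  rownames(out) <- NULL
  out[, c("peak_idx", "center_mz", "name", "adduct", "theoretical_mz",
          "ppm_error")]
}

#' Match peaks across experiments into a consensus set
#'
#' Peaks from all experiments are pooled, sorted by m/z, and chained into
#' groups wherever the relative gap to the previous centre is within
#' `match_ppm`. Only groups with exactly one member from every experiment are
#' kept (peaks must be common to all experiments). Consensus m/z is the
#' unweighted mean of member centres.
#'
#' @param peak_tables named list of `peak_table`s, one per experiment
#' @param match_ppm chaining tolerance (ppm)
#' @return a `matched_peak_set`: data.frame with consensus_mz and one
#'   `idx_<experiment>` column per experiment giving the member's row in that
#'   experiment's peak table
#' @export
match_peaks_across_experiments <- function(peak_tables, match_ppm = 50) {
  if (length(peak_tables) < 2) stopf("need at least 2 peak tables")
  if (is.null(names(peak_tables)) || any(!nzchar(names(peak_tables))))
    names(peak_tables) <- sprintf("exp%d", seq_along(peak_tables))
  exps <- names(peak_tables)
  for (e in exps) {
    ctr <- sort(peak_tables[[e]]$center_mz)
    if (length(ctr) > 1 && any(diff(ctr) / ctr[-length(ctr)] * 1e6 <= match_ppm))
      stopf("experiment %s has duplicate peak centres within %g ppm (ambiguous table)",
            e, match_ppm)
  }
  pool <- do.call(rbind, lapply(exps, function(e)
    data.frame(exp = e, idx = seq_len(nrow(peak_tables[[e]])),
               mz = peak_tables[[e]]$center_mz, stringsAsFactors = FALSE)))
  out <- data.frame(consensus_mz = numeric(0))
  for (e in exps) out[[paste0("idx_", e)]] <- integer(0)
  if (!nrow(pool)) return(structure(out, class = c("matched_peak_set", "data.frame")))
  pool <- pool[order(pool$mz), , drop = FALSE]
  gap <- c(Inf, diff(pool$mz) / pool$mz[-nrow(pool)] * 1e6)
  group <- cumsum(gap > match_ppm)
  keep <- lapply(split(pool, group), function(g) {
    if (nrow(g) == length(exps) && all(sort(g$exp) == sort(exps))) g else NULL
  })
  keep <- keep[!vapply(keep, is.null, logical(1))]
  rows <- lapply(keep, function(g) {
    r <- data.frame(consensus_mz = mean(g$mz))
    for (e in exps) r[[paste0("idx_", e)]] <- g$idx[g$exp == e]
    r
  })
  out <- if (length(rows)) do.call(rbind, rows) else out
  rownames(out) <- NULL
  structure(out[order(out$consensus_mz), , drop = FALSE],
            class = c("matched_peak_set", "data.frame"))
}
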