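# Spectrum and MSIDataset containers with the spectral preprocessing used by
# the pipeline: interpolation rebinning, RMS normalisation, mean spectra.

#' Construct a mass spectrum
#'
#' @param mz numeric vector of m/z values (Da), strictly ascending
#' @param intensity non-negative intensities, same length as `mz`
#' @return object of class `spectrum`: list with `mz`, `intensity`
#' @export
new_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    stopf("mz and intensity lengths differ (%d vs %d)", length(mz), length(intensity))
  if (length(mz) && any(diff(mz) <= 0)) stopf("mz must be strictly ascending")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stopf("intensities must be finite and non-negative")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "spectrum")
}

#' Uniform mass axis
#'
#' Half-open bins `[low + i*w, low + (i+1)*w)` anchored at `mass_range[1]`;
#' values are carried at bin centres.
#' @param mass_range numeric length-2, low < high (Da)
#' @param bin_width bin width (Da)
#' @return list with `lo`, `bin_width`, `n`, and `centers()` accessor field `centres`
#' @export
mass_axis <- function(mass_range, bin_width) {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  if (diff(mass_range) <= 0) stopf("mass_range must satisfy low < high")
  # guard against floating-point excess (e.g. 0.005/0.001 = 5.0000000000001)
  n <- as.integer(ceiling((mass_range[2] - mass_range[1]) / bin_width - 1e-9))
  structure(list(lo = mass_range[1], bin_width = bin_width, n = n),
            class = "mass_axis")
}

#' Bin-centre m/z values of a mass axis
#' @param axis a [mass_axis()]
#' @return numeric vector of bin centres
#' @export
axis_centres <- function(axis) {
  axis$lo + (seq_len(axis$n) - 0.5) * axis$bin_width
}

.axis_equal <- function(a, b) {
  isTRUE(all.equal(a$lo, b$lo)) && isTRUE(all.equal(a$bin_width, b$bin_width)) &&
    a$n == b$n
}

#' Interpolation rebinning onto a uniform axis
#'
#' Linear interpolation of the input spectrum at the centres of uniform bins;
#' zero outside the input support.
#'
#' @param spectrum a [new_spectrum()] with at least 2 points
#' @param bin_width bin width in Da (ignored when `axis` given)
#' @param mass_range axis span; defaults to the spectrum's own support
#' @param axis optionally a prebuilt [mass_axis()]
#' @return a `spectrum` on the uniform axis, with the axis attached as
#'   attribute `"axis"`
#' @export
rebin_spectrum <- function(spectrum, bin_width = NULL, mass_range = NULL,
                           axis = NULL) {
  if (length(spectrum$mz) < 2) stopf("cannot rebin a spectrum with < 2 points")
  if (is.null(axis)) {
    if (is.null(bin_width)) stopf("either bin_width or axis is required")
    if (is.null(mass_range)) mass_range <- range(spectrum$mz)
    axis <- mass_axis(mass_range, bin_width)
  }
  v <- cpp_rebin(spectrum$mz, spectrum$intensity, axis$lo, axis$bin_width, axis$n)
  out <- new_spectrum(axis_centres(axis), v)
  attr(out, "axis") <- axis
  out
}

#' Root-mean-square normalisation
#'
#' Divides intensities by sqrt(mean(intensity^2)) so the output spectrum has
#' RMS exactly 1. Scale-invariant and idempotent. RMS is taken over the full
#' intensity vector, zeros included.
#'
#' @param spectrum a `spectrum`
#' @return normalised `spectrum` (axis attribute preserved)
#' @export
rms_normalise <- function(spectrum) {
  r <- sqrt(mean(spectrum$intensity^2))
  if (!is.finite(r) || r <= 0) stopf("cannot RMS-normalise an all-zero spectrum")
  out <- spectrum
  out$intensity <- spectrum$intensity / r
  out
}

#' Pixel-wise mean spectrum over one or more datasets
#'
#' Rebins every pixel of every dataset onto the shared axis, optionally
#' RMS-normalises each pixel, and returns the arithmetic mean spectrum.
#' All-zero pixels are excluded when normalising.
#'
#' @param datasets a single `msi_dataset` or list of them (one experiment)
#' @param axis the common [mass_axis()]; defaults to the first dataset's
#'   mass range at `bin_width`
#' @param bin_width used to build the axis when `axis` is missing
#' @param normalise RMS-normalise each pixel before averaging (default TRUE)
#' @return mean `spectrum` with the axis attached; attribute `"n_pixels"`
#'   records how many pixels contributed
#' @export
mean_spectrum <- function(datasets, axis = NULL, bin_width = NULL,
                          normalise = TRUE) {
  if (inherits(datasets, "msi_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stopf("no datasets supplied")
  pol <- unique(vapply(datasets, function(d) d$polarity, character(1)))
  if (length(pol) != 1) stopf("datasets mix polarities: %s", paste(pol, collapse = ", "))
  if (is.null(axis)) {
    if (is.null(bin_width)) stopf("either axis or bin_width is required")
    axis <- mass_axis(datasets[[1]]$mass_range, bin_width)
  }
  mzs <- ints <- list()
  for (d in datasets) {
    mzs <- c(mzs, lapply(d$spectra, `[[`, "mz"))
    ints <- c(ints, lapply(d$spectra, `[[`, "intensity"))
  }
  res <- cpp_accumulate_mean(mzs, ints, axis$lo, axis$bin_width, axis$n, normalise)
  out <- new_spectrum(axis_centres(axis), res$mean)
  attr(out, "axis") <- axis
  attr(out, "n_pixels") <- res$n_used
  out
}

#' Construct an MSI dataset (one tissue section)
#'
#' @param coords data.frame with integer 0-based columns `x` (rightward) and
#'   `y` (downward), one row per pixel, unique
#' @param spectra list of [new_spectrum()] objects, one per pixel
#' @param pixel_pitch pixel spacing in µm
#' @param polarity "positive" or "negative"
#' @param modality "MALDI" or "DESI"
#' @param tissue_id,experiment_id,arm sample metadata
#' @param mass_range acquisition mass range (Da)
#' @return object of class `msi_dataset`
#' @export
msi_dataset <- function(coords, spectra, pixel_pitch, polarity = "negative",
                        modality = "MALDI", tissue_id = "tissue",
                        experiment_id = "exp", arm = "vehicle",
                        mass_range = NULL) {
  if (nrow(coords) != length(spectra))
    stopf("coords rows (%d) != spectra length (%d)", nrow(coords), length(spectra))
  if (nrow(coords) == 0) stopf("empty pixel list")
  if (anyDuplicated(coords[, c("x", "y")])) stopf("pixel coordinates must be unique")
  if (pixel_pitch <= 0) stopf("pixel_pitch must be > 0")
  if (is.null(mass_range)) {
    allmz <- range(unlist(lapply(spectra, `[[`, "mz")))
    mass_range <- c(floor(allmz[1]), ceiling(allmz[2]))
  }
  structure(list(coords = coords, spectra = spectra, pixel_pitch = pixel_pitch,
                 polarity = polarity, modality = modality, tissue_id = tissue_id,
                 experiment_id = experiment_id, arm = arm,
                 mass_range = as.numeric(mass_range)),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %s | experiment %s | arm %s\n  %d pixels, pitch %g um, %s %s, m/z %g-%g\n",
              x$tissue_id, x$experiment_id, x$arm, nrow(x$coords),
              x$pixel_pitch, x$modality, x$polarity,
              x$mass_range[1], x$mass_range[2]))
  invisible(x)
}
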