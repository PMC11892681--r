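# Shared fixture builders: everything is generated in code at test time.

tiny_config <- function(seed = 5, noise_cv = 0.2, jitter_ppm = 5,
                        grid = c(16, 16), n_metab = 30,
                        arms = c("vehicle", "drugA")) {
  prev <- setNames(c(0.7, 0.3, 0.5, 0.1)[seq_along(arms)], arms)
  study_config(n_experiments = 2, arms = arms, tissues_per_arm = 2,
               grid_shape = grid, region_prevalence = prev,
               metabolite_panel = default_metabolite_panel(arms, n_metab),
               noise_cv = noise_cv, jitter_ppm = jitter_ppm, seed = seed)
}

# A hand-sized three-pixel dataset with known spectra.
three_pixel_dataset <- function() {
  sp <- list(new_spectrum(c(100, 200, 300), c(1, 5, 2)),
             new_spectrum(c(100, 200, 300), c(0, 1, 0)),
             new_spectrum(c(100, 200, 300), c(2, 2, 2)))
  msi_dataset(data.frame(x = c(0L, 1L, 0L), y = c(0L, 0L, 1L)), sp,
              pixel_pitch = 50, tissue_id = "T1", experiment_id = "E1",
              arm = "vehicle", mass_range = c(90, 310))
}

# Peak matrix with two programmed pixel populations for segmentation tests.
two_population_matrix <- function(n_per = 60, n_peaks = 8, delta = 4,
                                  seed = 3) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_per * n_peaks), n_per, n_peaks)
    b <- matrix(rnorm(n_per * n_peaks), n_per, n_peaks)
    b[, 1:5] <- b[, 1:5] + delta
    m <- rbind(a, b)
  })
  colnames(m) <- sprintf("p%d", seq_len(n_peaks))
  n <- 2 * n_per
  px <- data.frame(tissue_id = "T1", experiment_id = "E1",
                   arm = rep(c("vehicle", "drugA"), each = n_per),
                   x = seq_len(n) - 1L, y = 0L)
  structure(list(intensity = m, pixels = px,
                 peaks = data.frame(center_mz = 100 + seq_len(n_peaks))),
            class = "peak_matrix")
}

make_seg <- function(tissue, x, y, region, cluster = NULL, arm = "vehicle",
                     experiment = "E1") {
  structure(data.frame(tissue_id = tissue, experiment_id = experiment,
                       arm = arm, x = x, y = y,
                       cluster = cluster %||% as.integer(factor(region)),
                       region = region, stringsAsFactors = FALSE),
            class = c("segmentation_map", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
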