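# Tissue-level pharmacodynamic statistics: per-tissue mean ion intensities,
# vehicle-normalised log2 fold changes per experiment, between-arm tests,
# boxplot summaries and the drug-ion report. Tissues (not pixels) are the
# statistical unit throughout.

#' Per-tissue mean ion intensities
#'
#' Arithmetic mean of the integrated peak intensity over each tissue's
#' retained pixels.
#'
#' @param peak_matrix a [integrate_peaks()] result
#' @return a `tissue_mean_table`: data.frame with tissue_id, experiment_id,
#'   arm and one column per peak
#' @export
tissue_means <- function(peak_matrix) {
  px <- peak_matrix$pixels
  tid <- unique(px$tissue_id)
  empty <- setdiff(tid, px$tissue_id[rowSums(!is.na(peak_matrix$intensity)) > 0])
  if (length(empty)) stopf("tissues with zero retained pixels: %s",
                           paste(empty, collapse = ", "))
  groups <- split(seq_len(nrow(px)), px$tissue_id)[tid]
  m <- do.call(rbind, lapply(groups, function(idx)
    colMeans(peak_matrix$intensity[idx, , drop = FALSE])))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("peak_%d", seq_len(ncol(m)))
  meta <- px[!duplicated(px$tissue_id), c("tissue_id", "experiment_id", "arm")]
  meta <- meta[match(tid, meta$tissue_id), ]
  out <- cbind(meta, as.data.frame(m, check.names = FALSE))
  rownames(out) <- NULL
  structure(out, class = c("tissue_mean_table", "data.frame"),
            peak_cols = colnames(m))
}

.peak_cols <- function(tbl) {
  attr(tbl, "peak_cols") %||%
    setdiff(colnames(tbl), c("tissue_id", "experiment_id", "arm"))
}

#' Vehicle-normalised log2 fold change per experiment
#'
#' Within each experiment, each tissue's mean intensity is divided by the
#' mean over that experiment's vehicle tissues, then log2-transformed. By
#' construction the plain ratios of an experiment's vehicle tissues average
#' exactly 1, which cancels batch scale factors and lets experiments be
#' pooled. Peaks with a zero vehicle mean in an experiment are set to NA for
#' that experiment and reported in attribute `"excluded"`.
#'
#' @param tissue_mean_table a [tissue_means()] result
#' @param vehicle_arm name of the vehicle arm
#' @return a `log2fc_table`, same shape as the input
#' @export
log2fc_vs_vehicle <- function(tissue_mean_table, vehicle_arm = "vehicle") {
  pk <- .peak_cols(tissue_mean_table)
  out <- tissue_mean_table
  excluded <- list()
  for (e in unique(out$experiment_id)) {
    sel <- out$experiment_id == e
    veh <- sel & out$arm == vehicle_arm
    if (!any(veh)) stopf("experiment %s has no %s tissues", e, vehicle_arm)
    vmean <- colMeans(as.matrix(tissue_mean_table[veh, pk, drop = FALSE]))
    bad <- vmean <= 0
    if (any(bad)) excluded[[e]] <- pk[bad]
    ratio <- sweep(as.matrix(tissue_mean_table[sel, pk, drop = FALSE]), 2,
                   vmean, `/`)
    ratio[, bad] <- NA_real_
    out[sel, pk] <- log2(ratio)
  }
  structure(out, class = c("log2fc_table", "data.frame"), peak_cols = pk,
            excluded = excluded)
}

#' Between-arm significance tests
#'
#' Per peak, either a two-sided two-sample t-test (Welch by default, Student
#' selectable) on per-tissue log2 fold changes pooled across experiments, or
#' a two-way ANOVA with additive factors arm and experiment (type-II sum of
#' squares, i.e. the arm effect adjusted for experiment). No multiplicity
#' adjustment is applied by default; set `p_adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param log2fc_table a [log2fc_vs_vehicle()] result (or tissue mean table)
#' @param arm_a,arm_b the two arms to compare
#' @param method "two_sided_t" or "two_way_anova"
#' @param var_equal use the Student (pooled-variance) t-test
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()],
#'   default "none"
#' @return data.frame: peak, statistic, p_value, test
#' @export
compare_arms <- function(log2fc_table, arm_a, arm_b,
                         method = c("two_sided_t", "two_way_anova"),
                         var_equal = FALSE, p_adjust = "none") {
  method <- match.arg(method)
  pk <- .peak_cols(log2fc_table)
  sel <- log2fc_table$arm %in% c(arm_a, arm_b)
  dat <- log2fc_table[sel, , drop = FALSE]
  counts <- table(dat$arm)
  if (method == "two_sided_t" &&
      (is.na(counts[arm_a]) || is.na(counts[arm_b]) ||
       counts[arm_a] < 2 || counts[arm_b] < 2))
    stopf("t-test needs >= 2 tissues per arm (%s: %d, %s: %d)",
          arm_a, ifelse(is.na(counts[arm_a]), 0, counts[arm_a]),
          arm_b, ifelse(is.na(counts[arm_b]), 0, counts[arm_b]))
  res <- lapply(pk, function(p) {
    y <- dat[[p]]
    ok <- is.finite(y)
    if (method == "two_sided_t") {
      ya <- y[ok & dat$arm == arm_a]; yb <- y[ok & dat$arm == arm_b]
      if (sd(c(ya, yb)) == 0) {
        # degenerate identical groups: no evidence against the null
        return(data.frame(peak = p, statistic = 0, p_value = 1,
                          test = "two_sided_t"))
      }
      tt <- t.test(ya, yb, var.equal = var_equal)
      data.frame(peak = p, statistic = unname(tt$statistic),
                 p_value = tt$p.value, test = "two_sided_t")
    } else {
      d <- data.frame(y = y[ok], arm = factor(dat$arm[ok]),
                      experiment = factor(dat$experiment_id[ok]))
      full <- lm(y ~ arm + experiment, data = d)
      red <- lm(y ~ experiment, data = d)
      a <- anova(red, full)
      data.frame(peak = p, statistic = a$F[2], p_value = a$`Pr(>F)`[2],
                 test = "two_way_anova")
    }
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Boxplot summary (median, quartiles, 1%/99% whiskers)
#'
#' Quantiles by linear interpolation; per-tissue points are retained with
#' their experiment tag so plots can mark each tissue by batch.
#'
#' @param log2fc_table a `log2fc_table`
#' @param peak peak column name
#' @param grouping column to group by (default "arm")
#' @return list with `summary` (group, q01, q25, median, q75, q99, n) and
#'   `points` (group, experiment_id, tissue_id, value)
#' @export
boxplot_summary <- function(log2fc_table, peak, grouping = "arm") {
  vals <- log2fc_table[[peak]]
  grp <- log2fc_table[[grouping]]
  ok <- is.finite(vals)
  if (!all(tapply(ok, grp, any))) stopf("empty group in boxplot summary")
  qs <- t(vapply(split(vals[ok], grp[ok]), quantile,
                 probs = c(0.01, 0.25, 0.5, 0.75, 0.99), numeric(5)))
  summary <- data.frame(group = rownames(qs), q01 = qs[, 1], q25 = qs[, 2],
                        median = qs[, 3], q75 = qs[, 4], q99 = qs[, 5],
                        n = as.vector(table(grp[ok])[rownames(qs)]))
  rownames(summary) <- NULL
  points <- data.frame(group = grp[ok],
                       experiment_id = log2fc_table$experiment_id[ok],
                       tissue_id = log2fc_table$tissue_id[ok],
                       value = vals[ok])
  list(summary = summary, points = points)
}

#' Drug-ion pharmacokinetic report
#'
#' Locates the consensus peak nearest the expected drug m/z (within `ppm`),
#' reports per-tissue mean drug intensity and log2 fold change versus
#' vehicle, and renders display-clipped ion images.
#'
#' @param peak_matrix a [integrate_peaks()] result
#' @param tissue_mean_table matching [tissue_means()] result
#' @param drug_mz expected drug adduct m/z
#' @param ppm matching tolerance
#' @param vehicle_arm vehicle arm name
#' @return list with `peak_col`, `observed_mz`, `ppm_error`, `per_tissue`
#'   (tissue_id, experiment_id, arm, intensity, log2fc) and `images`
#' @export
drug_ion_report <- function(peak_matrix, tissue_mean_table, drug_mz,
                            ppm = 70, vehicle_arm = "vehicle") {
  ctr <- peak_matrix$peaks$center_mz
  err <- abs(ppm_error(ctr, drug_mz))
  if (!any(err <= ppm))
    stopf("no consensus peak within %g ppm of m/z %.4f (closest: %.1f ppm)",
          ppm, drug_mz, min(err))
  j <- which.min(err)
  pk <- .peak_cols(tissue_mean_table)[j]
  fc <- log2fc_vs_vehicle(tissue_mean_table, vehicle_arm)
  per_tissue <- data.frame(
    tissue_id = tissue_mean_table$tissue_id,
    experiment_id = tissue_mean_table$experiment_id,
    arm = tissue_mean_table$arm,
    intensity = tissue_mean_table[[pk]],
    log2fc = fc[[pk]])
  list(peak_col = pk, observed_mz = ctr[j], ppm_error = ppm_error(ctr[j], drug_mz),
       per_tissue = per_tissue,
       images = render_ion_image(peak_matrix, j))
}
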