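# Pixel-level unsupervised segmentation: per-experiment nonlinear embedding
# (exact t-SNE with nearest-neighbour out-of-sample placement) + k-means
# (k = 2), automated cross-experiment cluster matching by metabolite
# signature correlation, region fractions, and pixel-occupancy overlap.

#' Segmentation configuration
#'
#' @param k number of clusters (>= 2; the pipeline uses 2)
#' @param embed_method "tsne_exact" (reference) or "passthrough" (embedding =
#'   standardised peak matrix; used for oracle tests)
#' @param embed_dims embedding dimensionality
#' @param perplexity t-SNE perplexity (must be below the fitted pixel count).
#'   The default is deliberately large relative to the fit subsample: a
#'   global-structure regime in which pixels of the same metabolic region
#'   coalesce rather than fragmenting into per-tissue or per-arm islands,
#'   which k = 2 clustering could not reassemble
#' @param max_pixels_for_fit exact t-SNE is fitted on a seeded subsample of
#'   at most this many pixels; remaining pixels are placed at the embedding
#'   coordinates of their nearest fitted neighbour in feature space
#' @param n_iter t-SNE gradient iterations
#' @param seed integer seed
#' @return object of class `segmentation_config`
#' @export
segmentation_config <- function(k = 2, embed_method = c("tsne_exact", "passthrough"),
                                embed_dims = 2, perplexity = 150,
                                max_pixels_for_fit = 2000, n_iter = 400,
                                seed = 7L) {
  embed_method <- match.arg(embed_method)
  if (k < 2) stopf("k must be >= 2")
  structure(list(k = as.integer(k), embed_method = embed_method,
                 embed_dims = as.integer(embed_dims), perplexity = perplexity,
                 max_pixels_for_fit = as.integer(max_pixels_for_fit),
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "segmentation_config")
}

.zscore_cols <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(m, 2, mu), 2, sdv, `/`)
}

#' Embed the pixels of one experiment
#'
#' Input features are the RMS-normalised integrated peak intensities,
#' z-scored per peak within the experiment. With `tsne_exact`, an exact
#' t-SNE (PCA-initialised, deterministic) is fitted on a seeded subsample
#' and the remaining pixels are placed at the coordinates of their nearest
#' fitted neighbour.
#'
#' @param peak_matrix a `peak_matrix` holding a single experiment's pixels
#' @param config a [segmentation_config()]
#' @return numeric matrix (pixels x embed_dims)
#' @export
embed_pixels <- function(peak_matrix, config = segmentation_config()) {
  if (length(unique(peak_matrix$pixels$experiment_id)) != 1)
    stopf("embed_pixels expects the pixels of a single experiment")
  X <- .zscore_cols(peak_matrix$intensity)
  n <- nrow(X)
  if (config$embed_method == "passthrough") return(X)
  if (n < config$perplexity + 1)
    stopf("pixel count (%d) must exceed perplexity (%g)", n, config$perplexity)
  fit_idx <- if (n > config$max_pixels_for_fit)
    sort(with_seed(config$seed, sample.int(n, config$max_pixels_for_fit)))
  else seq_len(n)
  Xf <- X[fit_idx, , drop = FALSE]
  perp <- min(config$perplexity, (length(fit_idx) - 1) / 3)
  pc <- prcomp(Xf, center = FALSE, scale. = FALSE)
  Y0 <- pc$x[, seq_len(config$embed_dims), drop = FALSE]
  Y0 <- sweep(Y0, 2, apply(Y0, 2, sd) / 1e-4, `/`)
  Yf <- cpp_tsne(Xf, Y0, perp, config$n_iter, 200, 12, 100)
  if (length(fit_idx) == n) return(Yf)
  Y <- matrix(NA_real_, n, ncol(Yf))
  Y[fit_idx, ] <- Yf
  rest <- setdiff(seq_len(n), fit_idx)
  nn <- cpp_nearest_neighbour(Xf, X[rest, , drop = FALSE])
  Y[rest, ] <- Yf[nn, , drop = FALSE]
  Y
}

.kmeanspp_centres <- function(E, k, seed) {
  with_seed(seed, {
    n <- nrow(E)
    idx <- sample.int(n, 1)
    d2 <- rowSums(sweep(E, 2, E[idx, ])^2)
    for (j in seq_len(k - 1)) {
      nxt <- if (sum(d2) > 0) sample.int(n, 1, prob = d2 / sum(d2))
             else sample.int(n, 1)
      idx <- c(idx, nxt)
      d2 <- pmin(d2, rowSums(sweep(E, 2, E[nxt, ])^2))
    }
    E[idx, , drop = FALSE]
  })
}

#' k-means clustering of an embedding
#'
#' k-means++ seeded initialisation, `restarts` restarts with Lloyd
#' iterations, best within-cluster sum of squares kept (ties broken by the
#' lowest restart index, so the result is deterministic given the seed).
#'
#' @param embedding pixels x dims matrix
#' @param config a [segmentation_config()]
#' @param pixels pixel metadata (tissue_id, experiment_id, arm, x, y); when
#'   given, a `segmentation_map` data.frame is returned
#' @param restarts number of restarts
#' @param select_features optional pixels x peaks matrix: when given, the
#'   best restart is chosen by within-cluster sum of squares in this
#'   (feature) space rather than in the embedding. t-SNE equalises
#'   inter-blob distances, so embedding inertia can prefer a partition that
#'   is worse in feature space; candidate Lloyd runs still operate on the
#'   embedding
#' @return integer cluster labels, or a `segmentation_map` when `pixels`
#'   is supplied (columns tissue_id, x, y, cluster, region = NA)
#' @export
cluster_kmeans <- function(embedding, config = segmentation_config(),
                           pixels = NULL, restarts = 10,
                           select_features = NULL) {
  if (any(!is.finite(embedding))) stopf("embedding contains non-finite values")
  if (config$k > nrow(embedding)) stopf("k exceeds the pixel count")
  score <- function(fit) {
    if (is.null(select_features)) return(fit$tot.withinss)
    # within-SS in feature space = const - sum_c n_c ||mean_c||^2
    -sum(vapply(seq_len(config$k), function(kk) {
      idx <- fit$cluster == kk
      if (!any(idx)) return(0)
      sum(idx) * sum(colMeans(select_features[idx, , drop = FALSE])^2)
    }, numeric(1)))
  }
  best <- NULL; best_score <- Inf
  for (r in seq_len(restarts)) {
    # alternate kmeans++ and uniform-random seeding: the two init families
    # have different basins of attraction, and the selection step needs to
    # see both (kmeans++ favours extremal blobs)
    C <- if (r %% 2 == 1)
      .kmeanspp_centres(embedding, config$k, derive_seed(config$seed, "km", r))
    else
      embedding[with_seed(derive_seed(config$seed, "km", r),
                          sample.int(nrow(embedding), config$k)), , drop = FALSE]
    if (anyDuplicated(C)) next
    fit <- suppressWarnings(kmeans(embedding, centers = C, iter.max = 100,
                                   algorithm = "Lloyd"))
    s <- score(fit)
    if (is.null(best) || s < best_score) { best <- fit; best_score <- s }
  }
  labels <- best$cluster
  if (is.null(pixels)) return(labels)
  out <- data.frame(tissue_id = pixels$tissue_id,
                    experiment_id = pixels$experiment_id, arm = pixels$arm,
                    x = pixels$x, y = pixels$y, cluster = labels,
                    region = NA_character_, stringsAsFactors = FALSE)
  structure(out, class = c("segmentation_map", "data.frame"))
}

.cluster_signatures <- function(segmentation, peak_matrix) {
  ks <- sort(unique(segmentation$cluster))
  sig <- vapply(ks, function(kk)
    colMeans(peak_matrix$intensity[segmentation$cluster == kk, , drop = FALSE]),
    numeric(ncol(peak_matrix$intensity)))
  # z-score per peak across clusters
  mu <- rowMeans(sig); sdv <- apply(sig, 1, sd); sdv[sdv == 0] <- 1
  sig <- (sig - mu) / sdv
  colnames(sig) <- as.character(ks)
  sig
}

#' Match clusters across experiments and name regions
#'
#' Cluster signatures (mean intensity per consensus peak, z-scored across
#' clusters) are correlated between experiments; each experiment's clusters
#' are matched to the first experiment's by maximal Pearson correlation.
#' The matched family holding the larger pixel share in vehicle tissues is
#' named Region A (the control-dominant region), the other Region B.
#'
#' @param segmentations list of `segmentation_map`s, one per experiment
#' @param peak_matrices list of matching `peak_matrix` objects
#' @param vehicle_arm vehicle arm name
#' @return the segmentations with the `region` column filled
#' @export
match_clusters <- function(segmentations, peak_matrices, vehicle_arm = "vehicle") {
  stopifnot(length(segmentations) >= 1,
            length(segmentations) == length(peak_matrices))
  sigs <- mapply(.cluster_signatures, segmentations, peak_matrices,
                 SIMPLIFY = FALSE)
  k <- ncol(sigs[[1]])
  if (k != 2) stopf("cluster matching is defined for k = 2")
  # family assignment: family 1 anchored to cluster 1 of the first experiment
  family <- list()
  for (i in seq_along(sigs)) {
    cmat <- suppressWarnings(cor(sigs[[1]], sigs[[i]]))
    direct <- cmat[1, 1] + cmat[2, 2]
    crossed <- cmat[1, 2] + cmat[2, 1]
    if (abs(direct - crossed) < 1e-9)
      stopf("signature correlation tie: ambiguous cluster matching (need more peaks)")
    fam <- if (direct >= crossed) c(1L, 2L) else c(2L, 1L)
    family[[i]] <- setNames(fam, colnames(sigs[[i]]))
  }
  veh_counts <- c(`1` = 0, `2` = 0); veh_total <- 0
  for (i in seq_along(segmentations)) {
    seg <- segmentations[[i]]
    veh <- seg$arm == vehicle_arm
    if (!any(veh)) next
    fam <- family[[i]][as.character(seg$cluster[veh])]
    veh_counts <- veh_counts + c(sum(fam == 1L), sum(fam == 2L))
    veh_total <- veh_total + sum(veh)
  }
  a_family <- if (veh_counts[1] >= veh_counts[2]) 1L else 2L
  for (i in seq_along(segmentations)) {
    fam <- family[[i]][as.character(segmentations[[i]]$cluster)]
    segmentations[[i]]$region <- ifelse(fam == a_family, "A", "B")
  }
  segmentations
}

#' Percentage of a tissue occupied by Region A
#'
#' @param segmentation a matched `segmentation_map`
#' @param tissue_id tissue to report
#' @return percentage in [0, 100]
#' @export
region_fraction <- function(segmentation, tissue_id) {
  sel <- segmentation$tissue_id == tissue_id
  if (!any(sel)) stopf("tissue %s has no retained pixels", tissue_id)
  if (any(is.na(segmentation$region[sel])))
    stopf("segmentation has unmatched clusters; run match_clusters() first")
  100 * mean(segmentation$region[sel] == "A")
}

#' Pixel-occupancy overlap between two matched segmentations
#'
#' Percentage of pixels present in both segmentations (matched on tissue and
#' coordinates) that carry the same region label. Symmetric; 100 iff the
#' matched labels agree on every shared pixel.
#'
#' @param seg1,seg2 matched `segmentation_map`s
#' @return percentage in [0, 100]
#' @export
segmentation_overlap <- function(seg1, seg2) {
  for (s in list(seg1, seg2))
    if (any(is.na(s$region))) stopf("both segmentations must be region-matched")
  key1 <- paste(seg1$tissue_id, seg1$x, seg1$y)
  key2 <- paste(seg2$tissue_id, seg2$x, seg2$y)
  shared <- intersect(key1, key2)
  if (!length(shared)) stopf("segmentations share no pixels")
  r1 <- seg1$region[match(shared, key1)]
  r2 <- seg2$region[match(shared, key2)]
  100 * mean(r1 == r2)
}

#' Segment a study: per-experiment embedding + k-means + region matching
#'
#' Convenience wrapper running [embed_pixels()] and [cluster_kmeans()] for
#' every experiment in the peak matrix and matching clusters across
#' experiments.
#'
#' @param peak_matrix a `peak_matrix` covering one or more experiments
#' @param config a [segmentation_config()]
#' @param vehicle_arm vehicle arm name
#' @return named list of matched `segmentation_map`s, one per experiment
#' @export
segment_study <- function(peak_matrix, config = segmentation_config(),
                          vehicle_arm = "vehicle") {
  exps <- unique(peak_matrix$pixels$experiment_id)
  mats <- lapply(exps, function(e) {
    sel <- peak_matrix$pixels$experiment_id == e
    structure(list(intensity = peak_matrix$intensity[sel, , drop = FALSE],
                   pixels = peak_matrix$pixels[sel, , drop = FALSE],
                   peaks = peak_matrix$peaks), class = "peak_matrix")
  })
  segs <- lapply(seq_along(exps), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "embed", exps[i])
    emb <- embed_pixels(mats[[i]], cfg)
    cluster_kmeans(emb, cfg, pixels = mats[[i]]$pixels,
                   select_features = .zscore_cols(mats[[i]]$intensity))
  })
  segs <- match_clusters(segs, mats, vehicle_arm)
  names(segs) <- exps
  segs
}
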