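#' Normalize a trace to zero mean and unit standard deviation
#'
#' @param x Numeric vector with positive SD.
#' @return Normalized vector; errors on a constant trace (such traces should
#'   be flagged as outliers upstream).
#' @export
normalize_trace <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant trace cannot be normalized")
  (x - mean(x)) / s
}

#' Fit a PCA basis on normalized traces
#'
#' Principal component analysis of the (already variance-normalized) traces,
#' traces in rows. Traces from multiple subjects should be pooled before the
#' fit so the basis absorbs inter-subject differences.
#'
#' @param X Numeric matrix, one trace per row, equal lengths; >= 3 rows.
#' @param n_components Number of leading components to retain (default 2).
#' @return List with `rotation` (columns = components), `center`,
#'   `sdev`, `explained` (fraction of variance per component), and
#'   `n_components`.
#' @export
fit_pca <- function(X, n_components = 2) {
  if (nrow(X) < 3) stop("need at least 3 traces")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(rotation = p$rotation, center = p$center, sdev = p$sdev,
       explained = expl, n_components = n_components)
}

#' Project traces onto a fitted PCA basis
#' @param pca A basis from [fit_pca()].
#' @param X Trace matrix (rows = traces) on the same sample grid.
#' @return Score matrix (rows = traces, cols = components), leading
#'   `n_components` columns.
#' @export
pca_scores <- function(pca, X) {
  S <- sweep(X, 2, pca$center) %*% pca$rotation
  S[, seq_len(pca$n_components), drop = FALSE]
}

#' Build the 3-D spatiotemporal feature space
#'
#' Min-max normalizes the two temporal features (PC1, PC2 scores) and the
#' spatial feature (axial distance to BrM) to \[0, 1\] over the training set
#' and stores the constants so that new points are projected with the same
#' mapping (values outside \[0, 1\] are allowed and flagged).
#'
#' @param pc1,pc2 Numeric score vectors.
#' @param depth_to_brm Numeric vector (px anterior to BrM).
#' @return List with `points` (data.frame pc1, pc2, depth_norm), `ranges`
#'   (2 x 3 matrix of min/max), `out_of_range` (logical).
#' @export
build_feature_space <- function(pc1, pc2, depth_to_brm) {
  stopifnot(all(is.finite(pc1)), all(is.finite(pc2)),
            all(is.finite(depth_to_brm)))
  ranges <- vapply(list(pc1 = pc1, pc2 = pc2, depth = depth_to_brm),
                   range, numeric(2))
  if (any(ranges[2, ] - ranges[1, ] == 0))
    stop("degenerate feature axis (max == min)")
  pts <- project_features(cbind(pc1 = pc1, pc2 = pc2, depth = depth_to_brm),
                          ranges)
  list(points = pts$points, ranges = ranges, out_of_range = pts$out_of_range)
}

#' Project new points with stored feature-space constants
#' @param M Matrix/data.frame with columns pc1, pc2, depth.
#' @param ranges The 2 x 3 min/max matrix from [build_feature_space()].
#' @return List with `points` (data.frame pc1, pc2, depth_norm) and
#'   `out_of_range` (logical per point).
#' @export
project_features <- function(M, ranges) {
  M <- as.matrix(M)
  norm <- sweep(sweep(M, 2, ranges[1, ]), 2,
                ranges[2, ] - ranges[1, ], "/")
  oor <- apply(norm < 0 | norm > 1, 1, any)
  list(points = data.frame(pc1 = norm[, 1], pc2 = norm[, 2],
                           depth_norm = norm[, 3]),
       out_of_range = oor)
}

#' Distance-based outlier detection in the feature space
#'
#' For each point, computes the minimum radius of a sphere centered at the
#' point that covers a fraction `coverage` of the remaining points, i.e. the
#' Euclidean distance to its k-th nearest neighbor with
#' `k = ceiling(coverage * (N - 1))` (at least 1). A point is an outlier iff
#' its radius exceeds `Q3 + (Q3 - Q1) / 5`, quartiles taken over all radii
#' (linear-interpolation, median-exclusive convention).
#'
#' @param F Numeric matrix of feature points (rows = points).
#' @param coverage Coverage fraction (default 0.02).
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 6, median-exclusive linear interpolation).
#' @return List with `outlier` (logical), `radius`, `threshold`, `k`.
#' @export
detect_outliers <- function(F, coverage = 0.02, quantile_type = 6) {
  F <- as.matrix(F)
  N <- nrow(F)
  if (!(coverage > 0 && coverage < 1)) stop("coverage must be in (0, 1)")
  k <- max(1L, ceiling(coverage * (N - 1)))
  if (N - 1 < k) stop("too few points for the coverage radius")
  D <- as.matrix(stats::dist(F))
  radius <- vapply(seq_len(N), function(i)
    sort(D[i, -i], partial = k)[k], numeric(1))
  q <- stats::quantile(radius, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  threshold <- q[2] + (q[2] - q[1]) / 5
  list(outlier = radius > threshold, radius = radius, threshold = threshold,
       k = k)
}

#' Agglomerative Ward clustering of feature points
#'
#' Standard Ward-criterion agglomerative clustering on Euclidean distances
#' (each merge minimizes the increase in total within-cluster variance), cut
#' to `n_clusters` clusters.
#'
#' @param F Numeric matrix of non-outlier feature points.
#' @param n_clusters Number of clusters to cut to (default 3).
#' @return List with `labels` (integer cluster per point), `hclust` (the
#'   dendrogram object, `ward.D2` linkage), `n_clusters`.
#' @export
ward_cluster <- function(F, n_clusters = 3) {
  F <- as.matrix(F)
  if (nrow(F) < n_clusters) stop("fewer points than clusters")
  hc <- stats::hclust(stats::dist(F), method = "ward.D2")
  list(labels = stats::cutree(hc, k = n_clusters), hclust = hc,
       n_clusters = n_clusters)
}

#' Assign Type-I / intermediate / Type-II labels to three clusters
#'
#' The cluster nearest Bruch's membrane (smallest mean distance-to-BrM) is
#' Type-II (RPE); the most anterior is Type-I (photoreceptor OS); the middle
#' one is the intermediate transition band. Ties in mean depth are broken
#' deterministically by mean-trace peak latency (the faster-peaking cluster
#' is Type-I). As a sanity check, a warning is raised when the Type-I
#' cluster-mean trace does not peak earlier than the Type-II one.
#'
#' @param cluster_labels Integer vector from [ward_cluster()].
#' @param depth_to_brm Depth (px anterior to BrM) per point, original units.
#' @param traces Optional trace matrix (rows = points) for the latency
#'   tie-break/sanity check.
#' @param t Time grid matching `traces` columns.
#' @return Character vector in \{"type_I", "intermediate", "type_II"\}
#'   per point.
#' @export
assign_type_labels <- function(cluster_labels, depth_to_brm,
                               traces = NULL, t = NULL) {
  ids <- sort(unique(cluster_labels))
  if (length(ids) != 3) stop("expected exactly 3 clusters")
  mean_depth <- vapply(ids, function(g)
    mean(depth_to_brm[cluster_labels == g]), numeric(1))
  latency <- rep(NA_real_, 3)
  if (!is.null(traces) && !is.null(t)) {
    post <- t > 0
    latency <- vapply(ids, function(g) {
      m <- colMeans(traces[cluster_labels == g, , drop = FALSE])
      t[post][which.max(m[post])]
    }, numeric(1))
  }
  # ascending distance to BrM; on ties the later-peaking cluster sorts first
  # (so the fast-peaking one lands at the anterior/Type-I end)
  ord <- order(mean_depth, -latency, na.last = TRUE)
  type_of <- character(3)
  type_of[ord[1]] <- "type_II"
  type_of[ord[2]] <- "intermediate"
  type_of[ord[3]] <- "type_I"
  if (all(is.finite(latency))) {
    lat_I <- latency[ord[3]]; lat_II <- latency[ord[1]]
    if (!is.na(lat_I) && !is.na(lat_II) && lat_I >= lat_II)
      warning("Type-I cluster does not peak earlier than Type-II; check orientation")
  }
  type_of[match(cluster_labels, ids)]
}

#' Train a Gaussian-kernel SVM on pipeline labels in the feature space
#'
#' Radial-basis-function SVM on the (standardized) 3-D features with the
#' labels produced by the unsupervised stage. Hyperparameters are chosen by
#' 10-fold cross-validated grid search; the reported accuracy is the CV
#' accuracy of the selected model. Fold assignment is seeded for
#' reproducibility.
#'
#' @param features Matrix/data.frame of feature points (pc1, pc2, depth_norm).
#' @param labels Factor/character labels (outlier, intermediate, type_I,
#'   type_II); >= 2 classes required.
#' @param cost_grid,gamma_grid Hyperparameter search grids.
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed for fold assignment.
#' @return List of class `org_classifier`: `svm` (the fitted e1071 model),
#'   `cv_accuracy` (percent), `best` (cost, gamma), `levels`, `seed`.
#' @export
train_classifier <- function(features, labels,
                             cost_grid = c(1, 10, 100),
                             gamma_grid = c(0.25, 0.5, 1, 2, 4),
                             folds = 10, seed = 1L) {
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  best <- NULL
  for (co in cost_grid) for (ga in gamma_grid) {
    set.seed(as.integer(seed))
    m <- e1071::svm(X, y, kernel = "radial", cost = co, gamma = ga,
                    scale = TRUE, cross = folds)
    if (is.null(best) || m$tot.accuracy > best$acc)
      best <- list(acc = m$tot.accuracy, cost = co, gamma = ga)
  }
  set.seed(as.integer(seed))
  final <- e1071::svm(X, y, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = TRUE, cross = folds)
  structure(list(svm = final, cv_accuracy = final$tot.accuracy,
                 best = best[c("cost", "gamma")], levels = levels(y),
                 seed = as.integer(seed)),
            class = "org_classifier")
}

#' Resample a trace to a regular 5 ms grid with optional Gaussian smoothing
#'
#' Linear interpolation onto the target grid; traces acquired at a lower
#' rate than the target are additionally smoothed with a Gaussian kernel
#' (sigma = half the native sampling interval by default) after
#' interpolation. Traces already on the target grid pass through unchanged
#' before smoothing.
#'
#' @param t Native time grid (s).
#' @param x Trace values.
#' @param t_out Target grid (s), default 5 ms steps over the native span.
#' @param dt_target Target interval (s), default 0.005.
#' @param smooth_sigma_s Gaussian sigma (s); `NULL` = automatic (0 for
#'   native-rate traces, half the native interval for low-rate traces).
#' @return List with `t`, `x` on the target grid.
#' @export
resample_trace <- function(t, x, t_out = NULL, dt_target = 0.005,
                           smooth_sigma_s = NULL) {
  dt_native <- stats::median(diff(t))
  if (is.null(t_out))
    t_out <- seq(t[1], t[length(t)], by = dt_target)
  xi <- if (isTRUE(all.equal(as.numeric(t), as.numeric(t_out)))) x
        else stats::approx(t, x, xout = t_out, rule = 2)$y
  if (is.null(smooth_sigma_s))
    smooth_sigma_s <- if (dt_native > dt_target * 1.5) dt_native / 2 else 0
  if (smooth_sigma_s > 0) {
    half <- max(1L, ceiling(3 * smooth_sigma_s / dt_target))
    kern <- stats::dnorm(seq(-half, half) * dt_target, sd = smooth_sigma_s)
    kern <- kern / sum(kern)
    pad <- c(rep(xi[1], half), xi, rep(xi[length(xi)], half))
    xi <- stats::convolve(pad, rev(kern), type = "filter")
  }
  list(t = t_out, x = xi)
}

#' The unsupervised discovery pipeline on a trace set
#'
#' Runs the full label-discovery chain on a matrix of phase traces:
#' windowing to the classification window, resampling to the 5 ms grid,
#' per-trace normalization, PCA (top two components), 3-D min-max feature
#' space with depth, distance-based outlier removal, Ward clustering cut to
#' three clusters, and anatomical type assignment.
#'
#' @param trace_mat Phase matrix (rows = traces, rad).
#' @param t Time grid (s) for the columns.
#' @param depth_to_brm Depth (px anterior to BrM) per trace.
#' @param window Classification window c(from, to) seconds around onset.
#' @param dt_target Classification grid interval (s).
#' @param coverage,n_clusters Parameters of the outlier and cluster stages.
#' @return List with `labels` (outlier/intermediate/type_I/type_II per
#'   trace), `features` (normalized 3-D points for all traces), `pca`,
#'   `ranges`, `outlier`, `cluster`, `t_grid`, `window`.
#' @export
discover_patterns <- function(trace_mat, t, depth_to_brm,
                              window = c(-1, 3.5), dt_target = 0.005,
                              coverage = 0.02, n_clusters = 3) {
  grid <- seq(max(window[1], t[1]), min(window[2], t[length(t)]),
              by = dt_target)
  W <- t(apply(trace_mat, 1, function(x) resample_trace(t, x, grid)$x))
  sds <- apply(W, 1, stats::sd)
  if (any(sds == 0)) stop("constant trace(s) in input; flag them as outliers upstream")
  Wn <- t(apply(W, 1, normalize_trace))
  pca <- fit_pca(Wn, n_components = 2)
  sc <- pca_scores(pca, Wn)
  fs <- build_feature_space(sc[, 1], sc[, 2], depth_to_brm)
  Fm <- as.matrix(fs$points)
  out <- detect_outliers(Fm, coverage = coverage)
  labels <- rep(NA_character_, nrow(Fm))
  labels[out$outlier] <- "outlier"
  keep <- !out$outlier
  cl <- ward_cluster(Fm[keep, , drop = FALSE], n_clusters = n_clusters)
  types <- assign_type_labels(cl$labels, depth_to_brm[keep],
                              traces = W[keep, , drop = FALSE], t = grid)
  labels[keep] <- types
  list(labels = labels, features = fs$points, pca = pca, ranges = fs$ranges,
       outlier = out, cluster = cl, t_grid = grid, window = window,
       normalized = Wn)
}

#' Classify new phase traces with a trained model
#'
#' Preprocesses new traces exactly as in training - linear interpolation to
#' the 5 ms classification grid (low-rate traces are Gaussian-smoothed),
#' normalization, projection on the same PCA basis and the same min-max
#' feature constants - then predicts labels with the stored SVM.
#'
#' @param trace_mat Phase matrix (rows = traces, rad), any protocol rate.
#' @param t Time grid (s) of the columns.
#' @param depth_to_brm Depth (px anterior to BrM) per trace.
#' @param model A model bundle from [bundle_model()] or a list with `pca`,
#'   `ranges`, `classifier`, `t_grid`.
#' @return List with `labels` (predicted), `features` (projected points),
#'   `out_of_range` (logical).
#' @export
classify_new <- function(trace_mat, t, depth_to_brm, model) {
  grid <- model$t_grid
  if (t[1] > grid[1] + 1e-9 || t[length(t)] < grid[length(grid)] - 1e-9)
    stop("trace window shorter than the classification window")
  W <- t(apply(trace_mat, 1, function(x) resample_trace(t, x, grid)$x))
  Wn <- t(apply(W, 1, normalize_trace))
  sc <- pca_scores(model$pca, Wn)
  pr <- project_features(cbind(sc[, 1], sc[, 2], depth_to_brm), model$ranges)
  pred <- stats::predict(model$classifier$svm, as.matrix(pr$points))
  list(labels = as.character(pred), features = pr$points,
       out_of_range = pr$out_of_range)
}

#' Bundle and persist a trained classification model
#'
#' The bundle holds everything needed to classify new traces with the same
#' criteria: PCA basis, feature-space min-max constants, the SVM, the
#' classification grid, the seed, and a schema version.
#'
#' @param discovery Output of [discover_patterns()].
#' @param classifier Output of [train_classifier()].
#' @return List of class `org_model_bundle`.
#' @export
bundle_model <- function(discovery, classifier) {
  structure(list(
    version = "org-model-v1",
    pca = discovery$pca,
    ranges = discovery$ranges,
    classifier = classifier,
    t_grid = discovery$t_grid,
    window = discovery$window,
    seed = classifier$seed
  ), class = "org_model_bundle")
}

#' @rdname bundle_model
#' @param model An `org_model_bundle`.
#' @param path File path for the single-file bundle.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname bundle_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!identical(m$version, "org-model-v1"))
    stop("model bundle schema mismatch: expected org-model-v1, got ",
         m$version %||% "<none>")
  m
}
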