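test_that("trace normalization is affine-invariant with mean 0, SD 1", {
  set.seed(1)
  x <- rnorm(200)
  z <- normalize_trace(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(normalize_trace(3.2 * x + 7), z, tolerance = 1e-12)
  w <- normalize_trace(x)
  expect_equal(normalize_trace(w), w, tolerance = 1e-12)
  expect_error(normalize_trace(rep(2, 10)), "constant")
})

test_that("PCA matches the eigen-decomposition oracle and is reproducible", {
  set.seed(2)
  # data on a 2-plane embedded in 50-D: top-2 variance is 100%
  B <- qr.Q(qr(matrix(rnorm(50 * 2), 50, 2)))
  X <- matrix(rnorm(120 * 2), 120, 2) %*% t(B)
  p <- fit_pca(X)
  expect_equal(sum(p$explained[1:2]), 1, tolerance = 1e-9)
  # orthonormal components, non-increasing explained variance
  expect_equal(crossprod(p$rotation[, 1:2]), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained) < 1e-12))

  # oracle: eigenvectors of the sample covariance, up to sign
  Y <- matrix(rnorm(40 * 8), 40, 8)
  p2 <- fit_pca(Y)
  ev <- eigen(stats::cov(Y))$vectors
  for (k in 1:2) {
    dotp <- abs(sum(p2$rotation[, k] * ev[, k]))
    expect_equal(dotp, 1, tolerance = 1e-9)
  }
  # duplicated dataset gives the identical basis
  p3 <- fit_pca(rbind(Y, Y))
  for (k in 1:2)
    expect_equal(abs(sum(p3$rotation[, k] * p2$rotation[, k])), 1,
                 tolerance = 1e-9)
  # scores reproduce the data within the discarded-variance bound
  sc <- pca_scores(p2, Y)
  expect_equal(dim(sc), c(40, 2))
  expect_error(fit_pca(Y[1:2, ]), "at least 3")
})

test_that("feature space min-max mapping, persistence and out-of-range flags", {
  fs <- build_feature_space(c(-2, 0, 2), c(0, 1, 2), c(1, 5, 9))
  expect_equal(fs$points$pc1, c(0, 0.5, 1))
  expect_equal(fs$points$depth_norm, c(0, 0.5, 1))
  # same constants project new points identically after a round trip
  pr1 <- project_features(cbind(1, 0.5, 7), fs$ranges)
  rt <- jsonlite::fromJSON(jsonlite::toJSON(list(r = fs$ranges)))$r
  pr2 <- project_features(cbind(1, 0.5, 7), rt)
  expect_equal(pr1$points, pr2$points)
  # outside the training range: allowed, outside [0,1], flagged
  oor <- project_features(cbind(5, 1, 5), fs$ranges)
  expect_gt(oor$points$pc1, 1)
  expect_true(oor$out_of_range)
  expect_false(pr1$out_of_range)
  expect_error(build_feature_space(c(1, 1), c(0, 1), c(0, 1)), "degenerate")
})

test_that("outlier rule flags an isolated point and none among duplicates", {
  # homogeneous cluster (regular grid: all k-NN radii equal) + one far point
  g <- seq(0, 0.25, by = 0.05)
  pts <- as.matrix(expand.grid(g, g, g))
  pts <- rbind(pts, c(5, 5, 5)) # ~10 cluster radii away
  out <- detect_outliers(pts)
  expect_true(out$outlier[nrow(pts)])
  expect_equal(sum(out$outlier), 1)

  same <- matrix(1, 30, 3)
  out2 <- detect_outliers(same, coverage = 0.1)
  expect_true(all(out2$radius == 0))
  expect_false(any(out2$outlier))
})

test_that("outlier labels equal the exhaustive k-NN oracle", {
  set.seed(4)
  N <- 500
  pts <- matrix(rnorm(N * 3), N, 3)
  pts[1:10, ] <- pts[1:10, ] + 8 # implanted far points
  got <- detect_outliers(pts, coverage = 0.02)
  # brute-force pairwise-distance oracle, written independently
  k <- ceiling(0.02 * (N - 1))
  rad <- numeric(N)
  for (i in seq_len(N)) {
    d2 <- sqrt(colSums((t(pts[-i, ]) - pts[i, ])^2))
    rad[i] <- sort(d2)[k]
  }
  q1 <- stats::quantile(rad, 0.25, type = 6, names = FALSE)
  q3 <- stats::quantile(rad, 0.75, type = 6, names = FALSE)
  oracle <- rad > q3 + (q3 - q1) / 5
  expect_equal(got$outlier, oracle)
  expect_equal(got$radius, rad, tolerance = 1e-12)
  expect_true(all(got$outlier[1:10]))
})

test_that("Ward clustering recovers separated blobs and merges duplicates first", {
  set.seed(5)
  blob <- function(cx, n = 30) cbind(rnorm(n, cx, 0.05), rnorm(n, 0, 0.05),
                                     rnorm(n, cx, 0.05))
  F <- rbind(blob(0), blob(3), blob(6))
  cl <- ward_cluster(F, 3)
  truth <- rep(1:3, each = 30)
  expect_equal(length(unique(cl$labels[truth == 1])), 1)
  expect_equal(length(unique(cl$labels[truth == 2])), 1)
  expect_equal(length(unique(cl$labels[truth == 3])), 1)
  expect_true(all(diff(cl$hclust$height) > -1e-12)) # monotone merge heights

  dup <- rbind(c(1, 1, 1), c(1, 1, 1), c(5, 5, 5), c(9, 9, 9))
  cld <- ward_cluster(dup, 3)
  expect_equal(cld$hclust$height[1], 0)
  expect_equal(cld$labels[1], cld$labels[2])
  expect_error(ward_cluster(dup, 5), "fewer points")
})

test_that("Ward merge sequence equals the brute-force objective oracle", {
  # greedy minimization of the within-cluster variance increase, re-derived
  ward_oracle <- function(X) {
    groups <- as.list(seq_len(nrow(X)))
    merges <- list()
    while (length(groups) > 1) {
      best <- NULL
      for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
        a <- X[groups[[i]], , drop = FALSE]
        b <- X[groups[[j]], , drop = FALSE]
        d <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
          sum((colMeans(a) - colMeans(b))^2)
        if (is.null(best) || d < best$d) best <- list(d = d, i = i, j = j)
      }
      merges[[length(merges) + 1]] <-
        sort(c(sort(groups[[best$i]]), sort(groups[[best$j]])))
      groups[[best$j]] <- sort(c(groups[[best$j]], groups[[best$i]]))
      groups[[best$i]] <- NULL
    }
    merges
  }
  set.seed(6)
  for (rep in 1:3) {
    X <- matrix(rnorm(12 * 3), 12, 3)
    hc <- ward_cluster(X, 2)$hclust
    oracle <- ward_oracle(X)
    # member set of the cluster formed at each merge step
    members <- vector("list", nrow(hc$merge))
    got <- list()
    for (k in seq_len(nrow(hc$merge))) {
      s <- unlist(lapply(hc$merge[k, ], function(m)
        if (m < 0) -m else members[[m]]))
      members[[k]] <- sort(s)
      got[[k]] <- members[[k]]
    }
    expect_equal(got, oracle)
  }
})

test_that("type labels follow depth order with a latency tie-break and are
           invariant to cluster-id permutation", {
  cl <- c(1, 1, 2, 2, 3, 3)
  depth <- c(10, 10.5, 6, 6.4, 2, 2.2) # px to BrM
  lab <- assign_type_labels(cl, depth)
  expect_equal(lab, c("type_I", "type_I", "intermediate", "intermediate",
                      "type_II", "type_II"))
  # permuting cluster ids leaves the final type labels unchanged
  perm <- c(3, 3, 1, 1, 2, 2)
  expect_equal(assign_type_labels(perm, depth), lab)
  # equal depths: the faster-peaking cluster becomes Type-I
  t <- seq(-0.5, 3, by = 0.01)
  fast <- exp(-((t - 0.5) / 0.2)^2); slow <- exp(-((t - 2.5) / 0.4)^2)
  traces <- rbind(fast, fast, slow, slow, slow / 2, slow / 2)
  depth_tied <- c(5, 5, 5, 5, 1, 1)
  lab2 <- assign_type_labels(c(1, 1, 2, 2, 3, 3), depth_tied, traces, t)
  expect_equal(lab2[1:4], c("type_I", "type_I", "intermediate", "intermediate"))
  expect_error(assign_type_labels(c(1, 1, 2, 2), c(1, 2, 3, 4)), "3 clusters")
})

test_that("the discovery pipeline recovers the generative classes", {
  ts <- simulate_phase_traces(kinetics_spec(), org_protocol("protocol1"),
                              n_traces_per_class = 150, noise_sd_mrad = 30,
                              seed = 42)
  disc <- discover_patterns(ts$phase, ts$t, ts$depth_px_to_brm)
  mask <- ts$class %in% c("type_I", "type_II")
  expect_gte(mean(disc$labels[mask] == ts$class[mask]), 0.99)
  # classification is invariant to trace amplitude scaling
  disc2 <- discover_patterns(ts$phase * 3.7, ts$t, ts$depth_px_to_brm)
  expect_equal(disc2$labels, disc$labels)
})

test_that("SVM training on separable classes and model persistence", {
  set.seed(7)
  X <- rbind(matrix(rnorm(60 * 3, 0, 0.2), 60, 3),
             matrix(rnorm(60 * 3, 3, 0.2), 60, 3))
  y <- rep(c("a", "b"), each = 60)
  clf <- train_classifier(X, y, cost_grid = c(1, 10), gamma_grid = c(0.5, 1),
                          seed = 3)
  expect_equal(clf$cv_accuracy, 100)
  expect_equal(as.character(stats::predict(clf$svm, X)), y)
  expect_error(train_classifier(X, rep("a", 120)), "2 classes")
})

test_that("low-rate traces classified after 5 ms interpolation agree with
           native-rate labels", {
  ts <- simulate_phase_traces(kinetics_spec(), org_protocol("protocol1"),
                              n_traces_per_class = 150, noise_sd_mrad = 30,
                              seed = 42)
  disc <- discover_patterns(ts$phase, ts$t, ts$depth_px_to_brm)
  clf <- train_classifier(disc$features, disc$labels,
                          cost_grid = c(1, 10), gamma_grid = c(0.5, 1, 2),
                          seed = 7)
  model <- bundle_model(disc, clf)
  native <- classify_new(ts$phase, ts$t, ts$depth_px_to_brm, model)
  # 40 ms sampling (protocol-2 rate): every 8th sample of the same traces
  keep <- seq(1, length(ts$t), by = 8)
  low <- classify_new(ts$phase[, keep], ts$t[keep], ts$depth_px_to_brm, model)
  expect_gte(mean(low$labels == native$labels), 0.95)

  # persistence: reloaded model gives identical predictions
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(model, p)
  again <- classify_new(ts$phase, ts$t, ts$depth_px_to_brm, load_model(p))
  expect_identical(again$labels, native$labels)
  # window shorter than the classification window is rejected
  shrt <- ts$t > -0.2
  expect_error(classify_new(ts$phase[, shrt], ts$t[shrt],
                            ts$depth_px_to_brm, model), "shorter")
})

test_that("resampling to the 5 ms grid is exact on ramps and an identity on
           native-rate traces", {
  t <- seq(-1, 2, by = 0.005)
  x <- 3 * t + 1
  r <- resample_trace(t, x, smooth_sigma_s = 0)
  expect_equal(r$t, t)
  expect_equal(r$x, x)
  # linear interpolation is exact for a linear ramp at all grid points
  t40 <- seq(-1, 2, by = 0.04)
  r2 <- resample_trace(t40, 3 * t40 + 1, t_out = seq(-1, 1.9, by = 0.005),
                       smooth_sigma_s = 0)
  expect_equal(r2$x, 3 * r2$t + 1, tolerance = 1e-12)
})
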