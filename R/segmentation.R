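#' Despeckle by averaging registered B-scan intensities
#'
#' Averages the intensities of the first `n_average` frames. On fully
#' developed speckle with independent realizations the speckle contrast
#' (SD/mean over a homogeneous region) drops approximately as 1/sqrt(n).
#'
#' @param series A `frame_series` (registered for meaningful results).
#' @param n_average Number of frames to average (<= series length).
#' @return Real matrix of averaged intensity (depth x lateral).
#' @export
despeckle <- function(series, n_average) {
  fr <- series$frames
  nt <- dim(fr)[3]
  if (is.null(nt) || nt < 1) stop("empty series")
  if (n_average > nt) stop("n_average exceeds series length")
  acc <- matrix(0, dim(fr)[1], dim(fr)[2])
  for (i in seq_len(n_average)) acc <- acc + Mod(fr[, , i])^2
  acc / n_average
}

# minimum-cost lateral path by dynamic programming.
# cost: matrix (depth x lateral); rows restricted to [zmin, zmax];
# |depth step| <= max_jump between adjacent A-scans.
dp_min_path <- function(cost, zmin = 1, zmax = nrow(cost), max_jump = 2) {
  sub <- cost[zmin:zmax, , drop = FALSE]
  H <- nrow(sub); W <- ncol(sub)
  acc <- matrix(Inf, H, W)
  from <- matrix(0L, H, W)
  acc[, 1] <- sub[, 1]
  for (x in 2:W) {
    for (dj in (-max_jump):max_jump) {
      src <- seq_len(H) - dj
      ok <- src >= 1 & src <= H
      cand <- rep(Inf, H)
      cand[ok] <- acc[src[ok], x - 1]
      tot <- cand + sub[, x]
      upd <- tot < acc[, x]
      acc[upd, x] <- tot[upd]
      from[upd, x] <- src[upd]
    }
  }
  path <- integer(W)
  path[W] <- which.min(acc[, W])
  for (x in (W - 1):1) path[x] <- from[path[x + 1], x + 1]
  list(path = path + zmin - 1, cost = min(acc[, W]))
}

# dark-to-light vertical gradient cost, globally normalized: 2 - g + eps
gradient_cost <- function(image, eps = 1e-5) {
  g <- image - rbind(image[1, , drop = FALSE],
                     image[-nrow(image), , drop = FALSE])
  rng <- range(g)
  gn <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  2 - gn + eps
}

# prominent local maxima of the lateral-mean depth profile: a band must
# exceed both a fraction of the brightest band and a multiple of the
# background (median) level, so dim-but-real bands (ELM, BrM) survive a
# dominant IS/OS while the noise floor is rejected
profile_peaks <- function(image, min_rel_height = 0.05, smooth = 1) {
  prof <- rowMeans(image)
  if (smooth > 0) {
    k <- stats::dnorm(-3:3, sd = max(smooth, 0.5))
    k <- k / sum(k)
    prof <- stats::filter(prof, k, sides = 2)
    prof[is.na(prof)] <- 0
    prof <- as.numeric(prof)
  }
  n <- length(prof)
  is_pk <- c(FALSE, prof[2:(n - 1)] > prof[1:(n - 2)] &
               prof[2:(n - 1)] >= prof[3:n], FALSE)
  floor_h <- max(min_rel_height * max(prof), 3 * stats::median(prof))
  pk <- which(is_pk & prof >= floor_h)
  pk[order(pk)]
}

#' Segment outer-retina layer boundaries by shortest-path dynamic programming
#'
#' Finds, for each requested layer, the minimum-cost lateral path on a graph
#' whose node cost is `2 - (normalized dark-to-light vertical gradient) + eps`
#' and whose edges connect laterally adjacent depth pixels with
#' `|depth step| <= max_jump`. Layers are found sequentially - BrM first as
#' the most posterior prominent band, then IS/OS, then ELM - with each
#' search region restricted by the previously found boundaries. Coarse band
#' locations come from the prominent peaks of the lateral-mean depth profile.
#'
#' @param image Real intensity matrix (depth x lateral), finite.
#' @param config List of search constraints: `max_jump` (default 2 px),
#'   `search_half_width` (px around the coarse band, default 4),
#'   `min_separation_px` (required gap between successive boundaries,
#'   default 4), `min_rel_height` (profile-peak prominence, default 0.05).
#' @return An object of class `layer_boundaries`: list with `boundaries`
#'   (matrix layer x A-scan of depth indices, rows ELM/ISOS/BrM, NA rows for
#'   failed layers), `failed` (character vector naming undetected layers),
#'   and the `config` used.
#' @export
segment_layers <- function(image, config = list()) {
  if (!all(is.finite(image))) stop("image must be finite")
  if (nrow(image) < 3) stop("image too small to contain three layers")
  cfg <- utils::modifyList(list(max_jump = 2, search_half_width = 4,
                                min_separation_px = 4, min_rel_height = 0.05),
                           config)
  cost <- gradient_cost(image)
  pk <- profile_peaks(image, cfg$min_rel_height)
  W <- ncol(image)
  bnd <- matrix(NA_real_, 3, W, dimnames = list(c("ELM", "ISOS", "BrM"), NULL))
  failed <- character(0)

  trace_one <- function(center, zmax_cap = nrow(image)) {
    zmin <- max(2, floor(center - cfg$search_half_width))
    zmax <- min(nrow(image), ceiling(center + cfg$search_half_width),
                zmax_cap)
    dp_min_path(cost, zmin, zmax, cfg$max_jump)$path
  }

  # BrM: most posterior prominent band
  if (length(pk) >= 1) {
    brm_c <- max(pk)
    bnd["BrM", ] <- trace_one(brm_c)
  } else failed <- c(failed, "BrM")

  # ISOS: strongest band anterior to BrM (with separation margin)
  isos_lim <- if (!anyNA(bnd["BrM", ]))
    min(bnd["BrM", ]) - cfg$min_separation_px else nrow(image)
  cand <- pk[pk < isos_lim]
  if (length(cand) >= 1) {
    prof <- rowMeans(image)
    isos_c <- cand[which.max(prof[cand])]
    bnd["ISOS", ] <- trace_one(isos_c, zmax_cap = isos_lim)
  } else failed <- c(failed, "ISOS")

  # ELM: strongest band anterior to ISOS
  elm_lim <- if (!anyNA(bnd["ISOS", ]))
    min(bnd["ISOS", ]) - cfg$min_separation_px else isos_lim
  cand <- pk[pk < elm_lim]
  if (length(cand) >= 1) {
    prof <- rowMeans(image)
    elm_c <- cand[which.max(prof[cand])]
    bnd["ELM", ] <- trace_one(elm_c, zmax_cap = elm_lim)
  } else failed <- c(failed, "ELM")

  ok <- rownames(bnd)[!apply(bnd, 1, anyNA)]
  if (all(c("ELM", "ISOS", "BrM") %in% ok)) {
    bad <- !(bnd["ELM", ] < bnd["ISOS", ] & bnd["ISOS", ] < bnd["BrM", ])
    if (any(bad)) warning(sum(bad), " A-scans violate layer ordering")
  }
  if (length(failed))
    warning("no valid band found for layer(s): ", paste(failed, collapse = ", "))
  structure(list(boundaries = bnd, failed = failed, config = cfg),
            class = "layer_boundaries")
}

#' Split the mixed OS+RPE layer into equal-depth sub-bands
#'
#' Divides the IS/OS-to-BrM interval of each A-scan into `n_bands`
#' contiguous sub-bands of (as near as possible) equal depth. Remainder
#' pixels are distributed one per band starting from the most anterior band
#' (deterministic largest-remainder rule). Band 1 is the most anterior
#' ("top band", presumed OS tips).
#'
#' @param boundaries A `layer_boundaries` with valid ISOS and BrM rows.
#' @param n_bands Number of sub-bands (>= 1).
#' @return List of length `n_bands`; element k is a 2 x W matrix with rows
#'   `from`, `to` (inclusive depth indices) per A-scan.
#' @export
define_mixed_bands <- function(boundaries, n_bands = 5) {
  if (n_bands < 1) stop("n_bands must be >= 1")
  b <- boundaries$boundaries
  if (anyNA(b["ISOS", ]) || anyNA(b["BrM", ]))
    stop("mixed bands need valid ISOS and BrM boundaries")
  W <- ncol(b)
  lens <- b["BrM", ] - b["ISOS", ]
  if (any(lens < n_bands))
    stop("mixed layer thinner than n_bands pixels on some A-scans")
  out <- lapply(seq_len(n_bands), function(k)
    matrix(NA_real_, 2, W, dimnames = list(c("from", "to"), NULL)))
  for (x in seq_len(W)) {
    L <- lens[x]
    base <- L %/% n_bands
    rem <- L %% n_bands
    widths <- rep(base, n_bands) + c(rep(1, rem), rep(0, n_bands - rem))
    starts <- b["ISOS", x] + c(0, cumsum(widths))[seq_len(n_bands)]
    for (k in seq_len(n_bands)) {
      out[[k]]["from", x] <- starts[k]
      out[[k]]["to", x] <- starts[k] + widths[k] - 1
    }
  }
  out
}

#' Export layer boundaries as TSV
#' @param boundaries A `layer_boundaries`.
#' @param path Output TSV path.
#' @param frame Frame index recorded in the table.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path, frame = 1L) {
  b <- boundaries$boundaries
  df <- data.frame(
    frame = frame,
    ascan = rep(seq_len(ncol(b)), times = nrow(b)),
    layer = rep(rownames(b), each = ncol(b)),
    depth_px = as.vector(t(b))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
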