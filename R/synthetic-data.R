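# signed DFT frequencies (cycles per sample)
dft_freqs <- function(n) {
  f <- seq_len(n) - 1
  f[f > n / 2] <- f[f > n / 2] - n
  f / n
}

# carrier phase per depth pixel (rad/px): a reflector moving one depth pixel
# (= one pixel pitch of air optical path) shifts the interferometric phase by
# 4*pi*pitch/lambda in reflection geometry
carrier_rad_per_px <- function(optics) {
  4 * pi * optics$axial_pixel_pitch_um * 1000 / optics$center_wavelength_nm
}

#' Time axis of an acquisition protocol
#'
#' @param protocol A [protocol_spec()].
#' @return Numeric vector of sample times (s), 0 at stimulus onset; for volume
#'   protocols, one sample per volume.
#' @export
protocol_times <- function(protocol) {
  rate <- if (!is.na(protocol$volume_rate)) protocol$volume_rate else
    protocol$bscan_rate
  n <- floor(protocol$duration * rate)
  (seq_len(n) - 1) / rate - protocol$baseline
}

#' Simulate labeled phase traces with known class and depth ground truth
#'
#' Generates self-referenced temporal phase traces (rad) of four classes:
#' Type-I (fast OS elongation), Type-II (slow RPE-referenced rise),
#' intermediate (convex mixtures of the two templates with mixing weight
#' alpha in \[0.35, 0.65\]), and outlier (sample-shuffled templates with no
#' temporal structure). Depths (axial distance to Bruch's membrane, px) are
#' drawn from two Gaussians, Type-I anterior to Type-II, Type-II just
#' anterior to BrM. Pre-stimulus baselines are flat with zero mean.
#'
#' @param kinetics A [kinetics_spec()].
#' @param protocol A [protocol_spec()]; traces are sampled at its B-scan rate.
#' @param n_traces_per_class Traces per class (>= 1).
#' @param noise_sd_mrad White phase-noise standard deviation (mrad).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param center_wavelength_nm Wavelength for the nm-to-rad conversion.
#' @param depth_means_px Named c(type_I=, type_II=) Gaussian depth means
#'   (px anterior to BrM); defaults separated by 6 px.
#' @param depth_sds_px Matching Gaussian depth SDs.
#' @return An object of class `org_trace_set`: list with `t` (s), `phase`
#'   (n_traces x n_t matrix, rad), `class`, `depth_px_to_brm`, `fs`,
#'   `center_wavelength_nm`.
#' @export
simulate_phase_traces <- function(kinetics, protocol,
                                  n_traces_per_class = 500,
                                  noise_sd_mrad = 30,
                                  seed = 1L,
                                  center_wavelength_nm = 840,
                                  depth_means_px = c(type_I = 10, type_II = 4),
                                  depth_sds_px = c(type_I = 1.2, type_II = 1.0)) {
  if (n_traces_per_class < 1) stop("n_traces_per_class must be >= 1")
  if (noise_sd_mrad < 0) stop("noise_sd_mrad must be >= 0")
  set.seed(as.integer(seed))
  t <- protocol_times(protocol)
  tmpl <- kinetics_templates(kinetics, t)
  to_rad <- 4 * pi / center_wavelength_nm # nm -> rad
  phi_I <- tmpl$type_I * to_rad
  phi_II <- tmpl$type_II * to_rad

  n <- n_traces_per_class
  nt <- length(t)
  sd_rad <- noise_sd_mrad / 1000

  classes <- rep(c("type_I", "type_II", "intermediate", "outlier"), each = n)
  phase <- matrix(0, nrow = 4 * n, ncol = nt)
  depth <- numeric(4 * n)

  # Type-I
  idx <- seq_len(n)
  phase[idx, ] <- matrix(phi_I, n, nt, byrow = TRUE)
  depth[idx] <- stats::rnorm(n, depth_means_px["type_I"], depth_sds_px["type_I"])
  # Type-II
  idx <- n + seq_len(n)
  phase[idx, ] <- matrix(phi_II, n, nt, byrow = TRUE)
  depth[idx] <- stats::rnorm(n, depth_means_px["type_II"], depth_sds_px["type_II"])
  # intermediate: convex mixtures
  idx <- 2 * n + seq_len(n)
  alpha <- stats::runif(n, 0.35, 0.65)
  phase[idx, ] <- alpha %o% phi_I + (1 - alpha) %o% phi_II
  depth[idx] <- alpha * depth_means_px["type_I"] +
    (1 - alpha) * depth_means_px["type_II"] + stats::rnorm(n, 0, 1)
  # outlier: shape-shuffled templates (temporal structure destroyed) plus a
  # low-frequency random-walk drift of random magnitude, emulating the
  # aberrant traces of low-SNR / vessel pixels that scatter into low-density
  # regions of the feature space
  idx <- 3 * n + seq_len(n)
  src <- sample(c("I", "II"), n, replace = TRUE)
  for (j in seq_len(n)) {
    base <- if (src[j] == "I") phi_I else phi_II
    shuf <- base[sample.int(nt)]
    drift <- cumsum(stats::rnorm(nt))
    drift <- drift - mean(drift)
    dsd <- stats::sd(drift)
    if (dsd > 0)
      drift <- drift / dsd * stats::runif(1, 0.5, 3) * max(stats::sd(base), 1e-6)
    phase[idx[j], ] <- shuf + drift
  }
  depth[idx] <- stats::runif(n, 0.5,
                             depth_means_px["type_I"] + 4 * depth_sds_px["type_I"])

  if (sd_rad > 0)
    phase <- phase + matrix(stats::rnorm(length(phase), 0, sd_rad),
                            nrow = nrow(phase))

  structure(list(
    t = t, phase = phase, class = classes, depth_px_to_brm = depth,
    fs = protocol$bscan_rate, center_wavelength_nm = center_wavelength_nm,
    noise_sd_mrad = noise_sd_mrad, protocol_id = protocol$id,
    trace_id = sprintf("tr%05d", seq_along(classes))
  ), class = "org_trace_set")
}

#' Write / read a trace table as TSV
#'
#' Long format with columns trace_id, class, depth_px_to_brm, t_s, phase_rad.
#' @param traces An `org_trace_set`.
#' @param path Output TSV path.
#' @return `write_trace_table` returns `path` invisibly; `read_trace_table`
#'   returns an `org_trace_set` (metadata columns restored, `fs` inferred
#'   from the time grid).
#' @export
write_trace_table <- function(traces, path) {
  nt <- length(traces$t)
  df <- data.frame(
    trace_id = rep(traces$trace_id, each = nt),
    class = rep(traces$class, each = nt),
    depth_px_to_brm = rep(traces$depth_px_to_brm, each = nt),
    t_s = rep(traces$t, times = nrow(traces$phase)),
    phase_rad = as.vector(t(traces$phase))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  df <- utils::read.delim(path)
  need <- c("trace_id", "class", "depth_px_to_brm", "t_s", "phase_rad")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace table missing columns: ",
                         paste(miss, collapse = ", "))
  ids <- unique(df$trace_id)
  t <- sort(unique(df$t_s))
  phase <- matrix(df$phase_rad[order(match(df$trace_id, ids), df$t_s)],
                  nrow = length(ids), ncol = length(t), byrow = TRUE)
  first <- df[!duplicated(df$trace_id), ]
  first <- first[match(ids, first$trace_id), ]
  structure(list(
    t = t, phase = phase, class = first$class,
    depth_px_to_brm = first$depth_px_to_brm,
    fs = 1 / stats::median(diff(t)), center_wavelength_nm = NA_real_,
    noise_sd_mrad = NA_real_, protocol_id = "unknown", trace_id = ids
  ), class = "org_trace_set")
}

# per-layer scatterer fields convolved with the complex PSF, pre-transformed
# along depth (rows: k_z, cols: x). Returns list of n_z x n_x complex mats.
build_layer_fields <- function(layer_depths, layer_refl, layer_halfwidth,
                               n_depth, n_lateral, optics) {
  nl <- length(layer_depths)
  # complex Gaussian PSF, unit L2 energy, separable
  n_idx <- optics$tissue_refractive_index
  sig_z <- optics$axial_resolution_um * n_idx / 2.355 /
    optics$axial_pixel_pitch_um
  sig_x <- optics$lateral_beam_diameter_um / 4 / optics$lateral_pixel_pitch_um
  # kernel centered at index 0 (wrap-around) so layers stay at their depths
  dz0 <- pmin(seq_len(n_depth) - 1, n_depth - (seq_len(n_depth) - 1))
  dx0 <- pmin(seq_len(n_lateral) - 1, n_lateral - (seq_len(n_lateral) - 1))
  gz <- exp(-dz0^2 / (2 * sig_z^2))
  gx <- exp(-dx0^2 / (2 * sig_x^2))
  psf <- gz %o% gx
  psf <- psf / sqrt(sum(psf^2))
  Hp <- stats::fft(psf)
  fields <- vector("list", nl)
  for (l in seq_len(nl)) {
    rows <- round(layer_depths[l] - layer_halfwidth[l]):
      round(layer_depths[l] + layer_halfwidth[l])
    rows <- rows[rows >= 1 & rows <= n_depth]
    S <- matrix(0 + 0i, n_depth, n_lateral)
    nsc <- length(rows) * n_lateral
    S[rows, ] <- complex(
      real = stats::rnorm(nsc, 0, layer_refl[l] / sqrt(2)),
      imaginary = stats::rnorm(nsc, 0, layer_refl[l] / sqrt(2))
    )
    G <- stats::fft(S) * Hp
    # back to (z, x) space, then forward along depth only
    g <- stats::fft(G, inverse = TRUE) / length(G)
    fields[[l]] <- stats::mvfft(g)
  }
  fields
}

# bulk-motion waveforms (px) on a time grid. Oscillation phases derive from
# the motion seed through a private RNG stream so the caller's stream (the
# scene seed) is untouched.
motion_waveforms <- function(motion, t) {
  ph <- local({
    rs <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(rs)) assign(".Random.seed", rs, globalenv())
            else if (exists(".Random.seed", globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()))
    set.seed(motion$seed + 7L)
    stats::runif(4, 0, 2 * pi)
  })
  span <- max(t) - min(t)
  drift <- motion$drift_amplitude *
    (1 - cos(pi * (t - min(t)) / span)) / 2
  dz <- drift +
    motion$heartbeat_amp * sin(2 * pi * motion$heartbeat_freq * t + ph[1]) +
    motion$respiration_amp * sin(2 * pi * motion$respiration_freq * t + ph[2])
  dx <- motion$lateral_fraction *
    (drift +
       motion$heartbeat_amp * sin(2 * pi * motion$heartbeat_freq * t + ph[3]) +
       motion$respiration_amp * sin(2 * pi * motion$respiration_freq * t + ph[4]))
  list(dz = dz, dx = dx)
}

#' Simulate a complex B-scan time series with known ground truth
#'
#' Each frame is a sum of per-layer speckle fields (circular-complex scatterer
#' amplitudes, fixed across time) convolved with a complex Gaussian PSF.
#' Stimulus-evoked layer kinetics displace each layer sub-pixel in the depth
#' frequency domain together with the physical carrier phase
#' (4*pi*pitch/lambda per pixel); rigid bulk motion displaces whole frames the
#' same way; circular-complex noise of unit standard deviation is added, so
#' `optics$snr_profile` is the per-layer linear amplitude SNR.
#'
#' @param layers List with numeric vectors `depths_px` (strictly increasing,
#'   named ELM, ISOS, OStips, RPE, BrM), optional `half_width_px`.
#' @param kinetics,motion,optics,protocol Spec objects.
#' @param seed Integer seed.
#' @param n_depth,n_lateral Frame dimensions in pixels.
#' @return A `frame_series`: list with complex array `frames`
#'   (depth x lateral x time), `meta`, and `ground_truth` (per-frame bulk
#'   shifts, per-layer positions and OPL displacement (nm), and the derived
#'   structure signals OS, TypeII, ELM_rel_ISOS, SRS).
#' @export
simulate_bscan_series <- function(layers = default_layers(),
                                  kinetics = kinetics_spec(),
                                  motion = motion_spec(),
                                  optics = optics_spec(),
                                  protocol = org_protocol("protocol1"),
                                  seed = 1L,
                                  n_depth = 128, n_lateral = 96) {
  set.seed(as.integer(seed))
  d <- layers$depths_px
  if (is.null(names(d))) names(d) <- c("ELM", "ISOS", "OStips", "RPE", "BrM")
  if (any(diff(d) <= 0)) stop("layer depths must be strictly increasing (ELM < ISOS < OStips < RPE < BrM)")
  if (any(d < 1) || any(d > n_depth)) stop("layer depths outside the depth grid")
  hw <- layers$half_width_px %||% c(ELM = 0.5, ISOS = 0.8, OStips = 1.0,
                                    RPE = 1.2, BrM = 0.5)[names(d)]
  refl <- optics$snr_profile[names(d)]
  if (anyNA(refl)) stop("snr_profile must name every layer")

  t <- protocol_times(protocol)
  nt <- length(t)
  disp <- layer_displacements_px(kinetics, t, names(d), optics)
  mot <- motion_waveforms(motion, t)

  fields <- build_layer_fields(d, refl, hw, n_depth, n_lateral, optics)
  fz <- dft_freqs(n_depth)
  fx <- dft_freqs(n_lateral)
  phic <- carrier_rad_per_px(optics)

  frames <- array(0i, dim = c(n_depth, n_lateral, nt))
  for (k in seq_len(nt)) {
    M <- matrix(0 + 0i, n_depth, n_lateral)
    for (l in seq_along(fields)) {
      dtot <- disp[k, l] + mot$dz[k]
      ramp <- exp((-2i * pi * fz + 0i) * dtot) * exp(1i * phic * dtot)
      M <- M + fields[[l]] * ramp
    }
    M <- stats::mvfft(M, inverse = TRUE) / n_depth
    # lateral bulk shift
    Mx <- t(stats::mvfft(t(M)))
    Mx <- Mx * matrix(exp(-2i * pi * fx * mot$dx[k]), n_depth, n_lateral,
                      byrow = TRUE)
    M <- t(stats::mvfft(t(Mx), inverse = TRUE)) / n_lateral
    nz <- n_depth * n_lateral
    M <- M + complex(real = stats::rnorm(nz, 0, 1 / sqrt(2)),
                     imaginary = stats::rnorm(nz, 0, 1 / sqrt(2)))
    frames[, , k] <- M
  }

  gt_sig <- ground_truth_signals(kinetics, t)
  meta <- list(center_wavelength_nm = optics$center_wavelength_nm,
               pixel_pitch_um_air = optics$axial_pixel_pitch_um,
               lateral_pixel_pitch_um = optics$lateral_pixel_pitch_um,
               frame_rate_hz = protocol$bscan_rate,
               stimulus_onset_s = 0,
               protocol_id = protocol$id,
               schema_version = "v1")
  structure(list(
    frames = frames, t = t, meta = meta,
    ground_truth = list(
      shifts = data.frame(frame = seq_len(nt), t_s = t,
                          dz_px = mot$dz, dx_px = mot$dx),
      layer_positions_px = d,
      layer_disp_px = disp,
      signals = gt_sig
    )
  ), class = "frame_series")
}

#' Default outer-retina layer geometry for the simulator
#'
#' Depth indices (px) of the hyperreflective outer-retinal bands on the
#' simulated depth grid, ordered anterior to posterior.
#' @param n_depth Depth grid size the defaults are designed for.
#' @return List with `depths_px` and `half_width_px`.
#' @export
default_layers <- function(n_depth = 128) {
  list(
    depths_px = c(ELM = 40, ISOS = 52, OStips = 60, RPE = 66, BrM = 72),
    half_width_px = c(ELM = 0.5, ISOS = 0.8, OStips = 1.0, RPE = 1.2,
                      BrM = 0.5)
  )
}

# per-layer axial displacements (px, posterior positive) from the kinetics.
# BrM is the static anchor; SRS expansion moves ELM/ISOS (and everything
# anterior of RPE) anteriorly; IS compression moves ISOS further anterior;
# the OS elongation moves the OS tips posteriorly relative to ISOS.
layer_displacements_px <- function(kinetics, t, layer_names, optics) {
  tmpl <- kinetics_templates(kinetics, t)
  nm_per_px <- optics$axial_pixel_pitch_um * 1000
  s <- tmpl$srs / nm_per_px
  cIS <- tmpl$is_comp / nm_per_px
  e <- tmpl$type_I / nm_per_px
  disp <- sapply(layer_names, function(nm) switch(nm,
    ELM = -s,
    ISOS = -s - cIS,
    OStips = -s - cIS + e,
    RPE = rep(0, length(t)),
    BrM = rep(0, length(t)),
    rep(0, length(t))
  ))
  matrix(disp, nrow = length(t), dimnames = list(NULL, layer_names))
}

# ground-truth structure signals (nm OPL, expansion positive)
ground_truth_signals <- function(kinetics, t) {
  tmpl <- kinetics_templates(kinetics, t)
  data.frame(
    t_s = t,
    OS = tmpl$type_I,
    TypeII = tmpl$srs + tmpl$is_comp,
    ELM_rel_ISOS = -tmpl$is_comp,
    SRS = tmpl$srs
  )
}

#' Simulate a volume time series with a regionally varying response map
#'
#' Repeats [simulate_bscan_series()] across B-scan (y) positions with the
#' Type-I/SRS kinetic amplitudes scaled per en-face grid cell, emulating a
#' repeated-volume acquisition over a square field of view.
#'
#' @inheritParams simulate_bscan_series
#' @param amplitude_map Numeric matrix (cells_x x cells_y) of kinetics scale
#'   factors; `matrix(1, 1, 1)` gives a uniform field.
#' @param fov_deg Field of view (degrees), used to attach en-face geometry.
#' @return A `frame_series` whose `frames` is a 4-D complex array
#'   (depth x lateral x y x time); `ground_truth$amplitude_map` echoes the
#'   per-cell scale factors.
#' @export
simulate_volume_series <- function(layers = default_layers(),
                                   kinetics = kinetics_spec(),
                                   motion = motion_spec(),
                                   optics = optics_spec(),
                                   protocol = org_protocol("protocol3"),
                                   amplitude_map = matrix(1, 1, 1),
                                   fov_deg = 12,
                                   seed = 1L,
                                   n_depth = 128, n_lateral = 96) {
  if (is.na(protocol$volume_rate) || is.na(protocol$bscans_per_volume))
    stop("volume simulation needs a volume protocol (volume_rate, bscans_per_volume)")
  n_y <- protocol$bscans_per_volume
  n_vol <- floor(protocol$duration * protocol$volume_rate)
  t <- protocol_times(protocol)

  cells_x <- nrow(amplitude_map)
  cells_y <- ncol(amplitude_map)
  y_cell <- ceiling(seq_len(n_y) / (n_y / cells_y))

  frames <- array(0i, dim = c(n_depth, n_lateral, n_y, n_vol))
  gt_sig <- vector("list", n_y)
  for (iy in seq_len(n_y)) {
    # one amplitude scale per y position (x variation handled by cell column)
    # use the x-cell structure: simulate each x-cell block with its own scale
    blocks <- split(seq_len(n_lateral),
                    ceiling(seq_len(n_lateral) / (n_lateral / cells_x)))
    sub <- vector("list", cells_x)
    for (ix in seq_len(cells_x)) {
      sc <- amplitude_map[ix, y_cell[iy]]
      kin <- kinetics
      for (f in c("type_I_amp", "type_I_undershoot_amp", "type_II_rate",
                  "srs_peak_amp", "srs_slope", "is_compression_amp"))
        kin[[f]] <- kin[[f]] * sc
      sub[[ix]] <- simulate_bscan_series(
        layers, kin, motion, optics, protocol,
        seed = seed + 1000L * iy + ix,
        n_depth = n_depth, n_lateral = length(blocks[[ix]])
      )
    }
    for (ix in seq_len(cells_x))
      frames[, blocks[[ix]], iy, ] <- sub[[ix]]$frames
    gt_sig[[iy]] <- lapply(sub, function(s) s$ground_truth$signals)
  }
  meta <- sub[[1]]$meta
  meta$fov_deg <- fov_deg
  meta$n_y <- n_y
  structure(list(
    frames = frames, t = t, meta = meta,
    ground_truth = list(amplitude_map = amplitude_map,
                        signals_by_position = gt_sig,
                        t_s = t)
  ), class = "frame_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
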