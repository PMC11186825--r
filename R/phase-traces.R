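#' Extract a self-referenced temporal phase trace from a registered series
#'
#' For one target pixel, computes per frame the phase of
#' `S_target * Conj(mean(S_reference))`, where the reference is the complex
#' mean over the reference-layer pixels of the same A-scan (amplitude-
#' weighted, noise-robust). The trace is temporally unwrapped (frame-to-frame
#' differences mapped to (-pi, pi\]) and zeroed at stimulus onset.
#'
#' @param series A registered `frame_series`.
#' @param target_px Integer c(depth, ascan) of the target pixel.
#' @param boundaries A `layer_boundaries` for the series (used for the
#'   reference band and the depth-to-BrM bookkeeping).
#' @param reference_layer Name of the reference boundary row (default
#'   `"ISOS"`).
#' @param ref_half_width Half-width (px) of the reference band around the
#'   reference boundary.
#' @param min_ref_snr Minimum mean reference amplitude (in noise-SD units)
#'   below which the trace is flagged invalid.
#' @return An object of class `phase_trace`: list with `t` (s), `phi` (rad,
#'   unwrapped, 0 at onset), `depth_px_to_brm`, `target_layer`,
#'   `reference_layer`, `prestim_sd_mrad`, `fs`, `valid`.
#' @export
extract_phase_trace <- function(series, target_px, boundaries,
                                reference_layer = "ISOS",
                                ref_half_width = 1,
                                min_ref_snr = 3) {
  fr <- series$frames
  z <- target_px[1]; x <- target_px[2]
  nt <- dim(fr)[3]
  t_s <- series$t %||% ((seq_len(nt) - 1) / series$meta$frame_rate_hz)
  zr <- boundaries$boundaries[reference_layer, x]
  if (is.na(zr)) stop("reference layer '", reference_layer,
                      "' is empty at A-scan ", x)
  rows <- max(1, round(zr - ref_half_width)):min(dim(fr)[1],
                                                 round(zr + ref_half_width))
  tgt <- fr[z, x, ]
  ref <- if (length(rows) > 1) colMeans(fr[rows, x, , drop = FALSE][, 1, ])
         else fr[rows, x, ]
  raw <- Arg(tgt * Conj(ref))
  phi <- unwrap_phase(raw)
  onset <- which.min(abs(t_s - 0))
  phi <- phi - phi[onset]
  pre <- phi[t_s < 0]
  prestim_sd <- if (length(pre) >= 2) stats::sd(pre) * 1000 else NA_real_
  zb <- boundaries$boundaries["BrM", x]
  valid <- mean(Mod(ref)) >= min_ref_snr
  structure(list(
    t = t_s, phi = phi,
    depth_px_to_brm = if (is.na(zb)) NA_real_ else zb - z,
    target_layer = sprintf("px(%d,%d)", z, x),
    reference_layer = reference_layer,
    prestim_sd_mrad = prestim_sd,
    fs = series$meta$frame_rate_hz %||% (1 / stats::median(diff(t_s))),
    valid = valid
  ), class = "phase_trace")
}

# temporal unwrapping: successive differences mapped to (-pi, pi]
unwrap_phase <- function(raw) {
  d <- diff(raw)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(raw[1], d))
}

#' Convert an unwrapped phase trace into an OPL change series
#'
#' Uses the reflection-geometry relation `dOPL = s * lambda * dphi / (4*pi)`
#' with `s = -1` when the target layer is anterior to the reference layer and
#' `+1` otherwise, so that an OPL increase always reads as an expansion of
#' the inter-layer space.
#'
#' @param trace A `phase_trace`, or a numeric vector of phase (rad).
#' @param params A [conversion_params()].
#' @param target_anterior_to_reference Logical sign flag.
#' @return Numeric vector of OPL change (nm).
#' @export
phase_to_opl <- function(trace, params = conversion_params(),
                         target_anterior_to_reference = FALSE) {
  phi <- if (inherits(trace, "phase_trace")) trace$phi else trace
  s <- if (isTRUE(target_anterior_to_reference)) -1 else 1
  s * params$center_wavelength_nm * phi / (4 * pi)
}

#' Convert an OPL change into physical deformation
#'
#' @param dopl_nm OPL change (nm).
#' @param params A [conversion_params()]; divides by the tissue refractive
#'   index (default 1.41).
#' @return Physical deformation (nm).
#' @export
opl_to_deformation <- function(dopl_nm, params = conversion_params()) {
  dopl_nm / params$tissue_refractive_index
}

#' Filter a phase trace (bandstop artifacts, optional low-pass) zero-phase
#'
#' Applies forward-backward (zero-phase) Butterworth filters: one bandstop
#' per artifact band (heartbeat, respiration) and, optionally, a low-pass.
#' The low-pass branch exists for signal classification only; reported
#' signals should be filtered with `lowpass_cutoff = NULL` to avoid signal
#' distortion. `trim` samples are dropped at both ends where the zero-phase
#' filtering leaves edge transients. DC is preserved.
#'
#' @param trace A `phase_trace` (or numeric vector with attribute-free phase;
#'   then `fs` must be given).
#' @param bandstop_bands List of c(f_lo, f_hi) Hz pairs; bands at or above
#'   Nyquist are skipped.
#' @param lowpass_cutoff Low-pass cutoff (Hz) or `NULL` for none.
#' @param trim Samples removed from each end after filtering.
#' @param fs Sampling rate (Hz), taken from the trace when available.
#' @return The filtered `phase_trace` (t and phi shortened by `trim` on both
#'   ends), or a numeric vector if the input was one.
#' @export
filter_trace <- function(trace,
                         bandstop_bands = list(c(4.5, 5.5), c(0.8, 1.2)),
                         lowpass_cutoff = NULL, trim = 0, fs = NULL) {
  is_obj <- inherits(trace, "phase_trace")
  x <- if (is_obj) trace$phi else as.numeric(trace)
  fs <- if (is_obj) trace$fs else fs
  if (is.null(fs)) stop("sampling rate fs required")
  nyq <- fs / 2
  if (!is.null(lowpass_cutoff) && lowpass_cutoff >= nyq)
    stop("low-pass cutoff must be below the Nyquist frequency")
  if (length(x) < 24) stop("trace shorter than the filter warm-up")
  # odd-symmetric reflection padding suppresses filtfilt edge transients
  # (the residual edge variance is what `trim` removes); the pad must cover
  # several time constants of the narrowest filter, ~ fs / (pi * bandwidth)
  bws <- vapply(bandstop_bands, function(b) b[2] - b[1], numeric(1))
  bw_min <- min(c(bws[bws > 0], lowpass_cutoff, Inf))
  np <- min(length(x) - 1,
            max(24, ceiling(12 * fs / (pi * bw_min))))
  pad <- function(v) c(2 * v[1] - rev(v[2:(np + 1)]), v,
                       2 * v[length(v)] - rev(v[(length(v) - np):(length(v) - 1)]))
  unpad <- function(v) v[(np + 1):(length(v) - np)]
  for (b in bandstop_bands) {
    if (b[2] >= nyq) next
    bf <- signal::butter(2, c(b[1], b[2]) / nyq, type = "stop")
    x <- unpad(signal::filtfilt(bf, pad(x)))
  }
  if (!is.null(lowpass_cutoff)) {
    lf <- signal::butter(4, lowpass_cutoff / nyq, type = "low")
    x <- unpad(signal::filtfilt(lf, pad(x)))
  }
  if (trim > 0) {
    keep <- (trim + 1):(length(x) - trim)
    x <- x[keep]
    if (is_obj) trace$t <- trace$t[keep]
  }
  if (is_obj) {
    trace$phi <- x
    trace
  } else x
}

#' Quality-control exclusion of noisy phase traces
#'
#' Excludes traces whose pre-stimulus standard deviation exceeds the
#' threshold (strictly greater than; a trace at exactly the threshold is
#' retained). High pre-stimulus SD typically marks low-SNR pixels or pixels
#' underneath blood vessels.
#'
#' @param traces List of `phase_trace` objects.
#' @param threshold_mrad Exclusion threshold (mrad), default 60.
#' @return List with `retained` (the surviving traces), `excluded`, and
#'   `log` (data.frame of counts by reason).
#' @export
qc_exclude <- function(traces, threshold_mrad = 60) {
  sds <- vapply(traces, function(tr) {
    if (is.na(tr$prestim_sd_mrad)) stop("trace has no pre-stimulus samples")
    tr$prestim_sd_mrad
  }, numeric(1))
  invalid <- vapply(traces, function(tr) !isTRUE(tr$valid), logical(1))
  drop_sd <- sds > threshold_mrad & !invalid
  keep <- !drop_sd & !invalid
  list(
    retained = traces[keep],
    excluded = traces[!keep],
    log = data.frame(
      reason = c("retained", "prestim_sd_above_threshold", "low_reference_snr"),
      n = c(sum(keep), sum(drop_sd), sum(invalid))
    )
  )
}

#' Average QC-passed phase traces within a band into one signal
#'
#' Arithmetic mean of the unwrapped phase traces (all on the same time
#' grid), reported with the number of contributing pixels.
#'
#' @param traces Non-empty list of `phase_trace` objects on a common grid.
#' @param structure_name Name of the anatomical structure or band.
#' @param params [conversion_params()] for the OPL conversion.
#' @param target_anterior_to_reference Sign flag passed to [phase_to_opl()].
#' @return An `org_signal`: data.frame with columns `structure`, `t_s`,
#'   `dopl_nm`, `n_pixels`.
#' @export
average_band_trace <- function(traces, structure_name = "band",
                               params = conversion_params(),
                               target_anterior_to_reference = FALSE) {
  if (length(traces) < 1) stop("empty band after QC")
  t0 <- traces[[1]]$t
  phis <- vapply(traces, function(tr) {
    if (length(tr$phi) != length(t0)) stop("traces not on a common time grid")
    tr$phi
  }, numeric(length(t0)))
  mphi <- if (is.matrix(phis)) rowMeans(phis) else phis
  dopl <- phase_to_opl(mphi, params, target_anterior_to_reference)
  org_signal(structure_name, t0, dopl, n_pixels = length(traces))
}

#' Construct an ORG signal table
#'
#' @param structure Structure name (e.g. "OS", "RPE", "SRS", "band_1").
#' @param t_s Time grid (s), 0 at stimulus onset.
#' @param dopl_nm OPL change (nm).
#' @param n_pixels Number of pixels averaged into the signal.
#' @return data.frame of class `org_signal`.
#' @export
org_signal <- function(structure, t_s, dopl_nm, n_pixels = 1L) {
  structure(data.frame(structure = structure, t_s = t_s, dopl_nm = dopl_nm,
                       n_pixels = n_pixels),
            class = c("org_signal", "data.frame"))
}
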