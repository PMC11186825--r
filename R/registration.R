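# raised-cosine (Tukey) 2-D window with the given taper fraction per edge
tukey_window <- function(n, taper) {
  if (taper <= 0) return(rep(1, n))
  w <- rep(1, n)
  m <- floor(taper * n)
  if (m < 1) return(w)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / m))
  w[seq_len(m)] <- ramp
  w[n + 1 - seq_len(m)] <- ramp
  w
}

#' Estimate the subpixel translation between two complex frames
#'
#' Locates the peak of the cross-correlation magnitude between two
#' complex-valued B-scans on the integer grid (via FFT), then refines it on
#' an upsampled grid restricted to a +/-1.5 px neighborhood of the coarse
#' peak using a single matrix-product DFT evaluation, giving a shift
#' resolution of 1/upsample pixels without upsampling the full plane.
#'
#' @param reference,moving Complex matrices of identical dimension; the
#'   estimate is the displacement of `moving` relative to `reference`
#'   (`moving ~ reference` translated by `(dz, dx)`).
#' @param upsample Upsampling factor (>= 1); default 100 (0.01 px).
#' @param taper Raised-cosine edge taper fraction applied to both frames
#'   before correlation. Tapering suppresses wrap-around artifacts when
#'   frame content enters or leaves the field of view, but it biases the
#'   subpixel estimate (up to ~0.1 px at 5% taper), so the default is 0;
#'   enable it only for non-circular scene motion.
#' @return List with `dz`, `dx` (signed subpixel pixels) and
#'   `peak_correlation` (normalized magnitude in \[0, 1\]).
#' @export
estimate_shift <- function(reference, moving, upsample = 100, taper = 0) {
  if (!all(dim(reference) == dim(moving)))
    stop("frames must have identical dimensions")
  if (upsample < 1) stop("upsample must be >= 1")
  if (all(reference == 0) || all(moving == 0))
    stop("cross-correlation undefined for an all-zero frame")
  nz <- nrow(reference); nx <- ncol(reference)
  wz <- tukey_window(nz, taper); wx <- tukey_window(nx, taper)
  W <- wz %o% wx
  A <- reference * W
  B <- moving * W
  R <- stats::fft(B) * Conj(stats::fft(A))
  cc <- stats::fft(R, inverse = TRUE) / length(R)
  p <- which.max(abs(cc))
  pz <- (p - 1) %% nz
  px <- (p - 1) %/% nz
  if (pz > nz / 2) pz <- pz - nz
  if (px > nx / 2) px <- px - nx

  fz <- dft_freqs(nz); fx <- dft_freqs(nx)
  if (upsample > 1) {
    grid <- seq(-1.5, 1.5, by = 1 / upsample)
    uz <- pz + grid
    ux <- px + grid
    Ez <- exp(2i * pi * outer(uz, fz))        # n_uz x nz
    Ex <- exp(2i * pi * outer(fx, ux))        # nx x n_ux
    Cf <- Ez %*% R %*% Ex
    pk <- which.max(abs(Cf))
    iz <- (pk - 1) %% length(uz) + 1
    ix <- (pk - 1) %/% length(uz) + 1
    dz <- uz[iz]; dx <- ux[ix]
    peak <- abs(Cf[iz, ix]) / length(R)
  } else {
    dz <- pz; dx <- px
    peak <- abs(cc[p]) * 1 # already normalized by length via ifft
  }
  denom <- sqrt(sum(Mod(A)^2) * sum(Mod(B)^2))
  list(dz = dz, dx = dx, peak_correlation = min(peak / denom, 1))
}

#' Translate a complex frame while restoring the interferometric phase
#'
#' Translates the frame by `(-dz, -dx)`: the lateral shift is applied as a
#' linear phase ramp in the lateral spatial-frequency domain; the axial shift
#' as a linear ramp in the depth-conjugate (spectral) domain together with
#' the carrier phase `4*pi*pitch/lambda` per pixel, which simultaneously
#' removes the bulk phase offset associated with axial motion. Both are pure
#' phase multiplications, so frame energy is conserved exactly.
#'
#' @param frame Complex matrix (depth x lateral).
#' @param shift List or numeric with `dz`, `dx` (px), e.g. from
#'   [estimate_shift()].
#' @param pixel_pitch_um Axial pixel pitch in air (um).
#' @param center_wavelength_nm Center wavelength (nm).
#' @return The corrected complex frame.
#' @export
apply_phase_restoring_shift <- function(frame, shift,
                                        pixel_pitch_um = 1.05,
                                        center_wavelength_nm = 840) {
  dz <- if (is.list(shift)) shift$dz else shift[[1]]
  dx <- if (is.list(shift)) shift$dx else shift[[2]]
  if (!is.finite(dz) || !is.finite(dx)) stop("shift must be finite")
  nz <- nrow(frame); nx <- ncol(frame)
  fz <- dft_freqs(nz); fx <- dft_freqs(nx)
  phic <- 4 * pi * pixel_pitch_um * 1000 / center_wavelength_nm
  Fz <- stats::mvfft(frame)
  Fz <- Fz * exp(2i * pi * fz * dz) * exp(-1i * phic * dz)
  out <- stats::mvfft(Fz, inverse = TRUE) / nz
  Fx <- t(stats::mvfft(t(out)))
  Fx <- Fx * matrix(exp(2i * pi * fx * dx), nz, nx, byrow = TRUE)
  t(stats::mvfft(t(Fx), inverse = TRUE)) / nx
}

#' Register a complex frame series to a reference frame
#'
#' Estimates and corrects the subpixel bulk motion of every frame relative
#' to a reference frame, restoring phase. By default the reference is the
#' frame with the highest mean intensity among the first ten (a
#' quality-based choice; configurable).
#'
#' @param series A `frame_series` (B-scan series, depth x lateral x time).
#' @param reference_index Index of the reference frame, or `NULL` to pick
#'   the brightest of the first ten frames.
#' @param upsample Upsampling factor for [estimate_shift()].
#' @param taper Edge taper fraction for [estimate_shift()].
#' @return The input series with `frames` replaced by registered frames and
#'   a `shifts` data.frame (frame, t_s, dz_px, dx_px, peak_correlation)
#'   appended.
#' @export
register_series <- function(series, reference_index = NULL, upsample = 100,
                            taper = 0) {
  fr <- series$frames
  if (length(dim(fr)) != 3) stop("register_series expects a B-scan series")
  nt <- dim(fr)[3]
  if (nt < 2) stop("need at least 2 frames")
  if (is.null(reference_index)) {
    k <- min(10, nt)
    mi <- vapply(seq_len(k), function(i) mean(Mod(fr[, , i])^2), numeric(1))
    reference_index <- which.max(mi)
  }
  ref <- fr[, , reference_index]
  pitch <- series$meta$pixel_pitch_um_air
  wl <- series$meta$center_wavelength_nm
  t_s <- series$t %||% ((seq_len(nt) - 1) / series$meta$frame_rate_hz)
  out <- fr
  shifts <- data.frame(frame = seq_len(nt), t_s = t_s, dz_px = 0, dx_px = 0,
                       peak_correlation = NA_real_)
  for (i in seq_len(nt)) {
    if (i == reference_index) {
      shifts$peak_correlation[i] <- 1
      next
    }
    est <- estimate_shift(ref, fr[, , i], upsample = upsample, taper = taper)
    out[, , i] <- apply_phase_restoring_shift(fr[, , i], est, pitch, wl)
    shifts$dz_px[i] <- est$dz
    shifts$dx_px[i] <- est$dx
    shifts$peak_correlation[i] <- est$peak_correlation
  }
  series$frames <- out
  series$shifts <- shifts
  series$reference_index <- reference_index
  series
}

#' Export a shift trace as TSV
#' @param shifts The `shifts` data.frame from [register_series()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_shift_trace <- function(shifts, path) {
  utils::write.table(shifts[, c("frame", "t_s", "dz_px", "dx_px")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
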