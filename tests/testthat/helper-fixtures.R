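# shared fixtures, built in code at test time

# band-limited complex speckle frame (circular-complex Gaussian field)
make_speckle_frame <- function(nz = 128, nx = 96, seed = 1, sig_z = 1.2,
                               sig_x = 2) {
  set.seed(seed)
  S <- matrix(complex(real = rnorm(nz * nx), imaginary = rnorm(nz * nx)),
              nz, nx)
  dz0 <- pmin(seq_len(nz) - 1, nz - (seq_len(nz) - 1))
  dx0 <- pmin(seq_len(nx) - 1, nx - (seq_len(nx) - 1))
  H <- stats::fft(exp(-dz0^2 / (2 * sig_z^2)) %o%
                    exp(-dx0^2 / (2 * sig_x^2)))
  stats::fft(stats::fft(S) * H / sqrt(mean(Mod(H)^2)), inverse = TRUE) /
    length(S)
}

# pure Fourier translation (no carrier), the ground-truth shift operator
fourier_shift <- function(A, dz, dx) {
  nz <- nrow(A); nx <- ncol(A)
  fz <- (seq_len(nz) - 1); fz[fz > nz / 2] <- fz[fz > nz / 2] - nz; fz <- fz / nz
  fx <- (seq_len(nx) - 1); fx[fx > nx / 2] <- fx[fx > nx / 2] - nx; fx <- fx / nx
  Fz <- stats::mvfft(A) * exp(-2i * pi * fz * dz)
  A2 <- stats::mvfft(Fz, inverse = TRUE) / nz
  Fx <- t(stats::mvfft(t(A2))) * matrix(exp(-2i * pi * fx * dx), nz, nx,
                                        byrow = TRUE)
  t(stats::mvfft(t(Fx), inverse = TRUE)) / nx
}

# kinetics with all responses switched off (static scene)
static_kinetics <- function() {
  kinetics_spec(type_I_amp = 1e-9, type_I_undershoot_amp = 1e-9,
                type_II_rate = 1e-9, srs_peak_amp = 1e-9, srs_slope = 1e-9,
                is_compression_amp = 0)
}

no_motion <- function() {
  motion_spec(drift_amplitude = 0, heartbeat_amp = 0, respiration_amp = 0)
}

# small, fast acquisition protocol for image-pipeline tests
test_protocol <- function(n_x = 96, rate = 100, duration = 3, baseline = 1) {
  protocol_spec(n_x, rate, duration = duration, baseline = baseline,
                id = "test")
}

# near-noise-free optics (very high per-layer SNR)
bright_optics <- function() {
  optics_spec(snr_profile = c(ELM = 1e6, ISOS = 1e6, OStips = 1e6,
                              RPE = 1e6, BrM = 1e6))
}

# single-row reflector geometry
delta_layers <- function() {
  list(depths_px = c(ELM = 20, ISOS = 40, OStips = 60, RPE = 80, BrM = 100),
       half_width_px = c(ELM = 0, ISOS = 0, OStips = 0, RPE = 0, BrM = 0))
}

# simple phase_trace object for unit tests
make_trace <- function(t, phi, prestim_sd = 10, fs = NULL, valid = TRUE,
                       depth = 5) {
  structure(list(t = t, phi = phi, depth_px_to_brm = depth,
                 target_layer = "px", reference_layer = "ISOS",
                 prestim_sd_mrad = prestim_sd,
                 fs = fs %||% (1 / median(diff(t))), valid = valid),
            class = "phase_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
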