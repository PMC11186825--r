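#' Kinetics specification for stimulus-evoked outer-retina dynamics
#'
#' Bundles the layer kinetics that the synthetic-data module programs into
#' phase traces and B-scan series. Defaults reflect the shapes measured in
#' dark-adapted rat retina: a fast Type-I (photoreceptor outer segment, OS)
#' elongation peaking within ~0.5 s followed by a negative undershoot that
#' peaks around 10 s and recovers within ~30 s; a slow Type-II (RPE-referenced)
#' rise; a subretinal-space (SRS) expansion of ~15 nm/s that peaks near
#' 250 nm around 20 s; and a small (~10 nm) inner-segment compression.
#'
#' @param type_I_amp Peak amplitude of the fast OS elongation (nm OPL).
#' @param type_I_peak_latency Time to OS peak after stimulus onset (s).
#' @param type_I_undershoot_amp Amplitude of the negative undershoot (nm).
#' @param type_I_undershoot_latency Time to undershoot minimum (s).
#' @param type_I_recovery_time Approximate return-to-baseline time (s).
#' @param type_II_rate Initial rise rate of the Type-II signal (nm/s).
#' @param type_II_onset Onset delay of the Type-II rise (s).
#' @param srs_peak_amp Peak SRS expansion (nm OPL).
#' @param srs_peak_latency Time to SRS peak (s).
#' @param srs_slope Ramp slope of SRS expansion (nm/s).
#' @param srs_onset Onset delay of SRS expansion (s).
#' @param is_compression_amp Inner-segment compression amplitude (nm).
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(type_I_amp = 50,
                          type_I_peak_latency = 0.5,
                          type_I_undershoot_amp = 15,
                          type_I_undershoot_latency = 10,
                          type_I_recovery_time = 30,
                          type_II_rate = 12,
                          type_II_onset = 1.0,
                          srs_peak_amp = 250,
                          srs_peak_latency = 20,
                          srs_slope = 15,
                          srs_onset = 1.5,
                          is_compression_amp = 10) {
  stopifnot(
    type_I_peak_latency > 0, type_I_undershoot_latency > 0,
    srs_peak_latency > 0, type_II_onset >= 0, srs_onset >= 0,
    srs_peak_latency > type_I_peak_latency
  )
  amps <- c(type_I_amp, type_I_undershoot_amp, type_II_rate,
            srs_peak_amp, srs_slope, is_compression_amp)
  if (!all(is.finite(amps))) stop("kinetics amplitudes must be finite")
  structure(list(
    type_I_amp = type_I_amp,
    type_I_peak_latency = type_I_peak_latency,
    type_I_undershoot_amp = type_I_undershoot_amp,
    type_I_undershoot_latency = type_I_undershoot_latency,
    type_I_recovery_time = type_I_recovery_time,
    type_II_rate = type_II_rate,
    type_II_onset = type_II_onset,
    srs_peak_amp = srs_peak_amp,
    srs_peak_latency = srs_peak_latency,
    srs_slope = srs_slope,
    srs_onset = srs_onset,
    is_compression_amp = is_compression_amp
  ), class = "kinetics_spec")
}

#' Bulk-motion specification for the simulator
#'
#' Rigid in-plane bulk motion: a slow drift over the recording plus
#' heartbeat- and respiration-locked oscillations. The study system names
#' these artifacts without printing their frequencies; defaults use typical
#' anesthetized-rat physiology (heartbeat ~5 Hz, respiration ~1 Hz).
#'
#' @param drift_amplitude Peak-to-peak slow axial drift over the recording (px).
#' @param heartbeat_freq Heartbeat frequency (Hz).
#' @param heartbeat_amp Heartbeat oscillation amplitude (px).
#' @param respiration_freq Respiration frequency (Hz).
#' @param respiration_amp Respiration oscillation amplitude (px).
#' @param lateral_fraction Lateral motion amplitude as a fraction of axial.
#' @param seed Integer seed controlling the oscillation phases.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(drift_amplitude = 1.5,
                        heartbeat_freq = 5,
                        heartbeat_amp = 0.3,
                        respiration_freq = 1,
                        respiration_amp = 0.2,
                        lateral_fraction = 0.5,
                        seed = 1L) {
  stopifnot(heartbeat_freq >= 0, respiration_freq >= 0,
            drift_amplitude >= 0, heartbeat_amp >= 0, respiration_amp >= 0)
  structure(list(
    drift_amplitude = drift_amplitude,
    heartbeat_freq = heartbeat_freq, heartbeat_amp = heartbeat_amp,
    respiration_freq = respiration_freq, respiration_amp = respiration_amp,
    lateral_fraction = lateral_fraction, seed = as.integer(seed)
  ), class = "motion_spec")
}

#' Optics specification for the simulated OCT system
#'
#' @param center_wavelength_nm Source center wavelength (nm).
#' @param axial_resolution_um Axial resolution in tissue (um, FWHM).
#' @param axial_pixel_pitch_um Axial pixel pitch in air (um). The default
#'   corresponds to a 1.07 mm image depth sampled over 1024 depth pixels.
#' @param lateral_beam_diameter_um Beam diameter at the retina (um, 1/e^2).
#' @param lateral_pixel_pitch_um Lateral pixel pitch (um).
#' @param snr_profile Named numeric vector of per-layer linear amplitude SNR
#'   (layer field amplitude over the additive-noise standard deviation).
#' @param tissue_refractive_index Refractive index used to map tissue
#'   resolution to air-equivalent optical path.
#' @return An object of class `optics_spec`.
#' @export
optics_spec <- function(center_wavelength_nm = 840,
                        axial_resolution_um = 2.0,
                        axial_pixel_pitch_um = 1.05,
                        lateral_beam_diameter_um = 12.2,
                        lateral_pixel_pitch_um = 0.8,
                        snr_profile = c(ELM = 20, ISOS = 40, OStips = 25,
                                        RPE = 25, BrM = 35),
                        tissue_refractive_index = 1.41) {
  stopifnot(center_wavelength_nm > 0, axial_pixel_pitch_um > 0,
            lateral_beam_diameter_um > 0, lateral_pixel_pitch_um > 0)
  # the PSF must be resolvable on the depth grid
  if (!(axial_pixel_pitch_um < axial_resolution_um * 2))
    stop("axial pixel pitch must undersample the axial PSF (pitch < 2 x resolution)")
  structure(list(
    center_wavelength_nm = center_wavelength_nm,
    axial_resolution_um = axial_resolution_um,
    axial_pixel_pitch_um = axial_pixel_pitch_um,
    lateral_beam_diameter_um = lateral_beam_diameter_um,
    lateral_pixel_pitch_um = lateral_pixel_pitch_um,
    snr_profile = snr_profile,
    tissue_refractive_index = tissue_refractive_index
  ), class = "optics_spec")
}

#' Acquisition-protocol specification
#'
#' Three standard protocols: repeated B-scans at 200 Hz for 5 s (protocol 1),
#' repeated B-scans at 25 Hz for 55 s (protocol 2), and repeated volumes of
#' 25 B-scans at 8 volumes/s for 5 s (protocol 3).
#'
#' @param a_scans_per_bscan A-scans per B-scan.
#' @param bscan_rate B-scan rate (Hz).
#' @param bscans_per_volume B-scans per volume (volume protocols).
#' @param volume_rate Volume rate (Hz, volume protocols).
#' @param duration Total recording duration (s).
#' @param baseline Pre-stimulus baseline duration (s).
#' @param id Protocol identifier string.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(a_scans_per_bscan = 1000,
                          bscan_rate = 200,
                          bscans_per_volume = NA_integer_,
                          volume_rate = NA_real_,
                          duration = 5,
                          baseline = 1,
                          id = "custom") {
  if (!(duration > baseline && baseline >= 0))
    stop("protocol requires duration > baseline >= 0")
  if (!(bscan_rate > 0)) stop("bscan_rate must be > 0")
  if (!is.na(volume_rate) && volume_rate <= 0) stop("volume_rate must be > 0")
  structure(list(
    a_scans_per_bscan = a_scans_per_bscan,
    bscan_rate = bscan_rate,
    bscans_per_volume = bscans_per_volume,
    volume_rate = volume_rate,
    duration = duration,
    baseline = baseline,
    id = id
  ), class = "protocol_spec")
}

#' Standard acquisition protocols
#'
#' @param which One of `"protocol1"`, `"protocol2"`, `"protocol3"`.
#' @return A [protocol_spec()].
#' @export
org_protocol <- function(which = c("protocol1", "protocol2", "protocol3")) {
  which <- match.arg(which)
  switch(which,
    protocol1 = protocol_spec(1000, 200, duration = 5, baseline = 1,
                              id = "protocol1"),
    protocol2 = protocol_spec(1000, 25, duration = 55, baseline = 5,
                              id = "protocol2"),
    protocol3 = protocol_spec(1000, 25 * 8, bscans_per_volume = 25,
                              volume_rate = 8, duration = 5, baseline = 1,
                              id = "protocol3")
  )
}

#' Conversion parameters between phase, OPL and physical deformation
#'
#' @param center_wavelength_nm Center wavelength (nm).
#' @param tissue_refractive_index Refractive index used when converting OPL
#'   change into physical deformation (default 1.41).
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(center_wavelength_nm = 840,
                              tissue_refractive_index = 1.41) {
  stopifnot(center_wavelength_nm > 0, tissue_refractive_index >= 1)
  structure(list(center_wavelength_nm = center_wavelength_nm,
                 tissue_refractive_index = tissue_refractive_index),
            class = "conversion_params")
}

# --- kinetic templates ------------------------------------------------------

# gamma-shaped unit-peak kernel: (t/tp)^k exp(k (1 - t/tp)) for t > 0
gamma_kernel <- function(t, t_peak, shape) {
  y <- numeric(length(t))
  pos <- t > 0
  u <- t[pos] / t_peak
  y[pos] <- u^shape * exp(shape * (1 - u))
  y
}

# smooth ramp: linear rise at rate `slope` from t0, blended by a half-cosine
# into a zero-slope peak of amplitude `amp` at tp, then Gaussian-tailed decay
ramp_peak_template <- function(t, amp, slope, t0, tp, tau_rec = 40) {
  stopifnot(tp > t0, amp > 0, slope > 0)
  span <- slope * (tp - t0)
  if (span <= amp) {
    # rate-limited: pure smoothstep to the reachable amplitude
    amp <- span * 2 / pi # half-cosine peak consistent with the ramp rate
    L <- tp - t0
    tb <- t0
  } else {
    L <- (span - amp) / (slope * (1 - 2 / pi))
    L <- min(L, tp - t0)
    tb <- tp - L
  }
  sb <- slope * (tb - t0)
  y <- numeric(length(t))
  ramp <- t > t0 & t <= tb
  y[ramp] <- slope * (t[ramp] - t0)
  blend <- t > tb & t <= tp
  y[blend] <- amp - (amp - sb) / 2 * (1 + cos(pi * (t[blend] - tb) / L))
  rec <- t > tp
  y[rec] <- amp * exp(-((t[rec] - tp) / tau_rec)^2)
  y
}

#' Evaluate the programmed kinetic templates
#'
#' Returns, for a vector of times relative to stimulus onset, the programmed
#' OPL changes (nm) of the elementary responses: the fast Type-I OS
#' elongation (with undershoot), the slow Type-II rise, the SRS expansion,
#' and the inner-segment compression. All are identically zero before onset.
#'
#' @param kinetics A [kinetics_spec()].
#' @param t Numeric vector of times (s), 0 = stimulus onset.
#' @return A list of numeric vectors `type_I`, `type_II`, `srs`, `is_comp`.
#' @export
kinetics_templates <- function(kinetics, t) {
  k <- kinetics
  type_I <- k$type_I_amp * gamma_kernel(t, k$type_I_peak_latency, 3) -
    k$type_I_undershoot_amp * gamma_kernel(t, k$type_I_undershoot_latency, 2)
  t2_amp <- 0.75 * k$type_II_rate * (k$srs_peak_latency - k$type_II_onset)
  type_II <- ramp_peak_template(t, t2_amp, k$type_II_rate,
                                k$type_II_onset, k$srs_peak_latency)
  srs <- ramp_peak_template(t, k$srs_peak_amp, k$srs_slope,
                            k$srs_onset, k$srs_peak_latency)
  is_comp <- k$is_compression_amp *
    smoothstep01(t, 0, 1.5)
  list(type_I = type_I, type_II = type_II, srs = srs, is_comp = is_comp)
}

smoothstep01 <- function(t, t0, t1) {
  u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  u * u * (3 - 2 * u)
}
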