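test_that("spec constructors enforce their invariants", {
  expect_error(protocol_spec(duration = 1, baseline = 2), "duration > baseline")
  expect_error(protocol_spec(bscan_rate = 0), "bscan_rate")
  expect_error(kinetics_spec(srs_peak_latency = 0.1), ">")
  expect_error(optics_spec(axial_pixel_pitch_um = 10), "pitch")
  expect_error(simulate_phase_traces(kinetics_spec(), org_protocol("protocol1"),
                                     n_traces_per_class = 0), "n_traces")
  expect_error(simulate_phase_traces(kinetics_spec(), org_protocol("protocol1"),
                                     noise_sd_mrad = -1), "noise_sd")
})

test_that("standard protocols reproduce the published acquisition geometry", {
  p1 <- org_protocol("protocol1")
  expect_equal(p1$bscan_rate, 200)
  expect_equal(length(protocol_times(p1)), 1000)
  p2 <- org_protocol("protocol2")
  expect_equal(length(protocol_times(p2)), 1375) # 55 s at 25 B-scans/s
  p3 <- org_protocol("protocol3")
  # 40 repeated volumes at 8 volumes/s over 5 s
  expect_equal(length(protocol_times(p3)), 40)
})

test_that("noise-free Type-I trace peaks at the programmed latency", {
  kin <- kinetics_spec()
  prot <- org_protocol("protocol1")
  ts <- simulate_phase_traces(kin, prot, n_traces_per_class = 2,
                              noise_sd_mrad = 0, seed = 1)
  i <- which(ts$class == "type_I")[1]
  pk_t <- ts$t[which.max(ts$phase[i, ])]
  expect_lt(abs(pk_t - kin$type_I_peak_latency), 1 / prot$bscan_rate + 1e-12)
  # flat zero-mean pre-stimulus baseline
  expect_equal(max(abs(ts$phase[i, ts$t < 0])), 0)
})

test_that("same seed gives bit-identical trace tables", {
  a <- simulate_phase_traces(kinetics_spec(), org_protocol("protocol1"),
                             n_traces_per_class = 20, seed = 9)
  b <- simulate_phase_traces(kinetics_spec(), org_protocol("protocol1"),
                             n_traces_per_class = 20, seed = 9)
  expect_identical(a$phase, b$phase)
  expect_identical(a$depth_px_to_brm, b$depth_px_to_brm)
})

test_that("pre-stimulus sample SD matches the generating noise SD", {
  ts <- simulate_phase_traces(kinetics_spec(), org_protocol("protocol1"),
                              n_traces_per_class = 500, noise_sd_mrad = 30,
                              seed = 3)
  # outlier-class baselines are deliberately not flat; measure on the rest
  flat <- ts$class != "outlier"
  pre <- ts$phase[flat, ts$t < 0]
  measured <- stats::sd(as.vector(pre)) * 1000
  expect_lt(abs(measured - 30) / 30, 0.10)
})

test_that("intermediate traces are convex template mixtures, depths ordered", {
  ts <- simulate_phase_traces(kinetics_spec(), org_protocol("protocol1"),
                              n_traces_per_class = 200, noise_sd_mrad = 0,
                              seed = 5)
  d_I <- mean(ts$depth_px_to_brm[ts$class == "type_I"])
  d_II <- mean(ts$depth_px_to_brm[ts$class == "type_II"])
  expect_gt(d_I - d_II, 3) # Type-II just anterior to BrM, >= 3 px separation
  # an intermediate trace lies between the two pure templates pointwise
  i <- which(ts$class == "intermediate")[1]
  tI <- ts$phase[which(ts$class == "type_I")[1], ]
  tII <- ts$phase[which(ts$class == "type_II")[1], ]
  lo <- pmin(tI, tII) - 1e-12; hi <- pmax(tI, tII) + 1e-12
  expect_true(all(ts$phase[i, ] >= lo & ts$phase[i, ] <= hi))
})

test_that("layer geometry violations are rejected", {
  bad <- list(depths_px = c(ELM = 50, ISOS = 40, OStips = 60, RPE = 66,
                            BrM = 72))
  expect_error(simulate_bscan_series(bad, protocol = test_protocol()),
               "strictly increasing")
  off <- list(depths_px = c(ELM = 40, ISOS = 52, OStips = 60, RPE = 66,
                            BrM = 500))
  expect_error(simulate_bscan_series(off, protocol = test_protocol()),
               "depth grid")
})

test_that("static scene yields frames identical up to additive noise", {
  prot <- test_protocol(n_x = 48, rate = 20, duration = 1, baseline = 0.2)
  ser <- simulate_bscan_series(kinetics = static_kinetics(),
                               motion = no_motion(), optics = bright_optics(),
                               protocol = prot, seed = 2,
                               n_depth = 96, n_lateral = 48)
  d <- ser$frames[, , 1] - ser$frames[, , 2]
  # residual difference is only the unit-SD additive noise (signal ~1e6)
  expect_lt(stats::sd(Re(d)), 2)
  expect_gt(stats::sd(Re(d)), 0.2)
})

test_that("ground-truth record echoes the programmed kinetics", {
  kin <- kinetics_spec(type_I_amp = 100, type_I_undershoot_amp = 0)
  prot <- test_protocol(n_x = 32, rate = 50, duration = 2, baseline = 0.5)
  ser <- simulate_bscan_series(kinetics = kin, motion = no_motion(),
                               protocol = prot, seed = 4,
                               n_depth = 96, n_lateral = 32)
  expect_equal(max(ser$ground_truth$signals$OS), 100, tolerance = 1e-9)
  expect_equal(ser$ground_truth$signals$SRS,
               ser$ground_truth$signals$TypeII +
                 ser$ground_truth$signals$ELM_rel_ISOS,
               tolerance = 1e-9)
})

test_that("a single moved reflector shifts phase by 4*pi*dOPL/lambda", {
  kin <- kinetics_spec(type_I_amp = 100, type_I_undershoot_amp = 1e-9,
                       srs_peak_amp = 1e-9, srs_slope = 1e-9,
                       type_II_rate = 1e-9, is_compression_amp = 0)
  prot <- test_protocol(n_x = 8, rate = 100, duration = 1.5, baseline = 0.5)
  ser <- simulate_bscan_series(delta_layers(), kin, no_motion(),
                               bright_optics(), prot, seed = 5,
                               n_depth = 192, n_lateral = 8)
  x <- 3
  phi <- Arg(ser$frames[60, x, ] * Conj(ser$frames[40, x, ]))
  k0 <- which.min(abs(ser$t))
  ipk <- which.max(ser$ground_truth$signals$OS)
  expect_equal(phi[ipk] - phi[k0], 4 * pi * 100 / 840, tolerance = 1e-3)
})

test_that("simulated speckle in a thick band is fully developed", {
  lay <- list(depths_px = c(ELM = 20, ISOS = 35, OStips = 70, RPE = 120,
                            BrM = 140),
              half_width_px = c(ELM = 0.5, ISOS = 0.8, OStips = 25,
                                RPE = 1.2, BrM = 0.5))
  op <- optics_spec(snr_profile = c(ELM = 20, ISOS = 40, OStips = 200,
                                    RPE = 25, BrM = 35))
  prot <- test_protocol(n_x = 160, rate = 10, duration = 0.3, baseline = 0.1)
  ser <- simulate_bscan_series(lay, static_kinetics(), no_motion(), op, prot,
                               seed = 8, n_depth = 192, n_lateral = 160)
  I <- Mod(ser$frames[, , 1])^2
  reg <- I[56:84, ] # interior of the homogeneous band
  expect_gte(length(reg), 4000)
  contrast <- stats::sd(reg) / mean(reg)
  # Rayleigh statistics: unit contrast for fully developed speckle
  expect_lt(abs(contrast - 1), 0.10)
})

test_that("volume simulator emits the protocol-3 volume count and echoes maps", {
  prot <- org_protocol("protocol3")
  prot$a_scans_per_bscan <- 24
  prot$bscans_per_volume <- 4
  amp <- matrix(1, 2, 2)
  amp[2, 1] <- 2
  vol <- simulate_volume_series(kinetics = kinetics_spec(type_I_amp = 50),
                                motion = no_motion(),
                                protocol = prot, amplitude_map = amp,
                                seed = 6, n_depth = 96, n_lateral = 24)
  expect_equal(dim(vol$frames)[4], 40) # 8 volumes/s x 5 s
  expect_identical(vol$ground_truth$amplitude_map, amp)
  # doubled cell is reflected exactly in the ground truth signals
  gt11 <- vol$ground_truth$signals_by_position[[1]][[1]]$OS
  gt21 <- vol$ground_truth$signals_by_position[[1]][[2]]$OS
  expect_equal(max(gt21), 2 * max(gt11), tolerance = 1e-9)
})

test_that("trace tables round-trip through TSV", {
  ts <- simulate_phase_traces(kinetics_spec(), test_protocol(rate = 50,
                                                             duration = 1.5,
                                                             baseline = 0.5),
                              n_traces_per_class = 3, seed = 11)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_trace_table(ts, p)
  back <- read_trace_table(p)
  expect_equal(back$phase, ts$phase, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$class, ts$class)
})
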