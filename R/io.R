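REQUIRED_META <- c("center_wavelength_nm", "pixel_pitch_um_air",
                   "frame_rate_hz", "stimulus_onset_s", "protocol_id",
                   "schema_version")
SCHEMA_VERSION <- "v1"

#' Write / read a complex frame series container
#'
#' The container is a directory holding `meta.json` (all acquisition
#' attributes and the array shape), `frames.bin` (float32 interleaved
#' real/imag pairs in column-major order - a lossless float32 round trip),
#' an optional `t.tsv` time axis, and optional ground-truth tables.
#'
#' @param series A `frame_series`.
#' @param path Directory path for the container.
#' @return `write_frameseries` returns `path` invisibly; `read_frameseries`
#'   returns the `frame_series`.
#' @export
write_frameseries <- function(series, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- series$meta
  meta$schema_version <- meta$schema_version %||% SCHEMA_VERSION
  meta$dim <- dim(series$frames)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(path, "frames.bin"), "wb")
  on.exit(close(con))
  v <- as.vector(series$frames)
  inter <- as.numeric(rbind(Re(v), Im(v)))
  writeBin(inter, con, size = 4)
  if (!is.null(series$t))
    utils::write.table(data.frame(t_s = series$t),
                       file.path(path, "t.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(series$ground_truth$shifts))
    utils::write.table(series$ground_truth$shifts,
                       file.path(path, "ground_truth_shifts.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(series$ground_truth$signals))
    utils::write.table(series$ground_truth$signals,
                       file.path(path, "ground_truth_signals.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frameseries
#' @export
read_frameseries <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a frame-series container (no meta.json): ",
                             path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  miss <- setdiff(REQUIRED_META, names(meta))
  if (length(miss))
    stop("frame-series container missing attribute(s): ",
         paste(miss, collapse = ", "))
  if (!identical(meta$schema_version, SCHEMA_VERSION))
    stop("frame-series schema version mismatch: file has '",
         meta$schema_version, "', this build reads '", SCHEMA_VERSION,
         "'; regenerate or upgrade the container")
  dm <- as.integer(meta$dim)
  n <- prod(dm)
  con <- file(file.path(path, "frames.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = 2 * n, size = 4)
  fr <- array(complex(real = raw[seq(1, 2 * n, 2)],
                      imaginary = raw[seq(2, 2 * n, 2)]), dim = dm)
  meta$dim <- NULL
  out <- list(frames = fr, meta = meta)
  tf <- file.path(path, "t.tsv")
  if (file.exists(tf)) out$t <- utils::read.delim(tf)$t_s
  gts <- file.path(path, "ground_truth_shifts.tsv")
  gsg <- file.path(path, "ground_truth_signals.tsv")
  gt <- list()
  if (file.exists(gts)) gt$shifts <- utils::read.delim(gts)
  if (file.exists(gsg)) gt$signals <- utils::read.delim(gsg)
  if (length(gt)) out$ground_truth <- gt
  structure(out, class = "frame_series")
}

#' Default run configuration
#'
#' Every pipeline constant surfaced as a named key with its default: QC
#' threshold 60 mrad, classification low-pass 10 Hz, outlier coverage 2%
#' with threshold divisor 5, 5 ms classification grid over a -1.0 to +3.5 s
#' window, 3 clusters, refractive index 1.41, center wavelength 840 nm,
#' registration upsampling 100 (taper off by default), SRS slope window
#' 2-10 s.
#'
#' @return Nested named list.
#' @export
org_default_config <- function() {
  list(
    protocol = "protocol1",
    seed = 1L,
    registration = list(upsample = 100L, taper = 0,
                        reference_index = NULL),
    segmentation = list(max_jump = 2L, search_half_width = 6L,
                        min_separation_px = 4L, n_mixed_bands = 5L),
    filtering = list(bandstop_bands = list(c(4.5, 5.5), c(0.8, 1.2)),
                     lowpass_hz = 10, trim_samples = 10L),
    qc = list(prestim_sd_threshold_mrad = 60),
    features = list(window_s = c(-1.0, 3.5), dt_s = 0.005,
                    n_components = 2L),
    outliers = list(coverage = 0.02, threshold_divisor = 5),
    clustering = list(n_clusters = 3L),
    svm = list(cost_grid = c(1, 10, 100), gamma_grid = c(0.25, 0.5, 1, 2, 4),
               folds = 10L),
    conversion = list(center_wavelength_nm = 840,
                      tissue_refractive_index = 1.41),
    metrics = list(srs_slope_window_s = c(2, 10), peak_window_s = c(0, 3)),
    enface = list(fov_deg = 12, cell_deg = c(1.2, 0.48)),
    bleach = list(photosensitivity_um2 = org_constants()$photosensitivity_um2)
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to
#' [org_default_config()] values.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL) {
  def <- org_default_config()
  if (is.null(path)) return(def)
  usr <- yaml::read_yaml(path)
  bad <- setdiff(names(usr), names(def))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(usr)) {
    if (is.list(def[[k]]) && is.list(usr[[k]])) {
      badk <- setdiff(names(usr[[k]]), names(def[[k]]))
      if (length(badk))
        stop("unknown config key(s) under '", k, "': ",
             paste(badk, collapse = ", "))
      def[[k]] <- utils::modifyList(def[[k]], usr[[k]])
    } else def[[k]] <- usr[[k]]
  }
  def
}

#' Command-line pipeline dispatcher
#'
#' Thin subcommand interface over the package functions, intended to be
#' called from a two-line Rscript wrapper (see
#' `system.file("scripts", "org-pipeline.R", package = "retorg")`).
#' Subcommands: `simulate`, `register`, `segment`, `traces`, `cluster`,
#' `classify`, `quantify`, `enface`. Each stage reads the previous stage's
#' artifact from `--in` and writes its own under `--out`; a JSON run log
#' (config, seed, package version) is written next to each output. Identical
#' config and seed give identical outputs.
#'
#' @param args Character vector of command-line arguments
#'   (subcommand, then `--key value` pairs: `in`, `out`, `config`, `seed`).
#' @return Exit status, 0 on success (invisibly).
#' @export
org_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop("usage: org-pipeline <simulate|register|segment|traces|cluster|classify|quantify|enface> [--in PATH] [--out PATH] [--config YAML] [--seed INT]")
  sub <- args[1]
  opt <- parse_cli_opts(args[-1])
  cfg <- read_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  need_in <- function() {
    if (is.null(opt$`in`) || !file.exists(opt$`in`))
      stop("[", sub, "] missing upstream artifact: ",
           opt$`in` %||% "(no --in given)")
    opt$`in`
  }
  out <- opt$out %||% stop("[", sub, "] --out required")
  ok <- switch(sub,
    simulate = cli_simulate(cfg, out),
    register = cli_register(cfg, need_in(), out),
    segment = cli_segment(cfg, need_in(), out),
    traces = cli_traces(cfg, need_in(), out),
    cluster = cli_cluster(cfg, need_in(), out),
    classify = cli_classify(cfg, need_in(), opt$model, out),
    quantify = cli_quantify(cfg, need_in(), out),
    enface = cli_enface(cfg, need_in(), out),
    stop("unknown subcommand: ", sub)
  )
  write_run_log(cfg, sub, out)
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("missing value for --", key)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  opt
}

write_run_log <- function(cfg, stage, out) {
  log_path <- paste0(sub("/$", "", out), ".runlog.json")
  jsonlite::write_json(list(
    stage = stage,
    config_hash = digest_config(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("retorg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), log_path, auto_unbox = TRUE)
  invisible(log_path)
}

digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small stable checksum without extra deps
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(as.character(s)))) %% 2^31
}

cli_simulate <- function(cfg, out) {
  series <- simulate_bscan_series(
    protocol = org_protocol(cfg$protocol), seed = cfg$seed,
    optics = optics_spec(center_wavelength_nm =
                           cfg$conversion$center_wavelength_nm)
  )
  write_frameseries(series, out)
}

cli_register <- function(cfg, inp, out) {
  series <- read_frameseries(inp)
  reg <- register_series(series,
                         reference_index = cfg$registration$reference_index,
                         upsample = cfg$registration$upsample,
                         taper = cfg$registration$taper)
  write_frameseries(reg, out)
  write_shift_trace(reg$shifts, file.path(out, "shifts.tsv"))
}

cli_segment <- function(cfg, inp, out) {
  series <- read_frameseries(inp)
  img <- despeckle(series, dim(series$frames)[3])
  b <- segment_layers(img, cfg$segmentation)
  write_boundaries(b, out)
}

cli_traces <- function(cfg, inp, out) {
  series <- read_frameseries(inp)
  img <- despeckle(series, dim(series$frames)[3])
  b <- segment_layers(img, cfg$segmentation)
  tr <- extract_mixed_layer_traces(series, b)
  qc <- qc_exclude(tr, cfg$qc$prestim_sd_threshold_mrad)
  ts <- traces_to_set(qc$retained, series)
  write_trace_table(ts, out)
}

cli_cluster <- function(cfg, inp, out) {
  ts <- read_trace_table(inp)
  disc <- discover_patterns(ts$phase, ts$t, ts$depth_px_to_brm,
                            window = cfg$features$window_s,
                            dt_target = cfg$features$dt_s,
                            coverage = cfg$outliers$coverage,
                            n_clusters = cfg$clustering$n_clusters)
  clf <- train_classifier(disc$features, disc$labels,
                          cost_grid = cfg$svm$cost_grid,
                          gamma_grid = cfg$svm$gamma_grid,
                          folds = cfg$svm$folds, seed = cfg$seed)
  save_model(bundle_model(disc, clf), out)
  labels_path <- paste0(sub("\\.rds$", "", out), "_labels.tsv")
  utils::write.table(
    data.frame(trace_id = ts$trace_id, label = disc$labels,
               pc1 = disc$features$pc1, pc2 = disc$features$pc2,
               depth_norm = disc$features$depth_norm),
    labels_path, sep = "\t", row.names = FALSE, quote = FALSE)
}

cli_classify <- function(cfg, inp, model_path, out) {
  if (is.null(model_path) || !file.exists(model_path))
    stop("[classify] missing model artifact (--model)")
  ts <- read_trace_table(inp)
  model <- load_model(model_path)
  res <- classify_new(ts$phase, ts$t, ts$depth_px_to_brm, model)
  utils::write.table(
    data.frame(trace_id = ts$trace_id, label = res$labels,
               pc1 = res$features$pc1, pc2 = res$features$pc2,
               depth_norm = res$features$depth_norm),
    out, sep = "\t", row.names = FALSE, quote = FALSE)
}

cli_quantify <- function(cfg, inp, out) {
  ts <- read_trace_table(inp)
  params <- conversion_params(cfg$conversion$center_wavelength_nm,
                              cfg$conversion$tissue_refractive_index)
  by_class <- split(seq_along(ts$class), ts$class)
  rows <- list()
  for (cls in names(by_class)) {
    m <- colMeans(ts$phase[by_class[[cls]], , drop = FALSE])
    sig <- org_signal(cls, ts$t, phase_to_opl(m, params),
                      n_pixels = length(by_class[[cls]]))
    pm <- peak_metrics(sig, cfg$metrics$peak_window_s)
    rows[[cls]] <- data.frame(
      structure = cls, metric = c("peak_amplitude_nm", "peak_latency_s"),
      value = c(pm$peak_amplitude_nm, pm$peak_latency_s), se = NA_real_)
  }
  utils::write.table(do.call(rbind, rows), out, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

cli_enface <- function(cfg, inp, out) {
  df <- utils::read.delim(inp)
  need <- c("x_deg", "y_deg", "type", "t_s", "dopl_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("[enface] input table missing column(s): ",
         paste(miss, collapse = ", "))
  em <- enface_map(df, fov_deg = cfg$enface$fov_deg,
                   cell_deg = cfg$enface$cell_deg)
  utils::write.table(em$cells, out, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

# helper used by the CLI: one trace per mixed-layer pixel column band
extract_mixed_layer_traces <- function(series, boundaries, stride = 4) {
  b <- boundaries$boundaries
  xs <- seq(2, ncol(b) - 1, by = stride)
  traces <- list()
  for (x in xs) {
    if (anyNA(b[, x])) next
    zr <- round(seq(b["ISOS", x] + 2, b["BrM", x] - 1, by = 2))
    for (z in zr)
      traces[[length(traces) + 1]] <-
        extract_phase_trace(series, c(z, x), boundaries)
  }
  traces
}

traces_to_set <- function(traces, series) {
  t0 <- traces[[1]]$t
  phase <- do.call(rbind, lapply(traces, function(tr) tr$phi))
  structure(list(
    t = t0, phase = phase,
    class = rep("unlabeled", length(traces)),
    depth_px_to_brm = vapply(traces, function(tr) tr$depth_px_to_brm,
                             numeric(1)),
    fs = traces[[1]]$fs,
    center_wavelength_nm = series$meta$center_wavelength_nm,
    noise_sd_mrad = NA_real_, protocol_id = series$meta$protocol_id,
    trace_id = sprintf("tr%05d", seq_along(traces))
  ), class = "org_trace_set")
}
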