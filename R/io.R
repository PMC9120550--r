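# Recording I/O: European Data Format (EDF), a flat binary float64
# dialect with a JSON sidecar, and delimited text. All readers return the
# canonical channels x samples orientation.

#' Read a continuous recording from disk
#'
#' @param path Input file.
#' @param format One of `"edf"`, `"binary-float"`, `"delimited-text"`.
#'   Default: guessed from the file extension (`.edf`, `.bin`, else text).
#' @param orientation For headerless formats: `"channels-by-samples"`
#'   (default) or `"samples-by-channels"`.
#' @param srate Sampling rate override (Hz); required for headerless
#'   formats, taken from the header for EDF.
#' @param sep Field separator for delimited text (default tab).
#' @return A [recording()].
#' @export
read_recording <- function(path, format = NULL,
                           orientation = c("channels-by-samples",
                                           "samples-by-channels"),
                           srate = NULL, sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    zap_abort("zap_unreadable_file", "file not found: %s", path)
  }
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", bin = "binary-float", "delimited-text")
  }
  switch(format,
    "edf" = read_edf(path),
    "binary-float" = read_binary_float(path, orientation, srate),
    "delimited-text" = read_delimited(path, orientation, srate, sep),
    zap_abort("zap_unreadable_file", "unknown format '%s'", format))
}

#' Write a recording to disk
#'
#' @param rec A [recording()].
#' @param path Output file.
#' @inheritParams read_recording
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL,
                            orientation = "channels-by-samples", sep = "\t") {
  stopifnot(inherits(rec, "recording"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", bin = "binary-float", "delimited-text")
  }
  switch(format,
    "edf" = write_edf(rec, path),
    "binary-float" = write_binary_float(rec, path, orientation),
    "delimited-text" = write_delimited(rec, path, orientation, sep),
    zap_abort("zap_write_failed", "unknown format '%s'", format))
  invisible(path)
}

# ---- binary float64 dialect: little-endian, channel-major, JSON sidecar ----

sidecar_path <- function(path) paste0(path, ".json")

read_binary_float <- function(path, orientation, srate) {
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
  if (is.null(srate)) srate <- meta$srate
  if (is.null(srate)) {
    zap_abort("zap_missing_srate",
              "no srate given and no sidecar %s; cannot interpret %s", sc, path)
  }
  n_ch <- meta$n_channels
  if (is.null(n_ch)) {
    zap_abort("zap_unreadable_file", "sidecar %s lacks n_channels", sc)
  }
  sz <- file.size(path)
  vals <- readBin(path, "double", n = sz %/% 8, size = 8, endian = "little")
  if (length(vals) %% n_ch != 0) {
    zap_abort("zap_inconsistent_channels",
              "%d values not divisible by %d channels", length(vals), n_ch)
  }
  if (!is.null(meta$orientation)) orientation <- meta$orientation
  m <- if (orientation == "channels-by-samples") {
    matrix(vals, nrow = n_ch, byrow = TRUE)
  } else {
    t(matrix(vals, ncol = n_ch, byrow = TRUE))
  }
  labels <- meta$channel_labels
  if (!is.null(labels) && length(labels) == 0) labels <- NULL
  recording(m, srate, labels)
}

write_binary_float <- function(rec, path, orientation) {
  vals <- if (orientation == "channels-by-samples") {
    as.vector(t(rec$data))   # channel-major: all samples of ch1, then ch2 ...
  } else {
    as.vector(rec$data)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = 8, endian = "little")
  jsonlite::write_json(list(n_channels = n_channels(rec),
                            n_samples = n_samples(rec),
                            srate = rec$srate,
                            orientation = orientation,
                            channel_labels = rec$channel_labels),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- delimited text ----

read_delimited <- function(path, orientation, srate, sep) {
  if (is.null(srate)) {
    zap_abort("zap_missing_srate", "srate must be given for delimited text")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) != 1) {
    zap_abort("zap_inconsistent_channels",
              "ragged rows: %s fields", paste(unique(lens), collapse = "/"))
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (anyNA(m)) {
    zap_abort("zap_unreadable_file", "non-numeric fields in %s", path)
  }
  if (orientation == "samples-by-channels") m <- t(m)
  recording(m, srate)
}

write_delimited <- function(rec, path, orientation, sep) {
  m <- rec$data
  if (orientation == "samples-by-channels") m <- t(m)
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- EDF (16-bit integer samples per the published specification) ----

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Read / write European Data Format files
#'
#' A minimal EDF implementation: continuous signals, identical sampling
#' rate across channels, 16-bit samples with per-signal physical scaling.
#' Precision on round trip is limited by the 16-bit quantization of the
#' channel's amplitude range.
#'
#' @param path File path.
#' @return `read_edf` returns a [recording()]; `write_edf` returns `path`
#'   invisibly.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_records <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  n_sig <- as.integer(fld(hdr, 253, 4))
  if (is.na(n_sig) || n_sig < 1 || is.na(n_records)) {
    zap_abort("zap_unreadable_file", "not a parseable EDF header: %s", path)
  }
  sig_hdr <- rawToChar(readBin(con, "raw", 256 * n_sig))
  # byte offsets of the per-signal field blocks (each field is stored for
  # all signals consecutively): label 16, transducer 80, dim 8, phys_min 8,
  # phys_max 8, dig_min 8, dig_max 8, prefilter 80, n_samples 8, reserved 32
  off <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 8, 80, 8)) * n_sig
  take <- function(block, width) {
    vapply(seq_len(n_sig), function(i) {
      trimws(substr(sig_hdr, block + (i - 1) * width + 1, block + i * width))
    }, character(1))
  }
  labels <- take(off[1], 16)
  phys_min <- as.numeric(take(off[4], 8))
  phys_max <- as.numeric(take(off[5], 8))
  dig_min <- as.numeric(take(off[6], 8))
  dig_max <- as.numeric(take(off[7], 8))
  spr <- as.integer(take(off[9], 8))
  if (length(unique(spr)) != 1) {
    zap_abort("zap_inconsistent_channels",
              "EDF signals have differing sampling rates")
  }
  srate <- spr[1] / rec_dur
  data <- matrix(0, n_sig, n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(n_sig)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little",
                     signed = TRUE)
      gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        phys_min[s] + (dig - dig_min[s]) * gain
    }
  }
  recording(data, srate, labels)
}

#' @rdname read_edf
#' @param rec A [recording()]; its sampling rate must be a whole number of
#'   samples per 1 s data record.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  spr <- rec$srate
  if (abs(spr - round(spr)) > 1e-9) {
    zap_abort("zap_write_failed",
              "EDF writer requires an integer sampling rate (got %g)", spr)
  }
  spr <- as.integer(round(spr))
  n_sig <- n_channels(rec)
  ns <- n_samples(rec)
  n_records <- ns %/% spr
  if (n_records < 1) {
    zap_abort("zap_write_failed", "recording shorter than one 1 s EDF record")
  }
  used <- n_records * spr
  labels <- rec$channel_labels
  if (is.null(labels)) labels <- sprintf("Ch%d", seq_len(n_sig))
  phys_min <- apply(rec$data[, 1:used, drop = FALSE], 1, min)
  phys_max <- apply(rec$data[, 1:used, drop = FALSE], 1, max)
  same <- phys_max - phys_min < .Machine$double.eps
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8),
                pad_field("synthetic", 80),
                pad_field("zaplinr export", 80),
                pad_field("01.01.26", 8),
                pad_field("00.00.00", 8),
                pad_field(256 * (1 + n_sig), 8),
                pad_field("", 44),
                pad_field(n_records, 8),
                pad_field(1, 8),
                pad_field(n_sig, 4))
  writeChar(hdr, con, eos = NULL)
  field_block <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_field, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field_block(labels, 16)
  field_block(rep("", n_sig), 80)
  field_block(rep("au", n_sig), 8)
  field_block(formatC(phys_min, format = "g", digits = 6), 8)
  field_block(formatC(phys_max, format = "g", digits = 6), 8)
  field_block(rep(dig_min, n_sig), 8)
  field_block(rep(dig_max, n_sig), 8)
  field_block(rep("", n_sig), 80)
  field_block(rep(spr, n_sig), 8)
  field_block(rep("", n_sig), 32)
  # re-parse the scaling exactly as a reader will, so the round trip only
  # loses the 16-bit quantization
  pm <- as.numeric(formatC(phys_min, format = "g", digits = 6))
  px <- as.numeric(formatC(phys_max, format = "g", digits = 6))
  for (r in seq_len(n_records)) {
    for (s in seq_len(n_sig)) {
      x <- rec$data[s, ((r - 1) * spr + 1):(r * spr)]
      dig <- round((x - pm[s]) / (px[s] - pm[s]) * (dig_max - dig_min) + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# ---- outputs ----

#' Write the cleaned recording, report and figures of a run
#'
#' @param result A [zap_clean()] result.
#' @param outdir Output directory (created if missing).
#' @param format Output format for the cleaned data (see
#'   [write_recording()]).
#' @param basename Stem for the output file names.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(result, outdir, format = "binary-float",
                          basename = "cleaned") {
  stopifnot(inherits(result, "zap_result"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!dir.exists(outdir)) zap_abort("zap_write_failed", "cannot create %s", outdir)
  ext <- switch(format, edf = "edf", "binary-float" = "bin",
                "delimited-text" = "tsv")
  data_path <- file.path(outdir, paste0(basename, ".", ext))
  write_recording(result$clean, data_path, format = format)
  report_path <- file.path(outdir, paste0(basename, "_report.json"))
  write_report_json(result$report, report_path)
  paths <- c(data = data_path, report = report_path)
  if (isTRUE(result$report$final_config$plot_results)) {
    for (i in seq_along(result$report$frequencies)) {
      f <- result$report$frequencies[[i]]$frequency
      fig_path <- file.path(outdir, sprintf("%s_fig_%gHz.png", basename, f))
      render_frequency_figure(result$report, i, fig_path)
      paths[sprintf("figure_%gHz", f)] <- fig_path
    }
  }
  invisible(paths)
}

#' Serialize a cleaning report to JSON
#'
#' Contains the final configuration (externally documented field
#' spellings), the raw and cleaned log spectra of all channels, and every
#' per-frequency / per-chunk analytics value, so a completed cleaning can
#' be audited and replicated from the document alone.
#'
#' @param report A `zap_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "zap_report"))
  cfg <- unclass(report$final_config)
  names(cfg) <- config_name_map[names(cfg)]
  spec_out <- function(s) list(freqs = s$freqs, log_psd = s$log_psd,
                               mean_log_psd = s$mean_log_psd)
  freqs <- lapply(report$frequencies, function(fr) {
    list(frequency = fr$frequency,
         sigma_used = fr$sigma_used,
         fixed_nremove_used = fr$fixed_nremove_used,
         n_passes = fr$n_passes,
         proportion_above_upper = fr$proportion_above_upper,
         proportion_below_lower = fr$proportion_below_lower,
         analytics = fr$analytics,
         n_removed = fr$n_removed,
         artifact_scores = fr$artifact_scores,
         chunk_peak_frequency = fr$chunk_peak_frequency,
         noise_present_flag = fr$noise_present_flag,
         chunk_boundaries = fr$chunk_boundaries,
         chunk_method = fr$chunk_method)
  })
  jsonlite::write_json(list(schema_version = 1L,
                            final_config = cfg,
                            raw_log_spectrum = spec_out(report$raw_log_spectrum),
                            clean_log_spectrum = spec_out(report$clean_log_spectrum),
                            frequencies = freqs),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
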