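# Record and configuration containers on disk: raw little-endian float32
# samples with a JSON metadata sidecar, CSV export, YAML/JSON configs.

record_meta_fields <- c("fs", "f0", "n_cycles", "pulse_starts", "medium",
                        "pressure_kPa", "replicate_id", "travel_time_us",
                        "envelope")

strip_ext <- function(path) sub("\\.(json|f32)$", "", path)

#' Write an acquisition record to disk
#'
#' Stores the waveform as raw little-endian float32 samples (`<path>.f32`)
#' and all metadata as a JSON sidecar (`<path>.json`). Samples are quantized
#' to single precision; metadata round-trips exactly.
#'
#' @param rec an `acquisition_record`.
#' @param path output basename (extensions are appended).
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(rec, path) {
  stopifnot(inherits(rec, "acquisition_record"))
  path <- strip_ext(path)
  con <- file(paste0(path, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4L, endian = "little")
  meta <- rec[record_meta_fields]
  meta$n_samples <- length(rec$samples)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read an acquisition record from disk
#'
#' @param path basename (or `.f32`/`.json` path) written by
#'   [write_acquisition()].
#' @return An `acquisition_record`.
#' @export
read_acquisition <- function(path) {
  path <- strip_ext(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".f32"), "rb")
  on.exit(close(con))
  samples <- readBin(con, numeric(), n = meta$n_samples, size = 4L,
                     endian = "little")
  structure(list(
    samples = samples, fs = meta$fs, f0 = meta$f0,
    n_cycles = meta$n_cycles, pulse_starts = as.integer(meta$pulse_starts),
    medium = meta$medium,
    pressure_kPa = if (is.null(meta$pressure_kPa)) NA_real_
                   else as.numeric(meta$pressure_kPa),
    replicate_id = as.integer(meta$replicate_id),
    travel_time_us = meta$travel_time_us, envelope = meta$envelope
  ), class = "acquisition_record")
}

#' Export an acquisition record as CSV
#'
#' Two columns, `time_us` and `amplitude`; intended for small fixtures.
#'
#' @param rec an `acquisition_record`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_acquisition_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

config_from_list <- function(lst, constructor) {
  if (!is.null(lst$harmonic_ratios)) {
    lst$harmonic_ratios <- unlist(lst$harmonic_ratios)
  }
  do.call(constructor, lst)
}

#' Read a simulation or bolus configuration file
#'
#' YAML or JSON (by extension) mirroring the [sim_config()] /
#' [bolus_config()] field names; `harmonic_ratios` is a map from order to
#' ratio.
#'
#' @param path configuration file.
#' @param type `"sim"` or `"bolus"`.
#' @return A `sim_config` or `bolus_config`.
#' @export
read_config <- function(path, type = c("sim", "bolus")) {
  type <- match.arg(type)
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  config_from_list(lst, if (type == "sim") sim_config else bolus_config)
}

#' Write a configuration file
#'
#' @param cfg a `sim_config` or `bolus_config`.
#' @param path output path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  lst <- unclass(cfg)
  if (!is.null(lst$harmonic_ratios)) {
    lst$harmonic_ratios <- as.list(lst$harmonic_ratios)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a harmonic table or replicate summary as CSV
#'
#' @param x a `harmonic_table` or `replicate_summary`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# Provenance sidecar written next to CLI outputs
write_provenance <- function(path, seed, config = NULL, inputs = NULL) {
  jsonlite::write_json(list(
    tool = "ucachar",
    version = as.character(utils::packageVersion("ucachar")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (!is.null(config)) unclass(config),
    inputs = inputs
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
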