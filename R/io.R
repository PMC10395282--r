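# Readers/writers: BrainVision triplet, tabular recording dialect,
# BIDS-style events.tsv, telemetry CSV, ground-truth JSON.

#' Write a recording to disk
#'
#' Two on-disk dialects are supported. `"brainvision"` writes the standard
#' `.vhdr`/`.vmrk`/`.eeg` triplet (IEEE float32, multiplexed, microvolts);
#' `"tabular"` writes a TSV with a small commented header, which round-trips
#' doubles bit-exactly.
#'
#' @param rec A [new_recording()] object.
#' @param path Base path; extensions are added per dialect.
#' @param format `"tabular"` (default) or `"brainvision"`.
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(rec, path, format = c("tabular", "brainvision")) {
  stopifnot(inherits(rec, "ContinuousRecording"))
  format <- match.arg(format)
  if (format == "tabular") {
    file <- paste0(sub("\\.tsv$", "", path), ".tsv")
    hdr <- c(sprintf("# driveload-recording v1"),
             sprintf("# sample_rate: %.17g", rec$sample_rate),
             sprintf("# n_channels: %d", nrow(rec$data)),
             sprintf("# unit: uV"))
    writeLines(hdr, file)
    # 17 significant digits round-trip IEEE doubles exactly
    chr <- matrix(formatC(t(rec$data), digits = 17, format = "g"),
                  ncol = nrow(rec$data),
                  dimnames = list(NULL, rec$channel_names))
    dt <- data.table::as.data.table(chr)
    data.table::fwrite(dt, file, sep = "\t", append = TRUE,
                       col.names = TRUE, quote = FALSE)
    return(invisible(file))
  }
  base <- sub("\\.(vhdr|eeg|vmrk)$", "", path)
  vhdr <- paste0(base, ".vhdr"); vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  nm <- basename(base)
  ch_lines <- sprintf("Ch%d=%s,,1,µV", seq_along(rec$channel_names),
                      rec$channel_names)
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "", "[Common Infos]",
               sprintf("DataFile=%s.eeg", nm),
               sprintf("MarkerFile=%s.vmrk", nm),
               "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
               sprintf("NumberOfChannels=%d", nrow(rec$data)),
               sprintf("SamplingInterval=%.10g", 1e6 / rec$sample_rate),
               "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
               "", "[Channel Infos]", ch_lines), vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]", sprintf("DataFile=%s.eeg", nm),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(rec$trigger_samples))
    mk <- c(mk, sprintf("Mk%d=Stimulus,D%.3f,%d,1,0",
                        seq_len(nrow(rec$trigger_samples)) + 1L,
                        rec$trigger_samples$distance_m,
                        rec$trigger_samples$sample + 1L))
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  invisible(c(vhdr, vmrk, eeg))
}

#' Load a recording from disk
#'
#' Reads either the tabular dialect written by [write_recording()] or a
#' BrainVision triplet (binary, IEEE float32, multiplexed — other encodings
#' are rejected). Units must be microvolts.
#'
#' @param path Path to a `.tsv` or `.vhdr` file.
#' @return A [new_recording()] object.
#' @export
load_recording <- function(path) {
  if (grepl("\\.tsv$", path)) return(.load_tabular(path))
  if (!grepl("\\.vhdr$", path))
    stop("load_recording expects a .tsv or .vhdr file: ", path)
  if (!file.exists(path)) stop("missing header file: ", path)
  lines <- readLines(path, warn = FALSE)
  get <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(ln)) stop("BrainVision header lacks ", key, " in ", path)
    sub(paste0("^", key, "="), "", ln[1])
  }
  if (get("DataFormat") != "BINARY" ||
      get("DataOrientation") != "MULTIPLEXED" ||
      get("BinaryFormat") != "IEEE_FLOAT_32")
    stop("unsupported BrainVision encoding in ", path,
         " (only BINARY/MULTIPLEXED/IEEE_FLOAT_32 is read)")
  n_ch <- as.integer(get("NumberOfChannels"))
  srate <- 1e6 / as.numeric(get("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labs <- vapply(parts, `[`, "", 1L)
  units <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "µV", "")
  if (!all(units %in% c("µV", "uV", "")))
    stop("unit mismatch in ", path, ": expected µV, got ",
         paste(unique(units), collapse = ","))
  if (length(labs) != n_ch)
    stop("channel list length disagrees with NumberOfChannels in ", path)
  known <- c(rownames(.montage_angles()))
  bad <- setdiff(labs, known)
  if (length(bad))
    stop("unknown channel label(s) in ", path, ": ", paste(bad, collapse = ", "))
  base <- sub("\\.vhdr$", "", path)
  eeg <- file.path(dirname(path), get("DataFile"))
  vmrk <- file.path(dirname(path), get("MarkerFile"))
  if (!file.exists(eeg)) stop("missing data file: ", eeg)
  if (!file.exists(vmrk)) stop("missing marker file: ", vmrk)
  n_bytes <- file.info(eeg)$size
  vals <- readBin(eeg, "numeric", n = n_bytes / 4L, size = 4L,
                  endian = "little")
  data <- matrix(vals, nrow = n_ch)
  mk <- readLines(vmrk, warn = FALSE)
  stim <- grep("^Mk[0-9]+=Stimulus", mk, value = TRUE)
  trig <- NULL
  if (length(stim)) {
    f <- strsplit(sub("^Mk[0-9]+=", "", stim), ",")
    trig <- data.frame(
      sample = vapply(f, function(p) as.integer(p[3]), 1L) - 1L,
      distance_m = vapply(f, function(p) as.numeric(sub("^D", "", p[2])), 1.0))
  }
  new_recording(data, srate, labs, trigger_samples = trig)
}

.load_tabular <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  sr_line <- grep("sample_rate:", hdr, value = TRUE)
  if (!length(sr_line)) stop("tabular recording lacks sample_rate header: ", path)
  srate <- as.numeric(sub(".*sample_rate:\\s*", "", sr_line[1]))
  dt <- data.table::fread(path, sep = "\t", skip = length(hdr))
  new_recording(t(as.matrix(dt)), srate, colnames(dt))
}

#' Write / read ocular events (BIDS-style events.tsv)
#'
#' Onsets are written in seconds with 1-ms precision; the round trip is
#' lossless at that precision.
#'
#' @param events An [ocular_events()] data.frame.
#' @param sample_rate Sampling rate used to convert samples to onsets.
#' @param path Output `.tsv` path.
#' @return `write_events()`: the path, invisibly. `load_events()`: an
#'   [ocular_events()] data.frame.
#' @export
write_events <- function(events, sample_rate, path) {
  onset <- sprintf("%.3f", events$sample / sample_rate)
  df <- data.frame(onset = onset, duration = rep("0.000", length(onset)),
                   trial_type = events$kind, direction = events$direction,
                   sacc_type = events$sacc_type,
                   quality = ifelse(is.na(events$quality), "n/a",
                                    sprintf("%.6f", events$quality)),
                   load = ifelse(is.na(events$load), "n/a", events$load))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
load_events <- function(path, sample_rate) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("onset", "trial_type")
  if (!all(need %in% names(df)))
    stop("events file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  onset <- suppressWarnings(as.numeric(df$onset))
  if (anyNA(onset))
    stop("malformed onset in events file row(s): ",
         paste(which(is.na(onset)), collapse = ", "))
  qual <- suppressWarnings(as.numeric(ifelse(df$quality == "n/a", NA, df$quality)))
  ld <- if ("load" %in% names(df)) ifelse(df$load == "n/a", NA, df$load)
        else NA_character_
  ocular_events(sample = round(onset * sample_rate), kind = df$trial_type,
                direction = df$direction %||% "none",
                sacc_type = df$sacc_type %||% "none",
                quality = qual, load = ld)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read telemetry CSV
#'
#' @param telemetry data.frame with `time_s`, `velocity_kmh`, `steering_deg`.
#' @param path Output `.csv` path.
#' @export
write_telemetry <- function(telemetry, path) {
  data.table::fwrite(telemetry[c("time_s", "velocity_kmh", "steering_deg")],
                     path)
  invisible(path)
}

#' @rdname write_telemetry
#' @export
load_telemetry <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write / read generator ground truth as JSON
#'
#' @param gt A `GroundTruth` list from [simulate_recording()].
#' @param path Output `.json` path.
#' @export
write_ground_truth <- function(gt, path) {
  cfg <- unclass(gt$config)
  cfg$components <- NULL  # already under injected_components
  out <- list(events = as.data.frame(unclass(gt$events)),
              segment_demand = gt$segment_demand,
              injected_components = gt$injected_components,
              config = cfg)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
load_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
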