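# Recording and result I/O: EDF (16-bit) writer/reader, BrainVision reader,
# annotation JSON round-trip, tidy CSV serialization, YAML study configs.
#
# Both EEG formats are implemented directly against their published layouts
# (no R package for either ships with the analysis stack).

.pad <- function(x, width) {
  x <- as.character(x)
  formatC(substr(x, 1, width), width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' European Data Format, 16-bit integer samples with per-channel physical
#' calibration in microvolt; one data record per second. Requires an
#' integer sampling rate and a whole number of seconds (trailing partial
#' seconds are dropped).
#'
#' @param rec A `raw_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-6
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad("0", 8), .pad("synthetic", 80), .pad("synthetic recording", 80),
    .pad("01.01.00", 8), .pad("00.00.00", 8),
    .pad(256 + ns * 256, 8), .pad("", 44), .pad(n_rec, 8), .pad(1, 8),
    .pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, .pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  labs <- rec$labels
  field(labs, 16)
  field(rep("AgAgCl", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.3f", pmin_), 8)
  field(sprintf("%.3f", pmax_), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - pmin_[ch]) / gain[ch] + dmin)
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file written with 16-bit samples.
#' @param montage Optional `montage_spec` to attach (default: the standard
#'   montage).
#' @return A `raw_recording` in physical units (microvolt).
#' @export
read_edf <- function(path, montage = generate_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labs <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  nspr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  fs <- nspr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, nrow = ns, ncol = n_rec * nspr[1],
                 dimnames = list(labs, NULL))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nspr[ch], size = 2, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1) * nspr[ch] + 1):(r * nspr[ch])
      data[ch, idx] <- (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  structure(
    list(data = data, fs = fs, labels = labs, montage = montage,
         annotations = list()),
    class = "raw_recording"
  )
}

# parse one INI-like BrainVision section into a named character vector
.bv_section <- function(lines, name) {
  start <- grep(paste0("^\\[", name, "\\]"), lines)
  if (length(start) == 0) return(character(0))
  rest <- lines[(start[1] + 1):length(lines)]
  stop_at <- grep("^\\[", rest)
  if (length(stop_at) > 0) rest <- rest[seq_len(stop_at[1] - 1)]
  rest <- rest[grepl("=", rest) & !grepl("^;", rest)]
  kv <- strsplit(rest, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                         character(1)),
                  vapply(kv, `[[`, character(1), 1))
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header, the binary `.eeg` data file (little-endian,
#' multiplexed; `INT_16` with per-channel resolution or `IEEE_FLOAT_32`)
#' and, when present, the `.vmrk` marker file (markers become annotations).
#'
#' @param vhdr_path Path to the `.vhdr` header.
#' @param montage Optional `montage_spec` to attach.
#' @return A `raw_recording` in microvolt.
#' @export
read_brainvision <- function(vhdr_path, montage = generate_montage()) {
  lines <- readLines(vhdr_path, warn = FALSE)
  common <- .bv_section(lines, "Common Infos")
  binary <- .bv_section(lines, "Binary Infos")
  chans <- .bv_section(lines, "Channel Infos")
  if (toupper(common[["DataOrientation"]]) != "MULTIPLEXED") {
    stop("only multiplexed BrainVision data is supported")
  }
  ns <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])
  fmt <- toupper(binary[["BinaryFormat"]])
  ch_fields <- strsplit(unname(chans[paste0("Ch", seq_len(ns))]), ",")
  labs <- vapply(ch_fields, `[[`, character(1), 1)
  res <- vapply(ch_fields, function(f) {
    r <- if (length(f) >= 3 && nzchar(f[3])) as.numeric(f[3]) else 1
    if (is.na(r)) 1 else r
  }, numeric(1))

  eeg_path <- file.path(dirname(vhdr_path), common[["DataFile"]])
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (fmt == "INT_16") {
    n_total <- sz / 2
    raw_vals <- readBin(con, "integer", n = n_total, size = 2, signed = TRUE,
                        endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    n_total <- sz / 4
    raw_vals <- readBin(con, "double", n = n_total, size = 4,
                        endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt)
  }
  n_samp <- floor(n_total / ns)
  data <- matrix(raw_vals[seq_len(n_samp * ns)], nrow = ns)
  data <- data * res
  rownames(data) <- labs

  annotations <- list()
  if (!is.null(common["MarkerFile"]) && !is.na(common["MarkerFile"])) {
    vmrk <- file.path(dirname(vhdr_path), common[["MarkerFile"]])
    if (file.exists(vmrk)) {
      mk <- .bv_section(readLines(vmrk, warn = FALSE), "Marker Infos")
      for (m in mk) {
        f <- strsplit(m, ",")[[1]]
        if (length(f) >= 4 && toupper(f[1]) == "BAD INTERVAL") {
          start <- as.integer(f[3]) - 1L  # positions are 1-based
          len <- max(1L, as.integer(f[4]))
          annotations[[length(annotations) + 1]] <-
            artifact_annotation(start, start + len, labs, "manual")
        }
      }
    }
  }
  structure(
    list(data = data, fs = fs, labels = labs, montage = montage,
         annotations = annotations),
    class = "raw_recording"
  )
}

#' Annotation JSON round-trip
#'
#' @param annotations List of annotations (`start`, `end`, `channels`,
#'   `reason`; half-open 0-based samples).
#' @param path JSON file.
#' @return `path` / the annotation list.
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  raw_list <- jsonlite::read_json(path)
  lapply(raw_list, function(a) {
    artifact_annotation(a$start, a$end,
                        as.character(unlist(a$channels)), a$reason)
  })
}

#' Epoch-set CSV export
#'
#' Long-format CSV (`epoch`, `channel`, `sample`, `value_uv`) plus a JSON
#' manifest (`condition`, `fs`, `labels`, counts).
#'
#' @param epochs An `epoch_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epoch_set <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$epochs)
  df <- data.frame(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(epochs$labels, each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value_uv = as.vector(epochs$epochs)
  )
  utils::write.csv(df, file.path(dir, "epochs.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(condition = epochs$condition, fs = epochs$fs,
         labels = epochs$labels, n_epochs = d[1], n_samples = d[3]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study configuration from YAML
#'
#' Accepts the documented keys (`n_subjects`, `conditions`, `features`,
#' `eeg`, `stats`, `behavior`, `seed`) and fills defaults from
#' [study_config()].
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("n_subjects", "conditions", "features", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$eeg)) args$eeg <- do.call(eeg_sim_config, y$eeg)
  if (!is.null(y$stats)) args$stats <- y$stats
  if (!is.null(y$behavior)) args$behavior <- y$behavior
  do.call(study_config, args)
}
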