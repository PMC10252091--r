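#' Write marker trajectories as long CSV
#'
#' Columns `time_s, marker, x, y, z` (mm); missing samples written as empty
#' fields. Numeric formatting is fixed so identical data give identical
#' files.
#'
#' @param markers A [marker_set].
#' @param path Output file.
#' @export
write_markers_csv <- function(markers, path) {
  rows <- lapply(names(markers$coords), function(nm) {
    m <- markers$coords[[nm]]
    data.frame(time_s = fmt_num(markers$time), marker = nm,
               x = fmt_num(m[, 1]), y = fmt_num(m[, 2]), z = fmt_num(m[, 3]))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.6f", x))

#' Read long-CSV marker trajectories
#'
#' @param path File written by [write_markers_csv()] (or equivalent).
#' @param rate_hz Sampling rate; inferred from the time column when `NULL`.
#' @return A [marker_set].
#' @export
read_markers_csv <- function(path, rate_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "marker", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("marker CSV must have columns ", paste(need, collapse = ", "))
  time <- sort(unique(df$time_s))
  rate_hz <- rate_hz %||% round(1 / stats::median(diff(time)), 3)
  coords <- lapply(split(df, df$marker), function(d) {
    d <- d[order(d$time_s), ]
    as.matrix(d[, c("x", "y", "z")])
  })
  marker_set(time, coords, rate_hz)
}

#' Write marker trajectories in TRC format
#'
#' Standard tab-separated TRC with the usual four header lines, coordinates
#' in mm.
#'
#' @param markers A [marker_set].
#' @param path Output file.
#' @export
write_trc <- function(markers, path) {
  nm <- names(markers$coords)
  nfr <- length(markers$time)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("PathFileType\t4\t(X/Y/Z)", basename(path), sep = "\t"), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(markers$rate_hz, markers$rate_hz, nfr, length(nm), "mm",
                   markers$rate_hz, 1, nfr, sep = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(nm, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(nm)),
                                    rep(seq_along(nm), each = 3))),
                   collapse = "\t"), con)
  dat <- do.call(cbind, lapply(markers$coords, function(m) m))
  lines <- vapply(seq_len(nfr), function(i) {
    paste(c(i, fmt_num(markers$time[i]), fmt_num(dat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a TRC marker file
#'
#' @param path TRC file.
#' @return A [marker_set].
#' @export
read_trc <- function(path) {
  hdr <- readLines(path, n = 5)
  meta <- strsplit(hdr[3], "\t")[[1]]
  rate <- as.numeric(meta[1])
  names_line <- strsplit(hdr[4], "\t")[[1]]
  nm <- names_line[-(1:2)]
  nm <- nm[nm != ""]
  dat <- utils::read.table(path, skip = 5, sep = "\t",
                           stringsAsFactors = FALSE)
  time <- as.numeric(dat[[2]])
  coords <- list()
  for (i in seq_along(nm)) {
    cols <- 2 + (i - 1) * 3 + 1:3
    coords[[nm[i]]] <- as.matrix(dat[, cols])
  }
  marker_set(time, coords, rate)
}

#' Write an sEMG channel as CSV (`time_s,value_v`)
#' @param channel An [emg_channel].
#' @param path Output file.
#' @export
write_emg_csv <- function(channel, path) {
  df <- data.frame(time_s = fmt_num(channel$time),
                   value_v = sprintf("%.8f", channel$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an sEMG channel CSV
#' @param path File with columns `time_s,value_v`.
#' @param rate_hz Sampling rate; inferred when `NULL`.
#' @param muscle,horse,lead Metadata attached to the channel.
#' @return An [emg_channel].
#' @export
read_emg_csv <- function(path, rate_hz = NULL, muscle = NA_character_,
                         horse = NA_character_, lead = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value_v") %in% names(df)))
    stop("sEMG CSV must have columns time_s, value_v")
  rate_hz <- rate_hz %||% round(1 / stats::median(diff(df$time_s)), 3)
  emg_channel(df$time_s, df$value_v, rate_hz, muscle, horse, lead)
}

#' Read a cohort manifest
#' @param path `manifest.yaml` written by [generate_cohort()].
#' @return List with `dataset` and `trials`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  yaml::read_yaml(path)
}

#' Read the ground-truth sidecar of a synthetic cohort
#' @param dir Dataset directory.
#' @return Named list of per-trial truth records.
#' @export
read_ground_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "ground_truth.json"),
                      simplifyVector = TRUE)
}
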