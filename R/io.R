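#' Read and write recordings as plain delimited text
#'
#' A recording is stored as a single text file: `#`-prefixed header lines with
#' the sampling rates, units, seed and mode sequence, followed by two
#' tab-separated blocks (the sEMG table and the IMU table, one column per
#' channel) introduced by `[semg]` / `[imu]` section markers. Window labels are
#' stored in the header and re-derived lengths are validated on read.
#'
#' @param rec A `lir_recording`.
#' @param path File path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `lir_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "lir_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("# fs_semg: ", rec$fs_semg),
    paste0("# fs_imu: ", rec$fs_imu),
    paste0("# units: semg=mV imu=m/s2,deg/s"),
    paste0("# subject: ", rec$meta$subject),
    paste0("# trial: ", rec$meta$trial),
    paste0("# seed: ", rec$meta$seed),
    paste0("# window_labels: ", paste(rec$window_labels, collapse = ","))
  )
  writeLines(hdr, con)
  writeLines("[semg]", con)
  write.table(rec$semg, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("[imu]", con)
  write.table(rec$imu, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)[1]
    trimws(sub(paste0("^# ", key, ":"), "", ln))
  }
  i_semg <- which(lines == "[semg]")
  i_imu <- which(lines == "[imu]")
  parse_block <- function(from, to) {
    as.matrix(read.table(text = paste(lines[from:to], collapse = "\n"),
                         header = TRUE, sep = "\t", check.names = FALSE))
  }
  semg <- parse_block(i_semg + 1, i_imu - 1)
  imu <- parse_block(i_imu + 1, length(lines))
  labels <- strsplit(get("window_labels"), ",", fixed = TRUE)[[1]]
  structure(list(
    semg = semg, fs_semg = as.numeric(get("fs_semg")),
    imu = imu, fs_imu = as.numeric(get("fs_imu")),
    window_labels = labels,
    meta = list(subject = get("subject"), trial = get("trial"),
                seed = suppressWarnings(as.integer(get("seed"))))
  ), class = "lir_recording")
}

#' Read and write feature tibbles as delimited tables
#'
#' Round-trips a feature tibble (from [extract_features()] or
#' [dataset_features()]) through a tab-separated table with a header row of
#' feature names and the `.label` (and `.trial`, if present) columns.
#'
#' @param features Feature tibble.
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()` a
#'   tibble.
#' @export
write_features <- function(features, path) {
  write.table(features, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
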