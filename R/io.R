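#' Write a raw recording to delimited text
#'
#' One sample per row: a timestamp column in seconds, one column per
#' channel (microvolts), and a trailing `marker` column holding the event
#' label at onset samples and `0` elsewhere (OpenBCI-style session export).
#'
#' @param recording a `raw_recording`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_raw_delimited <- function(recording, path, sep = "\t") {
  .assert(inherits(recording, "raw_recording"), "not a raw_recording")
  n <- ncol(recording$data)
  marker <- rep("0", n)
  marker[recording$events$onset] <- recording$events$label
  df <- data.frame(time = (seq_len(n) - 1L) / recording$sampling_rate,
                   t(recording$data), marker,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("time", recording$channel_names, "marker")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw recording from delimited text
#'
#' Expects the layout written by [write_raw_delimited()]: a header row
#' naming a `time` column, channel columns, and a `marker` column; events
#' are parsed from non-zero markers.
#'
#' @param path input file path.
#' @param sampling_rate sampling rate in Hz; if `NULL`, inferred from the
#'   `time` column.
#' @param sep field separator.
#' @return a `raw_recording`.
#' @export
read_raw_delimited <- function(path, sampling_rate = NULL, sep = "\t") {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  cols <- names(df)
  .assert("marker" %in% cols, "no 'marker' column in %s", path)
  ch_cols <- cols[!cols %in% c("time", "marker")]
  .assert(length(ch_cols) >= 1, "no channel columns in %s", path)
  dup <- ch_cols[duplicated(ch_cols)]
  .assert(length(dup) == 0, "duplicate channel column: %s",
          paste(unique(dup), collapse = ", "))
  ch_idx <- which(cols %in% ch_cols)
  data <- vapply(ch_idx, function(ci) {
    v <- suppressWarnings(as.numeric(df[[ci]]))
    .assert(!anyNA(v), "non-numeric samples in channel column '%s'",
            cols[ci])
    v
  }, numeric(nrow(df)))
  marker <- df$marker
  ev <- which(marker != "0" & marker != "" & !is.na(marker))
  .assert(length(ev) > 0, "no events found in %s", path)
  if (is.null(sampling_rate)) {
    tm <- as.numeric(df$time)
    sampling_rate <- round(1 / stats::median(diff(tm)))
  }
  structure(list(data = t(data),
                 sampling_rate = sampling_rate,
                 channel_names = ch_cols,
                 events = data.frame(onset = ev, label = marker[ev],
                                     stringsAsFactors = FALSE)),
            class = "raw_recording")
}

#' Construct an epoch set
#'
#' Container for segmented trials: a `trials x channels x samples` array in
#' microvolts plus per-trial labels and timing metadata.
#'
#' @param data numeric array `trials x channels x samples`.
#' @param labels factor or character, one label per trial.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names channel names (length = dim 2).
#' @param window two-element numeric, epoch window in seconds relative to
#'   trial onset.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sampling_rate, channel_names,
                      window = c(0, dim(data)[3] / sampling_rate)) {
  .assert(length(dim(data)) == 3L, "'data' must be a 3-d array")
  .assert(length(labels) == dim(data)[1],
          "labels length (%d) != trial count (%d)",
          length(labels), dim(data)[1])
  .assert(length(channel_names) == dim(data)[2],
          "channel_names length != channel count")
  .assert(sampling_rate > 0, "sampling_rate must be positive")
  structure(list(data = data,
                 labels = if (is.factor(labels)) labels else factor(labels),
                 sampling_rate = sampling_rate,
                 channel_names = as.character(channel_names),
                 window = as.numeric(window)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("epoch_set:", dim(x$data)[1], "trials x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "samples @", x$sampling_rate, "Hz\n")
  print(table(x$labels))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1]

# extract trial i as a channels x samples matrix
.trial <- function(es, i) {
  m <- es$data[i, , , drop = FALSE]
  dim(m) <- dim(es$data)[2:3]
  m
}

# list of trial matrices for a logical/integer subset
.trial_list <- function(es, idx) lapply(idx, function(i) .trial(es, i))

# subset an epoch_set by trial index
.subset_epochs <- function(es, idx) {
  epoch_set(es$data[idx, , , drop = FALSE], es$labels[idx],
            es$sampling_rate, es$channel_names, es$window)
}

#' Write an epoch set to a text container
#'
#' Stores samples as plain text (one `trial channel v1 v2 ...` row per
#' trial/channel pair, full `%.17g` precision so the round trip is
#' bit-exact) next to a JSON sidecar `<path>.json` holding labels and
#' metadata.
#'
#' @param epochs an `epoch_set`.
#' @param path data file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_epoch_set <- function(epochs, path) {
  .assert(inherits(epochs, "epoch_set"), "not an epoch_set")
  d <- dim(epochs$data)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(d[1])) for (ch in seq_len(d[2])) {
    writeLines(paste(i, ch, paste(sprintf("%.17g", epochs$data[i, ch, ]),
                                  collapse = " ")), con)
  }
  meta <- list(trials = d[1], channels = d[2], samples = d[3],
               labels = as.character(epochs$labels),
               label_levels = levels(epochs$labels),
               sampling_rate = epochs$sampling_rate,
               channel_names = epochs$channel_names,
               window = epochs$window)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param path data file path (sidecar `<path>.json` must exist).
#' @return an `epoch_set`.
#' @export
read_epoch_set <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  sidecar <- paste0(path, ".json")
  .assert(file.exists(sidecar), "metadata sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  lines <- readLines(path)
  arr <- array(NA_real_, c(meta$trials, meta$channels, meta$samples))
  for (ln in lines) {
    v <- scan(text = ln, quiet = TRUE)
    arr[v[1], v[2], ] <- v[-(1:2)]
  }
  epoch_set(arr, factor(meta$labels, levels = meta$label_levels),
            meta$sampling_rate, meta$channel_names, meta$window)
}
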