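# CSV schemas:
#   train:  stim_index, time_ms, amplitude_nA
#   trace:  time_ms, current_pA
#   events: peak_time_ms, amplitude_pA, rise_10_90_ms, decay_half_ms,
#           decay_10_90_ms, area_pA_ms
# Every file written by the pipeline carries a '# config=<hash>' comment line;
# readers skip '#' comments.

write_commented_csv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(sprintf("# config=%s", config_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write an EPSC train to CSV
#'
#' Columns: `stim_index`, `time_ms`, `amplitude_nA`.
#'
#' @param train An [epsc_train()].
#' @param path Output path.
#' @param config_hash Optional provenance hash written as a comment line.
#' @return `path`, invisibly.
#' @export
write_train_csv <- function(train, path, config_hash = NULL) {
  train <- as_train(train)
  n <- length(train$amplitudes_nA)
  df <- data.frame(stim_index = seq_len(n),
                   time_ms = (seq_len(n) - 1) * train$ipi_ms,
                   amplitude_nA = train$amplitudes_nA)
  write_commented_csv(df, path, config_hash)
}

#' Read an EPSC train from CSV
#'
#' @param path CSV with columns `stim_index`, `time_ms`, `amplitude_nA`
#'   (comment lines starting with `#` are ignored).
#' @return An [epsc_train()].
#' @export
read_train_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("stim_index", "time_ms", "amplitude_nA")
  if (!all(need %in% names(df))) {
    stop("train CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$stim_index), ]
  ipi <- if (nrow(df) > 1) diff(df$time_ms)[1] else 1
  epsc_train(df$amplitude_nA, ipi)
}

#' Write a current trace to CSV
#'
#' Columns: `time_ms`, `current_pA`.
#'
#' @param trace A `trace` object.
#' @param path Output path.
#' @param config_hash Optional provenance hash.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, config_hash = NULL) {
  stopifnot(inherits(trace, "trace"))
  df <- data.frame(
    time_ms = trace$t0_ms + (seq_along(trace$samples) - 1) * 1000 / trace$fs_hz,
    current_pA = trace$samples)
  write_commented_csv(df, path, config_hash)
}

#' Read a current trace from CSV
#'
#' @param path CSV with columns `time_ms`, `current_pA`.
#' @return A `trace` object (sampling rate inferred from the time column).
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_ms", "current_pA") %in% names(df))) {
    stop("trace CSV must have columns time_ms, current_pA", call. = FALSE)
  }
  dt <- diff(df$time_ms)[1]
  structure(list(fs_hz = 1000 / dt, samples = df$current_pA,
                 t0_ms = df$time_ms[1]),
            class = "trace")
}

#' Write detected events to CSV
#'
#' @param events Event data.frame from [detect_minis()].
#' @param path Output path.
#' @param config_hash Optional provenance hash.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, config_hash = NULL) {
  write_commented_csv(events, path, config_hash)
}

#' Read detected events from CSV
#'
#' @param path Events CSV.
#' @return Event data.frame.
#' @export
read_events_csv <- function(path) {
  read.csv(path, comment.char = "#")
}
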