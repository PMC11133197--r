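#' Read a recording from a delimited text file
#'
#' Loads a per-sample table (CSV/TSV with a header row, delimiter
#' auto-detected) and assembles a [recording()] from the columns named in
#' `column_map`. Timestamps are converted to seconds according to the
#' declared unit. A sample is valid only when its validity column is truthy
#' (logical `TRUE`, numeric non-zero, or the strings "true"/"TRUE"/"1") and
#' its value parses as a positive finite number; all other samples carry
#' `NA`.
#'
#' @param path Path to the file.
#' @param column_map A list describing the columns:
#'   \describe{
#'     \item{`time`}{name of the timestamp column (required);}
#'     \item{`time_unit`}{`"s"`, `"ms"` or `"us"` (default `"s"`);}
#'     \item{`eo_left`, `eo_right`, `ps_left`, `ps_right`}{for each channel
#'       present, a named character vector or list with entries `value` and
#'       `valid` giving the corresponding column names.}
#'   }
#' @param fs Nominal sampling frequency in Hz.
#' @return A [recording()]. A deviation of the median sample interval of
#'   more than 20% from `1/fs` is recorded as a note in `meta$notes` (and
#'   raised as a warning).
#' @export
read_recording <- function(path, column_map, fs) {
  df <- data.table::fread(path, data.table = FALSE)
  if (is.null(column_map$time)) {
    stop("column_map must name a `time` column", call. = FALSE)
  }
  unit <- if (is.null(column_map$time_unit)) "s" else column_map$time_unit
  scale <- switch(unit, s = 1, ms = 1e-3, us = 1e-6,
                  stop("`time_unit` must be one of s, ms, us", call. = FALSE))
  need_col <- function(nm) {
    if (!nm %in% names(df)) {
      stop("mapped column not found in file: `", nm, "`", call. = FALSE)
    }
    df[[nm]]
  }
  t <- as.numeric(need_col(column_map$time)) * scale
  if (anyNA(t)) stop("timestamp column contains unparseable values", call. = FALSE)
  if (anyDuplicated(t) || (length(t) > 1 && any(diff(t) <= 0))) {
    stop("timestamps must be strictly increasing (no duplicates)", call. = FALSE)
  }
  keys <- intersect(c("eo_left", "eo_right", "ps_left", "ps_right"),
                    names(column_map))
  if (length(keys) == 0) {
    stop("column_map declares no channel (eo_left/eo_right/ps_left/ps_right)",
         call. = FALSE)
  }
  truthy <- function(x) {
    if (is.logical(x)) return(!is.na(x) & x)
    if (is.numeric(x)) return(!is.na(x) & x != 0)
    xs <- tolower(trimws(as.character(x)))
    xs %in% c("true", "t", "1", "yes")
  }
  notes <- character()
  series <- list()
  for (key in keys) {
    m <- column_map[[key]]
    value <- suppressWarnings(as.numeric(need_col(m[["value"]])))
    valid <- truthy(need_col(m[["valid"]])) &
      is.finite(value) & value > 0
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    s <- withCallingHandlers(
      sample_series(t, value, valid = valid, fs = fs,
                    channel = parts[1], eye = parts[2]),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    series[[key]] <- s
  }
  notes <- unique(notes)
  for (msg in notes) warning(msg, call. = FALSE)
  recording(series, notes = notes)
}

# serialize numbers so that a write/read round trip is lossless well below
# 1e-9 relative tolerance
fmt_num <- function(x) {
  out <- trimws(formatC(x, format = "g", digits = 15))
  out[is.na(x)] <- ""
  out
}

#' Write a blink-event table to TSV
#'
#' One row per event in the canonical column order (see
#' [empty_blink_events()]); tab-separated, '.' decimal separator, header
#' row, `NA` kinematic fields as empty cells. Round-trips losslessly with
#' [read_events()] (to numeric tolerance well below 1e-9).
#'
#' @param events A `blink_events` table sorted by `onset_t`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  check_event_list(events, require_sorted = TRUE)
  events <- as_blink_events(events)
  out <- events
  num_cols <- setdiff(EVENT_COLS, c("eye", "source", "clipped"))
  for (nm in num_cols) out[[nm]] <- fmt_num(as.numeric(events[[nm]]))
  out$clipped <- ifelse(is.na(events$clipped), "",
                        ifelse(events$clipped, "TRUE", "FALSE"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a blink-event table from TSV
#'
#' @param path Path to a TSV written by [write_events()].
#' @return A `blink_events` table.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  missing <- setdiff(EVENT_COLS, names(df))
  if (length(missing)) {
    stop("event file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(EVENT_COLS, c("eye", "source", "clipped"))
  for (nm in num_cols) df[[nm]] <- as.numeric(df[[nm]])
  df$clipped <- as.logical(df$clipped)
  as_blink_events(df)
}

#' Write a recording to a delimited text file
#'
#' Inverse of [read_recording()] for the package's own simple layout: a
#' `time` column in seconds plus `<channel>_<eye>` and
#' `<channel>_<eye>_valid` columns per series; invalid values are written
#' as empty cells.
#'
#' @param rec A [recording()].
#' @param path Output path; a `.tsv` extension writes tabs, anything else
#'   commas.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time = fmt_num(rec$series[[1]]$t))
  for (key in names(rec$series)) {
    s <- rec$series[[key]]
    df[[key]] <- fmt_num(s$value)
    df[[paste0(key, "_valid")]] <- as.integer(s$valid)
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

# column map matching write_recording() output
default_column_map <- function(keys) {
  m <- list(time = "time", time_unit = "s")
  for (key in keys) {
    m[[key]] <- c(value = key, valid = paste0(key, "_valid"))
  }
  m
}
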