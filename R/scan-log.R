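#' Proximity scan log
#'
#' Container for timestamped scanner-to-detected proximity records together
#' with the class roster and the schedule of valid scan periods. One record
#' means: in scan period `period` of day `day` (within `wave`), device
#' `scanner` detected device `detected`. Within one scan period a node can
#' detect another at most once, so records are deduplicated on
#' (scanner, detected, wave, day, period); this guarantees that a pair's
#' detection count never exceeds either node's scan count.
#'
#' @param records data frame with columns `scanner`, `detected`, `wave`,
#'   `day` (integer, 1-based), `period` (integer, 0-based scan-period index).
#' @param roster optional data frame with column `id` and optional `gender`,
#'   `class` attributes. Records whose scanner or detected id is off the
#'   roster are excluded (unknown devices are not analyzed). Defaults to the
#'   ids observed in `records`.
#' @param schedule optional ordered integer vector of valid scan-period
#'   indices; defaults to the distinct periods observed.
#' @return An object of class `scan_log`: list with `records`, `roster`,
#'   `schedule`.
#' @export
scan_log <- function(records, roster = NULL, schedule = NULL) {
  records <- as.data.frame(records)
  need <- c("scanner", "detected", "wave", "day", "period")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records <- records[need]
  records$scanner <- as.character(records$scanner)
  records$detected <- as.character(records$detected)
  records$wave <- as.character(records$wave)
  records$day <- as.integer(records$day)
  records$period <- as.integer(records$period)
  if (nrow(records) > 0 && any(records$day < 1, na.rm = TRUE)) {
    stop("day indices must be >= 1", call. = FALSE)
  }
  if (nrow(records) > 0 && any(records$period < 0, na.rm = TRUE)) {
    stop("scan-period indices must be >= 0", call. = FALSE)
  }

  n_self <- sum(records$scanner == records$detected)
  if (n_self > 0) {
    warning(sprintf("dropped %d self-detection record(s)", n_self),
            call. = FALSE)
    records <- records[records$scanner != records$detected, , drop = FALSE]
  }

  if (is.null(roster)) {
    roster <- data.frame(id = sort(unique(c(records$scanner,
                                            records$detected))))
  }
  roster <- as.data.frame(roster)
  if (!"id" %in% names(roster)) stop("roster must have column `id`",
                                     call. = FALSE)
  roster$id <- as.character(roster$id)
  if (anyDuplicated(roster$id)) stop("duplicate roster ids", call. = FALSE)

  known <- records$scanner %in% roster$id & records$detected %in% roster$id
  if (any(!known)) {
    warning(sprintf("excluded %d record(s) involving unknown node ids",
                    sum(!known)), call. = FALSE)
    records <- records[known, , drop = FALSE]
  }

  key <- do.call(paste, c(records, sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) records <- records[!dup, , drop = FALSE]

  if (is.null(schedule)) schedule <- sort(unique(records$period))
  schedule <- as.integer(schedule)

  rownames(records) <- NULL
  structure(list(records = records, roster = roster, schedule = schedule),
            class = "scan_log")
}

#' @export
print.scan_log <- function(x, ...) {
  cat(sprintf(
    "<scan_log: %d records, %d roster nodes, %d day(s), %d scan period(s)>\n",
    nrow(x$records), nrow(x$roster),
    length(unique(x$records$day)), length(x$schedule)))
  invisible(x)
}

#' Column mapping for scan-log CSV files
#'
#' Source datasets name their columns differently; a dialect maps the
#' fields the package needs onto the columns present in the file. The
#' default matches the native schema written by [write_scan_log()];
#' field-study exports with `Child_ID`/`Detected_Child_ID` style headers
#' are mapped by naming those columns here.
#'
#' @param scanner,detected,wave,day,period column names in the file.
#' @return named character vector usable as `dialect` in [read_scan_log()].
#' @export
scan_dialect <- function(scanner = "Child_ID", detected = "Detected_Child_ID",
                         wave = "Wave", day = "Day", period = "Scan_Period") {
  c(scanner = scanner, detected = detected, wave = wave, day = day,
    period = period)
}

# Parse "S3"/"D2" style labels or plain integers; row-level error otherwise.
parse_label <- function(x, prefix, what) {
  x <- as.character(x)
  lab <- grepl(paste0("^", prefix, "[0-9]+$"), x)
  x[lab] <- sub(paste0("^", prefix), "", x[lab])
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("unparseable %s label '%s' at data row %d", what,
                 x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Read a proximity scan log from CSV
#'
#' @param path CSV file with a header row.
#' @param dialect column mapping, see [scan_dialect()].
#' @param roster optional roster data frame passed to [scan_log()].
#' @return a [scan_log], deduplicated, with self-detections dropped.
#' @export
read_scan_log <- function(path, dialect = scan_dialect(), roster = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(unname(dialect), names(df))
  if (length(missing_cols) > 0) {
    stop("scan log is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- data.frame(
    scanner = df[[dialect[["scanner"]]]],
    detected = df[[dialect[["detected"]]]],
    wave = df[[dialect[["wave"]]]],
    day = parse_label(df[[dialect[["day"]]]], "D", "day"),
    period = parse_label(df[[dialect[["period"]]]], "S", "scan-period"))
  scan_log(records, roster = roster)
}

#' Write a proximity scan log to CSV
#'
#' Emits the native schema (`Wave, Day, Scan_Period, Child_ID,
#' Detected_Child_ID`) readable by [read_scan_log()] with the default
#' dialect. Day and period indices are written as `D<k>`/`S<k>` labels.
#'
#' @param log a [scan_log].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_log <- function(log, path) {
  stopifnot(inherits(log, "scan_log"))
  out <- data.frame(
    Wave = log$records$wave,
    Day = sprintf("D%d", log$records$day),
    Scan_Period = sprintf("S%d", log$records$period),
    Child_ID = log$records$scanner,
    Detected_Child_ID = log$records$detected)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read peer nominations from CSV
#'
#' Expects columns `nominator`, `nominee`, `item`, `wave`. Items index the
#' six sociometric questions (advice, friends, leader, respect, hang out
#' with, want to be like); rows with an item outside 1..6 and
#' self-nominations are dropped with a warning.
#'
#' @param path CSV file.
#' @return data frame of nomination records.
#' @export
read_nominations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("nominator", "nominee", "item", "wave")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("nomination table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  df$item <- suppressWarnings(as.integer(df$item))
  bad_item <- is.na(df$item) | df$item < 1 | df$item > 6
  if (any(bad_item)) {
    warning(sprintf("rejected %d nomination(s) with item outside 1..6 (rows %s)",
                    sum(bad_item),
                    paste(utils::head(which(bad_item), 5), collapse = ", ")),
            call. = FALSE)
    df <- df[!bad_item, , drop = FALSE]
  }
  self <- df$nominator == df$nominee
  if (any(self)) {
    warning(sprintf("dropped %d self-nomination(s)", sum(self)),
            call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write peer nominations to CSV
#'
#' @param noms data frame as returned by [read_nominations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nominations <- function(noms, path) {
  utils::write.csv(noms[c("nominator", "nominee", "item", "wave")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Class participation filter
#'
#' Nomination-based ground truth is only trustworthy when enough of the
#' class takes part; the filter passes when the participation rate is
#' strictly greater than the threshold (a rate exactly at the threshold
#' fails).
#'
#' @param n_participants number of enrolled participants.
#' @param class_size total number of pupils in the class.
#' @param threshold minimal participation fraction (default 0.6).
#' @return list with `rate` and logical `pass`.
#' @export
filter_participation <- function(n_participants, class_size,
                                 threshold = 0.6) {
  if (class_size <= 0) stop("class_size must be positive", call. = FALSE)
  if (n_participants <= 0 || n_participants > class_size) {
    stop("need 0 < n_participants <= class_size", call. = FALSE)
  }
  rate <- n_participants / class_size
  list(rate = rate, pass = rate > threshold)
}

#' Drop sparsely observed scan periods
#'
#' Scan periods in which hardly any observations were collected carry
#' little signal; periods with fewer than `min_obs` records are removed
#' from the schedule and the records. Counts are taken per
#' (wave, scan period) aggregated over days by default, or per
#' (day, scan period) cell.
#'
#' @param log a [scan_log].
#' @param min_obs minimal number of records per scan period (default 30,
#'   "at least `min_obs`" is kept).
#' @param by `"wave_period"` (default) or `"day_period"`.
#' @return a filtered [scan_log].
#' @export
filter_scan_periods <- function(log, min_obs = 30,
                                by = c("wave_period", "day_period")) {
  stopifnot(inherits(log, "scan_log"))
  by <- match.arg(by)
  if (min_obs < 0) stop("min_obs must be >= 0", call. = FALSE)
  if (min_obs == 0 || nrow(log$records) == 0) {
    if (min_obs > 0 && nrow(log$records) == 0) log$schedule <- integer(0)
    return(log)
  }
  r <- log$records
  if (by == "wave_period") {
    cell <- paste(r$wave, r$period)
    counts <- table(cell)
    keep_cell <- names(counts)[counts >= min_obs]
    keep <- cell %in% keep_cell
  } else {
    cell <- paste(r$wave, r$day, r$period)
    counts <- table(cell)
    keep_cell <- names(counts)[counts >= min_obs]
    keep <- cell %in% keep_cell
  }
  r <- r[keep, , drop = FALSE]
  log$records <- r
  log$schedule <- intersect(log$schedule, sort(unique(r$period)))
  rownames(log$records) <- NULL
  log
}
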