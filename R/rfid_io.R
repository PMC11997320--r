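# Detection-log and covariate-table I/O.
#
# A detection log is the atomic input of the whole pipeline: one row per
# second per bird detected at an antenna-fitted feeder.  Internally it is a
# data.table with columns
#   timestamp  POSIXct, whole seconds, timezone-naive (stored as UTC)
#   bird_id    character (the RFID tag code)
#   antenna_id integer   (feeder number)
# sorted by (bird_id, timestamp).

.TS_FMT <- "%Y-%m-%dT%H:%M:%S"

.parse_ts <- function(x) {
  out <- as.POSIXct(x, format = .TS_FMT, tz = "UTC")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    # second chance: "YYYY-mm-dd HH:MM:SS"
    out[bad] <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  out
}

.format_ts <- function(x) format(x, .TS_FMT, tz = "UTC")

#' Read an RFID detection log
#'
#' Reads a delimited (comma or tab, autodetected) text log with one row per
#' detection second, validates it against a pen layout, collapses duplicate
#' rows, resolves simultaneous two-antenna detections and returns the
#' canonical sorted detection table.
#'
#' Validation is strict: a row whose antenna is not in the layout's
#' antenna-equipped set, or whose timestamp cannot be parsed (format
#' `YYYY-mm-ddTHH:MM:SS`, whole seconds), is a hard error naming the row.
#' A bird detected at two different antennas in the same second is resolved
#' by antenna continuity (keep the antenna seen in the previous second for
#' that bird), falling back to the lower antenna number; a warning reports
#' how many such collisions occurred.
#'
#' @param path Path to the log file.
#' @param layout A [pen_layout()] used for antenna validation.
#' @param col_map Named character vector mapping the canonical column names
#'   `timestamp`, `bird_id`, `antenna_id` to the names used in the file.
#' @return A `data.table` with columns `timestamp`, `bird_id`, `antenna_id`
#'   sorted by `(bird_id, timestamp)`.  Attributes `n_raw` (rows read),
#'   `n_collapsed` (duplicate rows removed) and `n_collisions` record what
#'   happened during ingestion.
#' @export
read_detection_log <- function(path, layout = pen_layout(),
                               col_map = c(timestamp = "timestamp",
                                           bird_id = "bird_id",
                                           antenna_id = "antenna_id")) {
  if (!file.exists(path)) stop("detection log not found: ", path)
  raw <- data.table::fread(path, colClasses = list(character = col_map[["bird_id"]]))
  miss <- setdiff(unname(col_map), names(raw))
  if (length(miss))
    stop("detection log lacks column(s): ", paste(miss, collapse = ", "))
  dt <- raw[, unname(col_map), with = FALSE]
  data.table::setnames(dt, names(col_map))
  n_raw <- nrow(dt)
  if (n_raw == 0L) {
    out <- data.table::data.table(timestamp = .parse_ts(character()),
                                  bird_id = character(),
                                  antenna_id = integer())
    data.table::setattr(out, "n_raw", 0L)
    data.table::setattr(out, "n_collapsed", 0L)
    data.table::setattr(out, "n_collisions", 0L)
    return(out)
  }
  ts <- .parse_ts(as.character(dt$timestamp))
  if (anyNA(ts)) {
    i <- which(is.na(ts))[1L]
    stop("unparseable timestamp in row ", i, ": '", dt$timestamp[i], "'")
  }
  dt[, `:=`(timestamp = ts,
            bird_id = as.character(bird_id),
            antenna_id = as.integer(antenna_id))]
  bad <- which(!(dt$antenna_id %in% layout$antenna_equipped))
  if (length(bad)) {
    stop("unknown antenna_id ", dt$antenna_id[bad[1L]], " in row ", bad[1L],
         " (not in the layout's antenna-equipped set)")
  }
  data.table::setkey(dt, bird_id, timestamp, antenna_id)
  n0 <- nrow(dt)
  dt <- unique(dt, by = c("bird_id", "timestamp", "antenna_id"))
  n_collapsed <- n0 - nrow(dt)

  # simultaneous detection of one bird at two antennas in the same second
  dup <- duplicated(dt, by = c("bird_id", "timestamp")) |
    duplicated(dt, by = c("bird_id", "timestamp"), fromLast = TRUE)
  n_collisions <- 0L
  if (any(dup)) {
    clean <- dt[!dup]
    coll <- dt[dup]
    n_collisions <- length(unique(coll[, paste(bird_id, timestamp)]))
    prev <- clean[, .(bird_id, timestamp = timestamp + 1, prev_ant = antenna_id)]
    coll <- prev[coll, on = c("bird_id", "timestamp")]
    pick <- coll[, {
      keep <- if (!all(is.na(prev_ant)) && any(antenna_id %in% prev_ant))
        antenna_id[antenna_id %in% prev_ant][1L] else min(antenna_id)
      .(antenna_id = keep)
    }, by = .(bird_id, timestamp)]
    warning(n_collisions, " simultaneous two-antenna detection(s) resolved ",
            "by antenna continuity / lower antenna number")
    dt <- rbind(clean[, .(timestamp, bird_id, antenna_id)],
                pick[, .(timestamp, bird_id, antenna_id)])
  }
  data.table::setkey(dt, bird_id, timestamp)
  out <- dt[, .(timestamp, bird_id, antenna_id)]
  data.table::setattr(out, "n_raw", n_raw)
  data.table::setattr(out, "n_collapsed", n_collapsed)
  data.table::setattr(out, "n_collisions", n_collisions)
  out[]
}

#' Write an RFID detection log
#'
#' Writes the canonical CSV form (ISO 8601 timestamps at second resolution),
#' sorted by `(bird_id, timestamp)`, such that
#' `read_detection_log(write_detection_log(x))` reproduces `x` exactly.
#'
#' @param records Detection table (columns `timestamp`, `bird_id`,
#'   `antenna_id`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detection_log <- function(records, path) {
  stopifnot(all(c("timestamp", "bird_id", "antenna_id") %in% names(records)))
  dt <- data.table::as.data.table(records)[, .(timestamp, bird_id, antenna_id)]
  data.table::setorder(dt, bird_id, timestamp)
  out <- dt[, .(timestamp = .format_ts(timestamp), bird_id, antenna_id)]
  ok <- tryCatch({
    data.table::fwrite(out, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write detection log to: ", path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# covariate tables

.SCORE_AGES <- c(21L, 27L, 35L)
.BW_AGES <- c(14L, 21L, 27L, 35L)

.wide_cov_cols <- function() {
  c("bird_id", "sex",
    paste0("bw_", .BW_AGES),
    paste0("hb_left_", .SCORE_AGES), paste0("hb_right_", .SCORE_AGES),
    paste0("fpd_left_", .SCORE_AGES), paste0("fpd_right_", .SCORE_AGES),
    paste0("gait_", .SCORE_AGES))
}

.check_scores <- function(x, what) {
  v <- x[!is.na(x)]
  if (length(v) && (any(v < 0) || any(v > 5)))
    stop(what, " score outside 0-5 range: ", v[v < 0 | v > 5][1L])
  invisible(TRUE)
}

#' Read a per-bird covariate table
#'
#' Accepts either the wide dialect (one row per bird; columns `bird_id`,
#' `sex`, `bw_14` ... `bw_35`, `hb_left_21` ... `gait_35`) or the long
#' dialect (one row per bird per scoring day; columns `bird_id`, `sex`,
#' `age_days`, `bw`, `hb_left`, `hb_right`, `fpd_left`, `fpd_right`,
#' `gait`).  The dialect is autodetected from the header.
#'
#' Scores outside 0-5 and non-positive body weights are hard errors.  Birds
#' missing any required field (BW at 14/21/27/35 d; leg scores and gait at
#' 21/27/35 d; sex) are flagged, not dropped: the returned table carries a
#' logical column `complete` plus an attribute `completeness` summarising
#' how many birds have full data.
#'
#' @param path CSV path.
#' @return A wide-format `data.table`, one row per bird, with a `complete`
#'   flag column.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  raw <- data.table::fread(path, colClasses = list(character = "bird_id"))
  long_cols <- c("bird_id", "age_days")
  if (all(long_cols %in% names(raw))) {
    wide <- .long_to_wide_cov(raw)
  } else {
    wide <- data.table::copy(raw)
  }
  need <- .wide_cov_cols()
  for (cc in setdiff(need, names(wide))) wide[, (cc) := NA]
  wide <- wide[, need, with = FALSE]
  wide[, sex := tolower(as.character(sex))]
  if (!all(wide$sex[!is.na(wide$sex)] %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  bw_cols <- paste0("bw_", .BW_AGES)
  for (cc in bw_cols) {
    v <- wide[[cc]]
    if (any(!is.na(v) & v <= 0)) stop("non-positive body weight in ", cc)
  }
  for (cc in grep("^(hb|fpd|gait)_", names(wide), value = TRUE))
    .check_scores(wide[[cc]], cc)
  wide[, complete := stats::complete.cases(.SD), .SDcols = setdiff(need, "bird_id")]
  data.table::setattr(wide, "completeness",
                      list(n_birds = nrow(wide),
                           n_complete = sum(wide$complete),
                           incomplete_birds = wide$bird_id[!wide$complete]))
  wide[]
}

.long_to_wide_cov <- function(raw) {
  dt <- data.table::as.data.table(raw)
  sexes <- dt[, .(sex = sex[1L]), by = bird_id]
  wide <- sexes
  grab <- function(col, age) {
    v <- dt[age_days == age, .(bird_id, val = get(col))]
    v[match(wide$bird_id, bird_id), val]
  }
  for (a in .BW_AGES) if ("bw" %in% names(dt)) wide[, paste0("bw_", a) := grab("bw", a)]
  for (col in c("hb_left", "hb_right", "fpd_left", "fpd_right", "gait")) {
    if (!col %in% names(dt)) next
    for (a in .SCORE_AGES) wide[, paste0(col, "_", a) := grab(col, a)]
  }
  wide
}

#' Write a covariate table (wide dialect)
#' @param covariates Wide covariate table as returned by [read_covariates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  dt <- data.table::as.data.table(covariates)
  keep <- intersect(.wide_cov_cols(), names(dt))
  data.table::fwrite(dt[, keep, with = FALSE], path)
  invisible(path)
}
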