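# Feeding-bout segmentation.
#
# The meal criterion: within one bird at one feeder, a gap of OVER
# `record_gap_threshold_s` seconds between consecutive detection records
# splits two bouts; shorter (or equal) gaps are bridged.  Because the reader
# keeps reporting a tag at its last antenna for `auto_extension_s` seconds
# after the last true detection, the threshold on *records* corresponds to an
# effective threshold of record_gap_threshold_s + auto_extension_s on true
# feeding interruptions.  The defaults (24 s + 6 s = 30 s) encode that
# convention; segmentation itself only ever looks at record timestamps.

#' Segmentation parameters
#'
#' @param record_gap_threshold_s Record-level gap threshold in seconds; gaps
#'   strictly greater than this split bouts. Default 24.
#' @param auto_extension_s Reader auto-extension in seconds (a property of
#'   the log, not applied by the segmenter). Default 6.
#' @return A `segmentation_params` list with the two inputs plus the derived
#'   `effective_gap_threshold_s` (their sum).
#' @examples
#' segmentation_params()$effective_gap_threshold_s  # 30
#' @export
segmentation_params <- function(record_gap_threshold_s = 24,
                                auto_extension_s = 6) {
  if (record_gap_threshold_s < 0 || auto_extension_s < 0)
    stop("segmentation parameters must be non-negative")
  structure(list(record_gap_threshold_s = record_gap_threshold_s,
                 auto_extension_s = auto_extension_s,
                 effective_gap_threshold_s =
                   record_gap_threshold_s + auto_extension_s),
            class = "segmentation_params")
}

.check_sorted <- function(records) {
  n <- nrow(records)
  if (n < 2L) return(invisible(TRUE))
  b1 <- records$bird_id[-n]; b2 <- records$bird_id[-1L]
  t <- as.numeric(records$timestamp)
  same <- b2 == b1
  ok <- all(t[-1L][same] >= t[-n][same]) && {
    chg <- which(!same)
    all(b2[chg] > b1[chg])
  }
  if (!ok)
    stop("records must be sorted by (bird_id, timestamp); refusing to sort silently")
  invisible(TRUE)
}

#' Segment detection records into feeding bouts
#'
#' Single pass over each bird's time-sorted records: a new bout starts at the
#' first record, whenever the gap to the previous record exceeds
#' `record_gap_threshold_s`, or whenever the antenna changes (the gap
#' criterion is defined for visits at the *same* feeder, so a feeder switch
#' always closes the bout, whatever the gap).
#'
#' Duration convention: each 1 Hz record stands for one second of presence,
#' so `duration_s = end - start + 1` and an isolated record is a 1 s bout.
#'
#' @param records Detection table sorted by `(bird_id, timestamp)` (as
#'   returned by [read_detection_log()] or [emit_detections()]). Unsorted
#'   input is an error, never silently reordered.
#' @param params A [segmentation_params()].
#' @return `data.table` with one row per bout: `bird_id`, `feeder_id`,
#'   `start`, `end`, `duration_s`, `n_records`, and `close_reason` in
#'   `{"gap", "switch", "end_of_log"}`.
#' @export
segment_bouts <- function(records, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  cols <- c("timestamp", "bird_id", "antenna_id")
  stopifnot(all(cols %in% names(records)))
  n <- nrow(records)
  if (n == 0L) {
    return(data.table::data.table(bird_id = character(), feeder_id = integer(),
                                  start = .parse_ts(character()),
                                  end = .parse_ts(character()),
                                  duration_s = numeric(), n_records = integer(),
                                  close_reason = character()))
  }
  thr <- params$record_gap_threshold_s
  t <- as.numeric(records$timestamp)
  bird <- records$bird_id
  ant <- records$antenna_id
  same <- bird[-1L] == bird[-n]
  dgap <- t[-1L] - t[-n]
  if (n > 1L) {
    # sortedness check shares the adjacent comparisons with segmentation
    chg <- which(!same)
    if (!(all(dgap[same] >= 0) && all(bird[-1L][chg] > bird[-n][chg])))
      stop("records must be sorted by (bird_id, timestamp); refusing to sort silently")
  }
  new_bird <- c(TRUE, !same)
  gap <- c(Inf, dgap)
  switch_ <- c(FALSE, ant[-1L] != ant[-n]) & !new_bird
  new_bout <- new_bird | switch_ | gap > thr
  si <- which(new_bout)
  ei <- c(si[-1L] - 1L, n)
  nb <- length(si)
  # close reason: why did the NEXT boundary occur
  reason <- rep("end_of_log", nb)
  if (nb > 1L) {
    same_bird_next <- bird[si][-nb] == bird[si][-1L]
    next_switch <- switch_[si[-1L]]
    reason[-nb][same_bird_next & next_switch] <- "switch"
    reason[-nb][same_bird_next & !next_switch] <- "gap"
  }
  out <- data.table::data.table(
    bird_id = bird[si], feeder_id = ant[si],
    start = records$timestamp[si], end = records$timestamp[ei],
    duration_s = t[ei] - t[si] + 1, n_records = ei - si + 1L,
    close_reason = reason)
  out[]
}

#' Quadratic reference segmenter (test oracle)
#'
#' Independent re-derivation of the bout partition used only for testing
#' [segment_bouts()]: every pair of records of the same bird is linked when
#' they are at the same feeder, at most the gap threshold apart, and no
#' detection of that bird at a different feeder falls between them; bouts
#' are the connected components (transitive closure) of that relation.
#' O(n^2) in records, intended for logs of at most a few thousand rows.
#'
#' @inheritParams segment_bouts
#' @return Same shape as [segment_bouts()] minus `close_reason`.
#' @export
merge_oracle <- function(records, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) {
    out <- segment_bouts(records, params)
    out[, close_reason := NULL]
    return(out)
  }
  .check_sorted(dt)
  thr <- params$record_gap_threshold_s
  res <- list()
  for (b in unique(dt$bird_id)) {
    sub <- dt[bird_id == b]
    n <- nrow(sub)
    t <- as.numeric(sub$timestamp)
    ant <- sub$antenna_id
    # feeder-run id: increments whenever this bird's antenna changes; a pair
    # with any different-feeder detection in between lies in different runs
    run <- cumsum(c(TRUE, ant[-1L] != ant[-n]))
    same_run <- outer(run, run, "==")
    close_enough <- abs(outer(t, t, "-")) <= thr
    adj <- same_run & close_enough
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    sub[, comp := comp]
    res[[b]] <- sub[, .(bird_id = b, feeder_id = antenna_id[1L],
                        start = timestamp[1L], end = timestamp[.N],
                        n_records = .N),
                    by = comp][, comp := NULL]
  }
  out <- data.table::rbindlist(res)
  out[, duration_s := as.numeric(end) - as.numeric(start) + 1]
  data.table::setorder(out, bird_id, start)
  out[, .(bird_id, feeder_id, start, end, duration_s, n_records)]
}

#' Write a bout table to CSV
#' @param bouts Bout table from [segment_bouts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  dt <- data.table::as.data.table(bouts)
  out <- data.table::copy(dt)
  out[, `:=`(start = .format_ts(start), end = .format_ts(end))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a bout table written by [write_bouts()]
#' @param path CSV path.
#' @return Bout `data.table`.
#' @export
read_bouts <- function(path) {
  if (!file.exists(path)) stop("bout file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "bird_id"))
  dt[, `:=`(start = .parse_ts(start), end = .parse_ts(end))]
  dt[]
}
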