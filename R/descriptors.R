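# Daily feeding-behaviour descriptors.
#
# For each bird and calendar day in the analysis window:
#   NFV    number of feeder visits (bouts)
#   MFBD   mean feeding bout duration per visit, seconds (NA when NFV = 0)
#   NDF    number of different feeders visited
# A bout belongs to the calendar day of its START; bouts spanning midnight
# are not split.

#' Analysis calendar
#'
#' Maps calendar dates to bird age in days and fixes the analysis window.
#'
#' @param hatch_date `Date`: day of age 0.
#' @param age_window Integer vector of ages (days) to analyse; default 20:30.
#' @return A `feed_calendar` list.
#' @export
feed_calendar <- function(hatch_date = as.Date("2024-01-01"),
                          age_window = 20:30) {
  stopifnot(inherits(hatch_date, "Date"), length(age_window) >= 1)
  structure(list(hatch_date = hatch_date,
                 age_window = as.integer(sort(age_window))),
            class = "feed_calendar")
}

#' Compute daily feeding descriptors per bird
#'
#' @param bouts Bout table ([segment_bouts()]).
#' @param calendar A [feed_calendar()] giving hatch date and age window.
#' @param birds Optional character vector of bird IDs to report; defaults to
#'   the birds present in `bouts`.  Birds with no bout on a window day get a
#'   row with `nfv = 0`, `ndf = 0`, `mfbd_s = NA`.
#' @param active_window Optional length-2 numeric `c(start_s, end_s)` seconds
#'   since midnight; when given, only bouts starting inside it contribute
#'   (lights-off masking). Default `NULL`: no masking.
#' @return `data.table` with one row per bird x window day: `bird_id`,
#'   `age_days`, `nfv`, `mfbd_s`, `ndf`, `total_feeding_s`.  Attribute
#'   `n_outside_window` counts bouts falling outside the age window.
#' @export
compute_daily_descriptors <- function(bouts, calendar = feed_calendar(),
                                      birds = NULL, active_window = NULL) {
  stopifnot(inherits(calendar, "feed_calendar"))
  dt <- data.table::as.data.table(bouts)
  if (is.null(birds)) birds <- sort(unique(dt$bird_id))
  grid <- data.table::CJ(bird_id = as.character(birds),
                         age_days = calendar$age_window)
  if (nrow(dt) == 0L) {
    out <- grid[, .(bird_id, age_days, nfv = 0L, mfbd_s = NA_real_,
                    ndf = 0L, total_feeding_s = 0)]
    data.table::setattr(out, "n_outside_window", 0L)
    return(out)
  }
  day <- as.Date(dt$start, tz = "UTC")
  dt[, age_days := as.integer(day - calendar$hatch_date)]
  n_out <- sum(!(dt$age_days %in% calendar$age_window))
  dt <- dt[age_days %in% calendar$age_window]
  if (!is.null(active_window)) {
    tod <- as.numeric(dt$start) %% 86400
    dt <- dt[tod >= active_window[1] & tod <= active_window[2]]
  }
  agg <- dt[, .(nfv = .N,
                mfbd_s = mean(duration_s),
                ndf = data.table::uniqueN(feeder_id),
                total_feeding_s = sum(duration_s)),
            by = .(bird_id, age_days)]
  out <- agg[grid, on = c("bird_id", "age_days")]
  out[is.na(nfv), `:=`(nfv = 0L, ndf = 0L, total_feeding_s = 0)]
  data.table::setorder(out, bird_id, age_days)
  data.table::setattr(out, "n_outside_window", n_out)
  out[]
}

#' Flag extreme descriptor outliers (k standard deviations)
#'
#' Marks bird-day observations whose descriptor value deviates from the
#' pooled mean of that descriptor by more than `k` standard deviations
#' (two-sided).  Mean and SD are computed once over ALL observations
#' (including the outliers) — a single pass, no re-computation after
#' removal — and exclusion is per descriptor and per observation: an NFV
#' outlier is only removed from the NFV analysis set.
#'
#' @param descriptors Table from [compute_daily_descriptors()].
#' @param k Positive threshold multiplier, default 4. `k = Inf` flags
#'   nothing.  Zero-SD (constant) descriptors flag nothing.
#' @param vars Descriptor columns to screen.
#' @return List with `data`: the input plus logical columns
#'   `<var>_outlier`; `filtered`: named list of per-descriptor analysis
#'   tables (rows with that descriptor's outliers removed, missing values
#'   kept out of MFBD's set); and `report`: per-descriptor mean, sd, k,
#'   and excluded observations.
#' @export
flag_outliers <- function(descriptors, k = 4,
                          vars = c("nfv", "mfbd_s", "ndf")) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop("k must be a single positive number")
  dt <- data.table::as.data.table(descriptors)
  stopifnot(all(vars %in% names(dt)))
  report <- list()
  filtered <- list()
  for (v in vars) {
    x <- dt[[v]]
    mu <- mean(x, na.rm = TRUE)
    sdv <- stats::sd(x, na.rm = TRUE)
    flag <- if (!is.finite(sdv) || sdv == 0 || !is.finite(k)) {
      rep(FALSE, length(x))
    } else {
      !is.na(x) & abs(x - mu) > k * sdv
    }
    dt[, paste0(v, "_outlier") := flag]
    report[[v]] <- list(mean = mu, sd = sdv, k = k,
                        n_excluded = sum(flag),
                        excluded = dt[flag, .(bird_id, age_days,
                                              value = get(v))])
    filtered[[v]] <- dt[!flag & !is.na(dt[[v]])]
  }
  list(data = dt[], filtered = filtered, report = report)
}

#' Write a descriptor table (with outlier flags if present) to CSV
#' @param descriptors Descriptor table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  data.table::fwrite(data.table::as.data.table(descriptors), path)
  invisible(path)
}
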