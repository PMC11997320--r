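# Diagnostic figures: per-bird spatio-temporal visit maps and the daily
# descriptor trend panels.

#' Spatio-temporal feeder-visit plot for one bird-day
#'
#' Time of day on the x-axis, feeder number on the y-axis, one horizontal
#' segment per bout, a dashed line at the virtual half-pen boundary, and a
#' distinct colour per feeder.  When the bird has no bout on the requested
#' day an annotated placeholder is returned rather than an error.
#'
#' @param bouts Bout table ([segment_bouts()] output).
#' @param bird_id Bird to plot.
#' @param date `Date` of the day to plot (calendar day of bout start).
#' @param layout A [pen_layout()] (for the half boundary and feeder range).
#' @return A `ggplot` object.
#' @export
plot_spatiotemporal <- function(bouts, bird_id, date, layout = pen_layout()) {
  dt <- data.table::as.data.table(bouts)
  bid <- bird_id
  dt <- dt[dt$bird_id == bid & as.Date(start, tz = "UTC") == date]
  halfA <- layout$feeder_ids[layout$pen_half == "A"]
  boundary <- max(halfA) + 0.5
  base <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = boundary, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = range(layout$feeder_ids) + c(-0.5, 0.5),
                                breaks = layout$feeder_ids) +
    ggplot2::labs(x = "Time of day (h)", y = "Feeder / antenna number",
                  title = paste0("Bird ", bid, ", ", format(date))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (nrow(dt) == 0L) {
    return(base + ggplot2::annotate("text", x = 12, y = boundary,
                                    label = "no feeder visits recorded"))
  }
  tod <- function(x) (as.numeric(x) %% 86400) / 3600
  dt[, `:=`(x0 = tod(start), x1 = tod(start) + duration_s / 3600,
            feeder = factor(feeder_id))]
  base +
    ggplot2::geom_segment(data = dt,
                          ggplot2::aes(x = x0, xend = x1,
                                       y = feeder_id, yend = feeder_id,
                                       colour = feeder),
                          linewidth = 2) +
    ggplot2::scale_x_continuous(limits = c(0, 24), breaks = seq(0, 24, 4))
}

#' Daily descriptor trend panels
#'
#' Three stacked panels: mean (across birds) NFV, MFBD and NDF per day of
#' age, the standard way to eyeball the age trends the mixed models
#' quantify.
#'
#' @param descriptors Daily descriptor table.
#' @return A `ggplot` object (facetted).
#' @export
plot_descriptor_trends <- function(descriptors) {
  dt <- data.table::as.data.table(descriptors)
  if (data.table::uniqueN(dt$age_days) < 2L)
    stop("need at least 2 days of data for a trend plot")
  m <- dt[, .(`NFV (visits/day)` = mean(nfv, na.rm = TRUE),
              `MFBD (s)` = mean(mfbd_s, na.rm = TRUE),
              `NDF (feeders/day)` = mean(ndf, na.rm = TRUE)),
          by = age_days]
  long <- data.table::melt(m, id.vars = "age_days",
                           variable.name = "descriptor")
  ggplot2::ggplot(long, ggplot2::aes(age_days, value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~descriptor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Age (days)", y = "Mean across birds") +
    ggplot2::theme_minimal()
}
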