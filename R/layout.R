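#' Pen layout: feeders, antennas and pen halves
#'
#' Describes the physical feeder line(s) of one pen: which feeder IDs exist,
#' which of them carry an RFID antenna (only those can ever appear in a
#' detection log), and which virtual pen half each feeder belongs to (used by
#' the spatio-temporal plots to draw the half-pen boundary).
#'
#' The default layout mirrors a 16-feeder pen in which one feeder (ID 1)
#' could not be fitted with an antenna, leaving 15 instrumented feeders, and
#' feeders 1-8 lie in half `"A"`, feeders 9-16 in half `"B"`.
#'
#' @param feeder_ids Integer vector of feeder identifiers (ordered).
#' @param antenna_equipped Integer vector, subset of `feeder_ids`: feeders
#'   carrying an RFID antenna.
#' @param pen_half Character vector (values `"A"`/`"B"`) parallel to
#'   `feeder_ids`, or `NULL` to split the ordered `feeder_ids` in two halves.
#' @return An object of class `pen_layout`: a list with elements
#'   `feeder_ids`, `antenna_equipped`, `pen_half` (named character vector)
#'   and `n_feeders_total`.
#' @examples
#' lay <- pen_layout()
#' length(lay$antenna_equipped)  # 15
#' @export
pen_layout <- function(feeder_ids = 1:16,
                       antenna_equipped = 2:16,
                       pen_half = NULL) {
  feeder_ids <- as.integer(feeder_ids)
  antenna_equipped <- as.integer(antenna_equipped)
  if (anyDuplicated(feeder_ids))
    stop("duplicate feeder_ids in layout")
  if (!all(antenna_equipped %in% feeder_ids))
    stop("antenna_equipped must be a subset of feeder_ids")
  if (is.null(pen_half)) {
    half <- rep(c("A", "B"), c(ceiling(length(feeder_ids) / 2),
                               floor(length(feeder_ids) / 2)))
  } else {
    half <- as.character(pen_half)
    if (length(half) != length(feeder_ids))
      stop("pen_half must have one entry per feeder")
    if (!all(half %in% c("A", "B")))
      stop("pen_half values must be 'A' or 'B'")
  }
  names(half) <- feeder_ids
  structure(list(feeder_ids = feeder_ids,
                 antenna_equipped = sort(antenna_equipped),
                 pen_half = half,
                 n_feeders_total = length(feeder_ids)),
            class = "pen_layout")
}

#' @export
print.pen_layout <- function(x, ...) {
  cat("<pen_layout> ", x$n_feeders_total, " feeders, ",
      length(x$antenna_equipped), " antenna-equipped\n", sep = "")
  cat("  no antenna:", setdiff(x$feeder_ids, x$antenna_equipped), "\n")
  cat("  half A:", x$feeder_ids[x$pen_half == "A"], "\n")
  cat("  half B:", x$feeder_ids[x$pen_half == "B"], "\n")
  invisible(x)
}

#' Read / write a pen layout config
#'
#' Layouts are stored as plain JSON so they can be versioned next to the
#' detection logs they describe.
#'
#' @param path File path.
#' @return `read_layout()` returns a [pen_layout()]; `write_layout()` its
#'   `path`, invisibly.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pen_layout(feeder_ids = x$feeder_ids,
             antenna_equipped = x$antenna_equipped,
             pen_half = x$pen_half)
}

#' @rdname read_layout
#' @param layout A [pen_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "pen_layout"))
  jsonlite::write_json(
    list(feeder_ids = layout$feeder_ids,
         antenna_equipped = layout$antenna_equipped,
         pen_half = unname(layout$pen_half)),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
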