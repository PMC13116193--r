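#' Canonical 18-unit insole sensor layout
#'
#' Returns the default layout of the 18-unit flexible pressure-sensing insole.
#' Each unit carries a planar coordinate (mm; x positive towards the medial
#' edge, y from heel towards the toes) and an anatomical region tag. Thirteen
#' units cover the five key plantar regions — calcaneus (Cal), navicular
#' (Nav), first metatarsal (M1), fifth metatarsal (M5) and phalanx (Pha) —
#' and the remaining five sit outside those regions (`Other`); with default
#' generator settings the `Other` units are the near-inactive channels that
#' the dataset builder later excludes.
#'
#' The coordinates are a declared module default: they place the regions in
#' their textbook anatomical order along the sole but are not measured from
#' any physical insole.
#'
#' @return An object of class `sensor_layout`: a data frame with columns
#'   `id`, `x_mm`, `y_mm`, `region` and `unit_gain` (a fixed within-region
#'   amplitude factor giving neighbouring units slightly different scale).
#' @export
#' @examples
#' layout <- make_default_layout()
#' table(layout$region)
make_default_layout <- function() {
  layout <- data.frame(
    id = 1:18,
    x_mm = c(-15,  15,   0,   25,  18, -30, -35,  30,  18,   5,
              20,   5, -12,  -25, -20, -10,  35, -38),
    y_mm = c( 30,  30,  10,   95,  75, 120, 145, 150, 155, 152,
             185, 195, 188,   60,  85, 105, 120,  95),
    region = c("Cal", "Cal", "Cal",
               "Nav", "Nav",
               "M5", "M5",
               "M1", "M1", "M1",
               "Pha", "Pha", "Pha",
               "Other", "Other", "Other", "Other", "Other"),
    unit_gain = c(1.00, 0.92, 0.85,
                  1.00, 0.90,
                  1.00, 0.88,
                  1.00, 0.93, 0.86,
                  1.00, 0.90, 0.82,
                  0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  class(layout) <- c("sensor_layout", "data.frame")
  validate_layout(layout)
  layout
}

#' @keywords internal
validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout))
  req <- c("id", "x_mm", "y_mm", "region")
  if (!all(req %in% names(layout)))
    stop("layout must have columns ", paste(req, collapse = ", "))
  if (nrow(layout) != 18L)
    stop("layout must contain exactly 18 sensing units, got ", nrow(layout))
  if (anyDuplicated(layout$id))
    stop("layout unit ids must be unique")
  bad <- setdiff(unique(layout$region), c(key_regions(), "Other"))
  if (length(bad))
    stop("unknown region tag(s): ", paste(bad, collapse = ", "))
  missing_regions <- setdiff(key_regions(), layout$region)
  if (length(missing_regions))
    stop("every key region needs at least one unit; missing: ",
         paste(missing_regions, collapse = ", "))
  invisible(layout)
}

#' The five key plantar regions
#'
#' @return Character vector `c("Cal", "Nav", "M1", "M5", "Pha")`.
#' @export
key_regions <- function() c("Cal", "Nav", "M1", "M5", "Pha")

#' Unit ids assigned to a region
#' @param layout A `sensor_layout`.
#' @param region Region tag.
#' @return Integer vector of unit ids.
#' @export
region_units <- function(layout, region) layout$id[layout$region == region]

#' Write / read a sensor layout as JSON
#'
#' @param layout A `sensor_layout`.
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns
#'   the `sensor_layout`.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  jsonlite::write_json(
    lapply(seq_len(nrow(layout)), function(i) list(
      id = layout$id[i], x_mm = layout$x_mm[i], y_mm = layout$y_mm[i],
      region = layout$region[i], unit_gain = layout$unit_gain[i]
    )),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  units <- jsonlite::read_json(path, simplifyVector = TRUE)
  layout <- data.frame(
    id = as.integer(units$id), x_mm = as.numeric(units$x_mm),
    y_mm = as.numeric(units$y_mm), region = as.character(units$region),
    unit_gain = as.numeric(units$unit_gain), stringsAsFactors = FALSE
  )
  layout <- layout[order(layout$id), , drop = FALSE]
  rownames(layout) <- NULL
  class(layout) <- c("sensor_layout", "data.frame")
  validate_layout(layout)
  layout
}
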