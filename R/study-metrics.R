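#' Relative proliferation rate of target cells in a co-culture assay
#'
#' In the co-culture design, target (e.g. pancreatic cancer) cells are
#' plated 1:1 with marker-tagged therapeutic cells, while the control well
#' receives twice the number of target cells alone.  Per field, the target
#' cell count in co-culture is the total count minus the marker-positive
#' count, and the relative proliferation rate is
#' `((co_total - co_marker) * 2 / control_count) * 100` percent — the
#' factor 2 compensates for the halved seeding density of the target cells
#' in the co-culture well.
#'
#' @param co_total Total cell count in the co-culture field.
#' @param co_marker Marker-positive (therapeutic) cell count in the same
#'   field; must not exceed `co_total`.
#' @param control_count Target-cell count in the control field; must be
#'   positive.
#' @return Relative proliferation rate, in percent.  Vectorized over
#'   fields.
#' @examples
#' relative_proliferation_rate(150, 50, 200)  # 100%
#' relative_proliferation_rate(113, 50, 200)  # 63%
#' @export
relative_proliferation_rate <- function(co_total, co_marker, control_count) {
  if (!is.numeric(co_total) || !is.numeric(co_marker) ||
      !is.numeric(control_count)) {
    rv_validation_error("all counts must be numeric")
  }
  n <- max(length(co_total), length(co_marker), length(control_count))
  co_total <- rep_len(co_total, n)
  co_marker <- rep_len(co_marker, n)
  control_count <- rep_len(control_count, n)
  if (any(!is.finite(co_total) | !is.finite(co_marker) |
          !is.finite(control_count))) {
    rv_validation_error("counts must be finite")
  }
  if (any(co_total < 0 | co_marker < 0)) {
    rv_validation_error("counts must be non-negative")
  }
  if (any(control_count <= 0)) {
    rv_validation_error("'control_count' must be positive")
  }
  if (any(co_marker > co_total)) {
    rv_validation_error("'co_marker' cannot exceed 'co_total'")
  }
  ((co_total - co_marker) * 2 / control_count) * 100
}

#' Caliper tumor volume
#'
#' Standard ellipsoid approximation from two caliper axes:
#' `volume = width^2 * length * 0.5`, with width the smaller axis.  If a
#' width larger than the paired length is supplied the two are swapped with
#' a warning, since the formula is not symmetric in its arguments.
#'
#' @param width,length_ Caliper measurements in mm.  Vectorized.
#' @return Tumor volume in mm^3.
#' @examples
#' tumor_volume(4, 8)  # 64
#' @export
tumor_volume <- function(width, length_) {
  if (!is.numeric(width) || !is.numeric(length_)) {
    rv_validation_error("dimensions must be numeric")
  }
  n <- max(length(width), length(length_))
  width <- rep_len(width, n)
  length_ <- rep_len(length_, n)
  if (any(!is.finite(width) | !is.finite(length_)) ||
      any(width <= 0 | length_ <= 0)) {
    rv_validation_error("tumor dimensions must be positive and finite")
  }
  flipped <- width > length_
  if (any(flipped)) {
    warning(sprintf(
      "%d measurement(s) had width > length; axes swapped (width is the smaller axis)",
      sum(flipped)), call. = FALSE)
    tmp <- width[flipped]
    width[flipped] <- length_[flipped]
    length_[flipped] <- tmp
  }
  width^2 * length_ * 0.5
}

#' Add caliper volumes to a tumor-measurement table
#'
#' Takes a tidy measurements table (columns `animal_id`, `day`, `width_mm`,
#' `length_mm`, optionally `body_weight_g` and `group`) and appends a
#' `volume_mm3` column, for export to standard group-comparison tools.
#'
#' @param measurements data.frame with at least `width_mm` and `length_mm`.
#' @return The input data.frame with a `volume_mm3` column appended.
#' @export
add_tumor_volumes <- function(measurements) {
  if (!is.data.frame(measurements)) {
    rv_validation_error("'measurements' must be a data.frame")
  }
  if (!all(c("width_mm", "length_mm") %in% names(measurements))) {
    rv_format_error("measurements need columns 'width_mm' and 'length_mm'")
  }
  measurements$volume_mm3 <- tumor_volume(measurements$width_mm,
                                          measurements$length_mm)
  measurements
}
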