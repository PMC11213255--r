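#' Pixel-to-millimetre calibration from a scale segment
#'
#' @param p1,p2 Endpoints of a segment of known physical length, `c(x, y)`
#'   pixels.
#' @param known_mm Physical length of the segment, mm.
#' @return An object of class `scale_calibration` with field `mm_per_px`.
#' @export
#' @examples
#' calibrate(c(0, 0), c(100, 0), 10)$mm_per_px  # 0.1 mm/px
calibrate <- function(p1, p2, known_mm) {
  if (!(known_mm > 0)) stop("known_mm must be > 0", call. = FALSE)
  d <- sqrt(sum((as.numeric(p2) - as.numeric(p1))^2))
  if (d == 0) stop("calibration points coincide", call. = FALSE)
  cal <- list(mm_per_px = known_mm / d)
  class(cal) <- "scale_calibration"
  cal
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> %.6g mm/px\n", x$mm_per_px))
  invisible(x)
}

#' Angle of a directed segment, in the y-up botanical convention
#'
#' Input points are in image coordinates (y down); the returned angle is
#' measured counter-clockwise from the horizontal with positive values
#' meaning the segment points upward in the scene, i.e.
#' `atan2(origin_y - end_y, end_x - origin_x)` in degrees, range (-180, 180].
#'
#' @param origin,end Segment endpoints `c(x, y)`, pixels.
#' @return Angle in degrees.
#' @export
#' @examples
#' segment_angle(c(0, 100), c(0, 50))  # 90: end is above origin
segment_angle <- function(origin, end) {
  dx <- end[1] - origin[1]
  dy <- origin[2] - end[2]  # flip image-down to plant-up
  if (dx == 0 && dy == 0) stop("segment endpoints coincide", call. = FALSE)
  atan2(dy, dx) * 180 / pi
}

#' Convert a pixel trajectory into leaf angle and length metrics
#'
#' Per frame: petiole angle and length from (center, junction), lamina from
#' (junction, tip), whole leaf from (center, tip); the junction angle is the
#' signed difference lamina minus petiole (a downward-kinked lamina gives
#' negative values); leaf-tip elevation is the vertical tip position above
#' the rosette center; projected lamina length is the absolute horizontal
#' extent from junction to tip. Angles are degrees above horizontal, lengths
#' millimetres. Frames flagged during tracking (or with confidence below
#' `min_confidence`) propagate as missing values — interpolation policy
#' belongs to the kinetics layer, never here.
#'
#' @param track A `track_table` from [track_sequence()] or
#'   [read_trajectory()].
#' @param cal A [calibrate()] result.
#' @param start_zt_h Zeitgeber time of the first frame, hours; used to fill
#'   the `zt_h` column (`NA` if unknown — [sync_by_transition()] can infer it
#'   from the day/night transition).
#' @param min_confidence Confidence below which a landmark's frame is
#'   treated as missing when explicit `lost_*` flags are absent.
#' @return A tibble of class `leaf_metrics`: per frame `frame`, `t_min`,
#'   `zt_h`, `illumination`, `petiole_angle_deg`, `lamina_angle_deg`,
#'   `leaf_angle_deg`, `junction_angle_deg`, `petiole_len_mm`,
#'   `lamina_len_mm`, `leaf_len_mm`, `tip_height_mm`, `projected_lamina_mm`.
#' @export
compute_metrics <- function(track, cal, start_zt_h = NA_real_,
                            min_confidence = 0.2) {
  stopifnot(inherits(cal, "scale_calibration"))
  mpp <- cal$mm_per_px
  lost_j <- if ("lost_j" %in% names(track)) track$lost_j else track$confidence_j < min_confidence
  lost_t <- if ("lost_t" %in% names(track)) track$lost_t else track$confidence_t < min_confidence
  bad <- lost_j | lost_t
  if (all(bad)) stop("all frames flagged; nothing to measure", call. = FALSE)

  deg <- 180 / pi
  ang <- function(x1, y1, x2, y2) atan2(y1 - y2, x2 - x1) * deg
  len <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2) * mpp

  out <- tibble::tibble(
    frame = track$frame,
    t_min = track$t_min,
    zt_h = if (is.na(start_zt_h)) NA_real_ else start_zt_h + track$t_min / 60,
    illumination = track$illumination,
    petiole_angle_deg = ang(track$cx, track$cy, track$jx, track$jy),
    lamina_angle_deg = ang(track$jx, track$jy, track$tx, track$ty),
    leaf_angle_deg = ang(track$cx, track$cy, track$tx, track$ty),
    petiole_len_mm = len(track$cx, track$cy, track$jx, track$jy),
    lamina_len_mm = len(track$jx, track$jy, track$tx, track$ty),
    leaf_len_mm = len(track$cx, track$cy, track$tx, track$ty)
  )
  out$junction_angle_deg <- out$lamina_angle_deg - out$petiole_angle_deg
  out$tip_height_mm <- (track$cy - track$ty) * mpp
  out$projected_lamina_mm <- abs(track$tx - track$jx) * mpp
  metric_cols <- metric_columns(out)
  out[bad, metric_cols] <- NA_real_
  out <- out[, c("frame", "t_min", "zt_h", "illumination",
                 "petiole_angle_deg", "lamina_angle_deg", "leaf_angle_deg",
                 "junction_angle_deg", "petiole_len_mm", "lamina_len_mm",
                 "leaf_len_mm", "tip_height_mm", "projected_lamina_mm")]
  class(out) <- c("leaf_metrics", class(out))
  out
}

# names of numeric metric columns in a metrics-like table
metric_columns <- function(df) {
  known <- c("petiole_angle_deg", "lamina_angle_deg", "leaf_angle_deg",
             "junction_angle_deg", "petiole_len_mm", "lamina_len_mm",
             "leaf_len_mm", "tip_height_mm", "projected_lamina_mm")
  intersect(known, names(df))
}

#' Read or write a leaf metrics table
#'
#' @param path CSV file path.
#' @return `read_metrics()` returns a `leaf_metrics` tibble;
#'   `write_metrics()` returns `path` invisibly.
#' @export
read_metrics <- function(path) {
  mt <- readr::read_csv(path, show_col_types = FALSE)
  class(mt) <- c("leaf_metrics", class(mt))
  mt
}

#' @rdname read_metrics
#' @param metrics A `leaf_metrics` tibble.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(path)
}
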