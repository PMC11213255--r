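#' Landmark annotation for one plant
#'
#' The annotation carries everything the tracker needs that a user supplies
#' by clicking (or, here, that the simulator writes): the rosette center in
#' the first and last frame, the petiole-lamina junction and leaf tip in the
#' first frame, and a scale segment of known physical length for
#' pixel-to-millimetre calibration. Points are `c(x, y)` in 0-based pixel
#' coordinates of the (cropped) frame.
#'
#' @param plant_id Plant identifier string.
#' @param center_first,center_last Rosette center in first/last frame.
#' @param junction_first,tip_first Junction and tip in the first frame.
#' @param scale_p1,scale_p2 Endpoints of the scale segment.
#' @param scale_len_mm Physical length of the scale segment, mm.
#' @param crop_rect Optional crop rectangle `c(x, y, w, h)` applied to raw
#'   frames before any coordinates are interpreted.
#' @param treatment Optional treatment label carried through to outputs.
#' @return An object of class `annotation`.
#' @export
annotation <- function(plant_id, center_first, center_last, junction_first,
                       tip_first, scale_p1, scale_p2, scale_len_mm,
                       crop_rect = NULL, treatment = NULL) {
  ann <- list(
    plant_id = as.character(plant_id),
    center_first = as.numeric(center_first),
    center_last = as.numeric(center_last),
    junction_first = as.numeric(junction_first),
    tip_first = as.numeric(tip_first),
    scale_p1 = as.numeric(scale_p1),
    scale_p2 = as.numeric(scale_p2),
    scale_len_mm = as.numeric(scale_len_mm),
    crop_rect = if (is.null(crop_rect)) NULL else as.numeric(crop_rect),
    treatment = treatment
  )
  class(ann) <- "annotation"
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann, image_dim = NULL) {
  pts <- c("center_first", "center_last", "junction_first", "tip_first",
           "scale_p1", "scale_p2")
  for (p in pts) {
    if (length(ann[[p]]) != 2 || any(!is.finite(ann[[p]]))) {
      stop("annotation field '", p, "' must be a finite (x, y) pair", call. = FALSE)
    }
  }
  if (identical(ann$scale_p1, ann$scale_p2)) {
    stop("scale_p1 and scale_p2 must differ", call. = FALSE)
  }
  if (!(ann$scale_len_mm > 0)) stop("scale_len_mm must be > 0", call. = FALSE)
  if (!is.null(image_dim)) {  # image_dim = c(h, w)
    for (p in pts) {
      xy <- ann[[p]]
      if (xy[1] < 0 || xy[1] > image_dim[2] - 1 || xy[2] < 0 || xy[2] > image_dim[1] - 1) {
        stop("annotation field '", p, "' lies outside the image", call. = FALSE)
      }
    }
  }
  invisible(ann)
}

#' Read or write an annotation file
#'
#' Annotations are flat YAML key:value files, one per plant, with exactly the
#' fields of [annotation()].
#'
#' @param path File path.
#' @return `read_annotation()` returns an `annotation`; `write_annotation()`
#'   returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(annotation))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown annotation keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(annotation, vals)
}

#' @rdname read_annotation
#' @param ann An `annotation`.
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  vals <- unclass(ann)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Load an ordered image sequence from a directory
#'
#' Frames are ordered by the timestamp parsed from their filenames (pattern
#' `frame_{index}_{t_min}.png`), never by file modification time, so
#' sequences survive copying between machines. Gaps relative to the modal
#' frame interval are tolerated with a warning up to `max_gap_fraction` of
#' the expected frames; larger losses raise an error because they would
#' corrupt downstream kinetics.
#'
#' @param dir Directory containing the frames.
#' @param pattern Filename regular expression with two capture groups:
#'   frame index and time in minutes.
#' @param max_gap_fraction Maximum tolerated fraction of missing frames.
#' @return A tibble of class `frame_sequence` with columns `frame`, `t_min`,
#'   `path`, sorted by `t_min`.
#' @export
load_sequence <- function(dir, pattern = "^frame_(\\d+)_([0-9.]+)\\.png$",
                          max_gap_fraction = 0.05) {
  files <- list.files(dir, full.names = FALSE)
  files <- files[grepl(pattern, files)]
  if (length(files) < 2) {
    stop("need at least 2 frames matching the pattern in ", dir, call. = FALSE)
  }
  m <- regmatches(files, regexec(pattern, files))
  idx <- suppressWarnings(as.integer(vapply(m, `[`, "", 2)))
  t_min <- suppressWarnings(as.numeric(vapply(m, `[`, "", 3)))
  if (any(is.na(idx)) || any(is.na(t_min))) {
    stop("unparseable frame filename: ", files[which(is.na(idx) | is.na(t_min))[1]],
         call. = FALSE)
  }
  ord <- order(t_min)
  seq_tbl <- tibble::tibble(
    frame = idx[ord], t_min = t_min[ord],
    path = file.path(dir, files[ord])
  )
  if (any(duplicated(seq_tbl$t_min))) {
    stop("duplicate frame timestamps in ", dir, call. = FALSE)
  }
  dt <- diff(seq_tbl$t_min)
  interval <- min(dt)
  n_missing <- sum(round(dt / interval) - 1)
  if (n_missing > 0) {
    n_expected <- nrow(seq_tbl) + n_missing
    if (n_missing / n_expected > max_gap_fraction) {
      stop(sprintf("%d of %d expected frames missing (> %.0f%%); re-acquire or relax max_gap_fraction",
                   n_missing, n_expected, 100 * max_gap_fraction), call. = FALSE)
    }
    warning(sprintf("%d missing frame(s) detected in %s (expected interval %g min)",
                    n_missing, dir, interval), call. = FALSE)
  }
  class(seq_tbl) <- c("frame_sequence", class(seq_tbl))
  seq_tbl
}

#' Read one frame as an RGB array
#'
#' @param path PNG file path.
#' @return An `h x w x 3` array in `[0, 1]`. Grayscale or RGBA files are
#'   promoted/truncated to 3 channels.
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Crop a frame to a rectangle
#'
#' The rectangle is `c(x, y, w, h)` in 0-based pixel coordinates: output
#' pixel (0, 0) is input pixel (x, y).
#'
#' @param frame An image array (`h x w` or `h x w x c`).
#' @param rect Crop rectangle `c(x, y, w, h)`.
#' @return The cropped image with dimensions `h x w` from `rect`.
#' @export
crop_frame <- function(frame, rect) {
  stopifnot(length(rect) == 4)
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  d <- dim(frame)
  if (w <= 0 || h <= 0 || x < 0 || y < 0 || x + w > d[2] || y + h > d[1]) {
    stop(sprintf("crop rect (%g, %g, %g, %g) out of bounds for %dx%d frame",
                 x, y, w, h, d[2], d[1]), call. = FALSE)
  }
  rows <- (y + 1):(y + h); cols <- (x + 1):(x + w)
  if (length(d) == 2) frame[rows, cols, drop = FALSE]
  else frame[rows, cols, , drop = FALSE]
}

#' Classify a frame as day or night from its channel spread
#'
#' Night frames from an infrared camera are achromatic: R, G and B carry the
#' same signal, so the per-pixel spread `max(R,G,B) - min(R,G,B)` is
#' essentially zero, while daytime frames on a blue background are strongly
#' chromatic. A frame is night when the mean per-pixel spread, in 8-bit gray
#' levels, does not exceed `gray_tol`.
#'
#' @param frame An `h x w x 3` array in `[0, 1]`.
#' @param gray_tol Threshold in 8-bit gray levels.
#' @return `"day"` or `"night"`.
#' @export
classify_illumination <- function(frame, gray_tol = 8) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] >= 3)
  spread <- pmax(frame[, , 1], frame[, , 2], frame[, , 3]) -
    pmin(frame[, , 1], frame[, , 2], frame[, , 3])
  if (mean(spread) * 255 <= gray_tol) "night" else "day"
}

#' Read or write a landmark trajectory table
#'
#' The trajectory CSV is the canonical interchange between tracking and
#' geometry: one row per frame with the rosette center (`cx, cy`,
#' interpolated), junction (`jx, jy`) and tip (`tx, ty`) pixel coordinates,
#' per-landmark tracking confidences, and the day/night label.
#'
#' @param path CSV file path.
#' @return `read_trajectory()` returns a tibble of class `track_table`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  tt <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("frame", "t_min", "illumination", "cx", "cy", "jx", "jy",
              "tx", "ty", "confidence_j", "confidence_t")
  missing <- setdiff(needed, names(tt))
  if (length(missing) > 0) {
    stop("trajectory file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  class(tt) <- c("track_table", class(tt))
  tt
}

#' @rdname read_trajectory
#' @param track A `track_table` tibble (see [track_sequence()]).
#' @export
write_trajectory <- function(track, path) {
  cols <- c("frame", "t_min", "illumination", "cx", "cy", "jx", "jy",
            "tx", "ty", "confidence_j", "confidence_t")
  readr::write_csv(track[, cols], path)
  invisible(path)
}
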