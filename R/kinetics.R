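#' Baseline-relative kinetic series
#'
#' Subtracts, per metric column, the mean of its first `n_baseline` valid
#' (non-missing) frames, so every series starts near zero and treatments are
#' compared as changes from their own pre-treatment state. Missing values
#' stay missing. With a `plant_id` column present, the baseline is computed
#' per plant.
#'
#' @param metrics A `leaf_metrics` tibble (optionally with `plant_id` /
#'   `treatment` columns for multi-plant input).
#' @param n_baseline Number of initial valid frames in the baseline.
#' @return The input with every metric column baseline-subtracted; class
#'   `kinetics_series`.
#' @export
relative_series <- function(metrics, n_baseline = 5) {
  cols <- metric_columns(metrics)
  if (length(cols) == 0) stop("no metric columns found", call. = FALSE)
  rebase <- function(df) {
    for (cl in cols) {
      v <- df[[cl]]
      ok <- which(!is.na(v))
      if (length(ok) < n_baseline) {
        stop(sprintf("fewer than %d valid frames for baseline of '%s'",
                     n_baseline, cl), call. = FALSE)
      }
      df[[cl]] <- v - mean(v[ok[seq_len(n_baseline)]])
    }
    df
  }
  out <- if ("plant_id" %in% names(metrics)) {
    metrics |>
      dplyr::group_by(.data$plant_id) |>
      dplyr::group_modify(~ rebase(.x)) |>
      dplyr::ungroup()
  } else {
    rebase(metrics)
  }
  class(out) <- unique(c("kinetics_series", class(out)))
  out
}

#' Time-synchronize plants on their day-to-night transition
#'
#' Acquisition clocks drift between cameras, but every frame records whether
#' the lights are on. Each plant's first day-to-night transition frame is
#' therefore assigned Zeitgeber time `lights_off_h`, and the whole series is
#' shifted (a pure time translation — no resampling) onto that common axis.
#' The resulting `zt_h` axis is continuous (it exceeds 24 on multi-day
#' runs). Plants whose implied shift exceeds `max_shift_min` relative to the
#' cohort median transition are flagged in `sync_flagged`.
#'
#' @param series A tibble with columns `plant_id`, `t_min`, `illumination`
#'   (e.g. stacked [relative_series()] outputs).
#' @param lights_off_h ZT hour of lights-off.
#' @param max_shift_min Largest credible clock offset, minutes.
#' @return The input with `zt_h` recomputed, plus `sync_shift_min` and
#'   `sync_flagged` columns.
#' @export
sync_by_transition <- function(series, lights_off_h = 9, max_shift_min = 30) {
  stopifnot(all(c("plant_id", "t_min", "illumination") %in% names(series)))
  find_transition <- function(df, id) {
    ill <- df$illumination
    i <- which(ill[-length(ill)] == "day" & ill[-1] == "night")
    if (length(i) == 0) {
      stop("no day-to-night transition found for plant ", id, call. = FALSE)
    }
    df$t_min[i[1] + 1]
  }
  trans <- series |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::group_modify(~ tibble::tibble(t_trans = find_transition(.x, .y$plant_id))) |>
    dplyr::ungroup()
  t_ref <- stats::median(trans$t_trans)
  trans$sync_shift_min <- trans$t_trans - t_ref
  trans$sync_flagged <- abs(trans$sync_shift_min) > max_shift_min

  out <- series |>
    dplyr::left_join(trans, by = "plant_id") |>
    dplyr::mutate(zt_h = lights_off_h + (.data$t_min - .data$t_trans) / 60) |>
    dplyr::select(-"t_trans")
  class(out) <- unique(c("kinetics_series", class(out)))
  out
}

#' Angular speed over a sliding window
#'
#' Speed at time t is the backward difference
#' `(theta(t) - theta(t - window)) / window`, reported in degrees per hour;
#' the first `window_min` of each plant's series yields missing values.
#' Because it is a difference, baseline subtraction cancels: relative and
#' absolute series give identical speeds.
#'
#' @param series A metrics or kinetics tibble with a `t_min` column sampled
#'   on a regular grid.
#' @param metric Name of the metric column to differentiate.
#' @param window_min Window length in minutes (at least two frame
#'   intervals).
#' @return A tibble with the identifying columns (`plant_id`, `treatment`,
#'   `frame`, `t_min`, `zt_h` where present) and `speed_deg_per_h`.
#' @export
angular_speed <- function(series, metric, window_min = 60) {
  if (!metric %in% names(series)) {
    stop("unknown metric '", metric, "'", call. = FALSE)
  }
  one <- function(df) {
    dt <- diff(df$t_min)
    interval <- dt[1]
    if (any(abs(dt - interval) > 1e-9)) {
      stop("angular_speed requires a regular time grid", call. = FALSE)
    }
    if (window_min < 2 * interval) {
      stop("window_min must be at least two frame intervals", call. = FALSE)
    }
    k <- window_min / interval
    if (abs(k - round(k)) > 1e-9) {
      stop("window_min must be a multiple of the frame interval", call. = FALSE)
    }
    k <- as.integer(round(k))
    v <- df[[metric]]
    speed <- rep(NA_real_, length(v))
    if (length(v) > k) {
      speed[(k + 1):length(v)] <- (v[(k + 1):length(v)] - v[1:(length(v) - k)]) /
        (window_min / 60)
    }
    df$speed_deg_per_h <- speed
    df
  }
  keep <- intersect(c("plant_id", "treatment", "frame", "t_min", "zt_h",
                      "illumination", "speed_deg_per_h"),
                    c(names(series), "speed_deg_per_h"))
  out <- if ("plant_id" %in% names(series)) {
    series |>
      dplyr::group_by(.data$plant_id) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(series)
  }
  out[, intersect(keep, names(out))]
}

#' Bin kinetic series on the common ZT axis
#'
#' Groups each plant's series into left-closed bins
#' `[k * bin_h, (k + 1) * bin_h)` anchored at ZT 0 and averages the valid
#' values per plant, metric and bin — the sampling unit for the per-bin
#' group statistics. Bins supported by fewer than `min_points` valid frames
#' are marked unreliable.
#'
#' @param series A synced kinetics tibble with `plant_id`, `zt_h` and metric
#'   columns (plus optional `treatment`, `genotype`).
#' @param bin_h Bin width, hours.
#' @param min_points Minimum valid frames per reliable bin.
#' @return A long tibble: `plant_id` (+ grouping columns), `metric`,
#'   `bin_start_zt_h`, `mean`, `n`, `reliable`.
#' @export
bin_series <- function(series, bin_h = 2, min_points = 10) {
  if (nrow(series) == 0) stop("empty input", call. = FALSE)
  stopifnot(all(c("plant_id", "zt_h") %in% names(series)))
  cols <- metric_columns(series)
  if (length(cols) == 0) stop("no metric columns found", call. = FALSE)
  group_cols <- intersect(c("plant_id", "treatment", "genotype"), names(series))
  series |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(bin_start_zt_h = floor(.data$zt_h / bin_h) * bin_h) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "metric", "bin_start_zt_h")))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean = ifelse(.data$n == 0, NA_real_, .data$mean),
      reliable = .data$n >= min_points
    )
}

#' Read or write a long-format kinetics table
#'
#' Long format: `plant_id, treatment, zt_h, metric, value`.
#'
#' @param path CSV file path.
#' @param series A kinetics tibble (wide metric columns).
#' @return `read_kinetics()` returns a wide `kinetics_series` tibble;
#'   `write_kinetics()` returns `path` invisibly.
#' @export
write_kinetics <- function(series, path) {
  cols <- metric_columns(series)
  id_cols <- intersect(c("plant_id", "treatment", "zt_h"), names(series))
  long <- tidyr::pivot_longer(series[, c(id_cols, cols)],
                              dplyr::all_of(cols),
                              names_to = "metric", values_to = "value")
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  out <- tidyr::pivot_wider(long, names_from = "metric", values_from = "value")
  class(out) <- unique(c("kinetics_series", class(out)))
  out
}
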