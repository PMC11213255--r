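#' Simulate the ground-truth pose of a moving, elongating leaf
#'
#' Evaluates the kinematic model described in [sim_scenario()] at every frame
#' time and returns the exact (noise-free) pose: petiole and lamina angles in
#' degrees above horizontal, lengths in mm, plus Zeitgeber time and the
#' day/night illumination state implied by the photoperiod.
#'
#' @param scenario A [sim_scenario()].
#' @return A tibble of class `pose_series` with one row per frame and columns
#'   `frame` (0-based), `t_min`, `zt_h`, `illumination`,
#'   `petiole_angle_deg`, `lamina_angle_deg`, `petiole_len_mm`,
#'   `lamina_len_mm`.
#' @export
#' @examples
#' pose <- simulate_pose(sim_scenario(duration_min = 60))
#' nrow(pose)  # 60 frames at 1/min
simulate_pose <- function(scenario) {
  validate_scenario(scenario)
  sc <- scenario
  n <- floor(sc$duration_min / sc$frame_interval_min)
  t_min <- (seq_len(n) - 1) * sc$frame_interval_min
  zt_h <- (sc$start_zt_h + t_min / 60) %% 24
  illum <- ifelse(zt_h >= sc$lights_on_zt_h & zt_h < sc$lights_off_zt_h,
                  "day", "night")

  sigma <- 1 / (1 + exp(-sc$hyponasty_rate_per_min * (t_min - sc$hyponasty_onset_min)))
  gate_on_min <- ((sc$lights_off_zt_h - sc$start_zt_h) %% 24) * 60
  gate <- as.numeric(t_min >= gate_on_min)
  diurnal <- sc$diurnal_amp_deg * sin(2 * pi * zt_h / 24)
  # oscillation phase is anchored at the first lights-off so the term turns
  # on continuously (zero crossing) instead of jumping mid-phase
  osc <- sc$dose * sc$osc_amp_deg *
    sin(2 * pi * (t_min - gate_on_min) / sc$osc_period_min) * gate

  theta_p <- sc$angle0_petiole_deg + diurnal + sc$dose * sc$hyponasty_amp_deg * sigma + osc
  theta_l <- sc$angle0_lamina_deg + diurnal + sc$dose * sc$hyponasty_amp_lamina_deg * sigma + osc

  pet_rate <- sc$elong_rate_mm_per_h * (1 + sc$dose * (sc$elong_fr_multiplier - 1))
  len_p <- sc$petiole_len0_mm + (t_min / 60) * pet_rate
  len_l <- sc$lamina_len0_mm + (t_min / 60) * sc$elong_rate_mm_per_h

  bad <- which(theta_p <= -90 | theta_p >= 180 | theta_l <= -90 | theta_l >= 180)
  if (length(bad) > 0) {
    stop(sprintf("pose leaves the valid angle range (-90, 180) at frame %d",
                 bad[1] - 1L), call. = FALSE)
  }

  out <- tibble::tibble(
    frame = seq_len(n) - 1L,
    t_min = t_min,
    zt_h = zt_h,
    illumination = illum,
    petiole_angle_deg = theta_p,
    lamina_angle_deg = theta_l,
    petiole_len_mm = len_p,
    lamina_len_mm = len_l
  )
  class(out) <- c("pose_series", class(out))
  out
}

#' Project a ground-truth pose onto image pixel coordinates
#'
#' Inverse of the triangulation used by the geometry layer. For each frame the
#' petiole-lamina junction is placed at
#' `center + (petiole_len / mm_per_px) * (cos, -sin)(petiole_angle)` and the
#' leaf tip one lamina length further along the lamina axis. The minus sign
#' flips the y axis because image coordinates point down while botanical
#' angles are measured upward. Coordinates are real-valued (sub-pixel); they
#' are rounded only at render time.
#'
#' @param pose A `pose_series` from [simulate_pose()].
#' @param scenario The generating [sim_scenario()] (supplies `mm_per_px`,
#'   image size and rosette-center drift).
#' @param center_px Optional fixed rosette center `c(x, y)`; by default the
#'   center drifts linearly from `scenario$center0_px` by
#'   `scenario$center_drift_px` over the sequence.
#' @return A tibble with columns `frame`, `t_min`, `cx`, `cy`, `jx`, `jy`,
#'   `tx`, `ty` (pixels, 0-based image coordinates).
#' @export
pose_to_pixels <- function(pose, scenario, center_px = NULL) {
  validate_scenario(scenario)
  sc <- scenario
  n <- nrow(pose)
  if (is.null(center_px)) {
    f <- if (n > 1) (seq_len(n) - 1) / (n - 1) else rep(0, n)
    cx <- sc$center0_px[1] + f * sc$center_drift_px[1]
    cy <- sc$center0_px[2] + f * sc$center_drift_px[2]
  } else {
    cx <- rep(center_px[1], n)
    cy <- rep(center_px[2], n)
  }
  rad <- pi / 180
  lp_px <- pose$petiole_len_mm / sc$mm_per_px
  ll_px <- pose$lamina_len_mm / sc$mm_per_px
  jx <- cx + lp_px * cos(pose$petiole_angle_deg * rad)
  jy <- cy - lp_px * sin(pose$petiole_angle_deg * rad)
  tx <- jx + ll_px * cos(pose$lamina_angle_deg * rad)
  ty <- jy - ll_px * sin(pose$lamina_angle_deg * rad)

  w <- sc$image_w_px; h <- sc$image_h_px
  xs <- cbind(cx, jx, tx); ys <- cbind(cy, jy, ty)
  bad <- which(apply(xs < 0 | xs > w - 1 | ys < 0 | ys > h - 1, 1, any))
  if (length(bad) > 0) {
    stop(sprintf("landmark outside the %dx%d image at frame %d",
                 w, h, pose$frame[bad[1]]), call. = FALSE)
  }
  tibble::tibble(
    frame = pose$frame, t_min = pose$t_min,
    cx = cx, cy = cy, jx = jx, jy = jy, tx = tx, ty = ty
  )
}
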