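#' Define a synthetic leaf time-lapse scenario
#'
#' A scenario bundles every parameter of the synthetic experiment: photoperiod
#' and treatment timing (in Zeitgeber time, ZT = hours since lights-on), the
#' kinematic model of petiole and lamina movement, elongation rates, rendering
#' geometry and the random seed. The defaults emulate a short-day experiment:
#' 9 h light / 15 h dark, imaging at 1 frame per minute for 24 h, treatment
#' starting at ZT 2, on a focal leaf whose petiole is about 5 mm long.
#'
#' The petiole angle over time follows
#' \deqn{\theta_p(t) = \theta_0 + A_d \sin(2\pi \, zt/24) + d\,H\,\sigma(t)
#'   + d\,A_{osc} \sin(2\pi t/T_{osc})\, g(t)}
#' where \eqn{\sigma(t)} is a logistic ramp \eqn{1/(1+e^{-k(t-t_{on})})}
#' modelling the far-red-induced hyponastic rise, \eqn{d} the treatment dose,
#' and \eqn{g(t)} gates the oscillatory term on from the first lights-off
#' onwards. The lamina angle follows the same form with its own hyponasty
#' amplitude. Petiole length grows linearly at
#' `elong_rate_mm_per_h * (1 + dose * (elong_fr_multiplier - 1))`; lamina
#' length grows at the white-light rate regardless of dose (far-red promotes
#' petiole but not lamina elongation).
#'
#' Pixel coordinates are zero-based with the origin at the top-left corner and
#' the y axis pointing down, as in raster images; all conversion to the y-up
#' botanical convention happens in the geometry layer.
#'
#' @param duration_min Total sequence duration in minutes.
#' @param frame_interval_min Minutes between frames.
#' @param lights_on_zt_h,lights_off_zt_h Photoperiod boundaries in ZT hours.
#' @param start_zt_h ZT time of the first frame (treatment onset), hours.
#' @param treatment One of `"WL"` (white light control), `"FRw"` (whole-plant
#'   supplemental far-red) or `"FRt"` (leaf-tip far-red).
#' @param dose Treatment dose in `[0, 1]`; must be 0 for `"WL"`.
#' @param petiole_len0_mm,lamina_len0_mm Initial lengths, mm.
#' @param angle0_petiole_deg,angle0_lamina_deg Initial angles above horizontal,
#'   degrees.
#' @param diurnal_amp_deg Amplitude of the shared diurnal sinusoid, degrees.
#' @param hyponasty_amp_deg,hyponasty_amp_lamina_deg Saturating amplitude of
#'   the treatment-induced rise for petiole and lamina, degrees.
#' @param hyponasty_onset_min Logistic midpoint of the rise, minutes.
#' @param hyponasty_rate_per_min Logistic steepness, 1/min.
#' @param osc_amp_deg,osc_period_min Night-gated oscillation amplitude
#'   (degrees) and period (minutes).
#' @param elong_rate_mm_per_h Baseline (white light) elongation rate, mm/h.
#' @param elong_fr_multiplier Fold change of petiole elongation at dose 1.
#' @param mm_per_px Physical size of one pixel, mm.
#' @param image_w_px,image_h_px Frame dimensions, pixels.
#' @param center0_px Rosette center in the first frame, `c(x, y)` pixels.
#' @param center_drift_px Total drift of the rosette center over the whole
#'   sequence, `c(dx, dy)` pixels.
#' @param scale_len_mm Physical length of the rendered scale bar, mm.
#' @param noise_sd Gaussian pixel noise standard deviation, 8-bit gray levels.
#' @param rng_seed Integer seed controlling rendering noise.
#'
#' @return An object of class `sim_scenario` (a named list).
#' @seealso [simulate_pose()], [render_sequence()], [benchmark_scenario()]
#' @export
#' @examples
#' sc <- sim_scenario(treatment = "FRw", dose = 1, duration_min = 120)
#' pose <- simulate_pose(sc)
#' head(pose)
sim_scenario <- function(duration_min = 1440,
                         frame_interval_min = 1,
                         lights_on_zt_h = 0,
                         lights_off_zt_h = 9,
                         start_zt_h = 2,
                         treatment = c("WL", "FRw", "FRt"),
                         dose = NULL,
                         petiole_len0_mm = 5,
                         lamina_len0_mm = 10,
                         angle0_petiole_deg = 20,
                         angle0_lamina_deg = 10,
                         diurnal_amp_deg = 5,
                         hyponasty_amp_deg = 15,
                         hyponasty_amp_lamina_deg = 9,
                         hyponasty_onset_min = 300,
                         hyponasty_rate_per_min = 0.02,
                         osc_amp_deg = 3,
                         osc_period_min = 90,
                         elong_rate_mm_per_h = 0.1,
                         elong_fr_multiplier = 2,
                         mm_per_px = 0.1,
                         image_w_px = 320,
                         image_h_px = 240,
                         center0_px = c(70, 170),
                         center_drift_px = c(0, 0),
                         scale_len_mm = 10,
                         noise_sd = 2,
                         rng_seed = 1L) {
  treatment <- match.arg(treatment)
  if (is.null(dose)) dose <- if (treatment == "WL") 0 else 1
  sc <- list(
    duration_min = duration_min,
    frame_interval_min = frame_interval_min,
    lights_on_zt_h = lights_on_zt_h,
    lights_off_zt_h = lights_off_zt_h,
    start_zt_h = start_zt_h,
    treatment = treatment,
    dose = dose,
    petiole_len0_mm = petiole_len0_mm,
    lamina_len0_mm = lamina_len0_mm,
    angle0_petiole_deg = angle0_petiole_deg,
    angle0_lamina_deg = angle0_lamina_deg,
    diurnal_amp_deg = diurnal_amp_deg,
    hyponasty_amp_deg = hyponasty_amp_deg,
    hyponasty_amp_lamina_deg = hyponasty_amp_lamina_deg,
    hyponasty_onset_min = hyponasty_onset_min,
    hyponasty_rate_per_min = hyponasty_rate_per_min,
    osc_amp_deg = osc_amp_deg,
    osc_period_min = osc_period_min,
    elong_rate_mm_per_h = elong_rate_mm_per_h,
    elong_fr_multiplier = elong_fr_multiplier,
    mm_per_px = mm_per_px,
    image_w_px = as.integer(image_w_px),
    image_h_px = as.integer(image_h_px),
    center0_px = as.numeric(center0_px),
    center_drift_px = as.numeric(center_drift_px),
    scale_len_mm = scale_len_mm,
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  )
  class(sc) <- "sim_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  if (!(sc$duration_min > 0)) stop("duration_min must be > 0", call. = FALSE)
  if (!(sc$frame_interval_min > 0)) stop("frame_interval_min must be > 0", call. = FALSE)
  if (!(sc$mm_per_px > 0)) stop("mm_per_px must be > 0", call. = FALSE)
  if (sc$dose < 0 || sc$dose > 1) stop("dose must lie in [0, 1]", call. = FALSE)
  if (sc$treatment == "WL" && sc$dose != 0) {
    stop("dose must be 0 when treatment is WL", call. = FALSE)
  }
  if (sc$lights_off_zt_h <= sc$lights_on_zt_h) {
    stop("lights_off_zt_h must exceed lights_on_zt_h", call. = FALSE)
  }
  if (length(sc$center0_px) != 2 || length(sc$center_drift_px) != 2) {
    stop("center0_px and center_drift_px must be length-2 (x, y)", call. = FALSE)
  }
  w <- sc$image_w_px; h <- sc$image_h_px
  if (sc$center0_px[1] < 0 || sc$center0_px[1] > w - 1 ||
      sc$center0_px[2] < 0 || sc$center0_px[2] > h - 1) {
    stop("center0_px must lie inside the image", call. = FALSE)
  }
  invisible(sc)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> %s (dose %.2f), %g min @ %g min/frame, %dx%d px, seed %d\n",
    x$treatment, x$dose, x$duration_min, x$frame_interval_min,
    x$image_w_px, x$image_h_px, x$rng_seed
  ))
  invisible(x)
}

#' Benchmark scenario preset
#'
#' A 240-frame day+night scenario used throughout the test suite: 720 minutes
#' sampled every 3 minutes starting at ZT 2, so the sequence crosses the
#' lights-off transition at ZT 9 and continues into the night. All other
#' parameters are the [sim_scenario()] defaults.
#'
#' @param treatment,dose,rng_seed,... Passed to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
benchmark_scenario <- function(treatment = "FRw", dose = NULL, rng_seed = 7L, ...) {
  sim_scenario(
    duration_min = 720, frame_interval_min = 3,
    treatment = treatment, dose = dose, rng_seed = rng_seed, ...
  )
}

#' Read or write a scenario file
#'
#' Scenarios are stored as flat YAML key:value files mirroring the fields of
#' [sim_scenario()].
#'
#' @param path File path.
#' @return `read_scenario()` returns a `sim_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_scenario))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown scenario keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(sim_scenario, vals)
}

#' @rdname read_scenario
#' @param scenario A `sim_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}
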