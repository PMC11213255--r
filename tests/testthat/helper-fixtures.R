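# Rendered sequences are expensive; cache them per test session.
fixture_root <- function() {
  d <- file.path(tempdir(), "leaflapse_fixtures")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# 240-frame day+night benchmark sequence, rendered once per (treatment, seed)
bench_fixture <- function(treatment = "FRw", seed = 7L, noise_sd = 2, ...) {
  key <- sprintf("bench_%s_s%d_n%g", treatment, seed, noise_sd)
  dir <- file.path(fixture_root(), key)
  if (!file.exists(file.path(dir, "ground_truth.csv"))) {
    sc <- benchmark_scenario(treatment, rng_seed = seed, noise_sd = noise_sd, ...)
    render_sequence(sc, dir)
  }
  list(
    dir = dir,
    seq = load_sequence(dir),
    ann = read_annotation(file.path(dir, "annotation.yaml")),
    truth = readr::read_csv(file.path(dir, "ground_truth.csv"),
                            show_col_types = FALSE)
  )
}

# small noise-free scenario for pixel-exact tracker tests
small_scenario <- function(...) {
  sim_scenario(
    duration_min = 60, frame_interval_min = 2,
    image_w_px = 200, image_h_px = 200, mm_per_px = 0.15,
    center0_px = c(40, 150), noise_sd = 0, scale_len_mm = 8,
    ...
  )
}

track_rmse <- function(track, truth, landmark = c("j", "t")) {
  landmark <- match.arg(landmark)
  x <- paste0(landmark, "x"); y <- paste0(landmark, "y")
  sqrt(mean((track[[x]] - truth[[x]])^2 + (track[[y]] - truth[[y]])^2))
}

# random noise-free pose table spanning the legal angle/length ranges
random_pose <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    frame = seq_len(n) - 1L,
    t_min = as.numeric(seq_len(n) - 1L),
    zt_h = 2 + (seq_len(n) - 1) / 60,
    illumination = "day",
    petiole_angle_deg = stats::runif(n, -30, 80),
    lamina_angle_deg = stats::runif(n, -40, 85),
    petiole_len_mm = stats::runif(n, 3, 8),
    lamina_len_mm = stats::runif(n, 6, 15)
  )
}

# scenario large enough that any random_pose() projects inside the frame
pose_scenario <- function() {
  sim_scenario(image_w_px = 500, image_h_px = 600,
               center0_px = c(120, 350), mm_per_px = 0.1)
}

track_from_pixels <- function(px, illumination = "day") {
  tt <- tibble::tibble(
    frame = px$frame, t_min = px$t_min, illumination = illumination,
    cx = px$cx, cy = px$cy, jx = px$jx, jy = px$jy, tx = px$tx, ty = px$ty,
    confidence_j = 1, confidence_t = 1, lost_j = FALSE, lost_t = FALSE
  )
  class(tt) <- c("track_table", class(tt))
  tt
}
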