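# Rasterization of synthetic frames. All drawing works in 0-based image
# coordinates (x right, y down); pixel (x, y) is matrix entry [y + 1, x + 1].

DAY_BG <- c(0.10, 0.30, 0.80)      # uniform blue background
DAY_PLANT <- c(0.20, 0.65, 0.25)   # green leaf
NIGHT_BG <- 0.08                    # IR: dark scene
NIGHT_PLANT <- 0.85                 # IR: bright leaf
BAR_DAY <- 0.90                     # scale bar, achromatic in both regimes
BAR_NIGHT <- 0.60
PETIOLE_HALFWIDTH <- 1.5            # px; 3 px-wide petiole
LAMINA_ASPECT <- 0.35               # lamina width / lamina length

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# coverage of a thick segment over the pixel grid X, Y (anti-aliased)
seg_coverage <- function(X, Y, p1, p2, half) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  l2 <- vx * vx + vy * vy
  tt <- if (l2 == 0) 0 else clamp01(((X - p1[1]) * vx + (Y - p1[2]) * vy) / l2)
  d <- sqrt((X - (p1[1] + tt * vx))^2 + (Y - (p1[2] + tt * vy))^2)
  clamp01(half + 0.5 - d)
}

# coverage of a filled ellipse with semi-axes a (along unit vector u) and b
ellipse_coverage <- function(X, Y, center, a, b, u) {
  dx <- X - center[1]; dy <- Y - center[2]
  uc <- dx * u[1] + dy * u[2]
  vc <- -dx * u[2] + dy * u[1]
  r <- sqrt((uc / a)^2 + (vc / b)^2)
  clamp01(b * (1 - r) + 0.5)
}

# pixel-grid matrices for a clamped bounding box; NULL if empty
grid_for_bbox <- function(xlim, ylim, w, h, margin) {
  x0 <- max(0L, floor(min(xlim) - margin)); x1 <- min(w - 1L, ceiling(max(xlim) + margin))
  y0 <- max(0L, floor(min(ylim) - margin)); y1 <- min(h - 1L, ceiling(max(ylim) + margin))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  list(
    rows = ys + 1L, cols = xs + 1L,
    X = matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE),
    Y = matrix(ys, nrow = length(ys), ncol = length(xs))
  )
}

# endpoints of the rendered calibration segment (sub-pixel exact)
scale_bar_px <- function(scenario) {
  len_px <- scenario$scale_len_mm / scenario$mm_per_px
  p1 <- c(12, 30)
  p2 <- c(12, 30 + len_px)
  if (p2[2] > scenario$image_h_px - 1) {
    stop("scale bar does not fit inside the image; reduce scale_len_mm",
         call. = FALSE)
  }
  list(p1 = p1, p2 = p2)
}

#' Render a single synthetic frame
#'
#' Draws the petiole as a thick anti-aliased line from rosette center to
#' junction and the lamina as a filled ellipse oriented along the
#' junction-to-tip axis, plus a vertical scale bar of known physical length.
#' Day frames are green-on-blue RGB; night frames emulate near-infrared
#' imaging: a single bright-on-dark intensity channel replicated over R, G
#' and B, so the three channels are exactly equal. Gaussian noise
#' (`scenario$noise_sd`, 8-bit gray levels) is added per channel by day and
#' to the single intensity channel by night; values are quantized to 8 bits
#' as they would be in a PNG file.
#'
#' @param scenario A [sim_scenario()].
#' @param landmarks A list or one-row data frame with `cx, cy, jx, jy, tx, ty`
#'   (pixels, 0-based).
#' @param illumination `"day"` or `"night"`.
#' @param noise Add pixel noise? Disable for noise-free fixtures.
#' @return An `image_h_px` x `image_w_px` x 3 array in `[0, 1]`.
#' @export
render_frame <- function(scenario, landmarks, illumination = "day", noise = TRUE) {
  sc <- scenario
  w <- sc$image_w_px; h <- sc$image_h_px
  lm <- lapply(landmarks[c("cx", "cy", "jx", "jy", "tx", "ty")], as.numeric)
  night <- identical(illumination, "night")

  # single-channel canvas; colorized (day) or replicated (night) at the end
  plant_val <- if (night) NIGHT_PLANT else 1  # day: coverage mask, colored later
  canvas <- matrix(0, h, w)                   # plant coverage in [0,1]

  half <- PETIOLE_HALFWIDTH
  g <- grid_for_bbox(c(lm$cx, lm$jx), c(lm$cy, lm$jy), w, h, half + 2)
  if (!is.null(g)) {
    cov <- seg_coverage(g$X, g$Y, c(lm$cx, lm$cy), c(lm$jx, lm$jy), half)
    canvas[g$rows, g$cols] <- pmax(canvas[g$rows, g$cols], cov)
  }
  axis <- c(lm$tx - lm$jx, lm$ty - lm$jy)
  a <- sqrt(sum(axis^2)) / 2
  if (a > 0) {
    b <- max(1.5, LAMINA_ASPECT * a)
    u <- axis / (2 * a)
    mid <- c((lm$jx + lm$tx) / 2, (lm$jy + lm$ty) / 2)
    g <- grid_for_bbox(mid[1] + c(-a, a), mid[2] + c(-a, a), w, h, b + 2)
    if (!is.null(g)) {
      cov <- ellipse_coverage(g$X, g$Y, mid, a, b, u)
      canvas[g$rows, g$cols] <- pmax(canvas[g$rows, g$cols], cov)
    }
  }

  bar <- scale_bar_px(sc)
  barcov <- matrix(0, h, w)
  g <- grid_for_bbox(c(bar$p1[1], bar$p2[1]), c(bar$p1[2], bar$p2[2]), w, h, 3)
  if (!is.null(g)) {
    barcov[g$rows, g$cols] <- seg_coverage(g$X, g$Y, bar$p1, bar$p2, 1.5)
  }

  sd01 <- sc$noise_sd / 255
  if (night) {
    gray <- NIGHT_BG * (1 - canvas) + NIGHT_PLANT * canvas
    gray <- gray * (1 - barcov) + BAR_NIGHT * barcov
    if (noise && sd01 > 0) gray <- gray + matrix(stats::rnorm(h * w, 0, sd01), h, w)
    gray <- round(clamp01(gray) * 255) / 255
    img <- array(gray, dim = c(h, w, 3))
  } else {
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- DAY_BG[ch] * (1 - canvas) + DAY_PLANT[ch] * canvas
      plane <- plane * (1 - barcov) + BAR_DAY * barcov
      if (noise && sd01 > 0) plane <- plane + matrix(stats::rnorm(h * w, 0, sd01), h, w)
      img[, , ch] <- plane
    }
    img <- round(clamp01(img) * 255) / 255
  }
  img
}

#' Render a full synthetic time-lapse sequence to disk
#'
#' Simulates the pose ([simulate_pose()]), projects it to pixels
#' ([pose_to_pixels()]), renders one 8-bit RGB PNG per frame (named
#' `frame_{index:06d}_{t_min}.png`), and writes the exact ground truth as
#' `ground_truth.csv` plus a ready-made `annotation.yaml` (first/last-frame
#' rosette center, first-frame junction and tip, and the scale-bar segment)
#' alongside. All randomness (pixel noise) is governed by
#' `scenario$rng_seed`, so identical scenarios produce byte-identical output.
#'
#' @param scenario A [sim_scenario()].
#' @param out_dir Output directory (created if needed).
#' @param noise Add pixel noise? Disable for noise-free fixtures.
#' @return Invisibly, a list with `frames` (file paths), `ground_truth` and
#'   `annotation` (file paths), and the `pose` and `pixels` tibbles.
#' @export
render_sequence <- function(scenario, out_dir, noise = TRUE) {
  validate_scenario(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pose <- simulate_pose(scenario)
  px <- pose_to_pixels(pose, scenario)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(scenario$rng_seed)

  files <- character(nrow(pose))
  for (i in seq_len(nrow(pose))) {
    img <- render_frame(scenario, px[i, ], pose$illumination[i], noise = noise)
    files[i] <- file.path(out_dir, sprintf("frame_%06d_%g.png", pose$frame[i], pose$t_min[i]))
    png::writePNG(img, files[i])
  }

  truth <- dplyr::bind_cols(
    pose[, c("frame", "t_min", "zt_h", "illumination")],
    px[, c("cx", "cy", "jx", "jy", "tx", "ty")],
    pose[, c("petiole_angle_deg", "lamina_angle_deg", "petiole_len_mm", "lamina_len_mm")]
  )
  truth_path <- file.path(out_dir, "ground_truth.csv")
  readr::write_csv(truth, truth_path)

  ann <- sim_annotation(scenario, px)
  ann_path <- file.path(out_dir, "annotation.yaml")
  write_annotation(ann, ann_path)

  invisible(list(frames = files, ground_truth = truth_path,
                 annotation = ann_path, pose = pose, pixels = px))
}

#' Build the landmark annotation implied by a simulated sequence
#'
#' Produces the same annotation a user would supply for real imagery:
#' rosette center in the first and last frame, petiole-lamina junction and
#' leaf tip in the first frame, and the rendered scale-bar segment with its
#' known physical length.
#'
#' @param scenario A [sim_scenario()].
#' @param pixels Landmark pixel table from [pose_to_pixels()].
#' @return An `annotation` object (see [read_annotation()]).
#' @export
sim_annotation <- function(scenario, pixels) {
  n <- nrow(pixels)
  bar <- scale_bar_px(scenario)
  annotation(
    plant_id = sprintf("sim_%s_seed%d", scenario$treatment, scenario$rng_seed),
    center_first = c(pixels$cx[1], pixels$cy[1]),
    center_last = c(pixels$cx[n], pixels$cy[n]),
    junction_first = c(pixels$jx[1], pixels$jy[1]),
    tip_first = c(pixels$tx[1], pixels$ty[1]),
    scale_p1 = bar$p1, scale_p2 = bar$p2,
    scale_len_mm = scenario$scale_len_mm,
    treatment = scenario$treatment
  )
}
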