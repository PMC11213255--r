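#' Tracker configuration
#'
#' Hyper-parameters of the adaptive-template landmark localizer. The 40 x 60
#' pixel bounding box is the template size around each user-annotated point;
#' the search radius bounds frame-to-frame motion (the simulator's default
#' scenarios move landmarks well under 3 px/frame); the learning rate blends
#' the stored appearance with the newly matched patch so the template
#' survives gradual appearance change (growth, day/night switch); matches
#' with confidence below `min_confidence`, or jumps above `max_jump_px`, are
#' flagged rather than silently accepted.
#'
#' @param box_w,box_h Template box size, pixels.
#' @param search_radius Half-width of the square search window, pixels.
#' @param learning_rate Appearance-model update rate in `[0, 1]`; 0 freezes
#'   the template.
#' @param anchor_rate Per-frame blend weight pulling the template back toward
#'   the appearance captured at the annotated point. Adaptive templates
#'   otherwise accumulate sub-pixel localization error and drift along the
#'   direction of motion; a small anchor pins them without blocking
#'   adaptation to growth or the day/night switch.
#' @param rot_step_deg,max_rot_deg In-plane rotation search step and limit,
#'   degrees.
#' @param rot_margin Minimum correlation gain required to move the rotation
#'   estimate by one step; hysteresis that keeps near-rotation-symmetric
#'   patches from random-walking their orientation. A petiole or lamina rotates as it moves; matching a purely
#'   translated template against a rotated shape biases the estimate
#'   tangentially, so each step also tries the template rotated one step
#'   either way and tracks the accumulated orientation.
#' @param min_confidence Minimum normalized correlation peak to accept a
#'   match.
#' @param max_jump_px Maximum plausible per-frame landmark displacement.
#' @param max_lost_fraction Maximum tolerated fraction of flagged frames
#'   before [track_sequence()] aborts and advises re-annotation.
#' @param gray_tol Day/night classification threshold, 8-bit gray levels
#'   (see [classify_illumination()]).
#' @return A named list of class `tracker_config`.
#' @export
tracker_config <- function(box_w = 40, box_h = 60, search_radius = 20,
                           learning_rate = 0.05, anchor_rate = 0.03,
                           rot_step_deg = 1, max_rot_deg = 45,
                           rot_margin = 0.002,
                           min_confidence = 0.2,
                           max_jump_px = 15, max_lost_fraction = 0.1,
                           gray_tol = 8) {
  cfg <- list(box_w = as.integer(box_w), box_h = as.integer(box_h),
              search_radius = as.integer(search_radius),
              learning_rate = learning_rate, anchor_rate = anchor_rate,
              rot_step_deg = rot_step_deg, max_rot_deg = max_rot_deg,
              rot_margin = rot_margin,
              min_confidence = min_confidence,
              max_jump_px = max_jump_px, max_lost_fraction = max_lost_fraction,
              gray_tol = gray_tol)
  stopifnot(cfg$box_w > 0, cfg$box_h > 0, cfg$search_radius > 0,
            cfg$learning_rate >= 0, cfg$learning_rate <= 1)
  class(cfg) <- "tracker_config"
  cfg
}

# single tracking channel of a frame: matrix pass-through, or one RGB plane
frame_channel <- function(frame, channel) {
  if (length(dim(frame)) == 2) frame else frame[, , channel]
}

# channel with the highest contrast (sd) inside the box; ties -> lowest index
pick_channel <- function(frame, x0, y0, bw, bh) {
  if (length(dim(frame)) == 2) return(1L)
  sds <- vapply(seq_len(dim(frame)[3]), function(ch) {
    stats::sd(frame[(y0 + 1):(y0 + bh), (x0 + 1):(x0 + bw), ch])
  }, numeric(1))
  which.max(sds)
}

# clamped 0-based top-left of a box centred on `point`
box_origin <- function(point, bw, bh, w, h) {
  x0 <- round(point[1]) - floor(bw / 2)
  y0 <- round(point[2]) - floor(bh / 2)
  c(min(max(x0, 0), w - bw), min(max(y0, 0), h - bh))
}

#' Initialize a landmark tracker at an annotated point
#'
#' Captures the appearance template inside the bounding box centred on the
#' point (clamped to stay inside the image near edges) on the channel with
#' the greatest contrast in that box; night frames are achromatic so the
#' choice is immaterial there. The state's point estimate equals the given
#' point exactly, sub-pixel part included.
#'
#' @param frame First frame (`h x w x 3` array or matrix).
#' @param point Landmark `c(x, y)`, 0-based pixels (sub-pixel allowed).
#' @param cfg A [tracker_config()].
#' @return A `tracker_state` list with fields `point`, `confidence`, `lost`.
#' @export
init_tracker <- function(frame, point, cfg = tracker_config()) {
  d <- dim(frame)
  h <- d[1]; w <- d[2]
  if (point[1] < 0 || point[1] > w - 1 || point[2] < 0 || point[2] > h - 1) {
    stop(sprintf("tracker init point (%g, %g) outside %dx%d image",
                 point[1], point[2], w, h), call. = FALSE)
  }
  bw <- min(cfg$box_w, w); bh <- min(cfg$box_h, h)
  o <- box_origin(point, bw, bh, w, h)
  channel <- pick_channel(frame, o[1], o[2], bw, bh)
  img <- frame_channel(frame, channel)
  templ <- img[(o[2] + 1):(o[2] + bh), (o[1] + 1):(o[1] + bw), drop = FALSE]
  # canonical appearance patch with margin, so rotated box crops stay inside
  pad <- ceiling(sqrt((bw / 2)^2 + (bh / 2)^2)) - floor(min(bw, bh) / 2) + 2
  ref <- as.numeric(point) - o
  canon <- extract_patch_subpix(img, as.numeric(point) - ref - pad,
                                bw + 2 * pad, bh + 2 * pad)
  state <- list(
    point = as.numeric(point),
    ref = ref,                     # sub-pixel offset of the point in the box
    ref_pad = ref + pad,           # ... and in the canonical patch
    box = c(bw, bh),
    pad = pad,
    template = templ,              # box crop at the current orientation
    canon = canon,                 # canonical-orientation appearance (padded)
    canon0 = canon,                # anchor: appearance at the annotation
    phi = 0,                       # current in-plane rotation estimate, deg
    channel = channel,
    confidence = 1,
    lost = FALSE
  )
  class(state) <- "tracker_state"
  state
}

# bilinear affine sampling: out[u] = mat[origin_pt + R(ang)(u - ref_pt)] for
# destination grid u of size dims = c(h, w); coordinates 0-based, border
# replicated. R(ang) rotates by ang degrees in image coordinates.
sample_affine <- function(mat, origin_pt, ref_pt, dims, ang) {
  hh <- dims[1]; ww <- dims[2]
  ux <- rep(0:(ww - 1), each = hh) - ref_pt[1]
  uy <- rep(0:(hh - 1), ww) - ref_pt[2]
  a <- ang * pi / 180
  sx <- origin_pt[1] + cos(a) * ux - sin(a) * uy
  sy <- origin_pt[2] + sin(a) * ux + cos(a) * uy
  h <- nrow(mat); w <- ncol(mat)
  x0 <- pmin(pmax(floor(sx), 0), w - 2); fx <- pmin(pmax(sx - x0, 0), 1)
  y0 <- pmin(pmax(floor(sy), 0), h - 2); fy <- pmin(pmax(sy - y0, 0), 1)
  v <- (1 - fy) * ((1 - fx) * mat[cbind(y0 + 1, x0 + 1)] +
                     fx * mat[cbind(y0 + 1, x0 + 2)]) +
    fy * ((1 - fx) * mat[cbind(y0 + 2, x0 + 1)] +
            fx * mat[cbind(y0 + 2, x0 + 2)])
  matrix(v, nrow = hh, ncol = ww)
}

# box-sized template at rotation ang, cropped from the canonical patch
rotated_template <- function(state, ang) {
  sample_affine(state$canon, state$ref_pad, state$ref,
                c(state$box[2], state$box[1]), ang)
}

# 1D sub-pixel refinement: parabola through (r[-1], r[0], r[+1]), clamped
subpixel_1d <- function(rm, r0, rp) {
  den <- rm - 2 * r0 + rp
  if (!is.finite(den) || den >= 0) return(0)
  min(0.5, max(-0.5, 0.5 * (rm - rp) / den))
}

# bilinear patch extraction at a real-valued 0-based top-left origin
extract_patch_subpix <- function(img, origin, bw, bh) {
  h <- nrow(img); w <- ncol(img)
  xs <- origin[1] + 0:(bw - 1)
  ys <- origin[2] + 0:(bh - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 2); fx <- pmin(pmax(xs - x0, 0), 1)
  y0 <- pmin(pmax(floor(ys), 0), h - 2); fy <- pmin(pmax(ys - y0, 0), 1)
  a <- img[cbind(rep(y0 + 1, bw), rep(x0 + 1, each = bh))]
  b <- img[cbind(rep(y0 + 1, bw), rep(x0 + 2, each = bh))]
  c_ <- img[cbind(rep(y0 + 2, bw), rep(x0 + 1, each = bh))]
  d <- img[cbind(rep(y0 + 2, bw), rep(x0 + 2, each = bh))]
  fxm <- rep(fx, each = bh); fym <- rep(fy, bw)
  v <- (1 - fym) * ((1 - fxm) * a + fxm * b) + fym * ((1 - fxm) * c_ + fxm * d)
  matrix(v, nrow = bh, ncol = bw)
}

#' Track a landmark into the next frame
#'
#' Slides the stored template over a square search window around the
#' previous estimate, takes the normalized cross-correlation peak, refines
#' it to sub-pixel precision with a quadratic fit, and blends the matched
#' patch into the template at `learning_rate`. Confidence is the correlation
#' peak clamped to `[0, 1]`; below `min_confidence` the frame is flagged
#' `lost`, the estimate and template are frozen at their last good values,
#' and tracking continues.
#'
#' @param state A `tracker_state` from [init_tracker()].
#' @param frame Next frame (same dimensions as the init frame).
#' @param cfg A [tracker_config()].
#' @return The updated `tracker_state` (fields `point`, `confidence`,
#'   `lost`).
#' @export
track_next <- function(state, frame, cfg = tracker_config()) {
  img <- frame_channel(frame, state$channel)
  bw <- state$box[1]; bh <- state$box[2]
  base <- round(state$point - state$ref)

  # decode the |NCC| peak of a response grid; matching works on |NCC| so a
  # global contrast inversion (day -> infrared night) does not defeat the
  # localizer; the sign is folded back in when updating the template
  decode <- function(resp) {
    if (all(is.na(resp))) return(NULL)
    aresp <- abs(resp)
    peak <- max(aresp, na.rm = TRUE)
    idx <- which(aresp == peak)[1]
    side <- nrow(resp)
    iy <- (idx - 1) %% side + 1
    ix <- (idx - 1) %/% side + 1
    radius <- (side - 1) / 2
    list(resp = resp, peak = peak, iy = iy, ix = ix, side = side,
         dx = ix - radius - 1, dy = iy - radius - 1,
         sgn = sign(resp[iy, ix]))
  }

  # full-window search at the current orientation estimate
  best <- decode(ncc_response(img, state$template, base[1], base[2],
                              cfg$search_radius))
  if (is.null(best)) {
    stop("search window entirely outside the image; frame size mismatch?",
         call. = FALSE)
  }
  best$phi <- state$phi
  best$origin <- base + c(best$dx, best$dy)

  # try one rotation step either way, locally around the best placement
  if (cfg$rot_step_deg > 0) {
    for (dphi in c(-cfg$rot_step_deg, cfg$rot_step_deg)) {
      phi_c <- state$phi + dphi
      if (abs(phi_c) > cfg$max_rot_deg) next
      templ_c <- rotated_template(state, phi_c)
      cand <- decode(ncc_response(img, templ_c, best$origin[1],
                                  best$origin[2], 3L))
      if (!is.null(cand) && cand$peak > best$peak + cfg$rot_margin) {
        cand$phi <- phi_c
        cand$origin <- best$origin + c(cand$dx, cand$dy)
        best <- cand
      }
    }
  }

  resp <- best$resp; iy <- best$iy; ix <- best$ix
  side <- best$side; sgn <- best$sgn
  sx <- sy <- 0
  if (ix > 1 && ix < side && all(is.finite(resp[iy, (ix - 1):(ix + 1)]))) {
    sx <- subpixel_1d(sgn * resp[iy, ix - 1], sgn * resp[iy, ix],
                      sgn * resp[iy, ix + 1])
  }
  if (iy > 1 && iy < side && all(is.finite(resp[(iy - 1):(iy + 1), ix]))) {
    sy <- subpixel_1d(sgn * resp[iy - 1, ix], sgn * resp[iy, ix],
                      sgn * resp[iy + 1, ix])
  }

  confidence <- min(1, best$peak)
  if (confidence >= cfg$min_confidence) {
    state$phi <- best$phi
    state$point <- best$origin + c(sx, sy) + state$ref
    # resample the matched appearance back into the canonical orientation at
    # the refined sub-pixel position, so the canonical patch stays registered
    # to the reference point (prevents drift)
    pd <- c(state$box[2], state$box[1]) + 2 * state$pad
    patch <- sample_affine(img, state$point, state$ref_pad, pd, -state$phi)
    if (sgn < 0) patch <- 2 * mean(patch) - patch  # undo contrast inversion
    lr <- cfg$learning_rate
    ar <- cfg$anchor_rate
    state$canon <- (1 - lr) * state$canon + lr * patch
    state$canon <- (1 - ar) * state$canon + ar * state$canon0
    state$template <- rotated_template(state, state$phi)
    state$lost <- FALSE
  } else {
    state$lost <- TRUE   # estimate, orientation and template frozen
  }
  state$confidence <- confidence
  state
}

#' Track junction and tip through a whole sequence
#'
#' Initializes one tracker per landmark from the first-frame annotation and
#' runs it through every frame. The rosette center is not tracked: it is
#' interpolated linearly in frame index between its first- and last-frame
#' annotations. Each frame is classified day/night from its channel spread.
#' Rows are flagged when the match confidence falls below
#' `cfg$min_confidence` or the implied jump exceeds `cfg$max_jump_px`; if
#' more than `cfg$max_lost_fraction` of frames are flagged the run aborts.
#'
#' @param seq A `frame_sequence` from [load_sequence()].
#' @param ann An [annotation()] (its `crop_rect`, if any, is applied to every
#'   frame before tracking).
#' @param cfg A [tracker_config()].
#' @return A tibble of class `track_table`: one row per frame with columns
#'   `frame`, `t_min`, `illumination`, `cx`, `cy`, `jx`, `jy`, `tx`, `ty`,
#'   `confidence_j`, `confidence_t`, `lost_j`, `lost_t`.
#' @export
track_sequence <- function(seq, ann, cfg = tracker_config()) {
  stopifnot(nrow(seq) >= 2)
  validate_annotation(ann)
  n <- nrow(seq)
  get_frame <- function(i) {
    img <- read_frame(seq$path[i])
    if (!is.null(ann$crop_rect)) img <- crop_frame(img, ann$crop_rect)
    img
  }
  first <- get_frame(1)
  dims <- dim(first)[1:2]
  validate_annotation(ann, image_dim = dims)

  st_j <- init_tracker(first, ann$junction_first, cfg)
  st_t <- init_tracker(first, ann$tip_first, cfg)

  out <- tibble::tibble(
    frame = seq$frame, t_min = seq$t_min,
    illumination = NA_character_,
    cx = NA_real_, cy = NA_real_,
    jx = NA_real_, jy = NA_real_, tx = NA_real_, ty = NA_real_,
    confidence_j = NA_real_, confidence_t = NA_real_,
    lost_j = FALSE, lost_t = FALSE
  )
  frac <- (seq_len(n) - 1) / (n - 1)
  out$cx <- ann$center_first[1] + frac * (ann$center_last[1] - ann$center_first[1])
  out$cy <- ann$center_first[2] + frac * (ann$center_last[2] - ann$center_first[2])

  out$illumination[1] <- classify_illumination(first, cfg$gray_tol)
  out$jx[1] <- st_j$point[1]; out$jy[1] <- st_j$point[2]
  out$tx[1] <- st_t$point[1]; out$ty[1] <- st_t$point[2]
  out$confidence_j[1] <- out$confidence_t[1] <- 1

  for (i in 2:n) {
    img <- get_frame(i)
    if (!identical(dim(img)[1:2], dims)) {
      stop("frame dimensions change at ", seq$path[i], call. = FALSE)
    }
    out$illumination[i] <- classify_illumination(img, cfg$gray_tol)
    prev_j <- st_j$point; prev_t <- st_t$point
    st_j <- track_next(st_j, img, cfg)
    st_t <- track_next(st_t, img, cfg)
    out$jx[i] <- st_j$point[1]; out$jy[i] <- st_j$point[2]
    out$tx[i] <- st_t$point[1]; out$ty[i] <- st_t$point[2]
    out$confidence_j[i] <- st_j$confidence
    out$confidence_t[i] <- st_t$confidence
    out$lost_j[i] <- st_j$lost || sqrt(sum((st_j$point - prev_j)^2)) > cfg$max_jump_px
    out$lost_t[i] <- st_t$lost || sqrt(sum((st_t$point - prev_t)^2)) > cfg$max_jump_px
  }

  lost_frac <- mean(out$lost_j | out$lost_t)
  if (lost_frac > cfg$max_lost_fraction) {
    stop(sprintf("%.0f%% of frames flagged as lost (max %.0f%%); re-annotate and retry",
                 100 * lost_frac, 100 * cfg$max_lost_fraction), call. = FALSE)
  }
  class(out) <- c("track_table", class(out))
  out
}
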