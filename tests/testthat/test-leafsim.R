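test_that("scenario validation rejects inconsistent parameters", {
  expect_error(sim_scenario(duration_min = 0), "duration_min")
  expect_error(sim_scenario(mm_per_px = 0), "mm_per_px")
  expect_error(sim_scenario(treatment = "WL", dose = 0.5), "dose")
  expect_error(sim_scenario(dose = 1.5, treatment = "FRw"), "dose")
  expect_error(sim_scenario(center0_px = c(1000, 10)), "center0_px")
  sc <- sim_scenario(treatment = "FRw")
  expect_equal(sc$dose, 1)  # non-control treatments default to full dose
})

test_that("scenario files round-trip through YAML", {
  sc <- benchmark_scenario("FRw", rng_seed = 11)
  path <- tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2, sc)
  expect_error(read_scenario(tempfile()), "not found")
})

test_that("pose with all motion terms off is constant at the initial angle", {
  sc <- sim_scenario(treatment = "WL", diurnal_amp_deg = 0, osc_amp_deg = 0,
                     duration_min = 120)
  pose <- simulate_pose(sc)
  expect_equal(pose$petiole_angle_deg, rep(sc$angle0_petiole_deg, 120))
  expect_equal(pose$lamina_angle_deg, rep(sc$angle0_lamina_deg, 120))
})

test_that("hyponastic rise saturates at the logistic asymptote", {
  sc <- sim_scenario(treatment = "FRw", dose = 1, diurnal_amp_deg = 0,
                     osc_amp_deg = 0, duration_min = 3000,
                     image_w_px = 400, image_h_px = 300)
  pose <- simulate_pose(sc)
  final <- pose$petiole_angle_deg[nrow(pose)]
  expect_equal(final, sc$angle0_petiole_deg + sc$hyponasty_amp_deg,
               tolerance = 1e-8)
})

test_that("petiole elongation follows the closed-form linear growth law", {
  # independent hand computation: rate 0.1 mm/h doubled by FR at dose 1
  # gives 0.2 mm/h; after 24 h: 5 + 24 * 0.2 = 9.8 mm
  sc <- sim_scenario(treatment = "FRw", dose = 1, duration_min = 1441,
                     rng_seed = 7)
  pose <- simulate_pose(sc)
  row <- pose[pose$t_min == 1440, ]
  expect_equal(row$petiole_len_mm, 9.8, tolerance = 1e-12)
  # lamina ignores the FR multiplier: 10 + 24 * 0.1 = 12.4 mm
  expect_equal(row$lamina_len_mm, 12.4, tolerance = 1e-12)
  # lengths never decrease
  expect_true(all(diff(pose$petiole_len_mm) >= 0))
  expect_true(all(diff(pose$lamina_len_mm) >= 0))
})

test_that("illumination labels follow the photoperiod arithmetic", {
  sc <- sim_scenario(duration_min = 1440)
  pose <- simulate_pose(sc)
  expected <- ifelse(pose$zt_h %% 24 >= sc$lights_on_zt_h &
                       pose$zt_h %% 24 < sc$lights_off_zt_h, "day", "night")
  expect_identical(pose$illumination, expected)
  # ZT 2 start, lights off at ZT 9: first night frame is at t = 420 min
  expect_equal(min(pose$t_min[pose$illumination == "night"]), 420)
})

test_that("pose rejects scenarios that leave the valid angle range", {
  expect_error(
    simulate_pose(sim_scenario(angle0_petiole_deg = 85, treatment = "FRw",
                               hyponasty_amp_deg = 100,
                               image_w_px = 2000, image_h_px = 2000,
                               center0_px = c(1000, 1000))),
    "angle range"
  )
})

test_that("pose_to_pixels places landmarks by angle and length", {
  sc <- pose_scenario()
  pose <- random_pose(1)
  pose$petiole_angle_deg <- 0
  pose$petiole_len_mm <- 50 * sc$mm_per_px  # 50 px
  px <- pose_to_pixels(pose, sc, center_px = c(100, 200))
  expect_equal(c(px$jx, px$jy), c(150, 200), tolerance = 1e-12)

  pose$petiole_angle_deg <- 90
  px <- pose_to_pixels(pose, sc, center_px = c(100, 200))
  expect_equal(c(px$jx, px$jy), c(100, 150), tolerance = 1e-12)
})

test_that("pose_to_pixels errors when a landmark leaves the frame", {
  sc <- sim_scenario()
  pose <- random_pose(3)
  pose$lamina_len_mm <- c(10, 10, 500)
  expect_error(pose_to_pixels(pose, sc), "frame 2")
})

test_that("rendered sequences have the right frame count and ground truth", {
  sc <- sim_scenario(duration_min = 60, frame_interval_min = 1, noise_sd = 0)
  dir <- file.path(tempdir(), "seq60")
  res <- render_sequence(sc, dir)
  expect_length(res$frames, 60)
  expect_true(all(file.exists(res$frames)))
  truth <- readr::read_csv(res$ground_truth, show_col_types = FALSE)
  expect_equal(nrow(truth), 60)
  expect_named(truth, c("frame", "t_min", "zt_h", "illumination",
                        "cx", "cy", "jx", "jy", "tx", "ty",
                        "petiole_angle_deg", "lamina_angle_deg",
                        "petiole_len_mm", "lamina_len_mm"))
})

test_that("night frames are exactly achromatic, day frames are not", {
  sc <- benchmark_scenario("FRw", noise_sd = 5)
  pose <- simulate_pose(sc)
  px <- pose_to_pixels(pose, sc)
  i_night <- which(pose$illumination == "night")[1]
  img <- render_frame(sc, px[i_night, ], "night")
  expect_equal(max(abs(img[, , 1] - img[, , 2])), 0)
  expect_equal(max(abs(img[, , 2] - img[, , 3])), 0)

  day <- render_frame(sc, px[1, ], "day")
  expect_gt(max(abs(day[, , 1] - day[, , 3])), 0.2)
})

test_that("day frames show the plant at the ground-truth landmark pixels", {
  sc <- sim_scenario(noise_sd = 0)
  pose <- simulate_pose(sc)
  px <- pose_to_pixels(pose, sc)
  img <- render_frame(sc, px[1, ], "day", noise = FALSE)
  bg <- img[1, dim(img)[2], ]  # far corner: pure background
  at <- function(x, y) img[round(y) + 1, round(x) + 1, ]
  expect_gt(sum(abs(at(px$jx[1], px$jy[1]) - bg)), 0.3)
  expect_gt(sum(abs(at(px$tx[1], px$ty[1]) - bg)), 0.3)
})

test_that("rendering is deterministic given the seed", {
  sc <- sim_scenario(duration_min = 6, noise_sd = 3, rng_seed = 42)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  render_sequence(sc, d1)
  render_sequence(sc, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])),
                     label = basename(f1[i]))
  }
})

test_that("inter-frame landmark displacement stays under 3 px for defaults", {
  for (tre in c("WL", "FRw")) {
    for (sc in list(sim_scenario(treatment = tre),
                    benchmark_scenario(tre))) {
      px <- pose_to_pixels(simulate_pose(sc), sc)
      dj <- sqrt(diff(px$jx)^2 + diff(px$jy)^2)
      dt <- sqrt(diff(px$tx)^2 + diff(px$ty)^2)
      expect_lt(max(dj, dt), 3)
    }
  }
})

test_that("rendered scale bar recovers the scenario calibration exactly", {
  sc <- sim_scenario()
  dir <- file.path(tempdir(), "calseq")
  res <- render_sequence(sim_scenario(duration_min = 2), dir)
  ann <- read_annotation(file.path(dir, "annotation.yaml"))
  cal <- calibrate(ann$scale_p1, ann$scale_p2, ann$scale_len_mm)
  expect_equal(cal$mm_per_px, sc$mm_per_px, tolerance = 1e-12)
})
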