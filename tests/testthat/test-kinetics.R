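make_metrics <- function(values, t_min = seq_along(values) - 1,
                         illumination = "day") {
  tibble::tibble(
    frame = seq_along(values) - 1L, t_min = as.numeric(t_min),
    zt_h = 2 + t_min / 60, illumination = illumination,
    petiole_angle_deg = values
  )
}

test_that("relative series subtract the first-5-frame baseline", {
  m <- make_metrics(rep(7, 10))
  expect_equal(relative_series(m)$petiole_angle_deg, rep(0, 10))

  m <- make_metrics(c(1, 2, 3, 4, 5, 10))
  expect_equal(relative_series(m)$petiole_angle_deg[6], 7)

  # baseline mean of the first 5 *valid* frames is zero to 1e-9
  set.seed(1)
  m <- make_metrics(stats::rnorm(50))
  r <- relative_series(m)
  expect_lt(abs(mean(r$petiole_angle_deg[1:5])), 1e-9)

  # missing frames are skipped, not counted
  m$petiole_angle_deg[2] <- NA
  r <- relative_series(m)
  expect_true(is.na(r$petiole_angle_deg[2]))
  expect_lt(abs(mean(r$petiole_angle_deg[c(1, 3:6)])), 1e-9)

  expect_error(relative_series(make_metrics(c(1, NA, NA, NA, NA, NA))),
               "fewer than 5")
})

test_that("relative_series is idempotent on intact baselines", {
  set.seed(2)
  m <- make_metrics(stats::rnorm(30, mean = 12))
  r1 <- relative_series(m)
  r2 <- relative_series(r1)
  expect_equal(r2$petiole_angle_deg, r1$petiole_angle_deg, tolerance = 1e-12)
})

test_that("plants are aligned on their day-night transition", {
  base_vals <- sin(seq(0, 3, length.out = 60))
  illum <- rep(c("day", "night"), c(30, 30))
  a <- make_metrics(base_vals, illumination = illum)
  a$plant_id <- "a"
  # plant b: same series, clock offset by 3 frames (transition 3 min later)
  b <- make_metrics(base_vals, illumination = rep(c("day", "night"), c(33, 27)))
  b$plant_id <- "b"
  synced <- sync_by_transition(dplyr::bind_rows(a, b))

  za <- synced$zt_h[synced$plant_id == "a"]
  zb <- synced$zt_h[synced$plant_id == "b"]
  # transition frame sits exactly at lights-off ZT for both plants
  expect_equal(za[31], 9)
  expect_equal(zb[34], 9)
  # shifts are +-1.5 min around the cohort median
  sh <- unique(synced[, c("plant_id", "sync_shift_min")])
  expect_equal(sort(sh$sync_shift_min), c(-1.5, 1.5))
  expect_false(any(synced$sync_flagged))
  # pure translation: within-plant pairwise time differences unchanged
  expect_equal(diff(za), diff(a$t_min) / 60)

  # single plant: output identical up to the global offset
  solo <- sync_by_transition(a)
  expect_equal(diff(solo$zt_h), diff(a$t_min) / 60)
  expect_equal(solo$zt_h[31], 9)

  all_day <- make_metrics(1:10)
  all_day$plant_id <- "c"
  expect_error(sync_by_transition(all_day), "no day-to-night transition")
})

test_that("angular speed of a linear ramp is its slope", {
  # 6 deg/h ramp sampled every minute
  m <- make_metrics(6 * (0:179) / 60)
  sp <- angular_speed(m, "petiole_angle_deg", window_min = 60)
  expect_true(all(is.na(sp$speed_deg_per_h[1:60])))
  expect_equal(sp$speed_deg_per_h[61:180], rep(6, 120), tolerance = 1e-9)

  cst <- angular_speed(make_metrics(rep(4, 120)), "petiole_angle_deg")
  expect_equal(cst$speed_deg_per_h[61:120], rep(0, 60))

  expect_error(angular_speed(m, "no_such_metric"), "unknown metric")
  expect_error(angular_speed(make_metrics(1:10), "petiole_angle_deg",
                             window_min = 1), "two frame intervals")
})

test_that("angular speed of a sinusoid matches the analytic difference", {
  A <- 10; Tper <- 240; w <- 60
  t <- 0:479
  m <- make_metrics(A * sin(2 * pi * t / Tper))
  sp <- angular_speed(m, "petiole_angle_deg", window_min = w)
  # closed form: theta(t) - theta(t-w) = 2 A sin(pi w / T) cos(2 pi (t - w/2) / T)
  expected <- 2 * A * sin(pi * w / Tper) * cos(2 * pi * (t - w / 2) / Tper) / (w / 60)
  got <- sp$speed_deg_per_h[(w + 1):480]
  expect_equal(got, expected[(w + 1):480], tolerance = 1e-9)
  expect_lte(max(abs(got)), 2 * pi * A / (Tper / 60))
})

test_that("speed is invariant to baseline subtraction", {
  set.seed(3)
  m <- make_metrics(cumsum(stats::rnorm(120)))
  sp_abs <- angular_speed(m, "petiole_angle_deg")
  sp_rel <- angular_speed(relative_series(m), "petiole_angle_deg")
  expect_equal(sp_rel$speed_deg_per_h, sp_abs$speed_deg_per_h,
               tolerance = 1e-12)
})

test_that("binning averages per plant on left-closed 2-h bins", {
  m <- make_metrics(rep(5, 120))
  m$plant_id <- "p"
  m$zt_h <- (0:119) / 60
  b <- bin_series(m)
  expect_equal(nrow(b), 1)
  expect_equal(b$mean, 5)
  expect_equal(b$bin_start_zt_h, 0)
  expect_true(b$reliable)

  # values equal to minute index, single 0-2 h bin: mean of 0..119 = 59.5
  m2 <- make_metrics(0:119)
  m2$plant_id <- "p"
  m2$zt_h <- (0:119) / 60
  expect_equal(bin_series(m2)$mean, 59.5)

  # 24 h at 1/min: 12 bins
  m3 <- make_metrics(stats::rnorm(1440))
  m3$plant_id <- "p"
  m3$zt_h <- (0:1439) / 60
  b3 <- bin_series(m3)
  expect_equal(nrow(b3), 12)
  expect_equal(b3$bin_start_zt_h, seq(0, 22, by = 2))

  # sparse bins are marked unreliable
  m4 <- make_metrics(1:5)
  m4$plant_id <- "p"
  m4$zt_h <- (0:4) / 60
  expect_false(bin_series(m4)$reliable)
  expect_error(bin_series(m4[0, ]), "empty")
})

test_that("kinetics tables round-trip through the long CSV format", {
  m <- make_metrics(stats::rnorm(10))
  m$plant_id <- "p1"
  m$treatment <- "FRw"
  m$zt_h <- 2 + m$t_min / 60
  path <- tempfile(fileext = ".csv")
  write_kinetics(m, path)
  long <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(long, c("plant_id", "treatment", "zt_h", "metric", "value"))
  back <- read_kinetics(path)
  expect_equal(back$petiole_angle_deg, m$petiole_angle_deg, tolerance = 1e-12)
})
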