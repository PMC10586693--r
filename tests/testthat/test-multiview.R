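test_that("gap filling reproduces cubic trajectories through short dropouts
          and passes long gaps through", {
  t <- (0:119) / 60
  pos <- array(0, dim = c(120, 20, 2))
  for (k in 1:20) {
    pos[, k, 1] <- 5 + 3 * t - 2 * t^2 + 0.7 * t^3 + k
    pos[, k, 2] <- 1 - t + 0.5 * t^2 - 0.2 * t^3 + 2 * k
  }
  conf <- matrix(0.9, 120, 20)
  conf[50:52, 3] <- 0.1                      # 3-frame dropout
  s <- keypoint_series_2d("c", t, pos, conf)
  s$positions[50:52, 3, ] <- 999             # corrupt the dropped samples
  filled <- fill_gaps(s, max_gap = 0.5, conf_floor = 0.4)
  expect_lt(max(abs(filled$positions[50:52, 3, ] - pos[50:52, 3, ])), 1e-9)
  expect_equal(unname(filled$confidence[51, 3]), 0.9)
  # identity when nothing is below the floor
  s2 <- keypoint_series_2d("c", t, pos, matrix(0.9, 120, 20))
  expect_equal(fill_gaps(s2)$positions, s2$positions)
  # a 2-second dropout with max_gap 0.5 s keeps confidence 0
  conf3 <- matrix(0.9, 120, 20)
  conf3[2:119, 5] <- 0.05
  s3 <- keypoint_series_2d("c", t, pos, conf3)
  f3 <- fill_gaps(s3, max_gap = 0.5)
  expect_true(all(f3$confidence[2:119, 5] == 0))
  expect_equal(f3$positions[2:119, 5, ], pos[2:119, 5, ],
               ignore_attr = TRUE)
})

test_that("the velocity signal matches a longhand construction and honors
          confidence weights", {
  s <- make_kp2d_fixture(n_frames = 60, seed = 3)
  sig <- velocity_signal(s)
  # longhand oracle
  dt <- 1 / s$frame_rate
  nf <- 60
  speeds <- matrix(0, nf, 20)
  for (k in 1:20) {
    vx <- c(diff(s$positions[1:2, k, 1]) / dt,
            (s$positions[3:nf, k, 1] - s$positions[1:(nf - 2), k, 1]) /
              (2 * dt),
            diff(s$positions[(nf - 1):nf, k, 1]) / dt)
    vy <- c(diff(s$positions[1:2, k, 2]) / dt,
            (s$positions[3:nf, k, 2] - s$positions[1:(nf - 2), k, 2]) /
              (2 * dt),
            diff(s$positions[(nf - 1):nf, k, 2]) / dt)
    speeds[, k] <- sqrt(vx^2 + vy^2)
  }
  oracle <- rowSums(speeds * s$confidence) / rowSums(s$confidence)
  expect_lt(max(abs(sig - oracle)), 1e-10)
  # static pose: zero signal
  st <- keypoint_series_2d("c", s$times,
                           array(5, dim = c(60, 20, 2)),
                           matrix(1, 60, 20))
  expect_equal(velocity_signal(st), rep(0, 60))
  # single moving keypoint at 60 px/s with all other confidences zero
  pos <- array(5, dim = c(60, 20, 2))
  pos[, 1, 1] <- s$times * 60
  conf <- matrix(0, 60, 20); conf[, 1] <- 1
  sm <- keypoint_series_2d("c", s$times, pos, conf)
  expect_equal(velocity_signal(sm)[2:59], rep(60, 58), tolerance = 1e-9)
  expect_error(velocity_signal(keypoint_series_2d(
    "c", s$times[1:2], s$positions[1:2, , , drop = FALSE],
    s$confidence[1:2, ])), "3 frames")
})

test_that("lag estimation is exact for every integer shift and rejects
          constant signals", {
  set.seed(9)
  n <- 700
  base <- sin(2 * pi * 1.3 * (1:n) / 60) + 0.8 * sin(2 * pi * 0.4 * (1:n) / 60)
  noise_a <- rnorm(n, 0, 0.2)
  for (k in c(-120, -37, -1, 0, 1, 17, 120)) {
    a <- base[121:(n - 121)] + noise_a[121:(n - 121)]
    idx <- 121:(n - 121) + k
    b <- base[idx] + rnorm(length(idx), 0, 0.2)
    expect_identical(estimate_lag(a, b, max_lag = 120), as.integer(-k))
  }
  expect_identical(estimate_lag(base, base, 120), 0L)
  expect_error(estimate_lag(rep(1, 500), base[1:500], 120), "zero-variance")
  expect_error(estimate_lag(base[1:100], base[1:100], 120), "2\\*max_lag")
})

test_that("synchronization recovers rig-applied offsets and trims to the
          common window", {
  m3 <- demo_model("demo3d")
  traj <- generate_motion("squat", m3, params = list(duration = 2.5),
                          seed = 2)
  config <- rig_config(n_cameras = 3, offsets = c(0L, 5L, -8L),
                       noise_sd = 0.002, dropout_rate = 0,
                       occlusion_rate = 0, seed = 4)
  cameras <- make_default_rig(config)
  obs <- render_observations(m3, traj, cameras, config, seed = 4)
  res <- synchronize(lapply(obs$series, fill_gaps), max_lag = 40)
  expect_identical(res$lags, c(0L, 5L, -8L))
  n_in <- length(obs$series[[1]]$times)
  n_out <- length(res$series[[1]]$times)
  expect_equal(n_in - n_out, 13)
  expect_equal(res$series[[1]]$times, res$series[[3]]$times)
  # two identical copies: zero lag, full window
  two <- synchronize(list(obs$series[[1]], obs$series[[1]]), max_lag = 40)
  expect_identical(two$lags, c(0L, 0L))
  expect_equal(length(two$series[[1]]$times), n_in)
})

test_that("confidence-weighted DLT matches its oracles", {
  cams <- make_camera_fixture()
  set.seed(21)
  pts <- cbind(runif(25, -0.4, 0.4), runif(25, 0.3, 1.7), runif(25, -0.4, 0.4))
  for (i in 1:25) {
    obs <- t(vapply(cams, function(cm) {
      project_points(matrix(pts[i, ], 1), cm$intrinsics,
                     cm$extrinsics)$pixels[1, ]
    }, numeric(2)))
    # noiseless reconstruction
    tri <- triangulate_frame(obs, c(0.9, 0.9), cams)
    expect_lt(sqrt(sum((tri$point - pts[i, ])^2)), 1e-6)
    # common confidence scaling leaves the result unchanged
    tri2 <- triangulate_frame(obs, c(0.45, 0.45), cams)
    expect_lt(max(abs(tri$point - tri2$point)), 1e-9)
  }
  # three cameras, one at confidence zero, equals the two-camera solution
  cams3 <- make_default_rig(rig_config(n_cameras = 3,
                                       angles = c(-45, 0, 45)))
  p <- c(0.1, 1.2, -0.2)
  obs3 <- t(vapply(cams3, function(cm) {
    project_points(matrix(p, 1), cm$intrinsics, cm$extrinsics)$pixels[1, ]
  }, numeric(2)))
  t3 <- triangulate_frame(obs3, c(0.8, 0, 0.8), cams3)
  t2 <- triangulate_frame(obs3[c(1, 3), ], c(0.8, 0.8), cams3[c(1, 3)])
  expect_lt(max(abs(t3$point - t2$point)), 1e-9)
  # fewer than two confident cameras: invalid, no exception
  t0 <- triangulate_frame(obs3, c(0.8, 0, 0.1), cams3)
  expect_false(t0$valid)
})

test_that("series triangulation is frame-wise consistent, propagates
          occlusion validity, and refuses unsynchronized input", {
  m3 <- demo_model("demo3d")
  traj <- generate_motion("squat", m3, params = list(duration = 1.2), seed = 6)
  config <- rig_config(offsets = c(0L, 0L), noise_sd = 0, dropout_rate = 0,
                       occlusion_rate = 0, seed = 8)
  cameras <- make_default_rig(config)
  obs <- render_observations(m3, traj, cameras, config, seed = 8)
  kp <- triangulate(obs$series, cameras)
  err <- sqrt(rowSums((matrix(kp$positions, ncol = 3) -
                         matrix(obs$truth_kp3d$positions, ncol = 3))^2))
  expect_lt(mean(err, na.rm = TRUE), 1e-6)
  f <- 10
  tf <- triangulate_frame(rbind(obs$series[[1]]$positions[f, 4, ],
                                obs$series[[2]]$positions[f, 4, ]),
                          c(obs$series[[1]]$confidence[f, 4],
                            obs$series[[2]]$confidence[f, 4]), cameras)
  expect_equal(kp$positions[f, 4, ], tf$point,
               ignore_attr = TRUE, tolerance = 1e-12)
  # keypoint occluded in all but one camera is invalid over that interval
  s2 <- obs$series
  s2[[2]]$confidence[20:40, 7] <- 0.0
  kp2 <- triangulate(s2, cameras)
  expect_true(all(!kp2$validity[20:40, 7]))
  # unsynchronized times rejected
  bad <- obs$series
  bad[[2]] <- keypoint_series_2d("c2", bad[[2]]$times + 0.5,
                                 bad[[2]]$positions, bad[[2]]$confidence)
  expect_error(triangulate(bad, cameras), "synchron")
})

test_that("reprojection of triangulated points stays within the injected
          2D noise (Monte-Carlo)", {
  cams <- make_camera_fixture()
  set.seed(31)
  pts <- cbind(runif(60, -0.3, 0.3), runif(60, 0.5, 1.6), runif(60, -0.3, 0.3))
  noise_px <- 2
  resid <- c()
  for (i in seq_len(nrow(pts))) {
    obs <- t(vapply(cams, function(cm) {
      project_points(matrix(pts[i, ], 1), cm$intrinsics,
                     cm$extrinsics)$pixels[1, ]
    }, numeric(2))) + matrix(rnorm(4, 0, noise_px), 2, 2)
    tri <- triangulate_frame(obs, c(1, 1), cams)
    for (ci in 1:2) {
      rp <- project_points(matrix(tri$point, 1), cams[[ci]]$intrinsics,
                           cams[[ci]]$extrinsics)$pixels
      resid <- c(resid, sqrt(sum((rp - obs[ci, ])^2)))
    }
  }
  expect_lt(sqrt(mean(resid^2)), noise_px * sqrt(2))
})
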