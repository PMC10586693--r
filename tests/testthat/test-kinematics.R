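test_that("model files load, validate, and round-trip through YAML", {
  m3 <- demo_model("demo3d")
  expect_equal(m3$n_coordinates, 21)
  m2 <- demo_model("demo2d")
  expect_equal(m2$n_coordinates, 9)
  expect_length(m2$muscles, 8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model(m2, f)
  back <- load_model(f)
  expect_equal(back$coordinates, m2$coordinates)
  q <- setNames(runif(9, -0.2, 0.2), m2$coordinates$name)
  expect_equal(forward_kinematics(back, q)$markers,
               forward_kinematics(m2, q)$markers, tolerance = 1e-12)
  # cyclic graphs and duplicates rejected
  segs <- m2$segments
  segs[[1]]$parent <- "calcn_l"
  expect_error(skeletal_model(segs), "root|cyclic")
  segs <- m2$segments
  segs[[3]]$name <- segs[[2]]$name
  expect_error(skeletal_model(segs), "duplicate")
})

test_that("forward kinematics matches the planar closed form and keeps
          segments rigid", {
  m2 <- demo_model("demo2d")
  q <- setNames(rep(0, 9), m2$coordinates$name)
  q["hip_flexion_r"] <- pi / 2
  fk <- forward_kinematics(m2, q)
  # hip at (0, -0.02); thigh 0.41 rotated +90 deg about z: knee at x=0.41
  expect_equal(unname(fk$keypoints["r_knee", ]),
               c(0.41, -0.02, 0), tolerance = 1e-12)
  q["knee_angle_r"] <- -pi / 2
  fk2 <- forward_kinematics(m2, q)
  expect_equal(unname(fk2$keypoints["r_ankle", ]),
               c(0.41, -0.02 - 0.43, 0), tolerance = 1e-12)
  # rigidity: intra-segment marker distances independent of posture
  m3 <- demo_model("demo3d")
  set.seed(7)
  d_ref <- NULL
  for (i in 1:20) {
    qq <- setNames(runif(21, -0.4, 0.4), m3$coordinates$name)
    f <- forward_kinematics(m3, qq)
    d <- sqrt(sum((f$markers["r_knee_lat", ] - f$markers["r_thigh1", ])^2))
    if (is.null(d_ref)) d_ref <- d
    expect_equal(d, d_ref, tolerance = 1e-12)
  }
  expect_error(forward_kinematics(m3, setNames(rep(10, 21),
                                               m3$coordinates$name)),
               "bounds")
})

test_that("anthropometric scaling is exact on identity, detects a longer
          thigh, conserves mass, and is idempotent", {
  m3 <- demo_model("demo3d")
  q0 <- setNames(rep(0, 21), m3$coordinates$name)
  fk <- forward_kinematics(m3, q0)
  neutral <- marker_set(seq(0, 0.5, by = 1 / 60),
                        aperm(array(t(fk$markers),
                                    dim = c(3, 43, 31)), c(3, 2, 1)),
                        rownames(fk$markers))
  sc <- scale_model(m3, neutral, height = 1.75, mass = 80)
  expect_true(all(abs(sc$scale_factors - 1) < 1e-6))
  expect_equal(sum(vapply(sc$model$segments, `[[`, numeric(1), "mass")), 80)
  # thigh x 1.1 via a stretched generator model
  m_long <- subject_model(m3, 1.75, 75, jitter_sd = 0)
  m_long$segments <- lapply(m_long$segments, function(s) s)
  ix <- which(vapply(m_long$segments, `[[`, character(1), "name") ==
                "femur_r")
  m_long$segments[[ix]]$markers <-
    lapply(m_long$segments[[ix]]$markers, function(p) p * 1.1)
  fk_l <- forward_kinematics(m_long, q0)
  neutral_l <- marker_set(seq(0, 0.5, by = 1 / 60),
                          aperm(array(t(fk_l$markers),
                                      dim = c(3, 43, 31)), c(3, 2, 1)),
                          rownames(fk_l$markers))
  sc2 <- scale_model(m3, neutral_l, 1.75, 75)
  expect_equal(unname(sc2$scale_factors["femur_r"]), 1.1, tolerance = 0.01)
  expect_lt(abs(sc2$scale_factors["tibia_l"] - 1), 0.02)
  # idempotence: rescaling a scaled model with its own neutral markers
  fk_s <- forward_kinematics(sc2$model, q0)
  neutral_s <- marker_set(seq(0, 0.5, by = 1 / 60),
                          aperm(array(t(fk_s$markers),
                                      dim = c(3, 43, 31)), c(3, 2, 1)),
                          rownames(fk_s$markers))
  sc3 <- scale_model(sc2$model, neutral_s, 1.75, 75)
  expect_true(all(abs(sc3$scale_factors - 1) < 1e-6))
  expect_error(scale_model(m3, make_marker_fixture(), 1.75, 75),
               "missing required scaling markers")
})

test_that("inverse kinematics inverts forward kinematics and stays exact at
          the default pose", {
  set.seed(19)
  for (which in c("demo2d", "demo3d")) {
    m <- demo_model(which)
    nq <- m$n_coordinates
    rot <- m$coordinates$type == "rotation"
    for (i in 1:6) {
      q_true <- setNames(0.3 * runif(nq, -1, 1) *
                           (abs(m$coordinates$lower) > 0.01),
                         m$coordinates$name)
      q_true <- pmin(pmax(q_true, m$coordinates$lower + 0.05),
                     m$coordinates$upper - 0.05)
      fk <- forward_kinematics(m, q_true)
      ms <- marker_set(0, array(fk$markers, dim = c(1, nrow(fk$markers), 3)),
                       rownames(fk$markers))
      ik <- inverse_kinematics(m, ms, max_iter = 40, tol = 1e-12)
      err <- abs(ik$trajectory$q[1, ] - q_true)
      expect_lt(max(err[rot]), 0.1 * pi / 180)
      expect_lt(max(err[!rot]), 5e-4)
    }
    # default pose: exact recovery with ~zero RMSE
    q0 <- setNames(rep(0, nq), m$coordinates$name)
    fk0 <- forward_kinematics(m, q0)
    ms0 <- marker_set(0, array(fk0$markers,
                               dim = c(1, nrow(fk0$markers), 3)),
                      rownames(fk0$markers))
    ik0 <- inverse_kinematics(m, ms0, max_iter = 40, tol = 1e-12)
    expect_lt(ik0$rmse[1], 1e-8)
  }
})

test_that("the zero-lag filter has no phase shift, -6 dB at the cutoff,
          and passes DC", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  y <- lowpass_filter(x, 12, fs = fs)
  mid <- 200:800
  cc <- ccf(x[mid], y[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
  # amplitude ratio at the cutoff: two passes of -3 dB each
  xc <- sin(2 * pi * 12 * t)
  yc <- lowpass_filter(xc, 12, fs = fs)
  expect_equal(max(abs(yc[mid])), 0.5, tolerance = 0.02)
  expect_equal(lowpass_filter(rep(3, 200), 6, fs = fs), rep(3, 200),
               tolerance = 1e-3)
  expect_error(lowpass_filter(x, 60, fs = fs), "Nyquist")
})

test_that("differentiation matches closed forms", {
  t <- seq(0, 2, by = 0.01)
  tr <- coordinate_trajectory(t, cbind(ramp = 3 * t,
                                       sine = sin(2 * pi * 1.5 * t),
                                       const = rep(2, length(t))))
  d <- differentiate(tr)
  i <- 10:190
  expect_equal(unname(d$qd[i, "ramp"]), rep(3, length(i)), tolerance = 1e-9)
  expect_lt(max(abs(d$qdd[i, "ramp"])), 1e-9)
  amp <- max(abs(d$qd[i, "sine"]))
  expect_equal(amp, 2 * pi * 1.5, tolerance = 1e-3 * 2 * pi * 1.5 * 3)
  expect_lt(max(abs(d$qd[i, "const"])), 1e-12)
  expect_error(differentiate(coordinate_trajectory((0:3) / 60,
                                                   matrix(0, 4, 1,
                                                          dimnames = list(NULL, "a")))),
               "5 frames")
})
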