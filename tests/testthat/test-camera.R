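test_that("projection maps the optical axis to the principal point and is
          linear in focal length", {
  intr <- camera_intrinsics(1000, 1100, 360, 640, rep(0, 5))
  extr <- camera_extrinsics(c(0, 0, 0), c(0, 0, 2))
  on_axis <- project_points(matrix(c(0, 0, 1), 1), intr, extr)
  expect_equal(as.vector(on_axis$pixels), c(360, 640))
  p <- matrix(c(0.3, -0.2, 1), 1)
  px1 <- project_points(p, intr, extr)$pixels
  intr2 <- camera_intrinsics(2000, 2200, 360, 640, rep(0, 5))
  px2 <- project_points(p, intr2, extr)$pixels
  expect_equal(as.vector(px2 - c(360, 640)),
               2 * as.vector(px1 - c(360, 640)), tolerance = 1e-12)
  behind <- project_points(matrix(c(0, 0, -5), 1), intr, extr)
  expect_false(behind$valid)
})

test_that("projection agrees with an independently coded longhand model", {
  set.seed(42)
  for (i in 1:20) {
    intr <- camera_intrinsics(runif(1, 500, 2000), runif(1, 500, 2000),
                              runif(1, 200, 500), runif(1, 400, 900),
                              c(runif(2, -0.1, 0.1), runif(2, -0.01, 0.01),
                                runif(1, -0.05, 0.05)),
                              image_size = c(720, 1280))
    extr <- camera_extrinsics(runif(3, -0.5, 0.5), c(runif(2, -1, 1), 3))
    P <- c(runif(2, -0.5, 0.5), runif(1, -0.5, 0.5))
    # longhand: rotate, translate, divide, distort, map
    th <- sqrt(sum(extr$rotation_vector^2))
    R <- if (th < 1e-15) diag(3) else {
      k <- extr$rotation_vector / th
      K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
      diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    pc <- as.vector(R %*% P) + extr$translation
    x <- pc[1] / pc[3]; y <- pc[2] / pc[3]
    r2 <- x^2 + y^2
    d <- intr$distortion
    rad <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
    xd <- x * rad + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
    yd <- y * rad + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
    expected <- c(intr$fx * xd + intr$cx, intr$fy * yd + intr$cy)
    got <- project_points(matrix(P, 1), intr, extr)$pixels
    expect_equal(as.vector(got), expected, tolerance = 1e-10)
  }
})

test_that("undistortion inverts the distortion map within 1e-6 px", {
  intr <- camera_intrinsics(980, 980, 360, 640,
                            c(-0.04, 0.01, 1e-4, -1e-4, 0),
                            image_size = c(720, 1280))
  g <- expand.grid(x = seq(50, 670, by = 120), y = seq(50, 1230, by = 200))
  px <- as.matrix(g)
  und <- undistort_points(px, intr)
  expect_true(all(und$converged))
  redist <- distort_normalized(und$normalized, intr$distortion)
  px_back <- cbind(intr$fx * redist[, 1] + intr$cx,
                   intr$fy * redist[, 2] + intr$cy)
  expect_lt(max(abs(px_back - px)), 1e-6)
  # zero distortion: exact closed form
  intr0 <- camera_intrinsics(980, 980, 360, 640, rep(0, 5),
                             image_size = c(720, 1280))
  und0 <- undistort_points(px, intr0)
  expect_equal(und0$normalized,
               cbind((px[, 1] - 360) / 980, (px[, 2] - 640) / 980))
  # strong distortion far outside the image can fail to converge
  intr_bad <- camera_intrinsics(980, 980, 360, 640, c(-0.9, 0, 0, 0, 0),
                                image_size = c(720, 1280))
  far <- undistort_points(matrix(c(30000, 30000), 1), intr_bad)
  expect_false(all(far$converged))
})

test_that("extrinsic calibration recovers generated poses exactly without
          noise and degrades gracefully with corner noise", {
  set.seed(11)
  board <- checkerboard_spec(6, 7, 0.025)
  intr <- camera_intrinsics(980, 980, 360, 640,
                            c(-0.04, 0.01, 1e-4, -1e-4, 0),
                            image_size = c(720, 1280))
  obj <- checkerboard_points(board)
  for (i in 1:15) {
    rvec <- runif(3, -0.4, 0.4)
    tvec <- c(runif(2, -0.15, 0.15), runif(1, 1.5, 3.5))
    tvec[1:2] <- tvec[1:2] - colMeans(obj)[1:2]  # keep board in view
    true_ext <- camera_extrinsics(rvec, tvec)
    px <- project_points(obj, intr, true_ext)$pixels
    est <- estimate_extrinsics(px, board, intr)
    rot_err <- sqrt(sum((est$extrinsics$rotation_vector -
                           true_ext$rotation_vector)^2))
    tra_err <- sqrt(sum((est$extrinsics$translation -
                           true_ext$translation)^2))
    expect_lt(rot_err, 1e-4)
    expect_lt(tra_err, 1e-5)
  }
  # 0.5-px corner noise: reprojection RMSE near the noise level
  true_ext <- camera_extrinsics(c(0.1, -0.2, 0.05), c(-0.1, -0.05, 2.5))
  px <- project_points(obj, intr, true_ext)$pixels +
    matrix(rnorm(2 * nrow(obj), 0, 0.5), ncol = 2)
  est <- estimate_extrinsics(px, board, intr)
  expect_lt(est$rmse_px, 1.0)
  expect_gt(est$rmse_px, 0.2)
})

test_that("degenerate calibration inputs are rejected", {
  board <- checkerboard_spec(6, 7, 0.025)
  intr <- camera_intrinsics(1000, 1000, 360, 640)
  expect_error(estimate_extrinsics(matrix(1, 3, 2), board, intr),
               "4 corners")
  expect_error(estimate_extrinsics(matrix(1, 10, 2),
                                   checkerboard_spec(2, 5, 0.025), intr),
               "degenerate")
})

test_that("projection is equivariant under a change of world frame", {
  set.seed(5)
  intr <- camera_intrinsics(900, 900, 350, 600)
  extr <- camera_extrinsics(c(0.2, 0.1, -0.3), c(0.1, -0.2, 3))
  P <- matrix(runif(30, -0.5, 0.5), 10, 3)
  # rigid world transform g: x' = Rw x + tw
  rw <- c(0.3, -0.1, 0.2); tw <- c(0.4, -0.3, 0.1)
  Rw <- rotvec_to_matrix(rw)
  P2 <- P %*% t(Rw) + matrix(tw, 10, 3, byrow = TRUE)
  # camera composed with the inverse transform sees identical pixels
  Rc <- rotvec_to_matrix(extr$rotation_vector)
  R2 <- Rc %*% t(Rw)
  t2 <- extr$translation - as.vector(R2 %*% tw)
  extr2 <- camera_extrinsics(matrix_to_rotvec(R2), t2)
  expect_equal(project_points(P, intr, extr)$pixels,
               project_points(P2, intr, extr2)$pixels, tolerance = 1e-9)
})
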