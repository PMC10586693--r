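#' Camera intrinsic parameters
#'
#' The fifteen-parameter pinhole camera model decomposes as 3 rotation + 3
#' translation (extrinsics) + 2 focal lengths + 2 principal-point
#' coordinates + 5 distortion coefficients (radial k1, k2, k3; tangential
#' p1, p2).
#'
#' @param fx,fy Focal lengths (px), > 0.
#' @param cx,cy Principal point (px), inside the image bounds.
#' @param distortion Numeric length-5 vector `(k1, k2, p1, p2, k3)`.
#' @param image_size `c(width, height)` in px.
#' @return A `camera_intrinsics` object.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy,
                              distortion = rep(0, 5),
                              image_size = c(1280, 720)) {
  stopifnot(fx > 0, fy > 0, length(distortion) == 5,
            cx >= 0, cx <= image_size[1], cy >= 0, cy <= image_size[2])
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 distortion = as.numeric(distortion),
                 image_size = as.numeric(image_size)),
            class = "camera_intrinsics")
}

#' Camera extrinsic parameters (world-to-camera)
#'
#' @param rotation_vector Axis-angle rotation vector (rad), world-to-camera;
#'   magnitude in `[0, pi]` (longer vectors are wrapped).
#' @param translation World origin expressed in the camera frame (m).
#' @return A `camera_extrinsics` object.
#' @export
camera_extrinsics <- function(rotation_vector, translation) {
  rotation_vector <- as.numeric(rotation_vector)
  th <- sqrt(sum(rotation_vector^2))
  if (th > pi) {
    # wrap to the canonical [0, pi] representation
    th_new <- th %% (2 * pi)
    ax <- rotation_vector / th
    if (th_new > pi) {
      th_new <- 2 * pi - th_new
      ax <- -ax
    }
    rotation_vector <- ax * th_new
  }
  structure(list(rotation_vector = rotation_vector,
                 translation = as.numeric(translation)),
            class = "camera_extrinsics")
}

#' @rdname camera_intrinsics
#' @param intrinsics,extrinsics Component objects.
#' @export
camera <- function(intrinsics, extrinsics) {
  structure(list(intrinsics = intrinsics, extrinsics = extrinsics),
            class = "camera")
}

#' Checkerboard specification
#'
#' @param inner_corner_rows,inner_corner_cols Inner-corner counts (>= 2).
#' @param square_size Square edge length (m), > 0. The default 25 mm matches
#'   a 210x175 mm board printed on A4 paper (8x7 squares, 7x6 inner corners).
#' @return A `checkerboard_spec` object.
#' @export
checkerboard_spec <- function(inner_corner_rows = 6, inner_corner_cols = 7,
                              square_size = 0.025) {
  stopifnot(inner_corner_rows >= 2, inner_corner_cols >= 2, square_size > 0)
  structure(list(inner_corner_rows = inner_corner_rows,
                 inner_corner_cols = inner_corner_cols,
                 square_size = square_size),
            class = "checkerboard_spec")
}

#' Board-frame coordinates of checkerboard inner corners (planar, z = 0)
#' @param board A [checkerboard_spec()].
#' @return `n x 3` matrix (m).
#' @export
checkerboard_points <- function(board) {
  g <- expand.grid(x = seq_len(board$inner_corner_cols) - 1,
                   y = seq_len(board$inner_corner_rows) - 1)
  cbind(g$x, g$y, 0) * board$square_size
}

#' Rodrigues rotation-vector / matrix conversions
#'
#' @param rvec Length-3 rotation vector (rad).
#' @return `rotvec_to_matrix`: 3x3 rotation matrix; `matrix_to_rotvec`: the
#'   rotation vector with magnitude in `[0, pi]`.
#' @export
rotvec_to_matrix <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th < 1e-14) return(diag(3))
  k <- rvec / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotvec_to_matrix
#' @param R 3x3 rotation matrix.
#' @export
matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(max(ct, -1), 1)
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near-pi: extract axis from R + I
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonals
    i <- which.max(ax)
    s <- sign(c(B[i, 1], B[i, 2], B[i, 3]))
    s[s == 0] <- 1
    ax <- ax * s * sign(ax[i])
    return(ax / sqrt(sum(ax^2)) * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  ax * th
}

#' Apply the 5-coefficient distortion model to normalized coordinates
#'
#' @param xn `n x 2` matrix of normalized (pinhole) image coordinates.
#' @param distortion `(k1, k2, p1, p2, k3)`.
#' @return `n x 2` matrix of distorted normalized coordinates.
#' @export
distort_normalized <- function(xn, distortion) {
  k1 <- distortion[1]; k2 <- distortion[2]
  p1 <- distortion[3]; p2 <- distortion[4]; k3 <- distortion[5]
  x <- xn[, 1]; y <- xn[, 2]
  r2 <- x^2 + y^2
  rad <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  cbind(xd, yd)
}

#' Project 3D world points to 2D pixels
#'
#' Applies the world-to-camera rigid transform, perspective division, the
#' 5-coefficient distortion model, then the focal / principal-point mapping.
#' Points with non-positive depth are flagged invalid rather than raising an
#' error.
#'
#' @param points_world `n x 3` matrix (m).
#' @param intr A [camera_intrinsics()].
#' @param extr A [camera_extrinsics()].
#' @return List with `pixels` (`n x 2`) and logical `valid` (positive depth).
#' @export
project_points <- function(points_world, intr, extr) {
  P <- matrix(points_world, ncol = 3)
  R <- rotvec_to_matrix(extr$rotation_vector)
  Pc <- P %*% t(R) + matrix(extr$translation, nrow(P), 3, byrow = TRUE)
  valid <- Pc[, 3] > 0
  xn <- cbind(Pc[, 1] / Pc[, 3], Pc[, 2] / Pc[, 3])
  xd <- distort_normalized(xn, intr$distortion)
  px <- cbind(intr$fx * xd[, 1] + intr$cx, intr$fy * xd[, 2] + intr$cy)
  px[!valid, ] <- NA_real_
  list(pixels = px, valid = valid)
}

#' Undistort pixel observations to normalized image coordinates
#'
#' Fixed-point inversion of the distortion map (the standard iteration used
#' for mild lens distortion); redistorting the output reproduces the input to
#' within 1e-6 px for points within the image. Non-converged points are
#' flagged.
#'
#' @param points_px `n x 2` matrix of pixel coordinates.
#' @param intr A [camera_intrinsics()].
#' @param max_iter,tol Iteration controls (tolerance in normalized units).
#' @return List with `normalized` (`n x 2`) and logical `converged`.
#' @export
undistort_points <- function(points_px, intr, max_iter = 50, tol = 1e-12) {
  px <- matrix(points_px, ncol = 2)
  xd <- cbind((px[, 1] - intr$cx) / intr$fx, (px[, 2] - intr$cy) / intr$fy)
  if (all(abs(intr$distortion) < 1e-15)) {
    return(list(normalized = xd, converged = rep(TRUE, nrow(xd))))
  }
  xn <- xd
  for (i in seq_len(max_iter)) {
    d <- distort_normalized(xn, intr$distortion)
    err <- xd - d
    err[!is.finite(err)] <- 0
    xn <- xn + err
    if (max(abs(err)) < tol) break
  }
  resid <- distort_normalized(xn, intr$distortion) - xd
  converged <- sqrt(rowSums(resid^2)) * max(intr$fx, intr$fy) < 1e-6 &
    apply(is.finite(xn), 1, all)
  converged[is.na(converged)] <- FALSE
  xn[!is.finite(xn)] <- NA_real_
  list(normalized = xn, converged = converged)
}

# Normalized homography estimation (DLT) from planar correspondences.
estimate_homography <- function(obj_xy, img_xy) {
  normalize_pts <- function(p) {
    mu <- colMeans(p)
    d <- sqrt(rowSums((p - matrix(mu, nrow(p), 2, byrow = TRUE))^2))
    s <- sqrt(2) / mean(d)
    if (!is.finite(s)) stop("degenerate (collinear) corner configuration")
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * mu[1], -s * mu[2], 1), 3, 3)
    list(T = T, p = cbind(p[, 1] * s - s * mu[1], p[, 2] * s - s * mu[2]))
  }
  na <- normalize_pts(obj_xy); nb <- normalize_pts(img_xy)
  n <- nrow(obj_xy)
  A <- matrix(0, 2 * n, 9)
  x <- na$p[, 1]; y <- na$p[, 2]; u <- nb$p[, 1]; v <- nb$p[, 2]
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  h <- svd(A)$v[, 9]
  H <- solve(nb$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% na$T
  H / H[3, 3]
}

#' Estimate camera extrinsics from a single checkerboard image
#'
#' Planar-pose initialization by homography decomposition followed by
#' nonlinear (Gauss-Newton) reprojection-error minimization over the six pose
#' parameters. Of the two planar-pose solutions, the one placing the board in
#' front of the camera with the lower reprojection RMSE is returned.
#'
#' @param corners_px `n x 2` detected inner-corner pixel coordinates, ordered
#'   as [checkerboard_points()].
#' @param board A [checkerboard_spec()].
#' @param intr A [camera_intrinsics()].
#' @return List with `extrinsics` ([camera_extrinsics()]) and `rmse_px`.
#' @export
estimate_extrinsics <- function(corners_px, board, intr) {
  obj <- checkerboard_points(board)
  corners_px <- matrix(corners_px, ncol = 2)
  if (nrow(corners_px) < 4) stop("need at least 4 corners")
  if (nrow(corners_px) != nrow(obj)) {
    stop("corner count does not match board specification")
  }
  # collinearity check
  c0 <- scale(obj[, 1:2], scale = FALSE)
  if (min(svd(c0)$d) < 1e-10) stop("degenerate (collinear) corner configuration")
  und <- undistort_points(corners_px, intr)
  xn <- und$normalized
  H <- estimate_homography(obj[, 1:2], xn)
  h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
  lambda <- 2 / (sqrt(sum(h1^2)) + sqrt(sum(h2^2)))
  poses <- lapply(c(1, -1), function(s) {
    r1 <- s * lambda * h1; r2 <- s * lambda * h2; t <- s * lambda * h3
    r3 <- cross3(r1, r2)
    Rr <- cbind(r1, r2, r3)
    # project to the nearest rotation matrix
    sv <- svd(Rr)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
    list(rvec = matrix_to_rotvec(R), t = t)
  })
  refine <- function(p0) {
    theta <- c(p0$rvec, p0$t)
    resid_fn <- function(th) {
      pr <- project_points(obj, intr,
                           camera_extrinsics(th[1:3], th[4:6]))
      r <- as.vector(pr$pixels - corners_px)
      r[!is.finite(r)] <- 1e3
      r
    }
    for (it in 1:50) {
      r0 <- resid_fn(theta)
      J <- matrix(0, length(r0), 6)
      h <- 1e-7
      for (j in 1:6) {
        tp <- theta; tp[j] <- tp[j] + h
        J[, j] <- (resid_fn(tp) - r0) / h
      }
      delta <- tryCatch(qr.solve(J, -r0), error = function(e) rep(0, 6))
      theta <- theta + delta
      if (sqrt(sum(delta^2)) < 1e-12) break
    }
    r <- resid_fn(theta)
    list(rvec = theta[1:3], t = theta[4:6],
         rmse = sqrt(mean(r^2)))
  }
  cand <- lapply(poses, function(p) {
    # board must be in front of the camera
    depth <- (rotvec_to_matrix(p$rvec) %*% colMeans(obj) + p$t)[3]
    if (depth <= 0) return(NULL)
    refine(p)
  })
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) stop("no pose places the board in front of the camera")
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "rmse"))]]
  list(extrinsics = camera_extrinsics(best$rvec, best$t),
       rmse_px = best$rmse)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
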