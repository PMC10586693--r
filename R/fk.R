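# Vectorized rigid-body kinematics over time.
#
# Rotations are stored as T x 9 matrices (column-major 3x3 per row), points
# and vectors as T x 3 matrices; every helper operates on all frames at once
# so that whole-trajectory kinematics costs a handful of vectorized ops per
# segment.

rot_identity <- function(n) {
  matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), n, 9)
}

# per-frame matrix product C = A %*% B for T x 9 rotation stacks
rot_mul <- function(A, B) {
  C <- matrix(0, nrow(A), 9)
  for (j in 1:3) {       # column of result
    for (i in 1:3) {     # row of result
      C[, i + 3 * (j - 1)] <-
        A[, i] * B[, 1 + 3 * (j - 1)] +
        A[, i + 3] * B[, 2 + 3 * (j - 1)] +
        A[, i + 6] * B[, 3 + 3 * (j - 1)]
    }
  }
  C
}

# v' = R %*% v per frame; R is T x 9, v is T x 3 (or length-3)
rot_apply <- function(R, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow(R), 3, byrow = TRUE)
  cbind(R[, 1] * v[, 1] + R[, 4] * v[, 2] + R[, 7] * v[, 3],
        R[, 2] * v[, 1] + R[, 5] * v[, 2] + R[, 8] * v[, 3],
        R[, 3] * v[, 1] + R[, 6] * v[, 2] + R[, 9] * v[, 3])
}

# rotation about a fixed unit axis u by per-frame angles th (Rodrigues)
rot_axis_angle <- function(u, th) {
  n <- length(th)
  ct <- cos(th); st <- sin(th); vt <- 1 - ct
  x <- u[1]; y <- u[2]; z <- u[3]
  cbind(ct + x * x * vt,      x * y * vt + z * st,  x * z * vt - y * st,
        x * y * vt - z * st,  ct + y * y * vt,      y * z * vt + x * st,
        x * z * vt + y * st,  y * z * vt - x * st,  ct + z * z * vt)
}

cross_t <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Full kinematic pass over the model tree. Q, Qd, Qdd: T x nq matrices
# (Qd/Qdd optional). Returns per-segment world kinematics and per-dof world
# axes/origins for the generalized-force pass.
fk_states <- function(model, Q, Qd = NULL, Qdd = NULL) {
  Q <- as_q_matrix(model, Q)
  n <- nrow(Q)
  want_vel <- !is.null(Qd)
  want_acc <- !is.null(Qdd)
  if (want_vel) Qd <- as_q_matrix(model, Qd)
  if (want_acc) Qdd <- as_q_matrix(model, Qdd)
  zero3 <- matrix(0, n, 3)
  ground <- list(R = rot_identity(n), o = zero3, omega = zero3,
                 alpha = zero3, v = zero3, a = zero3)
  states <- list(ground = ground)
  dof_info <- vector("list", model$n_coordinates)
  qi <- 0L
  for (s in model$segments) {
    p <- states[[s$parent]]
    r <- rot_apply(p$R, s$joint$location_in_parent)
    F <- list(R = p$R,
              o = p$o + r,
              omega = p$omega,
              alpha = p$alpha,
              v = p$v + cross_t(p$omega, r),
              a = p$a + cross_t(p$alpha, r) +
                cross_t(p$omega, cross_t(p$omega, r)))
    for (d in s$joint$dofs) {
      qi <- qi + 1L
      q <- Q[, qi]
      qd <- if (want_vel) Qd[, qi] else rep(0, n)
      qdd <- if (want_acc) Qdd[, qi] else rep(0, n)
      u <- d$axis / sqrt(sum(d$axis^2))
      w <- rot_apply(F$R, u)  # axis in world frame
      dof_info[[qi]] <- list(coordinate = d$coordinate, type = d$type,
                             segment = s$name, axis_world = w, origin = F$o)
      if (d$type == "rotation") {
        F$alpha <- F$alpha + w * qdd + cross_t(F$omega, w * qd)
        F$omega <- F$omega + w * qd
        F$R <- rot_mul(F$R, rot_axis_angle(u, q))
      } else {
        disp <- w * q
        F$o <- F$o + disp
        F$v <- F$v + w * qd + cross_t(F$omega, disp)
        F$a <- F$a + w * qdd + 2 * cross_t(F$omega, w * qd) +
          cross_t(F$alpha, disp) +
          cross_t(F$omega, cross_t(F$omega, disp))
      }
    }
    lc <- s$joint$location_in_child
    if (any(lc != 0)) {
      r2 <- rot_apply(F$R, -lc)
      F$o <- F$o + r2
      F$v <- F$v + cross_t(F$omega, r2)
      F$a <- F$a + cross_t(F$alpha, r2) +
        cross_t(F$omega, cross_t(F$omega, r2))
    }
    states[[s$name]] <- F
  }
  list(states = states, dofs = dof_info, n = n)
}

as_q_matrix <- function(model, q) {
  nq <- model$n_coordinates
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  q <- as.matrix(q)
  if (ncol(q) != nq) stop("expected ", nq, " coordinates, got ", ncol(q))
  if (!is.null(colnames(q)) &&
      !identical(colnames(q), model$coordinates$name)) {
    q <- q[, model$coordinates$name, drop = FALSE]
  }
  q
}

#' Forward kinematics: world positions of markers and keypoints
#'
#' Composes the joint transforms root-to-leaf and returns world positions of
#' all marker and keypoint attachments.
#'
#' @param model A `skeletal_model`.
#' @param q Coordinate values: named vector (single pose) or `frames x nq`
#'   matrix. Values outside the hard coordinate bounds raise an error.
#' @param check_bounds Validate against coordinate bounds (default TRUE).
#' @return For a single pose, a list with `markers` and `keypoints`
#'   (`n x 3` matrices with rownames); for a trajectory, `frames x n x 3`
#'   arrays.
#' @export
forward_kinematics <- function(model, q, check_bounds = TRUE) {
  single <- is.null(dim(q))
  Q <- as_q_matrix(model, q)
  if (check_bounds) {
    lo <- model$coordinates$lower; up <- model$coordinates$upper
    viol <- sweep(Q, 2, lo, `<`) | sweep(Q, 2, up, `>`)
    if (any(viol)) {
      stop("coordinate(s) outside hard bounds: ",
           paste(unique(model$coordinates$name[colSums(viol) > 0]),
                 collapse = ", "))
    }
  }
  fk <- fk_states(model, Q)
  mk <- attachment_positions(model, fk, "markers")
  kp <- attachment_positions(model, fk, "keypoints")
  if (single) {
    list(markers = mk[1, , , drop = TRUE],
         keypoints = kp[1, , , drop = TRUE])
  } else {
    list(markers = mk, keypoints = kp)
  }
}

attachment_positions <- function(model, fk, field = "markers") {
  names_all <- unlist(lapply(model$segments, function(s) names(s[[field]])))
  n <- fk$n
  out <- array(NA_real_, dim = c(n, length(names_all), 3),
               dimnames = list(NULL, names_all, c("x", "y", "z")))
  j <- 0L
  for (s in model$segments) {
    st <- fk$states[[s$name]]
    for (p in s[[field]]) {
      j <- j + 1L
      out[, j, ] <- st$o + rot_apply(st$R, p)
    }
  }
  out
}
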