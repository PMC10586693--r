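#' Inverse kinematics by per-frame weighted nonlinear least squares
#'
#' Solves, frame by frame, for the coordinates q minimizing the weighted sum
#' of squared distances between model marker positions and observed markers,
#' warm-started from the previous frame's solution. A tiny quadratic pull
#' (weight `regularization`) toward the previous frame resolves redundancy
#' and is switchable.
#'
#' @param model A `skeletal_model`.
#' @param markers A [marker_set()] whose names map onto model attachments.
#' @param weights Optional named per-marker weights (default uniform).
#' @param q_init Initial pose for the first frame (named vector; default the
#'   neutral pose).
#' @param regularization Weight of the pull toward the previous frame
#'   (default 1e-6; 0 disables).
#' @param max_iter Gauss-Newton iterations per frame.
#' @param tol Convergence tolerance on the step norm.
#' @return List with `trajectory` (a [coordinate_trajectory()]), `rmse`
#'   (per-frame marker RMSE, m), and `failed_frames`.
#' @export
inverse_kinematics <- function(model, markers, weights = NULL, q_init = NULL,
                               regularization = 1e-6, max_iter = 15,
                               tol = 1e-7) {
  nq <- model$n_coordinates
  model_marker_names <- unlist(lapply(model$segments,
                                      function(s) names(s$markers)))
  use <- intersect(markers$marker_names, model_marker_names)
  if (!length(use)) stop("no observed markers map onto model attachments")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(use)), use)
  w <- sqrt(weights[use])
  obs_ix <- match(use, markers$marker_names)
  mod_ix <- match(use, model_marker_names)
  nf <- length(markers$times)
  Q <- matrix(0, nf, nq, dimnames = list(NULL, model$coordinates$name))
  rmse <- numeric(nf)
  failed <- integer(0)
  q <- if (is.null(q_init)) rep(0, nq) else q_init[model$coordinates$name]
  lo <- model$coordinates$lower; up <- model$coordinates$upper
  h <- 1e-6
  for (f in seq_len(nf)) {
    obs <- matrix(markers$positions[f, obs_ix, ], ncol = 3)
    keep <- apply(is.finite(obs), 1, all)
    q_prev <- q
    ok <- FALSE
    lambda <- 1e-6
    sse_of <- function(qq) {
      mk <- attachment_positions(model, fk_states(model, matrix(qq, 1)),
                                 "markers")
      pred <- matrix(mk[1, mod_ix, ], ncol = 3)
      sum(((pred - obs)[keep, , drop = FALSE] * w[keep])^2) +
        regularization * sum((qq - q_prev)^2)
    }
    sse <- sse_of(q)
    for (it in seq_len(max_iter)) {
      # residuals + finite-difference Jacobian in one vectorized FK call
      Qp <- matrix(rep(q, nq + 1), nq + 1, nq, byrow = TRUE)
      Qp[cbind(2:(nq + 1), 1:nq)] <- q + h
      mk <- attachment_positions(model, fk_states(model, Qp), "markers")
      pred <- matrix(mk[1, mod_ix, ], ncol = 3)
      r <- (pred - obs)[keep, , drop = FALSE] * w[keep]
      r <- as.vector(r)
      J <- matrix(0, length(r), nq)
      for (j in seq_len(nq)) {
        pj <- matrix(mk[j + 1, mod_ix, ], ncol = 3)
        J[, j] <- as.vector(((pj - pred)[keep, , drop = FALSE] * w[keep]) / h)
      }
      if (regularization > 0) {
        r <- c(r, sqrt(regularization) * (q - q_prev))
        J <- rbind(J, sqrt(regularization) * diag(nq))
      }
      A0 <- crossprod(J)
      g <- crossprod(J, r)
      moved <- FALSE
      for (try in 1:8) {
        delta <- tryCatch(as.vector(solve(A0 + lambda * diag(nq), -g)),
                          error = function(e) NULL)
        if (is.null(delta)) { lambda <- lambda * 10; next }
        q_new <- pmin(pmax(q + delta, lo), up)
        sse_new <- sse_of(q_new)
        if (is.finite(sse_new) && sse_new <= sse) {
          q <- q_new; sse <- sse_new
          lambda <- max(lambda / 5, 1e-10)
          moved <- TRUE
          break
        }
        lambda <- lambda * 10
      }
      if (!moved) { ok <- TRUE; break }   # stationary (damped out)
      if (sqrt(sum(delta^2)) < tol) { ok <- TRUE; break }
      if (it == max_iter) ok <- TRUE      # converged to iteration budget
    }
    mk1 <- attachment_positions(model, fk_states(model, matrix(q, 1)),
                                "markers")
    pred <- matrix(mk1[1, mod_ix, ], ncol = 3)
    res <- sqrt(rowSums((pred - obs)^2))[keep]
    rmse[f] <- sqrt(mean(res^2))
    if (!ok || !all(is.finite(q))) failed <- c(failed, f)
    Q[f, ] <- q
  }
  if (length(failed) > 0.05 * nf) {
    stop("IK solver failed on more than 5% of frames: ",
         paste(utils::head(failed, 10), collapse = ", "))
  }
  list(trajectory = coordinate_trajectory(markers$times, Q),
       rmse = rmse, failed_frames = failed)
}

#' Zero-lag low-pass Butterworth filter
#'
#' Fourth-order by default, applied forward and backward (zero phase lag,
#' doubling the attenuation: -6 dB at the cutoff), with reflection padding
#' at the endpoints.
#'
#' @param traj A [coordinate_trajectory()], [marker_set()], or numeric
#'   matrix/vector sampled uniformly.
#' @param cutoff Cutoff frequency (Hz); must be below Nyquist.
#' @param fs Sampling rate (Hz); inferred for trajectory objects.
#' @param order Filter order per pass (default 4).
#' @return Object of the same type, filtered.
#' @export
lowpass_filter <- function(traj, cutoff, fs = NULL, order = 4) {
  if (inherits(traj, "coordinate_trajectory")) {
    fs <- 1 / median(diff(traj$times))
    out <- traj
    out$q <- apply_filtfilt(traj$q, cutoff, fs, order)
    out$qd <- NULL; out$qdd <- NULL
    return(out)
  }
  if (inherits(traj, "marker_set")) {
    fs <- 1 / median(diff(traj$times))
    out <- traj
    for (d in 1:3) {
      out$positions[, , d] <-
        apply_filtfilt(traj$positions[, , d, drop = TRUE], cutoff, fs, order)
    }
    return(out)
  }
  if (is.null(fs)) stop("fs must be supplied for plain numeric input")
  apply_filtfilt(traj, cutoff, fs, order)
}

apply_filtfilt <- function(x, cutoff, fs, order) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency (",
                             fs / 2, " Hz)")
  vec <- is.null(dim(x))
  X <- as.matrix(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- nrow(X)
  npad <- min(n - 1, max(3 * order, ceiling(3 * fs / cutoff)))
  out <- X
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    # odd reflection about the endpoints suppresses edge transients
    pre <- 2 * v[1] - v[seq(npad + 1, 2)]
    post <- 2 * v[n] - v[seq(n - 1, n - npad)]
    ext <- c(pre, v, post)
    fwd <- signal::filter(bf, ext)
    bwd <- rev(signal::filter(bf, rev(fwd)))
    out[, j] <- bwd[seq(npad + 1, npad + n)]
  }
  if (vec) as.vector(out) else out
}

#' Differentiate a coordinate trajectory
#'
#' Central differences (one-sided at the endpoints) populate the velocity
#' and acceleration fields.
#'
#' @param traj A [coordinate_trajectory()] with at least 5 frames.
#' @return The trajectory with `qd` and `qdd` filled in.
#' @export
differentiate <- function(traj) {
  n <- length(traj$times)
  if (n < 5) stop("need at least 5 frames to differentiate")
  dt <- median(diff(traj$times))
  traj$qd <- central_diff(traj$q, dt)
  traj$qdd <- central_diff(traj$qd, dt)
  traj
}

central_diff <- function(X, dt) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- X
  D[2:(n - 1), ] <- (X[3:n, , drop = FALSE] - X[1:(n - 2), , drop = FALSE]) /
    (2 * dt)
  D[1, ] <- (X[2, ] - X[1, ]) / dt
  D[n, ] <- (X[n, ] - X[n - 1, ]) / dt
  D
}
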