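#' Fill short low-confidence gaps by cubic-spline interpolation
#'
#' Runs of frames whose confidence falls below `conf_floor` and whose
#' duration is at most `max_gap` are replaced by cubic-spline interpolation
#' of the flanking well-observed positions; their confidence is set to the
#' mean of the flanking confidences. Longer occlusions keep confidence 0 and
#' are excluded downstream.
#'
#' @param series A [keypoint_series_2d()].
#' @param max_gap Longest gap to bridge (s).
#' @param conf_floor Confidence threshold below which a frame counts as a
#'   dropout.
#' @return A gap-filled [keypoint_series_2d()].
#' @export
fill_gaps <- function(series, max_gap = 0.5, conf_floor = 0.4) {
  nf <- length(series$times)
  dt <- 1 / series$frame_rate
  pos <- series$positions
  conf <- series$confidence
  for (k in seq_along(series$keypoint_names)) {
    low <- conf[, k] < conf_floor
    if (!any(low) || all(low)) {
      if (all(low)) conf[low, k] <- 0
      next
    }
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    good <- which(!low)
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      dur <- (i1 - i0 + 1) * dt
      interior <- i0 > 1 && i1 < nf
      if (dur <= max_gap && interior) {
        idx <- i0:i1
        for (d in 1:2) {
          pos[idx, k, d] <- stats::spline(series$times[good],
                                          series$positions[good, k, d],
                                          xout = series$times[idx],
                                          method = "fmm")$y
        }
        conf[idx, k] <- mean(c(conf[i0 - 1, k], conf[i1 + 1, k]))
      } else {
        conf[i0:i1, k] <- 0
      }
    }
  }
  keypoint_series_2d(series$camera_id, series$times, pos, conf,
                     series$keypoint_names)
}

#' Confidence-weighted mean keypoint speed signal
#'
#' Per-keypoint speeds by central finite differences, combined as the
#' confidence-weighted mean across keypoints per frame (weights renormalized
#' per frame; frames where all confidences are zero yield 0). This is the
#' scalar signal cross-correlated between cameras for synchronization.
#'
#' @param series A [keypoint_series_2d()].
#' @param presmooth_hz Optional low-pass cutoff (Hz) applied to the pixel
#'   positions before differencing; high-frequency detector jitter otherwise
#'   dominates the per-keypoint speeds. `NULL` differentiates the raw
#'   positions.
#' @param normalize Divide each keypoint's speed by its time-mean before
#'   averaging. Projection geometry gives each keypoint a view-dependent
#'   gain; removing it makes the signal shape comparable across cameras.
#' @return Numeric vector of speeds (px/s; unitless when normalized), one
#'   per frame.
#' @export
velocity_signal <- function(series, presmooth_hz = NULL, normalize = FALSE) {
  nf <- length(series$times)
  if (nf < 3) stop("need at least 3 frames to form a velocity signal")
  dt <- 1 / series$frame_rate
  pos <- series$positions
  if (!is.null(presmooth_hz)) {
    for (d in 1:2) {
      pos[, , d] <- apply_filtfilt(pos[, , d, drop = TRUE], presmooth_hz,
                                   series$frame_rate, 4)
    }
  }
  v <- array(0, dim = dim(pos))
  v[2:(nf - 1), , ] <-
    (pos[3:nf, , , drop = FALSE] -
       pos[1:(nf - 2), , , drop = FALSE]) / (2 * dt)
  v[1, , ] <- (pos[2, , ] - pos[1, , ]) / dt
  v[nf, , ] <- (pos[nf, , ] - pos[nf - 1, , ]) / dt
  speed <- sqrt(v[, , 1]^2 + v[, , 2]^2)
  w <- series$confidence
  # unobserved projections (e.g., outside the image) carry no weight
  w[!is.finite(speed)] <- 0
  speed[!is.finite(speed)] <- 0
  if (normalize) {
    mu <- colSums(speed * w) / pmax(colSums(w), 1e-12)
    speed <- sweep(speed, 2, pmax(mu, 1e-12), `/`)
  }
  wsum <- rowSums(w)
  out <- rowSums(speed * w)
  out[wsum > 0] <- out[wsum > 0] / wsum[wsum > 0]
  out[wsum == 0] <- 0
  out
}

#' Estimate the integer-frame lag between two signals
#'
#' Argmax over lags in `[-max_lag, max_lag]` of the normalized
#' cross-correlation of the mean-removed signals. A positive lag means `b`
#' starts later than `a`; ties are broken toward the smaller `|lag|`.
#'
#' @param signal_a,signal_b Numeric vectors.
#' @param max_lag Maximum lag magnitude (frames).
#' @return Integer lag (frames).
#' @export
estimate_lag <- function(signal_a, signal_b, max_lag = 240) {
  a <- signal_a - mean(signal_a)
  b <- signal_b - mean(signal_b)
  if (stats::sd(signal_a) == 0 || stats::sd(signal_b) == 0) {
    stop("cannot synchronize: zero-variance velocity signal (static scene)")
  }
  if (length(a) < 2 * max_lag || length(b) < 2 * max_lag) {
    stop("signals must be at least 2*max_lag frames long")
  }
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    # b delayed by L: compare a[t] with b[t + L]
    if (L >= 0) {
      ia <- seq_len(length(a) - L)
      ib <- ia + L
    } else {
      ib <- seq_len(length(b) + L)
      ia <- ib - L
    }
    if (length(ia) < 3) return(-Inf)
    aa <- a[ia]; bb <- b[ib]
    den <- sqrt(sum(aa^2) * sum(bb^2))
    if (den == 0) return(-Inf)
    sum(aa * bb) / den
  }, numeric(1))
  best <- max(cc)
  cand <- lags[cc >= best - 1e-12]
  as.integer(cand[which.min(abs(cand))])
}

#' Synchronize multiple camera series
#'
#' Lags are estimated pairwise against the first series using
#' [velocity_signal()] and [estimate_lag()]; all series are trimmed to the
#' maximal common window so that the resulting series share identical times.
#'
#' @param series_list List of [keypoint_series_2d()] sharing one frame rate.
#' @param max_lag Maximum lag magnitude (frames).
#' @param presmooth_hz Position pre-smoothing cutoff for the velocity
#'   signals (see [velocity_signal()]); 8 Hz by default for robustness to
#'   detector jitter.
#' @return List with `series` (aligned list) and `lags` (integer vector,
#'   first element 0).
#' @export
synchronize <- function(series_list, max_lag = 240, presmooth_hz = 8) {
  rates <- vapply(series_list, `[[`, numeric(1), "frame_rate")
  if (diff(range(rates)) > 1e-6) stop("all series must share one frame rate")
  # drop a few edge frames: one-sided differences and filter edge effects
  # otherwise leave identical artifacts at both ends of every signal
  trim <- function(x) {
    k <- min(8L, (length(x) - 1) %/% 4)
    x[(k + 1):(length(x) - k)]
  }
  ref_sig <- trim(velocity_signal(series_list[[1]], presmooth_hz))
  lags <- c(0L, vapply(series_list[-1], function(s) {
    estimate_lag(ref_sig, trim(velocity_signal(s, presmooth_hz)), max_lag)
  }, integer(1)))
  # a positive lag means series i's content is delayed relative to series 1:
  # its frame t + lag matches series 1's frame t, so drop its leading frames.
  n <- vapply(series_list, function(s) length(s$times), integer(1))
  off <- lags - min(lags)
  len <- min(n - off)
  if (len < 1) stop("no common window after synchronization")
  t0 <- series_list[[1]]$times[1]
  dt <- 1 / rates[1]
  aligned <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    idx <- seq_len(len) + off[i]
    keypoint_series_2d(s$camera_id,
                       t0 + (seq_len(len) - 1) * dt,
                       s$positions[idx, , , drop = FALSE],
                       s$confidence[idx, , drop = FALSE],
                       s$keypoint_names)
  })
  list(series = aligned, lags = lags)
}

#' Triangulate one multi-camera observation by confidence-weighted DLT
#'
#' Observations are undistorted, the homogeneous DLT system is assembled (two
#' equations per camera), each camera's pair of rows is scaled by its
#' confidence, and the point is the smallest-singular-vector solution. The
#' result is invalid when fewer than two cameras exceed `min_confidence`.
#'
#' @param obs `n_cameras x 2` matrix of pixel observations.
#' @param confidence Per-camera confidences.
#' @param cameras List of [camera()] objects.
#' @param min_confidence Minimum confidence for a camera to contribute.
#' @return List with `point` (length-3, m) and `valid`.
#' @export
triangulate_frame <- function(obs, confidence, cameras, min_confidence = 0.3) {
  obs <- matrix(obs, ncol = 2)
  use <- which(confidence >= min_confidence & apply(is.finite(obs), 1, all))
  if (length(use) < 2) return(list(point = rep(NA_real_, 3), valid = FALSE))
  A <- matrix(0, 2 * length(use), 4)
  for (i in seq_along(use)) {
    ci <- use[i]
    cam <- cameras[[ci]]
    xn <- undistort_points(obs[ci, , drop = FALSE], cam$intrinsics)$normalized
    R <- rotvec_to_matrix(cam$extrinsics$rotation_vector)
    P <- cbind(R, cam$extrinsics$translation)  # normalized projection
    w <- confidence[ci]
    A[2 * i - 1, ] <- w * (xn[1] * P[3, ] - P[1, ])
    A[2 * i, ]     <- w * (xn[2] * P[3, ] - P[2, ])
  }
  X <- svd(A)$v[, 4]
  if (abs(X[4]) < 1e-14) return(list(point = rep(NA_real_, 3), valid = FALSE))
  list(point = X[1:3] / X[4], valid = TRUE)
}

#' Triangulate synchronized 2D keypoint series to 3D
#'
#' @param series_list Synchronized list of [keypoint_series_2d()] (identical
#'   times).
#' @param cameras List of [camera()] objects, one per series.
#' @param min_confidence Per-camera confidence threshold.
#' @return A [keypoint_series_3d()].
#' @export
triangulate <- function(series_list, cameras, min_confidence = 0.3) {
  times <- series_list[[1]]$times
  for (s in series_list[-1]) {
    if (length(s$times) != length(times) ||
        max(abs(s$times - times)) > 1e-9) {
      stop("series are not synchronized (times differ); run synchronize() first")
    }
  }
  nf <- length(times)
  nk <- 20L
  pos <- array(NA_real_, dim = c(nf, nk, 3))
  valid <- matrix(FALSE, nf, nk)
  ncam <- length(series_list)
  for (f in seq_len(nf)) {
    for (k in seq_len(nk)) {
      obs <- t(vapply(series_list, function(s) s$positions[f, k, ],
                      numeric(2)))
      conf <- vapply(series_list, function(s) s$confidence[f, k], numeric(1))
      tri <- triangulate_frame(obs, conf, cameras, min_confidence)
      if (tri$valid) {
        pos[f, k, ] <- tri$point
        valid[f, k] <- TRUE
      }
    }
  }
  keypoint_series_3d(times, pos, valid, series_list[[1]]$keypoint_names)
}
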