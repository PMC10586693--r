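#' Synthetic acquisition-rig configuration
#'
#' Describes the emulated multi-camera smartphone rig: camera placement
#' (horizontal angles from the subject's facing direction, mounting height,
#' distance to the capture volume), frame rate, portrait image size, the 3D
#' keypoint noise injected before projection, a confidence model with
#' dropouts and occlusion intervals, and unknown integer inter-camera frame
#' offsets. Defaults mirror a two-camera collection: cameras at +/-45
#' degrees, 1.5 m high, 3 m away, 60 Hz, 720x1280 px, and 18-mm 3D keypoint
#' noise.
#'
#' @param n_cameras Number of cameras (>= 2).
#' @param angles Horizontal camera angles (degrees); defaults to the
#'   two-camera +/-45 preset, or the five-camera +/-70, +/-45, 0 layout when
#'   `n_cameras = 5`.
#' @param height Camera height (m).
#' @param distance Camera distance to the volume center (m).
#' @param frame_rate Hz.
#' @param image_size `c(width, height)` px (portrait).
#' @param noise_sd 3D keypoint noise magnitude (m): Gaussian with this RMS
#'   3D norm (per-axis SD `noise_sd/sqrt(3)`).
#' @param noise_ar First-order autocorrelation of the keypoint noise across
#'   frames; pose-detector error is strongly correlated in time. The
#'   marginal SD stays at `noise_sd`; 0 gives white noise.
#' @param confidence_base,confidence_sd Mean and spread of per-observation
#'   confidences.
#' @param dropout_rate Probability that a frame/keypoint/camera observation
#'   is a low-confidence dropout.
#' @param occlusion_rate Expected number of occlusion intervals per camera
#'   per 10 s; `occlusion_duration` their mean length (s).
#' @param offsets Integer per-camera frame offsets (0 = synchronized);
#'   `NULL` draws them in `[-max_offset, max_offset]`.
#' @param max_offset Offset range when drawing (frames).
#' @param target Aim point / capture-volume center (m).
#' @param seed RNG seed; every rig quantity is a pure function of
#'   (config, seed).
#' @return A `rig_config` list.
#' @export
rig_config <- function(n_cameras = 2, angles = NULL, height = 1.5,
                       distance = 3, frame_rate = 60,
                       image_size = c(720, 1280), noise_sd = 0.018,
                       noise_ar = 0.9,
                       confidence_base = 0.85, confidence_sd = 0.08,
                       dropout_rate = 0.01, occlusion_rate = 1,
                       occlusion_duration = 0.3, offsets = NULL,
                       max_offset = 30, target = c(0, 1, 0), seed = 1) {
  if (is.null(angles)) {
    angles <- if (n_cameras == 5) c(-70, -45, 0, 45, 70) else
      seq(-45, 45, length.out = n_cameras)
  }
  stopifnot(n_cameras >= 2, length(angles) == n_cameras, noise_sd >= 0)
  if (!is.null(offsets)) stopifnot(length(offsets) == n_cameras,
                                   offsets == round(offsets))
  structure(list(n_cameras = n_cameras, angles = angles, height = height,
                 distance = distance, frame_rate = frame_rate,
                 image_size = image_size, noise_sd = noise_sd,
                 noise_ar = noise_ar,
                 confidence_base = confidence_base,
                 confidence_sd = confidence_sd,
                 dropout_rate = dropout_rate,
                 occlusion_rate = occlusion_rate,
                 occlusion_duration = occlusion_duration,
                 offsets = offsets, max_offset = max_offset,
                 target = target, seed = seed),
            class = "rig_config")
}

#' Build the rig's cameras
#'
#' Cameras sit on a circle of the configured radius at the configured
#' height, aimed at the capture-volume center, with plausible
#' smartphone-like intrinsics (mild radial distortion).
#'
#' @param config A [rig_config()].
#' @return List of [camera()] objects.
#' @export
make_default_rig <- function(config = rig_config()) {
  lapply(seq_len(config$n_cameras), function(i) {
    th <- config$angles[i] * pi / 180
    # subject faces +x; angle measured from the facing direction
    pos <- c(config$target[1] + config$distance * cos(th), config$height,
             config$target[3] + config$distance * sin(th))
    z_c <- config$target - pos
    z_c <- z_c / sqrt(sum(z_c^2))
    x_c <- cross3(z_c, c(0, 1, 0))
    x_c <- x_c / sqrt(sum(x_c^2))
    y_c <- cross3(z_c, x_c)
    R <- rbind(x_c, y_c, z_c)
    camera(
      camera_intrinsics(fx = 700, fy = 700,
                        cx = config$image_size[1] / 2,
                        cy = config$image_size[2] / 2,
                        distortion = c(-0.04, 0.01, 1e-4, -1e-4, 0),
                        image_size = config$image_size),
      camera_extrinsics(matrix_to_rotvec(R), as.vector(-R %*% pos))
    )
  })
}

#' Standing equilibrium pose for a contact-bearing model
#'
#' Zero joint angles with the pelvis height solved (1D root find) so that
#' the total vertical contact force equals the model weight.
#'
#' @param model A `skeletal_model` with contact spheres.
#' @return Named coordinate vector.
#' @export
standing_pose <- function(model) {
  q <- stats::setNames(rep(0, model$n_coordinates), model$coordinates$name)
  if (!length(model$contact_spheres) || !"pelvis_ty" %in% names(q)) return(q)
  ankles <- intersect(c("ankle_angle_r", "ankle_angle_l"), names(q))
  pelvis_rows <- intersect(c("pelvis_ty", "pelvis_tilt"), names(q))
  resid <- function(x) {
    q["pelvis_ty"] <- x[1]
    q[ankles] <- x[2]
    Q <- matrix(q, 1, dimnames = list(NULL, names(q)))
    fk <- fk_states(model, Q, Q * 0, Q * 0)
    tau <- inverse_dynamics_core(model, fk)
    con <- contact_generalized_forces(model, fk)
    (tau - con$tau)[1, pelvis_rows]
  }
  # initial height: spheres just touching
  fk0 <- fk_states(model, matrix(q, 1, dimnames = list(NULL, names(q))))
  bottom <- min(vapply(model$contact_spheres, function(s) {
    st <- fk0$states[[s$segment]]
    (st$o + rot_apply(st$R, s$location))[2] - s$radius
  }, numeric(1)))
  x <- c(-bottom - 0.005, 0)
  for (it in 1:50) {
    r0 <- resid(x)
    if (max(abs(r0)) < 1e-8) break
    J <- matrix(0, length(r0), 2)
    h <- 1e-7
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (resid(xp) - r0) / h
    }
    step <- tryCatch(solve(J, -r0), error = function(e) -0.1 * r0[1:2])
    # damped Newton keeps the pose within the contact-supported regime
    x <- x + pmin(pmax(step, -0.02), 0.02)
  }
  q["pelvis_ty"] <- x[1]
  q[ankles] <- x[2]
  q
}

#' Generate a ground-truth motion on a fixture model
#'
#' Smooth task trajectories constructed within coordinate bounds:
#' `static` (constant standing pose), `squat` (single bell-profiled cycle
#' with the right foot anchored to its standing position and the foot kept
#' flat), `sit_to_stand` (flexed-to-standing ramp), and `walk` (periodic
#' gait pattern with forward progression). Subject-to-subject variation
#' (amplitudes, timing) is seeded; everything is a pure function of
#' (parameters, seed).
#'
#' @param task `"walk"`, `"squat"`, `"sit_to_stand"`, or `"static"`.
#' @param model A fixture `skeletal_model` (demo2d or demo3d layout).
#' @param params List: `duration` (s), `frame_rate` (Hz, default 60),
#'   `depth` (squat knee flexion, rad), `asymmetry` (extra left-knee-flexion
#'   fraction; 0 = symmetric), `speed` (walk, m/s), `vary` (SD of seeded
#'   amplitude variation, default 0.08).
#' @param seed RNG seed.
#' @return A [coordinate_trajectory()].
#' @export
generate_motion <- function(task, model, params = list(), seed = 1) {
  p <- utils::modifyList(list(duration = NULL, frame_rate = 60, depth = 1.0,
                              asymmetry = 0, speed = 1.2, vary = 0.08,
                              pad = NULL),
                         params)
  set.seed(seed)
  jitter <- function() 1 + p$vary * stats::rnorm(1)
  qn <- model$coordinates$name
  make_traj <- function(times, Q) {
    colnames(Q) <- qn
    coordinate_trajectory(times, Q)
  }
  if (task == "static") {
    dur <- p$duration %||% 1
    times <- seq(0, dur, by = 1 / p$frame_rate)
    q <- standing_pose(model)
    return(make_traj(times, matrix(q, length(times), length(qn),
                                   byrow = TRUE)))
  }
  if (task == "squat") return(squat_motion(model, p, jitter))
  if (task == "sit_to_stand") return(sts_motion(model, p, jitter))
  if (task == "walk") return(walk_motion(model, p, jitter))
  stop("unknown task: ", task)
}

# planar leg chain: world position of the ankle center given pelvis pose and
# leg angles (shared by demo2d / demo3d sagittal construction)
leg_chain_xy <- function(tilt, hip, knee, hip_off, thigh, shank) {
  a1 <- tilt
  a2 <- tilt + hip
  a3 <- tilt + hip + knee
  rot2 <- function(a, v) cbind(cos(a) * v[1] - sin(a) * v[2],
                               sin(a) * v[1] + cos(a) * v[2])
  rot2(a1, hip_off) + rot2(a2, c(0, -thigh)) + rot2(a3, c(0, -shank))
}

squat_motion <- function(model, p, jitter) {
  qn <- model$coordinates$name
  dur <- p$duration %||% 1.6
  pad <- p$pad %||% 0.4          # quiet standing before and after
  times <- seq(0, dur + 2 * pad, by = 1 / p$frame_rate)
  tm <- pmin(pmax(times - pad, 0), dur)
  B <- 0.5 * (1 - cos(2 * pi * tm / dur))         # 0 -> 1 -> 0 bell
  depth <- p$depth * jitter()
  hip_gain <- 0.85 * jitter()
  knee_r <- -depth * B
  # the involved (left) leg unloads early: its extra flexion rises steeply
  # at the start of the descent so the foot leaves the ground before the
  # leg is loaded at depth
  unload <- 1 - (1 - B)^3
  knee_l <- -depth * B - depth * p$asymmetry * unload
  knee_l <- pmax(knee_l, min(model$coordinates$lower[
    match("knee_angle_l", qn)] + 0.05, -0.01))
  hip_r <- hip_gain * depth * B
  hip_l <- hip_gain * (depth * B + 0.25 * depth * p$asymmetry * unload)
  q0 <- standing_pose(model)
  a0 <- if ("ankle_angle_r" %in% qn) q0["ankle_angle_r"] else 0
  hip_off <- hip_offset(model)
  seg_len <- segment_lengths(model)
  anchor <- leg_chain_xy(0, 0, 0, hip_off, seg_len$thigh, seg_len$shank)
  anchor <- c(anchor[1], anchor[2] + q0["pelvis_ty"])
  # the trunk lean (pelvis tilt) is solved per frame so the whole-body
  # center of mass stays vertically over its standing position: squatting
  # humans do exactly this, and it keeps the required friction forces small
  tilt <- -0.12 * B
  build_Q <- function(tilt) {
    ankle_r <- a0 - (tilt + hip_r + knee_r)
    ankle_l <- a0 - (tilt + hip_l + knee_l)
    chain <- leg_chain_xy(tilt, hip_r, knee_r, hip_off, seg_len$thigh,
                          seg_len$shank)
    Q <- matrix(0, length(times), length(qn), dimnames = list(NULL, qn))
    Q[, "pelvis_tx"] <- anchor[1] - chain[, 1]
    Q[, "pelvis_ty"] <- anchor[2] - chain[, 2]
    Q[, "pelvis_tilt"] <- tilt
    Q[, "hip_flexion_r"] <- hip_r
    Q[, "hip_flexion_l"] <- hip_l
    Q[, "knee_angle_r"] <- knee_r
    Q[, "knee_angle_l"] <- knee_l
    Q[, "ankle_angle_r"] <- ankle_r
    Q[, "ankle_angle_l"] <- ankle_l
    if ("lumbar_extension" %in% qn) Q[, "lumbar_extension"] <- -0.5 * tilt
    Q
  }
  com_target <- model_com_x(model, build_Q(tilt * 0)[1, , drop = FALSE])
  for (it in 1:25) {
    cx <- model_com_x(model, build_Q(tilt))
    resid <- cx - com_target
    if (max(abs(resid)) < 1e-6) break
    dcx <- (model_com_x(model, build_Q(tilt + 1e-5)) - cx) / 1e-5
    tilt <- tilt - pmin(pmax(resid / dcx, -0.1), 0.1)
  }
  clamp_bounds(model, coordinate_trajectory(times, build_Q(tilt)))
}

# horizontal center-of-mass position per frame
model_com_x <- function(model, Q) {
  fk <- fk_states(model, Q)
  tot <- 0; mtot <- 0
  for (s in model$segments) {
    st <- fk$states[[s$name]]
    cx <- (st$o + rot_apply(st$R, s$com))[, 1]
    tot <- tot + s$mass * cx
    mtot <- mtot + s$mass
  }
  tot / mtot
}

sts_motion <- function(model, p, jitter) {
  qn <- model$coordinates$name
  dur <- p$duration %||% 1.6
  times <- seq(0, dur, by = 1 / p$frame_rate)
  S <- 0.5 * (1 - cos(pi * pmin(times / (0.85 * dur), 1)))  # 0 -> 1 rise
  depth <- 1.3 * jitter()
  lean0 <- 0.35 * jitter()
  B <- 1 - S
  hip <- depth * 0.9 * B
  knee <- -depth * B
  seg_len <- segment_lengths(model)
  q0 <- standing_pose(model)
  a0 <- if ("ankle_angle_r" %in% qn) q0["ankle_angle_r"] else 0
  hip_off <- hip_offset(model)
  anchor <- leg_chain_xy(0, 0, 0, hip_off, seg_len$thigh, seg_len$shank)
  anchor <- c(anchor[1], anchor[2] + q0["pelvis_ty"])
  tilt <- -lean0 * B
  build_Q <- function(tilt) {
    ankle <- a0 - (tilt + hip + knee)
    chain <- leg_chain_xy(tilt, hip, knee, hip_off, seg_len$thigh,
                          seg_len$shank)
    Q <- matrix(0, length(times), length(qn), dimnames = list(NULL, qn))
    Q[, "pelvis_tx"] <- anchor[1] - chain[, 1]
    Q[, "pelvis_ty"] <- anchor[2] - chain[, 2]
    Q[, "pelvis_tilt"] <- tilt
    for (s in c("r", "l")) {
      Q[, paste0("hip_flexion_", s)] <- hip
      Q[, paste0("knee_angle_", s)] <- knee
      Q[, paste0("ankle_angle_", s)] <- ankle
    }
    if ("lumbar_extension" %in% qn) Q[, "lumbar_extension"] <- 0.6 * tilt
    Q
  }
  com_target <- model_com_x(model, build_Q(tilt * 0)[1, , drop = FALSE])
  for (it in 1:25) {
    cx <- model_com_x(model, build_Q(tilt))
    resid <- cx - com_target
    if (max(abs(resid)) < 1e-6) break
    dcx <- (model_com_x(model, build_Q(tilt + 1e-5)) - cx) / 1e-5
    tilt <- tilt - pmin(pmax(resid / dcx, -0.1), 0.1)
  }
  clamp_bounds(model, coordinate_trajectory(times, build_Q(tilt)))
}

walk_motion <- function(model, p, jitter) {
  qn <- model$coordinates$name
  dur <- p$duration %||% 3
  times <- seq(0, dur, by = 1 / p$frame_rate)
  f <- 0.9 * jitter()                      # stride frequency (Hz)
  Ah <- 0.42 * jitter()                    # hip flexion amplitude
  ph <- 2 * pi * f * times
  Q <- matrix(0, length(times), length(qn), dimnames = list(NULL, qn))
  Q[, "pelvis_tx"] <- p$speed * jitter() * (times - dur / 2)
  Q[, "pelvis_ty"] <- 0.95 + 0.02 * sin(2 * ph)
  Q[, "pelvis_tilt"] <- -0.05 + 0.02 * sin(2 * ph)
  Q[, "hip_flexion_r"] <- 0.05 + Ah * sin(ph)
  Q[, "hip_flexion_l"] <- 0.05 + Ah * sin(ph + pi)
  Q[, "knee_angle_r"] <- -0.35 + 0.3 * cos(ph + 0.4)
  Q[, "knee_angle_l"] <- -0.35 + 0.3 * cos(ph + pi + 0.4)
  Q[, "ankle_angle_r"] <- 0.08 * sin(ph + 1.2)
  Q[, "ankle_angle_l"] <- 0.08 * sin(ph + pi + 1.2)
  if ("pelvis_rotation" %in% qn) {
    Q[, "pelvis_rotation"] <- 0.06 * sin(ph)
    Q[, "pelvis_list"] <- 0.04 * sin(ph + pi / 2)
    Q[, "lumbar_extension"] <- -0.08 + 0.03 * sin(2 * ph)
    Q[, "lumbar_bending"] <- 0.05 * sin(ph)
    Q[, "lumbar_rotation"] <- -0.06 * sin(ph)
    Q[, "hip_adduction_r"] <- 0.05 * sin(ph + 0.8)
    Q[, "hip_adduction_l"] <- -0.05 * sin(ph + pi + 0.8)
    Q[, "subtalar_angle_r"] <- 0.04 * sin(ph)
    Q[, "subtalar_angle_l"] <- 0.04 * sin(ph + pi)
  }
  clamp_bounds(model, coordinate_trajectory(times, Q))
}

hip_offset <- function(model) {
  seg_names <- vapply(model$segments, `[[`, character(1), "name")
  fem <- model$segments[[match("femur_r", seg_names)]]
  fem$joint$location_in_parent[1:2]
}

segment_lengths <- function(model) {
  seg_names <- vapply(model$segments, `[[`, character(1), "name")
  tib <- model$segments[[match("tibia_r", seg_names)]]
  cal <- model$segments[[match("calcn_r", seg_names)]]
  list(thigh = abs(tib$joint$location_in_parent[2]),
       shank = abs(cal$joint$location_in_parent[2]))
}

clamp_bounds <- function(model, traj) {
  lo <- model$coordinates$lower; up <- model$coordinates$upper
  margin <- 1e-3
  traj$q <- pmin(pmax(traj$q,
                      matrix(lo + margin, nrow(traj$q), length(lo),
                             byrow = TRUE)),
                 matrix(up - margin, nrow(traj$q), length(up), byrow = TRUE))
  traj
}

#' Render multi-camera keypoint observations of a motion
#'
#' Forward kinematics yields ground-truth 3D keypoints and anatomical
#' markers; Gaussian 3D noise (per config) is added to the keypoints before
#' projection through each camera's full distortion model; per-camera
#' integer frame offsets are applied; confidences are drawn from the
#' confidence model, with seeded dropouts and occlusion intervals forcing
#' confidence near zero.
#'
#' @param model A `skeletal_model` carrying the 20-keypoint attachments.
#' @param traj Ground-truth [coordinate_trajectory()] at the rig frame rate.
#' @param cameras List of [camera()] (see [make_default_rig()]).
#' @param config A [rig_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List: `series` (per-camera [keypoint_series_2d()]),
#'   `truth_kp3d` ([keypoint_series_3d()]), `truth_markers`
#'   ([marker_set()]), `offsets` (applied integer offsets).
#' @export
render_observations <- function(model, traj, cameras, config = rig_config(),
                                seed = config$seed) {
  set.seed(seed)
  fkr <- forward_kinematics(model, traj$q, check_bounds = FALSE)
  kp_names <- dimnames(fkr$keypoints)[[2]]
  ord <- match(keypoint_canon(), kp_names)
  if (anyNA(ord)) stop("model does not carry the full 20-keypoint canon")
  kp <- fkr$keypoints[, ord, , drop = FALSE]
  nf <- dim(kp)[1]
  offsets <- config$offsets
  if (is.null(offsets)) {
    offsets <- c(0L, sample(seq(-config$max_offset, config$max_offset),
                            length(cameras) - 1, replace = TRUE))
  }
  offsets <- as.integer(offsets)
  cmax <- max(offsets); cmin <- min(offsets)
  len <- nf - (cmax - cmin)
  if (len < 10) stop("trajectory too short for the configured offsets")
  dt <- 1 / config$frame_rate
  series <- vector("list", length(cameras))
  phi <- config$noise_ar %||% 0
  for (ci in seq_along(cameras)) {
    eps <- array(stats::rnorm(length(kp), 0, config$noise_sd / sqrt(3)),
                 dim = dim(kp))
    if (phi > 0) {
      # AR(1) over frames with the same marginal SD
      for (f in 2:nf) {
        eps[f, , ] <- phi * eps[f - 1, , ] +
          sqrt(1 - phi^2) * eps[f, , ]
      }
    }
    noisy <- kp + eps
    start <- cmax - offsets[ci]
    idx <- seq_len(len) + start
    pos2 <- array(NA_real_, dim = c(len, 20, 2))
    conf <- matrix(
      pmin(pmax(stats::rnorm(len * 20, config$confidence_base,
                             config$confidence_sd), 0.05), 1), len, 20)
    drop <- matrix(stats::runif(len * 20) < config$dropout_rate, len, 20)
    conf[drop] <- stats::runif(sum(drop), 0, 0.15)
    n_occ <- stats::rpois(1, config$occlusion_rate * len * dt / 10)
    if (n_occ > 0) {
      for (o in seq_len(n_occ)) {
        k <- sample(20, 1)
        f0 <- sample(len, 1)
        f1 <- min(len, f0 + max(1, stats::rpois(
          1, config$occlusion_duration * config$frame_rate)))
        conf[f0:f1, k] <- stats::runif(f1 - f0 + 1, 0, 0.03)
      }
    }
    for (f in seq_len(len)) {
      pr <- project_points(noisy[idx[f], , ], cameras[[ci]]$intrinsics,
                           cameras[[ci]]$extrinsics)
      pos2[f, , ] <- pr$pixels
    }
    series[[ci]] <- keypoint_series_2d(
      paste0("cam", ci), (seq_len(len) - 1) * dt, pos2, conf,
      keypoint_canon())
  }
  # truth on the first camera's timeline (synchronize aligns to series 1)
  truth_idx <- seq_len(len) + (cmax - offsets[1])
  list(series = series,
       truth_kp3d = keypoint_series_3d((seq_len(len) - 1) * dt,
                                       kp[truth_idx, , , drop = FALSE],
                                       keypoint_names = keypoint_canon()),
       truth_markers = marker_set((seq_len(len) - 1) * dt,
                                  fkr$markers[truth_idx, , , drop = FALSE],
                                  dimnames(fkr$markers)[[2]]),
       offsets = offsets)
}

#' Scale a fixture model to a synthetic subject
#'
#' Applies a uniform anthropometric factor `height / 1.75` with small seeded
#' per-segment jitter and rescales masses to the subject's total mass.
#'
#' @param base Base `skeletal_model`.
#' @param height,mass Subject anthropometry (m, kg).
#' @param seed RNG seed for the per-segment jitter.
#' @param jitter_sd SD of the per-segment length jitter.
#' @return A scaled `skeletal_model` with `$subject` metadata.
#' @export
subject_model <- function(base, height, mass, seed = 1, jitter_sd = 0.02) {
  set.seed(seed)
  f <- height / 1.75
  seg_names <- vapply(base$segments, `[[`, character(1), "name")
  factors <- stats::setNames(
    f * (1 + jitter_sd * stats::rnorm(length(seg_names))), seg_names)
  apply_scale_factors(base, factors, mass, height)
}

apply_scale_factors <- function(model, factors, mass, height = NULL) {
  default_masses <- vapply(model$segments, `[[`, numeric(1), "mass")
  new_masses <- default_masses / sum(default_masses) * mass
  segs <- lapply(seq_along(model$segments), function(i) {
    s <- model$segments[[i]]
    fct <- factors[s$name]
    fp <- if (s$parent == "ground") 1 else factors[s$parent]
    s$joint$location_in_parent <- s$joint$location_in_parent * fp
    s$joint$location_in_child <- s$joint$location_in_child * fct
    s$com <- s$com * fct
    s$inertia <- s$inertia * (new_masses[i] / s$mass) * fct^2
    s$mass <- new_masses[i]
    s$markers <- lapply(s$markers, function(p) p * fct)
    s$keypoints <- lapply(s$keypoints, function(p) p * fct)
    s
  })
  mus <- lapply(model$muscles, function(m) {
    m$path <- lapply(m$path, function(p) {
      p$location <- p$location * factors[p$segment]
      p
    })
    fbar <- mean(factors[vapply(m$path, `[[`, character(1), "segment")])
    m$l_opt <- m$l_opt * fbar
    m$l_slack <- m$l_slack * fbar
    m
  })
  cs <- lapply(model$contact_spheres, function(s) {
    s$location <- s$location * factors[s$segment]
    s
  })
  out <- skeletal_model(segs, muscles = mus,
                        torque_motors = model$torque_motors,
                        contact_spheres = cs, gravity = model$gravity,
                        name = model$name)
  out$subject <- list(height = height, mass = mass)
  out
}

#' Generate a paired keypoint/marker training corpus
#'
#' Per synthetic subject, a scaled full-body fixture model performs the
#' requested tasks; aligned ground-truth 3D keypoints and anatomical markers
#' are collected with subject-level ~80/10/10 train/validation/test split
#' labels. This is the stand-in for a laboratory motion-capture corpus used
#' to train the marker augmenter.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param tasks Character vector of [generate_motion()] tasks.
#' @param config A [rig_config()] (frame rate is used).
#' @param seed RNG seed.
#' @return List with `trials` (list of `list(kp3d, markers, height, mass,
#'   subject, task)`) and `subjects` (tibble with split labels).
#' @export
generate_augmenter_corpus <- function(n_subjects = 50,
                                      tasks = c("squat", "walk",
                                                "sit_to_stand",
                                                "squat_asym"),
                                      config = rig_config(), seed = 1) {
  set.seed(seed)
  heights <- stats::runif(n_subjects, 1.50, 1.95)
  masses <- stats::runif(n_subjects, 50, 100)
  n_test <- max(1, round(0.1 * n_subjects))
  n_val <- max(1, round(0.1 * n_subjects))
  split <- rep("train", n_subjects)
  split[sample(n_subjects, n_val + n_test)] <- "val"
  split[sample(which(split == "val"), n_test)] <- "test"
  base <- demo_model("demo3d")
  trials <- list()
  for (i in seq_len(n_subjects)) {
    mod <- subject_model(base, heights[i], masses[i], seed = seed + i)
    for (task in tasks) {
      par <- list(frame_rate = config$frame_rate)
      gen_task <- task
      if (task == "squat_asym") {
        # staggered / unweighted-left squats keep asymmetric poses inside
        # the augmenter's training distribution
        gen_task <- "squat"
        par$asymmetry <- stats::runif(1, 0.15, 0.5)
      }
      traj <- generate_motion(gen_task, mod, params = par,
                              seed = seed * 1000 + i * 10 + match(task, tasks))
      fkr <- forward_kinematics(mod, traj$q, check_bounds = FALSE)
      ord <- match(keypoint_canon(), dimnames(fkr$keypoints)[[2]])
      trials[[length(trials) + 1]] <- list(
        kp3d = keypoint_series_3d(traj$times,
                                  fkr$keypoints[, ord, , drop = FALSE],
                                  keypoint_names = keypoint_canon()),
        markers = marker_set(traj$times, fkr$markers,
                             dimnames(fkr$markers)[[2]]),
        height = heights[i], mass = masses[i], subject = i, task = task,
        split = split[i])
    }
  }
  list(trials = trials,
       subjects = tibble::tibble(subject = seq_len(n_subjects),
                                 height = heights, mass = masses,
                                 split = split))
}

#' Generate a paired-condition study cohort with a known imposed effect
#'
#' Builds per-subject scaled fixture models and paired-condition squat (or
#' sit-to-stand / walking) trials in which the "modified" condition carries
#' a configurable imposed asymmetry (extra left-knee flexion unloading the
#' left leg). Ground-truth labels and imposed magnitudes are recorded so the
#' downstream analysis battery can be validated against a known effect.
#'
#' @param study `"squat_symmetry"`, `"sit_to_stand"`, or `"knee_loading"`.
#' @param n Subjects.
#' @param effect Imposed effect size (extra left-knee-flexion fraction in
#'   the modified condition; 0 = null).
#' @param seed RNG seed.
#' @return List with `subjects` (tibble), `trials` (tibble: subject,
#'   condition, height, mass, trial seed), and the `effect` used.
#' @export
generate_cohort <- function(study = "squat_symmetry", n = 20, effect = 0.4,
                            seed = 1) {
  set.seed(seed)
  heights <- stats::runif(n, 1.55, 1.92)
  masses <- stats::runif(n, 52, 98)
  trials <- tidyr::expand_grid(subject = seq_len(n),
                               condition = c("natural", "modified"))
  trials$height <- heights[trials$subject]
  trials$mass <- masses[trials$subject]
  trials$asymmetry <- ifelse(trials$condition == "modified", effect, 0)
  trials$trial_seed <- seed * 10000 + seq_len(nrow(trials))
  list(study = study,
       subjects = tibble::tibble(subject = seq_len(n), height = heights,
                                 mass = masses),
       trials = trials, effect = effect, seed = seed)
}
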