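#' Interpolate invalid 3D keypoint samples
#'
#' Short runs of invalid (occluded in too many views) 3D keypoint samples
#' are bridged by cubic-spline interpolation of the valid samples; longer
#' runs stay invalid.
#'
#' @param kp3d A [keypoint_series_3d()].
#' @param max_gap Longest gap to bridge (s).
#' @return A [keypoint_series_3d()].
#' @export
fill_gaps_3d <- function(kp3d, max_gap = 0.5) {
  dt <- median(diff(kp3d$times))
  nf <- length(kp3d$times)
  pos <- kp3d$positions
  valid <- kp3d$validity
  for (k in seq_along(kp3d$keypoint_names)) {
    bad <- !valid[, k]
    if (!any(bad) || sum(!bad) < 4) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    good <- which(!bad)
    for (j in which(r$values)) {
      if ((ends[j] - starts[j] + 1) * dt > max_gap) next
      idx <- starts[j]:ends[j]
      if (starts[j] == 1 || ends[j] == nf) {
        # leading/trailing gap: hold the nearest valid sample
        src_f <- if (starts[j] == 1) min(good) else max(good)
        for (d in 1:3) pos[idx, k, d] <- kp3d$positions[src_f, k, d]
        valid[idx, k] <- TRUE
        next
      }
      for (d in 1:3) {
        pos[idx, k, d] <- stats::spline(kp3d$times[good],
                                        kp3d$positions[good, k, d],
                                        xout = kp3d$times[idx],
                                        method = "fmm")$y
      }
      valid[idx, k] <- TRUE
    }
  }
  keypoint_series_3d(kp3d$times, pos, valid, kp3d$keypoint_names)
}

#' Multi-camera 2D keypoints to 3D keypoints
#'
#' The standard early pipeline: per-camera occlusion gap-filling,
#' cross-correlation synchronization, and confidence-weighted DLT
#' triangulation, followed by short-gap interpolation of the 3D result.
#'
#' @param series_list List of [keypoint_series_2d()].
#' @param cameras Matching list of [camera()] objects.
#' @param max_lag Synchronization search range (frames).
#' @param min_confidence Triangulation confidence gate.
#' @param max_gap Occlusion gap limit (s).
#' @return List with `kp3d` ([keypoint_series_3d()]) and `lags`.
#' @export
reconstruct_keypoints <- function(series_list, cameras, max_lag = 240,
                                  min_confidence = 0.3, max_gap = 0.5) {
  filled <- lapply(series_list, fill_gaps, max_gap = max_gap)
  n_min <- min(vapply(filled, function(s) length(s$times), integer(1)))
  sync <- synchronize(filled, max_lag = min(max_lag, n_min %/% 2 - 1))
  kp3d <- triangulate(sync$series, cameras, min_confidence = min_confidence)
  # the 3D pass bridges what per-camera filling could not (a keypoint can
  # drop below two confident views for longer than a single-camera gap)
  list(kp3d = fill_gaps_3d(kp3d, max_gap = max(max_gap, 1)),
       lags = sync$lags)
}

#' Run the full squat-symmetry study chain on a synthetic cohort
#'
#' For every trial of a [generate_cohort()] bundle: generate the
#' ground-truth squat on the subject's full-body model, render two-camera
#' keypoint observations, reconstruct 3D keypoints
#' ([reconstruct_keypoints()]), predict the 43 anatomical markers
#' ([augment_markers()]), solve inverse kinematics, map the sagittal
#' coordinates onto the subject's sagittal dynamics model, run the
#' muscle-driven tracking simulation, and extract the peak vasti activation
#' of each leg and their symmetry index (left = involved).
#'
#' @param cohort A [generate_cohort()] bundle.
#' @param augmenter A [train_augmenter()] model.
#' @param config A [rig_config()]; camera offsets are drawn per trial.
#' @param duration Squat duration (s).
#' @param pad Quiet-standing lead-in/out (s).
#' @param mesh_per_second Tracking-simulation mesh density.
#' @param max_outer Penalty-ladder stages allotted to each tracking solve.
#' @param filter_cutoff Low-pass cutoff for the IK coordinates (Hz).
#' @param use_cameras `FALSE` skips rendering/triangulation and feeds
#'   ground-truth 3D keypoints to the augmenter (faster variant for
#'   statistics-only studies).
#' @param progress Print one line per trial.
#' @return Tibble: subject, condition, peak left/right vasti activation,
#'   symmetry index, solver status.
#' @export
run_squat_symmetry_study <- function(cohort, augmenter,
                                     config = rig_config(max_offset = 10),
                                     duration = 1.0, pad = 0.3,
                                     mesh_per_second = 12,
                                     filter_cutoff = 4, max_outer = 4,
                                     use_cameras = TRUE, progress = FALSE) {
  base3 <- demo_model("demo3d")
  base2 <- demo_model("demo2d")
  cameras <- make_default_rig(config)
  out <- vector("list", nrow(cohort$trials))
  surr_cache <- list()
  for (i in seq_len(nrow(cohort$trials))) {
    tr <- cohort$trials[i, ]
    m3 <- subject_model(base3, tr$height, tr$mass,
                        seed = cohort$seed + tr$subject, jitter_sd = 0)
    m2 <- subject_model(base2, tr$height, tr$mass,
                        seed = cohort$seed + tr$subject, jitter_sd = 0)
    key <- as.character(tr$subject)
    if (is.null(surr_cache[[key]])) {
      surr_cache[[key]] <- fit_muscle_polynomials(m2, seed = cohort$seed)
    }
    traj3 <- generate_motion("squat", m3,
                             params = list(duration = duration, pad = pad,
                                           asymmetry = tr$asymmetry),
                             seed = tr$trial_seed)
    if (use_cameras) {
      obs <- render_observations(m3, traj3, cameras, config,
                                 seed = tr$trial_seed)
      rec <- reconstruct_keypoints(obs$series, cameras,
                                   max_lag = config$max_offset + 10)
      kp3d <- rec$kp3d
    } else {
      fkr <- forward_kinematics(m3, traj3$q, check_bounds = FALSE)
      ord <- match(keypoint_canon(), dimnames(fkr$keypoints)[[2]])
      noisy <- fkr$keypoints[, ord, , drop = FALSE]
      set.seed(tr$trial_seed)
      noisy <- noisy + array(stats::rnorm(length(noisy), 0,
                                          config$noise_sd / sqrt(3)),
                             dim = dim(noisy))
      kp3d <- keypoint_series_3d(traj3$times, noisy,
                                 keypoint_names = keypoint_canon())
    }
    markers <- augment_markers(kp3d, tr$height, tr$mass, augmenter)
    # IK at 20 Hz is ample for squat content (< 3 Hz); cuts the cost
    sub <- seq(1, length(markers$times), by = 3)
    markers30 <- marker_set(markers$times[sub],
                            markers$positions[sub, , , drop = FALSE],
                            markers$marker_names)
    ik <- inverse_kinematics(m3, markers30, max_iter = 10, tol = 1e-6)
    qtraj <- lowpass_filter(ik$trajectory, filter_cutoff)
    ref <- map_to_sagittal(m2, qtraj)
    span <- range(ref$times)
    sol <- solve_tracking(m2, differentiate(ref),
                          weights = tracking_weights(t0 = span[1] + 0.25,
                                                     tf = span[2] - 0.2),
                          settings = list(
                            surrogate = surr_cache[[key]],
                            mesh_per_second = mesh_per_second,
                            mu_max = 1e7, max_outer = max_outer,
                            max_inner = 12))
    # peak activation during the squat itself: frames where the reference
    # (right) knee is beyond 30% of its maximal flexion, excluding the
    # stand-still and touchdown transients at the trial edges
    kq <- sol$trajectory$q[, "knee_angle_r"]
    phase <- which(kq < 0.3 * min(kq))
    if (length(phase) < 3) phase <- seq_along(kq)
    peak_r <- max(sol$activations[phase, "vasti_r"])
    peak_l <- max(sol$activations[phase, "vasti_l"])
    mom_r <- max(sol$joint_moments[phase, "knee_angle_r"])
    mom_l <- max(sol$joint_moments[phase, "knee_angle_l"])
    mom_r <- max(mom_r, 1e-6)
    out[[i]] <- tibble::tibble(
      subject = tr$subject, condition = tr$condition,
      peak_vasti_left = peak_l, peak_vasti_right = peak_r,
      symmetry_index = symmetry_index(peak_l, peak_r),
      peak_knee_moment_left = mom_l, peak_knee_moment_right = mom_r,
      moment_symmetry_index = symmetry_index(mom_l, mom_r),
      solver_status = sol$status, constraint_max = sol$constraint_max)
    if (progress) {
      message(sprintf("trial %d/%d: subject %d %s SI = %.2f (%s)",
                      i, nrow(cohort$trials), tr$subject, tr$condition,
                      out[[i]]$moment_symmetry_index, sol$status))
    }
  }
  dplyr::bind_rows(out)
}

#' Map a full-body coordinate trajectory onto the sagittal dynamics model
#'
#' Copies the coordinates shared by name (pelvis tx/ty/tilt, hip flexion,
#' knee, ankle of both legs) and re-anchors the pelvis height so the model
#' starts at its standing contact equilibrium (absorbing augmenter / IK
#' bias in absolute height).
#'
#' @param model Target sagittal `skeletal_model`.
#' @param traj Source [coordinate_trajectory()] (full-body coordinate
#'   names).
#' @return A [coordinate_trajectory()] over the target model's coordinates.
#' @export
map_to_sagittal <- function(model, traj, ground_correction = TRUE) {
  qn <- model$coordinates$name
  Q <- matrix(0, length(traj$times), length(qn),
              dimnames = list(NULL, qn))
  shared <- intersect(qn, colnames(traj$q))
  Q[, shared] <- traj$q[, shared]
  q0 <- standing_pose(model)
  if ("pelvis_ty" %in% qn) {
    Q[, "pelvis_ty"] <- Q[, "pelvis_ty"] +
      (q0["pelvis_ty"] - Q[1, "pelvis_ty"])
  }
  if ("ankle_angle_r" %in% qn) {
    for (s in c("ankle_angle_r", "ankle_angle_l")) {
      Q[, s] <- Q[, s] + (q0[s] - Q[1, s])
    }
  }
  out <- clamp_bounds(model, coordinate_trajectory(traj$times, Q))
  if (ground_correction) out <- ground_feet(model, out)
  out
}

#' Foot-ground contact correction for estimated kinematics
#'
#' Millimeter-level marker and inverse-kinematics errors are enough to shift
#' the statically indeterminate left/right load split of a double-stance
#' pose, because compliant-contact penetrations are only a few millimeters.
#' This standard cleanup step detects frames where a foot is near the ground
#' and adjusts that leg's knee and ankle angles (a correction within the
#' kinematic error band) so the foot's contact spheres sit at their standing
#' equilibrium heights; clearly airborne feet are left untouched, and the
#' correction is blended smoothly in between.
#'
#' @param model Contact-bearing `skeletal_model`.
#' @param traj A [coordinate_trajectory()].
#' @param threshold Foot height (m) below which a foot counts as grounded.
#' @param blend Height band (m) over which the correction fades out.
#' @return The corrected [coordinate_trajectory()].
#' @export
ground_feet <- function(model, traj, threshold = 0.015, blend = 0.015) {
  q0 <- standing_pose(model)
  spheres <- model$contact_spheres
  if (!length(spheres)) return(traj)
  sph_seg <- vapply(spheres, `[[`, character(1), "segment")
  heights <- function(Q, side) {
    fk <- fk_states(model, Q)
    ix <- which(sph_seg == paste0("calcn_", side))
    h <- lapply(ix, function(i) {
      st <- fk$states[[spheres[[i]]$segment]]
      (st$o + rot_apply(st$R, spheres[[i]]$location))[, 2] -
        spheres[[i]]$radius
    })
    matrix(unlist(h), nrow = nrow(Q))
  }
  Q0 <- matrix(q0, 1, dimnames = list(NULL, names(q0)))
  Q <- traj$q
  for (side in c("r", "l")) {
    kc <- paste0("knee_angle_", side)
    ac <- paste0("ankle_angle_", side)
    if (!all(c(kc, ac) %in% colnames(Q))) next
    target <- heights(Q0, side)[1, ]
    Qc <- Q
    for (it in 1:6) {
      H <- heights(Qc, side)
      resid <- sweep(H, 2, target)
      if (max(abs(resid)) < 1e-6) break
      hk <- 1e-6
      Qk <- Qc; Qk[, kc] <- Qk[, kc] + hk
      Jk <- (heights(Qk, side) - H) / hk
      Qa <- Qc; Qa[, ac] <- Qa[, ac] + hk
      Ja <- (heights(Qa, side) - H) / hk
      for (f in seq_len(nrow(Q))) {
        J <- cbind(Jk[f, ], Ja[f, ])
        step <- tryCatch(solve(J, -resid[f, ]), error = function(e) c(0, 0))
        step <- pmin(pmax(step, -0.05), 0.05)
        Qc[f, kc] <- Qc[f, kc] + step[1]
        Qc[f, ac] <- Qc[f, ac] + step[2]
      }
    }
    # blend: full correction when the (uncorrected) foot is at or below the
    # grounded band, none when clearly airborne
    minh <- apply(heights(Q, side), 1, min)
    lam <- pmin(pmax((threshold + blend - minh) / blend, 0), 1)
    Q[, kc] <- Q[, kc] + lam * (Qc[, kc] - Q[, kc])
    Q[, ac] <- Q[, ac] + lam * (Qc[, ac] - Q[, ac])
  }
  clamp_bounds(model, coordinate_trajectory(traj$times, Q))
}
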