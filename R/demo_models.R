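#' Built-in fixture models
#'
#' Two reduced articulated models ship with the package so that every stage
#' of the pipeline is testable at desk scale. `demo3d` is a 21-DOF
#' full-body-lite kinematic model (pelvis 6, lumbar 3, hips 2x3, knees 2x1,
#' ankles 2x2) carrying the full 20-keypoint and 43-marker attachment sets
#' (arms are rigid on the torso). `demo2d` is a sagittal-plane 9-DOF
#' dynamics fixture (pelvis tx/ty/tilt, hips, knees, ankles) with 8 Hill-type
#' muscles, 6 reserve torque motors, and 2 contact spheres per foot. The
#' model file format (see [load_model()]) admits richer definitions,
#' including full-complement gait models.
#'
#' @param which `"demo2d"` or `"demo3d"`.
#' @return A `skeletal_model`.
#' @export
demo_model <- function(which = c("demo2d", "demo3d")) {
  which <- match.arg(which)
  if (which == "demo3d") demo3d_model() else demo2d_model()
}

seg_def <- function(name, parent, loc, dofs, mass, com, inertia,
                    markers = list(), keypoints = list(), scale_pair = NULL) {
  list(name = name, parent = parent,
       joint = list(location_in_parent = loc, location_in_child = c(0, 0, 0),
                    dofs = dofs),
       mass = mass, com = com, inertia = inertia,
       markers = markers, keypoints = keypoints, scale_pair = scale_pair)
}

rot_dof <- function(coordinate, axis, bounds) {
  list(coordinate = coordinate, type = "rotation", axis = axis, bounds = bounds)
}
tra_dof <- function(coordinate, axis, bounds) {
  list(coordinate = coordinate, type = "translation", axis = axis,
       bounds = bounds)
}

demo3d_model <- function() {
  hipw <- 0.09       # hip half-width (m)
  thigh <- 0.41      # hip-to-knee
  shank <- 0.43      # knee-to-ankle
  segs <- list(
    seg_def("pelvis", "ground", c(0, 0, 0),
            list(tra_dof("pelvis_tx", c(1, 0, 0), c(-10, 10)),
                 tra_dof("pelvis_ty", c(0, 1, 0), c(-3, 3)),
                 tra_dof("pelvis_tz", c(0, 0, 1), c(-10, 10)),
                 rot_dof("pelvis_tilt", c(0, 0, 1), c(-1.6, 1.6)),
                 rot_dof("pelvis_list", c(1, 0, 0), c(-1.6, 1.6)),
                 rot_dof("pelvis_rotation", c(0, 1, 0), c(-3.2, 3.2))),
            mass = 11.8, com = c(-0.05, 0, 0), inertia = c(0.10, 0.09, 0.06),
            markers = list(r_ASIS = c(0.07, 0.02, 0.12),
                           l_ASIS = c(0.07, 0.02, -0.12),
                           r_PSIS = c(-0.14, 0.03, 0.05),
                           l_PSIS = c(-0.14, 0.03, -0.05)),
            keypoints = list(mid_hip = c(0, 0, 0),
                             r_hip = c(0, 0, hipw),
                             l_hip = c(0, 0, -hipw)),
            scale_pair = c("r_ASIS", "l_ASIS")),
    seg_def("torso", "pelvis", c(-0.03, 0.08, 0),
            list(rot_dof("lumbar_extension", c(0, 0, 1), c(-1.6, 1.6)),
                 rot_dof("lumbar_bending", c(1, 0, 0), c(-1.6, 1.6)),
                 rot_dof("lumbar_rotation", c(0, 1, 0), c(-1.6, 1.6))),
            mass = 34.2, com = c(-0.03, 0.30, 0), inertia = c(1.47, 0.76, 1.43),
            markers = list(C7 = c(-0.05, 0.44, 0),
                           r_shoulder_mk = c(0, 0.42, 0.17),
                           l_shoulder_mk = c(0, 0.42, -0.17),
                           r_sh_cluster = c(-0.03, 0.35, 0.12),
                           l_sh_cluster = c(-0.03, 0.35, -0.12),
                           r_elbow_lat = c(0.02, 0.13, 0.22),
                           r_elbow_med = c(0.02, 0.13, 0.16),
                           l_elbow_lat = c(0.02, 0.13, -0.22),
                           l_elbow_med = c(0.02, 0.13, -0.16),
                           r_wrist_rad = c(0.24, 0.12, 0.21),
                           r_wrist_uln = c(0.24, 0.12, 0.17),
                           l_wrist_rad = c(0.24, 0.12, -0.21),
                           l_wrist_uln = c(0.24, 0.12, -0.17)),
            keypoints = list(neck = c(-0.03, 0.40, 0),
                             r_shoulder = c(0, 0.40, 0.19),
                             l_shoulder = c(0, 0.40, -0.19),
                             r_elbow = c(0.02, 0.13, 0.19),
                             l_elbow = c(0.02, 0.13, -0.19),
                             r_wrist = c(0.24, 0.12, 0.19),
                             l_wrist = c(0.24, 0.12, -0.19)),
            scale_pair = c("r_shoulder_mk", "l_shoulder_mk")),
    leg3d("r", hipw, thigh, shank, 1),
    leg3d_tibia("r", thigh, shank, 1),
    leg3d_foot("r", shank, 1),
    leg3d("l", hipw, thigh, shank, -1),
    leg3d_tibia("l", thigh, shank, -1),
    leg3d_foot("l", shank, -1)
  )
  skeletal_model(segs, name = "demo3d")
}

leg3d <- function(side, hipw, thigh, shank, sgn) {
  seg_def(paste0("femur_", side), "pelvis", c(0, 0, sgn * hipw),
          list(rot_dof(paste0("hip_flexion_", side), c(0, 0, 1), c(-0.9, 2.2)),
               rot_dof(paste0("hip_adduction_", side), c(1, 0, 0), c(-1.0, 1.0)),
               rot_dof(paste0("hip_rotation_", side), c(0, 1, 0), c(-1.0, 1.0))),
          mass = 9.3, com = c(0, -0.17, 0), inertia = c(0.13, 0.03, 0.14),
          markers = stats::setNames(
            list(c(0, -thigh, sgn * 0.055), c(0, -thigh, -sgn * 0.045),
                 c(0.02, -0.15, sgn * 0.07), c(0.03, -0.25, sgn * 0.06),
                 c(-0.02, -0.21, sgn * 0.07)),
            paste0(side, c("_knee_lat", "_knee_med", "_thigh1", "_thigh2",
                           "_thigh3"))),
          keypoints = stats::setNames(list(c(0, -thigh, 0)),
                                      paste0(side, "_knee")),
          scale_pair = paste0(side, c("_thigh2", "_knee_lat")))
}

leg3d_tibia <- function(side, thigh, shank, sgn) {
  seg_def(paste0("tibia_", side), paste0("femur_", side), c(0, -thigh, 0),
          list(rot_dof(paste0("knee_angle_", side), c(0, 0, 1), c(-2.2, 0.35))),
          mass = 3.7, com = c(0, -0.19, 0), inertia = c(0.05, 0.005, 0.05),
          markers = stats::setNames(
            list(c(0, -shank, sgn * 0.045), c(0, -shank, -sgn * 0.035),
                 c(0.01, -0.15, sgn * 0.05), c(0.005, -0.25, sgn * 0.055),
                 c(-0.01, -0.33, sgn * 0.05)),
            paste0(side, c("_ankle_lat", "_ankle_med", "_shank1", "_shank2",
                           "_shank3"))),
          keypoints = stats::setNames(list(c(0, -shank, 0)),
                                      paste0(side, "_ankle")),
          scale_pair = paste0(side, c("_shank1", "_ankle_lat")))
}

leg3d_foot <- function(side, shank, sgn) {
  seg_def(paste0("calcn_", side), paste0("tibia_", side), c(0, -shank, 0),
          list(rot_dof(paste0("ankle_angle_", side), c(0, 0, 1), c(-1.0, 0.9)),
               rot_dof(paste0("subtalar_angle_", side), c(1, 0, 0),
                       c(-0.6, 0.6))),
          mass = 1.25, com = c(0.07, -0.03, 0), inertia = c(1e-3, 4e-3, 4e-3),
          markers = stats::setNames(
            list(c(-0.04, -0.03, 0), c(0.19, -0.04, sgn * 0.01),
                 c(0.15, -0.04, sgn * 0.05)),
            paste0(side, c("_calc", "_toe_mk", "_5meta"))),
          keypoints = stats::setNames(
            list(c(-0.04, -0.04, 0), c(0.19, -0.05, -sgn * 0.02),
                 c(0.16, -0.05, sgn * 0.05)),
            paste0(side, c("_heel", "_big_toe", "_small_toe"))),
          scale_pair = paste0(side, c("_calc", "_toe_mk")))
}

demo2d_model <- function() {
  thigh <- 0.41
  shank <- 0.43
  leg <- function(side) {
    list(
      seg_def(paste0("femur_", side), "pelvis", c(0, -0.02, 0),
              list(rot_dof(paste0("hip_flexion_", side), c(0, 0, 1),
                           c(-0.9, 2.2))),
              mass = 9.3, com = c(0, -0.17, 0), inertia = c(0.13, 0.03, 0.14),
              markers = stats::setNames(
                list(c(0, -thigh, 0.05), c(0.03, -0.2, 0.06)),
                paste0(side, c("_knee_lat", "_thigh1"))),
              keypoints = stats::setNames(list(c(0, -thigh, 0)),
                                          paste0(side, "_knee")),
              scale_pair = paste0(side, c("_thigh1", "_knee_lat"))),
      seg_def(paste0("tibia_", side), paste0("femur_", side), c(0, -thigh, 0),
              list(rot_dof(paste0("knee_angle_", side), c(0, 0, 1),
                           c(-2.2, 0.35))),
              mass = 3.7, com = c(0, -0.19, 0), inertia = c(0.05, 0.005, 0.05),
              markers = stats::setNames(
                list(c(0, -shank, 0.04), c(0.01, -0.2, 0.05)),
                paste0(side, c("_ankle_lat", "_shank1"))),
              keypoints = stats::setNames(list(c(0, -shank, 0)),
                                          paste0(side, "_ankle")),
              scale_pair = paste0(side, c("_shank1", "_ankle_lat"))),
      seg_def(paste0("calcn_", side), paste0("tibia_", side), c(0, -shank, 0),
              list(rot_dof(paste0("ankle_angle_", side), c(0, 0, 1),
                           c(-1.0, 0.9))),
              mass = 1.25, com = c(0.07, -0.03, 0),
              inertia = c(1e-3, 4e-3, 4e-3),
              markers = stats::setNames(
                list(c(-0.04, -0.03, 0), c(0.19, -0.04, 0.01)),
                paste0(side, c("_calc", "_toe_mk"))),
              keypoints = stats::setNames(
                list(c(-0.04, -0.04, 0), c(0.19, -0.05, 0)),
                paste0(side, c("_heel", "_big_toe"))))
    )
  }
  segs <- c(
    list(seg_def("pelvis", "ground", c(0, 0, 0),
                 list(tra_dof("pelvis_tx", c(1, 0, 0), c(-10, 10)),
                      tra_dof("pelvis_ty", c(0, 1, 0), c(-3, 3)),
                      rot_dof("pelvis_tilt", c(0, 0, 1), c(-1.6, 1.6))),
                 mass = 11.8 + 34.2, com = c(-0.05, 0.25, 0),
                 inertia = c(1.5, 0.9, 1.5),
                 markers = list(r_ASIS = c(0.07, 0.02, 0.12),
                                l_ASIS = c(0.07, 0.02, -0.12),
                                C7 = c(-0.08, 0.52, 0)),
                 keypoints = list(mid_hip = c(0, -0.02, 0),
                                  neck = c(-0.06, 0.48, 0)),
                 scale_pair = c("r_ASIS", "l_ASIS"))),
    leg("r"), leg("l")
  )
  muscles <- c(leg_muscles("r"), leg_muscles("l"))
  motors <- list()
  for (side in c("r", "l")) {
    for (jj in c("hip_flexion", "knee_angle", "ankle_angle")) {
      motors[[length(motors) + 1]] <-
        list(name = paste0("reserve_", jj, "_", side),
             coordinate = paste0(jj, "_", side),
             max_torque = 90, time_constant = 0.035)
    }
  }
  spheres <- list()
  for (side in c("r", "l")) {
    for (sp in list(list(nm = "heel", loc = c(-0.035, -0.045, 0), r = 0.032),
                    list(nm = "toe", loc = c(0.17, -0.045, 0), r = 0.032))) {
      spheres[[length(spheres) + 1]] <-
        list(name = paste0(sp$nm, "_", side),
             segment = paste0("calcn_", side), location = sp$loc,
             radius = sp$r, stiffness = 2e5, dissipation = 2,
             friction_static = 0.8, friction_dynamic = 0.8,
             smoothing = 1e-4)
    }
  }
  m <- skeletal_model(segs, muscles = muscles, torque_motors = motors,
                      contact_spheres = spheres, name = "demo2d")
  # tendon slack lengths chosen so each fiber sits at optimal length in a
  # mid-task posture (half squat), where force demands peak
  q0 <- stats::setNames(rep(0, m$n_coordinates), m$coordinates$name)
  q0[grep("^hip_flexion", names(q0))] <- 0.5
  q0[grep("^knee_angle", names(q0))] <- -0.8
  q0[grep("^ankle_angle", names(q0))] <- 0.15
  L0 <- muscle_tendon_lengths(m, q0)[1, ]
  for (i in seq_along(m$muscles)) {
    m$muscles[[i]]$l_slack <- L0[i] - m$muscles[[i]]$l_opt
  }
  m
}

leg_muscles <- function(side) {
  femur <- paste0("femur_", side)
  tibia <- paste0("tibia_", side)
  calcn <- paste0("calcn_", side)
  mt <- function(name, f_max, l_opt, l_slack, path) {
    list(name = paste0(name, "_", side), f_max = f_max, l_opt = l_opt,
         l_slack = l_slack, pennation = 0, v_max = 10,
         tau_act = 0.015, tau_deact = 0.06, path = path)
  }
  pp <- function(segment, location) list(segment = segment,
                                         location = location)
  list(
    # uniarticular hip flexor (iliopsoas-like)
    mt("hip_flexor", 2400, 0.11, 0.13,
       list(pp("pelvis", c(0.05, 0.02, 0)), pp(femur, c(0.04, -0.10, 0)))),
    # uniarticular hip extensor (gluteal)
    mt("hip_extensor", 3000, 0.16, 0.12,
       list(pp("pelvis", c(-0.09, 0.02, 0)), pp(femur, c(-0.04, -0.12, 0)))),
    # vasti: knee extensor with a patellar via point on the femur
    mt("vasti", 9000, 0.14, 0.16,
       list(pp(femur, c(0.03, -0.15, 0)), pp(femur, c(0.04, -0.42, 0)),
            pp(tibia, c(0.06, -0.06, 0)))),
    # soleus: uniarticular plantarflexor
    mt("soleus", 3600, 0.05, 0.25,
       list(pp(tibia, c(-0.02, -0.15, 0)), pp(calcn, c(-0.045, -0.02, 0))))
  )
}

#' Single-pendulum dynamics fixture
#'
#' A torque-driven planar pendulum (one rotational coordinate, one ideal
#' torque motor, no contact): the smallest model on which the tracking
#' simulation, its inverse-dynamics oracle, and mesh-refinement behavior can
#' be exercised.
#'
#' @param length Pendulum length (m).
#' @param mass Bob mass (kg).
#' @return A `skeletal_model`.
#' @export
pendulum_model <- function(length = 1, mass = 5) {
  seg <- seg_def("pelvis", "ground", c(0, 0, 0),
                 list(rot_dof("swing", c(0, 0, 1), c(-3.1, 3.1))),
                 mass = mass, com = c(0, -length, 0),
                 inertia = c(1e-3, 1e-3, mass * length^2 / 12),
                 markers = list(bob = c(0, -length, 0)))
  skeletal_model(list(seg),
                 torque_motors = list(list(name = "swing_motor",
                                           coordinate = "swing",
                                           max_torque = 200,
                                           time_constant = 0.02)),
                 name = "pendulum")
}
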