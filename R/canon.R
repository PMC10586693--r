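#' Keypoint and marker name canons
#'
#' The pipeline's early currency is a fixed set of 20 body keypoints (the
#' output vocabulary of whole-body pose detectors that include feet): neck,
#' mid-hip, and left/right shoulders, hips, knees, ankles, heels, small and
#' big toes, elbows, and wrists. Downstream, a richer set of 43 anatomical
#' markers (35 body + 8 arm) in the style of conventional full-body gait
#' marker sets is predicted by the marker augmenter.
#'
#' @return Character vector of canonical names.
#' @export
keypoint_canon <- function() {
  c("neck", "mid_hip",
    "r_shoulder", "l_shoulder",
    "r_hip", "l_hip",
    "r_knee", "l_knee",
    "r_ankle", "l_ankle",
    "r_heel", "l_heel",
    "r_small_toe", "l_small_toe",
    "r_big_toe", "l_big_toe",
    "r_elbow", "l_elbow",
    "r_wrist", "l_wrist")
}

#' @rdname keypoint_canon
#' @export
body_keypoints <- function() {
  # 15 lower-limb and torso keypoints feeding the body augmenter submodel
  c("mid_hip", "r_shoulder", "l_shoulder",
    "r_hip", "l_hip", "r_knee", "l_knee",
    "r_ankle", "l_ankle", "r_heel", "l_heel",
    "r_small_toe", "l_small_toe", "r_big_toe", "l_big_toe")
}

#' @rdname keypoint_canon
#' @export
arm_keypoints <- function() {
  # 7 arm and torso keypoints feeding the arm augmenter submodel
  c("neck", "r_shoulder", "l_shoulder",
    "r_elbow", "l_elbow", "r_wrist", "l_wrist")
}

#' @rdname keypoint_canon
#' @export
marker_canon <- function() c(body_markers(), arm_markers())

#' @rdname keypoint_canon
#' @export
body_markers <- function() {
  # 35 body markers: anatomical landmarks + tracking clusters of a
  # conventional full-body gait set (names configurable; count fixed).
  c("C7", "r_shoulder_mk", "l_shoulder_mk",
    "r_ASIS", "l_ASIS", "r_PSIS", "l_PSIS",
    "r_knee_lat", "r_knee_med", "l_knee_lat", "l_knee_med",
    "r_ankle_lat", "r_ankle_med", "l_ankle_lat", "l_ankle_med",
    "r_calc", "l_calc", "r_toe_mk", "l_toe_mk", "r_5meta", "l_5meta",
    "r_thigh1", "r_thigh2", "r_thigh3", "l_thigh1", "l_thigh2", "l_thigh3",
    "r_shank1", "r_shank2", "r_shank3", "l_shank1", "l_shank2", "l_shank3",
    "r_sh_cluster", "l_sh_cluster")
}

#' @rdname keypoint_canon
#' @export
arm_markers <- function() {
  c("r_elbow_lat", "r_elbow_med", "l_elbow_lat", "l_elbow_med",
    "r_wrist_rad", "r_wrist_uln", "l_wrist_rad", "l_wrist_uln")
}

#' Clinically relevant symmetry-index threshold
#'
#' A peak-activation (or peak-moment) symmetry index above this value is
#' associated with functional deficits after knee surgery and is used as the
#' ground-truth label threshold in the squat-symmetry classification study.
#'
#' @export
SYMMETRY_THRESHOLD <- 1.15

#' Standard gravitational acceleration (m/s^2) used for bodyweight
#' normalization.
#' @export
GRAVITY <- 9.81
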