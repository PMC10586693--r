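# Shared fixtures: built in code, deterministic under fixed seeds.

make_marker_fixture <- function(n_markers = 3, n_frames = 5, seed = 1) {
  set.seed(seed)
  pos <- array(round(rnorm(n_frames * n_markers * 3), 4),
               dim = c(n_frames, n_markers, 3))
  marker_set(times = (seq_len(n_frames) - 1) / 60, positions = pos,
             marker_names = paste0("M", seq_len(n_markers)))
}

make_kp2d_fixture <- function(n_frames = 120, seed = 1, camera_id = "camA",
                              frame_rate = 60) {
  set.seed(seed)
  t <- (seq_len(n_frames) - 1) / frame_rate
  pos <- array(0, dim = c(n_frames, 20, 2))
  for (k in 1:20) {
    pos[, k, 1] <- 360 + 40 * sin(2 * pi * (0.7 + 0.05 * k) * t + k)
    pos[, k, 2] <- 640 + 30 * cos(2 * pi * (0.9 + 0.03 * k) * t)
  }
  conf <- matrix(runif(n_frames * 20, 0.6, 1), n_frames, 20)
  keypoint_series_2d(camera_id, t, pos, conf, keypoint_canon())
}

make_camera_fixture <- function(angle_deg = 45) {
  make_default_rig(rig_config(angles = c(-angle_deg, angle_deg)))
}

expect_equal_tol <- function(a, b, tol) {
  testthat::expect_lt(max(abs(a - b)), tol)
}
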