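test_that("the default rig aims both cameras at the volume center and sees
          a 2-m cube", {
  config <- rig_config()
  cams <- make_default_rig(config)
  expect_length(cams, 2)
  for (cm in cams) {
    # the optical axis (camera z) passes within 1 cm of the target
    R <- rotvec_to_matrix(cm$extrinsics$rotation_vector)
    C <- -as.vector(t(R) %*% cm$extrinsics$translation)   # camera center
    zdir <- as.vector(t(R)[, 3])
    tvec <- config$target - C
    dist_to_axis <- sqrt(sum((tvec - sum(tvec * zdir) * zdir)^2))
    expect_lt(dist_to_axis, 0.01)
    expect_equal(C[2], config$height, tolerance = 1e-9)
    expect_equal(sqrt(sum((C - config$target)[c(1, 3)]^2)),
                 config$distance, tolerance = 1e-9)
    # a 2-m cube centered on the target projects fully inside the image
    corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1),
                                     z = c(-1, 1)))
    corners <- sweep(corners, 2, config$target, `+`)
    pr <- project_points(corners, cm$intrinsics, cm$extrinsics)
    expect_true(all(pr$valid))
    expect_true(all(pr$pixels[, 1] >= 0 &
                      pr$pixels[, 1] <= config$image_size[1]))
    expect_true(all(pr$pixels[, 2] >= 0 &
                      pr$pixels[, 2] <= config$image_size[2]))
  }
  five <- rig_config(n_cameras = 5)
  expect_equal(five$angles, c(-70, -45, 0, 45, 70))
  expect_length(make_default_rig(five), 5)
})

test_that("motion generation is deterministic, respects tasks, and keeps
          the squat pelvis dipping once", {
  m3 <- demo_model("demo3d")
  a <- generate_motion("squat", m3, seed = 5)
  b <- generate_motion("squat", m3, seed = 5)
  expect_identical(a$q, b$q)
  cc <- generate_motion("squat", m3, seed = 6)
  expect_false(identical(a$q, cc$q))
  # static task: constant coordinates
  st <- generate_motion("static", demo_model("demo2d"), seed = 1)
  expect_true(all(apply(st$q, 2, sd) == 0))
  # squat pelvis height dips once: the global minimum sits mid-trial and
  # both ends return to standing height
  ty <- a$q[, "pelvis_ty"]
  n <- length(ty)
  k <- which.min(ty)
  expect_gt(k, n / 3)
  expect_lt(k, 2 * n / 3)
  expect_equal(ty[1], ty[n], tolerance = 1e-6)
  expect_lt(ty[k], ty[1] - 0.05)
  expect_error(generate_motion("moonwalk", m3), "unknown task")
})

test_that("rendering echoes the configured occlusions and offsets", {
  m3 <- demo_model("demo3d")
  traj <- generate_motion("squat", m3, params = list(duration = 1.5),
                          seed = 9)
  config <- rig_config(offsets = c(0L, 17L), occlusion_rate = 0,
                       dropout_rate = 0, noise_sd = 0.005, seed = 10)
  cams <- make_default_rig(config)
  obs <- render_observations(m3, traj, cams, config, seed = 10)
  expect_identical(obs$offsets, c(0L, 17L))
  res <- synchronize(lapply(obs$series, fill_gaps), max_lag = 30)
  expect_identical(res$lags, c(0L, 17L))
  # forced occlusion interval drives confidence to ~0
  config2 <- rig_config(offsets = c(0L, 0L), occlusion_rate = 40, seed = 3)
  obs2 <- render_observations(m3, traj, cams, config2, seed = 3)
  expect_lt(min(obs2$series[[1]]$confidence), 0.05)
})

test_that("the augmenter corpus partitions subjects and reproduces under a
          seed", {
  corpus <- generate_augmenter_corpus(n_subjects = 8,
                                      tasks = "squat", seed = 13)
  expect_equal(nrow(corpus$subjects), 8)
  expect_setequal(unique(corpus$subjects$split),
                  c("train", "val", "test"))
  # no subject appears in two splits
  per_subject <- vapply(split(corpus$subjects$split,
                              corpus$subjects$subject),
                        function(s) length(unique(s)), integer(1))
  expect_true(all(per_subject == 1))
  expect_true(all(corpus$subjects$height >= 1.5 &
                    corpus$subjects$height <= 1.95))
  corpus2 <- generate_augmenter_corpus(n_subjects = 8,
                                       tasks = "squat", seed = 13)
  expect_identical(corpus$trials[[1]]$kp3d$positions,
                   corpus2$trials[[1]]$kp3d$positions)
})

test_that("cohorts pair the same subject across conditions and record the
          imposed effect", {
  ch <- generate_cohort("squat_symmetry", n = 5, effect = 0.4, seed = 2)
  expect_equal(nrow(ch$trials), 10)
  by_subj <- split(ch$trials, ch$trials$subject)
  for (g in by_subj) {
    expect_setequal(g$condition, c("natural", "modified"))
    expect_equal(g$height[1], g$height[2])
    expect_equal(g$mass[1], g$mass[2])
  }
  expect_equal(unique(ch$trials$asymmetry[ch$trials$condition ==
                                            "natural"]), 0)
  expect_equal(unique(ch$trials$asymmetry[ch$trials$condition ==
                                            "modified"]), 0.4)
})

test_that("standing poses balance the contact-bearing fixture", {
  m2 <- demo_model("demo2d")
  q <- standing_pose(m2)
  Q <- matrix(q, 1, dimnames = list(NULL, names(q)))
  fk <- markerless:::fk_states(m2, Q, Q * 0, Q * 0)
  tau <- markerless:::inverse_dynamics_core(m2, fk)
  con <- markerless:::contact_generalized_forces(m2, fk)
  resid <- (tau - con$tau)[1, c("pelvis_ty", "pelvis_tilt")]
  expect_lt(max(abs(resid)), 1e-6)
})
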