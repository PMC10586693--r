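make_tiny_corpus <- function(n_subjects = 6, seed = 21) {
  generate_augmenter_corpus(n_subjects = n_subjects,
                            tasks = c("squat", "sit_to_stand"), seed = seed)
}

test_that("the augmenter spec enforces the window arithmetic and submodel
          shapes", {
  spec <- augmenter_spec()
  expect_equal(spec$n_frames, 30)
  expect_length(spec$submodels$body$keypoints, 15)
  expect_length(spec$submodels$body$markers, 35)
  expect_length(spec$submodels$arm$keypoints, 7)
  expect_length(spec$submodels$arm$markers, 8)
  expect_length(intersect(spec$submodels$body$markers,
                          spec$submodels$arm$markers), 0)
  expect_error(augmenter_spec(window = 0.47), "integer")
})

test_that("feature building is translation-invariant, scales with height,
          and zeroes a static centered pose", {
  m3 <- demo_model("demo3d")
  traj <- generate_motion("squat", m3, seed = 31)
  fk <- forward_kinematics(m3, traj$q, check_bounds = FALSE)
  ord <- match(keypoint_canon(), dimnames(fk$keypoints)[[2]])
  kp <- keypoint_series_3d(traj$times, fk$keypoints[, ord, , drop = FALSE],
                           keypoint_names = keypoint_canon())
  ft <- build_features(kp, 1.75, 70)
  shifted <- kp
  shifted$positions <- kp$positions + 0.73
  ft2 <- build_features(shifted, 1.75, 70)
  expect_equal(ft$windows, ft2$windows, tolerance = 1e-12)
  ft_tall <- build_features(kp, 3.5, 70)
  expect_equal(ft_tall$windows[[1]], ft$windows[[1]] * 0.5,
               tolerance = 1e-12)
  # trailing partial window is edge-padded and masked
  expect_false(all(ft$mask[[length(ft$mask)]]))
  # invalid hips are reported
  kp_bad <- kp
  kp_bad$validity[5, match("r_hip", keypoint_canon())] <- FALSE
  kp_bad$positions[5, match("r_hip", keypoint_canon()), ] <- NA
  expect_error(build_features(kp_bad, 1.75, 70), "hip")
})

test_that("training recovers an exact affine keypoint-to-marker map", {
  # corpus whose markers ARE an affine function of the keypoints; enough
  # subjects and tasks to span the pose manifold
  corpus <- generate_augmenter_corpus(n_subjects = 10, seed = 21)
  spec <- augmenter_spec(input_noise_sd = 0, ridge = 1e-8, context_lags = 0L)
  # each submodel's markers are affine in that submodel's own keypoints
  affine <- function(kp3d) {
    nf <- length(kp3d$times)
    out <- array(0, dim = c(nf, 43, 3))
    set.seed(99)
    names_all <- c(body_markers(), arm_markers())
    kp_of <- list(body = match(body_keypoints(), keypoint_canon()),
                  arm = match(arm_keypoints(), keypoint_canon()))
    col <- 0
    for (sm in c("body", "arm")) {
      nm <- if (sm == "body") 35 else 8
      ks <- kp_of[[sm]]
      for (m in seq_len(nm)) {
        col <- col + 1
        picks <- sample(ks, 3)
        w <- c(0.5, 0.3, 0.2)
        for (d in 1:3) {
          out[, col, d] <- kp3d$positions[, picks, d] %*% w
        }
      }
    }
    marker_set(kp3d$times, out, names_all)
  }
  corpus$trials <- lapply(corpus$trials, function(tr) {
    tr$markers <- affine(tr$kp3d)
    tr
  })
  fit <- train_augmenter(corpus, spec, seed = 1)
  expect_lt(fit$rmse$body["test"], 3e-3)
  expect_lt(fit$rmse$arm["test"], 3e-3)
})

test_that("training is bit-reproducible under a fixed seed", {
  corpus <- make_tiny_corpus(4)
  f1 <- train_augmenter(corpus, seed = 5)
  f2 <- train_augmenter(corpus, seed = 5)
  expect_identical(f1$rmse, f2$rmse)
  expect_identical(f1$models$body$beta, f2$models$body$beta)
  f3 <- train_augmenter(corpus, seed = 6)
  expect_false(identical(f1$rmse$body["test"], f3$rmse$body["test"]))
})

test_that("prediction is exactly translation-equivariant, produces the full
          43-marker set, and is temporally stable on a constant pose", {
  corpus <- make_tiny_corpus()
  fit <- train_augmenter(corpus, seed = 3)
  m3 <- demo_model("demo3d")
  traj <- generate_motion("squat", m3, seed = 44)
  fk <- forward_kinematics(m3, traj$q, check_bounds = FALSE)
  ord <- match(keypoint_canon(), dimnames(fk$keypoints)[[2]])
  kp <- keypoint_series_3d(traj$times, fk$keypoints[, ord, , drop = FALSE],
                           keypoint_names = keypoint_canon())
  mk <- augment_markers(kp, 1.78, 74, fit)
  expect_setequal(mk$marker_names, marker_canon())
  v <- c(0.31, -0.12, 0.54)
  kp_t <- kp
  for (d in 1:3) kp_t$positions[, , d] <- kp$positions[, , d] + v[d]
  mk_t <- augment_markers(kp_t, 1.78, 74, fit)
  for (d in 1:3) {
    expect_equal(mk_t$positions[, , d], mk$positions[, , d] + v[d],
                 tolerance = 1e-9)
  }
  # constant pose in, near-constant markers out
  nf <- 60
  kp_const <- keypoint_series_3d(
    (seq_len(nf) - 1) / 60,
    array(rep(kp$positions[1, , ], each = nf), dim = c(nf, 20, 3)),
    keypoint_names = keypoint_canon())
  mk_const <- augment_markers(kp_const, 1.78, 74, fit)
  sds <- apply(mk_const$positions, c(2, 3), sd)
  expect_lt(max(sds), 5e-3)
  expect_error(augment_markers(keypoint_series_3d(
    (0:9) / 30, kp$positions[1:10, , , drop = FALSE],
    keypoint_names = keypoint_canon()), 1.78, 74, fit), "rate")
})
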