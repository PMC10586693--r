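#' Marker-augmenter specification
#'
#' Two sequence-regression submodels map triangulated video keypoints (plus
#' height and mass) to anatomical marker trajectories: a *body* submodel
#' from 15 lower-limb and torso keypoints to 35 body markers, and an *arm*
#' submodel from 7 arm and torso keypoints to 8 arm markers. Preprocessing
#' follows the root-centering convention: positions are expressed relative
#' to a root (the midpoint of the hip keypoints), normalized by subject
#' height, resampled at 60 Hz, and split into non-overlapping 0.5-s windows;
#' training inputs carry Gaussian noise whose 3D magnitude is 18 mm.
#'
#' @param window Window length (s); `window * rate` must be an integer.
#' @param rate Sampling rate (Hz).
#' @param input_noise_sd Training-noise 3D magnitude (m).
#' @param context_lags Frame lags stacked as temporal context for each
#'   output frame (the sequence-regression receptive field).
#' @param ridge Ridge regularization weight.
#' @param splits Approximate train/validation/test fractions.
#' @return An `augmenter_spec` object.
#' @export
augmenter_spec <- function(window = 0.5, rate = 60, input_noise_sd = 0.018,
                           context_lags = c(-4L, -2L, 0L, 2L, 4L),
                           ridge = 1e-4, splits = c(0.8, 0.1, 0.1)) {
  n_frames <- window * rate
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("window * rate must be an integer number of frames")
  }
  structure(list(
    window = window, rate = rate, n_frames = as.integer(round(n_frames)),
    input_noise_sd = input_noise_sd, context_lags = as.integer(context_lags),
    ridge = ridge, splits = splits,
    submodels = list(
      body = list(keypoints = body_keypoints(), markers = body_markers()),
      arm = list(keypoints = arm_keypoints(), markers = arm_markers()))),
    class = "augmenter_spec")
}

#' Build root-centered, height-normalized feature windows
#'
#' The root is the per-frame midpoint of the left and right hip keypoints;
#' all positions are root-centered, divided by subject height, and split
#' into non-overlapping windows of `spec$window` seconds at `spec$rate` Hz.
#' A trailing partial window is padded by edge repetition and masked. Height
#' and mass are appended as per-window scalars; the root trajectory is
#' returned for later re-anchoring.
#'
#' @param kp3d A [keypoint_series_3d()] with valid hips on every frame.
#' @param height,mass Subject anthropometry (m, kg).
#' @param spec An [augmenter_spec()].
#' @return List: `windows` (list of `n_frames x 20 x 3` normalized keypoint
#'   arrays), `mask` (per-window logical vectors of real frames), `root`
#'   (`frames x 3`), `height`, `mass`, `times`.
#' @export
build_features <- function(kp3d, height, mass, spec = augmenter_spec()) {
  rate <- 1 / median(diff(kp3d$times))
  if (abs(rate - spec$rate) > 0.01 * spec$rate) {
    stop("keypoint series must be sampled at ", spec$rate, " Hz")
  }
  hips <- match(c("r_hip", "l_hip"), kp3d$keypoint_names)
  bad <- which(!(kp3d$validity[, hips[1]] & kp3d$validity[, hips[2]]))
  if (length(bad)) {
    stop("hip keypoints invalid at frame(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         "; run fill_gaps before feature building")
  }
  root <- (kp3d$positions[, hips[1], , drop = TRUE] +
             kp3d$positions[, hips[2], , drop = TRUE]) / 2
  root <- matrix(root, ncol = 3)
  nf <- length(kp3d$times)
  centered <- kp3d$positions
  for (d in 1:3) centered[, , d] <- (centered[, , d] - root[, d]) / height
  wlen <- spec$n_frames
  n_win <- ceiling(nf / wlen)
  windows <- vector("list", n_win)
  mask <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    real <- idx <= nf
    idx[!real] <- nf      # edge-repeat padding for the trailing window
    windows[[w]] <- centered[idx, , , drop = FALSE]
    mask[[w]] <- real
  }
  list(windows = windows, mask = mask, root = root,
       height = height, mass = mass, times = kp3d$times)
}

# lag-stacked design matrix for one submodel over one window:
# rows = frames, cols = keypoints x 3 x lags + height + mass + 1
window_design <- function(win, kp_ix, lags, height, mass) {
  wlen <- dim(win)[1]
  sub <- win[, kp_ix, , drop = FALSE]
  flat <- matrix(sub, wlen, length(kp_ix) * 3)
  blocks <- lapply(lags, function(L) {
    src <- pmin(pmax(seq_len(wlen) + L, 1), wlen)
    flat[src, , drop = FALSE]
  })
  cbind(do.call(cbind, blocks), height, mass, 1)
}

#' Train the marker augmenter on a paired corpus
#'
#' Fits the two ridge-regularized, lag-stacked linear sequence-regression
#' submodels on noise-augmented keypoint windows against root-centered,
#' height-normalized marker targets. The corpus is split at the subject
#' level (~80/10/10); training is deterministic under a fixed seed and the
#' fit is reproducible bit for bit.
#'
#' @param corpus A [generate_augmenter_corpus()] result (or an equivalent
#'   list of trials with `kp3d`, `markers`, `height`, `mass`, `subject`,
#'   `split`).
#' @param spec An [augmenter_spec()].
#' @param seed RNG seed for the noise augmentation.
#' @return A `trained_augmenter` with per-submodel coefficients and a
#'   train/validation/test RMSE report (meters).
#' @export
train_augmenter <- function(corpus, spec = augmenter_spec(), seed = 1) {
  set.seed(seed)
  trials <- corpus$trials
  if (!length(trials)) stop("empty corpus")
  splits <- vapply(trials, `[[`, character(1), "split")
  if (sum(splits == "train") < 1 || sum(splits == "test") < 1) {
    stop("corpus too small: need at least one training and one test trial")
  }
  models <- list()
  report <- list()
  for (sm_name in names(spec$submodels)) {
    sm <- spec$submodels[[sm_name]]
    acc <- list(train = list(X = list(), Y = list()),
                val = list(X = list(), Y = list()),
                test = list(X = list(), Y = list()))
    for (tr in trials) {
      ft <- build_features(tr$kp3d, tr$height, tr$mass, spec)
      kp_ix <- match(sm$keypoints, tr$kp3d$keypoint_names)
      mk_ix <- match(sm$markers, tr$markers$marker_names)
      nf <- length(tr$kp3d$times)
      targ <- tr$markers$positions[, mk_ix, , drop = FALSE]
      for (d in 1:3)

        targ[, , d] <- (targ[, , d] - ft$root[, d]) / tr$height
      for (w in seq_along(ft$windows)) {
        win <- ft$windows[[w]]
        if (tr$split == "train") {
          # per-time-step Gaussian noise, 3D magnitude = input_noise_sd
          win <- win + array(stats::rnorm(length(win), 0,
                                          spec$input_noise_sd /
                                            sqrt(3) / tr$height),
                             dim = dim(win))
        }
        X <- window_design(win, kp_ix, spec$context_lags, tr$height, tr$mass)
        idx <- ((w - 1) * spec$n_frames + 1):(w * spec$n_frames)
        real <- ft$mask[[w]]
        idx <- pmin(idx, nf)
        Y <- matrix(targ[idx, , ], spec$n_frames, length(mk_ix) * 3)
        X <- X[real, , drop = FALSE]    # padded frames are masked out
        Y <- Y[real, , drop = FALSE]
        acc[[tr$split]]$X[[length(acc[[tr$split]]$X) + 1]] <- X
        acc[[tr$split]]$Y[[length(acc[[tr$split]]$Y) + 1]] <- Y
      }
    }
    Xtr <- do.call(rbind, acc$train$X)
    Ytr <- do.call(rbind, acc$train$Y)
    XtX <- crossprod(Xtr) + spec$ridge * nrow(Xtr) * diag(ncol(Xtr))
    beta <- solve(XtX, crossprod(Xtr, Ytr))
    rmse_of <- function(part) {
      if (!length(acc[[part]]$X)) return(NA_real_)
      X <- do.call(rbind, acc[[part]]$X)
      Y <- do.call(rbind, acc[[part]]$Y)
      res <- X %*% beta - Y
      # back to meters: targets are height-normalized, so the 3D RMSE is
      # reported at the corpus mean height
      hbar <- mean(vapply(trials, `[[`, numeric(1), "height"))
      sqrt(mean(res^2) * 3) * hbar
    }
    models[[sm_name]] <- list(beta = beta, keypoints = sm$keypoints,
                              markers = sm$markers)
    report[[sm_name]] <- c(train = rmse_of("train"), val = rmse_of("val"),
                           test = rmse_of("test"))
  }
  structure(list(models = models, spec = spec,
                 rmse = report,
                 metadata = list(seed = seed,
                                 n_trials = length(trials),
                                 n_subjects = length(unique(
                                   vapply(trials, `[[`, numeric(1),
                                          "subject"))))),
            class = "trained_augmenter")
}

#' @export
print.trained_augmenter <- function(x, ...) {
  cat("<trained_augmenter>",
      sprintf("body RMSE %.1f mm / arm RMSE %.1f mm (held-out test)\n",
              1000 * x$rmse$body["test"], 1000 * x$rmse$arm["test"]))
  invisible(x)
}

#' @export
glance.trained_augmenter <- function(x, ...) {
  tibble::tibble(
    body_train_rmse = x$rmse$body["train"],
    body_test_rmse = x$rmse$body["test"],
    arm_train_rmse = x$rmse$arm["train"],
    arm_test_rmse = x$rmse$arm["test"],
    n_trials = x$metadata$n_trials,
    n_subjects = x$metadata$n_subjects,
    seed = x$metadata$seed)
}

#' Predict anatomical markers from triangulated keypoints
#'
#' Applies the trained body and arm submodels window by window, then
#' un-normalizes by height and re-adds the root keypoint position to every
#' predicted marker, yielding the 43-marker set in world coordinates.
#'
#' @param kp3d A [keypoint_series_3d()].
#' @param height,mass Subject anthropometry (m, kg).
#' @param model A [train_augmenter()] result.
#' @return A [marker_set()] with 43 markers.
#' @export
augment_markers <- function(kp3d, height, mass, model) {
  spec <- model$spec
  rate <- 1 / median(diff(kp3d$times))
  if (abs(rate - spec$rate) > 0.01 * spec$rate) {
    stop("rate mismatch: model trained at ", spec$rate, " Hz")
  }
  ft <- build_features(kp3d, height, mass, spec)
  nf <- length(kp3d$times)
  all_markers <- unlist(lapply(model$models, `[[`, "markers"))
  out <- array(NA_real_, dim = c(nf, length(all_markers), 3))
  col0 <- 0
  for (sm in model$models) {
    kp_ix <- match(sm$keypoints, kp3d$keypoint_names)
    pred_rows <- vector("list", length(ft$windows))
    for (w in seq_along(ft$windows)) {
      X <- window_design(ft$windows[[w]], kp_ix, spec$context_lags,
                         height, mass)
      P <- X %*% sm$beta
      pred_rows[[w]] <- P[ft$mask[[w]], , drop = FALSE]
    }
    P <- do.call(rbind, pred_rows)
    nm <- length(sm$markers)
    arr <- array(P, dim = c(nf, nm, 3))
    for (d in 1:3) arr[, , d] <- arr[, , d] * height + ft$root[, d]
    out[, col0 + seq_len(nm), ] <- arr
    col0 <- col0 + nm
  }
  marker_set(kp3d$times, out, all_markers)
}
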