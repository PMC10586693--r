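#' Static optimization of muscle activations
#'
#' Per frame, minimizes the sum of squared activations subject to the
#' joint-moment equality and activation bounds \[0, 1\]. With a rigid tendon
#' the muscle force is affine in activation, so each frame is a small
#' box-constrained quadratic program, solved here with an exact penalty on
#' the moment equality and projected quasi-Newton iterations. Reserve torque
#' motors take up any moment the muscles cannot produce; frames where they
#' engage beyond `reserve_tol` are flagged.
#'
#' @param model A `skeletal_model` with muscles.
#' @param traj A [coordinate_trajectory()] with velocities (see
#'   [differentiate()]).
#' @param moments `frames x nq` matrix of required generalized forces
#'   (N·m | N) for the actuated coordinates.
#' @param surrogate Optional [fit_muscle_polynomials()] result (fitted on the
#'   fly if missing).
#' @param reserve_weight Relative cost of normalized reserve-motor use.
#' @param reserve_tol Reserve torque (N·m) above which a frame is flagged.
#' @param control [stats::optim()] L-BFGS-B control list; the tracking
#'   solver passes a looser one when it only needs a warm start.
#' @return List with `activations` (`frames x n_muscles`), `reserves`
#'   (`frames x n_motors`), `flagged` (frames where reserves engaged), and
#'   `residual` (per-frame moment residual norm).
#' @export
static_optimization <- function(model, traj, moments, surrogate = NULL,
                                reserve_weight = 10, reserve_tol = 1,
                                control = list(maxit = 500, factr = 1e4)) {
  nm <- length(model$muscles)
  if (!nm) stop("model has no muscles")
  if (is.null(surrogate)) surrogate <- fit_muscle_polynomials(model)
  if (is.null(traj$qd)) traj <- differentiate(traj)
  geo <- evaluate_surrogate(surrogate, traj$q, traj$qd)
  nq <- model$n_coordinates
  nf <- nrow(traj$q)
  nmot <- length(model$torque_motors)
  mot_coord <- vapply(model$torque_motors, `[[`, character(1), "coordinate")
  mot_ix <- match(mot_coord, model$coordinates$name)
  mot_max <- vapply(model$torque_motors, `[[`, numeric(1), "max_torque")
  # coordinates spanned by any actuator (pelvis residual rows are excluded)
  act_cols <- sort(unique(c(mot_ix, unlist(lapply(seq_len(nm), function(m) {
    which(apply(abs(geo$moment_arms[, , m, drop = FALSE]) > 1e-9, 2, any))
  })))))
  A <- matrix(0, nf, nm)
  Rm <- matrix(0, nf, max(nmot, 1))
  flagged <- integer(0)
  resid <- numeric(nf)
  gain_fl <- muscle_linear_gains(model, geo)
  for (f in seq_len(nf)) {
    G <- t(gain_fl$gain[f, ] * t(geo$moment_arms[f, act_cols, , drop = TRUE]))
    if (length(act_cols) == 1) G <- matrix(G, nrow = 1)
    passive <- as.vector(matrix(geo$moment_arms[f, act_cols, ], ncol = nm) %*%
                           gain_fl$passive[f, ])
    Mmap <- matrix(0, length(act_cols), nmot)
    if (nmot) {
      for (j in seq_len(nmot)) {
        r <- match(mot_ix[j], act_cols)
        if (!is.na(r)) Mmap[r, j] <- 1
      }
    }
    tgt <- moments[f, act_cols] - passive
    obj <- function(x) {
      a <- x[seq_len(nm)]
      u <- if (nmot) x[nm + seq_len(nmot)] else numeric(0)
      res <- as.vector(G %*% a) + (if (nmot) as.vector(Mmap %*% (u * mot_max))
                                   else 0) - tgt
      sum(a^2) + reserve_weight * sum(u^2) + 1e4 * sum(res^2)
    }
    grad <- function(x) {
      a <- x[seq_len(nm)]
      u <- if (nmot) x[nm + seq_len(nmot)] else numeric(0)
      res <- as.vector(G %*% a) + (if (nmot) as.vector(Mmap %*% (u * mot_max))
                                   else 0) - tgt
      ga <- 2 * a + 2e4 * as.vector(t(G) %*% res)
      gu <- if (nmot) 2 * reserve_weight * u +
        2e4 * as.vector(t(Mmap) %*% res) * mot_max else numeric(0)
      c(ga, gu)
    }
    x0 <- rep(0, nm + nmot)
    fit <- stats::optim(x0, obj, grad, method = "L-BFGS-B",
                        lower = c(rep(0, nm), rep(-1, nmot)),
                        upper = rep(1, nm + nmot),
                        control = control)
    A[f, ] <- fit$par[seq_len(nm)]
    if (nmot) Rm[f, seq_len(nmot)] <- fit$par[nm + seq_len(nmot)] * mot_max
    res <- as.vector(G %*% A[f, ]) +
      (if (nmot) as.vector(Mmap %*% Rm[f, seq_len(nmot)]) else 0) - tgt
    resid[f] <- sqrt(sum(res^2))
    if (nmot && any(abs(Rm[f, seq_len(nmot)]) > reserve_tol)) {
      flagged <- c(flagged, f)
    }
  }
  colnames(A) <- vapply(model$muscles, `[[`, character(1), "name")
  list(activations = A,
       reserves = if (nmot) Rm[, seq_len(nmot), drop = FALSE] else
         matrix(0, nf, 0),
       flagged = flagged, residual = resid)
}

# Affine decomposition of rigid-tendon muscle force: F = gain * a + passive,
# with gain = Fmax * f_l(ln) * f_v(vn) * cos(pennation) and
# passive = Fmax * f_p(ln) * cos(pennation), per frame x muscle.
muscle_linear_gains <- function(model, geo) {
  nf <- nrow(geo$lengths)
  nm <- length(model$muscles)
  gain <- matrix(0, nf, nm)
  passive <- matrix(0, nf, nm)
  vel <- geo$velocities
  if (is.null(vel)) vel <- matrix(0, nf, nm)
  for (m in seq_len(nm)) {
    mu <- model$muscles[[m]]
    w <- mu$l_opt * sin(mu$pennation)
    proj <- pmax(geo$lengths[, m] - mu$l_slack, 0.01 * mu$l_opt)
    lm <- sqrt(proj^2 + w^2)
    cosa <- proj / lm
    ln <- lm / mu$l_opt
    vn <- (vel[, m] * cosa) / (mu$v_max * mu$l_opt)
    gain[, m] <- mu$f_max * force_length_active(ln) * force_velocity(vn) * cosa
    passive[, m] <- mu$f_max * force_length_passive(ln) * cosa
  }
  list(gain = gain, passive = passive)
}
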