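#' Raasch-style excitation-activation coupling
#'
#' First-order dynamics with the activation time constant when excitation
#' exceeds activation and the (slower) deactivation constant otherwise,
#' blended by a tanh switch for differentiability.
#'
#' @param e Excitation in \[0, 1\].
#' @param a Activation in \[0, 1\].
#' @param tau_act,tau_deact Activation / deactivation time constants (s);
#'   `tau_deact >= tau_act`.
#' @param smoothing Steepness of the tanh blend (larger = sharper switch).
#' @return `da/dt` (1/s), vectorized.
#' @export
activation_dynamics <- function(e, a, tau_act = 0.015, tau_deact = 0.06,
                                smoothing = 10) {
  s <- 0.5 + 0.5 * tanh(smoothing * (e - a))
  (e - a) * (s / tau_act + (1 - s) / tau_deact)
}

# Normalized Hill curves. Constants are normalized so that the active
# force-length curve peaks at exactly 1 at optimal length, the
# force-velocity multiplier is exactly 1 at zero velocity, and the passive
# curve is exactly 0 at optimal length.
force_length_active <- function(ln) exp(-((ln - 1) / 0.45)^2)

force_velocity <- function(vn) {
  # vn: fiber velocity / (v_max * l_opt), negative = shortening
  d1 <- -0.318; d2 <- -8.149; d3 <- -0.374
  d4 <- 1 - d1 * log(d3 + sqrt(d3^2 + 1))  # anchor fv(0) = 1
  d1 * log((d2 * vn + d3) + sqrt((d2 * vn + d3)^2 + 1)) + d4
}

force_length_passive <- function(ln, kpe = 4, e0 = 0.6) {
  (exp(kpe * (ln - 1) / e0) - 1) / (exp(kpe) - 1)
}

#' Hill-type muscle-tendon equilibrium (rigid tendon)
#'
#' With a rigid tendon the fiber length follows directly from the
#' muscle-tendon length and the force along the tendon is the closed form
#' `(a * f_l(ln) * f_v(vn) + f_p(ln)) * F_max * cos(pennation)`. In
#' compliant mode the implicit equilibrium residual
#' `F_tendon - F_fiber_along_tendon` is returned instead.
#'
#' @param a Activation in \[0, 1\].
#' @param l_mt Muscle-tendon length (m).
#' @param v_mt Muscle-tendon lengthening velocity (m/s).
#' @param muscle Muscle parameter list (`f_max`, `l_opt`, `l_slack`,
#'   `pennation`, `v_max`).
#' @param lt_norm (compliant mode) normalized tendon length.
#' @param compliant Use the compliant-tendon residual formulation.
#' @return Rigid mode: tendon force (N), vectorized. Compliant mode: list
#'   with `residual` (N) and `force`.
#' @export
hill_equilibrium <- function(a, l_mt, v_mt, muscle, lt_norm = NULL,
                             compliant = FALSE) {
  w <- muscle$l_opt * sin(muscle$pennation)
  if (!compliant) {
    proj <- l_mt - muscle$l_slack           # fiber length along tendon
    lm <- sqrt(proj^2 + w^2)
    cosa <- proj / lm
    ln <- lm / muscle$l_opt
    vn <- (v_mt * cosa) / (muscle$v_max * muscle$l_opt)
    f <- (a * force_length_active(ln) * force_velocity(vn) +
            force_length_passive(ln)) * muscle$f_max * cosa
    return(f)
  }
  lt <- lt_norm * muscle$l_slack
  proj <- l_mt - lt
  lm <- sqrt(proj^2 + w^2)
  cosa <- proj / lm
  ln <- lm / muscle$l_opt
  vn <- (v_mt * cosa) / (muscle$v_max * muscle$l_opt)
  f_fiber <- (a * force_length_active(ln) * force_velocity(vn) +
                force_length_passive(ln)) * muscle$f_max * cosa
  f_tendon <- tendon_force_length(lt_norm) * muscle$f_max
  list(residual = f_tendon - f_fiber, force = f_tendon)
}

tendon_force_length <- function(lt_norm, kT = 35) {
  c1 <- 0.2; c2 <- 0.995; c3 <- 0.25
  c1 * exp(kT * (lt_norm - c2)) - c3
}

#' Muscle-tendon path lengths over a trajectory
#'
#' Sum of straight-line distances between consecutive via points, all
#' expressed in world coordinates via forward kinematics.
#'
#' @param model A `skeletal_model` with muscle paths.
#' @param Q Coordinate matrix (`frames x nq`) or named vector.
#' @return `frames x n_muscles` matrix of lengths (m).
#' @export
muscle_tendon_lengths <- function(model, Q) {
  Q <- as_q_matrix(model, Q)
  fk <- fk_states(model, Q)
  n <- fk$n
  out <- matrix(0, n, length(model$muscles),
                dimnames = list(NULL, vapply(model$muscles, `[[`,
                                             character(1), "name")))
  for (m in seq_along(model$muscles)) {
    path <- model$muscles[[m]]$path
    pts <- lapply(path, function(p) {
      st <- fk$states[[p$segment]]
      st$o + rot_apply(st$R, p$location)
    })
    L <- 0
    for (i in seq_len(length(pts) - 1)) {
      L <- L + sqrt(rowSums((pts[[i + 1]] - pts[[i]])^2))
    }
    out[, m] <- L
  }
  out
}

# Exact moment arms by central finite differences of the path length,
# r_ij = -d l_i / d q_j. Used as the training oracle for the polynomial
# surrogate and in small cross-checks.
muscle_moment_arms_fd <- function(model, q, h = 1e-6) {
  nq <- model$n_coordinates
  nm <- length(model$muscles)
  Qp <- matrix(rep(q, 2 * nq), 2 * nq, nq, byrow = TRUE)
  Qp[cbind(1:nq, 1:nq)] <- q[1:nq] + h
  Qp[cbind(nq + 1:nq, 1:nq)] <- q[1:nq] - h
  L <- muscle_tendon_lengths(model, Qp)
  -(L[1:nq, , drop = FALSE] - L[nq + 1:nq, , drop = FALSE]) / (2 * h)
  # result: nq x nm; transpose for muscles x coords
}

#' Fit polynomial surrogates for muscle geometry
#'
#' Muscle-tendon lengths (and hence velocities and moment arms) are
#' approximated per muscle by a multivariate polynomial in the coordinates
#' the muscle actually spans. Postures are sampled uniformly within
#' coordinate bounds; the polynomial total order (<= `max_order`) is chosen
#' per muscle by held-out RMSE; moment arms are the analytic partial
#' derivatives `-dl/dq` of the fitted polynomial.
#'
#' @param model A `skeletal_model` with muscle paths.
#' @param n_postures Number of sampled postures (default 5000).
#' @param max_order Maximum polynomial total order (default 9).
#' @param seed RNG seed for posture sampling.
#' @param holdout Fraction of postures held out for order selection.
#' @return A `muscle_surrogate` object with per-muscle coefficient tables
#'   and a held-out RMSE report (`length_rmse`, `moment_arm_rmse`, meters).
#' @export
fit_muscle_polynomials <- function(model, n_postures = 5000, max_order = 9,
                                   seed = 1, holdout = 0.25) {
  if (!length(model$muscles)) stop("model has no muscle paths")
  nq <- model$n_coordinates
  rng <- local({
    set.seed(seed)
    lo <- pmax(model$coordinates$lower, -pi)
    up <- pmin(model$coordinates$upper, pi)
    # keep translations near the origin: path lengths are invariant to root
    # translation anyway
    tr <- model$coordinates$type == "translation"
    lo[tr] <- -0.1; up[tr] <- 0.1
    sapply(seq_len(nq), function(j) stats::runif(n_postures, lo[j], up[j]))
  })
  colnames(rng) <- model$coordinates$name
  L <- muscle_tendon_lengths(model, rng)
  # moment arms at a subsample (FD oracle is nq FK pairs per posture)
  n_ma <- min(300, n_postures)
  ma_ix <- seq_len(n_ma)
  MA <- array(NA_real_, dim = c(n_ma, nq, length(model$muscles)))
  for (i in ma_ix) {
    MA[i, , ] <- muscle_moment_arms_fd(model, rng[i, ])
  }
  n_test <- floor(holdout * n_postures)
  test <- seq_len(n_test)
  train <- setdiff(seq_len(n_postures), test)
  fits <- vector("list", length(model$muscles))
  for (m in seq_along(model$muscles)) {
    # coordinates this muscle spans (length actually varies)
    dep <- which(apply(MA[, , m, drop = TRUE], 2,
                       function(col) max(abs(col)) > 1e-6))
    if (!length(dep)) dep <- integer(0)
    best <- NULL
    for (ord in 0:max_order) {
      basis <- poly_basis(length(dep), ord)
      if (nrow(basis) > length(train) / 2) break
      Xtr <- poly_design(rng[train, dep, drop = FALSE], basis)
      qr_f <- qr(Xtr)
      if (qr_f$rank < ncol(Xtr)) {
        warning("rank-deficient polynomial fit for ",
                model$muscles[[m]]$name, "; reducing order")
        break
      }
      beta <- qr.coef(qr_f, L[train, m])
      Xte <- poly_design(rng[test, dep, drop = FALSE], basis)
      rmse <- sqrt(mean((Xte %*% beta - L[test, m])^2))
      if (is.null(best) || rmse < best$rmse * 0.95) {
        best <- list(order = ord, basis = basis, beta = as.vector(beta),
                     rmse = rmse, dep = dep)
      }
    }
    fits[[m]] <- best
  }
  # held-out moment-arm RMSE against the finite-difference oracle
  ma_test <- intersect(test, ma_ix)
  ma_rmse <- vapply(seq_along(model$muscles), function(m) {
    f <- fits[[m]]
    if (!length(f$dep)) return(0)
    pred <- surrogate_moment_arms_one(f, rng[ma_test, , drop = FALSE], nq)
    truth <- matrix(MA[ma_test, f$dep, m], nrow = length(ma_test))
    sqrt(mean((pred[, f$dep, drop = FALSE] - truth)^2))
  }, numeric(1))
  structure(list(fits = fits, n_coordinates = nq,
                 coordinate_names = model$coordinates$name,
                 muscle_names = vapply(model$muscles, `[[`, character(1),
                                       "name"),
                 length_rmse = vapply(fits, function(f) f$rmse, numeric(1)),
                 moment_arm_rmse = ma_rmse),
            class = "muscle_surrogate")
}

# exponent table for a total-order polynomial basis in d variables
poly_basis <- function(d, order) {
  if (d == 0) return(matrix(0, 1, 0))
  grids <- rep(list(0:order), d)
  ex <- as.matrix(expand.grid(grids))
  ex[rowSums(ex) <= order, , drop = FALSE]
}

poly_design <- function(X, basis) {
  n <- nrow(X)
  out <- matrix(1, n, nrow(basis))
  for (k in seq_len(nrow(basis))) {
    for (j in seq_len(ncol(basis))) {
      e <- basis[k, j]
      if (e > 0) out[, k] <- out[, k] * X[, j]^e
    }
  }
  out
}

# derivative of the design matrix w.r.t. variable j
poly_design_deriv <- function(X, basis, j) {
  n <- nrow(X)
  out <- matrix(0, n, nrow(basis))
  for (k in seq_len(nrow(basis))) {
    e <- basis[k, j]
    if (e == 0) next
    v <- rep(e, n)
    for (jj in seq_len(ncol(basis))) {
      ee <- basis[k, jj] - (jj == j)
      if (ee > 0) v <- v * X[, jj]^ee
    }
    out[, k] <- v
  }
  out
}

surrogate_moment_arms_one <- function(fit, Q, nq) {
  out <- matrix(0, nrow(Q), nq)
  if (!length(fit$dep)) return(out)
  Xd <- Q[, fit$dep, drop = FALSE]
  for (jj in seq_along(fit$dep)) {
    out[, fit$dep[jj]] <-
      -as.vector(poly_design_deriv(Xd, fit$basis, jj) %*% fit$beta)
  }
  out
}

#' Evaluate a muscle-geometry surrogate
#'
#' @param surrogate A `muscle_surrogate`.
#' @param Q Coordinate matrix (`frames x nq`).
#' @param Qd Optional coordinate velocities for lengthening velocities.
#' @return List with `lengths` (`frames x nm`), `moment_arms`
#'   (`frames x nq x nm`), and `velocities` when `Qd` is given
#'   (`v = -sum_j r_j qd_j`).
#' @export
evaluate_surrogate <- function(surrogate, Q, Qd = NULL) {
  Q <- as.matrix(Q)
  nq <- surrogate$n_coordinates
  nm <- length(surrogate$fits)
  n <- nrow(Q)
  lens <- matrix(0, n, nm, dimnames = list(NULL, surrogate$muscle_names))
  arms <- array(0, dim = c(n, nq, nm))
  for (m in seq_len(nm)) {
    f <- surrogate$fits[[m]]
    X <- poly_design(Q[, f$dep, drop = FALSE], f$basis)
    lens[, m] <- as.vector(X %*% f$beta)
    arms[, , m] <- surrogate_moment_arms_one(f, Q, nq)
  }
  out <- list(lengths = lens, moment_arms = arms)
  if (!is.null(Qd)) {
    Qd <- as.matrix(Qd)
    vel <- matrix(0, n, nm)
    for (m in seq_len(nm)) {
      vel[, m] <- -rowSums(Qd * arms[, , m])
    }
    out$velocities <- vel
  }
  out
}
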