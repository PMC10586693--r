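#' Smooth compliant (Hunt-Crossley) sphere-ground contact force
#'
#' Normal force `k * d^1.5 * (1 + c * d_dot)` on penetration depth `d` of a
#' sphere below the ground plane (y = 0), with a smooth-max penetration so
#' the force and all derivatives vanish smoothly as the sphere leaves the
#' ground, and a tanh-regularized Coulomb friction opposing tangential slip.
#'
#' @param center `n x 3` sphere-center positions (m).
#' @param velocity `n x 3` sphere-center velocities (m/s).
#' @param sphere Contact-sphere parameter list (`radius`, `stiffness`,
#'   `dissipation`, `friction_dynamic`, `smoothing`).
#   Tangential velocity scale of the friction regularization
#'   (m/s).
#' @return `n x 3` matrix of ground-on-sphere forces (N).
#' @export
contact_force <- function(center, velocity, sphere, v_reg = 0.5) {
  center <- matrix(center, ncol = 3)
  velocity <- matrix(velocity, ncol = 3)
  s <- sphere$smoothing %||% 1e-4
  d <- sphere$radius - center[, 2]          # penetration depth
  dp <- 0.5 * (d + sqrt(d^2 + s^2))         # smooth max(d, 0)
  ddot <- -velocity[, 2]
  # dissipation factor kept smoothly non-negative
  damp <- 1 + sphere$dissipation * ddot
  damp <- 0.5 * (damp + sqrt(damp^2 + 1e-4))
  fn <- sphere$stiffness * dp^1.5 * damp
  vt <- velocity[, c(1, 3), drop = FALSE]
  vt_norm <- sqrt(rowSums(vt^2) + 1e-12)
  ft <- -(sphere$friction_dynamic * fn * tanh(vt_norm / v_reg) / vt_norm) * vt
  cbind(ft[, 1], fn, ft[, 2])
}

# World positions/velocities of all contact spheres given a kinematic pass.
contact_sphere_states <- function(model, fk) {
  lapply(model$contact_spheres, function(sp) {
    st <- fk$states[[sp$segment]]
    r <- rot_apply(st$R, sp$location)
    list(pos = st$o + r,
         vel = st$v + cross_t(st$omega, r),
         segment = sp$segment, sphere = sp)
  })
}

#' Inverse dynamics over the model tree
#'
#' Computes, per frame, the generalized forces (net joint moments / forces,
#' including the six pelvis residuals) required to produce the motion
#' `(q, qd, qdd)` under gravity and the supplied external forces, using the
#' world-frame Newton-Euler equations projected onto each degree of freedom.
#'
#' @param model A `skeletal_model`.
#' @param Q,Qd,Qdd Coordinate matrices (`frames x nq`).
#' @param external Optional list of external forces, each
#'   `list(segment, force, point)` with `force`/`point` `frames x 3`
#'   matrices (world frame; `point` is the application point).
#' @return `frames x nq` matrix of generalized forces (N·m | N), with
#'   coordinate column names.
#' @export
inverse_dynamics <- function(model, Q, Qd, Qdd, external = list()) {
  Q <- as_q_matrix(model, Q)
  fk <- fk_states(model, Q, Qd, Qdd)
  inverse_dynamics_core(model, fk, external)
}

inverse_dynamics_core <- function(model, fk, external = list()) {
  n <- fk$n
  g <- model$gravity
  seg_names <- vapply(model$segments, `[[`, character(1), "name")
  # per-segment net inertial force at the COM minus applied external loads
  Fs <- list(); Ms <- list(); Cs <- list()
  for (s in model$segments) {
    st <- fk$states[[s$name]]
    rc <- rot_apply(st$R, s$com)
    c_pos <- st$o + rc
    a_c <- st$a + cross_t(st$alpha, rc) +
      cross_t(st$omega, cross_t(st$omega, rc))
    Fb <- s$mass * (a_c - matrix(g, n, 3, byrow = TRUE))
    # world inertia: I_w = R diag(I) R^T  (applied to alpha and omega)
    Iw_apply <- function(v) {
      loc <- rot_apply_transpose(st$R, v)
      rot_apply(st$R, loc * matrix(s$inertia, n, 3, byrow = TRUE))
    }
    Mb <- Iw_apply(st$alpha) + cross_t(st$omega, Iw_apply(st$omega))
    Fs[[s$name]] <- Fb
    Ms[[s$name]] <- Mb
    Cs[[s$name]] <- c_pos
  }
  for (ext in external) {
    f <- matrix(ext$force, ncol = 3)
    p <- matrix(ext$point, ncol = 3)
    Fs[[ext$segment]] <- Fs[[ext$segment]] - f
    Ms[[ext$segment]] <- Ms[[ext$segment]] -
      cross_t(p - Cs[[ext$segment]], f)
  }
  # subtree membership: segments distal to (and including) each dof's segment
  children <- lapply(seg_names, function(nm) {
    sub <- nm
    repeat {
      more <- seg_names[vapply(model$segments, function(s)
        s$parent %in% sub && !(s$name %in% sub), logical(1))]
      if (!length(more)) break
      sub <- c(sub, more)
    }
    sub
  })
  names(children) <- seg_names
  tau <- matrix(0, n, model$n_coordinates,
                dimnames = list(NULL, model$coordinates$name))
  for (qi in seq_len(model$n_coordinates)) {
    info <- fk$dofs[[qi]]
    sub <- children[[info$segment]]
    Ftot <- matrix(0, n, 3); Mtot <- matrix(0, n, 3)
    for (nm in sub) {
      Ftot <- Ftot + Fs[[nm]]
      Mtot <- Mtot + Ms[[nm]] + cross_t(Cs[[nm]] - info$origin, Fs[[nm]])
    }
    tau[, qi] <- if (info$type == "rotation") {
      rowSums(info$axis_world * Mtot)
    } else {
      rowSums(info$axis_world * Ftot)
    }
  }
  tau
}

rot_apply_transpose <- function(R, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow(R), 3, byrow = TRUE)
  cbind(R[, 1] * v[, 1] + R[, 2] * v[, 2] + R[, 3] * v[, 3],
        R[, 4] * v[, 1] + R[, 5] * v[, 2] + R[, 6] * v[, 3],
        R[, 7] * v[, 1] + R[, 8] * v[, 2] + R[, 9] * v[, 3])
}

# Generalized forces applied by the contact spheres (world forces mapped
# through the dof axes), plus the per-foot force/COP summary.
contact_generalized_forces <- function(model, fk) {
  n <- fk$n
  tau <- matrix(0, n, model$n_coordinates)
  if (!length(model$contact_spheres)) {
    return(list(tau = tau, forces = list()))
  }
  seg_names <- vapply(model$segments, `[[`, character(1), "name")
  sph <- contact_sphere_states(model, fk)
  forces <- lapply(sph, function(s) {
    f <- contact_force(s$pos, s$vel, s$sphere)
    p <- cbind(s$pos[, 1], s$pos[, 2] - s$sphere$radius, s$pos[, 3])
    list(force = f, point = p, segment = s$segment)
  })
  # ancestors chain for each segment
  for (qi in seq_len(model$n_coordinates)) {
    info <- fk$dofs[[qi]]
    for (fc in forces) {
      if (!segment_in_subtree(model, info$segment, fc$segment)) next
      tau[, qi] <- tau[, qi] + if (info$type == "rotation") {
        rowSums(info$axis_world *
                  cross_t(fc$point - info$origin, fc$force))
      } else {
        rowSums(info$axis_world * fc$force)
      }
    }
  }
  list(tau = tau, forces = forces)
}

segment_in_subtree <- function(model, root_seg, query_seg) {
  nm <- query_seg
  seg_names <- vapply(model$segments, `[[`, character(1), "name")
  while (nm != "ground") {
    if (nm == root_seg) return(TRUE)
    nm <- model$segments[[match(nm, seg_names)]]$parent
  }
  FALSE
}
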