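#' Tracking-simulation cost weights
#'
#' Weights of the tracking optimal-control cost: squared muscle activations
#' (`w1`), squared torque-motor excitations (`w2`), and squared tracking
#' errors on joint positions (`w3`), velocities (`w4`) and accelerations
#' (`w5`), plus a small penalty `wp` on the remaining control variables
#' (muscle excitations) to avoid singular arcs. The defaults are
#' fixture-tuned configuration values, not constants.
#'
#' @param w1,w2,w3,w4,w5,wp Non-negative weights; `w3` must be positive.
#' @param t0,tf Optional time window (s); defaults to the reference span.
#' @return A `tracking_weights` list.
#' @export
tracking_weights <- function(w1 = 0.1, w2 = 0.01, w3 = 100, w4 = 1,
                             w5 = 1e-4, wp = 0.01, t0 = NULL, tf = NULL) {
  stopifnot(w1 >= 0, w2 >= 0, w3 > 0, w4 >= 0, w5 >= 0, wp >= 0)
  list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5, wp = wp,
       t0 = t0, tf = tf)
}

# Radau IIA (2-stage, third order) differentiation matrix over nodes
# tau = {0, 1/3, 1} and quadrature weights at the stage points.
radau_D <- function() {
  matrix(c(-2, 1.5, 0.5,
           2, -4.5, 2.5), 2, 3, byrow = TRUE)
}
radau_b <- function() c(0.75, 0.25)

#' Muscle-driven tracking simulation by direct collocation
#'
#' Transcribes the tracking optimal-control problem (integrand
#' `w1*a^2 + w2*e_tm^2 + w3*||q_ref - q||^2 + w4*||qd_ref - qd||^2 +
#' w5*||qdd_ref - qdd||^2 + wp*(remaining controls)^2`) onto a fixed mesh
#' with third-order Radau collocation, enforcing excitation-activation
#' coupling, first-order torque-motor dynamics, and the skeleton dynamics
#' implicitly through inverse-dynamics residuals (including smooth compliant
#' foot-ground contact). The resulting sparse nonlinear least-squares
#' problem with equality constraints is solved by an augmented-Lagrangian
#' Levenberg-Marquardt scheme to a constraint tolerance of 1e-4 (scaled).
#'
#' @param model A `skeletal_model` (muscles/motors optional, but every
#'   coordinate must be actuated or in contact-balanced directions).
#' @param reference A [coordinate_trajectory()]; filter it first
#'   ([lowpass_filter()], 12 Hz gait / 30 Hz non-gait by default in the
#'   pipeline drivers) — derivatives are added if absent.
#' @param weights A [tracking_weights()].
#' @param settings List: `mesh_per_second` (default 50), `tol` (1e-4),
#'   `max_outer` (8), `max_inner` (30), `mu0` (1e3), `surrogate`
#'   (precomputed muscle-geometry surrogate), `verbose`.
#' @return A `tracking_solution`: mesh times, states, controls, motor
#'   torques, ground reaction forces and centers of pressure per foot, joint
#'   moments, cost breakdown, and solver status.
#' @export
solve_tracking <- function(model, reference, weights = tracking_weights(),
                           settings = list()) {
  s_def <- list(mesh_per_second = 50, tol = 1e-4, max_outer = 8,
                max_inner = 30, mu0 = 1e3, mu_ratio = 100, mu_max = 1e9,
                surrogate = NULL, verbose = FALSE)
  settings <- utils::modifyList(s_def, settings)
  if (is.null(reference$qd) || is.null(reference$qdd)) {
    reference <- differentiate(reference)
  }
  t0 <- weights$t0 %||% reference$times[1]
  tf <- weights$tf %||% reference$times[length(reference$times)]
  nq <- model$n_coordinates
  nmus <- length(model$muscles)
  nmot <- length(model$torque_motors)
  surrogate <- settings$surrogate
  if (nmus && is.null(surrogate)) {
    surrogate <- fit_muscle_polynomials(model)
  }
  N <- max(4L, ceiling((tf - t0) * settings$mesh_per_second))
  h <- (tf - t0) / N
  M <- 2L * N
  D <- radau_D(); b <- radau_b()
  stage_t <- as.vector(vapply(seq_len(N), function(k) {
    t0 + (k - 1) * h + h * c(1 / 3, 1)
  }, numeric(2)))
  interp <- function(Y) {
    apply(Y, 2, function(col) stats::approx(reference$times, col,
                                            xout = stage_t, rule = 2)$y)
  }
  Qref <- interp(reference$q); Vref <- interp(reference$qd)
  Wref <- interp(reference$qdd)
  ref0 <- list(
    q = apply(reference$q, 2, function(col)
      stats::approx(reference$times, col, xout = t0, rule = 2)$y),
    v = apply(reference$qd, 2, function(col)
      stats::approx(reference$times, col, xout = t0, rule = 2)$y))

  # ---- variable layout ---------------------------------------------------
  nx <- 2 * nq + nmus + nmot
  nw <- nq
  nu <- nmus + nmot
  nps <- nx + nw + nu
  nz <- nx + M * nps
  stage_base <- nx + (seq_len(M) - 1) * nps
  ix <- list(
    q0 = 1:nq, v0 = nq + 1:nq,
    a0 = if (nmus) 2 * nq + seq_len(nmus) else integer(0),
    m0 = if (nmot) 2 * nq + nmus + seq_len(nmot) else integer(0),
    q = outer(stage_base, 1:nq, `+`),
    v = outer(stage_base, nq + 1:nq, `+`),
    a = if (nmus) outer(stage_base, 2 * nq + seq_len(nmus), `+`) else NULL,
    m = if (nmot) outer(stage_base, 2 * nq + nmus + seq_len(nmot), `+`)
        else NULL,
    w = outer(stage_base, nx + 1:nq, `+`),
    e = if (nmus) outer(stage_base, nx + nw + seq_len(nmus), `+`) else NULL,
    u = if (nmot) outer(stage_base, nx + nw + nmus + seq_len(nmot), `+`)
        else NULL
  )
  odd <- seq(1, M, 2); even <- seq(2, M, 2)
  # node (interval-start) variable indices per interval
  node_ix <- function(stage_mat, x0_ix) {
    rbind(matrix(x0_ix, 1), stage_mat[even[-N], , drop = FALSE])
  }
  nqix <- node_ix(ix$q, ix$q0); nvix <- node_ix(ix$v, ix$v0)
  naix <- if (nmus) node_ix(ix$a, ix$a0) else NULL
  nmix <- if (nmot) node_ix(ix$m, ix$m0) else NULL

  mot_coord <- vapply(model$torque_motors, `[[`, character(1), "coordinate")
  mot_cix <- match(mot_coord, model$coordinates$name)
  mot_max <- vapply(model$torque_motors, `[[`, numeric(1), "max_torque")
  mot_tau <- vapply(model$torque_motors,
                    function(m) m$time_constant %||% 0.035, numeric(1))
  mus_tau_a <- vapply(model$muscles, function(m) m$tau_act %||% 0.015,
                      numeric(1))
  mus_tau_d <- vapply(model$muscles, function(m) m$tau_deact %||% 0.06,
                      numeric(1))

  m_tot <- sum(vapply(model$segments, `[[`, numeric(1), "mass"))
  dyn_scale <- 0.1 * m_tot * GRAVITY          # N or N·m per unit residual
  v_scale <- 1

  # bounds
  lo <- rep(-Inf, nz); up <- rep(Inf, nz)
  clo <- model$coordinates$lower; cup <- model$coordinates$upper
  lo[ix$q0] <- clo; up[ix$q0] <- cup
  lo[c(ix$q)] <- rep(clo, each = M); up[c(ix$q)] <- rep(cup, each = M)
  if (nmus) {
    lo[c(ix$a, ix$e, ix$a0)] <- 0; up[c(ix$a, ix$e, ix$a0)] <- 1
  }
  if (nmot) {
    lo[c(ix$u)] <- -1; up[c(ix$u)] <- 1
    lo[c(ix$m)] <- rep(-mot_max, each = M)
    up[c(ix$m)] <- rep(mot_max, each = M)
    lo[ix$m0] <- -mot_max; up[ix$m0] <- mot_max
  }

  unpack <- function(z) {
    list(Q = matrix(z[c(ix$q)], M, nq), V = matrix(z[c(ix$v)], M, nq),
         W = matrix(z[c(ix$w)], M, nq),
         A = if (nmus) matrix(z[c(ix$a)], M, nmus) else NULL,
         Mm = if (nmot) matrix(z[c(ix$m)], M, nmot) else NULL,
         E = if (nmus) matrix(z[c(ix$e)], M, nmus) else NULL,
         U = if (nmot) matrix(z[c(ix$u)], M, nmot) else NULL,
         Qn = matrix(z[c(nqix)], N, nq), Vn = matrix(z[c(nvix)], N, nq),
         An = if (nmus) matrix(z[c(naix)], N, nmus) else NULL,
         Mn = if (nmot) matrix(z[c(nmix)], N, nmot) else NULL)
  }

  # net required generalized force minus contact, divided by scale
  dyn_residual <- function(Q, V, W) {
    fk <- fk_states(model, Q, V, W)
    tau <- inverse_dynamics_from_fk(model, fk)
    con <- contact_generalized_forces(model, fk)
    (tau - con$tau) / dyn_scale
  }

  muscle_tau_parts <- function(Q, V) {
    if (!nmus) return(NULL)
    geo <- evaluate_surrogate(surrogate, Q, V)
    gl <- muscle_linear_gains(model, geo)
    list(geo = geo, gain = gl$gain, passive = gl$passive)
  }

  # constraint residuals, stacked: q/v/a/m defects then dynamics; also
  # returns pieces reused by the Jacobian
  constraints <- function(z) {
    st <- unpack(z)
    defq <- rbind(D[1, 1] * st$Qn + D[1, 2] * st$Q[odd, , drop = FALSE] +
                    D[1, 3] * st$Q[even, , drop = FALSE] -
                    h * st$V[odd, , drop = FALSE],
                  D[2, 1] * st$Qn + D[2, 2] * st$Q[odd, , drop = FALSE] +
                    D[2, 3] * st$Q[even, , drop = FALSE] -
                    h * st$V[even, , drop = FALSE])
    defv <- rbind(D[1, 1] * st$Vn + D[1, 2] * st$V[odd, , drop = FALSE] +
                    D[1, 3] * st$V[even, , drop = FALSE] -
                    h * st$W[odd, , drop = FALSE],
                  D[2, 1] * st$Vn + D[2, 2] * st$V[odd, , drop = FALSE] +
                    D[2, 3] * st$V[even, , drop = FALSE] -
                    h * st$W[even, , drop = FALSE]) * v_scale
    out <- c(defq, defv)
    fa <- NULL; fm <- NULL
    if (nmus) {
      fa <- activation_dynamics(st$E, st$A,
                                matrix(mus_tau_a, M, nmus, byrow = TRUE),
                                matrix(mus_tau_d, M, nmus, byrow = TRUE))
      defa <- rbind(D[1, 1] * st$An + D[1, 2] * st$A[odd, , drop = FALSE] +
                      D[1, 3] * st$A[even, , drop = FALSE] -
                      h * fa[odd, , drop = FALSE],
                    D[2, 1] * st$An + D[2, 2] * st$A[odd, , drop = FALSE] +
                      D[2, 3] * st$A[even, , drop = FALSE] -
                      h * fa[even, , drop = FALSE])
      out <- c(out, defa)
    }
    if (nmot) {
      fmv <- sweep(sweep(st$U, 2, mot_max, `*`) - st$Mm, 2, mot_tau, `/`)
      defm <- rbind(D[1, 1] * st$Mn + D[1, 2] * st$Mm[odd, , drop = FALSE] +
                      D[1, 3] * st$Mm[even, , drop = FALSE] -
                      h * fmv[odd, , drop = FALSE],
                    D[2, 1] * st$Mn + D[2, 2] * st$Mm[odd, , drop = FALSE] +
                      D[2, 3] * st$Mm[even, , drop = FALSE] -
                      h * fmv[even, , drop = FALSE]) / max(mot_max, 1)
      out <- c(out, defm)
    }
    Sd <- dyn_residual(st$Q, st$V, st$W)
    mp <- muscle_tau_parts(st$Q, st$V)
    if (nmus) {
      tmus <- matrix(0, M, nq)
      for (m in seq_len(nmus)) {
        f <- mp$gain[, m] * st$A[, m] + mp$passive[, m]
        tmus <- tmus + mp$geo$moment_arms[, , m] * f
      }
      Sd <- Sd - tmus / dyn_scale
    }
    if (nmot) {
      for (j in seq_len(nmot)) {
        Sd[, mot_cix[j]] <- Sd[, mot_cix[j]] - st$Mm[, j] / dyn_scale
      }
    }
    list(c = c(out, Sd), st = st, mp = mp, fa = fa, Sd = Sd, Sd_act = Sd)
  }

  # cost residuals (weighted, sqrt form); Radau quadrature weight per stage
  stage_b <- numeric(M); stage_b[odd] <- b[1]; stage_b[even] <- b[2]
  cost_resid <- function(st) {
    r <- c(sqrt(h * stage_b * weights$w3) * (st$Q - Qref),
           sqrt(h * stage_b * weights$w4) * (st$V - Vref),
           sqrt(h * stage_b * weights$w5) * (st$W - Wref))
    if (nmus) r <- c(r, sqrt(h * stage_b * weights$w1) * st$A,
                     sqrt(h * stage_b * weights$wp) * st$E)
    if (nmot) r <- c(r, sqrt(h * stage_b * weights$w2) * st$U)
    r
  }

  # ---- Jacobian assembly -------------------------------------------------
  off <- 2 * M * nq
  rows_defa <- if (nmus) off + seq_len(M * nmus) else integer(0)
  off <- off + length(rows_defa)
  rows_defm <- if (nmot) off + seq_len(M * nmot) else integer(0)
  off <- off + length(rows_defm)
  rows_dyn <- off + seq_len(M * nq)
  n_con <- off + M * nq

  # helper: triplets of D-structure defect rows for a state block
  def_triplets <- function(row_base, node_mat, stage_mat, nvar, scale) {
    # rows ordered: stage-major within odd block then even block, matching
    # rbind(odd_defects, even_defects) with column-major vectorization
    rows_odd <- row_base + as.vector(outer(seq_len(N), (seq_len(nvar) - 1) * 2 * N,
                                           function(i, o) i + o))
    rows_even <- row_base + as.vector(outer(N + seq_len(N),
                                            (seq_len(nvar) - 1) * 2 * N,
                                            function(i, o) i + o))
    list(
      i = c(rows_odd, rows_odd, rows_odd,
            rows_even, rows_even, rows_even),
      j = c(c(node_mat), c(stage_mat[odd, , drop = FALSE]),
            c(stage_mat[even, , drop = FALSE]),
            c(node_mat), c(stage_mat[odd, , drop = FALSE]),
            c(stage_mat[even, , drop = FALSE])),
      x = c(rep(D[1, 1] * scale, N * nvar), rep(D[1, 2] * scale, N * nvar),
            rep(D[1, 3] * scale, N * nvar),
            rep(D[2, 1] * scale, N * nvar), rep(D[2, 2] * scale, N * nvar),
            rep(D[2, 3] * scale, N * nvar)),
      rows_odd = rows_odd, rows_even = rows_even
    )
  }
  tq <- def_triplets(0, nqix, ix$q, nq, 1)
  tv <- def_triplets(M * nq, nvix, ix$v, nq, v_scale)
  ta <- if (nmus) def_triplets(2 * M * nq, naix, ix$a, nmus, 1) else NULL
  tm <- if (nmot) def_triplets(2 * M * nq + length(rows_defa), nmix, ix$m,
                               nmot, 1 / max(mot_max, 1)) else NULL
  # map stage-ordered (M x nvar) entries to defect row ids (stage s, var j)
  stage_rows <- function(tt, nvar) {
    rows <- matrix(0L, M, nvar)
    rows[odd, ] <- matrix(tt$rows_odd, N, nvar)
    rows[even, ] <- matrix(tt$rows_even, N, nvar)
    rows
  }
  rows_defq_stage <- stage_rows(tq, nq)
  rows_defv_stage <- stage_rows(tv, nq)
  rows_defa_stage <- if (nmus) stage_rows(ta, nmus) else NULL
  rows_defm_stage <- if (nmot) stage_rows(tm, nmot) else NULL
  rows_dyn_stage <- matrix(rows_dyn, M, nq)

  con_jacobian <- function(z, cs) {
    st <- cs$st
    trip_i <- c(tq$i, tv$i); trip_j <- c(tq$j, tv$j); trip_x <- c(tq$x, tv$x)
    # -h * v_stage in q defects; -h * w_stage in v defects
    trip_i <- c(trip_i, c(rows_defq_stage), c(rows_defv_stage))
    trip_j <- c(trip_j, c(ix$v), c(ix$w))
    trip_x <- c(trip_x, rep(-h, M * nq), rep(-h * v_scale, M * nq))
    if (nmus) {
      jac <- activation_dynamics_jac(st$E, st$A,
                                     matrix(mus_tau_a, M, nmus, byrow = TRUE),
                                     matrix(mus_tau_d, M, nmus, byrow = TRUE))
      trip_i <- c(trip_i, ta$i, c(rows_defa_stage), c(rows_defa_stage))
      trip_j <- c(trip_j, ta$j, c(ix$a), c(ix$e))
      trip_x <- c(trip_x, ta$x, -h * c(jac$dfda), -h * c(jac$dfde))
    }
    if (nmot) {
      sc <- 1 / max(mot_max, 1)
      trip_i <- c(trip_i, tm$i, c(rows_defm_stage), c(rows_defm_stage))
      trip_j <- c(trip_j, tm$j, c(ix$m), c(ix$u))
      trip_x <- c(trip_x, tm$x,
                  rep(h / mot_tau * sc, each = M) * rep(1, M * nmot),
                  rep(-h * mot_max / mot_tau * sc, each = M))
    }
    # dynamics block: FD over q, v, w at each stage (block-diagonal), and
    # analytic in a and m
    fd_h <- 1e-6
    eval_S <- function(Qp, Vp, Wp, reuse_mp) {
      Sp <- dyn_residual(Qp, Vp, Wp)
      if (nmus) {
        mp <- if (reuse_mp) cs$mp else muscle_tau_parts(Qp, Vp)
        tmus <- matrix(0, M, nq)
        for (m in seq_len(nmus)) {
          f <- mp$gain[, m] * st$A[, m] + mp$passive[, m]
          tmus <- tmus + mp$geo$moment_arms[, , m] * f
        }
        Sp <- Sp - tmus / dyn_scale
      }
      if (nmot) {
        for (j in seq_len(nmot)) {
          Sp[, mot_cix[j]] <- Sp[, mot_cix[j]] - st$Mm[, j] / dyn_scale
        }
      }
      Sp
    }
    for (grp in list(list(mat = "Q", cols = ix$q),
                     list(mat = "V", cols = ix$v),
                     list(mat = "W", cols = ix$w))) {
      for (jq in seq_len(nq)) {
        # q columns use central differences: the compliant contact force has
        # a large curvature near touchdown and forward differences are too
        # biased there. The residual is linear in the accelerations (mass
        # matrix) and nearly linear in the velocities (damping), so forward
        # differences are exact or adequate for those groups.
        Qp <- st$Q; Vp <- st$V; Wp <- st$W
        if (grp$mat == "Q") {
          Qm <- st$Q
          Qp[, jq] <- Qp[, jq] + fd_h
          Qm[, jq] <- Qm[, jq] - fd_h
          dS <- (eval_S(Qp, st$V, st$W, FALSE) -
                   eval_S(Qm, st$V, st$W, FALSE)) / (2 * fd_h)
        } else {
          if (grp$mat == "V") Vp[, jq] <- Vp[, jq] + fd_h
          if (grp$mat == "W") Wp[, jq] <- Wp[, jq] + fd_h
          reuse <- grp$mat == "W"
          dS <- (eval_S(Qp, Vp, Wp, reuse) - cs$Sd_act) / fd_h
        }
        # M x nq block for this column group
        nzr <- which(abs(dS) > 1e-12, arr.ind = TRUE)
        if (nrow(nzr)) {
          trip_i <- c(trip_i, rows_dyn_stage[cbind(nzr[, 1], nzr[, 2])])
          trip_j <- c(trip_j, grp$cols[cbind(nzr[, 1], rep(jq, nrow(nzr)))])
          trip_x <- c(trip_x, dS[nzr])
        }
      }
    }
    if (nmus) {
      for (m in seq_len(nmus)) {
        dd <- -(cs$mp$geo$moment_arms[, , m] * cs$mp$gain[, m]) / dyn_scale
        nzr <- which(abs(dd) > 1e-12, arr.ind = TRUE)
        if (nrow(nzr)) {
          trip_i <- c(trip_i, rows_dyn_stage[cbind(nzr[, 1], nzr[, 2])])
          trip_j <- c(trip_j, ix$a[cbind(nzr[, 1], rep(m, nrow(nzr)))])
          trip_x <- c(trip_x, dd[nzr])
        }
      }
    }
    if (nmot) {
      for (j in seq_len(nmot)) {
        trip_i <- c(trip_i, rows_dyn_stage[, mot_cix[j]])
        trip_j <- c(trip_j, ix$m[, j])
        trip_x <- c(trip_x, rep(-1 / dyn_scale, M))
      }
    }
    Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                         dims = c(n_con, nz))
  }

  # cost Jacobian: constant diagonal-ish structure
  cost_jacobian <- function() {
    i <- integer(0); j <- integer(0); x <- numeric(0)
    add <- function(cols, wvec) {
      k <- length(i)
      ii <- k + seq_len(length(cols))
      list(i = ii, j = c(cols), x = wvec)
    }
    nrows <- 0
    blocks <- list(list(cols = ix$q, w = weights$w3),
                   list(cols = ix$v, w = weights$w4),
                   list(cols = ix$w, w = weights$w5))
    if (nmus) blocks <- c(blocks, list(list(cols = ix$a, w = weights$w1),
                                       list(cols = ix$e, w = weights$wp)))
    if (nmot) blocks <- c(blocks, list(list(cols = ix$u, w = weights$w2)))
    for (blk in blocks) {
      nv <- ncol(blk$cols)
      sc <- rep(sqrt(h * stage_b * blk$w), nv)
      i <- c(i, nrows + seq_len(M * nv))
      j <- c(j, c(blk$cols))
      x <- c(x, sc)
      nrows <- nrows + M * nv
    }
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nrows, nz))
  }
  Jcost <- cost_jacobian()

  # ---- initialization ----------------------------------------------------
  z <- numeric(nz)
  z[ix$q0] <- ref0$q; z[ix$v0] <- ref0$v
  z[c(ix$q)] <- Qref; z[c(ix$v)] <- Vref; z[c(ix$w)] <- Wref
  req0 <- dyn_residual(Qref, Vref, Wref) * dyn_scale
  if (nmus) {
    so <- static_optimization(model,
                              list(times = stage_t, q = Qref, qd = Vref,
                                   qdd = Wref),
                              req0, surrogate = surrogate,
                              control = list(maxit = 150, factr = 1e6))
    z[c(ix$a)] <- pmin(pmax(so$activations, 1e-3), 0.99)
    z[c(ix$e)] <- z[c(ix$a)]
    z[ix$a0] <- pmin(pmax(so$activations[1, ], 1e-3), 0.99)
    if (nmot) {
      z[c(ix$u)] <- pmin(pmax(sweep(so$reserves, 2, mot_max, `/`), -1), 1)
      z[c(ix$m)] <- so$reserves
      z[ix$m0] <- so$reserves[1, ]
    }
  } else if (nmot) {
    mm <- matrix(0, M, nmot)
    for (j in seq_len(nmot)) mm[, j] <- req0[, mot_cix[j]]
    mm <- sweep(mm, 2, mot_max, function(a, b) pmin(pmax(a, -b), b))
    z[c(ix$m)] <- mm
    z[c(ix$u)] <- sweep(mm, 2, mot_max, `/`)
    z[ix$m0] <- mm[1, ]
  }
  z <- pmin(pmax(z, lo), up)

  if (isTRUE(settings$debug)) return(environment())

  # ---- penalty-continuation Levenberg-Marquardt --------------------------
  # The equality-constrained sparse NLLS is solved by minimizing
  # ||r_cost||^2 + mu ||c||^2 over a geometric ladder of penalty weights mu,
  # warm-starting each stage; steps come from Jacobi-scaled damped normal
  # equations with Nielsen gain-ratio adaptation of the damping. The stiff
  # compliant-contact columns make the unscaled normal equations too
  # ill-conditioned to use directly.
  cs <- constraints(z)
  mu <- settings$mu0
  target <- settings$tol * 0.1
  lambda_lm <- 1e-3
  nu <- 2
  total_iter <- 0
  max_total <- settings$max_outer * settings$max_inner
  status <- "max_iterations"
  repeat {
    merit_val <- function(csx, stx) {
      sum(cost_resid(stx)^2) + mu * sum(csx^2)
    }
    Fz <- merit_val(cs$c, cs$st)
    cmax_hist <- max(abs(cs$c))
    for (inner in seq_len(settings$max_inner)) {
      total_iter <- total_iter + 1
      Jc <- con_jacobian(z, cs)
      J <- rbind(Jcost, sqrt(mu) * Jc)
      r <- c(cost_resid(cs$st), sqrt(mu) * cs$c)
      g <- as.vector(Matrix::crossprod(J, r))
      A <- Matrix::crossprod(J)
      dsc <- 1 / sqrt(pmax(Matrix::diag(A), 1e-10))
      # freeze variables pinned at a bound with the gradient pushing outward,
      # so projection cannot shear the remaining step
      active <- (z <= lo + 1e-12 & g > 0) | (z >= up - 1e-12 & g < 0)
      mask <- as.numeric(!active)
      Ds <- Matrix::Diagonal(nz, dsc * mask)
      As <- Ds %*% A %*% Ds + Matrix::Diagonal(nz, as.numeric(active))
      gs <- dsc * g * mask
      accepted <- FALSE
      for (try in 1:12) {
        fac <- tryCatch(Matrix::Cholesky(
          methods::as(As + lambda_lm * Matrix::Diagonal(nz, mask),
                      "symmetricMatrix"), LDL = FALSE),
          error = function(e2) NULL)
        if (is.null(fac)) { lambda_lm <- lambda_lm * 4; nu <- 2 * nu; next }
        y <- as.vector(Matrix::solve(fac, -gs))
        delta <- dsc * y * mask
        # backtracking line search: the compliant-contact valley is narrow
        # and full Gauss-Newton steps regularly overshoot it
        for (alpha in 2^-(0:6)) {
          z_new <- pmin(pmax(z + alpha * delta, lo), up)
          cs_new <- constraints(z_new)
          F_new <- merit_val(cs_new$c, cs_new$st)
          if (is.finite(F_new) && F_new < Fz) break
        }
        pred <- sum((r + as.vector(J %*% (z_new - z)))^2)
        rho <- (Fz - F_new) / max(Fz - pred, 1e-300)
        if (is.finite(F_new) && F_new < Fz) {
          z <- z_new; cs <- cs_new; Fz <- F_new
          if (alpha == 1) {
            lambda_lm <- lambda_lm * max(1 / 3, 1 - (2 * rho - 1)^3)
          } else if (alpha < 0.2) {
            lambda_lm <- lambda_lm * 3
          }
          nu <- 2
          accepted <- TRUE
          # chord refinements: reuse the factorization with fresh residuals
          for (chord in 1:12) {
            r2 <- c(cost_resid(cs$st), sqrt(mu) * cs$c)
            g2 <- as.vector(Matrix::crossprod(J, r2))
            y2 <- as.vector(Matrix::solve(fac, -(dsc * g2 * mask)))
            d2 <- dsc * y2 * mask
            improved2 <- FALSE
            for (alpha2 in c(1, 0.5, 0.25, 0.1)) {
              z2 <- pmin(pmax(z + alpha2 * d2, lo), up)
              cs2 <- constraints(z2)
              F2 <- merit_val(cs2$c, cs2$st)
              if (is.finite(F2) && F2 < Fz) {
                z <- z2; cs <- cs2; Fz <- F2
                improved2 <- TRUE
                break
              }
            }
            if (!improved2) break
          }
          break
        }
        lambda_lm <- lambda_lm * nu
        nu <- 2 * nu
      }
      if (!accepted) break
      if (max(abs(cs$c)) < target) break
      if (sqrt(sum(delta^2)) < 1e-9 * (1 + sqrt(sum(z^2)))) break
      if (total_iter >= max_total) break
      # advance the penalty once constraint progress stagnates at this mu
      cmax_hist <- c(cmax_hist, max(abs(cs$c)))
      nh <- length(cmax_hist)
      if (nh >= 6 && cmax_hist[nh] > 0.5 * cmax_hist[nh - 5]) break
    }
    cmax <- max(abs(cs$c))
    if (settings$verbose) {
      message(sprintf("mu %.1e: max|c| = %.3e, merit = %.6e (%d iters)",
                      mu, cmax, Fz, inner))
    }
    if (cmax < target || total_iter >= max_total ||
        mu >= settings$mu_max) break
    mu <- mu * settings$mu_ratio
    lambda_lm <- max(lambda_lm, 1e-5)
    nu <- 2
  }
  cmax <- max(abs(cs$c))
  if (cmax < settings$tol) status <- "converged"

  # ---- package the solution ---------------------------------------------
  # the end-of-interval stages form a uniform grid (spacing h); they are the
  # public trajectory, while all collocation-point data stay available
  st <- cs$st
  fk <- fk_states(model, st$Q, st$V, st$W)
  con <- contact_generalized_forces(model, fk)
  grf_all <- summarize_grf(model, con, stage_t)
  moments_all <- extract_moments_internal(model, surrogate, st, mot_cix)
  sel <- even
  colnames(st$Q) <- colnames(st$V) <- colnames(st$W) <-
    model$coordinates$name
  if (!is.null(st$A)) colnames(st$A) <- colnames(st$E) <-
    vapply(model$muscles, `[[`, character(1), "name")
  if (!is.null(st$Mm)) colnames(st$Mm) <- colnames(st$U) <-
    vapply(model$torque_motors, `[[`, character(1), "name")
  grf <- if (!is.null(grf_all)) {
    dplyr::filter(grf_all, .data$time %in% stage_t[sel])
  } else NULL
  moments <- moments_all[sel, , drop = FALSE]
  cost_terms <- list(
    activations = sum((sqrt(h * stage_b * weights$w1) *
                         (st$A %||% 0))^2),
    motor_excitations = sum((sqrt(h * stage_b * weights$w2) *
                               (st$U %||% 0))^2),
    position_tracking = sum((sqrt(h * stage_b * weights$w3) *
                               (st$Q - Qref))^2),
    velocity_tracking = sum((sqrt(h * stage_b * weights$w4) *
                               (st$V - Vref))^2),
    acceleration_tracking = sum((sqrt(h * stage_b * weights$w5) *
                                   (st$W - Wref))^2),
    control_penalty = sum((sqrt(h * stage_b * weights$wp) *
                             (st$E %||% 0))^2))
  structure(list(
    times = stage_t[sel],
    trajectory = coordinate_trajectory(stage_t[sel],
                                       st$Q[sel, , drop = FALSE],
                                       st$V[sel, , drop = FALSE],
                                       st$W[sel, , drop = FALSE]),
    activations = if (!is.null(st$A)) st$A[sel, , drop = FALSE],
    excitations = if (!is.null(st$E)) st$E[sel, , drop = FALSE],
    motor_torques = if (!is.null(st$Mm)) st$Mm[sel, , drop = FALSE],
    motor_excitations = if (!is.null(st$U)) st$U[sel, , drop = FALSE],
    qdd = st$W[sel, , drop = FALSE],
    collocation = list(times = stage_t, Q = st$Q, V = st$V, W = st$W,
                       A = st$A, E = st$E, Mm = st$Mm, U = st$U,
                       grf = grf_all, moments = moments_all),
    grf = grf, joint_moments = moments,
    cost = sum(unlist(cost_terms)), cost_terms = cost_terms,
    constraint_max = cmax, status = status,
    weights = weights, mesh = list(N = N, h = h),
    model_name = model$name, surrogate = surrogate,
    reference = reference
  ), class = "tracking_solution")
}

activation_dynamics_jac <- function(e, a, tau_act, tau_deact, smoothing = 10) {
  d <- e - a
  s <- 0.5 + 0.5 * tanh(smoothing * d)
  ds <- 0.5 * smoothing * (1 - tanh(smoothing * d)^2)
  rate <- s / tau_act + (1 - s) / tau_deact
  drate <- ds * (1 / tau_act - 1 / tau_deact)
  list(dfde = rate + d * drate, dfda = -(rate + d * drate))
}

# per-foot GRF and center of pressure from the contact summary
summarize_grf <- function(model, con, times) {
  if (!length(con$forces)) return(NULL)
  segs <- unique(vapply(con$forces, `[[`, character(1), "segment"))
  out <- list()
  for (sg in segs) {
    fs <- con$forces[vapply(con$forces, `[[`, character(1), "segment") == sg]
    Ft <- Reduce(`+`, lapply(fs, `[[`, "force"))
    wsum <- Reduce(`+`, lapply(fs, function(f) pmax(f$force[, 2], 1e-9)))
    cop <- Reduce(`+`, lapply(fs, function(f)
      f$point * pmax(f$force[, 2], 1e-9))) / wsum
    side <- if (grepl("_r$", sg)) "right" else if (grepl("_l$", sg)) "left"
            else sg
    out[[length(out) + 1]] <- tibble::tibble(
      time = times, foot = side,
      fx = Ft[, 1], fy = Ft[, 2], fz = Ft[, 3],
      cop_x = cop[, 1], cop_z = cop[, 3])
  }
  dplyr::bind_rows(out)
}

extract_moments_internal <- function(model, surrogate, st, mot_cix) {
  nq <- model$n_coordinates
  M <- nrow(st$Q)
  mom <- matrix(0, M, nq, dimnames = list(NULL, model$coordinates$name))
  if (!is.null(st$A)) {
    geo <- evaluate_surrogate(surrogate, st$Q, st$V)
    gl <- muscle_linear_gains(model, geo)
    for (m in seq_len(ncol(st$A))) {
      f <- gl$gain[, m] * st$A[, m] + gl$passive[, m]
      mom <- mom + geo$moment_arms[, , m] * f
    }
  }
  if (!is.null(st$Mm)) {
    for (j in seq_len(ncol(st$Mm))) {
      mom[, mot_cix[j]] <- mom[, mot_cix[j]] + st$Mm[, j]
    }
  }
  mom
}

#' Joint moments realized by a tracking solution
#'
#' Per coordinate, the sum of muscle-force times moment-arm contributions
#' and torque-motor outputs; at convergence this equals the inverse-dynamics
#' generalized force of the solution's own kinematics and contact forces
#' within the solver tolerance.
#'
#' @param solution A `tracking_solution`.
#' @param model The `skeletal_model` the solution was computed on.
#' @return `frames x nq` matrix of moments (N·m | N).
#' @export
extract_joint_moments <- function(solution, model) {
  mot_coord <- vapply(model$torque_motors, `[[`, character(1), "coordinate")
  mot_cix <- match(mot_coord, model$coordinates$name)
  st <- list(Q = solution$trajectory$q, V = solution$trajectory$qd,
             A = solution$activations, Mm = solution$motor_torques)
  extract_moments_internal(model, solution$surrogate, st, mot_cix)
}

#' @export
print.tracking_solution <- function(x, ...) {
  cat("<tracking_solution>", x$model_name, "-", length(x$times),
      "collocation points,", x$status,
      sprintf("(max constraint %.2e, cost %.4g)\n", x$constraint_max, x$cost))
  invisible(x)
}

#' @export
glance.tracking_solution <- function(x, ...) {
  tibble::tibble(status = x$status, cost = x$cost,
                 constraint_max = x$constraint_max,
                 n_points = length(x$times),
                 mesh_intervals = x$mesh$N,
                 position_cost = x$cost_terms$position_tracking,
                 activation_cost = x$cost_terms$activations)
}

#' @export
tidy.tracking_solution <- function(x, ...) {
  out <- tidy(x$trajectory)
  out
}

#' Plot the ground reaction forces of a tracking solution
#' @param object A `tracking_solution`.
#' @param ... Unused.
#' @export
autoplot.tracking_solution <- function(object, ...) {
  if (is.null(object$grf)) {
    return(autoplot(object$trajectory))
  }
  df <- tidyr::pivot_longer(object$grf, cols = c("fx", "fy", "fz"),
                            names_to = "component", values_to = "force")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$force,
                                   color = .data$foot)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "ground reaction force (N)")
}

# inverse dynamics from a precomputed kinematic pass (no external forces)
inverse_dynamics_from_fk <- function(model, fk) {
  inverse_dynamics_core(model, fk, external = list())
}
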