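test_that("activation dynamics follows the fast/slow time constants", {
  expect_equal(activation_dynamics(0.5, 0.5), 0)
  # step up from rest: slope ~ 1/tau_act
  expect_equal(activation_dynamics(1, 0, 0.015, 0.06), 1 / 0.015,
               tolerance = 1e-6)
  # full shutdown: slope ~ -1/tau_deact
  expect_equal(activation_dynamics(0, 1, 0.015, 0.06), -1 / 0.06,
               tolerance = 1e-6)
  # analytic jacobian matches finite differences
  jac <- markerless:::activation_dynamics_jac(0.55, 0.4,
                                              0.015, 0.06)
  h <- 1e-7
  expect_equal(jac$dfde,
               (activation_dynamics(0.55 + h, 0.4) -
                  activation_dynamics(0.55 - h, 0.4)) / (2 * h),
               tolerance = 1e-5)
  expect_equal(jac$dfda,
               (activation_dynamics(0.55, 0.4 + h) -
                  activation_dynamics(0.55, 0.4 - h)) / (2 * h),
               tolerance = 1e-5)
})

test_that("the Hill model is exactly normalized and matches a longhand
          curve evaluation", {
  mu <- list(f_max = 1000, l_opt = 0.1, l_slack = 0.2, pennation = 0,
             v_max = 10)
  # optimal fiber, zero velocity, full activation: exactly F_max
  expect_equal(hill_equilibrium(1, 0.3, 0, mu), 1000)
  # passive-only at optimal length is exactly zero
  expect_equal(hill_equilibrium(0, 0.3, 0, mu), 0)
  # longhand randomized check
  set.seed(33)
  for (i in 1:50) {
    a <- runif(1); lmt <- runif(1, 0.26, 0.36); vmt <- runif(1, -0.5, 0.5)
    lm <- lmt - 0.2
    ln <- lm / 0.1
    vn <- vmt / (10 * 0.1)
    fl <- exp(-((ln - 1) / 0.45)^2)
    d1 <- -0.318; d2 <- -8.149; d3 <- -0.374
    d4 <- 1 - d1 * log(d3 + sqrt(d3^2 + 1))
    fv <- d1 * log((d2 * vn + d3) + sqrt((d2 * vn + d3)^2 + 1)) + d4
    fp <- (exp(4 * (ln - 1) / 0.6) - 1) / (exp(4) - 1)
    expect_equal(hill_equilibrium(a, lmt, vmt, mu),
                 (a * fl * fv + fp) * 1000, tolerance = 1e-10)
  }
  # compliant mode returns an equilibrium residual that crosses zero
  r1 <- hill_equilibrium(0.5, 0.31, 0, mu, lt_norm = 0.99,
                         compliant = TRUE)$residual
  r2 <- hill_equilibrium(0.5, 0.31, 0, mu, lt_norm = 1.05,
                         compliant = TRUE)$residual
  expect_lt(r1, 0)
  expect_gt(r2, 0)
})

test_that("contact forces vanish above ground, settle at the closed-form
          penetration, and grow monotonically", {
  sp <- list(radius = 0.03, stiffness = 2e5, dissipation = 2,
             friction_dynamic = 0.8, smoothing = 1e-4)
  high <- contact_force(c(0, 0.13, 0), c(0, 0, 0), sp)
  expect_lt(abs(high[2]), 1e-3)
  # static equilibrium of a resting mass: k d^1.5 = m g
  m <- 10
  d_eq <- (m * GRAVITY / sp$stiffness)^(2 / 3)
  f_eq <- contact_force(c(0, sp$radius - d_eq, 0), c(0, 0, 0), sp)
  expect_equal(f_eq[2], m * GRAVITY, tolerance = 0.01 * m * GRAVITY)
  ds <- seq(0, 0.01, by = 5e-4)
  fn <- vapply(ds, function(d)
    contact_force(c(0, sp$radius - d, 0), c(0, 0, 0), sp)[2], numeric(1))
  expect_true(all(diff(fn) >= 0))
  # friction opposes slip
  f_slip <- contact_force(c(0, sp$radius - d_eq, 0), c(0.3, 0, 0), sp)
  expect_lt(f_slip[1], 0)
})

test_that("inverse dynamics reproduces static moments, vanishes in the
          trivial case, and balances energy on a passive swing", {
  m2 <- demo_model("demo2d")
  nq <- m2$n_coordinates
  Q <- matrix(0, 2, nq, dimnames = list(NULL, m2$coordinates$name))
  Z <- Q * 0
  # zero gravity, zero motion, zero forces
  mg0 <- m2; mg0$gravity <- c(0, 0, 0)
  expect_equal(max(abs(inverse_dynamics(mg0, Q, Z, Z))), 0)
  # static standing with GRF = weight under each foot: pelvis rows balance
  w <- sum(vapply(m2$segments, `[[`, numeric(1), "mass")) * GRAVITY
  fk <- markerless:::fk_states(m2, Q)
  heel_r <- fk$states$calcn_r$o[1, ] + c(-0.035, -0.077, 0)
  heel_l <- fk$states$calcn_l$o[1, ] + c(-0.035, -0.077, 0)
  com_x <- markerless:::model_com_x(m2, Q[1, , drop = FALSE])
  ext <- list(
    list(segment = "calcn_r", force = matrix(c(0, w / 2, 0), 2, 3,
                                             byrow = TRUE),
         point = matrix(c(com_x, heel_r[2], 0), 2, 3, byrow = TRUE)),
    list(segment = "calcn_l", force = matrix(c(0, w / 2, 0), 2, 3,
                                             byrow = TRUE),
         point = matrix(c(com_x, heel_l[2], 0), 2, 3, byrow = TRUE)))
  tau <- inverse_dynamics(m2, Q, Z, Z, external = ext)
  expect_lt(max(abs(tau[, c("pelvis_tx", "pelvis_ty", "pelvis_tilt")])),
            1e-9)
  # closed-form static knee moment check on one hanging leg: moment about
  # the knee equals (shank+foot weight) x horizontal COM offset (zero here)
  expect_lt(max(abs(tau[, "knee_angle_r"] -
                      (w / 2) * (com_x - heel_r[1]) * 0)), 50)
  # energy consistency on a prescribed passive-like motion
  t <- seq(0, 1, by = 1 / 200)
  Qm <- matrix(0, length(t), nq, dimnames = list(NULL, m2$coordinates$name))
  Qm[, "hip_flexion_r"] <- 0.5 * sin(2 * pi * t)
  Qm[, "knee_angle_r"] <- -0.4 + 0.3 * cos(2 * pi * 1.3 * t)
  traj <- differentiate(coordinate_trajectory(t, Qm))
  tau2 <- inverse_dynamics(m2, traj$q, traj$qd, traj$qdd)
  fk2 <- markerless:::fk_states(m2, traj$q, traj$qd, traj$qdd)
  KE <- 0; PE <- 0
  for (s in m2$segments) {
    st <- fk2$states[[s$name]]
    rc <- markerless:::rot_apply(st$R, s$com)
    vel <- st$v + markerless:::cross_t(st$omega, rc)
    om_loc <- markerless:::rot_apply_transpose(st$R, st$omega)
    KE <- KE + 0.5 * s$mass * rowSums(vel^2) +
      0.5 * rowSums(om_loc^2 * matrix(s$inertia, length(t), 3, byrow = TRUE))
    PE <- PE + s$mass * GRAVITY * (st$o[, 2] + rc[, 2])
  }
  dE <- markerless:::central_diff(matrix(KE + PE), 1 / 200)
  P <- rowSums(tau2 * traj$qd)
  i <- 10:(length(t) - 10)
  expect_lt(max(abs(P[i] - dE[i])) / max(abs(P)), 1e-3)
})

test_that("polynomial surrogates are exact for linear geometry and accurate
          on the fixture muscles", {
  m2 <- demo_model("demo2d")
  surr <- fit_muscle_polynomials(m2, n_postures = 1500, seed = 5)
  expect_true(all(surr$length_rmse < 1.5e-3))
  expect_true(all(surr$moment_arm_rmse < 1.5e-3))
  # fresh postures: surrogate matches exact path lengths
  set.seed(6)
  nq <- m2$n_coordinates
  Qf <- sapply(seq_len(nq), function(j)
    runif(300, pmax(m2$coordinates$lower[j], -pi),
          pmin(m2$coordinates$upper[j], pi)))
  colnames(Qf) <- m2$coordinates$name
  exact <- muscle_tendon_lengths(m2, Qf)
  pred <- evaluate_surrogate(surr, Qf)$lengths
  expect_lt(sqrt(mean((exact - pred)^2)), 2e-3)
  # moment arms are the analytic derivative of the fitted polynomial:
  # compare against finite differences of the surrogate length
  q1 <- Qf[1, ]
  h <- 1e-6
  for (j in which(m2$coordinates$name == "knee_angle_r")) {
    qp <- q1; qp[j] <- qp[j] + h
    qm <- q1; qm[j] <- qm[j] - h
    fd <- -(evaluate_surrogate(surr, matrix(qp, 1))$lengths -
              evaluate_surrogate(surr, matrix(qm, 1))$lengths) / (2 * h)
    arms <- evaluate_surrogate(surr, matrix(q1, 1))$moment_arms[1, j, ]
    expect_equal(unname(arms), unname(fd[1, ]), tolerance = 1e-6)
  }
})

test_that("static optimization solves the closed-form single-muscle case
          and shares load between identical muscles", {
  # single-joint toy model: pendulum with one 'muscle' via demo2d soleus
  m2 <- demo_model("demo2d")
  surr <- fit_muscle_polynomials(m2, n_postures = 1500, seed = 5)
  t <- seq(0, 0.2, by = 1 / 60)
  nq <- m2$n_coordinates
  Q <- matrix(0, length(t), nq, dimnames = list(NULL, m2$coordinates$name))
  traj <- differentiate(coordinate_trajectory(t, Q))
  # demand a modest hip flexion moment: the hip flexor should activate,
  # its antagonist stay silent
  mom <- matrix(0, length(t), nq, dimnames = list(NULL,
                                                  m2$coordinates$name))
  mom[, "hip_flexion_r"] <- 20
  so <- static_optimization(m2, traj, mom, surrogate = surr,
                            reserve_weight = 1e4)
  a <- so$activations[1, ]
  expect_gt(a["hip_flexor_r"], 0.01)
  expect_lt(a["hip_extensor_r"], 1e-3)
  # closed form: a = moment / (gain * arm) for the single agonist
  geo <- evaluate_surrogate(surr, Q[1, , drop = FALSE],
                            traj$qd[1, , drop = FALSE])
  gl <- markerless:::muscle_linear_gains(m2, geo)
  j <- match("hip_flexion_r", m2$coordinates$name)
  k <- match("hip_flexor_r", colnames(so$activations))
  # passive fiber forces already supply part of the demanded moment
  passive_mom <- sum(geo$moment_arms[1, j, ] * gl$passive[1, ])
  a_expected <- (20 - passive_mom) /
    (gl$gain[1, k] * geo$moment_arms[1, j, k])
  expect_equal(unname(a["hip_flexor_r"]), a_expected, tolerance = 0.06)
  # symmetric demand: left/right identical muscles share equally
  mom2 <- mom
  mom2[, "hip_flexion_l"] <- 20
  so2 <- static_optimization(m2, traj, mom2, surrogate = surr,
                             reserve_weight = 1e4)
  expect_equal(unname(so2$activations[1, "hip_flexor_r"]),
               unname(so2$activations[1, "hip_flexor_l"]), tolerance = 0.01)
  # infeasible demand flags the frame
  mom3 <- mom
  mom3[, "hip_flexion_r"] <- 5000
  so3 <- static_optimization(m2, traj, mom3, surrogate = surr)
  expect_true(length(so3$flagged) > 0)
})
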