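# Kinematic chain, polyline geometry and rigid-tendon Hill mechanics.

test_that("tendon-excursion moment arms match a finite-difference oracle on independent kinematics", {
  model <- toy_model_fx(0L)
  cn <- names(zero_q(model))
  set.seed(11)
  for (rep in 1:4) {
    q <- setNames(runif(length(cn), -0.5, 0.5), cn)
    g <- musculotendon_geometry(model, q)
    # oracle: central differences of an independently coded polyline length
    h <- 1e-6
    for (j in cn) {
      qp <- q; qp[j] <- q[j] + h
      qm <- q; qm[j] <- q[j] - h
      for (mu in names(model$muscles)) {
        r_oracle <- -(oracle_muscle_length(model, qp, mu) -
                        oracle_muscle_length(model, qm, mu)) / (2 * h)
        expect_lt(abs(g$moment_arms[mu, j] - r_oracle), 1e-8)
      }
    }
    # lengths agree with the brute-force polyline oracle
    for (mu in names(model$muscles))
      expect_equal(unname(g$lengths[mu]),
                   oracle_muscle_length(model, q, mu), tolerance = 1e-12)
  }
})

test_that("muscles not spanning a joint have exactly zero moment arm, including an axis-collinear path", {
  model <- toy_model_fx(0L)
  q <- zero_q(model)
  g <- musculotendon_geometry(model, q)
  # uniarticular ankle muscles cannot act at the hip
  expect_identical(unname(g$moment_arms["soleus", "hip_flexion"]), 0)
  expect_identical(unname(g$moment_arms["tibialis", "knee_flexion"]), 0)

  # two-point muscle with both endpoints on the hinge axis: spanning but
  # zero excursion
  mini <- mini_model()
  mini$muscles$flexor$path[[1]] <- list(segment = "base",
                                        location = c(0, -0.1, 0.05),
                                        role = "origin")
  mini$muscles$flexor$path[[2]] <- list(segment = "arm",
                                        location = c(0, 0, -0.05),
                                        role = "insertion")
  g2 <- musculotendon_geometry(mini, c(elbow = 0.3))
  expect_lt(abs(g2$moment_arms["flexor", "elbow"]), 1e-12)
})

test_that("posture outside coordinate ranges and unresolved references are rejected", {
  model <- toy_model_fx(0L)
  q <- zero_q(model)
  q["knee_flexion"] <- 3
  expect_error(musculotendon_geometry(model, q), class = "capgap_domain_error")
  bad <- model
  bad$muscles$soleus$path[[1]]$segment <- "nonexistent"
  expect_error(validate_model(bad), class = "capgap_model_error")
})

test_that("rigid-tendon fiber state is the exact algebraic map and rejects infeasible geometry", {
  act <- list(name = "x", l_ts = 0.20, l_mo = 0.10, alpha = 0)
  fs <- fiber_state(0.30, act)
  expect_equal(fs$l, 0.10)
  expect_equal(fs$l_norm, 1.0)
  # optimal-length identity with pennation
  act2 <- list(name = "x", l_ts = 0.15, l_mo = 0.09, alpha = 0.2)
  expect_equal(fiber_state(0.15 + 0.09 * cos(0.2), act2)$l_norm, 1,
               tolerance = 1e-14)
  # randomized formula oracle
  set.seed(7)
  for (i in 1:50) {
    lts <- runif(1, 0.05, 0.3); lmo <- runif(1, 0.04, 0.15)
    al <- runif(1, 0, 0.4); lmt <- lts + runif(1, 0.01, 0.2)
    fs <- fiber_state(lmt, list(name = "x", l_ts = lts, l_mo = lmo,
                                alpha = al))
    expect_equal(fs$l, (lmt - lts) / cos(al), tolerance = 1e-15)
    expect_equal(fs$l_norm, (lmt - lts) / cos(al) / lmo, tolerance = 1e-15)
    # identity l_mt = l_ts + l cos(alpha) holds exactly
    expect_equal(lts + fs$l * cos(al), lmt, tolerance = 1e-15)
  }
  expect_error(fiber_state(0.19, act), class = "capgap_geometry_error")
})

test_that("force-length curves are calibrated: passive half-force near 1.5, active peak at 1", {
  cs <- muscle_curve_set()
  expect_equal(evaluate_curve(cs, "passive", 1.5), 0.5, tolerance = 0.05)
  expect_lte(evaluate_curve(cs, "passive", 1.0), 0.02)
  expect_equal(evaluate_curve(cs, "active", 1.0), 1.0)
  # root of passive = 0.5 found by bisection
  root <- passive_length_at_force(cs, 0.5)
  expect_equal(root, 1.5, tolerance = 0.05)
  expect_equal(evaluate_curve(cs, "passive", root), 0.5, tolerance = 1e-9)
  # active unimodal on [0.4, 1.6] with max at 1
  grid <- seq(0.4, 1.6, by = 0.01)
  fa <- evaluate_curve(cs, "active", grid)
  expect_true(all(fa <= 1 + 1e-12))
  expect_true(all(diff(fa[grid <= 1]) > 0))
  expect_true(all(diff(fa[grid >= 1]) < 0))
  # passive non-negative and non-decreasing on [1, 2]
  fp <- evaluate_curve(cs, "passive", seq(1, 2, by = 0.01))
  expect_true(all(fp >= 0))
  expect_true(all(diff(fp) >= 0))
  expect_error(evaluate_curve(cs, "sideways", 1), class = "capgap_usage_error")
})

test_that("muscle force follows the Hill form for subset M and proportionality for subset N", {
  cs <- muscle_curve_set()
  actN <- list(name = "n", F_max = 100, l_mo = 0.1, l_ts = 0.1, alpha = 0,
               subset = "N")
  expect_equal(muscle_force(actN, cs, 0.3), 30)
  # subset N invariant to fiber parameters
  actN2 <- actN; actN2$l_mo <- 0.5; actN2$l_ts <- 0.01; actN2$alpha <- 0.3
  expect_identical(muscle_force(actN, cs, 0.42), muscle_force(actN2, cs, 0.42))

  actM <- list(name = "m", F_max = 200, l_mo = 0.1, l_ts = 0.1, alpha = 0,
               subset = "M")
  expect_lt(muscle_force(actM, cs, 0, 1.0), 200 * 0.02)
  expect_equal(muscle_force(actM, cs, 0, 1.5),
               200 * evaluate_curve(cs, "passive", 1.5), tolerance = 1e-12)
  expect_equal(muscle_force(actM, cs, 0, 1.5), 100, tolerance = 10)
  expect_equal(muscle_force(actM, cs, 0.5, 1.2),
               200 * (0.5 * evaluate_curve(cs, "active", 1.2) +
                        evaluate_curve(cs, "passive", 1.2)),
               tolerance = 1e-12)
  expect_error(muscle_force(actM, cs, 1.2, 1), class = "capgap_domain_error")
})

test_that("model files round-trip losslessly through YAML", {
  model <- toy_model_fx(0L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(names(back$muscles), names(model$muscles))
  for (mm in names(model$muscles)) {
    for (f in c("F_max", "l_mo", "l_ts", "alpha"))
      expect_equal(back$muscles[[mm]][[f]], model$muscles[[mm]][[f]],
                   tolerance = 1e-12)
    for (k in seq_along(model$muscles[[mm]]$path))
      expect_equal(back$muscles[[mm]]$path[[k]]$location,
                   model$muscles[[mm]]$path[[k]]$location, tolerance = 1e-12)
  }
  for (ss in names(model$segments)) {
    expect_equal(back$segments[[ss]]$joint_center,
                 model$segments[[ss]]$joint_center, tolerance = 1e-12)
    for (lm in names(model$segments[[ss]]$landmarks))
      expect_equal(back$segments[[ss]]$landmarks[[lm]],
                   model$segments[[ss]]$landmarks[[lm]], tolerance = 1e-12)
  }
  for (co in names(model$coordinates))
    expect_equal(back$coordinates[[co]]$range, model$coordinates[[co]]$range,
                 tolerance = 1e-12)
  # geometry identical through the round trip
  q <- zero_q(model)
  expect_equal(musculotendon_geometry(back, q)$lengths,
               musculotendon_geometry(model, q)$lengths, tolerance = 1e-12)
})

test_that("model validation enforces chain and path invariants", {
  model <- toy_model_fx(0L)
  cyc <- model
  cyc$segments$pelvis$parent <- "foot"
  expect_error(validate_model(cyc), class = "capgap_model_error")
  two_origin <- model
  two_origin$muscles$soleus$path[[2]]$role <- "origin"
  expect_error(validate_model(two_origin), class = "capgap_model_error")
  bad_axis <- model
  bad_axis$segments$thigh$joint_axis <- c(0, 0, 2)
  expect_error(validate_model(bad_axis), class = "capgap_model_error")
})
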