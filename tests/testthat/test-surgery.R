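# Virtual surgery operators: osteotomies, transfers, patella advancement,
# strength changes, morphometrics and plans.

thigh_plane <- function() list(point = c(0, -0.20, 0), normal = c(0, 1, 0))

test_that("zero-angle derotation is the identity and opposite rotations invert", {
  model <- toy_model_fx(0L)
  i1 <- suppressWarnings(apply_derotation_osteotomy(model, "thigh",
                                                    thigh_plane(), 0))
  expect_identical(i1$segments$thigh$landmarks, model$segments$thigh$landmarks)
  expect_identical(i1$muscles$gastrocnemius$path,
                   model$muscles$gastrocnemius$path)
  expect_identical(i1$lineage, model$name)
  expect_identical(i1$label, "post-operative")

  d1 <- apply_derotation_osteotomy(model, "thigh", thigh_plane(), 15 * pi / 180)
  d2 <- apply_derotation_osteotomy(d1, "thigh", thigh_plane(), -15 * pi / 180)
  for (lm in names(model$segments$thigh$landmarks))
    expect_equal(d2$segments$thigh$landmarks[[lm]],
                 model$segments$thigh$landmarks[[lm]], tolerance = 1e-10)
  for (k in seq_along(model$muscles$gastrocnemius$path))
    expect_equal(d2$muscles$gastrocnemius$path[[k]]$location,
                 model$muscles$gastrocnemius$path[[k]]$location,
                 tolerance = 1e-10)
  # the input model is never mutated
  expect_identical(model$segments$thigh$landmarks$condyle_medial,
                   toy_model_fx(0L)$segments$thigh$landmarks$condyle_medial)
})

test_that("a long-axis derotation moves distal landmarks by exactly the rotation-matrix prediction", {
  model <- toy_model_fx(0L)
  ang <- 30 * pi / 180
  d <- apply_derotation_osteotomy(model, "thigh", thigh_plane(), ang)
  R <- capgap:::rotation_matrix(c(0, 1, 0), ang)  # rotation about the given normal
  p0 <- c(0, -0.20, 0)
  for (lm in c("condyle_medial", "condyle_lateral", "shaft_distal")) {
    expected <- as.vector(R %*% (model$segments$thigh$landmarks[[lm]] - p0)) + p0
    expect_equal(d$segments$thigh$landmarks[[lm]], expected, tolerance = 1e-12)
  }
  # child joint frame is carried along
  expect_equal(d$segments$shank$joint_center,
               as.vector(R %*% (model$segments$shank$joint_center - p0)) + p0,
               tolerance = 1e-12)
  # rigidity: pairwise distances among co-moving points preserved
  pts_pre <- rbind(model$segments$thigh$landmarks$condyle_medial,
                   model$segments$thigh$landmarks$condyle_lateral,
                   model$segments$thigh$landmarks$shaft_distal)
  pts_post <- rbind(d$segments$thigh$landmarks$condyle_medial,
                    d$segments$thigh$landmarks$condyle_lateral,
                    d$segments$thigh$landmarks$shaft_distal)
  expect_equal(as.vector(dist(pts_pre)), as.vector(dist(pts_post)),
               tolerance = 1e-10)
})

test_that("wedge osteotomy: coincident planes are the identity; the dihedral angle rotates the distal fragment", {
  model <- toy_model_fx(0L)
  pa <- thigh_plane()
  # coincident planes (zero offset, zero dihedral) are the identity
  tz <- apply_extension_derotation_osteotomy(model, "thigh", pa,
                                             list(point = pa$point,
                                                  normal = pa$normal),
                                             "trapezoidal")
  for (lm in names(model$segments$thigh$landmarks))
    expect_equal(tz$segments$thigh$landmarks[[lm]],
                 model$segments$thigh$landmarks[[lm]], tolerance = 1e-12)

  # 20-degree wedge about the knee-transverse (z) axis changes the distal
  # shaft direction by exactly 20 degrees (extension-deficit correction)
  ang <- 20 * pi / 180
  pb <- list(point = c(0, -0.22, 0),
             normal = c(sin(ang), cos(ang), 0))
  w <- apply_extension_derotation_osteotomy(model, "thigh", pa, pb,
                                            "triangular")
  mid <- function(m) (m$segments$thigh$landmarks$condyle_medial +
                        m$segments$thigh$landmarks$condyle_lateral) / 2
  # distal shaft direction in the plane perpendicular to the wedge axis
  v_pre <- mid(model) - model$segments$thigh$landmarks$shaft_distal
  v_post <- mid(w) - w$segments$thigh$landmarks$shaft_distal
  rot_angle <- acos(sum(v_pre * v_post) /
                      sqrt(sum(v_pre^2) * sum(v_post^2)))
  expect_equal(rot_angle, ang, tolerance = 1e-9)
})

test_that("trapezoidal and triangular wedges: rotation equals the dihedral, translation equals the inter-plane offset", {
  model <- toy_model_fx(0L)
  pa <- thigh_plane()
  # trapezoidal: parallel planes 3 cm apart -> pure 3 cm shortening
  pb <- list(point = c(0, -0.23, 0), normal = c(0, 1, 0))
  tz <- apply_extension_derotation_osteotomy(model, "thigh", pa, pb,
                                             "trapezoidal")
  shift <- tz$segments$thigh$landmarks$condyle_medial -
    model$segments$thigh$landmarks$condyle_medial
  expect_equal(shift, c(0, 0.03, 0), tolerance = 1e-12)
  # direction vectors unrotated
  v_pre <- model$segments$thigh$landmarks$condyle_lateral -
    model$segments$thigh$landmarks$condyle_medial
  v_post <- tz$segments$thigh$landmarks$condyle_lateral -
    tz$segments$thigh$landmarks$condyle_medial
  expect_equal(v_post, v_pre, tolerance = 1e-12)
  # shape/plane mismatches are rejected
  expect_error(apply_extension_derotation_osteotomy(model, "thigh", pa, pb,
                                                    "triangular"),
               class = "capgap_config_error")
  ang <- 20 * pi / 180
  pb2 <- list(point = c(0, -0.22, 0), normal = c(sin(ang), cos(ang), 0))
  expect_error(apply_extension_derotation_osteotomy(model, "thigh", pa, pb2,
                                                    "trapezoidal"),
               class = "capgap_config_error")
})

test_that("a muscle path point inside the resection wedge raises an error naming the muscle", {
  model <- toy_model_fx(0L)
  # gastrocnemius origin sits at thigh y = -0.36; cut a wedge around it
  pa <- list(point = c(0, -0.34, 0), normal = c(0, 1, 0))
  pb <- list(point = c(0, -0.38, 0), normal = c(0, 1, 0))
  err <- expect_error(
    apply_extension_derotation_osteotomy(model, "thigh", pa, pb,
                                         "trapezoidal"),
    class = "capgap_surgery_error")
  expect_match(conditionMessage(err), "gastrocnemius")
})

test_that("muscle transfers absorb the length change into the tendon slack length", {
  model <- toy_model_fx(0L)
  # no-op edit
  same <- apply_muscle_transfer(model, "soleus")
  expect_equal(same$muscles$soleus$l_ts, model$muscles$soleus$l_ts,
               tolerance = 1e-15)

  # move the insertion 2 cm distally along the straight line of action:
  # l_ts must grow by exactly 0.02
  q0 <- zero_q(model)
  tr <- capgap:::segment_transforms(model, q0)
  o <- capgap:::point_to_ground(tr, "shank",
                                model$muscles$soleus$path[[1]]$location)
  i <- capgap:::point_to_ground(tr, "foot",
                                model$muscles$soleus$path[[2]]$location)
  u <- (i - o) / sqrt(sum((i - o)^2))
  # at the zero posture every frame is axis-aligned with ground
  new_loc <- model$muscles$soleus$path[[2]]$location + 0.02 * u
  moved <- apply_muscle_transfer(model, "soleus",
                                 list(list(action = "move", index = 2,
                                           location = new_loc)))
  expect_equal(moved$muscles$soleus$l_ts - model$muscles$soleus$l_ts, 0.02,
               tolerance = 1e-10)
  # fiber state at the reference posture is untouched
  ln_pre <- fiber_state(musculotendon_geometry(model, q0)$lengths[["soleus"]],
                        model$muscles$soleus)$l_norm
  ln_post <- fiber_state(musculotendon_geometry(moved, q0)$lengths[["soleus"]],
                         moved$muscles$soleus)$l_norm
  expect_equal(ln_post, ln_pre, tolerance = 1e-10)
})

test_that("the rectus transfer recipe reroutes the insertion while preserving the operating state", {
  model <- toy_model_fx(0L)
  rt <- apply_rectus_transfer(model)
  q0 <- zero_q(model)
  ln_pre <- fiber_state(musculotendon_geometry(model, q0)$lengths[["rectus"]],
                        model$muscles$rectus)$l_norm
  ln_post <- fiber_state(musculotendon_geometry(rt, q0)$lengths[["rectus"]],
                         rt$muscles$rectus)$l_norm
  expect_equal(ln_post, ln_pre, tolerance = 1e-10)
  # insertion moved onto the hamstrings insertion; a thigh via point added
  ins <- rt$muscles$rectus$path[[length(rt$muscles$rectus$path)]]
  ham_ins <- model$muscles$hamstrings$path[[
    length(model$muscles$hamstrings$path)]]
  expect_identical(ins$segment, ham_ins$segment)
  expect_equal(ins$location, ham_ins$location)
  segs <- vapply(rt$muscles$rectus$path, `[[`, "", "segment")
  expect_true("thigh" %in% segs)
  # fiber parameters untouched
  expect_identical(rt$muscles$rectus$l_mo, model$muscles$rectus$l_mo)
  # knee moment arm sign flips from extensor to flexor after the transfer
  g_pre <- musculotendon_geometry(model, q0)$moment_arms["rectus",
                                                         "knee_flexion"]
  g_post <- musculotendon_geometry(rt, q0)$moment_arms["rectus",
                                                       "knee_flexion"]
  expect_true(sign(g_pre) != sign(g_post))
})

test_that("strength changes scale forces; release removes all moment contribution", {
  model <- toy_model_fx(0L)
  expect_identical(apply_strength_change(model, "soleus", 1)$muscles$soleus$F_max,
                   model$muscles$soleus$F_max)
  half <- apply_strength_change(model, "soleus", 0.5)
  cs <- model$curves
  for (ln in c(0.8, 1.0, 1.3)) {
    expect_equal(muscle_force(half$muscles$soleus, cs, 1, ln),
                 0.5 * muscle_force(model$muscles$soleus, cs, 1, ln),
                 tolerance = 1e-12)
  }
  released <- apply_strength_change(model, "soleus", 0)
  expect_identical(muscle_force(released$muscles$soleus, cs, 1, 1.4), 0)
  expect_error(apply_strength_change(model, "soleus", 1.2),
               class = "capgap_domain_error")
  expect_error(apply_strength_change(model, "not_a_muscle", 0.5),
               class = "capgap_config_error")
})

test_that("femoral morphometrics recover constructed angles and compose with derotations", {
  model <- make_toy_model(seed = 3L, anteversion_deg = 20,
                          neck_shaft_deg = 125)
  mm <- bone_morphometrics(model)
  expect_equal(mm$anteversion_deg, 20, tolerance = 1e-6)
  expect_equal(mm$neck_shaft_deg, 125, tolerance = 1e-6)

  # neck collinear with the proximal shaft axis: neck-shaft angle 180
  coll <- model
  coll$segments$thigh$landmarks$femoral_head_center <-
    coll$segments$thigh$landmarks$neck_base + c(0, 0.05, 0)
  expect_equal(bone_morphometrics(coll)$neck_shaft_deg, 180, tolerance = 1e-9)

  # +20 degrees about the shaft axis reduces anteversion by exactly 20
  d <- apply_derotation_osteotomy(model, "thigh", thigh_plane(), 20 * pi / 180)
  expect_equal(bone_morphometrics(d)$anteversion_deg, 0, tolerance = 1e-6)

  miss <- model
  miss$segments$thigh$landmarks$neck_base <- NULL
  err <- expect_error(bone_morphometrics(miss), class = "capgap_config_error")
  expect_match(conditionMessage(err), "neck_base")
})

test_that("patella advancement: zero change is a fixed point, shortening advances distally, the ligament constraint holds", {
  model <- toy_model_fx(0L)
  same <- apply_patella_advancement(model, delta_length = 0)
  expect_equal(same$patella$path, model$patella$path, tolerance = 1e-8)

  adv <- apply_patella_advancement(model, delta_length = -0.02)
  p <- model$patella
  d_to_tib <- function(mod) {
    vapply(seq_len(nrow(mod$patella$path)), function(i) {
      k <- mod$patella$path[i, "knee_angle"]
      tib <- mod$patella$knee_center +
        as.vector(capgap:::rot2(k) %*% mod$patella$tibia_insertion)
      sqrt(sum((mod$patella$path[i, c("x", "y")] - tib)^2))
    }, 0)
  }
  expect_true(all(d_to_tib(adv) < d_to_tib(model)))

  # ligament length constraint audited from the stored poses
  for (mod in list(model, adv)) {
    pp <- mod$patella
    for (i in seq_len(nrow(pp$path))) {
      k <- pp$path[i, "knee_angle"]
      tib <- pp$knee_center + as.vector(capgap:::rot2(k) %*% pp$tibia_insertion)
      attach <- pp$path[i, c("x", "y")] +
        as.vector(capgap:::rot2(pp$path[i, "theta"]) %*% pp$lig_attach)
      expect_lt(abs(sqrt(sum((attach - tib)^2)) - pp$lig_length), 1e-6)
    }
  }
  expect_error(apply_patella_advancement(model, delta_length = -0.045),
               class = "capgap_surgery_error")
})

test_that("surgery plans fold sequentially, record provenance and round-trip through YAML", {
  model <- toy_model_fx(0L)
  plan <- surgery_plan(list(
    list(kind = "derotation_osteotomy", segment = "thigh",
         plane = thigh_plane(), angle = 10 * pi / 180,
         translation = c(0, 0, 0)),
    list(kind = "strength_change", muscle = "gastrocnemius", scale = 0),
    list(kind = "muscle_transfer", muscle = "hamstrings",
         delta_lts = 0.005)),
    label = "combo")
  post <- apply_surgery_plan(model, plan)
  # folding one by one gives the same geometry
  step <- apply_derotation_osteotomy(model, "thigh", thigh_plane(),
                                     10 * pi / 180)
  step <- apply_strength_change(step, "gastrocnemius", 0)
  step <- apply_muscle_transfer(step, "hamstrings", delta_lts = 0.005)
  expect_equal(post$segments$thigh$landmarks, step$segments$thigh$landmarks)
  expect_equal(post$muscles$hamstrings$l_ts, step$muscles$hamstrings$l_ts)
  expect_identical(post$muscles$gastrocnemius$F_max, 0)
  expect_identical(post$lineage, model$name)
  expect_false(is.null(post$plan))

  path <- withr::local_tempfile(fileext = ".yaml")
  write_surgery_plan(plan, path)
  back <- read_surgery_plan(path)
  expect_identical(length(back$operations), length(plan$operations))
  expect_equal(back$operations[[1]]$angle, plan$operations[[1]]$angle,
               tolerance = 1e-12)
  expect_equal(back$operations[[3]]$delta_lts, 0.005, tolerance = 1e-15)
  post2 <- apply_surgery_plan(model, back)
  expect_equal(post2$segments$thigh$landmarks$condyle_medial,
               post$segments$thigh$landmarks$condyle_medial,
               tolerance = 1e-12)
  expect_error(surgery_plan(list(list(kind = "amputation"))),
               class = "capgap_config_error")
})
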