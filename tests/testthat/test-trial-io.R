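# Trial bundles, storage-dialect tables, ROM assessments and the
# typically-developing reference motion.

test_that("trial bundles round-trip losslessly through the storage dialect", {
  trial <- toy_trial_fx(0L)
  prefix <- file.path(withr::local_tempdir(), "trial")
  write_trial_bundle(trial$bundle, prefix)
  back <- read_trial_bundle(prefix)
  expect_equal(back$time, trial$bundle$time, tolerance = 1e-12)
  expect_equal(back$q, trial$bundle$q, tolerance = 1e-12)
  expect_equal(back$tau, trial$bundle$tau, tolerance = 1e-12)
  expect_equal(back$l_mt, trial$bundle$l_mt, tolerance = 1e-12)
  expect_equal(back$r, trial$bundle$r, tolerance = 1e-12)
  expect_equal(back$emg, trial$bundle$emg, tolerance = 1e-12)
  expect_identical(lapply(back$channel_map, as.character),
                   lapply(trial$bundle$channel_map, as.character))
})

test_that("the nRows/nColumns/endheader dialect is parsed with degree conversion", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("angles", "nRows=2", "nColumns=3", "inDegrees=yes",
               "endheader", "time\thip\tknee",
               "0.0\t90.0\t-45.0", "0.1\t45.0\t0.0"), path)
  out <- read_sto(path)
  expect_equal(out$time, c(0, 0.1))
  expect_equal(out$data[, "hip"], c(pi / 2, pi / 4), tolerance = 1e-12)
  expect_equal(out$data[, "knee"], c(-pi / 4, 0), tolerance = 1e-12)
})

test_that("format errors carry the offending location or channel", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("x", "endheader", "time\ta", "0\t1", "0.1\t2\t3"), path)
  err <- expect_error(read_sto(path), class = "capgap_format_error")
  expect_match(conditionMessage(err), "line 5")

  writeLines(c("x", "endheader", "time\ta", "0\t1", "0\t2"), path)
  expect_error(read_sto(path), class = "capgap_format_error")

  trial <- toy_trial_fx(0L)
  emg <- trial$bundle$emg
  colnames(emg)[1] <- "mystery_channel"
  err2 <- expect_error(
    trial_bundle(trial$bundle$time, trial$bundle$q, trial$bundle$tau,
                 trial$bundle$l_mt, trial$bundle$r, emg,
                 trial$bundle$channel_map),
    class = "capgap_format_error")
  expect_match(conditionMessage(err2), "mystery_channel")
})

test_that("derived trial geometry is time-invariant for constant postures and matches single-posture calls", {
  model <- toy_model_fx(0L)
  cn <- names(zero_q(model))
  q <- matrix(rep(c(0.1, 0.2, -0.3, 0.15), each = 10), 10, 4,
              dimnames = list(NULL, cn))
  b <- derive_trial_geometry(model, trial_bundle(time = (0:9) / 10, q = q))
  for (i in 2:10) {
    expect_equal(b$l_mt[i, ], b$l_mt[1, ], tolerance = 1e-14)
    expect_equal(b$r[i, , ], b$r[1, , ], tolerance = 1e-14)
  }
  g <- musculotendon_geometry(model, q[1, ])
  expect_equal(b$l_mt[1, ], g$lengths, tolerance = 1e-14)
  expect_equal(b$r[1, , ], g$moment_arms, tolerance = 1e-14)
})

test_that("a knee flexor's length is monotone in knee angle over each half-cycle", {
  model <- toy_model_fx(0L)
  cn <- names(zero_q(model))
  nT <- 60
  knee <- 0.6 * sin(2 * pi * (0:(nT - 1)) / nT)
  q <- matrix(0, nT, 4, dimnames = list(NULL, cn))
  q[, "knee_flexion"] <- knee
  b <- derive_trial_geometry(model, trial_bundle(time = (0:(nT - 1)) / nT,
                                                 q = q))
  # hamstrings length must be a monotone function of the knee angle alone
  ord <- order(knee)
  lens <- b$l_mt[ord, "hamstrings"]
  expect_true(all(diff(lens) > -1e-12) || all(diff(lens) < 1e-12))
  expect_gt(diff(range(lens)), 0.01)
})

test_that("ROM musculotendon lengths take the max over tests and ignore test order", {
  model <- toy_model_fx(0L)
  q1 <- c(hip_flexion = 0.4)
  q2 <- c(hip_flexion = 0.7, knee_flexion = 0.2)
  rom1 <- rom_assessment(list(
    list(name = "a", posture = q1, muscles = "hamstrings")))
  l1 <- rom_musculotendon_lengths(model, rom1)
  g1 <- musculotendon_geometry(model, c(hip_rotation = 0, hip_flexion = 0.4,
                                        knee_flexion = 0, ankle_flexion = 0))
  expect_equal(unname(l1["hamstrings"]), unname(g1$lengths["hamstrings"]),
               tolerance = 1e-14)

  rom2 <- rom_assessment(list(
    list(name = "a", posture = q1, muscles = "hamstrings"),
    list(name = "b", posture = q2, muscles = "hamstrings")))
  rom2r <- rom_assessment(rev(rom2$tests))
  l2 <- rom_musculotendon_lengths(model, rom2)
  expect_equal(l2, rom_musculotendon_lengths(model, rom2r))
  g2 <- musculotendon_geometry(model, c(hip_rotation = 0, hip_flexion = 0.7,
                                        knee_flexion = 0.2, ankle_flexion = 0))
  expect_equal(unname(l2["hamstrings"]),
               max(g1$lengths["hamstrings"], g2$lengths["hamstrings"]),
               tolerance = 1e-14)
  expect_error(rom_musculotendon_lengths(
    model, rom_assessment(list(list(name = "x", posture = q1,
                                    muscles = "not_a_muscle")))),
    class = "capgap_config_error")
})

test_that("the packaged full-scale exam mapping carries the clinical muscle groups", {
  path <- system.file("extdata", "rom_mapping_fullscale.yaml",
                      package = "capgap")
  if (path == "") path <- file.path("..", "..", "inst", "extdata",
                                    "rom_mapping_fullscale.yaml")
  rom <- read_rom_assessment(path)
  tests <- setNames(rom$tests, vapply(rom$tests, `[[`, "", "name"))
  expect_setequal(tests$knee_flexion_test$muscles,
                  c("Rectus_Fem", "Vast_Int", "Vast_Med", "Vast_Lat"))
  expect_setequal(tests$popliteal_angle_unilateral$muscles,
                  c("Semimembr", "Semitend", "Gracilis", "Bic_Fem_lh",
                    "Bic_Fem_sh"))
  expect_setequal(tests$dorsiflexion_knee_0$muscles,
                  c("Soleus", "Gastroc_Lat", "Gastroc_Med"))
  expect_equal(unname(tests$popliteal_angle_unilateral$posture["hip_flexion"]),
               pi / 2, tolerance = 1e-12)
})

test_that("reference-trial moments scale linearly with mass; angles are the template's when not retargeting", {
  model <- toy_model_fx(0L)
  template <- cached("template", default_gait_template)
  b1 <- make_reference_trial(template, model, mass = template$mass_ref)
  b2 <- make_reference_trial(template, model, mass = 2 * template$mass_ref)
  expect_equal(b2$tau, 2 * b1$tau, tolerance = 1e-12)
  expect_equal(b1$q, template$q[, colnames(b1$q)], tolerance = 1e-14)
  expect_equal(b1$tau, template$moments_per_kg[, colnames(b1$tau)] *
                 template$mass_ref, tolerance = 1e-12)
})

test_that("marker retargeting on the undeformed chain recovers the template angles", {
  model <- toy_model_fx(0L)
  template <- cached("template", default_gait_template)
  b <- make_reference_trial(template, model, mass = template$mass_ref,
                            retarget = TRUE)
  expect_lt(max(abs(b$q - template$q[, colnames(b$q)])), 1e-6)
})

test_that("marker retargeting compensates a long-axis derotation that imposed angles cannot", {
  model <- toy_model_fx(0L)
  template <- cached("template", default_gait_template)
  derot <- 30 * pi / 180
  patient <- apply_derotation_osteotomy(
    model, "thigh", list(point = c(0, -0.20, 0), normal = c(0, 1, 0)), derot)

  shank_axis_dev <- function(m, q_row) {
    # angle between the shank long axis in ground and the template chain's
    tr_m <- capgap:::segment_transforms(m, q_row)
    tr_t <- capgap:::segment_transforms(model, template$q[1, ])
    a <- tr_m$shank$R %*% c(0, -1, 0)
    b <- tr_t$shank$R %*% c(0, -1, 0)
    acos(min(1, sum(a * b))) * 180 / pi
  }
  # imposing template angles leaves the full derotation downstream, but the
  # shank's long axis is along the derotation axis, so measure a transverse
  # direction instead
  transverse_dev <- function(m, q_row) {
    tr_m <- capgap:::segment_transforms(m, q_row)
    tr_t <- capgap:::segment_transforms(model, template$q[1, ])
    a <- tr_m$shank$R %*% c(1, 0, 0)
    b <- tr_t$shank$R %*% c(1, 0, 0)
    acos(min(1, sum(a * b))) * 180 / pi
  }
  dev_imposed <- transverse_dev(patient, template$q[1, ])
  expect_equal(dev_imposed, 30, tolerance = 1)

  b_re <- make_reference_trial(template, patient, mass = template$mass_ref,
                               retarget = TRUE)
  dev_tracked <- transverse_dev(patient, b_re$q[1, ])
  expect_lt(dev_tracked, 5)
})

test_that("bundle resampling preserves endpoints and linear structure", {
  trial <- toy_trial_fx(0L)
  rs <- resample_bundle(trial$bundle, 77)
  expect_length(rs$time, 77)
  expect_equal(rs$q[1, ], trial$bundle$q[1, ])
  expect_equal(rs$q[77, ], trial$bundle$q[nrow(trial$bundle$q), ])
})

test_that("EMG preprocessing produces peak-normalized envelopes", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  raw <- cbind(ch1 = sin(2 * pi * 60 * t) * (1 + sin(2 * pi * 1 * t)),
               ch2 = rnorm(length(t), sd = 0.2))
  env <- process_emg(raw, fs)
  expect_equal(unname(apply(env, 2, max)), c(1, 1), tolerance = 1e-9)
  expect_true(all(env >= 0))
  # envelope follows the 1 Hz amplitude modulation of channel 1
  expect_gt(cor(env[, 1], 1 + sin(2 * pi * 1 * t)), 0.9)
})
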