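# Seeded desk-scale fixtures: a planar lower-limb analog chain and
# internally consistent synthetic gait trials with known ground truth.
# Moments are constructed from the model's own muscle forces, so a
# reserve-free solution exists by construction and every downstream
# optimization has a known optimum to recover.

#' Build the toy lower-limb model
#'
#' A planar four-link analog of pelvis-thigh-shank-foot with hinge joints
#' (hip flexion, knee flexion, ankle flexion) plus a long-axis hip rotation
#' coordinate carried by an intermediate segment, actuated by eight polyline
#' muscles including three biarticular ones (hamstrings, gastrocnemius and a
#' rectus femoris analog). Six muscles form the tuned subset M with full
#' force-length behavior; two are activation-proportional (subset N). The
#' thigh carries femur-style landmarks (head, neck, shaft, condyles) for
#' morphometrics, retargeting markers on thigh, shank and foot, and a planar
#' patella construct with a ligament and femoral profile for patella
#' advancement. Geometry is fixed; the seed jitters maximum isometric forces
#' by a few percent so distinct seeds give distinct but equivalent models.
#'
#' @param seed integer seed.
#' @param anteversion_deg constructed femoral anteversion angle (degrees).
#' @param neck_shaft_deg constructed neck-shaft angle (degrees).
#' @return A validated \code{\link{msk_model}}.
#' @export
make_toy_model <- function(seed = 0L, anteversion_deg = 15,
                           neck_shaft_deg = 130) {
  av <- anteversion_deg * DEG2RAD
  elev <- (neck_shaft_deg - 90) * DEG2RAD
  neck_dir <- c(cos(elev) * sin(av), sin(elev), cos(elev) * cos(av))
  neck_base <- c(0, -0.02, 0)
  segments <- list(
    pelvis = list(name = "pelvis", parent = NULL,
                  joint_axis = c(0, 0, 1), joint_center = c(0, 0, 0),
                  landmarks = list(pelvis_marker = c(0.10, 0.05, 0))),
    thigh_rot = list(name = "thigh_rot", parent = "pelvis",
                     joint_axis = c(0, 1, 0), joint_center = c(0, -0.10, 0),
                     landmarks = list()),
    thigh = list(name = "thigh", parent = "thigh_rot",
                 joint_axis = c(0, 0, 1), joint_center = c(0, 0, 0),
                 landmarks = list(
                   femoral_head_center = neck_base + 0.05 * neck_dir,
                   neck_base = neck_base,
                   shaft_proximal = c(0, -0.05, 0),
                   shaft_distal = c(0, -0.35, 0),
                   condyle_medial = c(0, -0.40, -0.03),
                   condyle_lateral = c(0, -0.40, 0.03),
                   thigh_marker = c(0.04, -0.12, 0.01))),
    shank = list(name = "shank", parent = "thigh",
                 joint_axis = c(0, 0, 1), joint_center = c(0, -0.40, 0),
                 landmarks = list(shank_marker_a = c(0.03, -0.15, 0.02),
                                  shank_marker_b = c(-0.02, -0.30, -0.03))),
    foot = list(name = "foot", parent = "shank",
                joint_axis = c(0, 0, 1), joint_center = c(0, -0.42, 0),
                landmarks = list(foot_toe = c(0.12, -0.03, 0.01),
                                 foot_heel = c(-0.05, -0.02, -0.02))))
  coordinates <- list(
    hip_rotation = list(name = "hip_rotation", segment = "thigh_rot",
                        range = c(-1.2, 1.2)),
    hip_flexion = list(name = "hip_flexion", segment = "thigh",
                       range = c(-1.6, 1.6)),
    knee_flexion = list(name = "knee_flexion", segment = "shank",
                        range = c(-1.6, 1.6)),
    ankle_flexion = list(name = "ankle_flexion", segment = "foot",
                         range = c(-1.6, 1.6)))
  pp <- function(segment, location, role = "via")
    list(segment = segment, location = location, role = role)
  paths <- list(
    hip_flexor = list(pp("pelvis", c(0.10, -0.02, 0.01), "origin"),
                      pp("thigh", c(0.03, -0.12, 0.025), "insertion")),
    hip_extensor = list(pp("pelvis", c(-0.06, 0.02, -0.01), "origin"),
                        pp("thigh", c(-0.025, -0.10, -0.025), "insertion")),
    knee_extensor = list(pp("thigh", c(0.035, -0.12, 0.005), "origin"),
                         pp("thigh", c(0.05, -0.38, 0)),
                         pp("shank", c(0.04, -0.07, 0), "insertion")),
    hamstrings = list(pp("pelvis", c(-0.10, -0.08, 0.01), "origin"),
                      pp("shank", c(-0.03, -0.06, 0.005), "insertion")),
    tibialis = list(pp("shank", c(0.03, -0.15, 0.005), "origin"),
                    pp("foot", c(0.06, 0.01, 0), "insertion")),
    gastrocnemius = list(pp("thigh", c(-0.03, -0.36, 0.005), "origin"),
                         pp("foot", c(-0.06, 0.005, 0), "insertion")),
    soleus = list(pp("shank", c(-0.03, -0.14, 0.005), "origin"),
                  pp("foot", c(-0.06, 0.005, 0), "insertion")),
    rectus = list(pp("pelvis", c(0.05, 0, 0.005), "origin"),
                  pp("thigh", c(0.046, -0.38, 0)),
                  pp("shank", c(0.038, -0.08, 0), "insertion")))
  fmax_base <- c(hip_flexor = 1200, hip_extensor = 1500, knee_extensor = 1800,
                 hamstrings = 1500, tibialis = 600, gastrocnemius = 1400,
                 soleus = 2500, rectus = 1000)
  subset_tag <- c(hip_flexor = "M", hip_extensor = "N", knee_extensor = "M",
                  hamstrings = "M", tibialis = "N", gastrocnemius = "M",
                  soleus = "M", rectus = "M")
  jit <- with_preserved_rng({
    set.seed(seed)
    stats::runif(length(fmax_base), 0.95, 1.05)
  })
  muscles <- list()
  for (i in seq_along(paths)) {
    nm <- names(paths)[i]
    muscles[[nm]] <- list(name = nm, path = paths[[nm]],
                          F_max = unname(fmax_base[nm]) * jit[i],
                          l_mo = 0.1, l_ts = 0.1, alpha = 0,
                          subset = unname(subset_tag[nm]))
  }
  model <- msk_model(name = sprintf("toy_model_seed%d", seed),
                     segments = segments, coordinates = coordinates,
                     muscles = muscles)
  # Hill parameters anchored at the neutral posture: optimal fiber length at
  # q = 0 so gait oscillations cross normalized length 1.
  q0 <- setNames(rep(0, 4), coordinate_names(model))
  L0 <- polyline_lengths(model, q0)
  for (nm in names(model$muscles)) {
    l_mo <- min(max(0.25 * L0[[nm]], 0.05), 0.14)
    model$muscles[[nm]]$l_mo <- l_mo
    model$muscles[[nm]]$l_ts <- L0[[nm]] - l_mo
  }
  model$patella <- default_patella_construct()
  model$patella$path <- solve_patella_path(model$patella)
  validate_model(model)
  model
}

# Planar patella construct in the thigh frame (x forward, y distal-negative),
# knee hinge at (0, -0.40).
default_patella_construct <- function() {
  knee <- c(0, -0.40)
  theta <- seq(-80, 80, by = 5) * DEG2RAD
  profile <- cbind(knee[1] + 0.048 * cos(theta), knee[2] + 0.048 * sin(theta))
  p <- list(points = list(prox = c(0, 0.015), dist = c(0, -0.015)),
            lig_attach = c(0, -0.02),
            tibia_insertion = c(0.045, -0.07),
            clearance = 0.008,
            profile = profile,
            knee_center = knee,
            knee_coordinate = "knee_flexion",
            grid = seq(-0.8, 1.2, by = 0.1))
  # baseline ligament length from a neutral antero-distal patella pose
  origin0 <- knee + c(0.048 + p$clearance, -0.02)
  attach0 <- origin0 + p$lig_attach
  tib0 <- knee + p$tibia_insertion  # knee angle 0
  p$lig_length <- sqrt(sum((attach0 - tib0)^2))
  p
}

#' Synthetic reference gait template
#'
#' Deterministic smooth gait-like template on the toy chain: Fourier-series
#' joint angles (one cycle, 101 samples, exactly periodic), joint moments per
#' kilogram generated by the reference chain's own muscles under a fixed
#' low-rank activation pattern, and virtual marker trajectories of the
#' chain's landmarks. It is a synthetic stand-in for an average
#' typically-developing gait data set, packaged so that an unimpaired copy of
#' the reference chain can reproduce the template moments without reserve
#' actuators.
#'
#' @param n_per_cycle samples per gait cycle.
#' @return A \code{\link{gait_template}}.
#' @export
default_gait_template <- function(n_per_cycle = 101) {
  ref <- make_toy_model(seed = 0L)
  phi <- seq(0, 1, length.out = n_per_cycle)
  q <- cbind(
    hip_rotation = 0.06 * sin(2 * pi * phi + 0.3),
    hip_flexion = 0.40 * sin(2 * pi * phi + 1.9) + 0.06 * sin(4 * pi * phi + 0.5),
    knee_flexion = 0.50 * sin(2 * pi * phi - 0.6) + 0.12 * sin(4 * pi * phi + 1.1),
    ankle_flexion = 0.30 * sin(2 * pi * phi + 0.8) + 0.08 * sin(4 * pi * phi - 0.4))
  mass_ref <- 35; height_ref <- 1.40
  # fixed synergy-like activation pattern driving the reference moments
  W_ref <- matrix(c(
    0.15, 0.85, 0.10,   # hip_flexor
    0.80, 0.05, 0.30,   # hip_extensor
    0.70, 0.15, 0.10,   # knee_extensor
    0.20, 0.10, 0.85,   # hamstrings
    0.05, 0.75, 0.15,   # tibialis
    0.55, 0.05, 0.45,   # gastrocnemius
    0.55, 0.05, 0.45,   # soleus
    0.35, 0.55, 0.05),  # rectus
    nrow = 8, byrow = TRUE,
    dimnames = list(muscle_names(ref), NULL))
  centers <- c(0.15, 0.65, 0.45)
  H_ref <- t(vapply(centers, function(cc)
    0.03 + exp(6 * (cos(2 * pi * (phi - cc)) - 1)), numeric(n_per_cycle)))
  a_ref <- W_ref %*% H_ref
  a_ref <- a_ref * (0.5 / max(a_ref))
  bundle <- derive_trial_geometry(ref, trial_bundle(time = phi, q = q))
  tau <- muscle_moments(ref, bundle, t(a_ref))
  markers <- marker_trajectories(ref, q)
  gait_template(phase = phi * 100, time = phi, q = q,
                moments_per_kg = tau / mass_ref, markers = markers,
                mass_ref = mass_ref, height_ref = height_ref)
}

# Joint moments produced by given activations on a model, frame by frame.
muscle_moments <- function(model, bundle, activations) {
  mn <- muscle_names(model)
  cn <- coordinate_names(model)
  nT <- length(bundle$time)
  tau <- matrix(0, nT, length(cn), dimnames = list(NULL, cn))
  for (m in mn) {
    mu <- model$muscles[[m]]
    if (mu$subset == "M") {
      ln <- fiber_state(bundle$l_mt[, m], mu)$l_norm
      F <- muscle_force(mu, model$curves, activations[, m], ln)
    } else {
      F <- mu$F_max * activations[, m]
    }
    tau <- tau + bundle$r[, m, ] * F
  }
  tau
}

marker_trajectories <- function(model, q) {
  tab <- list()
  for (s in model$segments)
    for (lm in names(s$landmarks))
      tab[[lm]] <- list(segment = s$name, location = s$landmarks[[lm]])
  # markers used for retargeting: all non-morphometric landmarks
  keep <- c("thigh_marker", "shank_marker_a", "shank_marker_b",
            "foot_toe", "foot_heel")
  keep <- intersect(keep, names(tab))
  out <- lapply(keep, function(nm) {
    tr <- matrix(NA_real_, nrow(q), 3)
    for (i in seq_len(nrow(q))) {
      trf <- segment_transforms(model, q[i, ])
      tr[i, ] <- point_to_ground(trf, tab[[nm]]$segment, tab[[nm]]$location)
    }
    tr
  })
  setNames(out, keep)
}

#' Generate a synthetic gait trial with known ground truth
#'
#' Seeded band-limited Fourier kinematics (zero-mean, so each tuned muscle
#' crosses its optimal length during the cycle), activations from a
#' non-negative low-rank synergy model \code{a = W H}, muscle forces from the
#' model's true Hill parameters, and joint moments defined as the resulting
#' muscle-moment sums so that a zero-reserve solution exists by construction.
#' EMG envelopes are the activations of the measured channel subset plus
#' optional Gaussian noise, clipped at zero and peak-normalized. If any tuned
#' muscle leaves the admissible normalized-length band the kinematic
#' amplitudes are rescaled and the trial regenerated (attempts are recorded
#' in the \code{generation} element).
#'
#' @param model an \code{msk_model} (its parameters are the ground truth).
#' @param n_cycles number of gait cycles.
#' @param n_per_cycle frames per cycle.
#' @param k_true true synergy count.
#' @param noise_sd standard deviation of additive EMG noise.
#' @param seed integer seed.
#' @param channels named list mapping channel names to muscle names; muscles
#'   sharing a channel share the same true activation.
#' @return list with \code{bundle} (a complete \code{trial_bundle}) and
#'   \code{truth} (W, H, activations, true parameters, generation log).
#' @export
generate_synthetic_trial <- function(model, n_cycles = 3, n_per_cycle = 51,
                                     k_true = 3, noise_sd = 0, seed = 0L,
                                     channels = default_emg_channels()) {
  cn <- coordinate_names(model)
  mn <- muscle_names(model)
  tuned <- mn[vapply(model$muscles, function(m) m$subset == "M", TRUE)]
  nT <- n_cycles * n_per_cycle
  phi <- (seq_len(nT) - 1) / n_per_cycle  # cycle phase, 0-based
  time <- (seq_len(nT) - 1) / n_per_cycle
  amp_base <- c(hip_rotation = 0.06, hip_flexion = 0.40,
                knee_flexion = 0.50, ankle_flexion = 0.30)[cn]
  amp_base[is.na(amp_base)] <- 0.3
  names(amp_base) <- cn

  draw <- with_preserved_rng({
    set.seed(seed)
    list(jit = stats::runif(length(cn), 0.85, 1.15),
         ph1 = stats::runif(length(cn), 0, 2 * pi),
         ph2 = stats::runif(length(cn), 0, 2 * pi),
         w_jit = stats::runif(length(mn), 0.6, 1.0),
         w_sec = stats::runif(length(mn), 0, 0.15),
         h_jit = stats::runif(k_true, -0.05, 0.05),
         noise = matrix(stats::rnorm(nT * length(channels), 0, noise_sd),
                        nT, length(channels)))
  })

  scale <- 1; attempts <- character()
  for (attempt in 1:10) {
    amps <- amp_base * draw$jit * scale
    q <- vapply(seq_along(cn), function(j)
      amps[j] * sin(2 * pi * phi + draw$ph1[j]) +
        0.2 * amps[j] * sin(4 * pi * phi + draw$ph2[j]), numeric(nT))
    colnames(q) <- cn
    bundle <- derive_trial_geometry(model, trial_bundle(time = time, q = q))
    ln_range <- vapply(tuned, function(m) {
      ln <- fiber_state(bundle$l_mt[, m], model$muscles[[m]])$l_norm
      c(min(ln), max(ln))
    }, numeric(2))
    over <- any(ln_range[2, ] > 1.45) || any(ln_range[1, ] < 0.55)
    under <- any(ln_range[2, ] < 1.01) || any(ln_range[1, ] > 0.99)
    if (!over && !under) break
    attempts <- c(attempts, sprintf(
      "attempt %d: lnorm in [%.3f, %.3f], rescaling amplitudes by %s",
      attempt, min(ln_range), max(ln_range), if (over) "0.85" else "1.15"))
    scale <- scale * if (over) 0.85 else 1.15
    if (attempt == 10)
      stop_capgap("could not generate feasible kinematics", "capgap_geometry_error")
  }

  # low-rank non-negative coordination with tied calf rows
  W <- matrix(0, length(mn), k_true, dimnames = list(mn, NULL))
  prim <- (seq_along(mn) - 1) %% k_true + 1
  names(prim) <- mn
  prim["soleus"] <- prim["gastrocnemius"]
  for (i in seq_along(mn)) {
    W[i, prim[i]] <- draw$w_jit[i]
    W[i, (prim[i] %% k_true) + 1] <- W[i, (prim[i] %% k_true) + 1] + draw$w_sec[i]
  }
  W["soleus", ] <- W["gastrocnemius", ]
  centers <- (seq_len(k_true) - 0.5) / k_true + draw$h_jit
  H <- t(vapply(centers, function(cc)
    0.05 + exp(6 * (cos(2 * pi * (phi - cc)) - 1)), numeric(nT)))
  a <- t(W %*% H)
  W <- W * (0.65 / max(a))
  a <- t(W %*% H)  # all entries in (0, 0.65]; clamp never active
  colnames(a) <- mn

  tau <- muscle_moments(model, bundle, a)
  colnames(tau) <- cn
  bundle$tau <- tau

  emg <- vapply(seq_along(channels), function(ci) {
    m1 <- channels[[ci]][1]
    e <- a[, m1] + draw$noise[, ci]
    e <- pmax(e, 0)
    if (max(e) > 0) e / max(e) else e
  }, numeric(nT))
  colnames(emg) <- names(channels)
  bundle$emg <- emg
  bundle$channel_map <- channels
  bundle <- trial_bundle(bundle$time, bundle$q, bundle$tau, bundle$l_mt,
                         bundle$r, bundle$emg, bundle$channel_map)

  list(bundle = bundle,
       truth = list(W = W, H = H, activations = a,
                    l_mo = vapply(model$muscles, `[[`, 0, "l_mo"),
                    l_ts = vapply(model$muscles, `[[`, 0, "l_ts"),
                    k_true = k_true, noise_sd = noise_sd,
                    generation = attempts))
}

#' Default EMG channel map of the toy model
#'
#' Five surface channels; the calf channel drives both plantarflexors
#' (they share one envelope, mirroring how one surface electrode is mapped
#' to several underlying muscles).
#' @return Named list of muscle-name vectors.
#' @export
default_emg_channels <- function() {
  list(quad = "knee_extensor", hams = "hamstrings",
       calf = c("gastrocnemius", "soleus"), rect = "rectus",
       hipflex = "hip_flexor")
}

#' Generate a clinical range-of-motion assessment for the toy model
#'
#' Four clinical-exam-style stretch tests (knee flexion for the knee
#' extensors, a popliteal-angle analog for the hamstrings, ankle
#' dorsiflexion with the knee extended for the plantarflexors, and hip
#' extension for the hip flexor). For each test the stretch posture is
#' calibrated on the model so that the most-stretched test muscle reaches
#' the target normalized fiber length (default 1.45, inside the passive
#' force-generating band), emulating an examiner moving the joint to the
#' end of range.
#'
#' @param model an \code{msk_model}.
#' @param target_lnorm normalized fiber length reached by the limiting
#'   muscle of each test.
#' @return A \code{\link{rom_assessment}} covering all tuned muscles.
#' @export
generate_rom_assessment <- function(model, target_lnorm = 1.45) {
  cn <- coordinate_names(model)
  tests_def <- list(
    knee_flexion_test = c("knee_extensor", "rectus"),
    popliteal_angle = "hamstrings",
    dorsiflexion_knee_0 = c("gastrocnemius", "soleus"),
    hip_extension_test = "hip_flexor")
  tests_def <- lapply(tests_def, intersect, y = muscle_names(model))
  tests_def <- Filter(length, tests_def)
  q0 <- setNames(rep(0, length(cn)), cn)
  g0 <- musculotendon_geometry(model, q0)
  lo <- vapply(model$coordinates, function(co) co$range[1], 0)
  hi <- vapply(model$coordinates, function(co) co$range[2], 0)
  tests <- list()
  sub_lo <- pmax(lo, -1.2); sub_hi <- pmin(hi, 1.2)
  for (tn in names(tests_def)) {
    mus <- tests_def[[tn]]
    rbar <- colMeans(g0$moment_arms[mus, , drop = FALSE])
    relevant <- abs(rbar) > 5e-3
    mean_ln_at <- function(q) {
      g <- musculotendon_geometry(model, setNames(q, cn), check = FALSE)
      mean(vapply(mus, function(m)
        fiber_state(g$lengths[[m]], model$muscles[[m]])$l_norm, 0))
    }
    # examiner's end-range posture: maximize the stretch of the test group
    # over the relevant coordinates
    start <- ifelse(relevant, -sign(rbar) * 0.4, 0)
    fit <- stats::optim(start, function(qf) {
      qf[!relevant] <- 0
      -mean_ln_at(pmin(pmax(qf, sub_lo), sub_hi))
    }, method = "L-BFGS-B", lower = sub_lo, upper = sub_hi,
    control = list(maxit = 200))
    q_star <- fit$par
    q_star[!relevant] <- 0
    max_ln <- function(s) {
      g <- musculotendon_geometry(model, setNames(s * q_star, cn),
                                  check = FALSE)
      max(vapply(mus, function(m)
        fiber_state(g$lengths[[m]], model$muscles[[m]])$l_norm, 0))
    }
    # scale the excursion back so the most-stretched muscle hits the target
    grid <- seq(0, 1, by = 0.05)
    vals <- vapply(grid, max_ln, 0)
    hit <- which(vals >= target_lnorm)
    if (length(hit) && hit[1] > 1) {
      k <- hit[1]
      s <- stats::uniroot(function(x) max_ln(x) - target_lnorm,
                          c(grid[k - 1], grid[k]), tol = 1e-10)$root
    } else {
      s <- grid[which.max(vals)]
      if (max(vals) < 1.05)
        stop_capgap(sprintf(
          "cannot stretch test '%s' into the passive range on this model", tn),
          "capgap_config_error")
    }
    posture <- setNames(s * q_star, cn)
    tests[[tn]] <- list(name = tn, posture = posture[relevant],
                        muscles = mus)
  }
  rom_assessment(unname(tests))
}

#' Apply a known deformity to a model
#'
#' Creates a "patient" model from a healthy one by (a) an internal long-axis
#' derotation osteotomy of the thigh about its shaft axis and (b) optional
#' tendon contractures (shortened tendon slack lengths). Returns the
#' deformed model together with the ground-truth deformity record and the
#' exact corrective surgery plan that inverts it.
#'
#' @param model an \code{msk_model}.
#' @param derotation_deg internal derotation angle applied to the thigh
#'   (degrees).
#' @param contracture_m named vector of tendon slack-length reductions (m),
#'   e.g. \code{c(hamstrings = 0.006)}.
#' @return list with \code{model} (the patient), \code{record} and
#'   \code{corrective_plan} (a \code{\link{surgery_plan}}).
#' @export
perturb_model <- function(model, derotation_deg = 25,
                          contracture_m = c(hamstrings = 0.006,
                                            gastrocnemius = 0.006)) {
  plane <- list(point = c(0, -0.20, 0), normal = c(0, 1, 0))
  patient <- apply_derotation_osteotomy(model, "thigh", plane,
                                        derotation_deg * DEG2RAD)
  for (m in names(contracture_m)) {
    if (!m %in% muscle_names(patient))
      stop_capgap(sprintf("unknown muscle '%s' in contracture spec", m),
                  "capgap_config_error")
    patient$muscles[[m]]$l_ts <- patient$muscles[[m]]$l_ts - contracture_m[[m]]
  }
  patient$name <- paste0(model$name, "_patient")
  patient$lineage <- NULL
  patient$label <- "pre-operative"
  ops <- list(list(kind = "derotation_osteotomy", segment = "thigh",
                   plane = plane, angle = -derotation_deg * DEG2RAD,
                   translation = c(0, 0, 0)))
  for (m in names(contracture_m))
    ops <- c(ops, list(list(kind = "muscle_transfer", muscle = m,
                            delta_lts = contracture_m[[m]])))
  list(model = patient,
       record = list(derotation_deg = derotation_deg,
                     contracture_m = contracture_m, plane = plane),
       corrective_plan = surgery_plan(ops, label = "corrective"))
}
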