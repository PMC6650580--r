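# Shared fixtures (cached per test session) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

toy_model_fx <- function(seed = 0L)
  cached(paste0("model_", seed), function() make_toy_model(seed = seed))

toy_trial_fx <- function(seed = 0L, k_true = 3, noise_sd = 0)
  cached(sprintf("trial_%d_%d_%g", seed, k_true, noise_sd), function()
    generate_synthetic_trial(toy_model_fx(seed), seed = seed,
                             k_true = k_true, noise_sd = noise_sd))

toy_rom_fx <- function(seed = 0L)
  cached(paste0("rom_", seed), function()
    generate_rom_assessment(toy_model_fx(seed)))

zero_q <- function(model)
  setNames(rep(0, length(model$coordinates)),
           vapply(model$coordinates, `[[`, "", "name"))

# --- independent forward-kinematics oracle -------------------------------
# Rotates vectors directly with the axis-angle formula (no rotation
# matrices) and walks the chain recursively; independent of the package's
# transform code path.
oracle_rotate <- function(v, axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  v * cos(angle) +
    c(k[2] * v[3] - k[3] * v[2],
      k[3] * v[1] - k[1] * v[3],
      k[1] * v[2] - k[2] * v[1]) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

oracle_point_ground <- function(model, q, segment, p) {
  s <- model$segments[[segment]]
  if (is.null(s$parent)) return(p)
  co <- NULL
  for (cc in model$coordinates) if (cc$segment == segment) co <- cc$name
  ang <- if (is.null(co)) 0 else q[[co]]
  oracle_point_ground(model, q, s$parent,
                      s$joint_center + oracle_rotate(p, s$joint_axis, ang))
}

oracle_muscle_length <- function(model, q, muscle) {
  pts <- lapply(model$muscles[[muscle]]$path, function(pp)
    oracle_point_ground(model, q, pp$segment, pp$location))
  sum(vapply(seq_len(length(pts) - 1), function(i)
    sqrt(sum((pts[[i + 1]] - pts[[i]])^2)), 0))
}

# --- independent box-constrained QP oracle -------------------------------
# Exact primal active-set method for min x'Mx - 2c'x, l <= x <= u:
# start from a projected-gradient guess, then iterate (solve the free
# subsystem exactly with base solve(), clamp violators, release bound
# variables with inward-pointing gradients) until the KKT conditions hold.
oracle_box_qp <- function(M, c, lower, upper, max_swaps = 200) {
  n <- length(c)
  x <- pmin(pmax(c / pmax(diag(M), 1e-12), lower), upper)
  at_lo <- x <= lower + 1e-12
  at_hi <- x >= upper - 1e-12
  for (it in seq_len(max_swaps)) {
    free <- !(at_lo | at_hi)
    x[at_lo] <- lower[at_lo]
    x[at_hi] <- upper[at_hi]
    if (any(free)) {
      rhs <- c[free] - M[free, !free, drop = FALSE] %*% x[!free]
      x[free] <- solve(M[free, free, drop = FALSE], rhs)
    }
    changed <- FALSE
    # clamp free variables that left the box
    for (j in which(free)) {
      if (x[j] < lower[j] - 1e-14) { at_lo[j] <- TRUE; changed <- TRUE }
      if (x[j] > upper[j] + 1e-14) { at_hi[j] <- TRUE; changed <- TRUE }
    }
    if (!changed) {
      # release bound variables whose gradient points inward
      g <- 2 * (M %*% x - c)
      for (j in which(at_lo)) if (g[j] < -1e-10) { at_lo[j] <- FALSE; changed <- TRUE }
      for (j in which(at_hi)) if (g[j] > 1e-10) { at_hi[j] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  pmin(pmax(as.vector(x), lower), upper)
}

# Per-frame plain static-optimization oracle (activations + penalized
# reserves, reserves eliminated analytically as the equilibrium residual).
oracle_static_opt_frame <- function(B, tau_free, w1, w2) {
  M <- diag(w1, ncol(B)) + w2 * crossprod(B)
  c <- w2 * as.vector(crossprod(B, tau_free))
  oracle_box_qp(M, c, rep(0, ncol(B)), rep(1, ncol(B)))
}

# A 1-DOF, 2-muscle toy (hinged forearm with an agonist/antagonist pair),
# used by closed-form QP and capability-gap deficit checks.
mini_model <- function(F_flex = 1000, F_ext = 1000, subset = "N") {
  segments <- list(
    base = list(name = "base", parent = NULL, joint_axis = c(0, 0, 1),
                joint_center = c(0, 0, 0), landmarks = list()),
    arm = list(name = "arm", parent = "base", joint_axis = c(0, 0, 1),
               joint_center = c(0, -0.1, 0), landmarks = list()))
  coordinates <- list(
    elbow = list(name = "elbow", segment = "arm", range = c(-1.6, 1.6)))
  pp <- function(seg, loc, role) list(segment = seg, location = loc, role = role)
  muscles <- list(
    flexor = list(name = "flexor",
                  path = list(pp("base", c(0.05, 0.02, 0), "origin"),
                              pp("arm", c(0.03, -0.15, 0), "insertion")),
                  F_max = F_flex, l_mo = 0.08, l_ts = 0.1, alpha = 0,
                  subset = subset),
    extensor = list(name = "extensor",
                    path = list(pp("base", c(-0.05, 0.02, 0), "origin"),
                                pp("arm", c(-0.03, -0.15, 0), "insertion")),
                    F_max = F_ext, l_mo = 0.08, l_ts = 0.1, alpha = 0,
                    subset = subset))
  m <- msk_model("mini", segments, coordinates, muscles)
  for (nm in names(m$muscles)) {
    L0 <- polyline_lengths(m, c(elbow = 0))[[nm]]
    m$muscles[[nm]]$l_mo <- 0.3 * L0
    m$muscles[[nm]]$l_ts <- 0.7 * L0
  }
  m
}

# Expensive shared runs (built once, reused by several test files).
tuned_run_fx <- function() cached("tuned_run", function() {
  model <- toy_model_fx(0L)
  trial <- toy_trial_fx(0L)
  rom <- toy_rom_fx(0L)
  init <- perturbed_init(model, 42L)
  list(model = model, init = init, trial = trial, rom = rom,
       result = tune_muscle_parameters(init, trial$bundle, rom,
                                       tuning_config(n_starts = 1)))
})

perturbed_init <- function(model, seed) {
  tuned <- names(which(vapply(model$muscles,
                              function(x) x$subset == "M", TRUE)))
  init <- model
  set.seed(seed)
  for (mm in tuned) {
    init$muscles[[mm]]$l_mo <- model$muscles[[mm]]$l_mo * runif(1, 0.8, 1.2)
    init$muscles[[mm]]$l_ts <- model$muscles[[mm]]$l_ts * runif(1, 0.8, 1.2)
  }
  init
}

cg_selfconsistent_fx <- function() cached("cg_self", function() {
  model <- toy_model_fx(0L)
  trial <- toy_trial_fx(0L)
  mc <- build_motor_control(trial$truth$activations, trial$truth$k_true,
                            seed = 5L)
  list(model = model, trial = trial, mc = mc,
       result = compute_capability_gap(model, mc, trial$bundle, cg_config()))
})
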