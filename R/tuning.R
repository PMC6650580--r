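#' Configuration for muscle-parameter tuning
#'
#' Weights and numerical settings of the coupled static-optimization problem
#' that estimates optimal fiber lengths and tendon slack lengths. The four
#' cost weights scale the squared activations (\code{w1}), squared reserve
#' moments (\code{w2}, per (N m)^2), squared EMG-tracking deviations
#' (\code{w3}) and the quadratic pull of the clinical-exam normalized length
#' toward 1.5 (\code{w4}). Defaults were chosen so the cost terms are of the
#' same order on the packaged synthetic fixture; all are configurable.
#'
#' @param w1,w2,w3,w4 non-negative cost weights.
#' @param delta strict-inequality tolerance for the "crosses optimal length"
#'   and exam-stretch conditions.
#' @param lnorm_bounds admissible normalized fiber-length band during gait.
#' @param param_range multiplicative bounds on the initial optimal fiber
#'   length and tendon slack length.
#' @param sigma_bounds bounds on the EMG-to-activation scale factors.
#' @param max_outer maximum evaluations of the reduced objective (each one
#'   solves the inner convex activation/scale problem).
#' @param tol relative parameter-change convergence tolerance of the
#'   reduced solver.
#' @param n_starts number of multi-start runs (first from the model values,
#'   remainder from seeded perturbations).
#' @param start_spread relative spread of the perturbed starts.
#' @param seed integer seed for the multi-start perturbations.
#' @return An object of class \code{tuning_config}.
#' @export
tuning_config <- function(w1 = 0.1, w2 = 10, w3 = 5, w4 = 10, delta = 1e-3,
                          lnorm_bounds = c(0.4, 1.5),
                          param_range = c(0.5, 1.5),
                          sigma_bounds = c(0.05, 20),
                          max_outer = 150, tol = 1e-6, n_starts = 3,
                          start_spread = 0.1, seed = 0L) {
  stopifnot(w1 >= 0, w2 >= 0, w3 >= 0, w4 >= 0, delta > 0,
            lnorm_bounds[1] < lnorm_bounds[2],
            param_range[1] < param_range[2],
            sigma_bounds[1] < sigma_bounds[2])
  structure(list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, delta = delta,
                 lnorm_bounds = lnorm_bounds, param_range = param_range,
                 sigma_bounds = sigma_bounds, max_outer = max_outer,
                 tol = tol, n_starts = n_starts, start_spread = start_spread,
                 seed = seed),
            class = "tuning_config")
}

# Concatenate trial bundles (multiple walking trials) on their common
# muscle/coordinate sets; time is re-indexed.
concat_bundles <- function(bundles) {
  if (inherits(bundles, "trial_bundle")) return(bundles)
  stopifnot(length(bundles) >= 1)
  b1 <- bundles[[1]]
  if (length(bundles) == 1) return(b1)
  dt <- diff(b1$time[1:2])
  glue <- function(f) do.call(rbind, lapply(bundles, `[[`, f))
  r_all <- NULL
  if (!is.null(b1$r)) {
    nT <- sum(vapply(bundles, function(b) length(b$time), 0L))
    dn <- dimnames(b1$r)
    r_all <- array(NA_real_, c(nT, dim(b1$r)[2], dim(b1$r)[3]),
                   dimnames = list(NULL, dn[[2]], dn[[3]]))
    off <- 0L
    for (b in bundles) {
      r_all[off + seq_along(b$time), , ] <- b$r
      off <- off + length(b$time)
    }
  }
  nT <- sum(vapply(bundles, function(b) length(b$time), 0L))
  trial_bundle(time = (seq_len(nT) - 1) * dt, q = glue("q"),
               tau = glue("tau"), l_mt = glue("l_mt"), r = r_all,
               emg = glue("emg"), channel_map = b1$channel_map)
}

# EMG envelope per mapped muscle (muscles sharing a channel share its
# envelope but get independent scale factors).
emg_per_muscle <- function(trial, model) {
  mn <- muscle_names(model)
  cols <- list()
  for (ch in names(trial$channel_map)) {
    for (m in trial$channel_map[[ch]]) {
      if (!m %in% mn)
        stop_capgap(sprintf("EMG channel '%s' maps to unknown muscle '%s'",
                            ch, m), "capgap_format_error")
      cols[[m]] <- trial$emg[, ch]
    }
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

# Linear inequality constraints A theta >= b on (l_mo, l_ts) of one tuned
# muscle. With kinematics fixed, the normalized length is monotone in the
# musculotendon length, so the gait extremes reduce to the precomputed
# min/max frames; all resulting constraints are linear in the parameters.
param_constraints <- function(Lmax, Lmin, LR, cosa, cfg) {
  lo <- cfg$lnorm_bounds[1]; hi <- cfg$lnorm_bounds[2]; d <- cfg$delta
  A <- rbind(c(hi * cosa, 1),         # max lnorm <= hi
             c(-(1 + d) * cosa, -1),  # max lnorm >= 1 + delta
             c(-lo * cosa, -1),       # min lnorm >= lo
             c((1 - d) * cosa, 1))    # min lnorm <= 1 - delta
  b <- c(Lmax, -Lmax, -Lmin, Lmin)
  if (!is.na(LR)) {
    A <- rbind(A, c(hi * cosa, 1), c(-(1 + d) * cosa, -1))
    b <- c(b, LR, -LR)
  }
  list(A = A, b = b)
}

project_params <- function(theta0, con, lower, upper) {
  A <- rbind(con$A, diag(2), -diag(2))
  b <- c(con$b + 1e-9, lower, -upper)
  sol <- tryCatch(
    quadprog::solve.QP(diag(2), theta0, t(A), b),
    error = function(e) NULL)
  if (is.null(sol))
    stop_capgap("no feasible muscle parameters under the length constraints",
                "capgap_init_error")
  sol$solution
}

#' Tune optimal fiber lengths and tendon slack lengths
#'
#' Estimates the two most influential Hill parameters of every tuned
#' (subset-M) muscle from gait data, EMG envelopes and the clinical
#' range-of-motion exam by an all-frames-coupled static optimization. The
#' decision variables are the per-frame activations, per-frame reserve
#' moments, the muscle parameters and one EMG scale factor per mapped
#' muscle. The cost sums squared activations, heavily penalized squared
#' reserve moments, squared deviations between scaled activations and EMG
#' envelopes, and a quadratic pull of the exam-stretch normalized length
#' toward 1.5 (where the passive curve transmits half the maximum isometric
#' force). Moment equilibrium at every frame and joint is enforced exactly
#' by construction (reserves are the equilibrium residual). Hard constraints
#' keep the normalized fiber length inside [0.4, 1.5] during gait, force it
#' to cross 1 within the cycle (the muscle operates around its optimal
#' length), and keep the exam stretch inside (1, 1.5].
#'
#' The problem is solved as a reduced program over the muscle parameters:
#' for fixed parameters the activations decouple into per-frame convex QPs
#' and the EMG scales have a closed-form update, so each evaluation of the
#' reduced objective solves that inner problem to optimality; the envelope
#' theorem then gives the exact reduced gradient, and a
#' sequential-quadratic-programming solver handles the (linear)
#' fiber-length constraints on the parameters. Seeded multi-start over
#' perturbed initial parameters guards against local minima of the
#' nonconvex reduced landscape.
#'
#' @param model an \code{msk_model} providing the initial parameters.
#' @param trial a \code{trial_bundle} (or list of bundles, concatenated)
#'   with moments, lengths, moment arms and EMG.
#' @param rom a \code{\link{rom_assessment}} covering the tuned muscles.
#' @param config a \code{\link{tuning_config}}.
#' @return An object of class \code{tuning_result}: estimated \code{l_mo},
#'   \code{l_ts}, EMG scales \code{sigma}, \code{activations},
#'   \code{reserves}, normalized lengths \code{lnorm}, cost breakdown and
#'   solver diagnostics.
#' @export
tune_muscle_parameters <- function(model, trial, rom,
                                   config = tuning_config()) {
  trial <- concat_bundles(trial)
  if (is.null(trial$tau) || is.null(trial$l_mt) || is.null(trial$r))
    stop_capgap("trial must carry moments, lengths and moment arms",
                "capgap_config_error")
  mn <- muscle_names(model)
  cn <- coordinate_names(model)
  tuned <- mn[vapply(model$muscles, function(m) m$subset == "M", TRUE)]
  nT <- length(trial$time)
  LMT <- trial$l_mt[, mn, drop = FALSE]
  Rarr <- trial$r[, mn, cn, drop = FALSE]
  TAU <- trial$tau[, cn, drop = FALSE]
  Emus <- emg_per_muscle(trial, model)
  emg_mus <- colnames(Emus)
  emg_idx <- match(emg_mus, mn)
  Fmax <- vapply(model$muscles, `[[`, 0, "F_max")[mn]
  cosa <- vapply(model$muscles, function(m) cos(m$alpha), 0)[mn]
  is_tuned <- mn %in% tuned

  rom_l <- rom_musculotendon_lengths(model, rom)
  missing_rom <- setdiff(tuned, names(rom_l))
  LR <- setNames(rep(NA_real_, length(tuned)), tuned)
  LR[intersect(tuned, names(rom_l))] <- rom_l[intersect(tuned, names(rom_l))]

  Lmax <- apply(LMT[, tuned, drop = FALSE], 2, max)
  Lmin <- apply(LMT[, tuned, drop = FALSE], 2, min)
  theta0 <- c(vapply(model$muscles[tuned], `[[`, 0, "l_mo"),
              vapply(model$muscles[tuned], `[[`, 0, "l_ts"))
  nt <- length(tuned)
  lower <- theta0 * config$param_range[1]
  upper <- theta0 * config$param_range[2]
  cons <- lapply(seq_len(nt), function(k)
    param_constraints(Lmax[k], Lmin[k], LR[k], cosa[tuned[k]], config))

  # stacked linear constraints for the joint parameter vector
  A_all <- matrix(0, sum(vapply(cons, function(cc) nrow(cc$A), 0L)), 2 * nt)
  b_all <- numeric(nrow(A_all))
  ri <- 0L
  for (k in seq_len(nt)) {
    nr <- nrow(cons[[k]]$A)
    A_all[ri + seq_len(nr), c(k, nt + k)] <- cons[[k]]$A
    b_all[ri + seq_len(nr)] <- cons[[k]]$b
    ri <- ri + nr
  }

  w1 <- config$w1; w2 <- config$w2; w3 <- config$w3; w4 <- config$w4

  model_quants <- function(theta, act = NULL) {
    lmo <- theta[seq_len(nt)]; lts <- theta[nt + seq_len(nt)]
    ln_t <- sweep(sweep(LMT[, tuned, drop = FALSE], 2, lts, "-"),
                  2, cosa[tuned] * lmo, "/")
    fL <- evaluate_curve(model$curves, "active", pmax(ln_t, 1e-6))
    fP <- evaluate_curve(model$curves, "passive", pmax(ln_t, 1e-6))
    G <- matrix(rep(Fmax, each = nT), nT, length(mn),
                dimnames = list(NULL, mn))
    P <- matrix(0, nT, length(mn), dimnames = list(NULL, mn))
    G[, tuned] <- sweep(fL, 2, Fmax[tuned], "*")
    P[, tuned] <- sweep(fP, 2, Fmax[tuned], "*")
    out <- list(lnorm = ln_t, G = G, P = P,
                lnR = (LR - lts) / (cosa[tuned] * lmo))
    if (!is.null(act)) {
      F <- act * G + P
      mom <- vapply(cn, function(j) rowSums(Rarr[, , j] * F), numeric(nT))
      out$reserves <- TAU - mom
    }
    out
  }

  cost_of <- function(a, sigma, theta) {
    q <- model_quants(theta, a)
    c_so <- w1 * sum(a^2) + w2 * sum(q$reserves^2)
    c_eps <- if (length(emg_mus))
      w3 * sum((sweep(a[, emg_mus, drop = FALSE], 2, sigma, "*") - Emus)^2)
    else 0
    lnR <- q$lnR[!is.na(q$lnR)]
    c_r <- w4 * sum((lnR - 1.5)^2)
    list(total = c_so + c_eps + c_r, C_SO = c_so, C_eps = c_eps, C_R = c_r)
  }

  a_step <- function(theta, sigma) {
    q <- model_quants(theta)
    a <- matrix(0, nT, length(mn), dimnames = list(NULL, mn))
    for (i in seq_len(nT)) {
      B <- t(Rarr[i, , ] * q$G[i, ])
      tau_free <- TAU[i, ] - as.vector(crossprod(Rarr[i, , ], q$P[i, ]))
      a[i, ] <- solve_activation_qp(B, tau_free, w1, w2, w3, sigma,
                                    if (length(emg_mus)) Emus[i, ],
                                    emg_idx)
    }
    a
  }

  sigma_step <- function(a) {
    if (!length(emg_mus)) return(numeric(0))
    s <- vapply(seq_along(emg_mus), function(k) {
      am <- a[, emg_mus[k]]
      den <- sum(am^2)
      if (den < 1e-12) 1 else sum(am * Emus[, k]) / den
    }, 0)
    pmin(pmax(s, config$sigma_bounds[1]), config$sigma_bounds[2])
  }

  theta_grad <- function(th, a) {
      lmo <- th[seq_len(nt)]; lts <- th[nt + seq_len(nt)]
      q <- model_quants(th, a)
      S <- matrix(0, nT, nt)
      for (j in seq_along(cn))
        S <- S + Rarr[, tuned, j, drop = TRUE] * q$reserves[, j]
      at <- a[, tuned, drop = FALSE]
      dfl <- curve_deriv(model$curves, "active", q$lnorm)
      dfp <- curve_deriv(model$curves, "passive", q$lnorm)
      dF_dln <- sweep(at * dfl + dfp, 2, Fmax[tuned], "*")
      dln_dlmo <- sweep(-q$lnorm, 2, lmo, "/")
      dln_dlts <- matrix(rep(-1 / (cosa[tuned] * lmo), each = nT), nT, nt)
      g_lmo <- -2 * w2 * colSums(S * dF_dln * dln_dlmo)
      g_lts <- -2 * w2 * colSums(S * dF_dln * dln_dlts)
      hasR <- !is.na(LR)
      lnR <- q$lnR
      g_lmo[hasR] <- g_lmo[hasR] +
        2 * w4 * (lnR[hasR] - 1.5) * (-lnR[hasR] / lmo[hasR])
      g_lts[hasR] <- g_lts[hasR] +
        2 * w4 * (lnR[hasR] - 1.5) * (-1 / (cosa[tuned][hasR] * lmo[hasR]))
      c(g_lmo, g_lts)
  }

  # Reduced problem over the muscle parameters: every evaluation solves the
  # convex inner (activation, EMG-scale) problem to optimality; by the
  # envelope theorem the gradient of the reduced objective is the partial
  # parameter gradient evaluated at the inner optimum.
  inner_solve <- function(theta) {
    sigma <- rep(1, length(emg_mus))
    a <- a_step(theta, sigma)
    for (k in seq_len(8)) {
      s_new <- sigma_step(a)
      moved <- if (length(sigma)) max(abs(s_new - sigma)) else 0
      sigma <- s_new
      a <- a_step(theta, sigma)
      if (moved < 1e-6) break
    }
    list(a = a, sigma = sigma, cost = cost_of(a, sigma, theta))
  }

  run_from <- function(theta_start) {
    cache <- new.env()
    solved_at <- function(theta) {
      key <- paste(format(theta, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        cache$sol <- inner_solve(theta)
        cache$key <- key
      }
      cache$sol
    }
    trace <- numeric(0)
    fn <- function(th) {
      v <- solved_at(th)$cost$total
      trace <<- c(trace, v)
      v
    }
    gr <- function(th) theta_grad(th, solved_at(th)$a)
    fit <- nloptr::slsqp(theta_start, fn, gr = gr,
                         lower = lower, upper = upper,
                         hin = function(th) b_all - as.vector(A_all %*% th),
                         hinjac = function(th) -A_all,
                         deprecatedBehavior = FALSE,
                         control = list(xtol_rel = config$tol,
                                        maxeval = config$max_outer))
    sol <- inner_solve(fit$par)
    list(theta = fit$par, a = sol$a, sigma = sol$sigma, cost = sol$cost,
         trace = trace,
         converged = fit$convergence > 0 && fit$convergence != 5L,
         status = fit$convergence,
         iterations = length(trace))
  }

  starts <- list(project_params_all(theta0, cons, lower, upper, nt))
  if (config$n_starts > 1) {
    perturbs <- with_preserved_rng({
      set.seed(config$seed)
      lapply(seq_len(config$n_starts - 1), function(s)
        stats::runif(2 * nt, 1 - config$start_spread,
                     1 + config$start_spread))
    })
    for (p in perturbs)
      starts <- c(starts, list(project_params_all(theta0 * p, cons,
                                                  lower, upper, nt)))
  }
  runs <- lapply(starts, run_from)
  best <- runs[[which.min(vapply(runs, function(r) r$cost$total, 0))]]

  q <- model_quants(best$theta, best$a)
  structure(list(
    l_mo = setNames(best$theta[seq_len(nt)], tuned),
    l_ts = setNames(best$theta[nt + seq_len(nt)], tuned),
    sigma = setNames(best$sigma, emg_mus),
    activations = best$a,
    reserves = q$reserves,
    lnorm = q$lnorm,
    lnorm_rom = q$lnR,
    cost = best$cost,
    trace = best$trace,
    start_costs = vapply(runs, function(r) r$cost$total, 0),
    converged = best$converged,
    status = best$status,
    iterations = best$iterations,
    missing_rom = missing_rom,
    tuned = tuned,
    config = unclass(config),
    model_name = model$name),
    class = "tuning_result")
}

project_params_all <- function(theta, cons, lower, upper, nt) {
  out <- theta
  for (k in seq_len(nt)) {
    th_k <- project_params(theta[c(k, nt + k)], cons[[k]],
                           lower[c(k, nt + k)], upper[c(k, nt + k)])
    out[k] <- th_k[1]; out[nt + k] <- th_k[2]
  }
  out
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d tuned muscles, converged: %s (%d outer iterations)\n",
              length(x$l_mo), x$converged, x$iterations))
  cat(sprintf("  cost: total %.4g (C_SO %.4g, C_eps %.4g, C_R %.4g)\n",
              x$cost$total, x$cost$C_SO, x$cost$C_eps, x$cost$C_R))
  cat(sprintf("  max |reserve| %.4g N m, lnorm in [%.3f, %.3f]\n",
              max(abs(x$reserves)), min(x$lnorm), max(x$lnorm)))
  invisible(x)
}

#' Write tuned parameters into a model
#'
#' Returns a copy of the model with the estimated optimal fiber lengths and
#' tendon slack lengths installed on the tuned muscles; untuned muscles are
#' unchanged and lineage is set to the input model.
#'
#' @param model the \code{msk_model} the result was computed for.
#' @param result a \code{tuning_result}.
#' @return The updated \code{msk_model}.
#' @export
apply_tuned_parameters <- function(model, result) {
  bad <- setdiff(names(result$l_mo), muscle_names(model))
  if (length(bad))
    stop_capgap(sprintf("tuning result references unknown muscle '%s'", bad[1]),
                "capgap_config_error")
  if (!isTRUE(result$converged))
    warning("applying parameters from a non-converged tuning result")
  new <- model
  for (m in names(result$l_mo)) {
    new$muscles[[m]]$l_mo <- unname(result$l_mo[m])
    new$muscles[[m]]$l_ts <- unname(result$l_ts[m])
  }
  new$lineage <- model$name
  new
}

#' Scale maximum isometric forces by body mass
#'
#' One-line utility implementing mass-ratio scaling of the maximum isometric
#' forces (strength scales with body weight); not an optimization.
#'
#' @param model an \code{msk_model}.
#' @param mass subject mass (kg).
#' @param mass_ref mass the model's forces are expressed at (kg).
#' @return The scaled model.
#' @export
scale_max_forces <- function(model, mass, mass_ref) {
  for (m in muscle_names(model))
    model$muscles[[m]]$F_max <- model$muscles[[m]]$F_max * mass / mass_ref
  model
}
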