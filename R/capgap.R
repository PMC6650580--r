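#' Configuration for the capability-gap computation
#'
#' @param use_synergies constrain activations to the synergy space
#'   (\code{FALSE} simulates unimpaired, fully selective motor control).
#' @param use_force_length include the muscle force-length relationship
#'   (\code{FALSE} makes every muscle activation-proportional).
#' @param delta_w_bound elementwise bound on the deviation from the
#'   max-normalized pre-operative synergy weights.
#' @param w1,w2 activation and reserve cost weights.
#' @param max_alternations maximum stage-2 alternations between the
#'   temporal and weight-deviation blocks.
#' @param tol objective-change convergence tolerance.
#' @param tau_floor denominator floor (summed |moment|, N m) protecting the
#'   per-joint gap ratio when a joint's desired moments are near zero.
#' @param seed integer seed (recorded; the solver itself is deterministic).
#' @return An object of class \code{cg_config}.
#' @export
cg_config <- function(use_synergies = TRUE, use_force_length = TRUE,
                      delta_w_bound = 0.05, w1 = 1, w2 = 10,
                      max_alternations = 10, tol = 1e-6, tau_floor = 1,
                      seed = 0L) {
  stopifnot(delta_w_bound >= 0, w1 >= 0, w2 > 0, tau_floor > 0)
  structure(list(use_synergies = use_synergies,
                 use_force_length = use_force_length,
                 delta_w_bound = delta_w_bound, w1 = w1, w2 = w2,
                 max_alternations = max_alternations, tol = tol,
                 tau_floor = tau_floor, seed = seed),
            class = "cg_config")
}

#' Compute the capability gap
#'
#' Quantifies how well a personalized model, constrained by the patient's
#' motor control, can generate the joint moments of a desired
#' (typically-developing) gait pattern. A synergy-constrained static
#' optimization minimizes squared activations plus heavily penalized squared
#' reserve moments subject to moment equilibrium at every frame and joint;
#' reserves absorb whatever the muscles cannot produce, so equilibrium holds
#' by construction. Activations are composed from the pre-operative synergy
#' weights, a bounded weight deviation and non-negative synergy activations,
#' \eqn{a_i = (W^{pre} + \Delta W) H_i}, clamped to [0, 1] through explicit
#' constraints. Stage 1 solves per-frame convex QPs in the synergy
#' activations with \eqn{\Delta W = 0}; stage 2 alternates convex QPs in the
#' temporal block and the (shared, time-invariant) weight-deviation block
#' until the objective stalls. The per-joint capability gap is
#' \eqn{CG_j = \sum_i |\tau^R_{ji}| / \sum_i |\tau^{ID}_{ji}|} and the
#' summary is its unweighted mean over joints.
#'
#' @param model the (pre- or post-operative) \code{msk_model}.
#' @param motor_control a \code{motor_control_model} matching the model's
#'   muscle set (ignored when \code{use_synergies = FALSE}).
#' @param desired a \code{trial_bundle} holding the desired motion evaluated
#'   on this model (see \code{\link{make_reference_trial}}).
#' @param config a \code{\link{cg_config}}.
#' @return An object of class \code{capgap_result}: \code{reserves},
#'   \code{H_opt}, \code{delta_W}, \code{activations}, per-joint \code{CG}
#'   and \code{CG_mean}, plus the objective trace.
#' @export
compute_capability_gap <- function(model, motor_control = NULL, desired,
                                   config = cg_config()) {
  mn <- muscle_names(model)
  cn <- coordinate_names(model)
  nT <- length(desired$time)
  if (is.null(desired$tau) || is.null(desired$l_mt) || is.null(desired$r))
    stop_capgap("desired trial must carry moments, lengths and moment arms",
                "capgap_config_error")
  LMT <- desired$l_mt[, mn, drop = FALSE]
  Rarr <- desired$r[, mn, cn, drop = FALSE]
  TAU <- desired$tau[, cn, drop = FALSE]
  G <- matrix(NA_real_, nT, length(mn), dimnames = list(NULL, mn))
  P <- matrix(0, nT, length(mn), dimnames = list(NULL, mn))
  for (m in mn) {
    mu <- model$muscles[[m]]
    if (config$use_force_length && mu$subset == "M") {
      ln <- fiber_state(LMT[, m], mu)$l_norm
      G[, m] <- mu$F_max * evaluate_curve(model$curves, "active", ln)
      P[, m] <- mu$F_max * evaluate_curve(model$curves, "passive", ln)
    } else {
      G[, m] <- mu$F_max
    }
  }
  w1 <- config$w1; w2 <- config$w2
  frameB <- function(i) t(Rarr[i, , ] * G[i, ])
  frame_tau_free <- function(i)
    TAU[i, ] - as.vector(crossprod(Rarr[i, , ], P[i, ]))

  if (!config$use_synergies) {
    a <- matrix(0, nT, length(mn), dimnames = list(NULL, mn))
    for (i in seq_len(nT))
      a[i, ] <- solve_activation_qp(frameB(i), frame_tau_free(i), w1, w2)
    H <- NULL; dW <- NULL; trace <- NA_real_
  } else {
    if (is.null(motor_control))
      stop_capgap("motor_control required when use_synergies = TRUE",
                  "capgap_config_error")
    W0 <- motor_control$W_pre
    if (!identical(sort(rownames(W0)), sort(mn)))
      stop_capgap("motor-control muscle set does not match the model",
                  "capgap_config_error")
    W0 <- W0[mn, , drop = FALSE]
    K <- ncol(W0)
    dW <- matrix(0, length(mn), K, dimnames = dimnames(W0))
    solve_H <- function(W) {
      H <- matrix(0, nT, K)
      for (i in seq_len(nT)) {
        C <- frameB(i) %*% W
        M <- w1 * crossprod(W) + w2 * crossprod(C)
        cvec <- w2 * as.vector(crossprod(C, frame_tau_free(i)))
        H[i, ] <- solve_qp(M, cvec, lower = rep(0, K),
                           A = -W, b = rep(-1, length(mn)), ridge = 1e-9)
      }
      H
    }
    objective <- function(W, H) {
      a <- pmin(pmax(H %*% t(W), 0), 1)
      F <- a * G + P
      mom <- vapply(cn, function(j) rowSums(Rarr[, , j] * F), numeric(nT))
      w1 * sum(a^2) + w2 * sum((TAU - mom)^2)
    }
    solve_dW <- function(H) {
      # quadratic in vec(dW): a_i = (W0 + dW) H_i, coupled across muscles
      # through the moment residual. Activation upper bounds are added by
      # constraint generation.
      nm <- length(mn)
      nv <- nm * K
      Q <- matrix(0, nv, nv)
      cvec <- numeric(nv)
      const_resid <- matrix(0, nT, length(cn))
      a0 <- H %*% t(W0)
      for (i in seq_len(nT)) {
        B <- frameB(i)
        resid0 <- frame_tau_free(i) - as.vector(B %*% a0[i, ])
        Ki <- kronecker(matrix(H[i, ], 1, K), diag(nm))  # a_i = a0_i + Ki x
        BK <- B %*% Ki
        Q <- Q + w1 * crossprod(Ki) + w2 * crossprod(BK)
        cvec <- cvec + w2 * as.vector(crossprod(BK, resid0)) -
          w1 * as.vector(crossprod(Ki, a0[i, ]))
        const_resid[i, ] <- resid0
      }
      lowv <- pmax(-config$delta_w_bound, -as.vector(W0))
      uppv <- rep(config$delta_w_bound, nv)
      Acons <- NULL; bcons <- NULL
      for (round in 1:5) {
        x <- solve_qp(Q, cvec, lower = lowv, upper = uppv,
                      A = Acons, b = bcons, ridge = 1e-9)
        dWx <- matrix(x, nm, K)
        a <- H %*% t(W0 + dWx)
        viol <- which(a > 1 + 1e-9, arr.ind = TRUE)
        if (!nrow(viol)) break
        viol <- viol[seq_len(min(nrow(viol), 50)), , drop = FALSE]
        for (vi in seq_len(nrow(viol))) {
          i <- viol[vi, 1]; m <- viol[vi, 2]
          row <- rep(0, nv)
          row[(seq_len(K) - 1) * nm + m] <- H[i, ]
          Acons <- rbind(Acons, -row)
          bcons <- c(bcons, -(1 - sum(W0[m, ] * H[i, ])))
        }
      }
      dWx
    }
    H <- solve_H(W0)
    trace <- objective(W0, H)
    if (config$delta_w_bound > 0 && config$max_alternations > 0) {
      for (alt in seq_len(config$max_alternations)) {
        dW_new <- solve_dW(H)
        H_new <- solve_H(W0 + dW_new)
        obj_new <- objective(W0 + dW_new, H_new)
        if (obj_new > trace[length(trace)] + 1e-12) break
        dW <- dW_new; H <- H_new
        dec <- trace[length(trace)] - obj_new
        trace <- c(trace, obj_new)
        if (dec < config$tol * max(1, obj_new)) break
      }
    }
    a <- pmin(pmax(H %*% t(W0 + dW), 0), 1)
    colnames(a) <- mn
  }

  F <- a * G + P
  mom <- vapply(cn, function(j) rowSums(Rarr[, , j] * F), numeric(nT))
  reserves <- TAU - mom
  denom <- pmax(colSums(abs(TAU)), config$tau_floor)
  CG <- colSums(abs(reserves)) / denom
  structure(list(reserves = reserves, H_opt = H, delta_W = dW,
                 activations = a, CG = setNames(CG, cn),
                 CG_mean = mean(CG), tau_desired = TAU,
                 muscle_moments = mom, lnorm = lnorm_matrix(model, LMT),
                 objective_trace = trace, config = unclass(config),
                 model_name = model$name),
            class = "capgap_result")
}

lnorm_matrix <- function(model, LMT) {
  mn <- muscle_names(model)
  tuned <- mn[vapply(model$muscles, function(m) m$subset == "M", TRUE)]
  out <- matrix(NA_real_, nrow(LMT), length(tuned),
                dimnames = list(NULL, tuned))
  for (m in tuned)
    out[, m] <- fiber_state(LMT[, m], model$muscles[[m]])$l_norm
  out
}

#' @export
print.capgap_result <- function(x, ...) {
  cat(sprintf("<capgap_result> model '%s', mean CG = %.4f\n",
              x$model_name, x$CG_mean))
  for (j in names(x$CG)) cat(sprintf("  %-14s CG = %.4f\n", j, x$CG[j]))
  invisible(x)
}

#' Muscle operating-length report
#'
#' Flags, frame by frame over the desired motion, muscles that are
#' excessively stretched (passive force above half the maximum isometric
#' force, i.e., normalized fiber length beyond the passive half-force
#' length) and muscles active at short lengths (activation above 0.25 while
#' the normalized fiber length is below 0.6, where little active force is
#' produced). Flags are summarized as maximal consecutive frame intervals.
#'
#' @param model the \code{msk_model} used for the gap computation.
#' @param result a \code{capgap_result}.
#' @param stretched_threshold passive-force threshold (fraction of
#'   F_max).
#' @param short_activation,short_lnorm thresholds of the short-active flag.
#' @return list with logical flag matrices \code{stretched} and
#'   \code{short_active} (time x tuned muscle) and an \code{intervals}
#'   data frame (muscle, flag, start, end).
#' @export
muscle_operating_report <- function(model, result,
                                    stretched_threshold = 0.5,
                                    short_activation = 0.25,
                                    short_lnorm = 0.6) {
  ln <- result$lnorm
  mus <- colnames(ln)
  fP <- evaluate_curve(model$curves, "passive", pmax(ln, 1e-6))
  stretched <- fP > stretched_threshold
  short_active <- (result$activations[, mus, drop = FALSE] > short_activation) &
    (ln < short_lnorm)
  rows <- list()
  for (m in mus) {
    for (fl in c("stretched", "short_active")) {
      runs <- flag_runs(if (fl == "stretched") stretched[, m]
                        else short_active[, m])
      if (nrow(runs))
        rows[[length(rows) + 1]] <- data.frame(
          muscle = m, flag = fl, start = runs[, "start"], end = runs[, "end"])
    }
  }
  intervals <- if (length(rows)) do.call(rbind, rows)
  else data.frame(muscle = character(), flag = character(),
                  start = integer(), end = integer())
  list(stretched = stretched, short_active = short_active,
       intervals = intervals)
}

#' Gait-profile-style RMSE between two kinematic patterns
#'
#' Per-joint root-mean-square error between subject and reference joint
#' angle curves over a common cycle grid (the per-joint values correspond to
#' gait variable scores) and their root-mean-square aggregate (the
#' gait-profile-style summary).
#'
#' @param q_subject,q_reference time x joint angle matrices (rad) on the
#'   same grid.
#' @return list with \code{per_joint_deg} and \code{aggregate_deg}.
#' @export
gait_profile_rmse <- function(q_subject, q_reference) {
  if (!all(dim(q_subject) == dim(q_reference)))
    stop_capgap("kinematic matrices must share dimensions and grid",
                "capgap_internal_error")
  d <- (q_subject - q_reference) * RAD2DEG
  per <- sqrt(colMeans(d^2))
  if (!is.null(colnames(q_subject))) names(per) <- colnames(q_subject)
  list(per_joint_deg = per, aggregate_deg = sqrt(mean(per^2)))
}

#' Compare pre- and post-operative capability gaps
#'
#' @param pre,post \code{capgap_result}s on the same joint set.
#' @return data frame with per-joint pre/post gaps and their change
#'   (post minus pre), plus a mean row.
#' @export
compare_conditions <- function(pre, post) {
  if (!identical(names(pre$CG), names(post$CG)))
    stop_capgap("pre and post results have different joint sets",
                "capgap_config_error")
  out <- data.frame(joint = names(pre$CG),
                    cg_pre = unname(pre$CG), cg_post = unname(post$CG),
                    delta = unname(post$CG - pre$CG))
  rbind(out, data.frame(joint = "mean", cg_pre = pre$CG_mean,
                        cg_post = post$CG_mean,
                        delta = post$CG_mean - pre$CG_mean))
}

#' Plot required versus produced joint moments with the gap shaded
#'
#' One panel per joint: the desired inverse-dynamics moment (solid), the
#' moment the muscles produce (dashed) and the capability gap between them
#' (shaded).
#'
#' @param x a \code{capgap_result}.
#' @param joints joints to plot (default all).
#' @param ... passed to \code{matplot}-style base graphics.
#' @return \code{x}, invisibly.
#' @export
plot.capgap_result <- function(x, joints = names(x$CG), ...) {
  old <- graphics::par(mfrow = c(length(joints), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  frames <- seq_len(nrow(x$tau_desired))
  for (j in joints) {
    des <- x$tau_desired[, j]
    prod <- x$muscle_moments[, j]
    graphics::plot(frames, des, type = "n",
                   ylim = range(c(des, prod)), xlab = "",
                   ylab = "moment (N m)", main = sprintf(
                     "%s  (CG = %.3f)", j, x$CG[[j]]), ...)
    graphics::polygon(c(frames, rev(frames)), c(des, rev(prod)),
                      col = "grey85", border = NA)
    graphics::lines(frames, des, lwd = 2)
    graphics::lines(frames, prod, lty = 2)
  }
  invisible(x)
}
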