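#' Non-negative matrix factorization of EMG or activation envelopes
#'
#' Factorizes a non-negative channel-by-time matrix E into non-negative
#' spatial weights W (channels x k) and temporal activations H (k x time)
#' with multiplicative updates, minimizing the Frobenius reconstruction
#' error. The best of \code{restarts} seeded uniform random initializations
#' is kept. Reconstruction quality is summarized as the variance accounted
#' for, \eqn{VAF = 1 - \|E - WH\|_F^2 / \|E\|_F^2} (global, not
#' per-channel).
#'
#' @param E non-negative matrix (channels x time) with no all-zero rows.
#' @param k number of synergies, at most \code{min(dim(E))}.
#' @param restarts number of random initializations.
#' @param seed integer seed.
#' @param max_iter maximum multiplicative updates per restart.
#' @param tol relative objective-change stopping tolerance.
#' @return An object of class \code{synergy_set} with \code{W}, \code{H},
#'   \code{k}, \code{vaf} and the per-iteration objective \code{trace} of
#'   the winning restart.
#' @export
nnmf_factorize <- function(E, k, restarts = 10, seed = 0L,
                           max_iter = 2000, tol = 1e-6) {
  E <- as.matrix(E)
  if (any(E < 0))
    stop_capgap("NNMF input must be non-negative", "capgap_domain_error")
  if (any(rowSums(E) == 0))
    stop_capgap("NNMF input has an all-zero row", "capgap_domain_error")
  if (k > min(dim(E)))
    stop_capgap("k must not exceed the matrix dimensions", "capgap_domain_error")
  n <- nrow(E); m <- ncol(E)
  inits <- with_preserved_rng({
    set.seed(seed)
    lapply(seq_len(restarts), function(s)
      list(W = matrix(stats::runif(n * k, 0.01, 1), n, k),
           H = matrix(stats::runif(k * m, 0.01, 1), k, m)))
  })
  best <- NULL
  for (init in inits) {
    W <- init$W; H <- init$H
    err_prev <- Inf; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      H <- H * crossprod(W, E) / (crossprod(W) %*% H + 1e-12)
      W <- W * tcrossprod(E, H) / (W %*% tcrossprod(H) + 1e-12)
      err <- sum((E - W %*% H)^2)
      trace <- c(trace, err)
      if (is.finite(err_prev) &&
          (err_prev - err) < tol * max(err_prev, 1e-300)) break
      err_prev <- err
    }
    if (is.null(best) || err < best$err)
      best <- list(W = W, H = H, err = err, trace = trace)
  }
  vaf <- 1 - best$err / sum(E^2)
  structure(list(W = best$W, H = best$H, k = k, vaf = vaf,
                 frob_error = best$err, trace = best$trace),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("<synergy_set> k = %d, VAF = %.4f\n", x$k, x$vaf))
  invisible(x)
}

#' Bootstrap configuration for synergy-number selection
#'
#' @param n_resamples number of with-replacement time resamples.
#' @param vaf_threshold VAF level a resample must exceed.
#' @param coverage required fraction of resamples above the threshold.
#' @param k_max largest synergy number considered.
#' @param restarts NNMF restarts per candidate k.
#' @param seed integer seed.
#' @return An object of class \code{bootstrap_config}.
#' @export
bootstrap_config <- function(n_resamples = 500, vaf_threshold = 0.90,
                             coverage = 0.95, k_max = 6, restarts = 10,
                             seed = 0L) {
  stopifnot(vaf_threshold > 0, vaf_threshold < 1,
            coverage > 0, coverage < 1, n_resamples >= 1, k_max >= 1)
  structure(list(n_resamples = n_resamples, vaf_threshold = vaf_threshold,
                 coverage = coverage, k_max = k_max, restarts = restarts,
                 seed = seed),
            class = "bootstrap_config")
}

#' Select the number of muscle synergies by bootstrap
#'
#' For each candidate synergy number k, the EMG matrix is factorized once;
#' then time instants are resampled with replacement (the same instants
#' taken from the EMG matrix and from the temporal activations H, which
#' stay paired), and the VAF of each resampled signal by the synergies
#' extracted from the original signal is computed with W held fixed. The
#' selected number of synergies is the smallest k for which the VAF exceeds
#' the threshold (default 90\%) in at least the required fraction of
#' resamples (default 95\% of 500).
#'
#' @param E non-negative channel x time EMG matrix.
#' @param config a \code{\link{bootstrap_config}}.
#' @return list with \code{N_s} (NA with \code{status =
#'   "insufficient VAF"} when no k qualifies), \code{status}, and the
#'   per-k \code{table} (vaf of the full signal, bootstrap coverage).
#' @export
select_num_synergies <- function(E, config = bootstrap_config()) {
  E <- as.matrix(E)
  k_max <- min(config$k_max, dim(E))
  nTime <- ncol(E)
  fits <- lapply(seq_len(k_max), function(k)
    nnmf_factorize(E, k, restarts = config$restarts, seed = config$seed))
  idx_draws <- with_preserved_rng({
    set.seed(config$seed)
    lapply(seq_len(config$n_resamples), function(b)
      sample.int(nTime, nTime, replace = TRUE))
  })
  cover <- vapply(seq_len(k_max), function(k) {
    W <- fits[[k]]$W; H <- fits[[k]]$H
    vafs <- vapply(idx_draws, function(idx) {
      Eb <- E[, idx, drop = FALSE]
      Hb <- H[, idx, drop = FALSE]
      1 - sum((Eb - W %*% Hb)^2) / sum(Eb^2)
    }, 0)
    mean(vafs > config$vaf_threshold)
  }, 0)
  tab <- data.frame(k = seq_len(k_max),
                    vaf = vapply(fits, `[[`, 0, "vaf"),
                    coverage = cover)
  qual <- which(cover >= config$coverage)
  if (length(qual)) {
    list(N_s = min(qual), status = "ok", table = tab)
  } else {
    list(N_s = NA_integer_, status = "insufficient VAF", table = tab)
  }
}

#' EMG-informed static optimization
#'
#' Resolves muscle redundancy on a (tuned) model over a gait trial with the
#' activation-versus-EMG tracking term included: per-frame convex QPs in the
#' activations (reserve moments are the heavily penalized equilibrium
#' residual), alternating with a closed-form least-squares update of each
#' EMG scale factor \eqn{\sigma_m = \sum_i a_{mi}\epsilon_{mi} / \sum_i
#' a_{mi}^2} (clipped to bounds), until the scales move less than
#' \code{tol}. With \code{w3 = 0} this reduces to plain static
#' optimization.
#'
#' @param model an \code{msk_model} (parameters fixed).
#' @param trial a complete \code{trial_bundle}.
#' @param w1,w2,w3 cost weights (activations, reserves, EMG tracking).
#' @param sigma_bounds bounds on the EMG scale factors.
#' @param max_iter maximum alternations.
#' @param tol convergence tolerance on the scale factors.
#' @return list with \code{activations} (time x muscle), \code{reserves}
#'   (time x joint), \code{sigma}, \code{iterations} and \code{converged}.
#' @export
emg_informed_activations <- function(model, trial, w1 = 1, w2 = 10, w3 = 5,
                                     sigma_bounds = c(0.05, 20),
                                     max_iter = 50, tol = 1e-4) {
  trial <- concat_bundles(trial)
  mn <- muscle_names(model)
  cn <- coordinate_names(model)
  nT <- length(trial$time)
  LMT <- trial$l_mt[, mn, drop = FALSE]
  Rarr <- trial$r[, mn, cn, drop = FALSE]
  TAU <- trial$tau[, cn, drop = FALSE]
  Emus <- if (w3 > 0) emg_per_muscle(trial, model) else NULL
  emg_mus <- colnames(Emus)
  emg_idx <- match(emg_mus, mn)
  G <- matrix(NA_real_, nT, length(mn), dimnames = list(NULL, mn))
  P <- matrix(0, nT, length(mn), dimnames = list(NULL, mn))
  for (m in mn) {
    mu <- model$muscles[[m]]
    if (mu$subset == "M") {
      ln <- fiber_state(LMT[, m], mu)$l_norm
      G[, m] <- mu$F_max * evaluate_curve(model$curves, "active", ln)
      P[, m] <- mu$F_max * evaluate_curve(model$curves, "passive", ln)
    } else {
      G[, m] <- mu$F_max
    }
  }
  solve_frames <- function(sigma) {
    a <- matrix(0, nT, length(mn), dimnames = list(NULL, mn))
    for (i in seq_len(nT)) {
      B <- t(Rarr[i, , ] * G[i, ])
      tau_free <- TAU[i, ] - as.vector(crossprod(Rarr[i, , ], P[i, ]))
      a[i, ] <- solve_activation_qp(B, tau_free, w1, w2,
                                    if (length(emg_mus)) w3 else 0,
                                    sigma, if (length(emg_mus)) Emus[i, ],
                                    emg_idx)
    }
    a
  }
  cost_of <- function(a, sigma) {
    F <- a * G + P
    mom <- vapply(cn, function(j) rowSums(Rarr[, , j] * F), numeric(nT))
    cst <- w1 * sum(a^2) + w2 * sum((TAU - mom)^2)
    if (length(emg_mus))
      cst <- cst + w3 * sum((sweep(a[, emg_mus, drop = FALSE], 2, sigma,
                                   "*") - Emus)^2)
    cst
  }
  sigma <- rep(1, length(emg_mus))
  converged <- length(emg_mus) == 0
  a <- solve_frames(sigma)
  cost <- cost_of(a, sigma)
  it <- 0L
  while (length(emg_mus) && it < max_iter) {
    it <- it + 1L
    s_new <- vapply(seq_along(emg_mus), function(k) {
      am <- a[, emg_mus[k]]
      den <- sum(am^2)
      if (den < 1e-12) 1 else sum(am * Emus[, k]) / den
    }, 0)
    s_new <- pmin(pmax(s_new, sigma_bounds[1]), sigma_bounds[2])
    moved <- max(abs(s_new - sigma))
    sigma <- s_new
    a <- solve_frames(sigma)
    cost_new <- cost_of(a, sigma)
    # both block steps are exact minimizations, so the cost is monotone;
    # stop on a stationary scale vector or a stationary cost (the scales
    # can wander along a flat valley of the joint cost)
    if (moved < tol || (cost - cost_new) < 1e-8 * max(1, cost)) {
      cost <- cost_new
      converged <- TRUE
      break
    }
    cost <- cost_new
  }
  F <- a * G + P
  mom <- vapply(cn, function(j) rowSums(Rarr[, , j] * F), numeric(nT))
  list(activations = a, reserves = TAU - mom,
       sigma = setNames(sigma, emg_mus), iterations = it,
       converged = converged)
}

#' Build the patient's motor-control model
#'
#' Extracts an extended synergy set from the all-muscle activation matrix of
#' the EMG-informed static optimization, using one synergy more than the
#' EMG-derived count so muscles without surface EMG can load onto the extra
#' component. Weight columns are rescaled to a maximum of one (with the
#' temporal activations rescaled inversely, leaving the reconstruction
#' unchanged).
#'
#' @param activations time x muscle activation matrix (all model muscles).
#' @param N_s EMG-derived synergy count.
#' @param restarts NNMF restarts.
#' @param seed integer seed.
#' @return An object of class \code{motor_control_model}: \code{W_pre}
#'   (muscle x (N_s + 1), column maxima 1), \code{H_pre}
#'   ((N_s + 1) x time) and \code{N_s}.
#' @export
build_motor_control <- function(activations, N_s, restarts = 10, seed = 0L) {
  A <- t(as.matrix(activations))  # muscles x time
  if (any(A < 0))
    stop_capgap("activations must be non-negative", "capgap_domain_error")
  k <- N_s + 1L
  live <- rowSums(A) > 0
  fit <- nnmf_factorize(A[live, , drop = FALSE], k, restarts = restarts,
                        seed = seed)
  W <- matrix(0, nrow(A), k, dimnames = list(rownames(A), NULL))
  W[live, ] <- fit$W
  H <- fit$H
  scales <- apply(W, 2, max)
  scales[scales < 1e-12] <- 1
  W <- sweep(W, 2, scales, "/")
  H <- sweep(H, 1, scales, "*")
  structure(list(W_pre = W, H_pre = H, N_s = as.integer(N_s),
                 vaf = fit$vaf),
            class = "motor_control_model")
}

#' @export
print.motor_control_model <- function(x, ...) {
  cat(sprintf("<motor_control_model> N_s = %d (%d synergies used), VAF = %.4f\n",
              x$N_s, ncol(x$W_pre), x$vaf))
  invisible(x)
}

#' Derive the full motor-control model from a trial
#'
#' Convenience pipeline: bootstrap selection of the synergy number from the
#' trial's EMG, EMG-informed static optimization for all-muscle activations,
#' and extended (N_s + 1) synergy extraction.
#'
#' @param model a tuned \code{msk_model}.
#' @param trial a complete \code{trial_bundle} with EMG.
#' @param boot a \code{\link{bootstrap_config}}.
#' @param w1,w2,w3 weights of the EMG-informed static optimization.
#' @param seed integer seed for the NNMF of the activation matrix.
#' @return A \code{motor_control_model} with the selection \code{table} and
#'   EMG-informed solution attached.
#' @export
derive_motor_control <- function(model, trial, boot = bootstrap_config(),
                                 w1 = 1, w2 = 10, w3 = 5, seed = 0L) {
  trial <- concat_bundles(trial)
  sel <- select_num_synergies(t(trial$emg), boot)
  if (is.na(sel$N_s))
    stop_capgap("no synergy number reaches the required bootstrap coverage",
                "capgap_solver_error")
  so <- emg_informed_activations(model, trial, w1 = w1, w2 = w2, w3 = w3)
  mc <- build_motor_control(so$activations, sel$N_s, restarts = boot$restarts,
                            seed = seed)
  mc$selection <- sel$table
  mc$sigma <- so$sigma
  mc
}

#' Write or read a motor-control model as JSON
#'
#' @param mc a \code{motor_control_model}.
#' @param path file path.
#' @return \code{read_motor_control} returns a \code{motor_control_model}.
#' @export
write_motor_control <- function(mc, path) {
  doc <- list(N_s = mc$N_s, muscles = rownames(mc$W_pre),
              W_pre = apply(mc$W_pre, 1, function(r) r, simplify = FALSE),
              H_pre = apply(mc$H_pre, 1, function(r) r, simplify = FALSE),
              vaf = mc$vaf)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_motor_control
#' @export
read_motor_control <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x
  else do.call(rbind, lapply(x, as.numeric))
  W <- as_mat(doc$W_pre)
  rownames(W) <- doc$muscles
  H <- as_mat(doc$H_pre)
  structure(list(W_pre = W, H_pre = H, N_s = as.integer(doc$N_s),
                 vaf = doc$vaf),
            class = "motor_control_model")
}
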