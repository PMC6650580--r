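# Convex QP plumbing. All static-optimization subproblems in the package are
# strictly convex quadratic programs solved with quadprog; objectives are
# assembled as min x' M x - 2 c' x (the 1/2 factor cancels in the argmin).

# minimize x' M x - 2 c' x  s.t.  lower <= x <= upper and optionally
# A x >= b (A given row-wise). Returns the solution vector.
solve_qp <- function(M, c, lower = NULL, upper = NULL, A = NULL, b = NULL,
                     ridge = 1e-10) {
  n <- length(c)
  Amat <- NULL; bvec <- NULL
  if (!is.null(lower)) {
    Amat <- cbind(Amat, diag(n)); bvec <- c(bvec, lower)
  }
  if (!is.null(upper)) {
    Amat <- cbind(Amat, -diag(n)); bvec <- c(bvec, -upper)
  }
  if (!is.null(A)) {
    Amat <- cbind(Amat, t(A)); bvec <- c(bvec, b)
  }
  scale <- max(1, max(abs(diag(M))))
  D <- 2 * (M + diag(ridge * scale, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = 2 * c,
                            Amat = Amat, bvec = bvec, meq = 0)
  x <- sol$solution
  if (!is.null(lower)) x <- pmax(x, lower)
  if (!is.null(upper)) x <- pmin(x, upper)
  x
}

# Per-frame activation QP of the (EMG-informed) static optimization:
#   min w1 ||a||^2 + w3 ||sigma a - emg||^2 (on mapped muscles)
#     + w2 ||tau_free - B a||^2,  0 <= a <= 1
# B[j, m] is the moment each muscle contributes per unit activation and
# tau_free is the inverse-dynamics moment minus passive contributions.
solve_activation_qp <- function(B, tau_free, w1, w2, w3 = 0, sigma = NULL,
                                emg = NULL, emg_idx = integer()) {
  nm <- ncol(B)
  M <- diag(w1, nm) + w2 * crossprod(B)
  c <- w2 * as.vector(crossprod(B, tau_free))
  if (w3 > 0 && length(emg_idx)) {
    M[cbind(emg_idx, emg_idx)] <- M[cbind(emg_idx, emg_idx)] + w3 * sigma^2
    c[emg_idx] <- c[emg_idx] + w3 * sigma * emg
  }
  solve_qp(M, c, lower = rep(0, nm), upper = rep(1, nm))
}
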