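#' Normalized muscle force-length curves
#'
#' Container for the shape parameters of the normalized active and passive
#' force-length relationships of a rigid-tendon Hill muscle. The active curve
#' is a Gaussian bump centered at normalized fiber length 1 where it attains
#' its maximum of 1. The passive curve is an exponential toe curve that is
#' zero at and below the optimal fiber length and rises so that a muscle
#' stretched to 1.5 times its optimal fiber length exerts a passive force of
#' about half its maximum isometric force, the calibration anchor used when
#' interpreting clinical range-of-motion stretches.
#'
#' Parameterization: active \eqn{f^L(\tilde l) = \exp(-((\tilde l - 1)/w)^2)}
#' with width \code{active_width} (default 0.45); passive
#' \eqn{f^P(\tilde l) = (e^{k(\tilde l - 1)/\epsilon} - 1)/(e^k - 1)} for
#' \eqn{\tilde l > 1}, else 0, with stiffness \code{passive_k} (default 4) and
#' strain scale \code{passive_eps} (default 0.6), which puts
#' \eqn{f^P(1.5) \approx 0.50}.
#'
#' @param active_width width of the active force-length bump (normalized
#'   length units).
#' @param passive_k exponential shape factor of the passive curve.
#' @param passive_eps passive strain scale (normalized length units).
#' @return An object of class \code{muscle_curve_set}.
#' @examples
#' cs <- muscle_curve_set()
#' evaluate_curve(cs, "passive", 1.5)  # ~0.50
#' @export
muscle_curve_set <- function(active_width = 0.45, passive_k = 4,
                             passive_eps = 0.6) {
  stopifnot(active_width > 0, passive_k > 0, passive_eps > 0)
  structure(list(active_width = active_width, passive_k = passive_k,
                 passive_eps = passive_eps),
            class = "muscle_curve_set")
}

#' Evaluate a normalized force-length curve
#'
#' @param curves a \code{\link{muscle_curve_set}}.
#' @param kind \code{"active"} or \code{"passive"}.
#' @param l_norm normalized fiber length(s), must be positive.
#' @return Normalized force, same length as \code{l_norm}. Active values lie
#'   in [0, 1]; passive values are non-negative and non-decreasing.
#' @export
evaluate_curve <- function(curves, kind = c("active", "passive"), l_norm) {
  stopifnot(inherits(curves, "muscle_curve_set"))
  if (!is.character(kind) || !all(kind %in% c("active", "passive")))
    stop_capgap("curve kind must be 'active' or 'passive'", "capgap_usage_error")
  kind <- match.arg(kind)
  if (any(l_norm <= 0))
    stop_capgap("normalized fiber length must be positive", "capgap_domain_error")
  if (kind == "active") {
    exp(-((l_norm - 1) / curves$active_width)^2)
  } else {
    k <- curves$passive_k; eps <- curves$passive_eps
    ifelse(l_norm > 1,
           (exp(k * (l_norm - 1) / eps) - 1) / (exp(k) - 1),
           0)
  }
}

# Derivatives of the normalized curves w.r.t. normalized length; used by the
# analytic gradients of the tuning optimizer.
curve_deriv <- function(curves, kind, l_norm) {
  if (kind == "active") {
    w <- curves$active_width
    -2 * (l_norm - 1) / w^2 * exp(-((l_norm - 1) / w)^2)
  } else {
    k <- curves$passive_k; eps <- curves$passive_eps
    ifelse(l_norm > 1,
           (k / eps) * exp(k * (l_norm - 1) / eps) / (exp(k) - 1),
           0)
  }
}

#' Normalized length at which the passive curve reaches a given force
#'
#' Solves \eqn{f^P(\tilde l) =} \code{target} by bisection on
#' \code{interval}. With the default curve, a target of 0.5 is reached close
#' to a normalized length of 1.5.
#'
#' @param curves a \code{\link{muscle_curve_set}}.
#' @param target normalized passive force level.
#' @param interval search interval for the normalized length.
#' @param tol bisection tolerance.
#' @return The normalized fiber length solving the equation.
#' @export
passive_length_at_force <- function(curves, target = 0.5,
                                    interval = c(1, 2), tol = 1e-10) {
  f <- function(l) evaluate_curve(curves, "passive", l) - target
  lo <- interval[1]; hi <- interval[2]
  if (f(lo) > 0 || f(hi) < 0)
    stop_capgap("target passive force not bracketed by interval",
                "capgap_domain_error")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
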