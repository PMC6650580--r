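# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

stop_capgap <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "capgap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Rotation matrix about an arbitrary unit axis
#'
#' Rodrigues' formula. `axis` must have unit norm.
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- axis
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c1 + s1 * K + (1 - c1) * tcrossprod(u)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_capgap("cannot normalize a zero vector", "capgap_domain_error")
  v / n
}

is_num3 <- function(x) is.numeric(x) && length(x) == 3 && all(is.finite(x))

# Evaluate and restore the RNG state so seeded internals do not clobber the
# caller's stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Maximal runs of TRUE in a logical vector, as a two-column matrix of
# (start, end) indices.
flag_runs <- function(flags) {
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

# Full-precision number formatting for text round-trips (1e-12 contract).
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

# Linear interpolation of every column of a matrix onto a new abscissa.
interp_matrix <- function(x, y, xout) {
  out <- matrix(NA_real_, length(xout), ncol(y),
                dimnames = list(NULL, colnames(y)))
  for (j in seq_len(ncol(y)))
    out[, j] <- stats::approx(x, y[, j], xout = xout, rule = 2)$y
  out
}
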