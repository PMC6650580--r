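#' Musculoskeletal model as a kinematic chain with polyline muscles
#'
#' Constructs and validates a model composed of rigid segments connected by
#' rotational (hinge) joints, generalized coordinates with ranges, and
#' muscle-tendon actuators whose paths are ordered polylines of points fixed
#' in segment frames. A point \code{p} in a segment's frame maps into its
#' parent frame as \code{joint_center + R(joint_axis, q) p}, where \code{q}
#' is the value of the coordinate attached to that segment (0 for segments
#' without a coordinate).
#'
#' @param name model identifier.
#' @param segments named list; each element has \code{name}, \code{parent}
#'   (\code{NULL} for the single root), \code{joint_axis} (unit 3-vector in
#'   the parent frame), \code{joint_center} (3-vector, m, parent frame) and
#'   optionally \code{landmarks} (named list of local 3-vectors, m).
#' @param coordinates named list; each element has \code{name},
#'   \code{segment} (the segment it rotates) and \code{range}
#'   \code{c(min, max)} in radians.
#' @param muscles named list; each element has \code{name}, \code{path}
#'   (list of path points: \code{segment}, \code{location} 3-vector m,
#'   \code{role} one of origin/via/insertion), \code{F_max} (N), \code{l_mo}
#'   (m), \code{l_ts} (m), \code{alpha} (rad) and \code{subset} (\code{"M"}
#'   for tuned muscles with full force-length behavior, \code{"N"} for
#'   activation-proportional muscles).
#' @param curves a \code{\link{muscle_curve_set}}.
#' @param patella optional planar patella construct (see
#'   \code{\link{apply_patella_advancement}}).
#' @param lineage identifier of the parent (pre-operative) model, or NULL.
#' @param label \code{"pre-operative"} or \code{"post-operative"}.
#' @return An object of class \code{msk_model}.
#' @export
msk_model <- function(name, segments, coordinates, muscles,
                      curves = muscle_curve_set(), patella = NULL,
                      lineage = NULL, label = "pre-operative") {
  m <- structure(list(name = name, segments = segments,
                      coordinates = coordinates, muscles = muscles,
                      curves = curves, patella = patella,
                      lineage = lineage, label = label),
                 class = "msk_model")
  validate_model(m)
  m
}

#' Validate a musculoskeletal model
#'
#' Checks chain acyclicity with a single root, unit joint axes, ordered
#' coordinate ranges, resolvable path-point segment references, exactly one
#' origin and one insertion per muscle, and parameter sign constraints.
#'
#' @param model an \code{msk_model}.
#' @return The model, invisibly; errors of class \code{capgap_model_error}
#'   otherwise.
#' @export
validate_model <- function(model) {
  segs <- model$segments
  seg_names <- vapply(segs, `[[`, "", "name")
  if (any(duplicated(seg_names)))
    stop_capgap("duplicated segment names", "capgap_model_error")
  names(model$segments) <- seg_names
  roots <- Filter(function(s) is.null(s$parent), segs)
  if (length(roots) != 1)
    stop_capgap("model must have exactly one root segment", "capgap_model_error")
  for (s in segs) {
    if (!is.null(s$parent)) {
      if (!s$parent %in% seg_names)
        stop_capgap(sprintf("segment '%s' has unresolved parent '%s'",
                            s$name, s$parent), "capgap_model_error")
      if (abs(sqrt(sum(s$joint_axis^2)) - 1) > 1e-9)
        stop_capgap(sprintf("joint axis of segment '%s' is not unit norm",
                            s$name), "capgap_model_error")
      if (!is_num3(s$joint_center))
        stop_capgap(sprintf("bad joint center for segment '%s'", s$name),
                    "capgap_model_error")
    }
  }
  # acyclicity: walking up from every segment must reach the root
  for (s in segs) {
    seen <- character(); cur <- s$name
    while (!is.null(segs[[cur]]$parent)) {
      if (cur %in% seen)
        stop_capgap("cycle detected in segment chain", "capgap_model_error")
      seen <- c(seen, cur)
      cur <- segs[[cur]]$parent
    }
  }
  for (co in model$coordinates) {
    if (!co$segment %in% seg_names)
      stop_capgap(sprintf("coordinate '%s' references unknown segment '%s'",
                          co$name, co$segment), "capgap_model_error")
    if (!(co$range[1] < co$range[2]))
      stop_capgap(sprintf("coordinate '%s' has an empty range", co$name),
                  "capgap_model_error")
  }
  mus_names <- vapply(model$muscles, `[[`, "", "name")
  if (any(duplicated(mus_names)))
    stop_capgap("duplicated muscle names", "capgap_model_error")
  for (mu in model$muscles) {
    roles <- vapply(mu$path, `[[`, "", "role")
    if (sum(roles == "origin") != 1 || sum(roles == "insertion") != 1)
      stop_capgap(sprintf(
        "muscle '%s' must have exactly one origin and one insertion", mu$name),
        "capgap_model_error")
    if (roles[1] != "origin" || roles[length(roles)] != "insertion")
      stop_capgap(sprintf("muscle '%s' path must run origin -> via* -> insertion",
                          mu$name), "capgap_model_error")
    for (pp in mu$path)
      if (!pp$segment %in% seg_names)
        stop_capgap(sprintf("muscle '%s' references unknown segment '%s'",
                            mu$name, pp$segment), "capgap_model_error")
    if (mu$F_max < 0 || mu$l_mo <= 0 || mu$l_ts < 0 ||
        mu$alpha < 0 || mu$alpha >= pi / 2)
      stop_capgap(sprintf("muscle '%s' has invalid Hill parameters", mu$name),
                  "capgap_model_error")
    if (!mu$subset %in% c("M", "N"))
      stop_capgap(sprintf("muscle '%s' subset must be 'M' or 'N'", mu$name),
                  "capgap_model_error")
  }
  invisible(model)
}

#' @export
print.msk_model <- function(x, ...) {
  cat(sprintf("<msk_model '%s'> %d segments, %d coordinates, %d muscles (%s)\n",
              x$name, length(x$segments), length(x$coordinates),
              length(x$muscles), x$label))
  if (!is.null(x$lineage)) cat("  lineage:", x$lineage, "\n")
  invisible(x)
}

coordinate_names <- function(model)
  unname(vapply(model$coordinates, `[[`, "", "name"))
muscle_names <- function(model)
  unname(vapply(model$muscles, `[[`, "", "name"))

# Segments in parent-before-child order.
topo_order <- function(model) {
  segs <- model$segments
  done <- character(); todo <- names(segs)
  while (length(todo)) {
    ready <- vapply(segs[todo], function(s)
      is.null(s$parent) || s$parent %in% done, TRUE)
    if (!any(ready)) stop_capgap("segment graph is not a tree", "capgap_model_error")
    done <- c(done, todo[ready]); todo <- todo[!ready]
  }
  done
}

# Coordinate attached to each segment (NA when the joint is welded).
segment_coordinate <- function(model) {
  sc <- setNames(rep(NA_character_, length(model$segments)),
                 names(model$segments))
  for (co in model$coordinates) sc[co$segment] <- co$name
  sc
}

# Ground-frame pose (R, t) of every segment for coordinate vector q (named,
# radians).
segment_transforms <- function(model, q) {
  segs <- model$segments
  sc <- segment_coordinate(model)
  out <- vector("list", length(segs)); names(out) <- names(segs)
  for (nm in topo_order(model)) {
    s <- segs[[nm]]
    if (is.null(s$parent)) {
      out[[nm]] <- list(R = diag(3), t = c(0, 0, 0))
    } else {
      qv <- if (is.na(sc[nm])) 0 else q[[sc[nm]]]
      Rl <- rotation_matrix(s$joint_axis, qv)
      par <- out[[s$parent]]
      out[[nm]] <- list(R = par$R %*% Rl,
                        t = par$t + as.vector(par$R %*% s$joint_center))
    }
  }
  out
}

point_to_ground <- function(transforms, segment, p_local) {
  tr <- transforms[[segment]]
  as.vector(tr$R %*% p_local) + tr$t
}

# Set of segments at or below each coordinate's segment; a muscle "spans" a
# coordinate iff its path points straddle that set.
descendant_sets <- function(model) {
  segs <- model$segments
  kids <- split(vapply(segs, `[[`, "", "name"),
                vapply(segs, function(s) s$parent %||% "", ""))
  below <- function(root) {
    acc <- root; frontier <- root
    while (length(frontier)) {
      nxt <- unlist(kids[frontier], use.names = FALSE)
      acc <- c(acc, nxt); frontier <- nxt
    }
    acc
  }
  lapply(setNames(model$coordinates, coordinate_names(model)),
         function(co) below(co$segment))
}

muscle_spans <- function(model) {
  dsets <- descendant_sets(model)
  cn <- coordinate_names(model)
  mn <- muscle_names(model)
  spans <- matrix(FALSE, length(mn), length(cn), dimnames = list(mn, cn))
  for (mu in model$muscles) {
    psegs <- vapply(mu$path, `[[`, "", "segment")
    for (j in cn) {
      inside <- psegs %in% dsets[[j]]
      spans[mu$name, j] <- any(inside) && !all(inside)
    }
  }
  spans
}

polyline_lengths <- function(model, q) {
  tr <- segment_transforms(model, q)
  vapply(model$muscles, function(mu) {
    pts <- vapply(mu$path, function(pp)
      point_to_ground(tr, pp$segment, pp$location), numeric(3))
    sum(sqrt(rowSums(diff(t(pts))^2)))
  }, 0)
}

check_q <- function(model, q) {
  cn <- coordinate_names(model)
  if (is.null(names(q))) {
    if (length(q) != length(cn))
      stop_capgap("q must be named or match the number of coordinates",
                  "capgap_domain_error")
    names(q) <- cn
  }
  if (!all(cn %in% names(q)))
    stop_capgap("q is missing coordinates", "capgap_domain_error")
  for (co in model$coordinates) {
    v <- q[[co$name]]
    if (v < co$range[1] - 1e-9 || v > co$range[2] + 1e-9)
      stop_capgap(sprintf("coordinate '%s' = %.4f outside range [%.4f, %.4f]",
                          co$name, v, co$range[1], co$range[2]),
                  "capgap_domain_error")
  }
  q[cn]
}

#' Musculotendon lengths and moment arms at a posture
#'
#' Computes each muscle's polyline length after forward kinematics and the
#' moment arm of each muscle about each coordinate using the tendon-excursion
#' method: the moment arm of muscle m about coordinate j is
#' \eqn{r_{jm} = -\partial l^{mt}_m / \partial q_j}, evaluated by central
#' finite differences with a step of 1e-6 rad. Under this sign convention a
#' positive moment arm produces a positive generalized moment about the
#' coordinate. Muscles whose path does not cross a coordinate's joint have a
#' moment arm of exactly zero for it.
#'
#' @param model an \code{msk_model}.
#' @param q named coordinate vector (radians), within coordinate ranges.
#' @param check validate the posture against coordinate ranges.
#' @return list with \code{lengths} (named vector, m) and \code{moment_arms}
#'   (muscles x coordinates matrix, m).
#' @export
musculotendon_geometry <- function(model, q, check = TRUE) {
  q <- if (check) check_q(model, q) else q[coordinate_names(model)]
  lens <- polyline_lengths(model, q)
  spans <- muscle_spans(model)
  cn <- coordinate_names(model)
  r <- matrix(0, length(lens), length(cn),
              dimnames = list(names(lens), cn))
  h <- 1e-6
  for (j in cn) {
    if (!any(spans[, j])) next
    qp <- q; qp[j] <- q[j] + h
    qm <- q; qm[j] <- q[j] - h
    dl <- (polyline_lengths(model, qp) - polyline_lengths(model, qm)) / (2 * h)
    r[, j] <- ifelse(spans[, j], -dl, 0)
  }
  list(lengths = lens, moment_arms = r)
}

#' Fiber state under the rigid-tendon assumption
#'
#' Fiber length \eqn{l = (l^{mt} - l^{ts}) / \cos\alpha} and normalized fiber
#' length \eqn{\tilde l = l / l^{mo}}; exact algebraic evaluation with no
#' clamping.
#'
#' @param l_mt musculotendon length(s), m; must exceed the tendon slack
#'   length.
#' @param actuator a muscle entry of an \code{msk_model} (fields \code{l_ts},
#'   \code{l_mo}, \code{alpha}, \code{name}).
#' @return list with \code{l} (fiber length, m) and \code{l_norm}.
#' @export
fiber_state <- function(l_mt, actuator) {
  if (any(l_mt <= actuator$l_ts))
    stop_capgap(sprintf(
      "infeasible geometry for muscle '%s': musculotendon length %.4f <= tendon slack length %.4f",
      actuator$name, min(l_mt), actuator$l_ts), "capgap_geometry_error",
      muscle = actuator$name)
  l <- (l_mt - actuator$l_ts) / cos(actuator$alpha)
  list(l = l, l_norm = l / actuator$l_mo)
}

#' Tendon force of a rigid-tendon Hill muscle
#'
#' For subset-M muscles the force is
#' \eqn{F = F_{max}[a f^L(\tilde l) + f^P(\tilde l)]}; for subset-N muscles
#' it is activation-proportional, \eqn{F = F_{max} a}, independent of fiber
#' length. The force-velocity relationship is deliberately absent throughout
#' the package (static analyses only).
#'
#' @param actuator a muscle entry of an \code{msk_model}.
#' @param curves a \code{\link{muscle_curve_set}}.
#' @param a activation in [0, 1].
#' @param l_norm normalized fiber length (ignored for subset N).
#' @return Tendon force in newtons.
#' @export
muscle_force <- function(actuator, curves, a, l_norm = NULL) {
  if (any(a < 0 | a > 1))
    stop_capgap("activation must lie in [0, 1]", "capgap_domain_error")
  if (actuator$subset == "N") return(actuator$F_max * a)
  if (is.null(l_norm))
    stop_capgap("l_norm required for subset-M muscles", "capgap_usage_error")
  actuator$F_max * (a * evaluate_curve(curves, "active", l_norm) +
                      evaluate_curve(curves, "passive", l_norm))
}
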