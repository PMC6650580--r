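# Parametric virtual surgeries. Every operator is pure: it returns a new
# model with `lineage` set to the input model's name and never mutates its
# input. All osteotomy transforms are rigid maps applied to the distal
# content of the cut segment (path points, landmarks, child joint frames).

post_op <- function(model, parent) {
  model$lineage <- parent$name
  model$label <- "post-operative"
  model
}

plane_side <- function(x, plane) sum(plane$normal * (x - plane$point))

# Distal side of a cutting plane: the half-space not containing the
# segment's own joint center (the origin of its frame); overridable.
distal_sign_for <- function(plane, override = NULL) {
  if (!is.null(override)) return(override)
  s0 <- plane_side(c(0, 0, 0), plane)
  if (abs(s0) < 1e-12) 1 else -sign(s0)
}

# Apply a rigid map f to all content of `segment` selected by `sel` (a
# predicate on local points). Child joints of the segment are carried along:
# their centers are mapped and their axes rotated by R.
transform_segment_content <- function(model, segment, sel, f, R) {
  touched <- FALSE
  for (mi in seq_along(model$muscles)) {
    path <- model$muscles[[mi]]$path
    for (pi in seq_along(path)) {
      if (path[[pi]]$segment == segment && sel(path[[pi]]$location)) {
        path[[pi]]$location <- f(path[[pi]]$location)
        touched <- TRUE
      }
    }
    model$muscles[[mi]]$path <- path
  }
  lms <- model$segments[[segment]]$landmarks
  for (ln in names(lms)) {
    if (sel(lms[[ln]])) {
      lms[[ln]] <- f(lms[[ln]])
      touched <- TRUE
    }
  }
  model$segments[[segment]]$landmarks <- lms
  for (si in seq_along(model$segments)) {
    s <- model$segments[[si]]
    if (identical(s$parent, segment) && sel(s$joint_center)) {
      model$segments[[si]]$joint_center <- f(s$joint_center)
      model$segments[[si]]$joint_axis <- as.vector(R %*% s$joint_axis)
      touched <- TRUE
    }
  }
  list(model = model, touched = touched)
}

#' Derotation osteotomy
#'
#' Cuts the bone of \code{segment} with a single plane (given in the segment
#' frame) and rigidly transforms everything on the distal side: rotation by
#' \code{angle} about the plane normal through the plane point, composed
#' with an in-plane translation. Path points, landmarks and child joint
#' frames on the distal side move together; the proximal side is untouched.
#'
#' @param model an \code{msk_model}.
#' @param segment name of the segment carrying the cut.
#' @param plane list with \code{point} (3-vector, m, segment frame) and unit
#'   \code{normal}.
#' @param angle rotation angle about the plane normal (rad), in (-pi, pi).
#' @param translation 3-vector (m); its out-of-plane component is discarded.
#' @param distal_sign optional override (+1/-1) for which side of the plane
#'   counts as distal; by default the side away from the segment's own joint
#'   center.
#' @return The post-operative model (lineage set to the input model).
#' @export
apply_derotation_osteotomy <- function(model, segment, plane, angle,
                                       translation = c(0, 0, 0),
                                       distal_sign = NULL) {
  if (!segment %in% names(model$segments))
    stop_capgap(sprintf("unknown segment '%s'", segment), "capgap_config_error")
  if (abs(angle) >= pi)
    stop_capgap("osteotomy angle must lie in (-pi, pi)", "capgap_domain_error")
  n <- unit(plane$normal)
  plane <- list(point = plane$point, normal = n)
  ds <- distal_sign_for(plane, distal_sign)
  R <- rotation_matrix(n, angle)
  t_ip <- translation - sum(translation * n) * n
  f <- function(x) as.vector(R %*% (x - plane$point)) + plane$point + t_ip
  sel <- function(x) ds * plane_side(x, plane) > 0
  out <- transform_segment_content(model, segment, sel, f, R)
  if (!out$touched)
    warning(sprintf("cutting plane misses all content of segment '%s'; identity transform",
                    segment))
  post_op(out$model, model)
}

#' Extension and derotation osteotomy (wedge resection)
#'
#' Two cutting planes in the segment frame define a bone wedge for removal.
#' The distal fragment is transformed by the rigid map that joins plane B
#' onto plane A, composed with a user derotation about the joined-plane
#' normal and an in-plane translation. For a \code{"triangular"} wedge the
#' planes must be non-parallel: the closure map is the rotation about their
#' intersection line by the dihedral (wedge) angle. For a
#' \code{"trapezoidal"} wedge the planes must be parallel: the closure map
#' is the translation by the inter-plane offset (a shortening without
#' angular change). Landmarks inside the wedge are removed with a warning; a
#' muscle path point inside the wedge is an error (transfer the muscle
#' first).
#'
#' @param model an \code{msk_model}.
#' @param segment segment to cut.
#' @param plane_a,plane_b proximal and distal cutting planes (\code{point},
#'   \code{normal} in the segment frame).
#' @param wedge_shape \code{"triangular"} or \code{"trapezoidal"}.
#' @param derotation additional rotation about the joined-plane normal
#'   (rad).
#' @param translation additional in-plane translation (m).
#' @param distal_sign optional override for the distal side of plane A.
#' @return The post-operative model.
#' @export
apply_extension_derotation_osteotomy <- function(model, segment, plane_a,
                                                 plane_b,
                                                 wedge_shape = c("triangular",
                                                                 "trapezoidal"),
                                                 derotation = 0,
                                                 translation = c(0, 0, 0),
                                                 distal_sign = NULL) {
  wedge_shape <- match.arg(wedge_shape)
  if (!segment %in% names(model$segments))
    stop_capgap(sprintf("unknown segment '%s'", segment), "capgap_config_error")
  nA <- unit(plane_a$normal); nB <- unit(plane_b$normal)
  ds <- distal_sign_for(list(point = plane_a$point, normal = nA), distal_sign)
  # orient both normals toward the distal side
  nA <- ds * nA
  if (sum(nA * nB) < 0) nB <- -nB
  pA <- plane_a$point; pB <- plane_b$point
  cr <- c(nA[2] * nB[3] - nA[3] * nB[2],
          nA[3] * nB[1] - nA[1] * nB[3],
          nA[1] * nB[2] - nA[2] * nB[1])
  parallel <- sqrt(sum(cr^2)) < 1e-10
  if (wedge_shape == "triangular" && parallel)
    stop_capgap("triangular wedge requires non-parallel cutting planes",
                "capgap_config_error")
  if (wedge_shape == "trapezoidal" && !parallel)
    stop_capgap("trapezoidal wedge requires parallel cutting planes",
                "capgap_config_error")
  in_wedge <- function(x)
    plane_side(x, list(point = pA, normal = nA)) > 1e-12 &&
    plane_side(x, list(point = pB, normal = nB)) < -1e-12
  is_distal <- function(x) plane_side(x, list(point = pB, normal = nB)) >= -1e-12

  if (parallel) {
    d <- sum((pA - pB) * nA)  # signed inter-plane offset along the normal
    close_f <- function(x) x + d * nA
    Rw <- diag(3)
  } else {
    u <- cr / sqrt(sum(cr^2))  # hmm: need rotation taking nB to nA
    u <- -u                    # cr = nA x nB; rotation nB -> nA is about nB x nA
    omega <- acos(min(1, max(-1, sum(nA * nB))))
    Rw <- rotation_matrix(u, omega)
    # point on the intersection line of the two planes
    c12 <- sum(nA * nB)
    rhs <- c(sum(nA * pA), sum(nB * pB))
    ab <- solve(matrix(c(1, c12, c12, 1), 2, 2), rhs)
    x0 <- ab[1] * nA + ab[2] * nB
    close_f <- function(x) as.vector(Rw %*% (x - x0)) + x0
  }
  Rd <- rotation_matrix(nA, derotation)
  t_ip <- translation - sum(translation * nA) * nA
  f <- function(x) {
    x1 <- close_f(x)
    as.vector(Rd %*% (x1 - pA)) + pA + t_ip
  }
  Rtot <- Rd %*% Rw

  # audit wedge interior before transforming
  for (mu in model$muscles)
    for (ppt in mu$path)
      if (ppt$segment == segment && in_wedge(ppt$location))
        stop_capgap(sprintf(
          "muscle '%s' has a path point inside the resection wedge; transfer it first",
          mu$name), "capgap_surgery_error", muscle = mu$name)
  lms <- model$segments[[segment]]$landmarks
  drop <- names(lms)[vapply(lms, in_wedge, TRUE)]
  if (length(drop)) {
    warning(sprintf("landmark(s) inside the resection wedge removed: %s",
                    paste(drop, collapse = ", ")))
    model$segments[[segment]]$landmarks <- lms[setdiff(names(lms), drop)]
  }
  for (s in model$segments)
    if (identical(s$parent, segment) && in_wedge(s$joint_center))
      stop_capgap(sprintf("child joint center of '%s' lies inside the wedge",
                          s$name), "capgap_surgery_error")

  out <- transform_segment_content(model, segment, is_distal, f, Rtot)
  post_op(out$model, model)
}

#' Muscle transfer and tendon lengthening
#'
#' Edits a muscle's path (add/move/remove attachment and via points) and/or
#' applies an explicit tendon slack-length change. The geometric change in
#' musculotendon length at the reference posture is absorbed into the tendon
#' slack length, \code{l_ts' = l_ts + (l_mt_new - l_mt_old) + delta_lts}, so
#' the transfer leaves the normalized fiber length at the reference posture
#' unchanged: transfers re-route the tendon, they do not alter the fiber
#' architecture.
#'
#' @param model an \code{msk_model}.
#' @param muscle muscle name.
#' @param point_edits list of edits applied in order; each is a list with
#'   \code{action} (\code{"add_via"}, \code{"move"}, \code{"remove"}),
#'   \code{index} (path position; for \code{"add_via"} the new point is
#'   inserted after it), and for add/move \code{segment} (optional for move)
#'   and \code{location}.
#' @param q_ref reference posture (named, rad); default all-zero.
#' @param delta_lts additional tendon slack-length change (m), positive =
#'   lengthening.
#' @return The post-operative model.
#' @export
apply_muscle_transfer <- function(model, muscle, point_edits = list(),
                                  q_ref = NULL, delta_lts = 0) {
  if (!muscle %in% muscle_names(model))
    stop_capgap(sprintf("unknown muscle '%s'", muscle), "capgap_config_error")
  cn <- coordinate_names(model)
  if (is.null(q_ref)) q_ref <- setNames(rep(0, length(cn)), cn)
  l_old <- polyline_lengths(model, check_q(model, q_ref))[[muscle]]
  new <- model
  path <- new$muscles[[muscle]]$path
  for (ed in point_edits) {
    if (ed$action == "add_via") {
      npp <- list(segment = ed$segment, location = ed$location, role = "via")
      path <- append(path, list(npp), after = ed$index)
    } else if (ed$action == "move") {
      path[[ed$index]]$location <- ed$location
      if (!is.null(ed$segment)) path[[ed$index]]$segment <- ed$segment
    } else if (ed$action == "remove") {
      if (path[[ed$index]]$role != "via")
        stop_capgap("only via points can be removed", "capgap_surgery_error")
      path[[ed$index]] <- NULL
    } else {
      stop_capgap(sprintf("unknown path edit action '%s'", ed$action),
                  "capgap_usage_error")
    }
  }
  new$muscles[[muscle]]$path <- path
  validate_model(new)
  l_new <- polyline_lengths(new, check_q(new, q_ref))[[muscle]]
  lts_new <- new$muscles[[muscle]]$l_ts + (l_new - l_old) + delta_lts
  if (lts_new < 0)
    stop_capgap(sprintf("transfer would give muscle '%s' a negative tendon slack length",
                        muscle), "capgap_surgery_error")
  new$muscles[[muscle]]$l_ts <- lts_new
  post_op(new, model)
}

#' Canned rectus femoris transfer recipe
#'
#' Two-step distal transfer of a biarticular knee-extending hip flexor onto
#' the insertion of a hamstring-side muscle: (1) a via point fixed in the
#' thigh frame is added at the path's arclength midpoint, preserving the
#' proximal hip-flexing route; (2) the insertion is moved to the target
#' muscle's insertion point. The tendon slack length is adjusted so the
#' musculotendon operating state at the reference posture is unchanged.
#'
#' @param model an \code{msk_model}.
#' @param muscle muscle to transfer (default \code{"rectus"}).
#' @param target muscle whose insertion receives the tendon (default
#'   \code{"hamstrings"}).
#' @param thigh_segment segment in whose frame the new via point is fixed.
#' @param q_ref reference posture (named, rad); default all-zero.
#' @return The post-operative model.
#' @export
apply_rectus_transfer <- function(model, muscle = "rectus",
                                  target = "hamstrings",
                                  thigh_segment = "thigh", q_ref = NULL) {
  if (!target %in% muscle_names(model))
    stop_capgap(sprintf("unknown target muscle '%s'", target),
                "capgap_config_error")
  cn <- coordinate_names(model)
  if (is.null(q_ref)) q_ref <- setNames(rep(0, length(cn)), cn)
  q_ref <- check_q(model, q_ref)
  tr <- segment_transforms(model, q_ref)
  path <- model$muscles[[muscle]]$path
  pts <- t(vapply(path, function(pp)
    point_to_ground(tr, pp$segment, pp$location), numeric(3)))
  seg_len <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg_len))
  half <- cum[length(cum)] / 2
  k <- max(which(cum <= half))            # midpoint lies on segment k
  w <- (half - cum[k]) / seg_len[k]
  mid_ground <- pts[k, ] + w * (pts[k + 1, ] - pts[k, ])
  thr <- tr[[thigh_segment]]
  mid_local <- as.vector(t(thr$R) %*% (mid_ground - thr$t))
  ins_target <- model$muscles[[target]]$path
  ins_target <- ins_target[[length(ins_target)]]
  # release the original distal route (via points beyond the midpoint),
  # pin the preserved proximal route with the new thigh via, and reattach
  # the insertion on the target tendon
  edits <- list()
  for (idx in rev(seq_len(length(path) - 1L)))
    if (idx > k) edits <- c(edits, list(list(action = "remove", index = idx)))
  edits <- c(edits,
             list(list(action = "add_via", index = k, segment = thigh_segment,
                       location = mid_local)),
             list(list(action = "move", index = k + 2L,
                       segment = ins_target$segment,
                       location = ins_target$location)))
  apply_muscle_transfer(model, muscle, edits, q_ref = q_ref)
}

#' Strength scaling (botulinum toxin injection / muscle release)
#'
#' Scales a muscle's maximum isometric force. A scale of zero encodes a
#' muscle release: the muscle then contributes zero moment in any subsequent
#' optimization.
#'
#' @param model an \code{msk_model}.
#' @param muscle muscle name.
#' @param scale force scale in [0, 1].
#' @return The post-operative model.
#' @export
apply_strength_change <- function(model, muscle, scale) {
  if (!muscle %in% muscle_names(model))
    stop_capgap(sprintf("unknown muscle '%s'", muscle), "capgap_config_error")
  if (scale < 0 || scale > 1)
    stop_capgap("strength scale must lie in [0, 1]", "capgap_domain_error")
  new <- model
  new$muscles[[muscle]]$F_max <- new$muscles[[muscle]]$F_max * scale
  post_op(new, model)
}

#' Femoral morphometrics from bony landmarks
#'
#' Anteversion is the signed angle between the neck axis and the condylar
#' axis after projecting both onto the plane perpendicular to the shaft
#' axis; the neck-shaft angle is the angle between the neck axis and the
#' distally directed shaft axis. Required landmarks on the segment:
#' \code{femoral_head_center}, \code{neck_base}, \code{shaft_proximal},
#' \code{shaft_distal}, \code{condyle_medial}, \code{condyle_lateral}.
#'
#' @param model an \code{msk_model}.
#' @param segment segment carrying the landmarks (default \code{"thigh"}).
#' @return list with \code{anteversion_deg} and \code{neck_shaft_deg}.
#' @export
bone_morphometrics <- function(model, segment = "thigh") {
  lms <- model$segments[[segment]]$landmarks
  need <- c("femoral_head_center", "neck_base", "shaft_proximal",
            "shaft_distal", "condyle_medial", "condyle_lateral")
  miss <- setdiff(need, names(lms))
  if (length(miss))
    stop_capgap(sprintf("segment '%s' is missing landmark(s): %s", segment,
                        paste(miss, collapse = ", ")), "capgap_config_error")
  neck <- unit(lms$femoral_head_center - lms$neck_base)
  shaft <- unit(lms$shaft_proximal - lms$shaft_distal)
  cond <- unit(lms$condyle_lateral - lms$condyle_medial)
  proj <- function(v) v - sum(v * shaft) * shaft
  np <- proj(neck); cp <- proj(cond)
  cr <- c(cp[2] * np[3] - cp[3] * np[2],
          cp[3] * np[1] - cp[1] * np[3],
          cp[1] * np[2] - cp[2] * np[1])
  av <- atan2(sum(shaft * cr), sum(np * cp))
  nsa <- acos(min(1, max(-1, sum(neck * -shaft))))
  list(anteversion_deg = av * RAD2DEG, neck_shaft_deg = nsa * RAD2DEG)
}

# ---------------------------------------------------------------------------
# Patella advancement

rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

dist_to_polyline <- function(p, poly) {
  n <- nrow(poly)
  d2 <- rep(NA_real_, n - 1)
  for (i in seq_len(n - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    d2[i] <- sum((p - a - t * ab)^2)
  }
  sqrt(min(d2))
}

# Per-knee-angle planar pose of the patella: the ligament fixes the patella
# attachment on a circle of radius lig_length around the (knee-angle
# dependent) tibial insertion; the remaining two parameters (circle angle
# phi, patella rotation theta) minimize the spread of the two patella-point
# distances to the femoral profile, with a mild pull toward the stored
# articular clearance to keep the pose well-defined.
solve_patella_path <- function(p, grid = p$grid) {
  knee <- p$knee_center
  tib_at <- function(kappa) knee + as.vector(rot2(kappa) %*% p$tibia_insertion)
  pose_of <- function(par, tib) {
    attach <- tib + p$lig_length * c(cos(par[1]), sin(par[1]))
    origin <- attach - as.vector(rot2(par[2]) %*% p$lig_attach)
    list(origin = origin,
         prox = origin + as.vector(rot2(par[2]) %*% p$points$prox),
         dist = origin + as.vector(rot2(par[2]) %*% p$points$dist))
  }
  obj <- function(par, tib) {
    ps <- pose_of(par, tib)
    d1 <- dist_to_polyline(ps$prox, p$profile)
    d2 <- dist_to_polyline(ps$dist, p$profile)
    (d1 - d2)^2 + 0.2 * ((d1 + d2) / 2 - p$clearance)^2
  }
  out <- matrix(NA_real_, length(grid), 5,
                dimnames = list(NULL, c("knee_angle", "phi", "theta", "x", "y")))
  tib0 <- tib_at(grid[1])
  v0 <- (knee + c(0.06, 0)) - tib0
  par <- c(atan2(v0[2], v0[1]), 0)
  for (gi in seq_along(grid)) {
    tib <- tib_at(grid[gi])
    for (rep in 1:2) {
      fit <- stats::optim(par, obj, tib = tib, method = "Nelder-Mead",
                          control = list(maxit = 600, reltol = 1e-13))
      par <- fit$par
    }
    ps <- pose_of(par, tib)
    d_mean <- (dist_to_polyline(ps$prox, p$profile) +
                 dist_to_polyline(ps$dist, p$profile)) / 2
    if (d_mean > 0.05)
      stop_capgap(sprintf(
        "patella pose infeasible at knee angle %.2f rad (ligament cannot reach the femoral profile)",
        grid[gi]), "capgap_surgery_error", knee_angle = grid[gi])
    out[gi, ] <- c(grid[gi], par[1], par[2], ps$origin[1], ps$origin[2])
  }
  out
}

#' Patella advancement
#'
#' Changes the patellar ligament length and/or its tibial insertion, then
#' recomputes the patella's planar path as a function of knee angle: for
#' each knee angle on the construct's grid the patella pose (rotation plus
#' two translations, reduced to two free parameters by the fixed-ligament
#' constraint) is optimized so the distances from the two patellar surface
#' points to the femoral profile stay as constant as possible. The problem
#' is posed in the plane perpendicular to the knee axis.
#'
#' @param model an \code{msk_model} with a patella construct.
#' @param delta_length change in ligament length (m); negative shortens
#'   (advances) the patella.
#' @param new_insertion optional replacement tibial insertion (2-vector, m,
#'   shank frame).
#' @return The post-operative model with the recomputed patella path.
#' @export
apply_patella_advancement <- function(model, delta_length = 0,
                                      new_insertion = NULL) {
  if (is.null(model$patella))
    stop_capgap("model has no patella construct", "capgap_config_error")
  new <- model
  new$patella$lig_length <- new$patella$lig_length + delta_length
  if (new$patella$lig_length <= 0)
    stop_capgap("patella ligament length must stay positive",
                "capgap_surgery_error")
  if (!is.null(new_insertion))
    new$patella$tibia_insertion <- as.numeric(new_insertion)
  new$patella$path <- solve_patella_path(new$patella)
  post_op(new, model)
}

# ---------------------------------------------------------------------------
# Surgery plans

#' Surgery plan
#'
#' An ordered list of surgery operations applied sequentially to a model.
#' Operation parameters are in SI units (radians, meters) in memory;
#' \code{\link{read_surgery_plan}} converts from the file units (degrees,
#' centimeters).
#'
#' @param operations list of operation descriptors (field \code{kind} plus
#'   kind-specific parameters mirroring the operator arguments).
#' @param label plan label.
#' @return An object of class \code{surgery_plan}.
#' @export
surgery_plan <- function(operations, label = "plan") {
  kinds <- vapply(operations, `[[`, "", "kind")
  ok <- kinds %in% c("derotation_osteotomy", "extension_derotation_osteotomy",
                     "muscle_transfer", "rectus_transfer",
                     "patella_advancement", "strength_change")
  if (!all(ok))
    stop_capgap(sprintf("unknown surgery kind '%s'", kinds[!ok][1]),
                "capgap_config_error")
  structure(list(operations = operations, label = label),
            class = "surgery_plan")
}

#' @export
print.surgery_plan <- function(x, ...) {
  cat(sprintf("<surgery_plan '%s'> %d operation(s): %s\n", x$label,
              length(x$operations),
              paste(vapply(x$operations, `[[`, "", "kind"), collapse = ", ")))
  invisible(x)
}

apply_surgery_op <- function(model, op) {
  switch(op$kind,
    derotation_osteotomy = apply_derotation_osteotomy(
      model, op$segment, op$plane, op$angle,
      op$translation %||% c(0, 0, 0), op$distal_sign),
    extension_derotation_osteotomy = apply_extension_derotation_osteotomy(
      model, op$segment, op$plane_a, op$plane_b,
      op$wedge_shape %||% "triangular", op$derotation %||% 0,
      op$translation %||% c(0, 0, 0), op$distal_sign),
    muscle_transfer = apply_muscle_transfer(
      model, op$muscle, op$point_edits %||% list(), op$q_ref,
      op$delta_lts %||% 0),
    rectus_transfer = apply_rectus_transfer(
      model, op$muscle %||% "rectus", op$target %||% "hamstrings",
      op$thigh_segment %||% "thigh", op$q_ref),
    patella_advancement = apply_patella_advancement(
      model, op$delta_length %||% 0, op$new_insertion),
    strength_change = apply_strength_change(model, op$muscle, op$scale))
}

#' Apply a surgery plan
#'
#' Folds the plan's operations over the model in order. The resulting model
#' records the plan (for provenance) and carries the original model's name
#' as lineage.
#'
#' @param model the pre-operative \code{msk_model}.
#' @param plan a \code{\link{surgery_plan}}.
#' @return The post-operative model.
#' @export
apply_surgery_plan <- function(model, plan) {
  out <- model
  for (op in plan$operations) out <- apply_surgery_op(out, op)
  out$lineage <- model$name
  out$label <- "post-operative"
  out$name <- paste0(model$name, "_", plan$label)
  out$plan <- serialize_plan(plan)
  out
}

vec_cm <- function(v) as.numeric(v) * 100
vec_m <- function(v) as.numeric(v) / 100

serialize_plan <- function(plan) {
  list(label = plan$label, operations = lapply(plan$operations, function(op) {
    o <- list(kind = op$kind)
    if (!is.null(op$segment)) o$segment <- op$segment
    if (!is.null(op$muscle)) o$muscle <- op$muscle
    if (!is.null(op$target)) o$target <- op$target
    if (!is.null(op$plane))
      o$plane <- list(point_cm = vec_cm(op$plane$point),
                      normal = as.numeric(op$plane$normal))
    for (pl in c("plane_a", "plane_b"))
      if (!is.null(op[[pl]]))
        o[[pl]] <- list(point_cm = vec_cm(op[[pl]]$point),
                        normal = as.numeric(op[[pl]]$normal))
    if (!is.null(op$angle)) o$angle_deg <- op$angle * RAD2DEG
    if (!is.null(op$derotation)) o$derotation_deg <- op$derotation * RAD2DEG
    if (!is.null(op$wedge_shape)) o$wedge_shape <- op$wedge_shape
    if (!is.null(op$translation)) o$translation_cm <- vec_cm(op$translation)
    if (!is.null(op$delta_lts)) o$delta_lts_cm <- op$delta_lts * 100
    if (!is.null(op$delta_length)) o$delta_length_cm <- op$delta_length * 100
    if (!is.null(op$new_insertion)) o$new_insertion_cm <- vec_cm(op$new_insertion)
    if (!is.null(op$scale)) o$scale <- op$scale
    if (!is.null(op$distal_sign)) o$distal_sign <- op$distal_sign
    if (!is.null(op$point_edits))
      o$point_edits <- lapply(op$point_edits, function(ed) {
        e <- list(action = ed$action, index = ed$index)
        if (!is.null(ed$segment)) e$segment <- ed$segment
        if (!is.null(ed$location)) e$location_cm <- vec_cm(ed$location)
        e
      })
    if (!is.null(op$q_ref))
      o$q_ref_deg <- as.list(setNames(as.numeric(op$q_ref) * RAD2DEG,
                                      names(op$q_ref)))
    o
  }))
}

deserialize_plan <- function(doc) {
  ops <- lapply(doc$operations, function(o) {
    op <- list(kind = o$kind)
    for (f in c("segment", "muscle", "target", "wedge_shape", "scale",
                "distal_sign"))
      if (!is.null(o[[f]])) op[[f]] <- o[[f]]
    if (!is.null(o$plane))
      op$plane <- list(point = vec_m(o$plane$point_cm),
                       normal = as.numeric(o$plane$normal))
    for (pl in c("plane_a", "plane_b"))
      if (!is.null(o[[pl]]))
        op[[pl]] <- list(point = vec_m(o[[pl]]$point_cm),
                         normal = as.numeric(o[[pl]]$normal))
    if (!is.null(o$angle_deg)) op$angle <- o$angle_deg * DEG2RAD
    if (!is.null(o$derotation_deg)) op$derotation <- o$derotation_deg * DEG2RAD
    if (!is.null(o$translation_cm)) op$translation <- vec_m(o$translation_cm)
    if (!is.null(o$delta_lts_cm)) op$delta_lts <- o$delta_lts_cm / 100
    if (!is.null(o$delta_length_cm)) op$delta_length <- o$delta_length_cm / 100
    if (!is.null(o$new_insertion_cm)) op$new_insertion <- vec_m(o$new_insertion_cm)
    if (!is.null(o$point_edits))
      op$point_edits <- lapply(o$point_edits, function(e) {
        ed <- list(action = e$action, index = e$index)
        if (!is.null(e$segment)) ed$segment <- e$segment
        if (!is.null(e$location_cm)) ed$location <- vec_m(e$location_cm)
        ed
      })
    if (!is.null(o$q_ref_deg)) {
      v <- unlist(o$q_ref_deg)
      op$q_ref <- setNames(as.numeric(v) * DEG2RAD, names(v))
    }
    op
  })
  surgery_plan(ops, label = doc$label %||% "plan")
}

#' Read or write a surgery plan file
#'
#' YAML file with a \code{label} and an ordered \code{operations} list;
#' angles are degrees and lengths centimeters on disk.
#'
#' @param path file path.
#' @param plan a \code{\link{surgery_plan}}.
#' @return \code{read_surgery_plan} returns a \code{surgery_plan}.
#' @export
read_surgery_plan <- function(path) {
  if (!file.exists(path))
    stop_capgap(sprintf("plan file '%s' not found", path), "capgap_io_error")
  deserialize_plan(yaml::read_yaml(path))
}

#' @rdname read_surgery_plan
#' @export
write_surgery_plan <- function(plan, path) {
  writeLines(yaml::as.yaml(serialize_plan(plan), precision = 17), path)
  invisible(path)
}
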