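#' Read and write musculoskeletal model files
#'
#' Models are stored as structured YAML. Angles (coordinate ranges, pennation)
#' are in degrees in the file and radians in memory; lengths are meters
#' throughout. Numeric values are written with 17 significant digits so that
#' a write/read round trip preserves every field to better than 1e-12.
#'
#' File schema (top-level keys): \code{name}, \code{label}, \code{lineage},
#' \code{curves} (active_width, passive_k, passive_eps),
#' \code{segments} (name, parent, joint_axis, joint_center, landmarks),
#' \code{coordinates} (name, segment, range_deg),
#' \code{muscles} (name, subset, F_max, l_mo, l_ts, alpha_deg, path:
#' list of \{segment, location, role\}), optional \code{patella} and
#' \code{plan} (the surgery plan that produced a post-operative model).
#'
#' @param model an \code{msk_model}.
#' @param path file path.
#' @return \code{read_model} returns an \code{msk_model};
#'   \code{write_model} returns \code{path} invisibly.
#' @export
write_model <- function(model, path) {
  seg_out <- lapply(unname(model$segments), function(s) {
    o <- list(name = s$name, parent = s$parent,
              joint_axis = as.numeric(s$joint_axis),
              joint_center = as.numeric(s$joint_center))
    if (length(s$landmarks))
      o$landmarks <- lapply(s$landmarks, as.numeric)
    o
  })
  coord_out <- lapply(unname(model$coordinates), function(co)
    list(name = co$name, segment = co$segment,
         range_deg = as.numeric(co$range) * RAD2DEG))
  mus_out <- lapply(unname(model$muscles), function(mu)
    list(name = mu$name, subset = mu$subset, F_max = mu$F_max,
         l_mo = mu$l_mo, l_ts = mu$l_ts, alpha_deg = mu$alpha * RAD2DEG,
         path = lapply(mu$path, function(pp)
           list(segment = pp$segment, location = as.numeric(pp$location),
                role = pp$role))))
  doc <- list(name = model$name, label = model$label,
              lineage = model$lineage,
              curves = unclass(model$curves),
              segments = seg_out, coordinates = coord_out,
              muscles = mus_out)
  if (!is.null(model$patella)) doc$patella <- serialize_patella(model$patella)
  if (!is.null(model$plan)) doc$plan <- model$plan
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path))
    stop_capgap(sprintf("model file '%s' not found", path), "capgap_io_error")
  doc <- yaml::read_yaml(path)
  segments <- lapply(doc$segments, function(s) {
    s$joint_axis <- as.numeric(s$joint_axis %||% c(0, 0, 1))
    s$joint_center <- as.numeric(s$joint_center %||% c(0, 0, 0))
    s$landmarks <- lapply(s$landmarks %||% list(), as.numeric)
    s
  })
  names(segments) <- vapply(segments, `[[`, "", "name")
  coordinates <- lapply(doc$coordinates, function(co)
    list(name = co$name, segment = co$segment,
         range = as.numeric(co$range_deg) * DEG2RAD))
  names(coordinates) <- vapply(coordinates, `[[`, "", "name")
  muscles <- lapply(doc$muscles, function(mu)
    list(name = mu$name, subset = mu$subset, F_max = mu$F_max,
         l_mo = mu$l_mo, l_ts = mu$l_ts, alpha = mu$alpha_deg * DEG2RAD,
         path = lapply(mu$path, function(pp)
           list(segment = pp$segment, location = as.numeric(pp$location),
                role = pp$role))))
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  cu <- doc$curves
  m <- msk_model(name = doc$name, segments = segments,
                 coordinates = coordinates, muscles = muscles,
                 curves = muscle_curve_set(cu$active_width, cu$passive_k,
                                           cu$passive_eps),
                 patella = deserialize_patella(doc$patella),
                 lineage = doc$lineage, label = doc$label)
  m$plan <- doc$plan
  m
}

serialize_patella <- function(p) {
  list(points = lapply(p$points, as.numeric),
       lig_attach = as.numeric(p$lig_attach),
       lig_length = p$lig_length,
       tibia_insertion = as.numeric(p$tibia_insertion),
       clearance = p$clearance,
       profile = lapply(seq_len(nrow(p$profile)),
                        function(i) as.numeric(p$profile[i, ])),
       knee_center = as.numeric(p$knee_center),
       knee_coordinate = p$knee_coordinate,
       grid = as.numeric(p$grid),
       path = if (!is.null(p$path))
         lapply(seq_len(nrow(p$path)), function(i) as.numeric(p$path[i, ])))
}

deserialize_patella <- function(p) {
  if (is.null(p)) return(NULL)
  out <- list(points = lapply(p$points, as.numeric),
              lig_attach = as.numeric(p$lig_attach),
              lig_length = p$lig_length,
              tibia_insertion = as.numeric(p$tibia_insertion),
              clearance = p$clearance,
              profile = do.call(rbind, lapply(p$profile, as.numeric)),
              knee_center = as.numeric(p$knee_center),
              knee_coordinate = p$knee_coordinate,
              grid = as.numeric(p$grid))
  if (!is.null(p$path)) {
    out$path <- do.call(rbind, lapply(p$path, as.numeric))
    colnames(out$path) <- c("knee_angle", "phi", "theta", "x", "y")
  }
  out
}
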