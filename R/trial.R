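#' Gait trial bundle
#'
#' A time-indexed bundle of everything the optimizations consume: joint
#' angles, inverse-dynamics joint moments, musculotendon lengths, moment arms
#' and EMG envelopes, all sampled on one common uniform time grid.
#'
#' @param time strictly increasing, uniformly sampled time vector (s).
#' @param q time x coordinate matrix of joint angles (rad).
#' @param tau time x coordinate matrix of inverse-dynamics moments (N m).
#' @param l_mt time x muscle matrix of musculotendon lengths (m).
#' @param r time x muscle x coordinate array of moment arms (m).
#' @param emg time x channel matrix of EMG envelopes in [0, 1] (may have zero
#'   columns).
#' @param channel_map named list mapping each EMG channel to the model muscle
#'   names it drives (the measured subset).
#' @return An object of class \code{trial_bundle}.
#' @export
trial_bundle <- function(time, q, tau = NULL, l_mt = NULL, r = NULL,
                         emg = NULL, channel_map = list()) {
  nT <- length(time)
  if (nT > 1 && any(diff(time) <= 0))
    stop_capgap("time must be strictly increasing", "capgap_format_error")
  for (nmx in list(q = q, tau = tau, l_mt = l_mt, emg = emg)) {
    if (!is.null(nmx) && nrow(nmx) != nT)
      stop_capgap("all trial arrays must share the time dimension",
                  "capgap_format_error")
  }
  if (!is.null(r) && dim(r)[1] != nT)
    stop_capgap("moment-arm array must share the time dimension",
                "capgap_format_error")
  if (!is.null(emg) && ncol(emg) > 0) {
    if (min(emg) < -1e-12 || max(emg) > 1 + 1e-9)
      stop_capgap("EMG envelopes must lie in [0, 1]", "capgap_format_error")
    if (!all(colnames(emg) %in% names(channel_map)))
      stop_capgap(sprintf("EMG channel '%s' has no channel-map entry",
                          setdiff(colnames(emg), names(channel_map))[1]),
                  "capgap_format_error")
  }
  structure(list(time = time, q = q, tau = tau, l_mt = l_mt, r = r,
                 emg = emg, channel_map = channel_map),
            class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf("<trial_bundle> %d frames, %d coordinates, %d muscles, %d EMG channels\n",
              length(x$time), ncol(x$q),
              if (is.null(x$l_mt)) 0 else ncol(x$l_mt),
              if (is.null(x$emg)) 0 else ncol(x$emg)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Storage-dialect tables: a small header of "key=value" lines terminated by
# "endheader", then a tab-separated table whose first column is time.

write_sto <- function(mat, time, path, name = "table", in_degrees = FALSE) {
  stopifnot(nrow(mat) == length(time))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(mat)),
               sprintf("nColumns=%d", ncol(mat) + 1L),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(c("time", colnames(mat)), collapse = "\t")), con)
  body <- apply(cbind(time, mat), 1, function(row)
    paste(fmt_num(row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

read_sto <- function(path) {
  if (!file.exists(path))
    stop_capgap(sprintf("file '%s' not found", path), "capgap_io_error")
  lines <- readLines(path)
  hdr_end <- match("endheader", trimws(lines))
  if (is.na(hdr_end))
    stop_capgap(sprintf("'%s': missing 'endheader' line", path),
                "capgap_format_error")
  hdr <- lines[seq_len(hdr_end - 1)]
  kv <- strsplit(grep("=", hdr, value = TRUE, fixed = TRUE), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, function(x) trimws(x[2]), ""),
                   vapply(kv, function(x) trimws(x[1]), ""))
  cols <- strsplit(trimws(lines[hdr_end + 1]), "[\t ]+")[[1]]
  body <- lines[-seq_len(hdr_end + 1)]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "[\t ]+")
  nc <- length(cols)
  bad <- which(lengths(rows) != nc)
  if (length(bad))
    stop_capgap(sprintf("'%s': ragged row at line %d (%d fields, expected %d)",
                        path, hdr_end + 1 + bad[1], lengths(rows)[bad[1]], nc),
                "capgap_format_error")
  dat <- matrix(as.numeric(unlist(rows)), ncol = nc, byrow = TRUE,
                dimnames = list(NULL, cols))
  time <- dat[, 1]
  if (length(time) > 1 && any(diff(time) <= 0))
    stop_capgap(sprintf("'%s': time column is not strictly increasing", path),
                "capgap_format_error")
  in_deg <- identical(unname(meta["inDegrees"]), "yes")
  mat <- dat[, -1, drop = FALSE]
  if (in_deg) mat <- mat * DEG2RAD
  list(time = time, data = mat, meta = meta)
}

#' Write or read a trial bundle
#'
#' A bundle is stored as a family of delimited tables sharing a path prefix:
#' \code{<prefix>.coords.sto} (angles, degrees on disk),
#' \code{<prefix>.moments.sto}, \code{<prefix>.lmt.sto},
#' \code{<prefix>.arms_<coordinate>.sto} (one moment-arm table per
#' coordinate), \code{<prefix>.emg.sto} and \code{<prefix>.channels.yaml}
#' (the EMG channel-to-muscle map). Tables use a storage-style preamble
#' (\code{nRows}/\code{nColumns}/\code{inDegrees}/\code{endheader}) and a tab
#' separated body whose first column is time. Values are written with 17
#' significant digits; a write/read round trip is lossless to 1e-12.
#'
#' @param bundle a \code{\link{trial_bundle}}.
#' @param prefix path prefix for the bundle files.
#' @return \code{read_trial_bundle} returns a \code{trial_bundle};
#'   \code{write_trial_bundle} returns \code{prefix} invisibly.
#' @export
write_trial_bundle <- function(bundle, prefix) {
  write_sto(bundle$q * RAD2DEG, bundle$time, paste0(prefix, ".coords.sto"),
            "coordinates", in_degrees = TRUE)
  if (!is.null(bundle$tau))
    write_sto(bundle$tau, bundle$time, paste0(prefix, ".moments.sto"),
              "moments")
  if (!is.null(bundle$l_mt))
    write_sto(bundle$l_mt, bundle$time, paste0(prefix, ".lmt.sto"),
              "musculotendon_lengths")
  if (!is.null(bundle$r)) {
    for (j in dimnames(bundle$r)[[3]])
      write_sto(bundle$r[, , j], bundle$time,
                paste0(prefix, ".arms_", j, ".sto"),
                paste0("moment_arms_", j))
  }
  if (!is.null(bundle$emg) && ncol(bundle$emg) > 0)
    write_sto(bundle$emg, bundle$time, paste0(prefix, ".emg.sto"), "emg")
  if (length(bundle$channel_map))
    writeLines(yaml::as.yaml(bundle$channel_map),
               paste0(prefix, ".channels.yaml"))
  invisible(prefix)
}

#' @rdname write_trial_bundle
#' @export
read_trial_bundle <- function(prefix) {
  co <- read_sto(paste0(prefix, ".coords.sto"))
  time <- co$time
  q <- co$data
  read_opt <- function(suffix) {
    p <- paste0(prefix, suffix)
    if (file.exists(p)) read_sto(p) else NULL
  }
  tau <- read_opt(".moments.sto")
  lmt <- read_opt(".lmt.sto")
  emg <- read_opt(".emg.sto")
  arm_files <- Sys.glob(paste0(prefix, ".arms_*.sto"))
  r <- NULL
  if (length(arm_files)) {
    coords <- sub("^.*\\.arms_(.*)\\.sto$", "\\1", arm_files)
    # keep the coordinate order of the angle table, not the glob order
    ord <- order(match(coords, colnames(q)))
    arm_files <- arm_files[ord]
    coords <- coords[ord]
    first <- read_sto(arm_files[1])
    r <- array(NA_real_, c(length(time), ncol(first$data), length(coords)),
               dimnames = list(NULL, colnames(first$data), coords))
    for (i in seq_along(arm_files))
      r[, , coords[i]] <- read_sto(arm_files[i])$data
  }
  cmap_path <- paste0(prefix, ".channels.yaml")
  cmap <- if (file.exists(cmap_path)) yaml::read_yaml(cmap_path) else list()
  cmap <- lapply(cmap, as.character)
  trial_bundle(time = time, q = q,
               tau = if (!is.null(tau)) tau$data,
               l_mt = if (!is.null(lmt)) lmt$data,
               r = r,
               emg = if (!is.null(emg)) emg$data,
               channel_map = cmap)
}

#' Fill trial geometry from kinematics
#'
#' Evaluates musculotendon lengths and tendon-excursion moment arms on the
#' model frame by frame and stores them in the bundle.
#'
#' @param model an \code{msk_model}.
#' @param bundle a \code{trial_bundle} with joint angles \code{q}.
#' @return The bundle with \code{l_mt} and \code{r} filled.
#' @export
derive_trial_geometry <- function(model, bundle) {
  nT <- length(bundle$time)
  mn <- muscle_names(model)
  cn <- coordinate_names(model)
  l_mt <- matrix(NA_real_, nT, length(mn), dimnames = list(NULL, mn))
  r <- array(NA_real_, c(nT, length(mn), length(cn)),
             dimnames = list(NULL, mn, cn))
  for (i in seq_len(nT)) {
    g <- musculotendon_geometry(model, bundle$q[i, ])
    l_mt[i, ] <- g$lengths
    r[i, , ] <- g$moment_arms
  }
  bundle$l_mt <- l_mt
  bundle$r <- r
  bundle
}

#' Resample a trial bundle onto a uniform cycle grid
#'
#' Linear interpolation of every field onto \code{n} uniformly spaced frames
#' spanning the original time range.
#'
#' @param bundle a \code{trial_bundle}.
#' @param n number of output frames.
#' @return A resampled \code{trial_bundle}.
#' @export
resample_bundle <- function(bundle, n) {
  t_new <- seq(bundle$time[1], bundle$time[length(bundle$time)], length.out = n)
  rs <- function(m) if (is.null(m)) NULL else interp_matrix(bundle$time, m, t_new)
  r_new <- NULL
  if (!is.null(bundle$r)) {
    dn <- dimnames(bundle$r)
    r_new <- array(NA_real_, c(n, dim(bundle$r)[2], dim(bundle$r)[3]),
                   dimnames = list(NULL, dn[[2]], dn[[3]]))
    for (j in seq_len(dim(bundle$r)[3]))
      r_new[, , j] <- interp_matrix(bundle$time, bundle$r[, , j], t_new)
  }
  trial_bundle(time = t_new, q = rs(bundle$q), tau = rs(bundle$tau),
               l_mt = rs(bundle$l_mt), r = r_new, emg = rs(bundle$emg),
               channel_map = bundle$channel_map)
}

#' EMG envelope preprocessing
#'
#' Optional plumbing for raw EMG: high-pass filter (default 20 Hz, 4th-order
#' Butterworth, zero phase), full-wave rectification, low-pass envelope
#' (default 6 Hz) and per-channel peak normalization. Requires the
#' \pkg{signal} package.
#'
#' @param raw time x channel matrix of raw EMG.
#' @param fs sampling frequency (Hz).
#' @param high_cut high-pass cutoff (Hz).
#' @param low_cut low-pass envelope cutoff (Hz).
#' @return Matrix of envelopes normalized to peak 1 per channel.
#' @export
process_emg <- function(raw, fs, high_cut = 20, low_cut = 6) {
  if (!requireNamespace("signal", quietly = TRUE))
    stop_capgap("the 'signal' package is required for EMG filtering",
                "capgap_usage_error")
  hp <- signal::butter(4, high_cut / (fs / 2), type = "high")
  lp <- signal::butter(4, low_cut / (fs / 2), type = "low")
  out <- apply(raw, 2, function(x) {
    x <- signal::filtfilt(hp, x)
    x <- abs(x)
    x <- signal::filtfilt(lp, x)
    x <- pmax(x, 0)
    if (max(x) > 0) x / max(x) else x
  })
  colnames(out) <- colnames(raw)
  out
}

# ---------------------------------------------------------------------------
# Range-of-motion assessment

#' Clinical range-of-motion assessment
#'
#' A set of named test postures, each stretching a listed set of muscles; the
#' per-muscle reference musculotendon length is the maximum over the tests
#' that include the muscle, mirroring how clinical end-range positions are
#' converted into muscle stretch references.
#'
#' @param tests list of tests, each with \code{name}, \code{posture} (named
#'   coordinate vector, rad) and \code{muscles} (character).
#' @return An object of class \code{rom_assessment}.
#' @export
rom_assessment <- function(tests) {
  for (te in tests)
    if (is.null(te$name) || is.null(te$posture) || !length(te$muscles))
      stop_capgap("each ROM test needs a name, a posture and muscles",
                  "capgap_config_error")
  structure(list(tests = tests), class = "rom_assessment")
}

#' @export
print.rom_assessment <- function(x, ...) {
  cat(sprintf("<rom_assessment> %d tests covering %d muscles\n",
              length(x$tests),
              length(unique(unlist(lapply(x$tests, `[[`, "muscles"))))))
  invisible(x)
}

rom_muscles <- function(rom) unique(unlist(lapply(rom$tests, `[[`, "muscles")))

#' Read/write a range-of-motion assessment file
#'
#' YAML schema: a list of tests, each with \code{name},
#' \code{posture_deg} (named map, degrees) and \code{muscles}. Default
#' posture values shipped with a mapping file are decisions and can be
#' overridden by editing the file.
#'
#' @param path file path.
#' @param rom a \code{rom_assessment}.
#' @return \code{read_rom_assessment} returns a \code{rom_assessment}.
#' @export
read_rom_assessment <- function(path) {
  doc <- yaml::read_yaml(path)
  tests <- lapply(doc$tests, function(te) {
    post <- unlist(te$posture_deg %||% list())
    list(name = te$name,
         posture = setNames(as.numeric(post) * DEG2RAD, names(post)),
         muscles = as.character(te$muscles))
  })
  rom_assessment(tests)
}

#' @rdname read_rom_assessment
#' @export
write_rom_assessment <- function(rom, path) {
  doc <- list(tests = lapply(rom$tests, function(te)
    list(name = te$name,
         posture_deg = as.list(setNames(as.numeric(te$posture) * RAD2DEG,
                                        names(te$posture))),
         muscles = as.list(te$muscles))))
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' Maximum musculotendon lengths over the clinical exam postures
#'
#' For every muscle covered by the assessment, evaluates the musculotendon
#' length at each test posture that lists the muscle and keeps the maximum.
#' Coordinates absent from a test posture are held at zero.
#'
#' @param model an \code{msk_model}.
#' @param rom a \code{\link{rom_assessment}}.
#' @return Named vector of reference musculotendon lengths (m).
#' @export
rom_musculotendon_lengths <- function(model, rom) {
  cn <- coordinate_names(model)
  out <- setNames(rep(-Inf, length(rom_muscles(rom))), rom_muscles(rom))
  unknown <- setdiff(names(out), muscle_names(model))
  if (length(unknown))
    stop_capgap(sprintf("ROM assessment references unknown muscle '%s'",
                        unknown[1]), "capgap_config_error")
  for (te in rom$tests) {
    q <- setNames(rep(0, length(cn)), cn)
    q[names(te$posture)] <- te$posture
    g <- musculotendon_geometry(model, q)
    for (m in te$muscles)
      out[m] <- max(out[m], g$lengths[[m]])
  }
  out
}

# ---------------------------------------------------------------------------
# Typically-developing reference gait template and reference trials

#' Reference gait template
#'
#' Normalized (0-100\% cycle) typically-developing-like gait data: joint
#' angles, joint moments per unit body mass, and virtual marker trajectories
#' computed on a reference chain. The packaged default
#' (\code{\link{default_gait_template}}) is a synthetic smooth gait-like
#' stand-in generated in code, not a clinical average.
#'
#' @param phase cycle phase vector in [0, 100], first and last samples
#'   periodic.
#' @param time time vector (s).
#' @param q time x coordinate joint-angle matrix (rad).
#' @param moments_per_kg time x coordinate moment matrix (N m / kg).
#' @param markers named list of time x 3 ground-frame marker trajectories
#'   (m).
#' @param mass_ref,height_ref reference body mass (kg) and height (m) the
#'   template is expressed at.
#' @return An object of class \code{gait_template}.
#' @export
gait_template <- function(phase, time, q, moments_per_kg, markers,
                          mass_ref, height_ref) {
  if (length(phase) < 100)
    stop_capgap("template must carry at least 100 samples per cycle",
                "capgap_config_error")
  if (max(abs(q[1, ] - q[nrow(q), ])) > 1e-6)
    stop_capgap("template angles must be periodic", "capgap_config_error")
  structure(list(phase = phase, time = time, q = q,
                 moments_per_kg = moments_per_kg, markers = markers,
                 mass_ref = mass_ref, height_ref = height_ref),
            class = "gait_template")
}

#' Build the desired-motion reference trial for a model
#'
#' Scales the reference gait template to the subject and evaluates it on the
#' given (possibly surgically modified) model: joint moments scale linearly
#' with body mass; kinematics are either taken directly from the template
#' (\code{retarget = FALSE}) or re-derived per frame by nonlinear least
#' squares tracking of the template's virtual marker trajectories (scaled by
#' the height ratio) with the model's matching landmarks
#' (\code{retarget = TRUE}). Tracking markers rather than imposing template
#' angles keeps distal segments oriented as in the reference gait even when
#' the model carries torsional bone deformities. Musculotendon lengths and
#' moment arms are then derived on the model.
#'
#' @param template a \code{\link{gait_template}}.
#' @param model an \code{msk_model} whose coordinates match the template.
#' @param mass subject body mass (kg).
#' @param height subject height (m).
#' @param retarget logical; track markers instead of copying angles.
#' @return A \code{trial_bundle} holding the desired motion.
#' @export
make_reference_trial <- function(template, model, mass,
                                 height = template$height_ref,
                                 retarget = FALSE) {
  cn <- coordinate_names(model)
  if (!all(cn %in% colnames(template$q)))
    stop_capgap("template does not cover all model coordinates",
                "capgap_config_error")
  tau <- template$moments_per_kg[, cn, drop = FALSE] * mass
  if (!retarget) {
    q <- template$q[, cn, drop = FALSE]
  } else {
    q <- retarget_kinematics(template, model, height)
  }
  b <- trial_bundle(time = template$time, q = q, tau = tau)
  derive_trial_geometry(model, b)
}

# Marker-name -> (segment, landmark) lookup on the model.
model_marker_table <- function(model, marker_names) {
  tab <- list()
  for (s in model$segments)
    for (lm in names(s$landmarks))
      tab[[lm]] <- list(segment = s$name, location = s$landmarks[[lm]])
  missing <- setdiff(marker_names, names(tab))
  if (length(missing))
    stop_capgap(sprintf(
      "retargeting requested but model lacks landmark(s): %s",
      paste(missing, collapse = ", ")), "capgap_config_error")
  tab[marker_names]
}

retarget_kinematics <- function(template, model, height) {
  mk_names <- names(template$markers)
  tab <- model_marker_table(model, mk_names)
  cn <- coordinate_names(model)
  scale <- height / template$height_ref
  lo <- vapply(model$coordinates, function(co) co$range[1], 0)
  hi <- vapply(model$coordinates, function(co) co$range[2], 0)
  nT <- nrow(template$q)
  q_out <- matrix(NA_real_, nT, length(cn), dimnames = list(NULL, cn))
  q_cur <- setNames(rep(0, length(cn)), cn)
  resid_fn <- function(qv) {
    qn <- setNames(pmin(pmax(qv, lo), hi), cn)
    tr <- segment_transforms(model, qn)
    unlist(lapply(mk_names, function(nm) {
      point_to_ground(tr, tab[[nm]]$segment, tab[[nm]]$location) -
        scale * template$markers[[nm]][i, ]
    }))
  }
  for (i in seq_len(nT)) {
    fit <- minpack.lm::nls.lm(par = q_cur, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    q_cur <- setNames(pmin(pmax(fit$par, lo), hi), cn)
    q_out[i, ] <- q_cur
  }
  q_out
}
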