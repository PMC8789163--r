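## File formats: a tab-delimited motion-storage dialect (header block with
## nRows/nColumns and an `endheader` sentinel, compatible with common
## musculoskeletal motion files), JSON model/config serialization, and
## reference-gait round-tripping.  All numeric output uses %.17g so
## read(write(x)) is bit-exact.

#' Write a motion table
#'
#' @param x list with `name` (string), `time` (numeric vector), `data`
#'   (data.frame or named list of numeric columns), and optional `meta`
#'   (named character vector embedded as `key=value` header lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motion <- function(x, path) {
  stopifnot(length(x$time) >= 1, !is.unsorted(x$time, strictly = TRUE))
  df <- as.data.frame(x$data, check.names = FALSE)
  stopifnot(nrow(df) == length(x$time))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(x$name %||% "motion", "version=1"), con)
  for (k in names(x$meta %||% character()))
    writeLines(sprintf("%s=%s", k, x$meta[[k]]), con)
  writeLines(sprintf("nRows=%d", nrow(df)), con)
  writeLines(sprintf("nColumns=%d", ncol(df) + 1L), con)
  writeLines("inDegrees=no", con)
  writeLines("endheader", con)
  writeLines(paste(c("time", names(df)), collapse = "\t"), con)
  fmt <- function(v) sprintf("%.17g", v)
  body <- cbind(fmt(x$time), vapply(df, fmt, character(nrow(df))))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a motion table
#'
#' @param path file written by [write_motion()] (or a compatible
#'   motion-storage file).
#' @return list with `name`, `time`, `data` (data.frame), `meta`.
#' @export
read_motion <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", lines)
  if (is.na(end)) stop(sprintf("%s: missing 'endheader' sentinel", path))
  header <- lines[seq_len(end - 1L)]
  meta <- character(0)
  nrows <- ncols <- NA_integer_
  for (i in seq_along(header)) {
    ln <- header[i]
    if (!grepl("=", ln)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (kv[1] == "nRows") nrows <- as.integer(kv[2])
    else if (kv[1] == "nColumns") ncols <- as.integer(kv[2])
    else if (!(kv[1] %in% c("version", "inDegrees")))
      meta[kv[1]] <- paste(kv[-1], collapse = "=")
  }
  if (is.na(nrows) || is.na(ncols))
    stop(sprintf("%s: malformed header (missing nRows/nColumns before line %d)",
                 path, end))
  cn <- strsplit(lines[end + 1L], "\t", fixed = TRUE)[[1]]
  if (length(cn) != ncols)
    stop(sprintf("%s: header declares %d columns but line %d has %d",
                 path, ncols, end + 1L, length(cn)))
  if (nrows < 1) stop(sprintf("%s: empty table", path))
  body <- lines[end + 1L + seq_len(nrows)]
  vals <- lapply(strsplit(body, "\t", fixed = TRUE), as.numeric)
  mat <- do.call(rbind, vals)
  if (ncol(mat) != ncols)
    stop(sprintf("%s: data row width mismatch after line %d", path, end + 1L))
  time <- mat[, 1]
  if (is.unsorted(time, strictly = TRUE))
    stop(sprintf("%s: time column must be strictly increasing", path))
  data <- as.data.frame(mat[, -1, drop = FALSE])
  names(data) <- cn[-1]
  list(name = lines[1], time = time, data = data, meta = meta)
}

#' Serialize a model to JSON
#'
#' Canonical on-disk model description (documented schema, SI units, angles
#' in radians, version field).
#'
#' @param m a `predgait_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  out <- list(schema = "predgait-model", version = m$version, name = m$name,
              gravity = m$gravity, segments = m$segments,
              joints = m$joints, muscles = m$muscles,
              contact_spheres = m$contact_spheres, passive = m$passive,
              torque_actuators = m$torque_actuators,
              collision_pairs = m$collision_pairs,
              variant_state = m$variant_state)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path file written by [write_model()].
#' @return a `predgait_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$schema, "predgait-model"))
    config_error("%s: not a predgait model file", path)
  num <- function(v) vapply(v, as.numeric, 0)
  segments <- do.call(rbind, lapply(x$segments, function(s)
    data.frame(name = s$name, mass = s$mass, inertia = s$inertia,
               length = s$length, com_x = s$com_x, com_y = s$com_y)))
  joints <- lapply(x$joints, function(j) {
    j$loc_parent <- num(j$loc_parent)
    j$coords <- vapply(j$coords, as.character, "")
    j$range <- lapply(j$range, num)
    if (!is.null(j$is_toe)) j$is_toe <- isTRUE(j$is_toe)
    j
  })
  muscles <- lapply(x$muscles, function(mu) {
    mu$path <- lapply(mu$path, function(pp)
      list(segment = pp$segment, point = num(pp$point)))
    mu
  })
  spheres <- lapply(x$contact_spheres, function(cs) {
    cs$center <- num(cs$center)
    cs
  })
  model_spec(name = x$name, segments = segments, joints = joints,
             muscles = muscles, contact_spheres = spheres,
             passive = lapply(x$passive, function(p) lapply(p, as.numeric)),
             torque_actuators = x$torque_actuators %||% list(),
             collision_pairs = lapply(x$collision_pairs %||% list(),
                                      function(cp) {
               cp$a$point <- num(cp$a$point); cp$b$point <- num(cp$b$point)
               cp
             }),
             gravity = x$gravity)
}

#' Write a reference gait to motion-storage files
#'
#' Writes `<stem>_mean.mot` and `<stem>_sd.mot` plus `<stem>.json`
#' metadata (generator seed and parameters for provenance).
#'
#' @param ref a `reference_gait`.
#' @param stem output path stem.
#' @return character vector of the three paths, invisibly.
#' @export
write_reference <- function(ref, stem) {
  sig <- ref$signals
  mk <- function(field) {
    df <- as.data.frame(lapply(sig, `[[`, field), check.names = FALSE)
    names(df) <- names(sig)
    df
  }
  t <- ref$grid / 100 * ref$cycle_duration
  meta <- c(seed = as.character(ref$seed),
            speed = sprintf("%.17g", ref$speed),
            stance_fraction = sprintf("%.17g", ref$stance_fraction),
            cycle_duration = sprintf("%.17g", ref$cycle_duration))
  p1 <- paste0(stem, "_mean.mot"); p2 <- paste0(stem, "_sd.mot")
  p3 <- paste0(stem, ".json")
  write_motion(list(name = "reference_gait_mean", time = t, data = mk("mean"),
                    meta = meta), p1)
  write_motion(list(name = "reference_gait_sd", time = t, data = mk("sd"),
                    meta = meta), p2)
  jsonlite::write_json(
    list(schema = "predgait-reference", seed = ref$seed, speed = ref$speed,
         stance_fraction = ref$stance_fraction, body_mass = ref$body_mass,
         cycle_duration = ref$cycle_duration, n_cycles = ref$n_cycles,
         sd_scale = ref$sd_scale,
         units = lapply(sig, `[[`, "unit")),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' Read a reference gait from motion-storage files
#'
#' @param stem path stem used by [write_reference()].
#' @return a `reference_gait` (passes [validate_reference()]).
#' @export
read_reference <- function(stem) {
  mn <- read_motion(paste0(stem, "_mean.mot"))
  sd <- read_motion(paste0(stem, "_sd.mot"))
  js <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  signals <- list()
  for (nmx in names(mn$data))
    signals[[nmx]] <- list(mean = mn$data[[nmx]], sd = sd$data[[nmx]],
                           unit = js$units[[nmx]])
  structure(list(grid = seq(0, 100, by = 1), signals = signals,
                 speed = js$speed, stance_fraction = js$stance_fraction,
                 body_mass = js$body_mass,
                 cycle_duration = js$cycle_duration, seed = js$seed,
                 n_cycles = js$n_cycles, sd_scale = js$sd_scale),
            class = "reference_gait")
}

#' Export a gait solution
#'
#' Writes the reconstructed full-cycle states and ground reaction forces as
#' motion-storage files and the outcome summary (objective terms, cost of
#' transport, stride length, solver statistics, configuration echo) as
#' JSON.
#'
#' @param sol a `gait_solution`.
#' @param dir output directory (created if needed).
#' @param stem file name stem, default the model name.
#' @return paths written, invisibly.
#' @export
write_solution <- function(sol, dir, stem = sol$model_name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- sol$cycle_frac / 100 * sol$cycle_duration
  states <- as.data.frame(t(sol$cycle_states))
  names(states) <- c(sol$coord_names, paste0(sol$coord_names, "_u"),
                     paste0("a_", sol$muscle_names),
                     paste0("ft_", sol$muscle_names))
  meta <- c(model = sol$model_name, guess = sol$guess,
            n_mesh = as.character(sol$n_mesh),
            seed = as.character(sol$config$seed))
  p1 <- file.path(dir, paste0(stem, "_states.mot"))
  write_motion(list(name = "gait_states", time = t, data = states,
                    meta = meta), p1)
  grf <- data.frame(Fx_r = sol$grf$r$Fx, Fy_r = sol$grf$r$Fy,
                    cop_r = sol$grf$r$cop, Fx_l = sol$grf$l$Fx,
                    Fy_l = sol$grf$l$Fy, cop_l = sol$grf$l$cop)
  p2 <- file.path(dir, paste0(stem, "_grf.mot"))
  write_motion(list(name = "gait_grf", time = t, data = grf, meta = meta), p2)
  p3 <- file.path(dir, paste0(stem, "_outcomes.json"))
  jsonlite::write_json(list(
    schema = "predgait-outcomes", model = sol$model_name,
    guess = sol$guess, status = sol$status, iterations = sol$iterations,
    feasibility = sol$feas, objective = sol$objective,
    terms = as.list(sol$terms), cot = sol$cot,
    stride_length = sol$stride_length, cycle_duration = sol$cycle_duration,
    stance_fraction = sol$stance_fraction, speed = sol$speed,
    config = unclass(sol$config)), p3, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(c(p1, p2, p3))
}
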