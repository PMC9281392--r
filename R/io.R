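#' Run configuration
#'
#' A declarative YAML file (or an in-memory list) describing one simulation:
#' group, ensemble, thermodynamic parameters and output paths. Unknown keys
#' are rejected; the standard defaults (`dt = 0.005`, `gamma = 0.1`,
#' `cutoff = 3.5`, `image_radius = 2`) are applied when omitted.
#'
#' @name run_config
NULL

config_known_keys <- c(
  "group", "dimension", "n_asym", "wyckoff", "density", "box", "ensemble",
  "steps", "dt", "gamma", "temperature", "pressure", "npt_interval",
  "npt_step", "cutoff", "epsilon", "sigma", "image_radius", "seed",
  "log_every", "output_prefix", "start_structure")

config_defaults <- list(dt = 0.005, gamma = 0.1, cutoff = 3.5, epsilon = 1,
                        sigma = 1, image_radius = 2, seed = 1,
                        log_every = 10, npt_interval = 10, npt_step = 0.01)

#' Validate a configuration list
#' @param cfg named list of settings.
#' @return the completed configuration (class `symdyn_config`).
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(config_defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- config_defaults[[k]]
  }
  req <- c("group", "ensemble", "steps")
  miss <- req[vapply(req, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(miss)) stop("missing config key(s): ", paste(miss, collapse = ", "))
  if (!cfg$ensemble %in% c("nve", "nvt", "npt")) {
    stop("ensemble must be one of nve, nvt, npt")
  }
  if (cfg$ensemble %in% c("nvt", "npt") && is.null(cfg$temperature)) {
    stop("ensemble '", cfg$ensemble, "' requires a temperature")
  }
  if (cfg$ensemble == "npt" && is.null(cfg$pressure)) {
    stop("ensemble 'npt' requires a pressure")
  }
  if (is.null(cfg$density) && is.null(cfg$box) && is.null(cfg$start_structure)) {
    stop("config needs a density, an explicit box, or a start_structure")
  }
  structure(cfg, class = "symdyn_config")
}

#' Read / write a run configuration
#' @param path file path (YAML).
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a validated configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a structure as extended XYZ
#'
#' One frame: atom count, a comment line carrying `Lattice="..."` (row-major
#' lattice vectors, zero-padded to 3D for 2D systems), `dimension`, `group`,
#' and per-atom `LJ x y z` lines at full precision. With `expand = TRUE` the
#' full unit cell is written and ghost mates are tagged by their
#' asymmetric-unit owner.
#'
#' @param state a [system_state()].
#' @param path output file.
#' @param expand write the expanded unit cell instead of the asymmetric
#'   unit.
#' @param append append a frame (trajectory writing).
#' @export
write_structure <- function(state, path, expand = FALSE, append = FALSE) {
  D <- state$group$D
  lat3 <- diag(3) * 0
  lat3[seq_len(D), seq_len(D)] <- state$box
  latstr <- paste(formatC(t(lat3), format = "g", digits = 17), collapse = " ")
  if (expand) {
    cf <- state_cellfrac(state)
    pos <- frac_to_cart(cf, state$box)
    sr <- attr(cf, "selfrow")
    ghost <- !(seq_len(nrow(pos)) %in% sr)
  } else {
    pos <- state$pos
    ghost <- rep(FALSE, nrow(pos))
  }
  pos3 <- cbind(pos, matrix(0, nrow(pos), 3 - D))
  hdr <- sprintf(
    'Lattice="%s" Properties=species:S:1:pos:R:3:ghost:I:1 dimension=%d group=%s expanded=%d',
    latstr, D, state$group$id, as.integer(expand))
  lines <- c(nrow(pos3), hdr,
             sprintf("LJ %.17g %.17g %.17g %d", pos3[, 1], pos3[, 2],
                     pos3[, 3], as.integer(ghost)))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Read an extended-XYZ structure written by [write_structure()]
#'
#' @param path file path.
#' @return list `positions` (n x D, non-ghost atoms only), `box`,
#'   `dimension`, `group` (identifier string), `expanded`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  hdr <- lines[2]
  lat <- as.numeric(strsplit(sub('.*Lattice="([^"]*)".*', "\\1", hdr),
                             "\\s+")[[1]])
  D <- as.integer(sub(".*dimension=([0-9]+).*", "\\1", hdr))
  grp <- sub(".*group=(\\S+).*", "\\1", hdr)
  expanded <- sub(".*expanded=([0-9]+).*", "\\1", hdr) == "1"
  box <- matrix(lat, 3, 3, byrow = TRUE)[seq_len(D), seq_len(D), drop = FALSE]
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  pos3 <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  ghost <- vapply(toks, function(tk) as.integer(tk[5]), integer(1)) == 1L
  list(positions = pos3[!ghost, seq_len(D), drop = FALSE], box = box,
       dimension = D, group = grp, expanded = expanded,
       all_positions = pos3[, seq_len(D), drop = FALSE])
}

#' Append a scalar record to a CSV log
#'
#' Fixed column schema `step, kinetic, potential, total, temperature,
#' density, volume`; the header is written when the file does not yet
#' exist.
#'
#' @param path CSV file path.
#' @param record named list or one-row data.frame with the schema columns.
#' @export
log_scalars <- function(path, record) {
  record <- as.data.frame(record)
  cols <- c("step", "kinetic", "potential", "total", "temperature",
            "density", "volume")
  stopifnot(all(cols %in% names(record)))
  record <- record[, cols, drop = FALSE]
  utils::write.table(record, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     quote = FALSE)
  invisible(path)
}

#' Run a simulation described by a configuration
#'
#' The programmatic equivalent of the command-line `run` subcommand: builds
#' the starting state, dispatches on the ensemble, and optionally writes the
#' scalar log and final structure.
#'
#' @param cfg a [validate_config()] result (or a plain list, validated
#'   here).
#' @return the `run_md()` / `run_npt()` result list.
#' @export
run_from_config <- function(cfg) {
  if (!inherits(cfg, "symdyn_config")) cfg <- validate_config(cfg)
  group <- load_group(cfg$group, cfg$dimension)
  lj <- lj_params(cfg$epsilon, cfg$sigma, cfg$cutoff)
  wy <- if (is.null(cfg$wyckoff)) NULL else {
    w <- rep(NA_character_, cfg$n_asym)
    for (lab in names(cfg$wyckoff)) w[cfg$wyckoff[[lab]]] <- lab
    w
  }
  T0 <- if (is.null(cfg$temperature)) 0.5 else cfg$temperature
  state <- build_start(group, cfg$n_asym, cfg$density, T0, wyckoff = wy,
                       image_radius = cfg$image_radius, seed = cfg$seed,
                       lj = lj)
  thermo <- thermo_params(dt = cfg$dt, gamma = cfg$gamma, temperature = T0)
  out <- switch(cfg$ensemble,
    nve = run_md(state, cfg$steps, thermo, integrator = "nve",
                 log_every = cfg$log_every, seed = cfg$seed + 1L),
    nvt = run_md(state, cfg$steps, thermo, integrator = "baoab",
                 log_every = cfg$log_every, seed = cfg$seed + 1L),
    npt = run_npt(state, cfg$steps, thermo,
                  npt_params(cfg$pressure, T0, cfg$npt_interval,
                             cfg$npt_step),
                  log_every = cfg$log_every, seed = cfg$seed + 1L))
  if (!is.null(cfg$output_prefix)) {
    if (!is.null(out$trace)) {
      utils::write.table(out$trace, paste0(cfg$output_prefix, "_scalars.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
    write_structure(out$state, paste0(cfg$output_prefix, "_final.xyz"),
                    expand = TRUE)
  }
  out
}
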