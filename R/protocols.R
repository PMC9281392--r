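#' NVE energy-conservation run
#'
#' Builds a random symmetric start at the given density and temperature and
#' integrates it with velocity Verlet, returning the scalar trace and the
#' relative drift of the conserved unit-cell total energy.
#'
#' @param group group identifier (name or number) or a loaded group.
#' @param n_asym asymmetric-unit particle count.
#' @param density unit-cell number density.
#' @param T0 starting temperature (Maxwell-Boltzmann draw).
#' @param nsteps NVE steps.
#' @param dt time step.
#' @param image_radius explicit image radius.
#' @param seed integer seed.
#' @param log_every trace stride.
#' @return list `trace`, `drift` (secular drift: magnitude of the
#'   least-squares linear trend of the total energy across the run, relative
#'   to |E(0)|), `max_excursion` (largest instantaneous |E(t) - E(0)|/|E(0)|,
#'   which also contains the bounded, reversible O(dt^2) oscillation every
#'   symplectic integrator shows during close encounters), `state`,
#'   `status`.
#' @export
run_conservation <- function(group, n_asym = 5, density = 0.2, T0 = 0.5,
                             nsteps = 5000, dt = 0.005, image_radius = 2,
                             seed = 1, log_every = 10) {
  if (!inherits(group, "symdyn_group")) group <- load_group(group)
  state <- build_start(group, n_asym, density, T0,
                       image_radius = image_radius, seed = seed)
  out <- run_md(state, nsteps, thermo_params(dt = dt), integrator = "nve",
                log_every = log_every)
  tr <- out$trace
  # The total energy can sit arbitrarily close to zero by kinetic/potential
  # cancellation at these conditions, which would make a |E(0)| denominator
  # meaningless; normalise by the larger of |E(0)| and the initial unit-cell
  # kinetic energy (a strictly positive energy scale of the system).
  scale <- max(abs(tr$total[1]), tr$kinetic[1])
  fit <- stats::lm(total ~ step, data = tr)
  drift <- abs(stats::coef(fit)[["step"]]) * nsteps / scale
  excursion <- max(abs(tr$total - tr$total[1])) / scale
  list(trace = tr, drift = drift, max_excursion = excursion,
       energy_scale = scale, state = out$state, status = out$status)
}

#' Build a randomized symmetric starting state
#'
#' Samples asymmetric-unit positions in the fundamental domain (overlap-free
#' after expansion), places Wyckoff-assigned particles on their sites, and
#' draws Maxwell-Boltzmann velocities.
#'
#' @param group a `symdyn_group`.
#' @param n_asym number of asymmetric-unit particles (including Wyckoff
#'   ones).
#' @param density unit-cell number density.
#' @param T0 starting temperature.
#' @param wyckoff optional character vector length `n_asym` of site labels
#'   (NA = general).
#' @param image_radius explicit image radius.
#' @param seed integer seed.
#' @param lj an [lj_params()].
#' @export
build_start <- function(group, n_asym, density, T0, wyckoff = NULL,
                        image_radius = 2, seed = 1, lj = lj_params()) {
  if (is.null(wyckoff)) wyckoff <- rep(NA_character_, n_asym)
  w <- vapply(seq_len(n_asym), function(i) {
    if (is.na(wyckoff[i])) group$order
    else group$wyckoff[[wyckoff[i]]]$multiplicity
  }, numeric(1))
  n_cell <- sum(w)
  proj <- make_projector(group$bravais_class, group$D)
  box <- box_from_density(proj, n_cell, density)
  set.seed(seed)
  frac <- sample_start_positions(group, wyckoff, box)
  pos <- frac_to_cart(frac, box)
  vel <- maxwell_velocities(n_asym, group$D, 1, T0)
  system_state(pos, group, box, velocities = vel, image_radius = image_radius,
               lj = lj, wyckoff = wyckoff)
}

# rejection-sample general particles in the fundamental domain and Wyckoff
# particles on their sites, jointly overlap-checked after full expansion
sample_start_positions <- function(group, wyckoff, box, min_sep = 1.0,
                                   max_attempts = 20000L) {
  n <- length(wyckoff)
  imgs <- generate_images(1, group$D)
  pts <- matrix(NA_real_, 0, group$D)
  attempts <- 0L
  stuck <- 0L
  while (nrow(pts) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("start-configuration sampling failed after ", max_attempts,
           " attempts; lower n or the density")
    }
    if (stuck > 200L) {
      # a zero-dof Wyckoff particle (fixed point) can clash with earlier
      # placements forever; restart the whole configuration
      pts <- matrix(NA_real_, 0, group$D)
      stuck <- 0L
    }
    i <- nrow(pts) + 1L
    cand <- if (is.na(wyckoff[i])) {
      canonical_rep(stats::runif(group$D), group)
    } else {
      wrap_frac(project_to_wyckoff(stats::runif(group$D),
                                   group$wyckoff[[wyckoff[i]]]))
    }
    trial <- rbind(pts, cand)
    cell <- expand_unit_cell(trial, group, wyckoff_sites = wyckoff[seq_len(i)])
    if (min_pair_sep(frac_to_cart(cell, box), box, imgs) < min_sep) {
      stuck <- stuck + 1L
      next
    }
    pts <- trial
    stuck <- 0L
  }
  dimnames(pts) <- NULL
  pts
}

#' Root-mean-square deviation between two configurations
#'
#' Per-particle Cartesian displacements are taken via the nearest periodic
#' image of the (frozen) reference box; no rotational or translational
#' fitting is applied.
#'
#' @param config,ref N x D Cartesian position matrices (same particle
#'   order).
#' @param box reference box matrix.
#' @export
rmsd <- function(config, ref, box) {
  config <- rbind(config); ref <- rbind(ref)
  stopifnot(nrow(config) == nrow(ref))
  d <- config - ref
  s <- cart_to_frac(d, box)
  s <- s - round(s)
  d <- frac_to_cart(s, box)
  sqrt(mean(rowSums(d^2)))
}

#' Hexatic bond-orientational order parameter
#'
#' For each unit-cell particle, `psi6_i = |mean_j exp(6 i theta_ij)|` over
#' its `k` nearest neighbours (neighbours include periodic images), and the
#' reported value is the mean over particles: 1 for a perfect triangular
#' lattice, ~0 for square packing (with `k = 4`), small for a fluid.
#'
#' @param cellpos N x 2 Cartesian unit-cell positions.
#' @param box 2 x 2 box matrix.
#' @param k number of nearest neighbours (default 6).
#' @export
hexatic_order <- function(cellpos, box, k = 6) {
  cellpos <- rbind(cellpos)
  stopifnot(ncol(cellpos) == 2)
  imgs <- generate_images(1, 2)
  shifts <- imgs$offsets %*% box
  allpos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(r) {
    cellpos + matrix(shifts[r, ], nrow(cellpos), 2, byrow = TRUE)
  }))
  self_block <- imgs$zero_row
  psis <- vapply(seq_len(nrow(cellpos)), function(i) {
    d <- allpos - matrix(cellpos[i, ], nrow(allpos), 2, byrow = TRUE)
    r2 <- rowSums(d^2)
    r2[(self_block - 1) * nrow(cellpos) + i] <- Inf   # the particle itself
    nb <- order(r2)[seq_len(k)]
    th <- atan2(d[nb, 2], d[nb, 1])
    Mod(mean(exp(6i * th)))
  }, numeric(1))
  mean(psis)
}

#' Define one structure-screen job
#'
#' @param group group identifier or loaded group.
#' @param n_general number of general-position asymmetric-unit particles.
#' @param wyckoff_occupancy character vector of occupied site labels (one
#'   particle each).
#' @param npt_steps,nvt_steps,nve_steps protocol stage lengths.
#' @param start_density initial number density of the random start.
#' @param pressure,T_npt,T_nvt stage thermodynamic parameters.
#' @param seed integer seed.
#' @export
atlas_job <- function(group, n_general = 1, wyckoff_occupancy = character(0),
                      npt_steps = 50000, nvt_steps = 10000, nve_steps = 5000,
                      start_density = 0.4, pressure = 0.25,
                      T_npt = 0.1, T_nvt = 0.05, seed = 1) {
  if (!inherits(group, "symdyn_group")) group <- load_group(group)
  wy <- c(rep(NA_character_, n_general), wyckoff_occupancy)
  structure(list(group = group, wyckoff = wy,
                 n_asym = length(wy),
                 npt_steps = npt_steps, nvt_steps = nvt_steps,
                 nve_steps = nve_steps, start_density = start_density,
                 pressure = pressure, T_npt = T_npt, T_nvt = T_nvt,
                 seed = seed), class = "atlas_job")
}

#' Classify a structure-screen outcome
#'
#' `diverged` if any stage blew up; `low_density` if the NPT stage ended at
#' number density <= 0.5; `unstable` if the unconstrained NVE RMSD rose
#' above `threshold` (in sigma); `stable` otherwise.
#'
#' @param diverged logical.
#' @param final_density number density after the NPT stage.
#' @param rmsd_rise maximum RMSD of the unconstrained NVE trace.
#' @param threshold stability threshold (default 0.5 sigma).
#' @export
classify_status <- function(diverged, final_density, rmsd_rise,
                            threshold = 0.5) {
  if (isTRUE(diverged)) return("diverged")
  if (!is.na(final_density) && final_density <= 0.5) return("low_density")
  if (!is.na(rmsd_rise) && rmsd_rise > threshold) return("unstable")
  "stable"
}

#' Run one crystal-structure screen job
#'
#' Three stages: (1) constrained NPT compression at (`pressure`, `T_npt`);
#' (2) constrained NVT equilibration at `T_nvt` - the result is the proposed
#' crystal structure; (3) the unit cell is expanded and ALL particles are
#' integrated with unconstrained NVE in the frozen box, tracking RMSD from
#' the stage-3 starting configuration. A flat trace marks the structure
#' metastable.
#'
#' @param job an [atlas_job()].
#' @param rmsd_every RMSD sampling stride during stage 3.
#' @return list of class `atlas_result`: `status`, `rmsd_trace`
#'   (data.frame), `psi6` (2D only), `final_density`, `structure` (stage-3
#'   start state), `traces` (per-stage scalar logs).
#' @export
run_atlas_job <- function(job, rmsd_every = 25) {
  g <- job$group
  state <- tryCatch(
    build_start(g, job$n_asym, job$start_density, job$T_npt,
                wyckoff = ifelse(is.na(job$wyckoff), NA_character_, job$wyckoff),
                seed = job$seed),
    error = function(e) e)
  if (inherits(state, "error")) {
    return(structure(list(status = "diverged", rmsd_trace = NULL, psi6 = NA,
                          final_density = NA, structure = NULL,
                          traces = NULL, error = conditionMessage(state)),
                     class = "atlas_result"))
  }
  set.seed(job$seed + 1L)
  npt_out <- run_npt(state, job$npt_steps,
                     thermo_params(temperature = job$T_npt),
                     npt_params(job$pressure, job$T_npt),
                     log_every = 50)
  final_density <- sum(state_weights(npt_out$state)) / det(npt_out$state$box)
  if (npt_out$status == "diverged") {
    return(structure(list(status = "diverged", rmsd_trace = NULL, psi6 = NA,
                          final_density = final_density, structure = NULL,
                          traces = list(npt = npt_out$trace)),
                     class = "atlas_result"))
  }
  nvt_out <- run_md(npt_out$state, job$nvt_steps,
                    thermo_params(temperature = job$T_nvt),
                    integrator = "baoab", log_every = 50)
  if (nvt_out$status == "diverged") {
    return(structure(list(status = "diverged", rmsd_trace = NULL, psi6 = NA,
                          final_density = final_density, structure = NULL,
                          traces = list(npt = npt_out$trace,
                                        nvt = nvt_out$trace)),
                     class = "atlas_result"))
  }
  # stage 3: expand the cell, drop the symmetry constraint, freeze the box.
  # Net momentum (inherited from the thermostatted stages) is removed once,
  # as usual before NVE production; otherwise the RMSD trace measures
  # centre-of-mass drift instead of structural change.
  full <- expand_state(nvt_out$state)
  vcom <- colSums(full$vel * full$mass) / sum(full$mass)
  full$vel <- sweep(full$vel, 2, vcom)
  ref <- full$pos
  thermo <- thermo_params()
  rows <- list(data.frame(step = 0, rmsd = 0))
  status <- "ok"
  st <- full
  for (s in seq_len(job$nve_steps)) {
    st <- tryCatch(step_nve(st, thermo), error = function(e) {
      if (grepl("overlap", conditionMessage(e))) {
        attr(st, "diverged") <- TRUE
        st
      } else stop(e)
    })
    if (isTRUE(attr(st, "diverged"))) {
      status <- "diverged"
      break
    }
    if (s %% rmsd_every == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        step = s, rmsd = rmsd(st$pos, ref, st$box))
    }
  }
  tr <- do.call(rbind, rows)
  rise <- max(tr$rmsd)
  psi6 <- if (g$D == 2 && status == "ok") {
    hexatic_order(st$pos, st$box)
  } else NA_real_
  structure(list(
    status = classify_status(status == "diverged", final_density, rise),
    rmsd_trace = tr, psi6 = psi6, final_density = final_density,
    structure = full, final_state = st,
    traces = list(npt = npt_out$trace, nvt = nvt_out$trace)),
    class = "atlas_result")
}

#' Expand a constrained state into an unconstrained full-cell state
#'
#' Every unit-cell particle becomes a real integrated particle of a
#' symmetry-free (`p1`-type) system in the same box; velocities of the
#' mates are the group-transformed velocities of their asymmetric-unit
#' representatives.
#'
#' @param state a [system_state()].
#' @export
expand_state <- function(state) {
  g <- state$group
  cf <- state_cellfrac(state)
  pos <- frac_to_cart(cf, state$box)
  Binv <- solve(state$box)
  vel <- NULL
  mass <- numeric(0)
  for (i in seq_len(nrow(state$pos))) {
    ops <- state_ops(state, i)
    vf <- rbind(state$vel[i, ]) %*% Binv
    for (g_op in ops) {
      vel <- rbind(vel, (vf %*% t(g_op$W)) %*% state$box)
      mass <- c(mass, state$mass[i])
    }
  }
  trivial <- structure(list(
    id = "p1-cell", D = g$D,
    elements = list(op_identity(g$D)), bravais_class = g$bravais_class,
    order = 1L, wyckoff = list()), class = "symdyn_group")
  a_need <- required_image_radius(state$box, state$lj$cutoff,
                                  minimum = state$image_radius_min)
  system_state(pos, trivial, state$box, velocities = vel, mass = mass,
               image_radius = a_need, lj = state$lj)
}

#' Enumerate screen jobs for a set of groups
#'
#' For each group: the four general-position cell sizes `{1,2,3,4} x |G|`,
#' plus, for each bundled Wyckoff site, one job with that site occupied and
#' one or two general particles.
#'
#' @param groups character vector of group identifiers.
#' @param ... forwarded to [atlas_job()] (stage lengths, seed, ...).
#' @return list of [atlas_job()]s with a manifest in
#'   `attr(, "manifest")`.
#' @export
atlas_jobs <- function(groups, ...) {
  jobs <- list()
  man <- list()
  for (gid in groups) {
    g <- load_group(gid)
    for (k in 1:4) {
      jobs[[length(jobs) + 1L]] <- atlas_job(g, n_general = k, ...)
      man[[length(man) + 1L]] <- data.frame(
        group = g$id, n_general = k, wyckoff = "",
        cell_count = k * g$order)
    }
    for (lab in names(g$wyckoff)) {
      jobs[[length(jobs) + 1L]] <- atlas_job(g, n_general = 1,
                                             wyckoff_occupancy = lab, ...)
      man[[length(man) + 1L]] <- data.frame(
        group = g$id, n_general = 1, wyckoff = lab,
        cell_count = g$order + g$wyckoff[[lab]]$multiplicity)
    }
  }
  attr(jobs, "manifest") <- do.call(rbind, man)
  jobs
}
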