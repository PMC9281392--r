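#' Constant-pressure (NPT) parameters
#'
#' Pressure enters only through the Metropolis acceptance rule of the box
#' moves; no virial is ever computed (a virial over the asymmetric unit
#' alone would be meaningless).
#'
#' @param pressure reduced pressure.
#' @param temperature reduced temperature of the Monte Carlo acceptance (use
#'   the thermostat temperature).
#' @param move_interval MD steps between box-move attempts.
#' @param max_step half-width of the symmetric ln-V proposal.
#' @param shear_step absolute half-width of additive shear proposals for the
#'   oblique/triclinic classes (reduced length).
#' @param min_aspect tilt clamp: proposals whose projected cell has
#'   min(face-to-face height) below `min_aspect * V^(1/D)` are auto-rejected.
#'   Nothing in the ensemble penalises near-degenerate representations of
#'   the same lattice, so an unclamped shear random-walks toward cells that
#'   need ever more explicit images; the clamp bounds the aspect ratio
#'   without touching the volume marginal.
#' @param seed optional integer seed.
#' @export
npt_params <- function(pressure, temperature, move_interval = 10,
                       max_step = 0.01, shear_step = 0.02, min_aspect = 0.4,
                       seed = NULL) {
  stopifnot(pressure >= 0, temperature > 0, move_interval >= 1, max_step > 0,
            min_aspect > 0, min_aspect < 1)
  structure(list(pressure = pressure, temperature = temperature,
                 move_interval = move_interval, max_step = max_step,
                 shear_step = shear_step, min_aspect = min_aspect,
                 seed = seed),
            class = "npt_params")
}

# free "lattice parameter" row-sets per Bravais class: rows scaled together
free_param_sets <- function(proj) {
  switch(proj$bravais_class,
    rectangular = , `centered-rectangular` = list(1L, 2L),
    orthorhombic = list(1L, 2L, 3L),
    tetragonal = list(c(1L, 2L), 3L),
    hexagonal = if (proj$D == 3) list(c(1L, 2L), 3L) else list(),
    trigonal = list(c(1L, 2L), 3L),
    monoclinic = list(1L, 2L, 3L),
    oblique = list(1L, 2L),
    triclinic = list(1L, 2L, 3L),
    list())
}

#' Propose a perturbed working box
#'
#' Symmetric random walk: an isotropic step in ln V, plus (for classes with
#' more than one free lattice parameter) a log-scaling of one randomly
#' chosen parameter, plus (oblique/triclinic only) an additive perturbation
#' of one off-diagonal shear component with a fixed step size. The working
#' box the system actually uses is `apply_projector(proj, B_new)`, so every
#' proposal lands exactly on the group's Bravais class.
#'
#' @param Bp current working (unconstrained) box matrix.
#' @param proj the group's [make_projector()].
#' @param params an [npt_params()].
#' @return proposed working box matrix (possibly with `det <= 0`, which the
#'   caller must auto-reject).
#' @export
propose_box <- function(Bp, proj, params) {
  D <- proj$D
  Bn <- Bp * exp(stats::runif(1, -params$max_step, params$max_step) / D)
  sets <- free_param_sets(proj)
  if (length(sets) > 1) {
    k <- sets[[sample.int(length(sets), 1)]]
    Bn[k, ] <- Bn[k, , drop = FALSE] *
      exp(stats::runif(1, -params$max_step, params$max_step))
  }
  if (proj$bravais_class %in% c("oblique", "triclinic")) {
    ij <- sample.int(D, 2, replace = TRUE)
    Bn[ij[1], ij[2]] <- Bn[ij[1], ij[2]] +
      stats::runif(1, -params$shear_step, params$shear_step)
  }
  Bn
}

#' Metropolis acceptance for a box-scaling move
#'
#' `min(1, exp(-[dU + P dV - (N + 1) T ln(V_new/V_old)] / T))` - the
#' standard constant-pressure rule for proposals symmetric in ln V, which
#' reproduces the ideal-gas equation of state `<N/V> = P/T` exactly.
#'
#' @param dU potential-energy change of the unit cell.
#' @param V_old,V_new cell volumes (positive).
#' @param N unit-cell particle count.
#' @param params an [npt_params()].
#' @export
accept_move <- function(dU, V_old, V_new, N, params) {
  stopifnot(V_old > 0, V_new > 0)
  arg <- -(dU + params$pressure * (V_new - V_old) -
             (N + 1) * params$temperature * log(V_new / V_old)) /
    params$temperature
  if (arg >= 0) return(TRUE)
  stats::runif(1) < exp(arg)
}

# ensure the explicit image shell still reaches past the cutoff after the
# box shrinks: radius a covers (3^a - 1)/2 cells per side
required_image_radius <- function(box, cutoff, minimum = 1L) {
  ext <- min(cell_heights(box))
  a <- minimum
  while ((3^a - 1) / 2 * ext < cutoff) a <- a + 1L
  a
}

# perpendicular heights of the cell (distance between opposite faces)
cell_heights <- function(box) {
  box <- as.matrix(box)
  D <- nrow(box)
  V <- abs(det(box))
  vapply(seq_len(D), function(i) {
    others <- box[-i, , drop = FALSE]
    if (D == 2) {
      V / sqrt(sum(others^2))
    } else {
      cr <- c(others[1, 2] * others[2, 3] - others[1, 3] * others[2, 2],
              others[1, 3] * others[2, 1] - others[1, 1] * others[2, 3],
              others[1, 1] * others[2, 2] - others[1, 2] * others[2, 1])
      V / sqrt(sum(cr^2))
    }
  }, numeric(1))
}

#' Run NPT: BAOAB dynamics interleaved with Monte Carlo box moves
#'
#' Every `move_interval` MD steps one box move is attempted: the
#' unconstrained working box is perturbed, projected onto the Bravais class,
#' the particles' fractional coordinates are held fixed (affine rescale),
#' and the move is accepted by [accept_move()]. Periodic wrapping plays no
#' role: interactions are entirely via the explicit image shell, whose
#' radius is enlarged automatically if the cell shrinks below what the
#' cutoff requires.
#'
#' @param state a [system_state()].
#' @param nsteps total MD steps.
#' @param thermo a [thermo_params()].
#' @param npt an [npt_params()].
#' @param log_every scalar-log stride.
#' @param seed optional integer seed.
#' @return list `state`, `trace`, `status`, `accept_rate`, `Bp` (final
#'   working box).
#' @export
run_npt <- function(state, nsteps, thermo, npt, log_every = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  proj <- make_projector(state$group$bravais_class, state$group$D)
  Bp <- state$box
  N <- sum(state_weights(state))
  rows <- list()
  att <- acc <- 0L
  status <- "ok"
  for (s in seq_len(nsteps)) {
    state <- tryCatch(step_baoab(state, thermo), error = function(e) {
      if (grepl("overlap", conditionMessage(e))) {
        attr(state, "diverged") <- TRUE
        state
      } else stop(e)
    })
    if (isTRUE(attr(state, "diverged"))) {
      status <- "diverged"
      break
    }
    if (s %% npt$move_interval == 0) {
      att <- att + 1L
      Bp_new <- propose_box(Bp, proj, npt)
      box_new <- if (det(Bp_new) > 1e-10) apply_projector(proj, Bp_new)
      if (!is.null(box_new) &&
          min(cell_heights(box_new)) >=
            npt$min_aspect * det(box_new)^(1 / state$group$D)) {
        U_old <- state$cache$energy
        if (is.null(U_old)) U_old <- total_energy(state)
        trial <- set_box(state, box_new)
        U_new <- tryCatch(total_energy(trial), error = function(e) Inf)
        if (is.finite(U_new) &&
            accept_move(U_new - U_old, det(state$box), det(box_new), N, npt)) {
          acc <- acc + 1L
          state <- trial
          Bp <- Bp_new
          a_need <- required_image_radius(state$box, state$lj$cutoff,
                                          minimum = state$image_radius_min)
          if (a_need != state$images$radius) {
            state$images <- generate_images(a_need, state$group$D)
          }
          state$cache$forces <- NULL   # stale after rescale
          state$cache$energy <- U_new
        }
      }
    }
    if (log_every > 0 && s %% log_every == 0) {
      e <- total_energy_report(state, use_cache = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        step = s, kinetic = e[["kinetic"]], potential = e[["potential"]],
        total = e[["total"]], temperature = temperature(state),
        density = N / det(state$box), volume = det(state$box))
    }
  }
  list(state = state, trace = do.call(rbind, rows), status = status,
       accept_rate = if (att > 0) acc / att else NA_real_, Bp = Bp)
}
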