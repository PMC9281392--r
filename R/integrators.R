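#' Thermostat / integration parameters
#'
#' Defaults follow the package's standard protocol: time step 0.005 tau and
#' Langevin friction 0.1 in reduced units.
#'
#' @param dt time step (reduced tau units).
#' @param gamma Langevin friction (1/tau); `0` turns BAOAB into plain
#'   velocity Verlet.
#' @param temperature target reduced temperature (ignored by NVE).
#' @param seed optional integer seed applied by the run drivers.
#' @export
thermo_params <- function(dt = 0.005, gamma = 0.1, temperature = 0, seed = NULL) {
  stopifnot(dt > 0, gamma >= 0, temperature >= 0)
  structure(list(dt = dt, gamma = gamma, temperature = temperature, seed = seed),
            class = "thermo_params")
}

#' Draw Maxwell-Boltzmann velocities
#' @param n particles; @param D dimension; @param mass per-particle masses;
#' @param temperature reduced temperature.
#' @export
maxwell_velocities <- function(n, D, mass, temperature) {
  mass <- rep_len(mass, n)
  matrix(stats::rnorm(n * D), n, D) * sqrt(temperature / mass)
}

#' One velocity-Verlet step on plain coordinates
#'
#' Low-level integrator core used both by the constrained engine and by
#' closed-form test potentials. `force_fn(q)` returns the force matrix;
#' `post_pos`/`post_vel` hooks apply holonomic corrections.
#'
#' @param q,v n x D position/velocity matrices.
#' @param f cached force at `q`.
#' @param m per-particle masses.
#' @param dt time step.
#' @param force_fn function of `q` returning n x D forces.
#' @param post_pos,post_vel optional correction hooks.
#' @return list `q`, `v`, `f`.
#' @export
vv_core <- function(q, v, f, m, dt, force_fn,
                    post_pos = identity, post_vel = identity) {
  v <- v + 0.5 * dt * f / m
  q <- post_pos(q + dt * v)
  v <- post_vel(v)
  f <- force_fn(q)
  v <- post_vel(v + 0.5 * dt * f / m)
  list(q = q, v = v, f = f)
}

#' One BAOAB Langevin step on plain coordinates
#'
#' Splitting B(half kick) - A(half drift) - O(Ornstein-Uhlenbeck) -
#' A(half drift) - B(half kick), with O-step decay `exp(-gamma dt)` and noise
#' scale `sqrt(T (1 - exp(-2 gamma dt)) / m)`. With `gamma = 0` the O step is
#' the identity and the scheme reduces to velocity Verlet.
#'
#' @inheritParams vv_core
#' @param gamma friction; @param temperature target temperature.
#' @export
baoab_core <- function(q, v, f, m, dt, gamma, temperature, force_fn,
                       post_pos = identity, post_vel = identity) {
  n <- nrow(q); D <- ncol(q)
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(temperature * (1 - c1^2) / m)
  v <- v + 0.5 * dt * f / m                       # B
  q <- post_pos(q + 0.5 * dt * v)                 # A
  v <- c1 * v + c2 * matrix(stats::rnorm(n * D), n, D)  # O
  v <- post_vel(v)
  q <- post_pos(q + 0.5 * dt * v)                 # A
  f <- force_fn(q)
  v <- post_vel(v + 0.5 * dt * f / m)             # B
  list(q = q, v = v, f = f)
}

state_force_hooks <- function(state) {
  env <- new.env(parent = emptyenv())
  env$state <- state
  list(
    force = function(q) {
      env$state$pos <- q                 # ghosts re-derived inside lj_eval
      res <- lj_eval(env$state)
      env$state$cache$energy <- res$energy
      env$state$cache$forces_pos <- q
      res$forces
    },
    post_pos = function(q) {
      # wrap into the root cell (ghost bookkeeping identifies each particle
      # with its wrapped root copy), then restore any Wyckoff constraint
      st <- env$state
      st$pos <- wrap_frac(q %*% state_binv(st)) %*% st$box
      env$state <- apply_constraints_pos(st)
      env$state$pos
    },
    post_vel = function(v) {
      env$state$vel <- v
      env$state <- apply_constraints_vel(env$state)
      env$state$vel
    },
    env = env
  )
}

#' One NVE velocity-Verlet step of a constrained state
#'
#' Ghost positions are re-derived from the asymmetric unit before every
#' force evaluation; Wyckoff corrections are applied within the position
#' update and the normal velocity components are removed after every kick.
#'
#' @param state a [system_state()] with cached forces (`state$cache$forces`
#'   is filled on first use).
#' @param params a [thermo_params()].
#' @export
step_nve <- function(state, params) {
  hooks <- state_force_hooks(state)
  f <- state_cached_force(state)
  out <- vv_core(state$pos, state$vel, f, state$mass, params$dt, hooks$force,
                 hooks$post_pos, hooks$post_vel)
  finish_step(hooks$env$state, out)
}

#' One BAOAB Langevin step of a constrained state
#' @inheritParams step_nve
#' @export
step_baoab <- function(state, params) {
  hooks <- state_force_hooks(state)
  f <- state_cached_force(state)
  out <- baoab_core(state$pos, state$vel, f, state$mass, params$dt,
                    params$gamma, params$temperature, hooks$force,
                    hooks$post_pos, hooks$post_vel)
  finish_step(hooks$env$state, out)
}

# cached forces are only valid for the exact positions they were computed
# at; anything else (a reused state, a mutated position) recomputes
state_cached_force <- function(state) {
  f <- state$cache$forces
  if (is.null(f) || !identical(state$cache$forces_pos, state$pos)) {
    res <- lj_eval(state)
    state$cache$forces <- res$forces
    state$cache$forces_pos <- state$pos
    state$cache$energy <- res$energy
    f <- res$forces
  }
  f
}

finish_step <- function(state, out) {
  state$pos <- out$q
  state$vel <- out$v
  state$cache$forces <- out$f
  if (!all(is.finite(out$q)) || !all(is.finite(out$v)) ||
      max(abs(out$v)) > 1e6) {
    attr(state, "diverged") <- TRUE
  }
  state
}

#' Instantaneous reduced temperature
#'
#' `T = 2 KE / dof` with the kinetic energy of the asymmetric-unit particles
#' and `dof = D * n - (degrees of freedom removed by Wyckoff constraints)`.
#'
#' @param state a [system_state()].
#' @param dof override the degree-of-freedom count.
#' @export
temperature <- function(state, dof = NULL) {
  if (is.null(dof)) dof <- state_dof(state)
  stopifnot(dof > 0)
  ke <- 0.5 * sum(state$mass * rowSums(state$vel^2))
  2 * ke / dof
}

state_dof <- function(state) {
  nrow(state$pos) * state$group$D - removed_dof_total(state$constraints)
}

#' Kinetic, potential and total energy of the unit cell
#'
#' Kinetic energy counts each asymmetric-unit particle with its orbit
#' multiplicity (the unit cell holds that many copies moving with mapped
#' velocities); the potential is the per-cell sum. Their sum is the
#' conserved quantity of the constrained NVE dynamics.
#'
#' @param state a [system_state()].
#' @param use_cache reuse the potential energy computed at the last force
#'   evaluation (valid immediately after a completed step).
#' @return named numeric vector `kinetic`, `potential`, `total`, plus
#'   `kinetic_asym` for the per-asymmetric-unit bookkeeping.
#' @export
total_energy_report <- function(state, use_cache = FALSE) {
  w <- state_weights(state)
  ke_asym <- 0.5 * sum(state$mass * rowSums(state$vel^2))
  ke <- 0.5 * sum(w * state$mass * rowSums(state$vel^2))
  pe <- if (use_cache && !is.null(state$cache$energy)) state$cache$energy
        else total_energy(state)
  c(kinetic = ke, potential = pe, total = ke + pe, kinetic_asym = ke_asym)
}

#' Run constrained molecular dynamics
#'
#' Drives [step_nve()] or [step_baoab()] for `nsteps`, logging scalars every
#' `log_every` steps. Any non-finite coordinate or a speed above `1e6`
#' terminates the run with status `"diverged"` (no exception: the structure
#' screen consumes this status).
#'
#' @param state a [system_state()].
#' @param nsteps number of steps.
#' @param params a [thermo_params()].
#' @param integrator `"nve"` or `"baoab"`.
#' @param log_every scalar-log stride (0 disables the trace).
#' @param seed optional integer seed (`set.seed`) for the noise stream.
#' @return list with `state`, `trace` (data.frame: step, kinetic, potential,
#'   total, temperature, density, volume), `status` (`"ok"`/`"diverged"`).
#' @export
run_md <- function(state, nsteps, params, integrator = c("baoab", "nve"),
                   log_every = 10, seed = NULL) {
  integrator <- match.arg(integrator)
  if (!is.null(seed)) set.seed(seed)
  stepper <- if (integrator == "nve") step_nve else step_baoab
  rows <- list()
  logit <- function(step) {
    if (log_every > 0 && (step %% log_every == 0 || step == 0)) {
      e <- total_energy_report(state, use_cache = step > 0)
      rows[[length(rows) + 1L]] <<- data.frame(
        step = step, kinetic = e[["kinetic"]], potential = e[["potential"]],
        total = e[["total"]], temperature = temperature(state),
        density = sum(state_weights(state)) / det(state$box),
        volume = det(state$box))
    }
  }
  logit(0)
  status <- "ok"
  for (s in seq_len(nsteps)) {
    state <- tryCatch(stepper(state, params), error = function(e) {
      if (grepl("overlap", conditionMessage(e))) {
        attr(state, "diverged") <- TRUE
        state
      } else stop(e)
    })
    if (isTRUE(attr(state, "diverged"))) {
      status <- "diverged"
      attr(state, "diverged") <- NULL
      break
    }
    logit(s)
  }
  list(state = state, trace = do.call(rbind, rows), status = status)
}
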