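#' Lennard-Jones parameters (reduced units)
#'
#' Energies are in units of the well depth \eqn{\epsilon}, lengths in units
#' of \eqn{\sigma}, masses in units of the particle mass, and times in the
#' derived unit \eqn{\tau = \sqrt{m \sigma^2 / \epsilon}}.
#'
#' @param epsilon well depth (default 1).
#' @param sigma zero-crossing length (default 1).
#' @param cutoff truncation radius (default 3.5; no tail correction).
#' @param shift subtract the pair energy at the cutoff (cut-and-shift) so
#'   the potential is continuous there. Forces are identical either way;
#'   shifting only removes the O(u(r_c)) jumps in the bookkept energy each
#'   time a pair crosses the cutoff, which would otherwise swamp the NVE
#'   conservation signal. Default `TRUE`.
#' @export
lj_params <- function(epsilon = 1, sigma = 1, cutoff = 3.5, shift = TRUE) {
  stopifnot(epsilon >= 0, sigma > 0, cutoff > sigma)
  src6 <- (sigma / cutoff)^6
  ushift <- if (shift) 4 * epsilon * (src6^2 - src6) else 0
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff,
                 shift = shift, ushift = ushift),
            class = "lj_params")
}

#' Lennard-Jones pair energy and scalar force
#'
#' @param r pair distance(s), `r > 0`.
#' @param params an [lj_params()] object.
#' @return list with vectors `energy` (`4eps[(s/r)^12 - (s/r)^6]`, zero at
#'   and beyond the cutoff) and `force` (`-du/dr`, zero at/beyond cutoff).
#' @export
lj_pair <- function(r, params = lj_params()) {
  if (any(r <= 0)) stop("particle overlap: pair distance must be > 0")
  sr6 <- (params$sigma / r)^6
  inside <- r < params$cutoff
  energy <- ifelse(inside, 4 * params$epsilon * (sr6^2 - sr6) - params$ushift, 0)
  force <- ifelse(inside, 24 * params$epsilon * (2 * sr6^2 - sr6) / r, 0)
  list(energy = energy, force = force)
}

#' Construct the dynamical state of a constrained system
#'
#' The generalized coordinates of the dynamics are the Cartesian positions
#' and velocities of the asymmetric-unit particles only. Every symmetry mate
#' and lattice image is a ghost: a pure function of the asymmetric unit, the
#' group, the box, and the image offsets, re-derived before every force
#' evaluation and never independently integrated.
#'
#' @param positions n x D Cartesian positions of the asymmetric unit.
#' @param group a [load_group()] object.
#' @param box D x D box matrix.
#' @param velocities n x D Cartesian velocities (default zero).
#' @param mass per-particle masses (scalar recycled; default 1).
#' @param image_radius explicit-image radius `a` (default 2, i.e. `3^(2D)`
#'   images).
#' @param lj an [lj_params()] object.
#' @param wyckoff optional character vector length n of Wyckoff labels
#'   (NA = general position). Constrained particles are projected onto their
#'   site at construction.
#' @return object of class `symdyn_state`.
#' @export
system_state <- function(positions, group, box, velocities = NULL, mass = 1,
                         image_radius = 2, lj = lj_params(), wyckoff = NULL) {
  positions <- rbind(positions)
  dimnames(positions) <- NULL
  n <- nrow(positions)
  D <- group$D
  stopifnot(ncol(positions) == D)
  box <- check_box(box)
  dimnames(box) <- NULL
  if (is.null(velocities)) velocities <- matrix(0, n, D)
  velocities <- rbind(velocities)
  dimnames(velocities) <- NULL
  mass <- rep_len(mass, n)
  if (is.null(wyckoff)) wyckoff <- rep(NA_character_, n)
  st <- structure(list(
    pos = positions, vel = velocities, mass = mass,
    group = group, box = box,
    images = generate_images(image_radius, D),
    image_radius_min = image_radius,
    lj = lj, wyckoff = wyckoff,
    constraints = list(), cache = new.env(parent = emptyenv())
  ), class = "symdyn_state")
  st <- refresh_constraints(st)
  # snap constrained particles (and the normal part of their velocities)
  # onto their sites so sigma = 0 from step zero
  for (con in st$constraints) {
    i <- con$particle
    st$pos[i, ] <- constrain_position(st$pos[i, ], con)
    st$vel[i, ] <- project_velocity(st$vel[i, ], con)
  }
  st
}

#' @export
print.symdyn_state <- function(x, ...) {
  cat("<symdyn_state> n_asym=", nrow(x$pos), " group=", x$group$id,
      " N_cell=", sum(state_weights(x)), " V=", round(det(x$box), 4), "\n", sep = "")
  invisible(x)
}

# orbit multiplicity (ghost-op count) per asymmetric-unit particle
state_weights <- function(state) {
  vapply(seq_len(nrow(state$pos)), function(i) {
    lab <- state$wyckoff[i]
    if (is.na(lab)) state$group$order
    else state$group$wyckoff[[lab]]$multiplicity
  }, numeric(1))
}

state_ops <- function(state, i) {
  lab <- state$wyckoff[i]
  if (is.na(lab)) state$group$elements
  else state$group$wyckoff[[lab]]$subgroup
}

# wrapped fractional unit-cell expansion of the current state
# (orbit-major; attribute selfrow marks each particle's own root row)
state_cellfrac <- function(state) {
  n <- nrow(state$pos)
  D <- state$group$D
  frac <- wrap_frac(state$pos %*% state_binv(state))
  if (!any(!is.na(state$wyckoff))) {
    # all general positions: vectorize across particles, one pass per op
    k <- state$group$order
    if (k == 1L) {
      attr(frac, "selfrow") <- seq_len(n)
      attr(frac, "owner") <- seq_len(n)
      return(frac)
    }
    blocks <- lapply(state$group$elements, function(op) {
      wrap_frac(frac %*% t(op$W) + matrix(op$t, n, D, byrow = TRUE))
    })
    opstack <- do.call(rbind, blocks)
    # reorder op-major stacking into orbit-major (particle-major) rows
    src <- (rep(seq_len(k), times = n) - 1L) * n + rep(seq_len(n), each = k)
    out <- opstack[src, , drop = FALSE]
    attr(out, "selfrow") <- (seq_len(n) - 1L) * k + 1L
    attr(out, "owner") <- rep(seq_len(n), each = k)
    return(out)
  }
  rows <- vector("list", n)
  selfrow <- integer(n)
  owner <- integer(0)
  total <- 0L
  for (i in seq_len(n)) {
    ops <- state_ops(state, i)
    pts <- t(vapply(ops, function(g) wrap_frac(op_apply(g, frac[i, ])),
                    numeric(D)))
    rows[[i]] <- pts
    selfrow[i] <- total + 1L
    owner <- c(owner, rep(i, nrow(pts)))
    total <- total + nrow(pts)
  }
  out <- do.call(rbind, rows)
  attr(out, "selfrow") <- selfrow
  attr(out, "owner") <- owner
  out
}

# cached inverse of the current box (rebuilt on box change)
state_binv <- function(state) {
  cb <- state$cache$binv
  if (!is.null(cb) && identical(state$cache$binv_box, state$box)) return(cb)
  binv <- solve(state$box)
  state$cache$binv <- binv
  state$cache$binv_box <- state$box
  binv
}

#' All explicit particle positions (cell plus images)
#'
#' Deterministic ordering: orbit-major over asymmetric-unit particles, then
#' group operator, then image offset.
#'
#' @param state a [system_state()].
#' @return N_explicit x D matrix of Cartesian positions.
#' @export
ghost_positions <- function(state) {
  cf <- state_cellfrac(state)
  K <- nrow(state$images$offsets)
  M <- nrow(cf)
  idx <- rep(seq_len(M), each = K)
  off <- state$images$offsets[rep(seq_len(K), M), , drop = FALSE]
  frac_to_cart(cf[idx, , drop = FALSE] + off, state$box)
}

#' Unit-cell particle positions of a state
#' @param state a [system_state()].
#' @param cartesian return Cartesian (default) or fractional coordinates.
#' @export
cell_positions <- function(state, cartesian = TRUE) {
  cf <- state_cellfrac(state)
  sr <- attr(cf, "selfrow")
  out <- if (cartesian) frac_to_cart(cf, state$box) else cf
  attr(out, "selfrow") <- sr
  out
}

# single kernel call returning per-cell energy and asymmetric-unit forces
lj_eval <- function(state) {
  cf <- state_cellfrac(state)
  res <- lj_eval_kernel(state$pos, cf, attr(cf, "owner"),
                        state$images$offsets,
                        state$box, state_weights(state),
                        state$lj$epsilon, state$lj$sigma, state$lj$cutoff,
                        state$lj$ushift)
  if (res$overlap) stop("particle overlap (r ~ 0) during force evaluation")
  res
}

#' Potential energy of the unit cell
#'
#' Computed as the orbit-weighted asymmetric-unit sum (outer loop over the
#' asymmetric unit, inner loop over every explicit particle, prefactor the
#' orbit multiplicity) which, for a symmetric configuration with sufficient
#' explicit images, equals the brute-force sum over all unit-cell pairs plus
#' half of every cell-image interaction.
#'
#' @param state a [system_state()].
#' @export
total_energy <- function(state) lj_eval(state)$energy

#' Physical forces on the asymmetric-unit particles
#'
#' Force on particle k is the sum of pair forces exerted by every other
#' explicit particle (orbit mates, lattice images, and its own images). The
#' potential is group-invariant, so these forces are group-equivariant, and
#' `m q'' = F` is the equation of motion of the constrained dynamics.
#'
#' @param state a [system_state()].
#' @export
forces_asym <- function(state) lj_eval(state)$forces

# replace the working box; fractional coordinates are held fixed so the
# Cartesian positions rescale affinely. Constraint Jacobians depend on the
# box and are rebuilt.
set_box <- function(state, box) {
  frac <- cart_to_frac(state$pos, state$box)
  state$box <- check_box(box)
  state$pos <- frac_to_cart(frac, state$box)
  state <- refresh_constraints(state)
  for (con in state$constraints) {
    i <- con$particle
    state$pos[i, ] <- constrain_position(state$pos[i, ], con)
  }
  state
}
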