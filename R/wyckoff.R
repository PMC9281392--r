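#' Wyckoff-position holonomic constraints
#'
#' A particle assigned to a Wyckoff site must satisfy the holonomic
#' constraint \eqn{\sigma[q] = q - P q = 0}, where `P` is the site projector
#' acting in fractional coordinates and `q` is Cartesian (the residual is
#' mapped through the current box, so the constraint stays exact under
#' constant-pressure box changes). Because `sigma` is affine in `q`, the
#' Lagrange multiplier of the end-of-step correction solves a single linear
#' system exactly - no iteration.
#'
#' @name wyckoff_constraints
NULL

# Moore-Penrose pseudoinverse via SVD (the Gram matrix J J^T is rank
# deficient by construction: sigma has D components but only removed_dof
# independent ones).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 1)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Build the constraint object for one particle on one site
#'
#' Precomputes the affine residual map `sigma(q) = q M + c` (row convention,
#' `M = B^-1 (I - W_P^T) B`), its constant Jacobian, and the Gram
#' pseudoinverse used by the multiplier solve.
#'
#' @param particle_index index of the constrained asymmetric-unit particle.
#' @param site Wyckoff site definition (from `group$wyckoff`).
#' @param box current box matrix.
#' @return object of class `wyckoff_constraint`.
#' @export
wyckoff_constraint <- function(particle_index, site, box) {
  box <- check_box(box)
  D <- nrow(box)
  Binv <- solve(box)
  M <- Binv %*% (diag(D) - t(site$projector$W)) %*% box
  cc <- -as.numeric(rbind(site$projector$t) %*% box)
  A <- crossprod(M)           # J J^T in row convention
  Ainv <- pinv(A)
  rk <- qr(M)$rank
  if (rk != D - site$site_dof) {
    stop("malformed Wyckoff site '", site$label, "': Jacobian rank ", rk,
         " != ", D - site$site_dof)
  }
  structure(list(particle = particle_index, site = site, box = box,
                 Binv = Binv, M = M, c = cc, jacobian = t(M),
                 gram_pinv = Ainv, removed_dof = D - site$site_dof),
            class = "wyckoff_constraint")
}

refresh_constraints <- function(state) {
  cons <- list()
  for (i in seq_len(nrow(state$pos))) {
    lab <- state$wyckoff[i]
    if (!is.na(lab)) {
      site <- state$group$wyckoff[[lab]]
      if (is.null(site)) {
        stop("group '", state$group$id, "' has no Wyckoff site '", lab, "'")
      }
      cons[[length(cons) + 1L]] <- wyckoff_constraint(i, site, state$box)
    }
  }
  state$constraints <- cons
  state
}

#' Constraint residual
#'
#' Zero exactly when the particle sits on its Wyckoff site (or any of its
#' lattice translates: the fractional residual is wrapped to the nearest
#' integer, so the constraint is compatible with cell wrapping); locally
#' affine in `q`.
#'
#' @param q Cartesian D-vector.
#' @param constraint a [wyckoff_constraint()].
#' @export
sigma <- function(q, constraint) {
  P <- constraint$site$projector
  s <- as.numeric(rbind(q) %*% constraint$Binv)
  res <- as.numeric(rbind(s) %*% (diag(length(s)) - t(P$W))) - P$t
  res <- res - round(res)
  as.numeric(rbind(res) %*% constraint$box)
}

#' Force exerted by a constraint for a given multiplier
#'
#' `F = -J^T lambda`; lies in the row space of the Jacobian, i.e. normal to
#' the site.
#'
#' @param lambda multiplier D-vector.
#' @param constraint a [wyckoff_constraint()].
#' @export
constraint_force <- function(lambda, constraint) {
  -as.numeric(rbind(lambda) %*% t(constraint$M))
}

#' Solve for the Lagrange multiplier of an end-of-step correction
#'
#' Given the unconstrained end-of-step position `q'`, the multiplier is
#' chosen so that applying the constraint force over the step lands the
#' particle exactly back on the site: `sigma[q' + (dt^2/m) F_c] = 0`. With an
#' affine residual this is one linear solve in the (pseudo-inverted) Gram
#' matrix - exact in a single iteration.
#'
#' @param q_unconstrained unconstrained end-of-step Cartesian position.
#' @param constraint a [wyckoff_constraint()].
#' @param dt time step.
#' @param m particle mass.
#' @export
solve_lambda <- function(q_unconstrained, constraint, dt, m) {
  stopifnot(dt > 0, m > 0)
  s <- sigma(q_unconstrained, constraint)
  as.numeric((m / dt^2) * rbind(s) %*% constraint$gram_pinv)
}

# exact position correction (independent of dt and m, as it must be for an
# affine residual): q <- q' - sigma(q') pinv(M^T M) M^T
constrain_position <- function(q, constraint) {
  s <- sigma(q, constraint)
  q - as.numeric(rbind(s) %*% constraint$gram_pinv %*% t(constraint$M))
}

#' Remove the velocity component normal to a Wyckoff site
#'
#' After the position correction, the component of the velocity normal to
#' the site is discarded (projection onto the site tangent space) so that
#' constrained particles do not accumulate kinetic energy in the removed
#' directions.
#'
#' @param v Cartesian velocity D-vector.
#' @param constraint a [wyckoff_constraint()].
#' @export
project_velocity <- function(v, constraint) {
  s <- as.numeric(rbind(v) %*% constraint$M)
  v - as.numeric(rbind(s) %*% constraint$gram_pinv %*% t(constraint$M))
}

#' Total degrees of freedom removed by Wyckoff constraints
#'
#' Subtracted from `D * n` when converting kinetic energy to temperature.
#'
#' @param constraints list of [wyckoff_constraint()] objects (as stored on a
#'   state).
#' @export
removed_dof_total <- function(constraints) {
  if (!length(constraints)) return(0L)
  sum(vapply(constraints, function(cn) cn$removed_dof, numeric(1)))
}

# apply all constraint corrections of a state after a position update;
# the correction targets the NEAREST lattice copy of the site, which can sit
# on the far cell face (fractional coordinate exactly 1), so constrained
# particles are re-wrapped afterwards
apply_constraints_pos <- function(state) {
  for (con in state$constraints) {
    i <- con$particle
    qi <- constrain_position(state$pos[i, ], con)
    s <- wrap_frac(as.numeric(rbind(qi) %*% con$Binv))
    state$pos[i, ] <- as.numeric(rbind(s) %*% con$box)
  }
  state
}

apply_constraints_vel <- function(state) {
  for (con in state$constraints) {
    i <- con$particle
    state$vel[i, ] <- project_velocity(state$vel[i, ], con)
  }
  state
}
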