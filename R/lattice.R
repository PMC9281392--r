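#' Box-matrix algebra
#'
#' The simulation cell is a D x D matrix `B` whose row i holds the Cartesian
#' components of lattice vector i (row-vector convention: `x = s %*% B` for a
#' fractional row `s`). All boxes are required to be nonsingular with
#' `det(B) > 0` (right-handed).
#'
#' @name lattice
NULL

check_box <- function(box) {
  box <- as.matrix(box)
  if (nrow(box) != ncol(box)) stop("box matrix must be square")
  d <- det(box)
  if (!is.finite(d) || abs(d) < 1e-12) stop("box matrix is singular")
  if (d < 0) stop("box matrix must be right-handed (det > 0)")
  box
}

#' Convert fractional to Cartesian coordinates
#' @param s fractional row vector or n x D matrix.
#' @param box D x D box matrix (rows = lattice vectors).
#' @export
frac_to_cart <- function(s, box) {
  box <- check_box(box)
  vec <- is.null(dim(s))
  out <- rbind(s) %*% box
  if (vec) out[1, ] else out
}

#' Convert Cartesian to fractional coordinates
#' @param x Cartesian row vector or n x D matrix.
#' @inheritParams frac_to_cart
#' @export
cart_to_frac <- function(x, box) {
  box <- check_box(box)
  vec <- is.null(dim(x))
  out <- rbind(x) %*% solve(box)
  if (vec) out[1, ] else out
}

#' Wrap fractional coordinates into the unit cell
#'
#' Floor-based wrap to `[0, 1)`: negative coordinates map into the cell
#' (`-0.25 -> 0.75`), which keeps orbit set-comparisons canonical.
#' @param s fractional vector or matrix.
#' @export
wrap_frac <- function(s) s - floor(s)

bravais_classes <- list(
  `2` = c("oblique", "rectangular", "centered-rectangular", "square", "hexagonal"),
  `3` = c("triclinic", "monoclinic", "orthorhombic", "tetragonal", "trigonal",
          "hexagonal", "cubic")
)

#' Bravais-lattice projector
#'
#' Builds the map taking an arbitrary (triclinic/oblique) working box `B'` to
#' the nearest box consistent with the given Bravais class, e.g. any 3 x 3
#' matrix to `a * I` for the cubic class. Free parameters are extracted by
#' averaging the constrained-equal quantities (cubic `a` = mean of the three
#' vector lengths), which makes the map continuous and idempotent. Constant-
#' pressure box moves are proposed in the unconstrained box and pushed through
#' this projector, so the working cell always tiles under the group.
#'
#' @param bravais_class class name; see `symdyn_bravais_classes()`.
#' @param D dimension (2 or 3).
#' @return object of class `bravais_projector` with fields `bravais_class`,
#'   `D`, and `nfree` (number of free lattice parameters).
#' @export
make_projector <- function(bravais_class, D) {
  valid <- bravais_classes[[as.character(D)]]
  if (is.null(valid) || !(bravais_class %in% valid)) {
    stop("unknown Bravais class '", bravais_class, "' for D=", D,
         "; valid: ", paste(valid, collapse = ", "))
  }
  nfree <- switch(bravais_class,
    oblique = 4L, triclinic = 9L,
    rectangular = 2L, `centered-rectangular` = 2L,
    square = 1L, hexagonal = if (D == 2) 1L else 2L,
    monoclinic = 4L, orthorhombic = 3L,
    tetragonal = 2L, trigonal = 2L, cubic = 1L)
  structure(list(bravais_class = bravais_class, D = D, nfree = nfree),
            class = "bravais_projector")
}

#' List the supported Bravais classes
#' @param D dimension.
#' @export
symdyn_bravais_classes <- function(D) bravais_classes[[as.character(D)]]

rowlen <- function(B) sqrt(rowSums(B^2))

#' Project a working box onto its Bravais class
#'
#' @param proj a [make_projector()] object.
#' @param B D x D working (triclinic) box matrix.
#' @return a Bravais-consistent box matrix of the same volume scale.
#' @export
apply_projector <- function(proj, B) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == proj$D)
  l <- rowlen(B)
  cls <- proj$bravais_class
  D <- proj$D
  if (cls %in% c("oblique", "triclinic")) return(B)
  if (cls %in% c("rectangular", "centered-rectangular", "orthorhombic")) {
    return(diag(l, D))
  }
  if (cls == "square") {
    a <- mean(l)
    return(diag(a, 2))
  }
  if (cls == "cubic") {
    a <- mean(l)
    return(diag(a, 3))
  }
  if (cls == "hexagonal" && D == 2) {
    a <- mean(l)
    return(matrix(c(a, 0, -a / 2, a * sqrt(3) / 2), 2, 2, byrow = TRUE))
  }
  if (cls %in% c("hexagonal", "trigonal") && D == 3) {
    a <- mean(l[1:2])
    return(matrix(c(a, 0, 0, -a / 2, a * sqrt(3) / 2, 0, 0, 0, l[3]),
                  3, 3, byrow = TRUE))
  }
  if (cls == "tetragonal") {
    a <- mean(l[1:2])
    return(diag(c(a, a, l[3])))
  }
  if (cls == "monoclinic") {
    # unique axis b: beta angle between vectors 1 and 3 is retained
    cb <- sum(B[1, ] * B[3, ]) / (l[1] * l[3])
    cb <- max(min(cb, 1), -1)
    sb <- sqrt(1 - cb^2)
    return(matrix(c(l[1], 0, 0, 0, l[2], 0, l[3] * cb, 0, l[3] * sb),
                  3, 3, byrow = TRUE))
  }
  stop("unhandled Bravais class: ", cls)
}

#' Explicit lattice-image offsets
#'
#' With image radius `a` every dimension carries `3^a` cells (offsets
#' `-(3^a - 1)/2 ... +(3^a - 1)/2`), for `3^(a*D)` images in total; radius 1
#' in 3D is the root cell plus its 26 neighbours. Enough images let the cell
#' shrink to `1/a`-ish of the interaction cutoff while every neighbour within
#' the cutoff stays explicit.
#'
#' @param radius integer image radius `a >= 1`.
#' @param D dimension.
#' @return object of class `image_offsets`: fields `offsets` (matrix
#'   `3^(a*D)` x D of integers), `radius`, `zero_row` (row index of the zero
#'   offset).
#' @export
generate_images <- function(radius, D) {
  if (radius < 1) stop("image radius must be >= 1")
  span <- (3^radius - 1) / 2
  vals <- seq(-span, span)
  grid <- as.matrix(expand.grid(rep(list(vals), D)))
  dimnames(grid) <- NULL
  zero_row <- which(rowSums(abs(grid)) == 0)
  stopifnot(length(zero_row) == 1)
  structure(list(offsets = grid, radius = radius, zero_row = zero_row),
            class = "image_offsets")
}

#' Construct an initial Bravais-consistent box from a density
#'
#' @param proj projector (Bravais class) of the group.
#' @param n_cell number of particles in the full unit cell.
#' @param density target number density (particles per volume).
#' @export
box_from_density <- function(proj, n_cell, density) {
  stopifnot(density > 0, n_cell >= 1)
  B0 <- apply_projector(proj, diag(proj$D))
  V <- n_cell / density
  B0 * (V / det(B0))^(1 / proj$D)
}
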