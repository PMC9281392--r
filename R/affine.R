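#' Affine operators on fractional coordinates
#'
#' A group element of a space or wallpaper group acts on fractional
#' coordinates as an affine map \eqn{s' = W s + t}: a dimensionless linear
#' part `W` (a D x D integer-like matrix in the crystallographic settings
#' used here) and a fractional translation `t` with components in `[0, 1)`.
#' Positions are stored as row vectors throughout the package, so the map is
#' applied as `s %*% t(W) + t`.
#'
#' @param W D x D linear part (column-action convention).
#' @param t length-D fractional translation.
#' @return An object of class `affine_op`.
#' @export
affine_op <- function(W, t = rep(0, nrow(W))) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W), length(t) == nrow(W))
  structure(list(W = W, t = as.numeric(t)), class = "affine_op")
}

#' @export
print.affine_op <- function(x, ...) {
  cat("<affine_op>", op_to_string(x), "\n")
  invisible(x)
}

#' Identity operator in D dimensions
#' @param D dimension (2 or 3).
#' @export
op_identity <- function(D) affine_op(diag(D), rep(0, D))

#' Apply an affine operator to fractional positions
#'
#' @param op an `affine_op`.
#' @param s numeric vector (one point) or n x D matrix of fractional rows.
#' @param wrap wrap the result into `[0,1)` componentwise (floor-based).
#' @return object of the same shape as `s`.
#' @export
op_apply <- function(op, s, wrap = FALSE) {
  vec <- is.null(dim(s))
  s <- rbind(s)
  out <- s %*% t(op$W) + matrix(op$t, nrow(s), length(op$t), byrow = TRUE)
  if (wrap) out <- wrap_frac(out)
  if (vec) out[1, ] else out
}

#' Compose two affine operators
#'
#' `op_compose(a, b)` is the operator "apply `b` first, then `a`", with the
#' translation wrapped back into the cell so the result is again a canonical
#' group-element representative.
#'
#' @param a,b `affine_op` objects.
#' @param wrap wrap the composite translation to `[0,1)`.
#' @export
op_compose <- function(a, b, wrap = TRUE) {
  W <- a$W %*% b$W
  t <- as.numeric(a$W %*% b$t) + a$t
  if (wrap) t <- t - floor(t)
  affine_op(W, t)
}

#' Test two operators for equality modulo lattice translations
#' @param a,b `affine_op` objects.
#' @param tol numeric tolerance.
#' @export
op_equal <- function(a, b, tol = 1e-9) {
  if (max(abs(a$W - b$W)) > tol) return(FALSE)
  dt <- a$t - b$t
  max(abs(dt - round(dt))) < tol
}

op_is_identity <- function(op, tol = 1e-9) op_equal(op, op_identity(length(op$t)), tol)

#' Parse a crystallographic coordinate-triplet string
#'
#' Accepts the standard table notation, e.g. `"-y, x-y"` or
#' `"-x+1/2, y+1/2, -z"`, and returns the corresponding [affine_op()].
#' Coefficients are recovered exactly by probing the (affine) expression at
#' the origin and the unit vectors.
#'
#' @param str coordinate triplet, components separated by commas.
#' @param dimension 2 or 3; defaults to the number of components.
#' @export
parse_xyz_op <- function(str, dimension = NULL) {
  parts <- strsplit(str, ",", fixed = TRUE)[[1]]
  D <- if (is.null(dimension)) length(parts) else dimension
  if (length(parts) != D) {
    stop("operator '", str, "' has ", length(parts), " components, expected ", D)
  }
  vars <- c("x", "y", "z")[seq_len(D)]
  exprs <- lapply(parts, function(p) parse(text = p)[[1]])
  evalat <- function(pt) {
    env <- as.list(pt)
    names(env) <- vars
    vapply(exprs, function(e) eval(e, env), numeric(1))
  }
  t0 <- evalat(rep(0, D))
  W <- matrix(0, D, D)
  for (j in seq_len(D)) {
    ej <- rep(0, D)
    ej[j] <- 1
    W[, j] <- evalat(ej) - t0
  }
  affine_op(W, t0 - floor(t0))
}

op_to_string <- function(op) {
  D <- length(op$t)
  vars <- c("x", "y", "z")[seq_len(D)]
  comp <- character(D)
  for (i in seq_len(D)) {
    terms <- character(0)
    for (j in seq_len(D)) {
      w <- op$W[i, j]
      if (abs(w) > 1e-12) {
        terms <- c(terms, paste0(if (w < 0) "-" else if (length(terms)) "+" else "",
                                 if (abs(abs(w) - 1) > 1e-12) paste0(abs(w), "*") else "",
                                 vars[j]))
      }
    }
    tt <- op$t[i]
    if (abs(tt) > 1e-12) {
      terms <- c(terms, paste0(if (length(terms)) "+" else "", format(tt)))
    }
    comp[i] <- if (length(terms)) paste(terms, collapse = "") else "0"
  }
  paste(comp, collapse = ", ")
}

#' Generate the closure of a set of operators
#'
#' Repeatedly composes the supplied generators (plus the identity) and wraps
#' translations until no new element appears. Used to build the full element
#' list of a group from its tabulated generators.
#'
#' @param gens list of `affine_op` generators.
#' @param D dimension.
#' @param cap safety cap on the group order.
#' @return list of `affine_op`, identity first.
#' @export
op_closure <- function(gens, D, cap = 256) {
  elems <- list(op_identity(D))
  queue <- gens
  while (length(queue)) {
    g <- queue[[1]]
    queue <- queue[-1]
    if (any(vapply(elems, op_equal, logical(1), b = g))) next
    elems <- c(elems, list(g))
    # compose with everything known, both orders
    for (h in elems) {
      for (cand in list(op_compose(g, h), op_compose(h, g))) {
        if (!any(vapply(elems, op_equal, logical(1), b = cand))) {
          queue <- c(queue, list(cand))
        }
      }
    }
    if (length(elems) > cap) stop("group closure exceeded cap (", cap, "); bad generators?")
  }
  elems
}
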