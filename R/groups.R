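#' Load a bundled symmetry group
#'
#' Operator tables for all 17 wallpaper groups and a small set of 3D space
#' groups (1, 2, 127) ship with the package as plain-text fixture files:
#' dimension, Bravais class, generator triplets, tabulated general-position
#' multiplicity, and Wyckoff-site coordinate expressions. The full element
#' list is generated at load time as the closure of the generators and
#' validated against the tabulated multiplicity.
#'
#' @param identifier wallpaper-group name (e.g. `"p6m"`) or space-group
#'   number (e.g. `127`).
#' @param dimension 2 or 3; used to disambiguate and validate.
#' @return An object of class `symdyn_group` with fields `id`, `D`,
#'   `elements` (list of [affine_op()], identity first), `bravais_class`,
#'   `order`, and `wyckoff` (named list of site definitions).
#' @export
load_group <- function(identifier, dimension = NULL) {
  dir <- system.file("extdata", "groups", package = "symdyn")
  id <- as.character(identifier)
  fname <- if (grepl("^[0-9]+$", id)) paste0("sg", id, ".yaml") else paste0(id, ".yaml")
  path <- file.path(dir, fname)
  if (!file.exists(path)) {
    avail <- sub("^sg", "", sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
    stop("group '", id, "' is not bundled; available groups: ",
         paste(sort(avail), collapse = ", "))
  }
  raw <- yaml::read_yaml(path)
  D <- raw$dimension
  if (!is.null(dimension) && dimension != D) {
    stop("group '", id, "' is ", D, "-dimensional, not ", dimension)
  }
  gens <- lapply(raw$generators, parse_xyz_op, dimension = D)
  for (g in gens) {
    if (abs(abs(det(g$W)) - 1) > 1e-9) {
      stop("generator of '", id, "' has |det| != 1")
    }
  }
  elements <- op_closure(gens, D)
  if (length(elements) != raw$multiplicity) {
    stop("closure of '", id, "' has ", length(elements),
         " elements; tabulated multiplicity is ", raw$multiplicity)
  }
  grp <- structure(list(
    id = raw$name, D = D, elements = elements,
    bravais_class = raw$bravais, order = length(elements),
    wyckoff = list()
  ), class = "symdyn_group")
  sites <- list()
  for (w in raw$wyckoff) {
    sites[[w$label]] <- build_wyckoff_site(w$label, w$site, grp)
  }
  grp$wyckoff <- sites
  grp
}

#' @export
print.symdyn_group <- function(x, ...) {
  cat("<symdyn_group> ", x$id, " (D=", x$D, ", |G|=", x$order,
      ", ", x$bravais_class, ")\n", sep = "")
  if (length(x$wyckoff)) {
    cat("  Wyckoff sites:",
        paste(vapply(x$wyckoff, function(w)
          sprintf("%s[mult %d, dof %d]", w$label, w$multiplicity, w$site_dof),
          character(1)), collapse = ", "), "\n")
  }
  invisible(x)
}

# A Wyckoff site is stored as its projector P (the affine map sending a
# general position onto the site; idempotent), the number of free parameters
# on the site, and the coset operators that generate the site's (reduced)
# orbit. The coset representatives are found by applying every group element
# to a generic point of the site and keeping the first operator producing
# each distinct image.
build_wyckoff_site <- function(label, site_str, group) {
  P <- parse_xyz_op(site_str, dimension = group$D)
  if (!op_equal(op_compose(P, P, wrap = FALSE), P)) {
    stop("Wyckoff site '", label, "' projector is not idempotent: ", site_str)
  }
  site_dof <- qr(P$W)$rank
  # generic point on the site (irrational-ish parameters avoid accidents)
  s0 <- wrap_frac(op_apply(P, c(0.337754, 0.571231, 0.718281)[seq_len(group$D)]))
  imgs <- list()
  reps <- integer(0)
  stab <- 0L
  for (j in seq_along(group$elements)) {
    sj <- wrap_frac(op_apply(group$elements[[j]], s0))
    if (frac_dist(sj, s0) < 1e-8) stab <- stab + 1L
    new <- TRUE
    for (im in imgs) if (frac_dist(sj, im) < 1e-8) { new <- FALSE; break }
    if (new) {
      imgs <- c(imgs, list(sj))
      reps <- c(reps, j)
    }
  }
  if (stab < 2L) {
    stop("Wyckoff site '", label, "' (", site_str, ") has a trivial stabilizer; ",
         "it is a general position")
  }
  coset_ops <- lapply(group$elements[reps], function(g) op_compose(g, P))
  list(label = label, projector = P, site_dof = site_dof,
       removed_dof = group$D - site_dof,
       multiplicity = length(reps), stabilizer_order = stab,
       subgroup = coset_ops)
}

# minimal periodic distance between two wrapped fractional points
frac_dist <- function(a, b) {
  d <- a - b
  d <- d - round(d)
  sqrt(sum(d^2))
}

#' Group orbit of a fractional point
#'
#' Applies every group element to `q` and wraps into the cell. For a general
#' position the orbit has `|G|` entries (entry 1 is `q` itself); points on
#' special Wyckoff positions yield repeated entries.
#'
#' @param q fractional D-vector in `[0,1)`.
#' @param group a [load_group()] object.
#' @return `|G|` x D matrix of wrapped fractional positions.
#' @export
orbit <- function(q, group) {
  t(vapply(group$elements, function(g) wrap_frac(op_apply(g, q)),
           numeric(group$D)))
}

# operators generating the (possibly reduced) orbit of particle i
particle_ops <- function(group, site = NULL) {
  if (is.null(site)) group$elements else site$subgroup
}

#' Expand asymmetric-unit positions to the full unit cell
#'
#' Concatenates the group orbit of every asymmetric-unit particle (orbit-major
#' ordering, asymmetric-unit representative first within each orbit). A
#' particle sitting on a special position must be declared via
#' `wyckoff_sites`; otherwise the expansion would create coincident copies and
#' an error is raised directing the caller to the Wyckoff machinery.
#'
#' @param asym_pos n x D matrix of fractional positions.
#' @param group a `symdyn_group`.
#' @param wyckoff_sites optional character vector length n: Wyckoff label per
#'   particle (NA = general position).
#' @return N x D matrix of fractional unit-cell positions with attributes
#'   `owner` (asymmetric-unit index) and `op` (operator index within the
#'   particle's orbit).
#' @export
expand_unit_cell <- function(asym_pos, group, wyckoff_sites = NULL) {
  asym_pos <- rbind(asym_pos)
  n <- nrow(asym_pos)
  if (is.null(wyckoff_sites)) wyckoff_sites <- rep(NA_character_, n)
  out <- NULL
  owner <- integer(0)
  opidx <- integer(0)
  for (i in seq_len(n)) {
    s <- wrap_frac(asym_pos[i, ])
    lab <- wyckoff_sites[i]
    if (is.na(lab)) {
      # Eq-2-style check: a general position may not be fixed by any
      # non-identity element
      for (j in seq_along(group$elements)[-1]) {
        if (frac_dist(wrap_frac(op_apply(group$elements[[j]], s)), s) < 1e-6) {
          stop("particle ", i, " at a special position is fixed by a ",
               "non-identity group element; declare a Wyckoff site for it")
        }
      }
      ops <- group$elements
    } else {
      site <- group$wyckoff[[lab]]
      if (is.null(site)) {
        stop("group '", group$id, "' has no bundled Wyckoff site '", lab,
             "'; available: ", paste(names(group$wyckoff), collapse = ", "))
      }
      ops <- site$subgroup
    }
    pts <- t(vapply(ops, function(g) wrap_frac(op_apply(g, s)), numeric(group$D)))
    out <- rbind(out, pts)
    owner <- c(owner, rep(i, nrow(pts)))
    opidx <- c(opidx, seq_len(nrow(pts)))
  }
  attr(out, "owner") <- owner
  attr(out, "op") <- opidx
  out
}

#' Test whether a fractional point lies in the asymmetric unit
#'
#' The fundamental domain used throughout the package is the canonical-
#' representative domain: a wrapped point belongs to the asymmetric unit iff
#' it is the lexicographically smallest member of its own orbit. This is a
#' valid fundamental domain for every bundled group by construction.
#'
#' @param s fractional D-vector.
#' @param group a `symdyn_group`.
#' @param tol comparison tolerance.
#' @export
in_asym_unit <- function(s, group, tol = 1e-9) {
  s <- wrap_frac(s)
  all(apply(orbit(s, group), 1, function(o) lex_leq(s, o, tol)))
}

lex_leq <- function(a, b, tol = 1e-9) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - tol) return(TRUE)
    if (a[k] > b[k] + tol) return(FALSE)
  }
  TRUE
}

canonical_rep <- function(s, group) {
  ob <- orbit(s, group)
  best <- ob[1, ]
  for (r in seq_len(nrow(ob))[-1]) {
    if (!lex_leq(best, ob[r, ])) best <- ob[r, ]
  }
  best
}

#' Sample starting positions inside the asymmetric unit
#'
#' Uniform points in the cell are mapped to their canonical orbit
#' representative (uniform on the fundamental domain) and accepted only if,
#' after expansion to the full cell plus one shell of lattice images, every
#' Cartesian pair distance exceeds `min_sep` (Lennard-Jones forces diverge
#' for overlapping starts).
#'
#' @param group a `symdyn_group`.
#' @param n number of asymmetric-unit particles.
#' @param box box matrix used for the Cartesian separation check; `NULL`
#'   skips the check.
#' @param min_sep minimum Cartesian pair separation (reduced length); the
#'   default 1.0 sigma keeps every initial pair energy at or below zero, so
#'   starts are consistent with the thermal scale of the run.
#' @param seed optional integer seed (`set.seed`) for reproducibility.
#' @param max_attempts rejection-sampling cap before failing.
#' @return n x D matrix of fractional positions in the asymmetric unit.
#' @export
sample_asymmetric_unit <- function(group, n, box = NULL, min_sep = 1.0,
                                   seed = NULL, max_attempts = 20000L) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  imgs <- if (!is.null(box)) generate_images(1, group$D)
  pts <- matrix(NA_real_, 0, group$D)
  attempts <- 0L
  while (nrow(pts) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("rejection sampling failed after ", max_attempts,
           " attempts; lower n or the density")
    }
    cand <- canonical_rep(stats::runif(group$D), group)
    trial <- rbind(pts, cand)
    if (!is.null(box)) {
      cell <- expand_unit_cell(trial, group)
      cart <- frac_to_cart(cell, box)
      if (min_pair_sep(cart, box, imgs) < min_sep) next
    }
    pts <- trial
  }
  dimnames(pts) <- NULL
  pts
}

# smallest pair distance among cell particles and their first image shell
min_pair_sep <- function(cart, box, imgs) {
  shifts <- imgs$offsets %*% box
  m <- Inf
  for (k in seq_len(nrow(shifts))) {
    pos <- cart + matrix(shifts[k, ], nrow(cart), ncol(cart), byrow = TRUE)
    d2 <- cross_dist2(cart, pos)
    if (k == imgs$zero_row) diag(d2) <- Inf
    m <- min(m, sqrt(min(d2)))
  }
  m
}

cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  outer(an, bn, "+") - 2 * tcrossprod(a, b)
}

#' Project a point onto a Wyckoff site
#'
#' Applies the site's projector (the identity element of the site subgroup),
#' e.g. the map `x' = 0, y' = y` for the line `x = 0`. Idempotent.
#'
#' @param q fractional D-vector.
#' @param site a Wyckoff site definition from a group's `wyckoff` list.
#' @export
project_to_wyckoff <- function(q, site) {
  op_apply(site$projector, q)
}
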