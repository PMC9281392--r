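# Shared fixtures and independent oracles for the test suite.

planar_groups <- c("p1", "p2", "pm", "pg", "cm", "pmm", "pmg", "pgg", "cmm",
                   "p4", "p4m", "p4g", "p3", "p3m1", "p31m", "p6", "p6m")

# tabulated general-position multiplicities (standard crystallographic
# tables; independent of the fixture files' `multiplicity` field usage)
planar_orders <- c(p1 = 1L, p2 = 2L, pm = 2L, pg = 2L, cm = 4L, pmm = 4L,
                   pmg = 4L, pgg = 4L, cmm = 8L, p4 = 4L, p4m = 8L, p4g = 8L,
                   p3 = 3L, p3m1 = 6L, p31m = 6L, p6 = 6L, p6m = 12L)

# Independent brute-force oracle for the per-cell potential, written in
# plain R against the raw pair formula: all unordered cell pairs plus half
# of every cell<->image interaction.
brute_cell_energy <- function(cellfrac, box, images, lj = lj_params()) {
  cart <- cellfrac %*% box
  M <- nrow(cart)
  K <- nrow(images$offsets)
  shifts <- images$offsets %*% box
  u <- function(r) {
    inside <- r < lj$cutoff
    ifelse(inside,
           4 * lj$epsilon * ((lj$sigma / r)^12 - (lj$sigma / r)^6) - lj$ushift,
           0)
  }
  e <- 0
  for (i in seq_len(M)) for (j in seq_len(M)) {
    xj <- matrix(cart[j, ], K, ncol(cart), byrow = TRUE) + shifts
    r <- sqrt(rowSums((matrix(cart[i, ], K, ncol(cart), byrow = TRUE) - xj)^2))
    if (i == j) r[images$zero_row] <- Inf
    e <- e + 0.5 * sum(u(r))
  }
  e
}

# deterministic triangular lattice in a hexagonal cell, m x m sites
triangular_config <- function(m = 4, spacing = 1.1) {
  a <- m * spacing
  box <- matrix(c(a, 0, -a / 2, a * sqrt(3) / 2), 2, 2, byrow = TRUE)
  grid <- as.matrix(expand.grid((seq_len(m) - 1) / m, (seq_len(m) - 1) / m))
  list(pos = grid %*% box, box = box, frac = grid)
}

square_config <- function(m = 4, spacing = 1.0) {
  a <- m * spacing
  box <- diag(2) * a
  grid <- as.matrix(expand.grid((seq_len(m) - 1) / m, (seq_len(m) - 1) / m))
  list(pos = grid %*% box, box = box, frac = grid)
}

# set distance between two point sets in wrapped fractional coordinates
frac_set_distance <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  d <- vapply(seq_len(nrow(A)), function(i) {
    min(vapply(seq_len(nrow(B)), function(j) {
      dd <- A[i, ] - B[j, ]
      sqrt(sum((dd - round(dd))^2))
    }, numeric(1)))
  }, numeric(1))
  max(d)
}
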