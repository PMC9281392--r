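test_that("bare pair potential hits its closed-form landmarks", {
  lj <- lj_params(shift = FALSE)
  at_min <- lj_pair(2^(1 / 6), lj)
  expect_equal(at_min$energy, -1, tolerance = 1e-12)
  expect_equal(at_min$force, 0, tolerance = 1e-12)
  expect_equal(lj_pair(1, lj)$energy, 0, tolerance = 1e-12)
  beyond <- lj_pair(3.6, lj)
  expect_identical(c(beyond$energy, beyond$force), c(0, 0))
  expect_error(lj_pair(0, lj), "overlap")
})

test_that("cut-and-shift only offsets the energy inside the cutoff", {
  lj_s <- lj_params(shift = TRUE)
  lj_b <- lj_params(shift = FALSE)
  r <- c(0.95, 1.2, 2.0, 3.4)
  es <- lj_pair(r, lj_s)
  eb <- lj_pair(r, lj_b)
  expect_equal(es$force, eb$force)                       # identical dynamics
  expect_equal(es$energy - eb$energy, rep(-lj_s$ushift, 4))
  # continuity at the cutoff: the residual is the slope u'(r_c) times the gap
  expect_lt(abs(lj_pair(3.5 - 1e-5, lj_s)$energy), 1e-7)
  expect_gt(abs(lj_pair(3.5 - 1e-5, lj_b)$energy), 1e-3)   # bare form jumps
})

test_that("ghost expansion enumerates orbit mates and lattice images", {
  p1 <- load_group("p1")
  st <- system_state(rbind(c(1, 1), c(3, 2)), p1, diag(2) * 5, image_radius = 1)
  expect_identical(nrow(ghost_positions(st)), 2L * 9L)
  p2 <- load_group("p2")
  st2 <- system_state(frac_to_cart(c(0.25, 0.25), diag(2) * 4), p2,
                      diag(2) * 4, image_radius = 1)
  cellc <- cell_positions(st2, cartesian = FALSE)
  expect_equal(cellc[2, ], c(0.75, 0.75))
  g127 <- load_group(127)
  pos <- sample_asymmetric_unit(g127, 5, seed = 2)
  st3 <- system_state(frac_to_cart(pos, diag(3) * 8), g127, diag(3) * 8,
                      image_radius = 1)
  expect_identical(nrow(cell_positions(st3)), 80L)
})

test_that("orbit-weighted energy equals the brute-force cell sum", {
  for (nm in c("p1", "p2", "cmm", "p4g", "p6m")) {
    g <- load_group(nm)
    for (seed in 1:3) {
      st <- build_start(g, 2, density = 0.3, T0 = 0.5, seed = seed,
                        image_radius = 1)
      ref <- brute_cell_energy(symdyn:::state_cellfrac(st), st$box,
                               st$images, st$lj)
      expect_equal(total_energy(st), ref, tolerance = 1e-12, label = nm)
    }
  }
  # zero interaction strength means zero energy
  g <- load_group("p2")
  st0 <- build_start(g, 2, density = 0.3, T0 = 0.5, seed = 1,
                     lj = lj_params(epsilon = 0))
  expect_identical(total_energy(st0), 0)
})

test_that("forces are minus the constrained energy gradient over |G|", {
  for (nm in c("p2", "p4")) {
    g <- load_group(nm)
    st <- build_start(g, 3, density = 0.25, T0 = 0.5, seed = 3)
    f <- forces_asym(st)
    h <- 1e-6
    for (i in 1:3) for (d in 1:2) {
      sp <- st; sp$pos[i, d] <- sp$pos[i, d] + h
      sm <- st; sm$pos[i, d] <- sm$pos[i, d] - h
      grad <- (total_energy(sp) - total_energy(sm)) / (2 * h)
      expect_equal(f[i, d], -grad / g$order, tolerance = 1e-6,
                   label = sprintf("%s particle %d dim %d", nm, i, d))
    }
  }
})

test_that("forces are equivariant under every group element", {
  for (nm in c("p2", "p4", "p3")) {
    g <- load_group(nm)
    st <- build_start(g, 2, density = 0.3, T0 = 0.5, seed = 6)
    f <- forces_asym(st)
    Binv <- solve(st$box)
    frac <- st$pos %*% Binv
    for (el in g$elements) {
      A <- Binv %*% t(el$W) %*% st$box       # Cartesian action of el
      moved <- wrap_frac(frac %*% t(el$W) +
                         matrix(el$t, 2, 2, byrow = TRUE)) %*% st$box
      st2 <- st
      st2$pos <- moved
      f2 <- forces_asym(st2)
      expect_lt(max(abs(f2 - f %*% A)), 1e-10)
    }
  }
})

test_that("the cell energy is invariant under any group element", {
  g <- load_group("p6")
  st <- build_start(g, 2, density = 0.3, T0 = 0.5, seed = 2)
  e0 <- total_energy(st)
  Binv <- solve(st$box)
  frac <- st$pos %*% Binv
  for (el in g$elements) {
    st2 <- st
    st2$pos <- wrap_frac(frac %*% t(el$W) +
                         matrix(el$t, 2, 2, byrow = TRUE)) %*% st$box
    expect_equal(total_energy(st2), e0, tolerance = 1e-10)
  }
})

test_that("an isolated particle feels no force", {
  p1 <- load_group("p1")
  st <- system_state(rbind(c(5, 5)), p1, diag(2) * 10, image_radius = 2)
  expect_equal(forces_asym(st), matrix(0, 1, 2))
  expect_identical(total_energy(st), 0)
})
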