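# Constraint fixtures: pm site a is the mirror line x = 0, p4m site a is the
# origin (a fixed point), p4m site d is the diagonal x = y.

make_con <- function(group, label, box, particle = 1L) {
  g <- load_group(group)
  wyckoff_constraint(particle, g$wyckoff[[label]], box)
}

test_that("the residual is zero exactly on the site and affine off it", {
  con <- make_con("pm", "a", diag(2))      # line x = 0
  expect_equal(sigma(c(0.3, 0.7), con), c(0.3, 0))
  expect_equal(sigma(c(0.0, 0.42), con), c(0, 0))
  q <- c(0.3, 0.7)
  proj <- symdyn:::constrain_position(q, con)
  expect_equal(sigma(proj, con), c(0, 0), tolerance = 1e-14)
  # lattice-periodic: the nearest site copy also has zero residual
  expect_equal(sigma(c(1.0, 0.2), con), c(0, 0), tolerance = 1e-14)
})

test_that("constraint force is -J^T lambda, in the row space of J", {
  con <- make_con("pm", "a", diag(2))
  expect_equal(constraint_force(c(0, 0), con), c(0, 0))
  expect_equal(constraint_force(c(2, 0), con), c(-2, 0))
  # force must be normal to the site (x-direction for the line x = 0)
  f <- constraint_force(c(1.3, 0.4), con)
  expect_equal(f[2], 0)
})

test_that("the multiplier solve lands the particle on the site in one step", {
  con <- make_con("pm", "a", diag(2))
  dt <- 0.005; m <- 1
  lam <- solve_lambda(c(0.3, 0.7), con, dt, m)
  expect_equal(lam[1], (m / dt^2) * 0.3, tolerance = 1e-12)
  # stepping with the constraint force reproduces the correction
  qc <- c(0.3, 0.7) + (dt^2 / m) * constraint_force(lam, con)
  expect_equal(sigma(qc, con), c(0, 0), tolerance = 1e-10)
  expect_equal(qc, c(0, 0.7), tolerance = 1e-12)
  # sigma already zero -> lambda = 0
  expect_equal(solve_lambda(c(0, 0.1), con, dt, m), c(0, 0))
})

test_that("corrections are exact for every bundled site, including sheared boxes", {
  set.seed(13)
  B <- matrix(c(2.1, 0.3, -0.4, 1.8), 2, 2, byrow = TRUE)
  for (nm in c("pm", "pmm", "p4m", "p4g", "p3m1", "p6m")) {
    g <- load_group(nm)
    for (w in g$wyckoff) {
      con <- wyckoff_constraint(1L, w, B)
      for (k in 1:20) {
        q <- runif(2, -1, 2) %*% B
        qc <- symdyn:::constrain_position(as.numeric(q), con)
        expect_lt(max(abs(sigma(qc, con))), 1e-12)
        # velocity projection removes the normal component entirely
        v <- rnorm(2)
        vt <- project_velocity(v, con)
        expect_lt(max(abs(as.numeric(rbind(vt) %*% con$M))), 1e-12)
        # constraint force does no work along the tangent space
        lam <- rnorm(2)
        f <- constraint_force(lam, con)
        expect_lt(abs(sum(f * vt)), 1e-12 * max(1, sqrt(sum(f^2))))
      }
    }
  }
})

test_that("removed degrees of freedom follow D minus the site dimension", {
  g <- load_group("p4m")
  line <- wyckoff_constraint(1L, g$wyckoff$e, diag(2))
  point <- wyckoff_constraint(2L, g$wyckoff$a, diag(2))
  expect_identical(line$removed_dof, 1L)
  expect_identical(point$removed_dof, 2L)
  expect_equal(removed_dof_total(list(line, point)), 3)
  expect_identical(removed_dof_total(list()), 0L)
  # D*n convention with no constraints
  st <- build_start(load_group("p2"), 5, density = 0.2, T0 = 0.5, seed = 1)
  expect_equal(symdyn:::state_dof(st), 10)
})

test_that("constraints hold to machine precision through dynamics and box changes", {
  g <- load_group("p4m")
  st <- build_start(g, 3, density = 0.15, T0 = 0.3,
                    wyckoff = c(NA, "e", "a"), seed = 4)
  p <- thermo_params(temperature = 0.3)
  set.seed(9)
  worst <- 0
  for (k in 1:200) {
    st <- step_baoab(st, p)
    for (con in st$constraints) {
      worst <- max(worst, max(abs(sigma(st$pos[con$particle, ], con))))
    }
  }
  expect_lt(worst, 1e-10)
  # an NPT-style box rescale keeps the particle on the (fractional) site
  st2 <- symdyn:::set_box(st, st$box * 1.07)
  for (con in st2$constraints) {
    expect_lt(max(abs(sigma(st2$pos[con$particle, ], con))), 1e-12)
  }
})

test_that("NVE conservation is preserved with active constraints", {
  g <- load_group("p4m")
  st <- build_start(g, 3, density = 0.15, T0 = 0.3,
                    wyckoff = c(NA, "e", "a"), seed = 4)
  out <- run_md(st, 1500, thermo_params(), integrator = "nve", log_every = 10)
  expect_identical(out$status, "ok")
  tr <- out$trace
  scale <- max(abs(tr$total[1]), tr$kinetic[1])
  fit <- stats::lm(total ~ step, data = tr)
  expect_lt(abs(stats::coef(fit)[["step"]]) * 1500 / scale, 1e-3)
})
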