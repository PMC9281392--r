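test_that("coordinate-triplet parsing recovers exact affine operators", {
  op <- parse_xyz_op("-y, x-y")
  expect_equal(op$W, matrix(c(0, -1, 1, -1), 2, 2, byrow = TRUE))
  expect_equal(op$t, c(0, 0))
  op <- parse_xyz_op("-x+1/2, y+1/2, -z")
  expect_equal(op$W, diag(c(-1, 1, -1)))
  expect_equal(op$t, c(0.5, 0.5, 0))
})

test_that("every bundled group closes under composition at its tabulated order", {
  for (nm in planar_groups) {
    g <- load_group(nm)
    expect_identical(g$order, unname(planar_orders[nm]), label = nm)
    expect_true(symdyn:::op_is_identity(g$elements[[1]]))
    for (a in g$elements) {
      expect_equal(abs(det(a$W)), 1, tolerance = 1e-12)
      for (b in g$elements) {
        comp <- op_compose(a, b)
        hits <- vapply(g$elements, op_equal, logical(1), b = comp)
        expect_identical(sum(hits), 1L,
                         label = paste(nm, "closure/uniqueness"))
      }
    }
  }
})

test_that("unknown identifiers fail with the list of bundled groups", {
  expect_error(load_group("p7"), "not bundled")
  expect_error(load_group(225), "available groups")
})

test_that("orbit has |G| entries, starts at q, and respects known images", {
  p1 <- load_group("p1")
  expect_equal(orbit(c(0.3, 0.4), p1), rbind(c(0.3, 0.4)))
  p2 <- load_group("p2")
  ob <- orbit(c(0.25, 0.25), p2)
  expect_equal(ob, rbind(c(0.25, 0.25), c(0.75, 0.75)))
  g127 <- load_group(127)
  ob <- orbit(c(0.11, 0.23, 0.37), g127)
  expect_identical(nrow(ob), 16L)
  expect_identical(nrow(unique(round(ob, 9))), 16L)  # general position: all distinct
})

test_that("unit-cell expansion reproduces the group-order multiplicities", {
  g127 <- load_group(127)
  set.seed(1)
  pos <- matrix(runif(15, 0.02, 0.45), 5, 3)
  cell <- expand_unit_cell(pos, g127)
  expect_identical(nrow(cell), 80L)   # 5 asymmetric-unit particles x |G| = 16
  p1 <- load_group("p1")
  pos2 <- matrix(runif(6), 3, 2)
  expect_equal(nrow(expand_unit_cell(pos2, p1)), 3L)
  p2 <- load_group("p2")
  cell2 <- expand_unit_cell(matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE), p2)
  expect_identical(nrow(cell2), 4L)
  # rows 2 and 4 are the 2-fold images of rows 1 and 3
  expect_equal(cell2[2, ], wrap_frac(-cell2[1, ]))
  expect_equal(cell2[4, ], wrap_frac(-cell2[3, ]))
})

test_that("expanding an undeclared special position is an explicit error", {
  p2 <- load_group("p2")
  expect_error(expand_unit_cell(rbind(c(0.5, 0.5)), p2), "Wyckoff")
  # declared via its site label it expands to the site multiplicity
  cell <- expand_unit_cell(rbind(c(0.5, 0.5)), p2, wyckoff_sites = "d")
  expect_identical(nrow(cell), 1L)
})

test_that("applying any group element permutes the expanded cell (invariance)", {
  set.seed(7)
  for (nm in planar_groups) {
    g <- load_group(nm)
    pos <- sample_asymmetric_unit(g, 2, seed = 7)
    cell <- expand_unit_cell(pos, g)
    for (el in g$elements) {
      moved <- wrap_frac(op_apply(el, cell))
      expect_lt(frac_set_distance(moved, cell), 1e-10)
    }
  }
})

test_that("asymmetric-unit sampling is deterministic, in-domain, and separated", {
  p2 <- load_group("p2")
  a <- sample_asymmetric_unit(p2, 4, seed = 42)
  b <- sample_asymmetric_unit(p2, 4, seed = 42)
  expect_identical(a, b)
  for (i in seq_len(nrow(a))) expect_true(in_asym_unit(a[i, ], p2))
  # p1: the whole cell is the fundamental domain
  p1 <- load_group("p1")
  s <- sample_asymmetric_unit(p1, 4, seed = 3)
  expect_true(all(s >= 0 & s < 1))
  # with a box, the expanded cell respects the minimum separation
  box <- diag(2) * 6
  s2 <- sample_asymmetric_unit(p2, 3, box = box, min_sep = 1.0, seed = 9)
  cell <- expand_unit_cell(s2, p2)
  d <- as.matrix(dist(cell %*% box))
  diag(d) <- Inf
  expect_gt(min(d), 1.0)
})

test_that("the canonical fundamental domain tiles the cell exactly once", {
  # area check: fraction of uniform points landing in the domain ~ 1/|G|
  set.seed(11)
  for (nm in c("p2", "p4", "p6m")) {
    g <- load_group(nm)
    pts <- matrix(runif(2000), ncol = 2)
    frac_in <- mean(apply(pts, 1, in_asym_unit, group = g))
    expect_equal(frac_in, 1 / g$order, tolerance = 0.15, label = nm)
    # canonical representative is idempotent and in-domain
    for (k in 1:20) {
      cr <- symdyn:::canonical_rep(runif(2), g)
      expect_true(in_asym_unit(cr, g))
    }
  }
})

test_that("Wyckoff projectors are idempotent and project onto their sites", {
  p4m <- load_group("p4m")
  site_line <- p4m$wyckoff$e          # (x, 0)
  expect_equal(project_to_wyckoff(c(0.3, 0.7), site_line), c(0.3, 0.0))
  site_origin <- p4m$wyckoff$a        # (0, 0)
  expect_equal(project_to_wyckoff(c(0.3, 0.7), site_origin), c(0.0, 0.0))
  set.seed(5)
  for (nm in planar_groups) {
    g <- load_group(nm)
    for (w in g$wyckoff) {
      for (k in 1:50) {
        q <- runif(2)
        p1x <- project_to_wyckoff(q, w)
        expect_equal(project_to_wyckoff(p1x, w), p1x, tolerance = 1e-12)
      }
      # orbit of a site point has the site multiplicity, dividing |G|
      expect_identical(g$order %% w$multiplicity, 0L)
      expect_true(w$multiplicity < g$order)
    }
  }
})

test_that("space group 127 matches its published multiplicity structure", {
  g <- load_group(127, dimension = 3)
  expect_identical(g$order, 16L)
  expect_identical(g$bravais_class, "tetragonal")
  expect_identical(g$wyckoff$a$multiplicity, 2L)  # (0,0,0) + (1/2,1/2,0)
  expect_identical(g$wyckoff$e$multiplicity, 4L)  # (0,0,z) family
  expect_identical(g$wyckoff$e$site_dof, 1L)
  expect_error(load_group(127, dimension = 2), "3-dimensional")
})
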