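test_that("fractional/Cartesian transforms follow the row-vector convention", {
  expect_equal(frac_to_cart(c(0.5, 0.5), diag(2)), c(0.5, 0.5))
  B <- matrix(c(2, 0, 1, 2), 2, 2, byrow = TRUE)
  expect_equal(frac_to_cart(c(0.5, 0.5), B), c(1.5, 1.0))
  set.seed(4)
  for (k in 1:100) {
    B <- diag(3) + matrix(runif(9, -0.3, 0.3), 3, 3)
    if (det(B) <= 0.1) next
    s <- runif(3)
    expect_equal(cart_to_frac(frac_to_cart(s, B), B), s, tolerance = 1e-12)
  }
  expect_error(frac_to_cart(c(1, 0), matrix(0, 2, 2)), "singular")
})

test_that("floor-based wrap maps any coordinate into [0,1)", {
  expect_equal(wrap_frac(1.25), 0.25)
  expect_equal(wrap_frac(-0.25), 0.75)
  expect_equal(wrap_frac(0.0), 0.0)
  expect_equal(wrap_frac(c(-3.7, 2.0)), c(0.3, 0.0))
})

test_that("Bravais projection extracts free parameters by length averaging", {
  cub <- make_projector("cubic", 3)
  expect_equal(apply_projector(cub, diag(c(1, 2, 3))), diag(2, 3))
  sq <- make_projector("square", 2)
  expect_equal(apply_projector(sq, matrix(c(2, 0, 0, 4), 2, 2)), diag(3, 2))
  tri <- make_projector("triclinic", 3)
  B <- matrix(rnorm(9), 3, 3)
  expect_identical(apply_projector(tri, B), B)
  expect_error(make_projector("rhombic", 2), "unknown Bravais class")
})

test_that("projection is idempotent and satisfies the class constraints", {
  set.seed(8)
  for (cls in symdyn_bravais_classes(2)) {
    proj <- make_projector(cls, 2)
    for (k in 1:200) {
      B <- diag(2) * runif(1, 0.5, 3) + matrix(runif(4, -0.5, 0.5), 2, 2)
      if (det(B) <= 0.05) next
      P1 <- apply_projector(proj, B)
      expect_lt(max(abs(apply_projector(proj, P1) - P1)), 1e-12)
      expect_gt(det(P1), 0)
      l <- sqrt(rowSums(P1^2))
      if (cls == "square") {
        expect_equal(P1, diag(l[1], 2), tolerance = 1e-12)
      } else if (cls == "hexagonal") {
        expect_equal(l[1], l[2], tolerance = 1e-12)
        cosang <- sum(P1[1, ] * P1[2, ]) / (l[1] * l[2])
        expect_equal(cosang, -0.5, tolerance = 1e-12)
      } else if (cls %in% c("rectangular", "centered-rectangular")) {
        expect_equal(P1[1, 2], 0, tolerance = 1e-12)
        expect_equal(P1[2, 1], 0, tolerance = 1e-12)
      }
    }
  }
  # 3D: tetragonal keeps a = b only
  proj <- make_projector("tetragonal", 3)
  for (k in 1:100) {
    B <- diag(3) + matrix(runif(9, -0.3, 0.3), 3, 3)
    if (det(B) <= 0.05) next
    P1 <- apply_projector(proj, B)
    expect_lt(max(abs(apply_projector(proj, P1) - P1)), 1e-12)
    expect_equal(P1[1, 1], P1[2, 2], tolerance = 1e-12)
  }
})

test_that("image offsets span 3^(a*D) cells with one zero offset", {
  im <- generate_images(1, 3)
  expect_identical(nrow(im$offsets), 27L)            # root + 26 neighbours
  expect_identical(sum(rowSums(abs(im$offsets)) == 0), 1L)
  im2 <- generate_images(2, 2)
  expect_identical(nrow(im2$offsets), 81L)           # 3^(2*2)
  expect_equal(range(im2$offsets), c(-4, 4))
  # symmetric under negation
  neg <- -im2$offsets
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(neg), key(im2$offsets))
  expect_error(generate_images(0, 2), "radius")
})

test_that("explicit images cover every neighbour within the cutoff", {
  # brute check: for random small boxes, any point within r_c of a cell
  # particle coincides with some explicit image when min height >= r_c / a
  set.seed(12)
  rc <- 3.5
  for (k in 1:5) {
    a <- 2
    L <- runif(1, rc / a + 0.2, rc)     # cell smaller than the cutoff
    box <- diag(2) * L
    im <- generate_images(a, 2)
    s <- matrix(runif(4), 2, 2)
    cart <- s %*% box
    shifts <- im$offsets %*% box
    # all images of particle 2 within rc of particle 1
    img2 <- matrix(cart[2, ], nrow(shifts), 2, byrow = TRUE) + shifts
    r <- sqrt(rowSums((img2 - matrix(cart[1, ], nrow(shifts), 2,
                                     byrow = TRUE))^2))
    # compare against a much larger direct enumeration
    big <- as.matrix(expand.grid(-12:12, -12:12)) %*% box
    imgbig <- matrix(cart[2, ], nrow(big), 2, byrow = TRUE) + big
    rbig <- sqrt(rowSums((imgbig - matrix(cart[1, ], nrow(big), 2,
                                          byrow = TRUE))^2))
    expect_identical(sum(r < rc), sum(rbig < rc))
  }
})

test_that("boxes built from a density have the right volume and class", {
  proj <- make_projector("hexagonal", 2)
  B <- box_from_density(proj, n_cell = 12, density = 0.3)
  expect_equal(det(B), 40, tolerance = 1e-12)
  expect_equal(sqrt(sum(B[1, ]^2)), sqrt(sum(B[2, ]^2)), tolerance = 1e-12)
})
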