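# Discrete curvature estimation: analytic primitives, sign conventions,
# invariances, and region averaging.

test_that("principal curvatures match analytic values on primitives", {
  # convex sphere r = 4: k1 = k2 = -1/4 within 5% everywhere
  s <- icosphere(4, 4)
  f <- principal_curvatures(s, 1)
  expect_true(all(f$ok))
  expect_lt(max(abs(f$k1 + 0.25)) / 0.25, 0.05)
  expect_lt(max(abs(f$k2 + 0.25)) / 0.25, 0.05)

  # plane: flat to 1e-3 1/mm
  pl <- make_primitive("plane", list(half_extent = 4), 0.4)
  fp <- principal_curvatures(pl, 1.5)
  expect_lt(max(abs(c(fp$k1, fp$k2)), na.rm = TRUE), 1e-3)

  # cylinder r = 2: k2 = -0.5, k1 = 0 away from the end rims
  cy <- make_primitive("cylinder", list(radius = 2, height = 10), 0.3)
  fc <- principal_curvatures(cy, 1)
  z <- cy$vertices[, 3]
  rho <- sqrt(rowSums(cy$vertices[, 1:2]^2))
  body <- abs(rho - 2) < 1e-9 & abs(z) < 5 - 1.2
  expect_lt(max(abs(fc$k2[body] + 0.5)) / 0.5, 0.05)
  expect_lt(max(abs(fc$k1[body])), 0.025)
})

test_that("signed Gaussian is convex-positive, concave-negative, flat-zero", {
  s <- icosphere(2, 4)
  f <- principal_curvatures(s, 0.8)
  expect_true(all(f$K_signed > 0))
  expect_equal(mean(f$K_signed), 0.25, tolerance = 0.01)

  # concave dish: paraboloid opening toward +z, normals up
  R <- 5
  dish <- make_primitive("plane", list(half_extent = 3), 0.3)
  dish <- surface_mesh(cbind(dish$vertices[, 1:2],
                             rowSums(dish$vertices[, 1:2]^2) / (2 * R)),
                       dish$faces, orient = FALSE)
  fd <- principal_curvatures(dish, 1)
  apex <- which.min(rowSums(dish$vertices[, 1:2]^2))
  expect_equal(fd$K_signed[apex], -1 / R^2, tolerance = 0.05 / R^2)

  pl <- make_primitive("plane", list(half_extent = 3), 0.3)
  fp <- principal_curvatures(pl, 1)
  expect_equal(max(abs(fp$K_signed)), 0, tolerance = 1e-6)
})

test_that("saddle has negative Gaussian curvature -1/R^2 at the apex", {
  sa <- make_primitive("saddle", list(R = 10, half_extent = 5), 0.3)
  fs <- principal_curvatures(sa, 1.5)
  o <- which.min(rowSums(sa$vertices[, 1:2]^2))
  expect_equal(fs$K[o], -0.01, tolerance = 0.05)
  expect_lt(fs$K_signed[o], 0.01)  # sign attribution near-zero mean curvature
})

test_that("curvature is rigid-motion invariant and scale covariant", {
  s <- icosphere(4, 3)
  f0 <- principal_curvatures(s, 1)
  R <- rotation_about(c(2, -1, 0.5), 1.1)
  f1 <- principal_curvatures(transform_mesh(s, R, c(7, -3, 2)), 1)
  expect_lt(max(abs(f1$k1 - f0$k1), abs(f1$k2 - f0$k2)), 1e-6)

  sc <- 2.5
  s2 <- surface_mesh(s$vertices * sc, s$faces)
  f2 <- principal_curvatures(s2, 1 * sc)
  expect_equal(f2$k2, f0$k2 / sc, tolerance = 1e-4)
  expect_equal(f2$K, f0$K / sc^2, tolerance = 1e-4)
})

test_that("sphere error decreases monotonically under mesh refinement", {
  errs <- vapply(2:4, function(sub) {
    s <- icosphere(4, sub)
    f <- principal_curvatures(s, 1.5)
    max(abs(f$k2 + 0.25)) / 0.25
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[1], 0.05)
})

test_that("starved neighborhoods grow the radius and then flag failure", {
  # a coarse sphere with a tiny radius: growth by 1.5^k rescues the fit
  s <- icosphere(4, 2)
  med <- mean_edge_length(s)
  f <- principal_curvatures(s, med * 1.05)
  expect_true(all(f$ok))
  expect_equal(median(f$k2), -0.25, tolerance = 0.05)
})

test_that("region means are area-weighted and cancel antisymmetric fields", {
  sq <- make_primitive("plane", list(half_extent = 2), 0.5)
  p <- surface_patch(sq, seq_len(nrow(sq$faces)))
  nv <- nrow(sq$vertices)
  fake <- structure(list(k1 = rep(0, nv), k2 = rep(0, nv), K = rep(0, nv),
                         K_signed = rep(3.7, nv), ok = rep(TRUE, nv),
                         fitting_radius = 1), class = "curvature_field")
  expect_equal(region_mean_curvature(fake, p), 3.7, tolerance = 1e-12)
  # antisymmetric in x: equal-area halves cancel
  fake$K_signed <- sign(sq$vertices[, 1]) * 2
  expect_lt(abs(region_mean_curvature(fake, p)), 1e-9)
  # full unit sphere: |mean| = 1 within 2%
  s <- icosphere(1, 4)
  f <- principal_curvatures(s, 0.5)
  ps <- surface_patch(s, seq_len(nrow(s$faces)))
  expect_equal(abs(region_mean_curvature(f, ps)), 1, tolerance = 0.02)
})

test_that("curvature CSV export has one row per vertex", {
  s <- icosphere(1, 2)
  f <- principal_curvatures(s, 0.6)
  csv <- tempfile(fileext = ".csv")
  export_curvature_csv(f, csv)
  df <- read.csv(csv)
  expect_identical(nrow(df), nrow(s$vertices))
  expect_named(df, c("vertex", "k1", "k2", "K", "K_signed", "ok"))
})
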