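# Size and shape in the anatomic frame: extents, width profiles, quadrants.

canon_frame <- function(origin = c(0, 0, 0))
  anatomic_frame(origin, c(1, 0, 0), c(0, 1, 0), c(0, 0, -1), side = "right")

# rectangular patch in the x (ML) - y (DP) plane, centered at the origin
rect_patch <- function(w, h, step = 0.5) {
  xs <- seq(-w / 2, w / 2, by = step)
  ys <- seq(-h / 2, h / 2, by = step)
  m <- articmorph:::grid_patch(xs, ys, function(x, y) rep(0, length(x)))
  surface_patch(m, seq_len(nrow(m$faces)))
}

test_that("max extents measure the ML and DP spans exactly", {
  p <- rect_patch(10, 20)
  ext <- max_extents(p, canon_frame())
  expect_equal(unname(ext), c(10, 20), tolerance = 1e-12)
  # invariance under a common rigid motion of patch and frame
  R <- rotation_about(c(1, 0.5, -2), 1.3)
  tr <- c(3, -7, 2)
  m2 <- transform_mesh(p$mesh, R, tr)
  p2 <- surface_patch(m2, p$faces)
  fr <- canon_frame()
  fr2 <- anatomic_frame(as.numeric(R %*% fr$origin + tr),
                        as.numeric(R %*% fr$axis_ml),
                        as.numeric(R %*% fr$axis_dp),
                        as.numeric(R %*% fr$axis_pd), side = "right")
  expect_equal(unname(max_extents(p2, fr2)), c(10, 20), tolerance = 1e-9)
})

test_that("width profile of a centered rectangle is exact at every height", {
  p <- rect_patch(10, 8)
  wp <- width_profile(p, canon_frame(), step = 2)
  for (h in c(-2, 0, 2)) {
    row <- wp[wp$height == h, ]
    expect_equal(row$medial_distance, 5, tolerance = 1e-9)
    expect_equal(row$lateral_distance, 5, tolerance = 1e-9)
    expect_equal(row$total_distance, 10, tolerance = 1e-9)
  }
  # heights beyond the dorsal extent are flagged absent
  expect_true(any(!wp$present))
  expect_false(wp$present[wp$height == max(wp$height)])
})

test_that("width profile matches linear interpolation on a trapezoid", {
  # symmetric trapezoid: half-width 6 at y = -4 narrowing to 2 at y = +4
  ys <- seq(-4, 4, by = 0.5)
  rows <- lapply(ys, function(y) {
    hw <- 6 - (y + 4) / 2
    cbind(seq(-hw, hw, length.out = 9), y, 0)
  })
  V <- do.call(rbind, rows)
  n <- 9
  F <- do.call(rbind, lapply(seq_len(length(ys) - 1), function(j) {
    a <- (j - 1) * n + seq_len(n - 1)
    b <- j * n + seq_len(n - 1)
    rbind(cbind(a, a + 1, b + 1), cbind(a, b + 1, b))
  }))
  m <- surface_mesh(V, F, orient = FALSE)
  p <- surface_patch(m, seq_len(nrow(F)))
  cen <- surface_centroid(p)
  wp <- width_profile(p, canon_frame(origin = cen), step = 2)
  for (i in which(wp$present)) {
    y_abs <- cen[2] + wp$height[i]
    hw <- 6 - (y_abs + 4) / 2
    expect_equal(wp$medial_distance[i], hw - cen[1], tolerance = 1e-9)
    expect_equal(wp$lateral_distance[i], hw + cen[1], tolerance = 1e-9)
  }
})

test_that("width profile demands the frame origin at the patch centroid", {
  p <- rect_patch(10, 8)
  expect_error(width_profile(p, canon_frame(origin = c(1, 0, 0))),
               "centroid")
})

test_that("quadrants partition the patch area exactly", {
  p <- rect_patch(10, 8)
  q <- quadrant_split(p, canon_frame())
  expect_named(q, c("dorsal-medial", "plantar-medial", "dorsal-lateral",
                    "plantar-lateral"))
  areas <- vapply(q, patch_area, 0)
  expect_equal(sum(areas), patch_area(p), tolerance = 1e-12)
  # symmetric rectangle: four equal areas within one face's area
  expect_lt(diff(range(areas)), max(mesh_face_areas(p$mesh)))
  # every face in exactly one quadrant
  expect_identical(sort(unname(unlist(lapply(q, `[[`, "faces")))),
                   sort(p$faces))
})

test_that("a patch wholly in one quadrant leaves the others empty with warning", {
  p <- rect_patch(4, 4)
  fr <- canon_frame(origin = c(-5, -5, 0))  # patch is dorsal-medial of origin
  w <- capture_warnings(q <- quadrant_split(p, fr))
  expect_length(w, 3L)
  expect_true(all(grepl("empty quadrant", w)))
  expect_length(q[["dorsal-medial"]]$faces, length(p$faces))
  expect_null(q[["plantar-lateral"]])
})

test_that("quadrant means recombine area-weighted to the whole-patch mean", {
  pb <- small_phantom()
  p <- truth_patch(pb, "distal")
  fr <- pb$truth$frame
  nv <- nrow(pb$mesh$vertices)
  set.seed(4)
  fake <- structure(list(k1 = rep(0, nv), k2 = rep(0, nv), K = rep(0, nv),
                         K_signed = rnorm(nv), ok = rep(TRUE, nv),
                         fitting_radius = 1), class = "curvature_field")
  q <- quadrant_split(p, fr)
  wsum <- 0; vsum <- 0
  for (qq in q) {
    vw <- articmorph:::patch_vertex_weights(qq)
    wsum <- wsum + sum(vw$w)
    vsum <- vsum + sum(vw$w * fake$K_signed[vw$ids])
  }
  expect_equal(vsum / wsum, region_mean_curvature(fake, p), tolerance = 1e-9)
})

test_that("profile widths never exceed the maximal extent", {
  pb <- small_phantom()
  f <- principal_curvatures(pb$mesh, 1.5)
  patch <- extract_articular_surface(pb$mesh, f, -0.25,
                                     seed_point = cap_seed_point(pb, "distal"))
  prox <- extract_articular_surface(pb$mesh, f, -0.25,
                                    seed_point = cap_seed_point(pb, "proximal"))
  fr <- cuneiform_frame(prox, patch, "medial", c(0, 1, 0), "right")
  ext <- max_extents(patch, fr)
  wp <- width_profile(patch, fr)
  expect_lte(max(wp$total_distance, na.rm = TRUE),
             ext[["width"]] + mean_edge_length(pb$mesh))
  # convex contour: total distance is unimodal in height (one sign change
  # of the finite differences, within discretization tolerance)
  tot <- wp$total_distance[wp$present]
  d <- diff(tot)
  flips <- sum(diff(sign(d[abs(d) > 0.05])) != 0)
  expect_lte(flips, 1)
})
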