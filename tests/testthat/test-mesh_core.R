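# Mesh substrate: validity, orientation, centroids, areas, components,
# boundary loops and hole filling.

test_that("mesh construction validates indices, areas and orientation", {
  expect_error(surface_mesh(matrix(0, 3, 3), rbind(c(1, 2, 4))),
               "out of range")
  # zero-area triangle (collinear vertices) named in the error
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  expect_error(surface_mesh(V, rbind(c(1, 2, 4), c(1, 2, 3))),
               "degenerate.*2")
  # inward cube is flipped to outward on construction
  m <- surface_mesh(cube_mesh(2)$vertices, cube_mesh(2, inward = TRUE)$faces)
  expect_gt(mesh_signed_volume(m), 0)
  expect_equal(mesh_signed_volume(m), 8, tolerance = 1e-12)
})

test_that("surface centroids are area-weighted centers of gravity", {
  sq <- unit_square_mesh()
  expect_equal(surface_centroid(surface_patch(sq, 1:2)), c(0.5, 0.5, 0),
               tolerance = 1e-12)
  # single triangle: mean of its vertices
  expect_equal(surface_centroid(surface_patch(sq, 1L)),
               colMeans(sq$vertices[sq$faces[1L, ], ]), tolerance = 1e-12)
  # hemispherical cap is symmetric about the z axis: no lateral offset
  s <- icosphere(3, 3)
  F <- s$faces
  zmin <- pmin(s$vertices[F[, 1], 3], s$vertices[F[, 2], 3],
               s$vertices[F[, 3], 3])
  cap <- surface_patch(s, which(zmin > 1e-9))
  expect_lt(max(abs(surface_centroid(cap)[1:2])), 1e-9)
})

test_that("volume centroid uses the divergence theorem and needs a closed mesh", {
  expect_equal(volume_centroid(cube_mesh(1)), c(0.5, 0.5, 0.5),
               tolerance = 1e-12)
  s <- icosphere(2, 3, center = c(3, -2, 7))
  expect_equal(volume_centroid(s), c(3, -2, 7), tolerance = 1e-6)
  # translation equivariance
  t <- c(-4, 2.5, 11)
  expect_equal(volume_centroid(transform_mesh(s, diag(3), t)),
               volume_centroid(s) + t, tolerance = 1e-9)
  expect_error(volume_centroid(unit_square_mesh()), "not watertight")
})

test_that("patch areas are exact sums and rigid-motion invariant", {
  expect_equal(patch_area(surface_patch(unit_square_mesh(), 1:2)), 1,
               tolerance = 1e-12)
  s <- icosphere(1, 4)
  p <- surface_patch(s, seq_len(nrow(s$faces)))
  expect_equal(patch_area(p), 4 * pi, tolerance = 0.005)
  R <- rotation_about(c(1, 2, 3), 0.8)
  s2 <- transform_mesh(s, R, c(5, -1, 2))
  expect_equal(patch_area(surface_patch(s2, seq_len(nrow(s2$faces)))),
               patch_area(p), tolerance = 1e-12)
})

test_that("connected components partition a face set by shared edges", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(5, 0, 0), c(6, 0, 0), c(5, 1, 0))
  m <- surface_mesh(V, rbind(c(1, 2, 3), c(4, 5, 6)), orient = FALSE)
  comps <- connected_components(m)
  expect_length(comps, 2L)
  s <- icosphere(1, 2)
  expect_length(connected_components(s), 1L)
  expect_identical(connected_components(s, integer(0)), list())
  # area conservation across the partition
  pb <- cube_mesh(1)
  sub <- c(1:3, 7:9)
  comps <- connected_components(pb, sub)
  expect_equal(sum(vapply(comps, patch_area, 0)),
               sum(mesh_face_areas(pb, sub)), tolerance = 1e-12)
})

test_that("hole filling closes interior loops only, preserving input faces", {
  an <- annulus_mesh()
  p <- surface_patch(an, seq_len(nrow(an$faces)))
  expect_length(boundary_loops(an, p$faces), 2L)
  filled <- fill_interior_holes(p)
  expect_length(boundary_loops(filled$mesh, filled$faces), 1L)
  # all input faces kept, coordinates untouched
  expect_true(all(p$faces %in% filled$faces))
  expect_equal(filled$mesh$vertices[seq_len(nrow(an$vertices)), ],
               an$vertices, tolerance = 0)
  # disk topology: faces only added
  expect_gt(length(filled$faces), length(p$faces))

  # patch with no interior holes is returned unchanged
  sq <- surface_patch(unit_square_mesh(), 1:2)
  expect_identical(fill_interior_holes(sq)$faces, sq$faces)

  # closed patch: warning, unchanged
  cb <- cube_mesh(1)
  pcb <- surface_patch(cb, seq_len(12L))
  expect_warning(out <- fill_interior_holes(pcb), "closed")
  expect_identical(out$faces, pcb$faces)
})

test_that("a two-hole patch is filled to a single boundary loop", {
  # plane grid with two interior vertices' stars removed
  pl <- make_primitive("plane", list(half_extent = 4), 0.5)
  holes_at <- rbind(c(-2, -2), c(2, 2))
  F <- pl$faces
  cen <- (pl$vertices[F[, 1], 1:2] + pl$vertices[F[, 2], 1:2] +
            pl$vertices[F[, 3], 1:2]) / 3
  drop <- unique(unlist(lapply(seq_len(nrow(holes_at)), function(i)
    which(sqrt((cen[, 1] - holes_at[i, 1])^2 +
                 (cen[, 2] - holes_at[i, 2])^2) < 0.6))))
  keep <- setdiff(seq_len(nrow(F)), drop)
  p <- surface_patch(pl, keep)
  expect_length(boundary_loops(pl, keep), 3L)
  filled <- fill_interior_holes(p)
  expect_length(boundary_loops(filled$mesh, filled$faces), 1L)
})
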