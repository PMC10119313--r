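# Anatomic coordinate frames: extrema, recovery of phantom truth frames,
# equivariance, mirror symmetry, orthonormality.

frame_orthonormal <- function(fr, side) {
  M <- cbind(fr$axis_ml, fr$axis_dp, fr$axis_pd)
  expect_equal(crossprod(M), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(M), if (side == "right") 1 else -1, tolerance = 1e-9)
}

frame_close <- function(fr, truth, tol_deg = 2) {
  for (ax in c("axis_ml", "axis_dp", "axis_pd"))
    expect_lt(axis_angle_deg(fr[[ax]], truth[[ax]]), tol_deg)
  expect_equal(sign(sum(fr$axis_dp * truth$axis_dp)), 1)
  expect_equal(sign(sum(fr$axis_ml * truth$axis_ml)), 1)
  expect_equal(sign(sum(fr$axis_pd * truth$axis_pd)), 1)
}

test_that("directional extremum maximizes the dot product with index ties broken low", {
  P <- cube_mesh(1)$vertices
  e <- directional_extremum(P, c(0, 0, 1))
  expect_equal(e$point[3], 1)
  expect_identical(e$index, which(P[, 3] == 1)[1])  # lowest index on ties
  single <- matrix(c(1, 2, 3), 1)
  expect_equal(directional_extremum(single, c(1, 0, 0))$point, c(1, 2, 3))
  eneg <- directional_extremum(P, c(0, 0, -1))
  expect_equal(eneg$point[3], 0)
  expect_error(directional_extremum(P[0, , drop = FALSE], c(1, 0, 0)),
               "empty")
})

test_that("cuneiform frames recover the phantom truth within 2 degrees", {
  for (variant in c("medial", "intermediate")) {
    bone <- paste0(variant, "_cuneiform")
    pb <- small_phantom(bone = bone)
    fr <- cuneiform_frame(truth_patch(pb, "proximal"),
                          truth_patch(pb, "distal"),
                          variant, dorsal_hint = c(0, 1, 0), side = "right")
    frame_orthonormal(fr, "right")
    frame_close(fr, pb$truth$frame)
    expect_equal(fr$origin,
                 surface_centroid(truth_patch(pb, "distal")),
                 tolerance = 1e-9)
  }
})

test_that("metatarsal frames recover the phantom truth within 2 degrees", {
  for (variant in c("MT1", "MT2")) {
    bone <- if (variant == "MT1") "metatarsal1" else "metatarsal2"
    pb <- small_phantom(bone = bone, k_distal = 0)
    fr <- metatarsal_frame(truth_patch(pb, "proximal"), pb$mesh, variant,
                           dorsal_hint = c(0, 1, 0),
                           lateral_hint = -pb$truth$frame$axis_ml,
                           side = "right")
    frame_orthonormal(fr, "right")
    frame_close(fr, pb$truth$frame)
    expect_equal(fr$origin,
                 surface_centroid(truth_patch(pb, "proximal")),
                 tolerance = 1e-9)
  }
})

test_that("frames are equivariant under rigid motion", {
  pb <- small_phantom()
  R <- rotation_about(c(0.3, -1, 2), 2.2)
  tr <- c(12, 5, -8)
  pb2 <- transform_phantom_bone(pb, R, tr)
  fr <- cuneiform_frame(truth_patch(pb2, "proximal"),
                        truth_patch(pb2, "distal"), "medial",
                        dorsal_hint = pb2$truth$frame$axis_dp, side = "right")
  frame_close(fr, pb2$truth$frame)
  expect_equal(fr$origin, pb2$truth$frame$origin, tolerance = 1e-6)
})

test_that("mirrored phantoms with flipped side give mirror-image ML axes", {
  pb <- small_phantom(side = "right")
  # mirror across the sagittal plane x = 0 (flip faces to keep orientation)
  Vm <- pb$mesh$vertices
  Vm[, 1] <- -Vm[, 1]
  mm <- surface_mesh(Vm, pb$mesh$faces[, c(1, 3, 2)], orient = FALSE)
  prox <- surface_patch(mm, pb$truth$caps$proximal)
  dist <- surface_patch(mm, pb$truth$caps$distal)
  fl <- cuneiform_frame(prox, dist, "medial", c(0, 1, 0), side = "left")
  fr <- cuneiform_frame(truth_patch(pb, "proximal"),
                        truth_patch(pb, "distal"), "medial", c(0, 1, 0),
                        side = "right")
  mirror <- function(v) c(-v[1], v[2], v[3])
  expect_lt(axis_angle_deg(fl$axis_ml, mirror(fr$axis_ml)), 2)
  expect_equal(sign(sum(fl$axis_ml * mirror(fr$axis_ml))), 1)
  frame_orthonormal(fl, "left")
})

test_that("degenerate hints and open bones are rejected", {
  pb <- small_phantom()
  prox <- truth_patch(pb, "proximal")
  dist <- truth_patch(pb, "distal")
  expect_error(cuneiform_frame(prox, dist, "medial",
                               dorsal_hint = c(0, 0, 1), side = "right"),
               "ambiguous")
  open_mesh <- unit_square_mesh()
  expect_error(metatarsal_frame(prox, open_mesh, "MT2", c(0, 1, 0),
                                c(1, 0, 0), "right"),
               "not watertight")
})

test_that("frame JSON serialization round-trips", {
  pb <- small_phantom()
  fr <- pb$truth$frame
  f <- tempfile(fileext = ".json")
  frame_to_json(fr, f)
  back <- frame_from_json(f)
  expect_equal(back$axis_ml, fr$axis_ml, tolerance = 1e-12)
  expect_equal(back$origin, fr$origin, tolerance = 1e-12)
  expect_identical(back$side, fr$side)
})
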