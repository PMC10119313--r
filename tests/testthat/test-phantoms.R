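# Synthetic phantom generation: analytic ground truth, watertightness,
# determinism, degradation operators.

test_that("primitive generators validate inputs and attach analytic truth", {
  expect_error(make_primitive("sphere", list(radius = -1), 0.3),
               "non-positive")
  s <- make_primitive("sphere", list(radius = 10), 1)
  an <- attr(s, "analytic")
  expect_equal(an$k1, rep(-0.1, nrow(s$vertices)))
  expect_true(mesh_is_closed(s))
  el <- make_primitive("ellipsoid", list(a = 3, b = 2, c = 1.5), 0.5)
  expect_true(mesh_is_closed(el))
  expect_true(all(attr(el, "analytic")$K > 0))
  expect_false(mesh_is_closed(make_primitive("saddle", list(R = 10), 1)))
})

test_that("phantom bones are watertight with truth populated by construction", {
  pb <- small_phantom()
  expect_true(mesh_is_closed(pb$mesh))
  expect_gt(mesh_signed_volume(pb$mesh), 0)
  # caps disjoint and nonempty
  expect_gt(length(pb$truth$caps$proximal), 0)
  expect_gt(length(pb$truth$caps$distal), 0)
  expect_length(intersect(pb$truth$caps$proximal, pb$truth$caps$distal), 0)
  # truth extents equal the inputs by construction
  expect_equal(unname(pb$truth$extents$distal), c(13, 16))
  expect_identical(pb$truth$curvature[["proximal"]], 0)
  # cap extents measured on the truth cap vertices match the inputs
  P <- articmorph:::patch_vertices(truth_patch(pb, "distal"))
  co <- frame_coords(P, pb$truth$frame)
  expect_equal(diff(range(co[, "ml"])), 13, tolerance = 0.02)
  expect_equal(diff(range(co[, "dp"])), 16, tolerance = 0.02)
})

test_that("cap and rim curvatures respect the 2x extraction margin", {
  pb <- small_phantom()
  thr <- default_thresholds()[["medial_cuneiform"]]
  # analytic cap principal curvature magnitude sqrt(|K|) is flatter than
  # half the threshold; the rim (1/rim_radius) is at least twice it
  expect_lt(sqrt(abs(pb$truth$curvature[["distal"]])), abs(thr) / 2)
  expect_gte(1 / pb$params$rim_radius, 2 * abs(thr))
})

test_that("phantom generation is deterministic per seed", {
  a <- small_phantom()
  b <- small_phantom()
  expect_identical(a$mesh, b$mesh)
})

test_that("infeasible caps and bad geometry are rejected", {
  expect_error(make_phantom_bone(
    cap_specs = list(proximal = list(k = 0, width = 10, height = 10),
                     distal = list(k = 0.05, width = 13, height = 16))),
    "curvature too high")
  expect_error(make_phantom_bone(rim_radius = -1), "rim_radius")
  expect_error(make_phantom_bone(
    cap_specs = list(proximal = list(k = 0, width = -3, height = 10),
                     distal = list(k = 0, width = 10, height = 10))),
    "positive")
  expect_error(make_joint_phantom(0.01, -0.01, gap = 0), "gap")
})

test_that("joint phantoms carry the closed-form similarity truth", {
  ext <- list(cun = c(width = 9, height = 11), met = c(width = 9, height = 11))
  jp1 <- make_joint_phantom(-0.01, 0.01, extents = ext, resolution = 0.6)
  expect_equal(jp1$truth_similarity, 1)
  jp2 <- make_joint_phantom(0.01, 0.01, extents = ext, resolution = 0.6)
  expect_equal(jp2$truth_similarity, -1)
  jp3 <- make_joint_phantom(-0.01 * exp(1), 0.01, extents = ext,
                            resolution = 0.6)
  expect_equal(jp3$truth_similarity, 0.5)
  # the truth always equals the closed form of the similarity operation
  expect_identical(jp3$truth_similarity,
                   curvature_similarity(jp3$k_cun, jp3$k_met))
  # opposing caps separated along the joint axis
  expect_gt(min(jp1$cuneiform$mesh$vertices[, 3]), 0)
  expect_lt(max(jp1$metatarsal$mesh$vertices[, 3]), 0)
})

test_that("voxelize_remesh reproduces areas and stays watertight", {
  s <- make_primitive("sphere", list(radius = 10), 0.5)
  vm <- voxelize_remesh(s, 0.148)
  expect_true(mesh_is_closed(vm))
  expect_gt(mesh_signed_volume(vm), 0)
  expect_equal(sum(mesh_face_areas(vm)), 4 * pi * 100,
               tolerance = 0.02 * 4 * pi * 100)
  expect_error(voxelize_remesh(s, -0.1), "positive")
  expect_error(voxelize_remesh(s, 1000), "empty")
})

test_that("vertex noise is seeded, bounded, and zero-amplitude is identity", {
  s <- icosphere(3, 3)
  expect_identical(add_vertex_noise(s, 0, seed = 1), s)
  n1 <- add_vertex_noise(s, 0.05, seed = 9)
  n2 <- add_vertex_noise(s, 0.05, seed = 9)
  expect_identical(n1, n2)
  d <- sqrt(rowSums((n1$vertices - s$vertices)^2))
  expect_lte(max(d), 0.05 + 1e-12)
  expect_gt(max(d), 0.02)
})

test_that("pose transforms are recorded and honored by truth predicates", {
  pb <- small_phantom()
  R <- rotation_about(c(1, 1, 0), 0.9)
  tr <- c(4, -6, 10)
  pb2 <- transform_phantom_bone(pb, R, tr)
  # truth frame moves with the pose
  expect_equal(pb2$truth$frame$axis_pd, as.numeric(R %*% pb$truth$frame$axis_pd),
               tolerance = 1e-12)
  # analytic membership agrees with the constructed face set on the posed mesh
  pred <- truth_cap_faces(pb2, "distal", tol = 0.1)
  jac <- jaccard_area(pb2$mesh, pred, pb2$truth$caps$distal)
  expect_gt(jac, 0.9)
})
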