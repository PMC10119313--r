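# Shared fixtures and measures for the geometry tests.  All fixtures are
# built in code; nothing is read from disk.

# two-triangle unit square in the z = 0 plane
unit_square_mesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  F <- rbind(c(1, 2, 3), c(1, 3, 4))
  surface_mesh(V, F, orient = FALSE)
}

# axis-aligned cube [0, side]^3, outward-oriented unless inward = TRUE
cube_mesh <- function(side = 1, inward = FALSE) {
  V <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  dimnames(V) <- NULL
  F <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = side
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = side
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = side
  if (inward) F <- F[, c(1, 3, 2)]
  surface_mesh(V, F, orient = FALSE)
}

# flat annulus (two boundary loops) in the z = 0 plane
annulus_mesh <- function(r_in = 1, r_out = 2, n = 24) {
  th <- 2 * pi * seq_len(n) / n
  V <- rbind(cbind(r_in * cos(th), r_in * sin(th), 0),
             cbind(r_out * cos(th), r_out * sin(th), 0))
  nxt <- c(2:n, 1L)
  F <- rbind(cbind(seq_len(n), n + seq_len(n), n + nxt),
             cbind(seq_len(n), n + nxt, nxt))
  surface_mesh(V, F, orient = FALSE)
}

# area-weighted Jaccard overlap between two face sets of one mesh
jaccard_area <- function(mesh, faces_a, faces_b) {
  faces_a <- faces_a[faces_a <= nrow(mesh$faces)]
  fa <- mesh_face_areas(mesh)
  sum(fa[intersect(faces_a, faces_b)]) / sum(fa[union(faces_a, faces_b)])
}

# unsigned angle (degrees) between two axis directions
axis_angle_deg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# small phantom bone used across extraction/frame/morphometry tests
small_phantom <- function(bone = "medial_cuneiform", side = "right",
                          k_distal = 0.004, resolution = 0.45) {
  make_phantom_bone(
    body_length = 12,
    cap_specs = list(proximal = list(k = 0, width = 11, height = 14),
                     distal = list(k = k_distal, width = 13, height = 16)),
    rim_radius = 2, resolution = resolution, seed = 5,
    bone = bone, side = side)
}

truth_patch <- function(pb, end) surface_patch(pb$mesh, pb$truth$caps[[end]])

cap_seed_point <- function(pb, end) surface_centroid(truth_patch(pb, end))
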