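# Mesh substrate: triangulated surfaces in mm, surface patches, and the
# geometric primitives (areas, centroids, components, boundary loops, hole
# filling) used by every downstream stage.

#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` stores vertex positions in millimetres and triangles as
#' 1-based vertex-index triples.  On construction the mesh is validated (all
#' indices in range, every triangle with positive area) and, if it is closed
#' and consistently oriented, re-oriented outward (signed enclosed volume
#' positive) by flipping all triangles when necessary.
#'
#' @param vertices numeric matrix (n x 3), positions in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param validate check invariants (default `TRUE`).
#' @param orient flip all triangles if the mesh is closed with negative
#'   signed volume (default `TRUE`).
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE, orient = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "surface_mesh")
  if (validate) {
    if (nrow(faces) == 0L) stop("mesh has no faces")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    areas <- mesh_face_areas(mesh)
    bad <- which(areas < 1e-12)
    if (length(bad))
      stop("degenerate (zero-area) triangles at faces: ",
           paste(utils::head(bad, 20L), collapse = ", "))
  }
  if (orient && mesh_is_closed(mesh)) {
    if (mesh_signed_volume(mesh) < 0) {
      mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
    }
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (mesh_is_closed(x)) " (closed)" else ""))
  invisible(x)
}

# cross products of the two edge vectors of each face (magnitude 2*area)
tri_cross <- function(V, F) {
  a <- V[F[, 1L], , drop = FALSE]
  e1 <- V[F[, 2L], , drop = FALSE] - a
  e2 <- V[F[, 3L], , drop = FALSE] - a
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Per-face triangle areas
#' @param mesh a `surface_mesh`.
#' @param faces optional face-index subset (default all faces).
#' @return numeric vector of areas (mm^2).
#' @export
mesh_face_areas <- function(mesh, faces = NULL) {
  F <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  cr <- tri_cross(mesh$vertices, F)
  0.5 * sqrt(rowSums(cr^2))
}

#' Signed volume enclosed by a mesh
#'
#' Divergence-theorem sum of signed tetrahedra against the origin; positive
#' for a closed, outward-oriented mesh.
#' @param mesh a `surface_mesh`.
#' @export
mesh_signed_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1L], , drop = FALSE]
  cr <- tri_cross(V, F)
  # (a - a) cancels: use absolute triple product a . (b - a) x (c - a)
  sum(rowSums(a * cr)) / 6
}

#' Is the mesh closed (watertight) and consistently oriented?
#' @param mesh a `surface_mesh`.
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  chk <- cpp_edge_manifold_check(mesh$faces)
  isTRUE(chk$closed) && isTRUE(chk$consistent)
}

#' Construct a surface patch (a face subset of a parent mesh)
#'
#' @param mesh parent `surface_mesh`.
#' @param faces integer vector of face indices into `mesh$faces`.
#' @param label list with elements `bone`, `end`, `side` (any may be `NA`).
#' @return an object of class `surface_patch`.
#' @export
surface_patch <- function(mesh, faces,
                          label = list(bone = NA, end = NA, side = NA)) {
  faces <- as.integer(faces)
  if (length(faces) == 0L) stop("empty patch")
  if (min(faces) < 1L || max(faces) > nrow(mesh$faces))
    stop("patch face indices out of range")
  structure(list(mesh = mesh, faces = faces, label = label),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  lb <- x$label
  cat(sprintf("surface_patch: %d faces, area %.3f mm^2 [%s %s %s]\n",
              length(x$faces), patch_area(x),
              lb$bone, lb$end, lb$side))
  invisible(x)
}

#' Total area of a surface patch
#' @param patch a `surface_patch`.
#' @return area in mm^2.
#' @export
patch_area <- function(patch) {
  if (length(patch$faces) == 0L) stop("empty patch")
  sum(mesh_face_areas(patch$mesh, patch$faces))
}

#' Area-weighted centroid of a surface patch
#'
#' Each triangle contributes its own centroid weighted by its area (the
#' "center of gravity" of the surface).
#' @param patch a `surface_patch`.
#' @return length-3 numeric, mm.
#' @export
surface_centroid <- function(patch) {
  if (length(patch$faces) == 0L) stop("empty patch")
  V <- patch$mesh$vertices
  F <- patch$mesh$faces[patch$faces, , drop = FALSE]
  cen <- (V[F[, 1L], , drop = FALSE] + V[F[, 2L], , drop = FALSE] +
            V[F[, 3L], , drop = FALSE]) / 3
  a <- mesh_face_areas(patch$mesh, patch$faces)
  colSums(cen * a) / sum(a)
}

#' Volume centroid of a closed mesh
#'
#' Centroid of the enclosed solid ("center of gravity of the bone object"),
#' computed by the divergence theorem over signed tetrahedra.
#' @param mesh a closed, outward-oriented `surface_mesh`.
#' @return length-3 numeric, mm.
#' @export
volume_centroid <- function(mesh) {
  if (!mesh_is_closed(mesh)) stop("not watertight")
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1L], , drop = FALSE]
  b <- V[F[, 2L], , drop = FALSE]
  c_ <- V[F[, 3L], , drop = FALSE]
  cr <- tri_cross(V, F)
  vol6 <- rowSums(a * cr)            # 6 * signed tet volume
  cen <- (a + b + c_) / 4            # tet centroid (4th vertex at origin)
  colSums(cen * vol6) / sum(vol6)
}

#' Edge-connected components of a face subset
#'
#' Partitions a face subset into maximal edge-connected components, returned
#' as patches sorted by descending area.
#'
#' @param mesh a `surface_mesh`.
#' @param faces face-index subset (default: all faces).
#' @param label label attached to each component patch.
#' @return list of `surface_patch`, largest area first; empty input gives an
#'   empty list.
#' @export
connected_components <- function(mesh, faces = NULL,
                                 label = list(bone = NA, end = NA, side = NA)) {
  if (is.null(faces)) faces <- seq_len(nrow(mesh$faces))
  faces <- as.integer(faces)
  if (length(faces) == 0L) return(list())
  comp <- cpp_face_components(mesh$faces[faces, , drop = FALSE])
  groups <- split(faces, comp)
  areas <- vapply(groups, function(fs) sum(mesh_face_areas(mesh, fs)), 0)
  groups <- groups[order(areas, decreasing = TRUE)]
  lapply(groups, function(fs) surface_patch(mesh, fs, label))
}

#' Boundary loops of a face subset
#'
#' Returns the closed boundary loops (cycles of vertex ids) of the given face
#' subset, walking directed boundary edges as oriented by the faces.
#' @param mesh a `surface_mesh`.
#' @param faces face-index subset.
#' @return list of integer vectors (each a closed loop of vertex ids, not
#'   repeating the first vertex at the end); empty list for a closed patch.
#' @export
boundary_loops <- function(mesh, faces) {
  be <- cpp_boundary_edges(mesh$faces[faces, , drop = FALSE])
  if (nrow(be) == 0L) return(list())
  # successor map tail -> head; at non-manifold vertices pick lowest head
  o <- order(be[, 1L], be[, 2L])
  be <- be[o, , drop = FALSE]
  used <- rep(FALSE, nrow(be))
  first_of <- match(unique(be[, 1L]), be[, 1L])
  names(first_of) <- unique(be[, 1L])
  loops <- list()
  for (start in seq_len(nrow(be))) {
    if (used[start]) next
    loop <- integer(0)
    e <- start
    repeat {
      used[e] <- TRUE
      loop <- c(loop, be[e, 1L])
      nxt_tail <- be[e, 2L]
      # first unused edge with this tail
      i <- first_of[as.character(nxt_tail)]
      if (is.na(i)) break
      e <- NA_integer_
      j <- i
      while (j <= nrow(be) && be[j, 1L] == nxt_tail) {
        if (!used[j]) { e <- j; break }
        j <- j + 1L
      }
      if (is.na(e)) break
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

loop_length <- function(V, loop) {
  p <- V[loop, , drop = FALSE]
  q <- V[c(loop[-1L], loop[1L]), , drop = FALSE]
  sum(sqrt(rowSums((p - q)^2)))
}

#' Fill interior holes of a surface patch
#'
#' The boundary loop of greatest total edge length is taken as the outer rim;
#' every other loop is triangulated by a fan from the loop's centroid (a new
#' vertex appended to the parent mesh).  Input faces and vertex coordinates
#' are never modified; the returned patch references an augmented copy of the
#' parent mesh.
#'
#' @param patch a `surface_patch` with at least one boundary loop.
#' @return a `surface_patch` with exactly one boundary loop.
#' @export
fill_interior_holes <- function(patch) {
  mesh <- patch$mesh
  loops <- boundary_loops(mesh, patch$faces)
  if (length(loops) == 0L) {
    warning("patch is closed (no boundary); returned unchanged")
    return(patch)
  }
  if (length(loops) == 1L) return(patch)
  lens <- vapply(loops, function(l) loop_length(mesh$vertices, l), 0)
  holes <- loops[-which.max(lens)]
  V <- mesh$vertices
  F <- mesh$faces
  new_faces <- integer(0)
  for (h in holes) {
    cen <- colMeans(V[h, , drop = FALSE])
    V <- rbind(V, cen)
    ci <- nrow(V)
    nxt <- c(h[-1L], h[1L])
    # boundary edges run a -> b in the patch; fill faces reversed: (b, a, c)
    add <- cbind(nxt, h, ci)
    new_faces <- c(new_faces, nrow(F) + seq_len(nrow(add)))
    F <- rbind(F, add)
  }
  mesh2 <- surface_mesh(V, F, validate = FALSE, orient = FALSE)
  surface_patch(mesh2, c(patch$faces, new_faces), patch$label)
}

#' Extract a patch as a stand-alone mesh
#'
#' Builds a new `surface_mesh` from the patch's faces, dropping unused
#' vertices, together with the patch on it and the map back to parent vertex
#' ids.  Used to compute curvature on an exported articular surface part.
#' @param patch a `surface_patch`.
#' @return list with `mesh`, `patch` (covering all faces) and `vertex_map`
#'   (parent ids of the submesh vertices).
#' @export
patch_submesh <- function(patch) {
  F <- patch$mesh$faces[patch$faces, , drop = FALSE]
  ids <- sort(unique(as.vector(F)))
  remap <- integer(nrow(patch$mesh$vertices))
  remap[ids] <- seq_along(ids)
  F2 <- matrix(remap[F], ncol = 3L)
  mesh2 <- surface_mesh(patch$mesh$vertices[ids, , drop = FALSE], F2,
                        validate = FALSE, orient = FALSE)
  list(mesh = mesh2,
       patch = surface_patch(mesh2, seq_len(nrow(F2)), patch$label),
       vertex_map = ids)
}

#' Apply a rigid motion to a mesh
#' @param mesh a `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  V <- mesh$vertices %*% t(rotation)
  V <- sweep(V, 2L, translation, "+")
  surface_mesh(V, mesh$faces, validate = FALSE, orient = FALSE)
}
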