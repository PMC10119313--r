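# Articular surface extraction: connected low-curvature regions bounded by
# high curvature, thresholded on the second principal curvature.

#' Extract an articular surface by second-principal-curvature thresholding
#'
#' Faces whose three vertices all have `k2 >= threshold` (flatter than the
#' threshold under the convex-negative convention) form the candidate set;
#' its edge-connected components are computed, the component containing (or
#' nearest to) `seed_point` — or the largest by area when no seed is given —
#' is selected, and interior holes are filled.
#'
#' Default thresholds in this anatomy are -0.25 1/mm for the medial cuneiform
#' and first metatarsal and -0.35 1/mm for the intermediate cuneiform and
#' second metatarsal (see [default_thresholds()]).
#'
#' @param mesh a [surface_mesh()].
#' @param field a [principal_curvatures()] field on `mesh`.
#' @param threshold second-principal-curvature threshold, 1/mm; must be
#'   negative.
#' @param seed_point optional 3-D point; selects the candidate component
#'   nearest to it.
#' @param fill fill interior holes of the selected component (default TRUE).
#' @param label label attached to the resulting patch.
#' @return a [surface_patch()] with a `provenance` attribute recording the
#'   threshold, component rank and candidate count.
#' @export
extract_articular_surface <- function(mesh, field, threshold,
                                      seed_point = NULL, fill = TRUE,
                                      label = list(bone = NA, end = NA, side = NA)) {
  if (!is.numeric(threshold) || threshold >= 0)
    stop("threshold must be negative (1/mm, convex-negative convention)")
  flat_v <- field$ok & !is.na(field$k2) & field$k2 >= threshold
  F <- mesh$faces
  flat_f <- flat_v[F[, 1L]] & flat_v[F[, 2L]] & flat_v[F[, 3L]]
  cand <- which(flat_f)
  if (length(cand) == 0L) stop("threshold excludes entire surface")
  if (length(cand) == nrow(F)) stop("no bounding high-curvature region")
  comps <- connected_components(mesh, cand, label)
  rank <- 1L
  if (!is.null(seed_point)) {
    seed_point <- as.numeric(seed_point)
    d2 <- vapply(comps, function(p) {
      Fc <- mesh$faces[p$faces, , drop = FALSE]
      cen <- (mesh$vertices[Fc[, 1L], , drop = FALSE] +
                mesh$vertices[Fc[, 2L], , drop = FALSE] +
                mesh$vertices[Fc[, 3L], , drop = FALSE]) / 3
      min(colSums((t(cen) - seed_point)^2))
    }, 0)
    rank <- which.min(d2)
  }
  patch <- comps[[rank]]
  if (fill) patch <- fill_interior_holes(patch)
  attr(patch, "provenance") <- list(threshold = threshold,
                                    component_rank = rank,
                                    n_components = length(comps),
                                    n_candidate_faces = length(cand),
                                    filled = fill)
  patch
}

#' Default extraction thresholds per bone
#'
#' -0.25 1/mm for medial cuneiform and first metatarsal, -0.35 1/mm for
#' intermediate cuneiform and second metatarsal.
#' @return named numeric vector.
#' @export
default_thresholds <- function() {
  c(medial_cuneiform = -0.25, metatarsal1 = -0.25,
    intermediate_cuneiform = -0.35, metatarsal2 = -0.35)
}
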