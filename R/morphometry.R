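# Size and shape in the anatomic frame: maximal extents, width profiles at
# fixed height steps, and quadrant subdivision.

#' Maximum width and height of a patch in its anatomic frame
#'
#' Width is the span of the patch vertices along the medial-lateral axis
#' (furthest medial to furthest lateral point); height the span along the
#' dorsal-plantar axis.
#' @param patch a `surface_patch`.
#' @param frame an `anatomic_frame`.
#' @return named numeric `c(width, height)` in mm.
#' @export
max_extents <- function(patch, frame) {
  P <- patch_vertices(patch)
  co <- frame_coords(P, frame)
  c(width = diff(range(co[, "ml"])), height = diff(range(co[, "dp"])))
}

#' Width profile of an articular surface at fixed height steps
#'
#' The patch's outer boundary loop (the longest) is projected onto the
#' frontal plane spanned by the ML and DP axes through the frame origin.  At
#' each height `h = k * step` (dorsal positive) the projected contour is
#' intersected with the line parallel to ML: `medial_distance` is the signed
#' ML-coordinate of the outermost crossing on the medial side and
#' `lateral_distance` the signed magnitude of the outermost lateral crossing;
#' either may be negative when the whole contour at that height lies on the
#' other side of the DP axis.  Heights without a crossing are flagged absent.
#'
#' The frame origin must coincide with the patch centroid (the projection
#' plane passes through the center of gravity of the surface).
#'
#' @param patch a `surface_patch`.
#' @param frame an `anatomic_frame` with origin at the patch centroid.
#' @param step height spacing in mm (default 2, the approximate thickness of
#'   an arthrodesis saw blade).
#' @return data.frame of class `width_profile` with columns `height`,
#'   `medial_distance`, `lateral_distance`, `total_distance`, `present`.
#' @export
width_profile <- function(patch, frame, step = 2) {
  if (step <= 0) stop("step must be positive")
  cen <- surface_centroid(patch)
  if (sqrt(sum((cen - frame$origin)^2)) > 1e-6)
    stop("frame origin must coincide with the patch centroid")
  loops <- boundary_loops(patch$mesh, patch$faces)
  if (length(loops) == 0L) stop("patch has no boundary loop")
  lens <- vapply(loops, function(l) loop_length(patch$mesh$vertices, l), 0)
  loop <- loops[[which.max(lens)]]
  co <- frame_coords(patch$mesh$vertices[loop, , drop = FALSE], frame)
  ml <- co[, "ml"]
  dp <- co[, "dp"]
  # one step beyond the extent on each side, so out-of-range heights are
  # reported as explicitly absent
  kmin <- ceiling(min(dp) / step) - 1L
  kmax <- floor(max(dp) / step) + 1L
  ks <- seq(kmin, kmax)
  n <- length(loop)
  nxt <- c(2:n, 1L)
  rows <- lapply(ks, function(k) {
    h <- k * step
    below <- dp <= h
    crossing <- which(below != below[nxt])
    if (length(crossing) == 0L)
      return(data.frame(height = h, medial_distance = NA_real_,
                        lateral_distance = NA_real_, total_distance = NA_real_,
                        present = FALSE))
    i <- crossing
    j <- nxt[crossing]
    t <- (h - dp[i]) / (dp[j] - dp[i])
    x <- ml[i] + t * (ml[j] - ml[i])
    med <- max(x)          # outermost crossing on the medial side (signed)
    lat <- -min(x)         # signed magnitude of the outermost lateral crossing
    data.frame(height = h, medial_distance = med, lateral_distance = lat,
               total_distance = med + lat, present = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "step") <- step
  class(out) <- c("width_profile", class(out))
  out
}

#' Split a patch into anatomical quadrants
#'
#' Faces are assigned by the frame-coordinates of their centroids: the
#' sagittal plane (ML sign) separates medial from lateral and the transverse
#' plane (DP sign) dorsal from plantar, yielding the four subregions
#' dorsal-medial, plantar-medial, dorsal-lateral and plantar-lateral.  Every
#' face lands in exactly one quadrant; empty quadrants are returned as `NULL`
#' with a warning.
#'
#' @param patch a `surface_patch`.
#' @param frame an `anatomic_frame` with origin at the patch centroid.
#' @return named list of four `surface_patch` (or `NULL`) entries.
#' @export
quadrant_split <- function(patch, frame) {
  if (length(patch$faces) == 0L) stop("empty patch")
  F <- patch$mesh$faces[patch$faces, , drop = FALSE]
  V <- patch$mesh$vertices
  cen <- (V[F[, 1L], , drop = FALSE] + V[F[, 2L], , drop = FALSE] +
            V[F[, 3L], , drop = FALSE]) / 3
  co <- frame_coords(cen, frame)
  dorsal <- co[, "dp"] >= 0
  medial <- co[, "ml"] >= 0
  labs <- ifelse(dorsal, "dorsal", "plantar")
  labs <- paste0(labs, "-", ifelse(medial, "medial", "lateral"))
  quads <- c("dorsal-medial", "plantar-medial", "dorsal-lateral",
             "plantar-lateral")
  out <- setNames(vector("list", 4L), quads)
  for (q in quads) {
    fs <- patch$faces[labs == q]
    if (length(fs) == 0L) {
      warning("empty quadrant: ", q)
      out[q] <- list(NULL)
    } else {
      lb <- patch$label
      lb$region <- q
      out[[q]] <- surface_patch(patch$mesh, fs, lb)
    }
  }
  out
}
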