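# Automatic anatomic coordinate frames from surface centroids and
# directional extrema.
#
# Axis conventions (fixed package-wide):
#   * axis_pd points distal-ward: from the proximal to the distal surface
#     centroid in cuneiforms, from the proximal articular surface toward the
#     bone's volume centroid (the shaft) in metatarsals;
#   * axis_dp always points dorsal;
#   * axis_ml always points medial.
# A frame with anatomically fixed directions is necessarily mirrored between
# sides: det(ml, dp, pd) = +1 for right-side bones and -1 for left-side
# bones.  Orthogonality is enforced by Gram-Schmidt in the order
# pd -> dp -> ml, and the origin is the centroid of the analyzed articular
# surface.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  v / n
}

orth_unit <- function(v, against) unit(v - sum(v * against) * against)

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

angle_deg <- function(a, b) {
  d <- sum(unit(a) * unit(b))
  acos(max(-1, min(1, d))) * 180 / pi
}

check_hint <- function(hint, pd, what = "dorsal") {
  ang <- angle_deg(hint, pd)
  if (ang < 5 || ang > 175)
    stop(sprintf("ambiguous %s direction: hint within 5 degrees of the PD axis", what))
}

#' Construct an anatomic frame from explicit axes
#'
#' Axes must be unit length and mutually orthogonal (within 1e-9); `axis_ml`
#' points medial, `axis_dp` dorsal, `axis_pd` distal.
#' @param origin frame origin (mm), conventionally the analyzed articular
#'   surface centroid.
#' @param axis_ml,axis_dp,axis_pd unit axes.
#' @param side `"left"` or `"right"`.
#' @param bone bone label.
#' @return an `anatomic_frame`.
#' @export
anatomic_frame <- function(origin, axis_ml, axis_dp, axis_pd,
                           side = "right", bone = NA_character_) {
  axes <- list(axis_ml, axis_dp, axis_pd)
  for (a in axes)
    if (abs(sqrt(sum(a^2)) - 1) > 1e-9) stop("axes must be unit length")
  if (abs(sum(axis_ml * axis_dp)) > 1e-9 ||
      abs(sum(axis_ml * axis_pd)) > 1e-9 ||
      abs(sum(axis_dp * axis_pd)) > 1e-9)
    stop("axes must be mutually orthogonal")
  new_frame(origin, axis_ml, axis_dp, axis_pd, side, bone)
}

new_frame <- function(origin, ml, dp, pd, side, bone) {
  structure(list(origin = as.numeric(origin), axis_ml = as.numeric(ml),
                 axis_dp = as.numeric(dp), axis_pd = as.numeric(pd),
                 side = side, bone = bone),
            class = "anatomic_frame")
}

#' @export
print.anatomic_frame <- function(x, ...) {
  cat(sprintf("anatomic_frame (%s, %s)\n  origin: %s\n  ml: %s\n  dp: %s\n  pd: %s\n",
              x$bone, x$side,
              paste(sprintf("%.3f", x$origin), collapse = " "),
              paste(sprintf("%.4f", x$axis_ml), collapse = " "),
              paste(sprintf("%.4f", x$axis_dp), collapse = " "),
              paste(sprintf("%.4f", x$axis_pd), collapse = " ")))
  invisible(x)
}

# medial completion: ml = dp x pd on the right, its negation on the left
complete_ml <- function(dp, pd, side) {
  ml <- cross3(dp, pd)
  if (identical(side, "left")) ml <- -ml
  unit(ml)
}

#' Extremum of a point set along a direction
#'
#' The point maximizing the dot product with `direction`; exact ties are
#' broken by the lowest point index.
#' @param points n x 3 matrix.
#' @param direction unit direction.
#' @return list with `point` (length-3) and `index`.
#' @export
directional_extremum <- function(points, direction) {
  points <- rbind(points)
  if (nrow(points) == 0L) stop("empty point set")
  s <- as.numeric(points %*% unit(direction))
  i <- which.max(s)  # first maximum = lowest index on ties
  list(point = as.numeric(points[i, ]), index = i)
}

patch_vertices <- function(patch) {
  ids <- sort(unique(as.vector(patch$mesh$faces[patch$faces, , drop = FALSE])))
  patch$mesh$vertices[ids, , drop = FALSE]
}

#' Anatomic frame for a cuneiform-like bone
#'
#' The proximal-distal axis joins the centroids of the proximal and distal
#' articular surfaces (pointing distal); the origin is the distal-surface
#' centroid (the analyzed surface).  The dorsal-plantar axis is the direction
#' from the midpoint of the two centroids to the midpoint of the per-surface
#' directional extrema — the most dorsal points for the medial cuneiform, the
#' most plantar points for the intermediate cuneiform — orthogonalized
#' against PD and oriented to point dorsal.  The medial-lateral axis
#' completes the frame, pointing medial.
#'
#' @param prox,dist proximal and distal articular `surface_patch`es.
#' @param variant `"medial"` (dorsal extrema) or `"intermediate"` (plantar
#'   extrema).
#' @param dorsal_hint approximate dorsal direction (e.g. scanner +z); must
#'   not be within 5 degrees of the PD axis.
#' @param side `"left"` or `"right"`.
#' @return an `anatomic_frame`.
#' @export
cuneiform_frame <- function(prox, dist, variant = c("medial", "intermediate"),
                            dorsal_hint, side = c("right", "left")) {
  variant <- match.arg(variant)
  side <- match.arg(side)
  cp <- surface_centroid(prox)
  cd <- surface_centroid(dist)
  if (sqrt(sum((cd - cp)^2)) < 1e-6) stop("degenerate PD axis")
  pd <- unit(cd - cp)                       # proximal -> distal
  check_hint(dorsal_hint, pd)
  dors <- orth_unit(dorsal_hint, pd)
  ext_dir <- if (variant == "medial") dors else -dors
  ep <- directional_extremum(patch_vertices(prox), ext_dir)$point
  ed <- directional_extremum(patch_vertices(dist), ext_dir)$point
  mid_c <- (cp + cd) / 2
  mid_e <- (ep + ed) / 2
  dp <- orth_unit(mid_e - mid_c, pd)
  if (variant == "intermediate") dp <- -dp  # always point dorsal
  ml <- complete_ml(dp, pd, side)
  new_frame(cd, ml, dp, pd, side,
            paste0(variant, "_cuneiform"))
}

#' Anatomic frame for a metatarsal-like bone
#'
#' The proximal-distal axis runs from the proximal articular surface centroid
#' (the origin) toward the volume centroid of the whole bone.  For the first
#' metatarsal (`variant = "MT1"`), the proximal surface is split into dorsal
#' and plantar halves and the lateral extremum of each half is found; the ML
#' axis points from the origin to the midpoint of the two extrema,
#' orthogonalized against PD and oriented medial; DP completes the frame
#' (oriented dorsal).  For the second metatarsal (`"MT2"`), the plantar
#' extremum of the proximal surface defines the DP axis (negated to point
#' dorsal) and ML completes the frame.
#'
#' @param prox proximal articular `surface_patch`.
#' @param bone the whole bone as a closed `surface_mesh`.
#' @param variant `"MT1"` or `"MT2"`.
#' @param dorsal_hint,lateral_hint approximate dorsal and lateral directions.
#' @param side `"left"` or `"right"`.
#' @return an `anatomic_frame`.
#' @export
metatarsal_frame <- function(prox, bone, variant = c("MT1", "MT2"),
                             dorsal_hint, lateral_hint,
                             side = c("right", "left")) {
  variant <- match.arg(variant)
  side <- match.arg(side)
  cp <- surface_centroid(prox)
  cb <- volume_centroid(bone)
  if (sqrt(sum((cb - cp)^2)) < 1e-6) stop("degenerate PD axis")
  pd <- unit(cb - cp)                        # proximal surface -> shaft
  check_hint(dorsal_hint, pd)
  dors <- orth_unit(dorsal_hint, pd)
  P <- patch_vertices(prox)
  if (variant == "MT1") {
    check_hint(lateral_hint, pd, "lateral")
    lat <- orth_unit(lateral_hint, pd)
    h <- as.numeric(sweep(P, 2L, cp) %*% dors)
    dorsal_half <- P[h >= 0, , drop = FALSE]
    plantar_half <- P[h < 0, , drop = FALSE]
    if (nrow(dorsal_half) == 0L || nrow(plantar_half) == 0L)
      stop("cannot split proximal surface into dorsal/plantar halves")
    e1 <- directional_extremum(dorsal_half, lat)$point
    e2 <- directional_extremum(plantar_half, lat)$point
    ml_raw <- (e1 + e2) / 2 - cp
    ml <- -orth_unit(ml_raw, pd)             # extrema are lateral; ML medial
    dp <- cross3(pd, ml)
    if (identical(side, "left")) dp <- -dp
    dp <- unit(dp)
    if (sum(dp * dors) < 0) {
      warning("orientation hints inconsistent with side; trusting dorsal hint")
      dp <- -dp
    }
    return(new_frame(cp, ml, dp, pd, side, "metatarsal1"))
  }
  # MT2: plantar extremum defines DP
  e <- directional_extremum(P, -dors)$point
  dp <- -orth_unit(e - cp, pd)               # negate to point dorsal
  ml <- complete_ml(dp, pd, side)
  new_frame(cp, ml, dp, pd, side, "metatarsal2")
}

#' Coordinates of points in an anatomic frame
#' @param points n x 3 matrix (mm).
#' @param frame an `anatomic_frame`.
#' @return n x 3 matrix with columns `ml`, `dp`, `pd`.
#' @export
frame_coords <- function(points, frame) {
  points <- rbind(points)
  d <- sweep(points, 2L, frame$origin)
  out <- cbind(ml = as.numeric(d %*% frame$axis_ml),
               dp = as.numeric(d %*% frame$axis_dp),
               pd = as.numeric(d %*% frame$axis_pd))
  out
}

#' Serialize an anatomic frame to JSON
#' @param frame an `anatomic_frame`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
frame_to_json <- function(frame, path = NULL) {
  js <- jsonlite::toJSON(unclass(frame), digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}

#' Read an anatomic frame from JSON
#' @param path JSON file path (or JSON string).
#' @export
frame_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  new_frame(x$origin, x$axis_ml, x$axis_dp, x$axis_pd, x$side, x$bone)
}
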