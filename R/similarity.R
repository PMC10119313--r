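# Curvature similarity between opposing articular surfaces.
#
# The statistic maps a pair of signed Gaussian curvature means (k_cun, k_met)
# to a value in [-1, 1]:
#
#   value = -sign(k_cun * k_met) / (1 + |log|k_cun / k_met||)
#
# +1 means equal magnitudes with matched curvature (one concave and one
# convex surface, a congruent pairing); -1 equal magnitudes with mismatched
# curvature (two concave or two convex); values shrink toward 0 as the
# magnitudes diverge.  The logarithm is natural by default; the base only
# changes the decay rate, not the +-1 landmarks.  When either curvature is
# numerically zero (|k| < eps) the value is defined as 0 — the statistic
# carries no information on flat surfaces.

#' Curvature similarity of an opposing surface pair
#'
#' @param k_cun,k_met signed Gaussian curvature means (1/mm^2) of the two
#'   opposing surfaces; vectorized.
#' @param base logarithm base (default natural).
#' @param eps magnitude below which a curvature counts as zero.
#' @return similarity value(s) in `[-1, 1]`.
#' @export
curvature_similarity <- function(k_cun, k_met, base = exp(1), eps = 1e-9) {
  if (any(!is.finite(k_cun)) || any(!is.finite(k_met)))
    stop("non-finite curvature input")
  v <- -sign(k_cun * k_met) / (1 + abs(log(abs(k_cun / k_met), base = base)))
  v[abs(k_cun) < eps | abs(k_met) < eps] <- 0
  v
}

#' Whole-joint and quadrant curvature similarity
#'
#' Computes the area-weighted mean signed Gaussian curvature of each surface
#' for the whole patch and each anatomical quadrant, pairs quadrants by
#' identical label, and applies [curvature_similarity()] to each pair.
#' Regions missing on either side are flagged absent.
#'
#' @param cun,met lists with elements `patch` (a `surface_patch`), `field`
#'   (a `curvature_field` on the patch's mesh) and `frame` (an
#'   `anatomic_frame` with origin at the patch centroid).
#' @param base logarithm base passed to [curvature_similarity()].
#' @return data.frame with columns `region`, `k_cun`, `k_met`, `value`,
#'   `present`; regions are `whole` plus the four quadrants.
#' @export
joint_similarity <- function(cun, met, base = exp(1)) {
  region_means <- function(side) {
    quads <- quadrant_split(side$patch, side$frame)
    vals <- c(whole = region_mean_curvature(side$field, side$patch))
    for (q in names(quads)) {
      vals[q] <- if (is.null(quads[[q]])) NA_real_
                 else region_mean_curvature(side$field, quads[[q]])
    }
    vals
  }
  kc <- suppressWarnings(region_means(cun))
  km <- suppressWarnings(region_means(met))
  regions <- names(kc)
  present <- !is.na(kc) & !is.na(km)
  value <- rep(NA_real_, length(regions))
  value[present] <- curvature_similarity(kc[present], km[present], base = base)
  data.frame(region = regions, k_cun = as.numeric(kc), k_met = as.numeric(km),
             value = value, present = present, row.names = NULL)
}
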