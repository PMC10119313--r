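# Synthetic phantoms with analytic ground truth.
#
# Phantom bones are closed prism-like solids whose two end caps are
# spherical patches (constant curvature) over elliptical extents, joined to
# an elliptical-cylinder body by a tangent-continuous circular fillet of
# prescribed rim radius.  Every quantity the pipeline later estimates —
# cap membership, cap curvature, anatomic frame, extents, width contour —
# is known in closed form by construction.  Primitive meshes (sphere,
# ellipsoid, cylinder, saddle, plane) provide curvature test fixtures.

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# ---- primitives ----

#' Icosphere (subdivided icosahedron projected to a sphere)
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 subdivisions of the icosahedron.
#' @param center sphere center.
#' @return a closed `surface_mesh`.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  V <- V / sqrt(rowSums(V^2))
  for (s in seq_len(subdivisions)) {
    e <- rbind(F[, 1:2], F[, 2:3], F[, c(3L, 1L)])
    ek <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    key <- paste(ek[, 1L], ek[, 2L])
    uk <- !duplicated(key)
    mid_id <- nrow(V) + match(key, key[uk])
    mids <- (V[ek[uk, 1L], , drop = FALSE] + V[ek[uk, 2L], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    V <- rbind(V, mids)
    m <- nrow(F)
    m12 <- mid_id[seq_len(m)]
    m23 <- mid_id[m + seq_len(m)]
    m31 <- mid_id[2L * m + seq_len(m)]
    F <- rbind(cbind(F[, 1L], m12, m31),
               cbind(F[, 2L], m23, m12),
               cbind(F[, 3L], m31, m23),
               cbind(m12, m23, m31))
  }
  V <- sweep(V * radius, 2L, center, "+")
  surface_mesh(V, F)
}

# rectangular height-field patch (open mesh)
grid_patch <- function(xs, ys, fz) {
  g <- expand.grid(x = xs, y = ys)
  V <- cbind(g$x, g$y, fz(g$x, g$y))
  nx <- length(xs)
  ny <- length(ys)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  F <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  surface_mesh(V, F, validate = TRUE, orient = FALSE)
}

# rows of ntheta points each, capped by apex vertices; consistent winding
assemble_rows <- function(apex_top, rows, apex_bot) {
  ntheta <- nrow(rows[[1L]])
  V <- rbind(apex_top, do.call(rbind, rows), apex_bot)
  idx <- function(r) 1L + (r - 1L) * ntheta + seq_len(ntheta)
  Fs <- list()
  r1 <- idx(1L)
  Fs[[1L]] <- cbind(1L, r1, c(r1[-1L], r1[1L]))
  for (r in seq_len(length(rows) - 1L)) {
    a <- idx(r); b <- idx(r + 1L)
    a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
    Fs[[length(Fs) + 1L]] <- cbind(a, b, b2)
    Fs[[length(Fs) + 1L]] <- cbind(a, b2, a2)
  }
  last <- idx(length(rows))
  Fs[[length(Fs) + 1L]] <- cbind(nrow(V), c(last[-1L], last[1L]), last)
  list(V = V, F = do.call(rbind, Fs))
}

#' Analytic test primitives
#'
#' Meshes with curvature known in closed form at every vertex: `sphere`,
#' `ellipsoid` and `cylinder` are closed; `saddle` (z = (x^2 - y^2) / (2R))
#' and `plane` are open patches.  The analytic principal curvatures (where
#' uniquely defined) are attached as the `analytic` attribute, in the
#' convex-negative convention.
#'
#' @param kind primitive type.
#' @param params named list of dimensions (mm): sphere `radius`; ellipsoid
#'   `a`, `b`, `c`; cylinder `radius`, `height`; saddle `R`, `half_extent`;
#'   plane `half_extent`.
#' @param resolution target edge length (mm).
#' @return a `surface_mesh`, with attribute `analytic` (list with per-vertex
#'   `k1`, `k2` where defined, `NA` elsewhere).
#' @export
make_primitive <- function(kind = c("sphere", "ellipsoid", "cylinder",
                                    "saddle", "plane"),
                           params = list(), resolution = 0.3) {
  kind <- match.arg(kind)
  if (resolution <= 0) stop("resolution must be positive")
  p <- params
  chk <- function(x) if (is.null(x) || any(x <= 0)) stop("non-positive dimension")
  if (kind == "sphere") {
    chk(p$radius)
    n <- max(1L, ceiling(log2(1.05146 * p$radius / resolution)))
    mesh <- icosphere(p$radius, n)
    nv <- nrow(mesh$vertices)
    attr(mesh, "analytic") <- list(k1 = rep(-1 / p$radius, nv),
                                   k2 = rep(-1 / p$radius, nv))
    return(mesh)
  }
  if (kind == "ellipsoid") {
    chk(c(p$a, p$b, p$c))
    n <- max(1L, ceiling(log2(1.05146 * max(p$a, p$b, p$c) / resolution)))
    mesh <- icosphere(1, n)
    U <- mesh$vertices
    V <- cbind(U[, 1L] * p$a, U[, 2L] * p$b, U[, 3L] * p$c)
    mesh <- surface_mesh(V, mesh$faces)
    h <- U[, 1L]^2 / p$a^2 + U[, 2L]^2 / p$b^2 + U[, 3L]^2 / p$c^2
    K <- 1 / (p$a^2 * p$b^2 * p$c^2 * h^2)   # Gaussian curvature, convex
    attr(mesh, "analytic") <- list(K = K)
    return(mesh)
  }
  if (kind == "cylinder") {
    chk(c(p$radius, p$height))
    r <- p$radius; h <- p$height
    ntheta <- max(16L, ceiling(2 * pi * r / resolution))
    theta <- 2 * pi * seq_len(ntheta) / ntheta
    dxy <- cbind(cos(theta), sin(theta))
    nrc <- max(2L, ceiling(r / resolution))
    nz <- max(2L, ceiling(h / resolution))
    rows <- list()
    for (i in seq_len(nrc))               # top cap rings
      rows[[length(rows) + 1L]] <- cbind(dxy * (i / nrc * r), h / 2)
    for (j in seq_len(nz - 1L))           # body rows (top ring already there)
      rows[[length(rows) + 1L]] <- cbind(dxy * r, h / 2 - j / nz * h)
    for (i in seq(nrc, 1L))               # bottom cap rings
      rows[[length(rows) + 1L]] <- cbind(dxy * (i / nrc * r), -h / 2)
    asm <- assemble_rows(c(0, 0, h / 2), rows, c(0, 0, -h / 2))
    mesh <- surface_mesh(asm$V, asm$F)
    nv <- nrow(mesh$vertices)
    # analytic: caps flat, body k1 = 0, k2 = -1/r; rims undefined (NA)
    k1 <- rep(NA_real_, nv); k2 <- rep(NA_real_, nv)
    z <- mesh$vertices[, 3L]
    rho <- sqrt(mesh$vertices[, 1L]^2 + mesh$vertices[, 2L]^2)
    on_cap <- abs(abs(z) - h / 2) < 1e-9 & rho < r - 1e-9
    on_body <- abs(rho - r) < 1e-9 & abs(z) < h / 2 - 1e-9
    k1[on_cap] <- 0; k2[on_cap] <- 0
    k1[on_body] <- 0; k2[on_body] <- -1 / r
    attr(mesh, "analytic") <- list(k1 = k1, k2 = k2)
    return(mesh)
  }
  if (kind == "saddle") {
    chk(p$R)
    he <- if (is.null(p$half_extent)) p$R / 2 else p$half_extent
    chk(he)
    xs <- seq(-he, he, length.out = max(3L, ceiling(2 * he / resolution) + 1L))
    mesh <- grid_patch(xs, xs, function(x, y) (x^2 - y^2) / (2 * p$R))
    # Gaussian at the apex: -1/R^2
    attr(mesh, "analytic") <- list(K_origin = -1 / p$R^2)
    return(mesh)
  }
  # plane
  he <- if (is.null(p$half_extent)) 5 else p$half_extent
  chk(he)
  xs <- seq(-he, he, length.out = max(3L, ceiling(2 * he / resolution) + 1L))
  mesh <- grid_patch(xs, xs, function(x, y) rep(0, length(x)))
  nv <- nrow(mesh$vertices)
  attr(mesh, "analytic") <- list(k1 = rep(0, nv), k2 = rep(0, nv))
  mesh
}

# ---- phantom bones ----

# 2-D profile of one end in (rho, zeta): spherical cap of signed curvature k
# over an elliptical extent, tangent-continuous fillet of radius rr, wall
# start.  All quantities vectorized over theta.
end_profile <- function(k, A, B, rr, theta) {
  rho_b <- sqrt((A * cos(theta))^2 + (B * sin(theta))^2)
  rho_max <- max(A, B)
  if (abs(k) < 1e-12) {
    zeta_cap <- function(rho) rep(0, length(rho))
    Fc_rho <- rho_b
    Fc_zeta <- rep(-rr, length(theta))
    a0 <- rep(pi / 2, length(theta))
    geom <- list(s = 0, R = Inf, A = A, B = B, center_zeta = NA_real_)
  } else {
    s <- sign(k)
    R <- 1 / sqrt(abs(k))
    if (R < 1.05 * rho_max)
      stop(sprintf("cap curvature too high for extent: |k| = %.4g needs R >= %.3g mm",
                   abs(k), 1.05 * rho_max))
    if (s > 0 && R <= rr) stop("convex cap radius must exceed the rim radius")
    D <- sqrt(R^2 - rho_max^2)
    zeta_cap <- function(rho) s * (sqrt(R^2 - rho^2) - D)
    cc <- sqrt(R^2 - rho_b^2)
    if (s > 0) {
      Fc_rho <- (R - rr) * rho_b / R
      Fc_zeta <- -D + (R - rr) * cc / R
      a0 <- atan2(cc / R, rho_b / R)
    } else {
      Fc_rho <- (R + rr) * rho_b / R
      Fc_zeta <- D - (R + rr) * cc / R
      a0 <- atan2(cc / R, -rho_b / R)
    }
    geom <- list(s = s, R = R, A = A, B = B, center_zeta = -s * D)
  }
  list(rho_b = rho_b, zeta_cap = zeta_cap, Fc_rho = Fc_rho,
       Fc_zeta = Fc_zeta, a0 = a0, wall_rho = Fc_rho + rr,
       wall_zeta = Fc_zeta, geom = geom)
}

#' Generate a phantom bone with analytic ground truth
#'
#' A closed prism-like solid with two spherical-patch end caps (the proximal
#' cap at +z, the distal at -z; the global z axis points proximal, i.e.
#' decreases distal-ward) of prescribed signed Gaussian curvature and
#' elliptical extents, joined to the body by a rounded rim of principal
#' curvature magnitude `1/rim_radius`.  All ground-truth fields (cap face
#' sets, curvatures, extents, anatomic frame, analytic cap geometry) are
#' populated by construction.
#'
#' @param body_length distance between the two cap reference planes (mm).
#' @param cap_specs list with `proximal` and `distal`, each a list with `k`
#'   (signed Gaussian curvature, 1/mm^2; positive = convex), `width` and
#'   `height` (mm).
#' @param rim_radius fillet radius (mm); its curvature `1/rim_radius` should
#'   be at least twice the intended extraction threshold magnitude.
#' @param resolution target edge length (mm).
#' @param seed optional integer; randomizes the azimuthal mesh phase (the
#'   same seed reproduces the mesh exactly).
#' @param bone bone label (determines which cap is the analyzed articular
#'   surface: distal for cuneiforms, proximal for metatarsals).
#' @param side `"left"` or `"right"`.
#' @return an object of class `phantom_bone`: list with `mesh`, `truth`
#'   (caps, curvature, extents, frame, cap_geom, pose), `bone`, `side`.
#' @export
make_phantom_bone <- function(body_length = 14,
                              cap_specs = list(
                                proximal = list(k = 0, width = 14, height = 20),
                                distal = list(k = 0.002, width = 14, height = 20)),
                              rim_radius = 2, resolution = 0.3, seed = NULL,
                              bone = "medial_cuneiform",
                              side = c("right", "left")) {
  side <- match.arg(side)
  if (rim_radius <= 0) stop("rim_radius must be positive")
  if (body_length <= 0) stop("body_length must be positive")
  if (resolution <= 0) stop("resolution must be positive")
  for (end in c("proximal", "distal")) {
    sp <- cap_specs[[end]]
    if (is.null(sp) || any(c(sp$width, sp$height) <= 0))
      stop("cap widths and heights must be positive")
    if (abs(sp$k) > 0.25) stop("cap |curvature| must not exceed 0.25 1/mm^2")
  }
  Ap <- cap_specs$proximal$width / 2;  Bp <- cap_specs$proximal$height / 2
  Ad <- cap_specs$distal$width / 2;    Bd <- cap_specs$distal$height / 2

  per <- function(A, B) pi * (3 * (A + B) - sqrt((3 * A + B) * (A + 3 * B)))
  ntheta <- max(48L, ceiling(max(per(Ap + rim_radius, Bp + rim_radius),
                                 per(Ad + rim_radius, Bd + rim_radius)) / resolution))
  off <- if (is.null(seed)) 0 else with_seed(seed, runif(1))
  theta <- 2 * pi * (seq_len(ntheta) - 1L + off) / ntheta

  L2 <- body_length / 2
  ends <- list(
    proximal = list(spec = cap_specs$proximal, z0 = L2, zsgn = 1,
                    A = Ap, B = Bp),
    distal = list(spec = cap_specs$distal, z0 = -L2, zsgn = -1,
                  A = Ad, B = Bd))

  build_end <- function(e) {
    pr <- end_profile(e$spec$k, e$A, e$B, rim_radius, theta)
    dxy <- cbind(e$A * cos(theta), e$B * sin(theta)) / pr$rho_b
    # radial ring positions: uniform at `resolution` along the major
    # semi-axis, refined 3x in the outer band to resolve the rim transition
    rmax <- max(e$A, e$B)
    band <- min(1.5, rmax / 4)
    t_band <- 1 - band / rmax
    n1 <- max(2L, ceiling(t_band * rmax / resolution))
    n2 <- max(3L, ceiling(band / (resolution / 3)))
    ts <- c(seq(0, t_band, length.out = n1 + 1L)[-1L],
            seq(t_band, 1, length.out = n2 + 1L)[-1L])
    nr <- length(ts)
    nf <- max(4L, ceiling(rim_radius * pi / 2 / (resolution / 2)))
    rows <- vector("list", nr + nf)
    for (i in seq_len(nr)) {
      rho <- ts[i] * pr$rho_b
      rows[[i]] <- cbind(dxy * rho, e$z0 + e$zsgn * pr$zeta_cap(rho))
    }
    for (j in seq_len(nf)) {
      a <- pr$a0 * (1 - j / nf)
      rho <- pr$Fc_rho + rim_radius * cos(a)
      zeta <- pr$Fc_zeta + rim_radius * sin(a)
      rows[[nr + j]] <- cbind(dxy * rho, e$z0 + e$zsgn * zeta)
    }
    apex <- c(0, 0, e$z0 + e$zsgn * pr$zeta_cap(0))
    list(rows = rows, apex = apex, nr = nr, nf = nf,
         wall_xy = dxy * pr$wall_rho,
         wall_z = e$z0 + e$zsgn * pr$wall_zeta,
         geom = c(pr$geom, list(z0 = e$z0, zsgn = e$zsgn, k = e$spec$k)))
  }
  ep <- build_end(ends$proximal)
  ed <- build_end(ends$distal)
  if (min(ep$wall_z - ed$wall_z) < 2 * resolution)
    stop("body too short for the requested caps and rim radius")

  nw <- max(2L, ceiling(mean(ep$wall_z - ed$wall_z) / resolution))
  wall_rows <- lapply(seq_len(nw - 1L), function(j) {
    u <- j / nw
    cbind((1 - u) * ep$wall_xy + u * ed$wall_xy,
          (1 - u) * ep$wall_z + u * ed$wall_z)
  })
  rows <- c(ep$rows, wall_rows, rev(ed$rows))
  asm <- assemble_rows(ep$apex, rows, ed$apex)
  mesh <- surface_mesh(asm$V, asm$F, validate = TRUE, orient = TRUE)

  # ground-truth cap face sets from the construction layout
  cap_p_ids <- c(1L, 1L + seq_len(ep$nr * ntheta))
  n_rows_before_d <- length(ep$rows) + length(wall_rows) + ed$nf
  d_start <- 1L + n_rows_before_d * ntheta
  cap_d_ids <- c(d_start + seq_len(ed$nr * ntheta), nrow(asm$V))
  in_set <- function(ids) {
    m <- matrix(mesh$faces %in% ids, ncol = 3L)
    which(rowSums(m) == 3L)
  }
  caps <- list(proximal = in_set(cap_p_ids), distal = in_set(cap_d_ids))

  analyzed <- if (grepl("cuneiform", bone)) "distal" else "proximal"
  origin <- surface_centroid(surface_patch(mesh, caps[[analyzed]]))
  pd <- c(0, 0, -1)                 # z decreases distal-ward
  dp <- c(0, 1, 0)
  ml <- complete_ml(dp, pd, side)
  frame <- new_frame(origin, ml, dp, pd, side, bone)

  truth <- list(
    caps = caps,
    curvature = c(proximal = cap_specs$proximal$k,
                  distal = cap_specs$distal$k),
    extents = list(proximal = c(width = cap_specs$proximal$width,
                                height = cap_specs$proximal$height),
                   distal = c(width = cap_specs$distal$width,
                              height = cap_specs$distal$height)),
    frame = frame,
    analyzed_end = analyzed,
    cap_geom = list(proximal = ep$geom, distal = ed$geom),
    pose = list(rotation = diag(3), translation = c(0, 0, 0)))
  structure(list(mesh = mesh, truth = truth, bone = bone, side = side,
                 params = list(body_length = body_length,
                               cap_specs = cap_specs,
                               rim_radius = rim_radius,
                               resolution = resolution, seed = seed)),
            class = "phantom_bone")
}

#' @export
print.phantom_bone <- function(x, ...) {
  cat(sprintf("phantom_bone %s (%s): %d vertices, analyzed end %s, k = %.4g 1/mm^2\n",
              x$bone, x$side, nrow(x$mesh$vertices), x$truth$analyzed_end,
              x$truth$curvature[[x$truth$analyzed_end]]))
  invisible(x)
}

#' Apply a rigid motion to a phantom bone (pose recorded in the truth)
#' @param bone a `phantom_bone`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @export
transform_phantom_bone <- function(bone, rotation = diag(3),
                                   translation = c(0, 0, 0)) {
  bone$mesh <- transform_mesh(bone$mesh, rotation, translation)
  fr <- bone$truth$frame
  fr$origin <- as.numeric(rotation %*% fr$origin + translation)
  for (ax in c("axis_ml", "axis_dp", "axis_pd"))
    fr[[ax]] <- as.numeric(rotation %*% fr[[ax]])
  bone$truth$frame <- fr
  po <- bone$truth$pose
  bone$truth$pose <- list(rotation = rotation %*% po$rotation,
                          translation = as.numeric(rotation %*% po$translation + translation))
  bone
}

#' Ground-truth cap membership of mesh faces
#'
#' Classifies faces of a mesh (by face centroid) against the analytic cap
#' geometry of a phantom bone, honoring the recorded pose.  Used to score
#' extraction on remeshed or noisy variants of the phantom, where the
#' constructed face sets no longer apply.
#'
#' @param bone a `phantom_bone`.
#' @param end `"proximal"` or `"distal"`.
#' @param mesh mesh to classify (default: the phantom's own mesh).
#' @param tol distance tolerance to the analytic cap surface (mm).
#' @return integer vector of face indices.
#' @export
truth_cap_faces <- function(bone, end = c("distal", "proximal"), mesh = NULL,
                            tol = 0.3) {
  end <- match.arg(end)
  if (is.null(mesh)) mesh <- bone$mesh
  g <- bone$truth$cap_geom[[end]]
  po <- bone$truth$pose
  F <- mesh$faces
  cen <- (mesh$vertices[F[, 1L], , drop = FALSE] +
            mesh$vertices[F[, 2L], , drop = FALSE] +
            mesh$vertices[F[, 3L], , drop = FALSE]) / 3
  loc <- sweep(cen, 2L, po$translation) %*% po$rotation  # R^T (p - t)
  x <- loc[, 1L]; y <- loc[, 2L]
  zeta <- g$zsgn * (loc[, 3L] - g$z0)
  in_ell <- sqrt((x / g$A)^2 + (y / g$B)^2) <= 1 + tol / min(g$A, g$B)
  on_surf <- if (g$s == 0) abs(zeta) <= tol else {
    rho <- sqrt(x^2 + y^2)
    abs(sqrt(rho^2 + (zeta - g$center_zeta)^2) - g$R) <= tol
  }
  which(in_ell & on_surf)
}

# ---- joint phantoms ----

#' Generate an opposing joint pair with closed-form similarity
#'
#' Builds a cuneiform-like and a metatarsal-like phantom bone whose analyzed
#' caps carry the prescribed signed Gaussian curvatures, posed facing each
#' other with the given joint space (apex-to-apex along the joint axis).
#' The ground-truth curvature similarity is the closed form
#' [curvature_similarity()] of `(k_cun, k_met)`.
#'
#' @param k_cun,k_met signed cap curvatures (1/mm^2) of the cuneiform distal
#'   and metatarsal proximal surfaces.
#' @param gap joint space (mm), > 0.
#' @param extents list with `cun` and `met`, each `c(width, height)` in mm.
#' @param resolution target edge length (mm).
#' @param joint `"TMT1"` (medial cuneiform vs first metatarsal) or `"TMT2"`.
#' @param side `"left"` or `"right"`.
#' @param body_length per-bone body length (mm).
#' @param seed optional integer mesh-phase seed.
#' @return an object of class `joint_phantom`.
#' @export
make_joint_phantom <- function(k_cun, k_met, gap = 2,
                               extents = list(cun = c(width = 18.2, height = 29.21),
                                              met = c(width = 17.59, height = 28.53)),
                               resolution = 0.3,
                               joint = c("TMT1", "TMT2"),
                               side = c("right", "left"),
                               body_length = 14, seed = NULL) {
  joint <- match.arg(joint)
  side <- match.arg(side)
  if (gap <= 0) stop("gap must be positive")
  cun_label <- if (joint == "TMT1") "medial_cuneiform" else "intermediate_cuneiform"
  met_label <- if (joint == "TMT1") "metatarsal1" else "metatarsal2"
  thr <- default_thresholds()
  rr_cun <- 1 / (2 * abs(thr[[cun_label]]))
  rr_met <- 1 / (2 * abs(thr[[met_label]]))
  sec <- 0.85  # non-analyzed caps: flat, slightly smaller
  cun <- make_phantom_bone(
    body_length = body_length,
    cap_specs = list(
      proximal = list(k = 0, width = sec * extents$cun[["width"]],
                      height = sec * extents$cun[["height"]]),
      distal = list(k = k_cun, width = extents$cun[["width"]],
                    height = extents$cun[["height"]])),
    rim_radius = rr_cun, resolution = resolution, seed = seed,
    bone = cun_label, side = side)
  met <- make_phantom_bone(
    body_length = body_length,
    cap_specs = list(
      proximal = list(k = k_met, width = extents$met[["width"]],
                      height = extents$met[["height"]]),
      distal = list(k = 0, width = sec * extents$met[["width"]],
                    height = sec * extents$met[["height"]])),
    rim_radius = rr_met, resolution = resolution,
    seed = if (is.null(seed)) NULL else seed + 1L,
    bone = met_label, side = side)
  # pose: cuneiform above (+z, its distal cap facing down), metatarsal below
  apex_cun <- min(cun$mesh$vertices[, 3L])
  apex_met <- max(met$mesh$vertices[, 3L])
  cun <- transform_phantom_bone(cun, diag(3), c(0, 0, gap / 2 - apex_cun))
  met <- transform_phantom_bone(met, diag(3), c(0, 0, -gap / 2 - apex_met))
  structure(list(cuneiform = cun, metatarsal = met,
                 k_cun = k_cun, k_met = k_met, gap = gap, joint = joint,
                 side = side,
                 truth_similarity = curvature_similarity(k_cun, k_met)),
            class = "joint_phantom")
}

#' Apply a rigid motion to a joint phantom (both bones)
#' @param jp a `joint_phantom`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @export
transform_joint_phantom <- function(jp, rotation = diag(3),
                                    translation = c(0, 0, 0)) {
  jp$cuneiform <- transform_phantom_bone(jp$cuneiform, rotation, translation)
  jp$metatarsal <- transform_phantom_bone(jp$metatarsal, rotation, translation)
  jp
}

# ---- degradation operators ----

#' Voxelize and re-triangulate a mesh
#'
#' Emulates image-based segmentation: the closed mesh is converted to a
#' binary occupancy grid at the given voxel pitch by z-column ray parity,
#' the occupancy field is lightly smoothed (two passes of a 3-point box
#' filter per axis), and the 0.5 isosurface is re-triangulated by surface
#' nets.  The output is watertight and outward-oriented.
#'
#' @param mesh a closed `surface_mesh`.
#' @param voxel voxel pitch (mm), > 0 and smaller than the smallest feature.
#' @return a `surface_mesh`.
#' @export
voxelize_remesh <- function(mesh, voxel) {
  if (!is.numeric(voxel) || voxel <= 0) stop("voxel must be positive")
  vox <- cpp_voxelize_occupancy(mesh$vertices, mesh$faces, voxel, 4L)
  if (sum(vox$field) == 0)
    stop("voxelization produced an empty volume (voxel larger than object?)")
  sm <- cpp_smooth_field(vox$field, vox$dims, 2L)
  iso <- cpp_surface_nets(sm, vox$dims, vox$origin, voxel, 0.5)
  if (nrow(iso$faces) == 0L) stop("isosurface is empty")
  surface_mesh(iso$vertices, iso$faces, validate = TRUE, orient = TRUE)
}

#' Displace vertices along their normals by seeded uniform noise
#' @param mesh a `surface_mesh`.
#' @param amplitude maximum displacement (mm), >= 0.
#' @param seed integer RNG seed.
#' @return a `surface_mesh`.
#' @export
add_vertex_noise <- function(mesh, amplitude, seed = 1L) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(mesh)
  N <- cpp_vertex_normals(mesh$vertices, mesh$faces)
  u <- with_seed(seed, runif(nrow(mesh$vertices), -amplitude, amplitude))
  surface_mesh(mesh$vertices + u * N, mesh$faces,
               validate = FALSE, orient = FALSE)
}
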