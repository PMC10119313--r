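# Cohort pipeline: orchestrates extraction -> frames -> morphometry ->
# curvature -> similarity over a manifest of bone meshes and emits
# cohort-level report tables and the statistics battery.

#' Pipeline configuration
#'
#' @param thresholds named per-bone extraction thresholds (1/mm, negative);
#'   see [default_thresholds()].
#' @param gaussian_radius fitting radius (mm) for the Gaussian-curvature
#'   stage computed on the exported articular surface (default 10 mm,
#'   approximately half the articular surface height).
#' @param extraction_radius fitting radius (mm) for the extraction-stage
#'   curvature on the whole bone (default 1.5 mm).
#' @param profile_step width-profile height spacing (mm, default 2).
#' @param min_n minimum sample size for a height to enter the filtered
#'   profile table (default: half the per-bone cohort size).
#' @param log_base logarithm base of the similarity statistic (default
#'   natural).
#' @param seed seed recorded for provenance.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = default_thresholds(),
                            gaussian_radius = 10, extraction_radius = 1.5,
                            profile_step = 2, min_n = NULL,
                            log_base = exp(1), seed = 1L) {
  stopifnot(all(thresholds < 0), gaussian_radius > 0, extraction_radius > 0,
            profile_step > 0, is.null(min_n) || min_n >= 1)
  structure(list(thresholds = thresholds, gaussian_radius = gaussian_radius,
                 extraction_radius = extraction_radius,
                 profile_step = profile_step, min_n = min_n,
                 log_base = log_base, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  for (nm in names(y)) defaults[[nm]] <- y[[nm]]
  if (!is.null(y$thresholds)) defaults$thresholds <- unlist(y$thresholds)
  do.call(pipeline_config, unclass(defaults))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rand_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# cohort generation conditions: Table-1-scale extents per bone; cap
# curvature magnitudes drawn in the spherical-cap-feasible band for the
# drawn extents; half the joints congruent (convex-on-concave), half
# mismatched (convex-on-convex)
cohort_bone_params <- list(
  TMT1 = list(cun = list(w = 18.20, w_sd = 1.98, h = 29.21, h_sd = 1.63),
              met = list(w = 17.59, w_sd = 1.58, h = 28.53, h_sd = 1.57)),
  TMT2 = list(cun = list(w = 13.26, w_sd = 1.23, h = 21.85, h_sd = 2.03),
              met = list(w = 12.48, w_sd = 1.08, h = 20.59, h_sd = 2.09)))

#' Generate a phantom cohort on disk
#'
#' Draws a seeded cohort of joint phantoms (alternating first and second
#' tarsometatarsal joints and sides), poses each joint by a random rigid
#' motion, writes the bone meshes as PLY plus a cohort manifest and ground
#' truth tables, and returns everything invisibly.
#'
#' @param dir output directory (created if needed).
#' @param n_joints number of joint phantoms (default 24).
#' @param seed integer RNG seed for all draws.
#' @param resolution target mesh edge length (mm, default 0.3).
#' @param gap joint space (mm).
#' @param write write meshes and CSVs (default TRUE; FALSE returns the
#'   objects only).
#' @return (invisibly) list with `manifest`, `truth_bones`, `truth_joints`
#'   data.frames and the list of posed `joint_phantom` objects.
#' @export
phantom_cohort <- function(dir = tempfile("phantoms"), n_joints = 24,
                           seed = 7L, resolution = 0.3, gap = 2,
                           write = TRUE) {
  if (write) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # bilateral design: consecutive joints share a donor (same joint type,
  # right then left), so side is not aliased with the specimen factor
  joints <- rep(rep(c("TMT1", "TMT2"), each = 2), length.out = n_joints)
  sides <- rep(c("right", "left"), length.out = n_joints)
  donors <- sprintf("D%02d", ceiling(seq_len(n_joints) / 2))
  congruent <- rep(c(TRUE, FALSE), each = 2, length.out = n_joints)
  out <- with_seed(seed, {
    lapply(seq_len(n_joints), function(i) {
      jp_type <- joints[i]
      pp <- cohort_bone_params[[jp_type]]
      draw <- function(m, s) clamp(rnorm(1, m, s), m - 2 * s, m + 2 * s)
      cw <- draw(pp$cun$w, pp$cun$w_sd); ch <- draw(pp$cun$h, pp$cun$h_sd)
      mw <- draw(pp$met$w, pp$met$w_sd); mh <- draw(pp$met$h, pp$met$h_sd)
      kmax <- function(w, h) (1 / (1.10 * max(w, h) / 2))^2
      k_cun <- runif(1, 0.35, 0.8) * kmax(cw, ch)
      k_met <- runif(1, 0.35, 0.8) * kmax(mw, mh)
      if (congruent[i]) k_met <- -k_met   # concave metatarsal: congruent pair
      jitter_seed <- sample.int(2^30, 1L)
      rot <- rand_rotation()
      tra <- runif(3, -20, 20)
      jp <- make_joint_phantom(k_cun, k_met, gap = gap,
                               extents = list(cun = c(width = cw, height = ch),
                                              met = c(width = mw, height = mh)),
                               resolution = resolution, joint = jp_type,
                               side = sides[i], seed = jitter_seed)
      transform_joint_phantom(jp, rot, tra)
    })
  })
  manifest <- list(); truth_b <- list(); truth_j <- list()
  for (i in seq_along(out)) {
    jp <- out[[i]]
    spec <- sprintf("S%02d", i)
    for (role in c("cuneiform", "metatarsal")) {
      pb <- jp[[role]]
      path <- file.path(dir, sprintf("%s_%s.ply", spec, pb$bone))
      if (write) write_mesh(pb$mesh, path, format = "ply")
      fr <- pb$truth$frame
      seed_of <- function(end) {
        fs <- pb$truth$caps[[end]]
        surface_centroid(surface_patch(pb$mesh, fs))
      }
      sp <- seed_of("proximal"); sd_ <- seed_of("distal")
      lat <- -fr$axis_ml
      an <- pb$truth$analyzed_end
      manifest[[length(manifest) + 1L]] <- data.frame(
        specimen = spec, donor = donors[i], joint = jp$joint, bone = pb$bone,
        role = role, side = pb$side, path = path,
        dorsal_hint_x = fr$axis_dp[1], dorsal_hint_y = fr$axis_dp[2],
        dorsal_hint_z = fr$axis_dp[3],
        lateral_hint_x = lat[1], lateral_hint_y = lat[2], lateral_hint_z = lat[3],
        seed_prox_x = sp[1], seed_prox_y = sp[2], seed_prox_z = sp[3],
        seed_dist_x = sd_[1], seed_dist_y = sd_[2], seed_dist_z = sd_[3],
        stringsAsFactors = FALSE)
      ext <- pb$truth$extents[[an]]
      truth_b[[length(truth_b) + 1L]] <- data.frame(
        specimen = spec, donor = donors[i], joint = jp$joint, bone = pb$bone,
        side = pb$side,
        analyzed_end = an, k_true = pb$truth$curvature[[an]],
        width_true = ext[["width"]], height_true = ext[["height"]],
        resolution = resolution,
        ml_x = fr$axis_ml[1], ml_y = fr$axis_ml[2], ml_z = fr$axis_ml[3],
        dp_x = fr$axis_dp[1], dp_y = fr$axis_dp[2], dp_z = fr$axis_dp[3],
        pd_x = fr$axis_pd[1], pd_y = fr$axis_pd[2], pd_z = fr$axis_pd[3],
        origin_x = fr$origin[1], origin_y = fr$origin[2], origin_z = fr$origin[3],
        stringsAsFactors = FALSE)
    }
    truth_j[[length(truth_j) + 1L]] <- data.frame(
      specimen = spec, joint = jp$joint, side = jp$side,
      k_cun = jp$k_cun, k_met = jp$k_met, gap = jp$gap,
      truth_similarity = jp$truth_similarity, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  truth_bones <- do.call(rbind, truth_b)
  truth_joints <- do.call(rbind, truth_j)
  if (write) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(truth_bones, file.path(dir, "truth_bones.csv"), row.names = FALSE)
    write.csv(truth_joints, file.path(dir, "truth_joints.csv"), row.names = FALSE)
  }
  invisible(list(dir = dir, manifest = manifest, truth_bones = truth_bones,
                 truth_joints = truth_joints, joints = out))
}

row_hint <- function(row, prefix) {
  as.numeric(row[paste0(prefix, c("_x", "_y", "_z"))])
}

# one bone: read, curvature, extract analyzed (and proximal for cuneiforms),
# frame, morphometry, Gaussian stage on the exported surface part
process_bone <- function(row, config) {
  mesh <- read_mesh(row$path)
  field <- principal_curvatures(mesh, config$extraction_radius)
  thr <- config$thresholds[[row$bone]]
  if (is.null(thr) || is.na(thr)) stop("no threshold for bone: ", row$bone)
  is_cun <- grepl("cuneiform", row$bone)
  analyzed_end <- if (is_cun) "distal" else "proximal"
  lbl <- list(bone = row$bone, end = analyzed_end, side = row$side)
  seed_pt <- row_hint(row, if (is_cun) "seed_dist" else "seed_prox")
  patch <- extract_articular_surface(mesh, field, thr, seed_point = seed_pt,
                                     label = lbl)
  dorsal <- row_hint(row, "dorsal_hint")
  lateral <- row_hint(row, "lateral_hint")
  if (is_cun) {
    prox <- extract_articular_surface(mesh, field, thr,
                                      seed_point = row_hint(row, "seed_prox"),
                                      label = list(bone = row$bone,
                                                   end = "proximal",
                                                   side = row$side))
    variant <- if (row$bone == "medial_cuneiform") "medial" else "intermediate"
    frame <- cuneiform_frame(prox, patch, variant, dorsal, row$side)
  } else {
    variant <- if (row$bone == "metatarsal1") "MT1" else "MT2"
    frame <- metatarsal_frame(patch, mesh, variant, dorsal, lateral, row$side)
  }
  ext <- max_extents(patch, frame)
  prof <- width_profile(patch, frame, config$profile_step)
  sm <- patch_submesh(patch)
  gfield <- principal_curvatures(sm$mesh, config$gaussian_radius)
  quads <- suppressWarnings(quadrant_split(sm$patch, frame))
  region_k <- c(whole = region_mean_curvature(gfield, sm$patch))
  for (q in names(quads))
    region_k[q] <- if (is.null(quads[[q]])) NA_real_ else
      suppressWarnings(region_mean_curvature(gfield, quads[[q]]))
  list(mesh = mesh, patch = patch, frame = frame, area = patch_area(patch),
       extents = ext, profile = prof, submesh = sm, gfield = gfield,
       region_k = region_k)
}

summarize_groups <- function(df, by, value) {
  sp <- split(df[[value]], df[by], drop = TRUE, sep = "\x01")
  keys <- strsplit(names(sp), "\x01", fixed = TRUE)
  rows <- lapply(seq_along(sp), function(i) {
    v <- sp[[i]][!is.na(sp[[i]])]
    key <- setNames(as.list(keys[[i]]), by)
    if (length(v) >= 2L) {
      s <- summary_ci(v)
      data.frame(key, metric = value, n = length(v), mean = s$estimate,
                 sd = s$statistic, ci_low = s$ci_low, ci_high = s$ci_high,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(key, metric = value, n = length(v),
                 mean = if (length(v)) v else NA_real_, sd = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Run the full analysis over a cohort manifest
#'
#' Per specimen: articular-surface extraction, anatomic frames, size and
#' width-profile morphometry, Gaussian curvature of whole surfaces and
#' quadrants, and per-joint curvature similarity; then cohort summary tables
#' (size, profiles, curvature, similarity) and the statistics battery.
#' Specimens failing any stage are logged and excluded; the run fails only
#' if every specimen fails.
#'
#' @param manifest data.frame or CSV path (see [phantom_cohort()] for the
#'   column layout).
#' @param config a [pipeline_config()].
#' @param outdir output directory for the report bundle; `NULL` to skip
#'   writing.
#' @return list with `tables` (size, profiles, profiles_full, curvature,
#'   similarity, stats), `measurements` (per-specimen tidy data),
#'   `details` (per-bone patches/frames for validation), `failures`,
#'   `config`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), outdir = NULL) {
  t_start <- proc.time()[["elapsed"]]
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  specs <- unique(manifest$specimen)
  size_rows <- list(); prof_rows <- list(); curv_rows <- list()
  sim_rows <- list(); details <- list(); failures <- list()
  timings <- list()
  for (spec in specs) {
    rows <- manifest[manifest$specimen == spec, , drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      cun_row <- rows[rows$role == "cuneiform", , drop = FALSE][1, ]
      met_row <- rows[rows$role == "metatarsal", , drop = FALSE][1, ]
      cun <- process_bone(cun_row, config)
      met <- process_bone(met_row, config)
      sim <- joint_similarity(
        cun = list(patch = cun$submesh$patch, field = cun$gfield,
                   frame = cun$frame),
        met = list(patch = met$submesh$patch, field = met$gfield,
                   frame = met$frame),
        base = config$log_base)
      list(cun = cun, met = met, cun_row = cun_row, met_row = met_row,
           sim = sim)
    }, error = function(e) e)
    timings[[spec]] <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures[[spec]] <- conditionMessage(res)
      next
    }
    for (role in c("cun", "met")) {
      b <- res[[role]]
      row <- res[[paste0(role, "_row")]]
      donor <- if ("donor" %in% names(row)) row$donor else spec
      size_rows[[length(size_rows) + 1L]] <- data.frame(
        specimen = spec, donor = donor, joint = row$joint, bone = row$bone,
        side = row$side, role = row$role, area = b$area,
        width = b$extents[["width"]], height = b$extents[["height"]],
        stringsAsFactors = FALSE)
      pr <- b$profile
      prof_rows[[length(prof_rows) + 1L]] <- data.frame(
        specimen = spec, joint = row$joint, bone = row$bone, side = row$side,
        pr, stringsAsFactors = FALSE)
      curv_rows[[length(curv_rows) + 1L]] <- data.frame(
        specimen = spec, donor = donor, joint = row$joint, bone = row$bone,
        side = row$side, region = names(b$region_k),
        K_signed = as.numeric(b$region_k), stringsAsFactors = FALSE)
    }
    sim_rows[[length(sim_rows) + 1L]] <- data.frame(
      specimen = spec,
      donor = if ("donor" %in% names(res$cun_row)) res$cun_row$donor else spec,
      joint = res$cun_row$joint, side = res$cun_row$side,
      res$sim, stringsAsFactors = FALSE)
    details[[spec]] <- list(
      cun = res$cun[c("patch", "frame", "area", "extents", "region_k")],
      met = res$met[c("patch", "frame", "area", "extents", "region_k")])
  }
  if (length(details) == 0L)
    stop("all specimens failed; first error: ", failures[[1]])
  size <- do.call(rbind, size_rows)
  profiles <- do.call(rbind, prof_rows)
  curv <- do.call(rbind, curv_rows)
  sims <- do.call(rbind, sim_rows)

  table1 <- do.call(rbind, lapply(c("area", "width", "height"), function(m)
    summarize_groups(size, "bone", m)))
  prof_sum <- do.call(rbind, lapply(
    c("medial_distance", "lateral_distance", "total_distance"),
    function(m) summarize_groups(profiles[profiles$present, ], c("bone", "height"), m)))
  prof_sum$height <- as.numeric(prof_sum$height)
  n_per_bone <- vapply(split(size$specimen, size$bone), length, 0L)
  min_n <- if (is.null(config$min_n)) ceiling(max(n_per_bone) / 2) else config$min_n
  table2 <- prof_sum[prof_sum$n >= min_n, , drop = FALSE]
  table3 <- summarize_groups(curv, c("bone", "region"), "K_signed")
  table4 <- summarize_groups(sims[sims$present, ], c("joint", "region"), "value")
  stats_tab <- cohort_stats(size, curv, sims)

  tables <- list(size = table1, profiles = table2, profiles_full = prof_sum,
                 curvature = table3, similarity = table4, stats = stats_tab)
  result <- list(tables = tables,
                 measurements = list(size = size, profiles = profiles,
                                     curvature = curv, similarity = sims),
                 details = details, failures = failures, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(table1, file.path(outdir, "table1_size.csv"), row.names = FALSE)
    write.csv(table2, file.path(outdir, "table2_profiles.csv"), row.names = FALSE)
    write.csv(prof_sum, file.path(outdir, "table2_profiles_full.csv"),
              row.names = FALSE)
    write.csv(table3, file.path(outdir, "table3_curvature.csv"), row.names = FALSE)
    write.csv(table4, file.path(outdir, "table4_similarity.csv"), row.names = FALSE)
    write.csv(stats_tab, file.path(outdir, "stats_report.csv"), row.names = FALSE)
    log_lines <- c("articmorph pipeline run",
                   paste0("time: ", format(Sys.time())),
                   "config:",
                   strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]],
                   sprintf("specimens: %d processed, %d failed",
                           length(details), length(failures)),
                   sprintf("  %s: %.2f s%s", names(timings),
                           unlist(timings),
                           ifelse(names(timings) %in% names(failures),
                                  paste0("  FAILED: ", unlist(failures[names(timings)[names(timings) %in% names(failures)]])[1], ""),
                                  "")),
                   sprintf("total: %.2f s", proc.time()[["elapsed"]] - t_start))
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  result
}

# the statistics battery over the cohort measurement tables
cohort_stats <- function(size, curv, sims) {
  out <- list()
  add <- function(analysis, context, df) {
    out[[length(out) + 1L]] <<- data.frame(analysis = analysis,
                                           context = context, df,
                                           stringsAsFactors = FALSE)
  }
  try_add <- function(analysis, context, expr)
    tryCatch(add(analysis, context, expr), error = function(e) invisible(NULL))

  # paired size comparisons: cuneiform vs metatarsal within each joint
  for (jt in unique(size$joint)) {
    sj <- size[size$joint == jt, ]
    for (m in c("area", "width", "height")) {
      cunv <- setNames(sj[[m]][sj$role == "cuneiform"],
                       sj$specimen[sj$role == "cuneiform"])
      metv <- setNames(sj[[m]][sj$role == "metatarsal"],
                       sj$specimen[sj$role == "metatarsal"])
      common <- intersect(names(cunv), names(metv))
      if (length(common) >= 2L)
        try_add("paired_t", paste(jt, m),
                t_test(cunv[common], metv[common], mode = "paired"))
    }
  }
  # curvature vs zero (two-tailed one-sample)
  for (b in unique(curv$bone)) for (r in unique(curv$region)) {
    v <- curv$K_signed[curv$bone == b & curv$region == r]
    v <- v[!is.na(v)]
    if (length(v) >= 2L)
      try_add("curvature_vs_zero", paste(b, r),
              t_test(v, mu0 = 0, mode = "one_sample_two_tailed"))
  }
  # ANOVA: whole-surface curvature between bones, specimens (donors), sides
  spec_factor <- if ("donor" %in% names(curv)) "donor" else "specimen"
  whole <- curv[curv$region == "whole", ]
  try_add("anova_curvature", "whole-surface",
          three_way_anova(whole, "K_signed", c("bone", spec_factor, "side")))
  # per-bone region ANOVA + Games-Howell over quadrants
  quad <- curv[curv$region != "whole" & !is.na(curv$K_signed), ]
  for (b in unique(quad$bone)) {
    qb <- quad[quad$bone == b, ]
    try_add("anova_region", b,
            three_way_anova(qb, "K_signed", c("region", spec_factor, "side")))
    try_add("games_howell_region", b,
            games_howell(split(qb$K_signed, qb$region)))
  }
  # similarity tests
  for (jt in unique(sims$joint)) for (r in unique(sims$region)) {
    v <- sims$value[sims$joint == jt & sims$region == r & sims$present]
    if (length(v) < 2L) next
    try_add("similarity_vs_one", paste(jt, r),
            t_test(v, mu0 = 1, mode = "one_sample_two_tailed"))
    try_add("similarity_vs_neg_one", paste(jt, r),
            t_test(v, mu0 = -1, mode = "one_sample_two_tailed"))
    try_add("similarity_vs_zero", paste(jt, r),
            t_test(v, mu0 = 0, mode = "one_sample_one_tailed"))
  }
  pres <- sims[sims$present & sims$region != "whole", ]
  sim_spec <- if ("donor" %in% names(sims)) "donor" else "specimen"
  for (jt in unique(pres$joint)) {
    pj <- pres[pres$joint == jt, ]
    try_add("anova_similarity", jt,
            three_way_anova(pj, "value", c("region", sim_spec, "side")))
    try_add("games_howell_similarity", jt,
            games_howell(split(pj$value, pj$region)))
  }
  # normality checks on selected measurements
  for (b in unique(curv$bone)) {
    v <- curv$K_signed[curv$bone == b & curv$region == "whole"]
    v <- v[!is.na(v)]
    if (length(v) >= 3L) try_add("shapiro_curvature", b, shapiro_wilk(v))
    a <- size$area[size$bone == b]
    if (length(a) >= 3L) try_add("shapiro_area", b, shapiro_wilk(a))
  }
  if (length(out) == 0L) return(data.frame())
  # bind heterogenous result frames on the union of columns
  cols <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[cols]
  })
  do.call(rbind, out)
}
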