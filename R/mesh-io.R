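# Readers and writers for the three triangle-mesh interchange formats used
# by segmentation pipelines (STL binary/ASCII, PLY ASCII, OBJ).  Units are
# taken as mm verbatim; none of these formats carries unit metadata.

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "ply", "obj"))
    stop("cannot infer mesh format from extension: ", ext)
  ext
}

#' Read a triangle mesh from file
#'
#' Supports STL (binary and ASCII; soup vertices are welded at 1e-6 mm),
#' ASCII PLY, and OBJ.  The returned mesh is validated and, when closed,
#' oriented outward (positive signed volume).
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; inferred from the file
#'   extension when omitted.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  format <- if (is.null(format)) infer_format(path) else match.arg(format, c("stl", "ply", "obj"))
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  raw <- switch(format,
                stl = read_stl(path),
                ply = read_ply(path),
                obj = read_obj(path))
  surface_mesh(raw$vertices, raw$faces, validate = TRUE, orient = TRUE)
}

#' Write a triangle mesh to file
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; inferred from the
#'   extension when omitted.
#' @param binary for STL, write the binary flavor (default `FALSE`).
#' @param comments character vector of comment lines (PLY/OBJ only).
#' @param vertex_data optional named list of per-vertex numeric vectors
#'   written as extra PLY vertex properties.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE,
                       comments = NULL, vertex_data = NULL) {
  format <- if (is.null(format)) infer_format(path) else match.arg(format, c("stl", "ply", "obj"))
  switch(format,
         stl = write_stl(mesh, path, binary),
         ply = write_ply(mesh, path, comments, vertex_data),
         obj = write_obj(mesh, path, comments))
  invisible(path)
}

# ---- STL ----

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 512L)
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  weld_vertices(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("malformed ASCII STL: vertex count not a multiple of 3")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  do.call(rbind, nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (n <= 0L) stop("malformed binary STL")
  rec <- readBin(con, "raw", n * 50L)
  if (length(rec) < n * 50L) stop("truncated binary STL")
  m <- matrix(rec, nrow = 50L)
  vals <- readBin(as.vector(m[1:48, ]), "double", size = 4L, n = n * 12L,
                  endian = "little")
  vm <- matrix(vals, ncol = 12L, byrow = TRUE)    # nx ny nz v1 v2 v3
  # interleave so rows are v1,v2,v3 per facet
  out <- matrix(NA_real_, 3L * n, 3L)
  out[seq(1L, 3L * n, by = 3L), ] <- vm[, 4:6, drop = FALSE]
  out[seq(2L, 3L * n, by = 3L), ] <- vm[, 7:9, drop = FALSE]
  out[seq(3L, 3L * n, by = 3L), ] <- vm[, 10:12, drop = FALSE]
  out
}

# triangle soup (3m x 3 vertex rows) -> welded vertices + faces
weld_vertices <- function(tri, tol = 1e-6) {
  key <- paste(round(tri[, 1L] / tol), round(tri[, 2L] / tol),
               round(tri[, 3L] / tol))
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  list(vertices = tri[uk, , drop = FALSE],
       faces = matrix(ids, ncol = 3L, byrow = TRUE))
}

write_stl <- function(mesh, path, binary = FALSE) {
  V <- mesh$vertices
  F <- mesh$faces
  cr <- tri_cross(V, F)
  nr <- cr / pmax(sqrt(rowSums(cr^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(F)), con, size = 4L, endian = "little")
    block <- matrix(0, nrow(F), 12L)
    block[, 1:3] <- nr
    block[, 4:6] <- V[F[, 1L], , drop = FALSE]
    block[, 7:9] <- V[F[, 2L], , drop = FALSE]
    block[, 10:12] <- V[F[, 3L], , drop = FALSE]
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(0)
    out <- c(out, "solid articmorph")
    for (i in seq_len(nrow(F))) {
      a <- V[F[i, 1L], ]; b <- V[F[i, 2L], ]; c_ <- V[F[i, 3L], ]
      out <- c(out,
               sprintf("  facet normal %s %s %s", fmt(nr[i, 1]), fmt(nr[i, 2]), fmt(nr[i, 3])),
               "    outer loop",
               sprintf("      vertex %s %s %s", fmt(a[1]), fmt(a[2]), fmt(a[3])),
               sprintf("      vertex %s %s %s", fmt(b[1]), fmt(b[2]), fmt(b[3])),
               sprintf("      vertex %s %s %s", fmt(c_[1]), fmt(c_[2]), fmt(c_[3])),
               "    endloop",
               "  endfacet")
    }
    out <- c(out, "endsolid articmorph")
    writeLines(out, path)
  }
  invisible(path)
}

# ---- PLY (ASCII) ----

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("malformed PLY header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  ev <- grep("^element vertex ", hdr)
  ef <- grep("^element face ", hdr)
  nv <- as.integer(sub("^element vertex ", "", hdr[ev[1L]]))
  nf <- as.integer(sub("^element face ", "", hdr[ef[1L]]))
  # vertex property order (x,y,z must be the first three scalar properties)
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- matrix(as.numeric(unlist(lapply(vrows, `[`, 1:3))), ncol = 3L, byrow = TRUE)
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  cnt <- vapply(frows, function(r) as.integer(r[1L]), 0L)
  if (any(cnt != 3L)) stop("PLY contains non-triangular faces")
  F <- matrix(as.integer(unlist(lapply(frows, `[`, 2:4))), ncol = 3L,
              byrow = TRUE) + 1L
  list(vertices = V, faces = F)
}

write_ply <- function(mesh, path, comments = NULL, vertex_data = NULL) {
  V <- mesh$vertices
  F <- mesh$faces
  extra_names <- names(vertex_data)
  hdr <- c("ply", "format ascii 1.0")
  if (!is.null(comments)) hdr <- c(hdr, paste("comment", comments))
  hdr <- c(hdr,
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z")
  if (length(extra_names))
    hdr <- c(hdr, sprintf("property double %s", extra_names))
  hdr <- c(hdr,
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices",
           "end_header")
  vm <- V
  if (length(extra_names))
    vm <- cbind(vm, do.call(cbind, vertex_data))
  vlines <- do.call(paste, c(lapply(seq_len(ncol(vm)), function(j)
    sprintf("%.10g", vm[, j])), sep = " "))
  flines <- sprintf("3 %d %d %d", F[, 1L] - 1L, F[, 2L] - 1L, F[, 3L] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  fidx <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ids <- vapply(x[-1L], function(t) as.integer(strsplit(t, "/")[[1L]][1L]), 0L)
    if (length(ids) != 3L) stop("OBJ contains non-triangular faces")
    ids
  })
  list(vertices = V, faces = do.call(rbind, fidx))
}

write_obj <- function(mesh, path, comments = NULL) {
  out <- character(0)
  if (!is.null(comments)) out <- paste("#", comments)
  out <- c(out, sprintf("v %.10g %.10g %.10g", mesh$vertices[, 1L],
                        mesh$vertices[, 2L], mesh$vertices[, 3L]),
           sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                   mesh$faces[, 3L]))
  writeLines(out, path)
  invisible(path)
}

#' Write a surface patch as PLY with a face-label comment header
#'
#' The patch is exported as a stand-alone mesh; its label is recorded in
#' `comment label ...` header lines.
#' @param patch a `surface_patch`.
#' @param path output path (`.ply`).
#' @export
write_patch <- function(patch, path) {
  sm <- patch_submesh(patch)
  lb <- patch$label
  write_mesh(sm$mesh, path, format = "ply",
             comments = sprintf("label bone=%s end=%s side=%s",
                                lb$bone, lb$end, lb$side))
}
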