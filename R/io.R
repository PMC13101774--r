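# Surface and per-vertex-map file I/O.
#
# Supported formats:
#   meshes: VTK legacy ASCII polydata (strict DATASET POLYDATA dialect),
#           OFF, FreeSurfer binary triangle surface.
#   maps:   CSV "vertex,value" (0-based vertex index on disk),
#           FreeSurfer new-format binary curv.
#   masks:  FreeSurfer-style ASCII label (0-based vertex list).
# All on-disk vertex indices are 0-based; in-memory indices are 1-based.

#' Read a triangular surface mesh
#'
#' @param path file path.
#' @param format one of `"vtk"` (legacy ASCII polydata), `"off"`,
#'   `"freesurfer"` (binary triangle surface). Default guesses from the
#'   file extension (`.vtk`, `.off`; anything else is tried as FreeSurfer).
#' @return a `triangle_mesh` with vertex order preserved from the file.
#' @export
read_mesh <- function(path, format = c("auto", "vtk", "off", "freesurfer")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_mesh_format(path)
  switch(format,
         vtk = read_vtk(path),
         off = read_off(path),
         freesurfer = read_fs_surface(path))
}

#' Write a triangular surface mesh
#'
#' Coordinates are written with 17 significant digits (VTK/OFF) or as
#' 32-bit floats (FreeSurfer), so ASCII round-trips are exact for doubles
#' representable in text.
#'
#' @param mesh a `triangle_mesh`.
#' @inheritParams read_mesh
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "vtk", "off", "freesurfer")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  switch(format,
         vtk = write_vtk(mesh, path),
         off = write_off(mesh, path),
         freesurfer = write_fs_surface(mesh, path))
  invisible(path)
}

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "vtk") "vtk" else if (ext == "off") "off" else "freesurfer"
}

# --- VTK legacy ASCII polydata (strict: POINTS + triangle POLYGONS) -------

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    stop("VTK format error at line 1: missing '# vtk DataFile' header in ", path)
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("VTK format error at line 3: expected ASCII, got '", lines[3], "'")
  if (!grepl("^DATASET\\s+POLYDATA", toupper(trimws(lines[4]))))
    stop("VTK format error at line 4: expected DATASET POLYDATA")
  pts_at <- grep("^POINTS\\s", lines)
  if (length(pts_at) != 1)
    stop("VTK format error: expected exactly one POINTS section")
  np <- as.integer(strsplit(trimws(lines[pts_at]), "\\s+")[[1]][2])
  if (is.na(np) || np < 1) stop("VTK format error at line ", pts_at, ": bad POINTS count")
  coords <- scan_numbers(lines, pts_at + 1L, 3L * np,
                         sprintf("POINTS section (need %d values)", 3L * np))
  v <- matrix(coords$values, ncol = 3, byrow = TRUE)
  poly_at <- grep("^POLYGONS\\s", lines)
  if (length(poly_at) != 1)
    stop("VTK format error: expected exactly one POLYGONS section")
  hdr <- as.integer(strsplit(trimws(lines[poly_at]), "\\s+")[[1]][2:3])
  nf <- hdr[1]; ntot <- hdr[2]
  ints <- scan_numbers(lines, poly_at + 1L, ntot, "POLYGONS section")
  vals <- as.integer(ints$values)
  f <- matrix(NA_integer_, nf, 3); pos <- 1L
  for (i in seq_len(nf)) {
    k <- vals[pos]
    if (is.na(k) || k != 3L)
      stop("unsupported topology: POLYGONS entry ", i, " lists ", k,
           " indices (only triangles supported)")
    f[i, ] <- vals[(pos + 1L):(pos + 3L)] + 1L
    pos <- pos + 4L
  }
  triangle_mesh(v, f)
}

# Collect `n` whitespace-separated numbers starting at line `from`.
scan_numbers <- function(lines, from, n, what) {
  out <- numeric(0); i <- from
  while (length(out) < n) {
    if (i > length(lines))
      stop("format error: ran out of lines reading ", what)
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    num <- suppressWarnings(as.numeric(tok))
    if (anyNA(num))
      stop("format error at line ", i, ": non-numeric token in ", what)
    out <- c(out, num); i <- i + 1L
  }
  if (length(out) > n)
    stop("format error near line ", i - 1L, ": surplus values in ", what)
  list(values = out, next_line = i)
}

write_vtk <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 4.2",
               if (is.null(mesh$name)) "surface" else mesh$name,
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n_vertices(mesh))), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  nf <- n_faces(mesh)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

# --- OFF ------------------------------------------------------------------

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines) || !grepl("^OFF", trimws(lines[1])))
    stop("OFF format error at line 1: missing OFF keyword in ", path)
  rest <- trimws(sub("^OFF", "", trimws(lines[1])))
  if (nzchar(rest)) {
    counts <- as.integer(strsplit(rest, "\\s+")[[1]])
    body_at <- 2L
  } else {
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    body_at <- 3L
  }
  if (length(counts) < 2 || anyNA(counts[1:2]))
    stop("OFF format error: bad vertex/face counts")
  nv <- counts[1]; nf <- counts[2]
  coords <- scan_numbers(lines, body_at, 3L * nv, "OFF vertex block")
  v <- matrix(coords$values, ncol = 3, byrow = TRUE)
  f <- matrix(NA_integer_, nf, 3)
  fi <- coords$next_line
  for (i in seq_len(nf)) {
    tok <- as.numeric(strsplit(trimws(lines[fi + i - 1L]), "\\s+")[[1]])
    if (tok[1] != 3)
      stop("unsupported topology: OFF face ", i, " has ", tok[1], " vertices")
    f[i, ] <- as.integer(tok[2:4]) + 1L
  }
  triangle_mesh(v, f)
}

write_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), n_faces(mesh)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

# --- FreeSurfer binary triangle surface (big-endian) ----------------------

FS_TRIANGLE_MAGIC <- 16777214L  # 0xFFFFFE

read_int24 <- function(con) {
  b <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  b[1] * 65536L + b[2] * 256L + b[3]
}

write_int24 <- function(con, x) {
  writeBin(as.integer(c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L)),
           con, size = 1)
}

read_fs_surface <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- read_int24(con)
  if (magic != FS_TRIANGLE_MAGIC)
    stop("format error: not a FreeSurfer triangle surface (magic ", magic, ")")
  # comment line terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", 1)
    if (!length(ch)) stop("format error: truncated FreeSurfer header")
    if (ch == as.raw(10) && prev == as.raw(10)) break
    prev <- ch
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  v <- matrix(readBin(con, "double", 3 * nv, size = 4, endian = "big"),
              ncol = 3, byrow = TRUE)
  f <- matrix(readBin(con, "integer", 3 * nf, size = 4, endian = "big"),
              ncol = 3, byrow = TRUE) + 1L
  triangle_mesh(v, f)
}

write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  write_int24(con, FS_TRIANGLE_MAGIC)
  writeBin(charToRaw("created by mbmorph\n\n"), con)
  writeBin(as.integer(n_vertices(mesh)), con, size = 4, endian = "big")
  writeBin(as.integer(n_faces(mesh)), con, size = 4, endian = "big")
  writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.vector(t(mesh$faces - 1L)), con, size = 4, endian = "big")
}

# --- Per-vertex scalar maps ----------------------------------------------

#' Read a per-vertex scalar map
#'
#' @param path file path.
#' @param mesh mesh the map lives on (defines the expected vertex count).
#' @param format `"csv"` for two-column `vertex,value` text (0-based vertex
#'   index, header optional) or `"curv"` for FreeSurfer new-format binary
#'   curv. `"auto"` picks curv unless the extension is `.csv`.
#' @param mask optional logical mask attached to the returned map.
#' @return a `surface_map`.
#' @export
read_surface_map <- function(path, mesh, format = c("auto", "csv", "curv"),
                             mask = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "curv"
  values <- if (format == "csv") {
    df <- utils::read.csv(path, header = csv_has_header(path))
    if (ncol(df) < 2) stop("map CSV must have columns vertex,value")
    out <- rep(NA_real_, n_vertices(mesh))
    out[as.integer(df[[1]]) + 1L] <- as.numeric(df[[2]])
    if (anyNA(out)) stop("map CSV does not cover all ", n_vertices(mesh),
                         " vertices: ", path)
    out
  } else {
    read_fs_curv(path)
  }
  surface_map(values, mesh, mask = mask,
              name = tools::file_path_sans_ext(basename(path)))
}

csv_has_header <- function(path) {
  first <- readLines(path, n = 1L)
  is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
}

#' Write a per-vertex scalar map
#'
#' @param map a `surface_map`.
#' @inheritParams read_surface_map
#' @return `path`, invisibly.
#' @export
write_surface_map <- function(map, path, format = c("auto", "csv", "curv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "curv"
  if (format == "csv") {
    utils::write.csv(
      data.frame(vertex = seq_along(map$values) - 1L, value = map$values),
      path, row.names = FALSE, quote = FALSE)
  } else {
    write_fs_curv(map$values, path)
  }
  invisible(path)
}

FS_CURV_MAGIC <- 16777215L  # 0xFFFFFF, "new" curv format

read_fs_curv <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  if (read_int24(con) != FS_CURV_MAGIC)
    stop("format error: not a new-format FreeSurfer curv file: ", path)
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 4, endian = "big")  # nfaces, vals/vertex
  readBin(con, "double", nv, size = 4, endian = "big")
}

write_fs_curv <- function(values, path) {
  con <- file(path, "wb"); on.exit(close(con))
  write_int24(con, FS_CURV_MAGIC)
  writeBin(c(length(values), 0L, 1L), con, size = 4, endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
}

# --- FreeSurfer-style ASCII label (vertex-index list) ---------------------

#' Read a vertex label (cortex mask) file
#'
#' FreeSurfer-style ASCII label: one comment line, a vertex count, then
#' rows `index x y z value` with 0-based indices. Coordinates are ignored;
#' only membership matters.
#'
#' @param path file path.
#' @param mesh mesh defining the vertex count.
#' @return logical mask vector (`TRUE` = listed vertex).
#' @export
read_label <- function(path, mesh) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n)) stop("label format error: missing vertex count in ", path)
  idx <- vapply(strsplit(trimws(lines[1 + seq_len(n)]), "\\s+"),
                function(t) as.integer(t[1]), integer(1))
  if (anyNA(idx) || any(idx < 0) || any(idx >= n_vertices(mesh)))
    stop("label format error: vertex index out of range in ", path)
  mask <- logical(n_vertices(mesh))
  mask[idx + 1L] <- TRUE
  mask
}

#' Write a vertex label (cortex mask) file
#'
#' @param mask logical vector over mesh vertices.
#' @param mesh the mesh supplying coordinates for the label rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label <- function(mask, mesh, path) {
  idx <- which(mask)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#!ascii label, written by mbmorph",
               as.character(length(idx))), con)
  writeLines(sprintf("%d  %.6f  %.6f  %.6f 0.000000",
                     idx - 1L, mesh$vertices[idx, 1],
                     mesh$vertices[idx, 2], mesh$vertices[idx, 3]), con)
  invisible(path)
}
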