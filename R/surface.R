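# Mesh and per-vertex data model: constructors, synthetic templates,
# areas/connectivity utilities. File I/O lives in R/io.R.

#' Construct a triangular surface mesh
#'
#' A `triangle_mesh` holds vertex coordinates (mm) and triangular faces.
#' Faces are stored 1-based in memory (R convention); every on-disk format
#' written or read by this package uses 0-based vertex indices.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param name optional identifier (e.g. `"lh"`, `"rh"`).
#' @param check validate invariants (index range, no zero-area faces,
#'   edge-connectivity). Disable only for meshes known valid.
#' @return an object of class `triangle_mesh` with elements
#'   `vertices`, `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = NULL, check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  mesh <- structure(list(vertices = vertices, faces = faces, name = name),
                    class = "triangle_mesh")
  if (check) validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh%s: %d vertices, %d faces, area %.4g mm^2\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$vertices), nrow(x$faces), mesh_surface_area(x)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Validate triangle-mesh invariants
#'
#' Checks positive vertex/face counts, index range, triangle-only topology,
#' absence of zero-area faces and (unless `allow_disconnected`) that the
#' mesh is a single edge-connected component.
#'
#' @param mesh a `triangle_mesh`.
#' @param allow_disconnected skip the connectivity check.
#' @return the mesh, invisibly; errors describe the first violation found.
#' @export
validate_mesh <- function(mesh, allow_disconnected = FALSE) {
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  if (nv < 1L || nf < 1L) stop("mesh must have positive vertex and face counts")
  f <- mesh$faces
  if (anyNA(f) || min(f) < 1L || max(f) > nv)
    stop("face indices out of range [1, ", nv, "]")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate face: repeated vertex index")
  fa <- face_areas(mesh)
  if (any(fa <= .Machine$double.eps))
    stop("zero-area face(s) at rows: ",
         paste(utils::head(which(fa <= .Machine$double.eps), 5), collapse = ", "))
  if (!allow_disconnected) {
    comp <- vertex_components(mesh, seq_len(nv))
    if (max(comp) > 1L)
      stop("mesh is not edge-connected (", max(comp), " components)")
  }
  invisible(mesh)
}

#' Triangle areas of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Barycentric (lumped) vertex areas
#'
#' Each vertex receives one third of the area of every incident triangle.
#' These lumped areas are also the diagonal mass weights used by
#' [assemble_operators()], so modal orthonormality and cluster areas share
#' one definition of local surface area.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of per-vertex areas (mm^2); sums to the total
#'   surface area.
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  if (any(fa <= .Machine$double.eps)) stop("degenerate (zero-area) triangle")
  va <- numeric(n_vertices(mesh))
  third <- fa / 3
  for (j in 1:3) {
    acc <- rowsum(third, mesh$faces[, j])
    idx <- as.integer(rownames(acc))
    va[idx] <- va[idx] + acc[, 1]
  }
  va
}

#' Total mesh surface area (mm^2)
#' @param mesh a `triangle_mesh`.
#' @export
mesh_surface_area <- function(mesh) sum(face_areas(mesh))

# Undirected edge list (unique pairs, i < j) as a 2-column integer matrix.
mesh_edge_list <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

# Connected-component labels for an induced vertex subset, by BFS over the
# adjacency restricted to the subset. Returns labels 1..ncomp aligned with
# `subset` order.
vertex_components <- function(mesh, subset) {
  subset <- as.integer(subset)
  nv <- n_vertices(mesh)
  in_set <- logical(nv); in_set[subset] <- TRUE
  e <- mesh_edge_list(mesh)
  keep <- in_set[e[, 1]] & in_set[e[, 2]]
  e <- e[keep, , drop = FALSE]
  # adjacency as index ranges into a sorted neighbor vector
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = nv)
  adj <- vector("list", nv)
  if (nrow(e)) {
    nb <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
    adj[as.integer(names(nb))] <- nb
  }
  comp <- integer(nv)  # 0 = unvisited
  label <- 0L
  for (s in subset) {
    if (comp[s] != 0L) next
    label <- label + 1L
    queue <- s; comp[s] <- label
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nbs <- adj[[v]]
      new <- nbs[comp[nbs] == 0L]
      if (length(new)) {
        comp[new] <- label
        queue <- c(queue, new)
      }
    }
  }
  comp[subset]
}

#' Edge-connected clusters of a vertex subset
#'
#' Partitions `vertex_subset` into maximal edge-connected components of the
#' induced subgraph and reports each component's surface area as the sum of
#' its members' barycentric vertex areas. Used for the minimum-cluster-area
#' rule (e.g. 100 mm^2) in vertex-wise thresholding.
#'
#' @param mesh a `triangle_mesh`.
#' @param vertex_subset integer vertex indices (1-based).
#' @return list of clusters sorted by decreasing area; each element has
#'   `vertices` (integer) and `area` (mm^2). Empty subset gives `list()`.
#' @export
mesh_clusters <- function(mesh, vertex_subset) {
  vertex_subset <- as.integer(vertex_subset)
  if (!length(vertex_subset)) return(list())
  if (anyDuplicated(vertex_subset)) vertex_subset <- unique(vertex_subset)
  if (min(vertex_subset) < 1L || max(vertex_subset) > n_vertices(mesh))
    stop("vertex_subset indices out of range")
  comp <- vertex_components(mesh, vertex_subset)
  va <- vertex_areas(mesh)
  groups <- split(vertex_subset, comp)
  clusters <- lapply(groups, function(vs)
    list(vertices = sort(vs), area = sum(va[vs])))
  ord <- order(vapply(clusters, `[[`, numeric(1), "area"), decreasing = TRUE)
  unname(clusters[ord])
}

#' Geodesic icosphere
#'
#' Repeated 4-fold subdivision of a regular icosahedron with projection to
#' the sphere: `10 * 4^s + 2` vertices and `20 * 4^s` faces. Serves as the
#' shared synthetic template surface standing in for a registered cortical
#' mesh.
#'
#' @param subdivisions non-negative integer `s`.
#' @param radius sphere radius in mm.
#' @return a `triangle_mesh`.
#' @export
make_icosphere <- function(subdivisions = 0L, radius = 1) {
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  if (radius <= 0) stop("radius must be > 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    key <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ek <- key(edges[, 1], edges[, 2])
    uk <- !duplicated(ek)
    mid_of <- new.env(hash = TRUE)
    mids <- (v[edges[uk, 1], , drop = FALSE] + v[edges[uk, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    mid_idx <- nv + seq_len(sum(uk))
    lookup <- stats::setNames(mid_idx, as.character(ek[uk]))
    v <- rbind(v, mids)
    m12 <- lookup[as.character(key(f[, 1], f[, 2]))]
    m23 <- lookup[as.character(key(f[, 2], f[, 3]))]
    m31 <- lookup[as.character(key(f[, 3], f[, 1]))]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
    rownames(f) <- NULL
  }
  triangle_mesh(v * radius, f, name = sprintf("icosphere_s%d", subdivisions),
                check = FALSE)
}

#' Per-vertex scalar map on a mesh
#'
#' Bundles one scalar per vertex (mm for thickness, unitless for
#' statistics) with a binary cortex mask; masked-out vertices carry values
#' but are excluded from projection and statistics.
#'
#' @param values numeric vector, one per mesh vertex.
#' @param mesh the `triangle_mesh` the map lives on.
#' @param mask logical (or 0/1) vector; `TRUE` = cortex. Default all-in.
#' @param name optional identifier.
#' @return an object of class `surface_map`.
#' @export
surface_map <- function(values, mesh, mask = NULL, name = NULL) {
  nv <- n_vertices(mesh)
  values <- as.numeric(values)
  if (length(values) != nv)
    stop("values length ", length(values), " != vertex count ", nv)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  mask <- as.logical(mask)
  if (length(mask) != nv) stop("mask length != vertex count")
  if (!any(mask)) stop("mask must contain at least one cortex vertex")
  structure(list(values = values, mask = mask, mesh = mesh, name = name),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("surface_map%s: %d vertices (%d in mask), range [%.4g, %.4g]\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$values), sum(x$mask), min(v), max(v)))
  invisible(x)
}

same_mesh <- function(a, b) {
  isTRUE(all.equal(a$vertices, b$vertices, tolerance = 0)) &&
    identical(a$faces, b$faces)
}
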