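# Laplace-Beltrami operator assembly and geometric eigenmodes.
#
# Discretization: cotangent stiffness matrix with barycentric lumped mass.
# The generalized symmetric problem  K psi = lambda M psi  with diagonal M
# whitens exactly to the standard symmetric problem
#   (M^-1/2 K M^-1/2) u = lambda u,  psi = M^-1/2 u,
# which is solved densely (LAPACK, deterministic). At the mesh sizes this
# package targets (<= a few thousand vertices) the dense solve is exact,
# reproducible and fast; modes are mass-orthonormal by construction.

#' Assemble the cotangent stiffness matrix and lumped mass weights
#'
#' The stiffness matrix `K` is symmetric positive semidefinite with zero
#' row sums; the off-diagonal entry for edge (i,j) is
#' `-(cot a + cot b)/2` over the two angles opposite the edge. Mass
#' weights are the barycentric vertex areas of [vertex_areas()].
#'
#' @param mesh a valid, connected `triangle_mesh`.
#' @return list with `stiffness` (a `dgCMatrix`, 1/1) and `mass`
#'   (numeric vector, mm^2).
#' @export
assemble_operators <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fa <- face_areas(mesh)
  if (any(fa <= .Machine$double.eps))
    stop("degenerate (zero-area) triangle in mesh")
  cot_at <- function(a, b, c) {
    # cotangent of the angle at vertex a of triangle (a, b, c)
    e1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    e2 <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(e1 * e2)
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    dot / sqrt(cx^2 + cy^2 + cz^2)
  }
  c1 <- cot_at(f[, 1], f[, 2], f[, 3])  # opposite edge (2,3)
  c2 <- cot_at(f[, 2], f[, 3], f[, 1])  # opposite edge (3,1)
  c3 <- cot_at(f[, 3], f[, 1], f[, 2])  # opposite edge (1,2)
  i <- c(f[, 2], f[, 3], f[, 3], f[, 1], f[, 1], f[, 2])
  j <- c(f[, 3], f[, 2], f[, 1], f[, 3], f[, 2], f[, 1])
  w <- c(c1, c1, c2, c2, c3, c3) / 2
  off <- Matrix::sparseMatrix(i = i, j = j, x = -w,
                              dims = c(nrow(v), nrow(v)))
  K <- off - Matrix::Diagonal(x = Matrix::rowSums(off))
  list(stiffness = methods::as(K, "CsparseMatrix"), mass = vertex_areas(mesh))
}

#' Compute geometric eigenmodes of a surface mesh
#'
#' Solves `K psi = lambda M psi` for the `n_modes` smallest eigenpairs of
#' the cotangent Laplace-Beltrami operator. Eigenvalues are returned in
#' ascending order (1/mm^2); modes are mass-orthonormal
#' (`t(psi) %*% diag(mass) %*% psi = I`) and sign-fixed by the canonical
#' rule of [align_mode_signs()]. The first eigenvalue is clamped to zero
#' when numerically in the kernel (`|lambda_1| < 1e-10 * lambda_2`).
#'
#' @param mesh a `triangle_mesh`.
#' @param n_modes number of modes (must be `< n_vertices`).
#' @param operators optional precomputed result of [assemble_operators()].
#' @return an `eigenmode_basis`: list with `modes` (vertices x n_modes),
#'   `evals`, `mass`, `mesh`, `n_modes`.
#' @export
compute_eigenmodes <- function(mesh, n_modes, operators = NULL) {
  nv <- n_vertices(mesh)
  if (n_modes >= nv)
    stop("n_modes (", n_modes, ") must be < number of vertices (", nv, ")")
  if (n_modes < 1) stop("n_modes must be >= 1")
  if (is.null(operators)) operators <- assemble_operators(mesh)
  d <- operators$mass
  s <- 1 / sqrt(d)
  A <- as.matrix(operators$stiffness) * tcrossprod(s)
  A <- (A + t(A)) / 2
  ee <- eigen(A, symmetric = TRUE)
  sel <- nv:(nv - n_modes + 1L)  # eigen() returns descending order
  evals <- ee$values[sel]
  modes <- ee$vectors[, sel, drop = FALSE] * s
  if (n_modes >= 2 && abs(evals[1]) < 1e-10 * abs(evals[2])) evals[1] <- 0
  basis <- structure(list(modes = modes, evals = evals, mass = d,
                          mesh = mesh, n_modes = n_modes),
                     class = "eigenmode_basis")
  align_mode_signs(basis)
}

#' @export
print.eigenmode_basis <- function(x, ...) {
  cat(sprintf("eigenmode_basis: %d modes on %d vertices, lambda in [%.4g, %.4g] mm^-2\n",
              x$n_modes, nrow(x$modes), x$evals[1], x$evals[x$n_modes]))
  invisible(x)
}

#' Eigengroup labels for a mode range
#'
#' Mode 1 (the constant mode) forms group 0; thereafter consecutive blocks
#' of `2g + 1` modes form groups `g = 1, 2, ...`, mirroring spherical
#' harmonic multiplicities. The 25-mode truncation used for the asymmetry
#' index is exactly group 0 plus groups 1-4.
#'
#' @param n_modes number of leading modes to label.
#' @return integer vector of group labels with attribute `sizes` (modes
#'   per group, last group possibly truncated).
#' @export
eigengroup_partition <- function(n_modes) {
  if (n_modes < 1) stop("n_modes must be >= 1")
  labels <- integer(n_modes)
  g <- 0L; pos <- 1L
  while (pos <= n_modes) {
    size <- if (g == 0L) 1L else 2L * g + 1L
    take <- min(size, n_modes - pos + 1L)
    labels[pos:(pos + take - 1L)] <- g
    pos <- pos + take; g <- g + 1L
  }
  structure(labels, sizes = as.integer(table(labels)))
}

#' Fix eigenvector signs
#'
#' Eigenvector sign is arbitrary; comparability of modal coefficients
#' across hemispheres and runs requires a convention. With a `reference`
#' basis, each mode is flipped so its mass-weighted inner product with the
#' reference mode is non-negative; a zero inner product falls back to the
#' canonical rule with a message. The canonical rule makes the vertex of
#' largest `|value|` positive (ties broken by lowest vertex index).
#'
#' @param basis an `eigenmode_basis`.
#' @param reference optional `eigenmode_basis` with the same mode count and
#'   mesh topology.
#' @return the sign-aligned basis.
#' @export
align_mode_signs <- function(basis, reference = NULL) {
  m <- basis$modes
  if (is.null(reference)) {
    signs <- apply(m, 2, canonical_sign)
  } else {
    if (reference$n_modes != basis$n_modes || nrow(reference$modes) != nrow(m))
      stop("reference basis must share mode count and mesh topology")
    ip <- colSums(m * basis$mass * reference$modes)
    signs <- sign(ip)
    zero <- abs(ip) < 1e-12
    if (any(zero)) {
      message(sum(zero), " mode(s) orthogonal to reference; using canonical rule")
      signs[zero] <- vapply(which(zero), function(k) canonical_sign(m[, k]),
                            numeric(1))
    }
  }
  basis$modes <- sweep(m, 2, signs, `*`)
  basis
}

canonical_sign <- function(col) {
  peak <- which.max(abs(col))  # first index on ties
  if (col[peak] >= 0) 1 else -1
}

#' Persist an eigenmode basis as text files
#'
#' Writes `eigenvalues.csv` (`mode, lambda, group`) and one per-mode map
#' `mode_<k>.csv` under `dir`, in the package's standard map format.
#'
#' @param basis an `eigenmode_basis`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_basis <- function(basis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  part <- eigengroup_partition(basis$n_modes)
  utils::write.csv(data.frame(mode = seq_len(basis$n_modes),
                              lambda = basis$evals, group = as.integer(part)),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  for (k in seq_len(basis$n_modes))
    write_surface_map(surface_map(basis$modes[, k], basis$mesh),
                      file.path(dir, sprintf("mode_%03d.csv", k)))
  invisible(dir)
}
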