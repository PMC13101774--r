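# Shared fixtures, memoized so expensive eigendecompositions run once per
# test session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fix_sphere <- function(s = 3, r = 1) {
  memo(sprintf("mesh_%d_%g", s, r), make_icosphere(s, r))
}

fix_basis <- function(s = 3, K = 50, r = 1) {
  memo(sprintf("basis_%d_%d_%g", s, K, r),
       compute_eigenmodes(fix_sphere(s, r), K))
}

# basis on the default synthetic template (subdivisions 3, radius 90)
fix_template_basis <- function(cfg = simulation_config(), K = cfg$basis_modes) {
  memo(sprintf("tpl_basis_%d_%g_%g_%d", cfg$subdivisions, cfg$radius,
               cfg$perturbation, K), {
    tpl <- generate_template_pair(cfg)
    compute_eigenmodes(tpl$lh, K)
  })
}

# two equilateral unit triangles sharing an edge (planar)
fix_diamond <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, -sqrt(3) / 2, 0))
  triangle_mesh(v, rbind(c(1, 2, 3), c(1, 4, 2)), check = FALSE)
}

fix_tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  triangle_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3)))
}

# dense generalized eigenproblem oracle: solves M^-1 K directly by a
# nonsymmetric full eigendecomposition (independent of the package's
# whitened symmetric route)
dense_generalized_eigs <- function(mesh, n) {
  op <- assemble_operators(mesh)
  A <- diag(1 / op$mass) %*% as.matrix(op$stiffness)
  ee <- eigen(A)
  ord <- order(Re(ee$values))
  list(values = Re(ee$values[ord])[seq_len(n)],
       vectors = Re(ee$vectors[, ord, drop = FALSE])[, seq_len(n)],
       mass = op$mass)
}

# mass-weighted eigen-subspace projector over a set of mode columns
subspace_projector <- function(modes, mass) {
  # orthonormalize w.r.t. the mass inner product, then P = Q Q^T M
  g <- t(modes) %*% (mass * modes)
  q <- modes %*% solve(chol(g))
  q %*% t(q * mass)
}
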