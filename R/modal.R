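# Modal decomposition: least-squares projection of per-vertex maps onto an
# eigenmode basis, reconstruction, and beta-spectrum tables.

#' Project a surface map onto eigenmodes
#'
#' Computes the modal loading coefficients `beta` minimizing the unweighted
#' sum of squared residuals over masked-in vertices between the map and
#' `sum_k beta_k psi_k`, with all `n_modes` columns fitted jointly. Because
#' the masked columns are not mutually orthogonal, a truncated fit refits
#' the leading columns jointly rather than slicing a longer fit (an
#' alternative slicing behavior is available in [beta_slice()]).
#'
#' @param basis an `eigenmode_basis`.
#' @param map a `surface_map` on the same mesh.
#' @param n_modes optional truncation (default: all basis modes).
#' @return a `modal_coefficients` object: list with `beta` (numeric,
#'   source-map units), `n_modes`, `map_name`, `basis_evals` (for identity
#'   checks), `n_mask`.
#' @export
project_map <- function(basis, map, n_modes = NULL) {
  if (is.null(n_modes)) n_modes <- basis$n_modes
  if (n_modes > basis$n_modes)
    stop("n_modes exceeds basis mode count (", basis$n_modes, ")")
  if (length(map$values) != nrow(basis$modes))
    stop("map and basis do not share a mesh (vertex counts differ)")
  mask <- map$mask
  if (sum(mask) < n_modes)
    stop("masked-in vertex count (", sum(mask),
         ") is smaller than n_modes (", n_modes, ")")
  X <- basis$modes[mask, seq_len(n_modes), drop = FALSE]
  qr_x <- qr(X)
  if (qr_x$rank < n_modes)
    stop("rank-deficient restricted design (rank ", qr_x$rank, " < ",
         n_modes, "); condition number ", format(kappa(X), digits = 4))
  beta <- qr.coef(qr_x, map$values[mask])
  structure(list(beta = as.numeric(beta), n_modes = n_modes,
                 map_name = map$name, basis_evals = basis$evals,
                 n_mask = sum(mask)),
            class = "modal_coefficients")
}

# Linear operator version of project_map for repeated projections of maps
# sharing one mask: returns P (n_modes x n_masked) with beta = P %*% f[mask].
projection_operator <- function(basis, mask, n_modes = NULL) {
  if (is.null(n_modes)) n_modes <- basis$n_modes
  X <- basis$modes[mask, seq_len(n_modes), drop = FALSE]
  qr_x <- qr(X)
  if (qr_x$rank < n_modes)
    stop("rank-deficient restricted design; condition number ",
         format(kappa(X), digits = 4))
  solve(qr.R(qr_x), t(qr.Q(qr_x)))
}

#' Reconstruct a surface map from modal coefficients
#'
#' @param basis an `eigenmode_basis`.
#' @param coeffs a `modal_coefficients` object (or bare numeric vector).
#' @param mode_subset optional mode indices to include (default: all modes
#'   of `coeffs`). An empty subset yields a zero map with a warning.
#' @param mask optional mask passed through to the result.
#' @return a `surface_map` with values `sum_{k in subset} beta_k psi_k`.
#' @export
reconstruct_map <- function(basis, coeffs, mode_subset = NULL, mask = NULL) {
  beta <- if (inherits(coeffs, "modal_coefficients")) coeffs$beta else as.numeric(coeffs)
  if (is.null(mode_subset)) mode_subset <- seq_along(beta)
  if (length(mode_subset) == 0) {
    warning("empty mode subset: reconstructing a zero map")
    return(surface_map(numeric(nrow(basis$modes)), basis$mesh, mask = mask))
  }
  mode_subset <- as.integer(mode_subset)
  if (max(mode_subset) > length(beta) || min(mode_subset) < 1)
    stop("mode_subset indices outside 1..", length(beta))
  vals <- basis$modes[, mode_subset, drop = FALSE] %*% beta[mode_subset]
  surface_map(as.numeric(vals), basis$mesh, mask = mask)
}

# Slice-of-full-fit truncation (sensitivity alternative to the joint refit
# in project_map): returns the first n entries of a K-mode fit.
beta_slice <- function(basis, map, n_modes) {
  full <- project_map(basis, map)
  full$beta <- full$beta[seq_len(n_modes)]
  full$n_modes <- n_modes
  full
}

#' Tabulate beta spectra
#'
#' Builds a long table of modal coefficients with eigengroup labels and an
#' influence ranking by decreasing `|beta|` (ties broken by lower mode
#' index). Accepts a single `modal_coefficients` object or a named list of
#' them sharing one basis.
#'
#' @param coeffs a `modal_coefficients` or named list thereof.
#' @return data.frame with columns `id` (for list input), `mode`, `group`,
#'   `beta`, `rank_abs`; rows sorted by mode index within id.
#' @export
beta_spectrum_table <- function(coeffs) {
  if (inherits(coeffs, "modal_coefficients")) coeffs <- list(coeffs)
  if (!length(coeffs)) {
    return(data.frame(id = character(0), mode = integer(0),
                      group = integer(0), beta = numeric(0),
                      rank_abs = integer(0)))
  }
  ref <- coeffs[[1]]$basis_evals
  ok <- vapply(coeffs, function(cf) isTRUE(all.equal(cf$basis_evals, ref)),
               logical(1))
  if (!all(ok)) stop("coefficient sets do not share a basis")
  ids <- names(coeffs)
  if (is.null(ids)) ids <- as.character(seq_along(coeffs))
  out <- do.call(rbind, lapply(seq_along(coeffs), function(i) {
    b <- coeffs[[i]]$beta
    k <- length(b)
    ord <- order(-abs(b), seq_len(k))  # desc |beta|, ties -> lower mode
    rank_abs <- integer(k); rank_abs[ord] <- seq_len(k)
    data.frame(id = ids[i], mode = seq_len(k),
               group = as.integer(eigengroup_partition(k)),
               beta = b, rank_abs = rank_abs)
  }))
  rownames(out) <- NULL
  out
}
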