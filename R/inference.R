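# Mode-based group inference: vertex-wise two-sample t maps, their modal
# decomposition, and permutation-based identification of significant
# eigenmodes; plus vertex-threshold/cluster maps for mask building.

#' Vertex-wise pooled-variance two-sample t map
#'
#' For each masked-in vertex, the pooled-variance two-sample t statistic
#' between groups A and B. The default contrast `a_minus_b` with A = HC
#' and B = carriers makes thinner cortex in carriers show as positive t.
#' Vertices with zero pooled variance get t = 0 (counted, not an error);
#' masked-out vertices are set to 0.
#'
#' @param maps_a,maps_b lists of `surface_map`s (>= 2 each) sharing a mesh
#'   and mask, or numeric matrices (vertices x subjects) with `mask` given.
#' @param direction `"a_minus_b"` (default) or `"b_minus_a"`.
#' @param mask required when matrices are supplied.
#' @param mesh required when matrices are supplied.
#' @return a `surface_map` of t values with attributes `df` and
#'   `n_zero_variance`.
#' @export
vertex_tmap <- function(maps_a, maps_b, direction = c("a_minus_b", "b_minus_a"),
                        mask = NULL, mesh = NULL) {
  direction <- match.arg(direction)
  if (is.null(mask)) mask <- shared_mask(c(maps_a, maps_b))
  if (is.null(mesh)) {
    first <- if (inherits(maps_a, "surface_map")) maps_a else maps_a[[1]]
    mesh <- first$mesh
  }
  xa <- stack_maps(maps_a); xb <- stack_maps(maps_b)
  na <- ncol(xa); nb <- ncol(xb)
  if (na < 2 || nb < 2) stop("each group needs >= 2 subjects")
  tvals <- pooled_t(xa[mask, , drop = FALSE], xb[mask, , drop = FALSE])
  if (direction == "b_minus_a") tvals$t <- -tvals$t
  out <- numeric(nrow(xa))
  out[mask] <- tvals$t
  if (tvals$n_zero > 0)
    message(tvals$n_zero, " vertex/vertices with zero pooled variance; t set to 0")
  structure(surface_map(out, mesh, mask = mask, name = "tmap"),
            df = na + nb - 2L, n_zero_variance = tvals$n_zero)
}

# Row-wise pooled two-sample t for matrices (rows = vertices).
pooled_t <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  zero <- !is.finite(t)
  t[zero] <- 0
  list(t = t, n_zero = sum(zero))
}

#' Permutation-based mode-wise group test
#'
#' The mode-based morphometry group analysis: the observed two-sample t
#' map is projected onto the eigenmode basis, and group labels are
#' permuted `n_perm` times to build a per-mode null for `|beta|`. P-values
#' use the add-one estimator `p_k = (1 + #{|beta_null| >= |beta_obs|}) /
#' (n_perm + 1)` (ties count toward the numerator), so `p >= 1/(n_perm+1)`
#' and the observed labeling is implicitly included. Per-mode p-values are
#' not further corrected across modes by default; set `family_wise = TRUE`
#' for a max-|beta| family-wise null.
#'
#' @param maps_a,maps_b per-group lists of `surface_map`s (A = reference,
#'   typically HC) or vertex-by-subject matrices (then give `mask`/`mesh`).
#' @param basis an `eigenmode_basis` on the shared mesh.
#' @param n_modes number of modes tested (default: all basis modes).
#' @param n_perm number of label permutations (>= 1).
#' @param alpha significance level for flagging modes.
#' @param seed integer seed; the result records it and is bit-reproducible.
#' @param direction contrast direction, see [vertex_tmap()].
#' @param family_wise also compute max-|beta| family-wise p-values and use
#'   them for flagging.
#' @param mask,mesh required when `maps_a`/`maps_b` are bare matrices.
#' @param chunk_size permutations processed per block (memory control).
#' @return a `mode_test_result`: list with `tmap`, `beta_obs`, `p_values`,
#'   `significant` (logical), `pattern` (reconstruction over flagged
#'   modes), `ranking` (flagged modes by decreasing `|beta|`), `alpha`,
#'   `n_perm`, `seed`, `df`, and `p_family` when requested.
#' @export
mbm_group_test <- function(maps_a, maps_b, basis, n_modes = NULL,
                           n_perm = 1000, alpha = 0.05, seed = 1,
                           direction = c("a_minus_b", "b_minus_a"),
                           family_wise = FALSE, mask = NULL, mesh = NULL,
                           chunk_size = 2000L) {
  direction <- match.arg(direction)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (1 / (n_perm + 1) > alpha)
    warning("n_perm = ", n_perm, " cannot reach significance at alpha = ",
            alpha, " (minimum attainable p = ", signif(1 / (n_perm + 1), 3), ")")
  if (is.null(n_modes)) n_modes <- basis$n_modes
  if (is.null(mask)) {
    if (!is.list(maps_a)) stop("supply mask/mesh when passing matrices")
    mask <- shared_mask(c(maps_a, maps_b))
  }
  xa <- stack_maps(maps_a); xb <- stack_maps(maps_b)
  na <- ncol(xa); nb <- ncol(xb); n <- na + nb
  if (na < 2 || nb < 2) stop("each group needs >= 2 subjects")

  tmap <- vertex_tmap(xa, xb, direction = direction, mask = mask,
                      mesh = if (is.null(mesh)) basis$mesh else mesh)
  P <- projection_operator(basis, mask, n_modes)
  beta_obs <- as.numeric(P %*% tmap$values[mask])

  x <- cbind(xa, xb)[mask, , drop = FALSE]
  x2 <- x^2
  sgn <- if (direction == "a_minus_b") 1 else -1
  exceed <- integer(n_modes)
  max_null <- numeric(n_perm)
  abs_obs <- abs(beta_obs)

  with_rng_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk_size, n_perm - done)
      ia <- matrix(0, n, m)
      for (p in seq_len(m)) ia[sample.int(n, na), p] <- 1
      meana <- x %*% (ia / na)
      meanb <- x %*% ((1 - ia) / nb)
      ea2 <- x2 %*% (ia / na)
      eb2 <- x2 %*% ((1 - ia) / nb)
      va <- (ea2 - meana^2) * (na / (na - 1))
      vb <- (eb2 - meanb^2) * (nb / (nb - 1))
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
      tn <- sgn * (meana - meanb) / sqrt(sp2 * (1 / na + 1 / nb))
      tn[!is.finite(tn)] <- 0
      bn <- abs(P %*% tn)  # n_modes x m
      exceed <- exceed + rowSums(bn >= abs_obs)
      max_null[done + seq_len(m)] <- apply(bn, 2, max)
      done <- done + m
    }
  })

  p_values <- (1 + exceed) / (n_perm + 1)
  p_family <- (1 + vapply(abs_obs, function(b) sum(max_null >= b),
                          numeric(1))) / (n_perm + 1)
  significant <- if (family_wise) p_family <= alpha else p_values <= alpha
  pattern <- if (any(significant)) {
    reconstruct_map(basis, beta_obs, mode_subset = which(significant),
                    mask = mask)
  } else {
    surface_map(numeric(nrow(basis$modes)), basis$mesh, mask = mask)
  }
  flagged <- which(significant)
  ranking <- flagged[order(-abs_obs[flagged], flagged)]
  structure(list(tmap = tmap, beta_obs = beta_obs, p_values = p_values,
                 significant = significant, pattern = pattern,
                 ranking = ranking, alpha = alpha, n_perm = n_perm,
                 seed = seed, df = attr(tmap, "df"),
                 p_family = if (family_wise) p_family else NULL),
            class = "mode_test_result")
}

#' @export
print.mode_test_result <- function(x, ...) {
  cat(sprintf("mode_test_result: %d modes, %d permutations (seed %s)\n",
              length(x$beta_obs), x$n_perm, format(x$seed)))
  if (length(x$ranking)) {
    cat("significant modes (by decreasing |beta|): ",
        paste(x$ranking, collapse = ", "), "\n", sep = "")
  } else cat("no significant modes at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Threshold a statistic map, optionally with a cluster-area rule
#'
#' Flags vertices with a two-tailed Student p below `p_threshold`; with
#' `min_cluster_area` given, flagged vertices outside edge-connected
#' clusters of at least that surface area are cleared. This deterministic
#' area filter is a deliberate simplification of Monte-Carlo cluster-wise
#' correction.
#'
#' @param stat_map `surface_map` of t statistics.
#' @param df degrees of freedom (>= 1).
#' @param p_threshold vertex-wise two-tailed p threshold.
#' @param min_cluster_area optional minimum cluster surface area (mm^2).
#' @return binary `surface_map` (1 = supra-threshold).
#' @export
threshold_map <- function(stat_map, df, p_threshold = 0.001,
                          min_cluster_area = NULL) {
  if (df < 1) stop("df must be >= 1")
  p <- 2 * stats::pt(-abs(stat_map$values), df = df)
  flag <- stat_map$mask & (p < p_threshold)
  if (!is.null(min_cluster_area) && any(flag)) {
    clusters <- mesh_clusters(stat_map$mesh, which(flag))
    keep <- unlist(lapply(clusters, function(cl)
      if (cl$area >= min_cluster_area) cl$vertices else integer(0)))
    flag <- logical(length(flag))
    flag[keep] <- TRUE
  }
  surface_map(as.numeric(flag), stat_map$mesh, mask = stat_map$mask,
              name = "thresholded")
}
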