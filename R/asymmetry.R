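# Interhemispheric asymmetry: the conventional surface-based index within
# a symmetric bilateral mask, and the mode-based index from the Pearson
# correlation of hemispheric modal coefficient vectors.
#
# Hemisphere convention: both hemispheres share one template topology (the
# right hemisphere is the mirrored template with identical vertex
# indexing), so homotopic correspondence is identity of vertex indices and
# both hemispheres decompose on one shared, sign-aligned basis.

#' Build a symmetric bilateral mask from a significance map
#'
#' Binarizes a p-value map on the dominant hemisphere at `p_threshold` and
#' copies the vertex-index set to the contralateral hemisphere (identity
#' correspondence under the shared-template convention), yielding the
#' symmetric region of interest used by [sbm_ai()].
#'
#' @param p_map `surface_map` of p-values on the dominant hemisphere.
#' @param p_threshold binarization threshold in (0, 1), default 0.05.
#' @return list with logical masks `lh` and `rh` (identical index sets).
#' @export
build_symmetric_mask <- function(p_map, p_threshold = 0.05) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  m <- p_map$mask & (p_map$values < p_threshold)
  if (!any(m))
    stop("empty mask after thresholding at p < ", p_threshold,
         ": asymmetry index undefined")
  list(lh = m, rh = m)
}

#' Conventional surface-based asymmetry index
#'
#' The normalized interhemispheric mean-thickness difference
#' `AI = (CT_RH - CT_LH) / (0.5 * (CT_RH + CT_LH))` over the bilateral
#' mask, plus the similarity transform `1 - |AI|` used when values near 1
#' should indicate interhemispheric similarity.
#'
#' @param lh_map,rh_map thickness `surface_map`s on the shared template.
#' @param bilateral_mask result of [build_symmetric_mask()], or a single
#'   logical vector applied to both hemispheres.
#' @return list with `raw` (signed) and `similarity` (`1 - |raw|`).
#' @export
sbm_ai <- function(lh_map, rh_map, bilateral_mask) {
  if (is.logical(bilateral_mask))
    bilateral_mask <- list(lh = bilateral_mask, rh = bilateral_mask)
  ct_lh <- mean(lh_map$values[bilateral_mask$lh])
  ct_rh <- mean(rh_map$values[bilateral_mask$rh])
  denom <- 0.5 * (ct_rh + ct_lh)
  if (abs(denom) < .Machine$double.eps)
    stop("undefined asymmetry index: mean thickness sums to zero")
  raw <- (ct_rh - ct_lh) / denom
  list(raw = raw, similarity = 1 - abs(raw))
}

#' Mode-based asymmetry index
#'
#' Projects each hemisphere's thickness map onto the first `n_modes` modes
#' of the shared sign-aligned basis (joint least squares within each
#' hemisphere's cortex mask) and returns the absolute Pearson correlation
#' of the two coefficient vectors. Values near 1 indicate interhemispheric
#' similarity; lower values indicate greater asymmetry. The constant mode
#' is included by default, per the first-`N`-modes convention.
#'
#' @param lh_map,rh_map thickness `surface_map`s on the shared template.
#' @param basis shared `eigenmode_basis`.
#' @param n_modes truncation (>= 3), default 25 (first four eigengroups).
#' @param include_constant drop the constant mode when `FALSE`.
#' @return `|cor(beta_LH, beta_RH)|` in `[0, 1]`.
#' @export
mbm_ai <- function(lh_map, rh_map, basis, n_modes = 25,
                   include_constant = TRUE) {
  if (n_modes < 3) stop("n_modes must be >= 3")
  b_lh <- project_map(basis, lh_map, n_modes = n_modes)$beta
  b_rh <- project_map(basis, rh_map, n_modes = n_modes)$beta
  if (!include_constant) {
    b_lh <- b_lh[-1]; b_rh <- b_rh[-1]
  }
  if (stats::sd(b_lh) < .Machine$double.eps ||
      stats::sd(b_rh) < .Machine$double.eps)
    stop("undefined correlation: zero variance in a beta vector")
  abs(stats::cor(b_lh, b_rh))
}

#' Per-subject asymmetry table for a cohort
#'
#' Computes the raw and similarity-form conventional index and the
#' mode-based index for every subject, returning one row per subject in
#' subject-id order. Subjects missing either hemisphere are skipped with a
#' warning.
#'
#' @param cohort an `mbm_cohort` (see [generate_cohort()]) or a list with
#'   `subjects` (data.frame with `subject_id`, `group`), `thickness_lh`,
#'   `thickness_rh` (vertex-by-subject matrices), `mask`, `mesh_lh`.
#' @param basis shared `eigenmode_basis`.
#' @param bilateral_mask mask for the conventional index
#'   (see [build_symmetric_mask()]).
#' @param n_modes mode count for the mode-based index, default 25.
#' @return data.frame: `subject_id`, `group`, `sbm_ai_raw`,
#'   `sbm_ai_similarity`, `mbm_ai`, `n_modes`.
#' @export
asymmetry_table <- function(cohort, basis, bilateral_mask, n_modes = 25) {
  subj <- cohort$subjects
  if (!nrow(subj)) {
    return(data.frame(subject_id = character(0), group = character(0),
                      sbm_ai_raw = numeric(0), sbm_ai_similarity = numeric(0),
                      mbm_ai = numeric(0), n_modes = integer(0)))
  }
  ord <- order(subj$subject_id)
  rows <- lapply(ord, function(i) {
    id <- subj$subject_id[i]
    lh <- cohort$thickness_lh[, i]
    rh <- cohort$thickness_rh[, i]
    if (anyNA(lh) || anyNA(rh)) {
      warning("subject ", id, " missing a hemisphere; skipped")
      return(NULL)
    }
    lmap <- surface_map(lh, cohort$mesh_lh, mask = cohort$mask)
    rmap <- surface_map(rh, cohort$mesh_lh, mask = cohort$mask)
    s <- sbm_ai(lmap, rmap, bilateral_mask)
    m <- mbm_ai(lmap, rmap, basis, n_modes = n_modes)
    data.frame(subject_id = id, group = subj$group[i], sbm_ai_raw = s$raw,
               sbm_ai_similarity = s$similarity, mbm_ai = m,
               n_modes = as.integer(n_modes))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- asymmetry_table(list(subjects = subj[0, ]), basis,
                                           bilateral_mask, n_modes)
  rownames(out) <- NULL
  out
}
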