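# End-to-end orchestration: configuration, the full analysis pipeline,
# cohort serialization, and a reproducibility manifest.

#' Pipeline configuration
#'
#' Defaults follow the reference analysis design: 150 basis modes, 25
#' modes (first four eigengroups) for the asymmetry index, 10000 label
#' permutations at alpha 0.05, vertex-wise p < 0.001 with a 100 mm^2
#' cluster rule for the thresholded t map, and p < 0.05 for the bilateral
#' mask.
#'
#' @param n_modes_basis eigenmodes computed on the template.
#' @param n_modes_ai modes entering the mode-based asymmetry index.
#' @param n_perm label permutations for the mode-wise test.
#' @param alpha mode-wise significance level.
#' @param vertex_p vertex-wise two-tailed p threshold for t-map display.
#' @param mask_p binarization threshold for the bilateral mask.
#' @param cluster_area minimum cluster surface area (mm^2).
#' @param seed master seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_modes_basis = 150L, n_modes_ai = 25L,
                            n_perm = 10000L, alpha = 0.05,
                            vertex_p = 0.001, mask_p = 0.05,
                            cluster_area = 100, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, vertex_p > 0, vertex_p < 1,
            mask_p > 0, mask_p < 1, n_modes_basis >= 1, n_modes_ai >= 1,
            n_perm >= 1, cluster_area >= 0)
  structure(list(n_modes_basis = as.integer(n_modes_basis),
                 n_modes_ai = as.integer(n_modes_ai),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 vertex_p = vertex_p, mask_p = mask_p,
                 cluster_area = cluster_area, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline or simulation configuration from YAML/JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose top-level keys match
#'   the arguments of [pipeline_config()] or [simulation_config()].
#' @param type `"pipeline"` or `"simulation"`.
#' @return the corresponding config object.
#' @export
read_config <- function(path, type = c("pipeline", "simulation")) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  fn <- if (type == "pipeline") pipeline_config else simulation_config
  keep <- intersect(names(vals), names(formals(fn)))
  do.call(fn, vals[keep])
}

#' Run the full mode-based morphometry pipeline on a cohort
#'
#' Computes the eigenmode basis on the shared template; runs the mode-wise
#' permutation contrasts symptomatic-vs-HC and presymptomatic-vs-HC on the
#' left hemisphere (and the symptomatic contrast on the right); builds the
#' symmetric bilateral mask from the symptomatic-vs-HC vertex t map
#' (two-tailed p < `mask_p`); computes per-subject asymmetry indices;
#' compares them across groups and across CDR stages (Kruskal-Wallis +
#' Dunn/BH + Cohen's d); correlates them with TMT scores in symptomatic
#' subjects (Spearman); and regresses CDR and TMT scores on the
#' significant-mode weights (left and right jointly). All tables are
#' written under `out_dir` together with a manifest (config, seed, file
#' MD5 hashes); the run is deterministic given the seed.
#'
#' @param cohort an `mbm_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the computed objects: `basis`,
#'   `contrasts`, `bilateral_mask`, `asymmetry`, `group_tests`,
#'   `cdr_tests`, `spearman`, `glm`, `manifest`.
#' @export
run_full_pipeline <- function(cohort, config = pipeline_config(),
                              out_dir = NULL) {
  stage <- "basis"
  res <- tryCatch({
    basis <- cohort$basis
    if (is.null(basis) || basis$n_modes < config$n_modes_basis)
      basis <- compute_eigenmodes(cohort$mesh_lh, config$n_modes_basis)
    grp <- cohort$subjects$group
    take <- function(hemi, g) cohort[[hemi]][, grp == g, drop = FALSE]
    mk_test <- function(hemi, g, seed_off) {
      stage <<- paste0("mode test ", hemi, " ", g, " vs hc")
      mbm_group_test(take(hemi, "hc"), take(hemi, g), basis,
                     n_modes = config$n_modes_basis, n_perm = config$n_perm,
                     alpha = config$alpha,
                     seed = derive_seed(config$seed, seed_off),
                     mask = cohort$mask, mesh = cohort$mesh_lh)
    }
    contrasts <- list(
      lh_symptomatic_vs_hc = mk_test("thickness_lh", "symptomatic", 1),
      lh_presymptomatic_vs_hc = mk_test("thickness_lh", "presymptomatic", 2),
      rh_symptomatic_vs_hc = mk_test("thickness_rh", "symptomatic", 3))

    stage <- "bilateral mask"
    tmap <- contrasts$lh_symptomatic_vs_hc$tmap
    pmap <- surface_map(2 * stats::pt(-abs(tmap$values), df = attr(tmap, "df")),
                        cohort$mesh_lh, mask = cohort$mask)
    bmask <- build_symmetric_mask(pmap, config$mask_p)

    stage <- "asymmetry indices"
    ai <- asymmetry_table(cohort, basis, bmask, n_modes = config$n_modes_ai)

    stage <- "group statistics"
    subj <- cohort$subjects[match(ai$subject_id, cohort$subjects$subject_id), ]
    group_tests <- lapply(c(mbm_ai = "mbm_ai", sbm_ai = "sbm_ai_similarity"),
                          function(col) list(
      omnibus = kruskal_wallis(ai[[col]], ai$group),
      pairwise = dunn_posthoc_bh(ai[[col]], ai$group)))

    stage <- "CDR staging"
    cdr_group <- ifelse(subj$group == "hc", "HC",
                        paste0("CDR", format(subj$cdr)))
    cdr_tests <- lapply(c(mbm_ai = "mbm_ai", sbm_ai = "sbm_ai_similarity"),
                        function(col) list(
      omnibus = kruskal_wallis(ai[[col]], cdr_group),
      pairwise = dunn_posthoc_bh(ai[[col]], cdr_group)))

    stage <- "Spearman AI vs TMT"
    sym <- subj$group == "symptomatic"
    spearman <- do.call(rbind, lapply(
      expand.grid(index = c("mbm_ai", "sbm_ai_similarity"),
                  score = c("tmt_a", "tmt_b"),
                  stringsAsFactors = FALSE) |> split(seq_len(4)),
      function(cell) {
        sc <- spearman_correlation(ai[[cell$index]][sym],
                                   subj[[cell$score]][sym])
        data.frame(index = cell$index, score = cell$score, rho = sc$rho,
                   p = sc$p_value, n = sc$n_used)
      }))
    rownames(spearman) <- NULL

    stage <- "mode-wise GLM"
    glm_tab <- modewise_clinical_glm(cohort, basis, contrasts, config)

    stage <- "outputs"
    manifest <- NULL
    if (!is.null(out_dir)) {
      manifest <- write_pipeline_outputs(out_dir, cohort, config, basis,
                                         contrasts, bmask, ai, group_tests,
                                         cdr_tests, spearman, glm_tab)
    }
    list(basis = basis, contrasts = contrasts, bilateral_mask = bmask,
         asymmetry = ai, group_tests = group_tests, cdr_tests = cdr_tests,
         spearman = spearman, glm = glm_tab, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# Joint regression of each clinical outcome on the significant-mode
# weights of both hemispheres (recovered per subject by least squares).
modewise_clinical_glm <- function(cohort, basis, contrasts, config) {
  sig_lh <- which(contrasts$lh_symptomatic_vs_hc$significant)
  sig_rh <- which(contrasts$rh_symptomatic_vs_hc$significant)
  if (!length(sig_lh) && !length(sig_rh)) return(NULL)
  pr <- projection_operator(basis, cohort$mask, config$n_modes_basis)
  bl <- pr %*% cohort$thickness_lh[cohort$mask, , drop = FALSE]
  br <- pr %*% cohort$thickness_rh[cohort$mask, , drop = FALSE]
  x <- cbind(if (length(sig_lh)) t(bl[sig_lh, , drop = FALSE]),
             if (length(sig_rh)) t(br[sig_rh, , drop = FALSE]))
  colnames(x) <- c(if (length(sig_lh)) paste0("lh_mode_", sig_lh),
                   if (length(sig_rh)) paste0("rh_mode_", sig_rh))
  subj <- cohort$subjects
  carriers <- subj$group != "hc"
  sym <- subj$group == "symptomatic"
  fit_one <- function(outcome, rows, label) {
    keep <- rows & !is.na(outcome)
    if (sum(keep) < ncol(x) + 2) return(NULL)
    fit <- tryCatch(modewise_glm(outcome[keep], x[keep, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cbind(outcome = label, fit)
  }
  out <- rbind(fit_one(subj$cdr, carriers, "cdr"),
               fit_one(subj$tmt_a, sym, "tmt_a"),
               fit_one(subj$tmt_b, sym, "tmt_b"))
  if (!is.null(out)) rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(out_dir, cohort, config, basis, contrasts,
                                   bmask, ai, group_tests, cdr_tests,
                                   spearman, glm_tab) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    p
  }
  files <- character(0)
  part <- eigengroup_partition(basis$n_modes)
  files <- c(files, wcsv(data.frame(mode = seq_len(basis$n_modes),
                                    lambda = basis$evals,
                                    group = as.integer(part)),
                         "eigenvalues.csv"))
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    files <- c(files, wcsv(data.frame(
      mode = seq_along(ct$beta_obs), beta = ct$beta_obs,
      p = ct$p_values, significant = ct$significant), paste0(nm, "_modes.csv")))
    tp <- file.path(out_dir, paste0(nm, "_tmap.csv"))
    write_surface_map(ct$tmap, tp)
    files <- c(files, tp)
  }
  mp <- file.path(out_dir, "bilateral_mask.label")
  write_label(bmask$lh, cohort$mesh_lh, mp)
  files <- c(files, mp, wcsv(ai, "asymmetry.csv"))
  flat_tests <- function(tl) do.call(rbind, lapply(names(tl), function(ix) {
    pw <- tl[[ix]]$pairwise
    cbind(index = ix, omnibus_H = tl[[ix]]$omnibus$statistic,
          omnibus_p = tl[[ix]]$omnibus$p_value, pw)
  }))
  files <- c(files, wcsv(flat_tests(group_tests), "ai_group_tests.csv"),
             wcsv(flat_tests(cdr_tests), "ai_cdr_tests.csv"),
             wcsv(spearman, "ai_tmt_spearman.csv"))
  if (!is.null(glm_tab)) files <- c(files, wcsv(glm_tab, "modewise_glm.csv"))
  sig <- lapply(contrasts, function(ct)
    list(significant_modes = as.integer(ct$ranking),
         n_perm = ct$n_perm, seed = ct$seed))
  jp <- file.path(out_dir, "mode_tests.json")
  jsonlite::write_json(sig, jp, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, jp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mbmorph")),
    seed = config$seed,
    config = unclass(config),
    n_subjects = nrow(cohort$subjects),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Write a cohort to disk in the pipeline's standard formats
#'
#' Meshes as VTK legacy ASCII, thickness maps as per-subject CSV maps,
#' the cortex mask as a label file, and the clinical table as CSV, so a
#' serialized synthetic cohort is consumed identically to real data.
#'
#' @param cohort an `mbm_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "maps"), showWarnings = FALSE, recursive = TRUE)
  write_mesh(cohort$mesh_lh, file.path(dir, "template_lh.vtk"))
  write_mesh(cohort$mesh_rh, file.path(dir, "template_rh.vtk"))
  write_label(cohort$mask, cohort$mesh_lh, file.path(dir, "cortex.label"))
  utils::write.csv(cohort$subjects, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    write_surface_map(surface_map(cohort$thickness_lh[, i], cohort$mesh_lh),
                      file.path(dir, "maps", paste0(sid, "_lh.csv")))
    write_surface_map(surface_map(cohort$thickness_rh[, i], cohort$mesh_rh),
                      file.path(dir, "maps", paste0(sid, "_rh.csv")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `template_lh.vtk`, `template_rh.vtk`,
#'   `cortex.label`, `clinical.csv` and `maps/<subject>_<hemi>.csv`.
#' @return an `mbm_cohort` (without ground truth or basis).
#' @export
read_cohort <- function(dir) {
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) stop("missing clinical table: ", clin_path)
  subjects <- utils::read.csv(clin_path)
  mesh_lh <- read_mesh(file.path(dir, "template_lh.vtk"))
  mesh_rh <- read_mesh(file.path(dir, "template_rh.vtk"))
  mask <- read_label(file.path(dir, "cortex.label"), mesh_lh)
  get_maps <- function(hemi) vapply(subjects$subject_id, function(sid) {
    p <- file.path(dir, "maps", paste0(sid, "_", hemi, ".csv"))
    if (!file.exists(p)) stop("missing map file: ", p)
    read_surface_map(p, mesh_lh)$values
  }, numeric(n_vertices(mesh_lh)))
  structure(list(subjects = subjects,
                 thickness_lh = get_maps("lh"), thickness_rh = get_maps("rh"),
                 mesh_lh = mesh_lh, mesh_rh = mesh_rh, mask = mask,
                 basis = NULL, config = NULL, ground_truth = NULL),
            class = "mbm_cohort")
}
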