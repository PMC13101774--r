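# Synthetic two-hemisphere cortical cohorts with planted modal atrophy,
# controlled asymmetry and linked clinical scores.
#
# The generator emulates a three-group genetic-FTD study design: healthy
# controls, presymptomatic mutation carriers (no structural effect), and
# symptomatic carriers whose left-lateralized atrophy is expressed in
# low-order geometric eigenmodes, attenuated on the right hemisphere, on
# top of a shared smooth baseline thickness and i.i.d. vertex noise.
# Trail-Making completion times are linear functions of each subject's
# planted left-hemisphere modal weights; disease stage (CDR-like score)
# scales atrophy severity.

#' Simulation configuration
#'
#' Returns the default study design; any field can be overridden. Planted
#' mode amplitudes are expressed in mm of root-mean-square thickness
#' change over the surface (modes are rescaled to unit spatial RMS before
#' planting), so amplitudes and `noise_sd` share units.
#'
#' @param group_sizes named integer vector `hc`, `presymptomatic`,
#'   `symptomatic`.
#' @param subdivisions,radius icosphere template: subdivision level and
#'   radius (mm). Radius 90 mm gives a hemispheric surface area close to
#'   the human value (~1000 cm^2).
#' @param perturbation relative amplitude of a smooth non-spherical radial
#'   deformation of the template (0 = pure sphere).
#' @param mask_cap_degrees angular radius of the excluded medial-wall cap
#'   around the +x pole (the mirror plane side).
#' @param baseline_mean mean cortical thickness (mm).
#' @param baseline_coeffs named vector: baseline modal coefficients
#'   (mm RMS) on low-order modes, shared by all subjects and hemispheres.
#' @param atrophy_lh named vector: symptomatic left-hemisphere atrophy
#'   amplitudes (mm RMS) per mode.
#' @param rh_ratio right-to-left atrophy ratio applied on `rh_modes`.
#' @param rh_modes modes carrying right-hemisphere atrophy.
#' @param mode_jitter_sd per-subject, per-mode amplitude heterogeneity
#'   (added to the stage severity multiplier).
#' @param noise_sd i.i.d. Gaussian vertex noise (mm).
#' @param thickness_floor lower clip for generated thickness (mm).
#' @param cdr_probs per-group probability vectors over CDR stages
#'   0, 0.5, 1, 2, 3.
#' @param stage_weights atrophy severity multiplier per CDR stage.
#' @param tmt_a,tmt_b clinical linkage: list with `intercept`, `coef`
#'   (named by mode, seconds per mm-RMS of planted modal weight), `sd`
#'   (residual seconds). Scores are generated for symptomatic subjects
#'   only and floored at 10 s.
#' @param basis_modes number of eigenmodes computed on the template.
#' @param seed master seed; all randomness derives from it via per-subject
#'   sub-seeds, so cohorts are reproducible and per-subject streams do not
#'   shift when other groups change size.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    group_sizes = c(hc = 19L, presymptomatic = 15L, symptomatic = 27L),
    subdivisions = 3L, radius = 90, perturbation = 0,
    mask_cap_degrees = 25,
    baseline_mean = 2.5,
    baseline_coeffs = c(`2` = 0.12, `3` = -0.08, `4` = 0.06, `5` = -0.05,
                        `6` = 0.05, `7` = -0.04, `8` = 0.04, `9` = 0.06,
                        `10` = -0.05, `11` = 0.04, `12` = -0.03, `13` = 0.05),
    atrophy_lh = c(`1` = 0.15, `2` = 0.10, `9` = 0.08, `10` = 0.08,
                   `13` = 0.12),
    rh_ratio = 0.4, rh_modes = c(9L, 13L),
    mode_jitter_sd = 0.35, noise_sd = 0.1, thickness_floor = 0.1,
    cdr_probs = list(
      hc = c(`0` = 1, `0.5` = 0, `1` = 0, `2` = 0, `3` = 0),
      presymptomatic = c(`0` = 9 / 15, `0.5` = 6 / 15, `1` = 0, `2` = 0,
                         `3` = 0),
      symptomatic = c(`0` = 0, `0.5` = 6 / 27, `1` = 7 / 27, `2` = 11 / 27,
                      `3` = 3 / 27)),
    stage_weights = c(`0` = 0, `0.5` = 0.5, `1` = 0.8, `2` = 1.2, `3` = 1.4),
    tmt_a = list(intercept = 150, coef = c(`9` = -800, `13` = -1200), sd = 30),
    tmt_b = list(intercept = 420, coef = c(`9` = -600, `13` = -800), sd = 60),
    basis_modes = 150L, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(all(cfg$group_sizes >= 0), cfg$noise_sd >= 0,
            cfg$mode_jitter_sd >= 0, cfg$radius > 0, cfg$subdivisions >= 0,
            all(is.finite(cfg$atrophy_lh)), all(is.finite(cfg$baseline_coeffs)),
            cfg$rh_ratio >= 0, cfg$basis_modes >= max(
              c(1L, as.integer(names(cfg$atrophy_lh)),
                as.integer(names(cfg$baseline_coeffs)))))
  for (g in names(cfg$cdr_probs)) {
    p <- cfg$cdr_probs[[g]]
    if (abs(sum(p) - 1) > 1e-8) stop("cdr_probs for ", g, " do not sum to 1")
    if (any(p < 0)) stop("negative cdr probability for ", g)
  }
  invisible(cfg)
}

#' Generate the shared left/right template meshes
#'
#' The left-hemisphere template is a (optionally smoothly perturbed)
#' icosphere; the right hemisphere is its mirror image across the x = 0
#' plane with identical vertex indexing, so homotopic correspondence is
#' vertex-index identity and the two meshes are exactly isometric.
#'
#' @param config a `simulation_config` (only the template fields are used).
#' @return list with `lh` and `rh` (`triangle_mesh`), plus `mask` (logical
#'   cortex mask excluding the medial-wall cap).
#' @export
generate_template_pair <- function(config = simulation_config()) {
  lh <- make_icosphere(config$subdivisions, config$radius)
  if (config$perturbation != 0) {
    u <- lh$vertices / config$radius
    bump <- u[, 1] * u[, 2] + 0.5 * u[, 1] * u[, 3] + 0.3 * u[, 2] * u[, 3]
    bump <- bump / max(abs(bump))
    lh$vertices <- lh$vertices * (1 + config$perturbation * bump)
    if (any(face_areas(lh) <= .Machine$double.eps) || flipped_faces(lh))
      stop("template perturbation ", config$perturbation,
           " flips or degenerates triangles")
  }
  lh$name <- "lh"
  rv <- lh$vertices
  rv[, 1] <- -rv[, 1]
  # mirroring reverses orientation; swap two face indices to restore it
  rh <- triangle_mesh(rv, lh$faces[, c(1, 3, 2)], name = "rh", check = FALSE)
  cap <- cos(config$mask_cap_degrees * pi / 180)
  mask <- lh$vertices[, 1] / sqrt(rowSums(lh$vertices^2)) < cap
  list(lh = lh, rh = rh, mask = mask)
}

flipped_faces <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  any(rowSums(cent * cbind(nx, ny, nz)) <= 0)
}

#' Generate a synthetic cohort with ground truth
#'
#' Each subject's hemisphere map is `baseline - atrophy + noise`:
#' a shared smooth baseline (mean thickness plus low-order modal
#' structure), minus the group's planted modal atrophy scaled by the
#' subject's stage severity and per-mode jitter (right hemisphere
#' attenuated by `rh_ratio` on `rh_modes`), plus i.i.d. Gaussian vertex
#' noise, clipped at `thickness_floor` (clip count reported via message).
#' Only the symptomatic group carries atrophy. TMT-A/TMT-B are linear in
#' the subject's planted left-hemisphere modal weights.
#'
#' @param config a `simulation_config`.
#' @param basis optional precomputed `eigenmode_basis` on the template
#'   (with at least `basis_modes` modes); computed if missing.
#' @return an `mbm_cohort`: list with `subjects` (data.frame:
#'   `subject_id`, `group`, `cdr`, `tmt_a`, `tmt_b`), `thickness_lh`,
#'   `thickness_rh` (vertex x subject matrices), `mesh_lh`, `mesh_rh`,
#'   `mask`, `basis`, `config`, `ground_truth` (per-subject planted modal
#'   deficits in mm RMS, severities, linkage coefficients, seeds).
#' @export
generate_cohort <- function(config = simulation_config(), basis = NULL) {
  validate_simulation_config(config)
  tpl <- generate_template_pair(config)
  if (is.null(basis))
    basis <- compute_eigenmodes(tpl$lh, config$basis_modes)
  total_area <- sum(basis$mass)
  rms_scale <- sqrt(total_area)  # mass-orthonormal -> unit-RMS conversion

  base_modes <- as.integer(names(config$baseline_coeffs))
  baseline <- config$baseline_mean +
    as.numeric(basis$modes[, base_modes, drop = FALSE] %*%
                 (config$baseline_coeffs * rms_scale))

  atr_modes <- as.integer(names(config$atrophy_lh))
  amp_lh <- unname(config$atrophy_lh)
  amp_rh <- ifelse(atr_modes %in% config$rh_modes,
                   amp_lh * config$rh_ratio, 0)
  stage_levels <- as.numeric(names(config$stage_weights))

  # config sanity: worst-case expected map must stay positive
  worst <- baseline - max(config$stage_weights) *
    as.numeric(basis$modes[, atr_modes, drop = FALSE] %*% (amp_lh * rms_scale))
  if (mean(worst[tpl$mask] <= 0) > 0.01)
    stop("config error: atrophy drives expected thickness <= 0 at >1% of ",
         "cortex vertices")

  groups <- c("hc", "presymptomatic", "symptomatic")
  nv <- n_vertices(tpl$lh)
  n_tot <- sum(config$group_sizes)
  th_lh <- matrix(NA_real_, nv, n_tot)
  th_rh <- matrix(NA_real_, nv, n_tot)
  subj <- vector("list", n_tot)
  gt <- vector("list", n_tot)
  n_clipped <- 0L
  col <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (i in seq_len(config$group_sizes[[g]])) {
      col <- col + 1L
      sid <- sprintf("%s%02d", c(hc = "hc", presymptomatic = "pre",
                                 symptomatic = "sym")[[g]], i)
      sseed <- derive_seed(config$seed, gi, i)
      draws <- with_rng_seed(sseed, {
        cdr <- sample(stage_levels, 1, prob = cfg_probs(config, g))
        jitter <- stats::rnorm(length(atr_modes), 0, config$mode_jitter_sd)
        noise_l <- stats::rnorm(nv, 0, config$noise_sd)
        noise_r <- stats::rnorm(nv, 0, config$noise_sd)
        eps_tmt <- stats::rnorm(2)
        list(cdr = cdr, jitter = jitter, noise_l = noise_l,
             noise_r = noise_r, eps_tmt = eps_tmt)
      })
      sev <- unname(config$stage_weights[as.character(draws$cdr)])
      has_atrophy <- g == "symptomatic"
      mult <- if (has_atrophy) pmax(sev + draws$jitter, 0) else rep(0, length(atr_modes))
      def_lh <- amp_lh * mult
      def_rh <- amp_rh * mult
      map_l <- baseline -
        as.numeric(basis$modes[, atr_modes, drop = FALSE] %*% (def_lh * rms_scale)) +
        draws$noise_l
      map_r <- baseline -
        as.numeric(basis$modes[, atr_modes, drop = FALSE] %*% (def_rh * rms_scale)) +
        draws$noise_r
      n_clipped <- n_clipped + sum(map_l < config$thickness_floor) +
        sum(map_r < config$thickness_floor)
      th_lh[, col] <- pmax(map_l, config$thickness_floor)
      th_rh[, col] <- pmax(map_r, config$thickness_floor)

      # planted LH modal weights (mm RMS) for the clinical linkage
      beta_planted <- stats::setNames(rep(0, length(union(base_modes, atr_modes))),
                                      sort(union(base_modes, atr_modes)))
      beta_planted[as.character(base_modes)] <- config$baseline_coeffs
      beta_planted[as.character(atr_modes)] <-
        beta_planted[as.character(atr_modes)] - def_lh
      tmt <- c(NA_real_, NA_real_)
      if (g == "symptomatic") {
        tmt[1] <- max(10, config$tmt_a$intercept +
          sum(config$tmt_a$coef * beta_planted[names(config$tmt_a$coef)]) +
          draws$eps_tmt[1] * config$tmt_a$sd)
        tmt[2] <- max(10, config$tmt_b$intercept +
          sum(config$tmt_b$coef * beta_planted[names(config$tmt_b$coef)]) +
          draws$eps_tmt[2] * config$tmt_b$sd)
      }
      subj[[col]] <- data.frame(subject_id = sid, group = g, cdr = draws$cdr,
                                tmt_a = tmt[1], tmt_b = tmt[2])
      gt[[col]] <- data.frame(subject_id = sid, mode = atr_modes,
                              deficit_lh = def_lh, deficit_rh = def_rh,
                              severity = sev, seed = sseed)
    }
  }
  if (n_clipped > 0)
    message(n_clipped, " vertex value(s) clipped at the ",
            config$thickness_floor, " mm floor")
  structure(list(
    subjects = do.call(rbind, subj),
    thickness_lh = th_lh, thickness_rh = th_rh,
    mesh_lh = tpl$lh, mesh_rh = tpl$rh, mask = tpl$mask, basis = basis,
    config = config,
    ground_truth = list(deficits = do.call(rbind, gt),
                        tmt_a = config$tmt_a, tmt_b = config$tmt_b,
                        master_seed = config$seed)),
    class = "mbm_cohort")
}

cfg_probs <- function(config, group) {
  p <- config$cdr_probs[[group]]
  p[as.character(as.numeric(names(config$stage_weights)))]
}

#' @export
print.mbm_cohort <- function(x, ...) {
  cat(sprintf("mbm_cohort: %s on %d vertices (seed %s)\n",
              paste(sprintf("%d %s", table(x$subjects$group)[unique(x$subjects$group)],
                            unique(x$subjects$group)), collapse = ", "),
              nrow(x$thickness_lh), format(x$config$seed)))
  invisible(x)
}

#' Power / type-I recovery experiment over an atrophy-amplitude grid
#'
#' For each amplitude scale and replicate, generates a cohort with the
#' left-hemisphere (and proportionally right-hemisphere) atrophy
#' amplitudes multiplied by the scale, runs the mode-wise permutation test
#' (symptomatic vs HC), the asymmetry indices, and optionally the clinical
#' mode-wise regression, and tabulates detection and recovery metrics.
#' Replicate seeds are shared across scales (common random numbers), so
#' amplitude sweeps are paired.
#'
#' @param config base `simulation_config`.
#' @param amplitude_scales numeric vector of multipliers (0 = null).
#' @param n_replicates replicate cohorts per scale.
#' @param n_perm permutations for the mode test.
#' @param n_modes_test modes tested (default 150 or basis size).
#' @param alpha significance level.
#' @param seed experiment seed (drives replicate sub-seeds).
#' @param include_glm also fit TMT-A ~ planted-linkage-mode weights per
#'   replicate and record whether all linkage coefficients reach p < 0.05.
#' @return list with `replicates` (one row per scale x replicate:
#'   `reject_frac` mean per-mode rejection rate, `all_planted_detected`,
#'   `top_ranked_planted`, group means of both asymmetry indices,
#'   `glm_recovered`) and `cells` (per-scale means with Monte-Carlo
#'   standard errors).
#' @export
run_recovery_experiment <- function(config = simulation_config(),
                                    amplitude_scales = c(0, 0.5, 1, 1.5, 2),
                                    n_replicates = 20, n_perm = 100,
                                    n_modes_test = NULL, alpha = 0.05,
                                    seed = 1, include_glm = FALSE) {
  tpl <- generate_template_pair(config)
  basis <- compute_eigenmodes(tpl$lh, config$basis_modes)
  if (is.null(n_modes_test)) n_modes_test <- config$basis_modes
  planted <- as.integer(names(config$atrophy_lh))
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, 500, r)
    for (s in amplitude_scales) {
      cfg <- config
      cfg$atrophy_lh <- config$atrophy_lh * s
      cfg$seed <- rep_seed
      cohort <- generate_cohort(cfg, basis = basis)
      is_hc <- cohort$subjects$group == "hc"
      is_sym <- cohort$subjects$group == "symptomatic"
      test <- mbm_group_test(
        cohort$thickness_lh[, is_hc, drop = FALSE],
        cohort$thickness_lh[, is_sym, drop = FALSE],
        basis, n_modes = n_modes_test, n_perm = n_perm, alpha = alpha,
        seed = derive_seed(rep_seed, 7, round(s * 1000)),
        mask = cohort$mask, mesh = cohort$mesh_lh)
      ai <- asymmetry_table(cohort, basis, bilateral_mask = cohort$mask)
      ai_mean <- function(g, col) mean(ai[[col]][ai$group == g])
      glm_rec <- NA
      if (include_glm && sum(is_sym) >= length(config$tmt_a$coef) + 2) {
        link_modes <- as.integer(names(config$tmt_a$coef))
        pr <- projection_operator(basis, cohort$mask, max(link_modes))
        bet <- pr %*% cohort$thickness_lh[cohort$mask, is_sym, drop = FALSE]
        x <- t(bet[link_modes, , drop = FALSE])
        colnames(x) <- paste0("mode_", link_modes)
        fit <- modewise_glm(cohort$subjects$tmt_a[is_sym], x)
        pv <- fit$p[match(colnames(x), fit$term)]
        glm_rec <- all(pv < 0.05)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scale = s, replicate = r,
        reject_frac = mean(test$significant),
        all_planted_detected = all(test$significant[planted]),
        top_ranked_planted = length(test$ranking) > 0 &&
          test$ranking[1] %in% planted,
        mbm_ai_hc = ai_mean("hc", "mbm_ai"),
        mbm_ai_symptomatic = ai_mean("symptomatic", "mbm_ai"),
        sbm_ai_hc = ai_mean("hc", "sbm_ai_similarity"),
        sbm_ai_symptomatic = ai_mean("symptomatic", "sbm_ai_similarity"),
        glm_recovered = glm_rec)
    }
  }
  reps <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  cells <- do.call(rbind, lapply(split(reps, reps$scale), function(d) {
    data.frame(scale = d$scale[1],
               reject_frac = mean(d$reject_frac),
               reject_frac_se = stats::sd(d$reject_frac) / sqrt(nrow(d)),
               detection_rate = mean(d$all_planted_detected),
               top_rank_rate = mean(d$top_ranked_planted),
               mbm_ai_hc = mean(d$mbm_ai_hc),
               mbm_ai_symptomatic = mean(d$mbm_ai_symptomatic),
               sbm_ai_symptomatic = mean(d$sbm_ai_symptomatic),
               glm_recovery_rate = mean(d$glm_recovered))
  }))
  rownames(cells) <- NULL
  list(replicates = reps, cells = cells)
}
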