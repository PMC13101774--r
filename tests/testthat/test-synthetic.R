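# Synthetic cohort generator: templates, determinism, planted effects,
# clinical linkage.

test_that("template pair is an exactly mirrored isometric couple", {
  cfg <- simulation_config(subdivisions = 2, radius = 50)
  tpl <- generate_template_pair(cfg)
  ico <- make_icosphere(2, 50)
  expect_equal(tpl$lh$vertices, ico$vertices, ignore_attr = TRUE)
  expect_equal(tpl$rh$vertices[, 1], -tpl$lh$vertices[, 1])
  expect_equal(tpl$rh$vertices[, 2:3], tpl$lh$vertices[, 2:3])
  expect_silent(validate_mesh(tpl$rh))
  # mirror isometry: identical LBO spectra
  e_lh <- compute_eigenmodes(tpl$lh, 15)$evals
  e_rh <- compute_eigenmodes(tpl$rh, 15)$evals
  expect_equal(e_rh, e_lh, tolerance = 1e-10)
  # medial-wall cap excluded from the cortex mask
  expect_true(mean(tpl$mask) > 0.9 && mean(tpl$mask) < 1)
  expect_true(all(tpl$lh$vertices[!tpl$mask, 1] > 0))

  perturbed <- simulation_config(subdivisions = 2, radius = 50,
                                 perturbation = 0.1)
  expect_silent(validate_mesh(generate_template_pair(perturbed)$lh))
  expect_error(generate_template_pair(
    simulation_config(subdivisions = 2, radius = 50, perturbation = 30)),
    "flips")
})

test_that("cohorts are bit-reproducible and per-subject streams are stable", {
  cfg <- simulation_config(group_sizes = c(hc = 4, presymptomatic = 3,
                                           symptomatic = 5),
                           basis_modes = 30, seed = 11)
  basis <- fix_template_basis(cfg, K = 30)
  c1 <- generate_cohort(cfg, basis = basis)
  c2 <- generate_cohort(cfg, basis = basis)
  expect_identical(c1$thickness_lh, c2$thickness_lh)
  expect_identical(c1$thickness_rh, c2$thickness_rh)
  expect_identical(c1$subjects, c2$subjects)

  # shrinking the HC group must not shift the symptomatic subjects' draws
  cfg3 <- cfg; cfg3$group_sizes["hc"] <- 2L
  c3 <- generate_cohort(cfg3, basis = basis)
  sym1 <- c1$thickness_lh[, c1$subjects$group == "symptomatic"]
  sym3 <- c3$thickness_lh[, c3$subjects$group == "symptomatic"]
  expect_identical(sym3, sym1)
})

test_that("planted modal deficits are recovered by projection", {
  cfg <- simulation_config(group_sizes = c(hc = 0, presymptomatic = 0,
                                           symptomatic = 27),
                           basis_modes = 30, seed = 13)
  basis <- fix_template_basis(cfg, K = 30)
  cohort <- generate_cohort(cfg, basis = basis)
  rms <- sqrt(sum(basis$mass))
  pr <- projection_operator(basis, cohort$mask, 30)
  beta <- pr %*% cohort$thickness_lh[cohort$mask, ] / rms  # mm-RMS units
  gt <- cohort$ground_truth$deficits
  d13 <- gt$deficit_lh[gt$mode == 13]
  recovered <- cfg$baseline_coeffs["13"] - beta[13, ]
  # per-subject projection noise is ~noise_sd/sqrt(nv); compare means
  mc_se <- sd(recovered - d13) / sqrt(length(d13))
  expect_lt(abs(mean(recovered - d13)), 3 * mc_se + 1e-3)
  expect_lt(max(abs(recovered - d13)), 0.05)
  # severity scaling: deficits proportional to planted severities
  expect_equal(gt$deficit_rh[gt$mode == 13],
               0.4 * gt$deficit_lh[gt$mode == 13], tolerance = 1e-12)
  expect_true(all(gt$deficit_rh[gt$mode %in% c(1, 2, 10)] == 0))
})

test_that("clinical scores are the stated linear function of planted weights", {
  cfg <- simulation_config(group_sizes = c(hc = 0, presymptomatic = 0,
                                           symptomatic = 20),
                           basis_modes = 30, seed = 17,
                           tmt_a = list(intercept = 150,
                                        coef = c(`9` = -800, `13` = -1200),
                                        sd = 0),
                           tmt_b = list(intercept = 420,
                                        coef = c(`9` = -600, `13` = -800),
                                        sd = 0))
  basis <- fix_template_basis(cfg, K = 30)
  cohort <- generate_cohort(cfg, basis = basis)
  gt <- cohort$ground_truth$deficits
  b9 <- cfg$baseline_coeffs["9"] - gt$deficit_lh[gt$mode == 9]
  b13 <- cfg$baseline_coeffs["13"] - gt$deficit_lh[gt$mode == 13]
  expected <- pmax(10, 150 - 800 * b9 - 1200 * b13)
  expect_equal(cohort$subjects$tmt_a, unname(expected), tolerance = 1e-12)
  expect_true(all(is.finite(cohort$subjects$tmt_b)))
  # CDR stages drawn from the configured support
  expect_true(all(cohort$subjects$cdr %in% c(0.5, 1, 2, 3)))
})

test_that("degenerate and invalid configurations are rejected", {
  expect_error(simulation_config(noise_sd = -1))
  expect_error(simulation_config(cdr_probs = list(
    hc = c(`0` = 0.5, `0.5` = 0, `1` = 0, `2` = 0, `3` = 0),
    presymptomatic = c(`0` = 1, `0.5` = 0, `1` = 0, `2` = 0, `3` = 0),
    symptomatic = c(`0` = 1, `0.5` = 0, `1` = 0, `2` = 0, `3` = 0))),
    "sum to 1")
  # atrophy so large the expected thickness goes negative
  cfg <- simulation_config(group_sizes = c(hc = 2, presymptomatic = 0,
                                           symptomatic = 2),
                           atrophy_lh = c(`1` = 4), basis_modes = 20,
                           subdivisions = 2)
  expect_error(generate_cohort(cfg), "thickness <= 0")
})

test_that("recovery experiment tabulates detection and asymmetry metrics", {
  cfg <- simulation_config(group_sizes = c(hc = 6, presymptomatic = 0,
                                           symptomatic = 8),
                           basis_modes = 25, subdivisions = 2, seed = 23)
  res <- run_recovery_experiment(cfg, amplitude_scales = c(0, 1),
                                 n_replicates = 2, n_perm = 39,
                                 n_modes_test = 25, seed = 3,
                                 include_glm = TRUE)
  expect_equal(nrow(res$replicates), 4L)
  expect_equal(sort(res$cells$scale), c(0, 1))
  expect_true(all(res$replicates$reject_frac >= 0 &
                    res$replicates$reject_frac <= 1))
  expect_true(all(!is.na(res$replicates$glm_recovered)))
  # common random numbers: the same replicate shares a cohort seed across scales
  expect_true(all(table(res$replicates$replicate) == 2))
})
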