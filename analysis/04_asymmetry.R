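#!/usr/bin/env Rscript
# Stage 4: interhemispheric asymmetry indices and their group structure.
#
# The bilateral region of interest comes from the symptomatic-vs-HC
# left-hemisphere t map thresholded at two-tailed p < 0.05 and mirrored to
# the right hemisphere (vertex-index identity on the shared template).
# Within it, the conventional index is the normalized mean-thickness
# difference; the mode-based index is the absolute Pearson correlation of
# the hemispheres' first-25-mode loading vectors. Both are compared across
# groups and across CDR stages (Kruskal-Wallis + Dunn/BH).

suppressPackageStartupMessages(library(mbmorph))

cohort <- read_cohort("results/cohort")
basis <- compute_eigenmodes(cohort$mesh_lh, 150)
grp <- cohort$subjects$group

tmap <- vertex_tmap(cohort$thickness_lh[, grp == "hc"],
                    cohort$thickness_lh[, grp == "symptomatic"],
                    mask = cohort$mask, mesh = cohort$mesh_lh)
pmap <- surface_map(2 * pt(-abs(tmap$values), df = attr(tmap, "df")),
                    cohort$mesh_lh, mask = cohort$mask)
bmask <- build_symmetric_mask(pmap, 0.05)
message("bilateral mask: ", sum(bmask$lh), " vertices per hemisphere")

ai <- asymmetry_table(cohort, basis, bmask, n_modes = 25)
dir.create("results/asymmetry", showWarnings = FALSE, recursive = TRUE)
write.csv(ai, "results/asymmetry/asymmetry.csv", row.names = FALSE)

for (col in c(mbm = "mbm_ai", sbm = "sbm_ai_similarity")) {
  means <- tapply(ai[[col]], ai$group, mean)
  kw <- kruskal_wallis(ai[[col]], ai$group)
  message(sprintf("%s: HC %.4f | presympt %.4f | sympt %.4f (KW p = %.3g)",
                  col, means["hc"], means["presymptomatic"],
                  means["symptomatic"], kw$p_value))
  pw <- dunn_posthoc_bh(ai[[col]], ai$group)
  write.csv(pw, sprintf("results/asymmetry/%s_group_dunn.csv", col),
            row.names = FALSE)
}

# staging by CDR score (HC kept as a separate reference group)
subj <- cohort$subjects[match(ai$subject_id, cohort$subjects$subject_id), ]
stage <- ifelse(subj$group == "hc", "HC", paste0("CDR", subj$cdr))
cdr_kw <- kruskal_wallis(ai$mbm_ai, stage)
message(sprintf("MBM-AI across CDR stages: KW p = %.3g", cdr_kw$p_value))
write.csv(cbind(stage = stage, ai),
          "results/asymmetry/asymmetry_by_stage.csv", row.names = FALSE)
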