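#!/usr/bin/env Rscript
# Builds the synthetic study sample: two reference morphotypes (an
# "ape-like" group with palmar flexor-sheath ridges and a monotone
# proximodistal thickness rise, and a "human-like" group with dorsal
# thickening and a mid-shaft thickness peak), 15 individuals each, plus
# one 50/50 parameter-blend specimen standing in for a fossil of
# intermediate morphology. Meshes are written as ASCII PLY together with
# each individual's ground-truth 97 x 50 thickness matrix.

library(phalmap)

seed <- 20260928L
out <- "results/cohort"
dir.create(file.path(out, "meshes"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)

groups <- reference_group_specs(mesh_resolution = c(200L, 100L), noise_sd = 0.02)
cohort <- generate_cohort(groups, n_per_group = 15L, seed = seed)

blend_spec <- blend_phalanx_spec(groups$ape_like$spec, groups$human_like$spec,
                                 w = 0.5, seed = seed + 1L)
blend <- generate_phalanx(blend_spec, label = "blend", id = "blend-01")
cohort <- c(cohort, list(list(pair = blend$pair, truth = blend$truth,
                              label = "blend", id = "blend-01")))

manifest <- do.call(rbind, lapply(cohort, function(ind) {
  op <- file.path("meshes", paste0(ind$id, "_outer.ply"))
  ip <- file.path("meshes", paste0(ind$id, "_inner.ply"))
  write_ply(ind$pair$outer, file.path(out, op))
  write_ply(ind$pair$inner, file.path(out, ip))
  tr <- ind$truth$values
  utils::write.csv(tr, file.path(out, "truth", paste0(ind$id, ".csv")),
                   row.names = FALSE)
  data.frame(id = ind$id, group = ind$label, element = "PP", digit = 3L,
             side = "right", outer_path = op, inner_path = ip)
}))
utils::write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)

cat("wrote", nrow(manifest), "specimens (",
    sum(manifest$group == "ape_like"), "ape-like,",
    sum(manifest$group == "human_like"), "human-like,",
    sum(manifest$group == "blend"), "blend ) under", out, "\n")
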