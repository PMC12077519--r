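#!/usr/bin/env Rscript
# Cross-sectional mechanics of the simulated sample: polar second moment
# of area J at 35/50/65% of bone length (raw and standardized by
# length^4) and longitudinal curvature via the included angle.

library(phalmap)

cohort_dir <- "results/cohort"
out <- "results/mechanics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- utils::read.csv(file.path(cohort_dir, "manifest.csv"))
pairs <- lapply(seq_len(nrow(manifest)), function(i) {
  r <- manifest[i, ]
  pair <- bone_pair(load_surface(file.path(cohort_dir, r$outer_path)),
                    load_surface(file.path(cohort_dir, r$inner_path)),
                    side = r$side, label = r$group, element = r$element,
                    digit = r$digit, id = r$id)
  mirror_to_right(orient_anatomical(pair))
})

tab <- mechanics_table(pairs)
utils::write.csv(tab, file.path(out, "mechanics.csv"), row.names = FALSE)

cat("median standardized J (x 1e6) by group and level:\n")
agg <- stats::aggregate(J_std ~ group + level_frac, tab, stats::median)
agg$J_std <- round(agg$J_std * 1e6, 2)
print(agg)

ang <- unique(tab[, c("id", "group", "included_angle")])
cat("\nmean included angle (deg) by group:\n")
print(round(tapply(ang$included_angle, ang$group, mean), 1))
cat("\nThe ape-like group is generated with stronger longitudinal",
    "\ncurvature (40 deg vs 20 deg); the blend specimen sits between.\n")
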