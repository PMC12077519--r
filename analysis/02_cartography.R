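#!/usr/bin/env Rscript
# Cortical cartography of the simulated sample: orients each mesh pair,
# computes the 97 x 50 thickness map, standardizes by maximum bone
# length, and exports per-specimen map CSVs/PNGs, group mean-model maps
# and proximodistal mean-thickness profiles.

library(phalmap)

cohort_dir <- "results/cohort"
out <- "results/cartography"
dir.create(file.path(out, "maps"), recursive = TRUE, showWarnings = FALSE)

manifest <- utils::read.csv(file.path(cohort_dir, "manifest.csv"))
maps <- list()
for (i in seq_len(nrow(manifest))) {
  r <- manifest[i, ]
  pair <- bone_pair(load_surface(file.path(cohort_dir, r$outer_path)),
                    load_surface(file.path(cohort_dir, r$inner_path)),
                    side = r$side, label = r$group, element = r$element,
                    digit = r$digit, id = r$id)
  pair <- mirror_to_right(orient_anatomical(pair))
  m <- standardize_map(compute_thickness_map(pair))
  write_map_csv(m, file.path(out, "maps", paste0(r$id, ".csv")))
  maps[[r$id]] <- m
}

labels <- vapply(maps, function(m) as.character(m$meta$label), "")
for (g in unique(labels)) {
  gm <- mean_map(unname(maps[labels == g]), require_standardized = TRUE)
  gm$meta$id <- paste0("mean_", g)
  export_map_image(gm, file.path(out, paste0("mean_map_", g, ".png")))
}

profiles <- do.call(rbind, lapply(names(maps), function(id) {
  pr <- thickness_profile(maps[[id]])
  data.frame(id = id, group = labels[[id]],
             level_percent = pr$levels * 100,
             mean_thickness_std = pr$mean_thickness)
}))
utils::write.csv(profiles, file.path(out, "profiles.csv"), row.names = FALSE)

peaks <- vapply(names(maps), function(id)
  profile_peak(thickness_profile(maps[[id]])), 0)
summ <- data.frame(id = names(maps), group = labels,
                   mean_thickness_std = vapply(maps, mean_cortical_thickness, 0),
                   peak_shaft_frac = peaks,
                   peak_bone_frac = 0.2 + 0.6 * peaks)
utils::write.csv(summ, file.path(out, "summary.csv"), row.names = FALSE)

cat("group median standardized mean thickness:\n")
print(tapply(summ$mean_thickness_std, summ$group, stats::median))
cat("\ngroup mean thickness-peak location (fraction of bone length):\n")
print(round(tapply(summ$peak_bone_frac, summ$group, mean), 3))
cat("\nThe human-like group peaks mid-distally (~0.65 of bone length);",
    "\nthe ape-like profile rises monotonically so its smoothed peak sits",
    "\nnear the distal end of the shaft window.\n")
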