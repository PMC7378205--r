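#!/usr/bin/env Rscript
# Generate the synthetic study data: ground-truth worm micrographs (TIFF +
# truth sidecar), a survival observation log, and a per-worm Nile red
# fluorescence table. Everything downstream (02-05) reads from results/data.

suppressMessages(library(nemascreen))

out <- "results/data"
dir.create(file.path(out, "images"), showWarnings = FALSE, recursive = TRUE)
seed <- 20260101L

## micrographs: 12 worms spanning the area range the size filter must pass,
## with varying foci loads, plus sub-filter bacteria-like artifacts
areas <- round(seq(3500, 18000, length.out = 12))
images <- lapply(seq_along(areas), function(i) {
  generate_worm_image(worm_image_config(seed = seed + i,
                                        worm_area_px = areas[i],
                                        n_foci = 6 + (i %% 5) * 5))
})
names(images) <- sprintf("worm%02d", seq_along(images))
for (id in names(images)) {
  write_worm_tiff(images[[id]]$pixels, file.path(out, "images", paste0(id, ".tiff")))
}
write_truth_sidecar(images, file.path(out, "image_truth.csv"))
cat(sprintf("wrote %d micrographs (worm areas %d-%d px) and truth sidecar\n",
            length(images), min(areas), max(areas)))

## training images for the pixel classifier (separate seeds from the assay set)
train <- lapply(1:3, function(i) {
  generate_worm_image(worm_image_config(seed = seed + 100L + i))
})
names(train) <- sprintf("train%02d", seq_along(train))
for (id in names(train)) {
  write_worm_tiff(train[[id]]$pixels, file.path(out, "images", paste0(id, ".tiff")))
}
write_truth_sidecar(train, file.path(out, "train_truth.csv"))

## survival assay: vehicle control, positive control emulating a reserpine-
## like 1.3x effect, one lifespan-extending and one toxic condition
surv_cfg <- survival_sim_config(
  effect_multipliers = c(control = 1, positive_ctrl = 1.3,
                         extract_A = 1.4, extract_B = 1.0, extract_C = 0.55),
  n_wells_per_condition = 9L, seed = seed)
write_survival_log(simulate_survival(surv_cfg), file.path(out, "survival_log.csv"))
cat("wrote survival log: 5 conditions x 9 wells (3 parallel experiments of triplicates)\n")

## Nile red plate: a halving, a null and a mildly increasing condition
nr_cfg <- nilered_sim_config(
  effect_fractions = c(control = 1, fat_reducer = 0.5,
                       extract_B = 1.0, fat_increaser = 1.3),
  seed = seed + 1L)
pw <- simulate_nilered_plate(nr_cfg)
utils::write.csv(pw, file.path(out, "nilered_per_worm.csv"), row.names = FALSE)
cat(sprintf("wrote per-worm Nile red table: %d worms across %d experiments\n",
            nrow(pw), nr_cfg$n_experiments))
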