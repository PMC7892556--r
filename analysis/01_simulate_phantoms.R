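#!/usr/bin/env Rscript
# Stage 1: generate one example of every synthetic input the study consumes
# and write it to disk with its ground truth, so the downstream stages (and
# any outside reader) can inspect the raw material.

suppressMessages(library(stiffpdx))

out <- "results/01_simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

## Stiffness maps: one tumor per preset at first and final timepoint --------
truths <- list()
for (nm in c("mesenchymal_stiff", "mesenchymal_soft", "non_mesenchymal")) {
  p <- swe_preset(nm)
  for (t in c(1L, p$growth$n_timepoints)) {
    g <- generate_stiffness_map(p, t, seed = mix_seed(seed, 1))
    write_stiffness_map(g$map, g$roi,
                        file.path(out, sprintf("%s_t%02d", nm, t)),
                        meta = list(preset = nm, timepoint = t, seed = seed))
    truths[[length(truths) + 1L]] <- g$truth
  }
}
truth <- do.call(rbind, truths)
write.csv(truth, file.path(out, "swe_truth.csv"), row.names = FALSE)
cat("Stiffness phantoms written for 3 presets x 2 timepoints.\n")
cat(sprintf("  Final-timepoint true mean stiffness: stiff %.1f, soft %.1f, non-mes %.1f kPa\n",
            truth$true_mean_kpa[2], truth$true_mean_kpa[4], truth$true_mean_kpa[6]))

## SHG fiber field -----------------------------------------------------------
shg <- generate_shg_image(n_fibers = 6, seed = mix_seed(seed, 2))
write_shg_stack(shg$stack, file.path(out, "shg_stack.tif"))
write.csv(shg$truth, file.path(out, "shg_truth.csv"), row.names = FALSE)
cat(sprintf("SHG stack written: %d fibers, true mean length %.1f um, thickness %.2f um.\n",
            nrow(shg$truth), mean(shg$truth$length_um),
            mean(shg$truth$thickness_um)))

## Trichrome field ------------------------------------------------------------
tri <- generate_trichrome_image(0.35, seed = mix_seed(seed, 3))
write_trichrome_png(tri$rgb, file.path(out, "trichrome.png"))
png::writePNG(tri$mask * 1, file.path(out, "trichrome_mask.png"))
cat(sprintf("Trichrome field written: collagen fraction %.3f (target 0.350).\n",
            tri$truth$realized_fraction))

## Expression datasets --------------------------------------------------------
ex <- generate_expression_dataset(seed = mix_seed(seed, 4))
write_expression(ex$human, file.path(out, "human"))
write_expression(ex$mouse, file.path(out, "mouse"))
write_signature(ex$truth$signature, file.path(out, "signature.txt"))
write.csv(ex$truth$de_genes, file.path(out, "de_truth.csv"), row.names = FALSE)
cat(sprintf("Expression data written: %d genes x %d samples per compartment, %d planted DE genes.\n",
            nrow(ex$human$mat), ncol(ex$human$mat), nrow(ex$truth$de_genes)))
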