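#!/usr/bin/env Rscript
# Step 1 -- simulate a demonstration dataset.
#
# Generates one synthetic median-nerve SEP recording (scaled down from the
# emulated acquisition to 16 channels and 200 stimuli so the whole workflow
# runs on a desktop), writes it in the delimited-matrix dialect together
# with its stimulus events and a ground-truth summary, and reports what was
# injected.

library(sepkit)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- synth_config(n_channels = 16, n_stimuli = 200, seed = 11)
sim <- generate_recording(cfg, keep_sources = FALSE)
gt <- sim$ground_truth

cat("Simulated recording:\n")
print(sim$recording)
cat(sprintf("  true N30 peak-to-peak (noiseless template at F3): %.3f uV\n",
            gt$true_n30_uv))
cat(sprintf("  epochs overlapping blink cores: %d, muscle cores: %d\n",
            sum(vapply(gt$epoch_labels, function(l) "eye" %in% l, logical(1))),
            sum(vapply(gt$epoch_labels, function(l) "muscle" %in% l, logical(1)))))
cat(sprintf("  flat channel(s): %s\n", paste(gt$flat_channels, collapse = ", ")))

write_recording_tsv(sim$recording, file.path(out_dir, "demo_recording.tsv"))
write_ica_model(sim$ica_model, file.path(out_dir, "demo_unmixing.tsv"))
truth <- data.frame(
  epoch = seq_along(gt$epoch_labels),
  artifact = vapply(gt$epoch_labels, paste, character(1), collapse = ","))
write.table(truth, file.path(out_dir, "demo_ground_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/demo_recording.tsv (+ events, sidecar, unmixing, ground truth)\n")
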