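#!/usr/bin/env Rscript
# Step 1 — build the digital two-kidney phantom and forward-simulate one
# subject: a 90-frame FAIR ASL series (30 tag/control pairs + 30 M0) and a
# 50-volume DCE series (dt 0.9 s, 15 baselines, 3 slices), both with mild
# frame noise. Everything downstream reads these files, never this script's
# memory, so the whole workflow is re-runnable from disk.

suppressPackageStartupMessages(library(renperf))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260927L

spec <- phantom_spec(noise_sigma = 0.3, seed = seed)  # 128x128, AKI left
truth <- make_phantom(spec)
print(truth)

write_mask_nifti(truth, file.path(out, "masks.nii.gz"))

asl <- simulate_asl(truth, ti = 1.2, n_pairs = 30, lambda_bt = 0.8)
write_asl_series(asl, file.path(out, "asl_series.nii.gz"),
                 file.path(out, "asl_labels.csv"))
print(asl)

dce <- simulate_dce(truth, dt = 0.9, n_baseline = 15, n_volumes = 50,
                    n_slices = 3, seed = seed + 1L)
write_dce_series(dce, file.path(out, "dce_series.nii.gz"))
print(dce)

saveRDS(spec, file.path(out, "phantom_spec.rds"))
cat("ground truth: cortex L", spec$f_cortex_left, "/ R", spec$f_cortex_right,
    "ml/100 g/min; series written to", out, "\n")
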