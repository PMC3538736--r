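#!/usr/bin/env Rscript
# Step 4 — the statistical comparison on the packaged per-animal tables:
# healthy/diseased group summaries, paired t-tests, Bland-Altman limits of
# agreement, left/right ratios and the repeated-scan summaries. This is the
# part of the workflow that runs on measured (printed) data rather than the
# simulation.

suppressPackageStartupMessages(library(renperf))

out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tabs <- read_rbf_table()
reps <- read_repeats_table()
report <- table_report(tabs, reps)

for (m in c("ASL", "DCE")) {
  r <- report[[m]]
  cat(sprintf(
    "%s: AKI %d+/-%d, healthy %d+/-%d ml/100 g/min; difference %d+/-%d; p = %.2f%%\n",
    m, round(r$diseased$mean), round(r$diseased$sd),
    round(r$healthy$mean), round(r$healthy$sd),
    round(r$bland_altman$mean_diff), round(r$bland_altman$sd_diff),
    100 * r$t_test$p_two_sided))
  cat(sprintf("  LoA [%.0f, %.0f] — zero %s included\n",
              r$bland_altman$loa_low, r$bland_altman$loa_high,
              if (r$bland_altman$loa_low > 0) "not" else "is"))
}
cat("repeatability:\n"); print(report$repeatability)

jsonlite::write_json(report, file.path(out, "agreement_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

ggplot2::ggsave(file.path(out, "bland_altman_asl.png"),
                plot_bland_altman(tabs$ASL), width = 5, height = 4, dpi = 150)
ggplot2::ggsave(file.path(out, "bland_altman_dce.png"),
                plot_bland_altman(tabs$DCE), width = 5, height = 4, dpi = 150)
ggplot2::ggsave(file.path(out, "lr_ratios.png"),
                plot_lr_ratios(tabs), width = 5, height = 4, dpi = 150)
cat("report and plots written to", out, "\n")
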