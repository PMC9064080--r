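#!/usr/bin/env Rscript

# Step 3: cohort-level statistics on the per-trial SampEn table from
# step 1: average the three repeats per condition, check assumptions
# (Shapiro-Wilk, Levene, Mauchly), fit the two-way mixed-design ANOVA
# (group between, task within) with generalized eta squared per
# direction, and run the Bonferroni pairwise post hocs.

suppressPackageStartupMessages(library(copentropy))

if (!file.exists("results/sampen_by_trial.csv")) {
  stop("run analysis/01_simulate_cohort.R first", call. = FALSE)
}
tab <- read.csv("results/sampen_by_trial.csv", skip = 1)
means <- average_repeats(tab)

for (dir in c("AP", "ML")) {
  cat(sprintf("\n===== %s direction =====\n", dir))
  a <- mixed_anova(means, dir)
  print(a)
  ph <- pairwise_posthoc(means, a)
  df <- as.data.frame(ph)
  cat("significant post hocs (Bonferroni within scope):\n")
  sig <- df[df$significant, c("scope", "within", "pair", "p_adj")]
  sig$p_adj <- signif(sig$p_adj, 3)
  print(sig, row.names = FALSE)
  res_dir <- "results"
  jsonlite::write_json(
    list(direction = dir, effects = a$effects, posthoc = df),
    file.path(res_dir, sprintf("anova_%s.json", tolower(dir))),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
}
cat("\nwrote results/anova_ap.json, results/anova_ml.json\n")
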