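#!/usr/bin/env Rscript
# Fit the Beta regression MI/H ~ H to every simulated calibration cohort
# and write the posterior coefficient tables (the package's analogues of
# the published calibration tables).

library(pluralinfo)

files <- list.files("results/cohorts", full.names = TRUE)
if (length(files) == 0) {
  stop("run analysis/02_simulate_cohorts.R first")
}
dir.create("results/posteriors", showWarnings = FALSE)

for (f in files) {
  label <- sub("\\.csv$", "", basename(f))
  fit <- fit_beta_regression(read_cohort(f), seed = 30000 + nchar(label))
  out <- file.path("results/posteriors", paste0(label, ".csv"))
  write.csv(posterior_summary(fit), out, row.names = FALSE)
  s <- posterior_summary(fit, digits = 2)
  cat(sprintf(
    "%-11s intercept %6.2f  H(C) slope %6.2f  phi %6.2f  (Rhat max %.3f)\n",
    label, s$Estimate[1], s$Estimate[2], s$Estimate[3],
    max(fit$diagnostics$rhat)
  ))
}
cat("\nSlope signs separate the hypotheses: positive under the null",
    "(plug-in MI noise grows with H) and negative under lexicon-level",
    "conditioning (structure is diluted as variation grows).\n")
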