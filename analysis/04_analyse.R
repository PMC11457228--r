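#!/usr/bin/env Rscript

# Stage 4: cohort-level statistics per sex - descriptive centile tables of
# the spurt parameters, Pearson correlations among the fitted random
# effects, and top-versus-bottom quintile contrasts (ranking by each of
# APHV/PHV/GSI and comparing the others) - plus the velocity-curve and
# boxplot figures.

suppressPackageStartupMessages(library(growthspurt))

for (preset_name in c("boys_gp2024", "girls_gp2024")) {
  fit <- read_sitar_fit(file.path("results",
                                  paste0(preset_name, "_fit.json")))
  sp <- utils::read.csv(file.path("results",
                                  paste0(preset_name,
                                         "_spurt_parameters.csv")),
                        stringsAsFactors = FALSE)
  sp$flag[is.na(sp$flag)] <- ""
  contrasts <- quintile_contrast_table(sp)
  files <- build_report(fit, sp, contrasts, dir = "results",
                        prefix = preset_name)

  cors <- random_effect_correlations(fit)
  message(sprintf(
    "%s: size-tempo r %.2f, size-velocity r %.2f, tempo-velocity r %.2f",
    preset_name, cors$r["size", "tempo"], cors$r["size", "velocity"],
    cors$r["tempo", "velocity"]))
  d_aphv <- contrasts[contrasts$rank_by == "aphv", ]
  message(sprintf(
    "%s: top-vs-bottom APHV quintiles: PHV difference %.2f cm/y (p %.2g), GSI difference %.2f y (p %.2g)",
    preset_name,
    d_aphv$diff[d_aphv$outcome == "phv"], d_aphv$p[d_aphv$outcome == "phv"],
    d_aphv$diff[d_aphv$outcome == "gsi"], d_aphv$p[d_aphv$outcome == "gsi"]))
  message(preset_name, ": wrote ", paste(basename(files), collapse = ", "))
}
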