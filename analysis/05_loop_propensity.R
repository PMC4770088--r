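#!/usr/bin/env Rscript
# Loop-closure propensity of a 90-step rigid base-pair chain under the
# per-condition fluctuation amplitudes: the Monte Carlo embodiment of the
# mechanism linking larger roll/twist fluctuations to faster cyclization.
#
# Capture criteria here (r_c = 220 A, theta_c = 120 deg, register off) are
# deliberately generous so that closure is measurable at 2e5 samples per
# condition; the reported numbers are comparative propensities, not
# absolute J-factors.

suppressPackageStartupMessages(library(modflex))
dir.create("results", showWarnings = FALSE)

base <- default_baseline()
eff <- default_modification_effects()
sd_of <- function(cond, p) {
  s <- base$sd[base$parameter == p]
  if (cond != "unmodified") {
    e <- eff[eff$condition == cond & eff$parameter == p, ]
    if (nrow(e)) s <- s + sum(e$dsd)
  }
  max(s, 0)
}

conds <- c("unmodified", "5mC", "5hmC", "5fC", "5caC")
specs <- list()
for (i in seq_along(conds)) {
  cond <- conds[i]
  specs[[cond]] <- chain_fluctuation_spec(
    n_steps = 90L,
    sds = c(shift = 0.5, slide = 0.5, rise = 0.3,
            tilt = sd_of(cond, "tilt"), roll = sd_of(cond, "roll"),
            twist = sd_of(cond, "twist")),
    r_c = 220, theta_c = 120, n_samples = 2e5, seed = 8800 + i)
}

cmp <- compare_conditions(specs)
tab <- cmp$table
tab$propensity <- signif(tab$propensity, 3)
tab$ci_lower <- signif(tab$ci_lower, 3)
tab$ci_upper <- signif(tab$ci_upper, 3)
tab$ratio <- round(tab$ratio, 2)
write.table(tab, "results/closure_propensity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Loop-closure propensity per condition (2e5 samples each):\n")
print(tab[, c("condition", "count", "propensity", "ci_lower", "ci_upper",
              "ratio")], row.names = FALSE)
cat("\nOrdering by closure propensity:\n  ", cmp$ranking$string, "\n")
cat("\nWrote results/closure_propensity.tsv\n")
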