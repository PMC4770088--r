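#!/usr/bin/env Rscript
# Two-state looping kinetics of the 90-bp cyclization construct: simulate
# salt-jump time courses for the five conditions, fit the apparent looping
# time tau, and report fold-changes relative to unmodified DNA.
#
# Generative taus are calibrated to the observed flexibility ordering for
# four-copy constructs (5fC threefold faster than unmodified, 5hmC
# intermediate, 5caC indistinguishable, 5mC slower); the equilibrium looped
# fraction is 0.8 (above 70%) for every construct.

suppressPackageStartupMessages(library(modflex))
dir.create("results", showWarnings = FALSE)
set.seed(20260927)

taus <- c(unmodified = 600, `5mC` = 900, `5hmC` = 300, `5fC` = 200,
          `5caC` = 600)
f_eq <- 0.8
n_molecules <- 500

fits <- list()
for (cond in names(taus)) {
  tau <- taus[[cond]]
  tc <- simulate_looping(n_molecules, f_eq / tau, (1 - f_eq) / tau,
                         default_sample_times(tau),
                         seed = sample.int(2^31 - 1, 1), condition = cond)
  write_timecourse_tsv(tc, file.path("results",
                                     paste0("timecourse_", cond, ".tsv")))
  fits[[cond]] <- fit_looping(tc)
}

rows <- lapply(names(fits), function(cond) {
  f <- fits[[cond]]
  fc <- fold_change(fits$unmodified, f)   # >1 = faster looping than unmod
  data.frame(condition = cond,
             tau_s = round(f$tau, 1), se_tau_s = round(f$se_tau, 1),
             f_eq = round(f$f_eq, 3),
             speedup_vs_unmodified = round(fc$ratio, 2),
             se_speedup = round(fc$se, 2))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/looping_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Apparent looping times (exponential fit, molecule-bootstrap errors):\n")
print(tab, row.names = FALSE)
cat("\nAll equilibrium looped fractions exceed 0.70:",
    all(vapply(fits, function(f) f$f_eq > 0.70, logical(1))), "\n")
cat("5fC speeds looping ~threefold relative to unmodified:",
    sprintf("%.2f-fold\n", fold_change(fits$unmodified, fits$`5fC`)$ratio))
cat("\nWrote results/looping_fits.tsv and per-condition time courses.\n")
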