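#!/usr/bin/env Rscript
# Stage 3: inhibitor potency. Fits tetramer-destabilization IC50s for the
# three inhibitor profiles from their titration fraction tables (tetramer
# curves, Hill slope fixed at 1.3), converts IC50 -> Ki with the empirically
# calibrated Cheng-Prusoff factor, and writes the potency summary table.
# Reads: results/fractions_inhibitor_*.csv (stage 1).
# Writes: results/summary_inhibition.csv, results/inhibition.json.

suppressPackageStartupMessages(library(assemblyMP))

# calibrate the empirical IC50/Ki factor from the study's potency table
table1 <- data.frame(inhibitor = c("C5", "C13", "C15"),
                     ic50 = c(19.7e-6, 19.4e-6, 3.1e-6),
                     ki = c(517.2e-9, 508.3e-9, 82.6e-9))
cal <- calibrate_lambda(table1$ic50, table1$ki)
message(sprintf("calibrated lambda = %.1f (max residual %.1f%%, %s)",
                cal$lambda, 100 * max(abs(cal$residuals)),
                if (cal$consistent) "consistent" else "inconsistent"))
cfg <- pharmacology_config("empirical_lambda", lambda = cal$lambda)

rows <- list()
fits <- list()
for (nm in c("C5", "C13", "C15")) {
  tab <- read.csv(sprintf("results/fractions_inhibitor_%s.csv", nm))
  sp <- split(tab, tab$b)
  ser <- titration_series(
    vapply(sp, function(d) d$b[1], numeric(1)),
    vapply(sp, function(d) mean(100 * d$conc_f_T), numeric(1)),
    vapply(sp, function(d) sd(100 * d$conc_f_T), numeric(1)),
    axis_kind = "inhibitor")
  fit <- fit_hill(ser, fix_n = 1.3)
  ic50 <- unname(fit$estimates["K"])
  ki <- ic50_to_ki(ic50, cfg)
  message(sprintf(
    "%s: IC50(T) = %.2f uM, Ki = %.0f nM (R2 = %.3f%s)", nm, ic50 * 1e6,
    ki$Ki * 1e9, fit$r_squared, if (fit$flagged) ", flagged" else ""))
  rows[[nm]] <- data.frame(inhibitor = nm, IC50_uM = ic50 * 1e6,
                           Ki_nM = ki$Ki * 1e9, r_squared = fit$r_squared,
                           flagged = fit$flagged)
  fits[[nm]] <- list(IC50 = ic50, Ki = ki$Ki, mode = ki$mode,
                     estimates = as.list(fit$estimates),
                     r_squared = fit$r_squared, flagged = fit$flagged)
}
summary <- do.call(rbind, rows)
ord <- order(summary$IC50_uM)
message("potency ranking: ",
        paste(summary$inhibitor[ord], collapse = " > "))
write.csv(summary, "results/summary_inhibition.csv", row.names = FALSE)
jsonlite::write_json(list(lambda = cal$lambda, fits = fits),
                     "results/inhibition.json", auto_unbox = TRUE,
                     digits = NA)
message("wrote results/summary_inhibition.csv and results/inhibition.json")
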