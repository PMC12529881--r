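#!/usr/bin/env Rscript
# Stage 4: mechanism of the most potent inhibitor. Extracts per-inhibitor-
# concentration EC50s from the Schild-grid substrate titrations (free Hill
# slope per curve), runs linear and allosteric Schild analyses, and globally
# fits the Hill-modified operational model (OMAM) to the full grid.
# Reads: results/fractions_schild_grid.csv, results/fractions_substrate_titration.csv.
# Writes: results/pharmacology.json.

suppressPackageStartupMessages(library(assemblyMP))

tab <- read.csv("results/fractions_schild_grid.csv")

# substrate-titration plateau and midpoint anchor the OMAM fixed parameters
sub <- read.csv("results/fractions_substrate_titration.csv")
sp <- split(sub, sub$s)
ser_sub <- titration_series(
  vapply(sp, function(d) d$s[1], numeric(1)),
  vapply(sp, function(d) mean(100 * d$conc_f_T), numeric(1)),
  vapply(sp, function(d) sd(100 * d$conc_f_T), numeric(1)),
  axis_kind = "substrate")
anchor <- fit_hill(ser_sub, fix_n = 1.3)
E_max <- unname(anchor$estimates["top"])
K_S <- unname(anchor$estimates["K"])
message(sprintf("fixed from substrate titration: E_max = %.1f%%, K_S = %.1f uM",
                E_max, K_S * 1e6))

# EC50 per inhibitor concentration (Hill slope free, per the convention for
# these response curves)
ec50 <- do.call(rbind, lapply(split(tab, tab$b), function(d) {
  spd <- split(d, d$s)
  ser <- titration_series(
    vapply(spd, function(x) x$s[1], numeric(1)),
    vapply(spd, function(x) mean(100 * x$conc_f_T), numeric(1)),
    vapply(spd, function(x) sd(100 * x$conc_f_T), numeric(1)),
    axis_kind = "substrate")
  fit <- fit_hill(ser)
  data.frame(B = d$b[1], EC50 = unname(fit$estimates["K"]),
             top = unname(fit$estimates["top"]), flagged = fit$flagged)
}))
print(ec50, row.names = FALSE)
ctrl <- ec50$EC50[ec50$B == 0]

usable <- ec50[ec50$B > 0 & !ec50$flagged, ]
sch <- schild_analysis(usable[, c("B", "EC50")], ctrl)
message(sprintf("linear Schild: slope %.2f, K_B,app = %.2f uM (R2 = %.2f)",
                sch$slope, sch$K_B_app * 1e6, sch$r_squared))
nl <- schild_nonlinear(usable[, c("B", "EC50")], ctrl)
message(sprintf("allosteric Schild: K_B = %.3g M, alpha = %.3g%s", nl$K_B,
                nl$alpha, if (nl$flagged) " (flagged)" else ""))

om_data <- data.frame(S = tab$s, B = tab$b, y = 100 * tab$conc_f_T)
om <- omam_global_fit(om_data, E_max = E_max, K_S = K_S)
print(om)
if (length(om$at_bounds)) {
  message("note: parameter(s) pinned at bounds (", paste(om$at_bounds,
          collapse = ", "), "): the operational model is an imperfect ",
          "description of the thermodynamic generator; see the vignette")
}

jsonlite::write_json(list(
  anchors = list(E_max = E_max, K_S = K_S),
  ec50_by_B = ec50,
  schild = list(slope = sch$slope, K_B_app = sch$K_B_app,
                r_squared = sch$r_squared,
                linear_region = sch$linear_region),
  schild_nonlinear = list(K_B = nl$K_B, alpha = nl$alpha,
                          flagged = nl$flagged),
  omam = list(tau_S = om$params$tau_S, tau_I = om$params$tau_I,
              alpha = om$params$alpha, beta = om$params$beta,
              K_B = om$params$K_B, n = om$params$n, sse = om$sse,
              flagged = om$flagged, at_bounds = om$at_bounds)),
  "results/pharmacology.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
message("wrote results/pharmacology.json")
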