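#' Build a run configuration for the full analysis pipeline
#'
#' Defaults mirror the emulated study design: 800 nM protein and 100 uM
#' substrate in inhibition assays, two-fold inhibitor dilutions 7.81-500 uM,
#' 8000 events per histogram, triplicate measurements.
#'
#' @param designs Character vector of designs to run, see
#'   [titration_design()].
#' @param params An [equilibrium_params()] object (generator truth).
#' @param inhibitors Named list of [inhibitor_model()]s used for the
#'   inhibitor designs (default: the three calibrated study-like profiles).
#' @param noise A [noise_model()].
#' @param n_events Events per histogram.
#' @param replicates Technical replicates per condition (>= 1).
#' @param seed Base seed recorded in every output.
#' @param pharm A [pharmacology_config()] for IC50 -> Ki conversion.
#' @param schild_B Inhibitor grid for the Schild design (molar; must include
#'   0).
#' @return Object of class `run_config`.
#' @export
run_config <- function(designs = c("protein_dilution", "substrate_titration",
                                   "inhibitor_titration"),
                       params = equilibrium_params(),
                       inhibitors = NULL,
                       noise = noise_model(),
                       n_events = 8000, replicates = 3, seed = 1,
                       pharm = pharmacology_config("empirical_lambda",
                                                   lambda = 37.9),
                       schild_B = c(0, 2e-8, 2e-7, 8e-7, 2e-6, 5e-6, 1e-5)) {
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(list(designs = designs, params = params,
                 inhibitors = inhibitors, noise = noise,
                 n_events = n_events, replicates = replicates, seed = seed,
                 pharm = pharm, schild_B = schild_B),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirror the [run_config()] arguments; nested blocks `params`,
#' `noise` and `pharm` map onto [equilibrium_params()], [noise_model()] and
#' [pharmacology_config()]. Inhibitors are given as a named block of
#' `{ic50: ..., alpha: ..., gamma_D: ...}` entries and calibrated via
#' [calibrate_inhibitor_kb()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  params <- do.call(equilibrium_params, cfg$params %||% list())
  inhibitors <- if (!is.null(cfg$inhibitors)) {
    stats::setNames(lapply(names(cfg$inhibitors), function(nm) {
      spec <- cfg$inhibitors[[nm]]
      calibrate_inhibitor_kb(spec$ic50, alpha = spec$alpha %||% 0.02,
                             gamma_D = spec$gamma_D %||% 1,
                             params = params, id = nm)
    }), names(cfg$inhibitors))
  }
  run_config(designs = cfg$designs %||% c("protein_dilution",
                                          "substrate_titration",
                                          "inhibitor_titration"),
             params = params, inhibitors = inhibitors,
             noise = do.call(noise_model, cfg$noise %||% list()),
             n_events = cfg$n_events %||% 8000,
             replicates = cfg$replicates %||% 3,
             seed = cfg$seed %||% 1,
             pharm = do.call(pharmacology_config, cfg$pharm %||%
                               list(mode = "empirical_lambda", lambda = 37.9)),
             schild_B = unlist(cfg$schild_B %||%
                                 c(0, 2e-8, 2e-7, 8e-7, 2e-6, 5e-6, 1e-5)))
}

# Simulate and quantify one design (all replicates); returns the fractions
# table with one row per condition x replicate.
quantify_design <- function(design, config, inh = NULL, conditions = NULL,
                            seed_offset = 0) {
  rows <- list()
  for (rep_i in seq_len(config$replicates)) {
    events <- simulate_titration(design, config$params, inh = inh,
                                 noise = config$noise,
                                 n_events = config$n_events,
                                 seed = derive_seed(config$seed,
                                                    seed_offset + rep_i),
                                 conditions = conditions)
    for (ev in events) {
      row <- quantify_events(ev)
      row$replicate <- rep_i
      row$design <- design
      if (!is.null(inh)) row$inhibitor_id <- inh$id
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

# Mean/SD titration series of one response column against one axis column.
series_from_table <- function(tab, xcol, ycol, axis_kind, percent = TRUE) {
  sp <- split(tab, tab[[xcol]])
  x <- vapply(sp, function(d) d[[xcol]][1], numeric(1))
  y <- vapply(sp, function(d) mean(d[[ycol]]), numeric(1))
  yerr <- vapply(sp, function(d)
    if (nrow(d) > 1) stats::sd(d[[ycol]]) else NA_real_, numeric(1))
  if (anyNA(yerr) || any(yerr == 0)) yerr <- NULL
  ord <- order(x)
  scale <- if (percent) 100 else 1
  titration_series(x[ord], scale * y[ord],
                   y_err = if (!is.null(yerr)) scale * yerr[ord],
                   axis_kind = axis_kind)
}

#' Run the full simulate -> quantify -> fit -> pharmacology pipeline
#'
#' Executes every stage for the configured designs and writes
#' machine-readable outputs under `outdir`: `fractions_<design>.csv` (and
#' per-inhibitor variants), `fits.json`, `pharmacology.json` and
#' `summary.csv` (per-inhibitor IC50 and Ki, the analog of the study's
#' potency table). A rerun with the same config produces identical files.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return The report bundle (named list), invisibly.
#' @export
run_pipeline <- function(config, outdir = "results") {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed)
  fits <- list()
  pharm_out <- list()
  inhibitors <- config$inhibitors %||%
    (if (any(c("inhibitor_titration", "schild_grid") %in% config$designs))
      inhibitor_profiles(config$params))

  if ("protein_dilution" %in% config$designs) {
    tab <- quantify_design("protein_dilution", config, seed_offset = 0)
    utils::write.csv(tab, file.path(outdir, "fractions_protein_dilution.csv"),
                     row.names = FALSE)
    aff <- fit_assembly_affinities(tab)
    fits$protein_dilution <- list(Kd_MM = aff$Kd_MM, Kd_DD = aff$Kd_DD,
                                  r_squared = c(MM = aff$fits$MM$r_squared,
                                                DD = aff$fits$DD$r_squared))
    # with-substrate companion series (fixed 100 uM substrate)
    conds <- titration_design("protein_dilution", S = 100e-6)
    tab_s <- quantify_design("protein_dilution", config, conditions = conds,
                             seed_offset = 100)
    utils::write.csv(tab_s,
                     file.path(outdir, "fractions_protein_dilution_S.csv"),
                     row.names = FALSE)
    aff_s <- fit_assembly_affinities(tab_s, S = 100e-6,
                                     params = config$params)
    fits$protein_dilution_substrate <- list(
      Kd_MM = aff_s$Kd_MM, Kd_DD = aff_s$Kd_DD,
      Kd_MM_sat = aff_s$Kd_MM_sat, Kd_DD_sat = aff_s$Kd_DD_sat)
    if (!is.na(aff$Kd_DD) && !is.na(aff_s$Kd_DD_sat)) {
      fits$fold_stabilization_DD <- aff$Kd_DD / aff_s$Kd_DD_sat
    }
  }

  if ("substrate_titration" %in% config$designs) {
    tab <- quantify_design("substrate_titration", config, seed_offset = 200)
    utils::write.csv(tab,
                     file.path(outdir, "fractions_substrate_titration.csv"),
                     row.names = FALSE)
    ser <- series_from_table(tab, "s", "conc_f_T", "substrate")
    fit_n <- fit_hill(ser)            # free slope: measured cooperativity
    fit <- fit_hill(ser, fix_n = 1.3) # tetramer-curve convention for K_S
    fits$substrate_titration <- list(
      K_S = unname(fit$estimates["K"]), n = unname(fit_n$estimates["n"]),
      E_max = unname(fit$estimates["top"]), r_squared = fit$r_squared,
      flagged = fit$flagged || fit_n$flagged)
  }

  if ("inhibitor_titration" %in% config$designs) {
    summary_rows <- list()
    # two-fold dilutions extended below the protocol floor so that the
    # transition of potent (low-micromolar) inhibitors is bracketed
    inh_conds <- data.frame(c_tot = 800e-9, s = 100e-6, b = 500e-6 / 2^(13:0))
    for (inh in inhibitors) {
      tab <- quantify_design("inhibitor_titration", config, inh = inh,
                             conditions = inh_conds,
                             seed_offset = 300 + match(inh$id,
                                                       names(inhibitors)))
      utils::write.csv(tab, file.path(
        outdir, sprintf("fractions_inhibitor_%s.csv", inh$id)),
        row.names = FALSE)
      ser <- series_from_table(tab, "b", "conc_f_T", "inhibitor")
      fit <- fit_hill(ser, fix_n = 1.3)  # tetramer-curve convention
      ic50 <- unname(fit$estimates["K"])
      ki <- ic50_to_ki(ic50, config$pharm)
      fits[[paste0("inhibitor_", inh$id)]] <- list(
        IC50_T = ic50, r_squared = fit$r_squared, flagged = fit$flagged)
      summary_rows[[inh$id]] <- data.frame(
        inhibitor = inh$id, IC50_uM = ic50 * 1e6, Ki_nM = ki$Ki * 1e9,
        ki_mode = ki$mode)
      pharm_out[[inh$id]] <- list(IC50 = ic50, Ki = ki$Ki, mode = ki$mode)
    }
    summary <- do.call(rbind, summary_rows)
    utils::write.csv(summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    report$summary <- summary
  }

  if ("schild_grid" %in% config$designs) {
    inh <- inhibitors[[length(inhibitors)]]  # most potent profile
    conds <- titration_design("schild_grid", B = config$schild_B)
    tab <- quantify_design("schild_grid", config, inh = inh,
                           conditions = conds, seed_offset = 600)
    utils::write.csv(tab, file.path(outdir, "fractions_schild_grid.csv"),
                     row.names = FALSE)
    ec50 <- lapply(split(tab, tab$b), function(d) {
      ser <- series_from_table(d, "s", "conc_f_T", "substrate")
      fit <- fit_hill(ser)
      data.frame(B = d$b[1], EC50 = unname(fit$estimates["K"]),
                 E_max = unname(fit$estimates["top"]),
                 flagged = fit$flagged)
    })
    ec50 <- do.call(rbind, ec50)
    ctrl <- ec50$EC50[ec50$B == 0]
    if (length(ctrl) != 1) {
      stop("identifiability: Schild analysis requires a B = 0 control curve",
           call. = FALSE)
    }
    sch <- try(schild_analysis(ec50[ec50$B > 0, ], ctrl), silent = TRUE)
    pharm_out$schild <- if (inherits(sch, "try-error")) {
      list(error = attr(sch, "condition")$message)
    } else {
      list(slope = sch$slope, K_B_app = sch$K_B_app,
           r_squared = sch$r_squared, linear_region = sch$linear_region)
    }
    om_data <- data.frame(S = tab$s, B = tab$b, y = 100 * tab$conc_f_T)
    om <- omam_global_fit(om_data,
                          E_max = fits$substrate_titration$E_max %||% 68.3,
                          K_S = fits$substrate_titration$K_S %||% 34.6e-6)
    pharm_out$omam <- if (!is.null(om$params)) {
      list(tau_S = om$params$tau_S, tau_I = om$params$tau_I,
           alpha = om$params$alpha, beta = om$params$beta,
           K_B = om$params$K_B, n = om$params$n, sse = om$sse,
           flagged = om$flagged)
    } else {
      list(flagged = TRUE)
    }
    fits$schild_ec50 <- ec50
  }

  jsonlite::write_json(fits, file.path(outdir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(c(list(seed = config$seed), pharm_out),
                       file.path(outdir, "pharmacology.json"),
                       auto_unbox = TRUE, digits = NA)
  report$fits <- fits
  report$pharmacology <- pharm_out
  invisible(report)
}
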