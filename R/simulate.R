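#' Simulate a single-particle mass event list for one condition
#'
#' Draws `n_events` particle landings from the equilibrium species
#' distribution. Mass photometry counts individual particles, so species are
#' drawn multinomially with probabilities proportional to the particle
#' concentrations `(M, D, T)` -- not mass-weighted. Each event mass is normal
#' around `k * monomer_mass` (k = 1, 2, 4) with standard deviation
#' `peak_cv * k * monomer_mass`; events below the detection floor are redrawn.
#' A fraction `background_rate` of events is replaced by uniform background
#' over `[min_mass, 300]` kDa.
#'
#' @param params An [equilibrium_params()] object.
#' @param inh An [inhibitor_model()] or `NULL`.
#' @param cond An [assay_condition()].
#' @param monomer_mass Monomer mass in kDa (default 46.4, the His-tagged GNE
#'   monomer).
#' @param n_events Number of particle events (default 8000, the per-histogram
#'   count floor of the emulated experiments).
#' @param noise A [noise_model()].
#' @param seed Integer seed; the same seed reproduces the event list exactly.
#' @return An object of class `event_list`: list with `masses` (kDa),
#'   `condition`, `seed`, `n_events`, `monomer_mass`, `noise`, and the
#'   per-species true counts `species_counts` (monomer/dimer/tetramer,
#'   background excluded).
#' @export
simulate_events <- function(params, inh = NULL, cond, monomer_mass = 46.4,
                            n_events = 8000, noise = noise_model(), seed = 1) {
  stopifnot(inherits(cond, "assay_condition"), inherits(noise, "noise_model"))
  if (n_events < 1) stop("`n_events` must be >= 1", call. = FALSE)
  species_mass <- monomer_mass * c(1, 2, 4)
  if (all(species_mass < noise$min_mass)) {
    stop("all species fall below the detection floor", call. = FALSE)
  }
  fr <- predict_fractions(params, inh, cond)
  sp <- fr$species
  probs <- c(sp$M, sp$D, sp$T)
  probs <- probs / sum(probs)
  with_seed(seed, {
    n_bg <- stats::rbinom(1, n_events, noise$background_rate)
    counts <- as.vector(stats::rmultinom(1, n_events - n_bg, probs))
    masses <- numeric(0)
    for (k in 1:3) {
      if (counts[k] == 0) next
      mu <- species_mass[k]
      sd_k <- noise$peak_cv * mu
      if (sd_k == 0 && mu < noise$min_mass) {
        stop("species mass below detection floor with zero peak width",
             call. = FALSE)
      }
      m <- stats::rnorm(counts[k], mu, sd_k)
      for (tries in seq_len(1000)) {
        low <- m < noise$min_mass
        if (!any(low)) break
        m[low] <- stats::rnorm(sum(low), mu, sd_k)
      }
      if (any(m < noise$min_mass)) {
        stop("could not draw events above the detection floor", call. = FALSE)
      }
      masses <- c(masses, m)
    }
    if (n_bg > 0) {
      masses <- c(masses, stats::runif(n_bg, noise$min_mass, 300))
    }
    structure(list(masses = masses, condition = cond, seed = seed,
                   n_events = length(masses), monomer_mass = monomer_mass,
                   noise = noise,
                   species_counts = c(monomer = counts[1], dimer = counts[2],
                                      tetramer = counts[3])),
              class = "event_list")
  })
}

#' Default concentration grids of the emulated titration designs
#'
#' Returns the table of conditions for one of the study designs:
#' \describe{
#'   \item{protein_dilution}{11 two-fold protein steps, 50 nM to 50 uM,
#'     optionally at a fixed substrate concentration `S`.}
#'   \item{substrate_titration}{7 two-fold substrate steps, 7.81 to 500 uM,
#'     at 800 nM protein.}
#'   \item{inhibitor_titration}{7 two-fold inhibitor steps, 7.81 to 500 uM,
#'     at 800 nM protein, with 100 uM substrate by default.}
#'   \item{schild_grid}{14 two-fold substrate steps, ~100 nM to 800 uM, at
#'     800 nM protein, crossed with an inhibitor grid spanning 2 nM to
#'     200 uM plus the B = 0 control.}
#' }
#'
#' @param design Design name.
#' @param C_tot,S,B Optional overrides: fixed protein/substrate concentration
#'   or inhibitor grid, depending on the design.
#' @return Data frame with columns `c_tot`, `s`, `b` (molar).
#' @export
titration_design <- function(design = c("protein_dilution", "substrate_titration",
                                        "inhibitor_titration", "schild_grid"),
                             C_tot = NULL, S = NULL, B = NULL) {
  valid <- c("protein_dilution", "substrate_titration",
             "inhibitor_titration", "schild_grid")
  if (!is.character(design) || !design[1] %in% valid) {
    stop("unknown design; valid designs: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  design <- match.arg(design)
  switch(design,
    protein_dilution = data.frame(
      c_tot = 50e-6 / 2^(10:0),
      s = S %||% 0,
      b = 0),
    substrate_titration = data.frame(
      c_tot = C_tot %||% 800e-9,
      s = 500e-6 / 2^(6:0),
      b = 0),
    inhibitor_titration = data.frame(
      c_tot = C_tot %||% 800e-9,
      s = S %||% 100e-6,
      b = 500e-6 / 2^(6:0)),
    schild_grid = {
      s_grid <- 800e-6 / 2^(13:0)
      b_grid <- B %||% c(0, 2e-9, 2e-8, 2e-7, 4e-7, 8e-7,
                         2e-6, 5e-6, 1e-5, 5e-5, 2e-4)
      expand.grid(c_tot = C_tot %||% 800e-9, s = s_grid, b = b_grid,
                  KEEP.OUT.ATTRS = FALSE)
    })
}

#' Simulate a full titration design
#'
#' Emits one [simulate_events()] event list per condition of the chosen
#' design, with per-condition seeds derived deterministically from `seed`.
#'
#' @inheritParams simulate_events
#' @param design Design name, see [titration_design()].
#' @param conditions Optional data frame of conditions (columns `c_tot`, `s`,
#'   `b`) overriding the design defaults.
#' @return List of `event_list` objects, one per condition.
#' @export
simulate_titration <- function(design, params, inh = NULL,
                               noise = noise_model(), n_events = 8000,
                               seed = 1, monomer_mass = 46.4,
                               conditions = NULL) {
  conds <- conditions %||% titration_design(design)
  lapply(seq_len(nrow(conds)), function(i) {
    cond <- assay_condition(conds$c_tot[i], conds$s[i], conds$b[i],
                            inhibitor_id = if (!is.null(inh) && conds$b[i] > 0)
                              inh$id else NA_character_)
    simulate_events(params, inh, cond, monomer_mass = monomer_mass,
                    n_events = n_events, noise = noise,
                    seed = derive_seed(seed, i))
  })
}

#' Simulate the glycinin calibration standard
#'
#' Four Gaussian populations at the characteristic glycinin assembly masses
#' 160, 320, 480 and 640 kDa (trimer, hexamer, nonamer, dodecamer), with
#' configurable mixture weights.
#'
#' @param n_events Number of events.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param weights Mixture weights over the four species (default equal).
#' @param known_masses Species masses in kDa.
#' @return An `event_list`; the `condition` field is `NULL` for a standard.
#' @export
simulate_calibration_standard <- function(n_events = 8000,
                                          noise = noise_model(), seed = 1,
                                          weights = rep(0.25, 4),
                                          known_masses = c(160, 320, 480, 640)) {
  if (n_events < 1) stop("`n_events` must be >= 1", call. = FALSE)
  stopifnot(length(weights) == length(known_masses), all(weights >= 0))
  weights <- weights / sum(weights)
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_events, weights))
    masses <- unlist(lapply(seq_along(known_masses), function(k) {
      if (counts[k] == 0) return(numeric(0))
      stats::rnorm(counts[k], known_masses[k], noise$peak_cv * known_masses[k])
    }))
    masses <- pmax(masses, noise$min_mass)
    structure(list(masses = masses, condition = NULL, seed = seed,
                   n_events = length(masses), monomer_mass = NA_real_,
                   noise = noise,
                   species_counts = stats::setNames(counts,
                                                    paste0(known_masses, "kDa"))),
              class = "event_list")
  })
}

#' Write / read an event list as CSV with a JSON metadata sidecar
#'
#' The CSV holds a single column `mass_kda`; `<path>.json` records the
#' condition, seed and noise model so that a run can be reproduced.
#'
#' @param x An `event_list`.
#' @param path CSV file path.
#' @return `write_event_list` returns `path` invisibly; `read_event_list`
#'   returns an `event_list`.
#' @export
write_event_list <- function(x, path) {
  stopifnot(inherits(x, "event_list"))
  utils::write.csv(data.frame(mass_kda = x$masses), path, row.names = FALSE)
  meta <- list(seed = x$seed, n_events = x$n_events,
               monomer_mass = x$monomer_mass,
               noise = unclass(x$noise),
               condition = if (!is.null(x$condition)) unclass(x$condition))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_event_list
#' @export
read_event_list <- function(path) {
  masses <- utils::read.csv(path)$mass_kda
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  cond <- if (!is.null(meta$condition)) {
    assay_condition(meta$condition$c_tot %||% meta$condition$C_tot,
                    meta$condition$S %||% 0, meta$condition$B %||% 0,
                    meta$condition$inhibitor_id %||% NA_character_)
  }
  nm <- if (!is.null(meta$noise)) {
    noise_model(meta$noise$peak_cv, meta$noise$background_rate,
                meta$noise$min_mass)
  } else noise_model()
  structure(list(masses = masses, condition = cond,
                 seed = meta$seed %||% NA_integer_, n_events = length(masses),
                 monomer_mass = meta$monomer_mass %||% NA_real_, noise = nm,
                 species_counts = NULL),
            class = "event_list")
}

#' Write a conditions table for a set of event lists
#'
#' Writes each event list as CSV under `dir` and a `conditions.csv` manifest
#' with columns `file`, `c_tot_molar`, `s_molar`, `b_molar`, `inhibitor_id`.
#'
#' @param events List of `event_list` objects.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_conditions_table <- function(events, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(events), function(i) {
    f <- file.path(dir, sprintf("events_%03d.csv", i))
    write_event_list(events[[i]], f)
    cond <- events[[i]]$condition
    data.frame(file = basename(f),
               c_tot_molar = cond$C_tot, s_molar = cond$S, b_molar = cond$B,
               inhibitor_id = cond$inhibitor_id %||% NA_character_)
  })
  manifest <- file.path(dir, "conditions.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Inhibitor concentration at half-maximal tetramer destabilization
#'
#' Noise-free model prediction of the tetramer IC50 under a standard assay:
#' the tetramer concentration-fraction is evaluated on a fine inhibitor grid
#' and the half-drop point between the uninhibited level and the high-B
#' plateau is located by monotone interpolation on log B.
#'
#' @param params An [equilibrium_params()] object.
#' @param inh An [inhibitor_model()].
#' @param C_tot,S Assay protein and substrate concentrations (molar).
#' @param B_max Upper end of the inhibitor grid (molar).
#' @return IC50 in molar.
#' @export
predict_tetramer_ic50 <- function(params, inh, C_tot = 800e-9, S = 100e-6,
                                  B_max = 1e-2) {
  f_at <- function(B) {
    predict_fractions(params, inh,
                      assay_condition(C_tot, S = S, B = B))$f_T
  }
  logB <- seq(log(inh$K_B) - 8, log(B_max), length.out = 400)
  fT <- vapply(exp(logB), f_at, numeric(1))
  f0 <- f_at(0)
  f_inf <- fT[length(fT)]
  half <- (f0 + f_inf) / 2
  if (f0 - f_inf < 1e-6) stop("inhibitor has no effect on tetramer fraction",
                              call. = FALSE)
  i <- which(fT <= half)[1]
  if (is.na(i) || i == 1) stop("half-drop not bracketed by the grid",
                               call. = FALSE)
  # linear interpolation in log B
  w <- (half - fT[i - 1]) / (fT[i] - fT[i - 1])
  exp(logB[i - 1] + w * (logB[i] - logB[i - 1]))
}

#' Calibrate an inhibitor affinity to a target tetramer IC50
#'
#' Solves for the `K_B` at which the model-predicted tetramer IC50 under the
#' standard assay equals `target_ic50`, holding the cooperativity `alpha` and
#' the dimer-destabilization factor `gamma_D` fixed. Used to parameterize
#' synthetic inhibitor profiles from measured potencies.
#'
#' @param target_ic50 Target tetramer IC50 (molar).
#' @param alpha,gamma_D Inhibitor model parameters, see [inhibitor_model()].
#' @param params An [equilibrium_params()] object.
#' @param C_tot,S Standard assay concentrations (molar).
#' @param id Inhibitor label.
#' @return An [inhibitor_model()] with the calibrated `K_B`.
#' @export
calibrate_inhibitor_kb <- function(target_ic50, alpha = 0.02, gamma_D = 1,
                                   params = equilibrium_params(),
                                   C_tot = 800e-9, S = 100e-6,
                                   id = "inhibitor") {
  check_positive(target_ic50, "target_ic50")
  f <- function(log_kb) {
    inh <- inhibitor_model(exp(log_kb), alpha = alpha, gamma_D = gamma_D,
                           id = id)
    log(predict_tetramer_ic50(params, inh, C_tot = C_tot, S = S)) -
      log(target_ic50)
  }
  root <- stats::uniroot(f, lower = log(1e-12), upper = log(1e-3),
                         tol = 1e-10)
  inhibitor_model(exp(root$root), alpha = alpha, gamma_D = gamma_D, id = id)
}

#' Synthetic inhibitor profiles emulating the three study compounds
#'
#' Returns C5-, C13- and C15-like [inhibitor_model()] objects whose affinities
#' are calibrated (via [calibrate_inhibitor_kb()]) so that the model tetramer
#' IC50 under the standard assay (800 nM protein, 100 uM substrate) matches
#' the measured potencies: 19.7, 19.4 and 3.1 uM. C5 leaves dimers intact
#' (`gamma_D = 1`); the pyrimidinone inhibitors C13/C15 additionally
#' destabilize dimers (`gamma_D = 8`). All share strong negative substrate
#' cooperativity (`alpha = 0.02`).
#'
#' @param params An [equilibrium_params()] object.
#' @return Named list of three `inhibitor_model` objects.
#' @export
inhibitor_profiles <- function(params = equilibrium_params()) {
  list(
    C5  = calibrate_inhibitor_kb(19.7e-6, alpha = 0.02, gamma_D = 1,
                                 params = params, id = "C5"),
    C13 = calibrate_inhibitor_kb(19.4e-6, alpha = 0.02, gamma_D = 8,
                                 params = params, id = "C13"),
    C15 = calibrate_inhibitor_kb(3.1e-6, alpha = 0.02, gamma_D = 8,
                                 params = params, id = "C15"))
}
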