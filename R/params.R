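#' Equilibrium parameters of the monomer-dimer-tetramer assembly model
#'
#' Bundles the dissociation constants of the two assembly interfaces with the
#' substrate-linkage parameters. `K1` refers to the monomer-monomer (dimer
#' forming) interface, `K2` to the dimer-dimer (tetramer forming) interface;
#' the `_0`/`_S` suffixes denote the substrate-free and substrate-saturated
#' limits. Defaults are the fitted constants of the GNE study system:
#' K1_0 = 12.6 nM, K1_S = 37.2 nM, K2_0 = 9.6 uM, K2_S = 98.1 nM,
#' K_S = 34.6 uM, linkage Hill exponent 1.3.
#'
#' @param K1_0,K1_S Monomer-monomer dissociation constant (molar) without and
#'   with saturating substrate.
#' @param K2_0,K2_S Dimer-dimer dissociation constant (molar) without and with
#'   saturating substrate.
#' @param K_S Substrate half-saturation constant (molar).
#' @param n_link Hill exponent of the substrate linkage, in `[0.5, 4]`.
#' @return An object of class `equilibrium_params`.
#' @export
equilibrium_params <- function(K1_0 = 12.6e-9, K1_S = 37.2e-9,
                               K2_0 = 9.6e-6, K2_S = 98.1e-9,
                               K_S = 34.6e-6, n_link = 1.3) {
  for (nm in c("K1_0", "K1_S", "K2_0", "K2_S", "K_S")) {
    check_positive(get(nm), nm)
  }
  if (!is.numeric(n_link) || n_link < 0.5 || n_link > 4) {
    stop("`n_link` must lie in [0.5, 4]", call. = FALSE)
  }
  structure(list(K1_0 = K1_0, K1_S = K1_S, K2_0 = K2_0, K2_S = K2_S,
                 K_S = K_S, n_link = n_link),
            class = "equilibrium_params")
}

#' Inhibitor model: affinity, substrate cooperativity and dimer destabilization
#'
#' Phenomenological description of an orthosteric assembly inhibitor. `K_B` is
#' the inhibitor dissociation constant, `alpha` the binding cooperativity with
#' the substrate (alpha < 1 means negative cooperativity, i.e. mutual
#' displacement), and `gamma_D` the fold-weakening of the monomer-monomer
#' interface at full inhibitor occupancy. `gamma_D = 1` gives a pure
#' tetramer-level inhibitor; `gamma_D > 1` additionally destabilizes dimers,
#' as observed for the pyrimidinone inhibitors.
#'
#' @param K_B Inhibitor dissociation constant (molar).
#' @param alpha Binding cooperativity with substrate, `>= 0`.
#' @param gamma_D Fold-weakening of K1 at full occupancy, `>= 1`.
#' @param id Label for the inhibitor.
#' @return An object of class `inhibitor_model`.
#' @export
inhibitor_model <- function(K_B, alpha = 1, gamma_D = 1, id = "inhibitor") {
  check_positive(K_B, "K_B")
  check_nonnegative(alpha, "alpha")
  if (!is.numeric(gamma_D) || gamma_D < 1) {
    stop("`gamma_D` must be >= 1", call. = FALSE)
  }
  structure(list(K_B = K_B, alpha = alpha, gamma_D = gamma_D, id = id),
            class = "inhibitor_model")
}

#' One experimental condition
#'
#' @param C_tot Total protein concentration in monomer equivalents (molar).
#' @param S Substrate concentration (molar).
#' @param B Inhibitor concentration (molar).
#' @param inhibitor_id Label of the inhibitor present, or `NA`.
#' @return An object of class `assay_condition`.
#' @export
assay_condition <- function(C_tot, S = 0, B = 0, inhibitor_id = NA_character_) {
  check_positive(C_tot, "C_tot")
  check_nonnegative(S, "S")
  check_nonnegative(B, "B")
  structure(list(C_tot = C_tot, S = S, B = B, inhibitor_id = inhibitor_id),
            class = "assay_condition")
}

#' Measurement noise model for simulated mass photometry events
#'
#' @param peak_cv Gaussian peak width as a fraction of the species mass.
#' @param background_rate Fraction of events drawn uniformly over
#'   `[min_mass, 300]` kDa, mimicking non-specific landings.
#' @param min_mass Detection floor in kDa.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(peak_cv = 0.08, background_rate = 0.02, min_mass = 40) {
  if (!is.numeric(peak_cv) || peak_cv < 0 || peak_cv > 0.3) {
    stop("`peak_cv` must lie in [0, 0.3]", call. = FALSE)
  }
  if (!is.numeric(background_rate) || background_rate < 0 || background_rate > 0.2) {
    stop("`background_rate` must lie in [0, 0.2]", call. = FALSE)
  }
  check_positive(min_mass, "min_mass")
  structure(list(peak_cv = peak_cv, background_rate = background_rate,
                 min_mass = min_mass),
            class = "noise_model")
}

#' Parameters of the Hill-modified operational model (OMAM)
#'
#' @param E_max Maximal response in percent, in `(0, 100]`.
#' @param K_S,K_B Substrate and inhibitor dissociation constants (molar).
#' @param tau_S,tau_I Operational efficacies of substrate and inhibitor.
#' @param alpha Binding cooperativity factor.
#' @param beta Operational (efficacy) cooperativity factor.
#' @param n Hill slope of the transducer function.
#' @return An object of class `omam_params`.
#' @export
omam_params <- function(E_max, K_S, K_B, tau_S, tau_I, alpha, beta, n) {
  if (!is.numeric(E_max) || E_max <= 0 || E_max > 100) {
    stop("`E_max` must lie in (0, 100]", call. = FALSE)
  }
  check_positive(K_S, "K_S")
  check_positive(K_B, "K_B")
  for (nm in c("tau_S", "tau_I", "alpha", "beta")) {
    check_nonnegative(get(nm), nm)
  }
  check_positive(n, "n")
  structure(list(E_max = E_max, K_S = K_S, K_B = K_B, tau_S = tau_S,
                 tau_I = tau_I, alpha = alpha, beta = beta, n = n),
            class = "omam_params")
}

#' Configuration for IC50 to Ki conversion
#'
#' The conversion mode must be chosen explicitly. `classical` applies the
#' Cheng-Prusoff competition factor `1 + S/K_S`; `hill` raises that factor to
#' the Hill exponent `n`; `empirical_lambda` divides by a calibrated factor
#' `lambda` (see [calibrate_lambda()]).
#'
#' @param mode One of `"classical"`, `"hill"`, `"empirical_lambda"`.
#' @param S Assay substrate concentration (molar).
#' @param K_S Substrate affinity (molar).
#' @param n Hill exponent (used by mode `"hill"`).
#' @param lambda Empirical IC50/Ki factor (required by mode
#'   `"empirical_lambda"`).
#' @return An object of class `pharmacology_config`.
#' @export
pharmacology_config <- function(mode = c("classical", "hill", "empirical_lambda"),
                                S = 100e-6, K_S = 34.6e-6, n = 1.3,
                                lambda = NULL) {
  mode <- match.arg(mode)
  check_nonnegative(S, "S")
  check_positive(K_S, "K_S")
  check_positive(n, "n")
  if (!is.null(lambda)) check_positive(lambda, "lambda")
  structure(list(mode = mode, S = S, K_S = K_S, n = n, lambda = lambda),
            class = "pharmacology_config")
}
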