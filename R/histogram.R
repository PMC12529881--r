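#' Bin an event list into a mass histogram
#'
#' @param events An `event_list`.
#' @param bin_width Bin width in kDa (default 4).
#' @return Object of class `mass_histogram`: list with `bin_edges`, `counts`,
#'   `n_total`. `sum(counts) == n_total` always holds.
#' @export
build_histogram <- function(events, bin_width = 4) {
  stopifnot(inherits(events, "event_list"))
  check_positive(bin_width, "bin_width")
  x <- events$masses
  if (length(x) == 0) stop("empty event list", call. = FALSE)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(list(bin_edges = edges, counts = counts, n_total = length(x)),
            class = "mass_histogram")
}

#' @export
print.mass_histogram <- function(x, ...) {
  cat(sprintf("mass_histogram: %d events, %d bins over [%g, %g] kDa\n",
              x$n_total, length(x$counts), min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

# Expectation-maximization for a K-Gaussian mixture with optional uniform
# background. Means are initialized at the nominal species masses.
gaussian_mixture_em <- function(x, mu0, sigma0, background = TRUE,
                                max_iter = 500, tol = 1e-8) {
  K <- length(mu0)
  n <- length(x)
  rng <- range(x)
  bg_dens <- if (background && diff(rng) > 0) 1 / diff(rng) else 0
  mu <- mu0
  sigma <- sigma0
  w <- if (background) c(rep(0.98 / K, K), 0.02) else rep(1 / K, K)
  ncomp <- K + as.integer(background)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- matrix(0, n, ncomp)
    for (k in seq_len(K)) dens[, k] <- w[k] * stats::dnorm(x, mu[k], sigma[k])
    if (background) dens[, K + 1] <- w[K + 1] * bg_dens
    rowsum_d <- rowSums(dens)
    if (any(!is.finite(rowsum_d)) || any(rowsum_d <= 0)) return(NULL)
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    w <- nk / n
    for (k in seq_len(K)) {
      if (nk[k] < 1e-8) next
      mu[k] <- sum(resp[, k] * x) / nk[k]
      sigma[k] <- sqrt(sum(resp[, k] * (x - mu[k])^2) / nk[k])
    }
    if (any(sigma < 1e-6)) return(NULL)  # degenerate peak, caller falls back
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (is.unsorted(mu)) return(NULL)  # components swapped; not a species fit
  # hard assignment by maximum posterior
  assign <- max.col(resp, ties.method = "first")
  counts <- tabulate(assign, nbins = ncomp)
  list(mu = mu, sigma = sigma, weights = w, counts = counts[seq_len(K)],
       background_count = if (background) counts[K + 1] else 0L,
       loglik = ll, converged = converged)
}

# Deterministic fixed-window fallback: events are assigned to the species
# window mu0[k] +/- window_sigmas * sigma0[k]; when windows overlap the
# nearest mean (in units of sigma) wins, with ties going to the lower-mass
# species. Events outside every window count as background.
fixed_window_counts <- function(x, mu0, sigma0, window_sigmas = 2.5) {
  K <- length(mu0)
  half <- window_sigmas * sigma0
  assign <- integer(length(x))
  zdist <- abs(outer(x, mu0, "-")) / rep(sigma0, each = length(x))
  inside <- abs(outer(x, mu0, "-")) <= rep(half, each = length(x))
  for (i in seq_along(x)) {
    cand <- which(inside[i, ])
    if (length(cand) == 0) {
      assign[i] <- 0L
    } else {
      d <- zdist[i, cand]
      assign[i] <- cand[which(d <= min(d) + 1e-12)[1]]  # tie -> lower species
    }
  }
  counts <- tabulate(assign[assign > 0], nbins = K)
  list(counts = counts, background_count = sum(assign == 0L))
}

#' Fit per-species Gaussian peaks to an event list
#'
#' Fits a three-component Gaussian mixture (monomer, dimer, tetramer at
#' nominal masses 1x/2x/4x the monomer mass) plus an optional uniform
#' background by maximum likelihood (EM), and returns per-species event
#' counts by maximum-posterior assignment. If the EM degenerates (zero-width
#' peaks, non-convergence, or reordered components) the result is flagged and
#' counting falls back to fixed windows at `mean +/- window_sigmas * sigma0`.
#'
#' @param events An `event_list` (at least 100 events).
#' @param init_masses Initial species masses in kDa; default
#'   `monomer_mass * c(1, 2, 4)` from the event list.
#' @param window_sigmas Half-width of the fallback windows in initial sigmas.
#' @param peak_cv_init Initial relative peak width.
#' @param background Include a uniform background component.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return Object of class `peak_fit`: `species` data frame (species, mean,
#'   sigma, count), `background_count`, `converged`, `method`
#'   (`"mixture"` or `"fixed_window"`), and `loglik`.
#' @export
fit_peaks <- function(events, init_masses = NULL, window_sigmas = 2.5,
                      peak_cv_init = 0.08, background = TRUE,
                      max_iter = 500, tol = 1e-8) {
  stopifnot(inherits(events, "event_list"))
  x <- events$masses
  if (length(x) < 100) stop("need at least 100 events to fit peaks",
                            call. = FALSE)
  mu0 <- init_masses %||% (events$monomer_mass * c(1, 2, 4))
  if (any(!is.finite(mu0))) stop("no valid initial masses", call. = FALSE)
  sigma0 <- pmax(peak_cv_init * mu0, 1e-3)
  em <- gaussian_mixture_em(x, mu0, sigma0, background = background,
                            max_iter = max_iter, tol = tol)
  if (!is.null(em) && em$converged) {
    species <- data.frame(species = c("monomer", "dimer", "tetramer"),
                          mean = em$mu, sigma = em$sigma, count = em$counts)
    return(structure(list(species = species,
                          background_count = em$background_count,
                          converged = TRUE, method = "mixture",
                          loglik = em$loglik),
                     class = "peak_fit"))
  }
  fw <- fixed_window_counts(x, mu0, sigma0, window_sigmas)
  # report per-window empirical moments
  mean_k <- sigma_k <- numeric(3)
  for (k in 1:3) {
    in_k <- abs(x - mu0[k]) <= window_sigmas * sigma0[k]
    mean_k[k] <- if (any(in_k)) mean(x[in_k]) else mu0[k]
    sigma_k[k] <- if (sum(in_k) > 1) stats::sd(x[in_k]) else 0
  }
  species <- data.frame(species = c("monomer", "dimer", "tetramer"),
                        mean = mean_k, sigma = sigma_k, count = fw$counts)
  structure(list(species = species, background_count = fw$background_count,
                 converged = FALSE, method = "fixed_window", loglik = NA_real_),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("peak_fit (%s%s): background = %d\n", x$method,
              if (x$converged) "" else ", flagged", x$background_count))
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Oligomer fractions from per-species counts
#'
#' Converts monomer/dimer/tetramer event counts into both reporting
#' conventions: count fractions (`c_k / sum(c)`, the "frequency
#' distribution" view of the raw histogram) and concentration fractions
#' (monomer-equivalent mass fractions, `(c_M, 2 c_D, 4 c_T)` normalized),
#' which express the fraction of total protein residing in each species.
#'
#' @param counts Numeric vector of length 3: counts for monomer, dimer,
#'   tetramer.
#' @return Object of class `oligomer_fractions`: `count_fractions` and
#'   `conc_fractions` (each named `f_M`, `f_D`, `f_T`, summing to 1) and
#'   `n_assigned`.
#' @export
fractions_from_counts <- function(counts) {
  if (length(counts) != 3 || any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be three non-negative numbers (M, D, T)",
         call. = FALSE)
  }
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  cf <- counts / sum(counts)
  wt <- counts * c(1, 2, 4)
  ccf <- wt / sum(wt)
  nm <- c("f_M", "f_D", "f_T")
  structure(list(count_fractions = stats::setNames(cf, nm),
                 conc_fractions = stats::setNames(ccf, nm),
                 n_assigned = sum(counts)),
            class = "oligomer_fractions")
}

#' Mass accuracy as the min/max ratio of observed and expected mass
#'
#' @param observed,expected Masses in kDa (vectorized).
#' @return Accuracy in percent, `100 * min / max`.
#' @examples
#' mass_accuracy(50, 46.4)  # 92.8
#' @export
mass_accuracy <- function(observed, expected) {
  check_positive(observed, "observed")
  check_positive(expected, "expected")
  100 * pmin(observed, expected) / pmax(observed, expected)
}

#' Linear mass calibration against a multi-species standard
#'
#' Locates one peak per known species in the raw measurements (k-means with
#' deterministic quantile initialization), then fits the least-squares linear
#' map from raw peak positions to the known masses. With input already in
#' kDa the map is the identity.
#'
#' @param standard_events An `event_list` of the calibration standard, in raw
#'   (possibly distorted) units.
#' @param known_masses Known species masses in kDa (>= 2 values).
#' @return Object of class `mass_calibration`: `slope`, `intercept`,
#'   `raw_peaks`, `known_masses`. Apply with [apply_calibration()].
#' @export
calibrate_masses <- function(standard_events,
                             known_masses = c(160, 320, 480, 640)) {
  stopifnot(inherits(standard_events, "event_list"))
  if (length(known_masses) < 2) {
    stop("need at least 2 known masses", call. = FALSE)
  }
  x <- standard_events$masses
  k <- length(known_masses)
  centers0 <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  if (length(unique(round(centers0, 6))) < k) {
    stop("fewer than 2 resolvable peaks in the standard", call. = FALSE)
  }
  km <- stats::kmeans(x, centers = matrix(centers0, ncol = 1), iter.max = 100)
  raw_peaks <- sort(as.vector(km$centers))
  if (min(diff(raw_peaks)) < 1e-9 * max(abs(raw_peaks))) {
    stop("fewer than 2 resolvable peaks in the standard", call. = FALSE)
  }
  fit <- stats::lm(known ~ raw, data = data.frame(known = sort(known_masses),
                                                  raw = raw_peaks))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 raw_peaks = raw_peaks, known_masses = sort(known_masses)),
            class = "mass_calibration")
}

#' @rdname calibrate_masses
#' @param cal A `mass_calibration`.
#' @param raw Raw measurements to map to kDa.
#' @export
apply_calibration <- function(cal, raw) {
  stopifnot(inherits(cal, "mass_calibration"))
  cal$intercept + cal$slope * raw
}

#' Quantify one event list: peak fit plus both fraction conventions
#'
#' @inheritParams fit_peaks
#' @param ... Passed to [fit_peaks()].
#' @return One-row data frame with the condition, per-species counts, both
#'   fraction conventions (as proportions), `n_assigned` and the fit method.
#' @export
quantify_events <- function(events, ...) {
  pf <- fit_peaks(events, ...)
  fr <- fractions_from_counts(pf$species$count)
  cond <- events$condition
  data.frame(c_tot = if (!is.null(cond)) cond$C_tot else NA_real_,
             s = if (!is.null(cond)) cond$S else NA_real_,
             b = if (!is.null(cond)) cond$B else NA_real_,
             inhibitor_id = if (!is.null(cond)) cond$inhibitor_id else NA,
             n_events = events$n_events,
             count_M = pf$species$count[1], count_D = pf$species$count[2],
             count_T = pf$species$count[3],
             count_f_M = fr$count_fractions[["f_M"]],
             count_f_D = fr$count_fractions[["f_D"]],
             count_f_T = fr$count_fractions[["f_T"]],
             conc_f_M = fr$conc_fractions[["f_M"]],
             conc_f_D = fr$conc_fractions[["f_D"]],
             conc_f_T = fr$conc_fractions[["f_T"]],
             n_assigned = fr$n_assigned, method = pf$method)
}
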