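make_events <- function(masses, monomer_mass = 46.4) {
  structure(list(masses = masses, condition = NULL, seed = NA_integer_,
                 n_events = length(masses), monomer_mass = monomer_mass,
                 noise = noise_model(), species_counts = NULL),
            class = "event_list")
}

test_that("histograms conserve counts and resolve discrete inputs", {
  p <- truth_params()
  ev <- simulate_events(p, NULL, assay_condition(800e-9), n_events = 8000,
                        seed = 1)
  h <- build_histogram(ev)
  expect_identical(sum(h$counts), 8000L)
  expect_identical(h$n_total, 8000L)
  expect_true(all(diff(h$bin_edges) > 0))

  h1 <- build_histogram(make_events(rep(100, 50)), bin_width = 4)
  expect_identical(sum(h1$counts > 0), 1L)

  quiet <- noise_model(peak_cv = 0, background_rate = 0)
  ev3 <- simulate_events(p, NULL, assay_condition(800e-9), n_events = 4000,
                         noise = quiet, seed = 2)
  h3 <- build_histogram(ev3, bin_width = 4)
  expect_identical(sum(h3$counts > 0), 3L)

  expect_error(build_histogram(make_events(numeric(0))), "empty")
  expect_error(build_histogram(ev, bin_width = 0), "positive")
})

test_that("mixture peak fit recovers species means and counts", {
  p <- truth_params()
  ev <- simulate_events(p, NULL, assay_condition(800e-9, S = 100e-6),
                        n_events = 8000,
                        noise = noise_model(peak_cv = 0.08,
                                            background_rate = 0.02),
                        seed = 13)
  pf <- fit_peaks(ev)
  expect_identical(pf$method, "mixture")
  expect_true(pf$converged)
  expect_true(all(abs(pf$species$mean / c(46.4, 92.8, 185.6) - 1) < 0.02))
  expect_true(all(diff(pf$species$mean) > 0))
  # counts close to the generator's true species counts
  expect_true(all(abs(pf$species$count - ev$species_counts) <
                    0.05 * ev$n_events))
})

test_that("noise-free input falls back to exact fixed-window counting", {
  p <- truth_params()
  quiet <- noise_model(peak_cv = 0, background_rate = 0)
  ev <- simulate_events(p, NULL, assay_condition(800e-9), n_events = 4000,
                        noise = quiet, seed = 6)
  pf <- fit_peaks(ev)
  expect_identical(pf$method, "fixed_window")
  expect_false(pf$converged)
  expect_identical(as.integer(pf$species$count),
                   as.integer(unname(ev$species_counts)))
})

test_that("absent tetramer yields a near-zero tetramer count", {
  # two-species input: strong dimer, no tetramer (huge K2)
  ev_masses <- with(list(), {
    set.seed(31)
    c(rnorm(3000, 46.4, 3.7), rnorm(5000, 92.8, 7.4))
  })
  pf <- fit_peaks(make_events(ev_masses))
  expect_lt(pf$species$count[3] / length(ev_masses), 0.005)
})

test_that("posterior and fixed-window counts agree for well-separated peaks", {
  p <- truth_params()
  ev <- simulate_events(p, NULL, assay_condition(800e-9),
                        noise = noise_model(peak_cv = 0.08,
                                            background_rate = 0),
                        n_events = 8000, seed = 17)
  pf_mix <- fit_peaks(ev, background = FALSE)
  pf_win <- assemblyMP:::fixed_window_counts(ev$masses, 46.4 * c(1, 2, 4),
                                             0.08 * 46.4 * c(1, 2, 4))
  expect_identical(pf_mix$method, "mixture")
  expect_true(all(abs(pf_mix$species$count - pf_win$counts) <
                    0.02 * ev$n_events))
})

test_that("fraction conventions follow the 1/2/4 monomer-equivalent weighting", {
  # observed count ratios of the dilute and concentrated regimes
  fr_lo <- fractions_from_counts(c(18, 31, 1))
  expect_equal(unname(fr_lo$conc_fractions),
               c(18, 62, 4) / 84, tolerance = 1e-12)
  expect_equal(unname(fr_lo$conc_fractions), c(0.214, 0.738, 0.048),
               tolerance = 0.01)
  fr_hi <- fractions_from_counts(c(4, 18, 7))
  expect_equal(unname(fr_hi$conc_fractions), c(4, 36, 28) / 68,
               tolerance = 1e-12)
  expect_equal(unname(fr_hi$conc_fractions), c(0.059, 0.529, 0.412),
               tolerance = 0.01)

  fr_m <- fractions_from_counts(c(1234, 0, 0))
  expect_equal(unname(fr_m$count_fractions), c(1, 0, 0))
  expect_equal(unname(fr_m$conc_fractions), c(1, 0, 0))

  expect_error(fractions_from_counts(c(0, 0, 0)), "zero")

  # consistency property: conc follows from count fractions exactly
  set.seed(23)
  for (i in 1:20) {
    cts <- rmultinom(1, 5000, runif(3))[, 1]
    if (sum(cts) == 0) next
    fr <- fractions_from_counts(cts)
    w <- fr$count_fractions * c(1, 2, 4)
    expect_equal(unname(fr$conc_fractions), unname(w / sum(w)),
                 tolerance = 1e-12)
    expect_equal(sum(fr$count_fractions), 1, tolerance = 1e-9)
    expect_equal(sum(fr$conc_fractions), 1, tolerance = 1e-9)
  }
})

test_that("mass accuracy is the min/max ratio in percent", {
  expect_equal(mass_accuracy(50, 46.4), 92.8)
  expect_equal(mass_accuracy(90, 92.8), 100 * 90 / 92.8)
  expect_equal(round(mass_accuracy(90, 92.8)), 97)
  expect_identical(mass_accuracy(123.4, 123.4), 100)
  expect_equal(mass_accuracy(46.4, 50), mass_accuracy(50, 46.4))  # symmetric
})

test_that("mass calibration recovers identity and linear distortions", {
  quiet <- noise_model(peak_cv = 0, background_rate = 0)
  std <- simulate_calibration_standard(4000, noise = quiet, seed = 12)
  cal <- calibrate_masses(std)
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-6)

  distorted <- make_events(0.5 * std$masses + 10, monomer_mass = NA_real_)
  cal2 <- calibrate_masses(distorted)
  expect_equal(cal2$slope, 2, tolerance = 0.01)
  expect_equal(cal2$intercept, -20, tolerance = 0.01 * 20)
  expect_equal(apply_calibration(cal2, 0.5 * 480 + 10), 480, tolerance = 1e-6)

  expect_error(calibrate_masses(std, known_masses = 160), "at least 2")
  expect_error(calibrate_masses(make_events(rep(100, 500), NA_real_)),
               "resolvable")
})

test_that("end-to-end: generator fractions recovered within 3 points at n = 8000", {
  p <- truth_params()
  for (C in c(800e-9, 10e-6)) {
    fr_true <- predict_fractions(p, NULL, assay_condition(C))
    ev <- simulate_events(p, NULL, assay_condition(C), n_events = 8000,
                          seed = 19)
    q <- quantify_events(ev)
    expect_lt(abs(q$conc_f_M - fr_true$f_M), 0.03)
    expect_lt(abs(q$conc_f_D - fr_true$f_D), 0.03)
    expect_lt(abs(q$conc_f_T - fr_true$f_T), 0.03)
  }
})
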