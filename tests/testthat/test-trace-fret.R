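test_that("per-frame FRET efficiency is the acceptor fraction of total intensity", {
  ft <- compute_fret(donor = c(40, 100, 50), acceptor = c(60, 0, 50))
  expect_equal(ft$efficiency, c(0.60, 0.0, 0.5))
  expect_equal(ft$usable_length, 3L)

  # scale invariance: multiplying both channels by c > 0 leaves E unchanged
  d <- runif(50, 100, 1000); a <- runif(50, 100, 1000)
  expect_equal(compute_fret(d, a)$efficiency,
               compute_fret(7.3 * d, 7.3 * a)$efficiency)

  # nonpositive total intensity is flagged invalid, not divided
  ft2 <- compute_fret(donor = c(100, 0, -5), acceptor = c(100, 0, 5))
  expect_equal(ft2$valid, c(TRUE, FALSE, FALSE))
  expect_equal(ft2$usable_length, 1L)
  expect_warning(compute_fret(donor = 0, acceptor = 0), "empty")
})

test_that("photobleach detection matches the exhaustive change-point oracle", {
  total <- c(rep(1000, 100), rep(50, 40))
  donor <- total / 2
  res <- detect_photobleach(donor, donor)
  expect_equal(res$bleach_frame, 101L)
  expect_equal(res$usable_length, 100L)
  expect_equal(oracle_changepoint(total), 100L)   # last pre-drop frame

  set.seed(1)
  for (k in c(20, 70, 120)) {
    noisy <- c(rnorm(k, 900, 30), rnorm(140 - k, 80, 15))
    res <- detect_photobleach(noisy / 2, noisy / 2)
    expect_equal(res$usable_length, oracle_changepoint(noisy))
  }

  # constant trace: no bleach, full length usable
  flat <- detect_photobleach(rep(500, 50), rep(500, 50))
  expect_true(is.na(flat$bleach_frame))
  expect_equal(flat$usable_length, 50L)

  # signal below the intensity floor from the start: nothing usable
  dead <- detect_photobleach(rep(10, 50) + rnorm(50), rep(10, 50),
                             min_intensity = 200)
  expect_equal(dead$usable_length, 0L)
})

test_that("histograms use 100 fixed 0.01 bins and normalize to one", {
  h <- build_histogram(rep(0.505, 200))
  expect_equal(nrow(h), 100L)
  expect_equal(h$height[h$bin_lo == 0.50], 1.0)
  expect_equal(sum(h$height[h$bin_lo != 0.50]), 0)

  set.seed(2)
  e <- runif(1e6)
  h2 <- build_histogram(e)
  expect_equal(sum(h2$height), 1, tolerance = 1e-12)
  se <- sqrt(0.01 * 0.99 / 1e6)
  expect_true(all(abs(h2$height - 0.01) < 3.5 * se))

  # edge values: 1.0 falls in the final closed bin
  h3 <- build_histogram(c(0, 1, 0.999, 0.01))
  expect_equal(h3$height[c(1, 2, 100)], c(0.25, 0.25, 0.5))

  # invariance to trace ordering and splitting across traces
  set.seed(3); e <- runif(5000)
  expect_equal(build_histogram(e)$height,
               build_histogram(list(e[1:1234], e[1235:5000]))$height)
  expect_equal(build_histogram(e)$height, build_histogram(rev(e))$height)
  expect_error(build_histogram(numeric(0)), "no usable frames")
})

test_that("burst efficiencies apply the photon threshold and background correction", {
  b <- data.frame(f_donor = c(25, 20, 20),
                  f_acceptor = c(30, 19, 20),
                  background_donor = c(5, 0, 0),
                  background_acceptor = c(5, 0, 0))
  out <- burst_efficiencies(b, threshold = 40)
  expect_equal(out$efficiency[1], 25 / 45)     # background-corrected
  expect_true(out$included[1])                 # total 55 >= 40
  expect_false(out$included[2])                # total 39 < 40
  expect_true(out$included[3])                 # boundary total 40
  expect_equal(out$efficiency[3], 0.5)

  # clamping of negative corrected counts
  neg <- data.frame(f_donor = c(50, 2, 3), f_acceptor = c(2, 50, 4),
                    background_donor = c(0, 10, 10),
                    background_acceptor = c(10, 0, 10))
  outn <- burst_efficiencies(neg, threshold = 40)
  expect_equal(outn$efficiency[1], 0)     # corrected acceptor < 0
  expect_equal(outn$efficiency[2], 1)     # corrected donor < 0
  expect_false(outn$included[3])          # both corrected <= 0: discarded

  # monotone inclusion: raising the threshold never adds bursts
  set.seed(4)
  rb <- data.frame(f_donor = rpois(300, 30), f_acceptor = rpois(300, 30))
  inc40 <- burst_efficiencies(rb, 40)$included
  inc60 <- burst_efficiencies(rb, 60)$included
  expect_true(all(inc60 <= inc40))
  expect_error(burst_efficiencies(data.frame(f_donor = -1, f_acceptor = 5)),
               "nonnegative")
})

test_that("noiseless single-state traces put all histogram mass in the generative bin", {
  em <- emission_model(mean_donor = 280, mean_acceptor = 720)
  kin <- two_state_kinetics(1e-12, 1e-12, p_high0 = 1)
  tr <- simulate_traces(kin, em, n_traces = 10, duration = 5, seed = 2)
  effs <- lapply(split(tr$traces, tr$traces$trace_id), compute_fret)
  h <- build_histogram(effs)
  expect_equal(h$height[h$bin_lo == 0.72], 1.0)
})
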