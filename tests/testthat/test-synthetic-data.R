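test_that("trace generator is deterministic given a seed and exact when noiseless", {
  kin <- two_state_kinetics(0.5, 1)
  em <- emission_model(mean_donor = c(300, 600), mean_acceptor = c(700, 400))
  a <- simulate_traces(kin, em, n_traces = 5, duration = 10, seed = 42)
  b <- simulate_traces(kin, em, n_traces = 5, duration = 10, seed = 42)
  expect_identical(a, b)
  d <- simulate_traces(kin, em, n_traces = 5, duration = 10, seed = 43)
  expect_false(identical(a$traces, d$traces))

  # degenerate noise, effectively single state: frames equal the state means
  em1 <- emission_model(mean_donor = 300, mean_acceptor = 700)
  kin1 <- two_state_kinetics(1e-12, 1e-12, p_high0 = 1)
  tr <- simulate_traces(kin1, em1, n_traces = 2, duration = 5, seed = 1)
  expect_true(all(tr$traces$donor == 300))
  expect_true(all(tr$traces$acceptor == 700))
  expect_equal(nrow(tr$traces), 2 * floor(5 / 0.1))

  expect_error(simulate_traces(kin, em, n_traces = 1, duration = -1),
               "positive")
  expect_error(simulate_traces(kin, em, n_traces = 1, duration = 0.05),
               "frame_time")
})

test_that("symmetric rates occupy the high state half the time", {
  kin <- two_state_kinetics(1, 1, p_high0 = 0.5)
  em <- emission_model(mean_donor = c(300, 600), mean_acceptor = c(700, 400))
  tr <- simulate_traces(kin, em, n_traces = 100, duration = 100, seed = 7)
  states <- unlist(tr$truth$state)
  frac_high <- mean(states == 1L)
  # correlated-chain standard error: p(1-p)/n * (1+lambda)/(1-lambda),
  # lambda = 1 - p_hl - p_lh = 0.8
  se <- sqrt(0.25 / length(states) * (1 + 0.8) / (1 - 0.8))
  expect_lt(abs(frac_high - 0.5), 3 * se)
})

test_that("simulated dwell lengths are geometric with mean 1/(k * frame_time)", {
  # long traces: interior dwells of a short observation window are length-
  # biased against long sojourns, so the window must dwarf the mean dwell
  kin <- two_state_kinetics(k_high_to_low = 0.5, k_low_to_high = 1)
  em <- emission_model(mean_donor = c(300, 600), mean_acceptor = c(700, 400))
  tr <- simulate_traces(kin, em, n_traces = 50, duration = 600, seed = 21)
  dw <- extract_dwells(tr$truth$state, frame_time = 0.1)
  u <- dw[!dw$censored, ]
  m_high <- mean(u$duration[u$state == 1]) / 0.1   # frames
  m_low <- mean(u$duration[u$state == 2]) / 0.1
  n_high <- sum(u$state == 1); n_low <- sum(u$state == 2)
  expect_gt(n_high + n_low, 5000)
  # geometric sd ~ mean; 3 standard errors of the mean
  expect_lt(abs(m_high - 20), 3 * 20 / sqrt(n_high))
  expect_lt(abs(m_low - 10), 3 * 10 / sqrt(n_low))
})

test_that("photobleach times are exponential with the stated rate", {
  kin <- two_state_kinetics(1e-12, 1e-12, p_high0 = 1)
  em <- emission_model(mean_donor = 300, mean_acceptor = 700,
                       photobleach_rate = 0.05)
  tr <- simulate_traces(kin, em, n_traces = 1000, duration = 100, seed = 9)
  bf <- tr$truth$bleach_frame
  observed <- bf[!is.na(bf)]
  expect_gt(length(observed), 900)    # mean 20 s versus 100 s window
  times <- (observed - 0.5) * 0.1     # mid-frame back-transform
  ks <- suppressWarnings(stats::ks.test(times, stats::pexp, rate = 0.05))
  expect_gt(ks$p.value, 0.01)
})

test_that("burst generator is reproducible and matches its Poisson means", {
  bm <- burst_model(photon_rate_donor = 4000, photon_rate_acceptor = 4000,
                    mean_burst_duration = 5e-3)
  a <- simulate_bursts(bm, 200, seed = 3)
  b <- simulate_bursts(bm, 200, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$bursts$f_donor == round(a$bursts$f_donor)))
  # symmetric rates, no background: true efficiency exactly 0.5
  expect_equal(unique(a$truth$efficiency), 0.5)

  big <- simulate_bursts(bm, 5000, seed = 4)
  mean_total <- mean(big$bursts$f_donor + big$bursts$f_acceptor)
  expected <- 8000 * mean(big$bursts$duration)
  expect_lt(abs(mean_total - expected) / expected, 0.02)
  expect_error(burst_model(-1, 10), "nonnegative")
})

test_that("titration generator lies exactly on the 4PL curve when noiseless", {
  conc <- halflog_grid(3.16e-10, 1e-7)
  tt <- titration_truth(0.1, 0.9, ec50 = 5.5e-9, hill = 1.2,
                        concentrations = conc, replicates = 2, noise_sd = 0)
  s <- simulate_titration(tt, seed = 1)
  expect_equal(s$response,
               four_pl(s$concentration, 0.1, 0.9, 5.5e-9, 1.2))
  # asymptotes of the generating curve
  expect_equal(four_pl(1e3, 0.1, 0.9, 5.5e-9, 1.2), 0.9, tolerance = 1e-9)
  expect_equal(four_pl(1e-30, 0.1, 0.9, 5.5e-9, 1.2), 0.1, tolerance = 1e-9)
  # round trip through the fitter
  fit <- fit_4pl(s)
  expect_equal(fit$ec50, 5.5e-9, tolerance = 1e-4)
  expect_error(titration_truth(0, 1, 1e-9, 1, concentrations = numeric(0)),
               "non-empty")
})

test_that("peak-list generator round-trips perturbations and drops missing residues", {
  truth <- nmr_truth(residues = 347:360, ddH = 0.03, ddN = 0.2,
                     missing = c(350, 355))
  pl <- simulate_peaklists(truth, seed = 1)
  expect_false(any(c(350, 355) %in% pl$reference$residue))
  expect_false(any(c(350, 355) %in% pl$probe$residue))
  prof <- compute_csp(pl$reference, pl$probe)
  expect_equal(prof$csp_ppm, rep(sqrt(0.03^2 + (0.2 / 5)^2), nrow(prof)))
  expect_false(any(c(350, 355) %in% prof$residue))

  flat <- simulate_peaklists(nmr_truth(residues = 347:360), seed = 2)
  expect_equal(compute_csp(flat$reference, flat$probe)$csp_ppm,
               rep(0, 14))
  expect_error(nmr_truth(residues = c(347, 347)), "duplicate")
})

test_that("toy Langevin dynamics reproduce the Ornstein-Uhlenbeck limit", {
  # deep single well: stationary variance = kT / stiffness, k = depth/width^2
  ls <- toy_landscape(well_centers = 50, well_depths = 50, well_width = 3,
                      diffusion_coefficient = 2, thermal_energy = 0.5)
  traj <- simulate_toy_dynamics(ls, x0 = 50, n_steps = 100000, dt = 0.002,
                                seed = 5)
  burnin <- traj$position[-(1:5000)]
  expect_lt(abs(var(burnin) - 0.5 / (50 / 9)) / (0.5 / (50 / 9)), 0.10)

  # zero thermal energy: deterministic descent into the nearest well
  ls0 <- toy_landscape(well_centers = c(40, 60), thermal_energy = 0)
  down <- simulate_toy_dynamics(ls0, x0 = 57, n_steps = 4000, dt = 0.05, seed = 1)
  expect_equal(tail(down$position, 1), 60, tolerance = 1e-3)
  expect_identical(down,
                   simulate_toy_dynamics(ls0, x0 = 57, n_steps = 4000,
                                         dt = 0.05, seed = 99))  # no RNG used
  a <- simulate_toy_dynamics(toy_landscape(), 60, 500, 0.5, seed = 8)
  b <- simulate_toy_dynamics(toy_landscape(), 60, 500, 0.5, seed = 8)
  expect_identical(a, b)
  expect_error(toy_landscape(diffusion_coefficient = 0), "positive")
})
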