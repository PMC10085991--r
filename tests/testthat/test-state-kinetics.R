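test_that("HMM recovers a noiseless alternating two-level signal exactly", {
  path <- rep(c(0.3, 0.8), length.out = 60)
  hm <- fit_hmm(list(path + rnorm(60, 0, 1e-4)), n_states = 2, seed = 1)
  expect_equal(hm$means, c(0.3, 0.8), tolerance = 1e-3)
  expect_equal(hm$idealizations[[1]], rep(c(1L, 2L), length.out = 60))
})

test_that("HMM recovers generator means and transition probabilities", {
  traces <- make_efficiency_traces(100, 300, means = c(0.40, 0.72),
                                   sds = c(0.05, 0.05), stay = 0.98, seed = 11)
  hm <- fit_hmm(traces, n_states = 2, seed = 2)
  expect_true(hm$converged)
  expect_false(hm$degenerate)
  expect_equal(hm$means, c(0.40, 0.72), tolerance = 0.01)
  # per-frame leave probability 0.02, within 20% relative
  expect_lt(abs(hm$transition[1, 2] - 0.02) / 0.02, 0.20)
  expect_lt(abs(hm$transition[2, 1] - 0.02) / 0.02, 0.20)
  # Baum-Welch log-likelihood is non-decreasing
  expect_true(all(diff(hm$loglik_trace) > -1e-6 * abs(hm$loglik)))
})

test_that("single-state data forced to two states is flagged degenerate", {
  set.seed(3)
  traces <- lapply(1:20, function(i) rnorm(200, 0.55, 0.05))
  hm <- fit_hmm(traces, n_states = 2, seed = 4)
  expect_true(hm$degenerate)
  expect_lt(abs(diff(hm$means)), 1.5 * (hm$sds[1] + hm$sds[2]))
})

test_that("dwell extraction censors boundary runs and enumerates correctly", {
  # H,H,H,L,L,H,H at 0.1 s/frame: one uncensored dwell (L, 0.2 s)
  dw <- extract_dwells(list(c(2L, 2L, 2L, 1L, 1L, 2L, 2L)), frame_time = 0.1)
  u <- dw[!dw$censored, ]
  expect_equal(nrow(u), 1L)
  expect_equal(u$state, 1L)
  expect_equal(u$duration, 0.2)
  expect_equal(sum(dw$censored), 2L)

  # constant path: zero uncensored dwells
  dwc <- extract_dwells(list(rep(1L, 50)), frame_time = 0.1)
  expect_equal(nrow(dwc[!dwc$censored, ]), 0L)

  # geometric dwells with mean 20 frames at 0.1 s -> mean 2.0 s
  set.seed(5)
  paths <- lapply(1:200, function(i) {
    runs <- pmax(1, rgeom(60, prob = 0.05) + 1)
    rep(rep(c(1L, 2L), 30), times = runs)[1:600]
  })
  dwg <- extract_dwells(paths, frame_time = 0.1)
  m <- mean_dwell(dwg)
  n_u <- sum(!dwg$censored)
  expect_gt(n_u, 4000)
  expect_lt(abs(m[["state1"]] - 2.0), 3 * 2.0 / sqrt(n_u / 2))
  expect_error(extract_dwells(list(integer(0))), "empty")
})

test_that("double-Gaussian fit recovers mixture weights and honors a fixed center", {
  set.seed(6)
  e <- c(rnorm(3e4, 0.40, 0.05), rnorm(7e4, 0.72, 0.068))
  h <- build_histogram(pmin(1, pmax(0, e)))
  f <- fit_double_gaussian(h)
  expect_true(f$converged)
  expect_equal(f$weights, c(0.3, 0.7), tolerance = 0.03)
  expect_equal(f$centers, c(0.40, 0.72), tolerance = 0.01)
  expect_equal(sum(f$weights), 1)
  # FWHM/sigma relation holds exactly for every component
  expect_equal(f$fwhm / f$sigmas, rep(2 * sqrt(2 * log(2)), 2))

  ffix <- fit_double_gaussian(h, fix_low_center = 0.38)
  expect_identical(ffix$centers[1], 0.38)

  # occupancies invariant to uniform scaling of the frame count
  h_half <- build_histogram(pmin(1, pmax(0, e[seq(1, 1e5, by = 2)])))
  f_half <- fit_double_gaussian(h_half)
  expect_equal(f_half$weights, f$weights, tolerance = 0.02)

  # single-component data: second component is marginal and flagged
  set.seed(7)
  h1 <- build_histogram(pmin(1, pmax(0, rnorm(5e4, 0.55, 0.05))))
  f1 <- fit_double_gaussian(h1)
  expect_true(f1$degenerate)
})

test_that("occupancy curves sum to one and track a simulated titration", {
  set.seed(8)
  occ_true <- c(0.05, 0.3, 0.6, 0.9)
  hists <- lapply(occ_true, function(p) {
    n <- 3e4
    k <- rbinom(1, n, p)
    build_histogram(pmin(1, pmax(0, c(rnorm(k, 0.40, 0.05),
                                      rnorm(n - k, 0.72, 0.05)))))
  })
  oc <- occupancy_curve(hists, conditions = 1:4)
  expect_equal(oc$occupancy_low + oc$occupancy_high, rep(1, 4))
  expect_equal(oc$occupancy_low, occ_true, tolerance = 0.05)
  expect_true(all(diff(oc$occupancy_low) > 0))   # monotone recovery

  # all mass in the low component
  h_low <- build_histogram(pmin(1, pmax(0, rnorm(2e4, 0.40, 0.05))))
  oc1 <- occupancy_curve(list(h_low))
  expect_gt(oc1$occupancy_low, 0.9)
})
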