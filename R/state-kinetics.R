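#' Fit a Gaussian-emission hidden Markov model to FRET traces
#'
#' Baum-Welch maximum-likelihood fit of an `n_states`-state HMM with
#' Gaussian emissions on the per-frame efficiency, followed by Viterbi
#' idealization of every trace. Initialization is k-means on the pooled
#' efficiencies; several seeded restarts are run and the best likelihood is
#' kept. States are returned ordered by increasing emission mean, so for two
#' states state 1 is the low-FRET and state 2 the high-FRET state.
#'
#' @param fret_traces list of numeric efficiency vectors (or of
#'   `ctdyn_fret_trace` objects; invalid frames are dropped).
#' @param n_states number of states (>= 2 for a meaningful fit).
#' @param seed integer seed controlling the restarts.
#' @param n_restarts number of jittered restarts (default 5).
#' @param max_iter Baum-Welch iteration cap (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @return object of class `ctdyn_hmm`: emission `means`, `sds`,
#'   `transition` matrix (row-stochastic, per frame), `initial`
#'   distribution, `loglik`, `loglik_trace`, `converged`, `degenerate`
#'   (TRUE when two state means are closer than 1.5 times the sum of their
#'   emission sds, i.e. the states are not resolvable),
#'   and `idealizations`, a list of per-trace Viterbi paths (state indices).
#' @export
fit_hmm <- function(fret_traces, n_states = 2, seed = 1L, n_restarts = 5,
                    max_iter = 500, tol = 1e-6) {
  obs <- lapply(fret_traces, function(x) {
    if (inherits(x, "ctdyn_fret_trace")) x <- x$efficiency[x$valid]
    as.numeric(x[is.finite(x)])
  })
  obs <- obs[vapply(obs, length, 1L) > 0L]
  assert_that(length(obs) >= 1, "need at least one usable trace")
  assert_that(n_states >= 2, "n_states must be >= 2")
  pooled <- unlist(obs, use.names = FALSE)
  assert_that(length(pooled) > n_states, "fewer frames than states")

  best <- NULL
  with_seed(seed, {
    km <- suppressWarnings(stats::kmeans(pooled, centers = n_states, nstart = 3))
    base_means <- sort(km$centers[, 1])
    for (r in seq_len(n_restarts)) {
      means0 <- if (r == 1) base_means else
        sort(base_means + stats::rnorm(n_states, 0, 0.05))
      fit <- baum_welch(obs, means0, n_states, max_iter, tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })

  ord <- order(best$means)
  means <- best$means[ord]; sds <- best$sds[ord]
  trans <- best$trans[ord, ord, drop = FALSE]
  init <- best$init[ord]
  relabel <- match(seq_len(n_states), ord)
  ideal <- lapply(obs, function(x)
    as.integer(relabel[hmm_viterbi(x, best$means, best$sds, best$trans, best$init)]))
  degenerate <- FALSE
  if (n_states >= 2) {
    # resolvability: peaks closer than ~3 pooled sds cannot be told apart
    # on these emissions and likely reflect one split population
    dm <- abs(outer(means, means, "-"))
    thr <- 1.5 * outer(sds, sds, "+")
    degenerate <- any(dm[upper.tri(dm)] < thr[upper.tri(thr)])
  }
  if (!best$converged)
    warning("Baum-Welch did not converge within max_iter iterations")
  structure(list(means = means, sds = sds, transition = trans,
                 initial = init, loglik = best$loglik,
                 loglik_trace = best$loglik_trace,
                 converged = best$converged, degenerate = degenerate,
                 n_states = n_states, idealizations = ideal),
            class = "ctdyn_hmm")
}

baum_welch <- function(obs, means, n_states, max_iter, tol) {
  sds <- rep(max(stats::sd(unlist(obs, use.names = FALSE)) / 2, 1e-3), n_states)
  trans <- matrix(0.1 / (n_states - 1), n_states, n_states)
  diag(trans) <- 0.9
  init <- rep(1 / n_states, n_states)
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g_sum <- numeric(n_states)        # sum of posteriors
    gx_sum <- numeric(n_states)       # posterior-weighted obs
    gxx_sum <- numeric(n_states)      # posterior-weighted obs^2
    xi_sum <- matrix(0, n_states, n_states)
    init_sum <- numeric(n_states)
    for (x in obs) {
      fb <- hmm_forward_backward(x, means, sds, trans, init)
      ll <- ll + fb$loglik
      g <- fb$gamma
      g_sum <- g_sum + colSums(g)
      gx_sum <- gx_sum + colSums(g * x)
      gxx_sum <- gxx_sum + colSums(g * x^2)
      xi_sum <- xi_sum + fb$xi
      init_sum <- init_sum + g[1, ]
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    means <- gx_sum / pmax(g_sum, 1e-12)
    sds <- sqrt(pmax(gxx_sum / pmax(g_sum, 1e-12) - means^2, 1e-8))
    rs <- rowSums(xi_sum)
    for (i in seq_len(n_states))
      trans[i, ] <- if (rs[i] > 0) xi_sum[i, ] / rs[i] else 1 / n_states
    init <- init_sum / sum(init_sum)
  }
  list(means = means, sds = sds, trans = trans, init = init,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged)
}

#' Extract state dwell times from idealized traces
#'
#' Maximal constant runs of each idealized state path become dwells of
#' `run length * frame_time` seconds. The first and last dwell of every
#' trace are truncated by the observation window and flagged censored;
#' summary statistics should use uncensored dwells only (see
#' [mean_dwell()]).
#'
#' @param idealizations a `ctdyn_hmm` object or a list of integer state
#'   paths.
#' @param frame_time frame time in seconds.
#' @return data frame of class `ctdyn_dwells` with columns `trace`, `state`,
#'   `duration` (s), `censored`.
#' @export
extract_dwells <- function(idealizations, frame_time = 0.1) {
  if (inherits(idealizations, "ctdyn_hmm"))
    idealizations <- idealizations$idealizations
  assert_that(is.list(idealizations) && length(idealizations) >= 1,
              "idealizations must be a non-empty list of state paths")
  assert_that(frame_time > 0, "frame_time must be positive")
  rows <- lapply(seq_along(idealizations), function(i) {
    path <- idealizations[[i]]
    assert_that(length(path) >= 1, "empty state path")
    r <- rle(as.integer(path))
    k <- length(r$lengths)
    data.frame(trace = i, state = r$values,
               duration = r$lengths * frame_time,
               censored = seq_len(k) %in% c(1L, k))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ctdyn_dwells", class(out))
  out
}

#' Mean dwell time per state over uncensored dwells
#'
#' @param dwells a [extract_dwells()] result.
#' @return named numeric vector of mean dwell times (s) per state; states
#'   with no uncensored dwell are `NaN`.
#' @export
mean_dwell <- function(dwells) {
  u <- dwells[!dwells$censored, , drop = FALSE]
  states <- sort(unique(dwells$state))
  out <- vapply(states, function(s) mean(u$duration[u$state == s]), 1.0)
  stats::setNames(out, paste0("state", states))
}

#' Fit Gaussian components to a FRET histogram
#'
#' Weighted nonlinear least squares of one or two Gaussian peaks on the bin
#' centers of a normalized 0.01-bin histogram. Weights are
#' `1 / max(height, 1/N)` (Poisson-motivated; stabilizes empty bins).
#' Occupancies are area fractions of the components, the probability masses
#' of the underlying populations. `fwhm = 2 sqrt(2 ln 2) sigma` per
#' component.
#'
#' @param hist a [build_histogram()] result (or data frame with `bin_lo`,
#'   `bin_hi`, `height`).
#' @param n_components 1 or 2.
#' @param fix_low_center optional value at which the low component's center
#'   is held exactly (two-component fits only), e.g. 0.38 for low-Gs
#'   conditions.
#' @return object of class `ctdyn_gaussfit`: `centers`, `sigmas`,
#'   `amplitudes`, `weights` (area fractions, sum 1), `occupancies` (alias
#'   of weights), `fwhm`, `converged`, `degenerate` (TRUE when a component
#'   carries < 5% of the area or the centers are unresolvable).
#' @export
fit_gaussian_peaks <- function(hist, n_components = 2, fix_low_center = NULL) {
  assert_that(all(c("bin_lo", "bin_hi", "height") %in% names(hist)),
              "hist needs bin_lo, bin_hi, height columns")
  assert_that(n_components %in% c(1, 2), "n_components must be 1 or 2")
  x <- (hist$bin_lo + hist$bin_hi) / 2
  y <- hist$height
  assert_that(sum(y) > 0, "histogram is empty")
  n_frames <- attr(hist, "n_frames") %||% 1e4
  w <- 1 / pmax(y, 1 / n_frames)

  gauss <- function(x, a, c, s) a * exp(-(x - c)^2 / (2 * s^2))
  mu0 <- sum(x * y) / sum(y)
  s0 <- sqrt(max(sum(y * (x - mu0)^2) / sum(y), 1e-6))

  fit <- NULL
  if (n_components == 1) {
    st <- list(a1 = max(y), c1 = mu0, s1 = s0)
    fit <- try(minpack.lm::nlsLM(
      y ~ gauss(x, a1, c1, s1), start = st, weights = w,
      lower = c(0, 0, 1e-4), upper = c(Inf, 1, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(gaussfit_failure(n_components))
    p <- coef(fit)
    centers <- p[["c1"]]; sigmas <- p[["s1"]]; amps <- p[["a1"]]
  } else {
    # split the histogram mass at its weighted median for starting values
    lowhalf <- x <= mu0
    c1_0 <- if (any(y[lowhalf] > 0)) sum((x * y)[lowhalf]) / sum(y[lowhalf]) else mu0 - s0
    c2_0 <- if (any(y[!lowhalf] > 0)) sum((x * y)[!lowhalf]) / sum(y[!lowhalf]) else mu0 + s0
    if (!is.null(fix_low_center)) {
      st <- list(a1 = max(y) / 2, s1 = s0 / 2,
                 a2 = max(y) / 2, c2 = max(c2_0, fix_low_center + 0.05),
                 s2 = s0 / 2)
      fit <- try(minpack.lm::nlsLM(
        y ~ gauss(x, a1, fix_low_center, s1) + gauss(x, a2, c2, s2),
        start = st, weights = w,
        lower = c(0, 1e-4, 0, 0, 1e-4), upper = c(Inf, 1, Inf, 1, 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fit, "try-error")) return(gaussfit_failure(n_components))
      p <- coef(fit)
      centers <- c(fix_low_center, p[["c2"]])
      sigmas <- c(p[["s1"]], p[["s2"]])
      amps <- c(p[["a1"]], p[["a2"]])
    } else {
      st <- list(a1 = max(y) / 2, c1 = c1_0, s1 = s0 / 2,
                 a2 = max(y) / 2, c2 = c2_0, s2 = s0 / 2)
      fit <- try(minpack.lm::nlsLM(
        y ~ gauss(x, a1, c1, s1) + gauss(x, a2, c2, s2),
        start = st, weights = w,
        lower = c(0, 0, 1e-4, 0, 0, 1e-4), upper = c(Inf, 1, 1, Inf, 1, 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fit, "try-error")) return(gaussfit_failure(n_components))
      p <- coef(fit)
      centers <- c(p[["c1"]], p[["c2"]])
      sigmas <- c(p[["s1"]], p[["s2"]])
      amps <- c(p[["a1"]], p[["a2"]])
    }
    if (centers[1] > centers[2]) {   # low component first
      ordc <- c(2, 1)
      centers <- centers[ordc]; sigmas <- sigmas[ordc]; amps <- amps[ordc]
    }
  }
  areas <- amps * sigmas               # proportional to component mass
  weights_frac <- if (sum(areas) > 0) areas / sum(areas) else rep(1 / length(areas), length(areas))
  degenerate <- length(centers) == 2 &&
    (min(weights_frac) < 0.05 ||
       abs(diff(centers)) < (sigmas[1] + sigmas[2]) / 2)
  structure(list(centers = unname(centers), sigmas = unname(sigmas),
                 amplitudes = unname(amps), weights = unname(weights_frac),
                 occupancies = unname(weights_frac),
                 fwhm = unname(2 * sqrt(2 * log(2)) * sigmas),
                 converged = TRUE, degenerate = degenerate),
            class = "ctdyn_gaussfit")
}

gaussfit_failure <- function(n_components) {
  structure(list(centers = rep(NA_real_, n_components),
                 sigmas = rep(NA_real_, n_components),
                 amplitudes = rep(NA_real_, n_components),
                 weights = rep(NA_real_, n_components),
                 occupancies = rep(NA_real_, n_components),
                 fwhm = rep(NA_real_, n_components),
                 converged = FALSE, degenerate = NA),
            class = "ctdyn_gaussfit")
}

#' @rdname fit_gaussian_peaks
#' @param hist a FRET histogram.
#' @export
fit_single_gaussian <- function(hist) fit_gaussian_peaks(hist, n_components = 1)

#' @rdname fit_gaussian_peaks
#' @export
fit_double_gaussian <- function(hist, fix_low_center = NULL)
  fit_gaussian_peaks(hist, n_components = 2, fix_low_center = fix_low_center)

#' Low/high-FRET occupancy across experimental conditions
#'
#' Fits the double-Gaussian model to one histogram per condition and
#' tabulates the low- and high-FRET occupancies (area fractions), ready for
#' concentration-response fitting with [fit_4pl()].
#'
#' @param histograms named list of FRET histograms, one per condition.
#' @param conditions optional numeric condition values (e.g. concentrations
#'   in mol/L); defaults to the list names.
#' @param fix_low_center passed to [fit_double_gaussian()].
#' @param low_max efficiency below which a fitted component counts as
#'   low-FRET (default 0.55, midway between the canonical displaced-CT
#'   ~0.4 and engaged-CT ~0.7 peaks). When both components land on the
#'   same side — e.g. a one-population histogram that the two-component
#'   model splits arbitrarily — their whole mass is assigned to that side.
#' @return data frame with columns `condition`, `occupancy_low`,
#'   `occupancy_high`, `center_low`, `center_high`, `converged`.
#' @export
occupancy_curve <- function(histograms, conditions = NULL,
                            fix_low_center = NULL, low_max = 0.55) {
  assert_that(length(histograms) >= 1, "need at least one histogram")
  conditions <- conditions %||% names(histograms) %||% seq_along(histograms)
  rows <- lapply(seq_along(histograms), function(i) {
    f <- fit_double_gaussian(histograms[[i]], fix_low_center = fix_low_center)
    is_low <- f$centers <= low_max
    data.frame(condition = conditions[[i]],
               occupancy_low = sum(f$occupancies[is_low]),
               occupancy_high = sum(f$occupancies[!is_low]),
               center_low = f$centers[1], center_high = f$centers[2],
               converged = f$converged)
  })
  do.call(rbind, rows)
}
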