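#' Fit a four-parameter logistic concentration-response curve
#'
#' Nonlinear least squares of
#' `R(c) = bottom + (top - bottom) / (1 + 10^(hill (log10 EC50 - log10 c)))`
#' on the log10-concentration axis (bounded Levenberg-Marquardt).
#' Replicates are fitted jointly (pooled), preserving the error structure.
#' Initialization takes bottom/top from the extreme-concentration means and
#' EC50 from the half-maximal crossing. `pEC50 = -log10(EC50 in mol/L)`.
#'
#' @param concentration concentrations in mol/L (positive; >= 4 distinct
#'   values), or a data frame with `concentration` and `response` columns.
#' @param response responses (occupancy, normalized luminescence, ...).
#' @param hill_bounds bounds for the free Hill slope (default `c(0.3, 5)`).
#' @param fixed_hill optional fixed Hill slope (e.g. 1).
#' @return object of class `ctdyn_4pl`: `bottom`, `top`, `ec50` (mol/L),
#'   `hill`, `pec50`, `se` (named parameter standard errors), `converged`,
#'   `fitted`, `residuals`.
#' @export
fit_4pl <- function(concentration, response = NULL,
                    hill_bounds = c(0.3, 5), fixed_hill = NULL) {
  if (is.data.frame(concentration)) {
    response <- concentration$response
    concentration <- concentration$concentration
  }
  assert_that(length(concentration) == length(response),
              "concentration and response must have equal length")
  keep <- is.finite(concentration) & is.finite(response)
  concentration <- concentration[keep]; response <- response[keep]
  assert_that(all(concentration > 0), "concentrations must be positive")
  assert_that(length(unique(concentration)) >= 4,
              "need at least 4 distinct concentrations")
  if (stats::var(response) < 1e-12 * (abs(mean(response)) + 1)^2)
    stop("flat response: no concentration-dependent signal to fit")

  lc <- log10(concentration)
  agg <- tapply(response, lc, mean)
  lc_u <- as.numeric(names(agg))
  bot0 <- unname(agg[which.min(lc_u)])
  top0 <- unname(agg[which.max(lc_u)])
  half <- (bot0 + top0) / 2
  cross <- which.min(abs(agg - half))
  lec0 <- lc_u[cross]

  span <- abs(top0 - bot0)
  env <- new.env(parent = environment())
  model <- if (is.null(fixed_hill)) {
    y ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - x)))
  } else {
    assign("fixed_hill", fixed_hill, envir = env)
    y ~ bottom + (top - bottom) / (1 + 10^(fixed_hill * (lec50 - x)))
  }
  environment(model) <- env
  dat <- data.frame(x = lc, y = response)
  st <- list(bottom = bot0, top = top0, lec50 = lec0)
  lower <- c(bottom = min(response) - 2 * span, top = min(response) - 2 * span,
             lec50 = min(lc) - 3)
  upper <- c(bottom = max(response) + 2 * span, top = max(response) + 2 * span,
             lec50 = max(lc) + 3)
  if (is.null(fixed_hill)) {
    st$hill <- 1
    lower <- c(lower, hill = hill_bounds[1])
    upper <- c(upper, hill = hill_bounds[2])
  }
  fit <- try(minpack.lm::nlsLM(model, data = dat, start = st,
                               lower = lower, upper = upper,
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("4PL fit did not converge: ", attr(fit, "condition")$message)
  p <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(p)))
  names(se) <- names(p)
  hill <- if (is.null(fixed_hill)) unname(p[["hill"]]) else fixed_hill
  ec50 <- 10^unname(p[["lec50"]])
  structure(list(bottom = unname(p[["bottom"]]), top = unname(p[["top"]]),
                 ec50 = ec50, hill = hill, pec50 = -log10(ec50),
                 se = se, converged = TRUE,
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit)),
            class = "ctdyn_4pl")
}

#' @export
print.ctdyn_4pl <- function(x, ...) {
  cat("4PL fit: bottom =", signif(x$bottom, 3),
      " top =", signif(x$top, 3),
      " EC50 =", signif(x$ec50, 3), "M",
      " (pEC50 =", signif(x$pec50, 4), ")",
      " hill =", signif(x$hill, 3), "\n")
  invisible(x)
}

#' Fold-change normalization of a luminescence time course
#'
#' Averages the counts in the response window (e.g. 3-5 min after ligand
#' addition) and divides by the average over the baseline window before
#' addition. With vehicle normalization applied to a vehicle well the result
#' is 1 by construction.
#'
#' @param time time points.
#' @param signal luminescence counts, same length as `time`.
#' @param baseline_window,response_window `c(from, to)` intervals
#'   (inclusive) on the `time` axis; both must contain data.
#' @param vehicle optional vehicle fold-change to divide by.
#' @return the fold-change (unitless scalar).
#' @export
normalize_foldchange <- function(time, signal, baseline_window,
                                 response_window, vehicle = NULL) {
  assert_that(length(time) == length(signal), "time/signal length mismatch")
  in_win <- function(w) time >= w[1] & time <= w[2]
  b <- signal[in_win(baseline_window)]
  r <- signal[in_win(response_window)]
  assert_that(length(b) > 0, "baseline window contains no points")
  assert_that(length(r) > 0, "response window contains no points")
  mb <- mean(b)
  if (abs(mb) < .Machine$double.eps)
    stop("baseline mean is zero; cannot normalize")
  fc <- mean(r) / mb
  if (!is.null(vehicle)) {
    if (abs(vehicle) < .Machine$double.eps)
      stop("vehicle fold-change is zero; cannot normalize")
    fc <- fc / vehicle
  }
  fc
}

#' Expression-normalized response slope
#'
#' Least-squares slope of response versus surface expression over wells in
#' the linear regime (the expression-normalized cAMP level), optionally as a
#' percentage of a reference (wild-type) slope.
#'
#' @param expression,response paired measurements (>= 2 points).
#' @param reference_slope optional wild-type slope for `percent_wt`.
#' @return list with `slope`, `intercept` and (when a reference is given)
#'   `percent_wt = 100 * slope / reference_slope`.
#' @export
expression_slope <- function(expression, response, reference_slope = NULL) {
  assert_that(length(expression) == length(response),
              "expression and response must be paired")
  assert_that(length(expression) >= 2, "need at least 2 points")
  fit <- stats::lm(response ~ expression)
  slope <- unname(coef(fit)[2])
  out <- list(slope = slope, intercept = unname(coef(fit)[1]))
  if (!is.null(reference_slope)) {
    assert_that(abs(reference_slope) > .Machine$double.eps,
                "reference slope is zero")
    out$percent_wt <- 100 * slope / reference_slope
  }
  out
}

#' Compare two 4PL fits
#'
#' `delta_pec50 = pEC50(test) - pEC50(reference)` (positive = leftward
#' shift, higher potency) and `relative_emax = span(test) / span(reference)`
#' where span = top - bottom.
#'
#' @param test,reference [fit_4pl()] results.
#' @return list with `delta_pec50` and `relative_emax`.
#' @export
compare_fits <- function(test, reference) {
  assert_that(inherits(test, "ctdyn_4pl") && inherits(reference, "ctdyn_4pl"),
              "both arguments must be ctdyn_4pl fits")
  ref_span <- reference$top - reference$bottom
  if (abs(ref_span) < 1e-12)
    stop("reference span is ~0; relative Emax undefined")
  list(delta_pec50 = test$pec50 - reference$pec50,
       relative_emax = (test$top - test$bottom) / ref_span)
}
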