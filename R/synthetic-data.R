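#' Two-state exchange kinetics
#'
#' Discrete-time two-state kinetics for a molecule switching between a
#' high-FRET (CT engaged with the receptor core) and a low-FRET (CT
#' displaced) state. Rates are continuous-time rate constants; the trace
#' generator converts them to per-frame switching probabilities
#' `k * frame_time`, so simulated dwell lengths are geometric with mean
#' `1 / (k * frame_time)` frames.
#'
#' @param k_high_to_low,k_low_to_high exit rates (s^-1), strictly positive.
#' @param p_high0 probability that a trace starts in the high-FRET state.
#' @return an object of class `ctdyn_kinetics`.
#' @export
two_state_kinetics <- function(k_high_to_low, k_low_to_high, p_high0 = 0.5) {
  assert_that(is.numeric(k_high_to_low) && length(k_high_to_low) == 1L &&
                is.finite(k_high_to_low) && k_high_to_low > 0,
              "k_high_to_low must be a single positive finite rate")
  assert_that(is.numeric(k_low_to_high) && length(k_low_to_high) == 1L &&
                is.finite(k_low_to_high) && k_low_to_high > 0,
              "k_low_to_high must be a single positive finite rate")
  assert_that(is.numeric(p_high0) && p_high0 >= 0 && p_high0 <= 1,
              "p_high0 must lie in [0, 1]")
  structure(list(k_high_to_low = k_high_to_low,
                 k_low_to_high = k_low_to_high,
                 p_high0 = p_high0),
            class = "ctdyn_kinetics")
}

#' Per-state emission model for TIRF intensity traces
#'
#' Each state emits a fixed mean total intensity split between the donor and
#' acceptor channels according to its mean FRET efficiency
#' `mean_acceptor / (mean_donor + mean_acceptor)`. Two noise sources are
#' available: `efficiency_sd` jitters the per-frame donor/acceptor partition
#' (so the per-frame apparent FRET efficiency has exactly that standard
#' deviation, before clamping), and `channel_noise_sd` adds Gaussian read
#' noise to each channel independently. Donor photobleaching is an absorbing
#' event with exponential waiting time; after it both channels emit
#' background only.
#'
#' @param mean_donor,mean_acceptor per-state mean counts/frame (vectors,
#'   one entry per state; state order must match the kinetics object:
#'   state 1 = high FRET, state 2 = low FRET for two-state kinetics).
#' @param efficiency_sd per-frame sd of the apparent FRET efficiency.
#' @param channel_noise_sd additive Gaussian noise sd per channel
#'   (counts/frame).
#' @param photobleach_rate donor bleach rate (s^-1); 0 disables bleaching.
#' @param background mean background counts/frame added to each channel.
#' @return an object of class `ctdyn_emission`.
#' @export
emission_model <- function(mean_donor, mean_acceptor,
                           efficiency_sd = 0, channel_noise_sd = 0,
                           photobleach_rate = 0, background = 0) {
  assert_that(length(mean_donor) == length(mean_acceptor) &&
                length(mean_donor) >= 1L,
              "mean_donor and mean_acceptor must have one entry per state")
  assert_that(all(mean_donor >= 0) && all(mean_acceptor >= 0),
              "channel means must be nonnegative")
  assert_that(all(mean_donor + mean_acceptor > 0),
              "per-state total intensity must be positive")
  assert_that(efficiency_sd >= 0 && channel_noise_sd >= 0,
              "noise standard deviations must be nonnegative")
  assert_that(photobleach_rate >= 0, "photobleach_rate must be nonnegative")
  assert_that(background >= 0, "background must be nonnegative")
  structure(list(mean_donor = as.numeric(mean_donor),
                 mean_acceptor = as.numeric(mean_acceptor),
                 efficiency_sd = efficiency_sd,
                 channel_noise_sd = channel_noise_sd,
                 photobleach_rate = photobleach_rate,
                 background = background),
            class = "ctdyn_emission")
}

#' Simulate two-channel smFRET intensity traces
#'
#' Generates TIRF-style donor/acceptor traces at a fixed frame time
#' (default 100 ms) from two-state Markov switching plus the emission model,
#' and returns the true state path and bleach frame per trace for oracle
#' testing. Identical `(kinetics, emission, seed, ...)` give bit-identical
#' output.
#'
#' @param kinetics a [two_state_kinetics()] object.
#' @param emission an [emission_model()] object with per-state means.
#' @param n_traces number of traces (>= 1).
#' @param duration trace duration in seconds (>= frame_time).
#' @param frame_time frame integration time in seconds (default 0.1).
#' @param seed integer RNG seed.
#' @return a list of class `ctdyn_traces` with elements `traces` (data frame
#'   with columns trace_id, frame, donor, acceptor), `truth` (list with
#'   per-trace integer state paths, 1 = high FRET, 2 = low FRET, and
#'   `bleach_frame`, the first bleached frame or NA), and `frame_time`.
#' @export
simulate_traces <- function(kinetics, emission, n_traces, duration,
                            frame_time = 0.1, seed = 1L) {
  assert_that(inherits(kinetics, "ctdyn_kinetics"), "kinetics must be a ctdyn_kinetics")
  assert_that(inherits(emission, "ctdyn_emission"), "emission must be a ctdyn_emission")
  assert_that(n_traces >= 1, "n_traces must be >= 1")
  assert_that(is.numeric(duration) && duration > 0, "duration must be positive")
  assert_that(is.numeric(frame_time) && frame_time > 0, "frame_time must be positive")
  assert_that(duration >= frame_time, "duration must be >= frame_time")
  n_states <- length(emission$mean_donor)
  assert_that(n_states >= 1, "emission model needs at least one state")

  p_hl <- kinetics$k_high_to_low * frame_time
  p_lh <- kinetics$k_low_to_high * frame_time
  assert_that(p_hl <= 1 && p_lh <= 1,
              "rate * frame_time exceeds 1; reduce frame_time")
  n_frames <- floor(duration / frame_time)
  total <- emission$mean_donor + emission$mean_acceptor
  e_state <- emission$mean_acceptor / total

  with_seed(seed, {
    states <- vector("list", n_traces)
    bleach_frame <- rep(NA_real_, n_traces)
    rows <- vector("list", n_traces)
    for (i in seq_len(n_traces)) {
      if (n_states >= 2) {
        s <- integer(n_frames)
        s[1L] <- if (stats::runif(1L) < kinetics$p_high0) 1L else 2L
        if (n_frames > 1L) {
          u <- stats::runif(n_frames - 1L)
          for (t in 2L:n_frames) {
            p_sw <- if (s[t - 1L] == 1L) p_hl else p_lh
            s[t] <- if (u[t - 1L] < p_sw) 3L - s[t - 1L] else s[t - 1L]
          }
        }
      } else {
        s <- rep(1L, n_frames)
      }
      # donor bleach: exponential waiting time, absorbing
      bleached <- rep(FALSE, n_frames)
      if (emission$photobleach_rate > 0) {
        t_bleach <- stats::rexp(1L, rate = emission$photobleach_rate)
        fb <- floor(t_bleach / frame_time) + 1
        if (fb <= n_frames) {
          bleached[fb:n_frames] <- TRUE
          bleach_frame[i] <- fb
        }
      }
      e_frame <- e_state[s]
      if (emission$efficiency_sd > 0)
        e_frame <- pmin(1, pmax(0, e_frame +
                                  stats::rnorm(n_frames, 0, emission$efficiency_sd)))
      acceptor <- e_frame * total[s]
      donor <- total[s] - acceptor
      donor[bleached] <- 0
      acceptor[bleached] <- 0
      donor <- donor + emission$background
      acceptor <- acceptor + emission$background
      if (emission$channel_noise_sd > 0) {
        donor <- donor + stats::rnorm(n_frames, 0, emission$channel_noise_sd)
        acceptor <- acceptor + stats::rnorm(n_frames, 0, emission$channel_noise_sd)
      }
      states[[i]] <- s
      rows[[i]] <- data.frame(trace_id = i, frame = seq_len(n_frames),
                              donor = donor, acceptor = acceptor)
    }
    structure(list(traces = do.call(rbind, rows),
                   truth = list(state = states, bleach_frame = bleach_frame),
                   frame_time = frame_time),
              class = "ctdyn_traces")
  })
}

#' Confocal burst model
#'
#' Photon bursts from freely diffusing molecules: burst durations are
#' exponential with a configurable mean, photon counts per channel are
#' Poisson with the per-state rate times the burst duration, and background
#' photons accrue at the channel background rate. Bins of `bin_time`
#' (default 1000 microseconds) set the time base of the recorded stream.
#'
#' @param photon_rate_donor,photon_rate_acceptor signal photon rates
#'   (counts/s) while a molecule transits the confocal spot.
#' @param background_rate_donor,background_rate_acceptor background rates
#'   (counts/s) per detection channel.
#' @param mean_burst_duration mean transit time (s).
#' @param bin_time recording bin (s), default 1e-3.
#' @return an object of class `ctdyn_burst_model`.
#' @export
burst_model <- function(photon_rate_donor, photon_rate_acceptor,
                        background_rate_donor = 0, background_rate_acceptor = 0,
                        mean_burst_duration = 5e-3, bin_time = 1e-3) {
  rates <- c(photon_rate_donor, photon_rate_acceptor,
             background_rate_donor, background_rate_acceptor)
  assert_that(all(rates >= 0), "photon rates must be nonnegative")
  assert_that(mean_burst_duration > 0, "mean_burst_duration must be positive")
  assert_that(bin_time > 0, "bin_time must be positive")
  structure(list(photon_rate_donor = photon_rate_donor,
                 photon_rate_acceptor = photon_rate_acceptor,
                 background_rate_donor = background_rate_donor,
                 background_rate_acceptor = background_rate_acceptor,
                 mean_burst_duration = mean_burst_duration,
                 bin_time = bin_time),
            class = "ctdyn_burst_model")
}

#' Simulate photon bursts
#'
#' @param model a [burst_model()].
#' @param n_bursts number of bursts (>= 1).
#' @param seed integer RNG seed.
#' @return a list of class `ctdyn_bursts`: `bursts`, a data frame with
#'   integer photon counts (`f_donor`, `f_acceptor` include background
#'   photons), the burst `duration` (s, rounded up to whole bins) and the
#'   expected background counts per channel; `truth$efficiency`, the
#'   background-free efficiency implied by the signal rates.
#' @export
simulate_bursts <- function(model, n_bursts, seed = 1L) {
  assert_that(inherits(model, "ctdyn_burst_model"), "model must be a ctdyn_burst_model")
  assert_that(n_bursts >= 1, "n_bursts must be >= 1")
  with_seed(seed, {
    dur <- stats::rexp(n_bursts, rate = 1 / model$mean_burst_duration)
    dur <- pmax(model$bin_time, ceiling(dur / model$bin_time) * model$bin_time)
    sig_d <- stats::rpois(n_bursts, model$photon_rate_donor * dur)
    sig_a <- stats::rpois(n_bursts, model$photon_rate_acceptor * dur)
    bg_d <- stats::rpois(n_bursts, model$background_rate_donor * dur)
    bg_a <- stats::rpois(n_bursts, model$background_rate_acceptor * dur)
    rate_tot <- model$photon_rate_donor + model$photon_rate_acceptor
    eff <- if (rate_tot > 0) model$photon_rate_acceptor / rate_tot else NA_real_
    structure(list(
      bursts = data.frame(burst_id = seq_len(n_bursts),
                          f_donor = sig_d + bg_d,
                          f_acceptor = sig_a + bg_a,
                          duration = dur,
                          background_donor = model$background_rate_donor * dur,
                          background_acceptor = model$background_rate_acceptor * dur),
      truth = list(efficiency = rep(eff, n_bursts))),
      class = "ctdyn_bursts")
  })
}

#' Four-parameter logistic response
#'
#' `bottom + (top - bottom) / (1 + (ec50 / conc)^hill)`, the standard 4PL
#' concentration-response curve.
#'
#' @param conc concentrations (mol/L), positive.
#' @param bottom,top lower/upper asymptotes (response units).
#' @param ec50 half-maximal concentration (mol/L).
#' @param hill Hill slope (unitless).
#' @return responses, same length as `conc`.
#' @export
four_pl <- function(conc, bottom, top, ec50, hill = 1) {
  assert_that(all(conc > 0), "concentrations must be positive")
  assert_that(ec50 > 0, "ec50 must be positive")
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Ground truth for a simulated titration
#'
#' @param bottom,top,ec50,hill generating 4PL parameters (`ec50` in mol/L).
#' @param concentrations positive, sorted concentrations (mol/L).
#' @param replicates replicate count per concentration (>= 1).
#' @param noise_sd Gaussian response noise sd.
#' @return an object of class `ctdyn_titration_truth`.
#' @export
titration_truth <- function(bottom, top, ec50, hill = 1,
                            concentrations, replicates = 3, noise_sd = 0) {
  assert_that(length(concentrations) >= 1, "concentration list must be non-empty")
  assert_that(all(concentrations > 0), "concentrations must be positive")
  assert_that(!is.unsorted(concentrations), "concentrations must be sorted")
  assert_that(ec50 > 0, "ec50 must be positive")
  assert_that(replicates >= 1, "replicates must be >= 1")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill,
                 concentrations = as.numeric(concentrations),
                 replicates = as.integer(replicates), noise_sd = noise_sd),
            class = "ctdyn_titration_truth")
}

#' Simulate a concentration-response series
#'
#' @param truth a [titration_truth()].
#' @param seed integer RNG seed.
#' @return data frame with columns `concentration` (mol/L), `replicate`,
#'   `response` = 4PL(truth) + Gaussian noise.
#' @export
simulate_titration <- function(truth, seed = 1L) {
  assert_that(inherits(truth, "ctdyn_titration_truth"),
              "truth must be a ctdyn_titration_truth")
  with_seed(seed, {
    conc <- rep(truth$concentrations, each = truth$replicates)
    repl <- rep(seq_len(truth$replicates), times = length(truth$concentrations))
    mu <- four_pl(conc, truth$bottom, truth$top, truth$ec50, truth$hill)
    resp <- mu + if (truth$noise_sd > 0)
      stats::rnorm(length(mu), 0, truth$noise_sd) else 0
    data.frame(concentration = conc, replicate = repl, response = resp)
  })
}

#' Ground truth for simulated NMR peak lists
#'
#' Per-residue reference amide shifts over the CT construct (residues
#' 347-413 by default), plus the perturbation and intensity scaling applied
#' in the probe condition. Missing residues (prolines, unassigned) are
#' absent from both generated lists.
#'
#' @param residues integer residue numbers, unique.
#' @param dH,dN reference amide shifts (ppm), one per residue.
#' @param intensity reference peak intensities, positive.
#' @param ddH,ddN perturbations added in the probe condition (ppm).
#' @param intensity_scale per-residue probe/reference intensity ratio.
#' @param missing residues to drop from both lists.
#' @return an object of class `ctdyn_nmr_truth`.
#' @export
nmr_truth <- function(residues = 347:413, dH = NULL, dN = NULL,
                      intensity = NULL, ddH = 0, ddN = 0,
                      intensity_scale = 1, missing = integer(0)) {
  residues <- as.integer(residues)
  assert_that(!anyDuplicated(residues), "duplicate residues in ground truth")
  n <- length(residues)
  dH <- rep_len(dH %||% 8.3, n)
  dN <- rep_len(dN %||% 120, n)
  intensity <- rep_len(intensity %||% 1, n)
  assert_that(all(intensity > 0), "intensities must be positive")
  structure(list(residues = residues, dH = dH, dN = dN,
                 intensity = intensity,
                 ddH = rep_len(ddH, n), ddN = rep_len(ddN, n),
                 intensity_scale = rep_len(intensity_scale, n),
                 missing = as.integer(missing)),
            class = "ctdyn_nmr_truth")
}

#' Simulate a reference/probe peak-list pair
#'
#' @param truth an [nmr_truth()].
#' @param shift_noise_sd Gaussian noise (ppm) added independently to each
#'   shift in each list (0 = exact round trip).
#' @param intensity_noise_cv coefficient of variation of multiplicative
#'   intensity noise.
#' @param seed integer RNG seed.
#' @return list with elements `reference` and `probe`, each a data frame
#'   with columns `residue`, `dH_ppm`, `dN_ppm`, `intensity`.
#' @export
simulate_peaklists <- function(truth, shift_noise_sd = 0,
                               intensity_noise_cv = 0, seed = 1L) {
  assert_that(inherits(truth, "ctdyn_nmr_truth"), "truth must be a ctdyn_nmr_truth")
  keep <- !(truth$residues %in% truth$missing)
  assert_that(any(keep), "all residues flagged missing")
  with_seed(seed, {
    mk <- function(dH, dN, intensity) {
      n <- sum(keep)
      if (shift_noise_sd > 0) {
        dH <- dH + stats::rnorm(n, 0, shift_noise_sd)
        dN <- dN + stats::rnorm(n, 0, shift_noise_sd)
      }
      if (intensity_noise_cv > 0)
        intensity <- intensity * pmax(1e-6, 1 + stats::rnorm(n, 0, intensity_noise_cv))
      data.frame(residue = truth$residues[keep], dH_ppm = dH, dN_ppm = dN,
                 intensity = intensity)
    }
    list(reference = mk(truth$dH[keep], truth$dN[keep], truth$intensity[keep]),
         probe = mk(truth$dH[keep] + truth$ddH[keep],
                    truth$dN[keep] + truth$ddN[keep],
                    truth$intensity[keep] * truth$intensity_scale[keep]))
  })
}

#' Toy free-energy landscape on the label-label distance axis
#'
#' A low-dimensional stand-in for CT dynamics: the observable is the
#' Cys148-Cys378 label distance D (Angstrom), moving on a potential built
#' from Gaussian wells, `U(x) = -sum_j depth_j exp(-(x - c_j)^2 / (2 w^2))`,
#' with harmonic walls outside `bounds` keeping D in the physically sensible
#' 30-70 Angstrom window. The default is a double well with minima near
#' 40 and 60 Angstrom.
#'
#' @param well_centers well positions (Angstrom).
#' @param well_depths well depths (units of `thermal_energy` when kT = 1).
#' @param well_width Gaussian well width (Angstrom).
#' @param diffusion_coefficient D (Angstrom^2/ns), positive.
#' @param thermal_energy kT in the same energy units as the depths; 0 gives
#'   deterministic gradient descent (mobility then equals the diffusion
#'   coefficient numerically).
#' @param bounds soft walls (harmonic, stiffness `wall_stiffness`) outside
#'   this interval.
#' @param wall_stiffness energy/Angstrom^2.
#' @return an object of class `ctdyn_landscape`.
#' @export
toy_landscape <- function(well_centers = c(40, 60), well_depths = c(3, 3),
                          well_width = 4, diffusion_coefficient = 2,
                          thermal_energy = 1, bounds = c(25, 75),
                          wall_stiffness = 1) {
  assert_that(length(well_centers) >= 1, "need at least one well")
  assert_that(length(well_depths) == length(well_centers),
              "one depth per well center")
  assert_that(diffusion_coefficient > 0, "diffusion coefficient must be positive")
  assert_that(thermal_energy >= 0, "thermal_energy must be nonnegative")
  assert_that(well_width > 0, "well_width must be positive")
  structure(list(well_centers = as.numeric(well_centers),
                 well_depths = as.numeric(well_depths),
                 well_width = well_width,
                 diffusion_coefficient = diffusion_coefficient,
                 thermal_energy = thermal_energy,
                 bounds = bounds, wall_stiffness = wall_stiffness),
            class = "ctdyn_landscape")
}

landscape_force <- function(ls, x) {
  # -dU/dx for the Gaussian wells plus wall restraints
  f <- 0
  for (j in seq_along(ls$well_centers)) {
    dxj <- x - ls$well_centers[j]
    # U_j = -d exp(-dx^2/(2w^2)); -dU/dx = -d * dx/w^2 * exp(...)
    f <- f - ls$well_depths[j] * dxj / ls$well_width^2 *
      exp(-dxj^2 / (2 * ls$well_width^2))
  }
  if (x < ls$bounds[1]) f <- f - ls$wall_stiffness * (x - ls$bounds[1])
  if (x > ls$bounds[2]) f <- f - ls$wall_stiffness * (x - ls$bounds[2])
  f
}

#' Simulate overdamped Langevin dynamics on a toy landscape
#'
#' Euler-Maruyama integration of
#' `dx = (D / kT) F(x) dt + sqrt(2 D dt) xi`, with `F = -dU/dx`. Frames are
#' emitted every `stride` steps; the scalar position doubles as the D
#' observable and the conformation descriptor.
#'
#' @param landscape a [toy_landscape()].
#' @param x0 starting position (Angstrom).
#' @param n_steps integration steps (>= 1).
#' @param dt time step (ns), positive.
#' @param seed integer RNG seed.
#' @param stride emit every `stride`-th step (default 1).
#' @return data frame of class `ctdyn_trajectory` with columns `frame`,
#'   `time` (ns), `position`, `D`, `descriptor`.
#' @export
simulate_toy_dynamics <- function(landscape, x0, n_steps, dt, seed = 1L,
                                  stride = 1L) {
  assert_that(inherits(landscape, "ctdyn_landscape"),
              "landscape must be a ctdyn_landscape")
  assert_that(n_steps >= 1, "n_steps must be >= 1")
  assert_that(dt > 0, "dt must be positive")
  assert_that(landscape$diffusion_coefficient > 0,
              "diffusion coefficient must be positive")
  kT <- landscape$thermal_energy
  mobility <- if (kT > 0) landscape$diffusion_coefficient / kT
              else landscape$diffusion_coefficient
  noise_amp <- if (kT > 0) sqrt(2 * landscape$diffusion_coefficient * dt) else 0
  with_seed(seed, {
    xs <- langevin_path(x0, as.integer(n_steps), dt, mobility, noise_amp,
                        landscape$well_centers, landscape$well_depths,
                        landscape$well_width, landscape$bounds,
                        landscape$wall_stiffness)
    idx <- seq(1L, n_steps, by = as.integer(stride))
    out <- data.frame(frame = seq_along(idx), time = idx * dt,
                      position = xs[idx + 1L])
    out$D <- out$position
    out$descriptor <- out$position
    class(out) <- c("ctdyn_trajectory", class(out))
    out
  })
}
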