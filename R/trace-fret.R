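#' Per-frame FRET efficiency from a two-channel intensity trace
#'
#' `E_t = acceptor_t / (acceptor_t + donor_t)`, clamped to `[0, 1]`.
#' Frames whose total intensity is not positive carry no signal and are
#' flagged invalid (`NA` efficiency) rather than divided.
#'
#' @param donor,acceptor per-frame counts (equal length >= 1), or `donor`
#'   may be a data frame with `donor`/`acceptor` columns.
#' @param frame_time frame time in seconds.
#' @return an object of class `ctdyn_fret_trace`: list with `efficiency`
#'   (per-frame, `NA` where invalid), `valid` (logical), `usable_length`
#'   (number of valid frames) and `frame_time`.
#' @export
compute_fret <- function(donor, acceptor = NULL, frame_time = 0.1) {
  if (is.data.frame(donor)) {
    acceptor <- donor$acceptor
    donor <- donor$donor
  }
  assert_that(length(donor) == length(acceptor) && length(donor) >= 1,
              "donor and acceptor must have equal length >= 1")
  assert_that(frame_time > 0, "frame_time must be positive")
  total <- donor + acceptor
  valid <- is.finite(total) & total > 0
  eff <- rep(NA_real_, length(total))
  eff[valid] <- pmin(1, pmax(0, acceptor[valid] / total[valid]))
  if (!any(valid))
    warning("no frame has positive total intensity; empty result")
  structure(list(efficiency = eff, valid = valid,
                 usable_length = sum(valid), frame_time = frame_time),
            class = "ctdyn_fret_trace")
}

#' Detect donor photobleaching as a change point in total intensity
#'
#' Searches all single change points of the total (donor + acceptor)
#' intensity by least squares and reports a bleach when the post-drop
#' segment mean falls persistently below `(1 - min_drop_frac)` of the
#' pre-drop mean for at least `min_persist` frames. Bleaching is an optional
#' outcome: a constant trace returns no bleach and full usable length.
#'
#' @param donor,acceptor per-frame counts, or `donor` a data frame with both
#'   columns. At least 4 frames.
#' @param min_drop_frac minimum fractional drop of the post segment mean
#'   relative to the pre segment mean (default 0.5).
#' @param min_persist minimum post-drop length in frames (default 5).
#' @param min_intensity optional floor: if the pre-drop mean itself is below
#'   this value the whole trace is considered bleached (`usable_length` 0).
#' @return list with `bleach_frame` (first bleached frame, 1-based, or `NA`)
#'   and `usable_length` (frames before the bleach).
#' @export
detect_photobleach <- function(donor, acceptor = NULL, min_drop_frac = 0.5,
                               min_persist = 5, min_intensity = NULL) {
  if (is.data.frame(donor)) {
    acceptor <- donor$acceptor
    donor <- donor$donor
  }
  total <- donor + acceptor
  n <- length(total)
  assert_that(n >= 4, "trace must have at least 4 frames")
  # least-squares single change point: minimize within-segment SSE
  cs <- cumsum(total)
  cs2 <- cumsum(total^2)
  ks <- seq_len(n - 1L)                      # last pre-drop frame
  pre_m <- cs[ks] / ks
  post_m <- (cs[n] - cs[ks]) / (n - ks)
  sse <- (cs2[ks] - cs[ks]^2 / ks) +
    ((cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / (n - ks))
  best <- which.min(sse)
  if (!is.null(min_intensity) && pre_m[best] < min_intensity)
    return(list(bleach_frame = 1L, usable_length = 0L))
  is_bleach <- (n - best) >= min_persist &&
    post_m[best] <= (1 - min_drop_frac) * pre_m[best]
  if (is_bleach)
    list(bleach_frame = best + 1L, usable_length = best)
  else
    list(bleach_frame = NA_integer_, usable_length = n)
}

#' Build a normalized 0.01-bin FRET histogram
#'
#' Pools per-frame efficiencies into 100 fixed bins on `[0, 1]` at width
#' 0.01 (bins half-open `[lo, hi)`, last bin closed) and normalizes heights
#' by the total number of usable frames so they sum to 1.
#'
#' @param fret either a numeric vector of efficiencies, a
#'   `ctdyn_fret_trace`, or a list of either.
#' @return data frame of class `ctdyn_fret_histogram` with columns
#'   `bin_lo`, `bin_hi`, `height`; attribute `n_frames` holds the frame
#'   count.
#' @export
build_histogram <- function(fret) {
  eff <- pool_efficiencies(fret)
  eff <- eff[is.finite(eff)]
  assert_that(length(eff) >= 1, "no usable frames to histogram")
  assert_that(all(eff >= 0 & eff <= 1), "efficiencies must lie in [0, 1]")
  edges <- seq(0, 1, by = 0.01)
  idx <- pmin(floor(eff / 0.01) + 1L, 100L)   # final bin closed at 1
  counts <- tabulate(idx, nbins = 100L)
  out <- data.frame(bin_lo = edges[-101], bin_hi = edges[-1],
                    height = counts / length(eff))
  attr(out, "n_frames") <- length(eff)
  class(out) <- c("ctdyn_fret_histogram", class(out))
  out
}

pool_efficiencies <- function(fret) {
  if (inherits(fret, "ctdyn_fret_trace")) return(fret$efficiency[fret$valid])
  if (is.numeric(fret)) return(fret)
  if (is.list(fret)) return(unlist(lapply(fret, pool_efficiencies), use.names = FALSE))
  stop_invalid("cannot extract efficiencies from object of class ",
               paste(class(fret), collapse = "/"))
}

#' Per-burst apparent FRET efficiencies with photon-count filtering
#'
#' Bursts whose raw photon total `f_donor + f_acceptor` is below the
#' threshold (default 40 photons) are excluded. For the rest the apparent
#' efficiency is computed on background-corrected counts,
#' `(f_A - b_A) / ((f_A - b_A) + (f_D - b_D))`. A negative corrected count
#' in one channel clamps the efficiency to the nearest boundary; bursts with
#' both corrected channels <= 0 are discarded.
#'
#' @param bursts data frame with columns `f_donor`, `f_acceptor` and
#'   optionally `background_donor`, `background_acceptor` (default 0), or a
#'   `ctdyn_bursts` object.
#' @param threshold minimum raw photon total for inclusion (default 40).
#' @return the input data frame with added columns `efficiency` and
#'   `included`.
#' @export
burst_efficiencies <- function(bursts, threshold = 40) {
  if (inherits(bursts, "ctdyn_bursts")) bursts <- bursts$bursts
  assert_that(all(c("f_donor", "f_acceptor") %in% names(bursts)),
              "bursts needs f_donor and f_acceptor columns")
  assert_that(all(bursts$f_donor >= 0) && all(bursts$f_acceptor >= 0),
              "raw photon counts must be nonnegative")
  bd <- bursts$background_donor %||% 0
  ba <- bursts$background_acceptor %||% 0
  cd <- bursts$f_donor - bd
  ca <- bursts$f_acceptor - ba
  included <- (bursts$f_donor + bursts$f_acceptor) >= threshold
  eff <- rep(NA_real_, nrow(bursts))
  ok <- ca > 0 | cd > 0
  eff[ok] <- ca[ok] / (ca[ok] + cd[ok])
  eff <- pmin(1, pmax(0, eff))
  included <- included & ok
  bursts$efficiency <- eff
  bursts$included <- included
  bursts
}
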