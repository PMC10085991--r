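#' Parameters of the explore/exploit seeding heuristic
#'
#' Frames are scored as
#' `P(frame) ~ W1 (1 - |D_target - D(frame)|) + W2 / P_obs`, where the D
#' observable is min-max rescaled to `[0, 1]` over the scoring pool before
#' the exploit term (keeping the two components commensurate) and `P_obs`
#' is the fraction of pool frames falling in the frame's descriptor bin.
#' Equal weights balance exploitation (closeness to the target distance,
#' e.g. the 44 Angstrom label-label distance of the high-FRET state) and
#' exploration (rarity of the conformation).
#'
#' @param w1,w2 exploit/explore weights, nonnegative, not both zero.
#' @param d_target target D value (Angstrom), finite.
#' @param descriptor_bin_width bin width for the conformation descriptor
#'   (default 2, in descriptor units).
#' @param n_seeds_per_epoch seeds drawn per epoch (>= 1).
#' @param d_bounds optional fixed `c(min, max)` for the D rescaling;
#'   `NULL` (default) uses the pooled range, refreshed at every scoring
#'   call.
#' @return an object of class `ctdyn_seeding_params`.
#' @export
seeding_params <- function(w1 = 1, w2 = 1, d_target = 44,
                           descriptor_bin_width = 2,
                           n_seeds_per_epoch = 10, d_bounds = NULL) {
  assert_that(w1 >= 0 && w2 >= 0, "weights must be nonnegative")
  assert_that(w1 + w2 > 0, "w1 and w2 must not both be zero")
  assert_that(is.finite(d_target), "d_target must be finite")
  assert_that(descriptor_bin_width > 0, "descriptor_bin_width must be positive")
  assert_that(n_seeds_per_epoch >= 1, "n_seeds_per_epoch must be >= 1")
  structure(list(w1 = w1, w2 = w2, d_target = d_target,
                 descriptor_bin_width = descriptor_bin_width,
                 n_seeds_per_epoch = as.integer(n_seeds_per_epoch),
                 d_bounds = d_bounds),
            class = "ctdyn_seeding_params")
}

#' Score frames for adaptive seeding
#'
#' @param frames data frame with a `D` column and optionally a `descriptor`
#'   column (defaults to `D`); one row per observed frame (>= 1).
#' @param params a [seeding_params()] object.
#' @return numeric probability per frame: nonnegative, sums to 1.
#' @export
score_frames <- function(frames, params) {
  assert_that(inherits(params, "ctdyn_seeding_params"),
              "params must be ctdyn_seeding_params")
  assert_that(is.data.frame(frames) && nrow(frames) >= 1 && "D" %in% names(frames),
              "frames must be a non-empty data frame with a D column")
  D <- frames$D
  assert_that(all(is.finite(D)), "D values must be finite")
  desc <- frames$descriptor %||% D
  n <- length(D)

  bounds <- params$d_bounds %||% range(D)
  span <- bounds[2] - bounds[1]
  if (span > 0) {
    dn <- pmin(1, pmax(0, (D - bounds[1]) / span))
    tn <- pmin(1, pmax(0, (params$d_target - bounds[1]) / span))
    exploit <- 1 - abs(tn - dn)
  } else {
    exploit <- rep(1, n)      # degenerate pool: all frames equally fit
  }

  bin <- floor(desc / params$descriptor_bin_width)
  counts <- table(bin)
  p_obs <- as.numeric(counts[match(as.character(bin), names(counts))]) / n
  explore <- 1 / p_obs        # p_obs >= 1/n, so always finite

  raw <- pmax(0, params$w1 * exploit + params$w2 * explore)
  tot <- sum(raw)
  if (tot <= 0) {
    warning("all scores zero after clipping; falling back to uniform")
    return(rep(1 / n, n))
  }
  raw / tot
}

#' Draw seed frames proportionally to their score
#'
#' Sampling without replacement, probability proportional to score;
#' reproducible from the seed.
#'
#' @param probabilities frame probabilities (nonnegative, positive sum).
#' @param n_seeds number of frames to draw.
#' @param seed integer RNG seed.
#' @return integer frame indices, length `n_seeds`.
#' @export
select_seeds <- function(probabilities, n_seeds, seed = 1L) {
  assert_that(all(probabilities >= 0) && sum(probabilities) > 0,
              "probabilities must be nonnegative with positive sum")
  assert_that(n_seeds >= 1, "n_seeds must be >= 1")
  assert_that(sum(probabilities > 0) >= n_seeds,
              "n_seeds exceeds the number of frames with nonzero probability")
  with_seed(seed,
            sample.int(length(probabilities), size = n_seeds,
                       replace = FALSE, prob = probabilities))
}

#' Build a trajectory engine from a toy landscape
#'
#' Wraps [simulate_toy_dynamics()] as the pluggable engine interface used by
#' [run_campaign()]: a function `(x0, seed) -> data.frame(position, D,
#' descriptor)`.
#'
#' @param landscape a [toy_landscape()].
#' @param n_steps,dt,stride forwarded to [simulate_toy_dynamics()].
#' @return an engine closure.
#' @export
toy_engine <- function(landscape, n_steps = 400, dt = 0.5, stride = 4) {
  force(landscape); force(n_steps); force(dt); force(stride)
  function(x0, seed) {
    simulate_toy_dynamics(landscape, x0 = x0, n_steps = n_steps, dt = dt,
                          seed = seed, stride = stride)
  }
}

#' Run an explore/exploit adaptive-sampling campaign
#'
#' Epoch 1 launches every trajectory from the initial conformation `x0`;
#' each later epoch scores the accumulated frame pool with [score_frames()],
#' draws `trajs_per_epoch` seed frames with [select_seeds()] and restarts
#' the engine from the seed positions. The default budget mirrors a
#' five-epoch, ten-trajectory campaign.
#'
#' @param engine function `(x0, seed) -> data.frame` with columns
#'   `position`, `D` and optionally `descriptor` (see [toy_engine()]).
#' @param params a [seeding_params()].
#' @param epochs,trajs_per_epoch campaign dimensions (default 5 and 10).
#' @param x0 initial conformation (start position).
#' @param seed integer RNG seed for the whole campaign.
#' @param enrich_window half-width (same units as D) of the window around
#'   `d_target` used for the enrichment summary (default 5).
#' @return object of class `ctdyn_campaign`: `frames` (epoch, traj, frame,
#'   position, D, descriptor), `seeds` (per-epoch data frame of selected
#'   seed frames; epoch 1 seeds are the initial conformation),
#'   `probabilities` (per-epoch score tables), and `enrichment`, the
#'   fraction of all frames with `|D - d_target| <= enrich_window`.
#' @export
run_campaign <- function(engine, params, epochs = 5, trajs_per_epoch = 10,
                         x0, seed = 1L, enrich_window = 5) {
  assert_that(is.function(engine), "engine must be a function(x0, seed)")
  assert_that(inherits(params, "ctdyn_seeding_params"),
              "params must be ctdyn_seeding_params")
  assert_that(epochs >= 1 && trajs_per_epoch >= 1,
              "epochs and trajs_per_epoch must be >= 1")
  seed <- as.numeric(seed)      # derived sub-seeds must not overflow ints
  pool <- NULL
  seeds <- vector("list", epochs)
  probs <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    if (ep == 1L) {
      starts <- rep(x0, trajs_per_epoch)
      seeds[[ep]] <- data.frame(epoch = 1L, start = starts)
    } else {
      p <- score_frames(pool, params)
      probs[[ep]] <- p
      idx <- select_seeds(p, n_seeds = trajs_per_epoch,
                          seed = seed * 1000L + ep)
      starts <- pool$position[idx]
      seeds[[ep]] <- cbind(pool[idx, c("epoch", "traj", "frame", "position", "D")],
                           data.frame(start = starts))
    }
    for (tr in seq_len(trajs_per_epoch)) {
      traj <- engine(starts[tr], seed = seed * 100000L + ep * 100L + tr)
      assert_that(is.data.frame(traj) && nrow(traj) >= 1 &&
                    all(c("position", "D") %in% names(traj)),
                  "engine must return frames with position and D columns")
      if (is.null(traj$descriptor)) traj$descriptor <- traj$D
      block <- data.frame(epoch = ep, traj = (ep - 1L) * trajs_per_epoch + tr,
                          frame = seq_len(nrow(traj)),
                          position = traj$position, D = traj$D,
                          descriptor = traj$descriptor)
      pool <- rbind(pool, block)
    }
  }
  enrichment <- mean(abs(pool$D - params$d_target) <= enrich_window)
  structure(list(frames = pool, seeds = seeds, probabilities = probs,
                 enrichment = enrichment, params = params),
            class = "ctdyn_campaign")
}

#' Minimum distance between two point sets, per frame
#'
#' @param a,b 3-column coordinate matrices (one frame), or lists of such
#'   matrices (one per frame).
#' @return the minimum pairwise Euclidean distance (scalar, or vector per
#'   frame for list input).
#' @export
min_pair_distance <- function(a, b) {
  if (is.list(a) && !is.matrix(a)) {
    assert_that(is.list(b) && length(a) == length(b),
                "frame lists must have equal length")
    return(vapply(seq_along(a), function(i) min_pair_distance(a[[i]], b[[i]]), 1.0))
  }
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(nrow(a) >= 1 && nrow(b) >= 1, "point sets must be non-empty")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Root-mean-square deviation of coordinates from a reference
#'
#' Plain positional RMSD (no superposition): for pre-aligned or
#' internal-coordinate data, `sqrt(mean(|x_i - ref_i|^2))` over atoms.
#'
#' @param coords 3-column coordinate matrix, or list of matrices (a
#'   trajectory).
#' @param reference `"start"` (first frame), `"mean"` (coordinate-wise
#'   trajectory average) or an explicit matrix.
#' @return scalar RMSD, or a per-frame vector for trajectory input.
#' @export
rmsd <- function(coords, reference = "start") {
  if (is.list(coords) && !is.matrix(coords)) {
    ref <- if (is.character(reference) && reference == "start") coords[[1]]
    else if (is.character(reference) && reference == "mean")
      Reduce(`+`, coords) / length(coords)
    else as.matrix(reference)
    return(vapply(coords, function(fr) rmsd(fr, ref), 1.0))
  }
  coords <- as.matrix(coords); reference <- as.matrix(reference)
  assert_that(all(dim(coords) == dim(reference)),
              "coordinates and reference must have matching dimensions")
  sqrt(mean(rowSums((coords - reference)^2)))
}

#' Centered running average
#'
#' Moving average with a centered window (shrunk near the edges), as used
#' to smooth trajectory time traces (e.g. a 50 ns window on distance or
#' RMSD series). A constant series is returned unchanged.
#'
#' @param x numeric series.
#' @param window window length in samples (>= 1).
#' @return smoothed series, same length as `x`.
#' @export
running_average <- function(x, window) {
  assert_that(window >= 1, "window must be >= 1")
  n <- length(x)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, 1.0)
}

#' Per-frame geometric descriptors of a trajectory
#'
#' Convenience wrapper computing, for a trajectory of coordinate frames:
#' the minimum distance between two labelled atom groups (the smFRET
#' label-site proxy), the backbone RMSD versus the starting frame and
#' versus the trajectory average, and running-averaged versions of each.
#'
#' @param traj list of 3-column coordinate matrices, one per frame.
#' @param site_a,site_b row indices of the two labelled atom groups.
#' @param window smoothing window in frames (default 1 = no smoothing).
#' @return data frame with columns `frame`, `min_distance`, `rmsd_vs_start`,
#'   `rmsd_vs_mean` and their `*_smooth` counterparts.
#' @export
trajectory_descriptors <- function(traj, site_a, site_b, window = 1) {
  assert_that(is.list(traj) && length(traj) >= 1, "traj must be a non-empty list")
  assert_that(length(site_a) >= 1 && length(site_b) >= 1,
              "labelled atom groups must be non-empty")
  a <- lapply(traj, function(fr) as.matrix(fr)[site_a, , drop = FALSE])
  b <- lapply(traj, function(fr) as.matrix(fr)[site_b, , drop = FALSE])
  md <- min_pair_distance(a, b)
  r_start <- rmsd(traj, "start")
  r_mean <- rmsd(traj, "mean")
  data.frame(frame = seq_along(traj),
             min_distance = md,
             rmsd_vs_start = r_start,
             rmsd_vs_mean = r_mean,
             min_distance_smooth = running_average(md, window),
             rmsd_vs_start_smooth = running_average(r_start, window),
             rmsd_vs_mean_smooth = running_average(r_mean, window))
}

#' Residue-residue contact frequency
#'
#' Fraction of frames in which the minimum distance between two residues'
#' atoms is within the cutoff (default 3.5 Angstrom).
#'
#' @param distances per-frame minimum inter-residue distances, or a pair of
#'   frame lists as accepted by [min_pair_distance()] via `b`.
#' @param b optional second frame list (then `distances` is the first).
#' @param cutoff contact cutoff (Angstrom), positive.
#' @return contact frequency in `[0, 1]`.
#' @export
contact_frequency <- function(distances, b = NULL, cutoff = 3.5) {
  assert_that(cutoff > 0, "cutoff must be positive")
  if (!is.null(b)) distances <- min_pair_distance(distances, b)
  assert_that(length(distances) >= 1, "no frames to analyze")
  mean(distances <= cutoff)
}
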