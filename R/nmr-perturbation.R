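#' Per-residue chemical shift perturbation (CSP)
#'
#' Weighted average amide perturbation between two assigned peak lists,
#' `delta_av = sqrt(ddH^2 + (ddN/5)^2)` per shared residue (nitrogen shifts
#' scaled by 1/5). Peaks are matched by residue number; residues present in
#' only one list are reported with `missing = TRUE` and `NA` CSP, never
#' imputed as zero. The measure is symmetric in its arguments and invariant
#' to a referencing offset applied to both lists.
#'
#' @param reference,probe data frames with columns `residue`, `dH_ppm`,
#'   `dN_ppm` (an `intensity` column is allowed and ignored here).
#' @return data frame of class `ctdyn_csp`: `residue`, `csp_ppm`, `missing`.
#' @export
compute_csp <- function(reference, probe) {
  check_peaklist(reference); check_peaklist(probe)
  shared <- intersect(reference$residue, probe$residue)
  if (length(shared) == 0)
    stop("peak lists share no residues")
  all_res <- sort(union(reference$residue, probe$residue))
  i_ref <- match(all_res, reference$residue)
  i_prb <- match(all_res, probe$residue)
  ddH <- probe$dH_ppm[i_prb] - reference$dH_ppm[i_ref]
  ddN <- probe$dN_ppm[i_prb] - reference$dN_ppm[i_ref]
  csp <- sqrt(ddH^2 + (ddN / 5)^2)
  out <- data.frame(residue = all_res, csp_ppm = csp,
                    missing = !(all_res %in% shared))
  class(out) <- c("ctdyn_csp", class(out))
  out
}

check_peaklist <- function(pl) {
  assert_that(is.data.frame(pl) &&
                all(c("residue", "dH_ppm", "dN_ppm") %in% names(pl)),
              "peak list needs residue, dH_ppm, dN_ppm columns")
  assert_that(!anyDuplicated(pl$residue), "duplicate residues in peak list")
}

#' Per-residue peak intensity ratios with replicate errors
#'
#' Ratio of probe to reference peak intensity per residue (e.g. the
#' receptor-Gs over receptor ratio). With several probe replicates the
#' default (`mode = "paired"`) computes one ratio per replicate and reports
#' the replicate mean and s.e.m.; `mode = "merged"` averages the replicate
#' intensities first and reports a single ratio. Residues with zero or
#' absent reference intensity are flagged, not divided.
#'
#' @param reference peak list with an `intensity` column.
#' @param probe a probe peak list or a list of replicate probe lists.
#' @param mode `"paired"` (ratio per replicate, then mean +/- s.e.m.) or
#'   `"merged"` (average intensities, then one ratio).
#' @return data frame: `residue`, `ratio` (mean over replicates),
#'   `ratio_sem` (`NA` for a single replicate), `missing`.
#' @export
intensity_ratio <- function(reference, probe, mode = c("paired", "merged")) {
  mode <- match.arg(mode)
  if (is.data.frame(probe)) probe <- list(probe)
  assert_that(length(probe) >= 1, "need at least one probe replicate")
  assert_that("intensity" %in% names(reference),
              "reference peak list needs an intensity column")
  for (p in probe)
    assert_that("intensity" %in% names(p),
                "probe peak lists need an intensity column")
  all_res <- sort(Reduce(union, c(list(reference$residue),
                                  lapply(probe, `[[`, "residue"))))
  i_ref <- match(all_res, reference$residue)
  ref_int <- reference$intensity[i_ref]
  ref_ok <- !is.na(ref_int) & ref_int > 0

  per_rep <- vapply(probe, function(p) {
    p$intensity[match(all_res, p$residue)]
  }, numeric(length(all_res)))
  per_rep <- matrix(per_rep, nrow = length(all_res))

  if (mode == "merged") {
    probe_int <- rowMeans(per_rep, na.rm = FALSE)
    ratio <- ifelse(ref_ok, probe_int / ref_int, NA_real_)
    sem <- rep(NA_real_, length(ratio))
  } else {
    ratios <- sweep(per_rep, 1, ref_int, "/")
    ratios[!ref_ok, ] <- NA_real_
    ratio <- rowMeans(ratios)
    sem <- if (ncol(ratios) > 1)
      apply(ratios, 1, stats::sd) / sqrt(ncol(ratios))
    else rep(NA_real_, length(ratio))
  }
  missing <- !ref_ok | apply(per_rep, 1, function(z) any(is.na(z)))
  ratio[missing] <- NA_real_
  sem[missing] <- NA_real_
  data.frame(residue = all_res, ratio = ratio, ratio_sem = sem,
             missing = missing)
}

#' Paramagnetic relaxation enhancement profile
#'
#' Per-residue `I_para / I_dia` from replicate paramagnetic and diamagnetic
#' peak lists (e.g. 3 sequential measurements each). Ratios near 1 indicate
#' residues far from the spin label; attenuation toward 0 indicates
#' proximity. Replicates are paired by position (replicate i para over
#' replicate i dia) and the profile reports mean +/- s.e.m. over pairs; with
#' unequal replicate counts the ratio of replicate means is reported
#' instead.
#'
#' @param para,dia a peak list or list of replicate peak lists with
#'   `intensity` columns.
#' @return data frame: `residue`, `ratio`, `ratio_sem`, `missing` (TRUE
#'   where the diamagnetic intensity is absent or nonpositive).
#' @export
pre_profile <- function(para, dia) {
  if (is.data.frame(para)) para <- list(para)
  if (is.data.frame(dia)) dia <- list(dia)
  assert_that(length(para) >= 1 && length(dia) >= 1,
              "need at least one replicate of each")
  all_res <- sort(Reduce(union, lapply(c(para, dia), `[[`, "residue")))
  get_mat <- function(lists) {
    m <- vapply(lists, function(p) p$intensity[match(all_res, p$residue)],
                numeric(length(all_res)))
    matrix(m, nrow = length(all_res))
  }
  pm <- get_mat(para); dm <- get_mat(dia)
  dia_ok <- apply(dm, 1, function(z) all(is.finite(z) & z > 0))
  if (ncol(pm) == ncol(dm)) {
    ratios <- pm / dm
    ratio <- rowMeans(ratios)
    sem <- if (ncol(ratios) > 1)
      apply(ratios, 1, stats::sd) / sqrt(ncol(ratios))
    else rep(NA_real_, length(ratio))
  } else {
    ratio <- rowMeans(pm) / rowMeans(dm)
    sem <- rep(NA_real_, length(ratio))
  }
  missing <- !dia_ok | apply(pm, 1, function(z) any(is.na(z)))
  ratio[missing] <- NA_real_
  sem[missing] <- NA_real_
  data.frame(residue = all_res, ratio = ratio, ratio_sem = sem,
             missing = missing)
}
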