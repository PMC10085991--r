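#' Read and write the package's TSV schemas
#'
#' Plain tab-separated interchange for every data product: intensity traces
#' (`trace_id`, `frame`, `donor`, `acceptor`), burst tables (`burst_id`,
#' `f_donor`, `f_acceptor`, `duration`, backgrounds), titrations
#' (`concentration`, `replicate`, `response`), peak lists (`residue`,
#' `dH_ppm`, `dN_ppm`, `intensity`), FRET histograms (`bin_lo`, `bin_hi`,
#' `height`) and campaign frame records (`epoch`, `traj`, `frame`,
#' `position`, `D`, `descriptor`).
#'
#' @param x a data frame (or an object carrying one, e.g. `ctdyn_traces`).
#' @param path file path.
#' @param required column names that must be present when reading.
#' @return `read_tsv_table()` returns a data frame; the writer returns
#'   `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  if (inherits(x, "ctdyn_traces")) x <- x$traces
  if (inherits(x, "ctdyn_bursts")) x <- x$bursts
  if (inherits(x, "ctdyn_campaign")) x <- x$frames
  assert_that(is.data.frame(x), "x must be (or carry) a data frame")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path, required = NULL) {
  out <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!is.null(required))
    assert_that(all(required %in% names(out)),
                paste("missing required columns:",
                      paste(setdiff(required, names(out)), collapse = ", ")))
  out
}
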