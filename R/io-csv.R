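# deterministic full-precision CSV writing: numbers are formatted with
# sprintf("%.17g") so identical inputs give byte-identical files
format_num_csv <- function(x) sprintf("%.17g", x)

write_csv_raw <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- format_num_csv(df[[j]])
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(df), sep = ",")))
  con <- suppressWarnings(try(file(path, open = "wb"), silent = TRUE))
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a spectrum from CSV files
#'
#' Two dialects are accepted:
#' \itemize{
#'   \item a pair of two-column files `ppm,real` and `ppm,imag` (the real and
#'     imaginary traces), whose ppm columns must agree row-by-row within
#'     `1e-9` ppm;
#'   \item a single three-column file `ppm,real,imag` (pass only
#'     `real_path`).
#' }
#'
#' @param real_path CSV with the real trace (or the single 3-column file).
#' @param imag_path CSV with the imaginary trace; `NULL` for the
#'   single-file dialect.
#' @return An [nmr_spectrum()] (canonicalised to ascending ppm).
#' @export
read_csv_pair <- function(real_path, imag_path = NULL) {
  read1 <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    utils::read.csv(p, header = TRUE)
  }
  re_df <- read1(real_path)
  if (is.null(imag_path)) {
    if (ncol(re_df) < 3L)
      stop("single-file CSV input must have three columns (ppm, real, ",
           "imag); ", real_path, " has ", ncol(re_df),
           ". Supply the imaginary trace: phase correction requires ",
           "complex data.")
    return(nmr_spectrum(re_df[[1L]],
                        complex(real = re_df[[2L]], imaginary = re_df[[3L]]),
                        meta = list(source = real_path)))
  }
  im_df <- read1(imag_path)
  if (ncol(re_df) < 2L || ncol(im_df) < 2L)
    stop("CSV spectrum files need two columns (ppm, intensity)")
  if (nrow(re_df) != nrow(im_df))
    stop("real and imaginary CSV files have different lengths (",
         nrow(re_df), " vs ", nrow(im_df), ")")
  dppm <- abs(re_df[[1L]] - im_df[[1L]])
  if (any(dppm > 1e-9)) {
    row <- which(dppm > 1e-9)[1L]
    stop("ppm grids of ", real_path, " and ", imag_path,
         " differ at row ", row, " (", format(re_df[[1L]][row]), " vs ",
         format(im_df[[1L]][row]), ")")
  }
  nmr_spectrum(re_df[[1L]],
               complex(real = re_df[[2L]], imaginary = im_df[[2L]]),
               meta = list(source = real_path))
}

#' Write a spectrum as a CSV pair
#'
#' Inverse of [read_csv_pair()]: two two-column files `ppm,real` and
#' `ppm,imag`, with the source axis orientation restored and full-precision
#' deterministic number formatting.
#'
#' @param spec An [nmr_spectrum()].
#' @param real_path,imag_path Output paths.
#' @return Invisibly, `c(real_path, imag_path)`.
#' @export
write_csv_pair <- function(spec, real_path, imag_path) {
  stopifnot(is_nmr_spectrum(spec))
  ppm <- spec$ppm; y <- spec$intensity
  if (spec$orientation == "descending") { ppm <- rev(ppm); y <- rev(y) }
  write_csv_raw(data.frame(ppm = ppm, real = Re(y)), real_path)
  write_csv_raw(data.frame(ppm = ppm, imag = Im(y)), imag_path)
  invisible(c(real_path, imag_path))
}

#' Write fit results to a directory
#'
#' Writes `parameters.csv` (a single row: `alpha1`, `alpha2`, `phi0_rad`,
#' `phi1_rad`, `delta_mix_ppm`, `delta_form1_ppm`, `pivot_index`,
#' `loss_type`, `loss_value`, `mode`, `converged`, `at_bound`, `normalized`)
#' and `processed_spectra.csv` (`ppm`, the phased and shifted mixture real
#' trace, the scaled form1 and form2 contributions, their sum, and the
#' residual). Both use a fixed column order and full-precision formatting, so
#' identical inputs and parameters give byte-identical files.
#'
#' @param result A `deconv_result` from [deconv_fit()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "deconv_result"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  p <- result$params
  params_path <- file.path(dir, "parameters.csv")
  write_csv_raw(data.frame(
    alpha1 = 1 - p$alpha2, alpha2 = p$alpha2,
    phi0_rad = p$phi0, phi1_rad = p$phi1,
    delta_mix_ppm = p$delta_mix, delta_form1_ppm = p$delta_form1,
    pivot_index = p$pivot_index,
    loss_type = result$loss_type, loss_value = result$loss_value,
    mode = result$mode, converged = result$converged,
    at_bound = result$at_bound, normalized = result$normalized,
    stringsAsFactors = FALSE), params_path)
  spectra_path <- file.path(dir, "processed_spectra.csv")
  write_csv_raw(data.frame(
    ppm = result$ppm, mix_processed = result$mix_processed,
    form1_scaled = result$form1_scaled, form2_scaled = result$form2_scaled,
    fitted = result$fitted, residual = result$residual), spectra_path)
  invisible(c(params_path, spectra_path))
}
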