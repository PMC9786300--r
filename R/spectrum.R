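#' Construct an NMR spectrum object
#'
#' The canonical in-memory representation of a frequency-domain NMR spectrum:
#' a strictly ascending chemical-shift axis (ppm) paired with complex
#' intensities. Spectra read from files with a descending axis (the usual NMR
#' display convention) are canonicalised to ascending order and the original
#' orientation is recorded so that writers can restore it.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#'   Descending input is reversed (together with `intensity`) and
#'   `orientation` is set to `"descending"` unless given explicitly.
#' @param intensity Complex (or numeric, taken as purely real) vector of the
#'   same length as `ppm`. All values must be finite.
#' @param orientation `"ascending"` or `"descending"`; the axis direction of
#'   the *source* data. Defaults to the direction of `ppm` as supplied.
#' @param meta Named list of free-form provenance (source file, title, ...).
#'
#' @return An object of class `nmr_spectrum`: a list with fields `ppm`
#'   (ascending), `intensity` (complex), `orientation`, `meta`.
#' @examples
#' s <- nmr_spectrum(ppm = 0:7, intensity = (1:8) + 0i)
#' s
#' @export
nmr_spectrum <- function(ppm, intensity, orientation = NULL, meta = list()) {
  ppm <- as.numeric(ppm)
  intensity <- as.complex(intensity)
  if (length(ppm) != length(intensity))
    stop("`ppm` and `intensity` must have the same length (",
         length(ppm), " vs ", length(intensity), ")")
  if (length(ppm) < 2L)
    stop("a spectrum needs at least 2 points, got ", length(ppm))
  if (anyNA(ppm) || any(!is.finite(ppm)))
    stop("`ppm` contains non-finite values")
  if (anyNA(intensity) || any(!is.finite(Re(intensity))) ||
      any(!is.finite(Im(intensity))))
    stop("`intensity` contains non-finite values")
  d <- diff(ppm)
  if (all(d > 0)) {
    src <- "ascending"
  } else if (all(d < 0)) {
    src <- "descending"
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  } else {
    stop("`ppm` must be strictly monotone")
  }
  if (is.null(orientation)) orientation <- src
  orientation <- match.arg(orientation, c("ascending", "descending"))
  structure(list(ppm = ppm, intensity = intensity,
                 orientation = orientation, meta = meta),
            class = "nmr_spectrum")
}

#' Test for the spectrum class
#' @param x Object.
#' @return `TRUE` if `x` is an `nmr_spectrum`.
#' @export
is_nmr_spectrum <- function(x) inherits(x, "nmr_spectrum")

#' @export
length.nmr_spectrum <- function(x) length(x$ppm)

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum: %d points, %.4f .. %.4f ppm (%s source)>\n",
              length(x$ppm), x$ppm[1L], x$ppm[length(x$ppm)], x$orientation))
  if (!is.null(x$meta$title)) cat("  title:", x$meta$title, "\n")
  if (!is.null(x$meta$source)) cat("  source:", x$meta$source, "\n")
  invisible(x)
}

#' @export
as.data.frame.nmr_spectrum <- function(x, ...) {
  data.frame(ppm = x$ppm, real = Re(x$intensity), imag = Im(x$intensity))
}

# internal: stop unless both spectra share a grid
check_same_grid <- function(a, b, what = "spectra") {
  if (length(a$ppm) != length(b$ppm) ||
      max(abs(a$ppm - b$ppm)) > 1e-9)
    stop(what, " are not on the same ppm grid; interpolate first ",
         "(see interpolate_to_reference)")
  invisible(TRUE)
}

# internal: grid spacing; errors when the grid is not uniform enough for
# index-based operations (synthetic generation, parameter scaling)
grid_spacing <- function(ppm, tol = 1e-6) {
  d <- diff(ppm)
  h <- stats::median(d)
  if (max(abs(d - h)) > tol * abs(h))
    stop("ppm grid is not uniform (max deviation ",
         format(max(abs(d - h))), " ppm)")
  h
}
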