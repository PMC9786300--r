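#' Phase-correction specification
#'
#' Bundles the zero-order term, the first-order (PH1) coefficient, the pivot
#' point and the spectrum length. The point-wise correction angle is
#' `phi0 + phi1 * (n - n_pivot) / N` with 1-based point indices `n`, so the
#' angle at the pivot equals `phi0` exactly and `phi1` is the total first-order
#' span across the full spectrum.
#'
#' @param phi0 Zero-order contribution at the pivot (radians).
#' @param phi1 First-order (PH1) coefficient (radians across the spectrum).
#' @param pivot_index 0-based index of the pivot point (where the first-order
#'   contribution vanishes).
#' @param n_points Number of points `N` in the spectrum.
#' @return An object of class `phase_spec`.
#' @examples
#' ps <- phase_spec(phi0 = 0.1, phi1 = 0.4, pivot_index = 1, n_points = 4)
#' phase_angles(ps)  # 0.0 0.1 0.2 0.3
#' @export
phase_spec <- function(phi0, phi1, pivot_index, n_points) {
  phi0 <- as.numeric(phi0); phi1 <- as.numeric(phi1)
  pivot_index <- as.integer(pivot_index); n_points <- as.integer(n_points)
  stopifnot(is.finite(phi0), is.finite(phi1), n_points >= 1L)
  if (pivot_index < 0L || pivot_index >= n_points)
    stop("pivot_index must be in [0, n_points): got ", pivot_index,
         " with n_points = ", n_points)
  structure(list(phi0 = phi0, phi1 = phi1, pivot_index = pivot_index,
                 n_points = n_points), class = "phase_spec")
}

#' Point-wise phase-correction angles
#'
#' Evaluates the linear phase ramp `(phi0 - phi1 * n_pivot / N) + phi1 * n / N`
#' over the 1-based point indices `n = 1..N`. Internal 0-based indices are
#' mapped as `n = index + 1`.
#'
#' @param ps A [phase_spec()].
#' @return Numeric vector of `N` angles in radians; the value at the pivot is
#'   exactly `phi0`.
#' @export
phase_angles <- function(ps) {
  stopifnot(inherits(ps, "phase_spec"))
  n <- seq_len(ps$n_points)            # 1-based, per convention
  npiv <- ps$pivot_index + 1L
  (ps$phi0 - ps$phi1 * npiv / ps$n_points) + ps$phi1 * n / ps$n_points
}

#' Apply phase correction to a complex spectrum
#'
#' Multiplies each complex intensity by `exp(1i * angle_n)`; a point-wise
#' unitary operation that preserves magnitudes and is inverted exactly by
#' negating `phi0` and `phi1` (same pivot).
#'
#' @param spec An [nmr_spectrum()].
#' @param ps A [phase_spec()] with `n_points == length(spec)`.
#' @return The phased `nmr_spectrum`.
#' @export
phase_correct <- function(spec, ps) {
  stopifnot(is_nmr_spectrum(spec), inherits(ps, "phase_spec"))
  if (ps$n_points != length(spec$ppm))
    stop("phase_spec is for N = ", ps$n_points, " points but spectrum has ",
         length(spec$ppm))
  y <- spec$intensity * exp(1i * phase_angles(ps))
  nmr_spectrum(spec$ppm, y, orientation = spec$orientation, meta = spec$meta)
}

#' Negate a phase specification
#'
#' Flips the signs of `phi0` and `phi1` (pivot unchanged), producing the exact
#' inverse correction.
#' @param ps A [phase_spec()].
#' @return A [phase_spec()].
#' @export
negate_phase <- function(ps) {
  phase_spec(-ps$phi0, -ps$phi1, ps$pivot_index, ps$n_points)
}

#' Interpolate a spectrum onto a reference ppm grid
#'
#' Real and imaginary parts are linearly interpolated onto `ref_ppm`
#' independently. Reference points outside the spectrum's range are filled
#' with the nearest edge value (constant extrapolation): real ssNMR baselines
#' are flat at the spectrum edges, and constant fill avoids fabricating slopes.
#' Deconvolution places all three spectra on the grid of the "form2" template
#' before modelling.
#'
#' @param spec An [nmr_spectrum()].
#' @param ref_ppm Strictly monotone numeric vector; the target grid (an
#'   `nmr_spectrum` is also accepted, its `ppm` is used).
#' @return An `nmr_spectrum` on `ref_ppm` (ascending).
#' @export
interpolate_to_reference <- function(spec, ref_ppm) {
  stopifnot(is_nmr_spectrum(spec))
  if (is_nmr_spectrum(ref_ppm)) ref_ppm <- ref_ppm$ppm
  ref_ppm <- as.numeric(ref_ppm)
  if (length(ref_ppm) < 2L) stop("`ref_ppm` must have at least 2 points")
  d <- diff(ref_ppm)
  if (all(d < 0)) ref_ppm <- rev(ref_ppm)
  else if (!all(d > 0)) stop("`ref_ppm` must be strictly monotone")
  lo <- spec$ppm[1L]; hi <- spec$ppm[length(spec$ppm)]
  if (ref_ppm[length(ref_ppm)] < lo || ref_ppm[1L] > hi)
    stop("no overlap between the spectrum (", format(lo), " .. ", format(hi),
         " ppm) and the reference grid")
  if (length(ref_ppm) == length(spec$ppm) &&
      max(abs(ref_ppm - spec$ppm)) == 0)
    return(spec)
  re <- stats::approx(spec$ppm, Re(spec$intensity), xout = ref_ppm,
                      rule = 2)$y
  im <- stats::approx(spec$ppm, Im(spec$intensity), xout = ref_ppm,
                      rule = 2)$y
  nmr_spectrum(ref_ppm, complex(real = re, imaginary = im),
               orientation = spec$orientation, meta = spec$meta)
}

# internal: linear-interpolation shift of a real vector on grid `ppm`;
# out[i] = y(ppm[i] - delta), edge-filled. This is the Delta() operator.
shift_real <- function(ppm, y, delta_ppm) {
  if (delta_ppm == 0) return(y)
  stats::approx(ppm, y, xout = ppm - delta_ppm, rule = 2)$y
}

#' Shift a spectrum along the chemical-shift axis
#'
#' Resamples the intensity at `ppm - delta_ppm` by linear interpolation on the
#' same output grid, so the spectrum appears moved by `+delta_ppm` along the
#' axis. Points sampled outside the original range take the nearest edge value
#' (constant fill), keeping the number of points constant — required for loss
#' values to be comparable across shift parameters during optimisation.
#'
#' @param spec An [nmr_spectrum()].
#' @param delta_ppm Horizontal offset in ppm.
#' @param max_shift Optional bound; `abs(delta_ppm)` beyond it is an error.
#' @return The shifted `nmr_spectrum` (complex: both parts shifted).
#' @export
shift_spectrum <- function(spec, delta_ppm, max_shift = NULL) {
  stopifnot(is_nmr_spectrum(spec), is.finite(delta_ppm))
  if (!is.null(max_shift) && abs(delta_ppm) > max_shift)
    stop("|delta_ppm| = ", format(abs(delta_ppm)),
         " exceeds the configured bound ", format(max_shift), " ppm")
  if (delta_ppm == 0) return(spec)
  re <- shift_real(spec$ppm, Re(spec$intensity), delta_ppm)
  im <- shift_real(spec$ppm, Im(spec$intensity), delta_ppm)
  nmr_spectrum(spec$ppm, complex(real = re, imaginary = im),
               orientation = spec$orientation, meta = spec$meta)
}

#' Automatic zero-order phase initialisation
#'
#' Grid search over zero-order angles that maximises the "positiveness" of the
#' real part: the score is `sum(Re(y')) - penalty * sum(pmax(-Re(y'), 0))`
#' with `y' = exp(1i * phi0) * y`. A pure absorption spectrum (all-positive
#' real part) scores highest at its correct phase; negative excursions are
#' penalised `penalty`-fold. Intended as a starting value for the optimiser,
#' not as a final estimate.
#'
#' @param spec An [nmr_spectrum()].
#' @param step_deg Grid resolution in degrees (default 1).
#' @param penalty Weight of the negativity penalty (default 5).
#' @return `phi0` in radians, in `[-pi, pi)`.
#' @export
auto_ph0 <- function(spec, step_deg = 1, penalty = 5) {
  stopifnot(is_nmr_spectrum(spec), step_deg > 0)
  y <- spec$intensity
  if (all(Mod(y) == 0)) {
    warning("all-zero spectrum; auto_ph0 returns 0")
    return(0)
  }
  grid <- seq(-180, 180 - step_deg, by = step_deg) * pi / 180
  score <- vapply(grid, function(phi) {
    re <- Re(y * exp(1i * phi))
    sum(re) - penalty * sum(pmax(-re, 0))
  }, numeric(1))
  grid[which.max(score)]
}
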