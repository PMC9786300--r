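#' Deconvolution parameter vector
#'
#' The five free parameters of the linear combination model plus the pivot
#' point. `alpha2` is the mixing proportion of the "form2" template
#' (crystalline form in the intended application); `alpha1` is always derived
#' as `1 - alpha2` and never stored, which enforces the sum-to-one constraint
#' by construction.
#'
#' @param alpha2 Proportion of form2, in `[0, 1]`.
#' @param phi0 Zero-order phase contribution at the pivot (radians).
#' @param phi1 First-order phase coefficient (radians across the spectrum).
#' @param delta_mix Horizontal shift applied to the mixture (ppm).
#' @param delta_form1 Horizontal shift applied to the form1 template (ppm).
#' @param pivot_index 0-based pivot point index (see [phase_spec()]), or `NA`
#'   to let [deconv_fit()] default to the mixture's magnitude maximum.
#' @return An object of class `deconv_params`.
#' @export
deconv_params <- function(alpha2 = 0, phi0 = 0, phi1 = 0, delta_mix = 0,
                          delta_form1 = 0, pivot_index = NA_integer_) {
  alpha2 <- as.numeric(alpha2)
  if (!is.finite(alpha2) || alpha2 < 0 || alpha2 > 1)
    stop("alpha2 must lie in [0, 1], got ", format(alpha2))
  stopifnot(is.finite(phi0), is.finite(phi1),
            is.finite(delta_mix), is.finite(delta_form1))
  structure(list(alpha2 = alpha2, phi0 = as.numeric(phi0),
                 phi1 = as.numeric(phi1), delta_mix = as.numeric(delta_mix),
                 delta_form1 = as.numeric(delta_form1),
                 pivot_index = as.integer(pivot_index)),
            class = "deconv_params")
}

#' @export
print.deconv_params <- function(x, ...) {
  cat(sprintf(paste0("<deconv_params: alpha2=%.6f (form2 %.2f%%), ",
                     "phi0=%.4f rad, phi1=%.4f rad,\n",
                     "  delta_mix=%.4f ppm, delta_form1=%.4f ppm, ",
                     "pivot=%s>\n"),
              x$alpha2, 100 * x$alpha2, x$phi0, x$phi1,
              x$delta_mix, x$delta_form1,
              ifelse(is.na(x$pivot_index), "auto", x$pivot_index)))
  invisible(x)
}

#' Box bounds for the deconvolution parameters
#'
#' `alpha2` is bounded to `[0, 1]` by the model constraint and cannot be
#' widened. Phase bounds exclude the `phi0` vs `phi0 + 2*pi` wrap-around
#' degeneracy; shift bounds reflect that input spectra are expected to be
#' referenced to within a fraction of a ppm.
#'
#' @param phi0 Length-2 interval for `phi0` (radians).
#' @param phi1 Length-2 interval for `phi1` (radians).
#' @param delta_mix,delta_form1 Length-2 intervals (ppm).
#' @return An object of class `param_bounds`.
#' @export
param_bounds <- function(phi0 = c(-pi, pi), phi1 = c(-2 * pi, 2 * pi),
                         delta_mix = c(-1, 1), delta_form1 = c(-1, 1)) {
  b <- list(alpha2 = c(0, 1), phi0 = as.numeric(phi0),
            phi1 = as.numeric(phi1), delta_mix = as.numeric(delta_mix),
            delta_form1 = as.numeric(delta_form1))
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2L || b[[nm]][1L] > b[[nm]][2L])
      stop("bound `", nm, "` must be a length-2 interval with lower <= upper")
  }
  structure(b, class = "param_bounds")
}

#' Area-normalise a mixture/template spectrum set
#'
#' With the sum-to-one constraint on the mixing proportions, the estimated
#' `alpha2` is only interpretable as a physical proportion if the three
#' spectra share an intensity scale. Each template is scaled so the
#' trapezoidal integral of its real part over the full grid equals 1 (the
#' templates are assumed carefully phased, so their real part is the
#' absorption signal). The mixture may carry an unknown phase error, so its
#' scale is estimated phase-robustly: the integral of the real part after a
#' PH0-only [auto_ph0()] pre-rotation. Only the scale is taken from that
#' rotation — the returned mixture is *not* phase-rotated, so normalisation
#' does not depend on the final fit.
#'
#' @param mix,form1,form2 [nmr_spectrum()] objects on a common grid.
#' @return List `(mix, form1, form2)` of scaled spectra; each carries its
#'   scaling factor in `meta$norm_factor`.
#' @export
normalize_set <- function(mix, form1, form2) {
  stopifnot(is_nmr_spectrum(mix), is_nmr_spectrum(form1),
            is_nmr_spectrum(form2))
  check_same_grid(mix, form2, "mixture and form2")
  check_same_grid(form1, form2, "form1 and form2")
  scale_one <- function(s, area, what) {
    if (!is.finite(area) || area <= 0)
      stop(what, " has nonpositive real-part area (", format(area),
           "); templates must be properly phased before use")
    f <- 1 / area
    s$intensity <- s$intensity * f
    s$meta$norm_factor <- f
    s
  }
  a1 <- pracma::trapz(form1$ppm, Re(form1$intensity))
  a2 <- pracma::trapz(form2$ppm, Re(form2$intensity))
  phi <- auto_ph0(mix)
  am <- pracma::trapz(mix$ppm, Re(mix$intensity * exp(1i * phi)))
  list(mix = scale_one(mix, am, "mixture (after PH0 pre-rotation)"),
       form1 = scale_one(form1, a1, "form1 template"),
       form2 = scale_one(form2, a2, "form2 template"))
}

#' Model residuals of the linear combination fit
#'
#' Computes, point by point,
#' `e_n = Delta_mix(Re(exp(1i*phi_n) * y_mix,n))
#'        - (1 - alpha2) * Delta_form1(Re(y_form1,n)) - alpha2 * Re(y_form2,n)`
#' where `Delta_` is the linear-interpolation shift operator
#' ([shift_spectrum()]) and `phi_n` the linear phase ramp ([phase_angles()]).
#' The form2 template fixes the ppm frame: it is never shifted.
#'
#' @param mix,form1,form2 [nmr_spectrum()] objects on a common grid
#'   (form2's grid is the reference).
#' @param p A [deconv_params()]; `pivot_index` must be set.
#' @return Numeric residual vector of length `N`.
#' @export
deconv_residuals <- function(mix, form1, form2, p) {
  stopifnot(is_nmr_spectrum(mix), inherits(p, "deconv_params"))
  check_same_grid(mix, form2, "mixture and form2")
  check_same_grid(form1, form2, "form1 and form2")
  pr <- processed_components(mix, form1, form2, p)
  pr$mix_processed - pr$fitted
}

# internal: the processed real traces used by residuals and result writers.
# Returns mix_processed (phased + shifted mixture real part), the scaled
# shifted form1 and scaled form2 contributions, and their sum.
processed_components <- function(mix, form1, form2, p) {
  n <- length(mix$ppm)
  piv <- p$pivot_index
  if (is.na(piv)) stop("pivot_index is not set")
  ps <- phase_spec(p$phi0, p$phi1, piv, n)
  mre <- Re(mix$intensity * exp(1i * phase_angles(ps)))
  mre <- shift_real(mix$ppm, mre, p$delta_mix)
  f1 <- shift_real(form1$ppm, Re(form1$intensity), p$delta_form1)
  s1 <- (1 - p$alpha2) * f1
  s2 <- p$alpha2 * Re(form2$intensity)
  list(mix_processed = mre, form1_scaled = s1, form2_scaled = s2,
       fitted = s1 + s2)
}

#' Loss of a residual vector
#'
#' Quadratic (`"L2"`, the residual sum of squares, the default of the fitting
#' procedure) or least absolute deviation (`"L1"`, robust to sparse
#' artefacts).
#'
#' @param e Numeric residual vector (finite).
#' @param norm `"L2"` or `"L1"`.
#' @return Nonnegative scalar: `sum(e^2)` or `sum(abs(e))`.
#' @export
spectral_loss <- function(e, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  if (anyNA(e) || any(!is.finite(e))) stop("residuals contain non-finite values")
  if (norm == "L2") sum(e * e) else sum(abs(e))
}
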