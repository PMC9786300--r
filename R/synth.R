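#' @rdname peak_spec
#' @export
sideband_spec <- function(spacing, n_orders = 2L, decay = 0.5) {
  stopifnot(spacing > 0, n_orders >= 0, decay > 0, decay < 1)
  structure(list(spacing = as.numeric(spacing),
                 n_orders = as.integer(n_orders),
                 decay = as.numeric(decay)), class = "sideband_spec")
}

#' Peak and sideband specifications for the spectrum simulator
#'
#' `peak_spec` describes one pseudo-Voigt line: `eta` interpolates between a
#' pure Lorentzian (`eta = 0`) and a pure Gaussian (`eta = 1`) lineshape.
#' `sideband_spec` describes a magic-angle-spinning sideband pattern: each
#' affected centreband is flanked by `n_orders` satellite copies per side at
#' `center + k * spacing` and `center - k * spacing`, scaled by `decay^k`.
#'
#' @param center Peak position (ppm).
#' @param width Half-width at half-maximum (ppm), `> 0`.
#' @param amplitude Integrated peak amplitude (arbitrary units), `>= 0`.
#' @param eta Gaussian fraction in `[0, 1]`.
#' @param spacing Sideband separation on the ppm axis (the spinning rate
#'   expressed in ppm), `> 0`.
#' @param n_orders Sideband orders per side, `>= 0`.
#' @param decay Per-order amplitude ratio, in `(0, 1)`.
#' @return An object of class `peak_spec` / `sideband_spec`.
#' @export
peak_spec <- function(center, width, amplitude = 1, eta = 0) {
  stopifnot(is.finite(center), width > 0, amplitude >= 0,
            eta >= 0, eta <= 1)
  structure(list(center = as.numeric(center), width = as.numeric(width),
                 amplitude = as.numeric(amplitude), eta = as.numeric(eta)),
            class = "peak_spec")
}

#' Generative description of a synthetic template spectrum
#'
#' @param grid Numeric `c(ppm_min, ppm_max, n_points)`; the template is
#'   evaluated on `n_points` equally spaced points (ascending internally).
#' @param peaks List of [peak_spec()] objects.
#' @param sidebands Optional [sideband_spec()].
#' @param sideband_peaks Indices (into `peaks`) of the peaks that carry
#'   sidebands; default all peaks when `sidebands` is given.
#' @param noise_sigma Standard deviation of additive complex Gaussian noise as
#'   a fraction of the maximum template magnitude (used by mixtures; templates
#'   themselves are generated noiseless).
#' @param seed Integer seed governing any randomness downstream.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(grid, peaks, sidebands = NULL, sideband_peaks = NULL,
                     noise_sigma = 0, seed = 1L) {
  stopifnot(length(grid) == 3L, grid[3L] >= 16, noise_sigma >= 0)
  if (grid[1L] == grid[2L]) stop("grid ppm_min and ppm_max must differ")
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  stopifnot(length(peaks) >= 1L,
            all(vapply(peaks, inherits, logical(1), "peak_spec")))
  if (!is.null(sidebands)) {
    stopifnot(inherits(sidebands, "sideband_spec"))
    if (is.null(sideband_peaks)) sideband_peaks <- seq_along(peaks)
  }
  structure(list(grid = c(sort(as.numeric(grid[1:2])), as.integer(grid[3L])),
                 peaks = peaks, sidebands = sidebands,
                 sideband_peaks = as.integer(sideband_peaks),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)), class = "sim_spec")
}

# internal: Dawson function F(x) = exp(-x^2) * integral_0^x exp(t^2) dt.
# erfi route below |x| = 10 (exp(x^2) still representable there),
# asymptotic series beyond (truncation ~1e-10 relative at the crossover).
dawson_fn <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) <= 10
  if (any(small)) {
    xs <- x[small]
    out[small] <- sqrt(pi) / 2 * exp(-xs^2) * pracma::erfi(xs)
  }
  if (any(!small)) {
    xl <- x[!small]
    z2 <- 1 / (2 * xl^2)
    out[!small] <- 1 / (2 * xl) *
      (1 + z2 * (1 + 3 * z2 * (1 + 5 * z2 * (1 + 7 * z2 * (1 + 9 * z2)))))
  }
  out
}

# internal: unit-area complex Lorentzian (absorption + i * dispersion)
lorentz_complex <- function(x, center, hwhm) {
  d <- x - center
  den <- hwhm^2 + d^2
  complex(real = hwhm / den, imaginary = -d / den) / pi
}

# internal: unit-area complex Gaussian; the dispersion part is the Hilbert
# pair of the absorption, expressed through the Dawson function
gauss_complex <- function(x, center, hwhm) {
  sigma <- hwhm / sqrt(2 * log(2))
  u <- (x - center) / (sigma * sqrt(2))
  n0 <- 1 / (sigma * sqrt(2 * pi))
  complex(real = n0 * exp(-u^2),
          imaginary = -n0 * (2 / sqrt(pi)) * dawson_fn(u))
}

# internal: one pseudo-Voigt complex line of integrated amplitude `amp`
pv_complex <- function(x, center, hwhm, amp, eta) {
  amp * ((1 - eta) * lorentz_complex(x, center, hwhm) +
         eta * gauss_complex(x, center, hwhm))
}

#' Generate a synthetic template spectrum
#'
#' Each peak contributes a complex pseudo-Voigt lineshape: the real part is
#' the absorption profile, the imaginary part the matching dispersion
#' (analytic for the Lorentzian component; via the Dawson-function Hilbert
#' pair for the Gaussian component), so phase correction acts on the result
#' physically. Sidebands are appended as scaled copies (sideband copies that
#' fall outside the grid are dropped). The real-part area is normalised to 1.
#'
#' @param spec A [sim_spec()].
#' @return A noiseless [nmr_spectrum()]; `meta$sim` records the generator
#'   parameters.
#' @export
make_template <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  g <- spec$grid
  ppm <- seq(g[1L], g[2L], length.out = g[3L])
  y <- complex(real = numeric(g[3L]), imaginary = numeric(g[3L]))
  for (i in seq_along(spec$peaks)) {
    pk <- spec$peaks[[i]]
    if (pk$center < g[1L] || pk$center > g[2L])
      stop("peak ", i, " at ", pk$center, " ppm lies outside the grid [",
           g[1L], ", ", g[2L], "] ppm")
    y <- y + pv_complex(ppm, pk$center, pk$width, pk$amplitude, pk$eta)
    if (!is.null(spec$sidebands) && i %in% spec$sideband_peaks) {
      sb <- spec$sidebands
      for (k in seq_len(sb$n_orders)) {
        a_k <- pk$amplitude * sb$decay^k
        for (ctr in c(pk$center - k * sb$spacing, pk$center + k * sb$spacing))
          if (ctr >= g[1L] && ctr <= g[2L])
            y <- y + pv_complex(ppm, ctr, pk$width, a_k, pk$eta)
      }
    }
  }
  area <- pracma::trapz(ppm, Re(y))
  nmr_spectrum(ppm, y / area, meta = list(sim = spec))
}

# internal: exact pre-image of the linear-interpolation shift operator.
# Returns w such that shift_real(ppm, w, delta) reproduces y exactly on all
# points whose sampling position falls inside the grid (edge-filled points
# agree when the baseline is flat at the edges). The two-band system is
# solved by a recursion run in its numerically stable direction.
unshift_exact <- function(ppm, y, delta) {
  if (delta == 0) return(y)
  h <- grid_spacing(ppm)
  n <- length(y)
  s <- delta / h
  if (s < 0) return(rev(unshift_exact(ppm, rev(y), -delta)))
  k <- floor(s + 1e-9)
  f <- s - k
  if (abs(f) < 1e-9 || f > 1 - 1e-9) {  # integer shift
    if (f > 1 - 1e-9) k <- k + 1L
    if (k >= n) stop("shift exceeds the spectral width")
    w <- c(y[(k + 1L):n], rep(y[n], k))
    return(w)
  }
  if (k + 2L > n) stop("shift exceeds the spectral width")
  # equations: f*w[j] + (1-f)*w[j+1] = y[j+k+1],  j = 1 .. n-k-1
  m <- n - k - 1L
  if (f < 0.5) {
    w1 <- mean(y[seq_len(k + 1L)])
    xs <- y[(k + 2L):n] / (1 - f)
    rest <- stats::filter(xs, filter = -f / (1 - f), method = "recursive",
                          init = w1)
    w <- c(w1, as.numeric(rest))
  } else {
    wtop <- y[n]
    xs <- rev(y[(k + 2L):n]) / f
    down <- stats::filter(xs, filter = -(1 - f) / f, method = "recursive",
                          init = wtop)
    w <- c(rev(as.numeric(down)), wtop)
  }
  c(w, rep(w[length(w)], k))
}

#' Generate a synthetic mixture spectrum with known parameters
#'
#' Builds the clean linear combination
#' `(1 - alpha2) * shift(form1, delta_form1) + alpha2 * form2`, then applies
#' the *inverses* of the model's forward operators: the horizontal shift is
#' inverted exactly (by solving the linear-interpolation operator, not by an
#' opposite-sign shift, which would be lossy) and the phase ramp is removed by
#' the conjugate phase factor. Consequently, evaluating the model residuals at
#' the generating parameters recovers the clean combination exactly, and for
#' `noise_sigma = 0` the global loss minimum is (numerically) zero at the
#' generating parameters. Complex circular Gaussian noise is added last.
#'
#' @param form1,form2 Area-1 templates on a common ascending uniform grid
#'   (see [make_template()]).
#' @param alpha2 True form2 proportion, in `[0, 1]`.
#' @param phi0,phi1 Injected phase error (radians; the *correction* that the
#'   model must apply to recover the clean spectrum).
#' @param pivot_index 0-based pivot; default: index of the maximum magnitude
#'   of the clean combination.
#' @param delta_mix Injected mixture misalignment (ppm); the model must shift
#'   the mixture by `+delta_mix` to align it.
#' @param delta_form1 Misreferencing of form1 baked into the mixture (ppm);
#'   the model must shift form1 by `+delta_form1` to match.
#' @param noise_sigma Complex noise standard deviation as a fraction of the
#'   maximum template magnitude.
#' @param seed Integer seed for the noise.
#' @return An [nmr_spectrum()]; `meta$truth` records every generating
#'   parameter (including the resolved `pivot_index`).
#' @export
make_mixture <- function(form1, form2, alpha2, phi0 = 0, phi1 = 0,
                         pivot_index = NULL, delta_mix = 0, delta_form1 = 0,
                         noise_sigma = 0, seed = 1L) {
  stopifnot(is_nmr_spectrum(form1), is_nmr_spectrum(form2))
  if (!is.finite(alpha2) || alpha2 < 0 || alpha2 > 1)
    stop("alpha2 must lie in [0, 1], got ", format(alpha2))
  check_same_grid(form1, form2, "templates")
  ppm <- form2$ppm
  n <- length(ppm)
  f1 <- if (delta_form1 != 0) shift_spectrum(form1, delta_form1) else form1
  clean <- (1 - alpha2) * f1$intensity + alpha2 * form2$intensity
  if (is.null(pivot_index)) pivot_index <- which.max(Mod(clean)) - 1L
  w <- complex(real = unshift_exact(ppm, Re(clean), delta_mix),
               imaginary = unshift_exact(ppm, Im(clean), delta_mix))
  ps <- phase_spec(phi0, phi1, pivot_index, n)
  y <- w * exp(-1i * phase_angles(ps))
  if (noise_sigma > 0) {
    ref <- max(max(Mod(form1$intensity)), max(Mod(form2$intensity)))
    set.seed(seed)
    y <- y + complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) *
      (noise_sigma * ref)
  }
  nmr_spectrum(ppm, y, meta = list(truth = list(
    alpha2 = alpha2, phi0 = phi0, phi1 = phi1,
    pivot_index = as.integer(pivot_index), delta_mix = delta_mix,
    delta_form1 = delta_form1, noise_sigma = noise_sigma,
    seed = as.integer(seed))))
}

#' Contaminate a spectrum with sparse spike artefacts
#'
#' Adds `n_spikes` single-point complex spikes of magnitude
#' `amplitude * max(Mod(intensity))` with random phases at random positions.
#' Used to study the robustness of the L1 loss against outlier artefacts.
#'
#' @param spec An [nmr_spectrum()].
#' @param n_spikes Number of contaminated points.
#' @param amplitude Spike magnitude as a fraction of the spectrum's maximum
#'   magnitude.
#' @param seed Integer seed.
#' @return The contaminated `nmr_spectrum`.
#' @export
add_spikes <- function(spec, n_spikes = 20L, amplitude = 3, seed = 1L) {
  stopifnot(is_nmr_spectrum(spec), n_spikes >= 1L, amplitude > 0)
  set.seed(seed)
  n <- length(spec$ppm)
  pos <- sample.int(n, min(n_spikes, n))
  amp <- amplitude * max(Mod(spec$intensity))
  th <- stats::runif(length(pos), 0, 2 * pi)
  spec$intensity[pos] <- spec$intensity[pos] + amp * exp(1i * th)
  spec
}

#' Demonstration template specifications
#'
#' The standard demo pair used throughout the package's tests and examples:
#' an amorphous "form1" of three broad pseudo-Voigt peaks, and a crystalline
#' "form2" of four narrow peaks carrying two orders of spinning sidebands.
#' The grid spans 0 to -150 ppm, mirroring a typical carbon-13 ssNMR window.
#'
#' @param n Number of grid points (default 4096).
#' @return List with elements `form1` and `form2`, each a [sim_spec()].
#' @export
demo_simspecs <- function(n = 4096L) {
  grid <- c(-150, 0, n)
  form1 <- sim_spec(grid, peaks = list(
    peak_spec(center = -35, width = 7.0, amplitude = 1.0, eta = 0.5),
    peak_spec(center = -62, width = 9.0, amplitude = 0.8, eta = 0.5),
    peak_spec(center = -95, width = 6.0, amplitude = 0.6, eta = 0.4)))
  form2 <- sim_spec(grid, peaks = list(
    peak_spec(center = -38, width = 0.40, amplitude = 1.0, eta = 0.3),
    peak_spec(center = -52, width = 0.55, amplitude = 0.8, eta = 0.3),
    peak_spec(center = -71, width = 0.35, amplitude = 0.6, eta = 0.3),
    peak_spec(center = -86, width = 0.60, amplitude = 0.5, eta = 0.3)),
    sidebands = sideband_spec(spacing = 27, n_orders = 2L, decay = 0.45))
  list(form1 = form1, form2 = form2)
}

#' Bundle of generating parameters for a fixture set
#'
#' @param form1,form2 [sim_spec()] objects on identical grids.
#' @param alpha2,phi0,phi1,pivot_index,delta_mix,delta_form1,noise_sigma,seed
#'   Mixture-generation parameters; see [make_mixture()].
#' @return An object of class `fixture_bundle`.
#' @export
fixture_bundle <- function(form1, form2, alpha2 = 0.10, phi0 = 0.5,
                           phi1 = 0.3, pivot_index = NULL, delta_mix = 0.1,
                           delta_form1 = -0.05, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(form1, "sim_spec"), inherits(form2, "sim_spec"))
  if (!isTRUE(all.equal(form1$grid, form2$grid)))
    stop("form1 and form2 must share the same grid")
  if (!is.finite(alpha2) || alpha2 < 0 || alpha2 > 1)
    stop("alpha2 must lie in [0, 1], got ", format(alpha2))
  structure(list(form1 = form1, form2 = form2, alpha2 = alpha2, phi0 = phi0,
                 phi1 = phi1, pivot_index = pivot_index,
                 delta_mix = delta_mix, delta_form1 = delta_form1,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fixture_bundle")
}

# internal: realise a bundle into spectra
build_fixture <- function(bundle) {
  f1 <- make_template(bundle$form1)
  f2 <- make_template(bundle$form2)
  mx <- make_mixture(f1, f2, alpha2 = bundle$alpha2, phi0 = bundle$phi0,
                     phi1 = bundle$phi1, pivot_index = bundle$pivot_index,
                     delta_mix = bundle$delta_mix,
                     delta_form1 = bundle$delta_form1,
                     noise_sigma = bundle$noise_sigma, seed = bundle$seed)
  list(form1 = f1, form2 = f2, mixture = mx)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits form1/form2/mixture as JCAMP-DX files and as CSV pairs, plus a flat
#' YAML manifest recording every generating parameter and the seed.
#' Regeneration from the same bundle is byte-identical (all writers use
#' deterministic formatting and the manifest contains no timestamps).
#'
#' @param dir Output directory (created if missing).
#' @param bundle A [fixture_bundle()].
#' @return Invisibly, the manifest path.
#' @export
write_fixture_set <- function(dir, bundle) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  fx <- build_fixture(bundle)
  for (nm in c("form1", "form2", "mixture")) {
    write_jcampdx(fx[[nm]], file.path(dir, paste0(nm, ".jdx")), title = nm)
    write_csv_pair(fx[[nm]], file.path(dir, paste0(nm, "_real.csv")),
                   file.path(dir, paste0(nm, "_imag.csv")))
  }
  manifest <- file.path(dir, "manifest.yml")
  writeLines(manifest_lines(bundle, fx$mixture$meta$truth$pivot_index),
             manifest)
  invisible(manifest)
}

# internal: deterministic flat key-value manifest
manifest_lines <- function(bundle, pivot_index) {
  num <- function(x) sprintf("%.17g", x)
  simspec_lines <- function(tag, s) {
    out <- c(sprintf("%s_grid_min: %s", tag, num(s$grid[1L])),
             sprintf("%s_grid_max: %s", tag, num(s$grid[2L])),
             sprintf("%s_grid_n: %d", tag, s$grid[3L]),
             sprintf("%s_n_peaks: %d", tag, length(s$peaks)))
    for (i in seq_along(s$peaks)) {
      pk <- s$peaks[[i]]
      out <- c(out, sprintf("%s_peak%d: [%s, %s, %s, %s]", tag, i,
                            num(pk$center), num(pk$width),
                            num(pk$amplitude), num(pk$eta)))
    }
    if (!is.null(s$sidebands)) {
      sb <- s$sidebands
      out <- c(out,
               sprintf("%s_sideband_spacing: %s", tag, num(sb$spacing)),
               sprintf("%s_sideband_orders: %d", tag, sb$n_orders),
               sprintf("%s_sideband_decay: %s", tag, num(sb$decay)),
               sprintf("%s_sideband_peaks: [%s]", tag,
                       paste(s$sideband_peaks, collapse = ", ")))
    }
    out
  }
  c("# nmrlcm synthetic fixture manifest",
    simspec_lines("form1", bundle$form1),
    simspec_lines("form2", bundle$form2),
    sprintf("alpha2: %s", num(bundle$alpha2)),
    sprintf("phi0: %s", num(bundle$phi0)),
    sprintf("phi1: %s", num(bundle$phi1)),
    sprintf("pivot_index: %d", as.integer(pivot_index)),
    sprintf("delta_mix: %s", num(bundle$delta_mix)),
    sprintf("delta_form1: %s", num(bundle$delta_form1)),
    sprintf("noise_sigma: %s", num(bundle$noise_sigma)),
    sprintf("seed: %d", bundle$seed))
}

#' Read a fixture manifest
#' @param path Path to a `manifest.yml` written by [write_fixture_set()].
#' @return Named list of the generating parameters.
#' @export
read_fixture_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  yaml::read_yaml(path)
}
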