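# shared fixtures, built in code and memoised for the whole test run

.fixture_cache <- new.env(parent = emptyenv())

# demo template pair at a given resolution, cached
get_templates <- function(n = 1024L) {
  key <- paste0("tpl", n)
  if (is.null(.fixture_cache[[key]])) {
    specs <- demo_simspecs(n)
    .fixture_cache[[key]] <- list(form1 = make_template(specs$form1),
                                  form2 = make_template(specs$form2))
  }
  .fixture_cache[[key]]
}

# seeded random complex spectrum on a uniform grid
rand_spectrum <- function(n = 64L, seed = 1L, ppm_range = c(-10, 10)) {
  set.seed(seed)
  nmr_spectrum(seq(ppm_range[1L], ppm_range[2L], length.out = n),
               complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)))
}

# smooth seeded random spectrum (low-pass filtered noise), real + dispersion-free
smooth_spectrum <- function(n = 512L, seed = 1L, ppm_range = c(-20, 0)) {
  set.seed(seed)
  raw <- stats::rnorm(n)
  k <- 25L
  sm <- stats::filter(raw, rep(1 / k, k), sides = 2L)
  sm[is.na(sm)] <- 0
  nmr_spectrum(seq(ppm_range[1L], ppm_range[2L], length.out = n),
               complex(real = as.numeric(sm), imaginary = 0))
}

# independent 1-D oracle: vertex of the exact quadratic through the L2 loss
# at alpha2 = 0, 1/2, 1 (phases and shifts fixed)
parabola_alpha2 <- function(mix, form1, form2, p_other) {
  L <- function(a) {
    p <- deconv_params(a, p_other$phi0, p_other$phi1, p_other$delta_mix,
                       p_other$delta_form1, p_other$pivot_index)
    spectral_loss(deconv_residuals(mix, form1, form2, p), "L2")
  }
  l0 <- L(0); lm <- L(0.5); l1 <- L(1)
  vertex <- 0.5 + 0.25 * (l0 - l1) / (l0 - 2 * lm + l1)
  min(max(vertex, 0), 1)
}

# smallest angular distance between two angles
ang_diff <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))

# truth parameters recorded by make_mixture, as a deconv_params
truth_params <- function(mix) {
  tr <- mix$meta$truth
  deconv_params(tr$alpha2, tr$phi0, tr$phi1, tr$delta_mix, tr$delta_form1,
                tr$pivot_index)
}
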