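test_that("a pure Lorentzian template matches the closed form", {
  n <- 2048L
  spec <- sim_spec(c(-40, 0, n),
                   peaks = peak_spec(center = -20, width = 0.5,
                                     amplitude = 2, eta = 0))
  tpl <- make_template(spec)
  ppm <- tpl$ppm
  # closed form, area-normalised: the amplitude cancels
  ana <- (1 / pi) * 0.5 / (0.5^2 + (ppm + 20)^2)
  ana <- ana / pracma::trapz(ppm, ana)
  expect_equal(Re(tpl$intensity), ana, tolerance = 1e-9)
  expect_identical(which.max(Re(tpl$intensity)), which.min(abs(ppm + 20)))
  expect_equal(pracma::trapz(ppm, Re(tpl$intensity)), 1, tolerance = 1e-12)
})

test_that("the Dawson function matches direct quadrature", {
  # independent oracle: F(x) = exp(-x^2) * integral_0^x exp(t^2) dt
  for (x in c(0.3, 1, 2, 4, 5.9, 6.1, 8, 15)) {
    # damped integrand avoids overflow: exp(-x^2) * int exp(t^2)
    direct <- stats::integrate(function(t) exp(t^2 - x^2), 0, x,
                               rel.tol = 1e-12)$value
    expect_equal(nmrlcm:::dawson_fn(x), direct, tolerance = 1e-7,
                 label = paste("dawson at", x))
    expect_equal(nmrlcm:::dawson_fn(-x), -direct, tolerance = 1e-7)
  }
})

test_that("the Gaussian dispersion has the Hilbert-pair far tail", {
  # any unit-area absorption line has dispersion ~ -1/(pi*(x-x0)) far from
  # the peak; this pins the scale and sign of the Dawson-based Gaussian
  # dispersion against the analytically known Lorentzian one
  n <- 8192L
  gspec <- sim_spec(c(-200, 0, n),
                    peaks = peak_spec(center = -100, width = 1, eta = 1))
  lspec <- sim_spec(c(-200, 0, n),
                    peaks = peak_spec(center = -100, width = 1, eta = 0))
  g <- make_template(gspec); l <- make_template(lspec)
  at <- function(s, x) Im(s$intensity)[which.min(abs(s$ppm - x))]
  for (x in c(-140, -130, -60)) {
    expect_equal(at(g, x), -1 / (pi * (x + 100)), tolerance = 0.02)
    expect_equal(at(g, x), at(l, x), tolerance = 0.02)
  }
})

test_that("sideband copies appear at the right places and heights", {
  n <- 8192L
  spec <- sim_spec(c(-100, 0, n),
                   peaks = peak_spec(center = -50, width = 0.3, eta = 0),
                   sidebands = sideband_spec(spacing = 15, n_orders = 2L,
                                             decay = 0.5))
  tpl <- make_template(spec)
  at <- function(x) Re(tpl$intensity)[which.min(abs(tpl$ppm - x))]
  centre <- at(-50)
  for (k in 1:2) {
    expect_equal(at(-50 - 15 * k) / centre, 0.5^k, tolerance = 0.01)
    expect_equal(at(-50 + 15 * k) / centre, 0.5^k, tolerance = 0.01)
  }
})

test_that("templates are physically phaseable", {
  tpl <- get_templates(512)$form2
  ps <- phase_spec(pi / 2, 0, 0L, 512L)
  back <- phase_correct(phase_correct(tpl, ps), negate_phase(ps))
  expect_lt(max(Mod(back$intensity - tpl$intensity)), 1e-12)
})

test_that("peaks outside the grid are rejected", {
  expect_error(make_template(sim_spec(c(-10, 0, 64),
                                      peak_spec(center = 5, width = 1))),
               "outside the grid")
})

test_that("mixture construction is the exact model inverse", {
  tpl <- get_templates(1024)
  # boundary: alpha2 = 0, no errors -> the mixture is form1
  mx0 <- make_mixture(tpl$form1, tpl$form2, 0)
  expect_equal(mx0$intensity, tpl$form1$intensity, tolerance = 1e-14)

  # residuals at the generating parameters vanish, including off-grid shifts
  # and first-order phase error
  for (case in list(c(0.1, 0.5, 0.3, 0.1, -0.05),
                    c(0.4, -1.0, 0.8, -0.13, 0.07),
                    c(0.03, 2.0, 0.0, 0.0, 0.0))) {
    mx <- make_mixture(tpl$form1, tpl$form2, alpha2 = case[1],
                       phi0 = case[2], phi1 = case[3], delta_mix = case[4],
                       delta_form1 = case[5])
    e <- deconv_residuals(mx, tpl$form1, tpl$form2, truth_params(mx))
    expect_lt(spectral_loss(e), 1e-10)
  }

  expect_error(make_mixture(tpl$form1, tpl$form2, 1.2), "\\[0, 1\\]")
})

test_that("synthetic outputs are a pure function of their seed", {
  tpl <- get_templates(512)
  m1 <- make_mixture(tpl$form1, tpl$form2, 0.1, noise_sigma = 0.01, seed = 42)
  m2 <- make_mixture(tpl$form1, tpl$form2, 0.1, noise_sigma = 0.01, seed = 42)
  expect_identical(m1$intensity, m2$intensity)
  m3 <- make_mixture(tpl$form1, tpl$form2, 0.1, noise_sigma = 0.01, seed = 43)
  expect_false(identical(m3$intensity, m1$intensity))
})

test_that("the L2 loss at truth sits at the expected noise floor", {
  tpl <- get_templates(1024)
  sigma_frac <- 0.01
  ref <- max(max(Mod(tpl$form1$intensity)), max(Mod(tpl$form2$intensity)))
  expected <- 1024 * (sigma_frac * ref)^2
  losses <- vapply(1:20, function(s) {
    mx <- make_mixture(tpl$form1, tpl$form2, 0.1, phi0 = 0.4, phi1 = 0.2,
                       noise_sigma = sigma_frac, seed = s)
    spectral_loss(deconv_residuals(mx, tpl$form1, tpl$form2,
                                   truth_params(mx)))
  }, numeric(1))
  expect_lt(abs(mean(losses) - expected) / expected, 0.3)
})

test_that("fixture sets round-trip through files and are byte-stable", {
  specs <- demo_simspecs(256)
  bundle <- fixture_bundle(specs$form1, specs$form2, alpha2 = 0.10,
                           phi0 = 0.5, phi1 = 0.3, delta_mix = 0.1,
                           delta_form1 = -0.05, noise_sigma = 0.01, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_set(d1, bundle)
  write_fixture_set(d2, bundle)
  files <- c("form1.jdx", "form2.jdx", "mixture.jdx", "form1_real.csv",
             "form1_imag.csv", "mixture_real.csv", "mixture_imag.csv",
             "manifest.yml")
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)

  # read back both formats and compare to the in-memory spectra
  fx <- list(form1 = make_template(specs$form1),
             form2 = make_template(specs$form2))
  j <- read_jcampdx(file.path(d1, "form1.jdx"))
  expect_equal(j$intensity, fx$form1$intensity, tolerance = 1e-12)
  cs <- read_csv_pair(file.path(d1, "form1_real.csv"),
                      file.path(d1, "form1_imag.csv"))
  expect_equal(cs$intensity, fx$form1$intensity, tolerance = 1e-12)

  # the manifest records the generating parameters
  man <- read_fixture_manifest(file.path(d1, "manifest.yml"))
  expect_equal(man$alpha2, 0.10)
  expect_equal(man$noise_sigma, 0.01)
  expect_equal(man$seed, 7)
})

test_that("the manifest proportion is recoverable from the emitted files", {
  specs <- demo_simspecs(1024)
  bundle <- fixture_bundle(specs$form1, specs$form2, alpha2 = 0.15,
                           phi0 = 0.4, phi1 = 0.2, delta_mix = 0.05,
                           delta_form1 = 0, noise_sigma = 0.005, seed = 11)
  d <- withr::local_tempdir()
  write_fixture_set(d, bundle)
  mix <- read_jcampdx(file.path(d, "mixture.jdx"))
  f1 <- read_jcampdx(file.path(d, "form1.jdx"))
  f2 <- read_jcampdx(file.path(d, "form2.jdx"))
  fit <- deconv_fit(mix, f1, f2, fit_config("full", normalize = FALSE))
  man <- read_fixture_manifest(file.path(d, "manifest.yml"))
  expect_lt(abs(fit$params$alpha2 - man$alpha2), 0.005)
})
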