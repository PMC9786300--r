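test_that("starting-value policy follows the documented defaults", {
  tpl <- get_templates(1024)
  mix <- make_mixture(tpl$form1, tpl$form2, 0.1)

  # explicit ph0 passes through
  st <- make_start(mix, fit_config(ph0_init = 0.3))
  expect_identical(st$phi0, 0.3)
  expect_identical(st$alpha2, 0)
  expect_identical(st$phi1, 0)
  expect_identical(st$delta_mix, 0)
  expect_identical(st$delta_form1, 0)

  # well-phased mixture: auto init lands near 0. On fully complex data the
  # positiveness score carries a small bias from the dispersion tails, so
  # "near" means a few degrees here; the exact one-grid-step inversion
  # property holds for absorption spectra (see the gridops tests).
  st_auto <- make_start(mix, fit_config(ph0_init = "auto"))
  expect_lte(ang_diff(st_auto$phi0, 0), 0.07)

  # dephased mixture (absorption-only construction): auto init recovers theta
  absn <- nmr_spectrum(mix$ppm, complex(real = Re(mix$intensity), imaginary = 0))
  set.seed(8)
  for (th in stats::runif(5, -2, 2)) {
    rot <- nmr_spectrum(absn$ppm, absn$intensity * exp(-1i * th))
    expect_lte(ang_diff(make_start(rot, fit_config())$phi0, th),
               pi / 90)  # within two grid steps for rough initialisation
  }
})

test_that("fixed mode applies the given values without optimisation", {
  tpl <- get_templates(512)
  mix <- make_mixture(tpl$form1, tpl$form2, 0.3, 0.4, -0.2, delta_mix = 0.07)
  p <- truth_params(mix)
  fit <- deconv_fit(mix, tpl$form1, tpl$form2,
                    fit_config("fixed", start = p, normalize = FALSE))
  expect_identical(fit$params$alpha2, p$alpha2)
  expect_identical(fit$params$phi0, p$phi0)
  expect_equal(fit$loss_value, fit$loss_start)
  expect_lt(fit$loss_value, 1e-12)
  # FitResult invariants
  expect_lt(max(abs(fit$residual - (fit$mix_processed - fit$fitted))), 1e-12)
  expect_equal(fit$loss_value, spectral_loss(fit$residual, fit$loss_type),
               tolerance = 1e-12)
})

test_that("proportion-only mode matches the convex 1-D oracle", {
  tpl <- get_templates(1024)
  set.seed(17)
  for (a2 in c(0.25, 0.03, 0.6)) {
    mix <- make_mixture(tpl$form1, tpl$form2, a2)
    st <- deconv_params(0, 0, 0, 0, 0)
    fit <- deconv_fit(mix, tpl$form1, tpl$form2,
                      fit_config("proportion_only", start = st,
                                 normalize = FALSE))
    expect_equal(fit$params$alpha2, a2, tolerance = 1e-6)
    # agrees with the independent closed-form quadratic minimiser
    oracle <- parabola_alpha2(mix, tpl$form1, tpl$form2, fit$params)
    expect_equal(fit$params$alpha2, oracle, tolerance = 1e-6)
    # other parameters are untouched
    expect_identical(fit$params$phi1, 0)
    expect_identical(fit$params$delta_mix, 0)
  }
})

test_that("full mode recovers generating parameters on a noiseless fixture", {
  tpl <- get_templates(1024)
  mix <- make_mixture(tpl$form1, tpl$form2, alpha2 = 0.10, phi0 = 0.5,
                      phi1 = 0.3, delta_mix = 0.1, delta_form1 = -0.05)
  fit <- deconv_fit(mix, tpl$form1, tpl$form2,
                    fit_config("full", normalize = FALSE))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$alpha2 - 0.10), 0.003)
  expect_lt(abs(fit$params$phi0 - 0.5), 0.01)
  expect_lt(abs(fit$params$delta_mix - 0.1), 0.01)
  expect_lt(abs(fit$params$delta_form1 + 0.05), 0.01)
  expect_lt(fit$loss_value, 1e-8 * fit$loss_start)
})

test_that("optimising modes never return a loss above the start", {
  tpl <- get_templates(512)
  cases <- expand.grid(a2 = c(0, 0.1, 0.5), noise = c(0, 0.02),
                       mode = c("proportion_only", "full"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    mix <- make_mixture(tpl$form1, tpl$form2, cases$a2[i], phi0 = 0.3,
                        phi1 = -0.4, delta_mix = 0.05,
                        noise_sigma = cases$noise[i], seed = i)
    fit <- deconv_fit(mix, tpl$form1, tpl$form2,
                      fit_config(cases$mode[i], normalize = FALSE,
                                 maxeval = 4000))
    expect_lte(fit$loss_value, fit$loss_start)
  }
})

test_that("the fit is deterministic given identical inputs and config", {
  tpl <- get_templates(512)
  mix <- make_mixture(tpl$form1, tpl$form2, 0.2, 0.3, 0.2, delta_mix = 0.05,
                      noise_sigma = 0.01, seed = 5)
  cfg <- fit_config("full", normalize = FALSE, maxeval = 3000)
  f1 <- deconv_fit(mix, tpl$form1, tpl$form2, cfg)
  f2 <- deconv_fit(mix, tpl$form1, tpl$form2, cfg)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$loss_value, f2$loss_value)
  expect_identical(f1$n_evals, f2$n_evals)
})

test_that("full mode started at the proportion-only solution never loses", {
  tpl <- get_templates(512)
  mix <- make_mixture(tpl$form1, tpl$form2, 0.3, 0.2, 0.1,
                      noise_sigma = 0.005, seed = 9)
  po <- deconv_fit(mix, tpl$form1, tpl$form2,
                   fit_config("proportion_only", normalize = FALSE))
  full <- deconv_fit(mix, tpl$form1, tpl$form2,
                     fit_config("full", start = po$params,
                                normalize = FALSE, maxeval = 4000))
  expect_lte(full$loss_value, po$loss_value)
})

test_that("alpha2 landing on a constraint bound is flagged", {
  tpl <- get_templates(512)
  mix <- make_mixture(tpl$form1, tpl$form2, 0)   # pure form1: truth at bound
  st <- deconv_params(0, 0, 0, 0, 0)
  fit <- deconv_fit(mix, tpl$form1, tpl$form2,
                    fit_config("proportion_only", start = st,
                               normalize = FALSE))
  expect_true(fit$at_bound)
  expect_lt(fit$params$alpha2, 1e-5)
  # a mid-range estimate is not flagged
  mix2 <- make_mixture(tpl$form1, tpl$form2, 0.4)
  fit2 <- deconv_fit(mix2, tpl$form1, tpl$form2,
                     fit_config("proportion_only", start = st,
                                normalize = FALSE))
  expect_false(fit2$at_bound)
})

test_that("bound-violating starts are clipped with a warning", {
  tpl <- get_templates(512)
  mix <- make_mixture(tpl$form1, tpl$form2, 0.2)
  bad <- deconv_params(0.5, phi0 = 2, delta_mix = 5)
  warns <- capture_warnings(
    fit <- deconv_fit(mix, tpl$form1, tpl$form2,
                      fit_config("fixed", start = bad, normalize = FALSE,
                                 bounds = param_bounds(phi0 = c(-1, 1)))))
  expect_length(warns, 2L)
  expect_match(warns, "clipped", all = TRUE)
  expect_identical(fit$params$phi0, 1)
  expect_identical(fit$params$delta_mix, 1)
})

test_that("L1 estimates resist sparse spike artefacts better than L2", {
  tpl <- get_templates(1024)
  st <- deconv_params(0, 0, 0, 0, 0)
  errs <- vapply(1:20, function(s) {
    mx <- make_mixture(tpl$form1, tpl$form2, 0.2, noise_sigma = 0.005,
                       seed = s)
    mx <- add_spikes(mx, n_spikes = 15, amplitude = 2, seed = 1000 + s)
    e2 <- deconv_fit(mx, tpl$form1, tpl$form2,
                     fit_config("proportion_only", "L2", start = st,
                                normalize = FALSE))$params$alpha2 - 0.2
    e1 <- deconv_fit(mx, tpl$form1, tpl$form2,
                     fit_config("proportion_only", "L1", start = st,
                                normalize = FALSE))$params$alpha2 - 0.2
    c(abs(e1), abs(e2))
  }, numeric(2))
  expect_lte(mean(errs[1, ]), mean(errs[2, ]))
})
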