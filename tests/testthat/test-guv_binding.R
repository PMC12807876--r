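test_that("the crop window follows the stated 2.4x rule", {
  st <- image_stack(array(runif(200 * 200), c(1, 1, 1, 200, 200)),
                    channel_roles = "guv_membrane")
  cr <- extract_guv(st, c(100, 100, 100, 150))   # line length 50
  expect_equal(dim(cr$data)[4:5], c(121L, 121L))  # 2.4 * 50, inclusive grid
  expect_error(extract_guv(st, c(100, 100, 100, 100)), "degenerate")
  expect_error(extract_guv(st, c(100, 100, 100, 500)), "inside")
})

test_that("rim binding is recovered from rendered GUVs", {
  for (rv in c(0.2, 0.8)) {
    st <- synth_guv_image(rim_value = rv, seed = 1)
    cr <- extract_guv(st, c(48, 48, 48, 73))
    m <- guv_rim_binding(cr, reference_signal = 1)
    expect_true(m$found)
    expect_equal(m$normalized_binding, rv, tolerance = 0.03 / max(rv, 0.03))
  }
  # ratio invariance: doubling protein image and reference cancels
  st <- synth_guv_image(rim_value = 0.5, seed = 2)
  cr <- extract_guv(st, c(48, 48, 48, 73))
  b1 <- guv_rim_binding(cr, reference_signal = 1)$normalized_binding
  cr2 <- cr
  pi2 <- channel_index(cr2, "protein")
  cr2$data[, pi2, , , ] <- cr2$data[, pi2, , , ] * 2
  b2 <- guv_rim_binding(cr2, reference_signal = 2)$normalized_binding
  expect_equal(b1, b2, tolerance = 1e-12)
  # zero protein channel -> zero binding
  cr3 <- cr
  cr3$data[, pi2, , , ] <- 0
  expect_equal(guv_rim_binding(cr3, 1)$normalized_binding, 0)
})

test_that("an empty crop is flagged rather than measured", {
  st <- image_stack(array(runif(5 * 60 * 60, 0, 1e-4) + 1e-6,
                          c(1, 2, 5, 60, 60)),
                    channel_roles = c("guv_membrane", "protein"))
  m <- guv_rim_binding(st, reference_signal = 1)
  expect_false(m$found)
  expect_true(is.na(m$normalized_binding))
})

test_that("noiseless titrations are recovered to numerical precision", {
  pres <- guv_presets()
  for (pn in names(pres)) {
    d <- synth_guv_titration(params = pres[[pn]], noise_cv = 0, seed = 1)
    fit <- fit_isotherm(d$measurements)
    expect_true(fit$converged)
    expect_lt(abs(fit$K_d / pres[[pn]]$K_d - 1), 1e-6)
    expect_lt(abs(fit$B_max / pres[[pn]]$B_max - 1), 1e-6)
    expect_lt(abs(fit$H - 1), 1e-6)
    # CIs contain the point estimates
    expect_true(fit$ci["lower", "K_d"] <= fit$K_d &&
                  fit$K_d <= fit$ci["upper", "K_d"])
  }
})

test_that("degenerate titrations fail loudly or are flagged", {
  d <- synth_guv_titration(concs = c(0, 100, 300),
                           n_per_conc = 5, noise_cv = 0, seed = 1,
                           params = list(B_max = 1, K_d = 150, H = 1))
  expect_error(fit_isotherm(d$measurements), "4 distinct")
  dz <- synth_guv_titration(noise_cv = 0, seed = 1)$measurements
  dz$binding <- 0
  fz <- fit_isotherm(dz)
  expect_false(fz$converged)
  expect_true(is.na(fz$K_d))
})

test_that("the fitted model predicts its closed-form identities", {
  d <- synth_guv_titration(noise_cv = 0, seed = 1)
  fit <- fit_isotherm(d$measurements)
  expect_equal(isotherm_predict(fit, fit$K_d), fit$B_max / 2)
  expect_equal(isotherm_predict(fit, 0), 0)
  cs <- c(1, 5, 20, 80, 320, 1280, 1e5)
  pred <- isotherm_predict(fit, cs)
  expect_true(all(diff(pred) > 0))            # strictly increasing
  expect_lt(pred[length(pred)], fit$B_max)    # bounded by the asymptote
  expect_error(isotherm_predict(fit, -1), "non-negative")
  bad <- fit; bad$converged <- FALSE
  expect_error(isotherm_predict(bad, 10), "converge")
})

test_that("noisy titrations recover K_d within 20% and the affinity ratio", {
  pres <- guv_presets()
  meds <- vapply(names(pres), function(pn) {
    p <- pres[[pn]]
    kds <- vapply(1:8, function(s) {
      d <- synth_guv_titration(p$concentrations, p$n_per_conc, p,
                               noise_cv = 0.15, seed = 500 + s)
      fit_isotherm(d$measurements)$K_d
    }, numeric(1))
    median(kds)
  }, numeric(1))
  expect_lt(abs(meds[["alps-hypotonic"]] / 150 - 1), 0.2)
  expect_lt(abs(meds[["c2-ca20"]] / 20 - 1), 0.2)
  expect_lt(abs(meds[["alps-hypotonic"]] / meds[["c2-ca20"]] / 7.5 - 1),
            0.25)
})
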