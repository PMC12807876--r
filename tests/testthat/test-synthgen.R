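test_that("generators are deterministic under a fixed seed", {
  g1 <- synth_nucleus_timelapse(single_nucleus_scene(seed = 42))
  g2 <- synth_nucleus_timelapse(single_nucleus_scene(seed = 42))
  expect_identical(g1$stack$data, g2$stack$data)
  e1 <- synth_er_scene(synth_scene(fov_shape = c(7, 80, 80),
                                   er = er_spec("vesicles", n_vesicles = 6),
                                   seed = 5))
  e2 <- synth_er_scene(synth_scene(fov_shape = c(7, 80, 80),
                                   er = er_spec("vesicles", n_vesicles = 6),
                                   seed = 5))
  expect_identical(e1$stack$data, e2$stack$data)
  t1 <- synth_guv_titration(seed = 3)
  t2 <- synth_guv_titration(seed = 3)
  expect_identical(t1$measurements, t2$measurements)
})

test_that("noise-free nuclei have rim exactly rho times the nucleoplasm", {
  g <- synth_nucleus_timelapse(single_nucleus_scene(rho = 2, noise = FALSE))
  sens <- get_channel(g$stack, "sensor", frame = 1)
  ne <- get_channel(g$stack, "ne_marker", frame = 1)
  lab <- g$truth$labels[[1]] == 1
  rim <- lab & ne > 0.5
  centre <- lab & ne <= 0.5
  expect_equal(median(sens[rim]) / median(sens[centre]), 2)
})

test_that("voxelized ellipsoid volume matches the analytic volume within 3%", {
  g <- synth_nucleus_timelapse(single_nucleus_scene(noise = FALSE,
                                                    fov = c(26, 70, 70),
                                                    semi = c(10, 20, 20)))
  expect_lt(abs(g$truth$volume_voxels[1, 1] / g$truth$volume_analytic[1, 1]
                - 1), 0.03)
})

test_that("super-threshold jumps are flagged in the ground truth", {
  sc <- synth_scene(fov_shape = c(8, 120, 320), n_frames = 2,
                    nuclei = list(
                      nucleus_spec(c(4.5, 60, 60), c(3, 18, 18),
                                   drift = c(0, 0, 200)),
                      nucleus_spec(c(4.5, 60, 150), c(3, 18, 18))),
                    noise = noise_spec(0, 0, 0), seed = 1)
  g <- synth_nucleus_timelapse(sc)
  expect_identical(unname(g$truth$jump_exceeded), c(TRUE, FALSE))
  expect_equal(g$truth$displacements[2, 1], 200)
})

test_that("the GUV isotherm generator honours closed-form identities", {
  p <- list(B_max = 1, K_d = 150, H = 1)
  expect_equal(hill_langmuir(0, 1, 150, 1), 0)
  expect_equal(hill_langmuir(150, 1, 150, 2.7), 0.5)  # half-saturation, any H
  expect_equal(hill_langmuir(300, 1, 150, 1), 2 / 3)
  d <- synth_guv_titration(params = p, noise_cv = 0, seed = 1)
  expect_equal(d$measurements$binding, d$measurements$true_binding)
  expect_error(synth_guv_titration(noise_cv = -0.1), "non-negative")
  expect_error(synth_guv_titration(concs = c(-5, 10, 20, 50)),
               "non-negative")
})

test_that("packaged presets carry the published titration design", {
  pres <- guv_presets()
  expect_equal(pres[["alps-hypotonic"]]$K_d, 150)
  expect_equal(pres[["c2-ca20"]]$K_d, 20)
  for (p in pres) {
    expect_equal(p$concentrations, c(0, 25, 50, 100, 200, 300, 400, 500))
    expect_equal(length(p$n_per_conc), 8L)
    expect_true(all(p$n_per_conc >= 14 & p$n_per_conc <= 89))
  }
})

test_that("ER ground truth reflects the vesiculation fraction", {
  sc0 <- synth_scene(fov_shape = c(9, 140, 140), er = er_spec("network"),
                     seed = 2)
  g0 <- synth_er_scene(sc0)
  expect_equal(max(g0$truth$labels[[1]]), 1L)  # phi = 0: one connected object
  sc1 <- synth_scene(fov_shape = c(9, 160, 160),
                     er = er_spec("vesicles", n_vesicles = 20), seed = 3)
  g1 <- synth_er_scene(sc1)
  expect_equal(g1$truth$n_vesicles_placed, 20L)
  expect_equal(max(g1$truth$labels[[1]]), 20L)
  expect_true(all(g1$truth$vesicles$circularity >= 0.9))
  # ground-truth mean circularity is non-decreasing along a phi sweep
  scp <- synth_scene(fov_shape = c(9, 160, 160),
                     er = er_spec("mixture", phi = seq(0, 1, 0.1),
                                  n_vesicles = 40), seed = 7)
  gp <- synth_er_scene(scp)
  gt <- er_fov_summary(gp$truth$objects)
  expect_true(all(diff(gt$mean_circularity) >= -1e-9))
  expect_true(all(diff(gt$largest_object_area) <= 1e-9))
})

test_that("the two-pool FLIP model follows its per-cycle recurrence", {
  e <- synth_flip_experiment(TRUE, n_frames = 12, exchange_rate = 0.3,
                             noise_sd = 0, seed = 1)
  expect_equal(e$truth$pool_measured, 0.7^(0:11))
  e1 <- synth_flip_experiment(TRUE, n_frames = 5, exchange_rate = 1,
                              noise_sd = 0, seed = 1)
  expect_equal(e1$truth$pool_measured[-1], rep(0, 4))
  ed <- synth_flip_experiment(FALSE, n_frames = 8, noise_sd = 0.01, seed = 1)
  expect_true(all(abs(ed$traces$opposite_site - 1) < 0.1))
  expect_error(synth_flip_experiment(exchange_rate = 1.5))
})
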