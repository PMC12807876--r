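test_that("circularity honours its analytic identities", {
  r <- 37
  expect_identical(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(2, 2 * sqrt(2 * pi)), 1)   # any circle
  # elongated rectangle, analytic: 4*pi*2000/420^2
  expect_lt(circularity(10 * 200, 2 * 210), 0.15)
  expect_error(circularity(-1, 5), "area")
  expect_error(circularity(1, 0))
})

test_that("rasterized circles measure within the isoperimetric band", {
  for (r in c(25, 50)) {
    m <- tensimetry:::disc_mask(2 * r + 30, 2 * r + 30,
                                rep(r + 15.5, 2), r)
    cir <- circularity(sum(m), tensimetry:::crofton_perimeter(m), clip = 1.05)
    expect_gte(cir, 0.95)
    expect_lte(cir, 1.05)
  }
  # scale invariance: 2x rasterization changes Cir by < 2%
  m1 <- tensimetry:::disc_mask(80, 80, c(40.5, 40.5), 25)
  m2 <- tensimetry:::disc_mask(160, 160, c(80.5, 80.5), 50)
  c1 <- circularity(sum(m1), tensimetry:::crofton_perimeter(m1))
  c2 <- circularity(sum(m2), tensimetry:::crofton_perimeter(m2))
  expect_lt(abs(c1 - c2) / c2, 0.02)
})

test_that("object metrics drop sub-cutoff specks and report px2/um2", {
  lab <- array(0L, c(3, 60, 60))
  lab[2, , ][tensimetry:::disc_mask(60, 60, c(20, 20), 10)] <- 1L   # 314 px2
  lab[2, 50:54, 50:55] <- 2L                                        # 30 px2
  obj <- er_object_metrics(lab, cutoff_px2 = 40,
                           voxel_size = c(1, 0.5, 0.5))
  expect_equal(nrow(obj), 1L)
  expect_equal(obj$area_um2, obj$area_px2 * 0.25)
  expect_equal(attr(obj, "mid_slice"), 2L)
  expect_gt(obj$circularity, 0.9)
  # an empty frame is flagged, not an error
  empty <- er_object_metrics(array(0L, c(2, 10, 10)))
  expect_equal(nrow(empty), 0L)
})

test_that("FOV summaries average circularity without weighting", {
  objs <- list(data.frame(object_id = 1:2, area_px2 = c(100, 900),
                          area_um2 = c(100, 900), perimeter_px = c(40, 110),
                          circularity = c(0.2, 0.8)),
               data.frame(object_id = 1, area_px2 = 500, area_um2 = 500,
                          perimeter_px = 80, circularity = 0.9),
               data.frame(object_id = integer(), area_px2 = numeric(),
                          area_um2 = numeric(), perimeter_px = numeric(),
                          circularity = numeric()))
  sm <- er_fov_summary(objs)
  expect_equal(sm$mean_circularity[1], 0.5)
  expect_equal(sm$largest_object_area[1], 900)
  expect_equal(sm$mean_circularity[2], 0.9)
  expect_true(sm$empty[3])
  expect_true(is.na(sm$mean_circularity[3]))
})

test_that("time-lapse normalization anchors frame 0 at exactly 1", {
  sm <- data.frame(frame = 1:4, n_objects = 5,
                   largest_object_area = c(2000, 1500, 1000, 500),
                   mean_circularity = c(0.4, 0.5, 0.6, 0.8), empty = FALSE)
  ns <- normalize_er_series(sm, "to_t0")
  expect_identical(ns$normalized_area[1], 1)
  expect_identical(ns$normalized_circularity[1], 1)
  expect_equal(ns$normalized_circularity[4], 2)
  const <- sm; const$mean_circularity <- 0.5
  const$largest_object_area <- 800
  nc <- normalize_er_series(const, "to_t0")
  expect_equal(nc$normalized_circularity, rep(1, 4))
  ctrl <- normalize_er_series(sm, "to_control", control = sm)
  expect_equal(ctrl$normalized_area[1], 2000 / mean(sm$largest_object_area))
  bad <- sm; bad$mean_circularity[1] <- 0
  expect_error(normalize_er_series(bad, "to_t0"), "baseline")
  expect_error(normalize_er_series(sm, "to_control"), "control")
})

test_that("luminal segmentation labels disjoint vesicles individually", {
  sc <- synth_scene(fov_shape = c(9, 160, 160),
                    er = er_spec("vesicles", n_vesicles = 20), seed = 3)
  g <- synth_er_scene(sc)
  labs <- segment_er(g$stack, "er_lumen", "luminal")
  expect_equal(max(labs[[1]]), 20L)
  blank <- image_stack(array(0, c(1, 1, 2, 30, 30)),
                       channel_roles = "er_lumen")
  expect_equal(max(segment_er(blank, "er_lumen", "luminal")[[1]]), 0L)
  expect_error(segment_er(g$stack, "er_lumen", "nonsense"))
})

test_that("membrane segmentation recovers the tube network as one object", {
  sc <- synth_scene(fov_shape = c(9, 160, 160),
                    er = er_spec("network", walk_steps = 500), seed = 4)
  g <- synth_er_scene(sc)
  labs <- segment_er(g$stack, "er_membrane", "membrane")
  truth <- g$truth$labels[[1]] > 0
  sizes <- tabulate(labs[[1]][labs[[1]] > 0])
  dom <- which.max(sizes)
  expect_gte(sum((labs[[1]] == dom) & truth) / sum(truth), 0.8)
})
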