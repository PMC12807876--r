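test_that("preprocessing removes a planar background gradient", {
  dims <- c(4, 90, 90)
  grad <- aperm(array(outer(seq_len(90) / 90, seq_len(90) / 90, `+`) * 0.2,
                      c(90, 90, 4)), c(3, 1, 2))
  x <- grad
  x[, 35:55, 35:55] <- x[, 35:55, 35:55] + 1   # flat foreground plateau
  st <- image_stack(array(x, c(1, 1, dims)), channel_roles = "sensor")
  pp <- preprocess(st, "sensor", gaussian_radius_px = 0.5,
                   rollball_radius_px = 15)
  y <- get_channel(pp, "sensor", frame = 1)
  expect_gte(min(y), 0)
  expect_lte(max(y), 1)
  fg <- y[, 38:52, 38:52]
  expect_lt(diff(range(fg)) / max(mean(fg), 1e-9), 0.05)
  bg <- y[, 70:88, 70:88]
  expect_lt(max(bg), 0.05)
})

test_that("preprocessing rejects an all-zero channel", {
  st <- image_stack(array(0, c(1, 1, 2, 8, 8)), channel_roles = "sensor")
  expect_error(preprocess(st, "sensor"), "constant zero")
})

test_that("well-separated nuclei segment with high voxel overlap", {
  sc <- synth_scene(fov_shape = c(14, 100, 220), n_frames = 1,
                    nuclei = list(
                      nucleus_spec(c(7.5, 50, 40), c(5, 22, 22)),
                      nucleus_spec(c(7.5, 50, 110), c(5, 22, 22)),
                      nucleus_spec(c(7.5, 50, 180), c(5, 22, 22))),
                    seed = 4)
  g <- synth_nucleus_timelapse(sc)
  pp <- preprocess(g$stack, "ne_marker")
  labs <- segment_nuclei(pp, "ne_marker")
  expect_equal(max(labs[[1]]), 3L)
  stats <- tensimetry:::label_stats_3d(labs[[1]])
  for (i in 1:3) {
    truth <- g$truth$labels[[1]] == i
    # match segmented label by centroid
    tc <- colMeans(which(truth, arr.ind = TRUE))
    j <- stats$label[which.min((stats$z - tc[1])^2 + (stats$y - tc[2])^2 +
                                 (stats$x - tc[3])^2)]
    seg <- labs[[1]] == j
    expect_gt(sum(truth & seg) / sum(truth | seg), 0.8)
  }
})

test_that("touching nuclei with distinct bright cores split into two labels", {
  sc <- synth_scene(fov_shape = c(14, 70, 110), n_frames = 1,
                    noise = noise_spec(0, 0, 0),
                    nuclei = list(
                      nucleus_spec(c(7.5, 35, 34), c(5, 20, 20),
                                   rim_enrichment = 1),
                      nucleus_spec(c(7.5, 35, 72), c(5, 20, 20),
                                   rim_enrichment = 1)),
                    seed = 2)
  g <- synth_nucleus_timelapse(sc)
  sens <- get_channel(g$stack, "sensor", frame = 1)
  core1 <- tensimetry:::ellipsoid_field(dim(sens), c(7.5, 35, 34),
                                        c(3, 8, 8)) <= 1
  core2 <- tensimetry:::ellipsoid_field(dim(sens), c(7.5, 35, 72),
                                        c(3, 8, 8)) <= 1
  sens[core1 | core2] <- 1
  st <- image_stack(array(sens, c(1, 1, dim(sens))),
                    channel_roles = "sensor")
  labs <- segment_nuclei(preprocess(st, "sensor"), "sensor")
  expect_equal(max(labs[[1]]), 2L)
})

test_that("a blank frame yields zero labels, not an error", {
  st <- image_stack(array(runif(2 * 20 * 20, 0, 1e-4), c(1, 1, 2, 20, 20)),
                    channel_roles = "ne_marker")
  labs <- segment_nuclei(st, "ne_marker")
  expect_equal(max(labs[[1]]), 0L)
})

test_that("tracking links static objects and preserves nearby identities", {
  mk <- function(centres) {
    a <- array(FALSE, c(1, 60, 120))
    lab <- array(0L, c(1, 60, 120))
    for (i in seq_along(centres))
      lab[1, , ][tensimetry:::disc_mask(60, 120, centres[[i]], 6)] <- i
    lab
  }
  # static object over 10 frames -> one full-length track
  labs <- replicate(10, mk(list(c(30, 40))), simplify = FALSE)
  trk <- track_nuclei(labs)
  expect_length(trk, 1L)
  expect_equal(trk[[1]]$frames, 1:10)
  # two objects drifting slightly keep their identities
  labs2 <- list(mk(list(c(30, 40), c(30, 80))),
                mk(list(c(32, 42), c(28, 78))))
  trk2 <- track_nuclei(labs2)
  expect_length(trk2, 2L)
  for (tr in trk2) {
    expect_equal(length(tr$frames), 2L)
    expect_lt(sqrt(sum(diff(tr$centroids)^2)), 10)
  }
  # a 200-px jump is not linked: the track splits
  labs3 <- list(mk(list(c(30, 20))), mk(list(c(30, 20))),
                mk(list(c(30, 110))))
  trk3 <- track_nuclei(labs3, max_link_px = 60)
  expect_length(trk3, 2L)
  expect_equal(trk3[[1]]$frames, 1:2)
  expect_equal(trk3[[2]]$frames, 3L)
})

test_that("S and volume are recovered on noise-free nuclei", {
  g <- synth_nucleus_timelapse(single_nucleus_scene(rho = 2, noise = FALSE))
  row <- measure_single(g)
  expect_equal(row$S, 2, tolerance = 0.05 / 2)
  expect_lt(abs(row$volume_um3 / g$truth$volume_analytic[1, 1] - 1), 0.03)
  expect_false(row$degenerate_centre)
  expect_true(row$S_alt > 0)
})

test_that("S is ratiometric: invariant to scaling, 1 for uniform sensor", {
  g <- synth_nucleus_timelapse(single_nucleus_scene(rho = 2, seed = 6))
  pp <- preprocess(g$stack, "ne_marker")
  labs <- segment_nuclei(pp, "ne_marker")
  trk <- track_nuclei(labs)
  m1 <- measure_all_nuclei(g$stack, labs, trk)
  scaled <- g$stack
  si <- channel_index(scaled, "sensor")
  scaled$data[, si, , , ] <- scaled$data[, si, , , ] * 7.3
  m2 <- measure_all_nuclei(scaled, labs, trk)
  expect_equal(m2$S, m1$S, tolerance = 1e-12)
  # uniform sensor -> S = 1 and V untouched by intensity
  uni <- g$stack
  uni$data[, si, , , ] <- 0.4
  m3 <- measure_all_nuclei(uni, labs, trk)
  expect_equal(m3$S, rep(1, nrow(m3)))
  expect_equal(m3$volume_px3, m1$volume_px3)
})

test_that("S recovers the rim enrichment within 10% under realistic noise", {
  for (rho in c(1, 2)) {
    ss <- vapply(1:5, function(s) {
      g <- synth_nucleus_timelapse(single_nucleus_scene(rho = rho, seed = s))
      measure_single(g)$S
    }, numeric(1))
    expect_lt(abs(median(ss) / rho - 1), 0.1)
  }
})

test_that("QC retains compliant tracks and reports each exclusion", {
  qc <- run_qc_toy()
  expect_equal(length(unique(qc$retained$track_id)), 1L)
  expect_equal(nrow(qc$report), 3L)
  reasons <- paste(qc$report$reason, collapse = ";")
  expect_match(reasons, "too_small")
  expect_match(reasons, "border_touching")
  expect_match(reasons, "jump_exceeded")
  # an all-compliant scene is fully retained with an empty report
  g <- synth_nucleus_timelapse(single_nucleus_scene(seed = 3,
                                                    fov = c(12, 140, 140),
                                                    semi = c(4, 55, 55)))
  pp <- preprocess(g$stack, "ne_marker")
  labs <- segment_nuclei(pp, "ne_marker")
  trk <- track_nuclei(labs)
  meas <- measure_all_nuclei(g$stack, labs, trk)
  qc2 <- apply_qc(meas, labs, trk)
  expect_equal(nrow(qc2$report), 0L)
  expect_equal(nrow(qc2$retained), nrow(meas))
})

test_that("a gapped track is excluded as broken", {
  mk <- function(present) {
    lab <- array(0L, c(1, 80, 80))
    if (present) lab[1, , ][tensimetry:::disc_mask(80, 80, c(40, 40), 10)] <- 1L
    lab
  }
  labs <- list(mk(TRUE), mk(FALSE), mk(TRUE))
  trk <- track_nuclei(labs)
  st <- image_stack(array(0.5, c(3, 1, 1, 80, 80)), channel_roles = "sensor")
  meas <- measure_all_nuclei(st, labs, trk, ne_channel = "none")
  qc <- apply_qc(meas, labs, trk, min_area_px2 = 100)
  expect_equal(nrow(qc$retained), 0L)
  expect_true(all(grepl("broken_track", qc$report$reason)))
})

test_that("MIP ROI traces capture lysis onset and sensor decay", {
  sc <- synth_scene(fov_shape = c(10, 72, 72), n_frames = 10,
                    nuclei = list(nucleus_spec(c(5.5, 36, 36), c(4, 20, 20),
                                               lysis_frame = 6)),
                    noise = noise_spec(0.005, 400, 0.02), seed = 3)
  g <- synth_nucleus_timelapse(sc)
  labs <- segment_nuclei(preprocess(g$stack, "ne_marker"), "ne_marker")
  tr <- roi_traces(g$stack, labs)$traces
  expect_gt(tr$nuclear_lysis[6] - tr$nuclear_lysis[5], 0.5)
  expect_lt(tr$extranuclear_sensor[10], tr$extranuclear_sensor[5] / 2)
  expect_lt(diff(range(tr$extranuclear_sensor[1:5])), 0.02)  # flat pre-lysis
})

test_that("the 20-px rim profile peaks at the boundary crossing", {
  g <- synth_nucleus_timelapse(single_nucleus_scene(rho = 2, noise = FALSE,
                                                    fov = c(10, 72, 72),
                                                    semi = c(4, 20, 20)))
  labs <- segment_nuclei(preprocess(g$stack, "ne_marker"), "ne_marker")
  pr <- roi_traces(g$stack, labs, profile_line = c(36, 2, 36, 36))$profile
  peak_d <- pr$distance[which.max(pr$intensity)]
  expect_gt(peak_d, 11)  # rim spans ~distance 14-17 along this line
  expect_lt(peak_d, 20)
  expect_gt(max(pr$intensity), pr$intensity[1])          # above cytoplasm
  expect_gt(max(pr$intensity), tail(pr$intensity, 1))    # above nucleoplasm
  expect_error(roi_traces(g$stack, labs, profile_line = c(1, 1, 1, 1)),
               "degenerate")
})
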