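# Shared fixture builders. Everything is generated in code at test time.

# ring + k inward spur phantom on a blank field (NE-outline geometry)
make_fold_phantom <- function(k, seed = 1, n = 160, R = 55, w = 3) {
  set.seed(seed)
  img <- matrix(0, n, n)
  ctr <- c(n / 2, n / 2)
  img[tensimetry:::ring_mask(n, n, ctr, R, w)] <- 1
  if (k > 0) {
    ang <- (seq_len(k) - 1) / k * 2 * pi + runif(1, 0, 2 * pi)
    len <- runif(k, 6, 14)
    r0 <- R - w / 2
    for (j in seq_len(k)) {
      p0 <- ctr + r0 * c(sin(ang[j]), cos(ang[j]))
      dirv <- (ctr - p0) / sqrt(sum((ctr - p0)^2))
      img <- tensimetry:::stamp_segment(img, p0, p0 + len[j] * dirv)
    }
  }
  img
}

# one centred nucleus, optionally noise-free
single_nucleus_scene <- function(rho = 2, seed = 1, noise = TRUE,
                                 fov = c(16, 80, 80), semi = c(6, 26, 26)) {
  synth_scene(
    fov_shape = fov, n_frames = 1,
    nuclei = list(nucleus_spec((fov + 1) / 2, semi, rim_enrichment = rho)),
    noise = if (noise) noise_spec() else noise_spec(0, 0, 0),
    seed = seed)
}

# segment + track + measure in one go; returns the row of the largest track
measure_single <- function(gen, stack = gen$stack) {
  pp <- preprocess(stack, "ne_marker")
  labs <- segment_nuclei(pp, "ne_marker")
  trk <- track_nuclei(labs)
  meas <- measure_all_nuclei(stack, labs, trk)
  meas[which.max(meas$volume_px3), , drop = FALSE]
}

# the four-nucleus QC scene: one undersized, one border-touching, one
# jumping 200 px, one compliant
qc_toy_scene <- function(seed = 9) {
  synth_scene(
    fov_shape = c(10, 360, 360), n_frames = 2,
    nuclei = list(
      nucleus_spec(c(5.5, 70, 70), c(4, 40, 40)),
      nucleus_spec(c(5.5, 60, 306), c(4, 55, 55)),
      nucleus_spec(c(5.5, 270, 60), c(4, 55, 55), drift = c(0, 0, 200)),
      nucleus_spec(c(5.5, 150, 230), c(4, 55, 55))),
    noise = noise_spec(0.005, 400, 0.02), seed = seed)
}

run_qc_toy <- function(seed = 9) {
  g <- synth_nucleus_timelapse(qc_toy_scene(seed))
  pp <- preprocess(g$stack, "ne_marker")
  labs <- segment_nuclei(pp, "ne_marker")
  trk <- track_nuclei(labs, max_link_px = 500)
  meas <- measure_all_nuclei(g$stack, labs, trk)
  apply_qc(meas, labs, trk)
}
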