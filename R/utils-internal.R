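# Internal numeric helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Shift an array along one axis with replicated borders.
shift_axis <- function(x, k, axis) {
  d <- dim(x)
  idx <- pmin(pmax(seq_len(d[axis]) + k, 1L), d[axis])
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# Separable Gaussian blur for 2-D or 3-D arrays (replicate-border).
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  w <- gauss_kernel(sigma)
  r <- (length(w) - 1L) / 2L
  for (axis in seq_along(d)) {
    if (d[axis] == 1L) next
    acc <- array(0, d)
    for (k in -r:r) acc <- acc + w[k + r + 1L] * shift_axis(x, k, axis)
    x <- acc
  }
  x
}

# Percentile-clipped min-max rescaling to [0, 1].
percentile_rescale <- function(x, lo = 0.005, hi = 0.995) {
  qs <- quantile(x, c(lo, hi), names = FALSE)
  if (qs[2] <= qs[1]) stop("channel has no intensity range to normalize")
  y <- (x - qs[1]) / (qs[2] - qs[1])
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}

# Otsu automatic threshold on the pooled intensity histogram (via EBImage;
# values are flattened so multi-frame arrays yield one global threshold).
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[1])
  vs <- (v - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(matrix(vs, ncol = 1L)),
                       range = c(0, 1), levels = 256L)
  thr * (rng[2] - rng[1]) + rng[1]
}

# Triangle threshold: maximise the distance between the histogram and the
# chord from its mode to its far tail. Suits strongly skewed ridge responses.
triangle_threshold <- function(x, breaks = 256L) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(rng[1])
  h <- tabulate(pmin(breaks, 1L + floor((x - rng[1]) / (rng[2] - rng[1]) * breaks)),
                nbins = breaks)
  peak <- which.max(h)
  nz <- which(h > 0)
  far <- if ((max(nz) - peak) >= (peak - min(nz))) max(nz) else min(nz)
  if (far == peak) return(rng[1])
  span <- seq(peak, far)
  # distance from points (i, h[i]) to the chord peak->far
  vx <- far - peak
  vy <- h[far] - h[peak]
  dist <- abs(vx * (h[span] - h[peak]) - vy * (span - peak)) / sqrt(vx^2 + vy^2)
  cut <- span[which.max(dist)]
  rng[1] + (cut - 0.5) / breaks * (rng[2] - rng[1])
}

# 3-D connected components; 2-D matrices are treated as single-slice volumes.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  m <- mask
  if (length(d) == 2L) {
    dim(m) <- c(d, 1L)
    connectivity <- if (connectivity >= 8L) 26L else 6L
  }
  lab <- cpp_label_components(as.logical(m) & !is.na(m), as.integer(connectivity))
  dim(lab) <- d
  lab
}

marker_watershed <- function(intensity, markers, mask, connectivity = 26L) {
  d <- dim(intensity)
  i2 <- intensity; m2 <- markers; k2 <- mask
  if (length(d) == 2L) {
    dim(i2) <- c(d, 1L); dim(m2) <- c(d, 1L); dim(k2) <- c(d, 1L)
    connectivity <- if (connectivity >= 8L) 26L else 6L
  }
  lab <- cpp_watershed(i2, as.integer(m2), as.logical(k2),
                       as.integer(connectivity))
  dim(lab) <- d
  lab
}

# Fill 2-D holes slice-by-slice in a (z, y, x) binary volume.
fill_holes_slices <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[1])) {
    sl <- matrix(mask[z, , ], d[2], d[3])
    out[z, , ] <- EBImage::fillHull(sl) > 0
  }
  out
}

# Binary boundary of a 2-D mask (pixels of the mask with a background
# 8-neighbour or on the image edge).
boundary_2d <- function(mask) {
  er <- EBImage::erode(mask * 1, EBImage::makeBrush(3L, "box")) > 0
  mask & !er
}

dilate_2d <- function(mask, width) {
  if (width <= 1) return(mask)
  b <- EBImage::makeBrush(as.integer(width) + (as.integer(width) %% 2L == 0L),
                          "box")
  EBImage::dilate(mask * 1, b) > 0
}

# Crofton perimeter estimator (4 directions) via 2x2 pixel-configuration
# counts; the LUT is the standard integral-geometry one (Rivollier 2010).
crofton_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  q <- matrix(0L, nr + 3L, nc + 3L)
  q[3:(nr + 2L), 3:(nc + 2L)] <- as.integer(mask > 0)
  a <- q[2:(nr + 3L), 2:(nc + 3L)]   # (i, j)
  b <- q[1:(nr + 2L), 2:(nc + 3L)]   # (i-1, j)
  cc <- q[2:(nr + 3L), 1:(nc + 2L)]  # (i, j-1)
  d <- q[1:(nr + 2L), 1:(nc + 2L)]   # (i-1, j-1)
  code <- a + 2L * b + 4L * cc + 8L * d
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

# Centroids (z, y, x) and voxel counts of a 3-D label volume.
label_stats_3d <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(), z = numeric(), y = numeric(),
                      x = numeric(), voxels = integer()))
  d <- dim(labels)
  lab <- labels[idx]
  i1 <- ((idx - 1L) %% d[1]) + 1L
  i2 <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  i3 <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  agg <- rowsum(cbind(z = i1, y = i2, x = i3, n = 1), lab)
  labs <- as.integer(rownames(agg))
  data.frame(label = labs, z = agg[, "z"] / agg[, "n"],
             y = agg[, "y"] / agg[, "n"], x = agg[, "x"] / agg[, "n"],
             voxels = as.integer(agg[, "n"]))
}

# Disk and ring rasterizers used by generators and contour measurements.
disc_mask <- function(nrow, ncol, centre, radius) {
  yy <- matrix(seq_len(nrow), nrow, ncol)
  xx <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (yy - centre[1])^2 + (xx - centre[2])^2 <= radius^2
}

ring_mask <- function(nrow, ncol, centre, radius, width) {
  yy <- matrix(seq_len(nrow), nrow, ncol)
  xx <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  d <- sqrt((yy - centre[1])^2 + (xx - centre[2])^2)
  abs(d - radius) <= width / 2
}

med <- function(x) median(x, na.rm = TRUE)
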