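#' Specify a synthetic ER scene
#'
#' The ER is rendered either as a connected tubular network (a random-walk
#' skeleton dilated to `tube_radius`), as disjoint spherical vesicles, or as
#' a mixture in which a fraction `phi` of the tube length has been converted
#' into vesicles. Vesicle positions and the walk are drawn once per scene,
#' and the `phi` schedule reuses them, so a `phi` sweep is nested: the tube
#' shrinks monotonically and the vesicle set grows monotonically (largest
#' vesicle first), giving a ground truth whose largest-object area is
#' non-increasing and whose mean circularity is non-decreasing in `phi`.
#'
#' @param mode `"network"`, `"vesicles"` or `"mixture"`.
#' @param phi vesiculation fraction in `[0, 1]`; scalar, or one value per
#'   frame for a time-lapse sweep.
#' @param tube_radius tube radius in pixels.
#' @param n_vesicles vesicle count at `phi = 1`.
#' @param vesicle_radius `(min, max)` vesicle radius range in pixels.
#' @param walk_steps length of the random-walk skeleton (steps of ~2 px).
#' @return an `ERSpec` list.
#' @export
er_spec <- function(mode = c("network", "vesicles", "mixture"), phi = 0,
                    tube_radius = 2, n_vesicles = 20,
                    vesicle_radius = c(4, 7), walk_steps = 500) {
  mode <- match.arg(mode)
  stopifnot(all(phi >= 0), all(phi <= 1), tube_radius > 0, n_vesicles >= 0,
            length(vesicle_radius) == 2L, walk_steps >= 2)
  structure(list(mode = mode, phi = phi, tube_radius = tube_radius,
                 n_vesicles = as.integer(n_vesicles),
                 vesicle_radius = vesicle_radius,
                 walk_steps = as.integer(walk_steps)),
            class = "ERSpec")
}

# In-plane-biased random walk confined to the central z slab and a lateral
# margin; returned as a walk_steps x 3 matrix of (z, y, x) positions.
er_random_walk <- function(dims, steps, margin) {
  zmid <- (dims[1] + 1) / 2
  pos <- matrix(0, steps, 3)
  pos[1, ] <- c(zmid, dims[2] / 2, dims[3] / 2)
  step_len <- 2
  ang <- runif(1, 0, 2 * pi)
  for (s in 2:steps) {
    ang <- ang + rnorm(1, 0, 0.6)
    dz <- rnorm(1, 0, 0.2)
    p <- pos[s - 1, ] + c(dz, step_len * sin(ang), step_len * cos(ang))
    # reflect off the allowed box
    lo <- c(max(1, zmid - 2), margin, margin)
    hi <- c(min(dims[1], zmid + 2), dims[2] - margin, dims[3] - margin)
    for (k in 1:3) {
      if (p[k] < lo[k]) { p[k] <- lo[k] + (lo[k] - p[k]); ang <- ang + pi / 2 }
      if (p[k] > hi[k]) { p[k] <- hi[k] - (p[k] - hi[k]); ang <- ang + pi / 2 }
    }
    pos[s, ] <- p
  }
  pos
}

stamp_balls <- function(mask, centres, radius) {
  dims <- dim(mask)
  r <- ceiling(radius)
  for (i in seq_len(nrow(centres))) {
    c0 <- centres[i, ]
    zr <- max(1, floor(c0[1] - r)):min(dims[1], ceiling(c0[1] + r))
    yr <- max(1, floor(c0[2] - r)):min(dims[2], ceiling(c0[2] + r))
    xr <- max(1, floor(c0[3] - r)):min(dims[3], ceiling(c0[3] + r))
    sub <- expand.grid(z = zr, y = yr, x = xr)
    keep <- (sub$z - c0[1])^2 + (sub$y - c0[2])^2 + (sub$x - c0[3])^2 <=
      radius^2
    idx <- cbind(sub$z, sub$y, sub$x)[keep, , drop = FALSE]
    mask[idx] <- TRUE
  }
  mask
}

place_vesicles <- function(dims, n, radius_range, forbidden, margin) {
  # largest-first so a growing prefix has a constant maximum area
  radii <- sort(runif(n, radius_range[1], radius_range[2]), decreasing = TRUE)
  centres <- matrix(0, 0, 3)
  zmid <- (dims[1] + 1) / 2
  tries <- 0L
  while (nrow(centres) < n && tries < 4000L) {
    tries <- tries + 1L
    r <- radii[nrow(centres) + 1L]
    p <- c(zmid, runif(1, margin + r, dims[2] - margin - r),
           runif(1, margin + r, dims[3] - margin - r))
    ok <- TRUE
    if (nrow(centres)) {
      prev_r <- radii[seq_len(nrow(centres))]
      dd <- sqrt(colSums((t(centres) - p)^2))
      if (any(dd < prev_r + r + 4)) ok <- FALSE
    }
    if (ok && nrow(forbidden)) {
      dd2 <- sqrt(colSums((t(forbidden) - p)^2))
      if (any(dd2 < r + 6)) ok <- FALSE
    }
    if (ok) centres <- rbind(centres, p)
  }
  list(centres = centres, radii = radii[seq_len(nrow(centres))])
}

#' Generate a synthetic ER stack with ground truth
#'
#' Both luminal (filled) and membrane (shell) renderings are produced as two
#' channels (`er_lumen`, `er_membrane`). Ground truth records, per frame, the
#' clean label volume, per-object mid-plane area/circularity measured on the
#' noise-free mask, and the analytic radius/area/circularity of each rendered
#' vesicle.
#'
#' @param scene a [synth_scene()]; `scene$er` configures the ER and
#'   `length(scene$er$phi)` frames are rendered (overriding `n_frames` when
#'   `phi` is a vector).
#' @return `list(stack = ImageStack, truth = GroundTruth)`.
#' @export
synth_er_scene <- function(scene) {
  stopifnot(inherits(scene, "SynthScene"))
  er <- scene$er
  dims <- scene$fov_shape
  phis <- switch(er$mode,
                 network = rep(0, max(1, scene$n_frames)),
                 vesicles = rep(1, max(1, scene$n_frames)),
                 mixture = er$phi)
  nt <- length(phis)
  with_seed(scene$seed, {
    margin <- 6
    path <- er_random_walk(dims, er$walk_steps, margin)
    # pure-vesicle scenes render no tube, so nothing constrains placement
    forbidden <- if (er$mode == "vesicles") matrix(0, 0, 3) else path
    ves <- place_vesicles(dims, er$n_vesicles, er$vesicle_radius, forbidden,
                          margin)
    arr <- array(0, c(nt, 2L, dims))
    labels <- vector("list", nt)
    objects <- vector("list", nt)
    for (f in seq_len(nt)) {
      phi <- phis[f]
      mask <- array(FALSE, dims)
      keep_steps <- if (er$mode == "vesicles") 0L
                    else max(0L, round((1 - phi) * er$walk_steps))
      if (keep_steps >= 2L)
        mask <- stamp_balls(mask, path[seq_len(keep_steps), , drop = FALSE],
                            er$tube_radius)
      n_ves <- if (er$mode == "network") 0L else round(phi * nrow(ves$centres))
      if (n_ves > 0L) for (i in seq_len(n_ves))
        mask <- stamp_balls(mask, ves$centres[i, , drop = FALSE],
                            ves$radii[i])
      lab <- label_components(mask, 26L)
      labels[[f]] <- lab
      # clean-mask mid-plane metrics as measurement-free ground truth
      zmid <- round((dims[1] + 1) / 2)
      sl <- matrix(lab[zmid, , ], dims[2], dims[3])
      objs <- data.frame(object_id = integer(), area_px2 = numeric(),
                         circularity = numeric())
      sl2 <- label_components(sl > 0, 8L)
      for (o in seq_len(max(sl2))) {
        m <- sl2 == o
        a <- sum(m)
        p <- crofton_perimeter(m)
        objs <- rbind(objs, data.frame(object_id = o, area_px2 = a,
                                       circularity = min(4 * pi * a / p^2,
                                                         1.05)))
      }
      objects[[f]] <- objs
      lumen <- mask * 1
      shell <- array(0, dims)
      for (z in seq_len(dims[1])) {
        m2 <- matrix(mask[z, , ], dims[2], dims[3])
        if (any(m2)) shell[z, , ] <- boundary_2d(m2) * 1
      }
      arr[f, 1, , , ] <- lumen
      arr[f, 2, , , ] <- shell
    }
    arr <- apply_scene_noise(arr, scene$noise)
    stack <- image_stack(arr, voxel_size = scene$voxel_size,
                         time_interval = scene$time_interval,
                         channel_roles = c("er_lumen", "er_membrane"))
    truth <- list(labels = labels, objects = objects, phi = phis,
                  vesicles = data.frame(radius = ves$radii,
                                        area = pi * ves$radii^2,
                                        circularity = rep(1,
                                                          length(ves$radii))),
                  n_vesicles_placed = nrow(ves$centres))
    list(stack = stack, truth = truth)
  })
}
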