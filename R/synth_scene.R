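#' Specify one synthetic nucleus
#'
#' Nuclei are rendered as ellipsoidal shells (the NE marker) around a
#' nucleoplasm, with the tension-sensor channel at intensity `I0` in the
#' nucleoplasm and `rim_enrichment * I0` on the shell, so the ratiometric
#' signal S of a noise-free nucleus equals `rim_enrichment` by construction.
#'
#' @param centre `(z, y, x)` centre in pixels (frame 1).
#' @param semi_axes `(az, ay, ax)` ellipsoid semi-axes in pixels.
#' @param rim_width shell thickness in pixels.
#' @param rim_enrichment rim:nucleoplasm sensor ratio, >= 0.
#' @param fold_spurs number of inward NE ridges rendered on the mid-plane;
#'   each produces exactly one skeleton junction, giving a countable truth.
#' @param drift per-frame displacement: either a `(dz, dy, dx)` step applied
#'   every frame, or an `n_frames x 3` matrix of absolute offsets.
#' @param volume_scale scalar or per-frame vector of volume scale factors
#'   (semi-axes scale with its cube root).
#' @param lysis_frame frame at which the cell lyses (`NA` = never): the lysis
#'   dye floods the nucleus and the cytoplasmic sensor signal decays.
#' @return a `NucleusSpec` list.
#' @export
nucleus_spec <- function(centre, semi_axes, rim_width = 3, rim_enrichment = 2,
                         fold_spurs = 0, drift = c(0, 0, 0), volume_scale = 1,
                         lysis_frame = NA) {
  stopifnot(length(centre) == 3L, length(semi_axes) == 3L,
            all(semi_axes > 0), rim_width > 0, rim_enrichment >= 0,
            fold_spurs >= 0)
  structure(list(centre = as.numeric(centre),
                 semi_axes = as.numeric(semi_axes),
                 rim_width = rim_width, rim_enrichment = rim_enrichment,
                 fold_spurs = as.integer(fold_spurs), drift = drift,
                 volume_scale = volume_scale, lysis_frame = lysis_frame),
            class = "NucleusSpec")
}

#' Noise model for synthetic stacks
#'
#' Poisson shot noise on the scaled signal, additive Gaussian read noise and
#' a planar background gradient — the components the preprocessing stage
#' (percentile rescaling, Gaussian blur, rolling-ball subtraction, median
#' contour statistics) is designed to be robust against.
#'
#' @param gaussian_sd additive Gaussian sd (intensity units).
#' @param poisson_scale photon scale: signal `s` is replaced by
#'   `Pois(s * poisson_scale) / poisson_scale`; `0` disables shot noise.
#' @param background_amp amplitude of a planar (y + x) background gradient.
#' @return a `NoiseSpec` list.
#' @export
noise_spec <- function(gaussian_sd = 0.01, poisson_scale = 400,
                       background_amp = 0.05) {
  stopifnot(gaussian_sd >= 0, poisson_scale >= 0, background_amp >= 0)
  list(gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
       background_amp = background_amp)
}

#' Specify a synthetic scene
#'
#' @param fov_shape `(z, y, x)` field-of-view size in pixels.
#' @param n_frames number of time points.
#' @param nuclei list of [nucleus_spec()] entries.
#' @param er an [er_spec()] (used by [synth_er_scene()]).
#' @param noise a [noise_spec()].
#' @param voxel_size `(dz, dy, dx)` in µm.
#' @param time_interval frame spacing.
#' @param seed integer seed; identical seeds give identical stacks.
#' @return a `SynthScene` list.
#' @export
synth_scene <- function(fov_shape = c(16, 96, 96), n_frames = 1,
                        nuclei = list(), er = er_spec(), noise = noise_spec(),
                        voxel_size = c(1, 1, 1), time_interval = 1, seed = 1) {
  stopifnot(length(fov_shape) == 3L, all(fov_shape >= 1), n_frames >= 1)
  structure(list(fov_shape = as.integer(fov_shape),
                 n_frames = as.integer(n_frames), nuclei = nuclei, er = er,
                 noise = noise, voxel_size = voxel_size,
                 time_interval = time_interval, seed = as.integer(seed)),
            class = "SynthScene")
}

nucleus_offsets <- function(spec, n_frames) {
  if (is.matrix(spec$drift)) {
    stopifnot(nrow(spec$drift) == n_frames, ncol(spec$drift) == 3L)
    return(spec$drift)
  }
  outer(seq_len(n_frames) - 1L, as.numeric(spec$drift))
}

ellipsoid_field <- function(dims, centre, semi_axes) {
  z <- (seq_len(dims[1]) - centre[1]) / semi_axes[1]
  y <- (seq_len(dims[2]) - centre[2]) / semi_axes[2]
  x <- (seq_len(dims[3]) - centre[3]) / semi_axes[3]
  u <- array(0, dims)
  u <- u + array(z^2, dims)
  u <- u + array(rep(y^2, each = dims[1]), dims)
  u <- u + array(rep(x^2, each = dims[1] * dims[2]), dims)
  u
}

# stamp a smooth capsule (distance-to-segment) ridge into a slice
stamp_segment <- function(slice, p0, p1, half_width = 1.5, value = 1) {
  ny <- nrow(slice); nx <- ncol(slice)
  lo <- pmax(floor(pmin(p0, p1)) - 3, 1)
  hi <- pmin(ceiling(pmax(p0, p1)) + 3, c(ny, nx))
  ys <- lo[1]:hi[1]; xs <- lo[2]:hi[2]
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  v <- p1 - p0
  vv <- sum(v^2)
  t <- if (vv > 0) pmin(pmax(((yy - p0[1]) * v[1] + (xx - p0[2]) * v[2]) / vv,
                             0), 1) else 0
  dist <- sqrt((yy - p0[1] - t * v[1])^2 + (xx - p0[2] - t * v[2])^2)
  sub <- slice[ys, xs]
  sub[dist <= half_width] <- value
  slice[ys, xs] <- sub
  slice
}

render_fold_spurs <- function(ne_slice, centre_yx, radii_yx, k, rng_jitter) {
  lengths <- runif(k, 6, 15)
  angles <- (seq_len(k) - 1L) / k * 2 * pi + rng_jitter
  for (j in seq_len(k)) {
    u <- c(sin(angles[j]), cos(angles[j]))
    p0 <- centre_yx + radii_yx * u
    dir <- centre_yx - p0
    dir <- dir / sqrt(sum(dir^2))
    ne_slice <- stamp_segment(ne_slice, p0 + 2 * dir * -1,
                              p0 + lengths[j] * dir)
  }
  ne_slice
}

apply_scene_noise <- function(arr, noise) {
  d <- dim(arr)
  if (noise$poisson_scale > 0)
    arr[] <- rpois(length(arr), pmax(arr, 0) * noise$poisson_scale) /
      noise$poisson_scale
  if (noise$gaussian_sd > 0)
    arr[] <- arr + rnorm(length(arr), 0, noise$gaussian_sd)
  if (noise$background_amp > 0) {
    ny <- d[4]; nx <- d[5]
    g <- outer(seq_len(ny) / ny, seq_len(nx) / nx, `+`) / 2 *
      noise$background_amp
    arr <- arr + aperm(array(g, c(ny, nx, d[1], d[2], d[3])), c(3, 4, 5, 1, 2))
  }
  arr[arr < 0] <- 0
  arr
}

#' Generate a synthetic nucleus time-lapse with ground truth
#'
#' Renders the NE-marker and sensor channels (plus a lysis-dye channel when
#' any nucleus has a `lysis_frame`) for every frame of the scene, applies
#' motion/volume schedules, fold spurs, lysis dynamics and finally the noise
#' model. The ground truth carries per-frame label volumes (stable ids),
#' analytic and voxelized volumes, true rim enrichments, fold counts, and
#' per-frame displacements.
#'
#' @param scene a [synth_scene()] with at least one nucleus.
#' @return `list(stack = ImageStack, truth = GroundTruth)`.
#' @export
synth_nucleus_timelapse <- function(scene) {
  stopifnot(inherits(scene, "SynthScene"), length(scene$nuclei) >= 1L)
  dims <- scene$fov_shape
  nt <- scene$n_frames
  nk <- length(scene$nuclei)
  any_lysis <- any(vapply(scene$nuclei, function(s) !is.na(s$lysis_frame),
                          logical(1)))
  nchan <- if (any_lysis) 3L else 2L
  with_seed(scene$seed, {
    jitter <- runif(nk, 0, 2 * pi)
    spur_seeds <- sample.int(1e6, nk)
    arr <- array(0, c(nt, nchan, dims))
    labels <- vector("list", nt)
    vol_vox <- matrix(0, nt, nk)
    vol_analytic <- matrix(0, nt, nk)
    disp <- matrix(0, nt, nk)
    border <- logical(nk)
    I0 <- 0.5
    cyto0 <- 0.15
    first_lysis <- suppressWarnings(min(vapply(scene$nuclei, function(s)
      ifelse(is.na(s$lysis_frame), Inf, s$lysis_frame), numeric(1))))
    for (f in seq_len(nt)) {
      ne <- array(0, dims)
      cyto_decay <- if (is.finite(first_lysis) && f >= first_lysis)
        exp(-0.7 * (f - first_lysis + 1)) else 1
      sens <- array(cyto0 * cyto_decay, dims)
      lys <- array(0, dims)
      lab <- array(0L, dims)
      for (i in seq_len(nk)) {
        sp <- scene$nuclei[[i]]
        off <- nucleus_offsets(sp, nt)
        ctr <- sp$centre + off[f, ]
        if (f > 1) disp[f, i] <- sqrt(sum((off[f, ] - off[f - 1, ])^2))
        vs <- if (length(sp$volume_scale) == 1L) sp$volume_scale
              else sp$volume_scale[f]
        ax <- sp$semi_axes * vs^(1 / 3)
        u <- ellipsoid_field(dims, ctr, ax)
        solid <- u <= 1
        ax_in <- pmax(ax - sp$rim_width, 0.5)
        inner <- ellipsoid_field(dims, ctr, ax_in) <= 1
        shell <- solid & !inner
        ne[shell] <- 1
        ne[inner] <- 0.08   # nucleoplasmic marker background (keeps S_alt finite)
        sens[inner] <- I0
        sens[shell] <- sp$rim_enrichment * I0
        lab[solid] <- i
        vol_vox[f, i] <- sum(solid)
        vol_analytic[f, i] <- 4 / 3 * pi * prod(ax)
        if (any(solid[, c(1, dims[2]), ]) || any(solid[, , c(1, dims[3])]))
          border[i] <- TRUE
        if (sp$fold_spurs > 0) {
          zmid <- round(ctr[1])
          if (zmid >= 1 && zmid <= dims[1]) {
            sl <- matrix(ne[zmid, , ], dims[2], dims[3])
            with_seed(spur_seeds[i], {
              # spurs start at the inner shell boundary so their whole
              # length protrudes into the nucleoplasm (one junction each)
              sl <- render_fold_spurs(sl, ctr[2:3], ax[2:3] - sp$rim_width,
                                      sp$fold_spurs, jitter[i])
            })
            ne[zmid, , ] <- sl
          }
        }
        if (!is.na(sp$lysis_frame) && f >= sp$lysis_frame) lys[solid] <- 0.8
      }
      arr[f, 1, , , ] <- ne
      arr[f, 2, , , ] <- sens
      if (any_lysis) arr[f, 3, , , ] <- lys
      labels[[f]] <- lab
    }
    arr <- apply_scene_noise(arr, scene$noise)
    roles <- c("ne_marker", "sensor", if (any_lysis) "lysis_dye")
    stack <- image_stack(arr, voxel_size = scene$voxel_size,
                         time_interval = scene$time_interval,
                         channel_roles = roles)
    truth <- list(labels = labels,
                  volume_voxels = vol_vox,
                  volume_analytic = vol_analytic,
                  rim_enrichment = vapply(scene$nuclei,
                                          `[[`, numeric(1), "rim_enrichment"),
                  fold_counts = vapply(scene$nuclei, `[[`, integer(1),
                                       "fold_spurs"),
                  displacements = disp,
                  border_touching = border,
                  jump_exceeded = apply(disp > 130, 2, any),
                  lysis_frames = vapply(scene$nuclei, function(s)
                    as.numeric(s$lysis_frame), numeric(1)))
    list(stack = stack, truth = truth)
  })
}
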