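#' Packaged GUV titration presets
#'
#' Two generating presets used throughout the tests, whose true parameters
#' follow the reported apparent affinities of the two tension sensors on
#' stretched GUV membranes: the ARFGAP1 ALPS1-2 domain in hypotonic binding
#' buffer (`K_d' = 150` nM) and the cPLA2 C2 domain at 20 µM free calcium
#' (`K_d' = 20` nM), a roughly eightfold affinity difference. Each preset
#' carries the eight titration concentrations (0-500 nM) and the
#' per-concentration GUV replicate counts of the corresponding buffer.
#'
#' @return named list of presets, each with `B_max`, `K_d`, `H`,
#'   `concentrations` (nM) and `n_per_conc`.
#' @export
guv_presets <- function() {
  concs <- c(0, 25, 50, 100, 200, 300, 400, 500)
  list(
    "alps-hypotonic" = list(B_max = 1, K_d = 150, H = 1,
                            concentrations = concs,
                            n_per_conc = c(47, 14, 28, 57, 61, 87, 89, 74)),
    "c2-ca20" = list(B_max = 1, K_d = 20, H = 1,
                     concentrations = concs,
                     n_per_conc = c(41, 28, 39, 54, 73, 86, 73, 64))
  )
}

#' Hill-expanded Langmuir adsorption isotherm
#'
#' `B(c) = B_max * c^H / (c^H + K_d^H)`: `B(0) = 0`, `B(K_d) = B_max / 2`
#' for any Hill coefficient, and `B` increases monotonically to the `B_max`
#' asymptote.
#'
#' @param conc concentration(s), same unit as `K_d` (nM throughout).
#' @param B_max saturation binding.
#' @param K_d apparent dissociation constant.
#' @param H apparent Hill coefficient.
#' @return predicted bound fraction(s).
#' @export
hill_langmuir <- function(conc, B_max, K_d, H) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  ch <- conc^H
  ifelse(conc == 0, 0, B_max * ch / (ch + K_d^H))
}

#' Generate a synthetic GUV titration
#'
#' Per GUV, the true rim binding follows the Hill-Langmuir isotherm at its
#' concentration; the observed value carries multiplicative Gaussian noise
#' `B * (1 + eps)`, `eps ~ N(0, noise_cv)`, emulating vesicle-to-vesicle
#' variability.
#'
#' @param concs concentrations in nM.
#' @param n_per_conc replicate GUVs per concentration (recycled if scalar).
#' @param params list with `B_max`, `K_d`, `H` (e.g. a [guv_presets()]
#'   entry).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return `list(measurements, truth)`: `measurements` is a data frame with
#'   `guv_id`, `concentration`, `true_binding`, `binding`.
#' @export
synth_guv_titration <- function(concs = guv_presets()[[1]]$concentrations,
                                n_per_conc = guv_presets()[[1]]$n_per_conc,
                                params = guv_presets()[["alps-hypotonic"]],
                                noise_cv = 0.15, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (any(concs < 0)) stop("concentrations must be non-negative")
  stopifnot(params$B_max > 0, params$K_d > 0, params$H > 0)
  n_per_conc <- rep_len(n_per_conc, length(concs))
  with_seed(seed, {
    conc <- rep(concs, n_per_conc)
    true_b <- hill_langmuir(conc, params$B_max, params$K_d, params$H)
    obs <- true_b * (1 + rnorm(length(conc), 0, noise_cv))
    meas <- data.frame(guv_id = seq_along(conc), concentration = conc,
                       true_binding = true_b, binding = obs)
    list(measurements = meas,
         truth = list(B_max = params$B_max, K_d = params$K_d, H = params$H))
  })
}

#' Render a single synthetic GUV image
#'
#' A spherical shell: the membrane-dye channel has constant rim intensity and
#' the protein channel carries `rim_value` on the same shell, over a faint
#' background.
#'
#' @param fov_shape `(z, y, x)` in px.
#' @param centre `(z, y, x)` sphere centre; defaults to the FOV centre.
#' @param radius sphere radius in px.
#' @param rim_value protein rim intensity.
#' @param rim_width shell thickness in px.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return an [image_stack()] with `guv_membrane` and `protein` channels.
#' @export
synth_guv_image <- function(fov_shape = c(13, 96, 96), centre = NULL,
                            radius = 25, rim_value = 0.5, rim_width = 3,
                            noise = noise_spec(gaussian_sd = 0.005,
                                               poisson_scale = 1000,
                                               background_amp = 0),
                            seed = 1) {
  dims <- as.integer(fov_shape)
  if (is.null(centre)) centre <- (dims + 1) / 2
  with_seed(seed, {
    u <- ellipsoid_field(dims, centre, rep(radius, 3))
    u_in <- ellipsoid_field(dims, centre, rep(radius - rim_width, 3))
    shell <- (u <= 1) & (u_in > 1)
    arr <- array(0, c(1L, 2L, dims))
    mem <- array(0.02, dims); mem[shell] <- 1
    pro <- array(0.02, dims); pro[shell] <- pmax(rim_value, 0.02)
    arr[1, 1, , , ] <- mem
    arr[1, 2, , , ] <- pro
    arr <- apply_scene_noise(arr, noise)
    image_stack(arr, channel_roles = c("guv_membrane", "protein"))
  })
}

#' Generate a synthetic FLIP experiment
#'
#' Two-pool model of repeated photobleaching: the bleach-site pool is zeroed
#' at every bleach frame, after which the measured (opposite-site) pool
#' exchanges a fraction `exchange_rate` of its difference with the bleach
#' pool per cycle when the compartments are connected — so under continuous
#' bleaching the measured pool obeys `m_k = (1 - r)^k`. Disconnected
#' compartments evolve independently and the measured pool stays at
#' baseline. A non-bleached control cell stays at baseline throughout.
#'
#' @param connected logical: are the bleached and measured compartments
#'   diffusionally connected?
#' @param n_frames number of frames (frame 1 is the pre-bleach baseline).
#' @param bleach_frames frames at which a bleach event occurs.
#' @param exchange_rate per-cycle exchange fraction in `[0, 1]`.
#' @param noise_sd additive Gaussian noise on the traces.
#' @param seed integer seed.
#' @param render if `TRUE`, additionally render an image time series (two
#'   cells; the bleach spot inside the target cell) for the ROI pipeline.
#' @param fov_shape rendered FOV `(z, y, x)`, single plane by default.
#' @return `list(traces, truth)` and, when rendered, `stack`,
#'   `bleach_centre` (y, x), `nucleus_labels` (2-D, target = 1, control = 2).
#' @export
synth_flip_experiment <- function(connected = TRUE, n_frames = 25,
                                  bleach_frames = 2:n_frames,
                                  exchange_rate = 0.3, noise_sd = 0.02,
                                  seed = 1, render = FALSE,
                                  fov_shape = c(1, 96, 160)) {
  stopifnot(exchange_rate >= 0, exchange_rate <= 1)
  with_seed(seed, {
    b <- 1; m <- 1
    bt <- mt <- numeric(n_frames)
    bt[1] <- b; mt[1] <- m
    for (f in 2:n_frames) {
      if (f %in% bleach_frames) b <- 0
      if (connected) {
        m_new <- (1 - exchange_rate) * m + exchange_rate * b
        b_new <- (1 - exchange_rate) * b + exchange_rate * m
        m <- m_new; b <- b_new
      }
      bt[f] <- b; mt[f] <- m
    }
    traces <- data.frame(
      frame = seq_len(n_frames),
      bleach_site = pmax(bt + rnorm(n_frames, 0, noise_sd), 0),
      median_axis_site = pmax((bt + mt) / 2 + rnorm(n_frames, 0, noise_sd), 0),
      opposite_site = pmax(mt + rnorm(n_frames, 0, noise_sd), 0),
      nuclear_mask = pmax(mt + rnorm(n_frames, 0, noise_sd), 0),
      control_cell = pmax(1 + rnorm(n_frames, 0, noise_sd), 0))
    truth <- list(connected = connected, exchange_rate = exchange_rate,
                  bleach_schedule = sort(intersect(bleach_frames,
                                                   seq_len(n_frames))),
                  final_measured = mt[n_frames], pool_measured = mt,
                  pool_bleach = bt)
    out <- list(traces = traces, truth = truth)
    if (render) {
      dims <- as.integer(fov_shape)
      ny <- dims[2]; nx <- dims[3]
      target_c <- c(ny / 2, nx * 0.3)
      ctrl_c <- c(ny / 2, nx * 0.78)
      cell_r <- min(ny, nx) * 0.28
      nuc_r <- cell_r * 0.45
      bleach_centre <- target_c + c(0, cell_r * 0.75)
      cell1 <- disc_mask(ny, nx, target_c, cell_r)
      nuc1 <- disc_mask(ny, nx, target_c, nuc_r)
      cell2 <- disc_mask(ny, nx, ctrl_c, cell_r)
      nuc2 <- disc_mask(ny, nx, ctrl_c, nuc_r)
      spot <- disc_mask(ny, nx, bleach_centre, cell_r * 0.35)
      arr <- array(0, c(n_frames, 1L, dims))
      for (f in seq_len(n_frames)) {
        img <- matrix(0.01, ny, nx)
        img[cell1] <- mt[f]
        img[cell1 & spot] <- bt[f]
        img[cell2] <- 1
        for (z in seq_len(dims[1])) arr[f, 1, z, , ] <- img
      }
      arr <- apply_scene_noise(arr, noise_spec(gaussian_sd = noise_sd,
                                               poisson_scale = 0,
                                               background_amp = 0))
      nucleus_labels <- matrix(0L, ny, nx)
      nucleus_labels[nuc1] <- 1L
      nucleus_labels[nuc2] <- 2L
      out$stack <- image_stack(arr, voxel_size = c(1, 0.18, 0.18),
                               channel_roles = "er_lumen")
      out$bleach_centre <- bleach_centre
      out$nucleus_labels <- nucleus_labels
    }
    out
  })
}
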