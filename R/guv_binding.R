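#' Crop a GUV from a stack using a user line
#'
#' The user draws a line from the GUV centre to its edge; the crop window is
#' a square of side `crop_factor * line length` centred on the line origin
#' (clipped to the image), which guarantees margin around the rim.
#'
#' @param stack an [image_stack()].
#' @param user_line `(y0, x0, y1, x1)` centre-to-edge segment, in px.
#' @param crop_factor window side in units of the line length.
#' @return the cropped [image_stack()].
#' @export
extract_guv <- function(stack, user_line, crop_factor = 2.4) {
  stopifnot(length(user_line) == 4L)
  d <- dim(stack$data)
  p0 <- user_line[1:2]; p1 <- user_line[3:4]
  if (any(c(p0, p1) < 1) || p0[1] > d[4] || p1[1] > d[4] || p0[2] > d[5] ||
      p1[2] > d[5])
    stop("user line endpoints must lie inside the image")
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop("user line is degenerate (zero length)")
  half <- crop_factor * len / 2
  ys <- max(1L, floor(p0[1] - half)):min(d[4], ceiling(p0[1] + half))
  xs <- max(1L, floor(p0[2] - half)):min(d[5], ceiling(p0[2] + half))
  sub <- stack$data[, , , ys, xs, drop = FALSE]
  image_stack(sub, voxel_size = stack$voxel_size,
              time_interval = stack$time_interval,
              channel_roles = stack$channel_roles,
              condition = stack$condition)
}

#' Measure GUV rim binding
#'
#' The membrane channel of the crop is preprocessed (intensity
#' normalization, 3-D Gaussian blur of 3-px radius) and segmented per slice
#' by automated threshold + hole filling; the slice with the largest
#' segmented GUV area is the middle section. A 3-px-wide contour centred on
#' the GUV boundary of that slice is transferred to the protein channel and
#' the rim binding is the median protein intensity along it, normalized by
#' `reference_signal` (the fluorescence of a 1 µM protein solution).
#'
#' @param cropped an [extract_guv()] output with `guv_membrane` and
#'   `protein` channels.
#' @param reference_signal positive normalization scalar.
#' @param frame frame to measure.
#' @param config an [analysis_config()] (`guv_gaussian_radius_px`,
#'   `contour_width_px`).
#' @return a `GUVMeasurement` data frame row: `rim_median`,
#'   `normalized_binding`, `mid_slice`, `found` (FALSE when no GUV was
#'   segmented in the crop; measurements are then `NA`).
#' @export
guv_rim_binding <- function(cropped, reference_signal, frame = 1L,
                            config = analysis_config()) {
  stopifnot(reference_signal > 0)
  mem_i <- channel_index(cropped, "guv_membrane")
  pro_i <- channel_index(cropped, "protein")
  pre <- preprocess(cropped, mem_i,
                    gaussian_radius_px = config$guv_gaussian_radius_px,
                    rollball_radius_px = 0)
  x <- get_channel(pre, mem_i, frame = frame)
  d <- dim(x)
  thr <- otsu_threshold(x)
  ring <- x > thr
  areas <- vapply(seq_len(d[1]), function(z) sum(ring[z, , ]), numeric(1))
  if (all(areas == 0))
    return(data.frame(rim_median = NA_real_, normalized_binding = NA_real_,
                      mid_slice = NA_integer_, found = FALSE))
  mid <- which.max(areas)
  sl <- matrix(x[mid, , ], d[2], d[3])
  # per-slice marker-controlled watershed: seeds at the crop centre (the
  # user line starts at the GUV centre) and at the crop border flood the
  # intensity landscape, so the region boundary forms on the rim crest
  markers <- matrix(0L, d[2], d[3])
  ctr <- round(c(d[2], d[3]) / 2)
  markers[disc_mask(d[2], d[3], ctr, max(2, min(d[2:3]) * 0.05))] <- 1L
  markers[1, ] <- 2L; markers[d[2], ] <- 2L
  markers[, 1] <- 2L; markers[, d[3]] <- 2L
  seg <- marker_watershed(-sl, markers, matrix(TRUE, d[2], d[3]), 8L)
  m2d <- seg == 1L
  band <- dilate_2d(boundary_2d(m2d), config$contour_width_px)
  # a real GUV shows a bright rim on the membrane channel along the contour;
  # without that contrast the crop holds no vesicle and is flagged
  if (!any(m2d) || !any(band) ||
      med(sl[band]) - med(sl) < 0.2 * diff(range(sl)))
    return(data.frame(rim_median = NA_real_, normalized_binding = NA_real_,
                      mid_slice = mid, found = FALSE))
  pro <- get_channel(cropped, pro_i, frame = frame)
  rim <- med(matrix(pro[mid, , ], d[2], d[3])[band])
  data.frame(rim_median = rim, normalized_binding = rim / reference_signal,
             mid_slice = mid, found = TRUE)
}

#' Fit the Hill-expanded Langmuir adsorption isotherm
#'
#' Bounded nonlinear least squares of
#' `B_bound(c) = B_max * c^H / (c^H + K_d'^H)` on per-GUV measurements
#' (unweighted). Initialization: `B_max` from the maximum per-concentration
#' mean, `K_d'` from the interpolated half-maximum concentration, `H = 1`.
#' Bounds: `B_max, K_d' > 0`, `H` in `[hill_lower, hill_upper]`. 95%
#' confidence intervals come from the parameter covariance.
#'
#' @param measurements data frame with `concentration` (nM) and `binding`
#'   columns (e.g. from [synth_guv_titration()] or assembled
#'   [guv_rim_binding()] outputs).
#' @param config an [analysis_config()] (Hill bounds).
#' @return an `IsothermFit` list: `B_max`, `K_d`, `H`, `se`, `ci` (2x3
#'   matrix), `rss`, `converged`, `n`, and the `fit` object when converged.
#' @export
fit_isotherm <- function(measurements, config = analysis_config()) {
  stopifnot(all(c("concentration", "binding") %in% names(measurements)))
  concs <- unique(measurements$concentration)
  if (length(concs) < 4L)
    stop("isotherm fitting requires at least 4 distinct concentrations")
  df <- data.frame(conc = measurements$concentration,
                   b = measurements$binding)
  means <- tapply(df$b, df$conc, mean)
  cs <- as.numeric(names(means))
  b_max0 <- max(means)
  fail <- function() list(B_max = NA_real_, K_d = NA_real_, H = NA_real_,
                          se = rep(NA_real_, 3), ci = NULL, rss = NA_real_,
                          converged = FALSE, n = nrow(df))
  if (!is.finite(b_max0) || b_max0 <= 0) return(fail())
  half <- b_max0 / 2
  above <- which(means >= half)
  kd0 <- if (length(above)) {
    i <- min(above)
    if (i == 1) max(cs[1], 1) else {
      # linear interpolation between the bracketing concentrations
      c0 <- cs[i - 1]; c1 <- cs[i]
      b0 <- means[i - 1]; b1 <- means[i]
      c0 + (half - b0) / (b1 - b0) * (c1 - c0)
    }
  } else max(cs)
  kd0 <- max(kd0, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      b ~ B_max * conc^H / (conc^H + K_d^H), data = df,
      start = list(B_max = b_max0, K_d = kd0, H = 1),
      lower = c(1e-9, 1e-9, config$hill_lower),
      upper = c(Inf, Inf, config$hill_upper),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  ci <- rbind(lower = est - 1.959964 * se, upper = est + 1.959964 * se)
  list(B_max = unname(est["B_max"]), K_d = unname(est["K_d"]),
       H = unname(est["H"]), se = se, ci = ci,
       rss = sum(stats::resid(fit)^2), converged = TRUE, n = nrow(df),
       fit = fit)
}

#' Predict binding from a fitted isotherm
#'
#' @param fit an [fit_isotherm()] result (must have converged).
#' @param concentration concentration(s) in nM, non-negative.
#' @return predicted `B_bound`.
#' @export
isotherm_predict <- function(fit, concentration) {
  if (!isTRUE(fit$converged)) stop("isotherm fit did not converge")
  if (any(concentration < 0)) stop("concentration must be non-negative")
  hill_langmuir(concentration, fit$B_max, fit$K_d, fit$H)
}
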