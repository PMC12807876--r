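#' Circularity shape metric
#'
#' `Circularity = 4 * pi * Area / Perimeter^2`: 1 for a perfect circle,
#' approaching 0 for highly elongated objects. With analytic inputs the
#' isoperimetric inequality bounds it at 1; rasterized measurements may
#' slightly exceed 1 and are conventionally clipped at `clip`.
#'
#' @param area object area.
#' @param perimeter object perimeter (same length unit).
#' @param clip upper clip for rasterization overshoot (`Inf` disables).
#' @return dimensionless circularity.
#' @export
circularity <- function(area, perimeter, clip = Inf) {
  stopifnot(all(perimeter > 0), all(area >= 0))
  pmin(4 * pi * area / perimeter^2, clip)
}

# maxima of the (further smoothed) channel above the coarse threshold,
# merged by single-linkage at merge_dist so plateau/ridge maxima seed one
# marker; the extra smoothing keeps shot noise from seeding spurious basins
er_markers <- function(x, coarse, merge_dist, marker_sigma = 2) {
  d <- dim(x)
  xs <- gauss_blur(x, marker_sigma)
  mx <- xs
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sh <- shift_axis(shift_axis(shift_axis(xs, dz, 1), dy, 2), dx, 3)
    mx <- pmax(mx, sh)
  }
  peaks <- which(coarse & xs >= mx)
  if (length(peaks) == 0) return(array(0L, d))
  i1 <- ((peaks - 1L) %% d[1]) + 1L
  i2 <- (((peaks - 1L) %/% d[1]) %% d[2]) + 1L
  i3 <- ((peaks - 1L) %/% (d[1] * d[2])) + 1L
  pts <- cbind(i1, i2, i3)
  cl <- if (nrow(pts) == 1L) 1L else {
    hc <- stats::hclust(stats::dist(pts), method = "single")
    stats::cutree(hc, h = merge_dist)
  }
  markers <- array(0L, d)
  markers[peaks] <- as.integer(cl)
  markers
}

#' Segment the endoplasmic reticulum
#'
#' Luminal mode (e.g. KDEL labelling): coarse automated threshold on the
#' preprocessed channel, watershed from merged local-maxima markers,
#' constrained to the coarse mask. Membrane mode (e.g. SEC61B): Hessian
#' ridge (filament) filter at scale `thickness`, automatic threshold on the
#' response, connected-component labels. Components are 26-connected in 3-D.
#'
#' @param stack an [image_stack()]; the channel is preprocessed internally
#'   (intensity normalization + 3-D Gaussian blur radius 1, no rolling
#'   ball).
#' @param channel channel role (`"er_lumen"` or `"er_membrane"` typically).
#' @param mode `"luminal"` or `"membrane"`.
#' @param config an [analysis_config()] (`filament_thickness`,
#'   `marker_merge_dist_px`, `connectivity_3d`).
#' @return list of per-frame integer label volumes.
#' @export
segment_er <- function(stack, channel, mode = c("luminal", "membrane"),
                       config = analysis_config()) {
  mode <- match.arg(mode)
  if (max(get_channel(stack, channel)) <= 0) {
    d <- dim(stack$data)
    return(lapply(seq_len(d[1]), function(f) array(0L, d[3:5])))
  }
  stack <- preprocess(stack, channel,
                      gaussian_radius_px = config$gaussian_radius_px,
                      rollball_radius_px = 0)
  conn <- as.integer(config$connectivity_3d)
  lapply(seq_len(n_frames(stack)), function(f) {
    x <- get_channel(stack, channel, frame = f)
    if (max(x) <= 0) return(array(0L, dim(x)))
    if (mode == "luminal") {
      thr <- otsu_threshold(x)
      coarse <- x > thr
      if (!any(coarse)) return(array(0L, dim(x)))
      markers <- er_markers(x, coarse, config$marker_merge_dist_px)
      marker_watershed(x, markers, coarse, conn)
    } else {
      resp <- array(0, dim(x))
      for (z in seq_len(dim(x)[1])) {
        sl <- matrix(x[z, , ], dim(x)[2], dim(x)[3])
        if (max(sl) > min(sl))
          resp[z, , ] <- ridge_response_2d(sl, config$filament_thickness)
      }
      if (max(resp) <= 0) return(array(0L, dim(x)))
      thr <- otsu_threshold(resp[resp > 0])
      label_components(resp > thr, conn)
    }
  })
}

#' Per-object ER metrics on the representative mid-section
#'
#' The mid-section is the z slice with the largest total segmented area
#' (ties to the lower index). Each 2-D 8-connected object on that slice is
#' measured: area as pixel count (and µm^2), perimeter with the Crofton
#' estimator, circularity clipped at 1.05 for rasterization overshoot.
#' Objects below the small-object cutoff are dropped.
#'
#' @param labels one frame's 3-D label volume.
#' @param cutoff_px2 small-object cutoff in px^2 (published range 30-50).
#' @param voxel_size `(dz, dy, dx)` in µm for the µm^2 conversion.
#' @return data frame of `ERObject` rows: `object_id`, `area_px2`,
#'   `area_um2`, `perimeter_px`, `circularity`, plus attribute `mid_slice`.
#' @export
er_object_metrics <- function(labels, cutoff_px2 = 40,
                              voxel_size = c(1, 1, 1)) {
  d <- dim(labels)
  areas <- vapply(seq_len(d[1]), function(z) sum(labels[z, , ] > 0),
                  numeric(1))
  if (all(areas == 0)) {
    out <- data.frame(object_id = integer(), area_px2 = numeric(),
                      area_um2 = numeric(), perimeter_px = numeric(),
                      circularity = numeric())
    attr(out, "mid_slice") <- NA_integer_
    return(out)
  }
  mid <- which.max(areas)
  sl <- matrix(labels[mid, , ] > 0, d[2], d[3])
  obj <- label_components(sl, 8L)
  px_area_um2 <- voxel_size[2] * voxel_size[3]
  rows <- lapply(seq_len(max(obj)), function(o) {
    m <- obj == o
    a <- sum(m)
    if (a < cutoff_px2) return(NULL)
    p <- crofton_perimeter(m)
    data.frame(object_id = o, area_px2 = a, area_um2 = a * px_area_um2,
               perimeter_px = p,
               circularity = circularity(a, p, clip = 1.05))
  })
  out <- do.call(rbind, c(rows, list(data.frame(object_id = integer(),
                                                area_px2 = numeric(),
                                                area_um2 = numeric(),
                                                perimeter_px = numeric(),
                                                circularity = numeric()))))
  attr(out, "mid_slice") <- mid
  out
}

#' Per-FOV ER summary series
#'
#' One largest-object area and one unweighted mean circularity per frame —
#' ER metrics are summarized per field of view, with no single-cell
#' attribution. Frames with zero retained objects carry `NA` metrics and an
#' `empty` flag.
#'
#' @param objects_per_frame list of [er_object_metrics()] outputs.
#' @return `ERFovSummary` data frame: `frame`, `n_objects`,
#'   `largest_object_area`, `mean_circularity`, `empty`.
#' @export
er_fov_summary <- function(objects_per_frame) {
  stopifnot(length(objects_per_frame) >= 1)
  do.call(rbind, lapply(seq_along(objects_per_frame), function(f) {
    ob <- objects_per_frame[[f]]
    n <- nrow(ob)
    data.frame(frame = f, n_objects = n,
               largest_object_area = if (n) max(ob$area_px2) else NA_real_,
               mean_circularity = if (n) mean(ob$circularity) else NA_real_,
               empty = n == 0)
  }))
}

#' Normalize an ER summary series
#'
#' `to_t0` divides each frame's metrics by the frame-0 value of the same
#' FOV, so the normalized baseline is exactly 1 (circularity then ranges
#' upward from 1 as vesiculation increases). `to_control` divides by the
#' mean of a control-condition summary (e.g. isosmotic).
#'
#' @param summary an [er_fov_summary()] data frame.
#' @param scheme `"to_t0"` or `"to_control"`.
#' @param control control summary (required for `to_control`).
#' @return the summary with `normalized_area` and `normalized_circularity`
#'   columns added.
#' @export
normalize_er_series <- function(summary, scheme = c("to_t0", "to_control"),
                                control = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "to_t0") {
    base_a <- summary$largest_object_area[1]
    base_c <- summary$mean_circularity[1]
    if (!is.finite(base_a) || base_a == 0 || !is.finite(base_c) ||
        base_c == 0)
      stop("zero or undefined baseline at frame 0 for this FOV")
    summary$normalized_area <- summary$largest_object_area / base_a
    summary$normalized_circularity <- summary$mean_circularity / base_c
  } else {
    if (is.null(control)) stop("scheme 'to_control' requires a control")
    base_a <- mean(control$largest_object_area, na.rm = TRUE)
    base_c <- mean(control$mean_circularity, na.rm = TRUE)
    if (!is.finite(base_a) || base_a == 0 || !is.finite(base_c) ||
        base_c == 0)
      stop("control summary has a zero or undefined mean")
    summary$normalized_area <- summary$largest_object_area / base_a
    summary$normalized_circularity <- summary$mean_circularity / base_c
  }
  attr(summary, "normalization") <- scheme
  summary
}
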