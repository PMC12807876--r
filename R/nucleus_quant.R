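#' Preprocess one channel of a stack
#'
#' Applies, per frame: percentile-clipped (0.5/99.5) min-max intensity
#' normalization to `[0, 1]`, a 3-D Gaussian blur, and per-slice rolling-ball
#' background subtraction (grayscale opening with a flat structuring element
#' of the given radius). Output intensities are within `[0, 1]`.
#'
#' @param stack an [image_stack()].
#' @param channel channel role (or index) to preprocess.
#' @param gaussian_radius_px Gaussian sigma in px.
#' @param rollball_radius_px rolling-ball radius in px; `0` disables
#'   background subtraction.
#' @return the stack with that channel replaced by its preprocessed version.
#' @export
preprocess <- function(stack, channel, gaussian_radius_px = 1,
                       rollball_radius_px = 50) {
  for (f in seq_len(n_frames(stack))) {
    x <- get_channel(stack, channel, frame = f)
    if (max(x) <= 0) stop("channel '", channel, "' is constant zero")
    x <- percentile_rescale(x)
    x <- gauss_blur(x, gaussian_radius_px)
    if (rollball_radius_px > 0) {
      r <- as.integer(rollball_radius_px)
      for (z in seq_len(dim(x)[1])) {
        sl <- matrix(x[z, , ], dim(x)[2], dim(x)[3])
        bg <- cpp_rect_filter(cpp_rect_filter(sl, r, FALSE), r, TRUE)
        x[z, , ] <- pmax(sl - bg, 0)
      }
    }
    x[x > 1] <- 1
    stack <- set_channel(stack, channel, x, frame = f)
  }
  stack
}

# Masked-object thresholding: a global automated threshold yields coarse
# components; within each, a stricter local threshold re-segments the bright
# object (NE shell or nucleoplasmic core), holes are closed slice-wise, and
# the local objects seed the watershed over the refined mask.
segment_volume <- function(x, connectivity = 26L, min_voxels = 60L,
                           min_marker_voxels = 20L, marker_merge_px = 10) {
  thr <- otsu_threshold(x)
  coarse <- fill_holes_slices(x > thr)
  cc <- label_components(coarse, connectivity)
  if (max(cc) == 0) return(array(0L, dim(x)))
  keep <- which(tabulate(cc[cc > 0]) >= min_voxels)
  if (length(keep) == 0) return(array(0L, dim(x)))
  markers <- array(0L, dim(x))
  refined <- array(FALSE, dim(x))
  next_lab <- 0L
  for (comp in keep) {
    inside <- cc == comp
    thr2 <- otsu_threshold(x[inside])
    obj <- inside & (x > thr2)
    if (!any(obj)) obj <- inside
    refined <- refined | obj
    sub <- label_components(obj, connectivity)
    sizes <- tabulate(sub[sub > 0])
    good <- which(sizes >= min_marker_voxels)
    if (length(good) == 0) good <- which.max(sizes)
    # a marker-fragmented object (e.g. top/bottom caps of one NE shell)
    # stays one nucleus: merge marker pieces whose centroids are close
    cl <- if (length(good) > 1L) {
      cent <- t(vapply(good, function(g) {
        idx <- which(sub == g)
        d <- dim(x)
        i1 <- ((idx - 1L) %% d[1]) + 1L
        i2 <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
        i3 <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
        c(mean(i1), mean(i2), mean(i3))
      }, numeric(3)))
      stats::cutree(stats::hclust(stats::dist(cent), method = "single"),
                    h = marker_merge_px)
    } else rep(1L, length(good))
    for (u in unique(cl)) {
      next_lab <- next_lab + 1L
      for (g in good[cl == u]) markers[sub == g] <- next_lab
    }
  }
  marker_watershed(x, markers, fill_holes_slices(refined), connectivity)
}

#' Segment nuclei in 3-D
#'
#' Masked-object thresholding (global automated threshold for the coarse
#' foreground, then a stricter per-component threshold to derive one marker
#' per nucleus) followed by a marker-controlled watershed over the smoothed
#' intensity, constrained to the coarse mask. Labels are 26-connected in 3-D
#' and non-overlapping. Nucleoplasmic holes behind a rim-only marker (NE
#' labelling) are closed slice-wise before component analysis.
#'
#' @param stack a preprocessed [image_stack()] (see [preprocess()]).
#' @param channel segmentation channel role (NE marker, or the sensor when no
#'   NE marker is expressed).
#' @param config an [analysis_config()].
#' @param min_voxels smallest 3-D component treated as a candidate nucleus
#'   (suppresses noise specks; far below the published per-slice size
#'   exclusion, which [apply_qc()] enforces separately).
#' @return list of integer `(z, y, x)` label volumes, one per frame; an empty
#'   frame yields an all-zero volume.
#' @export
segment_nuclei <- function(stack, channel = "ne_marker",
                           config = analysis_config(), min_voxels = 500L) {
  lapply(seq_len(n_frames(stack)), function(f) {
    x <- get_channel(stack, channel, frame = f)
    if (max(x) <= 0) return(array(0L, dim(x)))
    segment_volume(x, as.integer(config$connectivity_3d),
                   min_voxels = min_voxels)
  })
}

#' Track segmented nuclei over time
#'
#' Greedy mutual-nearest-neighbour linking of frame-to-frame label centroids.
#' A link whose displacement exceeds `max_link_px` is not made; unlinked
#' objects start or end tracks. No gap closing is attempted (broken tracks
#' are discarded downstream by QC).
#'
#' @param labels list of per-frame label volumes from [segment_nuclei()].
#' @param max_link_px maximum link distance in px.
#' @return list of track skeletons: `track_id`, `frames`, `labels` (per-frame
#'   label id), `centroids` (rows of `(z, y, x)`), with attribute `n_frames`.
#' @export
track_nuclei <- function(labels, max_link_px = 130) {
  nt <- length(labels)
  stopifnot(nt >= 1)
  stats <- lapply(labels, label_stats_3d)
  tracks <- list()
  open <- list()   # track index by current label id
  for (lab in stats[[1]]$label) {
    tracks[[length(tracks) + 1L]] <-
      list(frames = 1L, labels = lab,
           centroids = as.matrix(stats[[1]][stats[[1]]$label == lab,
                                            c("z", "y", "x")]))
    open[[as.character(lab)]] <- length(tracks)
  }
  for (f in seq_len(nt - 1L)) {
    a <- stats[[f]]; b <- stats[[f + 1L]]
    links <- integer(0)
    if (nrow(a) && nrow(b)) {
      D <- outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j)
        sqrt(sum((unlist(a[i, c("z", "y", "x")]) -
                    unlist(b[j, c("z", "y", "x")]))^2))))
      used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
      repeat {
        D2 <- D
        D2[used_a, ] <- Inf; D2[, used_b] <- Inf
        if (all(!is.finite(D2)) || min(D2) > max_link_px) break
        ij <- arrayInd(which.min(D2), dim(D2))
        i <- ij[1]; j <- ij[2]
        used_a[i] <- TRUE; used_b[j] <- TRUE
        links <- c(links, setNames(b$label[j], a$label[i]))
      }
    }
    new_open <- list()
    for (i in seq_len(nrow(b))) {
      blab <- b$label[i]
      src <- if (length(links)) names(links)[match(blab, links)]
             else NA_character_
      ctr <- as.matrix(b[i, c("z", "y", "x")])
      if (length(src) == 1L && !is.na(src) && !is.null(open[[src]])) {
        ti <- open[[src]]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f + 1L)
        tracks[[ti]]$labels <- c(tracks[[ti]]$labels, blab)
        tracks[[ti]]$centroids <- rbind(tracks[[ti]]$centroids, ctr)
        new_open[[as.character(blab)]] <- ti
      } else {
        tracks[[length(tracks) + 1L]] <-
          list(frames = f + 1L, labels = blab, centroids = ctr)
        new_open[[as.character(blab)]] <- length(tracks)
      }
    }
    open <- new_open
  }
  for (i in seq_along(tracks)) tracks[[i]]$track_id <- i
  attr(tracks, "n_frames") <- nt
  tracks
}

contour_masks <- function(mask2d, contour_width, centre_ring_fraction) {
  bnd <- boundary_2d(mask2d)
  membrane <- dilate_2d(bnd, contour_width)
  idx <- which(mask2d, arr.ind = TRUE)
  ctr <- colMeans(idx)
  area <- nrow(idx)
  r_eq <- sqrt(area / pi)
  ring <- ring_mask(nrow(mask2d), ncol(mask2d), ctr, centre_ring_fraction *
                      r_eq, contour_width)
  list(membrane = membrane, ring = ring, centre = ctr, area = area)
}

#' Measure a tracked nucleus
#'
#' Per retained frame: volume as the voxel sum of the label (px^3 and µm^3
#' via the voxel size); the representative mid-slice as the z plane with the
#' largest label area (ties to the lower index); the ratiometric signal
#' `S` = median sensor intensity on a 3-px membrane contour (boundary +/- 1
#' px) divided by the median on a 3-px background ring at
#' `centre_ring_fraction` of the equivalent radius around the centroid; and
#' the alternative ratio `S_alt` dividing the membrane-contour sensor median
#' by the NE-marker median over the whole mid-slice label.
#'
#' @param stack the (raw or preprocessed) [image_stack()].
#' @param labels per-frame label volumes.
#' @param track one track from [track_nuclei()].
#' @param sensor_channel,ne_channel channel roles.
#' @param config an [analysis_config()] (contour width and ring fraction).
#' @return data frame, one row per track frame, with volume, mid-slice,
#'   mid-slice area, `S`, `S_alt` and a `degenerate_centre` flag (background
#'   median zero, `S` undefined).
#' @export
measure_nucleus <- function(stack, labels, track, sensor_channel = "sensor",
                            ne_channel = "ne_marker",
                            config = analysis_config()) {
  vox <- prod(stack$voxel_size)
  has_ne <- ne_channel %in% stack$channel_roles
  out <- lapply(seq_along(track$frames), function(k) {
    f <- track$frames[k]
    lab <- track$labels[k]
    vol <- labels[[f]] == lab
    v_px <- sum(vol)
    areas <- apply(vol, 1, sum)
    mid <- which.max(areas)   # ties -> lower index
    m2d <- matrix(vol[mid, , ], dim(vol)[2], dim(vol)[3])
    cm <- contour_masks(m2d, config$contour_width_px,
                        config$centre_ring_fraction)
    sens <- get_channel(stack, sensor_channel, frame = f)
    s2d <- matrix(sens[mid, , ], dim(vol)[2], dim(vol)[3])
    mem_med <- med(s2d[cm$membrane])
    ring_med <- med(s2d[cm$ring])
    degenerate <- !is.finite(ring_med) || ring_med == 0
    s_alt <- NA_real_
    if (has_ne) {
      ne2d <- matrix(get_channel(stack, ne_channel, frame = f)[mid, , ],
                     dim(vol)[2], dim(vol)[3])
      ne_med <- med(ne2d[m2d])
      if (is.finite(ne_med) && ne_med > 0) s_alt <- mem_med / ne_med
    }
    data.frame(track_id = track$track_id, frame = f, label = lab,
               centroid_z = track$centroids[k, 1],
               centroid_y = track$centroids[k, 2],
               centroid_x = track$centroids[k, 3],
               volume_px3 = v_px, volume_um3 = v_px * vox,
               mid_slice = mid, area_mid_px2 = cm$area,
               S = if (degenerate) NA_real_ else mem_med / ring_med,
               S_alt = s_alt, degenerate_centre = degenerate)
  })
  do.call(rbind, out)
}

#' Measure all tracks of a stack
#'
#' @inheritParams measure_nucleus
#' @param tracks output of [track_nuclei()].
#' @return combined per-track-frame data frame (see [measure_nucleus()]).
#' @export
measure_all_nuclei <- function(stack, labels, tracks,
                               sensor_channel = "sensor",
                               ne_channel = "ne_marker",
                               config = analysis_config()) {
  out <- lapply(tracks, function(tr)
    measure_nucleus(stack, labels, tr, sensor_channel, ne_channel, config))
  res <- do.call(rbind, out)
  attr(res, "n_frames") <- attr(tracks, "n_frames")
  res
}

touches_border <- function(vol) {
  d <- dim(vol)
  any(vol[, c(1, d[2]), ]) || any(vol[, , c(1, d[3])])
}

#' Apply the published QC exclusions
#'
#' A track is retained only if no flag is ever raised: mid-slice area at or
#' above the size threshold on every frame, never touching the lateral image
#' border, no frame-to-frame displacement above the jump threshold, and an
#' unbroken track covering every frame of the movie. The report lists every
#' excluded track with its reasons.
#'
#' @param measurements output of [measure_all_nuclei()].
#' @param labels per-frame label volumes.
#' @param tracks output of [track_nuclei()].
#' @param min_area_px2 mid-slice area threshold (px^2).
#' @param max_jump_px displacement threshold (px).
#' @return `list(retained, report, flags)`: `retained` are the surviving
#'   measurement rows, `report` has one row per excluded track
#'   (`track_id`, `reason`), `flags` the full per-track QC table.
#' @export
apply_qc <- function(measurements, labels, tracks, min_area_px2 = 8000,
                     max_jump_px = 130) {
  nt <- attr(tracks, "n_frames")
  flags <- do.call(rbind, lapply(tracks, function(tr) {
    rows <- measurements[measurements$track_id == tr$track_id, , drop = FALSE]
    too_small <- any(rows$area_mid_px2 < min_area_px2)
    border <- any(vapply(seq_along(tr$frames), function(k)
      touches_border(labels[[tr$frames[k]]] == tr$labels[k]), logical(1)))
    disp <- if (length(tr$frames) > 1)
      sqrt(rowSums(diff(tr$centroids)^2)) else numeric(0)
    jump <- any(disp > max_jump_px)
    broken <- (nt > 1) && (length(tr$frames) < nt ||
                             any(diff(tr$frames) != 1L))
    leakage <- any(rows$degenerate_centre)
    data.frame(track_id = tr$track_id, too_small = too_small,
               border_touching = border, jump_exceeded = jump,
               broken_track = broken, marker_leakage = leakage)
  }))
  flag_cols <- c("too_small", "border_touching", "jump_exceeded",
                 "broken_track", "marker_leakage")
  excluded <- flags[rowSums(flags[, flag_cols]) > 0, , drop = FALSE]
  report <- data.frame(
    track_id = excluded$track_id,
    reason = vapply(seq_len(nrow(excluded)), function(i)
      paste(flag_cols[unlist(excluded[i, flag_cols])], collapse = ","),
      character(1)))
  keep <- flags$track_id[rowSums(flags[, flag_cols]) == 0]
  list(retained = measurements[measurements$track_id %in% keep, ,
                               drop = FALSE],
       report = report, flags = flags)
}

bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 1), ny); x <- pmin(pmax(x, 1), nx)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- pmin(y0 + 1, ny); x1 <- pmin(x0 + 1, nx)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x1)] * (1 - fy) * fx +
    img[cbind(y1, x1)] * fy * fx
}

#' Maximum-intensity-projection ROI traces and rim line profile
#'
#' Computed on per-frame MIPs: the intranuclear ROI is the projected label
#' mask, the extranuclear ROI is the projection minus the dilated labels.
#' Returns the nuclear lysis-dye trace, the extranuclear sensor trace and,
#' when a profile line is supplied, the mean rim profile across a 20-px-wide
#' band along it.
#'
#' @param stack an [image_stack()] with sensor (and optionally lysis-dye)
#'   channels.
#' @param labels per-frame label volumes.
#' @param profile_line optional `(y0, x0, y1, x1)` polyline endpoint pair for
#'   the rim profile, measured on the sensor mid-plane slice (the z plane
#'   with the largest projected label area) of `profile_frame`.
#' @param profile_frame frame for the rim profile.
#' @param band_width_px rim profile band width.
#' @param dilate_px dilation separating intra- and extranuclear ROIs.
#' @return list with `traces` (per-frame data frame) and optional `profile`
#'   (distance, intensity).
#' @export
roi_traces <- function(stack, labels, profile_line = NULL, profile_frame = 1L,
                       band_width_px = 20, dilate_px = 5) {
  has_lysis <- "lysis_dye" %in% stack$channel_roles
  if (!"sensor" %in% stack$channel_roles)
    stop("stack has no channel with role 'sensor'")
  nt <- n_frames(stack)
  traces <- do.call(rbind, lapply(seq_len(nt), function(f) {
    sens <- get_channel(stack, "sensor", frame = f)
    mip_s <- apply(sens, c(2, 3), max)
    mask <- apply(labels[[f]] > 0, c(2, 3), any)
    outer_m <- !dilate_2d(mask, 2 * dilate_px + 1)
    lys_val <- NA_real_
    if (has_lysis) {
      mip_l <- apply(get_channel(stack, "lysis_dye", frame = f), c(2, 3), max)
      lys_val <- mean(mip_l[mask])
    }
    data.frame(frame = f, nuclear_lysis = lys_val,
               extranuclear_sensor = mean(mip_s[outer_m]),
               nuclear_area_px2 = sum(mask))
  }))
  out <- list(traces = traces)
  if (!is.null(profile_line)) {
    stopifnot(length(profile_line) == 4L)
    p0 <- profile_line[1:2]; p1 <- profile_line[3:4]
    L <- sqrt(sum((p1 - p0)^2))
    if (L <= 0) stop("profile line is degenerate")
    dirv <- (p1 - p0) / L
    norv <- c(-dirv[2], dirv[1])
    sens <- get_channel(stack, "sensor", frame = profile_frame)
    lab_areas <- apply(labels[[profile_frame]] > 0, 1, sum)
    zmid <- if (any(lab_areas > 0)) which.max(lab_areas)
            else ceiling(dim(sens)[1] / 2)
    mip <- matrix(sens[zmid, , ], dim(sens)[2], dim(sens)[3])
    ts <- seq(0, L, by = 1)
    offs <- seq(-(band_width_px - 1) / 2, (band_width_px - 1) / 2, by = 1)
    prof <- vapply(ts, function(t) {
      pts_y <- p0[1] + t * dirv[1] + offs * norv[1]
      pts_x <- p0[2] + t * dirv[2] + offs * norv[2]
      mean(bilinear_sample(mip, pts_y, pts_x))
    }, numeric(1))
    out$profile <- data.frame(distance = ts, intensity = prof)
  }
  out
}
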