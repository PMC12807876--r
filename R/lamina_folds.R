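#' Filament-filtered lamina outline mask
#'
#' Single-scale Hessian ridge enhancement of the NE mid-slice at scale
#' `sigma = thickness` (the bright-ridge response is the magnitude of the
#' negative leading Hessian eigenvalue of the Gaussian-smoothed image),
#' followed by an automatic hysteresis threshold on the response: strong
#' ridges are cut at the Otsu level, and weaker response connected to them
#' (above `low_fraction` of that level) is retained. Junction zones between
#' crossing membranes are plate-like and respond more weakly than clean
#' ridges; the hysteresis keeps them attached so the skeleton preserves the
#' branch topology. Only Gaussian blurring is applied beforehand — no
#' rolling-ball or intensity normalization — to preserve membrane detail.
#'
#' @param img 2-D numeric matrix (NE-marker mid-slice).
#' @param thickness ridge scale; the default 1.6 targets membranes ~3-4 px
#'   thick.
#' @param low_fraction low hysteresis level as a fraction of the Otsu cut.
#' @return logical ridge mask (empty for blank input).
#' @export
lamina_outline_mask <- function(img, thickness = 1.6, low_fraction = 0.4) {
  stopifnot(is.matrix(img))
  if (max(img) <= min(img)) return(matrix(FALSE, nrow(img), ncol(img)))
  resp <- ridge_response_2d(matrix(as.numeric(img), nrow(img), ncol(img)),
                            thickness)
  if (max(resp) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  thr <- otsu_threshold(resp[resp > 0])
  low <- resp > low_fraction * thr
  lab <- label_components(low, 8L)
  keep <- unique(lab[resp > thr & lab > 0])
  mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  # close residual 1-px gaps at shallow-angle junctions
  EBImage::closing(mask * 1, EBImage::makeBrush(3L, "box")) > 0
}

# bright-ridge (negative leading Hessian eigenvalue) response at one scale
ridge_response_2d <- function(img, sigma) {
  g <- gauss_blur(img, sigma)
  dyy <- shift_axis(g, 1, 1) - 2 * g + shift_axis(g, -1, 1)
  dxx <- shift_axis(g, 1, 2) - 2 * g + shift_axis(g, -1, 2)
  dy <- (shift_axis(g, 1, 1) - shift_axis(g, -1, 1)) / 2
  dxy <- (shift_axis(dy, 1, 2) - shift_axis(dy, -1, 2)) / 2
  disc <- sqrt(pmax((dxx - dyy)^2 + 4 * dxy^2, 0))
  pmax(-((dxx + dyy) - disc) / 2, 0) * sigma^2
}

#' Skeletonize a binary outline mask
#'
#' Morphological (Zhang-Suen) thinning to unit width, followed by a
#' simple-point minimization pass that removes the staircase corner pixels
#' thinning leaves behind — the result is a minimal 8-connected skeleton in
#' which curve pixels have exactly two neighbours, so branch points reflect
#' genuine junctions. Topology (loops, components) is preserved throughout.
#' A filled disk thins to a small central cluster rather than its outline —
#' the filter stage is expected to produce ridge masks, not filled regions.
#'
#' @param mask logical matrix.
#' @return logical 1-px skeleton.
#' @export
outline_skeleton <- function(mask) {
  stopifnot(is.matrix(mask))
  sk <- cpp_thin(matrix(as.logical(mask), nrow(mask), ncol(mask)))
  cpp_skel_minimize(sk)
}

skeleton_neighbour_count <- function(skel) {
  s <- matrix(as.numeric(skel), nrow(skel), ncol(skel))
  acc <- matrix(0, nrow(skel), ncol(skel))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    acc <- acc + shift_axis_zero(s, dy, dx)
  }
  acc
}

# zero-padded 2-D shift (replicate borders would double-count edge pixels)
shift_axis_zero <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ys <- seq_len(nr) + dy; xs <- seq_len(nc) + dx
  ok_y <- ys >= 1 & ys <= nr; ok_x <- xs >= 1 & xs <= nc
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

prune_skeleton <- function(skel, iterations) {
  for (i in seq_len(iterations)) {
    nb <- skeleton_neighbour_count(skel)
    endpoints <- skel & nb <= 1
    if (!any(endpoints)) break
    skel <- skel & !endpoints
  }
  skel
}

#' Count condensed skeleton branch points (the fold metric)
#'
#' Raw branch points are skeleton pixels whose 8-neighbourhood contains at
#' least `neighbour_threshold` skeleton pixels (the standard junction
#' definition; set 4 for the strict "more than three neighbours" reading).
#' Nearby raw points — chains of adjacent junction pixels produced by noise
#' — are merged by single-linkage clustering at `condense_radius_px`, and
#' the number of clusters is the condensed fold count.
#'
#' @param skeleton logical 1-px skeleton matrix.
#' @param neighbour_threshold minimum skeleton-neighbour count of a branch
#'   pixel.
#' @param condense_radius_px single-linkage merge radius.
#' @param prune_px endpoint-pruning iterations applied before counting
#'   (0 disables; removes sub-pixel spurs left by thinning).
#' @param reference_count optional frame-0 condensed count for
#'   `normalized_folds`.
#' @return a `FoldMetric` list: `raw_branch_points`,
#'   `condensed_branch_points`, `skeleton`, `branch_coords`,
#'   `normalized_folds`.
#' @export
fold_count <- function(skeleton, neighbour_threshold = 3,
                       condense_radius_px = 4, prune_px = 0,
                       reference_count = NULL) {
  stopifnot(is.matrix(skeleton))
  skel <- as.logical(skeleton)
  dim(skel) <- dim(skeleton)
  if (prune_px > 0) skel <- prune_skeleton(skel, prune_px)
  nb <- skeleton_neighbour_count(skel)
  raw <- skel & nb >= neighbour_threshold
  pts <- which(raw, arr.ind = TRUE)
  n_raw <- nrow(pts)
  condensed <- if (n_raw <= 1L) n_raw else {
    hc <- stats::hclust(stats::dist(pts), method = "single")
    length(unique(stats::cutree(hc, h = condense_radius_px)))
  }
  structure(list(raw_branch_points = n_raw,
                 condensed_branch_points = condensed,
                 skeleton = skel, branch_coords = pts,
                 normalized_folds = if (!is.null(reference_count) &&
                                        reference_count > 0)
                   condensed / reference_count else NA_real_),
            class = "FoldMetric")
}

#' Fold count straight from an NE mid-slice image
#'
#' Convenience wrapper chaining [lamina_outline_mask()],
#' [outline_skeleton()] and [fold_count()].
#'
#' @param img 2-D NE-marker mid-slice.
#' @param config an [analysis_config()].
#' @return a `FoldMetric` (see [fold_count()]).
#' @export
count_ne_folds <- function(img, config = analysis_config()) {
  mask <- lamina_outline_mask(img, config$filament_thickness)
  skel <- outline_skeleton(mask)
  fold_count(skel, config$branch_neighbour_threshold,
             config$condense_radius_px, config$skeleton_prune_px)
}
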