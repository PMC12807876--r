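#' Plan the FLIP ROI set
#'
#' ROI 1 sits at the bleach centre; ROI 3 diametrically opposite across the
#' centroid of the nucleus nearest the bleach site; ROI 2 at the in-plane
#' median axis (midpoint between bleach centre and nucleus centroid); the
#' control ROI (Ctr) at the centroid of a different labelled cell. All ROIs
#' are invariant (fixed) across frames. ROI diameter and bleach radius are
#' specified in µm and converted with the lateral voxel size.
#'
#' @param stack an [image_stack()] (voxel size must be set).
#' @param bleach_centre `(y, x)` bleach spot centre in px.
#' @param nucleus_labels 2-D integer label image of nuclei.
#' @param roi_diameter_um measurement ROI diameter.
#' @param bleach_radius_um bleach spot radius (recorded, not used for
#'   measurement).
#' @return a `FlipROIs` list: named list `rois` of `(y, x)` centres
#'   (`bleach_site`, `median_axis_site`, `opposite_site`, optional
#'   `control_cell`), `radius_px`, `nucleus_label`.
#' @export
plan_rois <- function(stack, bleach_centre, nucleus_labels,
                      roi_diameter_um = 5, bleach_radius_um = 2.5) {
  d <- dim(stack$data)
  if (bleach_centre[1] < 1 || bleach_centre[1] > d[4] ||
      bleach_centre[2] < 1 || bleach_centre[2] > d[5])
    stop("bleach centre lies outside the field of view")
  labs <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  if (length(labs) == 0) stop("no nucleus labels supplied")
  cents <- t(vapply(labs, function(l) {
    idx <- which(nucleus_labels == l, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))
  dists <- sqrt(rowSums((cents - matrix(bleach_centre, length(labs), 2,
                                        byrow = TRUE))^2))
  target <- which.min(dists)
  ctr <- cents[target, ]
  rois <- list(bleach_site = as.numeric(bleach_centre),
               median_axis_site = (as.numeric(bleach_centre) + ctr) / 2,
               opposite_site = 2 * ctr - as.numeric(bleach_centre))
  if (length(labs) >= 2L) {
    other <- order(dists)[2]
    rois$control_cell <- cents[other, ]
  } else {
    warning("no second cell available for the control ROI; Ctr omitted")
  }
  radius_px <- roi_diameter_um / 2 / stack$voxel_size[3]
  structure(list(rois = rois, radius_px = radius_px,
                 bleach_radius_px = bleach_radius_um / stack$voxel_size[3],
                 nucleus_label = labs[target]),
            class = "FlipROIs")
}

#' Extract FLIP traces
#'
#' Per-frame mean intensity of the ER channel inside each planned circular
#' ROI (on the maximum-intensity projection when the stack has depth), plus
#' a nuclear trace from an Otsu threshold mask of the first frame. All
#' traces are normalized to their frame-0 value.
#'
#' @param stack an [image_stack()].
#' @param rois a [plan_rois()] result.
#' @param er_channel ER channel role.
#' @param bleach_schedule frames at which bleach events occurred (stored in
#'   the experiment record).
#' @return a `FlipExperiment` list: `traces` (raw), `normalized`,
#'   `bleach_schedule`.
#' @export
extract_flip_traces <- function(stack, rois, er_channel = "er_lumen",
                                bleach_schedule = integer(0)) {
  d <- dim(stack$data)
  nt <- d[1]
  masks <- lapply(rois$rois, function(cc)
    disc_mask(d[4], d[5], cc, rois$radius_px))
  first <- apply(get_channel(stack, er_channel, frame = 1L), c(2, 3), max)
  nuc_thr <- otsu_threshold(first)
  nuc_mask <- first > nuc_thr
  traces <- do.call(rbind, lapply(seq_len(nt), function(f) {
    mip <- apply(get_channel(stack, er_channel, frame = f), c(2, 3), max)
    vals <- vapply(masks, function(m) mean(mip[m]), numeric(1))
    row <- as.data.frame(as.list(vals))
    row$nuclear_mask <- mean(mip[nuc_mask])
    row$frame <- f
    row
  }))
  value_cols <- setdiff(names(traces), "frame")
  normalized <- traces
  for (cn in value_cols) {
    base <- traces[[cn]][1]
    normalized[[cn]] <- if (is.finite(base) && base > 0)
      traces[[cn]] / base else NA_real_
  }
  structure(list(traces = traces, normalized = normalized,
                 bleach_schedule = sort(unique(bleach_schedule))),
            class = "FlipExperiment")
}

#' Summarize FLIP experiments
#'
#' Pointwise mean and t-based 95% confidence interval of the normalized
#' traces across experiments (cells). With a single experiment the mean is
#' returned and the CI omitted.
#'
#' @param experiments list of `FlipExperiment` records (or data frames of
#'   normalized traces sharing columns).
#' @param roi which trace column to summarize.
#' @return data frame `frame`, `mean`, `ci_lower`, `ci_upper`, `n`.
#' @export
summarize_flip <- function(experiments, roi = "opposite_site") {
  stopifnot(length(experiments) >= 1)
  mats <- lapply(experiments, function(e) {
    tr <- if (inherits(e, "FlipExperiment")) e$normalized else e
    tr[[roi]]
  })
  len <- unique(vapply(mats, length, integer(1)))
  stopifnot(length(len) == 1)
  m <- do.call(cbind, mats)
  n <- ncol(m)
  mu <- rowMeans(m)
  if (n < 2L)
    return(data.frame(frame = seq_len(len), mean = mu, ci_lower = NA_real_,
                      ci_upper = NA_real_, n = n))
  se <- apply(m, 1, sd) / sqrt(n)
  tq <- stats::qt(0.975, df = n - 1)
  data.frame(frame = seq_len(len), mean = mu, ci_lower = mu - tq * se,
             ci_upper = mu + tq * se, n = n)
}
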