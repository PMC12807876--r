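#' Multi-dimensional fluorescence image stack
#'
#' The canonical in-memory container of the package: a 5-axis intensity array
#' ordered `(time, channel, plane, row, column)` — i.e. `(t, c, z, y, x)` —
#' with voxel-size and channel-role metadata. All downstream operations
#' (segmentation, tracking, rim measurements) consume this container.
#'
#' @param data numeric array with 2 to 5 dimensions; missing leading axes are
#'   inserted with length 1 so that the stored array is always 5-D
#'   `(t, c, z, y, x)`. Values must be finite and non-negative.
#' @param voxel_size numeric length-3 vector `(dz, dy, dx)` in micrometres,
#'   each strictly positive. Raw pixel sizes differ per microscope, so voxel
#'   size is mandatory metadata and never guessed.
#' @param time_interval frame spacing (seconds or minutes; the unit is carried
#'   through, not interpreted).
#' @param channel_roles character vector, one role per channel, from
#'   `c("ne_marker", "sensor", "er_lumen", "er_membrane", "lysis_dye",
#'   "guv_membrane", "protein")`. Roles must be unique within a stack.
#'   `NA` marks an unassigned channel.
#' @param condition a [condition_meta()] record.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, voxel_size = c(1, 1, 1), time_interval = 1,
                        channel_roles = NULL, condition = condition_meta()) {
  d <- dim(data)
  if (is.null(d)) stop("data must be an array with 2-5 dimensions")
  if (length(d) < 2L || length(d) > 5L)
    stop("data must have between 2 and 5 dimensions")
  while (length(dim(data)) < 5L) dim(data) <- c(1L, dim(data))
  if (any(!is.finite(data))) stop("image data must be finite")
  if (any(data < 0)) stop("image data must be non-negative")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values (dz, dy, dx)")
  nc <- dim(data)[2]
  if (is.null(channel_roles)) channel_roles <- rep(NA_character_, nc)
  if (length(channel_roles) != nc)
    stop("channel_roles must have one entry per channel")
  known <- c("ne_marker", "sensor", "er_lumen", "er_membrane", "lysis_dye",
             "guv_membrane", "protein")
  bad <- setdiff(channel_roles[!is.na(channel_roles)], known)
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  assigned <- channel_roles[!is.na(channel_roles)]
  if (anyDuplicated(assigned))
    stop("duplicate channel role assignment: ",
         paste(unique(assigned[duplicated(assigned)]), collapse = ", "))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 time_interval = time_interval,
                 channel_roles = as.character(channel_roles),
                 condition = condition),
            class = "ImageStack")
}

#' Acquisition condition metadata
#'
#' @param delta_pi osmotic differential (mOsm, non-negative).
#' @param ca_conc free calcium concentration (µM, non-negative).
#' @param pvp_percent colloid (PVP360) concentration in percent.
#' @param treatment free-text treatment label (e.g. `"ML162"`).
#' @param is_baseline_control logical flag for baseline/control acquisitions.
#' @return a `ConditionMeta` list.
#' @export
condition_meta <- function(delta_pi = NA_real_, ca_conc = NA_real_,
                           pvp_percent = NA_real_, treatment = NA_character_,
                           is_baseline_control = FALSE) {
  for (v in list(delta_pi = delta_pi, ca_conc = ca_conc,
                 pvp_percent = pvp_percent)) {
    if (!is.na(v) && v < 0) stop("condition metadata must be non-negative")
  }
  structure(list(delta_pi = delta_pi, ca_conc = ca_conc,
                 pvp_percent = pvp_percent, treatment = treatment,
                 is_baseline_control = isTRUE(is_baseline_control)),
            class = "ConditionMeta")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ImageStack> t=%d c=%d z=%d y=%d x=%d\n", d[1], d[2], d[3],
              d[4], d[5]))
  cat("  voxel (dz,dy,dx) um:", paste(signif(x$voxel_size, 4), collapse = ", "),
      "\n")
  roles <- ifelse(is.na(x$channel_roles), "<unassigned>", x$channel_roles)
  cat("  channels:", paste(sprintf("%d:%s", seq_along(roles), roles),
                           collapse = "  "), "\n")
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[1]
n_channels <- function(stack) dim(stack$data)[2]

#' Locate a channel by role
#'
#' @param stack an [image_stack()].
#' @param role channel role string.
#' @return integer channel index.
#' @export
channel_index <- function(stack, role) {
  i <- which(stack$channel_roles == role)
  if (length(i) != 1L) stop("stack has no channel with role '", role, "'")
  i
}

#' Extract one channel as a (t, z, y, x) or (z, y, x) array
#'
#' @inheritParams channel_index
#' @param frame optional frame index; if given, the time axis is dropped and a
#'   `(z, y, x)` volume is returned.
#' @return numeric array.
#' @export
get_channel <- function(stack, role, frame = NULL) {
  ci <- if (is.character(role)) channel_index(stack, role) else as.integer(role)
  d <- dim(stack$data)
  if (is.null(frame)) {
    out <- stack$data[, ci, , , , drop = FALSE]
    dim(out) <- d[c(1, 3, 4, 5)]
  } else {
    out <- stack$data[frame, ci, , , , drop = FALSE]
    dim(out) <- d[c(3, 4, 5)]
  }
  out
}

set_channel <- function(stack, role, value, frame = NULL) {
  ci <- if (is.character(role)) channel_index(stack, role) else as.integer(role)
  if (is.null(frame)) stack$data[, ci, , , ] <- value
  else stack$data[frame, ci, , , ] <- value
  stack
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a TIFF / OME-TIFF image stack
#'
#' Pages are interpreted in hyperstack order (channel fastest, then plane,
#' then time). Stacks written by [write_stack()] carry a JSON sidecar with the
#' axis lengths, voxel size, channel roles and value encoding; without a
#' sidecar the pages are treated as a single-channel, single-timepoint
#' z-stack, and 2-D files are promoted with singleton axes.
#'
#' @param path path to a readable TIFF file.
#' @param role_map optional named integer vector mapping roles to channel
#'   indices, e.g. `c(er_membrane = 1, sensor = 2)`; overrides sidecar roles.
#' @param voxel_size optional `(dz, dy, dx)` in µm; overrides sidecar
#'   metadata. Required when no sidecar is present.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, role_map = NULL, voxel_size = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path, " (",
                                             conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  first <- pages[[1]]
  if (length(dim(first)) == 3L && length(pages) == 1L) {
    # single RGB-style page: samples become channels
    ny <- dim(first)[1]; nx <- dim(first)[2]; nch <- dim(first)[3]
    arr <- array(0, c(1L, nch, 1L, ny, nx))
    for (ch in seq_len(nch)) arr[1, ch, 1, , ] <- first[, , ch]
    dims <- c(1L, nch, 1L, ny, nx)
  } else {
    ny <- nrow(first); nx <- ncol(first)
    if (!is.null(meta)) {
      dims <- as.integer(meta$dim)
      if (prod(dims[1:3]) != length(pages))
        stop("sidecar page count does not match TIFF: ", path)
    } else {
      dims <- c(1L, 1L, length(pages), ny, nx)
    }
    arr <- array(0, dims)
    p <- 1L
    for (t in seq_len(dims[1])) for (z in seq_len(dims[3]))
      for (ch in seq_len(dims[2])) {
        arr[t, ch, z, , ] <- pages[[p]]
        p <- p + 1L
      }
  }
  if (!is.null(meta) && identical(meta$encoding, "float32"))
    arr <- arr * meta$scale
  if (!is.null(meta) && identical(meta$encoding, "uint16"))
    arr <- round(arr * 65535)
  roles <- NULL
  if (!is.null(meta) && !is.null(meta$channel_roles))
    roles <- as.character(meta$channel_roles)
  if (!is.null(role_map)) {
    roles <- rep(NA_character_, dims[2])
    if (anyDuplicated(names(role_map)) || anyDuplicated(role_map))
      stop("duplicate role assignment in role_map")
    roles[as.integer(role_map)] <- names(role_map)
  }
  vox <- voxel_size
  if (is.null(vox) && !is.null(meta)) vox <- as.numeric(meta$voxel_size)
  if (is.null(vox)) vox <- c(1, 1, 1)
  ti <- if (!is.null(meta) && !is.null(meta$time_interval))
    meta$time_interval else 1
  image_stack(arr, voxel_size = vox, time_interval = ti, channel_roles = roles)
}

#' Write an image stack to multipage TIFF (plus JSON sidecar)
#'
#' Integer-valued data are stored as 16-bit samples and round-trip exactly;
#' other data are stored as 32-bit float with a recorded scale factor. The
#' sidecar records axis lengths, voxel size, time interval and channel roles.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  x <- stack$data
  is_int <- all(x == round(x)) && max(x) <= 65535
  pages <- vector("list", prod(d[1:3]))
  p <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[3])) for (ch in seq_len(d[2])) {
    sl <- matrix(x[t, ch, z, , ], d[4], d[5])
    pages[[p]] <- if (is_int) sl / 65535 else sl / max(max(x), 1)
    p <- p + 1L
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path,
                                 bits.per.sample = if (is_int) 16L else 32L),
                 error = function(e) stop("cannot write TIFF: ", path, " (",
                                          conditionMessage(e), ")"))
  meta <- list(dim = d, voxel_size = stack$voxel_size,
               time_interval = stack$time_interval,
               channel_roles = stack$channel_roles,
               encoding = if (is_int) "uint16" else "float32",
               scale = if (is_int) 1 else max(max(x), 1))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write keyed measurement records to CSV
#'
#' @param records a data frame (or list of rows sharing a schema).
#' @param path output path; UTF-8, `.` decimal separator, header row.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) records <- do.call(rbind.data.frame, records)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write table: ", path))
  on.exit(close(con))
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
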