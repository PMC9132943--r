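#' Calibrated fluorescence image series
#'
#' A time-ordered stack of 2D intensity frames with its physical calibration.
#' All pipeline stages consume this container.
#'
#' @param frames Numeric 3D array `(time, row, col)` of non-negative
#'   intensities, or a list of equally sized matrices.
#' @param pixel_size Pixel size in micrometres (> 0).
#' @param frame_interval Time between frames in seconds (> 0).
#' @param channel_label Optional channel name (e.g. `"shell"`, `"cargo"`).
#' @param timestamps Optional per-frame acquisition times (s); must be
#'   strictly increasing with one entry per frame. Defaults to
#'   `(0, frame_interval, 2 frame_interval, ...)`.
#' @return An object of class `image_series`.
#' @examples
#' s <- image_series(array(1, dim = c(3, 8, 16)), pixel_size = 0.05,
#'                   frame_interval = 60)
#' n_frames(s)
#' @export
image_series <- function(frames, pixel_size, frame_interval,
                         channel_label = "", timestamps = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1)
      stop("all frames must share the same shape", call. = FALSE)
    frames <- aperm(
      array(unlist(frames), dim = c(dims[[1]], length(frames))), c(3, 1, 2)
    )
  }
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("frames must be a (time, row, col) array", call. = FALSE)
  storage.mode(frames) <- "double"
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um)", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      frame_interval <= 0)
    stop("frame_interval must be a single positive number (s)", call. = FALSE)
  nt <- dim(frames)[1]
  if (is.null(timestamps)) {
    timestamps <- (seq_len(nt) - 1) * frame_interval
  } else {
    timestamps <- as.numeric(timestamps)
    if (length(timestamps) != nt)
      stop("timestamps length must equal the frame count", call. = FALSE)
    if (any(diff(timestamps) <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, channel_label = channel_label,
         timestamps = timestamps),
    class = "image_series"
  )
}

#' @rdname image_series
#' @param x An `image_series`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "image_series"))
  dim(x$frames)[1]
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "image_series%s: %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
    if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else "",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval
  ))
  invisible(x)
}

#' Extract one frame as a matrix
#'
#' @param series An [image_series()].
#' @param i Frame index (1-based).
#' @return The frame as a numeric matrix.
#' @export
get_frame <- function(series, i) {
  stopifnot(inherits(series, "image_series"))
  if (i < 1 || i > n_frames(series))
    stop("frame index out of range", call. = FALSE)
  series$frames[i, , ]
}

#' Read a TIFF stack as one or two image series
#'
#' Reads a multi-page TIFF (one page per frame) with calibration supplied by
#' the caller; pixel values are used as stored, with integer data converted to
#' float without rescaling. Two-channel stacks must either be separate files
#' or declare page interleaving via `channels = 2` (pages alternate channel 1,
#' channel 2, channel 1, ...). Mixed or guessed layouts are rejected.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size Pixel size (um/px).
#' @param frame_interval Frame interval (s).
#' @param channels 1 (default) or 2 for page-interleaved dual channel.
#' @param channel_labels Labels attached to the returned series.
#' @return A single [image_series()] when `channels = 1`, otherwise a list of
#'   two.
#' @export
read_image_series <- function(path, pixel_size, frame_interval, channels = 1,
                              channel_labels = c("ch1", "ch2")) {
  if (!file.exists(path))
    stop(sprintf("cannot read TIFF '%s': no such file", path), call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e)
      stop(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse grey-stored-as-RGB
    p
  })
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1)
    stop(sprintf("TIFF '%s': page shapes differ across frames", path),
         call. = FALSE)
  if (channels == 1) {
    return(image_series(pages, pixel_size, frame_interval,
                        channel_label = channel_labels[1]))
  }
  if (channels != 2)
    stop("channels must be 1 or 2", call. = FALSE)
  if (length(pages) %% 2 != 0)
    stop(sprintf("TIFF '%s': odd page count for a 2-channel interleaved stack",
                 path), call. = FALSE)
  idx <- seq_along(pages)
  list(
    image_series(pages[idx %% 2 == 1], pixel_size, frame_interval,
                 channel_label = channel_labels[1]),
    image_series(pages[idx %% 2 == 0], pixel_size, frame_interval,
                 channel_label = channel_labels[2])
  )
}

#' Write an image series to a 16-bit TIFF stack
#'
#' @param series An [image_series()]; intensities must fit in `[0, 65535]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  mx <- max(series$frames)
  if (mx > 65535)
    stop("intensities exceed the 16-bit range; rescale before writing",
         call. = FALSE)
  pages <- lapply(seq_len(n_frames(series)), function(i) {
    round(get_frame(series, i)) / 65535
  })
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L),
    error = function(e)
      stop(sprintf("cannot write TIFF '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
  )
  invisible(path)
}

#' Write a results table as CSV
#'
#' Serializes a list of homogeneous records (or a data frame) to CSV with a
#' header row, preserving input row order and writing numeric fields with 8
#' significant digits so a round trip is faithful to at least 6.
#'
#' @param records A data frame, or a list of named lists sharing one key set.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records) > 0) {
      keys <- unique(lapply(records, names))
      if (length(keys) != 1)
        stop("records must share one key set", call. = FALSE)
      df <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      df <- data.frame()
    }
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 8))
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE),
    error = function(e)
      stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
  )
  invisible(path)
}

#' Read pre-extracted axial profiles from CSV
#'
#' Accepts the profile-table interchange format: a `position_um` column
#' followed by one column per frame named `frame_0, frame_1, ...`.
#'
#' @param path CSV path.
#' @param frame_interval Frame interval (s).
#' @param prebleach_frames Number of leading pre-bleach frames (default 1).
#' @return An [axial_profile()].
#' @export
read_profile_csv <- function(path, frame_interval, prebleach_frames = 1) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"position_um" %in% names(df))
    stop(sprintf("'%s': missing position_um column", path), call. = FALSE)
  fcols <- grep("^frame_[0-9]+$", names(df), value = TRUE)
  if (length(fcols) < 2)
    stop(sprintf("'%s': need at least 2 frame_* columns", path), call. = FALSE)
  fcols <- fcols[order(as.integer(sub("frame_", "", fcols)))]
  profs <- lapply(fcols, function(cn) as.numeric(df[[cn]]))
  axial_profile(
    positions = as.numeric(df$position_um),
    profiles = profs,
    frame_times = (seq_along(fcols) - 1) * frame_interval,
    prebleach_index = prebleach_frames,
    bleach_index = prebleach_frames + 1
  )
}
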