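#' Per-frame axial intensity profiles of one cell
#'
#' Holds the 1D fluorescence profiles along the long axis of a cell (or of an
#' elongated intracellular structure), one profile per frame, together with
#' the indices separating pre-bleach from post-bleach frames.
#'
#' @param positions Positions along the long axis (um), one per grid point
#'   (pixel centres).
#' @param profiles List of numeric intensity vectors, one per frame, all on
#'   the `positions` grid.
#' @param frame_times Acquisition times (s), one per frame.
#' @param prebleach_index Index of the last pre-bleach frame.
#' @param bleach_index Index of the first post-bleach frame; must exceed
#'   `prebleach_index`.
#' @return An object of class `axial_profile`.
#' @export
axial_profile <- function(positions, profiles, frame_times,
                          prebleach_index, bleach_index) {
  positions <- as.numeric(positions)
  if (!is.list(profiles) || length(profiles) < 2)
    stop("profiles must be a list of at least 2 frames", call. = FALSE)
  lens <- unique(vapply(profiles, length, integer(1)))
  if (length(lens) != 1 || lens != length(positions))
    stop("all profiles must share the position grid", call. = FALSE)
  if (length(frame_times) != length(profiles))
    stop("frame_times length must equal the frame count", call. = FALSE)
  if (!(prebleach_index >= 1 && prebleach_index < bleach_index &&
        bleach_index <= length(profiles)))
    stop("need 1 <= prebleach_index < bleach_index <= n_frames", call. = FALSE)
  structure(
    list(positions = positions,
         profiles = lapply(profiles, as.numeric),
         frame_times = as.numeric(frame_times),
         prebleach_index = as.integer(prebleach_index),
         bleach_index = as.integer(bleach_index)),
    class = "axial_profile"
  )
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf(
    "axial_profile: %d frames x %d positions (%.3g um span), bleach at frame %d\n",
    length(x$profiles), length(x$positions),
    diff(range(x$positions)), x$bleach_index
  ))
  invisible(x)
}

# Mean pre-bleach profile (average of all frames up to prebleach_index).
.prebleach_profile <- function(profile) {
  pre <- profile$profiles[seq_len(profile$prebleach_index)]
  Reduce(`+`, pre) / length(pre)
}

# Segment a reference frame: Otsu threshold, keep the largest connected
# component, fill holes. Returns a logical matrix.
.segment_cell <- function(reference) {
  if (max(reference) <= min(reference))
    stop("segmentation failed: constant reference image", call. = FALSE)
  scaled <- (reference - min(reference)) / (max(reference) - min(reference))
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  bw <- scaled > thr
  if (!any(bw))
    stop("segmentation failed: empty mask after thresholding", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(tab)
  mask <- EBImage::fillHull(EBImage::Image((lab == keep) * 1))
  matrix(as.numeric(mask) > 0, nrow = nrow(reference))
}

# Principal axis of a binary mask via second moments of pixel coordinates.
# Returns unit vector (d_row, d_col) and the coordinate centre.
.mask_major_axis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  cv <- crossprod(cc) / nrow(cc)
  ev <- eigen(cv, symmetric = TRUE)
  list(direction = ev$vectors[, 1], centre = ctr)
}

#' Extract the axial intensity profile from an image series
#'
#' Segments the cell (Otsu threshold on the mean pre-bleach frame, largest
#' connected component, holes filled) unless a mask is supplied, finds the
#' long axis as the major axis of the mask's second-moment (best-fit) ellipse,
#' and for every frame sums the masked intensities across the short axis into
#' bins of one pixel pitch along the long axis.
#'
#' @param series An [image_series()].
#' @param mask Optional logical matrix with the cell footprint; auto-derived
#'   when `NULL`.
#' @param prebleach_frames Number of leading pre-bleach frames (default 1).
#' @return An [axial_profile()] with positions at pixel centres (um) and the
#'   pre-bleach profile equal to the mean of the pre-bleach frames.
#' @export
extract_axial_profile <- function(series, mask = NULL, prebleach_frames = 1) {
  stopifnot(inherits(series, "image_series"))
  nt <- n_frames(series)
  if (nt < prebleach_frames + 2)
    stop("series needs at least prebleach_frames + 2 frames", call. = FALSE)
  ref <- Reduce(`+`, lapply(seq_len(prebleach_frames), function(i)
    get_frame(series, i))) / prebleach_frames
  if (is.null(mask)) mask <- .segment_cell(ref)
  if (!any(mask))
    stop("segmentation failed: empty mask", call. = FALSE)

  ax <- .mask_major_axis(mask)
  idx <- which(mask, arr.ind = TRUE)
  # projected coordinate (px) of each masked pixel along the long axis
  proj <- as.numeric(sweep(idx, 2, ax$centre) %*% ax$direction)
  bins <- round(proj - min(proj)) + 1L
  nb <- max(bins)
  lin <- (idx[, 2] - 1) * nrow(mask) + idx[, 1]

  profiles <- lapply(seq_len(nt), function(i) {
    fr <- get_frame(series, i)
    as.numeric(tapply(fr[lin], factor(bins, levels = seq_len(nb)), sum,
                      default = 0))
  })
  pre <- Reduce(`+`, profiles[seq_len(prebleach_frames)]) / prebleach_frames
  profiles <- c(list(pre), profiles[(prebleach_frames + 1):nt])
  times <- c(series$timestamps[prebleach_frames],
             series$timestamps[(prebleach_frames + 1):nt])
  axial_profile(
    positions = (seq_len(nb) - 0.5) * series$pixel_size,
    profiles = profiles,
    frame_times = times,
    prebleach_index = 1,
    bleach_index = 2
  )
}

#' Normalize every frame to the pre-bleach total fluorescence
#'
#' Rescales each frame's profile so that its sum equals the pre-bleach
#' profile's sum. This compensates acquisition photobleaching and
#' frame-to-frame excitation fluctuations so fluorescence distributions
#' before and after the bleach are comparable.
#'
#' @param profile An [axial_profile()].
#' @return The normalized `axial_profile`.
#' @export
normalize_profiles <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  target <- sum(.prebleach_profile(profile))
  if (target <= 0)
    stop("pre-bleach total fluorescence must be positive", call. = FALSE)
  sums <- vapply(profile$profiles, sum, numeric(1))
  if (any(sums <= 0))
    stop("cannot normalize a frame with non-positive total fluorescence",
         call. = FALSE)
  profile$profiles <- lapply(profile$profiles, function(p) p * target / sum(p))
  profile
}
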