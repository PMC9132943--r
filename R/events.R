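#' Detect fluorescent foci in a frame
#'
#' A focus is a connected region of pixels brighter than `mean + k * SD` of
#' the masked intensities, with at least `min_area` pixels. The reported
#' position is the intensity-weighted centroid projected onto the cell's long
#' axis. An empty result is valid: a frame may carry no foci.
#'
#' @param frame Numeric 2D intensity matrix.
#' @param mask Logical cell mask (at least 10 pixels).
#' @param k Threshold multiplier (default 3).
#' @param min_area Minimum focus area in pixels (default 4).
#' @return A data frame with one row per focus: `axial_position_px` (along
#'   the mask's long axis, from its low end), `peak_intensity`, `area_px`.
#' @export
detect_foci <- function(frame, mask, k = 3, min_area = 4) {
  if (!identical(dim(frame), dim(mask)))
    stop("frame and mask shapes differ", call. = FALSE)
  if (sum(mask) < 10)
    stop("mask must contain at least 10 pixels", call. = FALSE)
  mu <- mean(frame[mask])
  sg <- stats::sd(frame[mask])
  bw <- (frame > mu + k * sg) & mask
  empty <- data.frame(axial_position_px = numeric(0),
                      peak_intensity = numeric(0), area_px = integer(0))
  if (!any(bw)) return(empty)

  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- matrix(as.integer(lab), nrow = nrow(frame))
  ax <- .mask_major_axis(mask)
  midx <- which(mask, arr.ind = TRUE)
  proj0 <- min(sweep(midx, 2, ax$centre) %*% ax$direction)

  out <- lapply(seq_len(max(labm)), function(id) {
    idx <- which(labm == id, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    wts <- frame[idx]
    proj <- as.numeric(sweep(idx, 2, ax$centre) %*% ax$direction) - proj0
    data.frame(axial_position_px = sum(proj * wts) / sum(wts),
               peak_intensity = max(wts), area_px = nrow(idx))
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' First persistent focus appearance in a time-lapse
#'
#' Scans the series for the first frame at which a focus is detected and
#' detection persists for at least `persistence` consecutive frames; earlier
#' single-frame flickers are ignored. Returns `NULL` when no focus ever
#' satisfies the persistence requirement.
#'
#' @param series An [image_series()].
#' @param mask Optional logical cell mask; derived from the mean frame when
#'   absent.
#' @param persistence Required consecutive detection frames (default 2).
#' @param k,min_area Focus-detection parameters (see [detect_foci()]).
#' @return An object of class `focus_event` (list with `channel`,
#'   `first_frame`, `time`, `position_um`, `folded_position`,
#'   `cell_length_um`), or `NULL`.
#' @export
first_appearance <- function(series, mask = NULL, persistence = 2, k = 3,
                             min_area = 4) {
  stopifnot(inherits(series, "image_series"))
  nt <- n_frames(series)
  if (is.null(mask)) {
    mean_frame <- apply(series$frames, c(2, 3), mean)
    mask <- .segment_cell(mean_frame)
  }
  ax <- .mask_major_axis(mask)
  midx <- which(mask, arr.ind = TRUE)
  proj <- as.numeric(sweep(midx, 2, ax$centre) %*% ax$direction)
  cell_length_px <- diff(range(proj)) + 1
  cell_length_um <- cell_length_px * series$pixel_size

  foci <- lapply(seq_len(nt), function(i)
    detect_foci(get_frame(series, i), mask, k = k, min_area = min_area))
  has <- vapply(foci, nrow, integer(1)) > 0

  runs <- rle(has)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= persistence)
  if (length(hit) == 0) return(NULL)
  f0 <- starts[hit[1]]

  first <- foci[[f0]]
  best <- which.max(first$peak_intensity)
  pos_um <- first$axial_position_px[best] * series$pixel_size
  pos_um <- min(max(pos_um, 0), cell_length_um)
  structure(
    list(channel = series$channel_label, first_frame = f0,
         time = series$timestamps[f0], position_um = pos_um,
         folded_position = folded_axial_position(pos_um, cell_length_um),
         cell_length_um = cell_length_um),
    class = "focus_event"
  )
}

#' Classify a shell/cargo appearance pair
#'
#' Labels the assembly order of one cell from the first-appearance frames of
#' its shell and cargo foci: `shell_first` when the shell focus precedes the
#' cargo focus by more than `window` frames, `cargo_first` in the opposite
#' case, and `concomitant` when the gap is within the window (default 0:
#' only same-frame appearances count as concomitant).
#'
#' @param shell,cargo `focus_event` objects (see [first_appearance()]).
#' @param window Concomitance window in frames (default 0).
#' @return An object of class `event_classification`: list with `label`
#'   (one of `"shell_first"`, `"cargo_first"`, `"concomitant"`) and `gap`
#'   (signed frames, shell minus cargo).
#' @export
classify_event <- function(shell, cargo, window = 0) {
  if (is.null(shell))
    stop("classification failed: no shell focus event", call. = FALSE)
  if (is.null(cargo))
    stop("classification failed: no cargo focus event", call. = FALSE)
  gap <- shell$first_frame - cargo$first_frame
  label <- if (gap < -window) "shell_first"
           else if (gap > window) "cargo_first"
           else "concomitant"
  structure(list(label = label, gap = gap), class = "event_classification")
}

#' Fold an axial position onto the pole-to-midcell half axis
#'
#' Normalizes a position along the cell's long axis by the cell length and
#' folds it about mid-cell, so 0 is the nearest pole and 0.5 is mid-cell.
#' Both poles map to 0; the map is invariant under
#' `position -> cell_length - position`.
#'
#' @param position Axial position (um) in `[0, cell_length]`.
#' @param cell_length Cell length (um).
#' @return Folded position, dimensionless in `[0, 0.5]`.
#' @examples
#' folded_axial_position(3, 3)    # 0 (pole)
#' folded_axial_position(1.5, 3)  # 0.5 (mid-cell)
#' @export
folded_axial_position <- function(position, cell_length) {
  if (cell_length <= 0) stop("cell_length must be positive", call. = FALSE)
  if (any(position < 0 | position > cell_length))
    stop("position outside the cell", call. = FALSE)
  p <- position / cell_length
  pmin(p, 1 - p)
}

#' Fraction of events in the polar quarter
#'
#' Fraction of folded axial positions at or below 0.25, i.e. events occurring
#' between a pole and the quarter position of the cell.
#'
#' @param folded_positions Numeric vector of folded positions in `[0, 0.5]`.
#' @return The fraction in `[0, 1]`.
#' @export
pole_quarter_fraction <- function(folded_positions) {
  if (length(folded_positions) == 0)
    stop("need at least one folded position", call. = FALSE)
  if (any(folded_positions < 0 | folded_positions > 0.5))
    stop("folded positions must lie in [0, 0.5]", call. = FALSE)
  mean(folded_positions <= 0.25)
}

#' Tally event classifications
#'
#' @param classifications List of [classify_event()] results (possibly
#'   empty), or a character vector of labels.
#' @return Named integer vector `c(shell_first, cargo_first, concomitant)`.
#' @export
count_events <- function(classifications) {
  labels <- if (is.character(classifications)) classifications
            else vapply(classifications, function(x) x$label, character(1))
  known <- c("shell_first", "cargo_first", "concomitant")
  bad <- setdiff(unique(labels), known)
  if (length(bad) > 0)
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  vapply(known, function(l) sum(labels == l), integer(1))
}
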