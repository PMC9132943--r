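# Run code under a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Named substreams: every stage draws from seed + a fixed stage offset so one
# top-level seed controls the whole run without coupling stages.
.substream <- function(seed, stage) {
  offsets <- c(frap_noise = 101L, coloc_place = 211L, coloc_noise = 223L,
               events_noise = 307L, schedule = 401L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Ground-truth simulation parameters
#'
#' Settings of the synthetic FRAP experiment: a rod-shaped cell containing an
#' elongated fluorescent structure, a line bleach across its centre, and
#' two-population (mobile + immobile) diffusive recovery imaged at fixed
#' intervals. Defaults emulate the study conditions: 1-minute frames for 60
#' minutes, a mid-cell bleach line, and 2% Gaussian detection noise.
#'
#' @param D_mobile Diffusion coefficient of the mobile population (um^2/s).
#' @param mobile_fraction Mobile fraction M in `[0, 1]`.
#' @param cell_length,cell_width Cell size (um); defaults 3.0 and 1.0.
#' @param pixel_size Pixel size (um, default 0.05).
#' @param frame_interval Frame interval (s, default 60).
#' @param n_frames Total frames including pre-bleach (default 61).
#' @param prebleach_frames Leading pre-bleach frames (default 1).
#' @param bleach_center Bleach-line centre as a fraction of the cell length
#'   (default 0.5).
#' @param bleach_width Bleach-line width (um, default 0.3).
#' @param bleach_depth Fraction of fluorescence removed in the line,
#'   in `(0, 1]` mapped from the configured value (0 disables the bleach;
#'   default 0.8).
#' @param intensity Mean pre-bleach intensity inside the structure
#'   (arbitrary units on a 16-bit-compatible scale, default 10000).
#' @param noise_gaussian_sigma Gaussian detection noise as a fraction of the
#'   pre-bleach mean intensity (default 0.02).
#' @param noise_poisson_scale Photons per intensity unit for Poisson shot
#'   noise; 0 disables (default 0).
#' @param seed Integer seed feeding all randomness through named substreams.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(D_mobile, mobile_fraction,
                              cell_length = 3.0, cell_width = 1.0,
                              pixel_size = 0.05, frame_interval = 60,
                              n_frames = 61, prebleach_frames = 1,
                              bleach_center = 0.5, bleach_width = 0.3,
                              bleach_depth = 0.8, intensity = 10000,
                              noise_gaussian_sigma = 0.02,
                              noise_poisson_scale = 0, seed = 1L) {
  p <- list(D_mobile = D_mobile, mobile_fraction = mobile_fraction,
            cell_length = cell_length, cell_width = cell_width,
            pixel_size = pixel_size, frame_interval = frame_interval,
            n_frames = n_frames, prebleach_frames = prebleach_frames,
            bleach_center = bleach_center, bleach_width = bleach_width,
            bleach_depth = bleach_depth, intensity = intensity,
            noise_gaussian_sigma = noise_gaussian_sigma,
            noise_poisson_scale = noise_poisson_scale,
            seed = as.integer(seed))
  stopifnot(
    p$D_mobile >= 0, p$mobile_fraction >= 0, p$mobile_fraction <= 1,
    p$cell_length > 0, p$cell_width > 0, p$pixel_size > 0,
    p$frame_interval > 0, p$n_frames >= p$prebleach_frames + 2,
    p$bleach_center > 0, p$bleach_center < 1,
    p$bleach_width > 0, p$bleach_depth >= 0, p$bleach_depth <= 1,
    p$intensity > 0, p$noise_gaussian_sigma >= 0, p$noise_poisson_scale >= 0
  )
  class(p) <- "simulation_params"
  p
}

#' Study-condition FRAP presets
#'
#' `cargo_like` reproduces the reported cargo-enzyme dynamics
#' (M = 0.83, D = 4.02e-4 um^2/s); `shell_like` the shell-protein dynamics
#' (M = 0.06, D = 0.28e-4 um^2/s).
#'
#' @param preset `"cargo_like"` or `"shell_like"`.
#' @param ... Overrides passed to [simulation_params()].
#' @return A `simulation_params` list.
#' @export
frap_preset <- function(preset = c("cargo_like", "shell_like"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    cargo_like = list(D_mobile = 4.02e-4, mobile_fraction = 0.83),
    shell_like = list(D_mobile = 0.28e-4, mobile_fraction = 0.06)
  )
  do.call(simulation_params, utils::modifyList(base, list(...)))
}

# Rod geometry shared by the generators: pixel footprint of the structure
# inside the frame, with a fixed dark margin.
.rod_geometry <- function(params, margin = 5L) {
  len_px <- max(3L, round(params$cell_length / params$pixel_size))
  wid_px <- max(3L, round(params$cell_width / params$pixel_size))
  list(
    len_px = len_px, wid_px = wid_px, margin = margin,
    nrow = wid_px + 2L * margin, ncol = len_px + 2L * margin,
    rows = margin + seq_len(wid_px), cols = margin + seq_len(len_px)
  )
}

# Render an axial profile (per-pixel column value) into a 2D frame.
.render_axial <- function(axial, geom) {
  fr <- matrix(0, geom$nrow, geom$ncol)
  fr[geom$rows, geom$cols] <- matrix(rep(axial, each = length(geom$rows)),
                                     nrow = length(geom$rows))
  fr
}

# Gaussian then Poisson detection noise, clipped to non-negative intensities.
.apply_noise <- function(frames, params) {
  sigma <- params$noise_gaussian_sigma * params$intensity
  out <- lapply(frames, function(fr) {
    if (sigma > 0) fr <- fr + matrix(stats::rnorm(length(fr), 0, sigma),
                                     nrow(fr), ncol(fr))
    if (params$noise_poisson_scale > 0) {
      lam <- pmax(fr, 0) * params$noise_poisson_scale
      fr <- matrix(stats::rpois(length(lam), lam), nrow(fr)) /
        params$noise_poisson_scale
    }
    pmax(fr, 0)
  })
  out
}

#' Generate a synthetic FRAP image series with known ground truth
#'
#' Builds a uniform elongated fluorescent structure, applies an instantaneous
#' multiplicative line bleach at its scheduled position, evolves the
#' post-bleach profile with the two-population diffusion model
#' ([simulate_recovery()]; or the engine-independent analytic cosine-series
#' solution when `engine = "analytic"` and M = 1 or M's immobile complement
#' needs no engine), renders each axial profile across the rod cross-section,
#' and applies seeded Gaussian and Poisson detection noise.
#'
#' @param params A [simulation_params()].
#' @param engine `"fd"` (finite-difference, default) or `"analytic"`
#'   (cosine-series solution of the no-flux diffusion equation; breaks the
#'   circularity of engine-based round-trip tests).
#' @return List with `series` (an [image_series()]) and `truth` (the params,
#'   the noiseless axial profiles per frame, frame times, and the bleach
#'   window in grid indices).
#' @export
generate_frap_series <- function(params, engine = c("fd", "analytic")) {
  stopifnot(inherits(params, "simulation_params"))
  engine <- match.arg(engine)
  geom <- .rod_geometry(params)
  n_post <- params$n_frames - params$prebleach_frames

  pre_axial <- rep(params$intensity, geom$len_px)
  x <- (seq_len(geom$len_px) - 0.5) * params$pixel_size
  ctr <- params$bleach_center * params$cell_length
  in_line <- abs(x - ctr) <= params$bleach_width / 2
  post_axial <- pre_axial
  post_axial[in_line] <- post_axial[in_line] * (1 - params$bleach_depth)

  post_times <- (seq_len(n_post) - 1) * params$frame_interval
  if (params$bleach_depth == 0) {
    post_profiles <- lapply(post_times, function(t) pre_axial)
  } else if (engine == "fd") {
    post_profiles <- simulate_recovery(
      pre_axial, post_axial, params$mobile_fraction, params$D_mobile,
      post_times, params$pixel_size
    )
  } else {
    immobile <- (1 - params$mobile_fraction) * post_axial
    mobile <- cosine_series_solution(
      params$mobile_fraction * post_axial, params$pixel_size,
      params$D_mobile, post_times
    )
    post_profiles <- lapply(mobile, function(m) m + immobile)
  }

  axials <- c(rep(list(pre_axial), params$prebleach_frames), post_profiles)
  frames <- lapply(axials, .render_axial, geom = geom)
  frames <- .with_seed(.substream(params$seed, "frap_noise"),
                       .apply_noise(frames, params))

  series <- image_series(frames, params$pixel_size, params$frame_interval)
  truth <- list(
    params = params,
    axial_profiles = axials,
    frame_times = (seq_len(params$n_frames) - 1) * params$frame_interval,
    bleach_window = which(in_line),
    positions_um = x
  )
  list(series = series, truth = truth)
}

#' Generate a dual-channel colocalization image pair
#'
#' Places `n_foci` Gaussian foci uniformly inside a rod-shaped cell in
#' channel 1; a fraction `overlap` of channel-2 foci share those centroids
#' and the remainder are placed independently, kept disjoint from the
#' channel-1 foci so that `overlap = 0` programs genuine independence.
#'
#' @param n_foci Number of foci per channel (>= 1).
#' @param overlap Programmed colocalized fraction rho in `[0, 1]`.
#' @param params A [simulation_params()] supplying geometry, noise and seed
#'   (the FRAP-specific fields are ignored); `intensity` sets the cytosolic
#'   background level and foci peak at 2x background above it, the modest
#'   contrast typical of fluorescent-protein puncta over their cytosolic
#'   pool (and the regime in which Otsu segmentation finds the cell rather
#'   than the puncta).
#' @param psf_sigma Gaussian point-spread sigma (um, default 0.1).
#' @return List with `channel1`, `channel2` (single-frame [image_series()])
#'   and `truth` (focus centres per channel).
#' @export
generate_coloc_pair <- function(n_foci, overlap, params, psf_sigma = 0.1) {
  stopifnot(inherits(params, "simulation_params"))
  if (n_foci < 1) stop("n_foci must be >= 1", call. = FALSE)
  if (overlap < 0 || overlap > 1)
    stop("overlap must lie in [0, 1]", call. = FALSE)
  geom <- .rod_geometry(params)
  s_px <- psf_sigma / params$pixel_size
  pad <- ceiling(2 * s_px)

  place <- function(n, avoid = NULL, min_sep = 4 * s_px) {
    out <- matrix(0, 0, 2)
    tries <- 0
    while (nrow(out) < n && tries < 10000) {
      cand <- c(stats::runif(1, min(geom$rows) + pad, max(geom$rows) - pad),
                stats::runif(1, min(geom$cols) + pad, max(geom$cols) - pad))
      near <- rbind(avoid, out)
      ok <- nrow(near) == 0 ||
        min(sqrt(rowSums(sweep(near, 2, cand)^2))) >= min_sep
      if (ok) out <- rbind(out, cand)
      tries <- tries + 1
    }
    if (nrow(out) < n)
      stop("could not place disjoint foci; reduce n_foci or cell crowding",
           call. = FALSE)
    out
  }

  render <- function(centres) {
    fr <- matrix(0, geom$nrow, geom$ncol)
    fr[geom$rows, geom$cols] <- params$intensity
    rr <- matrix(seq_len(geom$nrow), geom$nrow, geom$ncol)
    cc <- matrix(seq_len(geom$ncol), geom$nrow, geom$ncol, byrow = TRUE)
    for (i in seq_len(nrow(centres))) {
      fr <- fr + 2 * params$intensity *
        exp(-((rr - centres[i, 1])^2 + (cc - centres[i, 2])^2) / (2 * s_px^2))
    }
    fr
  }

  res <- .with_seed(.substream(params$seed, "coloc_place"), {
    c1 <- place(n_foci)
    n_shared <- round(overlap * n_foci)
    shared <- if (n_shared > 0) c1[seq_len(n_shared), , drop = FALSE]
              else matrix(0, 0, 2)
    indep <- if (n_foci - n_shared > 0) place(n_foci - n_shared, avoid = c1)
             else matrix(0, 0, 2)
    list(c1 = c1, c2 = rbind(shared, indep))
  })

  frames <- .with_seed(
    .substream(params$seed, "coloc_noise"),
    .apply_noise(list(render(res$c1), render(res$c2)), params)
  )
  list(
    channel1 = image_series(frames[1], params$pixel_size,
                            params$frame_interval, channel_label = "ch1"),
    channel2 = image_series(frames[2], params$pixel_size,
                            params$frame_interval, channel_label = "ch2"),
    truth = list(params = params, centres_ch1 = res$c1, centres_ch2 = res$c2,
                 overlap = overlap)
  )
}

#' Sample folded axial positions with a programmed polar bias
#'
#' Draws folded positions in `[0, 0.5]` such that a fraction
#' `p_pole_quarter` falls between the pole and the quarter position
#' (`<= 0.25`), uniformly within each stratum. The default bias mirrors the
#' observed spatial distribution of initial assembly events (70.4% between
#' pole and quarter).
#'
#' @param n Number of positions.
#' @param p_pole_quarter Probability of the `[0, 0.25]` stratum
#'   (default 0.704).
#' @param seed Integer seed.
#' @return Numeric vector of folded positions.
#' @export
sample_folded_positions <- function(n, p_pole_quarter = 0.704, seed = 1L) {
  .with_seed(.substream(seed, "schedule"), {
    polar <- stats::runif(n) < p_pole_quarter
    ifelse(polar, stats::runif(n, 0, 0.25), stats::runif(n, 0.25, 0.5))
  })
}

#' Generate a dual-channel birth-event time-lapse
#'
#' Each channel shows a rod-shaped cell with cytosolic background; a focus
#' ramps from zero to full intensity over 2 frames starting at its scheduled
#' frame, at the scheduled axial position. Detection noise is seeded.
#'
#' @param schedule Data frame with columns `channel` (`"shell"`/`"cargo"`),
#'   `frame` (1-based appearance frame) and `axial_frac` (position along the
#'   long axis as a fraction of cell length, in `[0, 1]`); one row per
#'   channel.
#' @param params A [simulation_params()] for geometry, noise, frame count and
#'   seed; `intensity` sets the cytosolic background level and the focus
#'   amplitude is 3x background.
#' @param psf_sigma Focus Gaussian sigma (um, default 0.1).
#' @return List with `shell`, `cargo` ([image_series()]) and `truth`.
#' @export
generate_birth_timelapse <- function(schedule, params, psf_sigma = 0.1) {
  stopifnot(inherits(params, "simulation_params"))
  need <- c("channel", "frame", "axial_frac")
  if (!all(need %in% names(schedule)))
    stop("schedule needs columns channel, frame, axial_frac", call. = FALSE)
  if (any(schedule$frame < 1 | schedule$frame > params$n_frames))
    stop("scheduled frames outside the series", call. = FALSE)
  if (any(schedule$axial_frac < 0 | schedule$axial_frac > 1))
    stop("axial_frac must lie in [0, 1]", call. = FALSE)
  geom <- .rod_geometry(params)
  s_px <- psf_sigma / params$pixel_size
  bg <- params$intensity
  amp <- 3 * bg

  make_channel <- function(ch) {
    row <- schedule[schedule$channel == ch, , drop = FALSE]
    if (nrow(row) != 1)
      stop(sprintf("schedule must have exactly one '%s' row", ch),
           call. = FALSE)
    r0 <- mean(geom$rows)
    c0 <- min(geom$cols) + row$axial_frac * (geom$len_px - 1)
    rr <- matrix(seq_len(geom$nrow), geom$nrow, geom$ncol)
    cc <- matrix(seq_len(geom$ncol), geom$nrow, geom$ncol, byrow = TRUE)
    spot <- exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * s_px^2))
    lapply(seq_len(params$n_frames), function(f) {
      ramp <- if (f < row$frame) 0
              else if (f == row$frame) 0.6
              else 1
      fr <- matrix(0, geom$nrow, geom$ncol)
      fr[geom$rows, geom$cols] <- bg
      fr + ramp * amp * spot
    })
  }

  shell_frames <- make_channel("shell")
  cargo_frames <- make_channel("cargo")
  noised <- .with_seed(
    .substream(params$seed, "events_noise"),
    list(shell = .apply_noise(shell_frames, params),
         cargo = .apply_noise(cargo_frames, params))
  )
  list(
    shell = image_series(noised$shell, params$pixel_size,
                         params$frame_interval, channel_label = "shell"),
    cargo = image_series(noised$cargo, params$pixel_size,
                         params$frame_interval, channel_label = "cargo"),
    truth = list(params = params, schedule = schedule)
  )
}
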