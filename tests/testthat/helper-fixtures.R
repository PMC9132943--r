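# Shared fixture builders; everything is generated in code at test time.

# Small, fast FRAP simulation settings (short series, coarse cell).
quick_params <- function(D = 4e-4, M = 0.8, seed = 1L, noise = 0,
                         n_frames = 31) {
  simulation_params(
    D_mobile = D, mobile_fraction = M, seed = seed,
    noise_gaussian_sigma = noise, n_frames = n_frames
  )
}

# Hand-built axial profile: uniform prebleach, one bleach scar, no dynamics.
static_profile <- function(n = 41, level = 100, scar_at = 21, scar_depth = 80,
                           n_frames = 6, dx = 0.05) {
  pre <- rep(level, n)
  post <- pre
  post[scar_at] <- post[scar_at] - scar_depth
  axial_profile(
    positions = (seq_len(n) - 0.5) * dx,
    profiles = c(list(pre), rep(list(post), n_frames - 1)),
    frame_times = (seq_len(n_frames) - 1) * 60,
    prebleach_index = 1, bleach_index = 2
  )
}

# A rod-on-dark-background frame with optional Gaussian foci.
rod_frame <- function(nrow = 30, ncol = 70, rows = 6:25, cols = 6:65,
                      bg = 1000, foci = NULL, amp = 3000, sigma = 2) {
  fr <- matrix(0, nrow, ncol)
  fr[rows, cols] <- bg
  if (!is.null(foci)) {
    rr <- matrix(seq_len(nrow), nrow, ncol)
    cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
    for (i in seq_len(nrow(foci))) {
      fr <- fr + amp * exp(-((rr - foci[i, 1])^2 + (cc - foci[i, 2])^2) /
                             (2 * sigma^2))
    }
  }
  fr
}
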