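#' Diffusion state on a 1D cell-centred grid
#'
#' A 1D fluorescence concentration profile together with its grid spacing and
#' elapsed time. This is the state evolved by the finite-difference diffusion
#' engine used for FRAP recovery simulation.
#'
#' @param concentration Numeric vector of non-negative intensities, one value
#'   per grid cell (pixel). Length must be at least 3.
#' @param dx Grid spacing in micrometres (> 0).
#' @param time Elapsed time in seconds (default 0).
#' @return An object of class `diffusion_state`: a list with elements
#'   `concentration`, `dx` and `time`.
#' @examples
#' st <- diffusion_state(rep(1, 10), dx = 0.05)
#' @export
diffusion_state <- function(concentration, dx, time = 0) {
  concentration <- as.numeric(concentration)
  if (length(concentration) < 3)
    stop("concentration profile must have at least 3 points", call. = FALSE)
  if (any(!is.finite(concentration)) || any(concentration < -1e-12))
    stop("concentration must be finite and non-negative", call. = FALSE)
  if (!is.numeric(dx) || length(dx) != 1 || dx <= 0)
    stop("dx must be a single positive number", call. = FALSE)
  structure(
    list(concentration = concentration, dx = dx, time = time),
    class = "diffusion_state"
  )
}

#' Discrete Laplacian with no-flux boundaries
#'
#' Second spatial difference of a profile, the right-hand side of the 1D
#' diffusion equation dC/dt = D d2C/dX2. Interior point i receives
#' `(C[i-1] - 2 C[i] + C[i+1]) / dx^2`. The grid is cell-centred (pixel
#' centres); the reflecting ghost cell mirrors the boundary cell itself, so
#' the boundary value is `(C[2] - C[1]) / dx^2` on the left (symmetric on
#' the right) and the Laplacian sums to zero exactly: no mass crosses the
#' cell envelope.
#'
#' @param concentration Numeric vector, length >= 3.
#' @param dx Grid spacing (micrometres).
#' @return Numeric vector of the same length.
#' @examples
#' discrete_laplacian(c(0, 1, 0), dx = 1)  # c(1, -2, 1)
#' @export
discrete_laplacian <- function(concentration, dx) {
  c0 <- as.numeric(concentration)
  n <- length(c0)
  if (n < 3)
    stop("concentration profile must have at least 3 points", call. = FALSE)
  lap <- numeric(n)
  lap[1] <- c0[2] - c0[1]
  lap[n] <- c0[n - 1] - c0[n]
  if (n > 2)
    lap[2:(n - 1)] <- c0[1:(n - 2)] - 2 * c0[2:(n - 1)] + c0[3:n]
  lap / dx^2
}

#' Advance a diffusion state by one explicit-Euler step
#'
#' Applies C <- C + D * dt * laplacian(C). The step is only stable when
#' D * dt / dx^2 <= 0.25; violating steps are refused with an error (use
#' [evolve_profile()] which subdivides automatically).
#'
#' @param state A [diffusion_state()].
#' @param D Diffusion coefficient (um^2/s, >= 0).
#' @param dt Time step (s, > 0).
#' @return The advanced `diffusion_state`.
#' @export
diffusion_step <- function(state, D, dt) {
  stopifnot(inherits(state, "diffusion_state"))
  if (D < 0) stop("D must be non-negative", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  alpha <- D * dt / state$dx^2
  if (alpha > 0.25 + 1e-12)
    stop(sprintf(
      "unstable step: D*dt/dx^2 = %.3g exceeds 0.25; use a smaller dt (<= %.3g s)",
      alpha, 0.25 * state$dx^2 / D
    ), call. = FALSE)
  conc <- state$concentration + D * dt * discrete_laplacian(state$concentration, state$dx)
  diffusion_state(pmax(conc, 0), state$dx, state$time + dt)
}

# Number of Euler substeps for an interval of length `gap`, honouring the
# stability bound D*dt/dx^2 <= 0.25.
.n_substeps <- function(gap, D, dx) {
  if (gap <= 0 || D <= 0) return(if (gap > 0) 1L else 0L)
  dt_max <- 0.25 * dx^2 / D
  max(1L, as.integer(ceiling(gap / dt_max - 1e-12)))
}

#' Evolve a profile to a set of sample times
#'
#' Integrates the no-flux 1D diffusion equation with explicit Euler steps,
#' automatically subdividing each inter-sample interval so that
#' D * dt / dx^2 <= 0.25. Deterministic; total fluorescence is conserved to
#' floating-point rounding.
#'
#' @param state A [diffusion_state()].
#' @param D Diffusion coefficient (um^2/s, >= 0).
#' @param sample_times Non-decreasing times (s), all >= `state$time`.
#' @return A list of concentration vectors, one per sample time.
#' @examples
#' st <- diffusion_state(c(rep(1, 20), rep(0, 20)), dx = 0.05)
#' out <- evolve_profile(st, D = 1e-3, sample_times = c(1, 10, 100))
#' @export
evolve_profile <- function(state, D, sample_times) {
  stopifnot(inherits(state, "diffusion_state"))
  if (D < 0) stop("D must be non-negative", call. = FALSE)
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) == 0)
    stop("sample_times must be non-empty", call. = FALSE)
  if (any(diff(sample_times) < 0))
    stop("sample_times must be non-decreasing", call. = FALSE)
  if (sample_times[1] < state$time - 1e-9)
    stop("sample_times must not precede the current state time", call. = FALSE)

  out <- vector("list", length(sample_times))
  conc <- state$concentration
  t_now <- state$time
  for (k in seq_along(sample_times)) {
    gap <- sample_times[k] - t_now
    if (gap > 1e-12 && D > 0) {
      nst <- .n_substeps(gap, D, state$dx)
      conc <- .euler_steps(conc, D, state$dx, gap / nst, nst)
    }
    t_now <- sample_times[k]
    out[[k]] <- conc
  }
  out
}

#' Predict FRAP recovery profiles for a partially mobile population
#'
#' Splits the first post-bleach profile into an immobile component
#' (1 - M) * postbleach, which keeps the bleach scar forever, and a mobile
#' component M * postbleach, which relaxes by free diffusion towards a uniform
#' distribution. The observable profile at each time is the evolved mobile
#' component plus the frozen immobile one. At M = 1 this reduces to plain
#' diffusion of the post-bleach profile; at M = 0 the profile never changes.
#'
#' @param prebleach Numeric profile before bleaching (same grid as
#'   `postbleach`); used only for grid validation — the decomposition acts on
#'   the post-bleach profile. Profiles are expected to be normalized to equal
#'   totals (see [normalize_profiles()]).
#' @param postbleach Numeric profile of the first post-bleach frame.
#' @param mobile_fraction Mobile fraction M in `[0, 1]`.
#' @param D Diffusion coefficient of the mobile population (um^2/s).
#' @param sample_times Times (s) after the bleach at which to report profiles;
#'   time 0 is the post-bleach frame.
#' @param dx Grid spacing (micrometres).
#' @return A list of observable profiles, one per sample time.
#' @export
simulate_recovery <- function(prebleach, postbleach, mobile_fraction, D,
                              sample_times, dx) {
  prebleach <- as.numeric(prebleach)
  postbleach <- as.numeric(postbleach)
  if (length(prebleach) != length(postbleach))
    stop("prebleach and postbleach must share the same grid", call. = FALSE)
  if (!is.numeric(mobile_fraction) || length(mobile_fraction) != 1 ||
      mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must be a single value in [0, 1]", call. = FALSE)
  immobile <- (1 - mobile_fraction) * postbleach
  mobile0 <- mobile_fraction * postbleach
  if (mobile_fraction == 0 || D == 0) {
    return(lapply(seq_along(sample_times), function(i) postbleach))
  }
  mob <- evolve_profile(diffusion_state(mobile0, dx, time = 0), D, sample_times)
  lapply(mob, function(m) m + immobile)
}

#' Analytic no-flux diffusion solution (cosine series)
#'
#' Closed-form solution of the 1D diffusion equation with reflecting
#' boundaries on `[0, L]`, evaluated at the cell-centred grid points
#' x_i = (i - 1/2) dx. The initial profile is expanded in the discrete cosine
#' basis (DCT-II), each mode is decayed by exp(-D (k pi / L)^2 t), and the
#' series is resummed. Serves as the independent oracle for the
#' finite-difference engine and as an engine-independent FRAP ground-truth
#' generator.
#'
#' @param initial Numeric initial profile at the cell-centred grid.
#' @param dx Grid spacing (micrometres).
#' @param D Diffusion coefficient (um^2/s).
#' @param times Times (s) at which to evaluate.
#' @return A list of profiles, one per time.
#' @export
cosine_series_solution <- function(initial, dx, D, times) {
  initial <- as.numeric(initial)
  n <- length(initial)
  if (n < 3) stop("initial profile must have at least 3 points", call. = FALSE)
  L <- n * dx
  x <- (seq_len(n) - 0.5) * dx
  k <- seq_len(n - 1)
  # DCT-II coefficients against cos(k pi x / L) on the midpoint grid
  basis <- cos(outer(x, k) * pi / L)          # n x (n-1)
  a0 <- mean(initial)
  ak <- as.numeric(crossprod(basis, initial)) * (2 / n)
  lam <- D * (k * pi / L)^2
  lapply(times, function(t) {
    a0 + as.numeric(basis %*% (ak * exp(-lam * t)))
  })
}
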