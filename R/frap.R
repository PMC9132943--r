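#' Construct a FRAP recovery curve directly
#'
#' Wraps pre-extracted normalized bleach-centre values as a `frap_curve`,
#' e.g. for fitting curves produced outside the image pipeline. Times are
#' relative to the first post-bleach frame (`times[1] = 0`) and values are
#' normalized so the pre-bleach level is 1.
#'
#' @param times Times in seconds, starting at 0.
#' @param values Normalized fluorescence values, one per time.
#' @return A `frap_curve` object.
#' @export
frap_curve <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values lengths differ", call. = FALSE)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and increase", call. = FALSE)
  structure(
    list(times = times, values = values, prebleach_window_value = NA_real_,
         center = NA_integer_, window = NA_integer_),
    class = "frap_curve"
  )
}

#' Locate the bleach centre along the axial profile
#'
#' Subtracts the (normalized) pre-bleach profile from the first post-bleach
#' profile and returns the index of the minimum of this difference profile —
#' the centre of the bleached line. Ties are broken toward the geometric cell
#' centre, then toward the lower index.
#'
#' @param profile A normalized [axial_profile()].
#' @return Integer grid index of the bleach centre.
#' @export
find_bleach_center <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  diffp <- profile$profiles[[profile$bleach_index]] - .prebleach_profile(profile)
  if (min(diffp) >= 0)
    stop("no bleach detected: difference profile is non-negative everywhere",
         call. = FALSE)
  cand <- which(diffp <= min(diffp) + 1e-12 * abs(min(diffp)))
  mid <- (length(diffp) + 1) / 2
  cand <- cand[order(abs(cand - mid), cand)]
  as.integer(cand[1])
}

#' FRAP recovery curve at the bleach centre
#'
#' Averages the normalized intensity over a window around the bleach centre
#' for every post-bleach frame and divides by the pre-bleach value over the
#' same window, yielding a dimensionless curve with the pre-bleach level at 1.
#' Times are reported relative to the first post-bleach frame.
#'
#' @param profile A normalized [axial_profile()].
#' @param center Bleach-centre grid index (see [find_bleach_center()]).
#' @param window Half-width of the averaging window in pixels (default 1,
#'   i.e. a 3-pixel window).
#' @return An object of class `frap_curve`: list with `times` (s, starting at
#'   0), `values` (normalized), and `prebleach_window_value` (the raw
#'   pre-bleach window mean used as the reference).
#' @export
recovery_curve <- function(profile, center, window = 1) {
  stopifnot(inherits(profile, "axial_profile"))
  n <- length(profile$positions)
  if (center < 1 || center > n)
    stop("center outside the position grid", call. = FALSE)
  if (window < 0 || center - window < 1 || center + window > n)
    stop("window exceeds the position grid", call. = FALSE)
  w <- (center - window):(center + window)
  pre_val <- mean(.prebleach_profile(profile)[w])
  if (pre_val <= 0)
    stop("pre-bleach window value must be positive", call. = FALSE)
  post_idx <- profile$bleach_index:length(profile$profiles)
  vals <- vapply(profile$profiles[post_idx],
                 function(p) mean(p[w]) / pre_val, numeric(1))
  times <- profile$frame_times[post_idx] -
    profile$frame_times[profile$bleach_index]
  if (any(vals < -0.2 | vals > 1.5))
    warning("recovery-curve values outside the sanity band [-0.2, 1.5]",
            call. = FALSE)
  structure(
    list(times = times, values = vals, prebleach_window_value = pre_val,
         center = center, window = window),
    class = "frap_curve"
  )
}

#' Mobile fraction from pre-bleach, post-bleach and final fluorescence
#'
#' The mobile proportion of fluorophores,
#' `M = (final - postbleach) / (prebleach - postbleach)`,
#' where all three values are normalized fluorescence at the bleach centre.
#' The raw value is returned together with its clip to `[0, 1]`.
#'
#' @param prebleach_value Scaled pre-bleach fluorescence at the centre.
#' @param postbleach_value Fluorescence immediately after the bleach.
#' @param final_value Final (plateau) fluorescence.
#' @return List with `raw` and `clipped` mobile fractions.
#' @examples
#' mobile_fraction(1.0, 0.2, 0.8)$raw  # 0.75
#' @export
mobile_fraction <- function(prebleach_value, postbleach_value, final_value) {
  if (prebleach_value <= postbleach_value)
    stop("no bleach: prebleach fluorescence must exceed postbleach",
         call. = FALSE)
  raw <- (final_value - postbleach_value) /
    (prebleach_value - postbleach_value)
  list(raw = raw, clipped = min(1, max(0, raw)))
}

#' Fit a single-exponential recovery
#'
#' Least-squares fit of the recovery above the post-bleach level,
#' `values(t) - values(0)`, to `f(t) = A (1 - exp(-tau t))`. Initial values
#' are `A0 = last - first` and `tau0 = 1 / t_half-rise`; fitting uses
#' Levenberg-Marquardt with a parameter tolerance of 1e-10 and a few
#' perturbed restarts before giving up.
#'
#' @param curve A [frap_curve()] with at least 4 points.
#' @return List with `A` (amplitude), `tau` (rate, 1/s), `fitted` (fitted
#'   recovery values on the curve's time grid, above-baseline scale) and
#'   `degenerate` (TRUE when the curve carries no rise and `A = 0`,
#'   `tau = NA` are returned).
#' @export
fit_exponential <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  t <- curve$times
  y <- curve$values - curve$values[1]
  if (length(t) < 4)
    stop("need at least 4 post-bleach points to fit", call. = FALSE)

  a0 <- y[length(y)]
  if (max(abs(y)) < 1e-12 || a0 <= 0) {
    return(list(A = 0, tau = NA_real_, fitted = rep(0, length(y)),
                degenerate = TRUE))
  }
  i_half <- which(y >= a0 / 2)[1]
  tau0 <- if (!is.na(i_half) && t[i_half] > 0) 1 / t[i_half] else 1 / max(t)

  fit <- NULL
  for (fac in c(1, 0.3, 3, 0.1, 10)) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = list(A = a0, tau = tau0 * fac),
        lower = c(0, 1e-12),
        fn = function(p) y - p$A * (1 - exp(-p$tau * t)),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ptol = 1e-10, ftol = 1e-10
        )
      ),
      error = function(e) NULL
    )
    # info codes 1-4 indicate convergence in f, parameters or gradient
    if (!is.null(res) && res$info %in% 1:4) { fit <- res; break }
  }
  if (is.null(fit))
    stop("exponential fit failed to converge after restarts ",
         sprintf("(A0 = %.3g, tau0 = %.3g, n = %d)", a0, tau0, length(t)),
         call. = FALSE)
  cf <- stats::coef(fit)
  list(A = unname(cf[1]), tau = unname(cf[2]),
       fitted = cf[1] * (1 - exp(-cf[2] * t)), degenerate = FALSE)
}

#' Recovery half-time from the exponential rate
#'
#' `tau_1/2 = ln(0.5) / (-tau)`, the time at which the exponential recovery
#' reaches half of its plateau.
#'
#' @param tau Exponential rate constant (1/s, > 0).
#' @return Half-time in seconds.
#' @examples
#' half_time(log(2))  # 1
#' @export
half_time <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0)
    stop("tau must be a single positive rate", call. = FALSE)
  log(0.5) / (-tau)
}

# Predicted bleach-centre curve for candidate D, on the observed time grid.
.predicted_curve <- function(pre, post, M, D, times, dx, w) {
  profs <- simulate_recovery(pre, post, M, D, times, dx)
  pre_val <- mean(pre[w])
  vapply(profs, function(p) mean(p[w]) / pre_val, numeric(1))
}

# Closed-form mobile fraction given D. The two-population model is linear in
# M: observable = M * evolve(post) + (1 - M) * post, so the least-squares M
# for a fixed D is a one-parameter regression of (obs - post-level) on
# (full-mobility curve - post-level), clipped to [0, 1].
.profile_M <- function(e_curve, p0, obs_values) {
  den <- sum((e_curve - p0)^2)
  if (den <= 0) return(0)
  min(1, max(0, sum((obs_values - p0) * (e_curve - p0)) / den))
}

#' Estimate the diffusion coefficient by simulation matching
#'
#' For candidate diffusion coefficients, predicts the bleach-centre recovery
#' curve by evolving the post-bleach profile's mobile component with the
#' finite-difference diffusion engine ([simulate_recovery()]) and measures
#' the sum of squared differences to the observed curve. The best D is found
#' by a deterministic log-spaced grid scan (25 points per decade) followed by
#' golden-section refinement, so results are exactly reproducible.
#'
#' When `M = NULL` the mobile fraction is profiled out instead of fixed:
#' because the two-population model is linear in M, the best M for each
#' candidate D has a closed form, and the search minimizes this profiled
#' objective, returning the joint least-squares pair (M, D). This is the
#' package's default estimator — conditioning D on a mobile fraction taken
#' from the exponential-fit plateau propagates the plateau's extrapolation
#' bias into D whenever recovery is incomplete within the imaging window.
#'
#' @param profile A normalized [axial_profile()].
#' @param center Bleach-centre index.
#' @param M Mobile fraction in `[0, 1]` to condition on, or `NULL` (default)
#'   to profile M out and estimate the pair jointly.
#' @param window Centre-window half-width in pixels (default 1).
#' @param D_range Search range in um^2/s (default `c(1e-6, 1e-1)`).
#' @param rel_tol Relative tolerance on D for the refinement (default 1e-3).
#' @param points_per_decade Grid density of the initial scan (default 25).
#' @return List with `D` (um^2/s), `M` (the supplied or profiled mobile
#'   fraction) and `rss` (residual sum of squares of the matched curve).
#' @export
estimate_D <- function(profile, center, M = NULL, window = 1,
                       D_range = c(1e-6, 1e-1), rel_tol = 1e-3,
                       points_per_decade = 25) {
  stopifnot(inherits(profile, "axial_profile"))
  if (!is.null(M) && (M < 0 || M > 1))
    stop("M must lie in [0, 1]", call. = FALSE)
  obs <- recovery_curve(profile, center, window)
  pre <- .prebleach_profile(profile)
  # after normalization all frames share the pre-bleach total
  post <- profile$profiles[[profile$bleach_index]]
  dx <- diff(profile$positions[1:2])
  w <- (center - window):(center + window)
  p0 <- mean(post[w]) / mean(pre[w])

  objective <- function(D) {
    if (is.null(M)) {
      e_curve <- .predicted_curve(pre, post, 1, D, obs$times, dx, w)
      m_hat <- .profile_M(e_curve, p0, obs$values)
      sum((m_hat * e_curve + (1 - m_hat) * p0 - obs$values)^2)
    } else {
      pred <- .predicted_curve(pre, post, M, D, obs$times, dx, w)
      sum((pred - obs$values)^2)
    }
  }

  lg <- seq(log10(D_range[1]), log10(D_range[2]),
            by = 1 / points_per_decade)
  if (lg[length(lg)] < log10(D_range[2]) - 1e-12)
    lg <- c(lg, log10(D_range[2]))
  vals <- vapply(10^lg, objective, numeric(1))
  if (max(vals) - min(vals) <= 1e-12 * max(max(vals), 1))
    stop("objective is flat across the D range: the curve carries no ",
         "recovery information (is the mobile fraction zero?)", call. = FALSE)
  i0 <- which.min(vals)

  # golden-section refinement in log10(D) between the grid neighbours
  lo <- lg[max(1, i0 - 1)]; hi <- lg[min(length(lg), i0 + 1)]
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- objective(10^c1); f2 <- objective(10^c2)
  while ((10^b - 10^a) / 10^((a + b) / 2) > rel_tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- objective(10^c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- objective(10^c2)
    }
  }
  D_hat <- 10^((a + b) / 2)
  M_hat <- if (is.null(M)) {
    e_curve <- .predicted_curve(pre, post, 1, D_hat, obs$times, dx, w)
    .profile_M(e_curve, p0, obs$values)
  } else M
  list(D = D_hat, M = M_hat, rss = objective(D_hat))
}

#' Full per-cell FRAP analysis
#'
#' Runs the complete estimation chain on one calibrated image series (or a
#' pre-extracted [axial_profile()]): profile extraction, total-fluorescence
#' normalization, bleach-centre finding, recovery-curve construction, the
#' single-exponential fit, the mobile fraction, the half-time, and
#' diffusion-coefficient estimation. With the default
#' `estimator = "profiled"` the mobile fraction and diffusion coefficient
#' are estimated jointly (M profiled out of the simulation match, see
#' [estimate_D()]); `estimator = "two_stage"` conditions the D search on the
#' mobile fraction obtained from the exponential-fit plateau. The raw
#' plateau-based mobile fraction is always reported as `M_raw` for QC.
#'
#' @param series An [image_series()] or an [axial_profile()].
#' @param config A configuration list (see [run_config()]); missing entries
#'   fall back to defaults.
#' @return An object of class `frap_estimate`: a one-row data frame with
#'   columns `M_raw`, `M` (clipped), `A`, `tau`, `half_time`, `D`, `rss`,
#'   `n_frames`, `qc_pass` (FALSE when `M_raw` falls outside
#'   `[-0.05, 1.05]`).
#' @export
analyze_frap_series <- function(series, config = run_config()) {
  config <- run_config(config)
  prof <- if (inherits(series, "axial_profile")) {
    series
  } else {
    extract_axial_profile(series, prebleach_frames = config$frap$prebleach_frames)
  }
  prof <- normalize_profiles(prof)
  center <- find_bleach_center(prof)
  curve <- recovery_curve(prof, center, window = config$frap$window)

  fit <- fit_exponential(curve)
  post_val <- curve$values[1]
  final_val <- if (config$frap$final_mode == "plateau" && !fit$degenerate) {
    post_val + fit$A
  } else {
    mean(utils::tail(curve$values, config$frap$final_last_k))
  }
  mf <- mobile_fraction(1, post_val, final_val)
  th <- if (!is.na(fit$tau) && fit$tau > 0) half_time(fit$tau) else NA_real_

  dres <- estimate_D(
    prof, center,
    M = if (config$frap$estimator == "two_stage") mf$clipped else NULL,
    window = config$frap$window,
    D_range = config$frap$D_range, rel_tol = config$frap$D_rel_tol
  )

  est <- data.frame(
    M_raw = mf$raw, M = dres$M, A = fit$A, tau = fit$tau,
    half_time = th, D = dres$D, rss = dres$rss,
    n_frames = length(curve$values),
    qc_pass = mf$raw >= -0.05 && mf$raw <= 1.05
  )
  class(est) <- c("frap_estimate", class(est))
  est
}

#' Summarize FRAP estimates per group
#'
#' Mean, standard deviation and n of the mobile fraction, half-time and
#' diffusion coefficient per group, in the reporting style `mean +- SD
#' (n = ...)`. When exactly two groups are present (or `ratio_groups` names
#' two), the fold ratio of their mean diffusion coefficients is attached.
#'
#' @param estimates A list of [analyze_frap_series()] results or a data frame
#'   with columns `M`, `half_time`, `D`.
#' @param group Optional grouping vector (one label per estimate); default is
#'   a single group `"all"`.
#' @param ratio_groups Optional character pair `c(numerator, denominator)`
#'   selecting the groups for the diffusion fold ratio.
#' @return A list with `table` (per-group data frame of means, SDs, n) and
#'   `D_fold_ratio` (or `NULL`).
#' @export
summarize_frap <- function(estimates, group = NULL, ratio_groups = NULL) {
  df <- if (is.data.frame(estimates)) estimates else do.call(rbind, estimates)
  if (nrow(df) == 0) stop("no estimates to summarize", call. = FALSE)
  if (is.null(group)) group <- rep("all", nrow(df))
  if (length(group) != nrow(df))
    stop("group must have one label per estimate", call. = FALSE)

  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  tab <- do.call(rbind, lapply(split(seq_len(nrow(df)), group), function(i) {
    data.frame(
      group = group[i[1]], n = length(i),
      M_mean = mean(df$M[i]), M_sd = sd0(df$M[i]),
      half_time_mean = mean(df$half_time[i], na.rm = TRUE),
      half_time_sd = sd0(df$half_time[i][!is.na(df$half_time[i])]),
      D_mean = mean(df$D[i]), D_sd = sd0(df$D[i])
    )
  }))
  rownames(tab) <- NULL

  ratio <- NULL
  gs <- unique(group)
  if (is.null(ratio_groups) && length(gs) == 2) ratio_groups <- gs
  if (!is.null(ratio_groups)) {
    num <- tab$D_mean[tab$group == ratio_groups[1]]
    den <- tab$D_mean[tab$group == ratio_groups[2]]
    if (length(num) == 1 && length(den) == 1 && den > 0)
      ratio <- num / den
  }
  list(table = tab, D_fold_ratio = ratio)
}
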