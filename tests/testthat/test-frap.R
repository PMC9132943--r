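test_that("normalization equalizes every frame to the prebleach total", {
  prof <- static_profile()
  half <- prof
  # a frame acquired at exactly half the prebleach total fluorescence
  half$profiles[[3]] <- half$profiles[[1]] * 0.5
  norm <- normalize_profiles(half)
  target <- sum(norm$profiles[[1]])
  # ... is scaled back up by exactly 2
  expect_equal(norm$profiles[[3]], half$profiles[[3]] * 2)
  # prebleach frame is left unchanged; all sums match to 1e-12 relative
  expect_equal(norm$profiles[[1]], prof$profiles[[1]])
  for (p in norm$profiles)
    expect_equal(sum(p) / target, 1, tolerance = 1e-12)
  zero <- prof
  zero$profiles[[2]] <- zero$profiles[[2]] * 0
  expect_error(normalize_profiles(zero), "non-positive")
})

test_that("bleach centre is the difference-profile minimum with tie rules", {
  prof <- normalize_profiles(static_profile(scar_at = 21))
  expect_identical(find_bleach_center(prof), 21L)
  # two equal minima at 11 and 31 on a 41-point grid: both equidistant from
  # the centre (21), the lower index wins
  pre <- rep(100, 41)
  post <- pre; post[c(11, 31)] <- 20
  prof2 <- axial_profile((1:41 - 0.5) * 0.05, list(pre, post, post),
                         c(0, 60, 120), 1, 2)
  expect_identical(find_bleach_center(normalize_profiles(prof2)), 11L)
  # an off-centre tie resolves to the centre-nearer minimum
  post3 <- pre; post3[c(5, 25)] <- 20
  prof3 <- axial_profile((1:41 - 0.5) * 0.05, list(pre, post3, post3),
                         c(0, 60, 120), 1, 2)
  expect_identical(find_bleach_center(normalize_profiles(prof3)), 25L)
  # unbleached series carries no minimum below zero
  prof4 <- axial_profile((1:41 - 0.5) * 0.05, list(pre, pre, pre),
                         c(0, 60, 120), 1, 2)
  expect_error(find_bleach_center(prof4), "no bleach")
})

test_that("recovery curve is normalized to the prebleach window", {
  prof <- normalize_profiles(static_profile(n_frames = 8))
  cv <- recovery_curve(prof, find_bleach_center(prof), window = 1)
  expect_equal(cv$times[1], 0)
  expect_lt(cv$values[1], 1)          # a bleach really happened
  # static scar: curve never recovers, stays at the postbleach level
  expect_equal(cv$values, rep(cv$values[1], length(cv$values)))
  # prebleach frame evaluated through the same window is exactly 1
  w <- (cv$center - 1):(cv$center + 1)
  pre <- prof$profiles[[1]]
  expect_equal(mean(pre[w]) / cv$prebleach_window_value, 1)
  expect_error(recovery_curve(prof, 1, window = 3), "window")
})

test_that("mobile fraction follows its defining closed form", {
  expect_equal(mobile_fraction(1.0, 0.2, 0.8)$raw, 0.75)
  expect_equal(mobile_fraction(1.0, 0.2, 1.0)$raw, 1)   # full recovery
  expect_equal(mobile_fraction(1.0, 0.2, 0.2)$raw, 0)   # no recovery
  # raw value is preserved, companion is clipped
  over <- mobile_fraction(1.0, 0.2, 1.1)
  expect_equal(over$raw, 1.125)
  expect_equal(over$clipped, 1)
  expect_error(mobile_fraction(0.5, 0.6, 0.7), "prebleach")
})

test_that("exponential fit recovers exact model parameters", {
  t <- seq(0, 3600, by = 60)
  cv <- frap_curve(t, 0.2 + 0.8 * (1 - exp(-0.1 * t)))
  fit <- fit_exponential(cv)
  expect_equal(fit$A, 0.8, tolerance = 1e-6)
  expect_equal(fit$tau, 0.1, tolerance = 1e-6)
  # constant curve: no rise to fit, flagged degenerate with A = 0
  flat <- fit_exponential(frap_curve(t, rep(0.3, length(t))))
  expect_equal(flat$A, 0)
  expect_true(is.na(flat$tau))
  expect_true(flat$degenerate)
  expect_error(fit_exponential(frap_curve(c(0, 60, 120), c(0.2, 0.3, 0.4))),
               "at least 4")
})

test_that("exponential fit is unbiased under modest Gaussian noise", {
  t <- seq(0, 3600, by = 60)
  clean <- 0.2 + 0.8 * (1 - exp(-0.1 * t))
  set.seed(11)
  a_hat <- replicate(20, {
    fit_exponential(frap_curve(t, clean + rnorm(length(t), 0, 0.02)))$A
  })
  expect_lt(abs(mean(a_hat) - 0.8), 0.02)
})

test_that("half-time transforms the exponential rate", {
  expect_equal(half_time(log(2)), 1.0)
  expect_equal(half_time(1), log(2))
  expect_error(half_time(0), "positive")
  expect_error(half_time(-1), "positive")
})

test_that("plateau-based mobile fraction equals A/(pre - post) exactly", {
  # Eq. consistency: with final = postbleach + A the two mobile-fraction
  # routes coincide algebraically
  set.seed(4)
  for (i in 1:10) {
    pre <- 1
    post <- runif(1, 0.05, 0.6)
    A <- runif(1, 0, pre - post)
    m1 <- mobile_fraction(pre, post, post + A)$raw
    expect_equal(m1, A / (pre - post), tolerance = 1e-10)
  }
})

test_that("D search recovers the generating coefficient exactly", {
  dx <- 0.05; n <- 60
  pre <- rep(2000, n)
  post <- pre; post[28:33] <- 400
  times <- seq(0, 1800, by = 60)
  truth <- simulate_recovery(pre, post, 0.8, 4e-4, times, dx)
  prof <- axial_profile((1:n - 0.5) * dx, c(list(pre), truth),
                        c(-60, times), 1, 2)
  # conditioned on the true mobile fraction: objective-zero minimum
  fixed <- estimate_D(normalize_profiles(prof), 30, M = 0.8)
  expect_equal(fixed$D, 4e-4, tolerance = 2e-3)
  expect_lt(fixed$rss, 1e-8)
  # profiled: joint (M, D) least squares lands on the same point
  joint <- estimate_D(normalize_profiles(prof), 30)
  expect_equal(joint$D, 4e-4, tolerance = 2e-3)
  expect_equal(joint$M, 0.8, tolerance = 1e-3)
})

test_that("a fully immobile curve carries no D information", {
  prof <- normalize_profiles(static_profile(n_frames = 10))
  centre <- find_bleach_center(prof)
  expect_error(estimate_D(prof, centre, M = 0), "flat|no recovery")
})

test_that("estimated half-time decreases with the true diffusion rate", {
  ths <- vapply(c(1e-4, 4e-4, 1.6e-3), function(D) {
    sim <- generate_frap_series(quick_params(D = D, M = 1, seed = 2))
    analyze_frap_series(sim$series)$half_time
  }, numeric(1))
  expect_true(all(diff(ths) < 0))
})

test_that("per-cell pipeline errors on too-short series", {
  sim <- generate_frap_series(quick_params(seed = 3))
  short <- image_series(sim$series$frames[1:2, , , drop = FALSE],
                        sim$series$pixel_size, sim$series$frame_interval)
  expect_error(analyze_frap_series(short), "frames")
})

test_that("group summary reports mean, SD, n and the D fold ratio", {
  mk <- function(M, D) {
    data.frame(M_raw = M, M = M, A = 0.5, tau = 0.01, half_time = 69,
               D = D, rss = 0, n_frames = 30, qc_pass = TRUE)
  }
  # two groups at the reported mean diffusion coefficients: cargo enzymes
  # diffuse more than 14-fold faster than shell proteins
  ests <- rbind(mk(0.83, 4.02e-4), mk(0.06, 0.28e-4))
  s <- summarize_frap(ests, group = c("cargo", "shell"),
                      ratio_groups = c("cargo", "shell"))
  expect_equal(s$D_fold_ratio, 4.02 / 0.28, tolerance = 1e-12)
  expect_gt(s$D_fold_ratio, 14)
  # single estimate: SD 0 with n = 1
  one <- summarize_frap(mk(0.5, 1e-4))
  expect_equal(one$table$n, 1)
  expect_equal(one$table$M_sd, 0)
  # duplicates: SD exactly 0
  dup <- summarize_frap(rbind(mk(0.5, 1e-4), mk(0.5, 1e-4)))
  expect_equal(dup$table$D_sd, 0)
  expect_error(summarize_frap(mk(0.5, 1e-4)[0, ]), "no estimates")
})
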