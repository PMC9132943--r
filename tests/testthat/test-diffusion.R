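test_that("discrete Laplacian: steady states, point source, conservation", {
  # constant profile is a steady state
  expect_equal(discrete_laplacian(rep(3, 10), dx = 0.1), rep(0, 10))
  # unit point source on a 3-point grid, reflecting boundaries
  expect_equal(discrete_laplacian(c(0, 1, 0), dx = 1), c(1, -2, 1))
  # dx scaling
  expect_equal(discrete_laplacian(c(0, 1, 0), dx = 0.5), c(4, -8, 4))
  # discrete divergence theorem: no-flux Laplacian sums to zero
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:80, 1), 0, 10)
    expect_lt(abs(sum(discrete_laplacian(p, dx = 0.05))), 1e-9)
  }
  expect_error(discrete_laplacian(c(1, 2), dx = 1), "at least 3")
})

test_that("single Euler step: identities and stability guard", {
  st <- diffusion_state(c(1, 5, 2, 8, 1), dx = 0.1)
  # zero diffusion leaves the profile unchanged
  expect_equal(diffusion_step(st, D = 0, dt = 10)$concentration,
               st$concentration)
  # uniform profile is invariant under any D
  u <- diffusion_state(rep(4, 8), dx = 0.1)
  expect_equal(diffusion_step(u, D = 1e-3, dt = 1)$concentration, rep(4, 8))
  # stability bound D*dt/dx^2 <= 0.25 is enforced
  expect_error(diffusion_step(st, D = 1e-2, dt = 1), "unstable")
  # time bookkeeping
  expect_equal(diffusion_step(st, D = 1e-4, dt = 2)$time, 2)
})

test_that("compiled evolution path agrees with the R reference step", {
  dx <- 0.05; D <- 1e-3
  dt_max <- 0.25 * dx^2 / D
  nst <- 40L
  st <- diffusion_state(c(rep(10, 10), rep(0, 10)), dx)
  ref <- st
  for (i in seq_len(nst)) ref <- diffusion_step(ref, D, dt_max)
  out <- evolve_profile(st, D, sample_times = nst * dt_max)[[1]]
  expect_equal(out, ref$concentration, tolerance = 1e-12)
})

test_that("Gaussian profile spreads with variance sigma0^2 + 2 D t", {
  dx <- 0.05; n <- 400
  x <- (seq_len(n) - 0.5) * dx
  mu <- n / 2 * dx; s0 <- 0.2; D <- 1e-3; t_end <- 10
  st <- diffusion_state(exp(-(x - mu)^2 / (2 * s0^2)), dx)
  out <- evolve_profile(st, D, t_end)[[1]]
  m <- sum(out * x) / sum(out)
  v <- sum(out * (x - m)^2) / sum(out)
  expect_equal(v, s0^2 + 2 * D * t_end, tolerance = 0.02)
  # mass conserved through the evolution
  expect_equal(sum(out), sum(st$concentration), tolerance = 1e-9)
})

test_that("long-time evolution converges to the uniform conserved mean", {
  dx <- 0.05; n <- 40
  st <- diffusion_state(c(rep(10, 20), rep(0, 20)), dx)
  L <- n * dx; D <- 1e-3
  out <- evolve_profile(st, D, sample_times = 10 * L^2 / D)[[1]]
  expect_lt(max(abs(out - 5)) / 5, 1e-3)
})

test_that("evolution at the current time returns the profile unchanged", {
  st <- diffusion_state(c(1, 2, 3, 4), dx = 0.1, time = 5)
  expect_equal(evolve_profile(st, D = 1e-3, sample_times = 5)[[1]],
               st$concentration)
  expect_error(evolve_profile(st, 1e-3, c(10, 7)), "non-decreasing")
  expect_error(evolve_profile(st, 1e-3, 1), "precede")
})

test_that("halving the time step changes the solution by < 0.1%", {
  dx <- 0.05; D <- 1e-4; t_end <- 600
  prof <- c(rep(10, 30), rep(2, 10), rep(10, 20))
  dt1 <- 0.25 * dx^2 / D
  n1 <- ceiling(t_end / dt1)
  a <- diffusion_state(prof, dx)
  b <- diffusion_state(prof, dx)
  for (i in seq_len(n1)) a <- diffusion_step(a, D, t_end / n1)
  for (i in seq_len(2 * n1)) b <- diffusion_step(b, D, t_end / (2 * n1))
  expect_lt(max(abs(a$concentration - b$concentration)) /
              max(b$concentration), 1e-3)
})

test_that("engine matches the analytic cosine-series no-flux solution", {
  n <- 64; dx <- 0.05; L <- n * dx; D <- 4e-4
  x <- (seq_len(n) - 0.5) * dx
  init <- 1 - 0.8 * exp(-(x - L / 2)^2 / (2 * 0.15^2))
  times <- c(1, 60, 600, L^2 / D * c(0.1, 0.5, 1))
  fd <- evolve_profile(diffusion_state(init, dx), D, times)
  an <- cosine_series_solution(init, dx, D, times)
  for (k in seq_along(times)) {
    expect_lt(max(abs(fd[[k]] - an[[k]])) / max(abs(an[[k]])), 0.005)
  }
})

test_that("evolution forms a semigroup on commensurate sample times", {
  dx <- 0.05; D <- 1e-3
  dt <- 0.25 * dx^2 / D              # the engine's stability step
  t1 <- 160 * dt; t2 <- 320 * dt
  prof <- c(rep(8, 15), rep(1, 5), rep(8, 20))
  one <- evolve_profile(diffusion_state(prof, dx), D, t1 + t2)[[1]]
  mid <- evolve_profile(diffusion_state(prof, dx), D, t1)[[1]]
  two <- evolve_profile(diffusion_state(mid, dx, time = t1), D, t1 + t2)[[1]]
  expect_equal(two, one, tolerance = 1e-10)
})

test_that("two-population recovery: frozen, equilibrated and mixed limits", {
  dx <- 0.05; n <- 40
  pre <- rep(10, n)
  post <- pre; post[18:23] <- 2
  L <- n * dx
  # M = 0: fully immobile, profile frozen at the post-bleach scar
  froz <- simulate_recovery(pre, post, 0, 1e-3, c(60, 600, 3600), dx)
  for (p in froz) expect_equal(p, post)
  # M = 1, long time: uniform at the post-bleach mean
  eq <- simulate_recovery(pre, post, 1, 1e-3, 10 * L^2 / 1e-3, dx)[[1]]
  expect_equal(eq, rep(mean(post), n), tolerance = 1e-3)
  # M = 0.5, long time: half frozen scar + half equilibrated mean
  mix <- simulate_recovery(pre, post, 0.5, 1e-3, 10 * L^2 / 1e-3, dx)[[1]]
  expect_equal(mix[20], 0.5 * mean(post) + 0.5 * post[20], tolerance = 1e-3)
  # mass conserved at every reported time
  obs <- simulate_recovery(pre, post, 0.7, 4e-4, c(60, 600, 1800), dx)
  for (p in obs) expect_equal(sum(p), sum(post), tolerance = 1e-9)
  expect_error(simulate_recovery(pre, post, 1.2, 1e-3, 60, dx), "0, 1")
  expect_error(simulate_recovery(pre, post[-1], 1, 1e-3, 60, dx), "grid")
})

test_that("recovery at the bleach centre is monotone non-decreasing", {
  dx <- 0.05; n <- 60
  pre <- rep(10, n)
  post <- pre; post[28:33] <- 2
  times <- seq(60, 3600, by = 60)
  obs <- simulate_recovery(pre, post, 0.8, 4e-4, times, dx)
  centre <- vapply(obs, function(p) p[30], numeric(1))
  expect_true(all(diff(centre) >= -1e-12))
})
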