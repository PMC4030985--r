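# Stochastic samplers: propagator contracts, equilibrium statistics and
# reproducibility.

test_that("langevin_step is the identity with zero force and zero noise", {
  lp <- langevin_params(kBT = 1, dt = 0.01)
  x <- matrix(rnorm(30), 10, 3)
  zero_f <- function(x) matrix(0, nrow(x), 3)
  expect_identical(langevin_step(x, zero_f, lp, noise = matrix(0, 10, 3)), x)
  # deterministic given the seed
  set.seed(9); a <- langevin_step(x, zero_f, lp)
  set.seed(9); b <- langevin_step(x, zero_f, lp)
  expect_identical(a, b)
  expect_error(langevin_params(kBT = 1, dt = 0.01, D = 99), "inconsistent")
  expect_error(langevin_step(x, function(x) x * NaN, lp), "non-finite")
})

test_that("harmonic-well statistics match closed forms (variance and autocorrelation)", {
  # 1-D overdamped particle in V = k x^2 / 2 with dt*D*k/kBT = 0.01:
  # stationary variance kBT/k, autocorrelation exp(-D k t / kBT)
  k <- 1; lp <- langevin_params(kBT = 1, dt = 0.01)
  force_fn <- function(x) -k * x
  set.seed(123)
  n_steps <- 2e5
  xs <- numeric(n_steps)
  x <- 0
  drift <- lp$dt * lp$D / lp$kBT
  sdn <- sqrt(2 * lp$D * lp$dt)
  noise <- rnorm(n_steps)
  for (i in seq_len(n_steps)) {
    x <- x + drift * force_fn(x) + sdn * noise[i]
    xs[i] <- x
  }
  xs <- xs[-(1:2000)]
  expect_equal(var(xs), lp$kBT / k, tolerance = 0.05)
  lag <- 50                                   # t = 0.5 reduced time units
  rho <- cor(xs[-(1:lag)], xs[1:(length(xs) - lag)])
  expect_equal(rho, exp(-lp$D * k * lag * lp$dt / lp$kBT), tolerance = 0.05)
})

test_that("mc_step obeys the zero-temperature limit and proposal geometry", {
  ms <- move_set(mix = 0)
  x <- extended_chain(6)
  # uphill proposals always rejected at kBT = 0
  uphill <- function(y) if (identical(y, x)) 0 else 1
  set.seed(2)
  for (i in 1:20) {
    r <- mc_step(x, uphill, ms, kBT = 0)
    expect_false(r$accepted)
    expect_identical(r$x, x)
  }
  # crankshaft proposals preserve all bond lengths
  ms2 <- move_set(mix = 1)
  y <- toy20()$trace$xyz
  set.seed(3)
  for (i in 1:20) {
    r <- mc_step(y, function(z) 0, ms2, kBT = 1)
    expect_lt(max(abs(sqrt(rowSums(diff(r$x)^2)) -
                      sqrt(rowSums(diff(y)^2)))), 1e-10)
    y <- r$x
  }
  # short chains fall back to single-bead moves with a warning
  expect_warning(mc_step(extended_chain(3), function(z) 0,
                         move_set(mix = 1), kBT = 1),
                 "single-bead")
})

test_that("two-state occupancy ratio follows the Boltzmann factor", {
  # equal-curvature 1-D double well offset by dE: Z+/Z- = exp(dE/kBT)
  dE <- 1; kBT <- 1
  energy_fn <- function(x) {
    0.5 * 8 * (abs(x[1, 1]) - 1)^2 + dE * (x[1, 1] < 0) +
      2 * (x[1, 2]^2 + x[1, 3]^2)
  }
  ms <- move_set(mix = 0, displacement_max = 0.6)
  set.seed(7)
  x <- matrix(c(1, 0, 0), 1, 3)
  n_prop <- 6e4
  occ <- logical(n_prop)
  for (i in seq_len(n_prop)) {
    r <- mc_step(x, energy_fn, ms, kBT)
    x <- r$x
    occ[i] <- x[1, 1] > 0
  }
  occ <- occ[-(1:5000)]
  # batch-means standard error over 20 batches
  bm <- tapply(occ, rep(1:20, each = length(occ) / 20), mean)
  ratio <- mean(bm) / (1 - mean(bm))
  lo <- log(ratio)
  se_lo <- sd(bm) / sqrt(20) / (mean(bm) * (1 - mean(bm)))
  expect_lt(abs(lo - dE / kBT), 3 * se_lo)
})

test_that("Metropolis sampling reproduces Boltzmann weights across bins (chi-square)", {
  # single bead in a quartic double well, x-marginal binned and compared
  # with numerically integrated Boltzmann weights
  kBT <- 1
  vx <- function(x) 2 * (x^2 - 1)^2
  energy_fn <- function(x) vx(x[1, 1]) + 2 * (x[1, 2]^2 + x[1, 3]^2)
  ms <- move_set(mix = 0, displacement_max = 0.7)
  set.seed(17)
  x <- matrix(c(1, 0, 0), 1, 3)
  n_prop <- 1.2e5
  thin <- 60
  xs <- numeric(0)
  for (i in seq_len(n_prop)) {
    x <- mc_step(x, energy_fn, ms, kBT)$x
    if (i %% thin == 0) xs <- c(xs, x[1, 1])
  }
  xs <- xs[-(1:200)]
  edges <- c(-Inf, -1.2, -0.8, -0.4, 0, 0.4, 0.8, 1.2, Inf)
  obs <- table(cut(xs, edges))
  pk <- vapply(seq_len(length(edges) - 1), function(b) {
    stats::integrate(function(u) exp(-vx(u) / kBT),
                     max(edges[b], -6), min(edges[b + 1], 6))$value
  }, numeric(1))
  pk <- pk / sum(pk)
  p <- suppressWarnings(stats::chisq.test(as.vector(obs), p = pk)$p.value)
  expect_gt(p, 0.01)
})

test_that("run_sampler is bit-reproducible and logs consistent scalars", {
  tn <- toy20()
  mod <- go_model(tn$trace, tn$map)
  t1 <- run_sampler(tn$trace$xyz, mod, "mc", n_sweeps = 300, kBT = 0.8,
                    stride = 50, seed = 99)
  t2 <- run_sampler(tn$trace$xyz, mod, "mc", n_sweeps = 300, kBT = 0.8,
                    stride = 50, seed = 99)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$scalars, t2$scalars)
  # logged energy and Q of the final frame match a fresh evaluation
  xf <- traj_frame(t1, n_frames(t1))
  expect_equal(utils::tail(t1$scalars$energy, 1), go_energy(xf, mod),
               tolerance = 1e-8)
  expect_equal(utils::tail(t1$scalars$q, 1),
               native_fraction(xf, tn$map, 1.2), tolerance = 1e-12)
  # langevin engine: same contracts
  lp <- langevin_params(kBT = 0.8, dt = 2e-4)
  l1 <- run_sampler(tn$trace$xyz, mod, "langevin", n_sweeps = 500,
                    stride = 100, seed = 5, lparams = lp)
  l2 <- run_sampler(tn$trace$xyz, mod, "langevin", n_sweeps = 500,
                    stride = 100, seed = 5, lparams = lp)
  expect_identical(l1$frames, l2$frames)
  # unstable step size is a hard configuration error
  expect_error(
    run_sampler(tn$trace$xyz, mod, "langevin", n_sweeps = 10, seed = 1,
                lparams = langevin_params(kBT = 0.8, dt = 0.1)),
    "unstable")
})

test_that("degenerate schedules are rejected", {
  tn <- toy20()
  mod <- go_model(tn$trace, tn$map)
  expect_error(run_sampler(tn$trace$xyz, mod, "mc", n_sweeps = 0, seed = 1),
               "n_sweeps")
})
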