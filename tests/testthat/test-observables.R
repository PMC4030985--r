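# RMSD, projections, free-energy surfaces, contact statistics, terminus
# energetics and Kramers pathway probabilities.

test_that("kabsch_rmsd: metric properties and proper-rotation restriction", {
  tn <- toy20()
  a <- tn$trace$xyz
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)
  R <- knotfold:::rotation_about_axis(c(2, 1, -1), 0.9)
  b <- sweep(a %*% t(R), 2, c(5, -3, 1), `+`)
  expect_lt(kabsch_rmsd(a, b), 1e-9)
  # symmetry
  set.seed(3)
  c_ <- a + matrix(rnorm(60), 20, 3)
  expect_equal(kabsch_rmsd(a, c_), kabsch_rmsd(c_, a), tolerance = 1e-9)
  # a mirror image must NOT superpose to zero (proper rotations only)
  m <- a
  m[, 1] <- -m[, 1]
  expect_gt(kabsch_rmsd(a, m), 0.5)
  # degenerate (collinear) subsets are refused by name
  line <- extended_chain(20)
  expect_error(kabsch_rmsd(line, line, subset = 1:5), "collinear")
})

test_that("kabsch_rmsd agrees with independent references", {
  tn <- toy20()
  a <- tn$trace$xyz
  set.seed(13)
  b <- a + matrix(rnorm(60, sd = 1), 20, 3)
  # bio3d as an independent superposition oracle (it rounds to 1e-3)
  expect_equal(kabsch_rmsd(a, b),
               bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE),
               tolerance = 1e-3)
  # coarse exhaustive rotation-grid oracle on a 4-point toy
  p <- matrix(c(0, 0, 0, 1.5, 0, 0, 1.5, 2, 0, 0, 2, 1), 4, 3, byrow = TRUE)
  set.seed(14)
  q <- p %*% t(knotfold:::rotation_about_axis(c(1, 1, 0), 0.4)) +
    matrix(rnorm(12, sd = 0.1), 4, 3)
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  score <- function(ang) {
    R <- knotfold:::rotation_about_axis(c(1, 0, 0), ang[1]) %*%
      knotfold:::rotation_about_axis(c(0, 1, 0), ang[2]) %*%
      knotfold:::rotation_about_axis(c(0, 0, 1), ang[3])
    sqrt(mean(rowSums((pc - qc %*% R)^2)))
  }
  # coarse Euler-angle grid followed by local grid refinement
  best <- Inf; best_ang <- c(0, 0, 0)
  for (ax in seq(0, pi, length.out = 13)) {
    for (ay in seq(0, 2 * pi, length.out = 25)) {
      for (az in seq(0, 2 * pi, length.out = 25)) {
        v <- score(c(ax, ay, az))
        if (v < best) { best <- v; best_ang <- c(ax, ay, az) }
      }
    }
  }
  step <- 2 * pi / 24
  for (refine in 1:6) {
    grid <- expand.grid(a = best_ang[1] + step * (-2:2),
                        b = best_ang[2] + step * (-2:2),
                        c = best_ang[3] + step * (-2:2))
    vals <- apply(grid, 1, score)
    k <- which.min(vals)
    if (vals[k] < best) { best <- vals[k]; best_ang <- as.numeric(grid[k, ]) }
    step <- step / 3
  }
  expect_lt(kabsch_rmsd(p, q), best + 1e-9)  # SVD optimum cannot be beaten
  expect_equal(kabsch_rmsd(p, q), best, tolerance = 1e-3)
})

test_that("project_trajectory tracks two-coordinate folding progress", {
  tn <- toy20()
  ref <- tn$trace$xyz
  # constant trajectory: a single repeated point
  const_traj <- cg_trajectory(list(ref, ref, ref), stride = 1)
  pr <- project_trajectory(const_traj, ref)
  expect_equal(pr$a, rep(0, 3), tolerance = 1e-9)
  expect_equal(pr$b, rep(0, 3), tolerance = 1e-9)
  # planted two-phase fixture: subset b (first helix) forms first
  sub_b <- 1:9
  mid <- ref
  set.seed(6)
  mid[10:20, ] <- mid[10:20, ] + matrix(rnorm(33, sd = 3), 11, 3)
  start <- ref + matrix(rnorm(60, sd = 3), 20, 3)
  traj <- cg_trajectory(list(start, mid, ref), stride = 1)
  pr2 <- project_trajectory(traj, ref, subset_a = NULL, subset_b = sub_b)
  expect_lt(pr2$b[2], 2)           # helix already formed at frame 2
  expect_gt(pr2$a[2], 2)           # whole chain still unfolded
  expect_lt(pr2$a[3], 1e-6)
})

test_that("fes_2d reproduces closed-form free-energy differences", {
  set.seed(21)
  # two bins with 10:1 occupancy: dF = kBT ln 10
  xs <- c(rep(0.25, 5000), rep(0.75, 500)) + runif(5500, -0.2, 0.2)
  ys <- runif(5500, 0, 1)
  fes <- fes_2d(cbind(xs, ys), breaks_a = c(0, 0.5, 1), breaks_b = c(0, 1),
                kBT = 2)
  expect_identical(min(fes$f, na.rm = TRUE), 0)
  expect_equal(fes$f[2, 1] - fes$f[1, 1], 2 * log(10), tolerance = 0.1)
  # equal occupancy: dF ~ 0
  xs2 <- runif(4000)
  fes2 <- fes_2d(cbind(xs2, runif(4000)), breaks_a = c(0, 0.5, 1),
                 breaks_b = c(0, 1), kBT = 1)
  expect_lt(abs(fes2$f[2, 1] - fes2$f[1, 1]), 0.15)
  # duplication invariance
  fes3 <- fes_2d(cbind(c(xs, xs), c(ys, ys)), breaks_a = c(0, 0.5, 1),
                 breaks_b = c(0, 1), kBT = 2)
  expect_equal(fes3$f, fes$f, tolerance = 1e-9)
  # empty bins masked, single-bin surfaces warn
  expect_warning(fes_2d(cbind(0.5, 0.5), 3, 3), "single bin")
})

test_that("ss-resolved fractions are consistent with the overall Q", {
  tn <- toy20()
  st <- ss_contact_fractions(tn$trace$xyz, tn$map, 1.2)
  expect_identical(st$overall, 1)
  ext <- ss_contact_fractions(extended_chain(20), tn$map, 1.2)
  expect_identical(ext$overall, 0)
  set.seed(9)
  x <- tn$trace$xyz + matrix(rnorm(60, sd = 1.2), 20, 3)
  st2 <- ss_contact_fractions(x, tn$map, 1.2)
  w <- st2$n_pairs
  cls_vals <- c(st2$alpha, st2$beta, st2$other)
  present <- w > 0
  expect_equal(sum(cls_vals[present] * w[present]) / sum(w),
               native_fraction(x, tn$map, 1.2), tolerance = 1e-12)
  # class without native pairs reported as NA, not 0
  if (any(w == 0)) expect_true(all(is.na(cls_vals[!present])))
})

test_that("terminus attraction equals a brute-force pair sum and scales like a mean", {
  tn <- toy40()
  mod0 <- go_model(tn$trace, tn$map, lambda_nn = 0)
  mod1 <- go_model(tn$trace, tn$map, lambda_nn = 0.5)
  x <- tn$trace$xyz
  expect_identical(terminus_attraction(list(x), mod0, 6)$mean, 0)
  ta <- terminus_attraction(list(x), mod1, 6)
  # brute force: non-native pairs with exactly one member in the last 6
  nat_key <- paste(tn$map$i, tn$map$j)
  n <- nrow(x)
  term <- (n - 5):n
  e <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < 3 || paste(i, j) %in% nat_key) next
      if (xor(i %in% term, j %in% term)) {
        r <- sqrt(sum((x[i, ] - x[j, ])^2))
        e <- e + mod1$lambda_nn * mod1$B[i, j] /
          (1 + exp((r - mod1$nn_cutoff) / mod1$nn_width))
      }
    }
  }
  expect_equal(ta$mean, e, tolerance = 1e-8)
  # duplicated ensemble: identical mean, se scaled by 1/sqrt(2)
  set.seed(2)
  ens <- lapply(1:6, function(k) x + matrix(rnorm(3 * n, sd = 0.5), n, 3))
  t1 <- terminus_attraction(ens, mod1, 6)
  t2 <- terminus_attraction(c(ens, ens), mod1, 6)
  expect_equal(t2$mean, t1$mean, tolerance = 1e-12)
  ratio <- t2$se / t1$se
  expect_equal(ratio, sqrt((6 - 1) / 6 * 12 / (12 - 1)) / sqrt(2),
               tolerance = 1e-6)
  expect_error(terminus_attraction(list(x), mod1, n), "below the chain")
})

test_that("Kramers pathway probabilities invert barrier differences", {
  expect_equal(
    suppressMessages(pathway_probability_from_barriers(2, 2, 1)),
    c(p1 = 0.5, p2 = 0.5))
  p <- suppressMessages(
    pathway_probability_from_barriers(-log(7 / 3), 0, 1))
  expect_equal(unname(p["p1"]), 0.7, tolerance = 1e-12)
  for (d in c(-2, 0, 1.3)) {
    pp <- suppressMessages(pathway_probability_from_barriers(d, 0.4, 0.8))
    expect_equal(unname(sum(pp)), 1, tolerance = 1e-12)
  }
  expect_error(suppressMessages(
    pathway_probability_from_barriers(Inf, 0, 1)), "finite")
})
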