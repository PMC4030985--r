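# Coarse-grained potential: native minimum, invariances, analytic forces
# against the finite-difference oracle, and the non-native term.

test_that("the native conformation minimizes every Go term", {
  tn <- toy20()
  mod <- go_model(tn$trace, tn$map)
  res <- total_energy_and_force(tn$trace$xyz, mod)
  # bonded terms vanish at the native geometry; each 12-10 well sits at
  # its minimum -eps
  expect_equal(unname(res$terms["bond"]), 0, tolerance = 1e-10)
  expect_equal(unname(res$terms["angle"]), 0, tolerance = 1e-10)
  expect_equal(unname(res$terms["dihedral"]), 0, tolerance = 1e-10)
  expect_equal(unname(res$terms["native"]), -nrow(tn$map), tolerance = 1e-9)
  # forces at the native state are tiny (only the soft repulsion acts)
  expect_lt(max(abs(res$force)), 0.01)
})

test_that("energy is invariant under rigid-body motion", {
  tn <- toy20()
  mod <- go_model(tn$trace, tn$map, lambda_nn = 0.4)
  set.seed(5)
  x <- tn$trace$xyz + matrix(rnorm(60, sd = 0.4), 20, 3)
  e0 <- total_energy_and_force(x, mod)$energy
  R <- knotfold:::rotation_about_axis(c(1, -2, 0.5), 1.1)
  e1 <- total_energy_and_force(sweep(x %*% t(R), 2, c(3, -7, 2), `+`),
                               mod)$energy
  expect_lt(abs(e1 - e0) / abs(e0), 1e-9)
})

test_that("analytic force matches the central finite difference", {
  tn <- toy20()
  for (lam in c(0, 0.5)) {
    mod <- go_model(tn$trace, tn$map, lambda_nn = lam)
    set.seed(11)
    x <- tn$trace$xyz + matrix(rnorm(60, sd = 0.3), 20, 3)
    res <- total_energy_and_force(x, mod)
    e_of <- function(y) {
      knotfold:::cpp_energy_force(y, knotfold:::as_cpp_model(mod),
                                  FALSE)$energy
    }
    h <- 1e-5
    for (i in c(1, 7, 13, 20)) {
      for (k in 1:3) {
        xa <- x; xa[i, k] <- xa[i, k] + h
        xb <- x; xb[i, k] <- xb[i, k] - h
        fd <- -(e_of(xa) - e_of(xb)) / (2 * h)
        expect_equal(res$force[i, k], fd,
                     tolerance = 1e-4 * max(1, abs(fd)))
      }
    }
    # internal forces carry no net translation
    expect_lt(max(abs(colSums(res$force))), 1e-10)
  }
})

test_that("first-order energy change matches force for small displacements", {
  tn <- toy20()
  mod <- go_model(tn$trace, tn$map)
  set.seed(21)
  x <- tn$trace$xyz + matrix(rnorm(60, sd = 0.2), 20, 3)
  res <- total_energy_and_force(x, mod)
  d <- matrix(rnorm(60), 20, 3)
  d <- d / sqrt(sum(d^2)) * 1e-4
  e1 <- go_energy(x + d, mod)
  predicted <- res$energy - sum(res$force * d)
  expect_equal(e1, predicted, tolerance = 1e-7 * max(1, abs(e1)))
})

test_that("non-native term: zero at lambda 0, brute-force sum otherwise", {
  tn <- toy20()
  mod0 <- go_model(tn$trace, tn$map, lambda_nn = 0)
  mod1 <- go_model(tn$trace, tn$map, lambda_nn = 0.7)
  set.seed(31)
  x <- tn$trace$xyz + matrix(rnorm(60, sd = 0.5), 20, 3)
  expect_identical(nonnative_energy(x, mod0), 0)
  # extended conformation far beyond the cutoff: effectively zero
  expect_lt(abs(nonnative_energy(extended_chain(20, spacing = 4.4), mod1)),
            1e-6)
  # brute-force pair loop over the non-native pair list
  nat_key <- paste(tn$map$i, tn$map$j)
  e_brute <- 0
  for (i in 1:19) {
    for (j in (i + 1):20) {
      if (j - i < 3 || paste(i, j) %in% nat_key) next
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      e_brute <- e_brute + mod1$lambda_nn * mod1$B[i, j] /
        (1 + exp((r - mod1$nn_cutoff) / mod1$nn_width))
    }
  }
  expect_equal(nonnative_energy(x, mod1), e_brute, tolerance = 1e-8)
})

test_that("lambda 0 and the pure Go model are bitwise identical", {
  tn <- toy20()
  mod0 <- go_model(tn$trace, tn$map)
  mod1 <- go_model(tn$trace, tn$map, lambda_nn = 0.5)
  set.seed(41)
  x <- tn$trace$xyz + matrix(rnorm(60, sd = 0.4), 20, 3)
  r0 <- total_energy_and_force(x, mod0)
  expect_identical(go_energy(x, mod0), go_energy(x, mod1))
  expect_identical(r0$energy,
                   total_energy_and_force(
                     x, go_model(tn$trace, tn$map, lambda_nn = 0))$energy)
})

test_that("steepest descent from the native state barely moves", {
  tn <- toy20()
  mod <- go_model(tn$trace, tn$map)
  x <- tn$trace$xyz
  for (it in 1:200) {
    f <- total_energy_and_force(x, mod)$force
    x <- x + 1e-3 * f
  }
  expect_lt(kabsch_rmsd(tn$trace$xyz, x), 0.1)
})

test_that("parameter and shape validation", {
  tn <- toy20()
  expect_error(go_model(tn$trace, tn$map, eps_native = -1), "eps_native")
  expect_error(go_model(tn$trace, tn$map, sigma_rep = 0), "sigma_rep")
  mod <- go_model(tn$trace, tn$map)
  expect_error(go_energy(extended_chain(10), mod), "10 beads")
  x <- tn$trace$xyz
  x[3, 2] <- NaN
  expect_error(go_energy(x, mod), "non-finite")
  # quasi-chemical matrix is symmetric and zero-mean over unique pairs
  qc <- qc_contact_matrix()
  expect_identical(dim(qc), c(20L, 20L))
  expect_equal(qc, t(qc))
  expect_lt(abs(mean(qc[upper.tri(qc, diag = TRUE)])), 1e-4)
})
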