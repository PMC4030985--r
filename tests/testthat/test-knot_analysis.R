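# Open-chain topology: closure, Alexander determinants, chirality,
# cores, slipknots and trajectory-level event detection.

test_that("parametric fixtures get the tabulated determinants and labels", {
  cases <- list(
    list(type = "unknot", det = 1L, label = "unknot"),
    list(type = "trefoil_right", det = 3L, label = "trefoil"),
    list(type = "trefoil_left", det = 3L, label = "trefoil"),
    list(type = "figure_eight", det = 5L, label = "det5")
  )
  for (cs in cases) {
    k <- classify_knot(parametric_knot(cs$type, 200))
    expect_identical(k$determinant, cs$det)
    expect_identical(k$label, cs$label)
  }
  # an alternative trefoil parametrization confirms the detector is not
  # tied to the torus-knot form
  tt <- seq(0, 2 * pi, length.out = 201)[1:200]
  alt <- cbind(sin(tt) + 2 * sin(2 * tt), cos(tt) - 2 * cos(2 * tt),
               -sin(3 * tt)) * 3
  expect_identical(classify_knot(alt)$determinant, 3L)
})

test_that("trefoil chirality follows the Gauss-integral writhe and flips under mirror", {
  tr_r <- parametric_knot("trefoil_right", 150)
  tr_l <- parametric_knot("trefoil_left", 150)
  expect_identical(classify_knot(tr_r)$chirality, "right")
  expect_identical(classify_knot(tr_l)$chirality, "left")
  # independent handedness reference: sign of the Gauss writhe
  expect_gt(gauss_writhe(tr_r), 0)
  expect_lt(gauss_writhe(tr_l), 0)
  # mirror flips chirality but not the determinant
  m <- tr_r
  m[, 1] <- -m[, 1]
  km <- classify_knot(m)
  expect_identical(km$chirality, "left")
  expect_identical(km$determinant, 3L)
  # unknots carry no chirality
  expect_identical(classify_knot(parametric_knot("unknot", 80))$chirality,
                   "n/a")
})

test_that("determinant is invariant under reversal, rigid motion and scaling", {
  for (type in c("trefoil_right", "figure_eight")) {
    x <- parametric_knot(type, 150, noise_A = 0.25, seed = 11)
    d0 <- classify_knot(x)$determinant
    expect_identical(classify_knot(x[rev(seq_len(nrow(x))), ])$determinant, d0)
    R <- cbind(c(0.36, -0.8, 0.48), c(0.48, 0.6, 0.64), c(-0.8, 0, 0.6))
    expect_identical(classify_knot(2.5 * x %*% R + 7)$determinant, d0)
    expect_identical(classify_knot(0.2 * x)$determinant, d0)
  }
})

test_that("determinant agrees with the Fox-coloring oracle on perturbed fixtures", {
  set.seed(99)
  n_checked <- 0
  for (rep in 1:12) {
    type <- c("unknot", "trefoil_right", "trefoil_left",
              "figure_eight")[1 + rep %% 4]
    x <- parametric_knot(type, 140, noise_A = 0.2, seed = rep)
    P <- kmt_reduce(close_chain(x))
    cd <- crossing_diagram(P)
    if (cd$n_crossings > 8) next   # keep the brute-force oracle tractable
    d <- classify_knot(x)$determinant
    for (p in c(3, 5)) {
      nontrivial <- fox_colorings(cd, p) > p
      expect_identical(d %% p == 0, nontrivial,
                       info = sprintf("%s rep %d p %d", type, rep, p))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 8)
})

test_that("chain closure is idempotent and deterministic", {
  x <- parametric_knot("trefoil_right", 100)
  p1 <- close_chain(x)
  p2 <- close_chain(x)
  expect_identical(p1, p2)
  # closing an already-closed polygon returns it unchanged
  closed <- rbind(x, x[1, ])
  expect_equal(close_chain(closed), x)
  expect_error(close_chain(x[1:3, ]), "at least 4")
})

test_that("KMT simplification preserves the knot type", {
  for (type in c("unknot", "trefoil_left", "figure_eight")) {
    x <- parametric_knot(type, 220, noise_A = 0.15, seed = 5)
    P <- close_chain(x)
    red <- kmt_reduce(P)
    expect_lt(nrow(red), nrow(P))
    expect_identical(alexander_determinant(P),
                     alexander_determinant(red, reduce = FALSE))
  }
})

test_that("locate_core recovers a planted core and satisfies the trim property", {
  # trefoil occupying the middle of a chain with straight tails
  body <- parametric_knot("trefoil_right", 60)
  d1 <- body[1, ] - body[2, ]
  d2 <- body[60, ] - body[59, ]
  tail_n <- sweep(outer(20:1, d1 / sqrt(sum(d1^2)) * 3), 2, body[1, ], `+`)
  tail_c <- sweep(outer(1:20, d2 / sqrt(sum(d2^2)) * 3), 2, body[60, ], `+`)
  x <- rbind(tail_n, body, tail_c)
  core <- locate_core(x)
  expect_gte(core$start, 18)
  expect_lte(core$end, 82)
  # the core interval is knotted; trimming one more residue from either
  # side unties it (asserted through the closure pipeline itself)
  sub <- x[core$start:core$end, ]
  expect_identical(classify_knot(sub)$label, "trefoil")
  expect_identical(
    classify_knot(x[(core$start + 1):core$end, ])$label, "unknot")
  expect_identical(
    classify_knot(x[core$start:(core$end - 1), ])$label, "unknot")
  # whole-chain trefoil with no tails: the core covers most of the chain
  # (radial closure tolerates trimming a few vertices at the cut point)
  core2 <- locate_core(body)
  expect_lte(core2$start, 12)
  expect_gte(core2$end - core2$start + 1, 2 / 3 * nrow(body))
  expect_error(locate_core(extended_chain(20)), "unknotted")
})

test_that("slipknot detection finds planted slipknots and nothing else", {
  expect_null(detect_slipknot(extended_chain(30)))
  # fully knotted chain: by definition not a slipknot
  expect_null(detect_slipknot(parametric_knot("trefoil_right", 100)))
  # scripted slipknotting intermediate: whole chain unknotted, threaded
  # subchain knotted
  tr <- scripted_mechanism_trajectory("slipknotting")
  ev <- first_knotting_event(tr, persistence = 5)
  mid <- traj_frame(tr, ev$frame - 2)
  expect_false(is_knotted(mid))
  sk <- detect_slipknot(mid)
  expect_false(is.null(sk))
  expect_identical(classify_knot(mid[sk$start:sk$end, ])$label, "trefoil")
})

test_that("first_knotting_event respects the persistence window", {
  base <- scripted_mechanism_trajectory("direct_threading")
  flags <- knot_flags(base)
  first_true <- which(flags)[1]
  ev <- first_knotting_event(base, persistence = 5, flags = flags)
  expect_identical(ev$frame, first_true)
  # planted transient: 2 knotted frames at position 10 in an otherwise
  # unknotted prefix do not trigger a persistence-5 event
  nf <- n_frames(base)
  fake <- rep(FALSE, nf)
  fake[10:11] <- TRUE
  fake[20:nf] <- TRUE
  ev2 <- first_knotting_event(base, persistence = 5, flags = fake)
  expect_identical(ev2$frame, 20L)
  expect_null(first_knotting_event(base, persistence = 5,
                                   flags = rep(FALSE, nf)))
})

test_that("knotting probability curve matches planted knotting times", {
  mk <- function(knot_from, F = 10) {
    frames <- lapply(seq_len(F), function(f) {
      if (f >= knot_from) parametric_knot("trefoil_right", 60)
      else extended_chain(60, spacing = 1)
    })
    cg_trajectory(frames, stride = 1)
  }
  trajs <- list(mk(3), mk(6), mk(Inf))
  curve <- knotting_probability_curve(trajs, time_grid = c(0, 2, 5, 9))
  expect_equal(curve$p_knot, c(0, 1 / 3, 2 / 3, 2 / 3))
  expect_equal(curve$se,
               sqrt(curve$p_knot * (1 - curve$p_knot) / 3))
  expect_error(knotting_probability_curve(list(), 1:3), "empty")
})
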