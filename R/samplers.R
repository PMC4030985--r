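# Stochastic samplers: discrete overdamped Langevin propagation and a
# Metropolis Monte Carlo engine with crankshaft and single-bead moves.
# Both engines are bit-reproducible given (initial state, parameters,
# seed): all randomness comes from R's RNG.

#' Langevin propagation parameters
#'
#' The overdamped propagator is
#' \deqn{x_{i+1} = x_i + \Delta t\, D / k_BT \; F(x_i) +
#'   \sqrt{2 D \Delta t}\,\eta_i}
#' with unit-variance Gaussian noise.  A single effective friction
#' \eqn{\Gamma = m_{eff}\gamma} links the diffusion constant to the
#' thermal energy via the Einstein relation \eqn{D = k_BT/\Gamma}, which
#' is enforced at construction: supply either \code{D} or
#' (\code{gamma}, \code{m_eff}), not an inconsistent combination.
#'
#' @param kBT thermal energy (reduced units)
#' @param dt integration time step
#' @param gamma friction coefficient (default 1)
#' @param m_eff effective mass prefactor (default 1)
#' @param D diffusion constant; if supplied it must equal
#'   \code{kBT / (m_eff * gamma)} to 1e-8 relative
#' @param n_steps default number of steps for \code{\link{run_sampler}}
#' @return list of validated parameters (class \code{langevin_params})
#' @export
langevin_params <- function(kBT, dt, gamma = 1, m_eff = 1, D = NULL,
                            n_steps = 1000) {
  if (kBT <= 0 || dt <= 0 || gamma <= 0 || m_eff <= 0) {
    stop("kBT, dt, gamma and m_eff must all be positive")
  }
  Gamma <- m_eff * gamma
  D_c <- kBT / Gamma
  if (!is.null(D) && abs(D - D_c) > 1e-8 * D_c) {
    stop(sprintf(
      "inconsistent parameters: D = %g but kBT/(m_eff*gamma) = %g", D, D_c))
  }
  structure(list(kBT = kBT, dt = dt, gamma = gamma, m_eff = m_eff,
                 Gamma = Gamma, D = D_c, n_steps = n_steps),
            class = "langevin_params")
}

#' Monte Carlo move set
#'
#' @param crankshaft_max_angle maximum crankshaft rotation (rad)
#' @param displacement_max maximum single-bead displacement per axis (A)
#' @param mix probability of proposing a crankshaft move (vs single-bead)
#' @param seg_min,seg_max crankshaft segment length range in beads
#' @return list of validated parameters (class \code{move_set})
#' @export
move_set <- function(crankshaft_max_angle = 0.4, displacement_max = 0.25,
                     mix = 0.5, seg_min = 2, seg_max = 8) {
  if (crankshaft_max_angle <= 0 || displacement_max <= 0) {
    stop("move amplitudes must be positive")
  }
  if (mix < 0 || mix > 1) stop("mix must be in [0, 1]")
  structure(list(crankshaft_max_angle = crankshaft_max_angle,
                 displacement_max = displacement_max, mix = mix,
                 seg_min = as.integer(seg_min),
                 seg_max = as.integer(seg_max)),
            class = "move_set")
}

#' One discrete overdamped Langevin step
#'
#' @param x conformation (n x 3)
#' @param force_fn function returning an n x 3 force matrix for a
#'   conformation
#' @param params a \code{\link{langevin_params}}
#' @param noise optional n x 3 matrix of unit-variance Gaussians (drawn
#'   from R's RNG when NULL; pass zeros to propagate the drift only)
#' @return the next conformation (n x 3)
#' @export
langevin_step <- function(x, force_fn, params, noise = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite coordinates")
  f <- force_fn(x)
  if (!all(is.finite(f))) stop("force function returned non-finite values")
  if (!all(dim(f) == dim(x))) stop("force must be n x 3 like x")
  if (is.null(noise)) {
    noise <- matrix(stats::rnorm(length(x)), nrow(x), 3)
  }
  x + (params$dt * params$D / params$kBT) * f +
    sqrt(2 * params$D * params$dt) * noise
}

#' One Metropolis Monte Carlo step
#'
#' Proposes either a crankshaft rotation of an interior segment about the
#' axis joining two beads, or a single-bead displacement, and accepts with
#' probability \code{min(1, exp(-dE/kBT))}.  Chains shorter than 4 beads
#' cannot crankshaft and fall back to single-bead moves with a warning.
#' This R-level engine accepts an arbitrary energy function; the fast
#' compiled path for the coarse-grained model is \code{\link{run_sampler}}.
#'
#' @param x conformation (n x 3)
#' @param energy_fn function(x) -> scalar energy
#' @param moveset a \code{\link{move_set}}
#' @param kBT thermal energy; 0 gives strict downhill acceptance
#' @return list with \code{x} (new or unchanged conformation) and
#'   \code{accepted} (logical)
#' @export
mc_step <- function(x, energy_fn, moveset, kBT) {
  x <- as.matrix(x)
  n <- nrow(x)
  use_crank <- stats::runif(1) < moveset$mix
  if (use_crank && n < 4) {
    warning("chain shorter than 4 beads cannot crankshaft; using a single-bead move")
    use_crank <- FALSE
  }
  xn <- x
  if (use_crank) {
    seg <- sample(moveset$seg_min:min(moveset$seg_max, n - 2), 1)
    i <- sample(seq_len(n - seg - 1), 1)
    j <- i + seg + 1
    ang <- stats::runif(1, -1, 1) * moveset$crankshaft_max_angle
    axis <- x[j, ] - x[i, ]
    if (vnorm(axis) > 1e-9) {
      R <- rotation_about_axis(axis, ang)
      seg_idx <- (i + 1):(j - 1)
      xn[seg_idx, ] <- sweep(sweep(x[seg_idx, , drop = FALSE], 2, x[i, ]) %*%
                               t(R), 2, x[i, ], `+`)
    }
  } else {
    b <- sample(n, 1)
    xn[b, ] <- x[b, ] + stats::runif(3, -1, 1) * moveset$displacement_max
  }
  dE <- energy_fn(xn) - energy_fn(x)
  acc <- if (dE <= 0) TRUE else if (kBT <= 0) FALSE else
    stats::runif(1) < exp(-dE / kBT)
  list(x = if (acc) xn else x, accepted = acc)
}

#' Run a sampler on a coarse-grained model
#'
#' Propagates \code{initial} under \code{model} with the compiled Monte
#' Carlo engine (time unit: sweeps of n proposals) or the overdamped
#' Langevin integrator (time unit: steps).  Fully reproducible from
#' \code{seed}; per-frame energy and native-contact fraction are logged.
#'
#' @param initial starting conformation (n x 3 matrix or \code{ca_trace})
#' @param model a \code{\link{go_model}}
#' @param engine "mc" or "langevin"
#' @param n_sweeps number of MC sweeps (or Langevin steps)
#' @param kBT thermal energy (MC; for Langevin taken from \code{lparams})
#' @param stride sweeps/steps between saved frames
#' @param seed integer RNG seed
#' @param moveset a \code{\link{move_set}} (MC engine)
#' @param lparams a \code{\link{langevin_params}} (Langevin engine)
#' @param q_tol contact tolerance factor for the logged Q (default 1.2)
#' @param q_stop stop early once Q reaches this value (0 = never)
#' @param k_ratchet ratchet stiffness; 0 disables the bias (see
#'   \code{\link{run_rmd}})
#' @param q_record0 initial ratchet record (default 0)
#' @return a \code{\link{cg_trajectory}}
#' @export
run_sampler <- function(initial, model, engine = c("mc", "langevin"),
                        n_sweeps = 1000, kBT = 1, stride = 10, seed = 1,
                        moveset = move_set(), lparams = NULL, q_tol = 1.2,
                        q_stop = 0, k_ratchet = 0, q_record0 = 0) {
  engine <- match.arg(engine)
  x0 <- check_conformation(initial, model)
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  seed <- as.integer(seed)
  set.seed(seed)
  if (engine == "mc") {
    res <- cpp_mc_run(x0, as_cpp_model(model), as.integer(n_sweeps), kBT,
                      moveset, as.integer(stride), k_ratchet, q_stop,
                      q_tol, q_record0)
  } else {
    if (is.null(lparams)) lparams <- langevin_params(kBT = kBT, dt = 1e-4)
    # stability guard: the stiffest curvature is 2*k_bond
    kmax <- 2 * max(model$k_bond, model$k_angle)
    if (lparams$dt * lparams$D * kmax / lparams$kBT >= 0.1) {
      stop(sprintf(
        "unstable Langevin step: dt*D*k_max/kBT = %.3g >= 0.1; reduce dt",
        lparams$dt * lparams$D * kmax / lparams$kBT))
    }
    res <- cpp_langevin_run(x0, as_cpp_model(model), as.integer(n_sweeps),
                            lparams$dt, lparams$Gamma, lparams$kBT,
                            as.integer(stride), k_ratchet, q_stop, q_tol,
                            0.2, q_record0)
    kBT <- lparams$kBT
  }
  if (isTRUE(res$diverged)) {
    warning("energy diverged; trajectory truncated at the last good frame")
  }
  frames <- aperm(array(res$frames, dim = dim(res$frames)), c(2, 1, 3))
  scalars <- data.frame(frame = seq_along(res$sweep), sweep = res$sweep,
                        energy = res$energy, q = res$q,
                        q_record = res$q_record,
                        bias_energy = res$bias_energy)
  cg_trajectory(frames, stride = stride, seed = seed, kBT = kBT,
                engine = engine, scalars = scalars,
                metadata = list(acceptance = res$acceptance,
                                k_ratchet = k_ratchet, q_tol = q_tol,
                                q_stop = q_stop,
                                reached_qstop = isTRUE(res$reached_qstop),
                                diverged = isTRUE(res$diverged),
                                lparams = if (engine == "langevin")
                                  lparams[c("kBT", "dt", "Gamma", "D")]
                                else NULL))
}
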