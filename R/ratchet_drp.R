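# Ratchet-and-pawl biasing along the fraction of native contacts,
# Onsager-Machlup action evaluation with the unbiased force, and
# dominant-pathway selection.

#' Fraction of native contacts formed
#'
#' A native pair counts as formed when its current distance is at most
#' \code{tolerance_factor} times its native distance (sharp count).
#'
#' @param x conformation (n x 3 matrix or \code{ca_trace})
#' @param map a \code{native_contact_map} (must be non-empty)
#' @param tolerance_factor contact tolerance (default 1.2)
#' @return Q in [0, 1]
#' @export
native_fraction <- function(x, map, tolerance_factor = 1.2) {
  if (nrow(map) == 0) {
    stop("native contact map is empty: reaction coordinate undefined")
  }
  x <- chain_coords(x)
  d <- sqrt(rowSums((x[map$i, , drop = FALSE] -
                     x[map$j, , drop = FALSE])^2))
  mean(d <= tolerance_factor * map$native_distance)
}

#' Ratchet-and-pawl bias at one conformation
#'
#' The pawl lets the system evolve freely whenever the native-contact
#' fraction Q is at (or above) its running record; when Q falls below the
#' record, a one-sided harmonic penalty
#' \eqn{E_b = \tfrac12 k (q_{rec} - Q)^2} pushes it back.  The returned
#' force uses a sigmoid-smoothed contact indicator for \eqn{\nabla Q}
#' (the sharp count is piecewise constant); the energy uses the sharp Q.
#'
#' @param x conformation
#' @param map \code{native_contact_map}
#' @param state list with \code{q_record} (in [0,1]) and \code{k_ratchet}
#'   (>= 0)
#' @param tolerance_factor contact tolerance (default 1.2)
#' @param smooth_width width (Angstrom) of the smoothed indicator used
#'   for the force
#' @return list with \code{bias_energy}, \code{bias_force} (n x 3),
#'   \code{state} (record updated to \code{max(q_record, Q)}) and
#'   \code{q}
#' @export
ratchet_bias <- function(x, map, state, tolerance_factor = 1.2,
                         smooth_width = 0.2) {
  if (state$k_ratchet < 0) stop("k_ratchet must be >= 0")
  x <- chain_coords(x)
  q <- native_fraction(x, map, tolerance_factor)
  if (q >= state$q_record) {
    state$q_record <- q
    return(list(bias_energy = 0,
                bias_force = matrix(0, nrow(x), 3),
                state = state, q = q))
  }
  delta <- state$q_record - q
  e <- 0.5 * state$k_ratchet * delta^2
  # smoothed gradient of Q
  grad <- matrix(0, nrow(x), 3)
  r0t <- tolerance_factor * map$native_distance
  dvec <- x[map$j, , drop = FALSE] - x[map$i, , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  z <- (r - r0t) / smooth_width
  s <- 1 / (1 + exp(pmin(z, 30)))
  ds <- -s * (1 - s) / smooth_width
  coef <- ds / (nrow(map) * r)
  for (k in seq_len(nrow(map))) {
    g <- coef[k] * dvec[k, ]
    grad[map$j[k], ] <- grad[map$j[k], ] + g
    grad[map$i[k], ] <- grad[map$i[k], ] - g
  }
  list(bias_energy = e, bias_force = state$k_ratchet * delta * grad,
       state = state, q = q)
}

#' Ratchet-and-pawl biased run (rMD)
#'
#' Evolves the chain under the model force plus the ratchet bias on the
#' native-contact fraction, with either the Monte Carlo engine (the bias
#' enters the Metropolis criterion through its energy) or the Langevin
#' engine (smoothed bias force).  The initial conformation is checked for
#' knots; a knotted start is reported with a warning and recorded in the
#' trajectory metadata, since productive folding studies start from
#' unknotted unfolded states.
#'
#' @inheritParams run_sampler
#' @param k_ratchet bias stiffness (energy per squared Q unit)
#' @param q_stop terminate once Q reaches this value (default 0.95)
#' @param check_knot verify the start is unknotted (default TRUE)
#' @return a \code{\link{cg_trajectory}} with per-frame Q, record and
#'   bias energy in \code{$scalars}
#' @export
run_rmd <- function(initial, model, engine = c("mc", "langevin"),
                    n_sweeps = 5000, kBT = 1, stride = 10, seed = 1,
                    k_ratchet = 100, q_stop = 0.95, moveset = move_set(),
                    lparams = NULL, q_tol = 1.2, check_knot = TRUE) {
  engine <- match.arg(engine)
  x0 <- check_conformation(initial, model)
  start_knotted <- FALSE
  if (check_knot) {
    start_knotted <- is_knotted(x0)
    if (start_knotted) {
      warning("rMD started from a knotted conformation")
    }
  }
  traj <- run_sampler(initial, model, engine = engine,
                      n_sweeps = n_sweeps, kBT = kBT, stride = stride,
                      seed = seed, moveset = moveset, lparams = lparams,
                      q_tol = q_tol, q_stop = q_stop,
                      k_ratchet = k_ratchet)
  traj$metadata$start_knotted <- start_knotted
  traj
}

#' Onsager-Machlup action of a trajectory
#'
#' \deqn{S_{OM} = \frac{\Gamma}{4 k_BT \Delta t} \sum_i
#'   \left(x_{i+1} - x_i - F(x_i)\Delta t/\Gamma\right)^2}
#' evaluated with the \emph{unbiased} force only (the gradient of the
#' molecular potential), even for trajectories generated under the
#' ratchet bias: the action scores each path's probability under the
#' unbiased dynamics.  Frames must be saved at the integration stride
#' (stride 1); coarser strides are refused rather than silently rescaled.
#'
#' @param traj a \code{cg_trajectory} (Langevin, stride 1)
#' @param model the \code{go_model} providing the unbiased force
#' @param lparams the \code{\link{langevin_params}} the trajectory was
#'   generated with
#' @return non-negative scalar action
#' @export
om_action <- function(traj, model, lparams) {
  if (!is.null(traj$stride) && traj$stride != 1) {
    stop("om_action needs frames saved at stride 1; re-run the sampler ",
         "with stride = 1 (coarser strides cannot be rescaled)")
  }
  cpp_om_action(aperm(traj$frames, c(2, 1, 3)), as_cpp_model(model),
                lparams$dt, lparams$Gamma, lparams$kBT)
}

#' Group trial trajectories that share an initial state
#'
#' @param members list of \code{cg_trajectory} objects
#' @param actions numeric vector of Onsager-Machlup actions, one per
#'   member
#' @param key identifier of the shared initial condition
#' @return object of class \code{path_ensemble} (dominant member not yet
#'   selected)
#' @export
path_ensemble <- function(members, actions, key = "start") {
  if (length(members) == 0) stop("empty ensemble")
  if (length(actions) != length(members)) {
    stop("need one action per member")
  }
  if (any(actions < 0)) stop("actions must be non-negative")
  structure(list(key = key, members = members, actions = actions,
                 dominant_index = NA_integer_),
            class = "path_ensemble")
}

#' Select the dominant (lowest-action) pathway of an ensemble
#'
#' The trajectory with the lowest Onsager-Machlup action is the most
#' probable path under the unbiased dynamics.  Ties are broken toward the
#' lowest member index (reported via a message).
#'
#' @param ensemble a \code{\link{path_ensemble}}
#' @return the ensemble with \code{dominant_index} set
#' @export
select_dominant <- function(ensemble) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  a <- ensemble$actions
  idx <- which(a == min(a))
  if (length(idx) > 1) {
    message("action tie between members ", paste(idx, collapse = ", "),
            "; keeping the lowest index")
  }
  ensemble$dominant_index <- idx[1]
  ensemble
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("path_ensemble '%s': %d members%s\n", x$key,
              length(x$members),
              if (!is.na(x$dominant_index))
                sprintf(", dominant = #%d (S = %.4g)", x$dominant_index,
                        x$actions[x$dominant_index]) else ""))
  invisible(x)
}
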