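# Knot-state assignment for open chains and trajectories: type, chirality,
# knotted core, slipknots, first-knotting events and mechanism labels.

#' Classify the knot state of an open chain
#'
#' Closes the chain (\code{\link{close_chain}}), simplifies it and computes
#' the Alexander determinant at t = -1.  Determinant 1 is reported as
#' unknot, 3 as trefoil, 5 as \code{"det5"} (figure-eight class), anything
#' else as \code{"other"}.  For trefoils the chirality is taken from the
#' sign of the summed crossing signs of the reduced diagram: positive
#' writhe is a right-handed trefoil, as for most natively-knotted proteins.
#'
#' @param xyz open-chain coordinates (n x 3) or an object with
#'   \code{coords()}-style coordinates (a \code{ca_trace})
#' @return object of class \code{knot_assignment}: list with
#'   \code{determinant}, \code{label}, \code{chirality}, \code{writhe}
#' @export
classify_knot <- function(xyz) {
  xyz <- chain_coords(xyz)
  cd <- open_chain_diagram(xyz)
  det <- alexander_det_from_diagram(cd)
  label <- switch(as.character(det),
                  "1" = "unknot", "3" = "trefoil", "5" = "det5", "other")
  chir <- "n/a"
  if (label == "trefoil") {
    chir <- if (cd$writhe > 0) "right" else "left"
  }
  structure(list(determinant = det, label = label, chirality = chir,
                 writhe = cd$writhe),
            class = "knot_assignment")
}

#' @export
print.knot_assignment <- function(x, ...) {
  cat("knot assignment: ", x$label, " (|Delta(-1)| = ", x$determinant,
      if (x$chirality != "n/a") paste0(", ", x$chirality, "-handed") else "",
      ")\n", sep = "")
  invisible(x)
}

#' Is an open chain knotted?
#'
#' TRUE when the Alexander determinant of the closed chain differs
#' from 1.  (Knots invisible to the determinant are out of scope of this
#' detector.)
#'
#' @param xyz open chain (n x 3) or \code{ca_trace}
#' @return logical
#' @export
is_knotted <- function(xyz) {
  alexander_det_from_diagram(open_chain_diagram(chain_coords(xyz))) != 1L
}

# close -> simplify -> project, escalating the closure tilt when no
# generic projection exists for the untilted closure
open_chain_diagram <- function(xyz) {
  last_err <- NULL
  for (tilt in c(0, 3, 7, 13, -5)) {
    P <- kmt_reduce(close_chain(xyz, tilt_deg = tilt))
    cd <- tryCatch(crossing_diagram(P, max_tries = 40), error = identity)
    if (!inherits(cd, "error")) return(cd)
    last_err <- cd
  }
  stop(last_err)
}

# accept a bare matrix, a ca_trace or a trajectory frame
chain_coords <- function(x) {
  if (inherits(x, "ca_trace")) return(x$xyz)
  as.matrix(x)
}

#' Locate the knotted core of a chain
#'
#' Bidirectional trimming: terminal residues are deleted (alternating N
#' and C side, re-closing the chain after each deletion) for as long as
#' the remaining subchain stays knotted.  The minimal surviving interval
#' is the knotted core, reported as 1-based inclusive residue indices of
#' the input chain.
#'
#' @param xyz knotted open chain (n x 3) or \code{ca_trace}
#' @return list with \code{start} and \code{end} (1-based, inclusive)
#' @export
locate_core <- function(xyz) {
  xyz <- chain_coords(xyz)
  n <- nrow(xyz)
  if (!is_knotted(xyz)) stop("locate_core called on an unknotted chain")
  lo <- 1L; hi <- n
  # trimming steps: large jumps for speed, then small steps that can
  # skip over isolated closure artifacts near a shallow boundary
  steps <- c(12L, 8L, 4L, 1L, 2L, 3L)
  trim_side <- function(lo, hi, side) {
    repeat {
      moved <- FALSE
      for (step in steps) {
        if (hi - lo + 1L - step < 5L) next
        ok <- if (side == "N") {
          is_knotted(xyz[(lo + step):hi, , drop = FALSE])
        } else {
          is_knotted(xyz[lo:(hi - step), , drop = FALSE])
        }
        if (ok) {
          if (side == "N") lo <- lo + step else hi <- hi - step
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
    c(lo, hi)
  }
  alternate <- function(first) {
    lo <- 1L; hi <- n
    order_ <- if (first == "N") c("N", "C") else c("C", "N")
    repeat {
      before <- c(lo, hi)
      for (side in order_) {
        r <- trim_side(lo, hi, side); lo <- r[1]; hi <- r[2]
      }
      if (identical(before, c(lo, hi))) break
    }
    c(lo, hi)
  }
  # closure noise at shallow boundaries can leave several minimal
  # intervals; run both alternation orders and keep the shorter core
  # (ties resolved toward the smaller end index)
  a <- alternate("N")
  b <- alternate("C")
  pick <- if (diff(a) < diff(b)) a else if (diff(b) < diff(a)) b else
    if (b[2] <= a[2]) b else a
  list(start = pick[1], end = pick[2])
}

#' Detect a slipknot
#'
#' A slipknot is a chain that is unknotted as a whole while some contiguous
#' subchain is knotted under closure.  The search scans a coarse grid of
#' subchain intervals (shorter intervals first) and returns the first
#' knotted one, or \code{NULL} if none exists (including the case where
#' the whole chain is itself knotted).
#'
#' @param xyz open chain (n x 3) or \code{ca_trace}
#' @param min_len minimal subchain length considered (default 10)
#' @param coarse grid step in residues (default 5)
#' @return list with \code{start}, \code{end}, or \code{NULL}
#' @export
detect_slipknot <- function(xyz, min_len = 10, coarse = 5) {
  xyz <- chain_coords(xyz)
  n <- nrow(xyz)
  if (n < min_len + 2) return(NULL)
  if (is_knotted(xyz)) return(NULL)
  lens <- seq(min_len, n - 1, by = coarse)
  for (L in lens) {
    starts <- unique(c(seq(1, n - L, by = coarse), n - L))
    for (a in starts) {
      b <- a + L
      if (is_knotted(xyz[a:b, , drop = FALSE])) {
        return(list(start = a, end = b))
      }
    }
  }
  NULL
}

#' Per-frame knot flags of a trajectory
#'
#' @param traj a \code{cg_trajectory}
#' @return logical vector, one flag per saved frame
#' @export
knot_flags <- function(traj) {
  vapply(seq_len(n_frames(traj)), function(f) is_knotted(traj_frame(traj, f)),
         logical(1))
}

#' First persistent knotting event of a trajectory
#'
#' @param traj a \code{cg_trajectory}
#' @param persistence number of consecutive knotted frames required
#'   (default 10)
#' @param flags optional precomputed \code{\link{knot_flags}}
#' @return object of class \code{knotting_event} (list with \code{frame},
#'   \code{core}, \code{mechanism = "unclassified"}), or \code{NULL} if the
#'   trajectory never knots persistently
#' @export
first_knotting_event <- function(traj, persistence = 10, flags = NULL) {
  if (is.null(flags)) flags <- knot_flags(traj)
  if (length(flags) != n_frames(traj)) {
    stop("flags must have one entry per trajectory frame")
  }
  persistence <- as.integer(persistence)
  nf <- length(flags)
  if (persistence < 1) stop("persistence must be >= 1")
  if (nf < persistence) return(NULL)
  run <- 0L
  for (f in seq_len(nf)) {
    run <- if (flags[f]) run + 1L else 0L
    if (run >= persistence) {
      ev_frame <- f - persistence + 1L
      core <- locate_core(traj_frame(traj, ev_frame))
      return(structure(list(frame = ev_frame, core = core,
                            mechanism = "unclassified"),
                       class = "knotting_event"))
    }
  }
  NULL
}

# bend angle (degrees) of the threading terminus at one frame: angle
# between the direction of the last 5 beads and of the preceding 5
terminus_bend_angle <- function(xyz, terminus = c("C", "N")) {
  terminus <- match.arg(terminus)
  n <- nrow(xyz)
  if (n < 10) return(0)
  if (terminus == "C") {
    d_last <- xyz[n, ] - xyz[n - 4, ]
    d_prev <- xyz[n - 5, ] - xyz[n - 9, ]
  } else {
    d_last <- xyz[1, ] - xyz[5, ]
    d_prev <- xyz[6, ] - xyz[10, ]
  }
  vec_angle_deg(d_last, d_prev)
}

#' Classify the knotting mechanism of an event
#'
#' Ordered decision rules over a window of frames preceding the event:
#' \enumerate{
#'   \item \strong{slipknotting} if some pre-event frame contains a
#'     slipknot while the threading terminus is backward-bent (end-segment
#'     bend angle above \code{bend_deg});
#'   \item \strong{direct threading} if the knot core at the event abuts a
#'     terminus (within \code{terminal_zone} residues) and the terminus
#'     stays straight (bend angle below \code{bend_deg}) throughout the
#'     window;
#'   \item \strong{mousetrapping} if the loop residues (event core minus
#'     the threading terminal segment) move more than
#'     \code{displacement_ratio} times as much per frame as the terminal
#'     residues;
#'   \item otherwise \strong{unclassified}.
#' }
#'
#' @param traj a \code{cg_trajectory}
#' @param event a \code{knotting_event} from
#'   \code{\link{first_knotting_event}}
#' @param window number of pre-event frames inspected (default 10)
#' @param bend_deg bend-angle threshold in degrees (default 90)
#' @param terminal_zone residues from a chain end that count as "abutting"
#'   (default 10)
#' @param displacement_ratio loop-over-terminus displacement ratio for the
#'   mousetrap rule (default 2)
#' @return one of \code{"direct_threading"}, \code{"slipknotting"},
#'   \code{"mousetrapping"}, \code{"unclassified"}
#' @export
classify_mechanism <- function(traj, event, window = 10, bend_deg = 90,
                               terminal_zone = 10, displacement_ratio = 2) {
  n <- n_beads(traj)
  f_ev <- event$frame
  w0 <- f_ev - window
  if (w0 < 1) {
    warning("window extends before the first frame; truncated")
    w0 <- 1
  }
  pre_frames <- seq(w0, max(w0, f_ev - 1))
  core <- event$core
  # which terminus threads: the one the core abuts (nearer end on a tie)
  d_n <- core$start - 1L
  d_c <- n - core$end
  terminus <- if (d_n < d_c) "N" else "C"
  abuts <- min(d_n, d_c) <= terminal_zone
  bends <- vapply(c(pre_frames, f_ev), function(f) {
    terminus_bend_angle(traj_frame(traj, f), terminus)
  }, numeric(1))
  # rule 1: slipknotting
  for (k in seq_along(pre_frames)) {
    if (bends[k] > bend_deg &&
        !is.null(detect_slipknot(traj_frame(traj, pre_frames[k])))) {
      return("slipknotting")
    }
  }
  # rule 2: direct threading
  if (abuts && all(bends < bend_deg)) return("direct_threading")
  # rule 3: mousetrapping
  term_idx <- if (terminus == "C") (n - terminal_zone + 1):n else 1:terminal_zone
  loop_idx <- setdiff(core$start:core$end, term_idx)
  if (length(loop_idx) > 0 && length(pre_frames) > 1) {
    disp <- function(idx) {
      d <- 0
      for (k in 2:length(pre_frames)) {
        a <- traj_frame(traj, pre_frames[k])[idx, , drop = FALSE]
        b <- traj_frame(traj, pre_frames[k - 1])[idx, , drop = FALSE]
        d <- d + mean(sqrt(rowSums((a - b)^2)))
      }
      d / (length(pre_frames) - 1)
    }
    if (disp(loop_idx) > displacement_ratio * disp(term_idx)) {
      return("mousetrapping")
    }
  }
  "unclassified"
}

#' Knotting probability as a function of time over an ensemble
#'
#' For every requested time (in the trajectory time unit, e.g. MC sweeps)
#' the fraction of trajectories whose frame at that time is knotted is
#' reported, together with a binomial standard-error band.
#'
#' @param trajs list of \code{cg_trajectory} objects sharing time units
#' @param time_grid numeric vector of times
#' @return data.frame with \code{time}, \code{p_knot}, \code{se},
#'   \code{n}
#' @export
knotting_probability_curve <- function(trajs, time_grid) {
  if (length(trajs) == 0) stop("empty trajectory ensemble")
  flags <- lapply(trajs, knot_flags)
  out <- data.frame(time = time_grid, p_knot = NA_real_, se = NA_real_,
                    n = length(trajs))
  for (g in seq_along(time_grid)) {
    kn <- vapply(seq_along(trajs), function(t) {
      tr <- trajs[[t]]
      f <- min(max(1L, 1L + floor(time_grid[g] / tr$stride)), n_frames(tr))
      flags[[t]][f]
    }, logical(1))
    p <- mean(kn)
    out$p_knot[g] <- p
    out$se[g] <- sqrt(p * (1 - p) / length(kn))
  }
  out
}
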