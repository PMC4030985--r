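# Geometric and thermodynamic observables: optimal-superposition RMSD,
# 2-D trajectory projections, free-energy surfaces, secondary-structure
# resolved contact statistics, terminus attraction energetics and
# barrier-based pathway probabilities.

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares superposes \code{b} onto \code{a} over \code{subset}
#' using the SVD construction restricted to proper rotations (the
#' determinant sign is corrected), then reports the RMSD over the subset.
#' A mirror image therefore does \emph{not} superpose to zero.
#'
#' @param a,b conformations (n x 3)
#' @param subset integer residue indices used for fitting and scoring
#'   (default: all)
#' @return RMSD in Angstrom
#' @export
kabsch_rmsd <- function(a, b, subset = NULL) {
  a <- chain_coords(a); b <- chain_coords(b)
  if (!all(dim(a) == dim(b))) stop("conformations differ in size")
  if (is.null(subset)) subset <- seq_len(nrow(a))
  if (length(subset) < 3) stop("subset needs at least 3 points")
  P <- a[subset, , drop = FALSE]
  Q <- b[subset, , drop = FALSE]
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  sv <- svd(crossprod(Q, P))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    stop("degenerate (collinear) subset [",
         paste(range(subset), collapse = "-"), "]: superposition undefined")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  Dm <- diag(c(1, 1, d))
  R <- sv$u %*% Dm %*% t(sv$v)
  sqrt(mean(rowSums((P - Q %*% R)^2)))
}

#' Project a trajectory onto two RMSD coordinates
#'
#' Computes, frame by frame, the RMSD to a reference conformation over
#' two residue subsets (for example a non-local beta-sheet and the whole
#' molecule), yielding the 2-D folding-progress path used to monitor
#' knotted-protein folding.
#'
#' @param traj a \code{cg_trajectory}
#' @param ref reference conformation (native; n x 3)
#' @param subset_a,subset_b residue index sets defining the two
#'   coordinates (default: whole chain for both)
#' @param flags optional logical knot flags to attach per frame
#' @return data.frame with \code{frame}, \code{a}, \code{b} and
#'   optionally \code{knotted}
#' @export
project_trajectory <- function(traj, ref, subset_a = NULL,
                               subset_b = NULL, flags = NULL) {
  ref <- chain_coords(ref)
  F <- n_frames(traj)
  out <- data.frame(frame = seq_len(F), a = NA_real_, b = NA_real_)
  for (f in seq_len(F)) {
    X <- traj_frame(traj, f)
    out$a[f] <- kabsch_rmsd(ref, X, subset_a)
    out$b[f] <- kabsch_rmsd(ref, X, subset_b)
  }
  if (!is.null(flags)) out$knotted <- flags
  out
}

#' Two-dimensional free-energy surface
#'
#' Histograms the samples on a regular grid and reports
#' \eqn{F = -k_BT \ln(n_{bin}/N)} with the minimum shifted to zero.
#' Empty bins are masked (NA), not zero-filled.
#'
#' @param samples data.frame (or 2-column matrix) of coordinate pairs
#' @param breaks_a,breaks_b bin edges for the two axes, or single numbers
#'   of bins
#' @param kBT thermal energy used for the conversion
#' @param contour_interval stored for plotting metadata (default 0.8)
#' @return object of class \code{fes_grid}: list with \code{f} (matrix),
#'   \code{mid_a}, \code{mid_b}, \code{kBT}, \code{contour_interval}
#' @export
fes_2d <- function(samples, breaks_a = 30, breaks_b = 30, kBT = 1,
                   contour_interval = 0.8) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("need at least one sample")
  br <- function(v, b) if (length(b) == 1) {
    seq(min(v) - 1e-9, max(v) + 1e-9, length.out = b + 1)
  } else b
  ba <- br(samples[, 1], breaks_a)
  bb <- br(samples[, 2], breaks_b)
  ia <- findInterval(samples[, 1], ba, rightmost.closed = TRUE)
  ib <- findInterval(samples[, 2], bb, rightmost.closed = TRUE)
  keep <- ia >= 1 & ia <= length(ba) - 1 & ib >= 1 & ib <= length(bb) - 1
  counts <- matrix(0, length(ba) - 1, length(bb) - 1)
  for (k in which(keep)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1
  if (sum(counts > 0) == 1) {
    warning("all samples fall in a single bin")
  }
  f <- -kBT * log(counts / sum(counts))
  f[!is.finite(f)] <- NA
  f <- f - min(f, na.rm = TRUE)
  structure(list(f = f, breaks_a = ba, breaks_b = bb,
                 mid_a = (ba[-1] + ba[-length(ba)]) / 2,
                 mid_b = (bb[-1] + bb[-length(bb)]) / 2,
                 counts = counts, kBT = kBT,
                 contour_interval = contour_interval),
            class = "fes_grid")
}

#' Secondary-structure-resolved native-contact fractions
#'
#' Formed-contact fractions with the same criterion as
#' \code{\link{native_fraction}}, reported overall and per contact class
#' (\code{alpha}: both residues helical; \code{beta}: both in strands;
#' \code{other}).  A class with no native pairs is reported as NA, not 0.
#'
#' @param x conformation
#' @param map \code{native_contact_map} with ss_class labels
#' @param tolerance_factor contact tolerance (default 1.2)
#' @return list with \code{overall}, \code{alpha}, \code{beta},
#'   \code{other} and the per-class pair counts
#' @export
ss_contact_fractions <- function(x, map, tolerance_factor = 1.2) {
  x <- chain_coords(x)
  d <- sqrt(rowSums((x[map$i, , drop = FALSE] -
                     x[map$j, , drop = FALSE])^2))
  formed <- d <= tolerance_factor * map$native_distance
  one <- function(cls) {
    idx <- map$ss_class == cls
    if (!any(idx)) NA_real_ else mean(formed[idx])
  }
  list(overall = mean(formed),
       alpha = one("alpha"), beta = one("beta"), other = one("other"),
       n_pairs = c(alpha = sum(map$ss_class == "alpha"),
                   beta = sum(map$ss_class == "beta"),
                   other = sum(map$ss_class == "other")))
}

#' Mean non-native attraction of a terminal segment
#'
#' For each conformation of the ensemble, sums the quasi-chemical
#' non-native energy over pairs with exactly one member in the terminal
#' segment, and reports the ensemble mean and standard error.  All
#' sampled structures contribute, irrespective of compactness or knotted
#' state.  Exactly zero when the model has \code{lambda_nn = 0}.
#'
#' @param ensemble list of conformations (n x 3 matrices) or a
#'   \code{cg_trajectory}
#' @param model a \code{\link{go_model}}
#' @param terminus_length number of terminal residues in the segment
#' @param terminus "C" (default) or "N"
#' @return list with \code{mean}, \code{se}, \code{per_conformation}
#' @export
terminus_attraction <- function(ensemble, model, terminus_length,
                                terminus = c("C", "N")) {
  terminus <- match.arg(terminus)
  if (inherits(ensemble, "cg_trajectory")) {
    ensemble <- lapply(seq_len(n_frames(ensemble)), traj_frame,
                       traj = ensemble)
  }
  if (length(ensemble) == 0) stop("empty ensemble")
  n <- model$n
  if (terminus_length >= n) stop("terminus_length must be below the chain length")
  if (model$lambda_nn == 0) {
    return(list(mean = 0, se = 0,
                per_conformation = rep(0, length(ensemble))))
  }
  term_idx <- if (terminus == "C") (n - terminus_length + 1):n else
    seq_len(terminus_length)
  # non-native pairs with exactly one member in the terminal segment
  nat_key <- paste(model$nat_i, model$nat_j)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$j - pairs$i >= model$min_seq_sep, ]
  in_term_i <- pairs$i %in% term_idx
  in_term_j <- pairs$j %in% term_idx
  pairs <- pairs[xor(in_term_i, in_term_j), ]
  pairs <- pairs[!(paste(pairs$i, pairs$j) %in% nat_key), ]
  Bv <- model$B[cbind(pairs$i, pairs$j)]
  vals <- vapply(ensemble, function(X) {
    X <- chain_coords(X)
    r <- sqrt(rowSums((X[pairs$i, , drop = FALSE] -
                       X[pairs$j, , drop = FALSE])^2))
    z <- pmin((r - model$nn_cutoff) / model$nn_width, 30)
    sum(model$lambda_nn * Bv / (1 + exp(z)))
  }, numeric(1))
  list(mean = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       per_conformation = vals)
}

#' Pathway probabilities from transition-state barriers
#'
#' Kramers estimate with equal prefactors: the rate ratio of two
#' pathways is \eqn{r = \exp(-( \Delta F_1 - \Delta F_2)/k_BT)} and the
#' pathway probabilities are \eqn{p_1 = r/(1+r)}, \eqn{p_2 = 1 - p_1}.
#'
#' @param delta_F1,delta_F2 transition-state free-energy barriers of the
#'   two pathways (same units as kBT)
#' @param kBT thermal energy
#' @return named vector \code{c(p1, p2)}; sums to 1
#' @export
pathway_probability_from_barriers <- function(delta_F1, delta_F2, kBT) {
  if (!is.finite(delta_F1) || !is.finite(delta_F2)) {
    stop("barriers must be finite")
  }
  message("Kramers estimate assumes equal kinetic prefactors for both pathways")
  r <- exp(-(delta_F1 - delta_F2) / kBT)
  p1 <- r / (1 + r)
  c(p1 = p1, p2 = 1 - p1)
}
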