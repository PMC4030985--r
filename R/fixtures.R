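# Deterministic fixture generators: parametric knotted curves, random
# coils, extended chains and toy native structures.  Every generator is a
# pure function of its arguments (identical spec -> identical output).

#' Parametric knotted (or unknotted) curve
#'
#' Samples a standard parametric curve at \code{n_beads} points:
#' \itemize{
#'   \item \code{unknot}: planar circle;
#'   \item \code{trefoil_left}: the (2,3) torus-knot parametrization
#'     \eqn{((2+\cos 3t)\cos 2t, (2+\cos 3t)\sin 2t, \sin 3t)}, whose
#'     Gauss-integral writhe is about -3.5 (left-handed under the
#'     standard crossing-sign convention);
#'   \item \code{trefoil_right}: its x-mirror image (writhe about +3.5);
#'   \item \code{figure_eight}: \eqn{((2+\cos 2t)\cos 3t,
#'     (2+\cos 2t)\sin 3t, \sin 4t)}, determinant 5.
#' }
#' Curves are scaled by \code{scale} (Angstrom-ish units) and the chain is
#' left open (the last sampled point does not coincide with the first), so
#' the result exercises the chain-closure pipeline.  Optional Gaussian
#' vertex noise is regenerated with halved amplitude (with a warning)
#' whenever it brings two non-adjacent segments closer than a tenth of the
#' mean bond length.
#'
#' @param type one of "unknot", "trefoil_right", "trefoil_left",
#'   "figure_eight"
#' @param n_beads number of sampled vertices (>= 20 recommended)
#' @param noise_A Gaussian noise amplitude per coordinate, in the same
#'   units as \code{scale}
#' @param seed RNG seed used for the noise (ignored when \code{noise_A} is
#'   0)
#' @param scale overall scale factor (default 3, protein-like in Angstrom)
#' @return n x 3 coordinate matrix
#' @export
parametric_knot <- function(type = c("unknot", "trefoil_right",
                                     "trefoil_left", "figure_eight"),
                            n_beads = 200, noise_A = 0, seed = 1,
                            scale = 3) {
  type <- match.arg(type)
  if (n_beads < 4) stop("n_beads must be >= 4")
  tt <- seq(0, 2 * pi, length.out = n_beads + 1)[1:n_beads]
  xyz <- switch(type,
    unknot = cbind(3 * cos(tt), 3 * sin(tt), 0),
    trefoil_left = cbind((2 + cos(3 * tt)) * cos(2 * tt),
                         (2 + cos(3 * tt)) * sin(2 * tt),
                         sin(3 * tt)),
    trefoil_right = {
      z <- cbind((2 + cos(3 * tt)) * cos(2 * tt),
                 (2 + cos(3 * tt)) * sin(2 * tt),
                 sin(3 * tt))
      z[, 1] <- -z[, 1]
      z
    },
    figure_eight = cbind((2 + cos(2 * tt)) * cos(3 * tt),
                         (2 + cos(2 * tt)) * sin(3 * tt),
                         sin(4 * tt))
  )
  xyz <- xyz * scale
  if (noise_A > 0) {
    amp <- noise_A
    repeat {
      set.seed(seed)
      cand <- xyz + matrix(stats::rnorm(3 * n_beads, sd = amp), ncol = 3)
      if (!self_intersecting(cand)) {
        xyz <- cand
        break
      }
      warning("noise caused near self-intersection; halving amplitude")
      amp <- amp / 2
      if (amp < 1e-6) break
    }
  }
  xyz
}

# crude self-intersection guard at polygon resolution: TRUE if two
# non-adjacent vertices come closer than a tenth of the mean bond length
self_intersecting <- function(xyz) {
  n <- nrow(xyz)
  bl <- mean(sqrt(rowSums(diff(xyz)^2)))
  d <- as.matrix(stats::dist(xyz))
  d[cbind(1:n, 1:n)] <- Inf
  for (i in 1:(n - 1)) { d[i, i + 1] <- Inf; d[i + 1, i] <- Inf }
  min(d) < 0.1 * bl
}

#' Straight extended chain
#'
#' @param n_beads number of beads
#' @param spacing bond length in Angstrom (default 3.8, the C-alpha
#'   virtual bond)
#' @return n x 3 coordinate matrix along the x axis
#' @export
extended_chain <- function(n_beads, spacing = 3.8) {
  cbind(spacing * (seq_len(n_beads) - 1), 0, 0)
}

#' Self-avoiding-ish random coil
#'
#' Fixed-bond-length random walk with a hard lower bound on non-bonded
#' distances, regrown from the offending bead on violation.
#'
#' @param n_beads number of beads
#' @param seed RNG seed (the generator is a pure function of it)
#' @param spacing bond length (default 3.8 A)
#' @param min_dist minimal non-bonded distance (default 4.0 A)
#' @return n x 3 coordinate matrix
#' @export
random_coil <- function(n_beads, seed = 1, spacing = 3.8, min_dist = 4.0) {
  set.seed(seed)
  xyz <- matrix(0, n_beads, 3)
  i <- 2
  tries <- 0
  while (i <= n_beads) {
    u <- stats::rnorm(3)
    cand <- xyz[i - 1, ] + spacing * u / vnorm(u)
    ok <- TRUE
    if (i > 2) {
      dd <- sqrt(rowSums(sweep(xyz[1:(i - 2), , drop = FALSE], 2, cand)^2))
      ok <- all(dd >= min_dist)
    }
    if (ok) {
      xyz[i, ] <- cand
      i <- i + 1
      tries <- 0
    } else {
      tries <- tries + 1
      if (tries > 200) {           # back up one bead and retry
        i <- max(2, i - 1)
        tries <- 0
      }
    }
  }
  xyz
}

# ideal right-handed C-alpha helix: radius 2.3 A, 100 deg per residue,
# 1.5 A rise (virtual dihedral ~ +50 deg)
ideal_helix <- function(n, phase = 0, axis_origin = c(0, 0, 0),
                        reverse = FALSE) {
  i <- seq_len(n) - 1
  th <- phase - i * 100 * pi / 180
  z <- i * 1.5
  if (reverse) z <- rev(z)
  sweep(cbind(2.3 * cos(th), 2.3 * sin(th), z), 2, axis_origin, `+`)
}

#' Toy native structures with their contact maps
#'
#' Compact, self-avoiding mini-folds used as folding targets:
#' \itemize{
#'   \item \code{helix_hairpin}: two packed ideal helices joined by a
#'     tight turn;
#'   \item \code{beta_hairpin_pair}: four short antiparallel strands;
#'   \item \code{shallow_trefoil}: a trefoil-knotted mini-fold whose knot
#'     core excludes the final ~6-bead straight tail, mimicking a shallow
#'     C-terminal protein knot.
#' }
#'
#' @param n_beads chain length (the motif geometry is resampled to this
#'   length)
#' @param motif one of "helix_hairpin", "beta_hairpin_pair",
#'   "shallow_trefoil"
#' @param seed RNG seed (kept for interface symmetry; the default motifs
#'   are deterministic)
#' @param cutoff,min_seq_sep contact-map parameters passed to
#'   \code{\link{build_contact_map}}
#' @return list with \code{trace} (a \code{ca_trace}) and \code{map} (a
#'   \code{native_contact_map})
#' @export
toy_native <- function(n_beads = 20,
                       motif = c("helix_hairpin", "beta_hairpin_pair",
                                 "shallow_trefoil"),
                       seed = 1, cutoff = 7.5, min_seq_sep = 3) {
  motif <- match.arg(motif)
  xyz <- switch(motif,
    helix_hairpin = {
      nh <- floor((n_beads - 2) / 2)
      h1 <- ideal_helix(nh)
      # second helix antiparallel, axis offset 9 A in x
      h2 <- ideal_helix(n_beads - nh - 2, phase = pi,
                        axis_origin = c(9, 0, 0))
      h2 <- h2[rev(seq_len(nrow(h2))), ]
      a <- h1[nh, ]; b <- h2[1, ]
      turn <- rbind(a + (b - a) / 3 + c(0, 0, 2.2),
                    a + 2 * (b - a) / 3 + c(0, 0, 2.2))
      rbind(h1, turn, h2)
    },
    beta_hairpin_pair = {
      per <- max(4, floor(n_beads / 4))
      strand <- function(x0, y0, rev = FALSE, n = per) {
        z <- 3.3 * (seq_len(n) - 1)
        if (rev) z <- rev(z)
        cbind(x0 + 0.5 * rep_len(c(-1, 1), n), y0, z)
      }
      s1 <- strand(0, 0)
      s2 <- strand(0, 4.3, rev = TRUE)
      s3 <- strand(4.3, 4.3)
      s4 <- strand(4.3, 0, rev = TRUE, n = n_beads - 3 * per)
      rbind(s1, s2, s3, s4)
    },
    shallow_trefoil = {
      # designed knotted mini-fold with the architecture of shallow
      # C-terminal protein knots: an N-tail whose entry strand passes
      # under the exit strand (layered in z), a wide pre-formed loop,
      # a routing arc, a C-terminal rod threading the loop, and a
      # 6-bead tail protruding beyond the knotted core
      ntail <- rbind(c(26, -8, -6.5), c(22, -6.6, -6.5), c(18, -5.2, -6.5),
                     c(14, -3.8, -6.3), c(10.5, -2.6, -3.5),
                     c(7.0, -1.5, -0.5))
      th <- seq(-15, 315, length.out = 12) * pi / 180
      loop <- cbind(7 * cos(th), 7 * sin(th), 0)
      ex <- rbind(c(9, -6.5, -2), c(13.5, -7.5, -4), c(18, -8, -4),
                  c(22, -8, -4))
      route <- rbind(c(25, -3, -7), c(22, 5, -10), c(13, 10, -12),
                     c(5, 6, -13), c(0, 1, -13))
      rod <- cbind(0, 0, seq(-11, 8, length.out = 6))
      tail <- rbind(c(1.2, 0.8, 10.8), c(3.2, 2.2, 12.8), c(5.8, 4, 14.2),
                    c(8.6, 6, 15.2), c(11.5, 8, 15.8), c(14.5, 10, 16.2))
      resample_arclength(rbind(ntail, loop, ex, route, rod, tail), n_beads)
    }
  )
  # sequence: shallow_trefoil gets a hydrophobic threading C-terminus
  # (the knot-promoting attraction acts on the terminal segment, as in
  # natively-knotted proteins); other motifs alternate polar/hydrophobic
  n_tot <- nrow(xyz)
  rtype <- rep_len(c("SER", "LEU", "ALA", "THR"), n_tot)
  if (motif == "shallow_trefoil") {
    rtype[max(1, n_tot - 15):n_tot] <- rep_len(c("ILE", "LEU"), 16)
  }
  trace <- ca_trace(xyz, residue_type = rtype, validate = FALSE)
  trace <- assign_ss_geometric(trace)
  map <- build_contact_map(trace, cutoff = cutoff, min_seq_sep = min_seq_sep)
  list(trace = trace, map = map)
}

# static scaffold shared by the scripted knotting mechanisms: an N-tail,
# an entry strand crossing under the exit strand (the "locked" native
# loop) and a routing arc leading to the C-terminal threading segment.
# The C-terminus threading the loop from below completes an overhand
# knot (trefoil).
mechanism_scaffold <- function() {
  pad <- cbind(seq(52, 19, length.out = 12), -3, -1.2)       # trimmable N-tail
  entry <- cbind(seq(16, 6.2, length.out = 5),
                 seq(-3, -1, length.out = 5), -1.2)
  th <- seq(-10, 330, length.out = 16) * pi / 180
  loop <- cbind(5 * cos(th), 5 * sin(th), 0)
  ex <- cbind(seq(6.2, 16, length.out = 5),
              seq(0.5, 3, length.out = 5), 1.2)
  route <- rbind(c(20, 8, -3), c(16, 14, -7), c(6, 12, -10),
                 c(0, 6, -12), c(0, 0, -12))
  rbind(pad, entry, loop, ex, route)                         # 43 beads
}

#' Scripted knotting-mechanism trajectories
#'
#' Kinematic (non-physical) trajectories that animate the three knotting
#' mechanisms around a common static scaffold (a pre-formed, locked
#' loop):
#' \itemize{
#'   \item \code{direct_threading}: a straight C-terminal rod translates
#'     upward through the loop;
#'   \item \code{slipknotting}: a hairpin-bent C-terminus is inserted
#'     through the loop (the intermediate frames contain a slipknot:
#'     whole chain unknotted, a subchain knotted), then straightens;
#'   \item \code{mousetrapping}: the loop region translates concertedly
#'     over a static, hooked C-terminus.
#' }
#' Every script ends in a persistent trefoil.  These trajectories exist
#' to pin the mechanism classifier's decision boundaries; the metadata
#' records \code{kinematic = TRUE}.
#'
#' @param label one of "direct_threading", "slipknotting",
#'   "mousetrapping"
#' @param seed kept for interface symmetry (the scripts are
#'   deterministic)
#' @param n_hold number of knotted hold frames appended after the event
#' @return a \code{\link{cg_trajectory}}
#' @export
scripted_mechanism_trajectory <- function(label = c("direct_threading",
                                                    "slipknotting",
                                                    "mousetrapping"),
                                          seed = 1, n_hold = 12) {
  label <- match.arg(label)
  scaf <- mechanism_scaffold()
  frames <- list()
  if (label == "direct_threading") {
    rod <- cbind(0, 0, seq(-9, 8, length.out = 10))
    for (dz in seq(-16, 0, length.out = 16)) {
      frames[[length(frames) + 1]] <- rbind(scaf, sweep(rod, 2, c(0, 0, dz), `+`))
    }
    for (h in seq_len(n_hold)) frames[[length(frames) + 1]] <- rbind(scaf, rod)
  } else if (label == "slipknotting") {
    upleg <- cbind(0, 0, seq(-7, 3, length.out = 6))
    fold <- cbind(1.8, 0, seq(2.2, -3.8, length.out = 4))
    hairpin <- rbind(upleg, fold)
    straight <- cbind(0, 0, seq(5, 11, length.out = 4))
    for (dz in seq(-10, 0, length.out = 10)) {
      frames[[length(frames) + 1]] <-
        rbind(scaf, sweep(hairpin, 2, c(0, 0, dz), `+`))
    }
    for (s in seq(0, 1, length.out = 6)[-1]) {
      unfolded <- rbind(upleg, (1 - s) * fold + s * straight)
      frames[[length(frames) + 1]] <- rbind(scaf, unfolded)
    }
    final <- rbind(upleg, straight)
    for (h in seq_len(n_hold)) frames[[length(frames) + 1]] <- rbind(scaf, final)
  } else {
    # hooked (backward-bent) static terminus; the loop assembly drops
    # concertedly over it, snapping shut in one step like a mousetrap
    hook <- rbind(cbind(0, 0, seq(-9, 3, length.out = 7)),
                  c(1.5, 0, 4.3), c(3.0, 0, 2.6), c(3.4, 0, 0.3))
    for (dz in c(seq(14, 8, length.out = 12), 0)) {
      frames[[length(frames) + 1]] <-
        rbind(sweep(scaf, 2, c(0, 0, dz), `+`), hook)
    }
    for (h in seq_len(n_hold)) frames[[length(frames) + 1]] <- rbind(scaf, hook)
  }
  cg_trajectory(frames, stride = 1, seed = seed, engine = "scripted",
                metadata = list(kinematic = TRUE, mechanism = label))
}
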