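# Independent oracles used across the suite.

# Gauss linking-integral writhe of a (cyclic) polygon: an absolute,
# projection-free handedness reference (right-handed trefoil ~ +3.4).
gauss_writhe <- function(P) {
  n <- nrow(P)
  nxt <- c(2:n, 1)
  Tg <- P[nxt, ] - P
  mid <- (P + P[nxt, ]) / 2
  w <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      r <- mid[i, ] - mid[j, ]
      d2 <- sum(r * r)
      if (d2 < 1e-12) next
      cr <- c(Tg[j, 2] * r[3] - Tg[j, 3] * r[2],
              Tg[j, 3] * r[1] - Tg[j, 1] * r[3],
              Tg[j, 1] * r[2] - Tg[j, 2] * r[1])
      w <- w + 2 * sum(Tg[i, ] * cr) / (d2 * sqrt(d2))
    }
  }
  w / (4 * pi)
}

# Number of Fox p-colorings of a crossing diagram: at every underpass,
# 2*over - in - out = 0 (mod p), counted by brute-force enumeration over
# arc colors.  |Delta(-1)| is divisible by p exactly when the diagram
# admits non-trivial p-colorings -- an invariant check independent of the
# Alexander-matrix determinant.
fox_colorings <- function(cd, p) {
  K <- cd$n_crossings
  if (K == 0) return(p)
  ax <- cd$alexander
  count <- 0
  colors <- rep(0L, K)
  total <- p^K
  for (code in 0:(total - 1)) {
    c0 <- code
    for (a in seq_len(K)) {
      colors[a] <- c0 %% p
      c0 <- c0 %/% p
    }
    ok <- TRUE
    for (k in seq_len(K)) {
      if ((2 * colors[ax$over_arc[k]] - colors[ax$in_arc[k]] -
           colors[ax$out_arc[k]]) %% p != 0) {
        ok <- FALSE
        break
      }
    }
    if (ok) count <- count + 1
  }
  count
}

# brute-force contact map: all-pairs distance scan
brute_contact_pairs <- function(xyz, cutoff, min_seq_sep) {
  n <- nrow(xyz)
  out <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < min_seq_sep) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# small shared fixtures (built once per test run)
toy20 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- toy_native(20, "helix_hairpin")
    val
  }
})
toy40 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- toy_native(40, "shallow_trefoil")
    val
  }
})
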