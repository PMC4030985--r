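# Native-structure handling: C-alpha traces, secondary-structure labels
# and native contact maps.  PDB parsing is delegated to bio3d.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Construct a C-alpha trace
#'
#' One bead per residue, internally renumbered 1..n.  For structures
#' accepted as native inputs consecutive beads must lie within
#' [2.5, 4.5] Angstrom of each other; larger gaps are annotated as chain
#' breaks (with a warning), not failures.
#'
#' @param xyz n x 3 coordinates in Angstrom
#' @param residue_type three-letter amino-acid codes (recycled if length
#'   1)
#' @param ss_label per-residue label in \{"helix","sheet","coil"\}
#' @param chain_id chain identifier
#' @param resno_orig original (author) residue numbers, for reporting
#' @param validate enforce the native-input invariants (>= 4 residues,
#'   bond-length window)
#' @return object of class \code{ca_trace}
#' @export
ca_trace <- function(xyz, residue_type = "ALA", ss_label = "coil",
                     chain_id = "A", resno_orig = NULL, validate = TRUE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  residue_type <- rep_len(residue_type, n)
  ss_label <- rep_len(ss_label, n)
  if (is.null(resno_orig)) resno_orig <- seq_len(n)
  breaks <- integer(0)
  if (n >= 2) {
    bl <- sqrt(rowSums(diff(xyz)^2))
    breaks <- which(bl > 4.5)
    if (validate && length(breaks) > 0) {
      warning(sprintf("chain break(s) after bead(s) %s (bond > 4.5 A)",
                      paste(breaks, collapse = ", ")))
    }
    if (validate && any(bl < 2.5)) {
      warning("consecutive-bead distance below 2.5 A; not a clean CA trace")
    }
  }
  if (validate && n < 4) stop("a CA trace needs at least 4 residues")
  structure(list(xyz = xyz, residue_index = seq_len(n),
                 residue_type = residue_type, ss_label = ss_label,
                 chain_id = chain_id, resno_orig = resno_orig,
                 chain_breaks = breaks),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("ca_trace: %d residues, chain %s (%d helix, %d sheet, %d coil)\n",
              length(x$residue_index), x$chain_id,
              sum(x$ss_label == "helix"), sum(x$ss_label == "sheet"),
              sum(x$ss_label == "coil")))
  if (length(x$chain_breaks)) {
    cat("  chain breaks after beads:",
        paste(x$chain_breaks, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a C-alpha trace from a PDB file
#'
#' Reads ATOM records with bio3d, keeps the CA atoms of the selected chain
#' and model, resolves alternate locations to the highest occupancy and
#' skips residues without a CA (with a warning).  Secondary structure from
#' HELIX/SHEET records is applied via
#' \code{\link{assign_secondary_structure}}.
#'
#' @param file path to a PDB file
#' @param chain chain identifier (a single chain must be selected
#'   explicitly when the file has several)
#' @param model model number for multi-model files (default 1)
#' @param apply_ss assign secondary structure from the file's HELIX/SHEET
#'   records (default TRUE)
#' @return a \code{ca_trace}
#' @export
load_ca_trace <- function(file, chain = NULL, model = 1, apply_ss = TRUE) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain[at$type == "ATOM"])
  if (is.null(chain)) {
    if (length(chains) > 1) {
      stop("file has chains ", paste(chains, collapse = ","),
           "; select one explicitly")
    }
    chain <- chains[1]
  }
  sel <- at$type == "ATOM" & at$chain == chain & at$elety == "CA"
  if (!any(sel)) stop("empty selection: no CA atoms for chain ", chain)
  ca <- at[sel, , drop = FALSE]
  # alternate locations: keep highest occupancy per residue
  key <- paste(ca$resno, ca$insert)
  if (anyDuplicated(key)) {
    ord <- order(key, -ca$o)
    ca <- ca[ord, , drop = FALSE]
    ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
    ca <- ca[order(ca$resno), , drop = FALSE]
  }
  if (model > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model) {
      stop("model ", model, " not present")
    }
    xyz_all <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    idx <- which(sel)
    # map atom rows to xyz rows (bio3d keeps atom order)
    xyz <- xyz_all[idx, , drop = FALSE]
  } else {
    xyz <- cbind(ca$x, ca$y, ca$z)
  }
  tr <- ca_trace(xyz, residue_type = ca$resid, chain_id = chain,
                 resno_orig = ca$resno,
                 validate = nrow(xyz) >= 4)
  if (nrow(xyz) < 4) return(tr)   # degenerate traces rejected downstream
  if (apply_ss) tr <- assign_secondary_structure(pdb, tr)
  tr
}

#' Assign secondary-structure labels to a trace
#'
#' Residues covered by the document's HELIX records become "helix", SHEET
#' records "sheet", everything else "coil".  Record ranges referencing
#' residues absent from the trace are clipped with a warning.  If the
#' document carries no HELIX/SHEET records at all, a geometric fallback
#' based on virtual C-alpha bond angles and dihedrals is applied
#' (\code{\link{assign_ss_geometric}}).
#'
#' @param pdb a bio3d \code{pdb} object (or path to a PDB file)
#' @param trace a \code{ca_trace} loaded from the same document
#' @return the trace with updated \code{ss_label}
#' @export
assign_secondary_structure <- function(pdb, trace) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  hel <- pdb$helix
  she <- pdb$sheet
  no_hel <- is.null(hel) || length(hel$start) == 0
  no_she <- is.null(she) || length(she$start) == 0
  if (no_hel && no_she) {
    return(assign_ss_geometric(trace))
  }
  lab <- rep("coil", length(trace$residue_index))
  apply_rec <- function(rec, what) {
    if (is.null(rec) || length(rec$start) == 0) return(invisible())
    ch <- rec$chain
    for (k in seq_along(rec$start)) {
      if (!is.null(ch) && !is.na(ch[k]) && ch[k] != trace$chain_id) next
      rng <- rec$start[k]:rec$end[k]
      hit <- which(trace$resno_orig %in% rng)
      if (length(hit) < length(rng)) {
        warning(sprintf("%s record %d references residues absent from the trace; clipped",
                        what, k))
      }
      lab[hit] <<- what
    }
  }
  apply_rec(hel, "helix")
  apply_rec(she, "sheet")
  trace$ss_label <- lab
  trace
}

#' Geometric secondary-structure fallback
#'
#' Labels residue i from the virtual angle (i-1, i, i+1) and dihedral
#' (i-1, i, i+1, i+2) of the C-alpha trace: helix for dihedrals of about
#' +50 deg with tight angles, sheet for nearly trans dihedrals with open
#' angles; everything else coil.  A crude stand-in for a full DSSP-style
#' assignment, adequate for idealized fixtures and knot bookkeeping.
#'
#' @param trace a \code{ca_trace}
#' @return the trace with updated \code{ss_label}
#' @export
assign_ss_geometric <- function(trace) {
  xyz <- trace$xyz
  n <- nrow(xyz)
  lab <- rep("coil", n)
  if (n >= 4) {
    for (i in 2:(n - 2)) {
      th <- bead_angle(xyz[i - 1, ], xyz[i, ], xyz[i + 1, ]) * 180 / pi
      dh <- bead_dihedral(xyz[i - 1, ], xyz[i, ], xyz[i + 1, ],
                          xyz[i + 2, ]) * 180 / pi
      if (dh > 30 && dh < 80 && th > 80 && th < 105) {
        lab[i] <- "helix"
      } else if (abs(dh) > 140 && th > 100 && th < 165) {
        lab[i] <- "sheet"
      }
    }
    # extend runs to their second flanking residue for contiguity
    for (i in 2:(n - 1)) {
      if (lab[i] == "coil" && lab[i - 1] != "coil" &&
          lab[i + 1] == lab[i - 1]) {
        lab[i] <- lab[i - 1]
      }
    }
  }
  trace$ss_label <- lab
  trace
}

#' Build the native contact map of a trace
#'
#' A native contact is a residue pair (i, j) with j - i >=
#' \code{min_seq_sep} whose C-alpha distance is at most \code{cutoff}.
#' Each pair is stored once (i < j) with its native distance and a
#' secondary-structure class: \code{alpha} if both residues are helix,
#' \code{beta} if both are sheet, \code{other} otherwise.
#'
#' @param trace a \code{ca_trace}
#' @param cutoff contact cutoff in Angstrom (default 7.5)
#' @param min_seq_sep minimal sequence separation (default 3)
#' @return object of class \code{native_contact_map}: data.frame with
#'   columns \code{i}, \code{j}, \code{native_distance}, \code{ss_class},
#'   plus attributes \code{cutoff} and \code{min_seq_sep}
#' @export
build_contact_map <- function(trace, cutoff = 7.5, min_seq_sep = 3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_seq_sep < 1) stop("min_seq_sep must be >= 1")
  xyz <- chain_coords(trace)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_seq_sep & d[idx] <= cutoff
  i <- idx[keep, 1]; j <- idx[keep, 2]
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  ss <- if (inherits(trace, "ca_trace")) trace$ss_label else rep("coil", n)
  cls <- ifelse(ss[i] == "helix" & ss[j] == "helix", "alpha",
         ifelse(ss[i] == "sheet" & ss[j] == "sheet", "beta", "other"))
  map <- data.frame(i = i, j = j,
                    native_distance = d[cbind(i, j)],
                    ss_class = cls, stringsAsFactors = FALSE)
  attr(map, "cutoff") <- cutoff
  attr(map, "min_seq_sep") <- min_seq_sep
  class(map) <- c("native_contact_map", "data.frame")
  map
}

#' Write a minimal single-chain CA-only PDB file
#'
#' @param trace a \code{ca_trace} (or bare coordinate matrix)
#' @param file output path
#' @param helix,sheet optional integer vectors of residue indices to emit
#'   as HELIX/SHEET records (contiguous runs are grouped); by default the
#'   trace's own labels are used
#' @export
write_ca_pdb <- function(trace, file, helix = NULL, sheet = NULL) {
  xyz <- chain_coords(trace)
  n <- nrow(xyz)
  rtype <- if (inherits(trace, "ca_trace")) trace$residue_type else rep("ALA", n)
  ch <- if (inherits(trace, "ca_trace")) trace$chain_id else "A"
  if (is.null(helix) && inherits(trace, "ca_trace")) {
    helix <- which(trace$ss_label == "helix")
  }
  if (is.null(sheet) && inherits(trace, "ca_trace")) {
    sheet <- which(trace$ss_label == "sheet")
  }
  runs <- function(v) {
    if (length(v) == 0) return(NULL)
    brk <- c(0, which(diff(v) != 1), length(v))
    lapply(seq_len(length(brk) - 1),
           function(k) c(v[brk[k] + 1], v[brk[k + 1]]))
  }
  con <- file(file, "w")
  on.exit(close(con))
  k <- 1
  for (r in runs(helix)) {
    writeLines(sprintf("HELIX  %3d %3s ALA %s %4d  ALA %s %4d  1%36d",
                       k, sprintf("H%d", k), ch, r[1], ch, r[2],
                       r[2] - r[1] + 1), con)
    k <- k + 1
  }
  k <- 1
  for (r in runs(sheet)) {
    writeLines(sprintf("SHEET  %3d %3s 1 ALA %s%4d  ALA %s%4d  0",
                       k, sprintf("S%d", k), ch, r[1], ch, r[2]), con)
    k <- k + 1
  }
  writeLines(sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), rtype, ch, seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines("TER", con)
  writeLines("END", con)
  invisible(file)
}

#' Serialize a structure/contact-map model to JSON
#'
#' @param trace a \code{ca_trace}
#' @param map a \code{native_contact_map}
#' @param file output path
#' @param extra named list merged into the JSON document (e.g. resolved
#'   force-field parameters, for provenance)
#' @export
write_model_json <- function(trace, map, file, extra = list()) {
  doc <- c(list(
    n_residues = nrow(trace$xyz),
    chain_id = trace$chain_id,
    residue_type = trace$residue_type,
    ss_label = trace$ss_label,
    xyz = unname(apply(trace$xyz, 1, function(r) round(r, 4),
                       simplify = FALSE)),
    contact_cutoff = attr(map, "cutoff"),
    min_seq_sep = attr(map, "min_seq_sep"),
    contacts = list(i = map$i, j = map$j,
                    native_distance = round(map$native_distance, 4),
                    ss_class = map$ss_class)
  ), extra)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a model written by \code{\link{write_model_json}}
#' @param file path
#' @return list with \code{trace}, \code{map} and any extra fields
#' @export
read_model_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  xyz <- if (is.matrix(doc$xyz)) doc$xyz else
    do.call(rbind, lapply(doc$xyz, as.numeric))
  tr <- ca_trace(xyz, residue_type = doc$residue_type,
                 ss_label = doc$ss_label, chain_id = doc$chain_id,
                 validate = FALSE)
  map <- data.frame(i = doc$contacts$i, j = doc$contacts$j,
                    native_distance = doc$contacts$native_distance,
                    ss_class = doc$contacts$ss_class,
                    stringsAsFactors = FALSE)
  attr(map, "cutoff") <- doc$contact_cutoff
  attr(map, "min_seq_sep") <- doc$min_seq_sep
  class(map) <- c("native_contact_map", "data.frame")
  list(trace = tr, map = map,
       extra = doc[setdiff(names(doc),
                           c("n_residues", "chain_id", "residue_type",
                             "ss_label", "xyz", "contact_cutoff",
                             "min_seq_sep", "contacts"))])
}
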