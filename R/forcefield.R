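# Coarse-grained potential-energy model: native-centric (Go) terms built
# from a native C-alpha trace, plus an optional quasi-chemical non-native
# contact term.  Reduced units: eps_native = 1 sets the energy scale,
# temperature is quoted as kBT in the same units, lengths in Angstrom.

KD_HYDROPATHY <- c(
  ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5, GLN = -3.5,
  GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5, LEU = 3.8, LYS = -3.9,
  MET = 1.9, PHE = 2.8, PRO = -1.6, SER = -0.8, THR = -0.7, TRP = -0.9,
  TYR = -1.3, VAL = 4.2)

#' Quasi-chemical contact-energy matrix (synthetic surrogate)
#'
#' Returns the symmetric 20 x 20 matrix of dimensionless amino-acid pair
#' contact energies used by the non-native term.  The default matrix is a
#' synthetic surrogate built from the Kyte-Doolittle hydropathy scale
#' (\eqn{e_{ab} = -(h_a + h_b)/2}, rescaled), shifted to zero mean over
#' the 210 unique pairs so that it encodes relative contact propensities:
#' hydrophobic pairs attract, polar pairs effectively repel.  It is
#' shipped as \code{inst/extdata/qc_contact_energies_synthetic.csv}; any
#' other matrix in the same format can be supplied to
#' \code{\link{go_model}}.
#'
#' @param file optional path to a CSV with 20 rows/columns named by
#'   three-letter amino-acid codes
#' @return symmetric 20 x 20 numeric matrix with zero mean over unique
#'   pairs
#' @export
qc_contact_matrix <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "qc_contact_energies_synthetic.csv",
                        package = "knotfold")
  }
  if (nzchar(file) && file.exists(file)) {
    m <- as.matrix(utils::read.csv(file, row.names = 1, check.names = FALSE))
  } else {
    # regenerate from the hydropathy scale (same construction as the file)
    h <- KD_HYDROPATHY / max(abs(KD_HYDROPATHY))
    m <- -outer(h, h, function(a, b) (a + b) / 2)
    dimnames(m) <- list(names(KD_HYDROPATHY), names(KD_HYDROPATHY))
    m <- m - mean(m[upper.tri(m, diag = TRUE)])
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("contact-energy matrix must be symmetric")
  }
  m
}

#' Build a coarse-grained potential-energy model
#'
#' Constructs the full term list from a native structure: harmonic bonds,
#' angles and periodic dihedrals restrained to their native values, a
#' 12-10 well per native contact (minimum \code{-eps_native} at the native
#' distance), excluded-volume repulsion for all other pairs with sequence
#' separation at least \code{min_seq_sep}, and (when \code{lambda_nn > 0})
#' a quasi-chemical non-native attraction with a smooth sigmoidal cutoff.
#'
#' @param trace native \code{ca_trace}
#' @param map \code{native_contact_map} built from the same trace
#' @param eps_native native-contact well depth (energy unit; default 1)
#' @param k_bond,k_angle bonded stiffnesses (energy/A^2, energy/rad^2)
#' @param k_dih1,k_dih3 1- and 3-fold dihedral amplitudes
#' @param sigma_rep excluded-volume radius in Angstrom
#' @param eps_rep repulsion prefactor
#' @param lambda_nn non-native energy scale; 0 recovers the pure
#'   native-centric model
#' @param nn_cutoff,nn_width centre and width (Angstrom) of the smooth
#'   non-native cutoff
#' @param qc_matrix 20 x 20 contact-energy matrix (default
#'   \code{\link{qc_contact_matrix}()})
#' @param attractive_only keep only attractive (negative) entries of the
#'   shifted matrix (default TRUE: the term models an overall attraction)
#' @return object of class \code{go_model}
#' @export
go_model <- function(trace, map, eps_native = 1, k_bond = 100,
                     k_angle = 20, k_dih1 = 1, k_dih3 = 0.5,
                     sigma_rep = 4.0, eps_rep = 1, lambda_nn = 0,
                     nn_cutoff = 8.5, nn_width = 0.5, qc_matrix = NULL,
                     attractive_only = TRUE) {
  stopifnot(inherits(trace, "ca_trace"))
  if (eps_native <= 0) stop("eps_native must be positive")
  if (sigma_rep <= 0) stop("sigma_rep must be positive")
  if (any(c(k_bond, k_angle, k_dih1, k_dih3, lambda_nn) < 0)) {
    stop("stiffnesses and lambda_nn must be non-negative")
  }
  xyz <- trace$xyz
  n <- nrow(xyz)
  bond_r0 <- sqrt(rowSums(diff(xyz)^2))
  angle_t0 <- vapply(2:(n - 1), function(i) {
    bead_angle(xyz[i - 1, ], xyz[i, ], xyz[i + 1, ])
  }, numeric(1))
  dih_phi0 <- vapply(seq_len(n - 3), function(i) {
    bead_dihedral(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ], xyz[i + 3, ])
  }, numeric(1))
  B <- NULL
  if (lambda_nn > 0) {
    qc <- if (is.null(qc_matrix)) qc_contact_matrix() else qc_matrix
    aa <- trace$residue_type
    aa[!aa %in% rownames(qc)] <- "ALA"     # unknown residues: neutral-ish
    B <- qc[aa, aa]
    if (attractive_only) B <- pmin(B, 0)
    dimnames(B) <- NULL
  }
  structure(list(
    n = n, trace = trace, map = map, native_xyz = xyz,
    k_bond = k_bond, k_angle = k_angle, k_dih1 = k_dih1, k_dih3 = k_dih3,
    bond_r0 = bond_r0, angle_t0 = angle_t0, dih_phi0 = dih_phi0,
    nat_i = map$i, nat_j = map$j, nat_r0 = map$native_distance,
    eps_native = eps_native, sigma_rep = sigma_rep, eps_rep = eps_rep,
    min_seq_sep = attr(map, "min_seq_sep"),
    lambda_nn = lambda_nn, nn_cutoff = nn_cutoff, nn_width = nn_width,
    B = B, attractive_only = attractive_only
  ), class = "go_model")
}

#' @export
print.go_model <- function(x, ...) {
  cat(sprintf(
    "go_model: %d beads, %d native contacts, lambda_nn = %g%s\n",
    x$n, length(x$nat_i), x$lambda_nn,
    if (x$lambda_nn > 0) " (quasi-chemical non-native term on)" else ""))
  invisible(x)
}

# plain list handed to the C++ kernels
as_cpp_model <- function(model, lambda_override = NULL) {
  lam <- if (is.null(lambda_override)) model$lambda_nn else lambda_override
  list(n = model$n, k_bond = model$k_bond, k_angle = model$k_angle,
       k_dih1 = model$k_dih1, k_dih3 = model$k_dih3,
       bond_r0 = model$bond_r0, angle_t0 = model$angle_t0,
       dih_phi0 = model$dih_phi0,
       nat_i = as.integer(model$nat_i), nat_j = as.integer(model$nat_j),
       nat_r0 = model$nat_r0, eps_native = model$eps_native,
       sigma_rep = model$sigma_rep, eps_rep = model$eps_rep,
       min_seq_sep = as.integer(model$min_seq_sep),
       lambda_nn = lam, nn_cutoff = model$nn_cutoff,
       nn_width = model$nn_width,
       B = if (lam > 0) {
         if (is.null(model$B)) stop("model has no quasi-chemical matrix")
         model$B
       } else matrix(0, 0, 0))
}

check_conformation <- function(x, model) {
  x <- chain_coords(x)
  if (nrow(x) != model$n) {
    stop(sprintf("conformation has %d beads but the model expects %d",
                 nrow(x), model$n))
  }
  if (!all(is.finite(x))) stop("non-finite coordinates")
  x
}

#' Native-centric (Go) energy of a conformation
#'
#' Sum of the bonded, angular, dihedral, native-contact and
#' excluded-volume terms; the non-native term is excluded regardless of
#' the model's \code{lambda_nn}.
#'
#' @param x conformation (n x 3 matrix)
#' @param model a \code{go_model}
#' @return scalar energy (reduced units)
#' @export
go_energy <- function(x, model) {
  x <- check_conformation(x, model)
  res <- cpp_energy_force(x, as_cpp_model(model, lambda_override = 0),
                          FALSE)
  res$energy
}

#' Quasi-chemical non-native energy of a conformation
#'
#' Sums \code{lambda_nn * B[a,b] * s(r)} over all pairs at sequence
#' separation >= \code{min_seq_sep} that are not native contacts, with
#' \code{s} a sigmoidal switch of width \code{nn_width} centred at
#' \code{nn_cutoff}.  Exactly 0 when \code{lambda_nn = 0}.
#'
#' @inheritParams go_energy
#' @return scalar energy
#' @export
nonnative_energy <- function(x, model) {
  x <- check_conformation(x, model)
  if (model$lambda_nn == 0) return(0)
  res <- cpp_energy_force(x, as_cpp_model(model), FALSE)
  unname(res$terms["nonnative"])
}

#' Total energy and force of a conformation
#'
#' @inheritParams go_energy
#' @return list with \code{energy} (scalar), \code{force} (n x 3 matrix,
#'   the analytic negative gradient) and \code{terms} (named breakdown)
#' @export
total_energy_and_force <- function(x, model) {
  x <- check_conformation(x, model)
  res <- cpp_energy_force(x, as_cpp_model(model), TRUE)
  list(energy = res$energy, force = res$force, terms = res$terms)
}
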