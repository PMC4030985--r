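# Trajectory container: time-ordered conformations plus run metadata.

#' Construct a trajectory object
#'
#' @param frames numeric array (n_beads x 3 x n_frames) or list of n x 3
#'   matrices
#' @param stride time units (MC sweeps or Langevin steps) between saved
#'   frames
#' @param seed RNG seed the run was started from
#' @param kBT thermal energy of the run (reduced units)
#' @param engine "mc", "langevin" or "scripted"
#' @param scalars optional data.frame of per-frame scalars (energy, q,
#'   q_record, bias_energy, ...)
#' @param metadata free-form list (bias parameters, fixture label, ...)
#' @return object of class \code{cg_trajectory}
#' @export
cg_trajectory <- function(frames, stride = 1, seed = NA_integer_,
                          kBT = NA_real_, engine = "scripted",
                          scalars = NULL, metadata = list()) {
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    dim = c(nrow(frames[[1]]), 3, length(frames)))
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] == 3)
  if (dim(frames)[3] < 2) {
    stop("a trajectory needs at least 2 frames")
  }
  structure(list(frames = frames, stride = stride, seed = seed, kBT = kBT,
                 engine = engine, scalars = scalars, metadata = metadata),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d beads, %d frames (stride %g, engine %s)\n",
              n_beads(x), n_frames(x), x$stride, x$engine))
  invisible(x)
}

#' Number of saved frames
#' @param traj a \code{cg_trajectory}
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Number of beads per frame
#' @param traj a \code{cg_trajectory}
#' @export
n_beads <- function(traj) dim(traj$frames)[1]

#' Extract one frame as an n x 3 matrix
#' @param traj a \code{cg_trajectory}
#' @param f frame index (1-based)
#' @export
traj_frame <- function(traj, f) traj$frames[, , f]

#' Write a trajectory as a compact XYZ file plus a JSON sidecar
#'
#' The XYZ variant stores one block per frame (bead count, comment line,
#' then \code{CA x y z} rows); the sidecar holds seed, parameters and the
#' per-frame scalar table.
#'
#' @param traj a \code{cg_trajectory}
#' @param file output path; sidecar written to \code{paste0(file, ".json")}
#' @export
write_trajectory_xyz <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- n_beads(traj)
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d", f), con)
    X <- traj_frame(traj, f)
    writeLines(sprintf("CA %.4f %.4f %.4f", X[, 1], X[, 2], X[, 3]), con)
  }
  meta <- list(stride = traj$stride, seed = traj$seed, kBT = traj$kBT,
               engine = traj$engine, metadata = traj$metadata,
               scalars = traj$scalars)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' Read a trajectory written by \code{\link{write_trajectory_xyz}}
#' @param file path to the XYZ file
#' @return a \code{cg_trajectory}
#' @export
read_trajectory_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    i <- i + 2 + n
  }
  meta_path <- paste0(file, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  scalars <- if (!is.null(meta$scalars)) as.data.frame(meta$scalars) else NULL
  cg_trajectory(frames,
                stride = meta$stride %||% 1,
                seed = meta$seed %||% NA_integer_,
                kBT = meta$kBT %||% NA_real_,
                engine = meta$engine %||% "scripted",
                scalars = scalars,
                metadata = meta$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as a multi-model CA-only PDB file
#' @param traj a \code{cg_trajectory}
#' @param file output path
#' @param chain chain identifier (default "A")
#' @export
write_trajectory_pdb <- function(traj, file, chain = "A") {
  con <- file(file, "w")
  on.exit(close(con))
  n <- n_beads(traj)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    X <- traj_frame(traj, f)
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), chain, seq_len(n), X[, 1], X[, 2], X[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
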