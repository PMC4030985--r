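# Pipeline orchestration: configuration handling and the full
# unfold -> biased-refold -> rank -> knot/mechanism-report protocol.

#' Default run configuration
#'
#' Returns the fully resolved configuration list; every run directory
#' gets a JSON snapshot of it, sufficient to reproduce the run
#' bit-for-bit together with the package version.
#'
#' @param ... named overrides for any nested field, e.g.
#'   \code{forcefield = list(lambda_nn = 0.5)}
#' @return nested configuration list
#' @export
default_config <- function(...) {
  cfg <- list(
    structure = list(source = "fixture:shallow_trefoil", n_beads = 40,
                     chain = "A", cutoff = 7.5, min_seq_sep = 3),
    forcefield = list(eps_native = 1, k_bond = 100, k_angle = 20,
                      k_dih1 = 1, k_dih3 = 0.5, sigma_rep = 4.0,
                      lambda_nn = 0, nn_cutoff = 8.5, nn_width = 0.5,
                      attractive_only = TRUE),
    sampler = list(engine = "mc", n_sweeps = 40000, kBT = 0.7,
                   stride = 1000, seed_base = 1,
                   crankshaft_max_angle = 0.4, displacement_max = 0.25,
                   mix = 0.5),
    unfold = list(kBT_factor = 5, n_sweeps = 8000, q_max = 0.1),
    # 48 independent biased trials per start is the conventional scale
    # for dominant-pathway studies; scale down for smoke runs
    ratchet = list(k_ratchet = 1500, q_stop = 0.95, n_trials = 48,
                   n_starts = 5, q_tol = 1.2),
    productive = list(q_min = 0.9, rmsd_max = 2.0,
                      require_native_knot = TRUE),
    analysis = list(persistence = 5, window = 8),
    output_dir = "knotfold_run"
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' \code{\link{default_config}}.
#'
#' @param file path to a YAML configuration
#' @return resolved configuration list
#' @export
read_run_config <- function(file) {
  user <- yaml::read_yaml(file)
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  do.call(default_config, user)
}

# resolve the structure block into (trace, map)
resolve_structure <- function(cfg) {
  src <- cfg$structure$source
  if (startsWith(src, "fixture:")) {
    motif <- sub("^fixture:", "", src)
    toy_native(cfg$structure$n_beads, motif,
               cutoff = cfg$structure$cutoff,
               min_seq_sep = cfg$structure$min_seq_sep)
  } else {
    tr <- load_ca_trace(src, chain = cfg$structure$chain)
    list(trace = tr,
         map = build_contact_map(tr, cutoff = cfg$structure$cutoff,
                                 min_seq_sep = cfg$structure$min_seq_sep))
  }
}

# unfolded, unknotted start by high-temperature evolution from native;
# returns NULL if the run never met both criteria
make_unfolded_start <- function(native_xyz, model, map, cfg, seed) {
  s <- cfg$sampler
  u <- cfg$unfold
  tr <- run_sampler(native_xyz, model, "mc",
                    n_sweeps = u$n_sweeps, kBT = u$kBT_factor * s$kBT,
                    stride = max(1, u$n_sweeps %/% 16), seed = seed)
  for (f in rev(seq_len(n_frames(tr)))) {
    X <- traj_frame(tr, f)
    if (native_fraction(X, map) < u$q_max && !is_knotted(X)) return(X)
  }
  NULL
}

#' Run the full folding-and-knotting protocol
#'
#' Executes the pipeline stages in order, writing per-stage outputs into
#' the run directory:
#' \enumerate{
#'   \item build the structure model (\code{model.json}, resolved config
#'     snapshot);
#'   \item generate unfolded, unknotted starting conformations by
#'     high-temperature runs (each start checked to be unknotted);
#'   \item evolve each start with independent ratchet-and-pawl trials;
#'   \item rank trials sharing a start by Onsager-Machlup action
#'     (Langevin, stride-1 runs) and flag the dominant productive one;
#'   \item knot, mechanism and observable reports
#'     (\code{events.tsv}, \code{dominant.tsv}, \code{summary.json}).
#' }
#' A stage failure preserves the completed stages plus a machine-readable
#' \code{failure.json}.
#'
#' @param config configuration list from \code{\link{default_config}} or
#'   \code{\link{read_run_config}}
#' @param verbose print per-stage progress (default TRUE)
#' @return the run directory path, invisibly; the summary list as
#'   attribute \code{"summary"}
#' @export
run_protocol <- function(config = default_config(), verbose = TRUE) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "build"
  res <- tryCatch({
    jsonlite::write_json(config, out("resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    st <- resolve_structure(config)
    ff <- config$forcefield
    model <- go_model(st$trace, st$map, eps_native = ff$eps_native,
                      k_bond = ff$k_bond, k_angle = ff$k_angle,
                      k_dih1 = ff$k_dih1, k_dih3 = ff$k_dih3,
                      sigma_rep = ff$sigma_rep, lambda_nn = ff$lambda_nn,
                      nn_cutoff = ff$nn_cutoff, nn_width = ff$nn_width,
                      attractive_only = ff$attractive_only)
    write_model_json(st$trace, st$map, out("model.json"),
                     extra = list(forcefield = ff))
    say("[build] %d beads, %d native contacts", model$n, length(model$nat_i))

    stage <- "starts"
    rt <- config$ratchet
    s <- config$sampler
    starts <- list()
    seed0 <- s$seed_base
    tries <- 0
    while (length(starts) < rt$n_starts && tries < 4 * rt$n_starts) {
      tries <- tries + 1
      x <- make_unfolded_start(st$trace$xyz, model, st$map, config,
                               seed = seed0 * 10000 + tries)
      if (!is.null(x)) starts[[length(starts) + 1]] <- x
    }
    if (length(starts) == 0) stop("no unfolded unknotted start generated")
    say("[starts] %d unfolded unknotted starts (from %d attempts)",
        length(starts), tries)

    stage <- "trials"
    ms <- move_set(s$crankshaft_max_angle, s$displacement_max, s$mix)
    rows <- list()
    events <- list()
    for (is_ in seq_along(starts)) {
      for (it in seq_len(rt$n_trials)) {
        seed <- seed0 * 100000 + is_ * 1000 + it
        traj <- run_rmd(starts[[is_]], model, engine = s$engine,
                        n_sweeps = s$n_sweeps, kBT = s$kBT,
                        stride = s$stride, seed = seed,
                        k_ratchet = rt$k_ratchet, q_stop = rt$q_stop,
                        moveset = ms, q_tol = rt$q_tol,
                        check_knot = FALSE)
        X <- traj_frame(traj, n_frames(traj))
        qf <- utils::tail(traj$scalars$q, 1)
        rmsd <- kabsch_rmsd(st$trace$xyz, X)
        kn <- classify_knot(X)
        native_kn <- classify_knot(st$trace$xyz)
        prod_ok <- qf >= config$productive$q_min &&
          rmsd <= config$productive$rmsd_max &&
          (!config$productive$require_native_knot ||
             (kn$label == native_kn$label &&
                kn$chirality == native_kn$chirality))
        act <- NA_real_
        if (s$engine == "langevin" && traj$stride == 1) {
          act <- om_action(traj, model,
                           langevin_params(kBT = s$kBT, dt = s$dt %||% 1e-4))
        }
        rows[[length(rows) + 1]] <- data.frame(
          start_id = is_, trial_id = it, seed = seed,
          q_final = qf, rmsd_final = rmsd, knot = kn$label,
          chirality = kn$chirality, productive = prod_ok, action = act)
        fl <- knot_flags(traj)
        ev <- first_knotting_event(traj,
                                   persistence = config$analysis$persistence,
                                   flags = fl)
        if (!is.null(ev)) {
          mech <- suppressWarnings(
            classify_mechanism(traj, ev, window = config$analysis$window))
          events[[length(events) + 1]] <- data.frame(
            start_id = is_, trial_id = it, frame = ev$frame,
            core_start = ev$core$start, core_end = ev$core$end,
            mechanism = mech)
        }
        write_trajectory_xyz(traj, out(sprintf("traj_s%02d_t%02d.xyz",
                                               is_, it)))
      }
      say("[trials] start %d/%d done", is_, length(starts))
    }
    trials <- do.call(rbind, rows)
    utils::write.table(trials, out("trials.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    ev_df <- if (length(events)) do.call(rbind, events) else
      data.frame(start_id = integer(0), trial_id = integer(0),
                 frame = integer(0), core_start = integer(0),
                 core_end = integer(0), mechanism = character(0))
    utils::write.table(ev_df, out("events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

    stage <- "rank"
    dom <- trials[c("start_id", "trial_id", "action", "productive")]
    dom$dominant <- FALSE
    for (is_ in unique(dom$start_id)) {
      idx <- which(dom$start_id == is_ & dom$productive)
      if (length(idx) == 0) next
      pick <- if (all(is.na(dom$action[idx]))) idx[1] else
        idx[which.min(dom$action[idx])]
      dom$dominant[pick] <- TRUE
    }
    utils::write.table(dom, out("dominant.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

    stage <- "summary"
    summary <- list(
      n_starts = length(starts),
      n_trials = nrow(trials),
      knotting_success_fraction = mean(tapply(trials$productive,
                                              trials$start_id, any)),
      fraction_trials_knotted = mean(trials$knot != "unknot"),
      mechanisms = as.list(table(ev_df$mechanism)),
      lambda_nn = config$forcefield$lambda_nn)
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("[summary] knotting success fraction: %.2f",
        summary$knotting_success_fraction)
    summary
  }, error = function(e) {
    jsonlite::write_json(list(stage = stage, error = conditionMessage(e)),
                         out("failure.json"), auto_unbox = TRUE)
    stop("protocol failed in stage '", stage, "': ", conditionMessage(e))
  })
  invisible(structure(config$output_dir, summary = res))
}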