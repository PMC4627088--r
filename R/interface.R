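# ---------------------------------------------------------------------------
# configuration, CLI, sweeps, report, manifest
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' All study constants (box, temperature, friction, cage constants,
#' classifier thresholds, kinetics protocol, Gaussian non-specific
#' moments) live in one JSON defaults file with provenance notes.
#'
#' @param file optional path to an alternative configuration file.
#' @return nested configuration list.
#' @export
default_config <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "defaults.json", package = "cgsearch")
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  problems <- character(0)
  if (!is.null(cfg$salt_mM) && cfg$salt_mM <= 0)
    problems <- c(problems, "salt_mM must be > 0")
  if (!is.null(cfg$temperature) && cfg$temperature < 0)
    problems <- c(problems, "temperature must be >= 0")
  if (!is.null(cfg$dt) && cfg$dt <= 0)
    problems <- c(problems, "dt must be > 0")
  if (!is.null(cfg$box) && any(unlist(cfg$box) <= 0))
    problems <- c(problems, "box edges must be > 0")
  if (length(problems) > 0)
    stop("invalid configuration: ", paste(problems, collapse = "; "))
  invisible(cfg)
}

config_cage <- function(cfg) {
  cg <- cfg$cage
  if (is.null(cg)) return(NULL)
  r <- cg$radius
  if (identical(r, "inf") || identical(r, Inf)) return(cage_spec("inf"))
  if (identical(r, "rigid") || identical(r, 0)) return(cage_spec("rigid"))
  cage_spec(as.numeric(r), K = cg$k, C = cg$c,
            continuity_shift = isTRUE(cg$continuity_shift))
}

#' One search run with mode classification
#'
#' Convenience pipeline used by the sweep runner and the CLI: build the
#' system (protein placed at random >= 30 A from the DNA), run Langevin
#' dynamics, classify every frame.
#'
#' @param dna `cgdna`.
#' @param protein `cgprotein`.
#' @param Cs salt (mM).
#' @param cage `cage_spec` or NULL.
#' @param n_steps,seed,output_stride,dt simulation controls.
#' @param equil_steps steps discarded before classification.
#' @param axis_mode passed to [classify_timeline()].
#' @return list: `timeline`, `propensities`, `traj`.
#' @export
run_search_experiment <- function(dna, protein, Cs = 20, cage = NULL,
                                  n_steps = 50000, seed = 1,
                                  output_stride = 100, dt = 0.01,
                                  equil_steps = 0, axis_mode = "global") {
  start <- random_protein_placement(dna, protein, min_dist = 30, seed = seed)
  sys <- build_system(dna = dna, protein = protein, protein_coords = start,
                      Cs = Cs, cage = cage)
  cfg <- simulation_config(n_steps = n_steps, seed = seed,
                           output_stride = output_stride, dt = dt)
  traj <- run_langevin(sys, cfg)
  fmin <- max(1, floor(equil_steps / output_stride) + 1)
  tl <- classify_timeline(traj, axis_mode = axis_mode,
                          frames = fmin:n_frames(traj))
  list(timeline = tl, propensities = mode_propensities(tl), traj = traj)
}

#' Parameter sweep over salt or cage radius
#'
#' Runs [run_search_experiment()] over a grid of values and replicate
#' seeds and collects propensities, search efficiency and D1 in a
#' long-format table; a failing cell is recorded and the sweep continues.
#'
#' @param dna `cgdna`.
#' @param protein `cgprotein`.
#' @param axis `"salt"` or `"cage.radius"`.
#' @param values vector of axis values (for `cage.radius`, numeric A or
#'   `"rigid"` / `"inf"`).
#' @param seeds vector of seeds (replicates per cell).
#' @param ... passed to [run_search_experiment()].
#' @return data.frame: axis, value, seed, sliding, hopping, diffusion_3d,
#'   n_frames, efficiency, D1, error.
#' @export
sweep_runner <- function(dna, protein, axis = c("salt", "cage.radius"),
                         values, seeds = 1, ...) {
  axis <- match.arg(axis)
  if (length(values) == 0) stop("values must be nonempty")
  rows <- list()
  for (v in values) {
    for (s in seeds) {
      res <- tryCatch({
        out <- if (axis == "salt") {
          run_search_experiment(dna, protein, Cs = as.numeric(v), seed = s, ...)
        } else {
          cg <- if (v %in% c("rigid", "inf")) cage_spec(v)
                else cage_spec(as.numeric(v))
          run_search_experiment(dna, protein, cage = cg, seed = s, ...)
        }
        fr <- out$propensities$fractions
        d1 <- tryCatch(estimate_D1(out$timeline)$D1, error = function(e) NA)
        data.frame(axis = axis, value = as.character(v), seed = s,
                   sliding = fr[["sliding"]], hopping = fr[["hopping"]],
                   diffusion_3d = fr[["diffusion_3d"]],
                   n_frames = nrow(out$timeline),
                   efficiency = search_efficiency(out$timeline)$mean_bp_scanned,
                   D1 = d1, error = NA_character_)
      }, error = function(e) {
        data.frame(axis = axis, value = as.character(v), seed = s,
                   sliding = NA, hopping = NA, diffusion_3d = NA,
                   n_frames = NA, efficiency = NA, D1 = NA,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Run manifest
#'
#' Inventory of a result directory: config hash, seeds, package version
#' and md5 checksums of every output file.
#'
#' @param dir result directory.
#' @param config configuration list used for the run.
#' @param seeds seeds used.
#' @param file output path (default `dir/manifest.json`).
#' @return manifest list, invisibly.
#' @export
write_manifest <- function(dir, config = list(), seeds = integer(0),
                           file = file.path(dir, "manifest.json")) {
  fls <- setdiff(list.files(dir, recursive = TRUE), basename(file))
  paths <- file.path(dir, fls)
  man <- list(
    package_version = as.character(utils::packageVersion("cgsearch")),
    config_hash = digest_config(config),
    seeds = seeds,
    outputs = data.frame(file = fls, md5 = unname(tools::md5sum(paths)))
  )
  jsonlite::write_json(man, file, auto_unbox = TRUE, digits = NA)
  invisible(man)
}

digest_config <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small stable checksum without extra dependencies
  v <- utf8ToInt(paste(s, collapse = ""))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

# ---------------------------------------------------------------------------
# CLI
# ---------------------------------------------------------------------------

cli_args <- function(argv) {
  # --key value pairs; bare flags become TRUE
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (i < length(argv) && !startsWith(argv[i + 1], "--")) {
      out[[key]] <- argv[i + 1]; i <- i + 2
    } else { out[[key]] <- TRUE; i <- i + 1 }
  }
  out
}

#' Command-line dispatcher
#'
#' Subcommands: `build-dna`, `build-protein`, `simulate`, `classify`,
#' `kinetics`, `report`, `fixtures`. Designed to be called from the
#' bundled `inst/cli/cgsearch` script; returns an exit status instead of
#' quitting so it can be tested in-process.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return integer exit status (0 = success).
#' @export
cli_dispatch <- function(argv) {
  status <- tryCatch({
    if (length(argv) == 0) stop("usage: cgsearch <subcommand> [--options]")
    cmd <- argv[1]
    args <- cli_args(argv[-1])
    switch(cmd,
      "build-dna" = cli_build_dna(args),
      "build-protein" = cli_build_protein(args),
      "simulate" = cli_simulate(args),
      "classify" = cli_classify(args),
      "kinetics" = cli_kinetics(args),
      "report" = cli_report(args),
      "fixtures" = cli_fixtures(args),
      stop(sprintf("unknown subcommand '%s'", cmd))
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}

need <- function(args, key) {
  if (is.null(args[[key]])) stop(sprintf("missing required --%s", key))
  args[[key]]
}

cli_build_dna <- function(args) {
  out <- need(args, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  n <- as.integer(if (is.null(args$length)) 200 else args$length)
  seed <- as.integer(if (is.null(args$seed)) 1 else args$seed)
  seqn <- if (!is.null(args$`sequence-file`)) {
    paste(readLines(args$`sequence-file`), collapse = "")
  } else random_dna_sequence(n, seed)
  if (!is.null(args$target)) seqn <- as.character(insert_target_site(seqn, args$target))
  dna <- build_ideal_bdna(seqn)
  write_dna_topology(dna, file.path(out, "dna_topology.json"))
  write_xyz(dna$coords, paste0(dna$beads$site, dna$beads$strand),
            file.path(out, "dna.xyz"), comment = "ideal B-DNA")
  message("wrote ", out)
}

cli_build_protein <- function(args) {
  out <- need(args, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rr <- as.integer(strsplit(if (is.null(args$recognition)) "17:32"
                            else args$recognition, ":")[[1]])
  p <- if (!is.null(args$pdb)) {
    load_protein_calpha(readLines(args$pdb), rr, chain = args$chain)
  } else {
    n <- as.integer(if (is.null(args$residues)) 48 else args$residues)
    make_synthetic_protein(n, rr, seed = as.integer(if (is.null(args$seed)) 1
                                                    else args$seed))
  }
  if (is.null(p$native_contacts))
    p$native_contacts <- contacts_from_calpha(p$ca_coords)
  jsonlite::write_json(list(sequence = p$sequence, charges = p$charges,
                            recognition_range = p$recognition_range,
                            synthetic = isTRUE(p$synthetic)),
                       file.path(out, "protein.json"), auto_unbox = TRUE,
                       digits = NA)
  write_xyz(p$ca_coords, strsplit(p$sequence, "")[[1]],
            file.path(out, "protein.xyz"), comment = "C-alpha beads")
  write.csv(p$native_contacts, file.path(out, "native_contacts.csv"),
            row.names = FALSE)
  message("wrote ", out)
}

cli_simulate <- function(args) {
  cfg <- if (is.null(args$config)) default_config() else default_config(args$config)
  out <- need(args, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(if (is.null(args$seed)) 1 else args$seed)
  n_steps <- as.integer(if (is.null(args$steps)) 20000 else args$steps)
  dna <- build_ideal_bdna(random_dna_sequence(cfg$dna_length_bp, seed))
  protein <- make_synthetic_protein(cfg$protein$n_residues,
                                    unlist(cfg$protein$recognition_range),
                                    seed = seed)
  res <- run_search_experiment(dna, protein, Cs = cfg$salt_mM,
                               cage = config_cage(cfg), n_steps = n_steps,
                               seed = seed, dt = cfg$dt)
  write_dna_topology(dna, file.path(out, "dna_topology.json"))
  write_protein_json(protein, file.path(out, "protein.json"))
  write_trajectory_xyz(res$traj, file.path(out, "traj.xyz"))
  write.csv(res$timeline, file.path(out, "timeline.csv"), row.names = FALSE)
  write.csv(res$traj$energies, file.path(out, "energies.csv"),
            row.names = FALSE)
  write_manifest(out, config = cfg, seeds = seed)
  message("wrote ", out)
}

cli_classify <- function(args) {
  traj_file <- need(args, "traj")
  topo <- need(args, "topology")
  prot_file <- need(args, "protein")
  out <- need(args, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dna <- read_dna_topology(topo)
  protein <- read_protein_json(prot_file)
  traj <- read_trajectory_xyz(traj_file, dna, protein)
  tl <- classify_timeline(traj)
  write.csv(tl, file.path(out, "timeline.csv"), row.names = FALSE)
  pr <- mode_propensities(tl)
  jsonlite::write_json(list(mode_fractions = as.list(pr$fractions),
                            mode_counts = as.list(pr$counts)),
                       file.path(out, "propensities.json"),
                       auto_unbox = TRUE, digits = NA)
  message("wrote ", out)
}

cli_kinetics <- function(args) {
  cfg <- if (is.null(args$config)) default_config() else default_config(args$config)
  out <- need(args, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(if (is.null(args$seed)) 1 else args$seed)
  reps <- as.integer(if (is.null(args$replicas)) 5 else args$replicas)
  steps <- as.integer(if (is.null(args$steps)) 20000 else args$steps)
  nbp <- as.integer(if (is.null(args$length)) 60 else args$length)
  seqn <- insert_target_site(random_dna_sequence(nbp, seed),
                             paste(rep("A", 10), collapse = ""))
  dna <- build_ideal_bdna(as.character(seqn))
  protein <- make_synthetic_protein(cfg$protein$n_residues,
                                    unlist(cfg$protein$recognition_range),
                                    seed = seed)
  kr <- run_kinetics_ensemble(dna, protein,
                              c(attr(seqn, "target_start"),
                                attr(seqn, "target_end")),
                              n_replicas = reps, n_steps = steps, seed = seed,
                              Cs = cfg$salt_mM, cage = config_cage(cfg))
  fp <- data.frame(replica = seq_along(kr$success), success = kr$success,
                   first_passage_step = kr$first_passage_steps)
  write.csv(fp, file.path(out, "first_passage.csv"), row.names = FALSE)
  jsonlite::write_json(list(success_fraction = kr$success_fraction,
                            steps = kr$steps, ensemble_Qsp = kr$ensemble_Qsp),
                       file.path(out, "ensemble.json"), auto_unbox = TRUE,
                       digits = NA)
  write_manifest(out, config = cfg, seeds = seed + seq_len(reps))
  message("wrote ", out)
}

cli_report <- function(args) {
  ind <- need(args, "in")
  tl_file <- file.path(ind, "timeline.csv")
  if (!file.exists(tl_file)) stop("no timeline.csv in ", ind)
  tl <- read.csv(tl_file, stringsAsFactors = FALSE)
  pr <- mode_propensities(tl)
  ev <- segment_sliding_events(tl)
  eff <- search_efficiency(tl)
  rep <- list(mode_fractions = as.list(pr$fractions),
              mode_counts = as.list(pr$counts),
              n_sliding_events = nrow(ev),
              mean_bp_scanned = eff$mean_bp_scanned)
  outf <- if (!is.null(args$out)) args$out else file.path(ind, "report.json")
  jsonlite::write_json(rep, outf, auto_unbox = TRUE, digits = NA)
  message("wrote ", outf)
}

cli_fixtures <- function(args) {
  out <- need(args, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(if (is.null(args$seed)) 1 else args$seed)
  dna <- build_ideal_bdna(random_dna_sequence(40, seed))
  write_dna_topology(dna, file.path(out, "dna_topology.json"))
  write_xyz(dna$coords, paste0(dna$beads$site, dna$beads$strand),
            file.path(out, "dna.xyz"), comment = "ideal B-DNA fixture")
  protein <- make_synthetic_protein(24, c(5, 20), seed = seed)
  write_xyz(protein$ca_coords, strsplit(protein$sequence, "")[[1]],
            file.path(out, "protein.xyz"), comment = "synthetic mini-protein")
  segs <- data.frame(mode = c("SLIDING", "SLIDING", "HOPPING", "DIFFUSION_3D"),
                     n_frames = c(10, 10, 10, 10))
  str_traj <- make_scripted_trajectory(dna, protein, segs, seed = seed)
  tl <- classify_timeline(str_traj)
  tl$label_true <- str_traj$labels_true
  write.csv(tl, file.path(out, "timeline.csv"), row.names = FALSE)
  write_manifest(out, seeds = seed)
  message("wrote ", out)
}
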