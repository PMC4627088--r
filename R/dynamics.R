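#' Simulation configuration
#'
#' @param n_steps number of integration steps.
#' @param dt time step (reduced time; default 0.01, chosen by a stability
#'   scan with the gamma = 0 drift criterion).
#' @param T temperature (K); kT enters in kcal/mol via kB.
#' @param gamma Langevin friction (1/reduced time), default 0.25.
#' @param seed integer seed; all randomness in a run flows from it.
#' @param output_stride frames/energies written every this many steps.
#' @param skin neighbour-list skin (A).
#' @param check_every displacement check interval (steps).
#' @param e_abort abort threshold on |potential energy| (divergence guard).
#' @param mts_r multiple-timestep split radius for electrostatics (A);
#'   0 disables the split (every pair evaluated every step). Pairs beyond
#'   `mts_r` have their (small, smooth) forces refreshed every
#'   `mts_every` steps instead of every step.
#' @param mts_every far-field refresh interval (steps).
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_steps, dt = 0.01, T = 300, gamma = 0.25,
                              seed = 1, output_stride = 100, skin = 3.0,
                              check_every = 10, e_abort = 1e9,
                              mts_r = 0, mts_every = 1) {
  stopifnot(dt > 0, n_steps >= 1, output_stride >= 1, mts_every >= 1)
  structure(list(n_steps = as.integer(n_steps), dt = dt, T = T, gamma = gamma,
                 seed = seed, output_stride = as.integer(output_stride),
                 skin = skin, check_every = as.integer(check_every),
                 e_abort = e_abort, mts_r = mts_r,
                 mts_every = as.integer(mts_every)), class = "sim_config")
}

#' Run Langevin dynamics
#'
#' BAOAB-splitting Langevin integration of a `cg_system`. The two
#' terminal DNA base-pair centers are held by stiff harmonic restraints
#' (if the system was built with `end_restraints = TRUE`); in rigid-DNA
#' systems the DNA beads are frozen and only the protein is integrated.
#' Trajectories are bitwise reproducible for a fixed seed.
#'
#' @param system a `cg_system`.
#' @param config a `sim_config`.
#' @param coords starting coordinates (default `system$coords`).
#' @param vel starting velocities (default: Maxwell-Boltzmann draw at T,
#'   or zero when T = 0).
#' @return object of class `cg_trajectory`: `frames` (n x 3 x n_frames
#'   array, unwrapped coordinates), `energies` (data.frame, one row per
#'   frame), `final_coords`, `final_vel`, `config`, `system`, counters
#'   `n_reject`, `n_rebuild`.
#' @export
run_langevin <- function(system, config, coords = NULL, vel = NULL) {
  if (is.null(coords)) coords <- system$coords
  kT <- .kB * config$T
  out <- cpp_run_langevin(system$cpp, coords, vel,
                          config$n_steps, config$dt, config$gamma, kT,
                          as.numeric(config$seed), config$output_stride,
                          config$skin, config$check_every, config$e_abort,
                          config$mts_r, config$mts_every)
  en <- as.data.frame(out$energies)
  en$step <- seq(0, config$n_steps, by = config$output_stride)[seq_len(nrow(en))]
  traj <- list(frames = out$frames, energies = en,
               final_coords = out$final_coords, final_vel = out$final_vel,
               config = config, system = system,
               n_reject = out$n_reject, n_rebuild = out$n_rebuild)
  class(traj) <- "cg_trajectory"
  traj
}

#' Number of frames / access one frame of a trajectory
#' @param traj `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' @param i frame index (1-based).
#' @rdname n_frames
#' @export
get_frame <- function(traj, i) traj$frames[, , i]

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d beads, %d frames, %d steps (dt=%g, seed=%s)\n",
              dim(x$frames)[1], n_frames(x), x$config$n_steps, x$config$dt,
              format(x$config$seed)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# protein placement
# ---------------------------------------------------------------------------

random_rotation <- function() {
  # uniform random rotation from a QR decomposition
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Place a protein at a given recognition-center position
#'
#' Rotates the native coordinates by `rot` and translates so the center
#' of the recognition region lands on `target`.
#'
#' @param protein `cgprotein`.
#' @param target length-3 position for the recognition-region center.
#' @param rot 3 x 3 rotation (default identity).
#' @return placed coordinate matrix.
#' @export
place_protein <- function(protein, target, rot = diag(3)) {
  rr <- protein$recognition_range
  pc <- protein$ca_coords %*% t(rot)
  ctr <- colMeans(pc[rr[1]:rr[2], , drop = FALSE])
  sweep(pc, 2, ctr - target)
}

#' Random search-start placement
#'
#' Random orientation and position with the recognition center at least
#' `min_dist` from every DNA bead (the "away from the DNA surface" start),
#' inside the box footprint of the DNA.
#'
#' @param dna `cgdna`.
#' @param protein `cgprotein`.
#' @param min_dist minimum distance to any DNA bead (A), default 30.
#' @param seed integer seed.
#' @param max_radial largest radial offset from the DNA axis tried (A).
#' @return placed coordinate matrix.
#' @export
random_protein_placement <- function(dna, protein, min_dist = 30, seed = 1,
                                     max_radial = 80) {
  set.seed(seed)
  zr <- range(dna$coords[, 3])
  for (try in 1:200) {
    rot <- random_rotation()
    rad <- runif(1, min_dist + 5, max_radial)
    ang <- runif(1, 0, 2 * pi)
    z <- runif(1, zr[1], zr[2])
    target <- c(rad * cos(ang), rad * sin(ang), z)
    pc <- place_protein(protein, target, rot)
    dmin <- min(proxy_cross_dist(pc, dna$coords))
    if (dmin >= min_dist) return(pc)
  }
  stop("could not place protein at the requested distance")
}

# minimum cross distance between two coordinate sets (no PBC; small sets)
proxy_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Kinetics-experiment start placement
#'
#' Recognition-region center placed radially `radial` from the DNA axis at
#' the axial position of `target_start_bp - offset_bp` (the "20 bp away
#' from the target site and 30 A away from the DNA surface" start).
#'
#' @param dna `cgdna`.
#' @param protein `cgprotein`.
#' @param target_start_bp 1-based bp index where the target begins.
#' @param offset_bp axial offset in bp (default 20).
#' @param radial radial distance from the DNA surface (A), default 30;
#'   the phosphate radius is added to convert to axis distance.
#' @param seed seed for the random azimuth/orientation.
#' @return placed coordinate matrix.
#' @export
kinetics_start_placement <- function(dna, protein, target_start_bp,
                                     offset_bp = 20, radial = 30, seed = 1) {
  set.seed(seed)
  bp <- max(1, target_start_bp - offset_bp)
  z <- (bp - 1) * dna$helix$rise
  ang <- runif(1, 0, 2 * pi)
  rad <- radial + dna$helix$p[["r"]]
  target <- c(rad * cos(ang), rad * sin(ang), z)
  place_protein(protein, target, random_rotation())
}
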