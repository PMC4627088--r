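# ---------------------------------------------------------------------------
# specific-complex formation kinetics
# ---------------------------------------------------------------------------

#' Reference bound pose of the protein on the DNA target
#'
#' Places the protein with its recognition-helix principal axis along the
#' local major-groove tangent and the recognition center on the
#' major-groove midline at the center of the target site. Serves as the
#' synthetic "co-crystal" geometry from which specific contacts are
#' extracted when no experimental complex is available.
#'
#' @param dna `cgdna` (target inserted).
#' @param protein `cgprotein`.
#' @param target_bp base pair at which to dock (e.g. target center).
#' @return placed protein coordinate matrix.
#' @export
make_bound_pose <- function(dna, protein, target_bp) {
  mid <- groove_midpoints(dna, which = "major")
  if (anyNA(mid[target_bp, ])) stop("no major-groove midline at target bp")
  tgt <- mid[target_bp, ]
  tangent <- groove_tangent(mid, target_bp)
  rr <- protein$recognition_range
  RR <- protein$ca_coords[rr[1]:rr[2], , drop = FALSE]
  sv <- svd(sweep(RR, 2, colMeans(RR)))
  hax <- sv$v[, 1]
  # rotation taking the helix axis onto the groove tangent
  v <- pracma_cross(hax, tangent)
  s <- sqrt(sum(v^2)); c0 <- sum(hax * tangent)
  R <- if (s < 1e-12) {
    if (c0 > 0) diag(3) else diag(c(-1, -1, 1))
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
  }
  place_protein(protein, tgt, R)
}

#' Specific contacts from a bound pose
#'
#' Every protein residue within `cutoff` of a DNA bead (any site) in the
#' bound pose becomes a specific contact at its pose distance.
#'
#' @param dna `cgdna`.
#' @param protein `cgprotein`.
#' @param pose_coords bound-pose protein coordinates
#'   ([make_bound_pose()]).
#' @param cutoff C-alpha-to-bead cutoff (A), default 10.
#' @param epsilon_sp well depth per pair (kcal/mol); default from the
#'   parameter file.
#' @return `specific_contacts` object with pairs (res, dna_bead, r0).
#' @export
make_specific_contacts <- function(dna, protein, pose_coords, cutoff = 10,
                                   epsilon_sp = NULL) {
  if (is.null(epsilon_sp)) epsilon_sp <- ff_params()$cross$specific_eps
  d <- proxy_cross_dist(pose_coords, dna$coords)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(res = hit[, 1], dna_bead = hit[, 2],
                      r0 = d[hit])
  if (nrow(pairs) == 0) warning("no specific contacts under cutoff")
  structure(list(pairs = pairs, epsilon_sp = epsilon_sp),
            class = "specific_contacts")
}

#' Gaussian non-specific interaction map
#'
#' One well depth per (recognition residue, non-target base bead) pair,
#' drawn from a Gaussian with mean `mean` (0.6) and standard deviation
#' `sd` (0.1); non-positive draws are redrawn (practically never at the
#' default moments). The map is frozen after setup.
#'
#' @param dna `cgdna`.
#' @param protein `cgprotein`.
#' @param target_range `c(first, last)` bp of the target site excluded
#'   from the map (NULL: no exclusion).
#' @param mean,sd Gaussian moments (kcal/mol).
#' @param seed integer seed.
#' @return data.frame (res, dna_bead, eps) with attribute `seed`.
#' @export
make_nonspecific_map <- function(dna, protein, target_range = NULL,
                                 mean = 0.6, sd = 0.1, seed = 1) {
  rr <- protein$recognition_range
  res <- rr[1]:rr[2]
  bpv <- dna$beads$bp
  base_idx <- which(dna$beads$site == "B")
  if (!is.null(target_range))
    base_idx <- base_idx[bpv[base_idx] < target_range[1] |
                         bpv[base_idx] > target_range[2]]
  grid <- expand.grid(res = res, dna_bead = base_idx)
  set.seed(seed)
  eps <- rnorm(nrow(grid), mean, sd)
  bad <- which(eps <= 0)
  while (length(bad) > 0) {
    eps[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(eps <= 0)
  }
  grid$eps <- eps
  attr(grid, "seed") <- seed
  grid
}

#' Q_sp / E_sp / R_pro-DNA time series of a trajectory
#'
#' @param traj `cg_trajectory` whose system carries specific contacts.
#' @param tolerance Q_sp distance tolerance.
#' @return data.frame: frame, Qsp, Esp, R_pro_dna.
#' @export
kinetics_timeseries <- function(traj, tolerance = 0.2) {
  sys <- traj$system
  sp <- sys$specific
  if (is.null(sp) || nrow(sp$pairs) == 0) stop("system has no specific contacts")
  nf <- n_frames(traj)
  i <- sys$protein_offset + sp$pairs$res
  j <- sp$pairs$dna_bead
  rr <- recognition_indices(sys)
  qsp <- numeric(nf); rpd <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- traj$frames[, , f]
    d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
    qsp[f] <- mean(d <= (1 + tolerance) * sp$pairs$r0)
    ctrR <- colMeans(X[rr, , drop = FALSE])
    ctr <- bp_centers(sys$dna, X[1:sys$n_dna, , drop = FALSE])
    rpd[f] <- min(sqrt(rowSums(minimum_image(sweep(ctr, 2, ctrR, "-"),
                                             sys$box)^2)))
  }
  data.frame(frame = seq_len(nf), Qsp = qsp,
             Esp = traj$energies$specific, R_pro_dna = rpd)
}

# first frame from which Qsp >= threshold holds for `sustain` frames
first_sustained <- function(q, threshold, sustain) {
  ok <- q >= threshold
  if (sustain <= 1) return(if (any(ok)) which(ok)[1] else NA_integer_)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  w <- which(r$values & r$lengths >= sustain)
  if (length(w) == 0) NA_integer_ else starts[w[1]]
}

#' Specific-binding kinetics ensemble
#'
#' Independent Langevin replicas of the search-and-bind experiment: the
#' protein starts `offset_bp` before the target and `radial` A off the DNA
#' surface; specific 12-6 wells act on the target site, Gaussian
#' non-specific wells on all other bases (fresh map per replica). A
#' replica is successful when Q_sp stays at or above `success_threshold`
#' for `sustain` consecutive output frames; the ensemble curve averages
#' Q_sp(t) over successful replicas only.
#'
#' @param dna `cgdna` with the target inserted.
#' @param protein `cgprotein`.
#' @param target_range `c(first, last)` bp of the target.
#' @param n_replicas number of replicas.
#' @param n_steps steps per replica.
#' @param seed base seed; replica r uses `seed + r`.
#' @param Cs salt (mM).
#' @param cage `cage_spec` or NULL.
#' @param rigid_dna freeze the DNA.
#' @param epsilon_sp specific well depth (kcal/mol).
#' @param nonspecific_on include the Gaussian non-specific map.
#' @param shared_map use one non-specific map for all replicas instead of
#'   per-replica draws.
#' @param offset_bp,radial start placement (default 20 bp, 30 A).
#' @param output_stride,dt,T,gamma passed to [simulation_config()].
#' @param success_threshold,sustain success rule (default 0.8 over 10
#'   frames).
#' @param start_coords optional explicit protein start coordinates
#'   (overrides the placement rule; e.g. the bound pose for quench tests).
#' @return object of class `kinetics_result`: per-replica series,
#'   `ensemble` (mean Q_sp(t) over successes), `success` logical vector,
#'   `first_passage_steps`, `success_fraction`.
#' @export
run_kinetics_ensemble <- function(dna, protein, target_range, n_replicas,
                                  n_steps, seed = 1, Cs = 20, cage = NULL,
                                  rigid_dna = FALSE, epsilon_sp = NULL,
                                  nonspecific_on = TRUE, shared_map = FALSE,
                                  offset_bp = 20, radial = 30,
                                  output_stride = 200, dt = 0.01, T = 300,
                                  gamma = 0.25, success_threshold = 0.8,
                                  sustain = 10, start_coords = NULL,
                                  params = ff_params()) {
  target_bp <- floor(mean(target_range))
  pose <- make_bound_pose(dna, protein, target_bp)
  sp <- make_specific_contacts(dna, protein, pose, epsilon_sp = epsilon_sp)
  shared <- if (shared_map && nonspecific_on)
    make_nonspecific_map(dna, protein, target_range, seed = seed) else NULL

  reps <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    rseed <- seed + r
    nsmap <- if (!nonspecific_on) NULL
             else if (shared_map) shared
             else make_nonspecific_map(dna, protein, target_range,
                                       mean = params$cross$nonspecific_mean,
                                       sd = params$cross$nonspecific_sd,
                                       seed = rseed)
    start <- if (!is.null(start_coords)) start_coords
             else kinetics_start_placement(dna, protein, target_range[1],
                                           offset_bp = offset_bp,
                                           radial = radial, seed = rseed)
    sys <- build_system(dna = dna, protein = protein, protein_coords = start,
                        params = params, Cs = Cs, cage = cage,
                        rigid_dna = rigid_dna, specific = sp,
                        nonspecific = nsmap)
    cfg <- simulation_config(n_steps = n_steps, dt = dt, T = T, gamma = gamma,
                             seed = rseed, output_stride = output_stride)
    traj <- run_langevin(sys, cfg)
    ts <- kinetics_timeseries(traj)
    fp <- first_sustained(ts$Qsp, success_threshold, sustain)
    reps[[r]] <- list(series = ts,
                      success = !is.na(fp),
                      first_passage_frame = fp,
                      first_passage_step = if (is.na(fp)) NA_real_
                                           else (fp - 1) * output_stride,
                      seed = rseed)
  }
  success <- vapply(reps, function(x) x$success, logical(1))
  qmat <- vapply(reps, function(x) x$series$Qsp,
                 numeric(nrow(reps[[1]]$series)))
  ensemble <- if (any(success)) {
    rowMeans(qmat[, success, drop = FALSE])
  } else NULL
  structure(list(
    replicas = reps, success = success,
    success_fraction = mean(success),
    first_passage_steps = vapply(reps, function(x) x$first_passage_step,
                                 numeric(1)),
    ensemble_Qsp = ensemble,
    steps = (seq_len(nrow(reps[[1]]$series)) - 1) * output_stride,
    specific_contacts = sp), class = "kinetics_result")
}

#' Median first-passage step over successful replicas
#'
#' @param kr `kinetics_result`.
#' @return median step count; `Inf` when no replica succeeded.
#' @export
kinetics_first_passage_median <- function(kr) {
  fp <- kr$first_passage_steps[kr$success]
  if (length(fp) == 0) return(Inf)
  stats::median(fp)
}
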