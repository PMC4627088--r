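# ---------------------------------------------------------------------------
# scripted fixtures: trajectories with known search-mode labels
# ---------------------------------------------------------------------------

# interpolated groove-midline position at fractional bp t (linear between bp)
midline_at <- function(mid, t) {
  n <- nrow(mid)
  t <- min(max(t, 1), n)
  i <- floor(t); f <- t - i
  if (i >= n) return(mid[n, ])
  (1 - f) * mid[i, ] + f * mid[i + 1, ]
}

#' Scripted protein-DNA trajectory with known mode labels
#'
#' Builds coordinate frames in which the protein is placed by
#' construction in a prescribed search mode: SLIDING frames thread the
#' recognition region along the major-groove midline (groove-tracking,
#' small Psi), HOPPING frames hold the recognition center ~24 A from the
#' closest base-pair center, DIFFUSION_3D frames ~40 A away. Used to test
#' the classifier end to end against ground truth.
#'
#' @param dna `cgdna` (rigid ideal geometry is used in every frame).
#' @param protein `cgprotein`.
#' @param segments data.frame with columns `mode` (label) and `n_frames`;
#'   sliding segments advance along the DNA.
#' @param start_bp starting base pair for the scripted path.
#' @param bp_per_frame sliding advance rate (bp/frame).
#' @param seed seed for the hopping/3D azimuth jitter.
#' @return `cg_trajectory`-compatible object with the true labels in
#'   `$labels_true`.
#' @export
make_scripted_trajectory <- function(dna, protein, segments,
                                     start_bp = NULL, bp_per_frame = 0.25,
                                     seed = 1) {
  set.seed(seed)
  sys <- build_system(dna = dna, protein = protein, end_restraints = FALSE)
  n <- sys$n; nd <- sys$n_dna
  rr <- protein$recognition_range
  rec <- rr[1]:rr[2]
  nrec <- length(rec)
  nf <- sum(segments$n_frames)
  frames <- array(NA_real_, c(n, 3, nf))
  labels <- character(nf)

  mid <- groove_midpoints(dna, which = "major")
  valid <- which(!is.na(mid[, 1]))
  if (is.null(start_bp)) start_bp <- valid[ceiling(length(valid) / 4)]
  # arc length of the midline per bp (for spacing beads ~1.5 A apart)
  seg_len <- sqrt(sum((mid[valid[2], ] - mid[valid[1], ])^2))
  dbp_bead <- 1.5 / seg_len

  bp_pos <- start_bp
  f <- 0
  for (s in seq_len(nrow(segments))) {
    mode <- segments$mode[s]
    for (k in seq_len(segments$n_frames[s])) {
      f <- f + 1
      labels[f] <- mode
      frames[1:nd, , f] <- dna$coords
      pc <- matrix(0, nrow(protein$ca_coords), 3)
      if (mode == "SLIDING") {
        bp_pos <- min(bp_pos + bp_per_frame, max(valid) - 3)
        for (b in seq_len(nrec)) {
          t <- bp_pos + (b - (nrec + 1) / 2) * dbp_bead
          pc[rec[b], ] <- midline_at(mid, t)
        }
        # non-recognition beads: parked radially outward, out of the way
        ctr <- colMeans(pc[rec, , drop = FALSE])
        outdir <- c(ctr[1], ctr[2], 0)
        outdir <- outdir / max(sqrt(sum(outdir^2)), 1e-9)
        others <- setdiff(seq_len(nrow(pc)), rec)
        for (o in seq_along(others))
          pc[others[o], ] <- ctr + outdir * (12 + 2 * o)
      } else {
        dist <- if (mode == "HOPPING") 24 else 40
        ang <- runif(1, 0, 2 * pi)
        zc <- (bp_pos - 1) * dna$helix$rise
        ctr <- c(dist * cos(ang), dist * sin(ang), zc)
        # native-shaped recognition helix centered at ctr
        base <- protein$ca_coords
        basec <- colMeans(base[rec, , drop = FALSE])
        pc <- sweep(base, 2, basec - ctr)
      }
      frames[nd + (1:nrow(pc)), , f] <- pc
    }
  }
  traj <- list(frames = frames,
               energies = data.frame(step = seq_len(nf) - 1),
               config = simulation_config(n_steps = nf, output_stride = 1),
               system = sys, labels_true = labels)
  class(traj) <- "cg_trajectory"
  traj
}

#' Minimal timeline from a label string
#'
#' For run-length/segmentation tests: builds a `ModeTimeline`-shaped
#' data.frame from a label vector with a synthetic Z/closest-bp path.
#'
#' @param labels vector of `"S"/"H"/"D"` (or full label names).
#' @param z optional Z series; default: advance 1 A per sliding frame.
#' @param closest_bp optional closest-bp series.
#' @return data.frame usable by the event/efficiency/D1 operations.
#' @export
labels_to_timeline <- function(labels, z = NULL, closest_bp = NULL) {
  full <- c(S = "SLIDING", H = "HOPPING", D = "DIFFUSION_3D")
  lab <- ifelse(labels %in% names(full), full[labels], labels)
  n <- length(lab)
  if (is.null(z)) z <- cumsum(ifelse(lab == "SLIDING", 1, 0))
  if (is.null(closest_bp)) closest_bp <- pmax(1L, 1L + as.integer(round(z / 3.38)))
  data.frame(frame = seq_len(n), label = unname(lab),
             d_closest = ifelse(lab == "DIFFUSION_3D", 40,
                                ifelse(lab == "HOPPING", 24, 10)),
             contact_fraction = ifelse(lab == "SLIDING", 1, 0),
             psi = ifelse(lab == "SLIDING", 5, 60),
             theta = (z / 3.38) * 36, z = z, closest_bp = closest_bp)
}

#' Synthetic 1D random walk timeline with known diffusion coefficient
#'
#' Gaussian steps with variance `2 D` per frame, all frames labeled
#' SLIDING (or a sliding/hopping mix), for validating [estimate_D1()].
#'
#' @param n_frames number of frames.
#' @param D true diffusion coefficient (A^2/frame).
#' @param seed integer seed.
#' @param mix_hopping fraction of frames relabeled HOPPING (labels only;
#'   the walk is unchanged).
#' @return `ModeTimeline`-shaped data.frame with attribute `D_true`.
#' @export
make_1d_walk_timeline <- function(n_frames, D, seed = 1, mix_hopping = 0) {
  set.seed(seed)
  z <- cumsum(c(0, rnorm(n_frames - 1, 0, sqrt(2 * D))))
  lab <- rep("SLIDING", n_frames)
  if (mix_hopping > 0) {
    nh <- floor(mix_hopping * n_frames)
    lab[sample(n_frames, nh)] <- "HOPPING"
  }
  tl <- data.frame(frame = seq_len(n_frames), label = lab,
                   d_closest = 10, contact_fraction = 1, psi = 5,
                   theta = 0, z = z,
                   closest_bp = pmax(1L, 100L + as.integer(round(z / 3.38))))
  attr(tl, "D_true") <- D
  tl
}
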