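# ---------------------------------------------------------------------------
# groove geometry
# ---------------------------------------------------------------------------

#' Major/minor groove widths from cross-strand phosphate distances
#'
#' Raw phosphate-phosphate distances at the calibrated groove registers:
#' `W_MN(i) = |P1(i) - P2(i + k_minor)|` and `W_MJ(i) = |P1(i) -
#' P2(i + k_major)|`. Base pairs whose register partner (or own phosphate)
#' does not exist are masked invalid.
#'
#' @param dna `cgdna`.
#' @param coords optional frame coordinates (defaults to build geometry).
#' @param registers optional `c(k_major, k_minor)` override.
#' @return data.frame: bp, W_MJ, W_MN, valid_major, valid_minor.
#' @export
compute_groove_widths <- function(dna, coords = NULL, registers = NULL) {
  if (is.null(coords)) coords <- dna$coords
  km <- if (is.null(registers)) dna$helix$k_major else registers[1]
  kn <- if (is.null(registers)) dna$helix$k_minor else registers[2]
  n <- dna$n_bp
  P1 <- dna$idx$P1; P2 <- dna$idx$P2
  width_at <- function(k) {
    vapply(seq_len(n), function(i) {
      j <- i + k
      if (is.na(P1[i]) || j < 1 || j > n || is.na(P2[j])) return(NA_real_)
      sqrt(sum((coords[P1[i], ] - coords[P2[j], ])^2))
    }, numeric(1))
  }
  wmj <- width_at(km); wmn <- width_at(kn)
  if (all(is.na(wmj)) && all(is.na(wmn)))
    stop("groove registers out of range for all base pairs")
  data.frame(bp = seq_len(n), W_MJ = wmj, W_MN = wmn,
             valid_major = !is.na(wmj), valid_minor = !is.na(wmn))
}

#' Groove midline points
#'
#' Midpoints of the register phosphate pairs defining each groove, per bp.
#'
#' @inheritParams compute_groove_widths
#' @param which `"major"` or `"minor"`.
#' @return n_bp x 3 matrix with NA rows where undefined.
#' @export
groove_midpoints <- function(dna, coords = NULL, which = "major") {
  if (is.null(coords)) coords <- dna$coords
  k <- if (which == "major") dna$helix$k_major else dna$helix$k_minor
  n <- dna$n_bp
  P1 <- dna$idx$P1; P2 <- dna$idx$P2
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    j <- i + k
    if (!is.na(P1[i]) && j >= 1 && j <= n && !is.na(P2[j]))
      out[i, ] <- 0.5 * (coords[P1[i], ] + coords[P2[j], ])
  }
  out
}

# local DNA axis from a +-half window line fit through bp centers
local_dna_axis <- function(ctr, bp, half = 5) {
  n <- nrow(ctr)
  w <- max(1, bp - half):min(n, bp + half)
  pts <- ctr[w, , drop = FALSE]
  mu <- colMeans(pts)
  sv <- svd(sweep(pts, 2, mu))
  u <- sv$v[, 1]
  if (u[3] < 0) u <- -u      # orient along +Z like the global axis
  list(a = mu, u = u)
}

# ---------------------------------------------------------------------------
# search-mode classification
# ---------------------------------------------------------------------------

#' Classifier thresholds
#'
#' The three search-mode rules: 3D when the recognition-region center is
#' more than `d_3d` (30 A) from the closest base-pair center; sliding when
#' it is within `d_slide` (18 A), at least `contact_min` (70%) of the
#' recognition region is in contact with the major groove, and the
#' orientation angle Psi is below `psi_max` (25 deg); hopping otherwise
#' within `d_3d`.
#'
#' @param d_3d,d_slide,contact_min,psi_max classification thresholds.
#' @param contact_dist bead-to-DNA contact distance (A).
#' @param minor_width width (A) below which an occupied groove counts as
#'   minor.
#' @return list of thresholds.
#' @export
classifier_thresholds <- function(d_3d = 30, d_slide = 18, contact_min = 0.7,
                                  psi_max = 25, contact_dist = 10,
                                  minor_width = 15) {
  list(d_3d = d_3d, d_slide = d_slide, contact_min = contact_min,
       psi_max = psi_max, contact_dist = contact_dist,
       minor_width = minor_width)
}

#' Label a frame from its features
#'
#' Pure decision rule on (d_closest, contact_fraction, Psi); total: every
#' feature combination receives exactly one label.
#'
#' @param d_closest distance recognition center to closest bp center (A).
#' @param contact_fraction fraction of recognition beads in major-groove
#'   contact.
#' @param psi orientation angle (degrees).
#' @param thresholds see [classifier_thresholds()].
#' @return one of `"SLIDING"`, `"HOPPING"`, `"DIFFUSION_3D"`.
#' @export
classify_features <- function(d_closest, contact_fraction, psi,
                              thresholds = classifier_thresholds()) {
  if (d_closest > thresholds$d_3d) return("DIFFUSION_3D")
  if (d_closest <= thresholds$d_slide &&
      contact_fraction >= thresholds$contact_min &&
      psi < thresholds$psi_max) return("SLIDING")
  "HOPPING"
}

#' Search features + label for one frame
#'
#' Computes all classifier inputs from coordinates: distance to the
#' closest base-pair center, recognition-region/major-groove contact
#' fraction, orientation angle Psi (recognition-helix principal axis vs
#' the local major-groove tangent), azimuth theta about the DNA axis and
#' axial coordinate Z.
#'
#' @param system combined `cg_system`.
#' @param coords frame coordinates.
#' @param thresholds see [classifier_thresholds()].
#' @param axis_mode `"global"` (cage/end-constraint axis) or `"local"`
#'   (+-5 bp line fit; used for unconfined dynamic DNA).
#' @param psi_mode construction of the orientation angle Psi:
#'   `"surface"` (default) is the angle between the recognition-helix
#'   principal axis and the local DNA surface plane (0 when the helix lies
#'   flat along the groove, 90 when it points radially away) -- this form
#'   is fold-agnostic and gives Psi ~ 0 both for groove-threading paths
#'   and for a straight helix seated in the groove; `"tangent"` is the
#'   angle between the helix axis and the major-groove midline tangent.
#'   Both give Psi ~ 0 for ideal groove tracking; the construction is kept
#'   behind this single switch.
#' @return list: label plus all features.
#' @export
classify_frame <- function(system, coords, thresholds = classifier_thresholds(),
                           axis_mode = c("global", "local"),
                           psi_mode = c("surface", "tangent")) {
  axis_mode <- match.arg(axis_mode)
  psi_mode <- match.arg(psi_mode)
  dna <- system$dna
  nd <- system$n_dna
  dc <- coords[1:nd, , drop = FALSE]
  rr <- recognition_indices(system)
  RR <- coords[rr, , drop = FALSE]
  ctrR <- colMeans(RR)
  ctr <- bp_centers(dna, dc)
  box <- system$box

  dvec <- minimum_image(sweep(ctr, 2, ctrR, "-"), box)
  dbp <- sqrt(rowSums(dvec^2))
  cb <- which.min(dbp)             # ties break to the lower index
  d_closest <- dbp[cb]

  mj <- groove_midpoints(dna, dc, "major")
  mn <- groove_midpoints(dna, dc, "minor")

  # contact fraction of the recognition region with the major groove
  sb_idx <- which(dna$beads$site %in% c("S", "B"))
  SB <- dc[sb_idx, , drop = FALSE]
  cf <- 0
  for (b in seq_len(nrow(RR))) {
    p <- RR[b, ]
    dsb <- sqrt(rowSums(minimum_image(sweep(SB, 2, p, "-"), box)^2))
    if (min(dsb) > thresholds$contact_dist) next
    dbpb <- sqrt(rowSums(minimum_image(sweep(ctr, 2, p, "-"), box)^2))
    k <- which.min(dbpb)
    dmj <- if (anyNA(mj[k, ])) Inf else
      sqrt(sum(minimum_image(p - mj[k, ], box)^2))
    dmn <- if (anyNA(mn[k, ])) Inf else
      sqrt(sum(minimum_image(p - mn[k, ], box)^2))
    if (dmj < dmn) cf <- cf + 1
  }
  cf <- cf / nrow(RR)

  # Psi: orientation of the recognition-helix principal axis
  sv <- svd(sweep(RR, 2, ctrR))
  hax <- sv$v[, 1]
  ax <- if (axis_mode == "local") local_dna_axis(ctr, cb) else system$axis
  if (psi_mode == "tangent") {
    tangent <- groove_tangent(mj, cb)
    psi <- if (is.null(tangent)) 90 else {
      cosv <- abs(sum(hax * tangent))
      acos(pmin(1, cosv)) * 180 / pi
    }
  } else {
    # angle to the local surface plane: 0 = lying flat along the DNA
    uu <- ax$u / sqrt(sum(ax$u^2))
    wrad <- (ctrR - ax$a) - sum((ctrR - ax$a) * uu) * uu
    nr <- sqrt(sum(wrad^2))
    psi <- if (nr < 1e-9) 90 else {
      sinv <- abs(sum(hax * (wrad / nr)))
      asin(pmin(1, sinv)) * 180 / pi
    }
  }
  u <- ax$u / sqrt(sum(ax$u^2))
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(u, e1)
  w <- ctrR - ax$a
  theta <- atan2(sum(w * e2), sum(w * e1)) * 180 / pi
  z <- sum((ctrR - system$axis$a) * system$axis$u)

  label <- classify_features(d_closest, cf, psi, thresholds)
  list(label = label, d_closest = d_closest, contact_fraction = cf,
       psi = psi, theta = theta, z = z, closest_bp = cb)
}

groove_tangent <- function(midpoints, bp) {
  n <- nrow(midpoints)
  lo <- bp - 1; hi <- bp + 1
  while (lo >= 1 && anyNA(midpoints[lo, ])) lo <- lo - 1
  while (hi <= n && anyNA(midpoints[hi, ])) hi <- hi + 1
  if (lo < 1 || hi > n) return(NULL)
  t <- midpoints[hi, ] - midpoints[lo, ]
  nt <- sqrt(sum(t^2))
  if (nt < 1e-9) return(NULL)
  t / nt
}

#' Classify every frame of a trajectory
#'
#' @param traj `cg_trajectory` of a protein-DNA system.
#' @param thresholds see [classifier_thresholds()].
#' @param axis_mode,psi_mode see [classify_frame()].
#' @param frames optional frame subset (indices).
#' @return `ModeTimeline` data.frame: frame, label, d_closest,
#'   contact_fraction, psi, theta (unwrapped, deg), z (A), closest_bp.
#' @export
classify_timeline <- function(traj, thresholds = classifier_thresholds(),
                              axis_mode = "global", psi_mode = "surface",
                              frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  rows <- lapply(frames, function(i)
    as.data.frame(classify_frame(traj$system, get_frame(traj, i),
                                 thresholds, axis_mode, psi_mode)))
  tl <- do.call(rbind, rows)
  tl$frame <- frames
  tl$theta <- unwrap_degrees(tl$theta)
  tl[, c("frame", "label", "d_closest", "contact_fraction", "psi",
         "theta", "z", "closest_bp")]
}

#' Unwrap an angle series (degrees): no jumps > 180 between frames
#' @param theta angle series in degrees.
#' @return unwrapped series.
#' @export
unwrap_degrees <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  d <- d - 360 * round(d / 360)
  theta[1] + c(0, cumsum(d))
}

#' Mode propensities
#'
#' @param timeline `ModeTimeline` data.frame (or label vector).
#' @return list: `fractions` (sliding, hopping, diffusion_3d; sums to 1)
#'   and `counts`.
#' @export
mode_propensities <- function(timeline) {
  lab <- if (is.data.frame(timeline)) timeline$label else timeline
  if (length(lab) == 0) stop("empty timeline")
  counts <- c(sliding = sum(lab == "SLIDING"),
              hopping = sum(lab == "HOPPING"),
              diffusion_3d = sum(lab == "DIFFUSION_3D"))
  list(fractions = counts / length(lab), counts = counts)
}

#' Groove occupied by the protein in one frame
#'
#' Assigns the recognition-region center to the geometrically nearest
#' groove midline at the closest base pair and labels the occupancy MINOR
#' if that groove's instantaneous width is below `minor_width` (15 A),
#' MAJOR otherwise.
#'
#' @param system combined `cg_system`.
#' @param coords frame coordinates.
#' @param thresholds see [classifier_thresholds()].
#' @return NULL when the protein is in 3D mode, else list(bp, groove
#'   (`"MAJOR"`/`"MINOR"`), width, which_midline).
#' @export
occupied_groove <- function(system, coords,
                            thresholds = classifier_thresholds()) {
  dna <- system$dna
  nd <- system$n_dna
  dc <- coords[1:nd, , drop = FALSE]
  rr <- recognition_indices(system)
  ctrR <- colMeans(coords[rr, , drop = FALSE])
  ctr <- bp_centers(dna, dc)
  dbp <- sqrt(rowSums(minimum_image(sweep(ctr, 2, ctrR, "-"), system$box)^2))
  cb <- which.min(dbp)
  if (dbp[cb] > thresholds$d_3d) return(NULL)
  mj <- groove_midpoints(dna, dc, "major")
  mn <- groove_midpoints(dna, dc, "minor")
  gw <- compute_groove_widths(dna, dc)
  dmj <- if (anyNA(mj[cb, ])) Inf else sqrt(sum((ctrR - mj[cb, ])^2))
  dmn <- if (anyNA(mn[cb, ])) Inf else sqrt(sum((ctrR - mn[cb, ])^2))
  if (!is.finite(dmj) && !is.finite(dmn)) return(NULL)
  which_mid <- if (dmj <= dmn) "major" else "minor"
  width <- if (which_mid == "major") gw$W_MJ[cb] else gw$W_MN[cb]
  groove <- if (!is.na(width) && width < thresholds$minor_width) "MINOR" else "MAJOR"
  list(bp = cb, groove = groove, width = width, which_midline = which_mid)
}

# ---------------------------------------------------------------------------
# sliding events, efficiency, diffusion, correlations
# ---------------------------------------------------------------------------

#' Segment maximal sliding events
#'
#' Maximal runs of SLIDING frames; each event carries its Z-axis
#' displacement `length_z = |Z_end - Z_start|` and the set of unique
#' closest base pairs visited.
#'
#' @param timeline `ModeTimeline` data.frame.
#' @return data.frame: start, end (frame indices), n_frames, length_z,
#'   n_bp_unique; attribute `bp_sets` holds the visited-bp sets.
#' @export
segment_sliding_events <- function(timeline) {
  lab <- timeline$label == "SLIDING"
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- data.frame(start = timeline$frame[starts[keep]],
                    end = timeline$frame[ends[keep]],
                    n_frames = r$lengths[keep])
  bp_sets <- list(); lz <- numeric(length(keep))
  for (q in seq_along(keep)) {
    rows <- starts[keep[q]]:ends[keep[q]]
    lz[q] <- abs(timeline$z[rows[length(rows)]] - timeline$z[rows[1]])
    bp_sets[[q]] <- sort(unique(timeline$closest_bp[rows]))
  }
  out$length_z <- lz
  out$n_bp_unique <- vapply(bp_sets, length, integer(1))
  attr(out, "bp_sets") <- bp_sets
  out
}

#' Cumulative sliding-event count vs event length
#'
#' @param events output of [segment_sliding_events()].
#' @param breaks histogram breaks on `length_z` (A).
#' @return data.frame: length upper edge, cumulative count.
#' @export
sliding_event_histogram <- function(events, breaks = seq(0, 50, by = 1)) {
  h <- graphics::hist(pmin(events$length_z, max(breaks)), breaks = breaks,
                      plot = FALSE)
  data.frame(length_z = h$breaks[-1], cumulative = cumsum(h$counts))
}

#' Search efficiency: base pairs scanned by sliding per association episode
#'
#' Association episodes are maximal stretches between 3D excursions. For
#' each episode, counts the unique closest base pairs visited during
#' SLIDING frames; returns the mean and per-episode values.
#'
#' @param timeline `ModeTimeline` data.frame.
#' @return list: `mean_bp_scanned`, `per_episode`, `n_episodes`.
#' @export
search_efficiency <- function(timeline) {
  on_dna <- timeline$label != "DIFFUSION_3D"
  r <- rle(on_dna)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  per <- vapply(keep, function(q) {
    rows <- starts[q]:ends[q]
    sl <- rows[timeline$label[rows] == "SLIDING"]
    length(unique(timeline$closest_bp[sl]))
  }, numeric(1))
  list(mean_bp_scanned = if (length(per)) mean(per) else 0,
       per_episode = per, n_episodes = length(per))
}

#' Rotation-translation coupling of sliding
#'
#' Pearson correlation between unwrapped theta and Z over the selected
#' frames, plus the fitted slope (A/deg) for comparison with the helical
#' pitch (3.38 x 10 / 360 A/deg for ideal rotation-coupled sliding).
#'
#' @param timeline `ModeTimeline` data.frame.
#' @param sliding_only restrict to SLIDING frames (default TRUE).
#' @return list: `correlation`, `slope` (A/deg), `n`; `correlation = NA`
#'   with a `reason` when either series has zero variance or fewer than 10
#'   frames are available.
#' @export
theta_z_correlation <- function(timeline, sliding_only = TRUE) {
  tl <- if (sliding_only) timeline[timeline$label == "SLIDING", ] else timeline
  if (nrow(tl) < 10)
    return(list(correlation = NA, slope = NA, n = nrow(tl),
                reason = "fewer than 10 frames"))
  if (var(tl$theta) < 1e-12 || var(tl$z) < 1e-12)
    return(list(correlation = NA, slope = NA, n = nrow(tl),
                reason = "zero variance"))
  fit <- lm(z ~ theta, data = tl)
  list(correlation = cor(tl$theta, tl$z), slope = unname(coef(fit)[2]),
       n = nrow(tl))
}

#' 1D diffusion coefficient from sliding + hopping MSD
#'
#' Mean square displacement of the unwrapped axial coordinate over time
#' lags within contiguous sliding/hopping stretches only (no bridging
#' across 3D excursions). Stretches shorter than `min_stretch` frames are
#' skipped; lags run from `lag_min` frames to 10% of each stretch length.
#' D1 is half the slope of the linear MSD fit.
#'
#' @param timeline `ModeTimeline` data.frame.
#' @param min_stretch minimum stretch length in frames (default 100).
#' @param lag_min smallest lag (frames, default 10).
#' @param lag_frac largest lag as a fraction of the stretch length.
#' @return list of class `diffusion_estimate`: `D1` (A^2/frame), `slope`,
#'   `r_squared`, `lags`, `msd`, `n_points`.
#' @export
estimate_D1 <- function(timeline, min_stretch = 100, lag_min = 10,
                        lag_frac = 0.1) {
  lab1d <- timeline$label %in% c("SLIDING", "HOPPING")
  if (sum(lab1d) < 100) stop("fewer than 100 sliding/hopping frames")
  r <- rle(lab1d)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_stretch)
  if (length(keep) == 0) stop("no sliding/hopping stretch >= min_stretch")
  max_lag <- max(floor(lag_frac * r$lengths[keep]))
  if (max_lag <= lag_min) stop("stretches too short for the fit window")
  lags <- lag_min:max_lag
  s2 <- numeric(length(lags)); cnt <- numeric(length(lags))
  for (q in keep) {
    z <- timeline$z[starts[q]:ends[q]]
    L <- length(z)
    top <- floor(lag_frac * L)
    for (li in seq_along(lags)) {
      tau <- lags[li]
      if (tau > top) next
      dz <- z[(1 + tau):L] - z[1:(L - tau)]
      s2[li] <- s2[li] + sum(dz^2)
      cnt[li] <- cnt[li] + length(dz)
    }
  }
  ok <- cnt > 0
  msd <- s2[ok] / cnt[ok]
  lg <- lags[ok]
  # MSD(0) = 0 by definition, so the line goes through the origin; the
  # variance of a single-trajectory MSD estimate grows steeply with the
  # lag, so weight the fit toward the shortest (most informative) lags.
  # Unweighted fits over the full window scatter by tens of percent on a
  # 1e5-frame walk; this estimator stays within a few percent.
  w <- cnt[ok] / lg^5
  fit <- lm(msd ~ lg + 0, weights = w)
  sl <- unname(coef(fit)[1])
  r2 <- summary(fit)$r.squared
  structure(list(D1 = max(0, sl / 2), slope = sl,
                 r_squared = if (is.nan(r2)) 1 else r2,
                 lags = lags[ok], msd = msd, n_points = sum(ok)),
            class = "diffusion_estimate")
}

#' Correlation between protein and DNA dynamics
#'
#' Pearson correlation of frame-to-frame displacement vectors of two
#' position series (componentwise displacements pooled), as used to
#' quantify the protein/DNA inter-communication.
#'
#' @param protein_series m x 3 positions of the recognition-region center.
#' @param dna_series m x 3 positions of the closest base-pair center.
#' @return list: `correlation` in `[-1, 1]`, `percentage`, `n`; NA with a
#'   reason on zero variance or fewer than 10 points.
#' @export
dynamics_correlation <- function(protein_series, dna_series) {
  stopifnot(nrow(protein_series) == nrow(dna_series))
  if (nrow(protein_series) < 10)
    return(list(correlation = NA, percentage = NA, n = nrow(protein_series),
                reason = "fewer than 10 points"))
  da <- diff(protein_series); db <- diff(dna_series)
  a <- as.vector(da); b <- as.vector(db)
  if (var(a) < 1e-15 || var(b) < 1e-15)
    return(list(correlation = NA, percentage = NA, n = nrow(protein_series),
                reason = "zero variance"))
  cc <- cor(a, b)
  list(correlation = cc, percentage = 100 * cc, n = nrow(protein_series))
}
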