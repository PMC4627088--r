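# ---------------------------------------------------------------------------
# cage specification
# ---------------------------------------------------------------------------

#' Cylindrical cage specification
#'
#' Confinement of DNA base-pair centers to radius R about the fixed axis
#' through the two constrained end base pairs. `R = 0` (or `"rigid"`) is
#' the rigid-DNA sentinel (ideal B-DNA geometry, frozen); `R = Inf` (or
#' `"inf"`) disables the caging potential.
#'
#' @param R radius in Angstrom, or `"rigid"` / `"inf"`.
#' @param K energy constant K_cage (default 100.0).
#' @param C length constant (default 4.0 A).
#' @param continuity_shift add +2K inside the active region so the energy
#'   is continuous at the Heaviside onset (forces identical either way).
#' @return object of class `cage_spec` with `mode` in
#'   `"active"/"rigid"/"off"`.
#' @export
cage_spec <- function(R, K = 100.0, C = 4.0, continuity_shift = FALSE) {
  mode <- if (identical(R, "rigid") || (is.numeric(R) && R == 0)) "rigid"
          else if (identical(R, "inf") || (is.numeric(R) && is.infinite(R))) "off"
          else "active"
  if (mode == "active") {
    R <- as.numeric(R)
    if (!is.finite(R) || R <= C / 2)
      stop("active cage requires finite R > C/2")
  } else R <- if (mode == "rigid") 0 else Inf
  structure(list(R = R, K = K, C = C, continuity_shift = continuity_shift,
                 mode = mode), class = "cage_spec")
}

#' Distance from a point to the cage axis
#'
#' Perpendicular distance from `p` to the line through `axis$a` with unit
#' direction `axis$u`.
#'
#' @param p point (length-3) or matrix of points (m x 3).
#' @param axis list with `a` (point on axis) and `u` (direction, need not
#'   be normalized).
#' @return distance(s) in Angstrom.
#' @export
axis_distance <- function(p, axis) {
  u <- axis$u / sqrt(sum(axis$u^2))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  w <- sweep(p, 2, axis$a)
  proj <- drop(w %*% u)
  perp <- w - outer(proj, u)
  sqrt(rowSums(perp^2))
}

#' Caging potential energy
#'
#' Literal implementation of the printed cylindrical wall potential
#' `V = sum_i K [x_i^4 - 2 x_i^2 - 1] H(C/2 - (R - d_i))` with
#' `x_i = C / (2 (R - d_i))`; `H(x) = 1` for `x > 0` and 0 otherwise.
#' RIGID and UNCONFINED sentinels contribute zero energy.
#'
#' @param bp_centers m x 3 matrix of base-pair centers.
#' @param cage a `cage_spec`.
#' @param axis axis list (`a`, `u`); defaults to the Z axis through the
#'   origin.
#' @return list: `energy`, per-bp `d` and `energy_i`, and per-bp radial
#'   force magnitude `f_radial` (positive = inward).
#' @export
cage_energy <- function(bp_centers, cage,
                        axis = list(a = c(0, 0, 0), u = c(0, 0, 1))) {
  if (is.null(dim(bp_centers))) bp_centers <- matrix(bp_centers, nrow = 1)
  m <- nrow(bp_centers)
  if (cage$mode != "active")
    return(list(energy = 0, d = axis_distance(bp_centers, axis),
                energy_i = numeric(m), f_radial = numeric(m)))
  d <- axis_distance(bp_centers, axis)
  if (any(d >= cage$R))
    stop("base-pair center at or beyond cage wall (d >= R)")
  g <- cage$R - d
  active <- (cage$C / 2 - g) > 0           # H(x) = 1 strictly for x > 0
  x <- cage$C / (2 * g)
  ei <- ifelse(active, cage$K * (x^4 - 2 * x^2 - 1), 0)
  if (cage$continuity_shift) ei <- ifelse(active, ei + 2 * cage$K, ei)
  fr <- ifelse(active, 4 * cage$K * x^2 * (x^2 - 1) / g, 0)
  list(energy = sum(ei), d = d, energy_i = ei, f_radial = fr)
}

# ---------------------------------------------------------------------------
# geometry helpers shared with the C++ kernels (same conventions)
# ---------------------------------------------------------------------------
geom_angle <- function(xi, xj, xk) {
  u <- xi - xj; v <- xk - xj
  c0 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, c0)))
}
geom_dihedral <- function(xi, xj, xk, xl) {
  b1 <- xj - xi; b2 <- xk - xj; b3 <- xl - xk
  m <- pracma_cross(b1, b2); nn <- pracma_cross(b2, b3)
  atan2(sum(pracma_cross(m, nn) * b2) / sqrt(sum(b2^2)), sum(m * nn))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---------------------------------------------------------------------------
# system assembly
# ---------------------------------------------------------------------------

# backbone chains as global bead indices (1-based), one vector per strand
dna_backbone_chains <- function(dna) {
  n <- dna$n_bp; ix <- dna$idx
  ch1 <- integer(0)
  for (i in seq_len(n)) {
    if (!is.na(ix$P1[i])) ch1 <- c(ch1, ix$P1[i])
    ch1 <- c(ch1, ix$S1[i])
  }
  # strand 2 runs 5'->3' from bp n down to bp 1: S2(n), P2(n-1), S2(n-1), ...
  ch2 <- ix$S2[n]
  if (n > 1) for (i in seq(n - 1, 1)) ch2 <- c(ch2, ix$P2[i], ix$S2[i])
  list(ch1 = ch1, ch2 = ch2)
}

consec <- function(v, k) {
  if (length(v) < k) return(matrix(integer(0), 0, k))
  m <- length(v) - k + 1
  out <- matrix(0L, m, k)
  for (c in seq_len(k)) out[, c] <- v[c:(c + m - 1)]
  out
}

#' Assemble a simulation system
#'
#' Combines a coarse-grained DNA duplex and (optionally) a protein into a
#' single topology ready for energy evaluation and Langevin dynamics: all
#' bonded terms take their equilibrium values from the build/native
#' geometry, non-bonded terms (stacking, Watson-Crick pairing, excluded
#' volume, solvent-induced cohesion, Debye-Huckel electrostatics) follow
#' the force-field parameter file.
#'
#' @param dna `cgdna` or NULL.
#' @param protein `cgprotein` or NULL.
#' @param protein_coords optional placed coordinates for the protein
#'   (defaults to its native coordinates).
#' @param params force field, [ff_params()].
#' @param Cs salt concentration (mM).
#' @param T temperature (K).
#' @param box periodic box lengths (A).
#' @param cage `cage_spec` or NULL (no cage).
#' @param rigid_dna freeze all DNA beads (implied by a `"rigid"` cage or
#'   `dna$rigid`).
#' @param end_restraints restrain the two terminal base-pair centers to
#'   their initial positions (the paper's constrained DNA ends).
#' @param specific optional specific-contact table: data.frame
#'   `(res, dna_bead, r0)` (see [make_specific_contacts()]).
#' @param nonspecific optional non-specific interaction map: data.frame
#'   `(res, dna_bead, eps)` (see [make_nonspecific_map()]).
#' @param elec_cross_scale multiplier on protein-DNA electrostatics (the
#'   single protein/DNA energy-scale calibration constant).
#' @return object of class `cg_system`.
#' @export
build_system <- function(dna = NULL, protein = NULL, protein_coords = NULL,
                         params = ff_params(), Cs = 20, T = 300,
                         box = c(220, 220, 820), cage = NULL,
                         rigid_dna = FALSE, end_restraints = TRUE,
                         specific = NULL, nonspecific = NULL,
                         elec_cross_scale = NULL) {
  if (is.null(dna) && is.null(protein)) stop("need at least one molecule")
  if (!is.null(cage) && cage$mode == "rigid") rigid_dna <- TRUE
  if (!is.null(dna) && isTRUE(dna$rigid)) rigid_dna <- TRUE
  if (is.null(elec_cross_scale)) elec_cross_scale <- params$cross$elec_scale

  nd <- if (is.null(dna)) 0L else nrow(dna$coords)
  np <- if (is.null(protein)) 0L else nrow(protein$ca_coords)
  n <- nd + np
  poff <- nd  # protein bead offset

  coords <- matrix(0, n, 3)
  charge <- numeric(n); sigma <- numeric(n)
  is_base <- integer(n); mol <- integer(n); frozen <- integer(n)

  bonds <- list(); angles <- list(); dihs <- list()
  p1210 <- list(); p126 <- list()

  if (!is.null(dna)) {
    coords[1:nd, ] <- dna$coords
    charge[1:nd] <- dna$charge
    sigma[1:nd] <- params$dna$ev_sigma
    is_base[1:nd] <- as.integer(dna$beads$site == "B")
    mol[1:nd] <- 0L
    if (rigid_dna) frozen[1:nd] <- 1L

    ch <- dna_backbone_chains(dna)
    kd <- params$dna
    for (chain in ch) {
      b <- consec(chain, 2)
      if (nrow(b)) bonds[[length(bonds) + 1]] <-
        data.frame(i = b[, 1], j = b[, 2], k2 = kd$bond_k2, k4 = kd$bond_k4,
                   comp = 0L)
      a <- consec(chain, 3)
      if (nrow(a)) angles[[length(angles) + 1]] <-
        data.frame(i = a[, 1], j = a[, 2], k = a[, 3], kk = kd$angle_k,
                   comp = 1L)
      d4 <- consec(chain, 4)
      if (nrow(d4)) dihs[[length(dihs) + 1]] <-
        data.frame(i = d4[, 1], j = d4[, 2], k = d4[, 3], l = d4[, 4],
                   k1 = kd$dihedral_k1, k3 = kd$dihedral_k3, comp = 2L)
    }
    ix <- dna$idx
    for (i in seq_len(dna$n_bp)) {
      for (s in 1:2) {
        S <- ix[[paste0("S", s)]][i]; B <- ix[[paste0("B", s)]][i]
        bonds[[length(bonds) + 1]] <-
          data.frame(i = S, j = B, k2 = kd$bond_k2, k4 = kd$bond_k4, comp = 0L)
        # branch angles B-S-P for each backbone phosphate attached to S
        chain <- if (s == 1) ch$ch1 else ch$ch2
        pos <- which(chain == S)
        for (nb in c(pos - 1, pos + 1)) {
          if (nb >= 1 && nb <= length(chain))
            angles[[length(angles) + 1]] <-
              data.frame(i = B, j = S, k = chain[nb], kk = kd$angle_k,
                         comp = 1L)
        }
      }
    }
    # stacking: consecutive base beads within each strand, plus
    # cross-stacking between diagonal cross-strand bases (pins the helical
    # register/twist, as in three-site DNA models with cross-stacking)
    seq1 <- strsplit(dna$sequence, "")[[1]]
    if (dna$n_bp > 1) {
      for (s in 1:2) {
        Bv <- ix[[paste0("B", s)]]
        st <- consec(Bv, 2)
        p1210[[length(p1210) + 1]] <-
          data.frame(i = st[, 1], j = st[, 2], eps = kd$stack_eps, comp = 3L)
      }
      ii <- seq_len(dna$n_bp - 1)
      p1210[[length(p1210) + 1]] <-
        data.frame(i = ix$B1[ii], j = ix$B2[ii + 1],
                   eps = kd$cross_stack_eps, comp = 3L)
      p1210[[length(p1210) + 1]] <-
        data.frame(i = ix$B1[ii + 1], j = ix$B2[ii],
                   eps = kd$cross_stack_eps, comp = 3L)
    }
    # Watson-Crick pairing
    epswc <- ifelse(seq1 %in% c("A", "T"), kd$pair_eps_AT, kd$pair_eps_GC)
    p1210[[length(p1210) + 1]] <-
      data.frame(i = ix$B1, j = ix$B2, eps = epswc, comp = 4L)
  }

  if (!is.null(protein)) {
    pc <- if (is.null(protein_coords)) protein$ca_coords else protein_coords
    stopifnot(nrow(pc) == np)
    coords[poff + (1:np), ] <- pc
    charge[poff + (1:np)] <- protein$charges
    sigma[poff + (1:np)] <- params$protein$ev_sigma
    mol[poff + (1:np)] <- 1L
    kp <- params$protein
    chain <- poff + (1:np)
    b <- consec(chain, 2)
    if (nrow(b)) bonds[[length(bonds) + 1]] <-
      data.frame(i = b[, 1], j = b[, 2], k2 = kp$bond_k2, k4 = kp$bond_k4,
                 comp = 10L)
    a <- consec(chain, 3)
    if (nrow(a)) angles[[length(angles) + 1]] <-
      data.frame(i = a[, 1], j = a[, 2], k = a[, 3], kk = kp$angle_k,
                 comp = 11L)
    d4 <- consec(chain, 4)
    if (nrow(d4)) dihs[[length(dihs) + 1]] <-
      data.frame(i = d4[, 1], j = d4[, 2], k = d4[, 3], l = d4[, 4],
                 k1 = kp$dihedral_k1, k3 = kp$dihedral_k3, comp = 12L)
    nc <- protein$native_contacts
    if (!is.null(nc) && nrow(nc) > 0) {
      p1210[[length(p1210) + 1]] <-
        data.frame(i = poff + nc$i, j = poff + nc$j, eps = kp$native_eps,
                   comp = 13L, r0_fixed = nc$r0)
    }
  }

  # specific / non-specific cross wells (12-6)
  if (!is.null(specific) && nrow(specific$pairs) > 0) {
    sp <- specific$pairs
    p126[[length(p126) + 1]] <-
      data.frame(i = poff + sp$res, j = sp$dna_bead, r0 = sp$r0,
                 eps = specific$epsilon_sp,
                 cut = params$cross$specific_cutoff_mult * sp$r0, comp = 15L)
  }
  if (!is.null(nonspecific) && nrow(nonspecific) > 0) {
    p126[[length(p126) + 1]] <-
      data.frame(i = poff + nonspecific$res, j = nonspecific$dna_bead,
                 r0 = params$cross$nonspecific_r0, eps = nonspecific$eps,
                 cut = params$cross$nonspecific_cutoff, comp = 16L)
  }

  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(), j = integer(), k2 = numeric(), k4 = numeric(),
               comp = integer())
  angles <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(), j = integer(), k = integer(), kk = numeric(),
               comp = integer())
  dihs <- if (length(dihs)) do.call(rbind, dihs) else
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               k1 = numeric(), k3 = numeric(), comp = integer())
  p1210 <- if (length(p1210)) {
    p1210 <- lapply(p1210, function(d) {
      if (!"r0_fixed" %in% names(d)) d$r0_fixed <- NA_real_
      d
    })
    do.call(rbind, p1210)
  } else NULL
  p126 <- if (length(p126)) do.call(rbind, p126) else NULL

  # equilibrium values from the build/native geometry
  bonds$r0 <- if (nrow(bonds)) sqrt(rowSums((coords[bonds$i, , drop = FALSE] -
                                             coords[bonds$j, , drop = FALSE])^2)) else numeric(0)
  angles$t0 <- if (nrow(angles)) vapply(seq_len(nrow(angles)), function(r)
    geom_angle(coords[angles$i[r], ], coords[angles$j[r], ],
               coords[angles$k[r], ]), numeric(1)) else numeric(0)
  dihs$phi0 <- if (nrow(dihs)) vapply(seq_len(nrow(dihs)), function(r)
    geom_dihedral(coords[dihs$i[r], ], coords[dihs$j[r], ],
                  coords[dihs$k[r], ], coords[dihs$l[r], ]), numeric(1)) else numeric(0)
  if (!is.null(p1210)) {
    r0 <- sqrt(rowSums((coords[p1210$i, , drop = FALSE] -
                        coords[p1210$j, , drop = FALSE])^2))
    if ("r0_fixed" %in% names(p1210))
      r0 <- ifelse(is.na(p1210$r0_fixed), r0, p1210$r0_fixed)
    p1210$r0 <- r0
  }

  # exclusions from the bond graph (1-2 and 1-3) + fixed attractive pairs
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  key <- function(i, j) {
    i0 <- pmin(i, j) - 1; j0 <- pmax(i, j) - 1
    i0 * n + j0
  }
  topo <- numeric(0)
  if (nrow(bonds)) topo <- c(topo, key(bonds$i, bonds$j))
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      topo <- c(topo, key(cmb[1, ], cmb[2, ]))
    }
  }
  topo <- unique(topo)
  # 12-10 wells (stacking/pairing/native) carry their own cores and are
  # excluded from excluded volume; the soft 12-6 wells (specific,
  # non-specific) have flat cores, so their pairs KEEP the WCA sterics
  attr_keys <- numeric(0)
  if (!is.null(p1210)) attr_keys <- c(attr_keys, key(p1210$i, p1210$j))
  excl_elec <- topo
  excl_solv <- unique(c(topo, if (!is.null(p1210)) key(p1210$i, p1210$j)))
  excl_ev <- unique(c(topo, attr_keys))

  # electrostatics
  ep <- electrostatics_params(Cs, T = T, params = params)

  # cage + axis through the end base-pair centers
  cage_list <- list(on = FALSE)
  ctr <- if (!is.null(dna)) bp_centers(dna) else NULL
  axis <- NULL
  if (!is.null(dna) && dna$n_bp > 1) {
    e <- dna$end_constraint_bps
    a1 <- ctr[e[1], ]; a2 <- ctr[e[2], ]
    if (sqrt(sum((a2 - a1)^2)) < 1e-9) stop("degenerate DNA axis")
    axis <- list(a = a1, u = (a2 - a1) / sqrt(sum((a2 - a1)^2)))
  }
  if (!is.null(cage) && cage$mode == "active") {
    if (is.null(axis)) stop("active cage requires a duplex of >= 2 bp")
    cage_list <- list(on = TRUE, R = cage$R, K = cage$K, C = cage$C,
                      continuity_shift = cage$continuity_shift,
                      axis_a = axis$a, axis_u = axis$u,
                      pairs = cbind(dna$idx$B1, dna$idx$B2) - 1L)
  }

  # end restraints on terminal bp centers
  res <- list(i = integer(0), j = integer(0), p = numeric(0), k = numeric(0))
  if (!is.null(dna) && dna$n_bp > 1 && end_restraints && !rigid_dna) {
    ke <- if (!is.null(params$dna$end_restraint_k)) params$dna$end_restraint_k else 20
    for (e in dna$end_constraint_bps) {
      res$i <- c(res$i, dna$idx$B1[e] - 1L)
      res$j <- c(res$j, dna$idx$B2[e] - 1L)
      res$p <- c(res$p, ctr[e, ])
      res$k <- c(res$k, ke)
    }
  }

  cpp <- list(
    n = n, box = box, frozen = frozen, charge = charge, ev_sigma = sigma,
    ev_eps = params$ev_eps, is_base = is_base, mol = mol,
    bonds = cbind(bonds$i, bonds$j) - 1L, bond_r0 = bonds$r0,
    bond_k2 = bonds$k2, bond_k4 = bonds$k4, bond_comp = as.integer(bonds$comp),
    angles = cbind(angles$i, angles$j, angles$k) - 1L, angle_t0 = angles$t0,
    angle_k = angles$kk, angle_comp = as.integer(angles$comp),
    dihedrals = cbind(dihs$i, dihs$j, dihs$k, dihs$l) - 1L,
    dih_phi0 = dihs$phi0, dih_k1 = dihs$k1, dih_k3 = dihs$k3,
    dih_comp = as.integer(dihs$comp),
    pairs1210 = if (is.null(p1210)) matrix(0L, 0, 2) else
      cbind(p1210$i, p1210$j) - 1L,
    p1210_r0 = if (is.null(p1210)) numeric(0) else p1210$r0,
    p1210_eps = if (is.null(p1210)) numeric(0) else p1210$eps,
    p1210_comp = if (is.null(p1210)) integer(0) else as.integer(p1210$comp),
    pairs126 = if (is.null(p126)) matrix(0L, 0, 2) else
      cbind(p126$i, p126$j) - 1L,
    p126_r0 = if (is.null(p126)) numeric(0) else p126$r0,
    p126_eps = if (is.null(p126)) numeric(0) else p126$eps,
    p126_cut = if (is.null(p126)) numeric(0) else p126$cut,
    p126_comp = if (is.null(p126)) integer(0) else as.integer(p126$comp),
    excl_ev = excl_ev, excl_elec = excl_elec, excl_solv = excl_solv,
    elec = list(lambda = ep$lambda, kpref = ep$kpref,
                cross_scale = elec_cross_scale, cutoff = ep$cutoff),
    solvent = list(on = isTRUE(params$dna$solvent_on) && !is.null(dna),
                   eps = params$dna$solvent_eps, r0 = params$dna$solvent_r0,
                   alpha = params$dna$solvent_alpha,
                   cutoff = params$dna$solvent_cutoff),
    cage = cage_list,
    restraints = res
  )

  sys <- list(cpp = cpp, coords = coords, dna = dna, protein = protein,
              n = n, n_dna = nd, protein_offset = poff, params = params,
              Cs = Cs, T = T, box = box, cage = cage, axis = axis,
              rigid_dna = rigid_dna, specific = specific,
              nonspecific = nonspecific, elec = ep)
  class(sys) <- "cg_system"
  sys
}

#' Protein bead indices (global, within a system)
#' @param system a `cg_system` containing a protein.
#' @return integer vector.
#' @export
protein_indices <- function(system) {
  if (is.null(system$protein)) stop("system has no protein")
  system$protein_offset + seq_len(nrow(system$protein$ca_coords))
}

#' Recognition-region bead indices (global)
#' @rdname protein_indices
#' @export
recognition_indices <- function(system) {
  rr <- system$protein$recognition_range
  system$protein_offset + (rr[1]:rr[2])
}
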