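#' Total energy and force breakdown of a system
#'
#' Evaluates every force-field term at the given coordinates. The
#' excluded-volume component `excluded_volume` (E_ev) is the intra-DNA
#' plus protein-DNA steric energy and never includes the cage term;
#' intra-protein non-native repulsion is booked separately under
#' `protein_nonnative`.
#'
#' @param system a `cg_system`.
#' @param coords coordinates (defaults to `system$coords`).
#' @return object of class `energy_breakdown`: named `components`,
#'   `total`, `forces` (n x 3), and the E_ev convenience field `E_ev`.
#' @export
total_energy <- function(system, coords = NULL) {
  if (is.null(coords)) coords <- system$coords
  out <- cpp_energy_forces(system$cpp, coords)
  structure(list(components = out$components, total = out$total,
                 E_ev = unname(out$components["excluded_volume"]),
                 forces = out$forces), class = "energy_breakdown")
}

#' DNA bonded energy (bond + bend + torsion)
#'
#' @param dna `cgdna` or a prebuilt `cg_system`.
#' @param coords optional coordinates.
#' @param ... passed to [build_system()] when `dna` is a `cgdna`.
#' @return list: `bond`, `angle`, `dihedral`, `total`, `forces`.
#' @export
dna_bonded_energy <- function(dna, coords = NULL, ...) {
  sys <- if (inherits(dna, "cg_system")) dna else build_system(dna = dna, ...)
  e <- total_energy(sys, coords)
  cc <- e$components
  list(bond = unname(cc["dna_bond"]), angle = unname(cc["dna_angle"]),
       dihedral = unname(cc["dna_dihedral"]),
       total = unname(cc["dna_bond"] + cc["dna_angle"] + cc["dna_dihedral"]),
       forces = e$forces)
}

#' DNA non-bonded energy (stacking, pairing, excluded volume, solvent,
#' electrostatics)
#'
#' @inheritParams dna_bonded_energy
#' @return list of components plus `forces`.
#' @export
dna_nonbonded_energy <- function(dna, coords = NULL, ...) {
  sys <- if (inherits(dna, "cg_system")) dna else build_system(dna = dna, ...)
  e <- total_energy(sys, coords)
  cc <- e$components
  list(stacking = unname(cc["stacking"]), pairing = unname(cc["pairing"]),
       excluded_volume = unname(cc["excluded_volume"]),
       solvent = unname(cc["solvent"]),
       electrostatic = unname(cc["electrostatic"]),
       total = unname(cc["stacking"] + cc["pairing"] + cc["excluded_volume"] +
                      cc["solvent"] + cc["electrostatic"]),
       forces = e$forces)
}

#' Per-base-pair Watson-Crick pairing energy
#'
#' @param system a `cg_system` with DNA.
#' @param coords optional coordinates.
#' @return numeric vector, one 12-10 well energy per base pair.
#' @export
pairing_energy_per_bp <- function(system, coords = NULL) {
  if (is.null(coords)) coords <- system$coords
  dna <- system$dna
  eps <- ifelse(strsplit(dna$sequence, "")[[1]] %in% c("A", "T"),
                system$params$dna$pair_eps_AT, system$params$dna$pair_eps_GC)
  i <- dna$idx$B1; j <- dna$idx$B2
  r <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  r0 <- sqrt(rowSums((dna$coords[i, , drop = FALSE] -
                      dna$coords[j, , drop = FALSE])^2))
  q <- r0 / pmax(r, 0.4 * r0)
  eps * (5 * q^12 - 6 * q^10)
}

#' Protein (Go-model) energy
#'
#' Bonds, angles, dihedrals, 12-10 native-contact attraction, non-native
#' repulsion and intra-protein Debye-Huckel among charged residues.
#'
#' @param protein `cgprotein` or a prebuilt protein-only `cg_system`.
#' @param coords optional coordinates.
#' @param ... passed to [build_system()].
#' @return list of components, `total`, `forces`, and the native-contact
#'   fraction `Q`.
#' @export
protein_energy <- function(protein, coords = NULL, ...) {
  sys <- if (inherits(protein, "cg_system")) protein
         else build_system(protein = protein, ...)
  e <- total_energy(sys, coords)
  cc <- e$components
  if (is.null(coords)) coords <- sys$coords
  q <- native_contact_fraction(sys$protein,
                               coords[protein_indices(sys), , drop = FALSE])
  list(bond = unname(cc["protein_bond"]), angle = unname(cc["protein_angle"]),
       dihedral = unname(cc["protein_dihedral"]),
       native = unname(cc["protein_native"]),
       nonnative = unname(cc["protein_nonnative"]),
       electrostatic = unname(cc["electrostatic"]),
       total = unname(sum(cc[c("protein_bond", "protein_angle",
                               "protein_dihedral", "protein_native",
                               "protein_nonnative", "electrostatic")])),
       Q = q, forces = e$forces)
}

#' Protein-DNA non-specific interaction energy
#'
#' Cross-molecule Debye-Huckel (charged residues x phosphates) plus
#' cross-molecule excluded volume, isolated by subtracting the energies of
#' each molecule alone from the combined system.
#'
#' @param system combined `cg_system` (protein + DNA).
#' @param coords optional coordinates.
#' @return list: `electrostatic`, `excluded_volume`, `total`.
#' @export
protein_dna_nonspecific_energy <- function(system, coords = NULL) {
  stopifnot(!is.null(system$dna), !is.null(system$protein))
  if (is.null(coords)) coords <- system$coords
  both <- total_energy(system, coords)
  nd <- system$n_dna
  sys_d <- build_system(dna = system$dna, params = system$params,
                        Cs = system$Cs, T = system$T, box = system$box,
                        end_restraints = FALSE)
  sys_p <- build_system(protein = system$protein,
                        protein_coords = coords[-(1:nd), , drop = FALSE],
                        params = system$params, Cs = system$Cs, T = system$T,
                        box = system$box)
  e_d <- total_energy(sys_d, coords[1:nd, , drop = FALSE])
  e_p <- total_energy(sys_p)
  el <- both$components["electrostatic"] - e_d$components["electrostatic"] -
    e_p$components["electrostatic"]
  ev <- both$components["excluded_volume"] - e_d$components["excluded_volume"]
  list(electrostatic = unname(el), excluded_volume = unname(ev),
       total = unname(el + ev))
}

#' Fraction of native contacts Q
#'
#' Fraction of native pairs whose current distance is at most
#' `(1 + tolerance) * r0`.
#'
#' @param protein `cgprotein` with `native_contacts`.
#' @param coords current C-alpha coordinates (defaults to native).
#' @param tolerance relative distance tolerance (default from the
#'   parameter file, 0.2).
#' @return Q in `[0, 1]`.
#' @export
native_contact_fraction <- function(protein, coords = NULL, tolerance = NULL) {
  nc <- protein$native_contacts
  if (is.null(nc) || nrow(nc) == 0) stop("empty native contact list")
  if (is.null(coords)) coords <- protein$ca_coords
  if (is.null(tolerance)) tolerance <- ff_params()$protein$native_q_tolerance
  d <- sqrt(rowSums((coords[nc$i, , drop = FALSE] -
                     coords[nc$j, , drop = FALSE])^2))
  mean(d <= (1 + tolerance) * nc$r0)
}

#' Fraction of specific protein-DNA contacts Q_sp
#'
#' @param system `cg_system` carrying a `specific` contact table.
#' @param coords current coordinates.
#' @param tolerance relative distance tolerance (default 0.2).
#' @return Q_sp in `[0, 1]`.
#' @export
compute_Qsp <- function(system, coords = NULL, tolerance = 0.2) {
  sp <- system$specific
  if (is.null(sp) || nrow(sp$pairs) == 0) stop("empty specific contact set")
  if (is.null(coords)) coords <- system$coords
  i <- system$protein_offset + sp$pairs$res
  j <- sp$pairs$dna_bead
  d <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  mean(d <= (1 + tolerance) * sp$pairs$r0)
}

#' Specific protein-DNA binding energy E_sp
#'
#' Sum of the attractive 12-6 wells over the specific contact set.
#'
#' @param system `cg_system` with specific contacts.
#' @param coords optional coordinates.
#' @return energy (kcal/mol).
#' @export
specific_energy <- function(system, coords = NULL) {
  e <- total_energy(system, coords)
  unname(e$components["specific"])
}

#' Sequence non-specific protein-DNA energy
#'
#' Short-ranged 12-6 wells between recognition-region residues and
#' non-target base beads with per-pair Gaussian-drawn depths.
#'
#' @param system `cg_system` with a `nonspecific` map.
#' @param coords optional coordinates.
#' @return energy (kcal/mol).
#' @export
nonspecific_sequence_energy <- function(system, coords = NULL) {
  e <- total_energy(system, coords)
  unname(e$components["nonspecific"])
}

#' Minimum-image displacement
#'
#' Componentwise wrap of a displacement vector into `[-L/2, L/2)`.
#'
#' @param dr displacement vector or matrix (rows = vectors).
#' @param box box lengths.
#' @return wrapped displacement, same shape.
#' @export
minimum_image <- function(dr, box) {
  if (is.null(dim(dr))) return(dr - box * floor(dr / box + 0.5))
  sweep_box <- matrix(box, nrow(dr), 3, byrow = TRUE)
  dr - sweep_box * floor(dr / sweep_box + 0.5)
}
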