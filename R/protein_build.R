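RESIDUE_CHARGE <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1)
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")
AA1TO3 <- setNames(names(AA3TO1), AA3TO1)
DNA_RESNAMES <- c("DA", "DC", "DG", "DT", "A", "C", "G", "T", "U",
                  "ADE", "CYT", "GUA", "THY")

#' Parse PDB-format text into an atom table
#'
#' Minimal fixed-width reader for ATOM/HETATM records: first MODEL only,
#' first alternate location kept (blank or the first letter encountered
#' per atom name/residue, with a warning if alternates were dropped).
#'
#' @param pdb_text character scalar or vector of lines.
#' @return data.frame: name, altloc, resname, chain, resseq, icode, x, y,
#'   z, element.
#' @export
parse_pdb <- function(pdb_text) {
  lines <- if (length(pdb_text) == 1 && grepl("\n", pdb_text))
    strsplit(pdb_text, "\n")[[1]] else pdb_text
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  atom <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[atom]
  if (length(lines) == 0) stop("no ATOM records found")
  fld <- function(a, b) trimws(substr(lines, a, b))
  df <- data.frame(
    name = fld(13, 16), altloc = fld(17, 17), resname = fld(18, 20),
    chain = fld(22, 22), resseq = as.integer(fld(23, 26)), icode = fld(27, 27),
    x = as.numeric(fld(31, 38)), y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)), element = fld(77, 78),
    stringsAsFactors = FALSE)
  # first altloc per (chain, resseq, icode, name)
  if (any(df$altloc != "")) {
    key <- paste(df$chain, df$resseq, df$icode, df$name)
    keep <- !duplicated(key)
    if (sum(!keep) > 0)
      warning(sprintf("dropped %d alternate-location atoms (kept first)",
                      sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (any(df$icode != ""))
    warning("insertion codes present; residues ordered by file position")
  df$element <- ifelse(df$element == "", substr(df$name, 1, 1), df$element)
  df
}

#' Coarse-grain a protein PDB to C-alpha beads
#'
#' One bead per residue at the C-alpha position; charges +1 for Arg/Lys,
#' -1 for Asp/Glu, 0 otherwise (His neutral).
#'
#' @param pdb_text PDB text (string or lines) or a parsed atom table from
#'   [parse_pdb()].
#' @param recognition_range integer vector `c(first, last)` of residue
#'   *positions* (1-based along the chain) forming the recognition region.
#' @param chain chain identifier; default: the first protein chain.
#' @return object of class `cgprotein`: `sequence`, `ca_coords` (n x 3),
#'   `charges`, `recognition_range`, `native_contacts` (may be NULL),
#'   `resseq` (original numbering).
#' @export
load_protein_calpha <- function(pdb_text, recognition_range, chain = NULL) {
  atoms <- if (is.data.frame(pdb_text)) pdb_text else parse_pdb(pdb_text)
  prot <- atoms[atoms$resname %in% names(AA3TO1), , drop = FALSE]
  if (nrow(prot) == 0) stop("no protein residues in structure")
  if (is.null(chain)) chain <- prot$chain[1]
  prot <- prot[prot$chain == chain, , drop = FALSE]
  if (nrow(prot) == 0) stop(sprintf("no residues in chain '%s'", chain))
  reskey <- paste(prot$resseq, prot$icode)
  resorder <- unique(reskey)
  n <- length(resorder)
  ca <- matrix(NA_real_, n, 3)
  seq1 <- character(n); resseq <- integer(n)
  for (i in seq_len(n)) {
    rows <- prot[reskey == resorder[i], , drop = FALSE]
    cai <- which(rows$name == "CA")
    if (length(cai) == 0)
      stop(sprintf("residue %s %s (chain %s) lacks a CA atom",
                   rows$resname[1], rows$resseq[1], chain))
    ca[i, ] <- as.numeric(rows[cai[1], c("x", "y", "z")])
    seq1[i] <- AA3TO1[[rows$resname[1]]]
    resseq[i] <- rows$resseq[1]
  }
  charges <- vapply(seq1, function(a) {
    r3 <- AA1TO3[[a]]
    if (r3 %in% names(RESIDUE_CHARGE)) RESIDUE_CHARGE[[r3]] else 0
  }, numeric(1))
  rr <- as.integer(recognition_range)
  if (length(rr) != 2 || rr[1] < 1 || rr[2] > n || rr[1] > rr[2])
    stop("recognition_range outside chain")
  p <- list(sequence = paste(seq1, collapse = ""), ca_coords = ca,
            charges = unname(charges), recognition_range = rr,
            native_contacts = NULL, resseq = resseq)
  class(p) <- "cgprotein"
  p
}

#' Extract native contacts from an all-atom structure
#'
#' Standard Go-model construction: residues i, j are in native contact if
#' any pair of heavy atoms is within `cutoff` and `|i - j| >=
#' min_separation`. The contact distance r0 is the native C-alpha
#' distance.
#'
#' @param atomic_structure parsed atom table ([parse_pdb()]) of one chain,
#'   or PDB text.
#' @param cutoff heavy-atom distance cutoff (A), default 4.5.
#' @param min_separation minimum sequence separation, default 3.
#' @return data.frame (i, j, r0) with i < j; empty (with a warning) if the
#'   structure has no residues in contact.
#' @export
extract_native_contacts <- function(atomic_structure, cutoff = 4.5,
                                    min_separation = 3) {
  atoms <- if (is.data.frame(atomic_structure)) atomic_structure
           else parse_pdb(atomic_structure)
  atoms <- atoms[atoms$resname %in% names(AA3TO1), , drop = FALSE]
  empty <- data.frame(i = integer(), j = integer(), r0 = numeric())
  if (nrow(atoms) == 0) { warning("empty structure"); return(empty) }
  heavy <- atoms[!grepl("^H", atoms$element), , drop = FALSE]
  reskey <- paste(heavy$chain, heavy$resseq, heavy$icode)
  resorder <- unique(reskey)
  n <- length(resorder)
  xyz <- lapply(resorder, function(k)
    as.matrix(heavy[reskey == k, c("x", "y", "z"), drop = FALSE]))
  ca <- t(vapply(resorder, function(k) {
    rows <- heavy[reskey == k, , drop = FALSE]
    w <- which(rows$name == "CA")
    if (length(w) == 0) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(rows[w[1], c("x", "y", "z")])
  }, numeric(3)))
  out <- list()
  for (i in seq_len(max(n - min_separation, 0))) {
    for (j in (i + min_separation):n) {
      d2 <- outer(rowSums(xyz[[i]]^2), rowSums(xyz[[j]]^2), "+") -
        2 * xyz[[i]] %*% t(xyz[[j]])
      if (min(d2) <= cutoff^2) {
        if (anyNA(ca[i, ]) || anyNA(ca[j, ]))
          stop(sprintf("residue %d or %d lacks a CA atom", i, j))
        out[[length(out) + 1]] <-
          data.frame(i = i, j = j, r0 = sqrt(sum((ca[i, ] - ca[j, ])^2)))
      }
    }
  }
  if (length(out) == 0) { warning("no native contacts found"); return(empty) }
  do.call(rbind, out)
}

# map DNA residue atoms to coarse-grained site groups
dna_atom_site <- function(name) {
  if (name %in% c("P", "OP1", "OP2", "O1P", "O2P")) return("P")
  if (grepl("'$|\\*$", name)) return("S")
  "B"
}

#' Extract specific protein-DNA contacts from a co-crystal structure
#'
#' DNA residues are coarse-grained on the fly (phosphate-group atoms ->
#' P, primed sugar atoms -> S, remaining base atoms -> B; bead = group
#' centroid). Every protein C-alpha within `cutoff` of a DNA bead center
#' becomes a specific contact at its native distance.
#'
#' @param complex_structure parsed atom table or PDB text containing both
#'   molecules.
#' @param cutoff C-alpha-to-bead cutoff (A), default 10.
#' @param epsilon_sp well depth assigned to each pair (kcal/mol).
#' @return object of class `specific_contacts`: data.frame (res, chain,
#'   resseq, site, bead_label, r0) plus `epsilon_sp`; empty with a warning
#'   if no cross-contacts exist under the cutoff.
#' @export
extract_specific_contacts <- function(complex_structure, cutoff = 10,
                                      epsilon_sp = 2.0) {
  atoms <- if (is.data.frame(complex_structure)) complex_structure
           else parse_pdb(complex_structure)
  prot <- atoms[atoms$resname %in% names(AA3TO1), , drop = FALSE]
  dna <- atoms[atoms$resname %in% DNA_RESNAMES, , drop = FALSE]
  if (nrow(prot) == 0 || nrow(dna) == 0)
    stop("complex must contain both protein and DNA residues")
  ca <- prot[prot$name == "CA", , drop = FALSE]
  reskey <- paste(dna$chain, dna$resseq, dna$icode)
  beads <- list()
  for (k in unique(reskey)) {
    rows <- dna[reskey == k, , drop = FALSE]
    site <- vapply(rows$name, dna_atom_site, "")
    for (s in unique(site)) {
      grp <- rows[site == s, , drop = FALSE]
      beads[[length(beads) + 1]] <- data.frame(
        chain = grp$chain[1], resseq = grp$resseq[1], site = s,
        x = mean(grp$x), y = mean(grp$y), z = mean(grp$z),
        stringsAsFactors = FALSE)
    }
  }
  beads <- do.call(rbind, beads)
  out <- list()
  if (cutoff > 0) {
    for (i in seq_len(nrow(ca))) {
      d <- sqrt((beads$x - ca$x[i])^2 + (beads$y - ca$y[i])^2 +
                (beads$z - ca$z[i])^2)
      hit <- which(d <= cutoff)
      for (h in hit) {
        out[[length(out) + 1]] <- data.frame(
          res = i, chain = beads$chain[h], resseq = beads$resseq[h],
          site = beads$site[h],
          bead_label = sprintf("%s:%d:%s", beads$chain[h], beads$resseq[h],
                               beads$site[h]),
          r0 = d[h], stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(out) == 0) {
    warning("no specific contacts under cutoff")
    data.frame(res = integer(), chain = character(), resseq = integer(),
               site = character(), bead_label = character(), r0 = numeric())
  } else do.call(rbind, out)
  structure(list(pairs = pairs, epsilon_sp = epsilon_sp),
            class = "specific_contacts")
}

#' Synthetic alpha-helical mini-protein
#'
#' Ideal alpha-helix C-alpha trace (rise 1.5 A/residue, 100 deg/residue,
#' radius 2.3 A) with a user-controlled charge pattern and native contacts
#' auto-extracted from its own coordinates (C-alpha cutoff 6.5 A,
#' `|i-j| >= 3`). Used as a stand-in for a downloaded DNA-binding domain;
#' it is synthetic and labelled as such.
#'
#' @param n_residues chain length (>= 4).
#' @param recognition_range `c(first, last)` residue positions.
#' @param charge_pattern numeric vector (length `n_residues`, values in
#'   -1/0/+1), or `"cationic-recognition"` (default: +1 on every
#'   recognition residue, 0 elsewhere).
#' @param seed integer seed controlling the sequence fill of uncharged
#'   positions.
#' @param fold `"helix"` (single ideal alpha-helix) or `"winged"` (the
#'   recognition helix flanked by two neutral wing helices at +-7 A
#'   lateral offset; the ~14 A wing span fits into the wide major groove
#'   but clashes with the phosphate ridges flanking the minor groove,
#'   mimicking the steric major-groove selectivity of real DNA-binding
#'   domains). `"winged"` requires the recognition range to be an interior
#'   segment with at least 8 residues on each side.
#' @return a `cgprotein` with `native_contacts` populated.
#' @export
make_synthetic_protein <- function(n_residues, recognition_range,
                                   charge_pattern = "cationic-recognition",
                                   seed = 1, fold = c("helix", "winged")) {
  fold <- match.arg(fold)
  if (n_residues < 4) stop("n_residues must be >= 4")
  rr <- as.integer(recognition_range)
  if (length(rr) != 2 || rr[1] < 1 || rr[2] > n_residues || rr[1] > rr[2])
    stop("recognition_range outside chain")
  if (identical(charge_pattern, "cationic-recognition")) {
    charge_pattern <- numeric(n_residues)
    charge_pattern[rr[1]:rr[2]] <- 1
  }
  stopifnot(length(charge_pattern) == n_residues,
            all(charge_pattern %in% c(-1, 0, 1)))
  i <- seq_len(n_residues)
  ang <- (i - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), (i - 1) * 1.5)
  if (fold == "winged") {
    if (rr[1] < 9 || rr[2] > n_residues - 8)
      stop("winged fold needs >= 8 residues flanking the recognition range")
    ca <- winged_fold_coords(n_residues, rr)
  }
  set.seed(seed)
  neutral <- sample(c("A", "L", "S", "G"), n_residues, replace = TRUE)
  seq1 <- ifelse(charge_pattern > 0, "K",
                 ifelse(charge_pattern < 0, "E", neutral))
  nc <- contacts_from_calpha(ca, cutoff = 6.5, min_separation = 3)
  p <- list(sequence = paste(seq1, collapse = ""), ca_coords = ca,
            charges = as.numeric(charge_pattern), recognition_range = rr,
            native_contacts = nc, resseq = i, synthetic = TRUE)
  class(p) <- "cgprotein"
  p
}

#' Native contacts directly from C-alpha coordinates
#'
#' Distance-cutoff contact map on a C-alpha trace (used by the synthetic
#' protein generator, and as a fall-back when no all-atom structure is
#' available).
#'
#' @param ca n x 3 coordinate matrix.
#' @param cutoff C-alpha distance cutoff (A).
#' @param min_separation minimum |i - j|.
#' @return data.frame (i, j, r0).
#' @export
contacts_from_calpha <- function(ca, cutoff = 6.5, min_separation = 3) {
  n <- nrow(ca)
  d <- as.matrix(stats::dist(ca))
  out <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  keep <- (out[, 2] - out[, 1]) >= min_separation
  out <- out[keep, , drop = FALSE]
  data.frame(i = out[, 1], j = out[, 2],
             r0 = d[cbind(out[, 1], out[, 2])])
}

# two-wing fold: recognition helix along z at the origin, wing helices
# antiparallel at lateral offset +-8 A and radial offset +2 A ("outward"
# = +y when the recognition helix points into a groove along -y); the
# ~16 A + bead-diameter wing span admits the major groove, not the minor
winged_fold_coords <- function(n, rr) {
  helix <- function(idx, origin, direction = 1) {
    k <- seq_along(idx) - 1
    a <- k * 100 * pi / 180
    cbind(origin[1] + 2.3 * cos(a), origin[2] + 2.3 * sin(a),
          origin[3] + direction * 1.5 * k)
  }
  nrec <- rr[2] - rr[1] + 1
  zrec <- 1.5 * (nrec - 1)
  ca <- matrix(NA_real_, n, 3)
  # recognition helix centered on z in [-zrec/2, zrec/2]
  ca[rr[1]:rr[2], ] <- helix(rr[1]:rr[2], c(0, 0, -zrec / 2))
  pre <- 1:(rr[1] - 1)          # N-terminal wing (+x side), antiparallel
  post <- (rr[2] + 1):n         # C-terminal wing (-x side)
  nw1 <- length(pre); nw2 <- length(post)
  ca[pre, ] <- helix(pre, c(8, 2, 1.5 * (nw1 - 1) / 2), direction = -1)
  ca[post, ] <- helix(post, c(-8, 2, -1.5 * (nw2 - 1) / 2), direction = 1)
  ca
}
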