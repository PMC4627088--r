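# shared fixtures and independent oracles (plain R, no package internals)

toy_dna <- function(n = 8, seed = 3, ...) {
  build_ideal_bdna(random_dna_sequence(n, seed), ...)
}

toy_protein <- function(n = 12, rr = c(3, 10), seed = 2, ...) {
  make_synthetic_protein(n, rr, seed = seed, ...)
}

# brute-force screened-Coulomb double loop (independent oracle)
brute_dh <- function(coords, q, lambda, kpref, cutoff = Inf, shift = FALSE) {
  n <- nrow(coords); e <- 0
  sh <- if (shift) exp(-cutoff / lambda) / cutoff else 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (r < cutoff) e <- e + kpref * q[i] * q[j] * (exp(-r / lambda) / r - sh)
  }
  e
}

# brute-force contact scan on CA coordinates
brute_contacts <- function(ca, cutoff, min_sep) {
  n <- nrow(ca); out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < min_sep) next
    r <- sqrt(sum((ca[i, ] - ca[j, ])^2))
    if (r <= cutoff) out <- rbind(out, data.frame(i = i, j = j, r0 = r))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(), r0 = numeric())
  else out
}

# central-difference force check; returns max relative error over a sample
grad_check <- function(sys, coords, n_beads = 12, h = 1e-5, seed = 1) {
  set.seed(seed)
  e <- total_energy(sys, coords)
  err <- 0
  for (i in sample(nrow(coords), min(n_beads, nrow(coords)))) {
    for (d in 1:3) {
      xp <- coords; xp[i, d] <- xp[i, d] + h
      xm <- coords; xm[i, d] <- xm[i, d] - h
      fn <- -(total_energy(sys, xp)$total - total_energy(sys, xm)$total) / (2 * h)
      err <- max(err, abs(fn - e$forces[i, d]) / max(abs(fn), 1))
    }
  }
  err
}

# minimal PDB writer for toy structures
pdb_line <- function(serial, name, resname, chain, resseq, xyz,
                     element = substr(name, 1, 1), altloc = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, altloc, resname, chain, resseq,
          xyz[1], xyz[2], xyz[3], element)
}

# 3-residue toy protein PDB: ALA-LYS-GLU along x, CA + CB atoms
toy_pdb3 <- function() {
  lines <- c(
    pdb_line(1, "N",  "ALA", "A", 1, c(0.0, 0.5, 0)),
    pdb_line(2, "CA", "ALA", "A", 1, c(0, 0, 0)),
    pdb_line(3, "CA", "LYS", "A", 2, c(3.8, 0, 0)),
    pdb_line(4, "CB", "LYS", "A", 2, c(4.2, 1.2, 0)),
    pdb_line(5, "CA", "GLU", "A", 3, c(7.6, 0, 0)),
    "END")
  paste(lines, collapse = "\n")
}

# toy protein-DNA complex: 2 residues + 1 DNA nucleotide
toy_complex_pdb <- function(ca1 = c(0, 0, 0), ca2 = c(30, 0, 0),
                            base = c(4, 0, 0)) {
  lines <- c(
    pdb_line(1, "CA", "ALA", "A", 1, ca1),
    pdb_line(2, "CA", "LYS", "A", 2, ca2),
    pdb_line(3, "P",   "DA", "B", 1, base + c(0, 6, 0), element = "P"),
    pdb_line(4, "C1'", "DA", "B", 1, base + c(0, 3, 0)),
    pdb_line(5, "N9",  "DA", "B", 1, base, element = "N"),
    pdb_line(6, "C8",  "DA", "B", 1, base + c(0.5, 0.5, 0)),
    "END")
  paste(lines, collapse = "\n")
}
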