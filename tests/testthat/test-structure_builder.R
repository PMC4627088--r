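test_that("ideal B-DNA duplex geometry: extent, symmetry, degenerate cases", {
  dna <- build_ideal_bdna(random_dna_sequence(200, 1))
  ctr <- bp_centers(dna)
  # axial extent of bp centers = (n-1) * rise
  expect_equal(max(ctr[, 3]) - min(ctr[, 3]), 199 * 3.38, tolerance = 1e-9)
  # helical symmetry: P of bp i and bp i+10 share (x, y) to 1e-6 A
  p1 <- dna$idx$P1
  for (i in c(2, 57, 120)) {
    expect_lt(max(abs(dna$coords[p1[i], 1:2] - dna$coords[p1[i + 10], 1:2])),
              1e-6)
  }
  # bp centers lie on the Z axis by construction
  expect_lt(max(abs(ctr[, 1:2])), 1e-9)
  validate_cgdna(dna)

  # single-bp duplex: no phosphates at all, 2 beads per strand
  d1 <- build_ideal_bdna("G")
  expect_equal(nrow(d1$coords), 4)
  expect_true(all(is.na(d1$idx$P1)) && all(is.na(d1$idx$P2)))
  eb <- dna_bonded_energy(d1, end_restraints = FALSE)
  expect_equal(eb$angle, 0)
  expect_equal(eb$dihedral, 0)

  # invalid characters rejected with position report
  expect_error(build_ideal_bdna("ACGX"), "position.*4")
  expect_error(build_ideal_bdna(""), "nonempty")
})

test_that("duplex is invariant under twist-rotation + rise-translation", {
  dna <- toy_dna(24, seed = 5)
  hp <- dna$helix
  a <- hp$twist * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- dna$coords %*% t(R)
  moved[, 3] <- moved[, 3] + hp$rise
  # bead of bp i maps onto bead of bp i+1, same strand/site
  for (s in 1:2) for (site in c("P", "S", "B")) {
    ix <- dna$idx[[paste0(site, s)]]
    for (i in which(!is.na(ix) & !is.na(c(ix[-1], NA)))) {
      expect_lt(max(abs(moved[ix[i], ] - dna$coords[ix[i + 1], ])), 1e-6)
    }
  }
})

test_that("5'-terminal phosphates are absent and charges are -1 on P", {
  dna <- toy_dna(6)
  expect_true(is.na(dna$idx$P1[1]))   # strand 1: 5' end at bp 1
  expect_true(is.na(dna$idx$P2[6]))   # strand 2: 5' end at bp n
  expect_false(anyNA(dna$idx$P1[2:6]))
  expect_false(anyNA(dna$idx$P2[1:5]))
  expect_true(all(dna$charge[dna$beads$site == "P"] == -1))
  expect_equal(sum(dna$charge), -(2 * 6 - 2))
})

test_that("coordinate round-trip through extended XYZ reproduces beads", {
  dna <- toy_dna(10)
  f <- tempfile(fileext = ".xyz")
  write_xyz(dna$coords, paste0(dna$beads$site, dna$beads$strand), f)
  back <- read_xyz(f)
  expect_lt(max(abs(back$coords - dna$coords)), 1e-4)
  # topology JSON round-trip rebuilds the identical duplex
  tf <- tempfile(fileext = ".json")
  write_dna_topology(dna, tf)
  dna2 <- read_dna_topology(tf)
  expect_equal(dna2$sequence, dna$sequence)
  expect_lt(max(abs(dna2$coords - dna$coords)), 1e-8)
})

test_that("insert_target_site centers the target with the floor convention", {
  host <- random_dna_sequence(200, 2)
  tgt <- paste(rep("A", 10), collapse = "")
  out <- insert_target_site(host, tgt)
  expect_equal(attr(out, "target_start"), 96L)
  expect_equal(attr(out, "target_end"), 105L)
  expect_equal(as.character(substr(out, 96, 105)), tgt)
  expect_equal(nchar(out), 200)
  # full-length target replaces everything
  full <- insert_target_site("ACGT", "TTTT")
  expect_equal(as.character(full), "TTTT")
  # empty target leaves the sequence unchanged
  same <- insert_target_site("ACGT", "")
  expect_equal(as.character(same), "ACGT")
  expect_error(insert_target_site("ACG", "ACGT"), "longer")
})

test_that("PDB ingestion: charges, recognition range, missing CA", {
  p <- load_protein_calpha(toy_pdb3(), recognition_range = c(1, 3))
  expect_equal(p$sequence, "AKE")
  expect_equal(p$charges, c(0, 1, -1))
  expect_equal(nrow(p$ca_coords), 3)
  # residue lacking CA is named in the error
  bad <- paste(c(pdb_line(1, "CA", "ALA", "A", 1, c(0, 0, 0)),
                 pdb_line(2, "CB", "LYS", "A", 2, c(3.8, 0, 0)), "END"),
               collapse = "\n")
  expect_error(load_protein_calpha(bad, c(1, 2)), "LYS 2.*lacks a CA")
  expect_error(load_protein_calpha(toy_pdb3(), c(1, 5)), "recognition_range")
})

test_that("native-contact extraction equals the brute-force pairwise scan", {
  # heavy atoms 4.0 A apart at |i-j|=5 and cutoff 4.5 -> contact present
  lines <- character(0); ser <- 0
  for (i in 1:6) {
    ser <- ser + 1
    lines <- c(lines, pdb_line(ser, "CA", "ALA", "A", i, c(5 * i, 0, 0)))
  }
  # add side-chain atoms bringing residues 1 and 6 within 4.0 A
  lines <- c(lines, pdb_line(90, "CB", "ALA", "A", 1, c(5, 10, 0)),
             pdb_line(91, "CB", "ALA", "A", 6, c(5, 14, 0)), "END")
  pdb <- paste(lines, collapse = "\n")
  nc <- extract_native_contacts(pdb, cutoff = 4.5, min_separation = 3)
  expect_true(any(nc$i == 1 & nc$j == 6))
  # r0 is the CA-CA distance
  expect_equal(nc$r0[nc$i == 1 & nc$j == 6], 25)
  # same pair excluded when min_separation exceeds |i-j|
  nc2 <- extract_native_contacts(pdb, cutoff = 4.5, min_separation = 6)
  expect_equal(nrow(nc2), 0)

  # toy helix: contact list equals exhaustive brute-force scan
  prot <- toy_protein(30, c(5, 20))
  oracle <- brute_contacts(prot$ca_coords, 6.5, 3)
  got <- prot$native_contacts
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$i, oracle$i)
  expect_equal(got$j, oracle$j)
  expect_equal(got$r0, oracle$r0, tolerance = 1e-12)
})

test_that("specific-contact extraction from a toy complex", {
  # one CA within 10 A of the coarse-grained base bead; the other far away
  pdb <- toy_complex_pdb()
  sp <- extract_specific_contacts(pdb, cutoff = 10)
  expect_s3_class(sp, "specific_contacts")
  expect_true(all(sp$pairs$res == 1))
  expect_true(nrow(sp$pairs) >= 1)
  # native distances match a brute-force recomputation of bead centroids
  base_centroid <- colMeans(rbind(c(4, 0, 0), c(4.5, 0.5, 0)))
  d_expect <- sqrt(sum(base_centroid^2))
  expect_true(any(abs(sp$pairs$r0 - d_expect) < 1e-6))
  # cutoff 0 -> empty set with warning
  expect_warning(sp0 <- extract_specific_contacts(pdb, cutoff = 0),
                 "no specific contacts")
  expect_equal(nrow(sp0$pairs), 0)
})

test_that("synthetic protein: determinism, charge pattern, contact oracle", {
  p1 <- make_synthetic_protein(16, c(1, 16))
  expect_equal(sum(p1$charges), 16)          # all-cationic recognition helix
  p2a <- toy_protein(20, c(5, 12), seed = 9)
  p2b <- toy_protein(20, c(5, 12), seed = 9)
  expect_identical(p2a$ca_coords, p2b$ca_coords)
  expect_identical(p2a$sequence, p2b$sequence)
  expect_error(make_synthetic_protein(3, c(1, 2)), "n_residues")
  expect_error(make_synthetic_protein(10, c(5, 12)), "recognition_range")
  # ideal helix geometry: rise 1.5 A per residue along z
  expect_equal(diff(p2a$ca_coords[, 3]), rep(1.5, 19), tolerance = 1e-12)
})
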