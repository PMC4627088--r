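#' @rdname build_ideal_bdna
#' @export
dna_complement <- function(sequence) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(sequence, "")[[1]]
  paste(map[chars], collapse = "")
}

#' Random DNA sequence
#'
#' @param n_bp length in base pairs.
#' @param seed integer seed (optional).
#' @return a string over \{A,C,G,T\}.
#' @export
random_dna_sequence <- function(n_bp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n_bp, replace = TRUE), collapse = "")
}

check_dna_alphabet <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0)
    stop(sprintf("invalid DNA character(s) '%s' at position(s) %s",
                 paste(unique(chars[bad]), collapse = ","),
                 paste(bad, collapse = ",")))
  chars
}

#' Build an ideal B-DNA duplex
#'
#' Generates an exactly helical three-bead-per-nucleotide duplex along +Z
#' with base pair 1 centered at the origin. Each non-terminal nucleotide
#' carries phosphate (P, charge -1), sugar (S) and base (B) beads; the
#' 5'-terminal nucleotide of each strand has no phosphate. Base-pair
#' centers (midpoints of the paired base beads) lie exactly on the Z axis.
#'
#' @param sequence strand-1 sequence, 5' to 3', over \{A,C,G,T\}.
#' @param hp helix parameters, see [helix_params()].
#' @param rigid mark the duplex as rigid (frozen during dynamics).
#' @return an object of class `cgdna`: list with `sequence`, `n_bp`,
#'   `beads` (data.frame strand/bp/site), `coords` (n x 3 matrix, A),
#'   `charge`, index map `idx` (`P1`,`S1`,`B1`,`P2`,`S2`,`B2`, `NA` where a
#'   terminal phosphate is absent), `helix`, `rigid`, and
#'   `end_constraint_bps = c(1, n_bp)`.
#' @examples
#' dna <- build_ideal_bdna("ACGT")
#' bp_centers(dna)
#' @export
build_ideal_bdna <- function(sequence, hp = helix_params(), rigid = FALSE) {
  if (!nzchar(sequence)) stop("sequence must be nonempty")
  chars <- check_dna_alphabet(sequence)
  n <- length(chars)
  comp <- strsplit(dna_complement(sequence), "")[[1]]

  site_xyz <- function(strand, bp, site) {
    pr <- hp[[tolower(site)]]
    sgn <- if (strand == 1) 1 else -1
    ang <- ((bp - 1) * hp$twist + sgn * pr[["phi"]]) * pi / 180
    z <- (bp - 1) * hp$rise + sgn * pr[["z"]]
    c(pr[["r"]] * cos(ang), pr[["r"]] * sin(ang), z)
  }

  rows <- list(); coords <- list(); k <- 0
  idx <- list(P1 = rep(NA_integer_, n), S1 = rep(NA_integer_, n),
              B1 = rep(NA_integer_, n), P2 = rep(NA_integer_, n),
              S2 = rep(NA_integer_, n), B2 = rep(NA_integer_, n))
  add <- function(strand, bp, site) {
    k <<- k + 1
    rows[[k]] <<- data.frame(strand = strand, bp = bp, site = site,
                             stringsAsFactors = FALSE)
    coords[[k]] <<- site_xyz(strand, bp, site)
    idx[[paste0(site, strand)]][bp] <<- k
  }
  # strand 1: 5' -> 3' is bp 1 -> n; 5' terminus (bp 1) has no phosphate
  for (i in seq_len(n)) {
    if (i > 1) add(1, i, "P")
    add(1, i, "S"); add(1, i, "B")
  }
  # strand 2: 5' -> 3' is bp n -> 1; 5' terminus (bp n) has no phosphate
  for (i in seq_len(n)) {
    if (i < n) add(2, i, "P")
    add(2, i, "S"); add(2, i, "B")
  }
  beads <- do.call(rbind, rows)
  coords <- do.call(rbind, coords)
  charge <- ifelse(beads$site == "P", -1, 0)

  dna <- list(sequence = sequence, sequence2 = paste(comp, collapse = ""),
              n_bp = n, beads = beads, coords = coords, charge = charge,
              idx = idx, helix = hp, rigid = rigid,
              end_constraint_bps = c(1L, n))
  class(dna) <- "cgdna"
  dna
}

#' Base-pair centers
#'
#' Midpoints of the two paired base beads for every base pair.
#'
#' @param dna a `cgdna` object.
#' @param coords optional replacement coordinates (n x 3), e.g. a
#'   trajectory frame; defaults to the stored build coordinates.
#' @return `n_bp` x 3 matrix.
#' @export
bp_centers <- function(dna, coords = NULL) {
  if (is.null(coords)) coords <- dna$coords
  0.5 * (coords[dna$idx$B1, , drop = FALSE] + coords[dna$idx$B2, , drop = FALSE])
}

#' Validate a cgdna object
#'
#' Checks strand complementarity, phosphate charges, per-nucleotide bead
#' counts and that base-pair centers recomputed from bead coordinates
#' match [bp_centers()] to 1e-6 A.
#'
#' @param dna a `cgdna` object.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_cgdna <- function(dna) {
  stopifnot(inherits(dna, "cgdna"))
  if (dna_complement(dna$sequence) != dna$sequence2)
    stop("strands are not Watson-Crick complementary")
  if (!all(dna$charge[dna$beads$site == "P"] == -1))
    stop("phosphate charges must all be -1")
  if (!all(dna$charge[dna$beads$site != "P"] == 0))
    stop("non-phosphate beads must be neutral")
  n <- dna$n_bp
  for (i in seq_len(n)) {
    n1 <- sum(dna$beads$strand == 1 & dna$beads$bp == i)
    n2 <- sum(dna$beads$strand == 2 & dna$beads$bp == i)
    exp1 <- if (i == 1) 2 else 3
    exp2 <- if (i == n) 2 else 3
    if (n1 != exp1 || n2 != exp2)
      stop(sprintf("base pair %d has wrong bead count", i))
  }
  ctr <- bp_centers(dna)
  ctr2 <- 0.5 * (dna$coords[dna$idx$B1, , drop = FALSE] +
                 dna$coords[dna$idx$B2, , drop = FALSE])
  if (max(abs(ctr - ctr2)) > 1e-6) stop("bp centers inconsistent")
  invisible(TRUE)
}

#' Insert a target sequence at the center of a DNA sequence
#'
#' Replaces the centered window of `sequence` with `target_sequence`. For
#' sequence length L and target length t the 1-based start index is
#' `floor((L - t)/2) + 1`.
#'
#' @param sequence host sequence.
#' @param target_sequence sequence to insert (may be empty).
#' @return the modified sequence, with attributes `target_start` and
#'   `target_end` (1-based, inclusive; both 0 for an empty target).
#' @export
insert_target_site <- function(sequence, target_sequence) {
  L <- nchar(sequence); t <- nchar(target_sequence)
  if (t > L) stop("target longer than sequence")
  if (t == 0) {
    out <- sequence
    attr(out, "target_start") <- 0L; attr(out, "target_end") <- 0L
    return(out)
  }
  start <- floor((L - t) / 2) + 1
  out <- paste0(substr(sequence, 1, start - 1), target_sequence,
                substr(sequence, start + t, L))
  attr(out, "target_start") <- as.integer(start)
  attr(out, "target_end") <- as.integer(start + t - 1)
  out
}

# ---------------------------------------------------------------------------
# I/O: extended XYZ + topology JSON
# ---------------------------------------------------------------------------

#' Write coordinates as extended XYZ
#'
#' @param coords n x 3 matrix (A).
#' @param labels per-bead labels (site names).
#' @param file output path.
#' @param comment comment line.
#' @export
write_xyz <- function(coords, labels, file, comment = "cgsearch") {
  stopifnot(nrow(coords) == length(labels))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(as.character(nrow(coords)), comment), con)
  writeLines(sprintf("%s %.8f %.8f %.8f", labels,
                     coords[, 1], coords[, 2], coords[, 3]), con)
  invisible(file)
}

#' Read extended XYZ written by [write_xyz()]
#'
#' @param file path. Multi-frame files return a list of frames.
#' @return list with `labels` and `coords` (single frame) or `frames`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list(); i <- 1
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    labels <- vapply(parts, `[`, "", 1)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- list(labels = labels, coords = coords)
    i <- i + 2 + n
  }
  if (length(frames) == 1) frames[[1]] else list(frames = frames)
}

#' Write / read duplex topology as JSON
#'
#' Stores the sequence, helix parameters and bead table; coordinates go to
#' XYZ via [write_xyz()].
#'
#' @param dna `cgdna` object.
#' @param file path.
#' @export
write_dna_topology <- function(dna, file) {
  hp <- unclass(dna$helix)
  attr(hp, "calibration") <- NULL
  for (s in c("p", "s", "b")) hp[[s]] <- as.list(hp[[s]])  # keep names in JSON
  obj <- list(sequence = dna$sequence, rigid = dna$rigid, helix = hp,
              end_constraint_bps = dna$end_constraint_bps)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_dna_topology
#' @export
read_dna_topology <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  hp <- obj$helix
  for (s in c("p", "s", "b"))
    hp[[s]] <- setNames(as.numeric(unlist(hp[[s]])), c("r", "phi", "z"))
  hp$k_major <- as.integer(hp$k_major); hp$k_minor <- as.integer(hp$k_minor)
  hp$twist <- as.numeric(hp$twist); hp$rise <- as.numeric(hp$rise)
  class(hp) <- "helix_params"
  build_ideal_bdna(obj$sequence, hp = hp, rigid = isTRUE(obj$rigid))
}

#' Write / read a cgprotein as JSON
#'
#' Serializes sequence, charges, recognition range, native contacts and
#' native coordinates.
#'
#' @param protein `cgprotein`.
#' @param file path.
#' @export
write_protein_json <- function(protein, file) {
  obj <- list(sequence = protein$sequence, charges = protein$charges,
              recognition_range = protein$recognition_range,
              ca_coords = protein$ca_coords,
              native_contacts = protein$native_contacts,
              synthetic = isTRUE(protein$synthetic))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_protein_json
#' @export
read_protein_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  p <- list(sequence = obj$sequence, ca_coords = as.matrix(obj$ca_coords),
            charges = as.numeric(obj$charges),
            recognition_range = as.integer(obj$recognition_range),
            native_contacts = as.data.frame(obj$native_contacts),
            resseq = seq_len(nchar(obj$sequence)),
            synthetic = isTRUE(obj$synthetic))
  class(p) <- "cgprotein"
  p
}

#' Write / read a trajectory as multi-frame extended XYZ
#'
#' @param traj `cg_trajectory`.
#' @param file path.
#' @export
write_trajectory_xyz <- function(traj, file) {
  sys <- traj$system
  labels <- character(sys$n)
  if (!is.null(sys$dna))
    labels[1:sys$n_dna] <- paste0(sys$dna$beads$site, sys$dna$beads$strand)
  if (!is.null(sys$protein))
    labels[sys$protein_offset + seq_len(nrow(sys$protein$ca_coords))] <- "CA"
  con <- file(file, "w"); on.exit(close(con))
  for (f in seq_len(dim(traj$frames)[3])) {
    X <- traj$frames[, , f]
    writeLines(c(as.character(sys$n), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, X[, 1], X[, 2], X[, 3]),
               con)
  }
  invisible(file)
}

#' @param dna,protein molecules matching the stored bead order.
#' @rdname write_trajectory_xyz
#' @export
read_trajectory_xyz <- function(file, dna, protein) {
  raw <- read_xyz(file)
  frames_list <- if (!is.null(raw$frames)) raw$frames else list(raw)
  sys <- build_system(dna = dna, protein = protein, end_restraints = FALSE)
  nf <- length(frames_list)
  frames <- array(NA_real_, c(sys$n, 3, nf))
  for (f in seq_len(nf)) frames[, , f] <- frames_list[[f]]$coords
  traj <- list(frames = frames, energies = data.frame(step = seq_len(nf) - 1),
               config = simulation_config(n_steps = nf, output_stride = 1),
               system = sys)
  class(traj) <- "cg_trajectory"
  traj
}
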