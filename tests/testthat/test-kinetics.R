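test_that("Gaussian non-specific map: moments, positivity, exclusions", {
  dna <- build_ideal_bdna(random_dna_sequence(150, 1))
  prot <- make_synthetic_protein(50, c(5, 40), seed = 1)  # 36 res x 288 bases
  map <- make_nonspecific_map(dna, prot, target_range = c(73, 78), seed = 7)
  # target bases excluded from the map entirely
  tgt_beads <- which(dna$beads$site == "B" &
                     dna$beads$bp >= 73 & dna$beads$bp <= 78)
  expect_false(any(map$dna_bead %in% tgt_beads))
  # all depths positive (truncated resampling)
  expect_true(all(map$eps > 0))
  # moments within 3 SE of (0.6, 0.1) over >= 1e4 draws
  expect_gte(nrow(map), 1e4)
  se_mean <- 0.1 / sqrt(nrow(map))
  expect_lt(abs(mean(map$eps) - 0.6), 3 * se_mean)
  se_sd <- 0.1 / sqrt(2 * (nrow(map) - 1))
  expect_lt(abs(sd(map$eps) - 0.1), 3 * se_sd)
  # frozen map: same seed reproduces it exactly
  map2 <- make_nonspecific_map(dna, prot, target_range = c(73, 78), seed = 7)
  expect_identical(map, map2)
})

test_that("sigma = 0 map makes every pair depth exactly the mean", {
  dna <- build_ideal_bdna(random_dna_sequence(12, 2))
  prot <- make_synthetic_protein(8, c(1, 8), seed = 1)
  map <- make_nonspecific_map(dna, prot, sd = 0, seed = 1)
  expect_true(all(map$eps == 0.6))
})

test_that("target-region bases contribute zero non-specific energy", {
  dna <- build_ideal_bdna(random_dna_sequence(20, 3))
  prot <- make_synthetic_protein(8, c(1, 8), seed = 2)
  map <- make_nonspecific_map(dna, prot, target_range = c(1, 20), seed = 1)
  expect_equal(nrow(map), 0)  # everything excluded
  # place protein right on the DNA: with an all-target map there is no
  # non-specific term no matter how close the bases are
  pose <- make_bound_pose(dna, prot, 10)
  sys <- build_system(dna = dna, protein = prot, protein_coords = pose,
                      Cs = 20, nonspecific = map, end_restraints = FALSE)
  expect_equal(nonspecific_sequence_energy(sys), 0)
})

test_that("specific energy: native minimum, range, 3-pair hand evaluation", {
  dna <- build_ideal_bdna(random_dna_sequence(30, 5))
  prot <- make_synthetic_protein(16, c(3, 14), seed = 3)
  pose <- make_bound_pose(dna, prot, 15)
  sp <- make_specific_contacts(dna, prot, pose, epsilon_sp = 2.0)
  expect_gt(nrow(sp$pairs), 5)
  sys <- build_system(dna = dna, protein = prot, protein_coords = pose,
                      Cs = 20, specific = sp, end_restraints = FALSE)
  # at the bound pose every well sits at its minimum (up to cutoff shift)
  esp <- specific_energy(sys)
  p <- ff_params()
  qc <- 1 / p$cross$specific_cutoff_mult
  shift_per_pair <- 2.0 * (qc^12 - 2 * qc^6)
  expect_equal(esp, -nrow(sp$pairs) * 2.0 - nrow(sp$pairs) * shift_per_pair,
               tolerance = 1e-6)
  # protein far away: ~0
  x <- sys$coords
  x[protein_indices(sys), ] <- sweep(pose, 2, c(100, 0, 0), "+")
  expect_equal(specific_energy(sys, x), 0)
  # 3-pair toy vs hand evaluation at a displaced geometry
  sp3 <- sp; sp3$pairs <- sp$pairs[1:3, ]
  sys3 <- build_system(dna = dna, protein = prot, protein_coords = pose,
                       Cs = 20, specific = sp3, end_restraints = FALSE)
  x3 <- sys3$coords
  x3[protein_indices(sys3), ] <- sweep(pose, 2, c(1.1, -0.4, 0.6), "+")
  # soft attractive well: flat -eps core below r0, 12-6 tail above,
  # shifted to zero at the per-pair cutoff
  hand <- 0
  for (r in 1:3) {
    i <- sys3$protein_offset + sp3$pairs$res[r]
    j <- sp3$pairs$dna_bead[r]
    rr <- sqrt(sum((x3[i, ] - x3[j, ])^2))
    r0 <- sp3$pairs$r0[r]; rc <- p$cross$specific_cutoff_mult * r0
    if (rr < rc) {
      qs <- r0 / rc
      ush <- 2.0 * (qs^12 - 2 * qs^6)
      hand <- hand + if (rr <= r0) -2.0 - ush else {
        q <- r0 / rr
        2.0 * (q^12 - 2 * q^6) - ush
      }
    }
  }
  expect_equal(specific_energy(sys3, x3), hand, tolerance = 1e-10)
})

test_that("Q_sp: limits and the 13-of-20 fixture", {
  dna <- build_ideal_bdna(random_dna_sequence(30, 5))
  prot <- make_synthetic_protein(16, c(3, 14), seed = 3)
  pose <- make_bound_pose(dna, prot, 15)
  sp <- make_specific_contacts(dna, prot, pose)
  sys <- build_system(dna = dna, protein = prot, protein_coords = pose,
                      Cs = 20, specific = sp, end_restraints = FALSE)
  expect_equal(compute_Qsp(sys), 1.0)
  x <- sys$coords
  x[protein_indices(sys), ] <- sweep(pose, 2, c(150, 0, 0), "+")
  expect_equal(compute_Qsp(sys, x), 0.0)
  # constructed 20-pair set with exactly 13 formed
  sp20 <- sp
  sp20$pairs <- sp$pairs[rep(1, 20), ]
  d_now <- sqrt(sum((pose[sp$pairs$res[1], ] -
                     dna$coords[sp$pairs$dna_bead[1], ])^2))
  sp20$pairs$r0 <- d_now                     # formed at tolerance 0.2
  sp20$pairs$r0[14:20] <- d_now / 2          # current distance = 2 r0: broken
  sys20 <- build_system(dna = dna, protein = prot, protein_coords = pose,
                        Cs = 20, specific = sp20, end_restraints = FALSE)
  expect_equal(compute_Qsp(sys20), 13 / 20)
  sys_empty <- sys; sys_empty$specific <- NULL
  expect_error(compute_Qsp(sys_empty), "empty")
})

test_that("quench control: bound start has Qsp(0) = 1 and immediate success", {
  dna <- build_ideal_bdna(as.character(
    insert_target_site(random_dna_sequence(24, 4), "AAAA")))
  prot <- make_synthetic_protein(12, c(3, 10), seed = 2)
  pose <- make_bound_pose(dna, prot, 12)
  kr <- run_kinetics_ensemble(dna, prot, c(11, 14), n_replicas = 2,
                              n_steps = 3000, seed = 5, Cs = 20,
                              epsilon_sp = 6, output_stride = 100,
                              sustain = 5, start_coords = pose)
  for (r in 1:2) expect_equal(kr$replicas[[r]]$series$Qsp[1], 1.0)
  expect_equal(kr$success_fraction, 1.0)
  expect_true(all(kr$first_passage_steps == 0))
  # determinism: same seeds give identical ensembles
  kr2 <- run_kinetics_ensemble(dna, prot, c(11, 14), n_replicas = 2,
                               n_steps = 3000, seed = 5, Cs = 20,
                               epsilon_sp = 6, output_stride = 100,
                               sustain = 5, start_coords = pose)
  expect_identical(kr$ensemble_Qsp, kr2$ensemble_Qsp)
  expect_identical(kr$first_passage_steps, kr2$first_passage_steps)
})

test_that("ensemble mean Qsp is computed over successful replicas only", {
  # synthetic result assembly check via first_sustained
  q <- c(0.1, 0.3, 0.85, 0.9, 0.95, 0.9, 0.85)
  expect_equal(cgsearch:::first_sustained(q, 0.8, 3), 3L)
  expect_true(is.na(cgsearch:::first_sustained(q, 0.8, 8)))
  expect_equal(cgsearch:::first_sustained(q, 0.8, 1), 3L)
})

test_that("deeper specific wells accelerate binding (strong-quench scaling)", {
  # protein started 5 bp from the target with deep wells; median first
  # passage decreases when epsilon_sp is doubled
  seqn <- insert_target_site(random_dna_sequence(40, 6), "AAAAAA")
  dna <- build_ideal_bdna(as.character(seqn))
  prot <- make_synthetic_protein(14, c(3, 12), seed = 4)
  tgt <- c(attr(seqn, "target_start"), attr(seqn, "target_end"))
  run1 <- run_kinetics_ensemble(dna, prot, tgt, n_replicas = 6,
                                n_steps = 15000, seed = 11, Cs = 20,
                                epsilon_sp = 1.5, offset_bp = 5, radial = 12,
                                output_stride = 150, sustain = 3,
                                nonspecific_on = FALSE)
  run2 <- run_kinetics_ensemble(dna, prot, tgt, n_replicas = 6,
                                n_steps = 15000, seed = 11, Cs = 20,
                                epsilon_sp = 3.0, offset_bp = 5, radial = 12,
                                output_stride = 150, sustain = 3,
                                nonspecific_on = FALSE)
  fp1 <- kinetics_first_passage_median(run1)
  fp2 <- kinetics_first_passage_median(run2)
  expect_true(fp2 <= fp1)
})

test_that("smoothed ensemble Qsp is non-decreasing in quench conditions", {
  dna <- build_ideal_bdna(as.character(
    insert_target_site(random_dna_sequence(24, 4), "AAAA")))
  prot <- make_synthetic_protein(12, c(3, 10), seed = 2)
  pose <- make_bound_pose(dna, prot, 12)
  start <- sweep(pose, 2, c(0, 0, 6), "+")   # shifted along the DNA axis
  kr <- run_kinetics_ensemble(dna, prot, c(11, 14), n_replicas = 4,
                              n_steps = 20000, seed = 9, Cs = 20,
                              epsilon_sp = 4, output_stride = 100,
                              sustain = 5, start_coords = start,
                              nonspecific_on = FALSE)
  expect_gt(kr$success_fraction, 0)
  q <- kr$ensemble_Qsp
  w <- 10
  sm <- stats::filter(q, rep(1 / w, w), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -0.12))   # non-decreasing after smoothing
})

test_that("bound complex sits closer to flexible-confined DNA than rigid DNA", {
  # one-sided comparison of R_pro-DNA at high Qsp, matched scaled ensembles
  seqn <- insert_target_site(random_dna_sequence(30, 8), "AAAA")
  dna <- build_ideal_bdna(as.character(seqn))
  prot <- make_synthetic_protein(12, c(3, 10), seed = 2)
  tgt <- c(attr(seqn, "target_start"), attr(seqn, "target_end"))
  pose <- make_bound_pose(dna, prot, floor(mean(tgt)))
  common <- list(dna = dna, protein = prot, target_range = tgt,
                 n_replicas = 20, n_steps = 6000, seed = 31, Cs = 20,
                 epsilon_sp = 5, output_stride = 200, sustain = 3,
                 start_coords = pose, nonspecific_on = FALSE)
  kr_rigid <- do.call(run_kinetics_ensemble, c(common, list(rigid_dna = TRUE)))
  kr_flex <- do.call(run_kinetics_ensemble,
                     c(common, list(cage = cage_spec(15))))
  rp <- function(kr) {
    v <- c()
    for (r in kr$replicas) {
      sel <- r$series$Qsp > 0.8
      if (any(sel)) v <- c(v, r$series$R_pro_dna[sel])
    }
    v
  }
  expect_lt(mean(rp(kr_flex)), mean(rp(kr_rigid)))
})
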