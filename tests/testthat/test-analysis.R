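test_that("groove widths reproduce the rigid B-DNA calibration everywhere", {
  dna <- build_ideal_bdna(random_dna_sequence(200, 1))
  gw <- compute_groove_widths(dna)
  expect_true(all(abs(gw$W_MJ[gw$valid_major] - 17.25) < 0.05))
  expect_true(all(abs(gw$W_MN[gw$valid_minor] - 11.58) < 0.05))
  # position independence on the rigid duplex (variance < 1e-6 A^2)
  expect_lt(var(gw$W_MJ[gw$valid_major]), 1e-6)
  expect_lt(var(gw$W_MN[gw$valid_minor]), 1e-6)
  # rigid translation + rotation leaves widths unchanged to 1e-8
  a <- 0.61
  R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
              byrow = TRUE)
  x2 <- sweep(dna$coords %*% t(R), 2, c(11, -4, 3), "+")
  gw2 <- compute_groove_widths(dna, x2)
  expect_lt(max(abs(gw2$W_MJ - gw$W_MJ), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(gw2$W_MN - gw$W_MN), na.rm = TRUE), 1e-8)
})

test_that("groove width equals the hand-computed phosphate distance", {
  dna <- toy_dna(12)
  x <- dna$coords
  i <- dna$idx$P1[6]; j <- dna$idx$P2[6 + dna$helix$k_minor]
  x[i, ] <- c(1, 2, 3); x[j, ] <- c(4, 6, 3)
  gw <- compute_groove_widths(dna, x)
  expect_equal(gw$W_MN[6], 5)   # 3-4-5 triangle
  expect_error(compute_groove_widths(dna, registers = c(100, -100)),
               "registers")
})

test_that("classifier decision rule matches the stated threshold cases", {
  th <- classifier_thresholds()
  # > 30 A -> 3D regardless of the other features
  expect_equal(classify_features(35, 1.0, 0, th), "DIFFUSION_3D")
  # all three sliding criteria met
  expect_equal(classify_features(17, 0.8, 20, th), "SLIDING")
  # inside 30 A but failing sliding criteria -> hopping
  expect_equal(classify_features(25, 1.0, 40, th), "HOPPING")
  # boundary bookkeeping: 30 A is not 3D; 18 A can still slide
  expect_equal(classify_features(30, 0, 90, th), "HOPPING")
  expect_equal(classify_features(18, 0.71, 24.9, th), "SLIDING")
  # conjunction: each sliding criterion is individually necessary
  expect_equal(classify_features(17, 0.6, 10, th), "HOPPING")
  expect_equal(classify_features(17, 0.9, 30, th), "HOPPING")
  expect_equal(classify_features(19, 0.9, 10, th), "HOPPING")
})

test_that("classifier is total and recovers scripted ground-truth labels", {
  dna <- build_ideal_bdna(random_dna_sequence(60, 2))
  prot <- make_synthetic_protein(24, c(5, 20), seed = 1)
  segs <- data.frame(mode = c("SLIDING", "HOPPING", "DIFFUSION_3D", "SLIDING"),
                     n_frames = c(12, 8, 8, 12))
  tr <- make_scripted_trajectory(dna, prot, segs, seed = 3)
  tl <- classify_timeline(tr)
  expect_equal(nrow(tl), sum(segs$n_frames))
  expect_true(all(tl$label %in% c("SLIDING", "HOPPING", "DIFFUSION_3D")))
  expect_equal(tl$label, tr$labels_true)
  # theta is unwrapped: no jumps above 180 degrees between frames
  expect_true(all(abs(diff(tl$theta)) <= 180 + 1e-9))
})

test_that("mode propensities: limits, arithmetic, brute-force count oracle", {
  expect_equal(mode_propensities(rep("SLIDING", 7))$fractions,
               c(sliding = 1, hopping = 0, diffusion_3d = 0))
  pr <- mode_propensities(c("SLIDING", "SLIDING", "HOPPING", "DIFFUSION_3D"))
  expect_equal(unname(pr$fractions), c(0.5, 0.25, 0.25))
  set.seed(12)
  lab <- sample(c("SLIDING", "HOPPING", "DIFFUSION_3D"), 500, replace = TRUE)
  pr2 <- mode_propensities(lab)
  expect_equal(sum(pr2$fractions), 1)
  expect_equal(unname(pr2$counts["sliding"]), sum(lab == "SLIDING"))
  expect_error(mode_propensities(character(0)), "empty")
})

test_that("occupied groove: placement on ideal DNA and width threshold", {
  dna <- build_ideal_bdna(random_dna_sequence(40, 3))
  prot <- make_synthetic_protein(16, c(1, 16), seed = 2)
  sys <- build_system(dna = dna, protein = prot, end_restraints = FALSE)
  # protein recognition center at the major-groove midline of bp 20
  mid <- groove_midpoints(dna, which = "major")
  x <- sys$coords
  pc <- place_protein(prot, mid[20, ])
  x[protein_indices(sys), ] <- pc
  og <- occupied_groove(sys, x)
  expect_equal(og$which_midline, "major")
  expect_equal(og$groove, "MAJOR")
  expect_equal(og$width, 17.25, tolerance = 0.05)
  # minor-groove midline placement: width 11.58 < 15 -> MINOR
  midn <- groove_midpoints(dna, which = "minor")
  x[protein_indices(sys), ] <- place_protein(prot, midn[20, ])
  ogn <- occupied_groove(sys, x)
  expect_equal(ogn$groove, "MINOR")
  # 3D placement yields no assignment
  x[protein_indices(sys), ] <- place_protein(prot, c(60, 0, 40))
  expect_null(occupied_groove(sys, x))
})

test_that("occupancy fractions on a scripted alternating-groove trajectory", {
  dna <- build_ideal_bdna(random_dna_sequence(40, 3))
  prot <- make_synthetic_protein(16, c(1, 16), seed = 2)
  sys <- build_system(dna = dna, protein = prot, end_restraints = FALSE)
  mid_major <- groove_midpoints(dna, which = "major")
  mid_minor <- groove_midpoints(dna, which = "minor")
  labs <- character(0)
  for (f in 1:20) {
    bp <- 10 + (f %% 5)
    tgt <- if (f %% 2 == 0) mid_major[bp, ] else mid_minor[bp, ]
    x <- sys$coords
    x[protein_indices(sys), ] <- place_protein(prot, tgt)
    labs <- c(labs, occupied_groove(sys, x)$groove)
  }
  expect_equal(mean(labs == "MAJOR"), 0.5)
  expect_equal(mean(labs == "MINOR"), 0.5)
})

test_that("theta-Z correlation: ideal helical path, degenerate, oracle", {
  # scripted ideal coupling Z = (34/360) theta
  theta <- seq(0, 3600, by = 36)
  tl <- data.frame(label = "SLIDING", theta = theta, z = 34 / 360 * theta)
  out <- theta_z_correlation(tl)
  expect_equal(out$correlation, 1.0, tolerance = 1e-12)
  expect_equal(out$slope, 34 / 360, tolerance = 1e-12)
  # constant theta -> zero variance -> null with reason
  tl2 <- data.frame(label = "SLIDING", theta = rep(1, 20), z = 1:20)
  out2 <- theta_z_correlation(tl2)
  expect_true(is.na(out2$correlation))
  expect_match(out2$reason, "variance")
  # 20-point synthetic series equals the hand-computed Pearson formula
  set.seed(5)
  th <- rnorm(20); z <- 0.3 * th + rnorm(20, 0, 0.4)
  tl3 <- data.frame(label = "SLIDING", theta = th, z = z)
  r_hand <- sum((th - mean(th)) * (z - mean(z))) /
    sqrt(sum((th - mean(th))^2) * sum((z - mean(z))^2))
  expect_equal(theta_z_correlation(tl3)$correlation, r_hand, tolerance = 1e-10)
  # fewer than 10 sliding frames -> null
  expect_true(is.na(theta_z_correlation(tl3[1:5, ])$correlation))
})

test_that("sliding-event segmentation equals a run-length oracle", {
  tl <- labels_to_timeline(c("S", "S", "H", "S", "D", "S", "S", "S"))
  ev <- segment_sliding_events(tl)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$n_frames, c(2, 1, 3))
  # all-sliding: single event spanning the trajectory
  tl2 <- labels_to_timeline(rep("S", 50), z = cumsum(runif(50)))
  ev2 <- segment_sliding_events(tl2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$length_z, abs(tl2$z[50] - tl2$z[1]))
  # random label string vs independent run-length encoding
  set.seed(8)
  lab <- sample(c("S", "H", "D"), 300, replace = TRUE)
  tl3 <- labels_to_timeline(lab)
  ev3 <- segment_sliding_events(tl3)
  r <- rle(lab == "S")
  expect_equal(nrow(ev3), sum(r$values))
  expect_equal(ev3$n_frames, r$lengths[r$values])
  # events are maximal: flanked by non-sliding or trajectory ends
  for (q in seq_len(nrow(ev3))) {
    if (ev3$start[q] > 1) expect_false(lab[ev3$start[q] - 1] == "S")
    if (ev3$end[q] < 300) expect_false(lab[ev3$end[q] + 1] == "S")
  }
})

test_that("search efficiency: per-episode unique bp, averaged", {
  # single event visiting bp {50, 51, 52}
  tl <- labels_to_timeline(rep("S", 6),
                           closest_bp = c(50, 50, 51, 51, 52, 52))
  expect_equal(search_efficiency(tl)$mean_bp_scanned, 3)
  # two episodes visiting {50,51} and {80,81,82}
  lab <- c("S", "S", "D", "D", "S", "S", "S")
  tl2 <- labels_to_timeline(lab, closest_bp = c(50, 51, 1, 1, 80, 81, 82))
  out <- search_efficiency(tl2)
  expect_equal(out$n_episodes, 2)
  expect_equal(out$mean_bp_scanned, 2.5)
  # brute-force oracle on a random scripted timeline
  set.seed(3)
  lab3 <- sample(c("S", "H", "D"), 200, replace = TRUE, prob = c(.5, .3, .2))
  bp3 <- cumsum(sample(c(0, 1), 200, replace = TRUE)) + 10
  tl3 <- labels_to_timeline(lab3, closest_bp = bp3)
  out3 <- search_efficiency(tl3)
  full <- ifelse(lab3 %in% c("S", "H"), "on", "off")
  r <- rle(full)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  per <- c()
  for (q in which(r$values == "on")) {
    rows <- starts[q]:ends[q]
    per <- c(per, length(unique(bp3[rows][lab3[rows] == "S"])))
  }
  expect_equal(out3$per_episode, per)
  expect_equal(out3$mean_bp_scanned, mean(per))
})

test_that("D1 estimation: stationary, known-D recovery, variance scaling", {
  # stationary protein: D1 = 0
  tl0 <- labels_to_timeline(rep("S", 300), z = rep(5, 300))
  expect_equal(estimate_D1(tl0)$D1, 0)
  # synthetic 1D walk with known D recovered within 5%
  D <- 0.8
  tl <- make_1d_walk_timeline(100000, D, seed = 2)
  est <- estimate_D1(tl)
  expect_lt(abs(est$D1 - D) / D, 0.05)
  expect_gt(est$r_squared, 0.99)
  # doubling the step variance doubles D1 (within fit error)
  tl2 <- make_1d_walk_timeline(100000, 2 * D, seed = 2)
  est2 <- estimate_D1(tl2)
  expect_lt(abs(est2$D1 / est$D1 - 2), 0.1)
  # stretches never bridge 3D excursions: insufficient data errors out
  tl3 <- labels_to_timeline(rep(c("S", "D"), 100))
  expect_error(estimate_D1(tl3), "stretch|frames")
  expect_error(estimate_D1(labels_to_timeline(rep("D", 200))), "frames")
})

test_that("dynamics correlation: offset, reflection, Pearson oracle", {
  set.seed(10)
  a <- apply(matrix(rnorm(150), 50, 3), 2, cumsum)
  # identical displacements with constant offset -> 1
  expect_equal(dynamics_correlation(a, sweep(a, 2, c(3, -1, 2), "+"))$correlation,
               1.0, tolerance = 1e-12)
  # reflected displacements -> -1
  b <- -a
  expect_equal(dynamics_correlation(a, b)$correlation, -1.0, tolerance = 1e-12)
  # 50-point synthetic pair equals the hand Pearson on pooled displacements
  c2 <- a + apply(matrix(rnorm(150, 0, 0.5), 50, 3), 2, cumsum)
  da <- as.vector(diff(a)); db <- as.vector(diff(c2))
  r_hand <- sum((da - mean(da)) * (db - mean(db))) /
    sqrt(sum((da - mean(da))^2) * sum((db - mean(db))^2))
  out <- dynamics_correlation(a, c2)
  expect_equal(out$correlation, r_hand, tolerance = 1e-10)
  expect_equal(out$percentage, 100 * r_hand, tolerance = 1e-8)
  # zero variance -> null with reason
  const <- matrix(1, 50, 3)
  expect_true(is.na(dynamics_correlation(a, const)$correlation))
})
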