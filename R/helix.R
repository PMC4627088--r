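#' Fiber-model helix parameters for ideal B-DNA
#'
#' Cylindrical placement parameters for the three coarse-grained sites of
#' each nucleotide. Strand 1 places site `s` of base pair `i` at azimuth
#' `(i-1)*twist + phi_s` and height `(i-1)*rise + z_s`; strand 2 uses the
#' dyad-mirrored placement `(i-1)*twist - phi_s`, `(i-1)*rise - z_s`. Base
#' beads sit at `phi = 90` degrees so that base-pair centers fall exactly
#' on the helix axis.
#'
#' The phosphate azimuth and axial offsets are calibrated once (see
#' [calibrate_helix_params()]) so that the cross-strand phosphate-phosphate
#' distances at the groove registers reproduce the rigid B-DNA groove
#' widths of 17.25 A (major) and 11.58 A (minor).
#'
#' @param twist helical twist, degrees per base pair.
#' @param rise helical rise, Angstrom per base pair.
#' @param calibrated use the stored groove-calibrated phosphate placement
#'   (default). With `FALSE`, the uncalibrated seed placement is returned.
#' @return an object of class `helix_params`: a list with `twist`, `rise`,
#'   per-site cylindrical placements `p`, `s`, `b` (each `r`, `phi`
#'   (degrees), `z`), and groove registers `k_major`, `k_minor`.
#' @export
helix_params <- function(twist = 36.0, rise = 3.38, calibrated = TRUE) {
  hp <- list(
    twist = twist, rise = rise,
    p = c(r = 8.91, phi = 94.0, z = 2.19),
    s = c(r = 6.29, phi = 112.0, z = 3.88),
    b = c(r = 2.40, phi = 90.0, z = 0.0),
    k_major = -3L, k_minor = 4L
  )
  class(hp) <- "helix_params"
  if (calibrated) hp <- calibrate_helix_params(hp)
  hp
}

#' Cross-strand phosphate-phosphate distance at a groove register
#'
#' Closed-form distance between the phosphate of base pair `i` on strand 1
#' and the phosphate of base pair `i + k` on strand 2 of the ideal duplex,
#' which is independent of `i` by helical symmetry.
#'
#' @param k integer register offset.
#' @param hp a `helix_params` object.
#' @return distance in Angstrom.
#' @export
register_pp_distance <- function(k, hp) {
  rp <- hp$p[["r"]]; phip <- hp$p[["phi"]]; zp <- hp$p[["z"]]
  dphi <- (k * hp$twist - 2 * phip) * pi / 180
  dz <- k * hp$rise - 2 * zp
  sqrt(2 * rp^2 * (1 - cos(dphi)) + dz^2)
}

#' Calibrate phosphate placement against rigid B-DNA groove widths
#'
#' Solves for the phosphate azimuth and axial offset such that the
#' cross-strand phosphate distances at the major and minor groove
#' registers equal the target rigid-B-DNA groove widths. The sugar
#' placement is then re-derived so that the two backbone bonds
#' (P(i)-S(i) and S(i)-P(i+1)) keep their design length.
#'
#' @param hp seed `helix_params`.
#' @param w_major,w_minor target groove widths (A).
#' @param backbone_bond design length for the two backbone P-S bonds (A).
#' @param tol convergence tolerance on groove widths (A).
#' @return calibrated `helix_params` with attribute `calibration` holding
#'   the achieved widths.
#' @export
calibrate_helix_params <- function(hp, w_major = 17.25, w_minor = 11.58,
                                   backbone_bond = 3.9, tol = 1e-10) {
  km <- hp$k_major; kn <- hp$k_minor
  fn <- function(par) {
    h2 <- hp; h2$p[["phi"]] <- par[1]; h2$p[["z"]] <- par[2]
    c(register_pp_distance(km, h2) - w_major,
      register_pp_distance(kn, h2) - w_minor)
  }
  par <- c(hp$p[["phi"]], hp$p[["z"]])
  for (it in 1:60) {
    f0 <- fn(par)
    if (max(abs(f0)) < tol) break
    # numerical Jacobian, 2x2 Newton step
    h <- 1e-6
    J <- cbind((fn(par + c(h, 0)) - f0) / h, (fn(par + c(0, h)) - f0) / h)
    par <- par - solve(J, f0)
  }
  hp$p[["phi"]] <- par[1]; hp$p[["z"]] <- par[2]

  # re-derive sugar radius on the symmetric backbone placement:
  # S sits half a step (twist/2, rise/2) beyond P along the strand
  phis <- hp$p[["phi"]] + hp$twist / 2
  zs <- hp$p[["z"]] + hp$rise / 2
  rp <- hp$p[["r"]]
  cosd <- cos((hp$twist / 2) * pi / 180)
  dz2 <- (hp$rise / 2)^2
  # rs^2 - 2 rp cosd rs + (rp^2 + dz2 - bond^2) = 0, take inner root
  disc <- (2 * rp * cosd)^2 - 4 * (rp^2 + dz2 - backbone_bond^2)
  if (disc <= 0) stop("no sugar placement for requested backbone bond length")
  rs <- (2 * rp * cosd - sqrt(disc)) / 2
  hp$s <- c(r = rs, phi = phis, z = zs)

  achieved <- c(major = register_pp_distance(km, hp),
                minor = register_pp_distance(kn, hp))
  if (max(abs(achieved - c(w_major, w_minor))) > 1e-6)
    stop("groove calibration failed to converge")
  attr(hp, "calibration") <- achieved
  hp
}
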