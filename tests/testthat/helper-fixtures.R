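# Shared fixtures and independent oracles for the test suite.

make_tube <- function(n_residues = 8L, n_unimers = 8L, spacing = 4.85,
                      radius = 4.0, amide_offset = 0.5) {
  stack_rings(build_ring(n_residues, radius, amide_offset),
              n_unimers, spacing)
}

make_octamer <- function() make_tube(8L, 8L)

# Brute-force hydrogen-bond oracle: a plain scan over every donor and
# every acceptor oxygen on ANY other ring (no adjacency shortcut), with
# the same geometric criteria and one-bond-per-donor closest-acceptor
# rule. Kept deliberately naive and loop-based, independent of the
# package's vectorized candidate-pair machinery.
brute_force_hbonds <- function(xyz, atoms, d_max = 3.5, theta_min = 120) {
  res_key <- paste(atoms$ring, atoms$residue)
  iN <- which(atoms$atom == "N")
  iO <- which(atoms$atom == "O")
  out <- NULL
  for (d in iN) {
    h <- which(atoms$atom == "H" & res_key == res_key[d])
    best <- NULL
    for (a in iO) {
      if (atoms$ring[a] == atoms$ring[d]) next  # intermolecular only
      dNO <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dNO > d_max) next
      u <- xyz[d, ] - xyz[h, ]
      v <- xyz[a, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang < theta_min) next
      cand <- list(a = a, d = dNO)
      if (is.null(best) || cand$d < best$d ||
          (cand$d == best$d &&
           (atoms$residue[cand$a] < atoms$residue[best$a] ||
            (atoms$residue[cand$a] == atoms$residue[best$a] &&
             atoms$ring[cand$a] < atoms$ring[best$a]))))
        best <- cand
    }
    if (!is.null(best))
      out <- rbind(out, data.frame(
        donor_ring = atoms$ring[d], donor_res = atoms$residue[d],
        acceptor_ring = atoms$ring[best$a],
        acceptor_res = atoms$residue[best$a]))
  }
  if (is.null(out))
    out <- data.frame(donor_ring = integer(), donor_res = integer(),
                      acceptor_ring = integer(), acceptor_res = integer())
  out[order(out$donor_ring, out$donor_res), , drop = FALSE]
}

# Canonical sortable bond keys for set comparison.
bond_keys <- function(rec)
  sort(paste0(rec$donor_ring, ".", rec$donor_res, ">",
              rec$acceptor_ring, ".", rec$acceptor_res))

# Orientation-averaged SOLID cylinder intensity via adaptive quadrature:
# an independent reference for the contrast-matched shell limit.
solid_cylinder_intensity <- function(q, R, L, contrast, scale, background,
                                     V_norm) {
  V <- pi * R^2 * L
  vapply(q, function(qi) {
    f2 <- function(a) {
      x1 <- qi * (L / 2) * cos(a)
      x2 <- qi * R * sin(a)
      j0 <- ifelse(abs(x1) < 1e-8, 1, sin(x1) / x1)
      lam <- ifelse(abs(x2) < 1e-8, 1, 2 * besselJ(abs(x2), 1) / abs(x2))
      (contrast * V * j0 * lam)^2 * sin(a)
    }
    1e-4 * scale / V_norm *
      stats::integrate(f2, 0, pi / 2, rel.tol = 1e-10)$value + background
  }, numeric(1))
}

# Random rigid-body transform (rotation from QR of a Gaussian matrix).
random_rigid_transform <- function(seed) {
  withr::with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    list(R = R, t = stats::runif(3, -20, 20))
  })
}
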