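# Synthetic condensed-phase water boxes with analytic dipole surfaces.
#
# Everything the labelling / training / spectrum loop needs can be exercised
# without electronic-structure code: periodic boxes of rigid-geometry water
# molecules, a harmonic intramolecular force field with a repulsive O-O core,
# and two analytic total-dipole models whose atomic polar tensors have closed
# forms. The toy dipole is deliberately single-valued (absolute positions,
# per-molecule charge neutrality), sidestepping the branch bookkeeping that
# periodic first-principles dipoles require.
#
# Force-field constants are documented package constants chosen to place the
# O-H stretch fundamentals near 3600 cm^-1 and the bend near 1600 cm^-1 so
# that sampling-theorem logic and spectral windows are exercised at realistic
# wavenumbers; they are not claims about real water.

.water_geom <- list(r0 = 0.9572, theta0 = 104.52 * pi / 180,
                    massO = 15.999, massH = 1.008, molMass = 18.015)

#' Toy total-dipole models for water boxes
#'
#' \code{variant = "fixed"}: fixed point charges (SPC-like, qH = 0.41 e);
#' the dipole is linear in positions and every APT is exactly q_i times the
#' identity.
#'
#' \code{variant = "fluctuating"}: the charges respond smoothly to geometry.
#' Each O-H bond stretch shifts charge between the H and its O
#' (\code{chargeResponse}, e/Angstrom), and each O acquires an
#' environment-dependent term from neighboring O atoms through a smooth
#' compactly supported kernel (\code{polarization}, e), compensated by its
#' own two H atoms so every molecule stays neutral. The environmental term
#' emulates condensed-phase polarization: an atom's polar tensor then depends
#' on molecules beyond its own, as it does for first-principles dipoles.
#' Closed-form APTs including all charge-gradient terms are available via
#' \code{\link{makeDipoleBackend}}.
#'
#' @param variant "fluctuating" (default) or "fixed".
#' @param qH hydrogen base charge, e (O carries -2 qH).
#' @param chargeResponse bond charge-flow coefficient, e/Angstrom.
#' @param polarization environmental charge coefficient, e (0 disables).
#' @param polarizationCutoff support radius of the O-O kernel, Angstrom.
#' @return a named list describing the model.
#' @export
toyDipoleModel <- function(variant = c("fluctuating", "fixed"), qH = 0.41,
                           chargeResponse = 0.40, polarization = 0.03,
                           polarizationCutoff = 5.5) {
  variant <- match.arg(variant)
  list(variant = variant, qH = qH, qO = -2 * qH,
       cb = if (variant == "fixed") 0 else chargeResponse,
       cp = if (variant == "fixed") 0 else polarization,
       rp = polarizationCutoff, d0 = .water_geom$r0)
}

# molecule bookkeeping: atoms are ordered O,H,H per molecule
.molecules <- function(species) {
  n <- length(species)
  .stop_if(n %% 3 != 0 ||
             !all(species == rep(c("O", "H", "H"), n / 3)),
           "expected water topology: atoms ordered O,H,H per molecule")
  nm <- n / 3L
  list(nMol = nm, O = 3L * seq_len(nm) - 2L,
       H1 = 3L * seq_len(nm) - 1L, H2 = 3L * seq_len(nm))
}

# polarization kernel and derivative: smooth, compact support
.polar_kernel <- function(d, rp) {
  x2 <- (d / rp)^2
  g <- ifelse(d < rp, (1 - x2)^3, 0)
  dg <- ifelse(d < rp, -6 * d / rp^2 * (1 - x2)^2, 0)
  list(g = g, dg = dg)
}

# per-atom charges of a toy model; also returns bond geometry reused by the
# analytic tensors
.toy_charges <- function(model, config) {
  mol <- .molecules(config@species)
  pos <- config@positions
  q <- numeric(nAtoms(config))
  q[mol$O] <- model$qO; q[mol$H1] <- model$qH; q[mol$H2] <- model$qH
  b1 <- pos[mol$H1, , drop = FALSE] - pos[mol$O, , drop = FALSE]
  b2 <- pos[mol$H2, , drop = FALSE] - pos[mol$O, , drop = FALSE]
  d1 <- sqrt(rowSums(b1^2)); d2 <- sqrt(rowSums(b2^2))
  if (model$cb != 0) {
    q[mol$H1] <- q[mol$H1] + model$cb * (d1 - model$d0)
    q[mol$H2] <- q[mol$H2] + model$cb * (d2 - model$d0)
    q[mol$O] <- q[mol$O] - model$cb * (d1 - model$d0 + d2 - model$d0)
  }
  pol <- NULL
  if (model$cp != 0 && mol$nMol > 1L) {
    # the kernel support must stay inside the Wigner-Seitz cell: beyond half
    # the cell height the minimum-image distance is not differentiable, which
    # would break the backend smoothness contract in small boxes
    rpEff <- if (!is.null(config@cell))
      min(model$rp, 0.495 * min(.cell_heights(config@cell))) else model$rp
    oo <- .oo_pairs(pos[mol$O, , drop = FALSE], config@cell, rpEff)
    if (nrow(oo$pairs)) {
      kern <- .polar_kernel(oo$dist, rpEff)
      polSum <- as.numeric(.rowsum_full(
        cbind(c(kern$g, kern$g)), c(oo$pairs[, 1], oo$pairs[, 2]), mol$nMol))
      q[mol$O] <- q[mol$O] + model$cp * polSum
      q[mol$H1] <- q[mol$H1] - model$cp * polSum / 2
      q[mol$H2] <- q[mol$H2] - model$cp * polSum / 2
      pol <- list(oo = oo, kern = kern)
    }
  }
  list(q = q, mol = mol, b1 = b1, b2 = b2, d1 = d1, d2 = d2, pol = pol)
}

# minimum-image distances from each row of `pts` to the single row `ref`
.mi_dist <- function(pts, ref, cell) {
  d <- sweep(pts, 2, as.numeric(ref), "-")
  d <- .min_image(d, cell)
  sqrt(rowSums(d^2))
}

# O-O pairs within a cutoff (minimum image when periodic)
.oo_pairs <- function(posO, cell, cutoff) {
  nm <- nrow(posO)
  idx <- which(upper.tri(matrix(0, nm, nm)), arr.ind = TRUE)
  d <- posO[idx[, 2], , drop = FALSE] - posO[idx[, 1], , drop = FALSE]
  if (!is.null(cell)) d <- .min_image(d, cell)
  r <- sqrt(rowSums(d^2))
  keep <- r < cutoff
  list(pairs = idx[keep, , drop = FALSE],
       disp = d[keep, , drop = FALSE], dist = r[keep])
}

#' Create a dipole backend for a toy model
#'
#' The backend evaluates M = sum_i q_i(geometry) r_i and carries the
#' closed-form atomic polar tensors (including all charge-gradient
#' contributions) so it can serve both as a labelling backend and as the
#' exact oracle for the finite-difference path. For the fixed-charge variant
#' the tensor of atom i is exactly q_i times the identity.
#'
#' @param model a \code{\link{toyDipoleModel}}.
#' @return a \linkS4class{DipoleBackend} with analytic capability.
#' @export
makeDipoleBackend <- function(model) {
  evalM <- function(config) {
    ch <- .toy_charges(model, config)
    as.numeric(crossprod(config@positions, ch$q))
  }
  # atomIndex = NULL returns the whole 3 x 3 x n array (bulk path)
  aptOne <- function(config, atomIndex = NULL) {
    P <- .toy_apts(model, config)
    if (is.null(atomIndex)) P else P[, , atomIndex]
  }
  dipoleBackend(evalM, name = paste0("toy-", model$variant), aptFun = aptOne)
}

# closed-form polar tensors of the toy dipole for all atoms
.toy_apts <- function(model, config) {
  ch <- .toy_charges(model, config)
  mol <- ch$mol
  n <- nAtoms(config)
  P <- array(0, c(3, 3, n))
  P[1, 1, ] <- ch$q; P[2, 2, ] <- ch$q; P[3, 3, ] <- ch$q
  if (model$cb != 0) {
    u1 <- ch$b1 / ch$d1; u2 <- ch$b2 / ch$d2
    for (a in 1:3) for (b in 1:3) {
      o1 <- model$cb * ch$d1 * u1[, a] * u1[, b]
      o2 <- model$cb * ch$d2 * u2[, a] * u2[, b]
      P[a, b, mol$H1] <- P[a, b, mol$H1] + o1
      P[a, b, mol$H2] <- P[a, b, mol$H2] + o2
      P[a, b, mol$O] <- P[a, b, mol$O] - o1 - o2
    }
  }
  if (!is.null(ch$pol)) {
    pos <- config@positions
    # molecule-internal lever arm: r_O minus the mean of its H positions
    w <- pos[mol$O, , drop = FALSE] -
      (pos[mol$H1, , drop = FALSE] + pos[mol$H2, , drop = FALSE]) / 2
    oo <- ch$pol$oo; kern <- ch$pol$kern
    e21 <- -oo$disp / oo$dist                  # unit vectors r_O(m1)-r_O(m2)
    s <- model$cp * kern$dg
    lever <- w[oo$pairs[, 1], , drop = FALSE] + w[oo$pairs[, 2], , drop = FALSE]
    for (a in 1:3) for (b in 1:3) {
      contrib <- s * lever[, a] * e21[, b]
      acc <- as.numeric(.rowsum_full(cbind(c(contrib, -contrib)),
                                     c(oo$pairs[, 1], oo$pairs[, 2]),
                                     mol$nMol))
      P[a, b, mol$O] <- P[a, b, mol$O] + acc
    }
  }
  P
}

#' Generate a periodic water box
#'
#' Places \code{nMolecules} rigid-geometry water molecules (O-H 0.9572
#' Angstrom, H-O-H 104.52 degrees) with random orientations on a jittered
#' cubic sublattice inside a cubic cell sized from the target density, and
#' rejects placements whose minimum-image O-O distance falls below 2.5
#' Angstrom. Deterministic for a given seed.
#'
#' @param nMolecules number of water molecules (>= 1).
#' @param density g/cm^3 (default 0.997, ambient liquid water).
#' @param seed integer seed.
#' @param maxAttempts packing retries before giving up.
#' @return an \linkS4class{AtomicConfiguration} (3 nMolecules atoms).
#' @examples
#' box <- generateWaterBox(8, seed = 1)
#' nAtoms(box)   # 24
#' @export
generateWaterBox <- function(nMolecules, density = 0.997, seed = 1L,
                             maxAttempts = 200L) {
  .stop_if(nMolecules < 1L, "nMolecules must be >= 1")
  .stop_if(density <= 0, "density must be positive")
  massG <- nMolecules * .water_geom$molMass * 1.66053906660e-24
  L <- (massG / density)^(1 / 3) * 1e8            # cm -> Angstrom
  cell <- diag(L, 3)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(seed, "box"))
  nside <- ceiling(nMolecules^(1 / 3))
  allSites <- (as.matrix(expand.grid(0:(nside - 1), 0:(nside - 1),
                                     0:(nside - 1))) + 0.5) * (L / nside)
  # fill even-parity (checkerboard) sites first so partially filled lattices
  # keep face-diagonal rather than edge spacings between occupied sites
  if (nMolecules < nrow(allSites)) {
    idxGrid <- as.matrix(expand.grid(0:(nside - 1), 0:(nside - 1),
                                     0:(nside - 1)))
    parity <- rowSums(idxGrid) %% 2
    sites <- allSites[order(parity), , drop = FALSE][seq_len(nMolecules), ,
                                                     drop = FALSE]
  } else sites <- allSites
  # jitter amplitude that provably preserves the 2.5 A O-O floor
  if (nMolecules > 1L) {
    oo0 <- .oo_pairs(sites, cell, Inf)
    dminSites <- min(oo0$dist)
    .stop_if(dminSites <= 2.5, sprintf(
      paste0("failed to pack %d molecules at %.3f g/cm^3: occupied lattice ",
             "sites are only %.2f A apart; reduce the density"),
      nMolecules, density, dminSites))
    jitterAmp <- min(0.28 * (dminSites - 2.5), 0.12 * L / nside)
  } else jitterAmp <- 0.12 * L / nside
  geom <- .water_geom
  half <- geom$theta0 / 2
  template <- rbind(c(0, 0, 0),
                    geom$r0 * c(sin(half), cos(half), 0),
                    geom$r0 * c(-sin(half), cos(half), 0))
  for (attempt in seq_len(maxAttempts)) {
    jitter <- matrix(stats::runif(3 * nMolecules, -jitterAmp, jitterAmp),
                     nMolecules, 3)
    centers <- sites + jitter
    pos <- matrix(0, 3 * nMolecules, 3)
    for (m in seq_len(nMolecules)) {
      R <- randomRotation()
      blk <- template %*% t(R)
      pos[(3 * m - 2):(3 * m), ] <- sweep(blk, 2, centers[m, ], "+")
    }
    if (nMolecules == 1L) break
    oo <- .oo_pairs(pos[3 * seq_len(nMolecules) - 2L, , drop = FALSE],
                    cell, 2.5)
    if (nrow(oo$pairs) == 0L) break
    .stop_if(attempt == maxAttempts, sprintf(
      paste0("failed to pack %d molecules at %.3f g/cm^3 after %d attempts; ",
             "reduce the density"), nMolecules, density, maxAttempts))
  }
  atomicConfiguration(rep(c("O", "H", "H"), nMolecules), pos, cell = cell,
                      id = sprintf("waterbox-n%d-seed%d", nMolecules, seed))
}

#' Harmonic intramolecular water force field
#'
#' Harmonic O-H bonds and H-O-H angle plus a purely repulsive (WCA-form)
#' O-O core that keeps molecules from interpenetrating. Energies are in
#' amu Angstrom^2 fs^-2. The default bond constant places the O-H stretch
#' fundamentals near 3600 cm^-1 and the angle constant the bend near
#' 1600 cm^-1.
#'
#' @param kBond bond force constant, amu/fs^2.
#' @param kAngle angle force constant, amu Angstrom^2 fs^-2 rad^-2.
#' @param r0 equilibrium bond length, Angstrom.
#' @param theta0 equilibrium angle, rad.
#' @param wcaEpsilon repulsive core strength, amu Angstrom^2 fs^-2 (0
#'   disables the intermolecular term).
#' @param wcaSigma core diameter, Angstrom.
#' @return a named list describing the force field.
#' @export
waterForceField <- function(kBond = 0.44, kAngle = 0.039,
                            r0 = .water_geom$r0,
                            theta0 = .water_geom$theta0,
                            wcaEpsilon = 6.5e-5, wcaSigma = 3.166) {
  list(kBond = kBond, kAngle = kAngle, r0 = r0, theta0 = theta0,
       wcaEpsilon = wcaEpsilon, wcaSigma = wcaSigma)
}

# potential energy and analytic forces (amu A^2/fs^2, amu A/fs^2)
.ff_forces <- function(ff, pos, species, cell) {
  mol <- .molecules(species)
  F <- matrix(0, nrow(pos), 3)
  E <- 0
  b1 <- pos[mol$H1, , drop = FALSE] - pos[mol$O, , drop = FALSE]
  b2 <- pos[mol$H2, , drop = FALSE] - pos[mol$O, , drop = FALSE]
  d1 <- sqrt(rowSums(b1^2)); d2 <- sqrt(rowSums(b2^2))
  u1 <- b1 / d1; u2 <- b2 / d2
  # bonds
  f1 <- ff$kBond * (d1 - ff$r0); f2 <- ff$kBond * (d2 - ff$r0)
  E <- E + 0.5 * sum(f1 * (d1 - ff$r0)) + 0.5 * sum(f2 * (d2 - ff$r0))
  F[mol$H1, ] <- F[mol$H1, ] - f1 * u1
  F[mol$H2, ] <- F[mol$H2, ] - f2 * u2
  F[mol$O, ] <- F[mol$O, ] + f1 * u1 + f2 * u2
  # angles
  cosT <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(u1 * u2)))
  th <- acos(cosT); sinT <- sqrt(1 - cosT^2)
  dE <- ff$kAngle * (th - ff$theta0)
  E <- E + 0.5 * sum(dE * (th - ff$theta0))
  g1 <- (cosT * u1 - u2) / (d1 * sinT)   # dtheta/dr_H1
  g2 <- (cosT * u2 - u1) / (d2 * sinT)
  F[mol$H1, ] <- F[mol$H1, ] - dE * g1
  F[mol$H2, ] <- F[mol$H2, ] - dE * g2
  F[mol$O, ] <- F[mol$O, ] + dE * (g1 + g2)
  # repulsive O-O core
  if (ff$wcaEpsilon > 0 && mol$nMol > 1L) {
    rc <- 2^(1 / 6) * ff$wcaSigma
    oo <- .oo_pairs(pos[mol$O, , drop = FALSE], cell, rc)
    if (nrow(oo$pairs)) {
      sr6 <- (ff$wcaSigma / oo$dist)^6
      E <- E + sum(4 * ff$wcaEpsilon * (sr6^2 - sr6) + ff$wcaEpsilon)
      fmag <- 24 * ff$wcaEpsilon * (2 * sr6^2 - sr6) / oo$dist
      fo <- fmag * (oo$disp / oo$dist)         # from O(m1) toward O(m2)
      F[mol$O, ] <- F[mol$O, ] + .rowsum_full(
        rbind(-fo, fo), c(oo$pairs[, 1], oo$pairs[, 2]), mol$nMol)
    }
  }
  list(E = E, F = F)
}

.atom_masses <- function(species) {
  m <- .atomic_masses[species]
  .stop_if(anyNA(m), "unknown species in mass table")
  as.numeric(m)
}

#' Normal modes from the force-field Hessian
#'
#' Hessian by central differences of the analytic forces (step 1e-4
#' Angstrom), mass-weighted and diagonalised. Negative-curvature modes are
#' reported as negative wavenumbers.
#'
#' @param config an \linkS4class{AtomicConfiguration} (water topology).
#' @param ff a \code{\link{waterForceField}}.
#' @return \code{normalModes}: list with \code{wavenumbers} (3N values,
#'   cm^-1, decreasing) and \code{displacements} (list of n x 3 Cartesian
#'   displacement patterns, one per mode).
#' @export
normalModes <- function(config, ff = waterForceField()) {
  pos <- config@positions
  n <- nrow(pos)
  h <- 1e-4
  H <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) for (x in 1:3) {
    pp <- pos; pp[a, x] <- pp[a, x] + h
    fp <- .ff_forces(ff, pp, config@species, config@cell)$F
    pp[a, x] <- pos[a, x] - h
    fm <- .ff_forces(ff, pp, config@species, config@cell)$F
    H[, 3 * (a - 1) + x] <- -as.vector(t(fp - fm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  invSqrtM <- rep(1 / sqrt(.atom_masses(config@species)), each = 3)
  D <- H * tcrossprod(invSqrtM)
  eg <- eigen(D, symmetric = TRUE)
  wn <- sign(eg$values) * sqrt(abs(eg$values)) / (2 * pi * .const$c_cmfs)
  disp <- lapply(seq_len(3 * n), function(k)
    matrix(eg$vectors[, k] * invSqrtM, n, 3, byrow = TRUE))
  list(wavenumbers = wn, displacements = disp)
}

#' @rdname normalModes
#' @return \code{normalModeWavenumbers}: the wavenumbers only.
#' @export
normalModeWavenumbers <- function(config, ff = waterForceField())
  normalModes(config, ff)$wavenumbers

#' Generate a molecular-dynamics trajectory of a water box
#'
#' Velocity-Verlet integration of the toy force field, with
#' Maxwell-Boltzmann initial velocities at the requested temperature (net
#' momentum removed) and exact integrator velocities stored on every frame.
#' Also reports the normal-mode wavenumbers of the starting configuration
#' (from the analytic-force Hessian) and the relative energy drift of the
#' run. A timestep too large for the stiffest mode aborts immediately.
#'
#' @param config starting \linkS4class{AtomicConfiguration}.
#' @param ff a \code{\link{waterForceField}}.
#' @param dt timestep, fs.
#' @param nSteps number of integration steps (the trajectory has nSteps + 1
#'   frames).
#' @param temperature initial-velocity temperature, K (0 = static start).
#' @param seed integer seed.
#' @param modes compute the starting Hessian's mode wavenumbers? (skippable
#'   for large boxes).
#' @param initialVelocities optional n x 3 matrix (Angstrom/fs) overriding
#'   the Maxwell-Boltzmann draw, e.g. to excite a single normal mode.
#' @param keepEvery store every k-th frame only (default 1 = all frames;
#'   the integration step is unchanged, so large boxes can be sampled
#'   sparsely without holding the full trajectory in memory). The returned
#'   trajectory's timestep is \code{dt * keepEvery}.
#' @return list with \code{trajectory} (a \linkS4class{Trajectory} with
#'   velocities), \code{modeWavenumbers} (or NULL) and \code{energyDrift}
#'   (relative, first-decile vs last-decile mean total energy).
#' @export
generateTrajectory <- function(config, ff = waterForceField(), dt = 0.25,
                               nSteps = 1000L, temperature = 300,
                               seed = 1L, modes = FALSE,
                               initialVelocities = NULL, keepEvery = 1L) {
  keepEvery <- as.integer(keepEvery)
  .stop_if(keepEvery < 1L, "keepEvery must be >= 1")
  # stiffest mode estimate: O-H stretch against the light H
  omegaMax <- sqrt(ff$kBond / (1 / (1 / .water_geom$massH +
                                      1 / .water_geom$massO)))
  .stop_if(omegaMax * dt >= 1.8, sprintf(
    paste0("dt = %g fs is unstable for the stiffest mode (omega = %.3f ",
           "rad/fs, stability requires omega dt < 2); reduce dt"),
    dt, omegaMax))
  pos <- config@positions
  n <- nrow(pos)
  mass <- .atom_masses(config@species)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(seed, "velocities"))
  vel <- if (!is.null(initialVelocities)) {
    stopifnot(is.matrix(initialVelocities),
              all(dim(initialVelocities) == c(n, 3L)))
    initialVelocities
  } else if (temperature > 0) {
    sd_ <- sqrt(.const$kB_int * temperature / mass)
    v <- matrix(stats::rnorm(3 * n), n, 3) * sd_
    sweep(v, 2, colSums(v * mass) / sum(mass), "-")   # remove net momentum
  } else matrix(0, n, 3)
  fr <- .ff_forces(ff, pos, config@species, config@cell)
  acc <- fr$F / mass
  nKeep <- nSteps %/% keepEvery + 1L
  frames <- vector("list", nKeep)
  vels <- vector("list", nKeep)
  energy <- numeric(nSteps + 1L)
  frames[[1L]] <- initialize(config, positions = pos,
                             id = sprintf("%s-t0", config@id))
  vels[[1L]] <- vel
  energy[1L] <- fr$E + 0.5 * sum(mass * rowSums(vel^2))
  for (s in seq_len(nSteps)) {
    pos <- pos + vel * dt + 0.5 * acc * dt^2
    fr <- .ff_forces(ff, pos, config@species, config@cell)
    accNew <- fr$F / mass
    vel <- vel + 0.5 * (acc + accNew) * dt
    acc <- accNew
    eTot <- fr$E + 0.5 * sum(mass * rowSums(vel^2))
    .stop_if(!is.finite(eTot) || (s > 10 && abs(eTot) >
               100 * (abs(energy[1L]) + 1e-8)), sprintf(
      paste0("integration unstable at step %d (dt = %g fs, stiffest mode ",
             "%.3f rad/fs): energy blow-up"), s, dt, omegaMax))
    if (s %% keepEvery == 0L) {
      frames[[s %/% keepEvery + 1L]] <-
        initialize(config, positions = pos,
                   id = sprintf("%s-t%d", config@id, s))
      vels[[s %/% keepEvery + 1L]] <- vel
    }
    energy[s + 1L] <- eTot
  }
  dec <- max(2L, floor((nSteps + 1L) / 10))
  drift <- abs(mean(energy[seq_len(dec)]) -
                 mean(energy[(nSteps + 2L - dec):(nSteps + 1L)])) /
    max(abs(mean(energy[seq_len(dec)])), 1e-12)
  list(trajectory = trajectory(frames, dt = dt * keepEvery,
                               velocities = vels),
       modeWavenumbers = if (modes) normalModeWavenumbers(config, ff)
                         else NULL,
       energyDrift = drift, energies = energy)
}

#' Build a labelled APT dataset from synthetic water trajectories
#'
#' Runs a short equilibration followed by decorrelated sampling of
#' configurations from a toy-water trajectory, then labels every snapshot
#' with atomic polar tensors: analytic closed forms by default, or the
#' central-finite-difference path (\code{labels = "fd"}).
#'
#' @param nConfigs number of snapshots to label.
#' @param nMolecules water molecules per snapshot.
#' @param model a \code{\link{toyDipoleModel}}.
#' @param ff a \code{\link{waterForceField}}.
#' @param seed integer seed.
#' @param labels "analytic" or "fd".
#' @param noise optional Gaussian label-noise amplitude (e) added to every
#'   tensor component; recorded in the \code{"labelNoise"} attribute of the
#'   returned dataset.
#' @param dt integration timestep, fs.
#' @param equilibration burn-in, fs.
#' @param decorrelation sampling stride, fs.
#' @param temperature K.
#' @param h finite-difference displacement when \code{labels = "fd"}.
#' @return an \linkS4class{APTDataset} (split labels "none").
#' @export
makeLabelledDataset <- function(nConfigs, nMolecules,
                                model = toyDipoleModel(),
                                ff = waterForceField(), seed = 1L,
                                labels = c("analytic", "fd"), noise = 0,
                                dt = 0.5, equilibration = 100,
                                decorrelation = 200, temperature = 300,
                                h = 0.01) {
  labels <- match.arg(labels)
  box <- generateWaterBox(nMolecules, seed = seed)
  stride <- max(1L, round(decorrelation / dt))
  equilStrides <- ceiling(equilibration / decorrelation)
  nSteps <- (equilStrides + nConfigs) * stride
  # only sampled frames are kept in memory; the integration step is dt
  run <- generateTrajectory(box, ff, dt = dt, nSteps = nSteps,
                            temperature = temperature, seed = seed,
                            keepEvery = stride)
  take <- equilStrides + seq_len(nConfigs)
  backend <- makeDipoleBackend(model)
  configs <- vector("list", nConfigs); aptsL <- vector("list", nConfigs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(seed, "label-noise"))
  for (k in seq_len(nConfigs)) {
    cfg <- run$trajectory@frames[[take[k] + 1L]]
    cfg <- initialize(cfg, id = sprintf("synth-%d-%d", seed, k))
    tens <- if (labels == "analytic") .toy_apts(model, cfg) else
      computeAPTConfig(cfg, backend, fdSettings(h))@tensors
    if (noise > 0)
      tens <- tens + array(stats::rnorm(length(tens), sd = noise),
                           dim(tens))
    configs[[k]] <- cfg
    aptsL[[k]] <- aptFrame(tens, configId = cfg@id)
  }
  ds <- aptDataset(configs, aptsL)
  attr(ds, "labelNoise") <- noise
  ds
}
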