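# Dipole velocities, correlation functions and IR spectra.

test_that("dipole velocity contracts: identity tensor, zeros, shapes", {
  apts <- list(aptFrame(array(diag(0.41, 3), c(3, 3, 1))),
               aptFrame(array(diag(0.41, 3), c(3, 3, 1))))
  vel <- list(matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1))
  s <- dipoleVelocity(apts, vel, dt = 1)
  expect_equal(s@values[1, ], c(0.41, 0, 0))
  vel0 <- list(matrix(0, 1, 3), matrix(0, 1, 3))
  expect_error(dipoleVelocitySeries(dipoleVelocity(apts, vel0, 1)@values * 0,
                                    1), NA)
  expect_equal(max(abs(dipoleVelocity(apts, vel0, 1)@values)), 0)
  bad <- list(matrix(0, 2, 3), matrix(0, 2, 3))
  expect_error(dipoleVelocity(apts, bad, 1), "shape")
})

test_that("P v equals dM/dt along a trajectory to discretisation error", {
  fx <- fx_traj_apts()
  bk <- fx_fluct_backend()
  M <- t(vapply(frames(fx$traj), function(f) evaluateDipole(bk, f),
                numeric(3)))
  nf <- nrow(M)
  dMdt <- (M[3:nf, ] - M[1:(nf - 2), ]) / (2 * timestep(fx$traj))
  s <- dipoleVelocity(fx$apts, velocities(fx$traj), timestep(fx$traj))
  dev <- max(abs(s@values[2:(nf - 1), ] - dMdt))
  expect_lt(dev / max(abs(dMdt)), 0.01)
})

test_that("velocity reconstruction from positions is faithful", {
  # linear motion: exact at interior frames
  n <- 10
  frames_ <- lapply(seq_len(n), function(t)
    atomicConfiguration("O", matrix(c(0.1 * t, 0, 0), 1), cell = diag(50, 3)))
  tr <- trajectory(frames_, dt = 2)
  v <- velocitiesFromPositions(tr)
  expect_equal(v[[5]][1, ], c(0.05, 0, 0), tolerance = 1e-12)
  # an atom crossing the periodic boundary yields a continuous velocity
  frames_ <- lapply(seq_len(6), function(t)
    atomicConfiguration("O", matrix(c((9.7 + 0.2 * t) %% 10, 5, 5), 1),
                        cell = diag(10, 3)))
  v <- velocitiesFromPositions(trajectory(frames_, dt = 1))
  expect_equal(v[[3]][1, 1], 0.2, tolerance = 1e-12)
  # the stored integrator velocities ARE the central differences for Verlet
  fx <- fx_traj_apts()
  vfp <- velocitiesFromPositions(fx$traj)
  expect_lt(max(abs(vfp[[5]] - velocities(fx$traj)[[5]])), 1e-12)
  two <- trajectory(frames_[1:2], dt = 1)
  expect_error(velocitiesFromPositions(two), "3 frames")
})

test_that("FFT autocorrelation equals the direct lag sum", {
  set.seed(21)
  for (n in c(257, 1024, 4096)) {
    x <- dipoleVelocitySeries(matrix(rnorm(3 * n), n, 3), 1)
    a_fft <- dipoleACF(x, maxLag = min(n - 1L, 600L))
    a_dir <- dipoleACF(x, maxLag = min(n - 1L, 600L), method = "direct")
    expect_lt(max(abs(a_fft - a_dir)) / max(abs(a_dir)), 1e-10)
  }
})

test_that("closed-form autocorrelations come out right", {
  # white noise: lag-0 value is the summed component variance
  set.seed(22)
  x <- matrix(rnorm(3 * 20000), 20000, 3)
  a <- dipoleACF(dipoleVelocitySeries(x, 1), maxLag = 5)
  expect_equal(a[1], 3, tolerance = 0.05)
  expect_lt(max(abs(a[-1])), 0.05)
  # constant series: |c|^2 at every lag (biased estimator, short lags)
  cs <- dipoleVelocitySeries(matrix(rep(c(1, 2, 3), each = 500), 500, 3), 1)
  a <- dipoleACF(cs, maxLag = 3)
  expect_equal(a[1], 14)
  expect_equal(a[4], 14 * (500 - 3) / 500)
  # single cosine: (A^2/2) cos(w tau)
  t <- 0:4095
  w0 <- 2 * pi * 2.99792458e-5 * 1000
  ser <- dipoleVelocitySeries(cbind(2 * cos(w0 * t), 0, 0), 1)
  a <- dipoleACF(ser, maxLag = 100)
  expect_equal(a[1], 2, tolerance = 0.01)
  expect_equal(a[51], 2 * cos(w0 * 50), tolerance = 0.05)
})

test_that("a single cosine gives a single peak at its wavenumber", {
  t <- 0:4095
  w0 <- 2 * pi * 2.99792458e-5 * 1000
  ser <- dipoleVelocitySeries(cbind(cos(w0 * t), 0, 0), 1)
  sp <- irSpectrum(ser, settings = spectrumSettings(wavenumberMax = 4000,
                                                    gridSpacing = 1))
  expect_equal(wavenumbers(sp)[which.max(intensity(sp))], 1000)
  expect_lt(sum(intensity(sp) > 0.5), 25)   # one narrow line
})

test_that("Nyquist violations are refused with the sampling limit", {
  ser <- dipoleVelocitySeries(matrix(rnorm(300), 100, 3), dt = 4)
  expect_error(irSpectrum(ser, settings = spectrumSettings(
    wavenumberMax = 4500)), "Nyquist")
  expect_equal(nyquistInterval(3500), 1 / (2 * 2.99792458e-5 * 3500))
  expect_equal(nyquistInterval(1750), 2 * nyquistInterval(3500))
  expect_equal(nyquistInterval(2 * 977), nyquistInterval(977) / 2)
})

test_that("unwindowed spectra satisfy a Parseval identity within 1%", {
  set.seed(23)
  n <- 2048
  x <- matrix(rnorm(3 * n), n, 3)
  ser <- dipoleVelocitySeries(x, 1)
  acf_ <- dipoleACF(ser)
  nyq <- 1 / (2 * 2.99792458e-5)
  grid <- seq(0.5, nyq, by = 1)
  dens <- aptIR:::.acf_to_spectrum(acf_, 1, grid, "none")
  expect_equal(sum(dens) * 1, acf_[1], tolerance = 0.01)
})

test_that("absolute intensities carry the Beer-Lambert prefactor", {
  fx <- fx_traj_apts()
  s <- dipoleVelocity(fx$apts, velocities(fx$traj), timestep(fx$traj))
  vol <- abs(det(cellMatrix(frames(fx$traj)[[1]])))
  sp <- irSpectrum(s, irSpectrumParams(300, vol),
                   settings = spectrumSettings(wavenumberMax = 4500))
  expect_true(sp@absolute)
  expect_true(all(is.finite(intensity(sp))))
  # doubling the volume halves the intensity
  sp2 <- irSpectrum(s, irSpectrumParams(300, 2 * vol),
                    settings = spectrumSettings(wavenumberMax = 4500))
  expect_equal(intensity(sp2), intensity(sp) / 2, tolerance = 1e-12)
})

test_that("group decomposition obeys its exact sum rule", {
  fx <- fx_traj_apts()
  n <- nAtoms(fx$traj)
  sp <- species(fx$traj)
  part <- atomPartition(list(O = which(sp == "O"), H = which(sp == "H")), n)
  dec <- decomposeSpectrum(fx$apts, velocities(fx$traj), part,
                           timestep(fx$traj))
  rec <- intensity(dec$groups$O) + intensity(dec$groups$H) +
    2 * intensity(dec$cross[["O|H"]])
  expect_lt(max(abs(rec - intensity(dec$total))) /
              max(abs(intensity(dec$total))), 1e-8)
  # trivial partition reproduces the total
  all1 <- atomPartition(list(all = seq_len(n)), n)
  dec1 <- decomposeSpectrum(fx$apts, velocities(fx$traj), all1,
                            timestep(fx$traj))
  expect_equal(intensity(dec1$groups$all), intensity(dec1$total),
               tolerance = 1e-12)
  # a group with zero velocities contributes nothing
  velz <- lapply(velocities(fx$traj), function(v) { v[sp == "O", ] <- 0; v })
  decz <- decomposeSpectrum(fx$apts, velz, part, timestep(fx$traj))
  expect_lt(max(abs(intensity(decz$groups$O))), 1e-12)
  expect_lt(max(abs(intensity(decz$cross[["O|H"]]))), 1e-12)
})

test_that("projector splits must resolve the identity; overlaps are caught", {
  n <- 12
  expect_error(atomPartition(list(a = 1:8, b = 5:12), n), "disjoint")
  expect_error(atomPartition(list(a = 1:6), n), "cover")
  prj <- function(d) array(rep(diag(d), n), c(3, 3, n))
  part <- atomPartition(list(para = seq_len(n), perp = seq_len(n)), n,
                        projectors = list(para = prj(c(1, 1, 0)),
                                          perp = prj(c(0, 0, 1))))
  expect_s4_class(part, "AtomPartition")
  bad <- list(para = prj(c(1, 1, 0)), perp = prj(c(0, 1, 1)))
  expect_error(atomPartition(list(para = seq_len(n), perp = seq_len(n)), n,
                             projectors = bad), "identity")
  # the projector split still reconstructs the total
  fx <- fx_traj_apts()
  dec <- decomposeSpectrum(fx$apts, velocities(fx$traj),
                           atomPartition(list(para = seq_len(nAtoms(fx$traj)),
                                              perp = seq_len(nAtoms(fx$traj))),
                                         nAtoms(fx$traj),
                                         projectors = list(
                                           para = prj(c(1, 1, 0))[, , seq_len(nAtoms(fx$traj))],
                                           perp = prj(c(0, 0, 1))[, , seq_len(nAtoms(fx$traj))])),
                           timestep(fx$traj))
  rec <- intensity(dec$groups$para) + intensity(dec$groups$perp) +
    2 * intensity(dec$cross[["para|perp"]])
  expect_lt(max(abs(rec - intensity(dec$total))) /
              max(abs(intensity(dec$total))), 1e-8)
})

test_that("multi-trajectory spectra average the correlation functions", {
  set.seed(24)
  s1 <- dipoleVelocitySeries(matrix(rnorm(900), 300, 3), 1)
  s2 <- dipoleVelocitySeries(matrix(rnorm(900), 300, 3), 1)
  both <- irSpectrum(list(s1, s2),
                     settings = spectrumSettings(wavenumberMax = 4500))
  expect_s4_class(both, "IRSpectrum")
  expect_error(irSpectrum(list(s1, dipoleVelocitySeries(s2@values, 2))),
               "timestep")
})
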