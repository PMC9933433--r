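# The synthetic water generator: boxes, toy dipoles, dynamics.

test_that("water boxes have the requested size, density and spacing", {
  box <- generateWaterBox(8, seed = 7)
  expect_equal(nAtoms(box), 24L)
  expect_identical(species(box), rep(c("O", "H", "H"), 8))
  # cell volume from density: V = n m / rho
  L <- cellMatrix(box)[1, 1]
  expect_equal(L^3, 8 * 18.015 * 1.66053906660e-24 / 0.997 * 1e24,
               tolerance = 1e-6)
  # minimum intermolecular O-O distance above the packing floor
  oPos <- positions(box)[seq(1, 24, by = 3), ]
  oo <- aptIR:::.oo_pairs(oPos, cellMatrix(box), 2.5)
  expect_equal(nrow(oo$pairs), 0L)
  one <- generateWaterBox(1, seed = 1)
  expect_equal(nAtoms(one), 3L)
  expect_identical(positions(generateWaterBox(16, seed = 4)),
                   positions(generateWaterBox(16, seed = 4)))
})

test_that("the fixed-charge dipole has q I tensors and a zero tensor sum", {
  cfg <- fx_perturbed_box()
  bk <- fx_fixed_backend()
  expect_equal(bk@aptFun(cfg, 1), diag(-0.82, 3))
  expect_equal(bk@aptFun(cfg, 3), diag(0.41, 3))
  total <- Reduce(`+`, lapply(seq_len(nAtoms(cfg)),
                              function(a) bk@aptFun(cfg, a)))
  expect_lt(max(abs(total)), 1e-12)
})

test_that("fluctuating-charge closed forms match the numerical oracle", {
  cfg <- fx_perturbed_box()
  bk <- fx_fluct_backend()
  for (a in c(1L, 5L, 12L, 22L))
    expect_lt(max_tensor_dev(bk@aptFun(cfg, a), richardsonAPT(cfg, a, bk)),
              1e-8)
})

test_that("the toy dipole is smooth and single-valued under displacements", {
  cfg <- fx_perturbed_box()
  bk <- fx_fluct_backend()
  m0 <- evaluateDipole(bk, cfg)
  expect_identical(evaluateDipole(bk, cfg), m0)   # deterministic
  for (d in c(1e-4, 1e-3, 1e-2)) {
    p <- positions(cfg); p[7, 1] <- p[7, 1] + d
    m1 <- evaluateDipole(bk, initialize(cfg, positions = p))
    expect_lt(max(abs(m1 - m0)), 2 * d)   # no branch jumps
  }
})

test_that("molecular dynamics conserves energy and reproduces itself", {
  box <- generateWaterBox(8, seed = 2)
  run <- generateTrajectory(box, dt = 0.25, nSteps = 8000, temperature = 300,
                            seed = 2)
  expect_lt(run$energyDrift, 1e-4)
  expect_true(hasVelocities(run$trajectory))
  short1 <- generateTrajectory(box, dt = 0.25, nSteps = 400,
                               temperature = 300, seed = 2)
  short2 <- generateTrajectory(box, dt = 0.25, nSteps = 400,
                               temperature = 300, seed = 2)
  expect_identical(positions(frames(short1$trajectory)[[401]]),
                   positions(frames(short2$trajectory)[[401]]))
  expect_error(generateTrajectory(box, dt = 3), "unstable")
})

test_that("a zero-temperature start at equilibrium stays static", {
  one <- generateWaterBox(1, seed = 1)   # single molecule: no core overlap
  run <- generateTrajectory(one, dt = 0.25, nSteps = 50, temperature = 0,
                            seed = 1)
  expect_equal(max(abs(unlist(velocities(run$trajectory)))), 0)
  expect_lt(max(abs(positions(frames(run$trajectory)[[51]]) -
                      positions(one))), 1e-12)
})

test_that("exciting one normal mode produces a spectral line at its
           wavenumber", {
  one <- generateWaterBox(1, seed = 2)
  nm <- normalModes(one)
  bk <- fx_fluct_backend()
  k <- which.max(nm$wavenumbers)   # the stiffest stretch
  v0 <- nm$displacements[[k]] * 0.002 / max(abs(nm$displacements[[k]]))
  run <- generateTrajectory(one, dt = 0.25, nSteps = 6000, temperature = 0,
                            seed = 1, initialVelocities = v0)
  apts <- lapply(frames(run$trajectory), computeAPTConfig, backend = bk,
                 method = "analytic")
  s <- dipoleVelocity(apts, velocities(run$trajectory), 0.25)
  sp <- irSpectrum(s, settings = spectrumSettings(wavenumberMax = 4500,
                                                  gridSpacing = 1))
  peak <- wavenumbers(sp)[which.max(intensity(sp))]
  expect_lt(abs(peak - nm$wavenumbers[k]), 8)   # grid + integrator shift
})

test_that("the harmonic parameters place stretch and bend realistically", {
  wn <- sort(normalModeWavenumbers(generateWaterBox(1, seed = 1)),
             decreasing = TRUE)
  expect_true(all(wn[1:2] > 3400 & wn[1:2] < 3800))
  expect_true(wn[3] > 1450 & wn[3] < 1750)
  expect_lt(max(abs(wn[4:9])), 50)    # free translations/rotations
})

test_that("labelled datasets have exact counts and exact analytic labels", {
  ds <- makeLabelledDataset(4, 2, seed = 31)
  expect_equal(nRecords(ds), 4L)
  expect_equal(nTensors(ds), 4L * 6L)
  expect_equal(attr(ds, "labelNoise"), 0)
  bk <- fx_fluct_backend()
  r <- records(ds)[[2]]
  expect_identical(tensors(r$apts),
                   computeAPTConfig(r$config, bk,
                                    method = "analytic")@tensors)
})

test_that("finite-difference labels agree with analytic labels to O(h^2)", {
  dsA <- makeLabelledDataset(2, 2, seed = 32, labels = "analytic")
  dsF <- makeLabelledDataset(2, 2, seed = 32, labels = "fd", h = 0.01)
  dev <- max(vapply(1:2, function(k)
    max(abs(tensors(records(dsA)[[k]]$apts) -
              tensors(records(dsF)[[k]]$apts))), numeric(1)))
  expect_lt(dev, 5e-4)     # consistent with h^2 truncation
  expect_gt(dev, 1e-9)     # and genuinely finite-difference labelled
})
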