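# Finite-difference polar tensors against analytic oracles.

test_that("fixed charges give exactly q times the identity at any h", {
  cfg <- fx_perturbed_box()
  bk <- fx_fixed_backend()
  for (h in c(0.01, 0.2)) {
    p <- computeAPTAtom(cfg, 2, bk, fdSettings(h))   # an H atom
    expect_lt(max_tensor_dev(p, diag(0.41, 3)), 1e-12)
  }
  pO <- computeAPTAtom(cfg, 1, bk)
  expect_lt(max_tensor_dev(pO, diag(-0.82, 3)), 1e-12)
})

test_that("one atom costs exactly 6 evaluations, a config 6 per atom", {
  cfg <- fx_perturbed_box()
  bk <- makeDipoleBackend(toyDipoleModel("fixed"))
  computeAPTAtom(cfg, 1, bk)
  expect_identical(callCount(bk), 6L)
  resetCallCount(bk)
  computeAPTConfig(cfg, bk)
  expect_identical(callCount(bk), 6L * nAtoms(cfg))
})

test_that("acoustic sum rule: fixed-charge neutral system sums to zero", {
  cfg <- fx_perturbed_box()
  apts <- computeAPTConfig(cfg, fx_fixed_backend())
  expect_lt(max(abs(apply(tensors(apts), c(1, 2), sum))), 1e-10)
})

test_that("central differences converge at order 2 on the smooth backend", {
  cfg <- fx_perturbed_box()
  bk <- fx_fluct_backend()
  hs <- c(0.04, 0.02, 0.01, 0.005)
  err <- vapply(hs, function(h)
    max_tensor_dev(computeAPTAtom(cfg, 1, bk, fdSettings(h)),
                   bk@aptFun(cfg, 1)), numeric(1))
  slope <- coef(lm(log(err) ~ log(hs)))[2]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})

test_that("Richardson extrapolation reproduces the closed form to 1e-8", {
  cfg <- fx_perturbed_box()
  bk <- fx_fluct_backend()
  for (a in c(1L, 2L, 10L, 24L))
    expect_lt(max_tensor_dev(richardsonAPT(cfg, a, bk, 0.01),
                             bk@aptFun(cfg, a)), 1e-8)
})

test_that("displacement audit: zero on linear surfaces, h^2 on smooth ones", {
  cfg <- fx_perturbed_box()
  devFixed <- displacementCheck(cfg, fx_fixed_backend(), 0.01, 0.04)
  expect_lt(max(devFixed), 1e-11)
  expect_identical(displacementCheck(cfg, fx_fluct_backend(), 0.02, 0.02),
                   rep(0, nAtoms(cfg)))
  # truncation error difference scales as h2^2 - h1^2
  d1 <- max(displacementCheck(cfg, fx_fluct_backend(), 0.01, 0.02))
  d2 <- max(displacementCheck(cfg, fx_fluct_backend(), 0.01, 0.04))
  expect_equal(d2 / d1, (0.04^2 - 0.01^2) / (0.02^2 - 0.01^2),
               tolerance = 0.2)
})

test_that("labelled data transform correctly under E(3) operations", {
  cfg <- fx_perturbed_box()
  bk <- fx_fluct_backend()
  p1 <- computeAPTAtom(cfg, 4, bk)
  # translation: exactly invariant (backend is molecule-neutral)
  shifted <- initialize(cfg, positions = sweep(positions(cfg), 2,
                                               c(0.7, -1.1, 0.4), "+"))
  expect_lt(max_tensor_dev(computeAPTAtom(shifted, 4, bk), p1), 1e-12)
  # rotation: R P R^T within finite-difference tolerance
  set.seed(31)
  R <- randomRotation()
  pR <- computeAPTAtom(rotate_config(cfg, R), 4, bk)
  expect_lt(max_tensor_dev(pR, R %*% p1 %*% t(R)), 1e-4)
})

test_that("a backend failure is reported with the displaced geometry", {
  cfg <- fx_perturbed_box()
  bad <- dipoleBackend(function(c_) c(NaN, 0, 0), name = "broken")
  expect_error(computeAPTAtom(cfg, 3, bad), "atom 3")
  expect_error(computeAPTAtom(cfg, 99, fx_fixed_backend()), "range")
})
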