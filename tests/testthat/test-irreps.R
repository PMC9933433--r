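# Irreducible decomposition of rank-2 tensors.

test_that("canonical tensors decompose as expected", {
  ir <- tensorToIrreps(diag(3))
  expect_equal(ir$scalar, 1)
  expect_equal(ir$vector, c(0, 0, 0))
  expect_equal(max(abs(ir$sym)), 0)

  p <- matrix(0, 3, 3); p[1, 2] <- 1; p[2, 1] <- -1
  ir <- tensorToIrreps(p)
  expect_equal(ir$scalar, 0)
  expect_false(all(ir$vector == 0))
  expect_equal(max(abs(ir$sym)), 0)
})

test_that("decompose/recompose is the identity for random tensors", {
  set.seed(12)
  for (k in 1:20) {
    p <- matrix(rnorm(9), 3, 3)
    ir <- tensorToIrreps(p)
    expect_lt(max(abs(irrepsToTensor(ir$scalar, ir$vector, ir$sym) - p)),
              1e-14)
    # the symmetric part is traceless
    expect_lt(abs(sum(diag(ir$sym))), 1e-14)
  }
})

test_that("the parts transform as l = 0, 1, 2 representations", {
  set.seed(13)
  p <- matrix(rnorm(9), 3, 3)
  ir <- tensorToIrreps(p)
  for (k in 1:5) {
    R <- randomRotation()
    irR <- tensorToIrreps(R %*% p %*% t(R))
    expect_equal(irR$scalar, ir$scalar, tolerance = 1e-12)
    expect_equal(irR$vector, as.numeric(R %*% ir$vector), tolerance = 1e-12)
    expect_lt(max(abs(irR$sym - R %*% ir$sym %*% t(R))), 1e-12)
  }
  # under an improper rotation the axial vector picks up det(R) = -1
  R <- -diag(3)
  irI <- tensorToIrreps(R %*% p %*% t(R))
  expect_equal(irI$vector, ir$vector, tolerance = 1e-14)  # -R a = a here
})

test_that("the orthonormal 5-basis preserves Frobenius norms", {
  set.seed(14)
  s <- matrix(rnorm(9), 3, 3); s <- (s + t(s)) / 2; s <- s - diag(mean(diag(s)), 3)
  coef <- aptIR:::.sym_to_5(s)
  expect_equal(sum(coef^2), sum(s^2), tolerance = 1e-12)
  expect_lt(max(abs(aptIR:::.five_to_sym(coef) - s)), 1e-12)
})
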