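# Neighbor graphs: cutoff semantics and the minimum-image convention.

test_that("edges follow the strict distance < cutoff rule", {
  near <- atomicConfiguration(c("H", "H"), rbind(c(0, 0, 0), c(5.9, 0, 0)),
                              cell = diag(50, 3))
  far <- atomicConfiguration(c("H", "H"), rbind(c(0, 0, 0), c(6.1, 0, 0)),
                             cell = diag(50, 3))
  expect_equal(length(buildGraph(near, 6)@from), 2L)  # both directions
  expect_equal(length(buildGraph(far, 6)@from), 0L)
})

test_that("nearest contact through a periodic boundary gets the image shift", {
  cfg <- atomicConfiguration(c("H", "H"), rbind(c(0.5, 5, 5), c(9.5, 5, 5)),
                             cell = diag(10, 3))
  g <- buildGraph(cfg, 2)
  expect_equal(length(g@from), 2L)
  e12 <- which(g@from == 1L)
  expect_equal(g@disp[e12, ], c(-1, 0, 0))
  expect_equal(g@dist[e12], 1)
})

test_that("a single atom in a roomy periodic cell has no edges", {
  cfg <- atomicConfiguration("O", matrix(c(1, 1, 1), 1), cell = diag(20, 3))
  expect_equal(length(buildGraph(cfg, 6)@from), 0L)
})

test_that("minimum-image edges equal brute-force image enumeration", {
  for (seed in 1:3) {
    box <- generateWaterBox(8, seed = seed)
    g1 <- buildGraph(box, 3.0)
    g2 <- buildGraph(box, 3.0, method = "images")
    expect_identical(g1@from, g2@from)
    expect_identical(g1@to, g2@to)
    expect_lt(max(abs(g1@disp - g2@disp)), 1e-12)
  }
})

test_that("cutoffs beyond the half-cell bound are rejected with the limit", {
  box <- generateWaterBox(8, seed = 1)     # 6.2 A cell
  expect_error(buildGraph(box, 6.0), "minimum-image bound")
  # ... but the explicit-image path handles them
  g <- buildGraph(box, 6.0, method = "images")
  expect_gt(length(g@from), 0L)
})
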