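# The equivariant polar-tensor regressor: exact symmetry contracts, learning
# on analytic targets, reproducibility.

test_that("a species-constant target is fit essentially exactly", {
  # fixed charges: every APT is q_s I, a learnable species constant
  ds <- makeLabelledDataset(5, 4, model = toyDipoleModel("fixed"), seed = 8)
  ds <- splitDataset(ds, 0.8, seed = 2)
  hp <- modelHyperparams(cutoff = 2.2, seed = 1)
  m <- trainAPTModel(ds, hp, trainConfig(maxEpochs = 10, seed = 1))
  ev <- evaluateModel(m, datasetSlice(ds, "validation"))
  expect_lt(ev$rmse, 1e-3)
})

test_that("predictions are equivariant under O(3), translations, permutations", {
  m <- fx_model()
  cfg <- records(fx_dataset())[[1]]$config
  p0 <- tensors(predictAPTs(m, cfg))
  scale <- max(abs(p0))
  set.seed(42)
  for (k in 1:5) {
    R <- randomRotation(improper = k %% 2 == 0)
    pR <- tensors(predictAPTs(m, rotate_config(cfg, R)))
    dev <- max(vapply(seq_len(nAtoms(cfg)), function(a)
      max(abs(pR[, , a] - R %*% p0[, , a] %*% t(R))), numeric(1)))
    expect_lt(dev / scale, 1e-5)
  }
  shifted <- initialize(cfg, positions = sweep(positions(cfg), 2,
                                               c(1.3, -2.1, 0.7), "+"))
  expect_lt(max(abs(tensors(predictAPTs(m, shifted)) - p0)), 1e-12)
  set.seed(43)
  perm <- sample(nAtoms(cfg))
  cfgP <- atomicConfiguration(species(cfg)[perm], positions(cfg)[perm, ],
                              cell = cellMatrix(cfg), pbc = pbcFlags(cfg))
  expect_lt(max(abs(tensors(predictAPTs(m, cfgP)) - p0[, , perm])), 1e-12)
})

test_that("training is bitwise reproducible from its seeds", {
  ds <- fx_dataset()
  m1 <- trainAPTModel(ds, fx_hp(), trainConfig(maxEpochs = 8, seed = 1))
  m2 <- trainAPTModel(ds, fx_hp(), trainConfig(maxEpochs = 8, seed = 1))
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  cfg <- records(ds)[[1]]$config
  expect_identical(tensors(predictAPTs(m1, cfg)),
                   tensors(predictAPTs(m2, cfg)))
})

test_that("perturbations beyond nLayers x cutoff cannot affect a prediction", {
  m <- fx_model()   # 2 hops x 2.9 A -> influence radius 5.8 A
  # two molecules 12 A apart in a large cell
  mol <- generateWaterBox(1, seed = 6)
  tpl <- positions(mol) - matrix(colMeans(positions(mol)), 3, 3, byrow = TRUE)
  pos <- rbind(sweep(tpl, 2, c(10, 10, 10), "+"),
               sweep(tpl, 2, c(22, 10, 10), "+"))
  cfg <- atomicConfiguration(rep(c("O", "H", "H"), 2), pos,
                             cell = diag(40, 3))
  p0 <- tensors(predictAPTs(m, cfg))[, , 1:3]
  moved <- pos
  moved[4:6, ] <- sweep(moved[4:6, ], 2, c(1.0, 0.4, -0.2), "+")
  cfg2 <- atomicConfiguration(rep(c("O", "H", "H"), 2), moved,
                              cell = diag(40, 3))
  p1 <- tensors(predictAPTs(m, cfg2))[, , 1:3]
  expect_lt(max(abs(p1 - p0)), 1e-12)
})

test_that("held-out error stays below an injected label-noise floor", {
  noise <- 0.05
  ds <- makeLabelledDataset(6, 8, model = toyDipoleModel("fixed"), seed = 15,
                            noise = noise)
  expect_equal(attr(ds, "labelNoise"), noise)
  ds <- splitDataset(ds, 0.75, seed = 3)
  m <- trainAPTModel(ds, fx_hp(), trainConfig(maxEpochs = 20, seed = 1))
  # the true function (q_s I) is learnable; residual error ~ the noise floor
  clean <- makeLabelledDataset(3, 8, model = toyDipoleModel("fixed"),
                               seed = 77)
  ev <- evaluateModel(m, clean)
  expect_lt(ev$rmse, noise)
})

test_that("evaluateModel reports the closed-form error metrics", {
  m <- fx_model()
  cfg <- records(fx_dataset())[[1]]$config
  pred <- predictAPTs(m, cfg)
  exact <- aptDataset(list(cfg), list(pred))
  expect_equal(evaluateModel(m, exact)$rmse, 0)
  offset <- aptFrame(tensors(pred) + 0.1, configId = configId(cfg))
  ev <- evaluateModel(m, aptDataset(list(cfg), list(offset)))
  expect_equal(ev$rmse, 0.1, tolerance = 1e-12)
  expect_setequal(ev$perSpecies$species, c("H", "O"))
  expect_equal(nrow(ev$scatter), 9L * nAtoms(cfg))
})

test_that("training-input contracts are enforced", {
  ds <- fx_dataset()
  noval <- new("APTDataset", records = records(ds),
               split = rep("train", nRecords(ds)))
  expect_error(trainAPTModel(noval, fx_hp()), "validation")
  m <- fx_model()
  alien <- atomicConfiguration(c("N", "N"), rbind(c(0, 0, 0), c(1, 0, 0)),
                               cell = diag(20, 3))
  expect_error(predictAPTs(m, alien), "N")
})

test_that("the plateau schedule reduces the learning rate by its factor", {
  h <- trainingHistory(fx_model())
  expect_true(all(h$lr %in% (0.01 * 0.1^(0:5))))
  expect_true(all(diff(h$lr) <= 0))
})

test_that("model checkpoints round trip through JSON", {
  m <- fx_model()
  f <- withr::local_tempfile(fileext = ".json")
  writeAPTModel(m, f)
  m2 <- readAPTModel(f)
  cfg <- records(fx_dataset())[[2]]$config
  expect_equal(tensors(predictAPTs(m2, cfg)), tensors(predictAPTs(m, cfg)),
               tolerance = 1e-12)
  expect_identical(m2@speciesLevels, m@speciesLevels)
})

test_that("batched frame prediction equals frame-by-frame prediction", {
  m <- fx_model()
  cfgs <- lapply(records(fx_dataset())[1:3], `[[`, "config")
  batched <- predictAPTsFrames(m, cfgs, maxAtoms = 50L)
  for (k in 1:3)
    expect_identical(tensors(batched[[k]]),
                     tensors(predictAPTs(m, cfgs[[k]])))
})
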