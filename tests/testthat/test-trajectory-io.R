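# Extended-XYZ and APT-container I/O.

test_that("extended-XYZ write/read round trip preserves everything", {
  box <- generateWaterBox(2, seed = 4)
  run <- generateTrajectory(box, dt = 0.5, nSteps = 3, temperature = 300,
                            seed = 4)
  f <- withr::local_tempfile(fileext = ".xyz")
  writeTrajectory(run$trajectory, f)
  back <- readTrajectory(f, dt = 0.5)
  expect_equal(nFrames(back), 4L)
  expect_true(hasVelocities(back))
  for (k in 1:4) {
    expect_identical(positions(frames(back)[[k]]),
                     unname(positions(frames(run$trajectory)[[k]])))
    expect_identical(unname(velocities(back)[[k]]),
                     unname(velocities(run$trajectory)[[k]]))
    expect_equal(cellMatrix(frames(back)[[k]]),
                 cellMatrix(frames(run$trajectory)[[k]]))
  }
  expect_identical(species(back), species(run$trajectory))
})

test_that("a stored n-step run spans (n-1) dt and keeps its literal frames", {
  # frame-count convention: the file's frames are taken as-is
  box <- generateWaterBox(1, seed = 1)
  run <- generateTrajectory(box, dt = 1, nSteps = 20, temperature = 100,
                            seed = 2)
  f <- withr::local_tempfile(fileext = ".xyz")
  writeTrajectory(run$trajectory, f)
  back <- readTrajectory(f, dt = 1)
  expect_equal(nFrames(back), 21L)
  expect_equal((nFrames(back) - 1L) * timestep(back), 20)
})

test_that("inconsistent atom ordering across frames is rejected by frame", {
  lines <- c("2", 'Properties=species:S:1:pos:R:3',
             "O 0 0 0", "H 1 0 0",
             "3", 'Properties=species:S:1:pos:R:3',
             "O 0 0 0", "H 1 0 0", "H 0 1 0")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(lines, f)
  expect_error(readTrajectory(f, dt = 1), "frame 2")
})

test_that("malformed headers produce parse errors naming the frame", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("notanumber", "comment", "O 0 0 0"), f)
  expect_error(readTrajectory(f, dt = 1), "frame 1")
  writeLines(c("2", 'Lattice="1 2 3"', "O 0 0 0", "H 1 0 0"), f)
  expect_error(readTrajectory(f, dt = 1), "Lattice")
})

test_that("APT container round trips bit for bit, including splits", {
  ds <- fx_dataset()
  f <- withr::local_tempfile(fileext = ".apt")
  writeAPTDataset(ds, f)
  back <- readAPTDataset(f)
  expect_equal(nRecords(back), nRecords(ds))
  expect_identical(splitLabels(back), splitLabels(ds))
  for (k in seq_len(nRecords(ds))) {
    expect_identical(tensors(records(back)[[k]]$apts),
                     tensors(records(ds)[[k]]$apts))
    expect_identical(positions(records(back)[[k]]$config),
                     unname(positions(records(ds)[[k]]$config)))
  }
})

test_that("empty dataset writes and reads back as empty but valid", {
  ds <- aptDataset(list(), list())
  f <- withr::local_tempfile(fileext = ".apt")
  writeAPTDataset(ds, f)
  expect_equal(nRecords(readAPTDataset(f)), 0L)
})

test_that("non-finite tensors are refused", {
  expect_error(aptFrame(array(NaN, c(3, 3, 1))), "finite")
  ds <- fx_dataset()
  ds@records[[1]]$apts@tensors[1, 1, 1] <- NaN
  f <- withr::local_tempfile(fileext = ".apt")
  expect_error(writeAPTDataset(ds, f), "finite")
})

test_that("atom-count mismatch between geometry and tensors is refused", {
  cfg <- generateWaterBox(1, seed = 1)
  expect_error(aptDataset(list(cfg), list(aptFrame(array(0, c(3, 3, 5))))),
               "match")
})

test_that("splitDataset is deterministic, by configuration, and validated", {
  ds <- makeLabelledDataset(10, 2, seed = 7)
  s1 <- splitDataset(ds, 0.9, seed = 5)
  s2 <- splitDataset(ds, 0.9, seed = 5)
  expect_identical(splitLabels(s1), splitLabels(s2))
  expect_equal(sum(splitLabels(s1) == "train"), 9L)
  expect_equal(sum(splitLabels(s1) == "validation"), 1L)
  # partition: every configuration in exactly one split
  expect_equal(nTensors(s1, "train") + nTensors(s1, "validation"),
               nTensors(s1))
  one <- aptDataset(list(records(ds)[[1]]$config),
                    list(records(ds)[[1]]$apts))
  expect_error(splitDataset(one, 0.9, seed = 1), "fewer than 2")
  expect_error(splitDataset(ds, 1.2, seed = 1), "between 0 and 1")
})
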