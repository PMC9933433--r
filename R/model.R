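# Training and applying the equivariant polar-tensor regressor.
#
# The target tensor of each atom is decomposed into its irreducible parts
# (isotropic scalar, axial vector, symmetric traceless) and each part is
# regressed linearly on the matching symmetry-adapted feature channel of that
# atom's species. Because the Frobenius norm splits exactly over the parts
# (|P|^2 = 3 s^2 + 2 |a|^2 + |S|^2 with the orthonormal 5-basis used here),
# the component-wise MSE optimised by Adam is the plain mean squared error
# over the 9 Cartesian tensor components in units of e, which is also the
# unit the training history reports.

#' Training configuration
#'
#' Defaults follow the canonical protocol: Adam with initial learning rate
#' 0.01, reduced by a factor 0.1 when the validation MSE has not improved
#' over the last 10 epochs, mean-squared-error loss over tensor components,
#' 100 epochs, one configuration (all its atoms) per batch.
#'
#' @param initialLR initial Adam learning rate.
#' @param plateauFactor multiplicative learning-rate reduction (0 < f < 1).
#' @param plateauPatience epochs without validation improvement before a
#'   reduction.
#' @param maxEpochs training epochs (an epoch is one pass over the training
#'   configurations).
#' @param minLR floor below which the schedule stops reducing.
#' @param weightDecay optional L2 penalty (default 0).
#' @param seed seed for batch shuffling.
#' @return named list.
#' @export
trainConfig <- function(initialLR = 0.01, plateauFactor = 0.1,
                        plateauPatience = 10L, maxEpochs = 100L,
                        minLR = 1e-6, weightDecay = 0, seed = 1L) {
  .stop_if(plateauFactor <= 0 || plateauFactor >= 1,
           "plateauFactor must lie strictly between 0 and 1")
  .stop_if(plateauPatience < 1L, "plateauPatience must be >= 1")
  list(initialLR = initialLR, plateauFactor = plateauFactor,
       plateauPatience = as.integer(plateauPatience),
       maxEpochs = as.integer(maxEpochs), minLR = minLR,
       weightDecay = weightDecay, seed = as.integer(seed))
}

# assemble per-species stacked design matrices and targets for a record list
.build_design <- function(recs, hp, proj, speciesLevels) {
  out <- lapply(seq_along(speciesLevels), function(s)
    list(X0 = list(), M1 = list(), M2 = list(),
         y0 = list(), y1 = list(), y2 = list(), cfg = list()))
  names(out) <- speciesLevels
  # feature evaluation batched over configurations (chunked to bound memory)
  fts <- .chunked_features(lapply(recs, `[[`, "config"), hp, proj,
                           speciesLevels)
  for (r in seq_along(recs)) {
    rec <- recs[[r]]
    ft <- fts[[r]]
    tn <- rec$apts@tensors
    n <- nAtoms(rec$config)
    sc <- numeric(n); ax <- matrix(0, n, 3); s5 <- matrix(0, n, 5)
    for (a in seq_len(n)) {
      ir <- tensorToIrreps(tn[, , a])
      sc[a] <- ir$scalar; ax[a, ] <- ir$vector; s5[a, ] <- .sym_to_5(ir$sym)
    }
    for (s in seq_along(speciesLevels)) {
      rows <- which(ft$speciesIdx == s)
      if (!length(rows)) next
      k <- length(out[[s]]$X0) + 1L
      out[[s]]$X0[[k]] <- ft$X0[rows, , drop = FALSE]
      out[[s]]$M1[[k]] <- .flatten_design(ft$X1[rows, , , drop = FALSE])
      out[[s]]$M2[[k]] <- .flatten_design(ft$X2[rows, , , drop = FALSE])
      out[[s]]$y0[[k]] <- sc[rows]
      out[[s]]$y1[[k]] <- as.vector(t(ax[rows, , drop = FALSE]))
      out[[s]]$y2[[k]] <- as.vector(t(s5[rows, , drop = FALSE]))
      out[[s]]$cfg[[k]] <- r
    }
  }
  for (s in seq_along(speciesLevels)) {
    o <- out[[s]]
    cfgRows0 <- c(0L, cumsum(vapply(o$X0, nrow, integer(1))))
    out[[s]] <- list(
      X0 = do.call(rbind, o$X0), M1 = do.call(rbind, o$M1),
      M2 = do.call(rbind, o$M2),
      y0 = unlist(o$y0), y1 = unlist(o$y1), y2 = unlist(o$y2),
      cfg = unlist(o$cfg),
      # row ranges per record index (for batch gradients)
      rowStart0 = cfgRows0)
  }
  out
}

# apply feature normalisers in place (scalars centred+scaled, others scaled)
.normalize_design <- function(d, nz) {
  if (is.null(d$X0) || !nrow(d$X0)) return(d)
  d$X0 <- sweep(sweep(d$X0, 2, nz$mu0, "-"), 2, nz$sd0, "/")
  d$M1 <- sweep(d$M1, 2, nz$sd1, "/")
  d$M2 <- sweep(d$M2, 2, nz$sd2, "/")
  d$y0 <- (d$y0 - nz$muT) / nz$sdT
  d$y1 <- d$y1 / nz$sdT
  d$y2 <- d$y2 / nz$sdT
  d
}

.colrms <- function(m) {
  v <- sqrt(colMeans(m^2))
  v[v < 1e-12] <- 1
  v
}

#' Train the equivariant polar-tensor model
#'
#' Requires a dataset with non-empty "train" and "validation" splits (see
#' \code{\link{splitDataset}}); splitting is by configuration. Per-epoch MSE
#' on both splits (e^2, over all 9 tensor components) is recorded in the
#' history together with the learning rate, and the plateau schedule acts on
#' the validation MSE. The run is fully reproducible from (dataset,
#' hyperparameters, training config): weights start at zero and all stochastic
#' choices derive from the recorded seeds.
#'
#' @param dataset an \linkS4class{APTDataset} with split labels.
#' @param hp hyperparameters from \code{\link{modelHyperparams}}.
#' @param tc training configuration from \code{\link{trainConfig}}.
#' @param verbose print per-epoch progress?
#' @return a \linkS4class{TrainedAPTModel}.
#' @export
trainAPTModel <- function(dataset, hp = modelHyperparams(),
                          tc = trainConfig(), verbose = FALSE) {
  validObject(dataset)
  trainIdx <- which(dataset@split == "train")
  valIdx <- which(dataset@split == "validation")
  .stop_if(length(trainIdx) == 0L, "training split is empty")
  .stop_if(length(valIdx) == 0L, "validation split is empty")
  speciesLevels <- sort(unique(unlist(
    lapply(dataset@records, function(r) unique(r$config@species)))))
  proj <- .make_projections(hp, length(speciesLevels))

  dTrain <- .build_design(dataset@records[trainIdx], hp, proj, speciesLevels)
  dVal <- .build_design(dataset@records[valIdx], hp, proj, speciesLevels)

  # normalisers from the training split only
  nz <- lapply(speciesLevels, function(s) NULL); names(nz) <- speciesLevels
  for (s in speciesLevels) {
    d <- dTrain[[s]]
    .stop_if(is.null(d$X0) || !nrow(d$X0),
             sprintf("species %s absent from the training split", s))
    allT <- c(3 * d$y0^2, 2 * d$y1^2, d$y2^2)
    sdT <- sqrt(mean(allT) * 3)           # scalar scale of the 9 components
    if (!is.finite(sdT) || sdT < 1e-10) sdT <- 1
    nz[[s]] <- list(mu0 = c(0, colMeans(d$X0[, -1, drop = FALSE])),
                    sd0 = c(1, .colrms(sweep(d$X0[, -1, drop = FALSE], 2,
                                             colMeans(d$X0[, -1, drop = FALSE]),
                                             "-"))),
                    sd1 = .colrms(d$M1), sd2 = .colrms(d$M2),
                    muT = mean(d$y0), sdT = sdT)
  }
  for (s in speciesLevels) {
    dTrain[[s]] <- .normalize_design(dTrain[[s]], nz[[s]])
    dVal[[s]] <- .normalize_design(dVal[[s]], nz[[s]])
  }

  # zero-initialised weights and Adam state per species and irrep block
  W <- lapply(speciesLevels, function(s) list(
    w0 = numeric(ncol(dTrain[[s]]$X0)),
    w1 = numeric(ncol(dTrain[[s]]$M1)),
    w2 = numeric(ncol(dTrain[[s]]$M2))))
  names(W) <- speciesLevels
  adam <- lapply(W, function(w) lapply(w, function(v)
    list(m = numeric(length(v)), v = numeric(length(v)), t = 0L)))
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8

  mse_of <- function(dd) {
    sse <- 0; nat <- 0
    for (s in speciesLevels) {
      d <- dd[[s]]
      if (is.null(d$X0) || !nrow(d$X0)) next
      w <- W[[s]]; sdT <- nz[[s]]$sdT
      r0 <- d$X0 %*% w$w0 - d$y0
      r1 <- d$M1 %*% w$w1 - d$y1
      r2 <- d$M2 %*% w$w2 - d$y2
      sse <- sse + sdT^2 * (3 * sum(r0^2) + 2 * sum(r1^2) + sum(r2^2))
      nat <- nat + nrow(d$X0)
    }
    sse / (9 * nat)
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(tc$seed, "batches"))
  lr <- tc$initialLR
  bestVal <- Inf; sincePlateau <- 0L
  hist <- data.frame(epoch = integer(), trainMSE = numeric(),
                     validationMSE = numeric(), lr = numeric())
  nTrainRecs <- length(trainIdx)

  for (epoch in seq_len(tc$maxEpochs)) {
    for (r in sample.int(nTrainRecs)) {
      # batch = one configuration: all its atoms, every species block
      nat <- 0L
      grads <- list()
      for (s in speciesLevels) {
        d <- dTrain[[s]]
        pos <- which(d$cfg == r)
        if (!length(pos)) next
        rows0 <- (d$rowStart0[pos] + 1L):d$rowStart0[pos + 1L]
        nat <- nat + length(rows0)
        grads[[s]] <- rows0
      }
      if (!nat) next
      for (s in names(grads)) {
        d <- dTrain[[s]]; w <- W[[s]]
        rows0 <- grads[[s]]
        rows1 <- rep((rows0 - 1L) * 3L, each = 3L) + 1:3
        rows2 <- rep((rows0 - 1L) * 5L, each = 5L) + 1:5
        X0 <- d$X0[rows0, , drop = FALSE]
        M1 <- d$M1[rows1, , drop = FALSE]
        M2 <- d$M2[rows2, , drop = FALSE]
        g <- list(
          w0 = as.numeric(crossprod(X0, X0 %*% w$w0 - d$y0[rows0])) *
            (6 / (9 * nat)),
          w1 = as.numeric(crossprod(M1, M1 %*% w$w1 - d$y1[rows1])) *
            (4 / (9 * nat)),
          w2 = as.numeric(crossprod(M2, M2 %*% w$w2 - d$y2[rows2])) *
            (2 / (9 * nat)))
        for (blk in c("w0", "w1", "w2")) {
          gv <- g[[blk]] + tc$weightDecay * w[[blk]]
          st <- adam[[s]][[blk]]
          st$t <- st$t + 1L
          st$m <- b1 * st$m + (1 - b1) * gv
          st$v <- b2 * st$v + (1 - b2) * gv^2
          mh <- st$m / (1 - b1^st$t)
          vh <- st$v / (1 - b2^st$t)
          W[[s]][[blk]] <- w[[blk]] - lr * mh / (sqrt(vh) + epsA)
          adam[[s]][[blk]] <- st
          w <- W[[s]]
        }
      }
    }
    trainMSE <- mse_of(dTrain)
    valMSE <- mse_of(dVal)
    .stop_if(!is.finite(trainMSE) || !is.finite(valMSE),
             sprintf("non-finite loss at epoch %d (diverged)", epoch))
    hist <- rbind(hist, data.frame(epoch = epoch, trainMSE = trainMSE,
                                   validationMSE = valMSE, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4e  val %.4e  lr %.2e",
                      epoch, trainMSE, valMSE, lr))
    if (valMSE < bestVal * (1 - 1e-12)) {
      bestVal <- valMSE; sincePlateau <- 0L
    } else {
      sincePlateau <- sincePlateau + 1L
      if (sincePlateau >= tc$plateauPatience && lr > tc$minLR) {
        lr <- max(lr * tc$plateauFactor, tc$minLR)
        sincePlateau <- 0L
      }
    }
  }

  prov <- list(datasetHash = .dataset_hash(dataset),
               nTrainConfigs = length(trainIdx),
               nValidationConfigs = length(valIdx),
               hpSeed = hp$seed, trainSeed = tc$seed,
               package = as.character(utils::packageVersion("aptIR")))
  new("TrainedAPTModel", hyperparams = hp, weights = W, normalizers = nz,
      projections = proj, speciesLevels = speciesLevels, history = hist,
      provenance = prov)
}

# evaluate features for many configurations in chunks of ~maxAtoms atoms and
# split the batched blocks back into per-configuration pieces
.chunked_features <- function(configs, hp, proj, speciesLevels,
                              maxAtoms = 1200L) {
  nAt <- vapply(configs, nAtoms, integer(1))
  res <- vector("list", length(configs))
  k <- 1L
  while (k <= length(configs)) {
    end <- k
    tot <- nAt[k]
    while (end < length(configs) && tot + nAt[end + 1L] <= maxAtoms) {
      end <- end + 1L; tot <- tot + nAt[end]
    }
    ft <- .configs_features(configs[k:end], hp, proj, speciesLevels)
    off <- c(0L, cumsum(nAt[k:end]))
    for (j in seq_len(end - k + 1L)) {
      rows <- (off[j] + 1L):off[j + 1L]
      res[[k + j - 1L]] <- list(
        X0 = ft$X0[rows, , drop = FALSE],
        X1 = ft$X1[rows, , , drop = FALSE],
        X2 = ft$X2[rows, , , drop = FALSE],
        speciesIdx = ft$speciesIdx[rows])
    }
    k <- end + 1L
  }
  res
}

.dataset_hash <- function(dataset) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(lapply(dataset@records, function(r)
    list(r$config@species, r$config@positions, r$apts@tensors)), f)
  unname(tools::md5sum(f))
}

#' Predict atomic polar tensors for a configuration
#'
#' Pure function of the stored weights and the configuration. Species outside
#' the model's vocabulary raise an error naming the species.
#'
#' @param model a \linkS4class{TrainedAPTModel}.
#' @param config an \linkS4class{AtomicConfiguration}.
#' @return an \linkS4class{APTFrame} (units of e).
#' @export
predictAPTs <- function(model, config) {
  ft <- .config_features(config, model@hyperparams, model@projections,
                         model@speciesLevels)
  aptFrame(.predict_from_features(model, ft), configId = config@id)
}

# compose predicted tensors from a feature block (n atoms)
.predict_from_features <- function(model, ft) {
  n <- length(ft$speciesIdx)
  tens <- array(0, c(3, 3, n))
  for (s in seq_along(model@speciesLevels)) {
    sp <- model@speciesLevels[s]
    rows <- which(ft$speciesIdx == s)
    if (!length(rows)) next
    nzs <- model@normalizers[[sp]]; w <- model@weights[[sp]]
    X0 <- sweep(sweep(ft$X0[rows, , drop = FALSE], 2, nzs$mu0, "-"),
                2, nzs$sd0, "/")
    M1 <- sweep(.flatten_design(ft$X1[rows, , , drop = FALSE]), 2,
                nzs$sd1, "/")
    M2 <- sweep(.flatten_design(ft$X2[rows, , , drop = FALSE]), 2,
                nzs$sd2, "/")
    s0 <- as.numeric(X0 %*% w$w0) * nzs$sdT + nzs$muT
    a <- matrix(M1 %*% w$w1, 3, length(rows)) * nzs$sdT
    c5 <- matrix(M2 %*% w$w2, 5, length(rows)) * nzs$sdT
    # recomposition, vectorised over atoms
    tens[1, 1, rows] <- s0 + (c5[4, ] / sqrt(2) + c5[5, ] / sqrt(6))
    tens[2, 2, rows] <- s0 + (-c5[4, ] / sqrt(2) + c5[5, ] / sqrt(6))
    tens[3, 3, rows] <- s0 - 2 * c5[5, ] / sqrt(6)
    tens[1, 2, rows] <- c5[1, ] / sqrt(2) - a[3, ]
    tens[2, 1, rows] <- c5[1, ] / sqrt(2) + a[3, ]
    tens[1, 3, rows] <- c5[2, ] / sqrt(2) + a[2, ]
    tens[3, 1, rows] <- c5[2, ] / sqrt(2) - a[2, ]
    tens[2, 3, rows] <- c5[3, ] / sqrt(2) - a[1, ]
    tens[3, 2, rows] <- c5[3, ] / sqrt(2) + a[1, ]
  }
  tens
}

#' Predict atomic polar tensors for many frames
#'
#' Same numbers as calling \code{\link{predictAPTs}} frame by frame, but the
#' feature algebra is batched over chunks of frames, which is substantially
#' faster for long trajectories.
#'
#' @param model a \linkS4class{TrainedAPTModel}.
#' @param configs list of \linkS4class{AtomicConfiguration} (e.g.
#'   \code{frames(traj)}).
#' @param maxAtoms atoms per evaluation chunk.
#' @return list of \linkS4class{APTFrame}.
#' @export
predictAPTsFrames <- function(model, configs, maxAtoms = 1200L) {
  nAt <- vapply(configs, nAtoms, integer(1))
  res <- vector("list", length(configs))
  k <- 1L
  while (k <= length(configs)) {
    end <- k; tot <- nAt[k]
    while (end < length(configs) && tot + nAt[end + 1L] <= maxAtoms) {
      end <- end + 1L; tot <- tot + nAt[end]
    }
    # features for this chunk only; turned into tensors, then discarded
    ft <- .configs_features(configs[k:end], model@hyperparams,
                            model@projections, model@speciesLevels)
    tens <- .predict_from_features(model, ft)
    off <- c(0L, cumsum(nAt[k:end]))
    for (j in seq_len(end - k + 1L)) {
      rows <- (off[j] + 1L):off[j + 1L]
      res[[k + j - 1L]] <- aptFrame(tens[, , rows, drop = FALSE],
                                    configId = configs[[k + j - 1L]]@id)
    }
    k <- end + 1L
  }
  res
}

#' Evaluate a trained model on a labelled dataset slice
#'
#' @param model a \linkS4class{TrainedAPTModel}.
#' @param dataset an \linkS4class{APTDataset} (all records are evaluated; use
#'   \code{\link{datasetSlice}} to restrict to one split).
#' @return list with \code{mse} and \code{rmse} (component-wise, e and e^2),
#'   \code{perSpecies} (data.frame of per-species MSE/RMSE and atom counts)
#'   and \code{scatter} (data.frame of reference vs predicted values per
#'   tensor component per species, for parity plots).
#' @export
evaluateModel <- function(model, dataset) {
  .stop_if(nRecords(dataset) == 0L, "dataset slice is empty")
  comp <- outer(1:3, 1:3, function(i, j) sprintf("P%d%d", i, j))
  ref <- list(); pred <- list(); spv <- list()
  for (r in dataset@records) {
    pf <- predictAPTs(model, r$config)
    n <- nAtoms(r$config)
    ref[[length(ref) + 1L]] <- matrix(r$apts@tensors, 9, n)
    pred[[length(pred) + 1L]] <- matrix(pf@tensors, 9, n)
    spv[[length(spv) + 1L]] <- r$config@species
  }
  refm <- do.call(cbind, ref); predm <- do.call(cbind, pred)
  spc <- unlist(spv)
  err2 <- (predm - refm)^2
  mse <- mean(err2)
  per <- do.call(rbind, lapply(sort(unique(spc)), function(s) {
    sel <- spc == s
    data.frame(species = s, nAtoms = sum(sel), mse = mean(err2[, sel]),
               rmse = sqrt(mean(err2[, sel])))
  }))
  scatter <- data.frame(
    species = rep(spc, each = 9),
    component = rep(as.vector(comp), length(spc)),
    reference = as.vector(refm), predicted = as.vector(predm))
  list(mse = mse, rmse = sqrt(mse), perSpecies = per, scatter = scatter)
}

#' Save / load a trained model as a self-describing text checkpoint
#'
#' The checkpoint stores hyperparameters, weights, normalisers, the fixed
#' feature projections and provenance as JSON with full-precision numbers.
#'
#' @param model a \linkS4class{TrainedAPTModel}.
#' @param path file path.
#' @return \code{path} (write) or the model (read).
#' @export
writeAPTModel <- function(model, path) {
  pack <- list(
    hyperparams = model@hyperparams,
    weights = model@weights,
    normalizers = model@normalizers,
    projections = lapply(model@projections, function(m)
      list(dim = dim(m), data = as.vector(m))),
    speciesLevels = model@speciesLevels,
    history = model@history,
    provenance = model@provenance)
  jsonlite::write_json(pack, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeAPTModel
#' @export
readAPTModel <- function(path) {
  pack <- jsonlite::read_json(path, simplifyVector = TRUE)
  hp <- pack$hyperparams
  hp$channels <- as.list(hp$channels)
  proj <- lapply(pack$projections, function(p)
    matrix(p$data, p$dim[1], p$dim[2]))
  W <- lapply(pack$weights, function(w) lapply(w, as.numeric))
  nz <- lapply(pack$normalizers, function(z) lapply(z, as.numeric))
  new("TrainedAPTModel", hyperparams = hp, weights = W, normalizers = nz,
      projections = proj, speciesLevels = pack$speciesLevels,
      history = as.data.frame(pack$history), provenance = pack$provenance)
}
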