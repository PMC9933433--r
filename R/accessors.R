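# Accessors, constructors and show() methods for the core data classes.

#' Construct an AtomicConfiguration
#'
#' @param species character element symbols.
#' @param positions n x 3 matrix, Angstrom.
#' @param cell 3x3 lattice matrix (rows = lattice vectors) or NULL.
#' @param pbc logical(3); defaults to all TRUE when a cell is given.
#' @param id optional identifier.
#' @return an \linkS4class{AtomicConfiguration}.
#' @examples
#' cfg <- atomicConfiguration(c("O", "H", "H"),
#'   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' nAtoms(cfg)
#' @export
atomicConfiguration <- function(species, positions, cell = NULL,
                                pbc = if (is.null(cell)) c(FALSE, FALSE, FALSE)
                                      else c(TRUE, TRUE, TRUE),
                                id = "") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (!is.null(cell)) { cell <- as.matrix(cell); storage.mode(cell) <- "double" }
  new("AtomicConfiguration", species = as.character(species),
      positions = positions, cell = cell, pbc = as.logical(pbc),
      id = as.character(id))
}

#' Construct a Trajectory
#' @param frames list of \linkS4class{AtomicConfiguration}.
#' @param dt timestep in fs.
#' @param velocities optional list of per-frame n x 3 velocity matrices (A/fs).
#' @export
trajectory <- function(frames, dt, velocities = list()) {
  new("Trajectory", frames = frames, dt = as.numeric(dt),
      velocities = velocities)
}

#' Construct an APTFrame
#' @param tensors 3 x 3 x n array (or list of 3x3 matrices), units of e.
#' @param configId id of the source configuration.
#' @export
aptFrame <- function(tensors, configId = "") {
  if (is.list(tensors))
    tensors <- array(unlist(tensors), c(3, 3, length(tensors)))
  new("APTFrame", tensors = tensors, configId = as.character(configId))
}

#' Construct an APTDataset
#' @param configs list of \linkS4class{AtomicConfiguration}.
#' @param aptFrames list of \linkS4class{APTFrame}, parallel to configs.
#' @param split optional character split labels; default "none".
#' @export
aptDataset <- function(configs, aptFrames, split = NULL) {
  stopifnot(length(configs) == length(aptFrames))
  recs <- mapply(function(c_, a_) list(config = c_, apts = a_),
                 configs, aptFrames, SIMPLIFY = FALSE)
  if (is.null(split)) split <- rep("none", length(recs))
  new("APTDataset", records = recs, split = split)
}

#' @export
irSpectrumParams <- function(temperature, volume)
  new("IRSpectrumParams", temperature = as.numeric(temperature),
      volume = as.numeric(volume))

#' Construct an AtomPartition
#' @param groups named list of atom index vectors.
#' @param nAtoms total number of atoms.
#' @param projectors optional named list of 3 x 3 x n_group projector arrays.
#' @export
atomPartition <- function(groups, nAtoms, projectors = list()) {
  groups <- lapply(groups, as.integer)
  new("AtomPartition", groups = groups, projectors = projectors,
      nAtoms = as.integer(nAtoms))
}

## ---- accessors -----------------------------------------------------------

#' @describeIn atomicConfiguration element symbols
#' @param x object.
#' @export
setMethod("species", "AtomicConfiguration", function(x) x@species)
#' @export
setMethod("positions", "AtomicConfiguration", function(x) x@positions)
#' @export
setMethod("cellMatrix", "AtomicConfiguration", function(x) x@cell)
#' @export
setMethod("pbcFlags", "AtomicConfiguration", function(x) x@pbc)
#' @export
setMethod("nAtoms", "AtomicConfiguration", function(x) nrow(x@positions))
#' @export
setMethod("configId", "AtomicConfiguration", function(x) x@id)

#' @export
setMethod("frames", "Trajectory", function(x) x@frames)
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@frames))
#' @export
setMethod("timestep", "Trajectory", function(x) x@dt)
#' @export
setMethod("velocities", "Trajectory", function(x) x@velocities)
#' @export
setMethod("hasVelocities", "Trajectory",
          function(x) length(x@velocities) > 0L)
#' @export
setMethod("nAtoms", "Trajectory", function(x) nAtoms(x@frames[[1L]]))
#' @export
setMethod("species", "Trajectory", function(x) species(x@frames[[1L]]))

#' @export
setMethod("tensors", "APTFrame", function(x) x@tensors)
#' @export
setMethod("configId", "APTFrame", function(x) x@configId)
#' @export
setMethod("nAtoms", "APTFrame", function(x) dim(x@tensors)[3])

#' @export
setMethod("records", "APTDataset", function(x) x@records)
#' @export
setMethod("splitLabels", "APTDataset", function(x) x@split)
#' @export
setMethod("nRecords", "APTDataset", function(x) length(x@records))

#' Total number of labelled tensors in a dataset (configurations x atoms)
#' @param dataset an \linkS4class{APTDataset}.
#' @param split optional split label to restrict the count.
#' @export
nTensors <- function(dataset, split = NULL) {
  keep <- if (is.null(split)) seq_along(dataset@records)
          else which(dataset@split == split)
  sum(vapply(dataset@records[keep],
             function(r) nAtoms(r$config), integer(1)))
}

#' Subset an APTDataset by split label
#' @param dataset an \linkS4class{APTDataset}.
#' @param split label(s) to keep.
#' @export
datasetSlice <- function(dataset, split) {
  keep <- which(dataset@split %in% split)
  new("APTDataset", records = dataset@records[keep],
      split = dataset@split[keep])
}

#' @export
setMethod("wavenumbers", "IRSpectrum", function(x) x@wavenumbers)
#' @export
setMethod("intensity", "IRSpectrum", function(x) x@intensity)

#' @export
setMethod("trainingHistory", "TrainedAPTModel", function(x) x@history)

## ---- show methods --------------------------------------------------------

setMethod("show", "AtomicConfiguration", function(object) {
  per <- if (any(object@pbc)) "periodic" else "non-periodic"
  cat(sprintf("AtomicConfiguration: %d atoms (%s)\n",
              nAtoms(object), per))
  tab <- table(object@species)
  cat("  composition:",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  if (!is.null(object@cell))
    cat(sprintf("  cell lengths: %.3f %.3f %.3f A\n",
                sqrt(sum(object@cell[1, ]^2)), sqrt(sum(object@cell[2, ]^2)),
                sqrt(sum(object@cell[3, ]^2))))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d frames x %d atoms, dt = %g fs (%.4g ps), velocities: %s\n",
    nFrames(object), nAtoms(object), object@dt,
    (nFrames(object) - 1L) * object@dt / 1000,
    if (hasVelocities(object)) "yes" else "no"))
})

setMethod("show", "APTFrame", function(object) {
  cat(sprintf("APTFrame: %d atomic polar tensors (e)", nAtoms(object)))
  if (nzchar(object@configId))
    cat(sprintf(" [config %s]", object@configId))
  cat("\n")
})

setMethod("show", "APTDataset", function(object) {
  cat(sprintf("APTDataset: %d configurations, %d tensors\n",
              nRecords(object), nTensors(object)))
  if (nRecords(object)) {
    tab <- table(object@split)
    cat("  splits:",
        paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
})

setMethod("show", "IRSpectrum", function(object) {
  cat(sprintf(
    "IRSpectrum: %d points, %.1f..%.1f cm^-1, %s intensities\n",
    length(object@wavenumbers), min(object@wavenumbers),
    max(object@wavenumbers),
    if (object@absolute) "absolute n(w)alpha(w) [cm^-1]" else
      "unit-max normalised"))
})

setMethod("show", "DipoleBackend", function(object) {
  cat(sprintf("DipoleBackend '%s' (%s), %d evaluations so far\n",
              object@name,
              if (is.null(object@aptFun)) "numeric only"
              else "analytic APTs available",
              callCount(object)))
})

setMethod("show", "TrainedAPTModel", function(object) {
  hp <- object@hyperparams
  cat(sprintf(
    "TrainedAPTModel: cutoff %.2f A, %d hops, %d radial channels, species: %s\n",
    hp$cutoff, hp$nLayers, hp$nRadial,
    paste(object@speciesLevels, collapse = ", ")))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final validation MSE %.3e e^2\n",
                nrow(object@history),
                object@history$validationMSE[nrow(object@history)]))
})
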