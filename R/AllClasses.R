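#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("functionOrNULL", c("function", "NULL"))

#' AtomicConfiguration: one (optionally periodic) snapshot
#'
#' Holds per-atom element symbols, Cartesian positions in Angstrom and, for
#' periodic systems, the 3x3 lattice matrix (rows are lattice vectors, in
#' Angstrom) together with per-axis periodicity flags. Coordinates are raw
#' Cartesian and are never wrapped implicitly: wrapping would break the branch
#' consistency that finite-difference dipole derivatives rely on.
#'
#' @slot species character vector of element symbols, one per atom.
#' @slot positions numeric n x 3 matrix, Angstrom.
#' @slot cell 3x3 lattice matrix (rows = lattice vectors) or NULL.
#' @slot pbc logical(3) periodicity flags.
#' @slot id character identifier (used to link APT frames to geometries).
#' @exportClass AtomicConfiguration
setClass("AtomicConfiguration",
  slots = c(species = "character", positions = "matrix",
            cell = "matrixOrNULL", pbc = "logical", id = "character"),
  prototype = prototype(cell = NULL, pbc = c(FALSE, FALSE, FALSE), id = ""))

setValidity("AtomicConfiguration", function(object) {
  msg <- character()
  if (!is.numeric(object@positions) || ncol(object@positions) != 3L)
    msg <- c(msg, "positions must be a numeric n x 3 matrix")
  else if (!all(is.finite(object@positions)))
    msg <- c(msg, "positions must be finite")
  if (length(object@species) != nrow(object@positions))
    msg <- c(msg, "species length must equal the number of position rows")
  if (length(object@pbc) != 3L)
    msg <- c(msg, "pbc must be logical(3)")
  if (any(object@pbc)) {
    if (is.null(object@cell))
      msg <- c(msg, "periodic configuration requires a cell")
    else if (!all(dim(object@cell) == c(3L, 3L)) ||
             !all(is.finite(object@cell)) ||
             abs(det(object@cell)) < 1e-10)
      msg <- c(msg, "cell must be a finite, invertible 3x3 matrix")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory: time-ordered configurations with a uniform timestep
#'
#' All frames must share the same atom count and species ordering. Velocities
#' (Angstrom/fs), when present, are stored per frame per atom and come either
#' from the file that was read or from the integrator that produced the
#' trajectory; \code{\link{velocitiesFromPositions}} reconstructs them by
#' finite differences when they are absent.
#'
#' @slot frames list of \linkS4class{AtomicConfiguration}.
#' @slot dt numeric timestep in fs.
#' @slot velocities list of n x 3 matrices (one per frame), or empty list.
#' @exportClass Trajectory
setClass("Trajectory",
  slots = c(frames = "list", dt = "numeric", velocities = "list"),
  prototype = prototype(velocities = list()))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number (fs)")
  if (length(object@frames) == 0L)
    msg <- c(msg, "trajectory must contain at least one frame")
  else {
    sp0 <- object@frames[[1L]]@species
    for (k in seq_along(object@frames)) {
      f <- object@frames[[k]]
      if (!is(f, "AtomicConfiguration")) {
        msg <- c(msg, "frames must be AtomicConfiguration objects"); break
      }
      if (!identical(f@species, sp0)) {
        msg <- c(msg, sprintf(
          "frame %d has a different atom count or species ordering", k))
        break
      }
    }
    if (length(object@velocities)) {
      if (length(object@velocities) != length(object@frames))
        msg <- c(msg, "velocities must have one entry per frame")
      else for (k in seq_along(object@velocities)) {
        v <- object@velocities[[k]]
        if (!is.matrix(v) || !all(dim(v) == c(length(sp0), 3L))) {
          msg <- c(msg, sprintf("velocities of frame %d have wrong shape", k))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' APTFrame: per-atom atomic polar tensors for one configuration
#'
#' The atomic polar tensor of atom i is the 3x3 matrix of derivatives of the
#' total dipole moment with respect to that atom's Cartesian position,
#' element (xi, zeta) = dM_xi / dr_{i,zeta}, in units of the elementary
#' charge e.
#'
#' @slot tensors numeric 3 x 3 x n array, units of e.
#' @slot configId character id of the source configuration.
#' @exportClass APTFrame
setClass("APTFrame",
  slots = c(tensors = "array", configId = "character"),
  prototype = prototype(configId = ""))

setValidity("APTFrame", function(object) {
  d <- dim(object@tensors)
  if (length(d) != 3L || d[1] != 3L || d[2] != 3L)
    return("tensors must be a 3 x 3 x n array")
  if (!all(is.finite(object@tensors)))
    return("all tensor entries must be finite")
  TRUE
})

#' APTDataset: labelled (configuration, APT frame) records with split tags
#'
#' @slot records list; each element is \code{list(config =, apts =)}.
#' @slot split character vector, one of "train", "validation", "test", "none"
#'   per record.
#' @exportClass APTDataset
setClass("APTDataset",
  slots = c(records = "list", split = "character"))

setValidity("APTDataset", function(object) {
  msg <- character()
  if (length(object@split) != length(object@records))
    msg <- c(msg, "split must have one label per record")
  bad <- setdiff(unique(object@split), c("train", "validation", "test", "none"))
  if (length(bad))
    msg <- c(msg, paste0("unknown split labels: ", paste(bad, collapse = ", ")))
  for (k in seq_along(object@records)) {
    r <- object@records[[k]]
    if (!is.list(r) || !is(r$config, "AtomicConfiguration") ||
        !is(r$apts, "APTFrame")) {
      msg <- c(msg, sprintf("record %d is not a (config, apts) pair", k)); break
    }
    if (dim(r$apts@tensors)[3] != length(r$config@species)) {
      msg <- c(msg, sprintf(
        "record %d: tensor count does not match atom count", k)); break
    }
    if (!all(is.finite(r$apts@tensors))) {
      msg <- c(msg, sprintf("record %d: tensors must be finite", k)); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' DipoleBackend: pluggable total-dipole evaluator
#'
#' A backend maps an \linkS4class{AtomicConfiguration} to the total dipole
#' moment M (3-vector, e Angstrom). Evaluations are counted (for the
#' finite-difference bookkeeping contract: 6 evaluations per atom). A backend
#' may additionally carry a closed-form polar-tensor function
#' (\code{aptFun(config, atomIndex)}), in which case it advertises the
#' analytic-derivative capability that bypasses finite differences.
#'
#' @slot fun function(config) -> numeric(3), total dipole in e Angstrom.
#' @slot aptFun optional function(config, atomIndex) -> 3x3 matrix (e).
#' @slot name character label used by the backend registry and CLI.
#' @slot counter environment holding the evaluation count.
#' @exportClass DipoleBackend
setClass("DipoleBackend",
  slots = c(fun = "function", aptFun = "functionOrNULL",
            name = "character", counter = "environment"))

#' FDSettings: central finite-difference settings
#'
#' @slot h displacement in Angstrom (default 0.01). The scheme is central
#'   (two-sided) and fixed; h is exposed because a displacement adequate for
#'   one system need not be small enough for another.
#' @exportClass FDSettings
setClass("FDSettings", slots = c(h = "numeric"),
         prototype = prototype(h = 0.01))

setValidity("FDSettings", function(object) {
  if (length(object@h) != 1L || !is.finite(object@h) || object@h <= 0)
    "h must be a single positive displacement (Angstrom)" else TRUE
})

#' IRSpectrumParams: thermodynamic parameters of the absolute intensity
#'
#' Temperature and box volume enter the Beer-Lambert prefactor
#' beta / (3 eps0 V c); the output reports n(omega) alpha(omega) jointly (the
#' frequency-dependent refractive index is not separated). The harmonic
#' quantum correction is implicit in the dipole-velocity formulation, so no
#' extra frequency-dependent factor is applied.
#'
#' @slot temperature K.
#' @slot volume Angstrom^3.
#' @exportClass IRSpectrumParams
setClass("IRSpectrumParams",
  slots = c(temperature = "numeric", volume = "numeric"))

setValidity("IRSpectrumParams", function(object) {
  msg <- character()
  if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
      object@temperature <= 0) msg <- c(msg, "temperature must be > 0 (K)")
  if (length(object@volume) != 1L || !is.finite(object@volume) ||
      object@volume <= 0) msg <- c(msg, "volume must be > 0 (Angstrom^3)")
  if (length(msg)) msg else TRUE
})

#' IRSpectrum: wavenumber grid vs intensity
#'
#' Intensity is n(omega) alpha(omega) in cm^-1 when thermodynamic parameters
#' were supplied, otherwise arbitrary units normalised to unit maximum.
#'
#' @slot wavenumbers strictly increasing grid, cm^-1.
#' @slot intensity real intensities, same length.
#' @slot absolute logical; TRUE when intensities are absolute.
#' @exportClass IRSpectrum
setClass("IRSpectrum",
  slots = c(wavenumbers = "numeric", intensity = "numeric",
            absolute = "logical"),
  prototype = prototype(absolute = FALSE))

setValidity("IRSpectrum", function(object) {
  msg <- character()
  if (length(object@wavenumbers) != length(object@intensity))
    msg <- c(msg, "wavenumbers and intensity must have equal length")
  if (length(object@wavenumbers) > 1L && any(diff(object@wavenumbers) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (!all(is.finite(object@intensity)))
    msg <- c(msg, "intensity must be real and finite")
  if (length(msg)) msg else TRUE
})

#' DipoleVelocitySeries: per-frame total dipole time derivative
#'
#' @slot values n x 3 matrix, e Angstrom / fs.
#' @slot dt timestep, fs.
#' @exportClass DipoleVelocitySeries
setClass("DipoleVelocitySeries",
  slots = c(values = "matrix", dt = "numeric"))

setValidity("DipoleVelocitySeries", function(object) {
  msg <- character()
  if (!is.numeric(object@values) || ncol(object@values) != 3L)
    msg <- c(msg, "values must be an n x 3 numeric matrix")
  else if (nrow(object@values) < 2L)
    msg <- c(msg, "series must contain at least 2 frames")
  else if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number (fs)")
  if (length(msg)) msg else TRUE
})

#' AtomPartition: named atom groups for spectral decomposition
#'
#' Groups must be disjoint and cover all atoms unless per-atom velocity
#' projectors are supplied, in which case groups may share atoms but the
#' projectors must sum to the identity on every atom (so the decomposition sum
#' rule holds exactly).
#'
#' @slot groups named list of integer atom-index vectors.
#' @slot projectors optional named list (parallel to groups) of 3 x 3 x n
#'   projector arrays (n = atoms in the group), or empty list.
#' @slot nAtoms total atom count the partition refers to.
#' @exportClass AtomPartition
setClass("AtomPartition",
  slots = c(groups = "list", projectors = "list", nAtoms = "integer"),
  prototype = prototype(projectors = list()))

setValidity("AtomPartition", function(object) {
  g <- object@groups
  if (length(g) == 0L || is.null(names(g)) || any(names(g) == ""))
    return("groups must be a non-empty named list")
  idx <- unlist(g, use.names = FALSE)
  if (any(idx < 1L | idx > object@nAtoms))
    return("group indices out of range")
  if (length(object@projectors) == 0L) {
    if (anyDuplicated(idx))
      return("groups must be disjoint (overlapping groups need projectors)")
    if (length(unique(idx)) != object@nAtoms)
      return("groups must cover all atoms")
  } else {
    if (!identical(names(object@projectors), names(g)))
      return("projectors must parallel the groups")
    # projectors must sum to the identity atom by atom
    acc <- array(0, c(3, 3, object@nAtoms))
    for (k in seq_along(g)) {
      pr <- object@projectors[[k]]
      if (!is.array(pr) || !all(dim(pr) == c(3, 3, length(g[[k]]))))
        return(sprintf("projectors for group '%s' have wrong shape",
                       names(g)[k]))
      acc[, , g[[k]]] <- acc[, , g[[k]], drop = FALSE] + pr
    }
    covered <- sort(unique(idx))
    if (length(covered) != object@nAtoms)
      return("projector groups must still cover all atoms")
    eye <- diag(3)
    for (a in covered)
      if (max(abs(acc[, , a] - eye)) > 1e-8)
        return("projectors must sum to the identity on every atom")
  }
  TRUE
})

#' TrainedAPTModel: fitted symmetry-adapted polar-tensor regressor
#'
#' Opaque weight state plus everything needed to reproduce a prediction:
#' hyperparameters, fixed feature projections, per-species normalisers,
#' per-epoch training history and provenance (dataset fingerprint, seeds).
#' Prediction is a pure function of (weights, configuration).
#'
#' @slot hyperparams list, see \code{\link{modelHyperparams}}.
#' @slot weights per-species weight lists.
#' @slot normalizers per-species feature/target normalisation constants.
#' @slot projections fixed seeded channel-compression matrices.
#' @slot speciesLevels character vocabulary the model was trained on.
#' @slot history data.frame with per-epoch train/validation MSE and lr.
#' @slot provenance list (dataset hash, seed, package version).
#' @exportClass TrainedAPTModel
setClass("TrainedAPTModel",
  slots = c(hyperparams = "list", weights = "list", normalizers = "list",
            projections = "list", speciesLevels = "character",
            history = "data.frame", provenance = "list"))
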