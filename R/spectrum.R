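# IR spectra from dipole-velocity time correlation functions.
#
# The total dipole time derivative is assembled from atomic polar tensors and
# atomic velocities by the chain rule, Mdot(t) = sum_i P_i(t) v_i(t). The
# absorption spectrum follows from the Fourier-transformed autocorrelation of
# Mdot with the Beer-Lambert prefactor,
#   n(w) alpha(w) = beta / (3 eps0 V c) * Int_0^inf <Mdot(0).Mdot(t)> cos(wt) dt,
# in which the harmonic quantum correction factor is already implicit (the
# dipole-velocity form absorbs it); no further frequency-dependent factor is
# applied. Because any group sum Mdot_g = sum_{i in g} P_i v_i is again a
# proper dipole velocity, APT weighting promotes any velocity spectrum to an
# IR spectrum, which is what the group decomposition exploits.

#' @export
dipoleVelocitySeries <- function(values, dt)
  new("DipoleVelocitySeries", values = values, dt = as.numeric(dt))

#' Spectrum estimator settings
#'
#' @param maxLag maximum correlation lag in fs (default: half the series
#'   duration). Longer lags sharpen resolution but add noise.
#' @param window taper applied to the lag range: "hann" (default) or "none".
#' @param zeroPad zero-padding factor (>= 1) controlling grid oversampling
#'   for FFT-based paths; the cosine-transform grid below is explicit, so
#'   this mainly documents intent.
#' @param wavenumberMax upper edge of the output grid, cm^-1 (default 4500).
#' @param gridSpacing output grid spacing, cm^-1 (default 2).
#' @return named list of settings.
#' @export
spectrumSettings <- function(maxLag = NULL, window = c("hann", "none"),
                             zeroPad = 4, wavenumberMax = 4500,
                             gridSpacing = 2) {
  window <- match.arg(window)
  .stop_if(zeroPad < 1, "zeroPad must be >= 1")
  list(maxLag = maxLag, window = window, zeroPad = zeroPad,
       wavenumberMax = wavenumberMax, gridSpacing = gridSpacing)
}

#' Dipole velocity from APTs and atomic velocities
#'
#' Chain rule: Mdot(t) = sum_i P_i(t) v_i(t), with each polar tensor acting
#' as the matrix (dM_xi / dr_{i,zeta}) on the atom's velocity.
#'
#' @param apts list of \linkS4class{APTFrame}, one per frame.
#' @param velocities list of n x 3 velocity matrices (Angstrom/fs), parallel
#'   to \code{apts}.
#' @param dt timestep in fs.
#' @param atoms optional integer subset of atoms to include (used by the
#'   group decomposition).
#' @param projectors optional 3 x 3 x length(atoms) array of per-atom
#'   velocity projectors applied before the APT weighting.
#' @return a \linkS4class{DipoleVelocitySeries}.
#' @export
dipoleVelocity <- function(apts, velocities, dt, atoms = NULL,
                           projectors = NULL) {
  .stop_if(length(apts) != length(velocities),
           "apts and velocities must have the same number of frames")
  nf <- length(apts)
  .stop_if(nf < 2L, "need at least 2 frames")
  out <- matrix(0, nf, 3)
  for (t in seq_len(nf)) {
    P <- apts[[t]]@tensors
    v <- velocities[[t]]
    .stop_if(!is.matrix(v) || nrow(v) != dim(P)[3] || ncol(v) != 3L,
             sprintf("frame %d: velocity shape does not match tensors", t))
    sel <- if (is.null(atoms)) seq_len(nrow(v)) else atoms
    vs <- v[sel, , drop = FALSE]
    if (!is.null(projectors)) {
      for (k in seq_along(sel))
        vs[k, ] <- projectors[, , k] %*% vs[k, ]
    }
    Ps <- P[, , sel, drop = FALSE]
    # sum_i P_i v_i  ==  matrix of stacked tensors times stacked velocities
    out[t, ] <- c(
      sum(Ps[1, 1, ] * vs[, 1] + Ps[1, 2, ] * vs[, 2] + Ps[1, 3, ] * vs[, 3]),
      sum(Ps[2, 1, ] * vs[, 1] + Ps[2, 2, ] * vs[, 2] + Ps[2, 3, ] * vs[, 3]),
      sum(Ps[3, 1, ] * vs[, 1] + Ps[3, 2, ] * vs[, 2] + Ps[3, 3, ] * vs[, 3]))
  }
  dipoleVelocitySeries(out, dt)
}

#' Reconstruct velocities from positions by central differences
#'
#' Interior frames use central differences over 2 dt, endpoints one-sided
#' differences. Per-step displacements are unwrapped through the minimum
#' image convention first, so an atom crossing a periodic boundary between
#' frames yields a continuous velocity rather than a box-length jump. A
#' per-step displacement exceeding half the smallest cell height makes the
#' unwrapping ambiguous and raises an error.
#'
#' @param traj a \linkS4class{Trajectory} with at least 3 frames.
#' @return list of n x 3 velocity matrices (Angstrom/fs), one per frame.
#' @export
velocitiesFromPositions <- function(traj) {
  nf <- nFrames(traj)
  .stop_if(nf < 3L, "need at least 3 frames to reconstruct velocities")
  cell <- traj@frames[[1L]]@cell
  periodic <- any(traj@frames[[1L]]@pbc) && !is.null(cell)
  n <- nAtoms(traj)
  # unwrap: accumulate minimum-image per-step displacements
  un <- vector("list", nf)
  un[[1L]] <- traj@frames[[1L]]@positions
  if (periodic) halfMin <- min(.cell_heights(cell)) / 2
  for (t in 2:nf) {
    step <- traj@frames[[t]]@positions - traj@frames[[t - 1L]]@positions
    if (periodic) {
      step <- .min_image(step, cell)
      .stop_if(max(sqrt(rowSums(step^2))) > halfMin, sprintf(
        paste0("displacement between frames %d and %d exceeds half the ",
               "smallest cell height; unwrapping is ambiguous"), t - 1L, t))
    }
    un[[t]] <- un[[t - 1L]] + step
  }
  dt <- traj@dt
  v <- vector("list", nf)
  v[[1L]] <- (un[[2L]] - un[[1L]]) / dt
  v[[nf]] <- (un[[nf]] - un[[nf - 1L]]) / dt
  for (t in 2:(nf - 1L)) v[[t]] <- (un[[t + 1L]] - un[[t - 1L]]) / (2 * dt)
  v
}

#' Autocorrelation of a dipole-velocity series
#'
#' Biased (divide by N) estimator of <Mdot(0).Mdot(tau)>, summed over the
#' three Cartesian components. The FFT fast path equals the direct O(N^2)
#' lag sum to near machine precision.
#'
#' @param series a \linkS4class{DipoleVelocitySeries} (or n x 3 matrix).
#' @param maxLag maximum lag in frames (default N - 1).
#' @param method "fft" (default) or "direct" (the brute-force oracle).
#' @return numeric vector of length maxLag + 1 (lags 0..maxLag).
#' @export
dipoleACF <- function(series, maxLag = NULL, method = c("fft", "direct")) {
  method <- match.arg(method)
  vals <- if (is(series, "DipoleVelocitySeries")) series@values else series
  n <- nrow(vals)
  if (is.null(maxLag)) maxLag <- n - 1L
  maxLag <- min(maxLag, n - 1L)
  if (method == "direct") {
    acf_ <- vapply(0:maxLag, function(lag) {
      idx <- seq_len(n - lag)
      sum(vals[idx, , drop = FALSE] *
            vals[idx + lag, , drop = FALSE]) / n
    }, numeric(1))
    return(acf_)
  }
  m <- stats::nextn(2L * n, 2)
  acc <- numeric(m)
  for (k in 1:3) {
    x <- c(vals[, k], numeric(m - n))
    f <- stats::fft(x)
    acc <- acc + Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  }
  acc[seq_len(maxLag + 1L)] / n
}

#' Shortest sampling interval resolving a given wavenumber
#'
#' The sampling theorem bound 1 / (2 c nu): data sampled at longer intervals
#' alias a vibration at that wavenumber. For the O-H stretch near 3500 cm^-1
#' this evaluates to about 4.8 fs.
#'
#' @param wavenumber cm^-1 (> 0).
#' @return interval in fs.
#' @examples
#' nyquistInterval(3500)
#' @export
nyquistInterval <- function(wavenumber) {
  .stop_if(any(wavenumber <= 0), "wavenumber must be positive")
  1 / (2 * .const$c_cmfs * wavenumber)
}

# windowed cosine transform of an ACF onto an explicit wavenumber grid;
# normalised such that for window "none" and full lag range the integral of
# the returned density over wavenumber equals acf[1] (Parseval)
.acf_to_spectrum <- function(acf_, dt, grid, window) {
  nlag <- length(acf_) - 1L
  tau <- (0:nlag) * dt
  w <- switch(window,
              hann = 0.5 * (1 + cos(pi * (0:nlag) / nlag)),
              none = rep(1, nlag + 1L))
  a <- acf_ * w
  # trapezoid-consistent cosine sum: half weight at lag 0
  a[1] <- a[1] / 2
  cosmat <- cos(2 * pi * .const$c_cmfs * outer(grid, tau))   # grid x lags
  as.numeric(cosmat %*% a) * 4 * .const$c_cmfs * dt
}

#' IR absorption spectrum from a dipole-velocity series
#'
#' Computes the spectrum as the windowed cosine transform of the dipole
#' velocity autocorrelation. With thermodynamic parameters the intensity is
#' the absolute product n(omega) alpha(omega) in cm^-1; without, intensities
#' are normalised to unit maximum. Multiple series (e.g. independent
#' trajectories) may be given as a list: their ACFs are averaged before the
#' transform.
#'
#' @param series a \linkS4class{DipoleVelocitySeries} or list of them (equal
#'   dt required).
#' @param params optional \linkS4class{IRSpectrumParams} for absolute units.
#' @param settings estimator settings from \code{\link{spectrumSettings}}.
#' @return an \linkS4class{IRSpectrum}.
#' @export
irSpectrum <- function(series, params = NULL, settings = spectrumSettings()) {
  if (is(series, "DipoleVelocitySeries")) series <- list(series)
  dt <- series[[1L]]@dt
  for (s in series) .stop_if(abs(s@dt - dt) > 1e-12,
                             "all series must share the same timestep")
  nyq <- 1 / (2 * .const$c_cmfs * dt)
  .stop_if(settings$wavenumberMax > nyq, sprintf(
    paste0("requested maximum wavenumber %.0f cm^-1 exceeds the Nyquist ",
           "limit %.0f cm^-1 for dt = %g fs; sample at intervals no longer ",
           "than %.3f fs"), settings$wavenumberMax, nyq, dt,
    nyquistInterval(settings$wavenumberMax)))
  maxLagFrames <- if (is.null(settings$maxLag))
    max(2L, floor((nrow(series[[1L]]@values) - 1L) / 2)) else {
      .stop_if(settings$maxLag > (nrow(series[[1L]]@values) - 1L) * dt,
               "maxLag exceeds the series duration")
      max(2L, floor(settings$maxLag / dt))
    }
  acfs <- lapply(series, dipoleACF, maxLag = maxLagFrames)
  acf_ <- Reduce(`+`, acfs) / length(acfs)
  grid <- seq(settings$gridSpacing, settings$wavenumberMax,
              by = settings$gridSpacing)
  dens <- .acf_to_spectrum(acf_, dt, grid, settings$window)
  if (!is.null(params)) {
    validObject(params)
    intensity <- dens * .ir_prefactor(params) / (4 * .const$c_cmfs)
    absolute <- TRUE
  } else {
    m <- max(abs(dens))
    intensity <- if (m > 0) dens / m else dens
    absolute <- FALSE
  }
  new("IRSpectrum", wavenumbers = grid, intensity = intensity,
      absolute = absolute)
}

# beta / (3 eps0 V c) in units converting the one-sided cosine integral of
# the ACF (e^2 A^2 fs^-2 * fs) into an absorption coefficient in cm^-1
.ir_prefactor <- function(params) {
  beta <- 1 / (.const$kB_SI * params@temperature)
  intUnit <- (.const$e_SI * 1e-10 / 1e-15)^2 * 1e-15   # (e A/fs)^2 fs in SI
  vol <- params@volume * 1e-30
  perM <- beta / (3 * .const$eps0_SI * vol * .const$c_SI) * intUnit
  perM / 100   # 1/m -> 1/cm
}

#' Decompose an IR spectrum into atom-group contributions
#'
#' Splits Mdot into group dipole velocities Mdot_g = sum_{i in g} P_i v_i
#' (with optional per-atom velocity projectors) and returns group auto
#' spectra together with symmetrised pairwise cross spectra, such that
#' sum_g auto_g + sum_{g<g'} 2 cross_{gg'} reproduces the total spectrum
#' pointwise (the estimator is bilinear in the series, so the sum rule is an
#' identity).
#'
#' @param apts list of per-frame \linkS4class{APTFrame}.
#' @param velocities list of per-frame n x 3 velocity matrices.
#' @param partition an \linkS4class{AtomPartition}.
#' @param dt timestep, fs.
#' @param params optional \linkS4class{IRSpectrumParams}. When omitted, all
#'   returned spectra share one normalisation (the total's maximum) so the
#'   sum rule remains exact.
#' @param settings estimator settings.
#' @return list with \code{groups} (named list of \linkS4class{IRSpectrum}),
#'   \code{cross} (named list, "g1|g2"), and \code{total}.
#' @export
decomposeSpectrum <- function(apts, velocities, partition, dt, params = NULL,
                              settings = spectrumSettings()) {
  validObject(partition)
  gnames <- names(partition@groups)
  series <- lapply(seq_along(partition@groups), function(k)
    dipoleVelocity(apts, velocities, dt, atoms = partition@groups[[k]],
                   projectors = if (length(partition@projectors))
                     partition@projectors[[k]] else NULL))
  names(series) <- gnames
  total <- dipoleVelocitySeries(Reduce(`+`, lapply(series, slot, "values")),
                                dt)
  maxLagFrames <- if (is.null(settings$maxLag))
    max(2L, floor((nrow(total@values) - 1L) / 2)) else
      max(2L, floor(settings$maxLag / dt))
  grid <- seq(settings$gridSpacing, settings$wavenumberMax,
              by = settings$gridSpacing)
  scale <- if (!is.null(params)) .ir_prefactor(params) / (4 * .const$c_cmfs)
           else NULL
  toSpec <- function(acf_) {
    dens <- .acf_to_spectrum(acf_, dt, grid, settings$window)
    if (!is.null(scale)) dens * scale else dens
  }
  totDens <- toSpec(dipoleACF(total, maxLag = maxLagFrames))
  norm <- if (is.null(scale)) max(abs(totDens)) else 1
  if (norm == 0) norm <- 1
  mkSpec <- function(dens) new("IRSpectrum", wavenumbers = grid,
                               intensity = dens / norm,
                               absolute = !is.null(scale))
  groups <- lapply(series, function(s)
    mkSpec(toSpec(dipoleACF(s, maxLag = maxLagFrames))))
  cross <- list()
  if (length(series) > 1L) {
    for (i in seq_len(length(series) - 1L)) for (j in (i + 1L):length(series)) {
      cacf <- .cross_acf(series[[i]]@values, series[[j]]@values, maxLagFrames)
      cross[[paste(gnames[i], gnames[j], sep = "|")]] <- mkSpec(toSpec(cacf))
    }
  }
  list(groups = groups, cross = cross, total = mkSpec(totDens))
}

# symmetrised cross-correlation (real spectra): biased estimator of
# (<a(0).b(tau)> + <b(0).a(tau)>) / 2
.cross_acf <- function(a, b, maxLag) {
  n <- nrow(a)
  maxLag <- min(maxLag, n - 1L)
  m <- stats::nextn(2L * n, 2)
  acc <- numeric(m)
  for (k in 1:3) {
    fa <- stats::fft(c(a[, k], numeric(m - n)))
    fb <- stats::fft(c(b[, k], numeric(m - n)))
    acc <- acc + Re(stats::fft(fa * Conj(fb) + fb * Conj(fa),
                               inverse = TRUE)) / (2 * m)
  }
  acc[seq_len(maxLag + 1L)] / n
}
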