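# Physical constants and small internal helpers.
#
# Package-wide unit system: lengths in Angstrom, time in fs, charge in units of
# the elementary charge e, temperature in K, wavenumbers in cm^-1, masses in
# amu. Energies produced by the toy force field are in amu Angstrom^2 fs^-2
# (1 amu A^2/fs^2 = 103.642 eV). Conversions to SI happen only where the
# absolute infrared intensity is assembled.

.const <- list(
  c_cmfs   = 2.99792458e-5,      # speed of light, cm / fs
  kB_SI    = 1.380649e-23,       # J / K
  e_SI     = 1.602176634e-19,    # C
  eps0_SI  = 8.8541878128e-12,   # F / m
  c_SI     = 2.99792458e8,       # m / s
  amu_SI   = 1.66053906660e-27,  # kg
  # Boltzmann constant in internal energy units (amu A^2 fs^-2) per K
  kB_int   = 1.380649e-23 / (1.66053906660e-27 * 1e10)
)

.atomic_masses <- c(H = 1.008, O = 15.999, C = 12.011, N = 14.007)

#' Derive a module-level seed from a global seed
#'
#' One global seed fans out to per-module seeds through a fixed, documented
#' hash so that independent stages (box packing, velocity initialisation,
#' dataset splitting, weight initialisation, batch shuffling) stay individually
#' reproducible. The derived seed is always a valid 32-bit integer.
#'
#' @param seed integer global seed.
#' @param label character tag naming the consumer (e.g. \code{"split"}).
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @export
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 1009)
  as.integer((abs(seed) * 48271 + h) %% 2147483646) + 1L
}

# format a double so that read-back reproduces it bit for bit
.fmt_num <- function(x) sprintf("%.17g", x)

.stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# heights of a (rows = lattice vectors) cell matrix; height k is the distance
# between the two cell faces spanned by the other two vectors
.cell_heights <- function(cell) {
  v <- abs(det(cell))
  a <- cell[1, ]; b <- cell[2, ]; c_ <- cell[3, ]
  crossn <- function(u, w) sqrt(sum(c(u[2] * w[3] - u[3] * w[2],
                                      u[3] * w[1] - u[1] * w[3],
                                      u[1] * w[2] - u[2] * w[1])^2))
  c(v / crossn(b, c_), v / crossn(a, c_), v / crossn(a, b))
}

# minimum-image displacement vectors for a matrix of raw displacements (rows)
.min_image <- function(disp, cell) {
  if (is.null(cell)) return(disp)
  frac <- disp %*% solve(cell)
  frac <- frac - round(frac)
  frac %*% cell
}

.cross3 <- function(u, w) {
  c(u[2] * w[3] - u[3] * w[2],
    u[3] * w[1] - u[1] * w[3],
    u[1] * w[2] - u[2] * w[1])
}

# rows of `a` crossed with rows of `b` (n x 3 each)
.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (or O(3) when \code{improper = TRUE},
#' in which case the returned matrix has determinant -1). Used throughout the
#' equivariance checks.
#'
#' @param improper logical; return an improper rotation (reflection included)?
#' @return 3x3 orthogonal matrix.
#' @export
randomRotation <- function(improper = FALSE) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)              # Haar-corrected
  if (det(q) < 0) q[, 1] <- -q[, 1]
  if (improper) q[, 1] <- -q[, 1]
  q
}
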