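# Irreducible decomposition of 3x3 Cartesian tensors.
#
# A general rank-2 tensor splits into rotationally independent parts:
# an l=0 scalar (isotropic trace part), an l=1 axial vector carrying the
# antisymmetric part, and an l=2 symmetric-traceless part. The polar tensor
# is parity-even (it is a derivative of a polar vector by a polar vector),
# so its l=1 component transforms as a pseudovector.

#' Decompose a 3x3 tensor into irreducible components
#'
#' @param P 3x3 numeric matrix.
#' @return list with elements \code{scalar} (tr(P)/3, so that
#'   \code{scalar * diag(3)} is the isotropic part), \code{vector} (axial
#'   3-vector a with cross-product matrix equal to the antisymmetric part)
#'   and \code{sym} (3x3 symmetric traceless part).
#' @examples
#' p <- matrix(rnorm(9), 3, 3)
#' ir <- tensorToIrreps(p)
#' max(abs(irrepsToTensor(ir$scalar, ir$vector, ir$sym) - p))  # ~1e-16
#' @export
tensorToIrreps <- function(P) {
  stopifnot(is.matrix(P), all(dim(P) == c(3L, 3L)))
  s <- (P[1, 1] + P[2, 2] + P[3, 3]) / 3
  A <- (P - t(P)) / 2
  a <- c(A[3, 2], A[1, 3], A[2, 1])
  S <- (P + t(P)) / 2 - diag(s, 3)
  list(scalar = s, vector = a, sym = S)
}

#' Recompose a 3x3 tensor from irreducible components
#' @param scalar isotropic component (tr/3).
#' @param vector axial 3-vector (antisymmetric part).
#' @param sym 3x3 symmetric traceless matrix.
#' @return 3x3 matrix.
#' @export
irrepsToTensor <- function(scalar, vector, sym) {
  diag(scalar, 3) + axialMatrix(vector) + sym
}

#' Cross-product matrix of an axial vector
#'
#' Returns the antisymmetric matrix A with \code{A \%*\% v == a x v}.
#' @param a numeric(3).
#' @export
axialMatrix <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

# Orthonormal (Frobenius) basis of the symmetric-traceless subspace; the five
# expansion coefficients preserve norms, |S|_F^2 = sum(coef^2), which keeps
# the tensor-component MSE decomposition exact across irrep channels.
.sym5_basis <- local({
  s2 <- 1 / sqrt(2); s6 <- 1 / sqrt(6)
  list(
    matrix(c(0, s2, 0,  s2, 0, 0,  0, 0, 0), 3, 3),
    matrix(c(0, 0, s2,  0, 0, 0,  s2, 0, 0), 3, 3),
    matrix(c(0, 0, 0,  0, 0, s2,  0, s2, 0), 3, 3),
    matrix(c(s2, 0, 0,  0, -s2, 0,  0, 0, 0), 3, 3),
    matrix(c(s6, 0, 0,  0, s6, 0,  0, 0, -2 * s6), 3, 3))
})

# symmetric-traceless 3x3 -> 5 coefficients (rows of input stacked in `S`)
.sym_to_5 <- function(S) {
  vapply(.sym5_basis, function(E) sum(E * S), numeric(1))
}

.five_to_sym <- function(coef) {
  out <- matrix(0, 3, 3)
  for (k in 1:5) out <- out + coef[k] * .sym5_basis[[k]]
  out
}
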