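# Symmetry-adapted atomic environment features.
#
# The regressor represents each atom by irreducible-representation features
# built from its neighbor graph in two message-passing hops:
#
#   hop 1 (density projections): species- and radially-resolved sums of
#     spherical tensors of the unit bond vectors --- scalars (l=0, even),
#     polar vectors (l=1, odd parity) and symmetric-traceless rank-2 tensors
#     (l=2, even).
#   hop 2 (message passing): the hop-1 features of the neighbors are
#     aggregated again with their own radial weights, extending the receptive
#     field to nLayers x cutoff.
#
# Tensor-product couplings between the pooled features then yield the three
# channels the polar tensor decomposes into, with even parity throughout:
# scalars (dot products of two odd vectors, traces of tensor products), axial
# vectors (cross products of two odd vectors, commutators of two even
# tensors) and symmetric-traceless tensors (symmetrised outer products and
# the direct l=2 features). The readout is linear per channel and per
# species, so predictions are exactly equivariant under rotations (proper and
# improper), exactly translation invariant and exactly permutation
# equivariant by construction. Fixed seeded channel-compression matrices keep
# the feature count moderate; they are part of the model state.

# Gaussian radial basis on (0, cutoff] with a smooth cosine envelope that
# vanishes (with zero slope) at the cutoff
.radial_basis <- function(d, cutoff, nRadial) {
  centers <- seq(0.7, cutoff - 0.2, length.out = nRadial)
  width <- if (nRadial > 1L) (centers[2] - centers[1]) else cutoff / 2
  width <- max(width, 0.35)
  env <- 0.5 * (1 + cos(pi * pmin(d, cutoff) / cutoff))
  B <- outer(d, centers, function(x, c0) exp(-0.5 * ((x - c0) / width)^2))
  B * env
}

# rowsum that always returns n rows (atoms with no edges get zeros)
.rowsum_full <- function(m, group, n) {
  if (!nrow(m)) return(matrix(0, n, ncol(m)))
  rs <- rowsum(m, group)
  if (nrow(rs) == n) return(unname(rs))    # every atom had edges
  out <- matrix(0, n, ncol(m))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# fixed seeded compression matrices (orthonormal columns); part of the model
.make_projections <- function(hp, nSpecies) {
  ch <- hp$channels
  ks <- hp$nRadial * nSpecies
  hs <- hp$nRadialHop          # hop weights are radial only (see below)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(hp$seed, "projections"))
  ortho <- function(nrow_, ncol_) {
    ncol_ <- min(ncol_, nrow_)
    qr.Q(qr(matrix(stats::rnorm(nrow_ * ncol_), nrow_, ncol_)))
  }
  twoHop <- hp$nLayers >= 2L
  c0 <- min(ch$c0, ks); c1 <- min(ch$c1, ks); c2 <- min(ch$c2, ks)
  hop <- ch$hop
  chop <- min(ch$chop, c0)         # neighbor channels entering the hop
  # hop channel counts after compression
  h1 <- min(hop, hs * chop); hdn <- min(hop, hs * chop)
  h2 <- min(hop, hs * chop); h0 <- min(hop, hs * chop)
  h2d <- min(hop, hs * chop)
  vpoolL <- c1 + if (twoHop) h1 + hdn else 0L
  tpoolL <- c2 + if (twoHop) h2 + h2d else 0L
  list(
    Q0  = ortho(ks, c0),
    Q1  = ortho(ks, c1),
    Q2  = ortho(ks, c2),
    Q0h = ortho(c0, chop),
    Q1h = ortho(c1, chop),
    Q2h = ortho(c2, chop),
    QH0 = ortho(hs * chop, h0),
    QH1 = ortho(hs * chop, h1),
    QHd = ortho(hs * chop, hdn),
    QH2 = ortho(hs * chop, h2),
    QH2d = ortho(hs * chop, h2d),
    QV = ortho(vpoolL, min(ch$vprod, vpoolL)),
    QT = ortho(tpoolL, min(ch$tprod, tpoolL)))
}

# contract the channel (last) dimension of an n x m x L array with a matrix
.contract_channels <- function(arr, Q) {
  d <- dim(arr)
  out <- matrix(arr, d[1] * d[2], d[3]) %*% Q
  array(out, c(d[1], d[2], ncol(Q)))
}

# 5-component (orthonormal basis) coefficients of u u^T - I/3 for unit rows u
.edge_sym5 <- function(u) {
  s2 <- sqrt(2); s6 <- 1 / sqrt(6)
  cbind(s2 * u[, 1] * u[, 2],
        s2 * u[, 1] * u[, 3],
        s2 * u[, 2] * u[, 3],
        (u[, 1]^2 - u[, 2]^2) / s2,
        (u[, 1]^2 + u[, 2]^2 - 2 * u[, 3]^2) * s6)
}

# flatten n x m x L -> (m n) x L design matrix (component index fastest)
.flatten_design <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' Model hyperparameters
#'
#' @param cutoff graph radial cutoff in Angstrom (default 6, adequate for
#'   condensed-phase water; must stay below half the smallest cell height).
#' @param nLayers number of message-passing hops (1 or 2; default 2).
#' @param nRadial radial basis functions per species channel (default 8).
#' @param nRadialHop radial basis size of the second hop (default 4).
#' @param seed integer seed governing the fixed feature projections, weight
#'   initialisation and batch shuffling.
#' @param channels internal channel widths (compression sizes); override only
#'   for experiments.
#' @return a named list of hyperparameters.
#' @export
modelHyperparams <- function(cutoff = 6.0, nLayers = 2L, nRadial = 8L,
                             nRadialHop = 4L, seed = 1L,
                             channels = list(c0 = 8L, c1 = 8L, c2 = 8L,
                                             chop = 4L, hop = 12L,
                                             vprod = 12L, tprod = 10L)) {
  .stop_if(cutoff <= 0, "cutoff must be positive")
  .stop_if(nLayers < 1L, "nLayers must be >= 1")
  .stop_if(nRadial < 1L || nRadialHop < 1L, "radial basis sizes must be >= 1")
  list(cutoff = cutoff, nLayers = as.integer(nLayers),
       nRadial = as.integer(nRadial), nRadialHop = as.integer(nRadialHop),
       seed = as.integer(seed), channels = channels)
}

# Build the full per-atom feature blocks for one configuration.
# Returns list(X0 [n x p0], X1 [n x 3 x p1], X2 [n x 5 x p2], speciesIdx).
.config_features <- function(config, hp, proj, speciesLevels) {
  .configs_features(list(config), hp, proj, speciesLevels)
}

# Batched variant: concatenates the neighbor graphs of several configurations
# (atom indices offset, no cross-configuration edges) so the dense feature
# algebra runs once over all atoms. Exact same numbers as per-configuration
# evaluation; used to amortise interpreter overhead over trajectory frames.
.configs_features <- function(configs, hp, proj, speciesLevels) {
  nS <- length(speciesLevels)
  nAt <- vapply(configs, nAtoms, integer(1))
  n <- sum(nAt)
  off <- c(0L, cumsum(nAt))
  spIdx <- integer(n)
  fromL <- vector("list", length(configs)); toL <- fromL; dispL <- fromL
  distL <- fromL
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    si <- match(cfg@species, speciesLevels)
    .stop_if(anyNA(si),
             paste0("configuration contains species outside the model ",
                    "vocabulary: ",
                    paste(setdiff(unique(cfg@species), speciesLevels),
                          collapse = ", ")))
    spIdx[(off[k] + 1L):off[k + 1L]] <- si
    g <- buildGraph(cfg, cutoff = hp$cutoff)
    fromL[[k]] <- g@from + off[k]
    toL[[k]] <- g@to + off[k]
    dispL[[k]] <- g@disp
    distL[[k]] <- g@dist
  }
  gfrom <- unlist(fromL); gto <- unlist(toL)
  gdisp <- do.call(rbind, dispL); gdist <- unlist(distL)
  ne <- length(gfrom)

  u <- if (ne) gdisp / gdist else matrix(0, 0, 3)
  B <- if (ne) .radial_basis(gdist, hp$cutoff, hp$nRadial) else
    matrix(0, 0, hp$nRadial)
  spTo <- if (ne) spIdx[gto] else integer()
  # edge weights resolved by (radial, neighbor species)
  W <- matrix(0, ne, hp$nRadial * nS)
  for (s in seq_len(nS)) {
    sel <- spTo == s
    if (any(sel))
      W[sel, ((s - 1L) * hp$nRadial + 1L):(s * hp$nRadial)] <- B[sel, ]
  }
  sym5e <- if (ne) .edge_sym5(u) else matrix(0, 0, 5)

  # ---- hop 1: density projections --------------------------------------
  # one edge-feature block [W | u (x) W | sym5 (x) W], one aggregation
  ks <- ncol(W)
  EA <- cbind(W,
              u[, 1] * W, u[, 2] * W, u[, 3] * W,
              sym5e[, 1] * W, sym5e[, 2] * W, sym5e[, 3] * W,
              sym5e[, 4] * W, sym5e[, 5] * W)
  SA <- .rowsum_full(EA, gfrom, n)
  A0 <- SA[, seq_len(ks), drop = FALSE]
  A1 <- aperm(array(SA[, ks + seq_len(3 * ks)], c(n, ks, 3)), c(1, 3, 2))
  A2 <- aperm(array(SA[, 4 * ks + seq_len(5 * ks)], c(n, ks, 5)), c(1, 3, 2))
  A0c <- A0 %*% proj$Q0
  A1c <- .contract_channels(A1, proj$Q1)
  A2c <- .contract_channels(A2, proj$Q2)

  # ---- hop 2: aggregate neighbor features ------------------------------
  if (hp$nLayers >= 2L) {
    Bh <- if (ne) .radial_basis(gdist, hp$cutoff, hp$nRadialHop) else
      matrix(0, 0, hp$nRadialHop)
    # hop weights are radial only: the neighbor's species is already encoded
    # in its own hop-1 feature channels, so resolving the hop by species
    # would double the edge-block width for little information gain
    Wh <- Bh
    # neighbor features compressed to a few channels, gathered onto edges
    A0h <- A0c %*% proj$Q0h
    A1h <- .contract_channels(A1c, proj$Q1h)
    A2h <- .contract_channels(A2c, proj$Q2h)
    chn <- ncol(A0h)
    ev0 <- A0h[gto, , drop = FALSE]                          # ne x chn
    ev1 <- matrix(A1h, n, 3L * chn)[gto, , drop = FALSE]
    ev2 <- matrix(A2h, n, 5L * chn)[gto, , drop = FALSE]
    khs <- ncol(Wh)
    kc <- khs * chn
    # one edge-feature matrix for all hop blocks, one aggregation:
    # [Wh (x) ev0 | Wh (x) ev1 | Wh (x) ev2 | u (x) WV0 | sym5 (x) WV0]
    WV0 <- matrix(0, ne, kc)
    for (c_ in seq_len(khs))
      WV0[, (c_ - 1L) * chn + seq_len(chn)] <- Wh[, c_] * ev0
    EH <- matrix(0, ne, kc * (1L + 3L + 5L + 3L + 5L))
    EH[, seq_len(kc)] <- WV0
    for (c_ in seq_len(khs)) {
      EH[, kc + (c_ - 1L) * 3L * chn + seq_len(3L * chn)] <- Wh[, c_] * ev1
      EH[, 4L * kc + (c_ - 1L) * 5L * chn + seq_len(5L * chn)] <-
        Wh[, c_] * ev2
    }
    for (comp in 1:3)
      EH[, 9L * kc + (comp - 1L) * kc + seq_len(kc)] <- u[, comp] * WV0
    for (comp in 1:5)
      EH[, 12L * kc + (comp - 1L) * kc + seq_len(kc)] <- sym5e[, comp] * WV0
    SH <- .rowsum_full(EH, gfrom, n)
    H0 <- SH[, seq_len(kc), drop = FALSE] %*% proj$QH0
    H1 <- .contract_channels(array(SH[, kc + seq_len(3L * kc)], c(n, 3, kc)),
                             proj$QH1)
    H2 <- .contract_channels(
      array(SH[, 4L * kc + seq_len(5L * kc)], c(n, 5, kc)), proj$QH2)
    Hd <- .contract_channels(
      aperm(array(SH[, 9L * kc + seq_len(3L * kc)], c(n, kc, 3)), c(1, 3, 2)),
      proj$QHd)
    H2d <- .contract_channels(
      aperm(array(SH[, 12L * kc + seq_len(5L * kc)], c(n, kc, 5)),
            c(1, 3, 2)), proj$QH2d)
  } else {
    H0 <- matrix(0, n, 0)
    H1 <- array(0, c(n, 3, 0)); Hd <- array(0, c(n, 3, 0))
    H2 <- array(0, c(n, 5, 0)); H2d <- array(0, c(n, 5, 0))
  }

  # ---- pools ------------------------------------------------------------
  Vpool <- array(c(A1c, H1, Hd), c(n, 3, ncol(proj$Q1) + dim(H1)[3] +
                                     dim(Hd)[3]))              # parity odd
  Tpool <- array(c(A2c, H2, H2d), c(n, 5, ncol(proj$Q2) + dim(H2)[3] +
                                      dim(H2d)[3]))            # even
  Spool <- cbind(A0c, H0)

  Vp <- .contract_channels(Vpool, proj$QV)   # n x 3 x vp   (odd)
  Tp <- .contract_channels(Tpool, proj$QT)   # n x 5 x tp   (even)
  vp <- dim(Vp)[3]; tp <- dim(Tp)[3]

  # ---- tensor-product couplings ----------------------------------------
  # scalars: v_i . v_j (odd x odd = even), tr(T_i T_j)
  nd <- vp * (vp + 1L) / 2L
  Vdots <- matrix(0, n, nd)
  k <- 0L
  for (i in seq_len(vp)) for (j in i:vp) {
    k <- k + 1L
    Vdots[, k] <- rowSums(Vp[, , i] * Vp[, , j])
  }
  ndt <- tp * (tp + 1L) / 2L
  Tdots <- matrix(0, n, ndt)
  k <- 0L
  for (i in seq_len(tp)) for (j in i:tp) {
    k <- k + 1L
    Tdots[, k] <- rowSums(Tp[, , i] * Tp[, , j])
  }

  # axial vectors: v_i x v_j (even pseudovector), commutators [T_i, T_j]
  ncx <- vp * (vp - 1L) / 2L
  Vcross <- array(0, c(n, 3, ncx))
  k <- 0L
  for (i in seq_len(vp - 1L)) for (j in (i + 1L):vp) {
    k <- k + 1L
    Vcross[, , k] <- .cross_rows(Vp[, , i], Vp[, , j])
  }
  # reconstruct 3x3 symmetric matrices from the 5-coefficients once
  B59 <- t(vapply(.sym5_basis, as.vector, numeric(9)))   # 5 x 9
  Tfull <- array(0, c(n, 9, tp))
  for (i in seq_len(tp)) Tfull[, , i] <- Tp[, , i] %*% B59
  nct <- tp * (tp - 1L) / 2L
  Tcomm <- array(0, c(n, 3, nct))
  k <- 0L
  for (i in seq_len(tp - 1L)) for (j in (i + 1L):tp) {
    Si <- Tfull[, , i]; Sj <- Tfull[, , j]   # columns: (11,21,31,12,22,32,...)
    # C = Si %*% Sj rowwise; need the antisymmetric components of C
    Cab <- function(a, b)   # C[a,b] = sum_c Si[a,c] Sj[c,b]
      Si[, a] * Sj[, b * 3 - 2] + Si[, a + 3] * Sj[, b * 3 - 1] +
      Si[, a + 6] * Sj[, b * 3]
    k <- k + 1L
    Tcomm[, 1, k] <- (Cab(3, 2) - Cab(2, 3)) / 2
    Tcomm[, 2, k] <- (Cab(1, 3) - Cab(3, 1)) / 2
    Tcomm[, 3, k] <- (Cab(2, 1) - Cab(1, 2)) / 2
  }

  # symmetric traceless: sym(v_i v_j^T) (even), plus the direct l=2 pool
  Vouter <- array(0, c(n, 5, nd))
  s2 <- sqrt(2); s6 <- 1 / sqrt(6)
  k <- 0L
  for (i in seq_len(vp)) for (j in i:vp) {
    k <- k + 1L
    a <- Vp[, , i]; b <- Vp[, , j]
    xy <- (a[, 1] * b[, 2] + a[, 2] * b[, 1]) / 2
    xz <- (a[, 1] * b[, 3] + a[, 3] * b[, 1]) / 2
    yz <- (a[, 2] * b[, 3] + a[, 3] * b[, 2]) / 2
    xx <- a[, 1] * b[, 1]; yy <- a[, 2] * b[, 2]; zz <- a[, 3] * b[, 3]
    Vouter[, , k] <- cbind(s2 * xy, s2 * xz, s2 * yz,
                           (xx - yy) / s2, (xx + yy - 2 * zz) * s6)
  }

  X0 <- cbind(1, Spool, Vdots, Tdots)
  X1 <- array(c(Vcross, Tcomm), c(n, 3, ncx + nct))
  X2 <- array(c(Tp, Vouter), c(n, 5, tp + nd))
  list(X0 = X0, X1 = X1, X2 = X2, speciesIdx = spIdx)
}
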