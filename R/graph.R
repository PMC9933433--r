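# Neighbor graphs under the minimum-image convention.

#' NeighborGraph: directed edges below a radial cutoff
#'
#' Edge (i -> j) is present iff the minimum-image distance between atoms i and
#' j is smaller than the cutoff; each edge stores the image-consistent
#' displacement vector r_j - r_i (Angstrom). Edges are sorted by (from, to,
#' image) so that downstream summations have a reproducible floating-point
#' order.
#'
#' @slot from,to integer edge endpoints.
#' @slot disp numeric nEdges x 3 displacement matrix.
#' @slot dist numeric edge lengths.
#' @slot cutoff numeric cutoff used, Angstrom.
#' @slot nAtoms integer atom count of the source configuration.
#' @exportClass NeighborGraph
setClass("NeighborGraph",
  slots = c(from = "integer", to = "integer", disp = "matrix",
            dist = "numeric", cutoff = "numeric", nAtoms = "integer"))

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d atoms, %d directed edges, cutoff %.2f A\n",
              object@nAtoms, length(object@from), object@cutoff))
})

#' Build the neighbor graph of a configuration
#'
#' For periodic systems the default minimum-image path requires the cutoff to
#' be smaller than half the smallest cell height; violating cells raise an
#' error naming the limiting lattice vector. \code{method = "images"}
#' enumerates explicit periodic images instead (the brute-force path, valid
#' for any cell and used as the oracle for the minimum-image implementation).
#'
#' @param config an \linkS4class{AtomicConfiguration}.
#' @param cutoff radial cutoff in Angstrom (default 6).
#' @param method "minimum-image" (default) or "images".
#' @return a \linkS4class{NeighborGraph}.
#' @export
buildGraph <- function(config, cutoff = 6.0,
                       method = c("minimum-image", "images")) {
  method <- match.arg(method)
  .stop_if(cutoff <= 0, "cutoff must be positive")
  pos <- config@positions
  n <- nrow(pos)
  periodic <- any(config@pbc) && !is.null(config@cell)
  if (!periodic) {
    eg <- .edges_all_pairs(pos, cutoff)
  } else if (method == "minimum-image") {
    hts <- .cell_heights(config@cell)
    lim <- which.min(hts)
    .stop_if(cutoff >= hts[lim] / 2, sprintf(
      paste0("cutoff %.3f A violates the minimum-image bound: half the ",
             "smallest cell height is %.3f A (limiting lattice vector %d); ",
             "use method = 'images'"), cutoff, hts[lim] / 2, lim))
    eg <- .edges_min_image(pos, config@cell, cutoff)
  } else {
    eg <- .edges_images(pos, config@cell, config@pbc, cutoff)
  }
  ord <- order(eg$from, eg$to, eg$disp[, 1], eg$disp[, 2], eg$disp[, 3])
  new("NeighborGraph", from = eg$from[ord], to = eg$to[ord],
      disp = eg$disp[ord, , drop = FALSE], dist = eg$dist[ord],
      cutoff = cutoff, nAtoms = as.integer(n))
}

.edges_all_pairs <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2L)
    return(list(from = integer(), to = integer(),
                disp = matrix(0, 0, 3), dist = numeric()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- pos[idx[, 2], , drop = FALSE] - pos[idx[, 1], , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  keep <- r < cutoff
  list(from = c(idx[keep, 1], idx[keep, 2]),
       to   = c(idx[keep, 2], idx[keep, 1]),
       disp = rbind(d[keep, , drop = FALSE], -d[keep, , drop = FALSE]),
       dist = c(r[keep], r[keep]))
}

.edges_min_image <- function(pos, cell, cutoff) {
  n <- nrow(pos)
  if (n < 2L)
    return(list(from = integer(), to = integer(),
                disp = matrix(0, 0, 3), dist = numeric()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- pos[idx[, 2], , drop = FALSE] - pos[idx[, 1], , drop = FALSE]
  d <- .min_image(d, cell)
  r <- sqrt(rowSums(d^2))
  keep <- r < cutoff
  list(from = c(idx[keep, 1], idx[keep, 2]),
       to   = c(idx[keep, 2], idx[keep, 1]),
       disp = rbind(d[keep, , drop = FALSE], -d[keep, , drop = FALSE]),
       dist = c(r[keep], r[keep]))
}

# explicit image enumeration; shell count adapts to the cutoff
.edges_images <- function(pos, cell, pbc, cutoff) {
  n <- nrow(pos)
  hts <- .cell_heights(cell)
  reach <- ifelse(pbc, pmax(1L, ceiling(cutoff / hts)), 0L)
  shifts <- as.matrix(expand.grid(-reach[1]:reach[1], -reach[2]:reach[2],
                                  -reach[3]:reach[3]))
  from <- integer(); to <- integer(); disp <- list(); dist <- list()
  for (s in seq_len(nrow(shifts))) {
    shift <- as.numeric(shifts[s, ] %*% cell)
    central <- all(shifts[s, ] == 0)
    for (i in seq_len(n)) {
      d <- sweep(pos, 2, pos[i, ], "-")
      d <- sweep(d, 2, shift, "+")
      r <- sqrt(rowSums(d^2))
      keep <- r < cutoff
      if (central) keep[i] <- FALSE        # no self edge in the home image
      if (any(keep)) {
        from <- c(from, rep(i, sum(keep)))
        to <- c(to, which(keep))
        disp[[length(disp) + 1L]] <- d[keep, , drop = FALSE]
        dist[[length(dist) + 1L]] <- r[keep]
      }
    }
  }
  list(from = from, to = to,
       disp = if (length(disp)) do.call(rbind, disp) else matrix(0, 0, 3),
       dist = if (length(dist)) unlist(dist) else numeric())
}
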