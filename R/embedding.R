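## Diffusion-map embedding of connectivity matrices and change-of-basis
## alignment to a group reference.

#' Normalized-angle affinity between connectivity rows
#'
#' Converts a sparsified Fisher-z connectivity matrix into a symmetric
#' affinity in \[0, 1\]: entry (i, j) is `1 - acos(cosine(row_i, row_j)) / pi`
#' (the normalized-angle similarity used by gradient toolboxes), with unit
#' diagonal. Requires a sparsified matrix; an all-zero row (no retained
#' connections) is an error.
#'
#' @param fc a sparsified [ConnectivityMatrix-class]
#' @return P x P numeric affinity matrix
#' @export
affinityMatrix <- function(fc) {
  stopifnot(is(fc, "ConnectivityMatrix"))
  if (!fc@sparsified) stop("affinityMatrix() requires a sparsified matrix")
  z <- zMatrix(fc)
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0))
    stop("all-zero row(s) in sparsified matrix: ",
         paste(which(nrm == 0), collapse = ", "))
  cs <- tcrossprod(z / nrm)
  cs <- pmin(pmax(cs, -1), 1)
  aff <- 1 - acos(cs) / pi
  aff <- (aff + t(aff)) / 2        # enforce exact symmetry
  aff <- pmax(aff, 0)
  diag(aff) <- 1
  aff
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Classical diffusion maps: the affinity `W` is density-normalized as
#' `W' = D^-alpha W D^-alpha` (alpha = 0.5 by default, retaining global
#' relations), converted to the row-stochastic transition matrix
#' `M = D'^-1 W'`, and eigendecomposed through its symmetric conjugate.
#' The trivial constant eigenvector (eigenvalue 1) is dropped and the
#' coordinates of component k are `lambda_k^t * v_k`, with the right
#' eigenvectors `v_k` scaled to unit norm under the stationary distribution
#' so that Euclidean distance in the full embedding equals the diffusion
#' distance at time `t`. Each column's sign is fixed (first entry of
#' non-negligible magnitude made positive), making the output
#' deterministic.
#'
#' @param aff symmetric non-negative affinity matrix with a connected graph
#' @param alpha density-normalization exponent in \[0, 1\] (default 0.5)
#' @param diffusionTime diffusion time t >= 0 (default 1)
#' @param nComponents number of non-trivial components K (default 30)
#' @return an [Embedding-class]
#' @export
diffusionMap <- function(aff, alpha = 0.5, diffusionTime = 1,
                         nComponents = 30L) {
  P <- nrow(aff)
  stopifnot(ncol(aff) == P, alpha >= 0, alpha <= 1, diffusionTime >= 0,
            nComponents >= 1L, nComponents < P)
  if (max(abs(aff - t(aff))) > 1e-10) stop("affinity must be symmetric")
  if (min(aff) < 0) stop("affinity must be non-negative")
  g <- igraph::graph_from_adjacency_matrix(aff > 0, mode = "undirected",
                                           diag = FALSE)
  if (igraph::components(g)$no > 1L)
    stop("affinity graph is disconnected")
  d <- rowSums(aff)
  w1 <- aff / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  s <- w1 / outer(sqrt(d1), sqrt(d1))
  eig <- eigen(s, symmetric = TRUE)
  lam <- eig$values[2:(nComponents + 1L)]
  v <- eig$vectors[, 2:(nComponents + 1L), drop = FALSE]
  ## right eigenvectors of M, unit-normed under the stationary distribution
  v <- v / sqrt(d1) * sqrt(sum(d1))
  for (k in seq_len(ncol(v))) {
    j <- which(abs(v[, k]) > 1e-12)[1L]
    if (!is.na(j) && v[j, k] < 0) v[, k] <- -v[, k]
  }
  if (any(lam < 0) && diffusionTime != round(diffusionTime))
    stop("negative eigenvalues with non-integer diffusion time")
  coords <- sweep(v, 2L, lam^diffusionTime, `*`)
  new("Embedding", coordinates = coords, eigenvalues = lam, alpha = alpha,
      diffusionTime = diffusionTime, isReference = FALSE, isAligned = FALSE)
}

#' Build the reference embedding from a mean connectivity matrix
#'
#' Convenience wrapper: affinity of the group-average matrix followed by
#' [diffusionMap()], flagged as the canonical reference template.
#'
#' @param meanFC sparsified group-average [ConnectivityMatrix-class]
#'   (see [groupAverage()])
#' @inheritParams diffusionMap
#' @return an [Embedding-class] with `isReference = TRUE`
#' @export
buildReference <- function(meanFC, alpha = 0.5, diffusionTime = 1,
                           nComponents = 30L) {
  emb <- diffusionMap(affinityMatrix(meanFC), alpha = alpha,
                      diffusionTime = diffusionTime,
                      nComponents = nComponents)
  emb@isReference <- TRUE
  emb
}

#' Align an individual embedding to the reference by change of basis
#'
#' Individual diffusion maps live in dataset-specific Euclidean spaces;
#' to compare them the individual embedding `Phi` is mapped into the
#' reference space by the K x K operator `O` minimizing
#' `||Phi O - Psi||_F` (unconstrained least squares over all shared parcel
#' rows, solved in closed form). If `Phi` is rank-deficient the
#' pseudoinverse is used with a warning.
#'
#' @param individual an [Embedding-class]
#' @param reference the reference [Embedding-class] (same parcels, same K)
#' @return a list with `operator` (K x K matrix), `residual` (Frobenius
#'   norm of the alignment error) and `aligned` (the mapped
#'   [Embedding-class], `isAligned = TRUE`)
#' @export
changeOfBasis <- function(individual, reference) {
  phi <- individual@coordinates
  psi <- reference@coordinates
  if (!all(dim(phi) == dim(psi)))
    stop("individual and reference embeddings must share P and K")
  qrp <- qr(phi)
  if (qrp$rank < ncol(phi)) {
    warning("rank-deficient embedding; using pseudoinverse")
    op <- MASS::ginv(phi) %*% psi
  } else {
    op <- qr.coef(qrp, psi)
  }
  alignedCoords <- phi %*% op
  res <- sqrt(sum((alignedCoords - psi)^2))
  aligned <- individual
  aligned@coordinates <- alignedCoords
  aligned@isAligned <- TRUE
  list(operator = op, residual = res, aligned = aligned)
}
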