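## TFCE, max-statistic permutation correction, spin tests and the
## reference-embedding bootstrap.

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates cluster extent and height across thresholds:
#' `TFCE(p) = sum_h extent(p, h)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ...` up to the map maximum, where `extent(p, h)` is the
#' size of the connected suprathreshold component containing p on the
#' parcel adjacency graph. The negative tail is processed symmetrically on
#' `-t` and returned with negative sign. Default `dh = max(|t|) / nsteps`.
#'
#' @param t per-parcel statistic map
#' @param adjacency E x 2 integer matrix of parcel adjacency edges
#' @param E,H extent and height exponents (defaults 0.5 and 2)
#' @param nsteps number of integration steps used to set `dh`
#' @param dh explicit threshold step (overrides `nsteps`)
#' @return signed enhanced map (same length as `t`)
#' @export
tfce <- function(t, adjacency, E = 0.5, H = 2, nsteps = 100L, dh = NULL) {
  if (is.null(dh)) dh <- max(abs(t)) / nsteps
  if (!length(t) || max(abs(t)) == 0 || dh <= 0) return(numeric(length(t)))
  stopifnot(dh > 0)
  from <- as.integer(adjacency[, 1L]); to <- as.integer(adjacency[, 2L])
  pos <- tfce_positive(pmax(t, 0), from, to, E, H, dh)
  neg <- tfce_positive(pmax(-t, 0), from, to, E, H, dh)
  pos - neg
}

## Within-block permutations of a vector's indices; columns are permutations.
permIndices <- function(n, blocks, nPerm, seed) {
  if (is.null(blocks)) blocks <- rep(1L, n)
  blocks <- as.integer(as.factor(blocks))
  withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(j) {
      idx <- seq_len(n)
      for (b in unique(blocks)) {
        at <- which(blocks == b)
        idx[at] <- at[sample.int(length(at))]
      }
      idx
    }, integer(n))
  })
}

## Residualize the columns of M against the column space of Z.
residualize <- function(M, Z) {
  q <- qr.Q(qr(Z))
  M - q %*% crossprod(q, M)
}

## FWL t statistics: rg, RY residualized against the same nuisance space.
## `yss` carries the raw sum of squares of each response column so that
## responses lying (numerically) in the nuisance span yield t = 0 instead
## of floating-point noise.
fwlT <- function(RY, rg, df, yss = colSums(RY^2)) {
  gg <- sum(rg^2)
  if (gg < .Machine$double.eps) return(numeric(ncol(RY)))
  cr <- drop(crossprod(RY, rg))
  ryy <- colSums(RY^2)
  beta <- cr / gg
  rss <- pmax(ryy - beta^2 * gg, 0)
  tval <- beta * sqrt(gg) / sqrt(pmax(rss / df, .Machine$double.xmin))
  tval[rss == 0 & beta == 0] <- 0
  tval[ryy <= 1e-14 * (yss + .Machine$double.xmin)] <- 0
  tval
}

#' Parcel-wise group contrast with TFCE and max-statistic permutation
#'
#' Computes the parcel-wise GLM group t map (group effect adjusted for the
#' nuisance columns of the design), enhances it with [tfce()], and
#' corrects family-wise error by the maximum-TFCE null distribution under
#' permutation of group labels (within site blocks by default):
#' `p_corr(p) = (1 + #\{null max >= |TFCE_obs(p)|\}) / (nPerm + 1)`.
#' Optional per-parcel extra covariates (e.g. each subject's SD and DD at
#' that parcel) enter the parcel's own nuisance space.
#'
#' @param Y n x P matrix of per-subject parcel values
#' @param design output of [designMatrix()]
#' @param adjacency parcel adjacency edges (E x 2)
#' @param nPerm number of permutations (warning below 100)
#' @param seed integer RNG seed
#' @param permuteWithin optional blocking factor (e.g. `cohort$site`);
#'   group labels are permuted within blocks
#' @param extraCovariates optional list of n x P matrices of per-parcel
#'   covariates
#' @param E,H,nsteps TFCE parameters
#' @param alpha significance level for the sign masks
#' @return list with `t`, `tfce`, `pCorr`, `posMask`, `negMask`,
#'   `maxNull`, `nPerm`
#' @export
permutationCorrect <- function(Y, design, adjacency, nPerm = 1000L,
                               seed = 1L, permuteWithin = NULL,
                               extraCovariates = NULL, E = 0.5, H = 2,
                               nsteps = 100L, alpha = 0.05) {
  if (nPerm < 100L) warning("nPerm < 100 gives a coarse null distribution")
  Y <- as.matrix(Y)
  n <- nrow(Y); P <- ncol(Y)
  X <- design$X
  g <- X[, design$groupCol]
  Zbase <- X[, -design$groupCol, drop = FALSE]
  idx <- permIndices(n, permuteWithin, nPerm, seed)
  G <- matrix(g[idx], n, nPerm)
  if (is.null(extraCovariates)) {
    df <- n - ncol(X)
    rg <- drop(residualize(cbind(g), Zbase))
    RY <- residualize(Y, Zbase)
    RG <- residualize(G, Zbase)
    yss <- colSums(Y^2)
    tObs <- fwlT(RY, rg, df, yss)
    Tnull <- matrix(0, P, nPerm)
    for (j in seq_len(nPerm)) Tnull[, j] <- fwlT(RY, RG[, j], df, yss)
  } else {
    extraCovariates <- lapply(extraCovariates, as.matrix)
    df <- n - ncol(X) - length(extraCovariates)
    tObs <- numeric(P)
    Tnull <- matrix(0, P, nPerm)
    for (p in seq_len(P)) {
      Zp <- cbind(Zbase, vapply(extraCovariates, function(m) m[, p],
                                numeric(n)))
      q <- qr.Q(qr(Zp))
      ryp <- Y[, p] - q %*% crossprod(q, Y[, p])
      rgp <- drop(cbind(g) - q %*% crossprod(q, cbind(g)))
      RGp <- G - q %*% crossprod(q, G)
      tObs[p] <- fwlT(cbind(ryp), rgp, df, sum(Y[, p]^2))
      if (sum(ryp^2) <= 1e-14 * (sum(Y[, p]^2) + .Machine$double.xmin)) next
      ## the FWL t is symmetric in (residualized y, residualized g), so the
      ## per-permutation t vector is one vectorized call
      Tnull[p, ] <- fwlT(RGp, drop(ryp), df)
    }
  }
  enhObs <- tfce(tObs, adjacency, E, H, nsteps)
  maxNull <- vapply(seq_len(nPerm), function(j)
    max(abs(tfce(Tnull[, j], adjacency, E, H, nsteps))), numeric(1L))
  pCorr <- vapply(abs(enhObs), function(e)
    (1 + sum(maxNull >= e)) / (nPerm + 1), numeric(1L))
  list(t = tObs, tfce = enhObs, pCorr = pCorr,
       posMask = pCorr < alpha & tObs > 0,
       negMask = pCorr < alpha & tObs < 0,
       maxNull = maxNull, nPerm = nPerm)
}

## Uniform random 3-D rotation (QR of a Gaussian matrix, det fixed to +1).
randomRotation <- function() {
  qd <- qr(matrix(rnorm(9L), 3L, 3L))
  q <- qr.Q(qd)
  q <- q %*% diag(sign(diag(qr.R(qd))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Spin permutation test for spatial map correlation
#'
#' Tests the Pearson correlation between two per-parcel maps against a
#' null that preserves spatial autocorrelation: parcel centroids are
#' randomly rotated on the sphere, each parcel takes the value of map A at
#' the nearest rotated parcel (duplicates allowed), and the correlation
#' with map B is recomputed. Two-sided
#' `p_spin = (1 + #\{|null r| >= |observed r|\}) / (nRot + 1)`.
#'
#' @param mapA,mapB per-parcel maps (non-constant)
#' @param centroids P x 3 parcel centroids on a common sphere
#' @param nRot number of random rotations (default 1000)
#' @param seed integer RNG seed
#' @return list with `r` (observed), `null` (length nRot), `pSpin`
#' @export
spinTest <- function(mapA, mapB, centroids, nRot = 1000L, seed = 1L) {
  if (sd(mapA) == 0 || sd(mapB) == 0)
    stop("spin test is undefined for constant maps")
  u <- centroids / sqrt(rowSums(centroids^2))
  obs <- cor(mapA, mapB)
  nullR <- withr::with_seed(seed, {
    vapply(seq_len(nRot), function(j) {
      rot <- u %*% t(randomRotation())
      nn <- max.col(u %*% t(rot), ties.method = "first")
      cor(mapA[nn], mapB)
    }, numeric(1L))
  })
  pSpin <- (1 + sum(abs(nullR) >= abs(obs))) / (nRot + 1)
  list(r = obs, null = nullR, pSpin = pSpin)
}

#' Robustness of descriptors to the reference embedding (bootstrap)
#'
#' Rebuilds the reference `nBoot` times from random half-samples (fraction
#' configurable) of the subjects: mean connectivity -> reference embedding
#' -> reference clustering; then recomputes cortex-wide Dice, Jaccard and
#' MSD for *all* subjects against each bootstrap reference and returns the
#' group-wise means per replicate.
#'
#' @param fcs list of per-subject (sparsified) [ConnectivityMatrix-class]
#' @param initLabels template labels initializing the reference GMM
#' @param gg a [GeodesicGraph-class]
#' @param cohort cohort `data.frame` aligned with `fcs`
#' @param fraction subsample fraction (default 0.5); each replicate uses
#'   `floor(fraction * n)` subjects
#' @param nBoot number of bootstrap replicates (>= 2)
#' @param seed integer RNG seed
#' @param nComponents,alpha,diffusionTime embedding parameters
#' @param refit per-subject EM refit flag (see [clusterIndividual()])
#' @return data.frame with `replicate`, `group`, `dice`, `jaccard`, `msd`
#' @export
referenceBootstrap <- function(fcs, initLabels, gg, cohort, fraction = 0.5,
                               nBoot = 10L, seed = 1L, nComponents = 10L,
                               alpha = 0.5, diffusionTime = 1,
                               refit = TRUE) {
  stopifnot(nBoot >= 2L, length(fcs) == nrow(cohort))
  n <- length(fcs)
  m <- floor(fraction * n)
  if (m < 2L) stop("subsample too small to build a reference embedding")
  embs <- lapply(fcs, function(f)
    diffusionMap(affinityMatrix(f), alpha = alpha,
                 diffusionTime = diffusionTime, nComponents = nComponents))
  subsets <- withr::with_seed(seed, {
    lapply(seq_len(nBoot), function(b) sort(sample.int(n, m)))
  })
  out <- lapply(seq_len(nBoot), function(b) {
    meanFC <- groupAverage(fcs[subsets[[b]]],
                           retainFraction = fcs[[1L]]@retainFraction)
    ref <- buildReference(meanFC, alpha = alpha,
                          diffusionTime = diffusionTime,
                          nComponents = nComponents)
    refGMM <- fitReferenceGMM(ref, initLabels)
    refAsn <- refGMM$assignment
    per <- vapply(seq_len(n), function(i) {
      aligned <- changeOfBasis(embs[[i]], ref)$aligned
      asn <- clusterIndividual(aligned, refGMM, refit = refit,
                               source = cohort$id[i])
      ov <- networkOverlap(asn, refAsn, gg)
      ok <- !is.na(ov$msd)
      w <- ov$sizeReference
      c(dice = cortexwideSummary(ov$dice, w),
        jaccard = cortexwideSummary(ov$jaccard, w),
        msd = cortexwideSummary(ov$msd[ok], w[ok]))
    }, numeric(3L))
    agg <- t(vapply(levels(cohort$group), function(gr)
      rowMeans(per[, cohort$group == gr, drop = FALSE]), numeric(3L)))
    data.frame(replicate = b, group = rownames(agg), dice = agg[, "dice"],
               jaccard = agg[, "jaccard"], msd = agg[, "msd"],
               row.names = NULL)
  })
  do.call(rbind, out)
}
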