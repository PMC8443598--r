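## Idiosyncrasy descriptors: per-parcel surface and diffusion distance,
## network-level overlap/shift scores, entropy of group probability maps,
## cortex-wide weighted summaries and principal-gradient stratification.

labelsOf <- function(x) {
  if (is(x, "NetworkAssignment")) x@hardLabels else as.integer(x)
}

#' Per-parcel surface distance (SD)
#'
#' For each parcel, the geodesic distance (along the surface, via
#' Dijkstra-derived shortest paths) to the closest parcel of the *same*
#' network in the reference assignment. Zero wherever the subject's label
#' agrees with the reference.
#'
#' @param subject subject labels (integer vector or
#'   [NetworkAssignment-class])
#' @param reference reference labels (same forms)
#' @param gg a [GeodesicGraph-class]
#' @return numeric vector of per-parcel distances (length units)
#' @export
surfaceDistance <- function(subject, reference, gg) {
  subj <- labelsOf(subject)
  ref <- labelsOf(reference)
  D <- gg@dist
  stopifnot(length(subj) == length(ref), length(ref) == nrow(D))
  out <- numeric(length(subj))
  for (cc in unique(subj)) {
    refC <- which(ref == cc)
    if (!length(refC))
      stop("network ", cc, " absent from the reference assignment")
    rows <- which(subj == cc)
    out[rows] <- apply(D[rows, refC, drop = FALSE], 1L, min)
  }
  out
}

#' Per-parcel diffusion distance (DD)
#'
#' For each parcel p assigned to network c in the subject, the minimum
#' *squared* Euclidean distance in the aligned embedding space between p's
#' coordinates and the coordinates of any reference parcel belonging to the
#' same network c.
#'
#' @param aligned the subject's aligned [Embedding-class]
#' @param reference the reference [Embedding-class]
#' @param subject subject network labels (vector or assignment)
#' @param referenceAssignment reference network labels (vector or assignment)
#' @return numeric vector of per-parcel squared distances
#' @export
diffusionDistance <- function(aligned, reference, subject,
                              referenceAssignment) {
  phi <- aligned@coordinates
  psi <- reference@coordinates
  subj <- labelsOf(subject)
  ref <- labelsOf(referenceAssignment)
  stopifnot(nrow(phi) == nrow(psi), length(subj) == nrow(phi),
            length(ref) == nrow(psi))
  out <- numeric(length(subj))
  sq1 <- rowSums(phi^2)
  sq2 <- rowSums(psi^2)
  for (cc in unique(subj)) {
    refC <- which(ref == cc)
    if (!length(refC))
      stop("network ", cc, " absent from the reference assignment")
    rows <- which(subj == cc)
    cross <- phi[rows, , drop = FALSE] %*% t(psi[refC, , drop = FALSE])
    d2 <- outer(sq1[rows], sq2[refC], `+`) - 2 * cross
    out[rows] <- pmax(apply(d2, 1L, min), 0)
  }
  out
}

#' Dice similarity coefficient between parcel sets
#'
#' `2|A ∩ B| / (|A| + |B|)`; returns 0 when `B` is empty.
#' @param a,b integer vectors of parcel indices (reference and individual
#'   sets of one network)
#' @export
diceCoef <- function(a, b) {
  stopifnot(length(a) > 0L)
  if (!length(b)) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Jaccard index between parcel sets
#'
#' `|A ∩ B| / |A ∪ B|`; returns 0 when `B` is empty.
#' @param a,b integer vectors of parcel indices
#' @export
jaccardIndex <- function(a, b) {
  stopifnot(length(a) > 0L)
  if (!length(b)) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Symmetric mean surface distance (MSD) between parcel sets
#'
#' `(sum_{a in A} d(a, B) + sum_{b in B} d(b, A)) / (|A| + |B|)`, where
#' `d(x, S)` is the geodesic distance from parcel x to the closest parcel
#' in set S (zero when x is in S). Zero exactly when the two sets
#' coincide.
#'
#' @param a,b integer vectors of parcel indices (both non-empty)
#' @param gg a [GeodesicGraph-class]
#' @export
meanSurfaceDistance <- function(a, b, gg) {
  if (!length(b)) stop("individual set B is empty")
  stopifnot(length(a) > 0L)
  D <- gg@dist
  dab <- apply(D[a, b, drop = FALSE], 1L, min)
  dba <- apply(D[b, a, drop = FALSE], 1L, min)
  (sum(dab) + sum(dba)) / (length(a) + length(b))
}

#' Per-parcel entropy of group probability maps
#'
#' Averages the posterior network-probability matrices across the subjects
#' of a group and returns the per-parcel Shannon entropy (natural log,
#' `0 * log 0 = 0`) of the averaged distribution. Low entropy: the location
#' is assigned to the same network in most subjects; high entropy (bounded
#' by `log(N)` at uniformity): the probability mass spreads across
#' networks, i.e. high inter-individual variability.
#'
#' @param posteriorList list of P x N posterior matrices (or
#'   [NetworkAssignment-class] objects)
#' @return numeric vector of per-parcel entropies (nats)
#' @export
networkEntropy <- function(posteriorList) {
  stopifnot(length(posteriorList) >= 1L)
  mats <- lapply(posteriorList, function(x)
    if (is(x, "NetworkAssignment")) x@posteriors else x)
  pbar <- Reduce(`+`, mats) / length(mats)
  -rowSums(ifelse(pbar > 0, pbar * log(pbar), 0))
}

#' Per-network parcel counts
#'
#' @param assignment labels (vector or [NetworkAssignment-class])
#' @param nNetworks total number of networks (zero counts reported for
#'   networks absent from a subject)
#' @return integer vector of counts summing to P
#' @export
networkSize <- function(assignment, nNetworks = max(labelsOf(assignment))) {
  tabulate(labelsOf(assignment), nNetworks)
}

#' Cortex-wide weighted summary of network scores
#'
#' Weighted average of per-network scores using the reference network sizes
#' as weights.
#'
#' @param scores numeric per-network scores
#' @param referenceSizes per-network reference parcel counts
#' @export
cortexwideSummary <- function(scores, referenceSizes) {
  stopifnot(length(scores) == length(referenceSizes))
  sum(referenceSizes * scores) / sum(referenceSizes)
}

#' Network-level overlap and shift summary for one subject
#'
#' Computes, per network, the Dice and Jaccard overlap between the
#' subject's and the reference parcel sets, the symmetric mean surface
#' distance, and both parcel counts.
#'
#' @param subject,reference labels (vectors or assignments)
#' @param gg a [GeodesicGraph-class]
#' @return data.frame with columns `network`, `dice`, `jaccard`, `msd`,
#'   `sizeSubject`, `sizeReference`
#' @export
networkOverlap <- function(subject, reference, gg) {
  subj <- labelsOf(subject)
  ref <- labelsOf(reference)
  nNet <- max(ref)
  res <- lapply(seq_len(nNet), function(cc) {
    a <- which(ref == cc)
    b <- which(subj == cc)
    data.frame(network = cc,
               dice = diceCoef(a, b),
               jaccard = jaccardIndex(a, b),
               msd = if (length(b)) meanSurfaceDistance(a, b, gg) else NA_real_,
               sizeSubject = length(b), sizeReference = length(a))
  })
  do.call(rbind, res)
}

#' Idiosyncrasy maps for one subject
#'
#' Bundles the per-parcel SD and DD maps for one subject.
#'
#' @param subjectAssignment,referenceAssignment [NetworkAssignment-class]
#'   objects
#' @param alignedEmbedding,referenceEmbedding [Embedding-class] objects
#' @param gg a [GeodesicGraph-class]
#' @return data.frame with columns `parcel`, `sd`, `dd`
#' @export
idiosyncrasyMaps <- function(subjectAssignment, referenceAssignment,
                             alignedEmbedding, referenceEmbedding, gg) {
  sdv <- surfaceDistance(subjectAssignment, referenceAssignment, gg)
  ddv <- diffusionDistance(alignedEmbedding, referenceEmbedding,
                           subjectAssignment, referenceAssignment)
  data.frame(parcel = seq_along(sdv), sd = sdv, dd = ddv)
}

#' Stratify an idiosyncrasy map along the principal gradient
#'
#' Bins parcels into `nBins` quantile bins of the first component of the
#' reference embedding (the principal connectivity gradient, ordering
#' cortex from sensory/motor to transmodal poles) and reports the mean of
#' the supplied map per bin plus a rank-trend statistic (Spearman
#' correlation of bin index with bin mean; 0 with `constant = TRUE` when
#' the map is constant).
#'
#' @param values per-parcel idiosyncrasy values
#' @param reference the reference [Embedding-class]
#' @param nBins number of quantile bins (default 10)
#' @return list with `binMeans`, `spearman`, `constant`
#' @export
gradientStratification <- function(values, reference, nBins = 10L) {
  grad <- reference@coordinates[, 1L]
  P <- length(grad)
  if (nBins > P) stop("nBins exceeds the number of parcels")
  stopifnot(length(values) == P)
  br <- quantile(grad, probs = seq(0, 1, length.out = nBins + 1L))
  br[1L] <- -Inf; br[nBins + 1L] <- Inf
  bins <- cut(grad, breaks = unique(br), labels = FALSE)
  nb <- max(bins)
  means <- vapply(seq_len(nb), function(b) mean(values[bins == b]),
                  numeric(1L))
  if (sd(values) == 0 || sd(means) == 0)
    return(list(binMeans = means, spearman = 0, constant = TRUE))
  rho <- cor(seq_len(nb), means, method = "spearman")
  list(binMeans = means, spearman = rho, constant = FALSE)
}
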