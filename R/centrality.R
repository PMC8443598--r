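## Degree and eigenvector centrality, and the group contrasts asking
## whether centrality differences survive controlling for idiosyncrasy.

#' Degree centrality of a correlation matrix
#'
#' Number of connections per parcel whose raw Pearson correlation exceeds
#' the threshold (strict `>`, default 0.2; computed on unsparsified,
#' non-Fisher-z correlations, diagonal excluded). Negative correlations
#' never count.
#'
#' @param r P x P symmetric correlation matrix (e.g. [corMatrix()])
#' @param threshold correlation cutoff in (0, 1)
#' @return integer vector of per-parcel counts
#' @export
degreeCentrality <- function(r, threshold = 0.2) {
  stopifnot(threshold > 0, threshold < 1, nrow(r) == ncol(r))
  if (max(abs(r - t(r))) > 1e-9) stop("correlation matrix must be symmetric")
  a <- r > threshold
  diag(a) <- FALSE
  as.integer(rowSums(a))
}

#' Eigenvector centrality of a connectivity matrix
#'
#' Each parcel's entry in the leading eigenvector of the (non-negative)
#' connectivity matrix, normalized to unit Euclidean norm with all entries
#' non-negative (Perron-Frobenius). Negative weights are floored at zero
#' with a message; an ambiguous leading eigenspace (disconnected graph) is
#' an error.
#'
#' @param w P x P symmetric connectivity matrix
#' @return numeric vector of per-parcel scores
#' @export
eigenvectorCentrality <- function(w) {
  stopifnot(nrow(w) == ncol(w))
  if (max(abs(w - t(w))) > 1e-9) stop("connectivity matrix must be symmetric")
  if (min(w) < 0) {
    message("eigenvectorCentrality: flooring ", sum(w < 0),
            " negative entries at 0")
    w[w < 0] <- 0
  }
  eig <- eigen(w, symmetric = TRUE)
  lam <- eig$values
  if (length(lam) > 1L && (lam[1L] - lam[2L]) <= 1e-10 * max(1, abs(lam[1L])))
    stop("ambiguous leading eigenspace (degenerate largest eigenvalue)")
  v <- eig$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8)
    stop("leading eigenvector is not sign-definite; graph may be disconnected")
  v <- pmax(v, 0)
  v / sqrt(sum(v^2))
}

#' Group contrast on centrality, before and after idiosyncrasy control
#'
#' Runs the parcel-wise GLM group contrast on per-subject centrality maps
#' with TFCE + max-statistic permutation correction, then (when
#' `withIdiosyncrasy = TRUE`) repeats it adding each subject's per-parcel
#' SD and DD as additional covariates of the parcel's own model. A drop in
#' the number of significant parcels after controlling indicates that the
#' apparent connectivity alterations reflect network idiosyncrasy.
#'
#' @param centrality n x P matrix of per-subject centrality maps
#' @param cohort cohort `data.frame`
#' @param adjacency parcel adjacency edges
#' @param sdMaps,ddMaps n x P matrices of per-subject surface / diffusion
#'   distance maps (required when `withIdiosyncrasy = TRUE`)
#' @param withIdiosyncrasy run the controlled second pass (default TRUE)
#' @param covariates nuisance covariates for [designMatrix()]
#' @param nPerm,seed,alpha,E,H,nsteps see [permutationCorrect()]
#' @return list with `before` and `after` ([permutationCorrect()] results;
#'   `after` is NULL when not requested) and the significant-parcel counts
#'   `nSigBefore`, `nSigAfter`
#' @export
centralityContrast <- function(centrality, cohort, adjacency,
                               sdMaps = NULL, ddMaps = NULL,
                               withIdiosyncrasy = TRUE,
                               covariates = c("site", "sex", "age"),
                               nPerm = 1000L, seed = 1L, alpha = 0.05,
                               E = 0.5, H = 2, nsteps = 100L) {
  design <- designMatrix(cohort, covariates)
  before <- permutationCorrect(centrality, design, adjacency, nPerm = nPerm,
                               seed = seed, permuteWithin = cohort$site,
                               E = E, H = H, nsteps = nsteps, alpha = alpha)
  after <- NULL
  if (withIdiosyncrasy) {
    if (is.null(sdMaps) || is.null(ddMaps))
      stop("sdMaps and ddMaps are required when withIdiosyncrasy = TRUE")
    after <- permutationCorrect(centrality, design, adjacency, nPerm = nPerm,
                                seed = seed, permuteWithin = cohort$site,
                                extraCovariates = list(sd = sdMaps,
                                                       dd = ddMaps),
                                E = E, H = H, nsteps = nsteps, alpha = alpha)
  }
  list(before = before, after = after,
       nSigBefore = sum(before$pCorr < alpha),
       nSigAfter = if (is.null(after)) NA_integer_
                   else sum(after$pCorr < alpha))
}
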