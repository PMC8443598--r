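## Gaussian-mixture identification of intrinsic connectivity networks in
## embedding space. EM with full covariances, deterministic initialization
## from a template labeling (no random restarts), so results are exactly
## reproducible.

## log N(x | mu, Sigma) for all rows of x; Sigma regularized/cholesky'd by
## caller. Returns the log-density vector.
logDmvnorm <- function(x, mu, cholS) {
  xc <- sweep(x, 2L, mu)
  ## solve t(R) y = t(xc)  => y = backsolve
  y <- backsolve(cholS, t(xc), transpose = TRUE)
  -0.5 * colSums(y^2) - sum(log(diag(cholS))) -
    0.5 * ncol(x) * log(2 * pi)
}

## Cholesky with escalating diagonal regularization (base 1e-6).
safeChol <- function(sigma, reg = 1e-6) {
  K <- nrow(sigma)
  for (mult in c(1, 10, 100, 1000, 1e4)) {
    ch <- tryCatch(chol(sigma + diag(reg * mult, K)), error = function(e) NULL)
    if (!is.null(ch)) {
      if (mult > 1)
        warning("covariance regularization escalated to ", reg * mult)
      return(ch)
    }
  }
  stop("covariance matrix could not be regularized")
}

## Mixture parameters from a hard labeling.
gmmFromLabels <- function(x, labels, nNet, reg = 1e-6) {
  K <- ncol(x)
  means <- matrix(NA_real_, nNet, K)
  covs <- vector("list", nNet)
  weights <- numeric(nNet)
  for (k in seq_len(nNet)) {
    idx <- labels == k
    if (!any(idx)) stop("empty initialization group for network ", k)
    xi <- x[idx, , drop = FALSE]
    means[k, ] <- colMeans(xi)
    xc <- sweep(xi, 2L, means[k, ])
    covs[[k]] <- crossprod(xc) / nrow(xi) + diag(reg, K)
    weights[k] <- mean(idx)
  }
  list(means = means, covs = covs, weights = weights, reg = reg)
}

## Core EM. Returns params + posteriors + log-likelihood trace.
gmmEM <- function(x, params, maxIter = 500L, tol = 1e-6, reg = 1e-6) {
  n <- nrow(x)
  nNet <- length(params$weights)
  loglik <- numeric(0L)
  for (iter in seq_len(maxIter)) {
    lp <- vapply(seq_len(nNet), function(k) {
      log(params$weights[k]) +
        logDmvnorm(x, params$means[k, ], safeChol(params$covs[[k]], reg))
    }, numeric(n))
    mx <- apply(lp, 1L, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    resp <- exp(lp - lse)
    loglik <- c(loglik, ll)
    if (iter > 1L) {
      rel <- abs(ll - loglik[iter - 1L]) /
        max(1, abs(loglik[iter - 1L]))
      if (rel < tol) break
    }
    nk <- colSums(resp)
    ## a component starved of responsibility keeps its previous parameters
    ## (with a floored weight) rather than collapsing the whole fit
    alive <- nk > ncol(x) * .Machine$double.eps
    params$weights <- pmax(nk / n, 1e-12)
    for (k in which(alive)) {
      params$means[k, ] <- colSums(resp[, k] * x) / nk[k]
      xc <- sweep(x, 2L, params$means[k, ])
      params$covs[[k]] <- crossprod(xc * resp[, k], xc) / nk[k] +
        diag(reg, ncol(x))
    }
  }
  lp <- vapply(seq_len(nNet), function(k) {
    log(params$weights[k]) +
      logDmvnorm(x, params$means[k, ], safeChol(params$covs[[k]], reg))
  }, numeric(n))
  mx <- apply(lp, 1L, max)
  lse <- mx + log(rowSums(exp(lp - mx)))
  resp <- exp(lp - lse)
  list(params = params, posteriors = resp, loglik = loglik)
}

## Posterior responsibilities under fixed parameters (no refit).
gmmPosterior <- function(x, params, reg = 1e-6) {
  n <- nrow(x)
  nNet <- length(params$weights)
  lp <- vapply(seq_len(nNet), function(k) {
    log(params$weights[k]) +
      logDmvnorm(x, params$means[k, ], safeChol(params$covs[[k]], reg))
  }, numeric(n))
  mx <- apply(lp, 1L, max)
  exp(lp - (mx + log(rowSums(exp(lp - mx)))))
}

makeAssignment <- function(posteriors, source) {
  new("NetworkAssignment",
      hardLabels = as.integer(max.col(posteriors, ties.method = "first")),
      posteriors = posteriors, source = source)
}

#' Fit the reference Gaussian mixture model
#'
#' Clusters the reference embedding into `max(initLabels)` components
#' (7 intrinsic connectivity networks under the default template) using a
#' full-covariance Gaussian mixture. EM is initialized with the means,
#' covariances and weights of the template label groups, so component k
#' stays identified with template network k. Convergence: relative
#' log-likelihood change below `tol` or `maxIter` iterations. Degenerate
#' covariances are regularized by `reg` on the diagonal.
#'
#' @param reference the reference [Embedding-class]
#' @param initLabels integer parcel -> network template labels covering all
#'   networks
#' @param maxIter,tol,reg EM controls (defaults 500, 1e-6, 1e-6)
#' @return a list with `model` (mixture parameters and log-likelihood
#'   trace) and `assignment` (a [NetworkAssignment-class] with
#'   `source = "reference"`)
#' @export
fitReferenceGMM <- function(reference, initLabels, maxIter = 500L,
                            tol = 1e-6, reg = 1e-6) {
  x <- reference@coordinates
  nNet <- max(initLabels)
  if (!all(seq_len(nNet) %in% initLabels))
    stop("initLabels must cover every network")
  params <- gmmFromLabels(x, initLabels, nNet, reg)
  fit <- gmmEM(x, params, maxIter, tol, reg)
  list(model = fit, assignment = makeAssignment(fit$posteriors, "reference"))
}

#' Cluster an aligned individual embedding
#'
#' Assigns each parcel of an aligned individual embedding to a network.
#' By default (`refit = TRUE`) a per-subject EM refit is run, initialized
#' from the reference mixture parameters; with `refit = FALSE` parcels are
#' simply assigned under the (unrefit) reference model. If the per-subject
#' EM fails, assignment falls back to the reference model with a warning.
#' After refitting, components are matched back to reference networks by
#' nearest mean; any remapping is reported via `message()`.
#'
#' @param aligned an aligned [Embedding-class] (see [changeOfBasis()])
#' @param referenceGMM result of [fitReferenceGMM()]
#' @param refit logical, run the per-subject EM refit (default TRUE)
#' @param source character id stored in the assignment
#' @param maxIter,tol,reg EM controls
#' @return a [NetworkAssignment-class]
#' @export
clusterIndividual <- function(aligned, referenceGMM, refit = TRUE,
                              source = "subject", maxIter = 500L,
                              tol = 1e-6, reg = 1e-6) {
  x <- aligned@coordinates
  refParams <- referenceGMM$model$params
  if (!refit)
    return(makeAssignment(gmmPosterior(x, refParams, reg), source))
  fit <- tryCatch(gmmEM(x, refParams, maxIter, tol, reg),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("per-subject EM failed for ", source,
            "; assigning under the reference model")
    return(makeAssignment(gmmPosterior(x, refParams, reg), source))
  }
  ## guard against component drift: match refit components to reference
  ## components by nearest mean
  nNet <- length(refParams$weights)
  dists <- as.matrix(stats::dist(rbind(fit$params$means, refParams$means)))
  dists <- dists[seq_len(nNet), nNet + seq_len(nNet), drop = FALSE]
  mapping <- apply(dists, 1L, which.min)
  if (!identical(as.integer(mapping), seq_len(nNet))) {
    if (anyDuplicated(mapping)) {
      warning("ambiguous component drift for ", source,
              "; assigning under the reference model")
      return(makeAssignment(gmmPosterior(x, refParams, reg), source))
    }
    message("clusterIndividual: remapping drifted components for ", source)
    post <- fit$posteriors
    post[, mapping] <- fit$posteriors
    fit$posteriors <- post
  }
  makeAssignment(fit$posteriors, source)
}
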