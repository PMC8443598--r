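## General linear model machinery for network-level and parcel-wise
## contrasts, effect sizes, FDR, and the age / severity analyses.

#' Build a design matrix for group contrasts
#'
#' Intercept + group indicator (typical = 0, atypical = 1) + nuisance
#' covariates (site one-hot, sex, age by default; categorical covariates
#' are expanded via treatment contrasts). The returned contrast vector
#' selects the group effect.
#'
#' @param cohort cohort `data.frame` with a `group` factor
#' @param covariates character vector of cohort column names to adjust for
#' @param extra optional named list of extra numeric covariate vectors
#'   (e.g. surface area)
#' @return list with `X` (n x k matrix), `contrast` (length-k vector) and
#'   `groupCol` (column index of the group indicator)
#' @export
designMatrix <- function(cohort, covariates = c("site", "sex", "age"),
                         extra = NULL) {
  stopifnot(is.factor(cohort$group))
  cohort <- droplevels(cohort)  # unused factor levels give all-zero columns
  covariates <- usableCovariates(cohort, covariates)
  rhs <- paste(c("group", covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = cohort)
  if (!is.null(extra))
    for (nm in names(extra)) {
      X <- cbind(X, extra[[nm]])
      colnames(X)[ncol(X)] <- nm
    }
  gcol <- grep("^group", colnames(X))
  stopifnot(length(gcol) == 1L)
  contrast <- as.numeric(seq_len(ncol(X)) == gcol)
  list(X = X, contrast = contrast, groupCol = gcol)
}

## Factor covariates that collapse to a single level (tiny or heavily
## filtered cohorts) carry no information and break model.matrix; drop
## them with a message.
usableCovariates <- function(cohort, covariates) {
  keep <- vapply(covariates, function(v) {
    x <- cohort[[v]]
    !(is.factor(x) && nlevels(droplevels(x)) < 2L)
  }, logical(1))
  if (any(!keep))
    message("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "))
  covariates[keep]
}

#' GLM contrast t-test
#'
#' Ordinary least squares of `y` on `X`; returns the t statistic for the
#' linear contrast `c'beta` with a two-sided p value on `n - rank(X)`
#' degrees of freedom. Rank deficiency is an error naming the collinear
#' columns. Perfect fits (residual sum of squares numerically zero) are
#' reported with `exactFit = TRUE` and an infinite t.
#'
#' @param y numeric response vector
#' @param X design matrix (n x k, n > k)
#' @param contrast numeric contrast vector of length k
#' @return list with `t`, `p`, `estimate`, `se`, `df`, `exactFit`
#' @export
glmContrast <- function(y, X, contrast) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(y) == n, length(contrast) == k, n > k)
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    if (is.null(bad)) bad <- qx$pivot[(qx$rank + 1L):k]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- n - k
  rss <- sum(res^2)
  xtxinv <- chol2inv(qr.R(qx))
  est <- sum(contrast * beta)
  tss <- sum((y - mean(y))^2)
  exactFit <- rss <= 1e-12 * max(tss, 1)
  sigma2 <- rss / df
  se <- sqrt(max(sigma2, 0) * drop(t(contrast) %*% xtxinv %*% contrast))
  tval <- if (se == 0) {
    if (est == 0) 0 else sign(est) * Inf
  } else est / se
  pval <- if (is.infinite(tval)) 0 else 2 * pt(-abs(tval), df)
  list(t = tval, p = pval, estimate = est, se = se, df = df,
       exactFit = exactFit)
}

## Vectorized OLS contrast t over the columns of a response matrix.
glmContrastMap <- function(Y, X, contrast) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(nrow(Y) == n)
  qx <- qr(X)
  if (qx$rank < k) stop("design matrix is rank deficient")
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  df <- n - k
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(contrast) %*% chol2inv(qr.R(qx)) %*% contrast)
  est <- drop(t(contrast) %*% beta)
  tval <- est / sqrt(pmax(sigma2 * cvar, .Machine$double.xmin))
  tval[sigma2 == 0 & est == 0] <- 0
  tval
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values: `p_(i) * m / i`, monotonized from the largest
#' p downwards and capped at 1.
#'
#' @param p numeric vector of p values in \[0, 1\]
#' @return adjusted p values in the original order
#' @export
fdrBH <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Cohen's d between two groups
#'
#' Mean difference (second level minus first) divided by the pooled
#' standard deviation (n - 1 denominators).
#'
#' @param y numeric values
#' @param group two-level factor (or coercible); first level is the
#'   baseline
#' @return numeric d
#' @export
cohensD <- function(y, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L)
  y0 <- y[group == levels(group)[1L]]
  y1 <- y[group == levels(group)[2L]]
  stopifnot(length(y0) >= 2L, length(y1) >= 2L)
  sp2 <- ((length(y0) - 1) * var(y0) + (length(y1) - 1) * var(y1)) /
    (length(y0) + length(y1) - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero")
  (mean(y1) - mean(y0)) / sqrt(sp2)
}

#' Severity association of a descriptor, controlling for covariates
#'
#' For each network column of `descriptor`: z-score with respect to the
#' typical group (its mean and sd), regress out the nuisance covariates
#' (age, sex, site by default), then correlate the residuals with the
#' severity score among atypical subjects. P values are BH-FDR corrected
#' across networks.
#'
#' @param descriptor n x N matrix (or vector) of per-subject network
#'   descriptors
#' @param cohort cohort `data.frame` with `group` and `severity`
#' @param covariates cohort columns to regress out
#' @return data.frame with `network`, `r`, `p`, `pAdj`
#' @export
severityCorrelation <- function(descriptor, cohort,
                                covariates = c("age", "sex", "site")) {
  descriptor <- as.matrix(descriptor)
  aty <- cohort$group == "atypical"
  if (sum(aty) < 4L) stop("fewer than 4 atypical subjects")
  typ <- cohort$group == "typical"
  cohort <- droplevels(cohort)
  covariates <- usableCovariates(cohort, covariates)
  Z <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", covariates), collapse = " + "))),
    data = cohort)
  res <- lapply(seq_len(ncol(descriptor)), function(j) {
    y <- descriptor[, j]
    zy <- (y - mean(y[typ])) / sd(y[typ])
    r <- stats::lm.fit(Z, zy)$residuals
    ct <- cor.test(r[aty], cohort$severity[aty])
    data.frame(network = j, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$pAdj <- fdrBH(out$p)
  out
}

#' Age effect on an idiosyncrasy descriptor
#'
#' GLM `y ~ group + site + sex + age + group:age`; reports the age-slope
#' and group-by-age interaction t statistics. `subset` reruns the model on
#' children (age < 18, strict) or adults (age >= 18) only.
#'
#' @param y per-subject descriptor values
#' @param cohort cohort `data.frame`
#' @param subset one of `"all"`, `"child"`, `"adult"`
#' @return list with `age` and `interaction` (each a [glmContrast()]
#'   result) and `n`
#' @export
ageEffect <- function(y, cohort, subset = c("all", "child", "adult")) {
  subset <- match.arg(subset)
  keep <- switch(subset, all = rep(TRUE, nrow(cohort)),
                 child = cohort$age < 18, adult = cohort$age >= 18)
  co <- droplevels(cohort[keep, , drop = FALSE])
  y <- y[keep]
  covs <- usableCovariates(co, c("site", "sex"))
  rhs <- paste(c("group", covs, "age", "group:age"), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = co)
  ageCol <- which(colnames(X) == "age")
  intCol <- grep(":age$", colnames(X))
  cAge <- as.numeric(seq_len(ncol(X)) == ageCol)
  cInt <- as.numeric(seq_len(ncol(X)) %in% intCol)
  list(age = glmContrast(y, X, cAge),
       interaction = glmContrast(y, X, cInt), n = sum(keep))
}
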