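## Subject-level and group-average functional connectivity, plus cohort QC.

#' Compute a subject's functional connectivity matrix
#'
#' Pearson correlations between all parcel time series, clipped to
#' `|r| <= 1 - 1e-7`, Fisher-z transformed (`atanh`), and row-sparsified to
#' keep only the top `retainFraction` (default 10%) most positive z values
#' per row, diagonal excluded (`k = round(retainFraction * (P - 1))`
#' entries per row; ties at the retention boundary resolved in favor of the
#' lower column index). The matrix may be asymmetric after row-wise
#' retention. Raw correlations are kept alongside for centrality analyses.
#'
#' @param ts P x T time-series matrix (e.g. from
#'   [simulateSubjectTimeseries()])
#' @param retainFraction fraction of off-diagonal entries kept per row,
#'   in (0, 1]
#' @param sparsify logical; set FALSE to keep the dense Fisher-z matrix
#'   (retention mask still computed)
#' @return a [ConnectivityMatrix-class]
#' @export
computeFC <- function(ts, retainFraction = 0.10, sparsify = TRUE) {
  stopifnot(retainFraction > 0, retainFraction <= 1)
  ts <- unclass(ts)
  v <- apply(ts, 1L, var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    stop("zero-variance parcel(s): ", paste(bad, collapse = ", "))
  }
  r <- cor(t(ts))
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  P <- nrow(z)
  retained <- rowRetainMask(z, round(retainFraction * (P - 1L)))
  new("ConnectivityMatrix", z = z, correlations = r, retained = retained,
      sparsified = sparsify, retainFraction = retainFraction)
}

## Per-row top-k mask over off-diagonal entries; ties broken by lower
## column index (order() is stable, secondary key = column index).
rowRetainMask <- function(z, k) {
  P <- nrow(z)
  mask <- matrix(FALSE, P, P)
  for (i in seq_len(P)) {
    cols <- setdiff(seq_len(P), i)
    ord <- cols[order(-z[i, cols], cols)]
    mask[i, ord[seq_len(k)]] <- TRUE
  }
  mask
}

#' Group-average connectivity matrix
#'
#' Averages the *unsparsified* Fisher-z matrices of all subjects
#' element-wise and applies row-wise retention once to the mean (averaging
#' sparsified matrices would dilute the retained-set semantics). Raw
#' correlations are likewise averaged.
#'
#' @param fcs list of [ConnectivityMatrix-class] objects of identical shape
#' @param retainFraction fraction retained per row of the mean matrix
#' @return a sparsified [ConnectivityMatrix-class]
#' @export
groupAverage <- function(fcs, retainFraction = 0.10) {
  stopifnot(length(fcs) >= 2L)
  P <- nrow(fcs[[1L]]@z)
  if (!all(vapply(fcs, function(f) nrow(f@z) == P && ncol(f@z) == P,
                  logical(1L))))
    stop("all connectivity matrices must have identical shape")
  z <- Reduce(`+`, lapply(fcs, function(f) f@z)) / length(fcs)
  r <- Reduce(`+`, lapply(fcs, function(f) f@correlations)) / length(fcs)
  retained <- rowRetainMask(z, round(retainFraction * (P - 1L)))
  new("ConnectivityMatrix", z = z, correlations = r, retained = retained,
      sparsified = TRUE, retainFraction = retainFraction)
}

#' Quality-control filter on framewise displacement
#'
#' Retains subjects whose mean framewise displacement does not exceed
#' `fdMax` (subjects with fd strictly greater than the cutoff, 0.3 mm by
#' default, are excluded). Excluded ids are reported via `message()`.
#'
#' @param cohort a cohort `data.frame` with an `fd` column
#' @param fdMax exclusion cutoff in mm
#' @return the filtered cohort (attributes `shiftMagnitudes` /
#'   `realizedShift`, when present, are subset accordingly)
#' @export
qcFilter <- function(cohort, fdMax = 0.3) {
  if (is.null(cohort$fd)) stop("cohort has no 'fd' column")
  keep <- cohort$fd <= fdMax
  if (any(!keep))
    message("qcFilter: excluding ", sum(!keep), " subject(s): ",
            paste(cohort$id[!keep], collapse = ", "))
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("shiftMagnitudes")) {
    m <- attr(cohort, a)
    if (!is.null(m)) attr(out, a) <- m[keep, , drop = FALSE]
  }
  rs <- attr(cohort, "realizedShift")
  if (!is.null(rs)) attr(out, "realizedShift") <- rs[keep]
  if (nrow(out) == 0L) warning("qcFilter: no subjects retained")
  out
}
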