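## Core S4 containers. Validity checks encode the structural invariants the
## rest of the pipeline relies on; accessors below are the supported way to
## reach slot contents.

#' SurfaceMesh: a triangulated sphere
#'
#' Triangle mesh whose vertices lie on a sphere of radius `sphereRadius`.
#' Stands in for the (spherically registered) cortical surface on which
#' geodesic distances are measured.
#'
#' @slot vertices numeric matrix, V x 3 coordinates (length units).
#' @slot faces integer matrix, F x 3 vertex indices (1-based).
#' @slot sphereRadius numeric scalar, sphere radius in length units.
#' @seealso [makeSphereMesh()]
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 sphereRadius = "numeric"))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces; r <- object@sphereRadius
  if (ncol(v) != 3L) return("vertices must be a V x 3 matrix")
  if (ncol(f) != 3L) return("faces must be an F x 3 matrix")
  if (length(r) != 1L || r <= 0) return("sphereRadius must be a positive scalar")
  if (min(f) < 1L || max(f) > nrow(v)) return("face indices out of range")
  if (!all(seq_len(nrow(v)) %in% as.vector(f)))
    return("every vertex must be referenced by at least one face")
  dev <- abs(sqrt(rowSums(v^2)) - r)
  if (max(dev) > 1e-6 * r)
    return("vertices deviate from the sphere surface by more than 1e-6 * radius")
  TRUE
})

#' Parcellation: parcel membership and geometry on a mesh
#'
#' Maps every mesh vertex to one of `nParcels` spatially contiguous parcels
#' and records parcel centroids (projected back to the sphere) plus the
#' parcel adjacency structure (pairs of parcels sharing a mesh edge, with the
#' great-circle centroid distance as edge length).
#'
#' @slot vertexToParcel integer vector, one parcel id in `1..nParcels` per vertex.
#' @slot centroids numeric matrix, nParcels x 3 centroid coordinates.
#' @slot nParcels integer scalar.
#' @slot adjacency integer matrix, E x 2 parcel index pairs.
#' @slot edgeLengths numeric vector of geodesic edge lengths (length units).
#' @seealso [makeParcellation()], [geodesicGraph()]
#' @export
setClass("Parcellation",
  representation(vertexToParcel = "integer", centroids = "matrix",
                 nParcels = "integer", adjacency = "matrix",
                 edgeLengths = "numeric"))

setValidity("Parcellation", function(object) {
  p <- object@nParcels
  if (!all(object@vertexToParcel %in% seq_len(p)))
    return("vertexToParcel contains ids outside 1..nParcels")
  if (!all(tabulate(object@vertexToParcel, p) > 0L))
    return("every parcel must be non-empty")
  if (nrow(object@centroids) != p) return("centroids must have nParcels rows")
  if (nrow(object@adjacency) != length(object@edgeLengths))
    return("adjacency and edgeLengths disagree in length")
  if (length(object@edgeLengths) && any(object@edgeLengths <= 0))
    return("edge lengths must be positive")
  TRUE
})

#' GeodesicGraph: all-pairs geodesic distances between parcels
#'
#' Weighted parcel adjacency graph (edges between parcels sharing a mesh edge,
#' weighted by the geodesic length between their centroids) together with the
#' precomputed all-pairs shortest-path (Dijkstra) distance matrix used by the
#' surface-distance descriptors.
#'
#' @slot dist numeric matrix, P x P symmetric geodesic distances.
#' @slot adjacency integer matrix, E x 2 parcel pairs.
#' @slot weights numeric edge weights (length units).
#' @seealso [geodesicGraph()], [surfaceDistance()], [meanSurfaceDistance()]
#' @export
setClass("GeodesicGraph",
  representation(dist = "matrix", adjacency = "matrix", weights = "numeric"))

setValidity("GeodesicGraph", function(object) {
  d <- object@dist
  if (nrow(d) != ncol(d)) return("dist must be square")
  if (any(!is.finite(d))) return("geodesic graph is disconnected (non-finite distances)")
  if (max(abs(d - t(d))) > 1e-9) return("dist must be symmetric")
  TRUE
})

#' ConnectivityMatrix: Fisher-z functional connectivity
#'
#' Parcel-by-parcel functional connectivity for one subject (or a group
#' average). Raw Pearson correlations are kept alongside the Fisher-z values;
#' when `sparsified` is TRUE, `retained` marks the per-row top fraction of
#' entries (diagonal excluded) and [zMatrix()] returns non-retained entries
#' as zero.
#'
#' @slot z numeric matrix, full Fisher-z values (diagonal zero).
#' @slot correlations numeric matrix of raw Pearson correlations.
#' @slot retained logical matrix of kept entries after row sparsification.
#' @slot sparsified logical flag.
#' @slot retainFraction numeric, fraction of off-diagonal entries kept per row.
#' @seealso [computeFC()], [groupAverage()]
#' @export
setClass("ConnectivityMatrix",
  representation(z = "matrix", correlations = "matrix", retained = "matrix",
                 sparsified = "logical", retainFraction = "numeric"))

setValidity("ConnectivityMatrix", function(object) {
  p <- nrow(object@z)
  if (ncol(object@z) != p) return("z must be square")
  if (any(!is.finite(object@z))) return("z values must be finite")
  if (any(diag(object@retained))) return("diagonal must be excluded from retention")
  if (object@sparsified) {
    k <- round(object@retainFraction * (p - 1L))
    if (!all(rowSums(object@retained) == k))
      return(sprintf("each row must retain exactly %d entries", k))
  }
  TRUE
})

#' Embedding: diffusion-map coordinates
#'
#' Low-dimensional diffusion-map representation of a connectivity matrix.
#' Rows are parcels; columns are the K leading non-trivial diffusion
#' coordinates (eigenvector scaled by eigenvalue^t). `isReference` marks the
#' group-template embedding, `isAligned` marks individual embeddings that have
#' been mapped into the reference space.
#'
#' @slot coordinates numeric matrix, P x K.
#' @slot eigenvalues numeric vector, K non-increasing values (trivial
#'   unit eigenvalue excluded).
#' @slot alpha numeric, density-normalization exponent used.
#' @slot diffusionTime numeric, diffusion time t used.
#' @slot isReference logical flag.
#' @slot isAligned logical flag.
#' @seealso [diffusionMap()], [buildReference()], [changeOfBasis()]
#' @export
setClass("Embedding",
  representation(coordinates = "matrix", eigenvalues = "numeric",
                 alpha = "numeric", diffusionTime = "numeric",
                 isReference = "logical", isAligned = "logical"))

setValidity("Embedding", function(object) {
  if (ncol(object@coordinates) != length(object@eigenvalues))
    return("coordinates column count must match eigenvalue count")
  if (any(!is.finite(object@coordinates))) return("coordinates must be finite")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE) &&
      any(diff(object@eigenvalues) > 1e-10))
    return("eigenvalues must be non-increasing")
  TRUE
})

#' NetworkAssignment: hard labels and posteriors over networks
#'
#' Result of Gaussian-mixture network identification: per-parcel posterior
#' probabilities over the N networks and the hard label (posterior argmax).
#' `source` is `"reference"` for the template assignment or a subject id.
#'
#' @slot hardLabels integer vector, parcel -> network id.
#' @slot posteriors numeric matrix, P x N (rows sum to 1).
#' @slot source character scalar.
#' @seealso [fitReferenceGMM()], [clusterIndividual()]
#' @export
setClass("NetworkAssignment",
  representation(hardLabels = "integer", posteriors = "matrix",
                 source = "character"))

setValidity("NetworkAssignment", function(object) {
  po <- object@posteriors
  if (length(object@hardLabels) != nrow(po))
    return("hardLabels length must equal posterior row count")
  if (any(abs(rowSums(po) - 1) > 1e-9)) return("posterior rows must sum to 1")
  if (!all(object@hardLabels == max.col(po, ties.method = "first")))
    return("hard labels must equal the posterior argmax")
  if (identical(object@source, "reference") &&
      !all(seq_len(ncol(po)) %in% object@hardLabels))
    return("every network must be present in the reference assignment")
  TRUE
})

## ---- accessors --------------------------------------------------------

#' @describeIn SurfaceMesh-class number of vertices
#' @param x an object
#' @export
meshVertices <- function(x) x@vertices

#' @describeIn SurfaceMesh-class faces matrix
#' @export
meshFaces <- function(x) x@faces

#' Number of parcels
#' @param x a `Parcellation`, `GeodesicGraph` or `ConnectivityMatrix`
#' @export
nParcels <- function(x) {
  if (is(x, "Parcellation")) return(x@nParcels)
  if (is(x, "GeodesicGraph")) return(nrow(x@dist))
  if (is(x, "ConnectivityMatrix")) return(nrow(x@z))
  if (is(x, "Embedding")) return(nrow(x@coordinates))
  stop("no parcel count for class ", class(x))
}

#' Parcel centroid coordinates
#' @param x a `Parcellation`
#' @export
parcelCentroids <- function(x) x@centroids

#' Vertex-to-parcel map
#' @param x a `Parcellation`
#' @export
vertexToParcel <- function(x) x@vertexToParcel

#' Geodesic distance matrix
#' @param x a `GeodesicGraph`
#' @export
geoDist <- function(x) x@dist

#' Fisher-z connectivity values
#'
#' Returns the Fisher-z matrix of a [ConnectivityMatrix-class]; when the
#' object is sparsified (or `sparsified = TRUE` is forced), non-retained
#' entries are zero.
#' @param x a `ConnectivityMatrix`
#' @param sparsified logical; default follows the object's flag
#' @export
zMatrix <- function(x, sparsified = x@sparsified) {
  if (sparsified) {
    z <- x@z
    z[!x@retained] <- 0
    z
  } else x@z
}

#' Raw correlation values of a connectivity matrix
#' @param x a `ConnectivityMatrix`
#' @export
corMatrix <- function(x) x@correlations

#' Embedding coordinates
#' @param x an `Embedding`
#' @export
embCoordinates <- function(x) x@coordinates

#' Embedding eigenvalues
#' @param x an `Embedding`
#' @export
embEigenvalues <- function(x) x@eigenvalues

#' Hard network labels
#' @param x a `NetworkAssignment`
#' @export
hardLabels <- function(x) x@hardLabels

#' Posterior network probabilities
#' @param x a `NetworkAssignment`
#' @export
posteriors <- function(x) x@posteriors

## ---- show methods -----------------------------------------------------

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, radius %g\n",
              nrow(object@vertices), nrow(object@faces), object@sphereRadius))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d parcels on %d vertices (%d adjacency edges)\n",
              object@nParcels, length(object@vertexToParcel),
              nrow(object@adjacency)))
})

setMethod("show", "GeodesicGraph", function(object) {
  cat(sprintf("GeodesicGraph: %d parcels, max geodesic %.3g\n",
              nrow(object@dist), max(object@dist)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d x %d Fisher-z%s\n",
              nrow(object@z), ncol(object@z),
              if (object@sparsified)
                sprintf(", row-sparsified (retain %.0f%%)",
                        100 * object@retainFraction) else " (dense)"))
})

setMethod("show", "Embedding", function(object) {
  cat(sprintf("Embedding: %d parcels x %d components (alpha=%g, t=%g)%s%s\n",
              nrow(object@coordinates), ncol(object@coordinates),
              object@alpha, object@diffusionTime,
              if (object@isReference) ", reference" else "",
              if (object@isAligned) ", aligned" else ""))
})

setMethod("show", "NetworkAssignment", function(object) {
  cat(sprintf("NetworkAssignment (%s): %d parcels, %d networks\n",
              object@source, length(object@hardLabels),
              ncol(object@posteriors)))
})
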