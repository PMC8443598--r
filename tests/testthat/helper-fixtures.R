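# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

# 40-parcel world on a subdivided icosahedron, 5 networks.
smallWorld <- function() {
  if (is.null(.fixtures$world)) {
    mesh <- makeSphereMesh(2, 100)
    parc <- makeParcellation(mesh, 40, seed = 7)
    gg <- geodesicGraph(parc)
    ref <- makeReferenceNetworks(parc, 5, seed = 3)
    .fixtures$world <- list(mesh = mesh, parc = parc, gg = gg, ref = ref)
  }
  .fixtures$world
}

# Small but complete synthetic study: 60 parcels, 5 networks, 8 + 8 subjects.
smallScenarioConfig <- function(...) {
  scenarioConfig(nSubdivisions = 2L, nParcels = 60L, nNetworks = 5L,
                 cohort = cohortConfig(nTypical = 8L, nAtypical = 8L,
                                       nNetworks = 5L),
                 nTimepoints = 300L, ...)
}

smallScenario <- function() {
  if (is.null(.fixtures$scenario))
    .fixtures$scenario <- simulateScenario(smallScenarioConfig(), seed = 11L)
  .fixtures$scenario
}

# Reference embedding + GMM for the small scenario (shared across tests).
smallReference <- function() {
  if (is.null(.fixtures$reference)) {
    scen <- smallScenario()
    fcs <- lapply(scen$timeseries, computeFC)
    refEmb <- buildReference(groupAverage(fcs), nComponents = 10L)
    gmm <- fitReferenceGMM(refEmb, scen$referenceLabels)
    .fixtures$reference <- list(fcs = fcs, refEmb = refEmb, gmm = gmm)
  }
  .fixtures$reference
}

# Hand-built geodesic graph on the unit-weight path 1-2-3-4-5.
pathGraph5 <- function() {
  D <- abs(outer(1:5, 1:5, "-")) * 1.0
  adj <- cbind(1:4, 2:5)
  storage.mode(adj) <- "integer"
  new("GeodesicGraph", dist = D, adjacency = adj, weights = rep(1, 4))
}

# Build a ConnectivityMatrix directly from a Fisher-z matrix (test oracle
# retention: rank by value, ties to lower column index).
fcFromZ <- function(z, retainFraction = 0.10, sparsify = TRUE) {
  P <- nrow(z)
  k <- round(retainFraction * (P - 1))
  mask <- matrix(FALSE, P, P)
  for (i in seq_len(P)) {
    cols <- setdiff(seq_len(P), i)
    ord <- cols[order(-z[i, cols], cols)]
    mask[i, ord[seq_len(k)]] <- TRUE
  }
  new("ConnectivityMatrix", z = z, correlations = tanh(z), retained = mask,
      sparsified = sparsify, retainFraction = retainFraction)
}

# Embedding object wrapper for hand-made coordinate matrices.
embFromCoords <- function(coords, isReference = FALSE, isAligned = FALSE) {
  new("Embedding", coordinates = coords,
      eigenvalues = sort(runif(ncol(coords)), decreasing = TRUE),
      alpha = 0.5, diffusionTime = 1,
      isReference = isReference, isAligned = isAligned)
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))

# scratch space shared by the acceptance blocks (the P = 200 reference is
# expensive enough to build once)
.acc <- new.env(parent = emptyenv())
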