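## Spherical geometry: icosphere construction, seeded parcellations and
## reference network territories. All region growing is shortest-path Voronoi
## on the relevant edge graph, which guarantees spatial contiguity.

#' Build an icosphere surface mesh
#'
#' Subdivides a regular icosahedron `nSubdivisions` times (each triangle into
#' four) and projects all vertices onto a sphere of the requested radius.
#' The result has `20 * 4^n` faces and a connected edge graph.
#'
#' @param nSubdivisions non-negative integer; 0 gives the icosahedron itself.
#' @param radius sphere radius in length units (mm-scale by convention;
#'   default 100, roughly a hemisphere-sized sphere).
#' @return a [SurfaceMesh-class]
#' @examples
#' m <- makeSphereMesh(1)
#' nrow(meshVertices(m))  # 42
#' @export
makeSphereMesh <- function(nSubdivisions = 3L, radius = 100) {
  stopifnot(length(nSubdivisions) == 1L, nSubdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(f) <- "integer"
  for (s in seq_len(nSubdivisions)) {
    midpoint <- new.env(hash = TRUE)
    verts <- v
    nv <- nrow(verts)
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint[[key]]
      if (is.null(idx)) {
        verts <<- rbind(verts, (verts[a, ] + verts[b, ]) / 2)
        nv <<- nv + 1L
        idx <- nv
        midpoint[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
      ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
      newf[(4L * i - 3L):(4L * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  dimnames(v) <- NULL
  new("SurfaceMesh", vertices = v, faces = f, sphereRadius = radius)
}

## Undirected edge list of a mesh (unique vertex pairs), Euclidean lengths.
meshEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  w <- sqrt(rowSums((mesh@vertices[e[, 1L], , drop = FALSE] -
                     mesh@vertices[e[, 2L], , drop = FALSE])^2))
  list(edges = e, weights = w)
}

meshGraph <- function(mesh) {
  ew <- meshEdges(mesh)
  igraph::graph_from_edgelist(ew$edges, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = ew$weights)
}

## Farthest-point sampling on a weighted igraph: first seed drawn at random,
## subsequent seeds maximize the minimum graph distance to the chosen set.
farthestPointSample <- function(g, n, start) {
  nv <- igraph::vcount(g)
  seeds <- integer(n)
  seeds[1L] <- start
  mind <- as.vector(igraph::distances(g, v = start))
  if (n > 1L) for (i in 2:n) {
    seeds[i] <- which.max(mind)
    mind <- pmin(mind, as.vector(igraph::distances(g, v = seeds[i])))
  }
  seeds
}

## Shortest-path Voronoi assignment of every node to its nearest seed
## (ties -> lowest seed index), contiguous by construction.
voronoiAssign <- function(g, seeds) {
  d <- igraph::distances(g, v = seeds)  # n_seeds x nv
  apply(d, 2L, which.min)
}

## Lloyd-style relaxation of a graph Voronoi partition: alternately
## recenter each seed on its territory's medoid (minimum summed distance to
## the territory) and reassign. Balances territory sizes while preserving
## contiguity; deterministic.
lloydAssign <- function(g, seeds, iterations = 8L) {
  assign <- voronoiAssign(g, seeds)
  for (it in seq_len(iterations)) {
    newSeeds <- vapply(seq_along(seeds), function(k) {
      members <- which(assign == k)
      d <- igraph::distances(g, v = members, to = members)
      members[which.min(rowSums(d))]
    }, integer(1L))
    if (all(newSeeds == seeds)) break
    seeds <- newSeeds
    assign <- voronoiAssign(g, seeds)
  }
  assign
}

#' Parcellate a mesh into contiguous parcels
#'
#' Seeds parcels by farthest-point sampling on the mesh edge graph (first seed
#' drawn at random under `seed`) and grows them as a shortest-path Voronoi
#' partition, so every parcel is non-empty and spatially contiguous.
#' Deterministic given `(mesh, nParcels, seed)`.
#'
#' @param mesh a [SurfaceMesh-class]
#' @param nParcels number of parcels (must not exceed the vertex count)
#' @param seed integer RNG seed
#' @return a [Parcellation-class]
#' @export
makeParcellation <- function(mesh, nParcels, seed = 1L) {
  nv <- nrow(mesh@vertices)
  if (nParcels > nv)
    stop("nParcels (", nParcels, ") exceeds the vertex count (", nv, ")")
  stopifnot(nParcels >= 1L)
  g <- meshGraph(mesh)
  assign <- withr::with_seed(seed, {
    start <- sample.int(nv, 1L)
    if (nParcels == nv) {
      seeds <- seq_len(nv)
      seq_len(nv)
    } else {
      seeds <- farthestPointSample(g, nParcels, start)
      lloydAssign(g, seeds, iterations = 4L)
    }
  })
  assign <- as.integer(assign)
  cen <- t(vapply(seq_len(nParcels), function(p)
    colMeans(mesh@vertices[assign == p, , drop = FALSE]), numeric(3L)))
  cen <- cen / sqrt(rowSums(cen^2)) * mesh@sphereRadius
  ## parcel adjacency: parcels joined by at least one mesh edge
  ew <- meshEdges(mesh)
  pe <- cbind(assign[ew$edges[, 1L]], assign[ew$edges[, 2L]])
  pe <- pe[pe[, 1L] != pe[, 2L], , drop = FALSE]
  pe <- unique(cbind(pmin(pe[, 1L], pe[, 2L]), pmax(pe[, 1L], pe[, 2L])))
  storage.mode(pe) <- "integer"
  wlen <- greatCircle(cen[pe[, 1L], , drop = FALSE],
                      cen[pe[, 2L], , drop = FALSE], mesh@sphereRadius)
  new("Parcellation", vertexToParcel = assign, centroids = cen,
      nParcels = as.integer(nParcels), adjacency = pe, edgeLengths = wlen)
}

## Great-circle (surface geodesic) distance between points on a sphere.
greatCircle <- function(a, b, radius) {
  ca <- pmin(1, pmax(-1, rowSums(a * b) / radius^2))
  radius * acos(ca)
}

#' Geodesic distance graph between parcels
#'
#' Builds the weighted parcel adjacency graph (edge weight = great-circle
#' distance between adjacent parcel centroids along the sphere) and
#' precomputes all-pairs shortest-path distances with Dijkstra's algorithm.
#'
#' @param parcellation a [Parcellation-class]
#' @return a [GeodesicGraph-class]
#' @export
geodesicGraph <- function(parcellation) {
  g <- igraph::graph_from_edgelist(parcellation@adjacency, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = parcellation@edgeLengths)
  if (igraph::vcount(g) < parcellation@nParcels)
    g <- igraph::add_vertices(g, parcellation@nParcels - igraph::vcount(g))
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- NULL
  new("GeodesicGraph", dist = d, adjacency = parcellation@adjacency,
      weights = parcellation@edgeLengths)
}

#' Reference network territories
#'
#' Partitions the parcels into `nNetworks` contiguous territories (the
#' template intrinsic connectivity networks, 7 by default) by farthest-point
#' sampling plus shortest-path Voronoi growth on the parcel geodesic graph.
#' Deterministic given `seed`.
#'
#' @param parcellation a [Parcellation-class]
#' @param nNetworks number of networks (default 7)
#' @param seed integer RNG seed
#' @return integer vector: parcel -> network id in `1..nNetworks`
#' @export
makeReferenceNetworks <- function(parcellation, nNetworks = 7L, seed = 1L) {
  P <- parcellation@nParcels
  stopifnot(nNetworks >= 1L, nNetworks <= P)
  g <- igraph::graph_from_edgelist(parcellation@adjacency, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = parcellation@edgeLengths)
  labels <- withr::with_seed(seed, {
    start <- sample.int(P, 1L)
    if (nNetworks == 1L) rep(1L, P)
    else lloydAssign(g, farthestPointSample(g, nNetworks, start))
  })
  as.integer(labels)
}
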