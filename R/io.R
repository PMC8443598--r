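## Readers and writers for the artifact formats: ASCII PLY meshes, CSV
## cohort/label tables, HDF5 time series and embeddings.

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [SurfaceMesh-class]
#' @param path output file
#' @export
writeMeshPLY <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment sphere_radius %.17g", mesh@sphereRadius),
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L),
             con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path PLY file written by [writeMeshPLY()] (or any ASCII PLY with
#'   x/y/z vertex properties and triangular faces)
#' @return a [SurfaceMesh-class]
#' @export
readMeshPLY <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1L], "ply")) stop("not a PLY file: ", path)
  hEnd <- match("end_header", lines)
  if (is.na(hEnd)) stop("malformed PLY header (no end_header): ", path)
  header <- lines[seq_len(hEnd)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("malformed PLY header: ", path)
  radLine <- grep("^comment sphere_radius ", header, value = TRUE)
  vert <- do.call(rbind, lapply(strsplit(
    lines[hEnd + seq_len(nv)], " ", fixed = TRUE), as.numeric))
  faceTok <- lapply(strsplit(lines[hEnd + nv + seq_len(nf)], " ",
                             fixed = TRUE), as.integer)
  if (any(vapply(faceTok, `[`, integer(1L), 1L) != 3L))
    stop("non-triangular face in PLY: ", path)
  faces <- do.call(rbind, lapply(faceTok, function(x) x[2:4] + 1L))
  radius <- if (length(radLine))
    as.numeric(sub("comment sphere_radius ", "", radLine[1L]))
  else max(sqrt(rowSums(vert^2)))
  new("SurfaceMesh", vertices = vert[, 1:3, drop = FALSE], faces = faces,
      sphereRadius = radius)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort cohort `data.frame`
#' @param path CSV file
#' @export
writeCohortCSV <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @param siteLevels optional site factor levels (defaults to order of
#'   appearance)
#' @export
readCohortCSV <- function(path, siteLevels = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(d$group))
    d$group <- factor(d$group, levels = c("typical", "atypical"))
  if (!is.null(d$site))
    d$site <- factor(d$site, levels = siteLevels %||% unique(d$site))
  if (!is.null(d$sex)) d$sex <- factor(d$sex, levels = c("F", "M"))
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read parcel network labels as CSV
#'
#' Two columns: `parcel_id`, `network_id`.
#' @param labels integer parcel -> network vector
#' @param path CSV file
#' @export
writeLabelsCSV <- function(labels, path) {
  write.csv(data.frame(parcel_id = seq_along(labels),
                       network_id = as.integer(labels)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelsCSV
#' @export
readLabelsCSV <- function(path) {
  d <- read.csv(path)
  as.integer(d$network_id[order(d$parcel_id)])
}

#' Write / read subject time series as HDF5
#'
#' One dataset per subject under `/timeseries`, plus a scalar `/tr`.
#' @param tsList named list of P x T matrices
#' @param path HDF5 file (overwritten)
#' @param tr sampling interval in seconds
#' @export
writeTimeseriesH5 <- function(tsList, path, tr = attr(tsList[[1L]], "tr") %||% 2) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "timeseries")
  for (id in names(tsList))
    rhdf5::h5write(unclass(tsList[[id]]), path, paste0("timeseries/", id))
  rhdf5::h5write(tr, path, "tr")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname writeTimeseriesH5
#' @export
readTimeseriesH5 <- function(path) {
  ids <- rhdf5::h5ls(path)
  ids <- ids$name[ids$group == "/timeseries"]
  tr <- as.numeric(rhdf5::h5read(path, "tr"))
  out <- lapply(ids, function(id) {
    m <- rhdf5::h5read(path, paste0("timeseries/", id))
    attr(m, "tr") <- tr
    m
  })
  names(out) <- ids
  rhdf5::h5closeAll()
  out
}

#' Write / read an embedding as HDF5
#'
#' @param emb an [Embedding-class]
#' @param path HDF5 file (overwritten)
#' @export
writeEmbeddingH5 <- function(emb, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(emb@coordinates, path, "coordinates")
  rhdf5::h5write(emb@eigenvalues, path, "eigenvalues")
  rhdf5::h5write(c(alpha = emb@alpha, diffusionTime = emb@diffusionTime),
                 path, "config")
  rhdf5::h5write(as.integer(c(emb@isReference, emb@isAligned)), path,
                 "flags")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname writeEmbeddingH5
#' @export
readEmbeddingH5 <- function(path) {
  coords <- rhdf5::h5read(path, "coordinates")
  ev <- as.numeric(rhdf5::h5read(path, "eigenvalues"))
  cfg <- rhdf5::h5read(path, "config")
  flags <- as.integer(rhdf5::h5read(path, "flags"))
  rhdf5::h5closeAll()
  new("Embedding", coordinates = coords, eigenvalues = ev,
      alpha = as.numeric(cfg[1L]), diffusionTime = as.numeric(cfg[2L]),
      isReference = flags[1L] == 1L, isAligned = flags[2L] == 1L)
}
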