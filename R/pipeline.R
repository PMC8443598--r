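## End-to-end orchestration: one configuration object whose defaults encode
## the published analysis parameters, and a deterministic pipeline runner.

#' Pipeline configuration
#'
#' Aggregates every stage's settings. Defaults restate the published
#' analysis parameters: 10% per-row retention, embedding alpha 0.5,
#' diffusion time 1, 30 components, 7 networks, degree-centrality
#' threshold 0.2, FD exclusion cutoff 0.3 mm, 1000 spin rotations;
#' the permutation count is configurable (200 by default here, suited to
#' the synthetic demo scale).
#'
#' @param scenario a [scenarioConfig()] describing the synthetic study
#' @param retainFraction per-row retention fraction
#' @param alpha,diffusionTime,nComponents embedding parameters
#' @param nNetworks number of intrinsic connectivity networks
#' @param dcThreshold degree-centrality correlation threshold
#' @param fdMax framewise-displacement exclusion cutoff (mm)
#' @param nPerm permutations for TFCE correction
#' @param nRot spin rotations for map correlations
#' @param refit per-subject GMM refit (see [clusterIndividual()])
#' @param gradientBins bins for principal-gradient stratification
#' @return a list of class `pipelineConfig` with a `configHash` attribute
#' @export
pipelineConfig <- function(scenario = scenarioConfig(),
                           retainFraction = 0.10, alpha = 0.5,
                           diffusionTime = 1, nComponents = 30L,
                           nNetworks = scenario$nNetworks,
                           dcThreshold = 0.2, fdMax = 0.3,
                           nPerm = 200L, nRot = 1000L, refit = TRUE,
                           gradientBins = 10L) {
  stopifnot(nNetworks == scenario$nNetworks,
            nComponents < scenario$nParcels)
  cfg <- list(scenario = scenario, retainFraction = retainFraction,
              alpha = alpha, diffusionTime = diffusionTime,
              nComponents = as.integer(nComponents),
              nNetworks = as.integer(nNetworks),
              dcThreshold = dcThreshold, fdMax = fdMax,
              nPerm = as.integer(nPerm), nRot = as.integer(nRot),
              refit = refit, gradientBins = as.integer(gradientBins))
  class(cfg) <- "pipelineConfig"
  attr(cfg, "configHash") <- configHash(cfg)
  cfg
}

#' Stable digest of a configuration
#'
#' Hash of the configuration content, invariant to the ordering of list
#' keys (lists are canonicalized by sorting names recursively).
#'
#' @param cfg any (nested) list
#' @return character digest
#' @export
configHash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x)) && any(nzchar(names(x))))
        x <- x[order(names(x))]
    }
    attributes(x) <- attributes(x)["names"]
    x
  }
  rlang::hash(canon(unclass(cfg)))
}

## Per-network two-sample contrast of group entropy maps: compares the
## per-parcel entropies of the two groups within each reference network.
entropyContrast <- function(entropyTypical, entropyAtypical, refLabels) {
  nNet <- max(refLabels)
  res <- lapply(seq_len(nNet), function(cc) {
    at <- refLabels == cc
    tt <- t.test(entropyAtypical[at], entropyTypical[at])
    d <- cohensD(c(entropyTypical[at], entropyAtypical[at]),
                 rep(c("typical", "atypical"), each = sum(at)) |>
                   factor(levels = c("typical", "atypical")))
    data.frame(network = cc, t = unname(tt$statistic), p = tt$p.value,
               cohensD = d)
  })
  out <- do.call(rbind, res)
  out$pAdj <- fdrBH(out$p)
  out
}

#' Run the full idiosyncrasy pipeline on a synthetic study
#'
#' Executes simulate -> QC filter -> connectivity -> reference embedding ->
#' align -> cluster -> idiosyncrasy descriptors -> group statistics ->
#' centrality contrasts, entirely determined by `(config, seed)`. When
#' `outDir` is given, CSV tables and a JSON run summary (recording every
#' stage parameter and the configuration hash) are written there.
#'
#' @param config a [pipelineConfig()]
#' @param seed integer seed driving every stochastic stage
#' @param outDir optional output directory
#' @param verbose print stage progress
#' @return a list with the scenario, per-subject results and the
#'   statistical tables (see vignette for a walk-through)
#' @export
runPipeline <- function(config = pipelineConfig(), seed = 1L,
                        outDir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (verbose) message("[idioconn] ", ...)
  t0 <- Sys.time()

  say("simulating scenario")
  scen <- simulateScenario(config$scenario, seed)
  parc <- scen$parcellation
  gg <- scen$gg
  refLabels <- scen$referenceLabels
  P <- config$scenario$nParcels

  say("quality control")
  cohort <- qcFilter(scen$cohort, config$fdMax)
  keep <- scen$cohort$id %in% cohort$id
  ts <- scen$timeseries[keep]
  n <- nrow(cohort)

  say("connectivity matrices (", n, " subjects)")
  fcs <- lapply(ts, computeFC, retainFraction = config$retainFraction)

  say("reference embedding")
  meanFC <- groupAverage(fcs, retainFraction = config$retainFraction)
  reference <- buildReference(meanFC, alpha = config$alpha,
                              diffusionTime = config$diffusionTime,
                              nComponents = config$nComponents)
  refGMM <- fitReferenceGMM(reference, refLabels)
  refAsn <- refGMM$assignment

  say("per-subject embedding, alignment, clustering")
  sdMaps <- matrix(NA_real_, n, P)
  ddMaps <- matrix(NA_real_, n, P)
  assignments <- vector("list", n)
  overlaps <- vector("list", n)
  residuals <- numeric(n)
  for (i in seq_len(n)) {
    emb <- diffusionMap(affinityMatrix(fcs[[i]]), alpha = config$alpha,
                        diffusionTime = config$diffusionTime,
                        nComponents = config$nComponents)
    cob <- changeOfBasis(emb, reference)
    residuals[i] <- cob$residual
    asn <- clusterIndividual(cob$aligned, refGMM, refit = config$refit,
                             source = cohort$id[i])
    assignments[[i]] <- asn
    sdMaps[i, ] <- surfaceDistance(asn, refAsn, gg)
    ddMaps[i, ] <- diffusionDistance(cob$aligned, reference, asn, refAsn)
    overlaps[[i]] <- cbind(id = cohort$id[i],
                           networkOverlap(asn, refAsn, gg))
  }
  overlapTab <- do.call(rbind, overlaps)

  say("network-level statistics")
  refSizes <- networkSize(refAsn, config$nNetworks)
  design <- designMatrix(cohort)
  netStats <- do.call(rbind, lapply(c("msd", "dice", "jaccard"), function(metric) {
    per <- matrix(overlapTab[[metric]], nrow = config$nNetworks)  # net x subj
    do.call(rbind, lapply(seq_len(config$nNetworks), function(cc) {
      y <- per[cc, ]
      ok <- !is.na(y)
      ## subjects lacking the network are dropped; rebuild the design on the
      ## subset so no dummy column becomes all-zero
      dsub <- if (all(ok)) design else designMatrix(cohort[ok, , drop = FALSE])
      gc <- glmContrast(y[ok], dsub$X, dsub$contrast)
      data.frame(metric = metric, network = cc, t = gc$t, p = gc$p,
                 cohensD = cohensD(y[ok], cohort$group[ok]))
    }))
  }))
  netStats$pAdj <- NA_real_
  for (m in unique(netStats$metric)) {
    at <- netStats$metric == m
    netStats$pAdj[at] <- fdrBH(netStats$p[at])
  }
  cortexMSD <- vapply(seq_len(n), function(i) {
    ov <- overlaps[[i]]
    ok <- !is.na(ov$msd)
    cortexwideSummary(ov$msd[ok], refSizes[ok])
  }, numeric(1L))
  cortexTest <- glmContrast(cortexMSD, design$X, design$contrast)

  say("entropy")
  grp <- cohort$group
  entTyp <- networkEntropy(assignments[grp == "typical"])
  entAty <- networkEntropy(assignments[grp == "atypical"])
  entStats <- entropyContrast(entTyp, entAty, hardLabels(refAsn))

  say("parcel-wise SD/DD contrasts (TFCE, ", config$nPerm, " permutations)")
  adjacency <- parc@adjacency
  sdContrast <- permutationCorrect(sdMaps, design, adjacency,
                                   nPerm = config$nPerm, seed = seed + 1L,
                                   permuteWithin = cohort$site)
  ddContrast <- permutationCorrect(ddMaps, design, adjacency,
                                   nPerm = config$nPerm, seed = seed + 2L,
                                   permuteWithin = cohort$site)

  say("map correlations (spin)")
  deltaEntropy <- entAty - entTyp
  spinSD <- spinTest(deltaEntropy, sdContrast$t, parcelCentroids(parc),
                     nRot = config$nRot, seed = seed + 3L)
  spinDD <- spinTest(deltaEntropy, ddContrast$t, parcelCentroids(parc),
                     nRot = config$nRot, seed = seed + 4L)

  say("age and severity")
  meanSD <- rowMeans(sdMaps)
  meanDD <- rowMeans(ddMaps)
  ageSD <- ageEffect(meanSD, cohort)
  ageDD <- ageEffect(meanDD, cohort)
  ddPerNetwork <- vapply(seq_len(config$nNetworks), function(cc)
    vapply(seq_len(n), function(i)
      mean(ddMaps[i, hardLabels(assignments[[i]]) == cc]), numeric(1L)),
    numeric(n))
  ddPerNetwork[is.nan(ddPerNetwork)] <- 0  # subject lost the network
  sevDD <- severityCorrelation(ddPerNetwork, cohort)
  sevCortex <- severityCorrelation(cbind(meanDD), cohort)

  say("gradient stratification")
  gradSD <- gradientStratification(colMeans(sdMaps), reference,
                                   config$gradientBins)

  say("centrality contrasts")
  dc <- t(vapply(fcs, function(f)
    as.numeric(degreeCentrality(corMatrix(f), config$dcThreshold)),
    numeric(P)))
  dcContrast <- centralityContrast(dc, cohort, adjacency, sdMaps, ddMaps,
                                   withIdiosyncrasy = TRUE,
                                   nPerm = config$nPerm, seed = seed + 5L)
  dcSpinSD <- spinTest(dcContrast$before$t, sdContrast$t,
                       parcelCentroids(parc), nRot = config$nRot,
                       seed = seed + 6L)

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  summary <- list(
    configHash = attr(config, "configHash"), seed = seed,
    parameters = list(retainFraction = config$retainFraction,
                      alpha = config$alpha,
                      diffusionTime = config$diffusionTime,
                      nComponents = config$nComponents,
                      nNetworks = config$nNetworks,
                      dcThreshold = config$dcThreshold,
                      fdMax = config$fdMax, nPerm = config$nPerm,
                      nRot = config$nRot),
    nSubjects = n, nExcluded = sum(!keep), nParcels = P,
    cortexMSD = list(t = cortexTest$t, p = cortexTest$p),
    spin = list(entropySD = list(r = spinSD$r, p = spinSD$pSpin),
                entropyDD = list(r = spinDD$r, p = spinDD$pSpin),
                dcSD = list(r = dcSpinSD$r, p = dcSpinSD$pSpin)),
    dcSignificant = list(before = dcContrast$nSigBefore,
                         after = dcContrast$nSigAfter),
    gradientTrend = gradSD$spearman,
    elapsedSec = elapsed)

  result <- list(scenario = scen, cohort = cohort, fcs = fcs,
                 reference = reference, referenceGMM = refGMM,
                 assignments = assignments, sdMaps = sdMaps,
                 ddMaps = ddMaps, overlap = overlapTab,
                 networkStats = netStats, cortexMSD = cortexMSD,
                 cortexTest = cortexTest, entropy = list(
                   typical = entTyp, atypical = entAty, stats = entStats),
                 sdContrast = sdContrast, ddContrast = ddContrast,
                 spin = list(entropySD = spinSD, entropyDD = spinDD,
                             dcSD = dcSpinSD),
                 age = list(sd = ageSD, dd = ageDD),
                 severity = list(perNetworkDD = sevDD, cortexDD = sevCortex),
                 gradient = gradSD, dc = dc, dcContrast = dcContrast,
                 alignmentResiduals = residuals, summary = summary,
                 config = config)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCohortCSV(cohort, file.path(outDir, "cohort.csv"))
    writeLabelsCSV(hardLabels(refAsn),
                   file.path(outDir, "reference_labels.csv"))
    write.csv(netStats, file.path(outDir, "network_stats.csv"),
              row.names = FALSE)
    write.csv(entStats, file.path(outDir, "entropy_stats.csv"),
              row.names = FALSE)
    write.csv(data.frame(parcel = seq_len(P), t_sd = sdContrast$t,
                         p_sd = sdContrast$pCorr, t_dd = ddContrast$t,
                         p_dd = ddContrast$pCorr),
              file.path(outDir, "parcel_stats.csv"), row.names = FALSE)
    write.csv(overlapTab, file.path(outDir, "network_overlap.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
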