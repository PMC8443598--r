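test_that("simulateCohort builds the requested groups deterministically", {
  cfg <- cohortConfig(nTypical = 10L, nAtypical = 10L)
  co <- simulateCohort(cfg, seed = 4)
  expect_equal(nrow(co), 20L)
  expect_equal(as.vector(table(co$group)), c(10L, 10L))
  expect_equal(anyDuplicated(co$id), 0L)
  expect_true(all(co$fd >= 0))
  # severity present iff atypical
  expect_true(all(is.na(co$severity[co$group == "typical"])))
  expect_true(all(!is.na(co$severity[co$group == "atypical"])))
  expect_identical(co, simulateCohort(cfg, seed = 4))
  expect_error(simulateCohort(cohortConfig(nTypical = 0L)), "positive")
})

test_that("noise-free severity is perfectly rank-coupled to realized shift", {
  cfg <- cohortConfig(nTypical = 5L, nAtypical = 30L, severityNoiseSD = 0,
                      severityCoupling = 0.3)
  co <- simulateCohort(cfg, seed = 9)
  aty <- co$group == "atypical"
  rs <- attr(co, "realizedShift")[aty]
  expect_equal(cor(co$severity[aty], rs, method = "spearman"), 1)
})

test_that("FD exclusion mass matches the log-normal/binomial oracle", {
  cfg <- cohortConfig(nTypical = 25L, nAtypical = 25L)
  pExceed <- 1 - stats::plnorm(0.3, cfg$fdMeanlog, cfg$fdSdlog)
  nTot <- 0L; nExc <- 0L
  for (s in 1:300) {
    co <- simulateCohort(cfg, seed = 1000L + s)
    nTot <- nTot + nrow(co)
    nExc <- nExc + sum(co$fd > 0.3)
  }
  # observed exclusions within 4 binomial standard deviations
  expect_lt(abs(nExc - nTot * pExceed), 4 * sqrt(nTot * pExceed * (1 - pExceed)))
})

test_that("shiftNetworks respects the geodesic shift budget", {
  w <- smallWorld()
  cen <- parcelCentroids(w$parc)
  # zero magnitudes leave labels untouched
  expect_identical(shiftNetworks(w$ref, rep(0, 5), w$gg, cen, seed = 2),
                   as.integer(w$ref))
  # single shifted network: every relabeled parcel lies within geodesic
  # distance m of that network's reference boundary (brute-force check)
  D <- geoDist(w$gg)
  adj <- w$parc@adjacency
  neighborOf <- function(p) unique(c(adj[adj[, 1] == p, 2], adj[adj[, 2] == p, 1]))
  for (m in c(55, 80)) {
    lab <- shiftNetworks(w$ref, c(m, 0, 0, 0, 0), w$gg, cen, seed = 6)
    changed <- which(lab != w$ref)
    inC <- w$ref == 1
    boundary <- which(vapply(seq_along(w$ref), function(p) {
      nb <- neighborOf(p)
      (inC[p] && any(!inC[nb])) || (!inC[p] && any(inC[nb]))
    }, logical(1)))
    for (p in changed)
      expect_lte(min(D[p, boundary]), m)
    # only network 1 membership changes
    expect_true(all(w$ref[changed] == 1 | lab[changed] == 1))
  }
})

test_that("boundary displacement grows monotonically with magnitude", {
  w <- smallWorld()
  cen <- parcelCentroids(w$parc)
  # parcel spacing on this 40-parcel sphere is ~60 mm, so magnitudes must
  # exceed it to relabel anything
  for (s in c(21, 22, 23)) {
    msd <- vapply(c(0, 50, 75, 100), function(m) {
      lab <- shiftNetworks(w$ref, c(m, 0, 0, 0, 0), w$gg, cen, seed = s)
      meanSurfaceDistance(which(w$ref == 1), which(lab == 1), w$gg)
    }, numeric(1))
    expect_true(all(diff(msd) >= 0))
    expect_gt(msd[4], 0)
  }
})

test_that("a shift that swallows a whole network raises an error", {
  w <- smallWorld()
  cen <- parcelCentroids(w$parc)
  D <- geoDist(w$gg)
  # single-parcel network flanked by two aggressively shifting networks
  q <- 1L; q2 <- which.max(D[q, ])
  ref3 <- rep(1L, 40); ref3[q] <- 2L; ref3[q2] <- 3L
  expect_error(shiftNetworks(ref3, c(1000, 0, 1000), w$gg, cen, seed = 18),
               "vanish")
})

test_that("time-series block model hits its target correlation", {
  labels <- rep(1:2, each = 20)
  # near-zero noise: within-network correlations approach 1
  x0 <- simulateSubjectTimeseries(labels, 200, noiseSD = 1e-8, seed = 1)
  r0 <- cor(t(x0))
  expect_gt(min(r0[1:20, 1:20]), 0.999)
  # independent latents: cross-network correlation centered on zero
  expect_lt(mean(abs(r0[1:20, 21:40])), 0.15)
  # Monte-Carlo against the analytic mixing r = 1/(1 + noiseSD^2)
  x <- simulateSubjectTimeseries(labels, 10000, withinNetworkCorr = 0.5,
                                 seed = 2)
  r <- cor(t(x))
  within <- c(r[1:20, 1:20][upper.tri(diag(20))],
              r[21:40, 21:40][upper.tri(diag(20))])
  expect_lt(abs(mean(within) - 0.5), 0.03)
  expect_error(simulateSubjectTimeseries(labels, 5), "at least 10")
  expect_identical(x, simulateSubjectTimeseries(labels, 10000,
                                                withinNetworkCorr = 0.5,
                                                seed = 2))
})

test_that("zero-shift, near-zero-noise scenarios give block-structured FC", {
  cfg <- scenarioConfig(
    nSubdivisions = 2L, nParcels = 40L, nNetworks = 4L,
    cohort = cohortConfig(nTypical = 2L, nAtypical = 2L, nNetworks = 4L,
                          shiftTypical = 0, shiftAtypical = 0,
                          shiftJitterSD = 0, ageSlope = 0),
    nTimepoints = 200L, withinNetworkCorr = 0.999)
  scen <- simulateScenario(cfg, seed = 5)
  expect_true(all(scen$subjectLabels == scen$referenceLabels))
  r <- corMatrix(computeFC(scen$timeseries[[1]]))
  same <- outer(scen$referenceLabels, scen$referenceLabels, "==")
  diag(same) <- NA
  expect_gt(min(r[which(same)]), 0.95)
  expect_lt(max(abs(r[which(!same)])), 0.5)
})

test_that("configured group difference is realized in every replicate", {
  for (s in 1:3) {
    cfg <- smallScenarioConfig()
    scen <- simulateScenario(cfg, seed = 30L + s)
    g <- scen$cohort$group
    # increase networks (1-4 under the recycled default): atypical > typical
    inc <- rowMeans(scen$realizedMSD[, 1:4])
    expect_gt(mean(inc[g == "atypical"]), mean(inc[g == "typical"]))
  }
})
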