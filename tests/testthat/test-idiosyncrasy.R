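test_that("surface distance follows the path-graph oracle", {
  g <- pathGraph5()
  ref <- c(1L, 1L, 1L, 2L, 2L)       # network 2 occupies parcels {4, 5}
  subj <- c(1L, 2L, 1L, 2L, 2L)      # parcel 2 reassigned to network 2
  sd <- surfaceDistance(subj, ref, g)
  expect_equal(sd, c(0, 2, 0, 0, 0))
  # identical assignments: zero everywhere
  expect_true(all(surfaceDistance(ref, ref, g) == 0))
  # consistent relabeling of network ids changes nothing
  expect_equal(surfaceDistance(3L - subj, 3L - ref, g), sd)
})

test_that("mean SD is zero exactly when assignments coincide", {
  w <- smallWorld()
  expect_equal(mean(surfaceDistance(w$ref, w$ref, w$gg)), 0)
  alt <- w$ref
  donor <- which(w$ref != w$ref[1])[1]
  alt[donor] <- w$ref[1]
  expect_gt(mean(surfaceDistance(alt, w$ref, w$gg)), 0)
})

test_that("diffusion distance is a per-cluster nearest squared distance", {
  # K = 1: reference cluster points at 0 and 3, subject point at 1 -> 1^2
  psi <- matrix(c(0, 3, 10), ncol = 1)
  phi <- matrix(c(1, 3, 10), ncol = 1)
  refLab <- c(1L, 1L, 2L)
  subjLab <- c(1L, 1L, 2L)
  dd <- diffusionDistance(embFromCoords(phi), embFromCoords(psi),
                          subjLab, refLab)
  expect_equal(dd, c(1, 0, 0))
  # scaling all coordinates by 2 scales dd by 4
  dd2 <- diffusionDistance(embFromCoords(2 * phi), embFromCoords(2 * psi),
                           subjLab, refLab)
  expect_equal(dd2, 4 * dd)
  # identical embeddings and assignments: zero
  expect_true(all(diffusionDistance(embFromCoords(psi), embFromCoords(psi),
                                    refLab, refLab) == 0))
})

test_that("overlap scores match their set-theoretic definitions", {
  expect_equal(diceCoef(1:4, 1:4), 1)
  expect_equal(diceCoef(1:4, 5:8), 0)
  expect_equal(diceCoef(1:4, c(2, 3, 4, 7, 8, 9)), 0.6)
  expect_equal(jaccardIndex(1:4, 1:4), 1)
  expect_equal(jaccardIndex(1:4, c(2, 3, 4, 7, 8, 9)), 3 / 7)
  expect_equal(diceCoef(1:4, integer(0)), 0)
  # exhaustive random-set oracle plus the J = D / (2 - D) identity
  set.seed(5)
  for (rep in 1:25) {
    a <- sample(10, sample(1:6, 1))
    b <- sample(10, sample(0:6, 1))
    inter <- sum(a %in% b)
    expect_equal(diceCoef(a, b), 2 * inter / (length(a) + length(b)))
    if (length(b)) {
      expect_equal(jaccardIndex(a, b),
                   inter / length(unique(c(a, b))))
      D <- diceCoef(a, b)
      expect_equal(jaccardIndex(a, b), D / (2 - D), tolerance = 1e-12)
      expect_lte(jaccardIndex(a, b), diceCoef(a, b))
    }
  }
})

test_that("mean surface distance matches the exhaustive double loop", {
  g <- pathGraph5()
  expect_equal(meanSurfaceDistance(c(1, 2), c(1, 2), g), 0)
  expect_equal(meanSurfaceDistance(1, 5, pathGraph5()), 4)  # (4+4)/2
  expect_error(meanSurfaceDistance(1:2, integer(0), g), "empty")
  w <- smallWorld()
  D <- geoDist(w$gg)
  set.seed(6)
  for (rep in 1:20) {
    a <- sample(40, sample(2:8, 1))
    b <- sample(40, sample(2:8, 1))
    oracle <- (sum(vapply(a, function(p) min(D[p, b]), numeric(1))) +
               sum(vapply(b, function(p) min(D[p, a]), numeric(1)))) /
      (length(a) + length(b))
    expect_equal(meanSurfaceDistance(a, b, w$gg), oracle, tolerance = 1e-12)
    expect_equal(meanSurfaceDistance(a, b, w$gg),
                 meanSurfaceDistance(b, a, w$gg))
  }
})

test_that("entropy of group probability maps follows Shannon's formula", {
  P <- 4L; N <- 7L
  onehot <- matrix(0, P, N); onehot[, 3] <- 1
  expect_equal(networkEntropy(list(onehot)), rep(0, P))
  unif <- matrix(1 / N, P, N)
  expect_equal(networkEntropy(list(unif)), rep(log(7), P))
  half <- matrix(0, P, N); half[, 1] <- 0.5; half[, 2] <- 0.5
  expect_equal(networkEntropy(list(half)), rep(log(2), P))
  # averaging across subjects precedes the entropy:
  # mean posterior is (0.25, 0.25, 0.5) over networks 1-3
  expect_equal(networkEntropy(list(onehot, half)),
               rep(-(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), P))
  # never exceeds log(N)
  set.seed(2)
  rnd <- matrix(rexp(P * N), P, N); rnd <- rnd / rowSums(rnd)
  expect_true(all(networkEntropy(list(rnd)) <= log(N) + 1e-12))
})

test_that("network sizes partition the parcels", {
  w <- smallWorld()
  sz <- networkSize(w$ref, 5)
  expect_equal(sum(sz), 40L)
  expect_equal(sz, tabulate(w$ref, 5))
  # subjects may lose a network; zero counts are reported
  expect_equal(networkSize(c(1L, 1L, 3L), 3), c(2L, 0L, 1L))
})

test_that("cortex-wide summaries are size-weighted means", {
  expect_equal(cortexwideSummary(c(1, 0), c(3, 1)), 0.75)
  expect_equal(cortexwideSummary(c(0.2, 0.8), c(5, 5)), 0.5)
  expect_equal(cortexwideSummary(rep(0.37, 4), c(9, 1, 5, 2)), 0.37)
})

test_that("gradient stratification recovers monotone trends", {
  set.seed(13)
  coords <- matrix(rnorm(50 * 3), 50, 3)
  coords[, 1] <- sort(coords[, 1])
  ref <- embFromCoords(coords, isReference = TRUE)
  gs <- gradientStratification(coords[, 1], ref, nBins = 5)
  expect_equal(gs$spearman, 1)
  expect_true(all(diff(gs$binMeans) > 0))
  gs0 <- gradientStratification(rep(2, 50), ref, nBins = 5)
  expect_equal(gs0$spearman, 0)
  expect_true(gs0$constant)
  expect_error(gradientStratification(coords[, 1], ref, nBins = 51), "exceeds")
})

test_that("a shift gradient along the principal axis is recovered", {
  # inject idiosyncrasy that grows along the first embedding axis and check
  # a positive rank trend comes back
  set.seed(14)
  coords <- matrix(rnorm(60 * 2), 60, 2)
  ref <- embFromCoords(coords, isReference = TRUE)
  idio <- 2 * coords[, 1] + rnorm(60, sd = 0.5)
  gs <- gradientStratification(idio, ref, nBins = 6)
  expect_gt(gs$spearman, 0.7)
})
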