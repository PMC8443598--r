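test_that("normalized-angle affinity has the stated geometry", {
  # 21 parcels, k = 2 retained per row
  z <- matrix(0, 21, 21)
  z[1, c(3, 4)] <- c(1, 2)
  z[2, c(3, 4)] <- c(1, 2)    # identical to row 1
  z[5, c(6, 7)] <- c(2, 1)    # shares no support with rows 1-2
  for (i in setdiff(1:21, c(1, 2, 5)))
    z[i, c(i %% 21 + 1, (i + 1) %% 21 + 1)] <- c(1, 2)
  fc <- fcFromZ(z)
  aff <- affinityMatrix(fc)
  expect_equal(aff[1, 2], 1)                       # zero angle
  expect_equal(aff[1, 5], 0.5, tolerance = 1e-12)  # orthogonal rows
  expect_lt(max(abs(aff - t(aff))), 1e-12)
  expect_true(all(aff >= 0 & aff <= 1))
  expect_true(all(diag(aff) == 1))
  # all-zero row is an error
  fcBad <- fc
  fcBad@retained[3, ] <- FALSE
  fcBad@retained[3, c(4, 5)] <- TRUE
  fcBad@z[3, ] <- 0
  expect_error(affinityMatrix(fcBad), "all-zero")
  expect_error(affinityMatrix(computeFC(matrix(rnorm(21 * 30), 21, 30),
                                        sparsify = FALSE)), "sparsified")
})

# small two-community affinity used by several tests
blockAffinity <- function(P = 20L, eps = 0.05, seed = 1) {
  set.seed(seed)
  half <- P / 2
  aff <- matrix(eps, P, P)
  aff[1:half, 1:half] <- 0.9
  aff[(half + 1):P, (half + 1):P] <- 0.9
  aff <- aff + matrix(runif(P * P, 0, 0.01), P, P)
  aff <- (aff + t(aff)) / 2
  diag(aff) <- 1
  aff
}

test_that("diffusion map separates two communities and bounds its spectrum", {
  aff <- blockAffinity()
  emb <- diffusionMap(aff, nComponents = 5L)
  x1 <- embCoordinates(emb)[, 1]
  expect_true(all(sign(x1[1:10]) == sign(x1[1])))
  expect_true(all(sign(x1[11:20]) == -sign(x1[1])))
  ev <- embEigenvalues(emb)
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(ev <= 1 + 1e-12))
  expect_lt(ev[1], 1)  # trivial component dropped
  # deterministic, sign convention fixed
  expect_identical(embCoordinates(emb),
                   embCoordinates(diffusionMap(aff, nComponents = 5L)))
})

test_that("Euclidean embedding distance equals brute-force diffusion distance", {
  # exact identity when K = P - 1, for t = 1 and t = 2
  aff <- blockAffinity(10L, eps = 0.2, seed = 4)
  for (t in c(1, 2)) {
    emb <- diffusionMap(aff, diffusionTime = t, nComponents = 9L)
    x <- embCoordinates(emb)
    d <- rowSums(aff)
    w1 <- aff / outer(d^0.5, d^0.5)
    M <- w1 / rowSums(w1)
    Mt <- M
    if (t == 2) Mt <- M %*% M
    pi0 <- rowSums(w1) / sum(w1)
    for (i in c(1, 3)) for (j in c(2, 7, 10)) {
      dd2 <- sum((Mt[i, ] - Mt[j, ])^2 / pi0)
      expect_equal(sum((x[i, ] - x[j, ])^2), dd2, tolerance = 1e-8)
    }
  }
})

test_that("alpha is irrelevant on a degree-regular graph", {
  # circulant ring: constant degree, so density normalization is a scalar
  P <- 16L
  aff <- matrix(0, P, P)
  for (i in 1:P) {
    aff[i, (i %% P) + 1] <- 0.5
    aff[(i %% P) + 1, i] <- 0.5
    aff[i, ((i + 1) %% P) + 1] <- 0.2
    aff[((i + 1) %% P) + 1, i] <- 0.2
  }
  diag(aff) <- 1
  e0 <- diffusionMap(aff, alpha = 0, nComponents = 4L)
  e1 <- diffusionMap(aff, alpha = 1, nComponents = 4L)
  # the circulant spectrum has degenerate eigenpairs, so individual columns
  # are only defined up to rotation within an eigenspace; the embedding
  # geometry (pairwise distances) must nevertheless coincide
  expect_equal(as.matrix(dist(embCoordinates(e0))),
               as.matrix(dist(embCoordinates(e1))), tolerance = 1e-8)
  expect_equal(embEigenvalues(e0), embEigenvalues(e1), tolerance = 1e-10)
})

test_that("a disconnected affinity graph is rejected", {
  aff <- diag(10)
  aff[1:5, 1:5] <- 0.8; aff[6:10, 6:10] <- 0.8
  diag(aff) <- 1
  expect_error(diffusionMap(aff, nComponents = 3L), "disconnected")
})

test_that("the reference embedding keeps the configured dimensionality", {
  refEmb <- smallReference()$refEmb
  expect_true(refEmb@isReference)
  expect_equal(ncol(embCoordinates(refEmb)), 10L)
  expect_lt(max(embEigenvalues(refEmb)), 1)
})

test_that("change of basis recovers exact linear maps", {
  set.seed(8)
  psi <- matrix(rnorm(40 * 6), 40, 6)
  ref <- embFromCoords(psi, isReference = TRUE)
  # identity
  cb <- changeOfBasis(embFromCoords(psi), ref)
  expect_equal(cb$operator, diag(6), tolerance = 1e-10)
  expect_lt(cb$residual, 1e-10)
  # column permutation
  perm <- c(3, 1, 2, 6, 4, 5)
  cbP <- changeOfBasis(embFromCoords(psi[, perm]), ref)
  Pm <- matrix(0, 6, 6)
  Pm[cbind(seq_len(6), perm)] <- 1  # row i sends phi column i back to slot perm[i]
  expect_equal(unname(cbP$operator), Pm, tolerance = 1e-8)
  expect_equal(embCoordinates(cbP$aligned), psi, tolerance = 1e-8)
  # random invertible G: operator recovers G^{-1}
  G <- matrix(rnorm(36), 6, 6) + diag(6)
  cbG <- changeOfBasis(embFromCoords(psi %*% G), ref)
  expect_equal(cbG$operator, solve(G), tolerance = 1e-6)
  expect_equal(embCoordinates(cbG$aligned), psi, tolerance = 1e-8)
  expect_true(cbG$aligned@isAligned)
  # idempotence: aligning an aligned embedding is a no-op
  cb2 <- changeOfBasis(cbG$aligned, ref)
  expect_lt(max(abs(embCoordinates(cb2$aligned) -
                    embCoordinates(cbG$aligned))), 1e-10)
})

test_that("rank-deficient embeddings fall back to the pseudoinverse", {
  set.seed(9)
  psi <- matrix(rnorm(30 * 4), 30, 4)
  phi <- psi
  phi[, 4] <- phi[, 3]  # rank 3
  expect_warning(cb <- changeOfBasis(embFromCoords(phi),
                                     embFromCoords(psi, isReference = TRUE)),
                 "pseudoinverse")
  expect_true(all(is.finite(cb$operator)))
  expect_error(changeOfBasis(embFromCoords(psi[, 1:3]),
                             embFromCoords(psi, isReference = TRUE)),
               "share")
})
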