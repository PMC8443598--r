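test_that("group-only GLM reproduces the pooled two-sample t", {
  y <- c(1, 2, 3, 4, 5, 6)
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))
  gc <- glmContrast(y, X, c(0, 1))
  expect_equal(gc$t, 3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_equal(gc$t, 3.674, tolerance = 1e-3)
  tt <- t.test(y[4:6], y[1:3], var.equal = TRUE)
  expect_equal(gc$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(gc$p, tt$p.value, tolerance = 1e-12)
  expect_equal(gc$df, 4)
})

test_that("GLM handles orthogonal responses and collinearity", {
  set.seed(20)
  g <- rep(0:1, each = 10)
  z <- rnorm(20)
  X <- cbind(intercept = 1, group = g, z = z)
  # response built purely from the covariate: zero group effect
  gc <- glmContrast(2 * z, X, c(0, 1, 0))
  expect_equal(gc$t, 0, tolerance = 1e-8)
  expect_error(glmContrast(rnorm(20), cbind(X, g2 = g), c(0, 1, 0, 0)),
               "collinear")
})

test_that("vectorized GLM map agrees with the scalar contrast", {
  set.seed(21)
  X <- cbind(1, rep(0:1, each = 8), rnorm(16))
  Y <- matrix(rnorm(16 * 7), 16, 7)
  tv <- idioconn:::glmContrastMap(Y, X, c(0, 1, 0))
  for (j in 1:7)
    expect_equal(tv[j], glmContrast(Y[, j], X, c(0, 1, 0))$t,
                 tolerance = 1e-10)
})

test_that("BH-FDR matches the definitional oracle", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrBH(0.2), 0.2)
  set.seed(22)
  for (rep in 1:20) {
    p <- runif(sample(2:40, 1))
    adj <- fdrBH(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    # monotone in the order statistics, capped at 1, never anti-conservative
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("Cohen's d uses the pooled n-1 standard deviation", {
  g <- factor(rep(c("a", "b"), each = 3))
  expect_equal(cohensD(c(1, 2, 3, 4, 5, 6), g), 3)
  expect_equal(cohensD(c(1, 2, 3, 1, 2, 3), g), 0)
  expect_equal(cohensD(c(4, 5, 6, 1, 2, 3), g), -3)
  expect_error(cohensD(rep(1, 6), g), "zero")
})

test_that("TFCE integrates extent and height as specified", {
  adj <- cbind(1:9, 2:10)  # path graph on 10 parcels
  t1 <- c(2, rep(0, 9))    # single isolated suprathreshold parcel
  # one threshold step: 1^0.5 * h0^2 * dh with h0 = dh = 2
  expect_equal(tfce(t1, adj, nsteps = 1)[1], 2^2 * 2)
  # explicit dh: sum over h in {1, 2} of h^2 * 1
  expect_equal(tfce(t1, adj, dh = 1)[1], 1 + 4)
  expect_equal(tfce(rep(0, 10), adj), rep(0, 10))
  # negative tail is processed symmetrically
  expect_equal(tfce(-t1, adj, dh = 1)[1], -5)
  # E = 0, H = 0, fine dh: enhancement approaches the height integral = t
  tmap <- c(0.5, 1.8, 1.2, 0, 0, 2.5, 0.3, 0, 0, 1)
  enh <- tfce(tmap, adj, E = 0, H = 0, nsteps = 4000)
  expect_equal(enh, tmap, tolerance = 2e-3)
  # cluster extent matters: a parcel inside a large cluster is enhanced
  # beyond an isolated parcel of the same height
  t2 <- c(2, 2, 2, 0, 0, 2, 0, 0, 0, 0)
  enh2 <- tfce(t2, adj, dh = 1)
  expect_gt(enh2[2], enh2[6])
  expect_equal(enh2[1], sqrt(3) * 5)
})

test_that("max-statistic permutation correction is calibrated at the edges", {
  set.seed(23)
  n <- 20; P <- 12
  cohort <- data.frame(group = factor(rep(c("typical", "atypical"), each = 10),
                                      levels = c("typical", "atypical")),
                       age = rnorm(n, 20, 5),
                       sex = factor(sample(c("F", "M"), n, TRUE)),
                       site = factor(rep(c("s1", "s2"), n / 2)))
  design <- designMatrix(cohort)
  adj <- cbind(1:(P - 1), 2:P)
  # constant response: invariant under permutation, p = 1 everywhere
  Yc <- matrix(5, n, P)  # constant response: permutation-invariant
  pc <- quietly(permutationCorrect(Yc, design, adj, nPerm = 60, seed = 1))
  expect_true(all(pc$pCorr == 1))
  # overwhelming group effect: p at the permutation lower bound
  Ys <- matrix(rnorm(n * P), n, P)
  Ys[cohort$group == "atypical", 1:6] <- Ys[cohort$group == "atypical", 1:6] + 50
  ps <- quietly(permutationCorrect(Ys, design, adj, nPerm = 60, seed = 2))
  expect_equal(min(ps$pCorr), 1 / 61)
  expect_true(all(ps$pCorr >= 1 / 61))
  expect_true(all(ps$posMask[1:6]))
  # seeded: reproducible
  ps2 <- quietly(permutationCorrect(Ys, design, adj, nPerm = 60, seed = 2))
  expect_identical(ps$pCorr, ps2$pCorr)
  expect_warning(permutationCorrect(Ys, design, adj, nPerm = 50, seed = 1),
                 "coarse")
})

test_that("spin test nails the self-correlation case and rejects constants", {
  w <- smallWorld()
  cen <- parcelCentroids(w$parc)
  set.seed(24)
  mapA <- rnorm(40)
  st <- spinTest(mapA, mapA, cen, nRot = 99, seed = 3)
  expect_equal(st$r, 1)
  expect_equal(st$pSpin, 1 / 100)
  expect_length(st$null, 99)
  expect_error(spinTest(rep(1, 40), mapA, cen), "constant")
  # reproducibility
  st2 <- spinTest(mapA, mapA, cen, nRot = 99, seed = 3)
  expect_identical(st$null, st2$null)
})

test_that("severity correlation recovers exact and null couplings", {
  set.seed(25)
  n <- 60
  cohort <- data.frame(
    id = sprintf("s%02d", 1:n),
    group = factor(rep(c("typical", "atypical"), each = n / 2),
                   levels = c("typical", "atypical")),
    age = rep(20, n),  # constant: residualization reduces to centering
    severity = NA_real_)
  y <- rnorm(n)
  cohort$severity[cohort$group == "atypical"] <-
    2 + 3 * y[cohort$group == "atypical"]
  res <- severityCorrelation(cbind(y), cohort, covariates = "age")
  expect_equal(res$r, 1, tolerance = 1e-8)
  # independent severity: r centered on zero across replicates
  rs <- vapply(1:40, function(k) {
    cohort$severity[cohort$group == "atypical"] <- rnorm(n / 2)
    severityCorrelation(cbind(rnorm(n)), cohort, covariates = "age")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(severityCorrelation(cbind(y), cohort[1:33, ], "age"),
               "fewer than 4")
})

test_that("covariate-free severity correlation approximates plain Pearson", {
  set.seed(26)
  n <- 400
  cohort <- data.frame(
    group = factor(rep(c("typical", "atypical"), each = n / 2),
                   levels = c("typical", "atypical")),
    age = rnorm(n, 20, 5),
    sex = factor(sample(c("F", "M"), n, TRUE)),
    site = factor(sample(c("s1", "s2", "s3"), n, TRUE)),
    severity = NA_real_)
  y <- rnorm(n)  # independent of all covariates
  aty <- cohort$group == "atypical"
  cohort$severity[aty] <- 1 + 0.8 * y[aty] + rnorm(n / 2, sd = 0.5)
  res <- severityCorrelation(cbind(y), cohort)
  expect_equal(res$r, cor(y[aty], cohort$severity[aty]), tolerance = 0.03)
})

test_that("age effects and the child/adult split behave as specified", {
  set.seed(27)
  n <- 80
  cohort <- data.frame(
    group = factor(rep(c("typical", "atypical"), each = n / 2),
                   levels = c("typical", "atypical")),
    age = runif(n, 6, 40),
    sex = factor(sample(c("F", "M"), n, TRUE)),
    site = factor(sample(c("s1", "s2"), n, TRUE)))
  # noiseless linear age dependence: exact fit flagged
  ae <- ageEffect(2 * cohort$age, cohort)
  expect_true(ae$age$exactFit)
  expect_true(is.infinite(ae$age$t) || abs(ae$age$t) > 1e6)
  # equal slopes in both groups: interaction t centered on zero
  ts <- vapply(1:30, function(k)
    ageEffect(0.5 * cohort$age + rnorm(n), cohort)$interaction$t, numeric(1))
  expect_lt(abs(mean(ts)), 0.5)
  # strict split at 18
  child <- ageEffect(rnorm(n) + 0.1 * cohort$age, cohort, subset = "child")
  adult <- ageEffect(rnorm(n) + 0.1 * cohort$age, cohort, subset = "adult")
  expect_equal(child$n + adult$n, n)
  expect_equal(child$n, sum(cohort$age < 18))
})

test_that("reference bootstrap is seeded and group-resolved", {
  scen <- smallScenario()
  sr <- smallReference()
  bt <- quietly(referenceBootstrap(sr$fcs, scen$referenceLabels, scen$gg,
                                   scen$cohort, nBoot = 2, seed = 5,
                                   nComponents = 8L))
  expect_equal(nrow(bt), 4L)
  expect_setequal(unique(bt$group), c("typical", "atypical"))
  expect_true(all(is.finite(bt$msd)) && all(bt$msd >= 0))
  expect_true(all(bt$dice >= 0 & bt$dice <= 1))
  bt2 <- quietly(referenceBootstrap(sr$fcs, scen$referenceLabels, scen$gg,
                                    scen$cohort, nBoot = 2, seed = 5,
                                    nComponents = 8L))
  expect_identical(bt, bt2)
  expect_error(referenceBootstrap(sr$fcs, scen$referenceLabels, scen$gg,
                                  scen$cohort, fraction = 0.05, nBoot = 2),
               "too small")
})
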