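## Synthetic two-group, multi-site cohort with ground-truth network shifts.
## The generator states a fixed "world": subjects carry per-network geodesic
## boundary shifts of a reference 7-network template; the atypical group has
## larger shifts in four networks and a smaller shift in one designated
## network; shift magnitude drifts linearly with age (same slope in both
## groups); a severity score is coupled to the realized mean shift in the
## atypical group; sites act on time-series amplitude only.

#' Cohort generator configuration
#'
#' Defaults encode the emulated study design: two groups scanned at five
#' sites with unequal enrolment weights, ages ~ truncated normal (mean 18.4,
#' sd 8, range 5-45 years), male-skewed sex ratio, log-normal framewise
#' displacement with a small mass above the 0.3 mm exclusion cutoff, and
#' per-network geodesic shift magnitudes in mm (sphere radius 100):
#' networks 1-4 shift more in the atypical group, network 5 shifts less,
#' networks 6-7 are equal. Severity (a calibrated-severity-score analog)
#' is `a + b * realized mean shift + noise` for atypical subjects.
#'
#' @param nTypical,nAtypical subjects per group
#' @param sites named numeric vector of site sampling weights
#' @param ageMean,ageSD,ageRange age distribution (years), truncated normal
#' @param pMale probability of sex `"M"`
#' @param fdMeanlog,fdSdlog log-normal framewise displacement parameters (mm)
#' @param nNetworks number of template networks
#' @param shiftTypical,shiftAtypical per-network mean shift magnitude (mm);
#'   recycled to `nNetworks`
#' @param shiftJitterSD subject-level shift jitter sd (mm)
#' @param ageSlope shift increase per year of age (mm/year), both groups
#' @param severityIntercept,severityCoupling,severityNoiseSD severity model
#'   `a + b * mean shift + N(0, sd)`, floored at 0
#' @return a list of class `cohortConfig`
#' @export
cohortConfig <- function(nTypical = 40L, nAtypical = 40L,
                         sites = c(siteA = 0.38, siteB = 0.28, siteC = 0.13,
                                   siteD = 0.11, siteE = 0.10),
                         ageMean = 18.4, ageSD = 8, ageRange = c(5, 45),
                         pMale = 0.8,
                         fdMeanlog = log(0.12), fdSdlog = 0.5,
                         nNetworks = 7L,
                         shiftTypical = c(20, 20, 20, 20, 65, 20, 20),
                         shiftAtypical = c(45, 45, 45, 45, 8, 20, 20),
                         shiftJitterSD = 5, ageSlope = 0.15,
                         severityIntercept = 1, severityCoupling = 0.4,
                         severityNoiseSD = 0.4) {
  if (nTypical <= 0 || nAtypical <= 0)
    stop("group sizes must be positive")
  cfg <- list(nTypical = as.integer(nTypical), nAtypical = as.integer(nAtypical),
              sites = sites, ageMean = ageMean, ageSD = ageSD,
              ageRange = ageRange, pMale = pMale, fdMeanlog = fdMeanlog,
              fdSdlog = fdSdlog, nNetworks = as.integer(nNetworks),
              shiftTypical = rep_len(shiftTypical, nNetworks),
              shiftAtypical = rep_len(shiftAtypical, nNetworks),
              shiftJitterSD = shiftJitterSD, ageSlope = ageSlope,
              severityIntercept = severityIntercept,
              severityCoupling = severityCoupling,
              severityNoiseSD = severityNoiseSD)
  class(cfg) <- "cohortConfig"
  cfg
}

#' Simulate a cohort table
#'
#' Draws demographics (group, site, age, sex, framewise displacement), the
#' per-subject per-network shift magnitudes that downstream
#' [shiftNetworks()] applies, and the severity score for atypical subjects,
#' coupled to the subject's realized mean shift (`a + b * shift + noise`,
#' floored at 0). Deterministic given `(config, seed)`.
#'
#' @param config a [cohortConfig()] list
#' @param seed integer RNG seed
#' @return a `data.frame` with columns `id`, `group`, `site`, `age`, `sex`,
#'   `fd`, `severity` (NA for typical subjects), plus attributes
#'   `shiftMagnitudes` (n x nNetworks matrix, mm) and `realizedShift`
#'   (per-subject mean magnitude, mm).
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- config$nTypical + config$nAtypical
  withr::with_seed(seed, {
    group <- factor(rep(c("typical", "atypical"),
                        c(config$nTypical, config$nAtypical)),
                    levels = c("typical", "atypical"))
    site <- factor(sample(names(config$sites), n, replace = TRUE,
                          prob = config$sites), levels = names(config$sites))
    age <- truncnorm::rtruncnorm(n, a = config$ageRange[1L],
                                 b = config$ageRange[2L],
                                 mean = config$ageMean, sd = config$ageSD)
    sex <- factor(ifelse(runif(n) < config$pMale, "M", "F"),
                  levels = c("F", "M"))
    fd <- rlnorm(n, config$fdMeanlog, config$fdSdlog)
    base <- rbind(config$shiftTypical, config$shiftAtypical)
    mag <- base[as.integer(group), , drop = FALSE] +
      config$ageSlope * (age - config$ageMean) +
      matrix(rnorm(n * config$nNetworks, sd = config$shiftJitterSD),
             n, config$nNetworks)
    mag <- pmax(mag, 0)
    realized <- rowMeans(mag)
    severity <- rep(NA_real_, n)
    aty <- group == "atypical"
    severity[aty] <- pmax(0, config$severityIntercept +
                          config$severityCoupling * realized[aty] +
                          rnorm(sum(aty), sd = config$severityNoiseSD))
    cohort <- data.frame(
      id = sprintf("sub-%03d", seq_len(n)), group = group, site = site,
      age = age, sex = sex, fd = fd, severity = severity,
      stringsAsFactors = FALSE)
    dimnames(mag) <- NULL
    attr(cohort, "shiftMagnitudes") <- mag
    attr(cohort, "realizedShift") <- realized
    cohort
  })
}

#' Shift network territories along the surface
#'
#' Displaces each network's boundary by a geodesic front: for network `c`
#' with magnitude `m`, a random direction on the sphere is drawn; parcels
#' outside the network within geodesic distance `m` of it on the advancing
#' side are captured, and parcels inside within distance `m` of the boundary
#' on the trailing side are released to their nearest other reference
#' network. Zero magnitude leaves labels unchanged; every relabeled parcel
#' lies within distance `m` of the network's reference boundary.
#'
#' @param referenceLabels integer parcel -> network labels
#' @param magnitudes per-network shift magnitudes (length units, >= 0)
#' @param gg a [GeodesicGraph-class]
#' @param centroids parcel centroid matrix (P x 3, on the sphere), used to
#'   orient the shift direction
#' @param seed integer RNG seed
#' @return integer vector of shifted labels
#' @export
shiftNetworks <- function(referenceLabels, magnitudes, gg, centroids,
                          seed = 1L) {
  stopifnot(all(magnitudes >= 0))
  nNet <- max(referenceLabels)
  stopifnot(length(magnitudes) == nNet)
  D <- gg@dist
  P <- length(referenceLabels)
  cur <- as.integer(referenceLabels)
  withr::with_seed(seed, {
    for (cc in seq_len(nNet)) {
      m <- magnitudes[cc]
      if (m <= 0) next
      u <- rnorm(3L)
      u <- u / sqrt(sum(u^2))
      s <- as.vector(centroids %*% u)
      inC <- referenceLabels == cc
      if (!any(inC)) stop("network ", cc, " absent from reference labels")
      dOut <- apply(D[, inC, drop = FALSE], 1L, min)
      dIn <- rep(Inf, P)
      dIn[inC] <- apply(D[inC, !inC, drop = FALSE], 1L, min)
      add <- !inC & dOut <= m & s > 0
      drop <- inC & dIn <= m & s <= 0
      if (any(drop)) {
        ## released parcels take the reference label of the nearest
        ## non-member parcel
        other <- which(!inC)
        nn <- other[apply(D[drop, other, drop = FALSE], 1L, which.min)]
        cur[drop] <- referenceLabels[nn]
      }
      cur[add] <- cc
    }
  })
  if (!all(seq_len(nNet) %in% cur))
    stop("shift magnitude too large: at least one network vanished")
  cur
}

#' Simulate a subject's parcel time series
#'
#' Latent-signal block model: each network has one shared latent Gaussian
#' signal; a parcel's series is its network latent plus independent noise
#' scaled so the expected within-network correlation equals
#' `withinNetworkCorr` (`noiseSD = sqrt(1/r - 1)`). Parcels in different
#' networks have independent latents (expected correlation 0). A scalar
#' `siteGain` rescales the amplitude only, leaving correlations untouched.
#'
#' @param labels integer parcel -> network labels
#' @param nTimepoints number of samples (>= 10)
#' @param withinNetworkCorr target within-network correlation in (0, 1);
#'   ignored when `noiseSD` is given directly
#' @param noiseSD optional noise sd overriding `withinNetworkCorr`
#' @param siteGain amplitude multiplier (site effect)
#' @param tr sampling interval, seconds (metadata only)
#' @param seed integer RNG seed
#' @return a P x nTimepoints matrix with attribute `tr`
#' @export
simulateSubjectTimeseries <- function(labels, nTimepoints = 150L,
                                      withinNetworkCorr = 0.5,
                                      noiseSD = NULL, siteGain = 1,
                                      tr = 2, seed = 1L) {
  if (nTimepoints < 10L) stop("nTimepoints must be at least 10")
  if (is.null(noiseSD)) {
    stopifnot(withinNetworkCorr > 0, withinNetworkCorr < 1)
    noiseSD <- sqrt(1 / withinNetworkCorr - 1)
  }
  P <- length(labels)
  nNet <- max(labels)
  x <- withr::with_seed(seed, {
    z <- matrix(rnorm(nTimepoints * nNet), nTimepoints, nNet)
    t(z[, labels, drop = FALSE]) +
      noiseSD * matrix(rnorm(P * nTimepoints), P, nTimepoints)
  })
  x <- x * siteGain
  attr(x, "tr") <- tr
  x
}

#' Scenario configuration for a full synthetic study
#'
#' Bundles the geometry (icosphere subdivisions, radius, parcel and network
#' counts), the cohort model ([cohortConfig()]) and the time-series model
#' into one stated world. Defaults: radius-100 sphere, 200 parcels,
#' 7 networks, 40 subjects per group, 150 timepoints at within-network
#' correlation 0.5, per-site amplitude gains spaced by `siteGainStep`.
#'
#' @param nSubdivisions,radius icosphere parameters
#' @param nParcels,nNetworks parcellation / template size
#' @param cohort a [cohortConfig()]; its `nNetworks` is forced to match
#' @param nTimepoints,withinNetworkCorr time-series model
#' @param siteGainStep spacing of per-site amplitude gains around 1
#' @return a list of class `scenarioConfig`
#' @export
scenarioConfig <- function(nSubdivisions = 3L, radius = 100,
                           nParcels = 200L, nNetworks = 7L,
                           cohort = cohortConfig(nNetworks = nNetworks),
                           nTimepoints = 300L, withinNetworkCorr = 0.5,
                           siteGainStep = 0.1) {
  stopifnot(cohort$nNetworks == nNetworks)
  cfg <- list(nSubdivisions = nSubdivisions, radius = radius,
              nParcels = as.integer(nParcels),
              nNetworks = as.integer(nNetworks), cohort = cohort,
              nTimepoints = as.integer(nTimepoints),
              withinNetworkCorr = withinNetworkCorr,
              siteGainStep = siteGainStep)
  class(cfg) <- "scenarioConfig"
  cfg
}

#' Simulate a complete synthetic study
#'
#' Generates the mesh, parcellation, geodesic graph, reference network
#' template, cohort table, per-subject shifted network labels and parcel
#' time series, and records ground truth (drawn shift magnitudes and the
#' realized per-network mean surface distance of each subject's labels from
#' the template). All stage seeds are derived deterministically from `seed`.
#'
#' @param config a [scenarioConfig()]
#' @param seed integer RNG seed
#' @return a list with elements `mesh`, `parcellation`, `gg`,
#'   `referenceLabels`, `cohort`, `subjectLabels` (P x n matrix),
#'   `timeseries` (list of P x T matrices), `shiftMagnitudes`,
#'   `realizedMSD` (n x nNetworks)
#' @export
simulateScenario <- function(config = scenarioConfig(), seed = 1L) {
  stopifnot(inherits(config, "scenarioConfig"))
  seed <- as.integer(seed)
  mesh <- makeSphereMesh(config$nSubdivisions, config$radius)
  parc <- makeParcellation(mesh, config$nParcels, seed = seed)
  gg <- geodesicGraph(parc)
  refLabels <- makeReferenceNetworks(parc, config$nNetworks, seed = seed + 1L)
  cohort <- simulateCohort(config$cohort, seed = seed + 2L)
  n <- nrow(cohort)
  mags <- attr(cohort, "shiftMagnitudes")
  gains <- 1 + config$siteGainStep *
    (seq_along(config$cohort$sites) - (length(config$cohort$sites) + 1) / 2)
  names(gains) <- names(config$cohort$sites)
  subjectLabels <- matrix(NA_integer_, nrow = config$nParcels, ncol = n)
  timeseries <- vector("list", n)
  realized <- matrix(NA_real_, n, config$nNetworks)
  for (i in seq_len(n)) {
    subjectLabels[, i] <- shiftNetworks(refLabels, mags[i, ], gg,
                                        parcelCentroids(parc),
                                        seed = seed + 100L + i)
    timeseries[[i]] <- simulateSubjectTimeseries(
      subjectLabels[, i], config$nTimepoints, config$withinNetworkCorr,
      siteGain = gains[[as.character(cohort$site[i])]],
      seed = seed + 10000L + i)
    realized[i, ] <- vapply(seq_len(config$nNetworks), function(cc)
      meanSurfaceDistance(which(refLabels == cc),
                          which(subjectLabels[, i] == cc), gg),
      numeric(1L))
  }
  names(timeseries) <- cohort$id
  list(mesh = mesh, parcellation = parc, gg = gg,
       referenceLabels = refLabels, cohort = cohort,
       subjectLabels = subjectLabels, timeseries = timeseries,
       shiftMagnitudes = mags, realizedMSD = realized, config = config,
       seed = seed)
}
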