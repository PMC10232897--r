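# RED: NMF decomposition, normalization, SDCP extraction, dominance.

test_that("an exactly factorizable matrix is reconstructed to 1e-6", {
  set.seed(20)
  A <- matrix(runif(120 * 2), 120, 2) %*% matrix(runif(2 * 40), 2, 40)
  A <- A / max(A)
  m <- fitRED(A, c = 2, maxIter = 5000, tol = 1e-14)
  expect_lt(m@reconError, 1e-6 * sqrt(sum(A^2)))
  # the stored factors reproduce the reported error
  expect_equal(m@reconError,
               sqrt(sum((A - temporalWeights(m) %*% spatialComponents(m))^2)),
               tolerance = 1e-8)
})

test_that("reconstruction error is non-increasing in the component count", {
  set.seed(21)
  A <- matrix(runif(100 * 4), 100, 4) %*% matrix(runif(4 * 30), 4, 30)
  errs <- vapply(2:4, function(k)
    suppressWarnings(fitRED(A, c = k, maxIter = 2000))@reconError,
    numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("negative input and degenerate sizes are rejected", {
  A <- matrix(1, 10, 4); A[1, 1] <- -0.1
  expect_error(fitRED(A, c = 2), "negative")
  expect_error(fitRED(abs(A), c = 1), "c must be >= 2")
})

test_that("two-state planted fixture: dominance switches at the event", {
  gen <- genPlantedTrajectory(plantedSpecSmall(31))
  res <- runREDOnPlanted(gen, window = 15)
  ev <- res$timeline$events
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$frame[1] - 300), 15)
  expect_true(all(res$timeline$weights >= 0))
})

test_that("constitutive pairs are the designed always-on pairs", {
  gen <- genPlantedTrajectory(plantedSpecSmall(32))
  raw <- computeContactSeries(gen$trajectory)
  sm <- smoothContacts(trimInvariantPairs(raw, verbose = FALSE), 15)
  fit <- fitRED(sm, c = 2)
  idx <- identifyConstitutivePairs(fit)
  got <- paste(pairIndex(fit)$resI[idx], pairIndex(fit)$resJ[idx])
  want <- paste(gen$truth$constitutivePairs[, 1],
                gen$truth$constitutivePairs[, 2])
  expect_setequal(got, want)
})

test_that("constitutive-pair selection follows the cv/mean thresholds", {
  spatial <- rbind(c(1.0, 1.0, 0.2, 0.9), c(1.0, 0.0, 0.2, 0.9))
  m <- new("REDModel", spatial = spatial,
           temporal = matrix(runif(20), 10, 2),
           normFactors = rep(NA_real_, 2), constitutivePairs = integer(),
           reconError = 0,
           pairIndex = data.frame(resI = 1:4, resJ = 5:8),
           segmentStarts = 1L, seed = NA_integer_, iterations = 1L,
           converged = TRUE)
  idx <- identifyConstitutivePairs(m, cvMax = 0.15, meanMin = 0.5)
  expect_true(1 %in% idx)   # identical across components: cv = 0
  expect_false(2 %in% idx)  # present in one component only: cv large
  expect_false(3 %in% idx)  # low mean
  expect_error(identifyConstitutivePairs(m, cvMax = 1e-9, meanMin = 1.5),
               "relax")
})

test_that("normalization puts constitutive pairs at 1, reconstruction fixed", {
  gen <- genPlantedTrajectory(plantedSpecSmall(33))
  raw <- computeContactSeries(gen$trajectory)
  sm <- smoothContacts(trimInvariantPairs(raw, verbose = FALSE), 15)
  fit <- fitRED(sm, c = 2)
  idx <- identifyConstitutivePairs(fit)
  nm <- normalizeComponents(fit, idx)
  expect_equal(unname(rowMeans(spatialComponents(nm)[, idx])), c(1, 1),
               tolerance = 1e-12)
  before <- temporalWeights(fit) %*% spatialComponents(fit)
  after <- temporalWeights(nm) %*% spatialComponents(nm)
  expect_lt(max(abs(before - after)), 1e-10)
  expect_error(normalizeComponents(fit, integer()), "empty")
})

test_that("SDCP extraction finds the planted switching pairs with signs", {
  gen <- genPlantedTrajectory(plantedSpecSmall(34))
  res <- runREDOnPlanted(gen, window = 15, kSigma = 0.5)
  sd <- res$sdcp
  sw <- gen$truth$switchingPairs
  swKey <- paste(sw$resI, sw$resJ)
  gotKey <- paste(sd$resI, sd$resJ)
  expect_true(all(swKey %in% gotKey))
  # direction agrees with the planted direction (first event is 1 -> 2)
  m <- merge(sd, sw, by = c("resI", "resJ"))
  expect_true(all(m$direction.x == m$direction.y))
})

test_that("SDCP threshold semantics: identical components and kSigma 0", {
  spatial <- rbind(c(1, 0.5, 0), c(1, 0.5, 0))
  m <- new("REDModel", spatial = spatial, temporal = matrix(1, 5, 2),
           normFactors = c(1, 1), constitutivePairs = 1L, reconError = 0,
           pairIndex = data.frame(resI = 1:3, resJ = 4:6),
           segmentStarts = 1L, seed = NA_integer_, iterations = 1L,
           converged = TRUE)
  expect_equal(nrow(extractSDCPs(m, 1, 2)), 0L)
  m@spatial[2, 3] <- 0.4
  allPairs <- extractSDCPs(m, 1, 2, kSigma = 0)
  expect_equal(allPairs$pair, 3L)
  expect_equal(allPairs$direction, "formed")
})

test_that("component permutation permutes outputs consistently", {
  gen <- genPlantedTrajectory(plantedSpecSmall(35))
  res <- runREDOnPlanted(gen, window = 15)
  m <- res$model
  mp <- m
  mp@spatial <- m@spatial[2:1, , drop = FALSE]
  mp@temporal <- m@temporal[, 2:1, drop = FALSE]
  mp@normFactors <- m@normFactors[2:1]
  tl <- dominanceTimeline(m); tlp <- dominanceTimeline(mp)
  expect_equal(tlp$dominant, 3L - tl$dominant)
  a <- extractSDCPs(m, 1, 2, kSigma = 0.5)
  b <- extractSDCPs(mp, 2, 1, kSigma = 0.5)
  expect_equal(a[c("resI", "resJ", "delta")], b[c("resI", "resJ", "delta")])
})

test_that("joint fit on two replicas generalizes their common event", {
  specA <- plantedSpecSmall(36, eventFrame = 250L)
  specB <- plantedSpecSmall(37, eventFrame = 350L)
  mkSm <- function(sp) {
    gen <- genPlantedTrajectory(sp)
    raw <- computeContactSeries(gen$trajectory)
    smoothContacts(trimInvariantPairs(raw, verbose = FALSE), 15)
  }
  smA <- mkSm(specA); smB <- mkSm(specB)
  joint <- suppressWarnings(concatenateContacts(list(smA, smB),
                                                mode = "intersect"))
  sdcpOf <- function(sm) {
    fit <- fitRED(sm, c = 2)
    m <- normalizeComponents(fit, identifyConstitutivePairs(fit))
    tl <- dominanceTimeline(m)
    ev <- tl$events[1, ]
    s <- extractSDCPs(m, ev$from, ev$to, kSigma = 0.5)
    paste(s$resI, s$resJ)
  }
  sJ <- sdcpOf(joint); sA <- sdcpOf(smA); sB <- sdcpOf(smB)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gte(jac(sJ, sA), 0.8)
  expect_gte(jac(sJ, sB), 0.8)
  # joint dominance shows one event per replica
  fitJ <- fitRED(joint, c = 2)
  mJ <- normalizeComponents(fitJ, identifyConstitutivePairs(fitJ))
  ev <- dominanceTimeline(mJ)$events
  expect_equal(nrow(ev), 2L)
})
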