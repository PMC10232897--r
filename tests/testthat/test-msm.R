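# Markov state models: clustering, TPM construction, implied
# timescales, GMRQ, PCCA+.

test_that("k-means recovers well-separated blobs with purity 1", {
  set.seed(60)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  lab <- sample(1:3, 600, replace = TRUE)
  X <- centers[lab, ] + matrix(rnorm(1200, sd = 0.5), ncol = 2)
  m <- clusterMicrostates(X, k = 3, seed = 1)
  a <- m@assignments[[1]]
  purity <- mean(vapply(1:3, function(b)
    max(table(a[lab == b])) / sum(lab == b), numeric(1)))
  expect_equal(purity, 1)
  # determinism
  m2 <- clusterMicrostates(X, k = 3, seed = 1)
  expect_identical(m@centers, m2@centers)
  # k = n: every frame its own center
  small <- X[1:20, ]
  mAll <- clusterMicrostates(small, k = 20, seed = 2)
  expect_equal(length(unique(mAll@assignments[[1]])), 20L)
  expect_error(clusterMicrostates(small, k = 21, seed = 1), "fewer frames")
})

test_that("deterministic cycle gives the permutation TPM; symmetrization
           restores detailed balance", {
  cyc <- rep(1:3, 50)
  un <- buildTPM(list(cyc), lag = 1, symmetrize = FALSE)
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  expect_equal(transitionMatrix(un), P, ignore_attr = TRUE)
  sym <- buildTPM(list(cyc), lag = 1)
  T <- transitionMatrix(sym); piv <- stationaryDistribution(sym)
  expect_lt(max(abs(piv * T - t(piv * T))), 1e-14)
  expect_equal(rowSums(T), rep(1, 3), ignore_attr = TRUE)
})

test_that("TPM estimated from a long chain approaches the truth", {
  Tstar <- matrix(c(.90, .08, .02,
                    .05, .90, .05,
                    .02, .08, .90), 3, byrow = TRUE)
  # symmetric stationary structure makes the symmetrized estimate
  # converge to Tstar itself
  s <- withr::with_seed(61, sampleMarkovChain(Tstar, 2e5))
  m <- buildTPM(list(s), lag = 1)
  expect_lt(max(abs(transitionMatrix(m) - Tstar)), 0.02)
  expect_equal(stationaryDistribution(m),
               allokin:::.stationaryFromTPM(Tstar), tolerance = 0.05)
})

test_that("states outside the largest connected set are trimmed", {
  # state 3 never visited; state 4 lives in its own disconnected segment
  segs <- list(rep(1:2, 50), rep(4L, 10))
  expect_warning(m <- buildTPM(segs, lag = 1, nStates = 4), "dropped")
  expect_equal(nrow(transitionMatrix(m)), 2L)
  expect_equal(m@active, 1:2)
})

test_that("implied timescales: closed form, disconnection, flatness", {
  T2 <- matrix(c(.95, .05, .10, .90), 2, byrow = TRUE)
  its <- tpmImpliedTimescales(T2, lag = 1)
  expect_equal(its$eigenvalue, 0.85)
  expect_equal(its$timescale, -1 / log(0.85), tolerance = 1e-12)
  # block-diagonal: second eigenvalue 1, infinite timescale
  Tdis <- diag(2)
  expect_equal(tpmImpliedTimescales(Tdis, 1)$timescale, Inf)
  # Markovian chain: estimated timescales flat across lags
  Tstar <- matrix(c(.95, .05, .10, .90), 2, byrow = TRUE)
  s <- withr::with_seed(62, sampleMarkovChain(Tstar, 3e5))
  tab <- impliedTimescales(list(s), lags = c(1, 2, 4, 8), nTimescales = 1)
  expect_lt(max(abs(tab$timescale / (-1 / log(0.85)) - 1)), 0.1)
  # non-positive eigenvalue flagged as NaN
  flip <- withr::with_seed(63, sampleMarkovChain(
    matrix(c(.05, .95, .95, .05), 2, byrow = TRUE), 2e4))
  expect_warning(out <- impliedTimescales(list(flip), lags = 1),
                 "non-positive")
  expect_true(is.nan(out$timescale[1]))
})

test_that("GMRQ: train = test equals the eigenvalue sum; sane splits", {
  Tstar <- matrix(c(.90, .08, .02,
                    .05, .90, .05,
                    .02, .08, .90), 3, byrow = TRUE)
  s <- withr::with_seed(64, sampleMarkovChain(Tstar, 1e5))
  half <- length(s) %/% 2
  a <- s[1:half]; b <- s[(half + 1):length(s)]
  m <- buildTPM(list(s), lag = 1)
  lam <- sort(eigen(transitionMatrix(m), only.values = TRUE)$values,
              decreasing = TRUE)
  expect_equal(gmrqScore(list(s), list(s), lag = 1, n = 3),
               sum(Re(lam[1:3])), tolerance = 1e-10)
  # n = 1: the stationary eigenvector scores the Perron eigenvalue 1
  expect_equal(gmrqScore(list(s), list(s), lag = 1, n = 1), 1,
               tolerance = 1e-10)
  # random split close to the resubstitution score
  expect_equal(gmrqScore(list(a), list(b), lag = 1, n = 2),
               gmrqScore(list(s), list(s), lag = 1, n = 2),
               tolerance = 0.05)
})

test_that("PCCA+ recovers planted blocks and degenerates gracefully", {
  mkBlockModel <- function(m, per, leak = 0.001) {
    K <- m * per
    blocks <- rep(seq_len(m), each = per)
    C <- matrix(leak, K, K)
    for (b in seq_len(m)) C[blocks == b, blocks == b] <- 1
    C <- (C + t(C)) / 2
    list(model = new("MarkovModel", centers = matrix(0, 0, 0),
                     assignments = list(), lag = 1L, counts = C,
                     tpm = C / rowSums(C), pi = rowSums(C) / sum(C),
                     active = seq_len(K), seed = NA_integer_),
         blocks = blocks)
  }
  fx <- mkBlockModel(2, 4)
  mac <- pccaMacrostates(fx$model, m = 2)
  expect_equal(length(unique(paste(mac@crisp, fx$blocks))), 2L)
  expect_equal(rowSums(mac@memberships), rep(1, 8), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(mac@populations), 1)
  # m = number of microstates: identity memberships up to relabeling
  mAll <- suppressWarnings(pccaMacrostates(fx$model, m = 8))
  expect_equal(sort(mAll@crisp), 1:8)
  expect_equal(max(abs(sort(as.vector(mAll@memberships)) -
                       sort(as.vector(diag(8))))), 0, tolerance = 1e-8)
  expect_error(pccaMacrostates(fx$model, m = 9), "more macrostates")
  # irreversible input rejected
  bad <- fx$model
  bad@tpm[1, 2] <- bad@tpm[1, 2] + 0.05
  bad@tpm <- bad@tpm / rowSums(bad@tpm)
  expect_error(pccaMacrostates(bad, m = 2), "not reversible")
})

test_that("macrostate populations aggregate the stationary weights", {
  expect_equal(macrostatePopulations(rep(0.25, 4), c(1, 1, 2, 2)),
               c(0.5, 0.5))
  expect_equal(macrostatePopulations(c(.1, .2, .3, .4), rep(1, 4)), 1)
  # frame-count oracle on a simulated chain
  Tstar <- matrix(c(.9, .1, 0, .05, .9, .05, 0, .1, .9), 3, byrow = TRUE)
  s <- withr::with_seed(65, sampleMarkovChain(Tstar, 2e5))
  m <- buildTPM(list(s), lag = 1)
  crisp <- c(1L, 1L, 2L)
  pops <- macrostatePopulations(stationaryDistribution(m), crisp)
  counts <- c(mean(s %in% 1:2), mean(s == 3))
  expect_equal(pops, counts, tolerance = 0.01)
})

test_that("Chapman-Kolmogorov holds for a Markovian fixture", {
  Tstar <- matrix(c(.9, .1, 0, .05, .9, .05, 0, .1, .9), 3, byrow = TRUE)
  s <- withr::with_seed(66, sampleMarkovChain(Tstar, 5e5))
  T1 <- transitionMatrix(buildTPM(list(s), lag = 5))
  T2 <- transitionMatrix(buildTPM(list(s), lag = 10))
  expect_lt(max(abs(T1 %*% T1 - T2)), 0.02)
})

test_that("full pipeline recovers planted macrostates from trajectories", {
  # 3 metastable basins in CV space -> cluster -> TPM -> PCCA+
  Tstar <- matrix(c(.97, .02, .01,
                    .02, .97, .01,
                    .01, .02, .97), 3, byrow = TRUE)
  gen <- genMarkovCV(list(tpm = Tstar,
                          means = rbind(c(0, 0), c(8, 0), c(4, 7)),
                          sds = 0.6, nFrames = 3e4, nSegments = 2,
                          seed = 67))
  micro <- clusterMicrostates(gen$segments, k = 30, seed = 67)
  micro <- buildTPM(micro, lag = 5)
  mac <- pccaMacrostates(micro, m = 3)
  # map each frame through cluster -> macrostate; compare to truth
  frameMacro <- unlist(lapply(micro@assignments, function(a)
    mac@crisp[match(a, micro@active)]))
  truth <- unlist(gen$labels)
  skip_if_not_installed("mclust")
  expect_gt(mclust::adjustedRandIndex(frameMacro, truth), 0.95)
})
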