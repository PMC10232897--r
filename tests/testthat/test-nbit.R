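# Gaussian configurational-entropy measures: entropies, total
# correlation, coordination information, channels.

test_that("differential entropy matches the Gaussian closed forms", {
  x <- withr::with_seed(80, matrix(rnorm(1e5), ncol = 1))
  expect_equal(nbitEntropy(x), 0.5 * log(2 * pi * exp(1)), tolerance = 0.01)
  expect_equal(nbitEntropy(2 * x),
               0.5 * log(2 * pi * exp(1)) + 0.5 * log(4), tolerance = 0.01)
  # 3-variable system with a designed covariance
  gn <- genGaussianNetwork(list(type = "factors", blocks = c(A = 3),
                                factors = list(list(targets = "A",
                                                    loading = 1.5)),
                                noiseSd = 0.8, nFrames = 1e5, seed = 81))
  expect_equal(nbitEntropy(gn$samples),
               oracleH(gn$covariance, 1:3), tolerance = 0.01)
  expect_error(nbitEntropy(matrix(c(1, NA), 2, 1)), "non-finite")
})

test_that("entropy is translation-invariant", {
  x <- withr::with_seed(82, matrix(rnorm(3000), ncol = 3))
  shifted <- sweep(x, 2, c(100, -7, 3.2), `+`)
  expect_lt(abs(nbitEntropy(x) - nbitEntropy(shifted)), 1e-10)
})

test_that("total correlation: independence, bivariate closed form, chain", {
  ind <- genGaussianNetwork(list(type = "factors", blocks = c(A = 2, B = 2),
                                 factors = list(), noiseSd = 1,
                                 nFrames = 5e4, seed = 83))
  tc0 <- totalCorrelation(list(ind$samples[, ind$blocks$A],
                               ind$samples[, ind$blocks$B]))
  expect_lt(abs(tc0), 0.01)
  expect_gt(tc0, -1e-6)
  # correlated scalar pair, rho chosen by loading/noise
  cor1 <- genGaussianNetwork(list(type = "factors", blocks = c(A = 1, B = 1),
                                  factors = list(list(targets = c("A", "B"),
                                                      loading = 3)),
                                  noiseSd = 1.4529663, nFrames = 1e5,
                                  seed = 84))
  rho <- cor1$covariance[1, 2] /
    sqrt(cor1$covariance[1, 1] * cor1$covariance[2, 2])
  expect_equal(rho, 0.81, tolerance = 1e-4)
  expect_equal(totalCorrelation(list(cor1$samples[, 1, drop = FALSE],
                                     cor1$samples[, 2, drop = FALSE])),
               -0.5 * log(1 - rho^2), tolerance = 0.02)
  # three blocks sharing one latent factor: closed form from covariance
  tri <- genGaussianNetwork(list(type = "factors",
                                 blocks = c(A = 2, B = 2, C = 2),
                                 factors = list(list(
                                   targets = c("A", "B", "C"), loading = 1)),
                                 noiseSd = 0.7, nFrames = 1e5, seed = 85))
  blocks <- tri$blocks
  expect_equal(totalCorrelation(lapply(blocks, function(b) tri$samples[, b])),
               oracleTC(tri$covariance, blocks), tolerance = 0.02)
  expect_error(totalCorrelation(list(tri$samples[, 1:2])), ">= 2 motifs")
})

test_that("conditional TC: independence, shielding, Schur-complement oracle", {
  net <- genGaussianNetwork(list(type = "chain",
                                 blocks = c(A = 2, B = 2, C = 2, D = 2),
                                 transfer = c(1, .9, .9, .9),
                                 latentNoise = .4, noiseSd = .4,
                                 nFrames = 1e5, seed = 86))
  S <- net$samples; b <- net$blocks
  # conditioning on an upstream-independent block changes nothing
  far <- genGaussianNetwork(list(type = "factors", blocks = c(Z = 2),
                                 factors = list(), noiseSd = 1,
                                 nFrames = 1e5, seed = 87))
  tc <- totalCorrelation(list(S[, b$C], S[, b$D]))
  tcCondInd <- conditionalTC(list(S[, b$C], S[, b$D]), far$samples)
  expect_equal(tc, tcCondInd, tolerance = 0.02)
  # shielding: C and D are coupled only through the chain; conditioning
  # on the full upstream path plus their own latents removes most TC
  tcCondB <- conditionalTC(list(S[, b$C], S[, b$D]), S[, b$B])
  expect_lt(tcCondB, tc)
  # closed-form oracle via sub-determinants of the exact covariance
  expect_equal(conditionalTC(list(S[, b$A], S[, b$B]), S[, b$C]),
               oracleCondTC(net$covariance, list(b$A, b$B), b$C),
               tolerance = 0.05)
  expect_error(conditionalTC(list(S[, b$A]), S[, b$C]), ">= 2 motifs")
})

test_that("coordination information: limits and normalization", {
  net <- genGaussianNetwork(list(type = "chain",
                                 blocks = c(T1 = 2, CH = 2, R1 = 2, R2 = 2),
                                 transfer = c(1, .9, .9, .9),
                                 latentNoise = .3, loading = 1,
                                 noiseSd = .3, nFrames = 1e5, seed = 88))
  S <- net$samples; b <- net$blocks
  recv <- list(S[, b$R1], S[, b$R2])
  # independent transmitter: CI ~ 0
  far <- withr::with_seed(89, matrix(rnorm(2e5), ncol = 2))
  ci0 <- coordinationInformation(recv, far)
  expect_lt(abs(ci0$ci), 0.02)
  expect_lt(abs(ci0$nci), 2)
  # the shared latent factor of the receiver blocks: NCI -> 100%
  ciSelf <- coordinationInformation(recv, S[, b$CH])
  expect_gt(ciSelf$nci, 75)
  # closed-form target from the exact covariance
  ciT <- coordinationInformation(recv, S[, b$T1])
  expect_equal(ciT$nci, oracleNCI(net$covariance, list(b$R1, b$R2), b$T1),
               tolerance = 0.05 * oracleNCI(net$covariance,
                                            list(b$R1, b$R2), b$T1))
})

test_that("mutual coordination distinguishes chain from bypass topology", {
  chain <- genGaussianNetwork(list(type = "chain",
                                   blocks = c(T1 = 2, CH = 2, R1 = 2,
                                              R2 = 2),
                                   transfer = c(1, .9, .9, .9),
                                   latentNoise = .3, noiseSd = .3,
                                   nFrames = 1e5, seed = 90))
  S <- chain$samples; b <- chain$blocks
  recv <- list(S[, b$R1], S[, b$R2])
  onPath <- mutualCoordination(recv, S[, b$T1], S[, b$CH])
  expect_gt(onPath$nmci, 80)
  # bypass: the transmitter couples to the receiver directly, the
  # "channel" block hangs off independently
  byp <- genGaussianNetwork(list(type = "factors",
                                 blocks = c(T1 = 2, CH = 2, R1 = 2, R2 = 2),
                                 factors = list(
                                   list(targets = c("T1", "R1", "R2"),
                                        loading = 1),
                                   list(targets = "CH", loading = 1)),
                                 noiseSd = .3, nFrames = 1e5, seed = 91))
  S2 <- byp$samples; b2 <- byp$blocks
  offPath <- mutualCoordination(list(S2[, b2$R1], S2[, b2$R2]),
                                S2[, b2$T1], S2[, b2$CH])
  expect_lt(abs(offPath$nmci), 10)
  # channel carrying an independent copy of nothing: MCI ~ 0
  far <- withr::with_seed(92, matrix(rnorm(2e5), ncol = 2))
  indep <- mutualCoordination(recv, S[, b$T1], far)
  expect_lt(abs(indep$mci), 0.02)
})

test_that("all measures agree with the sample-covariance oracle to 1e-9", {
  # same data, two routes: package entropies vs sub-determinants of the
  # one joint sample covariance (<= 50 variables)
  net <- genGaussianNetwork(list(type = "chain",
                                 blocks = c(A = 4, B = 4, C = 4, D = 4),
                                 transfer = c(1, .8, .8, .8),
                                 latentNoise = .5, noiseSd = .5,
                                 nFrames = 4000, seed = 93))
  S <- net$samples; b <- net$blocks
  Cs <- cov(S)  # the full joint sample covariance, assembled once
  expect_lt(abs(nbitEntropy(S[, b$A]) - oracleH(Cs, b$A)), 1e-9)
  expect_lt(abs(totalCorrelation(list(S[, b$A], S[, b$B], S[, b$C])) -
                oracleTC(Cs, list(b$A, b$B, b$C))), 1e-9)
  expect_lt(abs(conditionalTC(list(S[, b$A], S[, b$B]), S[, b$D]) -
                oracleCondTC(Cs, list(b$A, b$B), b$D)), 1e-9)
  expect_lt(abs(coordinationInformation(list(S[, b$A], S[, b$B]),
                                        S[, b$D])$ci -
                oracleCI(Cs, list(b$A, b$B), b$D)), 1e-9)
  expect_lt(abs(mutualCoordination(list(S[, b$A], S[, b$B]), S[, b$C],
                                   S[, b$D])$mci -
                oracleMCI(Cs, list(b$A, b$B), b$C, b$D)), 1e-9)
})

test_that("estimates are consistent between n and 4n frames", {
  mk <- function(n, seed) genGaussianNetwork(list(
    type = "chain", blocks = c(A = 2, B = 2, C = 2),
    transfer = c(1, .9, .9), latentNoise = .4, noiseSd = .4,
    nFrames = n, seed = seed))
  small <- mk(8000, 94); big <- mk(32000, 95)
  tcOf <- function(S, b) totalCorrelation(list(S[, b$A], S[, b$B],
                                               S[, b$C]))
  tcS <- tcOf(small$samples, small$blocks)
  tcB <- tcOf(big$samples, big$blocks)
  # bootstrap spread at the smaller n
  boots <- withr::with_seed(96, vapply(1:20, function(i) {
    idx <- sample.int(8000, replace = TRUE)
    tcOf(small$samples[idx, ], small$blocks)
  }, numeric(1)))
  expect_lt(abs(tcS - tcB), 2.5 * stats::sd(boots) + 1e-6)
})

test_that("displacement ensembles: modes, alignment guard, splitting", {
  gen <- genPlantedTrajectory(plantedSpecSmall(97))
  tr <- gen$trajectory
  ref <- tr; ref@coords <- tr@coords[1, , , drop = FALSE]
  expect_error(displacementEnsemble(tr, 1:2, ref, atoms = "all"),
               "superpose")
  aligned <- superpose(tr, ref, atomSelection(resIds = 7:12))
  sc <- displacementEnsemble(aligned, 1:2, ref, mode = "scalar",
                             atoms = "all")
  ve <- displacementEnsemble(aligned, 1:2, ref, mode = "vector",
                             atoms = "all")
  # scalar values are the row norms of the vector triplets
  nAt <- ncol(valueMatrix(sc))
  for (k in seq_len(nAt)) {
    expect_equal(valueMatrix(sc)[, k],
                 sqrt(rowSums(valueMatrix(ve)[, (3 * k - 2):(3 * k)]^2)),
                 tolerance = 1e-10)
  }
  # frame identical to the reference: zero displacement
  refAligned <- superpose(ref, ref, atomSelection(resIds = 7:12))
  z <- displacementEnsemble(refAligned, 1:2, ref, atoms = "all")
  expect_lt(max(valueMatrix(z)), 1e-10)
  # per-residue split covers all variables once
  parts <- splitByResidue(sc)
  expect_equal(sum(vapply(parts, function(p) ncol(valueMatrix(p)),
                          integer(1))), nAt)
  expect_error(dropResidues(sc, 1:2), "all residues")
  # overlapping motifs are rejected
  expect_error(totalCorrelation(list(sc, sc)), "share atoms")
})

test_that("coordination matrix has TC diagonal, NCI off-diagonal", {
  net <- genGaussianNetwork(list(type = "factors",
                                 blocks = c(A = 2, B = 2, C = 2),
                                 factors = list(list(targets = c("A", "B"),
                                                     loading = 1.2)),
                                 noiseSd = .5, nFrames = 3e4, seed = 98))
  # wrap sample blocks as ensembles with distinct residues
  mkEns <- function(cols, res, nm) new("DisplacementEnsemble",
    samples = net$samples[, cols],
    varMap = data.frame(atomId = cols, resId = res, comp = "d"),
    mode = "scalar", motif = nm)
  ens <- list(A = mkEns(1:2, c(1L, 2L), "A"),
              B = mkEns(3:4, c(3L, 4L), "B"),
              C = mkEns(5:6, c(5L, 6L), "C"))
  cm <- coordinationMatrix(ens)
  M <- valueMatrix(cm)
  expect_equal(dim(M), c(3L, 3L))
  expect_equal(M[1, 1], oracleTC(net$covariance, list(1, 2)),
               tolerance = 0.05)
  expect_gt(M[1, 2], 50)            # A strongly coordinated by B
  expect_lt(abs(M[1, 3]), 5)        # C independent
  # asymmetry allowed: receiver TC normalization differs
  expect_false(isTRUE(all.equal(M[1, 2], M[2, 1])))
})

test_that("channel profile ranks on-path residues above off-path ones", {
  net <- genGaussianNetwork(list(type = "chain",
                                 blocks = c(T1 = 2, CH = 2, R1 = 2, R2 = 2,
                                            OFF = 2),
                                 transfer = c(1, .9, .9, .9, 0),
                                 latentNoise = .3, noiseSd = .3,
                                 nFrames = 5e4, seed = 99))
  S <- net$samples; b <- net$blocks
  recv <- list(S[, b$R1], S[, b$R2])
  prof <- channelProfile(recv, S[, b$T1],
                         list(onPath = S[, b$CH], offPath = S[, b$OFF]))
  expect_gt(prof$nmci[prof$residue == "onPath"],
            prof$nmci[prof$residue == "offPath"] + 30)
  # zero-variance candidate scores ~ 0
  still <- matrix(0, nrow(S), 2)
  p0 <- suppressWarnings(channelProfile(recv, S[, b$T1],
                                        list(still = still)))
  expect_lt(abs(p0$nmci[1]), 5)
})

test_that("leave-one-out contribution finds the signal-carrying residue", {
  n <- 5e4
  z <- withr::with_seed(100, rnorm(n))
  noise <- function(s) withr::with_seed(s, matrix(rnorm(2 * n), ncol = 2))
  # receiver blocks share z; transmitter residue 1 carries z, residue 2
  # is pure noise
  recvEns <- new("DisplacementEnsemble",
                 samples = cbind(z + noise(101) * 0.4,
                                 z + noise(102) * 0.4),
                 varMap = data.frame(atomId = 1:4,
                                     resId = c(1L, 1L, 2L, 2L),
                                     comp = "d"),
                 mode = "scalar", motif = "recv")
  transEns <- new("DisplacementEnsemble",
                  samples = cbind(z + 0.2 * withr::with_seed(103, rnorm(n)),
                                  withr::with_seed(104, rnorm(n))),
                  varMap = data.frame(atomId = 5:6, resId = c(5L, 6L),
                                      comp = "d"),
                  mode = "scalar", motif = "trans")
  contrib <- transmitterContribution(recvEns, transEns)
  full <- coordinationInformation(recvEns, transEns)$ci
  expect_equal(contrib$contribution[contrib$residue == 5], full,
               tolerance = 0.15 * full)
  expect_lt(abs(contrib$contribution[contrib$residue == 6]), 0.1 * full)
  oneRes <- dropResidues(transEns, 6)
  expect_error(transmitterContribution(recvEns, oneRes), ">= 2 residues")
  # deterministic given the ensemble
  expect_identical(contrib, transmitterContribution(recvEns, transEns))
})
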