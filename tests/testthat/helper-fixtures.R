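# Shared fixtures and independent oracles. Everything here is built
# from first principles (closed forms, brute-force enumeration) so that
# package results are checked against code that does not share their
# implementation path.

mkPairs <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

toyTopology <- function(nres, atomsPerRes = 1L, names = "CA") {
  n <- nres * atomsPerRes
  data.frame(atomId = seq_len(n),
             atomName = rep(rep_len(names, atomsPerRes), nres),
             element = "C",
             resId = rep(seq_len(nres), each = atomsPerRes),
             resName = "BEA", chainId = "A", stringsAsFactors = FALSE)
}

toyTrajectory <- function(xyzFrames, top, ...) {
  # xyzFrames: list of natoms x 3 matrices
  co <- array(NA_real_, c(length(xyzFrames), nrow(top), 3))
  for (f in seq_along(xyzFrames)) co[f, , ] <- xyzFrames[[f]]
  trajectoryFromCoords(top, co, ...)
}

randomRotation <- function() {
  q <- svd(matrix(rnorm(9), 3, 3))
  R <- q$u %*% t(q$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigidTransform <- function(traj, R, shift) {
  co <- traj@coords
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- sweep(matrix(co[f, , ], ncol = 3) %*% R, 2, shift, `+`)
  out <- traj
  out@coords <- co
  out
}

# ---- Gaussian-entropy oracle (sub-determinant route) ------------------
# every entropy evaluated from sub-matrices of ONE covariance matrix;
# used both with the exact generator covariance (closed-form targets)
# and with a sample covariance (implementation cross-check).

oracleH <- function(C, idx) {
  S <- as.matrix(C[idx, idx, drop = FALSE])
  0.5 * (nrow(S) * log(2 * pi * exp(1)) +
         as.numeric(determinant(S, logarithm = TRUE)$modulus))
}

oracleTC <- function(C, blocks) {
  sum(vapply(blocks, function(b) oracleH(C, b), numeric(1))) -
    oracleH(C, unlist(blocks))
}

oracleCondTC <- function(C, blocks, m) {
  Hm <- oracleH(C, m)
  sum(vapply(blocks, function(b) oracleH(C, c(b, m)) - Hm, numeric(1))) -
    (oracleH(C, c(unlist(blocks), m)) - Hm)
}

oracleCI <- function(C, blocks, m)
  oracleTC(C, blocks) - oracleCondTC(C, blocks, m)

oracleNCI <- function(C, blocks, m)
  100 * oracleCI(C, blocks, m) / oracleTC(C, blocks)

oracleMCI <- function(C, blocks, m, n)
  oracleCI(C, blocks, m) + oracleCI(C, blocks, n) -
    oracleCI(C, blocks, c(m, n))

oracleNMCI <- function(C, blocks, m, n)
  100 * oracleMCI(C, blocks, m, n) / oracleCI(C, blocks, m)

# ---- brute-force pathway decomposition oracle -------------------------
# enumerate all simple paths, then greedily take the widest path
# (bottleneck objective, lexicographic tie-break) and subtract, exactly
# mirroring the defined semantics but via exhaustive search.

enumeratePaths <- function(W, src, dst) {
  n <- nrow(W)
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u %in% dst) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (v in seq_len(n))
      if (W[u, v] > 0 && !(v %in% path)) walk(c(path, v))
  }
  for (s in src) walk(s)
  out
}

bruteDecompose <- function(W, src, dst) {
  res <- list()
  repeat {
    paths <- enumeratePaths(W, src, dst)
    if (!length(paths)) break
    widths <- vapply(paths, function(p)
      min(W[cbind(p[-length(p)], p[-1])]), numeric(1))
    if (max(widths) <= 1e-15) break
    best <- which(widths == max(widths))
    if (length(best) > 1L) {
      keys <- vapply(paths[best], function(p)
        paste(sprintf("%06d", p), collapse = ""), character(1))
      best <- best[order(keys)][1]
    } else best <- best[1]
    p <- paths[[best]]
    f <- widths[[if (is.numeric(best)) best else 1L]]
    f <- min(W[cbind(p[-length(p)], p[-1])])
    W[cbind(p[-length(p)], p[-1])] <- W[cbind(p[-length(p)], p[-1])] - f
    res[[length(res) + 1L]] <- list(path = p, flux = f)
  }
  res
}

# ---- planted-event specs ---------------------------------------------

# small fixture: quick per-test runs
plantedSpecSmall <- function(seed, nFrames = 600L, eventFrame = 300L) {
  list(
    nResidues = 12, nFrames = nFrames, eventFrames = eventFrame,
    sigma = 0.2, seed = seed,
    states = list(
      list(contacts = mkPairs(1, 2, 3, 4), ligandSite = 3),
      list(contacts = mkPairs(1, 3, 2, 4), ligandSite = 6)),
    constitutivePairs = mkPairs(7, 8, 9, 10, 11, 12),
    flickerPairs = mkPairs(5, 6, 5, 7, 6, 7), flickerRate = 0.15)
}

# study-scale fixture: 20 residues (190 candidate pairs), 8 planted
# switching pairs, ~170 flicker pairs, 10 constitutive pairs
plantedSpecStudy <- function(seed, nFrames = 1000L, eventFrame = 500L) {
  sw1 <- mkPairs(1, 2, 3, 4, 5, 6, 7, 8)
  sw2 <- mkPairs(1, 3, 2, 4, 5, 7, 6, 8)
  allp <- t(combn(20, 2))
  key <- paste(allp[, 1], allp[, 2])
  used <- rbind(sw1, sw2)
  pool <- allp[!key %in% paste(used[, 1], used[, 2]), , drop = FALSE]
  consti <- pool[seq_len(10), , drop = FALSE]
  flick <- pool[-seq_len(10), , drop = FALSE]
  list(
    nResidues = 20, nFrames = nFrames, eventFrames = eventFrame,
    sigma = 0.2, seed = seed,
    states = list(list(contacts = sw1), list(contacts = sw2)),
    constitutivePairs = consti, flickerPairs = flick, flickerRate = 0.1)
}

# planted switching pairs among protein residues as "i-j" keys
plantedSwitchKeys <- function(gen, maxRes = Inf) {
  sw <- gen$truth$switchingPairs
  sw <- sw[sw$resJ <= maxRes, , drop = FALSE]
  unique(paste(sw$resI, sw$resJ))
}

runREDOnPlanted <- function(gen, c = 2, window = 25, kSigma = 4) {
  raw <- computeContactSeries(gen$trajectory)
  sm <- smoothContacts(trimInvariantPairs(raw, verbose = FALSE), window)
  fit <- fitRED(sm, c = c)
  model <- normalizeComponents(fit, identifyConstitutivePairs(fit))
  tl <- dominanceTimeline(model)
  ev <- tl$events[1, ]
  list(model = model, timeline = tl,
       sdcp = extractSDCPs(model, ev$from, ev$to, kSigma = kSigma),
       series = sm)
}

# pipeline config used by the end-to-end tests
pipelineDemoConfig <- function(seed = 5) {
  list(
    seed = seed,
    input = list(synthetic = plantedSpecSmall(seed)),
    contacts = list(window = 15),
    red = list(components = 2),
    cv = list(serSite = 3, trpSite = 6,
              contactPairs = list(c(1, 2), c(1, 3))),
    tica = list(lag = 10, k = 2),
    msm = list(k = 12, lag = 20, macrostates = 2),
    tpt = list(source = 1, target = 2),
    nbit = list(motifs = list(m1 = c(1, 2), m2 = c(3, 4), m3 = c(7, 8)))
  )
}
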