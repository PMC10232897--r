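# Internal helpers shared across modules.

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# stream. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Monatomic masses (Da) for mass-weighted centers; unknown elements fall
# back to carbon so bead models with synthetic element codes still work.
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, SE = 78.971, FE = 55.845)

atomMasses <- function(elements) {
  m <- .ELEMENT_MASS[toupper(elements)]
  m[is.na(m)] <- .ELEMENT_MASS[["C"]]
  unname(m)
}

# Frobenius norm
frobenius <- function(x) sqrt(sum(x^2))

# frames per segment implied by segment starts and a total length
segmentLengths <- function(starts, nTotal) {
  diff(c(starts, nTotal + 1L))
}

# split a frames x d matrix into per-segment matrices
splitSegments <- function(x, starts) {
  n <- nrow(x)
  ends <- c(starts[-1] - 1L, n)
  lapply(seq_along(starts), function(i) x[starts[i]:ends[i], , drop = FALSE])
}

# hydrogen test on an atom table: element H, or name starting with H/digit+H
isHydrogen <- function(top) {
  el <- toupper(top$element)
  byElement <- el == "H"
  nm <- toupper(top$atomName)
  byName <- grepl("^[0-9]*H", nm)
  ifelse(el != "" & !is.na(el), byElement, byName)
}

# greedy cosine matching of component rows between two non-negative factor
# matrices (c x p); returns for each row of a the matched row of b
matchComponents <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  k <- nrow(a)
  cosine <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(0)
    sum(x * y) / (nx * ny)
  }
  S <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) S[i, j] <- cosine(a[i, ], b[j, ])
  out <- integer(k)
  for (step in seq_len(k)) {
    ij <- arrayInd(which.max(S), dim(S))
    out[ij[1]] <- ij[2]
    S[ij[1], ] <- -Inf
    S[, ij[2]] <- -Inf
  }
  out
}
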