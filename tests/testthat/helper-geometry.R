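# shared helpers: random rigid motions and structure transforms

randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

applyRigidMatrix <- function(coords, R, t) {
  sweep(coords %*% t(R), 2, t, "+")
}

applyRigidStructure <- function(x, R, t) {
  a <- atomTable(x)
  m <- applyRigidMatrix(as.matrix(a[, c("x", "y", "z")]), R, t)
  a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
  initialize(x, atoms = a)
}

# literal pairwise double-sum gyration tensor (O(N^2)) -- independent oracle
gyrationTensorDoubleSum <- function(coords) {
  n <- nrow(coords)
  tens <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- sweep(coords, 2, coords[i, ], "-")   # r_i - r_j over all j
    tens <- tens + crossprod(d)
  }
  tens / (2 * n^2)
}

# exhaustive maximum non-crossing pair subset (bitmask enumeration, m <= 14)
maxNonCrossingBruteForce <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0L) return(0L)
  crosses <- function(a, b) {
    (pairs[a, 1] < pairs[b, 1] & pairs[b, 1] < pairs[a, 2] &
       pairs[a, 2] < pairs[b, 2]) ||
      (pairs[b, 1] < pairs[a, 1] & pairs[a, 1] < pairs[b, 2] &
         pairs[b, 2] < pairs[a, 2])
  }
  conflict <- integer(m)
  for (a in seq_len(m))
    for (b in seq_len(m))
      if (a != b && crosses(a, b))
        conflict[a] <- bitwOr(conflict[a], bitwShiftL(1L, b - 1L))
  best <- 0L
  valid <- logical(2^m); valid[1] <- TRUE
  popcount <- integer(2^m)
  for (s in 1:(2^m - 1L)) {
    low <- bitwAnd(s, -s)
    i <- which(bitwShiftL(1L, 0:(m - 1L)) == low)
    rest <- bitwXor(s, low)
    valid[s + 1L] <- valid[rest + 1L] &&
      bitwAnd(conflict[i], rest) == 0L
    popcount[s + 1L] <- popcount[rest + 1L] + 1L
    if (valid[s + 1L] && popcount[s + 1L] > best) best <- popcount[s + 1L]
  }
  best
}

randomPairInstance <- function(m, L = 30L) {
  # m pairs over 2m distinct residues drawn from 1..L
  res <- sample.int(L, 2L * m)
  cbind(i = pmin(res[1:m], res[(m + 1):(2 * m)]),
        j = pmax(res[1:m], res[(m + 1):(2 * m)]))
}
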