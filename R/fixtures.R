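# Synthetic structures with machine-readable ground truth.
#
# Base heavy-atom coordinates are the standard planar reference-frame
# geometries for the four ribonucleobases (idealised ring + exocyclic
# positions; the Watson-Crick partner is obtained by the dyad flip
# (x, y, z) -> (x, -y, -z)).  The duplex generator stacks such base pairs
# with a per-step twist/rise; the backbone is a simplified geometric trace
# (correct phosphate radius and O3'-P connectivity, schematic ribose) --
# fixtures are geometric oracles, not chemical models.

.STD_BASE_COORDS <- list(
  A = rbind(N9 = c(-1.291, 4.498, 0), C8 = c(0.024, 4.897, 0),
            N7 = c(0.877, 3.902, 0), C5 = c(0.071, 2.771, 0),
            C6 = c(0.369, 1.398, 0), N6 = c(1.611, 0.909, 0),
            N1 = c(-0.668, 0.532, 0), C2 = c(-1.912, 1.023, 0),
            N3 = c(-2.320, 2.290, 0), C4 = c(-1.267, 3.124, 0)),
  G = rbind(N9 = c(-1.289, 4.551, 0), C8 = c(0.023, 4.962, 0),
            N7 = c(0.870, 3.969, 0), C5 = c(0.071, 2.833, 0),
            C6 = c(0.424, 1.460, 0), O6 = c(1.554, 0.955, 0),
            N1 = c(-0.700, 0.641, 0), C2 = c(-1.999, 1.087, 0),
            N2 = c(-2.949, 0.139, 0), N3 = c(-2.342, 2.364, 0),
            C4 = c(-1.265, 3.177, 0)),
  C = rbind(N1 = c(-1.285, 4.542, 0), C2 = c(-1.472, 3.158, 0),
            O2 = c(-2.628, 2.709, 0), N3 = c(-0.391, 2.344, 0),
            C4 = c(0.837, 2.868, 0), N4 = c(1.875, 2.027, 0),
            C5 = c(1.056, 4.275, 0), C6 = c(-0.023, 5.068, 0)),
  U = rbind(N1 = c(-1.284, 4.500, 0), C2 = c(-1.462, 3.131, 0),
            O2 = c(-2.563, 2.608, 0), N3 = c(-0.302, 2.397, 0),
            C4 = c(0.989, 2.884, 0), O4 = c(1.935, 2.094, 0),
            C5 = c(1.089, 4.311, 0), C6 = c(-0.024, 5.053, 0)))

# in-plane displacement applied to the U base of a G.U wobble pair
# (slides U so that G(O6)..U(N3) and G(N1)..U(O2) sit at ~2.8-2.9 A)
.WOBBLE_SHIFT <- c(0.46, 0.82, 0)

.WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")
.WOBBLE_PARTNER <- c(G = "U", U = "G")

.rotZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# strand-I nucleotide template (base + schematic backbone) in the pair
# frame; twist/rise are needed so that O3' lands 1.6 A from the next P
.nucleotideTemplate <- function(base, twist, rise) {
  bm <- .STD_BASE_COORDS[[base]]
  glyc <- if (base %in% c("A", "G")) bm["N9", ] else bm["N1", ]
  ring <- bm[rownames(bm) %in% .RING_ATOMS[[base]], , drop = FALSE]
  c1 <- glyc + 1.47 * (glyc - colMeans(ring)) /
    sqrt(sum((glyc - colMeans(ring))^2))
  P <- c(9 * cos(100 * pi / 180), 9 * sin(100 * pi / 180), 0.5)
  o3 <- as.numeric(.rotZ(twist) %*% P) + c(0, 0, rise - 1.6)
  seg <- function(from, to, f, dz = 0) from + f * (to - from) + c(0, 0, dz)
  bb <- rbind(
    P = P,
    OP1 = P + c(0, 0, 1.45),
    OP2 = P + 1.45 * c(P[1], P[2], 0) / sqrt(P[1]^2 + P[2]^2),
    "O5'" = seg(P, c1, 0.15, 0.1),
    "C5'" = seg(P, c1, 0.35, 0.2),
    "C4'" = seg(P, c1, 0.55, 0.3),
    "O4'" = seg(P, c1, 0.75, 0.55),
    "C1'" = c1,
    "C2'" = seg(c1, o3, 0.30, -0.40),
    "O2'" = seg(c1, o3, 0.30, -1.80),
    "C3'" = seg(c1, o3, 0.60, -0.20),
    "O3'" = o3)
  rbind(bb, bm)
}

.flip <- function(m) {
  m[, 2] <- -m[, 2]; m[, 3] <- -m[, 3]
  m
}

.assembleStructure <- function(resList, id) {
  # resList: list of list(chain, resno, base, coords matrix w/ rownames)
  rows <- lapply(seq_along(resList), function(i) {
    r <- resList[[i]]
    data.frame(chain = r$chain, resno = r$resno, residx = i,
               base = r$base, name = rownames(r$coords),
               element = .elementFromName(rownames(r$coords)),
               x = r$coords[, 1], y = r$coords[, 2], z = r$coords[, 3],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  new("RNAStructure", id = id, atoms = atoms, log = character())
}

#' Generate geometric point clouds with known shape descriptors
#'
#' Degenerate and random point sets for exercising the size/shape
#' statistics: \code{"rod"} is exactly collinear (asphericity 1, shape 2),
#' \code{"disc"} a regular planar polygon (isotropic in plane; asphericity
#' 1/4, shape -1/4), \code{"sphere_octahedron"} the six axis vertices of an
#' octahedron (all eigenvalues equal; asphericity 0, shape 0) and
#' \code{"uniform_random"} a seeded uniform cloud in a cube.
#'
#' @param kind one of "sphere_octahedron", "rod", "disc", "uniform_random".
#' @param n number of points (>= 2 for rod, >= 3 for disc; the octahedron
#'   always has 6 points).
#' @param seed integer seed, used by "uniform_random" only.
#' @return n x 3 coordinate matrix.
#' @examples
#' shapeParameter(shapeDescriptors(makePointCloud("rod", 10)))   # 2
#' @export
makePointCloud <- function(kind = c("sphere_octahedron", "rod", "disc",
                                    "uniform_random"),
                           n = 50, seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    sphere_octahedron = {
      a <- 5
      rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0),
            c(0, -a, 0), c(0, 0, a), c(0, 0, -a))
    },
    rod = {
      if (n < 2) stop("rod needs n >= 2")
      cbind(0, 0, seq_len(n))
    },
    disc = {
      if (n < 3) stop("disc needs n >= 3")
      ang <- 2 * pi * (seq_len(n) - 1) / n
      cbind(5 * cos(ang), 5 * sin(ang), 0)
    },
    uniform_random = {
      if (n < 2) stop("uniform_random needs n >= 2")
      set.seed(seed)
      matrix(stats::runif(3 * n, -5, 5), ncol = 3)
    })
}

#' Generate an ideal RNA duplex with ground-truth annotation
#'
#' Builds a two-chain helix by stacking idealised Watson-Crick (or, where
#' requested, G.U wobble) base-pair templates with a fixed per-step twist
#' and rise (defaults follow the A-form convention: 32.7 deg/bp and
#' 2.81 A/bp).  Chain A carries \code{sequence} 5'->3'; chain B its
#' antiparallel complement.  The construction itself is the oracle: the
#' returned pair and stack lists are exact.
#'
#' @param sequence chain-A base string, e.g. "GGCAGC".
#' @param twist helical twist per base pair, degrees.
#' @param rise helical rise per base pair, Angstrom.
#' @param wobbleAt integer positions of \code{sequence} (must hold G or U)
#'   that pair as G.U wobble instead of Watson-Crick.
#' @param id structure identifier.
#' @return list with \code{structure} (an [RNAStructure-class]),
#'   \code{pairs} (data.frame i, j, base_i, base_j, canonical) and
#'   \code{stacks} (data.frame i, j of sequence-adjacent intra-strand
#'   stacked bases), indices in internal residue numbering.
#' @export
makeDuplex <- function(sequence, twist = 32.7, rise = 2.81,
                       wobbleAt = integer(), id = "duplex") {
  seqI <- strsplit(toupper(sequence), "")[[1]]
  if (!length(seqI) || !all(seqI %in% c("A", "C", "G", "U")))
    stop("sequence must be a non-empty string over A,C,G,U")
  n <- length(seqI)
  if (length(wobbleAt)) {
    if (!all(wobbleAt %in% seq_len(n)))
      stop("wobbleAt positions outside sequence")
    if (!all(seqI[wobbleAt] %in% c("G", "U")))
      stop("wobble positions must hold G or U")
  }
  seqII <- unname(ifelse(seq_len(n) %in% wobbleAt,
                         .WOBBLE_PARTNER[seqI], .WC_PARTNER[seqI]))

  place <- function(coords, k) {
    g <- coords %*% t(.rotZ((k - 1) * twist))
    g[, 3] <- g[, 3] + (k - 1) * rise
    g
  }
  resList <- list()
  for (k in seq_len(n)) {       # chain A, pair order 1..n
    tmpl <- .nucleotideTemplate(seqI[k], twist, rise)
    if (k %in% wobbleAt && seqI[k] == "U") {
      bn <- rownames(tmpl) %in% rownames(.STD_BASE_COORDS$U)
      tmpl[bn, ] <- sweep(tmpl[bn, , drop = FALSE], 2,
                          -.flip(matrix(.WOBBLE_SHIFT, 1))[1, ], "-")
    }
    resList[[k]] <- list(chain = "A", resno = k, base = seqI[k],
                         coords = place(tmpl, k))
  }
  for (m in seq_len(n)) {       # chain B runs antiparallel: pair n..1
    k <- n - m + 1L
    tmpl <- .flip(.nucleotideTemplate(seqII[k], twist, rise))
    if (k %in% wobbleAt && seqII[k] == "U") {
      bn <- rownames(tmpl) %in% rownames(.STD_BASE_COORDS$U)
      tmpl[bn, ] <- sweep(tmpl[bn, , drop = FALSE], 2, .WOBBLE_SHIFT, "+")
    }
    resList[[n + m]] <- list(chain = "B", resno = m, base = seqII[k],
                             coords = place(tmpl, k))
  }
  structure_ <- .assembleStructure(resList, id)
  pairs <- data.frame(i = seq_len(n), j = 2L * n - seq_len(n) + 1L,
                      base_i = seqI, base_j = seqII,
                      canonical = TRUE, stringsAsFactors = FALSE)
  stackA <- if (n > 1) cbind(i = 1:(n - 1), j = 2:n) else NULL
  stackB <- if (n > 1) cbind(i = (n + 1):(2 * n - 1), j = (n + 2):(2 * n))
            else NULL
  stacks <- as.data.frame(rbind(stackA, stackB))
  list(structure = structure_, pairs = pairs, stacks = stacks)
}

#' Generate a hairpin with ground-truth secondary structure
#'
#' One chain of \code{2 * stemLen + loopLen} residues: an idealised stem of
#' \code{stemLen} Watson-Crick pairs closed by \code{loopLen} unpaired
#' residues laid out on a wide outward arc (smooth backbone trace whose
#' bases cannot pair).  Coordinates get a small seeded jitter so different
#' seeds give different coordinates with identical annotation.
#'
#' @param stemLen number of stem pairs (>= 1).
#' @param loopLen number of loop residues (>= 3, steric convention).
#' @param seed integer seed for the coordinate jitter.
#' @param stemSeq optional chain-5' stem sequence (length \code{stemLen});
#'   random (seeded) if missing.
#' @param loopSeq optional loop sequence; random (seeded) if missing.
#' @return list with \code{structure}, \code{pairs} (ground-truth pair
#'   data.frame as in [makeDuplex()]), \code{stemLength},
#'   \code{loopLength} and \code{loopPositions}.
#' @export
makeHairpin <- function(stemLen, loopLen, seed = 1,
                        stemSeq = NULL, loopSeq = NULL) {
  if (stemLen < 1) stop("stemLen must be >= 1")
  if (loopLen < 3) stop("loopLen must be >= 3 (steric convention)")
  set.seed(seed)
  if (is.null(stemSeq))
    stemSeq <- sample(c("A", "C", "G", "U"), stemLen, replace = TRUE)
  else stemSeq <- strsplit(toupper(paste(stemSeq, collapse = "")), "")[[1]]
  if (is.null(loopSeq))
    loopSeq <- sample(c("A", "C", "G", "U"), loopLen, replace = TRUE)
  else loopSeq <- strsplit(toupper(paste(loopSeq, collapse = "")), "")[[1]]
  stopifnot(length(stemSeq) == stemLen, length(loopSeq) == loopLen)
  twist <- 32.7; rise <- 2.81
  place <- function(coords, k) {
    g <- coords %*% t(.rotZ((k - 1) * twist))
    g[, 3] <- g[, 3] + (k - 1) * rise
    g
  }
  resList <- list()
  for (k in seq_len(stemLen))   # 5' strand of the stem, pairs 1..stemLen
    resList[[k]] <- list(chain = "A", resno = k, base = stemSeq[k],
                         coords = place(.nucleotideTemplate(stemSeq[k],
                                                            twist, rise), k))
  # loop: wide outward arc above the stem, bases far apart
  for (m in seq_len(loopLen)) {
    b <- loopSeq[m]
    tmpl <- .nucleotideTemplate(b, twist, rise)
    ang <- 140 + 40 * m
    radial <- 13 + 2 * sin(pi * m / (loopLen + 1))
    centre <- c(radial * cos(ang * pi / 180), radial * sin(ang * pi / 180),
                stemLen * rise + 2 + 1.2 * m)
    off <- sweep(tmpl, 2, colMeans(tmpl))
    resList[[stemLen + m]] <- list(chain = "A", resno = stemLen + m,
                                   base = b,
                                   coords = sweep(off %*% t(.rotZ(ang)), 2,
                                                  centre, "+"))
  }
  compl <- unname(.WC_PARTNER[stemSeq])
  for (m in seq_len(stemLen)) { # 3' strand, antiparallel: pairs stemLen..1
    k <- stemLen - m + 1L
    resList[[stemLen + loopLen + m]] <-
      list(chain = "A", resno = stemLen + loopLen + m, base = compl[k],
           coords = place(.flip(.nucleotideTemplate(compl[k], twist, rise)),
                          k))
  }
  st <- .assembleStructure(resList, sprintf("hairpin_s%d_l%d", stemLen,
                                            loopLen))
  a <- st@atoms
  jit <- matrix(stats::rnorm(nrow(a) * 3, sd = 0.01), ncol = 3)
  a$x <- a$x + jit[, 1]; a$y <- a$y + jit[, 2]; a$z <- a$z + jit[, 3]
  st@atoms <- a
  nTot <- 2L * stemLen + loopLen
  pairs <- data.frame(i = seq_len(stemLen), j = nTot - seq_len(stemLen) + 1L,
                      base_i = stemSeq, base_j = compl,
                      canonical = TRUE, stringsAsFactors = FALSE)
  list(structure = st, pairs = pairs, stemLength = stemLen,
       loopLength = loopLen,
       loopPositions = (stemLen + 1L):(stemLen + loopLen))
}
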