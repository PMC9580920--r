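# Base-local reference frames and cylindrical pair/stack geometry.
#
# Each nucleobase (ring + exocyclic heavy atoms, no sugar/phosphate) is
# treated as a rigid group.  The frame origin is the geometric centre of the
# base heavy atoms.  Two in-plane direction vectors are built from ring
# atoms: u = C8 - N1 for purines, u = C4 - N1 for pyrimidines, and
# v = N3 - N1 for both.  The base-plane normal Z is unit(u x v) for purines
# and unit(v x u) for pyrimidines, which orients every base the same way:
# the Watson-Crick edge at theta ~ 0 and the Hoogsteen/C-H edge at positive
# theta.  X is the direction from the origin to the Watson-Crick edge
# anchor (N1 in purines, N3 in pyrimidines) projected orthogonal to Z
# (Gram-Schmidt) and renormalised; Y = Z x X completes a right-handed
# orthonormal triad.  (Anchoring X at the glycosidic N1 of pyrimidines
# would point it at the sugar, placing Watson-Crick partners of pyrimidines
# in the sugar sector; the WC anchor keeps the sector semantics uniform
# across bases.)
#
# The position of base j in the frame of base i is reported in cylindrical
# coordinates (rho, theta, z): rho >= 0 in-plane distance, theta in
# [0, 360) degrees measured from X towards Y (theta := 0 when rho = 0), z
# the signed out-of-plane offset.  theta localises the interacting edge of
# base i: Watson-Crick near 0 deg, Hoogsteen near 100 deg, sugar near
# 280 deg.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Build the local reference frame of one nucleobase
#'
#' @param residue data.frame of atoms of a single residue (rows of
#'   [atomTable()]) containing at least the base ring atoms N1, N3 and C8
#'   (purines) or C4 (pyrimidines).
#' @return a list with elements \code{origin}, \code{X}, \code{Y}, \code{Z}
#'   (numeric length-3 each), of class \code{"BaseFrame"}.
#' @examples
#' fx <- makeDuplex("GC")
#' fr <- buildBaseFrame(atomTable(fx$structure)[
#'   atomTable(fx$structure)$residx == 1, ])
#' crossprod(cbind(fr$X, fr$Y, fr$Z))   # identity
#' @export
buildBaseFrame <- function(residue) {
  base <- residue$base[1]
  if (!base %in% c("A", "C", "G", "U")) stop("non-standard base: ", base)
  purine <- base %in% c("A", "G")
  baseAtoms <- residue[residue$name %in% .BASE_ATOMS[[base]], , drop = FALSE]
  at <- function(nm) {
    k <- match(nm, residue$name)
    if (is.na(k)) stop("incomplete base: residue ", residue$residx[1],
                       " (", base, ") lacks atom ", nm)
    as.numeric(residue[k, c("x", "y", "z")])
  }
  if (nrow(baseAtoms) < 3L)
    stop("incomplete base: residue ", residue$residx[1],
         " has fewer than 3 base atoms")
  origin <- colMeans(as.matrix(baseAtoms[, c("x", "y", "z")]))
  n1 <- at("N1")
  u <- .unit((if (purine) at("C8") else at("C4")) - n1)
  v <- .unit(at("N3") - n1)
  Z <- if (purine) .unit(.cross3(u, v)) else .unit(.cross3(v, u))
  anchor <- if (purine) n1 else at("N3")
  xraw <- anchor - origin
  xproj <- xraw - sum(xraw * Z) * Z
  X <- .unit(xproj)
  Y <- .cross3(Z, X)
  structure(list(origin = origin, X = X, Y = Y, Z = Z, base = base),
            class = "BaseFrame")
}

# 3-vector cross product
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Base frames for every residue of a structure
#'
#' @param x an [RNAStructure-class].
#' @return list of length L; element i is the \code{BaseFrame} of residue i,
#'   or \code{NULL} with a warning-free log when the base is incomplete.
#' @export
baseFrames <- function(x) {
  a <- atomTable(x)
  L <- structureLength(x)
  out <- vector("list", L)
  for (i in seq_len(L)) {
    res <- a[a$residx == i, , drop = FALSE]
    out[[i]] <- tryCatch(buildBaseFrame(res), error = function(e) NULL)
  }
  out
}

#' Cylindrical coordinates of one base frame in another
#'
#' Expresses the origin of frame j in the (X, Y, Z) triad of frame i.
#' Invariant under any global rigid motion applied to both frames.
#'
#' @param frameI,frameJ \code{BaseFrame} objects from [buildBaseFrame()].
#' @return named numeric vector \code{c(rho, theta, z)}; rho in Angstrom,
#'   theta in degrees in [0, 360) (0 when rho = 0), z signed Angstrom.
#' @export
relativeCylindrical <- function(frameI, frameJ) {
  d <- frameJ$origin - frameI$origin
  xx <- sum(d * frameI$X)
  yy <- sum(d * frameI$Y)
  zz <- sum(d * frameI$Z)
  rho <- sqrt(xx^2 + yy^2)
  theta <- if (rho < 1e-12) 0 else (atan2(yy, xx) * 180 / pi) %% 360
  if (theta >= 360 - 1e-9) theta <- 0
  c(rho = rho, theta = theta, z = zz)
}

#' Interacting-edge sector of a cylindrical angle
#'
#' Partitions theta in [0, 360) into the three interacting edges of a base.
#' Default boundaries centre the empirical loci of the three edges
#' (Watson-Crick near 0 deg, Hoogsteen near 100 deg, sugar near 280 deg)
#' and keep the sugar-occluded band (180-260 deg) inside the sugar sector:
#' WC = [0, 60) + [300, 360), Hoogsteen = [60, 180), Sugar = [180, 300).
#'
#' @param theta numeric vector of angles in degrees (any real; reduced
#'   modulo 360).
#' @param boundaries numeric c(wcEnd, hoogsteenEnd, sugarEnd) in degrees;
#'   WC spans [0, wcEnd) and [sugarEnd, 360).
#' @return character vector: "WC", "Hoogsteen" or "Sugar".
#' @examples
#' edgeSectorOf(c(0, 100, 280))   # WC Hoogsteen Sugar
#' @export
edgeSectorOf <- function(theta, boundaries = c(60, 180, 300)) {
  t0 <- theta %% 360
  ifelse(t0 < boundaries[1] | t0 >= boundaries[3], "WC",
         ifelse(t0 < boundaries[2], "Hoogsteen", "Sugar"))
}
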