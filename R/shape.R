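# Global size/shape descriptors.
#
# The gyration tensor is the second central moment of the heavy-atom
# positions (equal masses assumed), normalised so that its trace equals
# Rg^2; its ordered eigenvalues (lambda1 >= lambda2 >= lambda3) are the
# squared principal radii.  With lbar = (l1+l2+l3)/3:
#
#   asphericity  Delta = 3/2 * sum_i (l_i - lbar)^2 / (tr T)^2,  in [0, 1]
#   shape        S     = 27 * prod_i (l_i - lbar)   / (tr T)^3,  in [-1/4, 2]
#
# Delta = 0 and S = 0 for spherically symmetric distributions; S > 0 for
# prolate, S < 0 for oblate shapes.  The pairwise double-sum form of the
# tensor, (1/(2N^2)) * sum_ij (r_i - r_j)(r_i - r_j)^T, is algebraically
# identical to the centred single-sum form used here and is exercised as an
# independent oracle in the test suite.

.coordsOf <- function(x) {
  if (is(x, "RNAStructure"))
    return(as.matrix(atomTable(x)[, c("x", "y", "z")]))
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop("expected an RNAStructure or an n x 3 coordinate matrix")
}

#' Radius of gyration of an RNA structure or point set
#'
#' Root-mean-square distance of all heavy atoms from their geometric centre,
#' with equal masses assumed for all heavy atoms.  All chains are pooled:
#' the measure describes the entire deposited structure, not individual
#' chains.
#'
#' @param x an [RNAStructure-class] or an n x 3 coordinate matrix (Angstrom).
#' @param ... unused.
#' @return radius of gyration in Angstrom.
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1
#' @rdname radiusOfGyration
#' @export
setMethod("radiusOfGyration", "ANY", function(x, ...) {
  r <- .coordsOf(x)
  if (nrow(r) < 1L) stop("empty structure")
  c0 <- colMeans(r)
  sqrt(mean(rowSums(sweep(r, 2, c0)^2)))
})

#' Gyration tensor of an RNA structure or point set
#'
#' Symmetric positive semi-definite 3 x 3 tensor of second central moments,
#' normalised so that \code{sum(diag(T))} equals the squared radius of
#' gyration.
#'
#' @inheritParams radiusOfGyration
#' @return 3 x 3 symmetric matrix (Angstrom^2) with attribute
#'   \code{"eigenvalues"} holding the descending eigenvalues.
#' @rdname gyrationTensor
#' @export
setMethod("gyrationTensor", "ANY", function(x, ...) {
  r <- .coordsOf(x)
  if (nrow(r) < 1L) stop("empty structure")
  rc <- sweep(r, 2, colMeans(r))
  tens <- crossprod(rc) / nrow(r)
  tens <- (tens + t(tens)) / 2
  ev <- eigen(tens, symmetric = TRUE, only.values = TRUE)$values
  # clamp tiny negative eigenvalues arising from round-off
  tol <- 1e-12 * max(sum(diag(tens)), .Machine$double.eps)
  ev[ev < 0 & ev > -tol] <- 0
  attr(tens, "eigenvalues") <- sort(ev, decreasing = TRUE)
  tens
})

#' Asphericity and shape parameter of an RNA structure or point set
#'
#' Computes the gyration-tensor eigenvalues and the two rotation-invariant
#' (and scale-invariant) shape statistics: asphericity (0 = sphere, 1 =
#' rod) and the signed shape parameter (in [-1/4, 2]; positive prolate,
#' negative oblate, 0 spherically symmetric).
#'
#' @inheritParams radiusOfGyration
#' @return a [ShapeDescriptors-class] object.
#' @examples
#' rod <- makePointCloud("rod", 10)
#' shapeDescriptors(rod)   # asphericity 1, shape 2
#' @rdname shapeDescriptors
#' @export
setMethod("shapeDescriptors", "ANY", function(x, ...) {
  r <- .coordsOf(x)
  if (nrow(r) < 2L) stop("need at least 2 atoms for shape descriptors")
  tens <- gyrationTensor(r)
  ev <- attr(tens, "eigenvalues")
  tr <- sum(ev)
  if (tr <= 0) stop("degenerate geometry: all atoms coincide")
  lbar <- tr / 3
  dl <- ev - lbar
  delta <- 1.5 * sum(dl^2) / tr^2
  s <- 27 * prod(dl) / tr^3
  # numerical guards at the analytic bounds
  delta <- min(max(delta, 0), 1)
  s <- min(max(s, -0.25), 2)
  new("ShapeDescriptors", rg = sqrt(tr), eigenvalues = ev,
      asphericity = delta, shape = s, nAtoms = nrow(r))
})

#' @rdname shapeDescriptors
#' @param object a [ShapeDescriptors-class].
#' @export
asphericity <- function(object) object@asphericity

#' @rdname shapeDescriptors
#' @export
shapeParameter <- function(object) object@shape

#' @rdname shapeDescriptors
#' @export
rgValue <- function(object) object@rg

#' @rdname shapeDescriptors
#' @export
eigenvalues <- function(object) object@eigenvalues
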