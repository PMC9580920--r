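# Atom-type-pair distance statistics.
#
# Distances are Euclidean, computed between heavy atoms of DIFFERENT
# residues only; the single covalent inter-residue contact, the
# phosphodiester O3'(i)-P(i+1) link, is excluded, so every emitted distance
# is a non-bonded one.  Atom types follow the 85-type (base, name) scheme;
# untyped atoms (OP3, modified-base extras) are skipped.  These
# distributions are the raw material of distance-dependent statistical
# potentials.

#' Non-bonded inter-residue atom-pair distances
#'
#' @param x an [RNAStructure-class].
#' @param selection \code{"ALL"} (default) for every typed heavy-atom pair,
#'   or a character vector of length 2 selecting the two atom classes to
#'   pair: plain atom names (e.g. \code{c("P", "P")}, pooled over bases) or
#'   full types (e.g. \code{c("G.N2", "C.O2")}).
#' @return data.frame with columns \code{type_a}, \code{type_b} (unordered,
#'   \code{type_a <= type_b}), \code{res_i}, \code{res_j}, \code{distance}
#'   (Angstrom).  Symmetric pairs are emitted once.
#' @examples
#' fx <- makeDuplex("GGC")
#' pp <- pairwiseDistances(fx$structure, c("P", "P"))
#' range(pp$distance)
#' @export
pairwiseDistances <- function(x, selection = "ALL") {
  a <- atomTable(x)
  a$type <- atomTypeOf(a$base, a$name)
  a <- a[!is.na(a$type), , drop = FALSE]
  tab <- atomTypeTable()
  validNames <- unique(tab$name)
  validTypes <- paste(tab$base, tab$name, sep = ".")
  if (!identical(selection, "ALL")) {
    if (length(selection) != 2L)
      stop("selection must be 'ALL' or two atom names/types")
    selIdx <- lapply(selection, function(s) {
      if (grepl("\\.", s)) {
        if (!s %in% validTypes)
          stop("unknown atom type '", s, "'; valid types are ",
               paste(utils::head(validTypes, 8), collapse = ", "),
               ", ... (85)")
        which(a$type == s)
      } else {
        if (!s %in% validNames)
          stop("unknown atom name '", s, "'; valid names are ",
               paste(validNames, collapse = ", "))
        which(a$name == s)
      }
    })
  } else {
    selIdx <- list(seq_len(nrow(a)), seq_len(nrow(a)))
  }
  i1 <- selIdx[[1]]; i2 <- selIdx[[2]]
  if (!length(i1) || !length(i2)) return(.emptyDistances())

  xyz <- as.matrix(a[, c("x", "y", "z")])
  # all (p, q) with p in i1, q in i2, different residues, counted once
  g <- expand.grid(p = i1, q = i2)
  g <- g[a$residx[g$p] != a$residx[g$q], , drop = FALSE]
  # unordered uniqueness by atom row index
  key <- paste(pmin(g$p, g$q), pmax(g$p, g$q))
  g <- g[!duplicated(key), , drop = FALSE]
  if (!nrow(g)) return(.emptyDistances())
  # drop bonded O3'(i)-P(i+1) across covalent chain links
  links <- which(chainLinks(x))
  if (length(links)) {
    bonded <- (a$name[g$p] == "O3'" & a$name[g$q] == "P" &
                 a$residx[g$q] == a$residx[g$p] + 1L &
                 a$residx[g$p] %in% links) |
              (a$name[g$q] == "O3'" & a$name[g$p] == "P" &
                 a$residx[g$p] == a$residx[g$q] + 1L &
                 a$residx[g$q] %in% links)
    g <- g[!bonded, , drop = FALSE]
  }
  d <- sqrt(rowSums((xyz[g$p, , drop = FALSE] -
                     xyz[g$q, , drop = FALSE])^2))
  ta <- a$type[g$p]; tb <- a$type[g$q]
  out <- data.frame(type_a = pmin(ta, tb), type_b = pmax(ta, tb),
                    res_i = pmin(a$residx[g$p], a$residx[g$q]),
                    res_j = pmax(a$residx[g$p], a$residx[g$q]),
                    distance = d, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$res_i, out$res_j, out$type_a, out$type_b), ]
}

.emptyDistances <- function() {
  data.frame(type_a = character(), type_b = character(),
             res_i = integer(), res_j = integer(), distance = numeric(),
             stringsAsFactors = FALSE)
}

#' Bin a distance stream into per-type-pair histograms
#'
#' Half-open bins [lo, hi) of width \code{binWidth} over [0, dMax);
#' distances >= dMax are dropped and the dropped count recorded in the
#' \code{"dropped"} attribute.  Bin counts conserve the (kept) stream
#' length per type pair.
#'
#' @param distances data.frame from [pairwiseDistances()].
#' @param binWidth bin width in Angstrom (> 0); default 0.1.
#' @param dMax histogram range upper end, Angstrom; default 100.
#' @return data.frame \code{type_a, type_b, bin_lo, bin_hi, count} (only
#'   occupied bins), with attributes \code{binWidth}, \code{dMax},
#'   \code{dropped}.
#' @export
distanceHistogram <- function(distances, binWidth = 0.1, dMax = 100) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  keep <- distances$distance < dMax
  dropped <- sum(!keep)
  dd <- distances[keep, , drop = FALSE]
  if (nrow(dd)) {
    bin <- floor(dd$distance / binWidth)
    key <- paste(dd$type_a, dd$type_b, bin, sep = "\r")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    out <- data.frame(type_a = parts[, 1], type_b = parts[, 2],
                      bin_lo = as.numeric(parts[, 3]) * binWidth,
                      bin_hi = (as.numeric(parts[, 3]) + 1) * binWidth,
                      count = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(out$type_a, out$type_b, out$bin_lo), ]
    rownames(out) <- NULL
  } else {
    out <- data.frame(type_a = character(), type_b = character(),
                      bin_lo = numeric(), bin_hi = numeric(),
                      count = integer(), stringsAsFactors = FALSE)
  }
  attr(out, "binWidth") <- binWidth
  attr(out, "dMax") <- dMax
  attr(out, "dropped") <- dropped
  out
}

#' Pool a per-type-pair histogram over all type pairs
#'
#' @param hist data.frame from [distanceHistogram()].
#' @return data.frame \code{bin_lo, bin_hi, count}.
#' @export
pooledHistogram <- function(hist) {
  if (!nrow(hist))
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer()))
  agg <- stats::aggregate(count ~ bin_lo + bin_hi, data = hist, FUN = sum)
  agg <- agg[order(agg$bin_lo), ]
  rownames(agg) <- NULL
  agg
}

#' Named phosphate-phosphate distance extracts
#'
#' Convenience extracts behind the P-P distance peaks: distances between P
#' atoms of nearest-neighbour nucleotides (covalently linked), of
#' second-nearest neighbours, and of paired nucleotides.
#'
#' @param x an [RNAStructure-class].
#' @param pairs optional pair data.frame (e.g. from [detectBasePairs()])
#'   for the paired-nucleotide extract.
#' @return list of numeric vectors \code{nearest}, \code{second},
#'   \code{paired} (Angstrom).
#' @export
ppDistanceExtracts <- function(x, pairs = NULL) {
  a <- atomTable(x)
  p <- a[a$name == "P", ]
  pOf <- function(res) {
    k <- match(res, p$residx)
    cbind(p$x[k], p$y[k], p$z[k])
  }
  links <- chainLinks(x)
  dvec <- function(ri, rj) {
    m1 <- pOf(ri); m2 <- pOf(rj)
    d <- sqrt(rowSums((m1 - m2)^2))
    d[!is.na(d)]
  }
  nearest <- if (any(links)) dvec(which(links), which(links) + 1L)
             else numeric(0)
  second <- if (length(links) > 1L) {
    i2 <- which(links[-length(links)] & links[-1])
    if (length(i2)) dvec(i2, i2 + 2L) else numeric(0)
  } else numeric(0)
  paired <- if (!is.null(pairs) && nrow(pairs))
    dvec(pairs$i, pairs$j) else numeric(0)
  list(nearest = nearest, second = second, paired = paired)
}
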