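# Secondary-structure motif decomposition.
#
# Input is a list of canonical pairs (one partner per residue).  A maximum-
# cardinality crossing-free subset is selected by exact dynamic programming;
# the removed pairs are the pseudoknot set.  The nested set is then split
# into stems (maximal runs of consecutively stacked pairs (i,j),(i+1,j-1))
# and loops classified by the number of bordering stems.  Stems are defined
# by canonical pairs only; non-canonical pairs enter pair statistics but not
# the decomposition.

#' Split a canonical pair list into a nested set and pseudoknot pairs
#'
#' Finds a maximum-cardinality crossing-free subset of the pairs by exact
#' interval dynamic programming (ties broken deterministically in favour of
#' the pair opening earliest).  Two pairs (i,j), (k,l) with i<k cross when
#' i < k < j < l.
#'
#' @param pairs data.frame or matrix with columns \code{i}, \code{j}
#'   (residue indices, i < j); every residue may appear in at most one pair
#'   (pre-filter multiplets first, see [filterMultiplets()]).
#' @return list with elements \code{nested} and \code{removed}, both
#'   two-column integer matrices (i, j); their union is the input.
#' @examples
#' resolvePseudoknots(cbind(i = c(1, 2, 5, 6), j = c(10, 9, 14, 13)))
#' @export
resolvePseudoknots <- function(pairs) {
  p <- .asPairMatrix(pairs)
  m <- nrow(p)
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (m == 0L) return(list(nested = empty, removed = empty))
  if (any(p[, 1] >= p[, 2])) stop("pairs must satisfy i < j")
  if (anyDuplicated(c(p)))
    stop("a residue takes part in more than one canonical pair; ",
         "filter multiplets first")
  ep <- sort(unique(c(p)))
  n <- length(ep)
  li <- match(p[, 1], ep); lj <- match(p[, 2], ep)
  partner <- rep(NA_integer_, n)
  partner[li] <- lj            # position of the right endpoint, if left
  # M[l, r]: max nested pairs using endpoints in positions l..r
  M <- matrix(0L, n + 1L, n + 1L)
  for (l in n:1) {
    for (r in l:n) {
      best <- M[l + 1L, r]
      pj <- partner[l]
      if (!is.na(pj) && pj <= r) {
        inner <- if (pj - 1L >= l + 1L) M[l + 1L, pj - 1L] else 0L
        outer <- if (pj + 1L <= r) M[pj + 1L, r] else 0L
        cand <- 1L + inner + outer
        if (cand >= best) best <- cand
      }
      M[l, r] <- best
    }
  }
  keep <- logical(m)
  stack <- list(c(1L, n))
  while (length(stack)) {
    lr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    l <- lr[1]; r <- lr[2]
    while (l <= r) {
      pj <- partner[l]
      took <- FALSE
      if (!is.na(pj) && pj <= r) {
        inner <- if (pj - 1L >= l + 1L) M[l + 1L, pj - 1L] else 0L
        outer <- if (pj + 1L <= r) M[pj + 1L, r] else 0L
        if (1L + inner + outer >= M[l + 1L, r]) {
          keep[which(li == l)] <- TRUE
          if (pj - 1L >= l + 1L) stack[[length(stack) + 1L]] <-
              c(l + 1L, pj - 1L)
          l <- pj + 1L
          took <- TRUE
        }
      }
      if (!took) l <- l + 1L
    }
  }
  list(nested = p[keep, , drop = FALSE], removed = p[!keep, , drop = FALSE])
}

.asPairMatrix <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, c("i", "j")])
  if (!is.matrix(pairs)) stop("pairs must be a matrix or data.frame")
  if (nrow(pairs) == 0L)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  p <- cbind(i = as.integer(pmin(pairs[, 1], pairs[, 2])),
             j = as.integer(pmax(pairs[, 1], pairs[, 2])))
  p[order(p[, 1]), , drop = FALSE]
}

#' Reduce base-pair multiplets to one canonical partner per residue
#'
#' Residues taking part in several canonical pairs (triplets etc.) keep only
#' their best-supported pair; pairs are ranked by hydrogen-bond contact
#' count (then by index order for determinism) and accepted greedily.
#'
#' @param pairs data.frame with columns i, j and optionally \code{n_hbonds}.
#' @return the filtered data.frame.
#' @export
filterMultiplets <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  nh <- if ("n_hbonds" %in% names(pairs)) pairs$n_hbonds else rep(0, nrow(pairs))
  ord <- order(-nh, pairs$i, pairs$j)
  used <- integer(0)
  keep <- logical(nrow(pairs))
  for (k in ord) {
    if (!(pairs$i[k] %in% used) && !(pairs$j[k] %in% used)) {
      keep[k] <- TRUE
      used <- c(used, pairs$i[k], pairs$j[k])
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Decompose a crossing-free pair set into stems and loops
#'
#' @param L chain/structure length in nucleotides.
#' @param nested crossing-free pair matrix/data.frame (i, j).
#' @param pseudoknot optional pair matrix of pseudoknotted pairs (shown in
#'   extra bracket tiers of the dot-bracket string, otherwise ignored).
#' @return a [SecondaryStructure-class]: stems (runs of >= 2 pairs), lone
#'   pairs, loops (hairpin / bulge / internal / junction with total unpaired
#'   length), and the dot-bracket string.  Exterior (dangling) residues
#'   belong to no loop.
#' @examples
#' ss <- decomposeSecondaryStructure(12, cbind(i = 1:3, j = 12:10))
#' ss@loops      # one hairpin of length 6
#' @export
decomposeSecondaryStructure <- function(L, nested, pseudoknot = NULL) {
  L <- as.integer(L)
  p <- .asPairMatrix(nested)
  if (any(p > L)) stop("pair index exceeds structure length")
  partner <- rep(NA_integer_, L)
  partner[p[, 1]] <- p[, 2]
  partner[p[, 2]] <- p[, 1]
  # crossing check
  if (nrow(p) > 1L) {
    for (a in seq_len(nrow(p) - 1L)) {
      b <- (a + 1L):nrow(p)
      if (any(p[a, 1] < p[b, 1] & p[b, 1] < p[a, 2] & p[a, 2] < p[b, 2]))
        stop("nested pair set contains crossing pairs")
    }
  }
  # helix units: maximal runs of consecutively stacked pairs
  units <- list()
  seen <- logical(L)
  for (i in seq_len(L)) {
    j <- partner[i]
    if (is.na(j) || j < i || seen[i]) next
    run <- cbind(i = i, j = j)
    while (run[nrow(run), 1] + 1L < run[nrow(run), 2] - 1L &&
           !is.na(partner[run[nrow(run), 1] + 1L]) &&
           partner[run[nrow(run), 1] + 1L] == run[nrow(run), 2] - 1L) {
      run <- rbind(run, c(run[nrow(run), 1] + 1L, run[nrow(run), 2] - 1L))
    }
    seen[run[, 1]] <- TRUE
    units[[length(units) + 1L]] <- run
  }
  stems <- Filter(function(u) nrow(u) >= 2L, units)
  lone <- do.call(rbind, lapply(Filter(function(u) nrow(u) == 1L, units),
                                identity))
  if (is.null(lone))
    lone <- matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j")))

  # loops: walk the interior of each unit's innermost pair
  loops <- list()
  outerOf <- vapply(units, function(u) u[1, 1], integer(1))
  for (u in units) {
    ci <- u[nrow(u), 1]; cj <- u[nrow(u), 2]   # innermost closing pair
    k <- ci + 1L
    unpaired <- integer(0)
    branches <- 0L
    sides <- integer(0)   # unpaired run lengths between branches
    runLen <- 0L
    while (k < cj) {
      q <- partner[k]
      if (is.na(q)) {
        unpaired <- c(unpaired, unname(k)); runLen <- runLen + 1L
        k <- k + 1L
      } else {
        branches <- branches + 1L
        sides <- c(sides, runLen); runLen <- 0L
        k <- unname(q) + 1L
      }
    }
    sides <- c(sides, runLen)
    kind <- if (branches == 0L) "hairpin"
            else if (branches == 1L) {
              if (min(sides) == 0L) "bulge" else "internal"
            } else "junction"
    loops[[length(loops) + 1L]] <-
      data.frame(kind = kind, length = length(unpaired),
                 branches = branches + 1L,
                 positions = I(list(unpaired)), stringsAsFactors = FALSE)
  }
  loops <- if (length(loops)) do.call(rbind, loops)
           else data.frame(kind = character(), length = integer(),
                           branches = integer(),
                           positions = I(list()))
  # drop degenerate "loops" of length 0 that are pure coaxial junctions?
  # no: junction/bulge loops of length 0 are real topological features, but
  # hairpins cannot have length 0 (steric); keep everything as computed.
  pk <- .asPairMatrix(if (is.null(pseudoknot)) matrix(integer(), 0, 2)
                      else pseudoknot)
  new("SecondaryStructure", length = L, stems = stems, lonePairs = lone,
      loops = loops, pseudoknotPairs = pk,
      dotbracket = .dotBracket(L, p, pk))
}

.dotBracket <- function(L, nested, pk) {
  s <- rep(".", L)
  s[nested[, 1]] <- "("; s[nested[, 2]] <- ")"
  if (nrow(pk)) {
    tiers <- list(c("[", "]"), c("{", "}"), c("<", ">"))
    assigned <- rep(NA_integer_, nrow(pk))
    for (t in seq_along(tiers)) {
      occ <- matrix(integer(), 0, 2)
      for (k in seq_len(nrow(pk))) {
        if (!is.na(assigned[k])) next
        crosses <- FALSE
        if (nrow(occ)) {
          a <- pk[k, ]
          crosses <- any((occ[, 1] < a[1] & a[1] < occ[, 2] & occ[, 2] < a[2]) |
                         (a[1] < occ[, 1] & occ[, 1] < a[2] & a[2] < occ[, 2]))
        }
        if (!crosses) {
          assigned[k] <- t
          occ <- rbind(occ, pk[k, ])
          s[pk[k, 1]] <- tiers[[t]][1]
          s[pk[k, 2]] <- tiers[[t]][2]
        }
      }
      if (!any(is.na(assigned))) break
    }
  }
  paste(s, collapse = "")
}

#' Motif length histograms and frequency tables over a structure set
#'
#' Aggregates decompositions and pair/stack annotations of one or more
#' structures into per-motif length histograms and normalised frequency
#' tables.  Lone pairs (stems of a single pair) are excluded from the stem
#' length histogram by default, mirroring annotation-tool conventions.
#'
#' @param annotations list of per-structure annotation lists as returned by
#'   [annotateStructure()].
#' @param includeLonePairs count lone pairs as stems of length 1 in the stem
#'   histogram (default FALSE).
#' @return list with integer histograms \code{stem}, \code{hairpin},
#'   \code{bulge}, \code{internal}, \code{junction} (names are lengths) and
#'   frequency tables \code{nucleotide}, \code{pair}, \code{stack}, each
#'   summing to 1 (empty when no events).
#' @export
motifHistograms <- function(annotations, includeLonePairs = FALSE) {
  if (!length(annotations)) stop("need at least one structure")
  if (!is.null(annotations$secstruct)) annotations <- list(annotations)
  stemLens <- integer(0); loopTab <- list()
  ntAll <- character(0); pairLab <- character(0); stackLab <- character(0)
  loopLens <- list(hairpin = integer(0), bulge = integer(0),
                   internal = integer(0), junction = integer(0))
  for (ann in annotations) {
    for (ss in ann$secstruct) {
      stemLens <- c(stemLens, vapply(ss@stems, nrow, integer(1)))
      if (includeLonePairs && nrow(ss@lonePairs))
        stemLens <- c(stemLens, rep(1L, nrow(ss@lonePairs)))
      if (nrow(ss@loops))
        for (kind in names(loopLens)) {
          sel <- ss@loops$kind == kind
          loopLens[[kind]] <- c(loopLens[[kind]], ss@loops$length[sel])
        }
    }
    ntAll <- c(ntAll, ann$bases)
    if (!is.null(ann$pairs) && nrow(ann$pairs))
      pairLab <- c(pairLab, .pairLabel(ann$pairs$base_i, ann$pairs$base_j))
    if (!is.null(ann$stacks) && nrow(ann$stacks))
      stackLab <- c(stackLab, .pairLabel(ann$stacks$base_i,
                                         ann$stacks$base_j))
  }
  hist1 <- function(v) {
    if (!length(v)) return(integer(0))
    tab <- table(v)
    out <- as.integer(tab); names(out) <- names(tab)
    out
  }
  freq <- function(v) {
    if (!length(v)) return(numeric(0))
    tab <- table(v)
    out <- as.numeric(tab) / sum(tab); names(out) <- names(tab)
    out
  }
  list(stem = hist1(stemLens), hairpin = hist1(loopLens$hairpin),
       bulge = hist1(loopLens$bulge), internal = hist1(loopLens$internal),
       junction = hist1(loopLens$junction),
       nucleotide = freq(ntAll), pair = freq(pairLab),
       stack = freq(stackLab))
}

.pairLabel <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}
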