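# Base-pair and base-stack annotation.
#
# Two sources are supported: a built-in geometric detector (hydrogen-bond
# heavy-atom contacts + base-plane coplanarity + small out-of-plane offset)
# and ingestion of DSSR JSON annotation.  The built-in thresholds are
# standard structural-biology heuristics, deliberately simple and fully
# configurable; they are not a re-implementation of DSSR.  Full
# Leontis-Westhof cis/trans labels are available only from DSSR ingestion;
# the detector classifies edges from the cylindrical angle sectors only.

#' Detection thresholds for the geometric pair/stack detector
#'
#' @param hbDist maximum donor-acceptor heavy-atom distance counted as a
#'   hydrogen-bond contact, Angstrom.
#' @param hbMin minimum number of such contacts between the two base
#'   moieties.
#' @param planeMax maximum inter-base-plane angle (between Z axes, folded to
#'   <= 90 deg), degrees, for pairing.
#' @param zPairMax maximum |z| offset of either base in the partner's
#'   frame, Angstrom, for pairing.
#' @param zStackMin,zStackMax |z| band for stacking, Angstrom.
#' @param rhoStackMax maximum in-plane offset for stacking, Angstrom.
#' @param stackPlaneMax maximum inter-plane angle for stacking, degrees.
#' @param sectorBoundaries passed to [edgeSectorOf()].
#' @return named list of thresholds.
#' @export
pairDetectionParams <- function(hbDist = 3.4, hbMin = 2, planeMax = 65,
                                zPairMax = 2.5, zStackMin = 2.5,
                                zStackMax = 4.5, rhoStackMax = 5.0,
                                stackPlaneMax = 30,
                                sectorBoundaries = c(60, 180, 300)) {
  p <- list(hbDist = hbDist, hbMin = hbMin, planeMax = planeMax,
            zPairMax = zPairMax, zStackMin = zStackMin,
            zStackMax = zStackMax, rhoStackMax = rhoStackMax,
            stackPlaneMax = stackPlaneMax,
            sectorBoundaries = sectorBoundaries)
  num <- vapply(p[1:8], is.numeric, logical(1))
  if (!all(num) || any(unlist(p[1:8]) <= 0))
    stop("all detection thresholds must be positive numbers")
  p
}

.canonicalBaseSet <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b))
  key %in% c("C G", "A U", "G U")
}

# per-residue base-moiety atom coordinates + polar subsets + frames
.baseContext <- function(x) {
  a <- atomTable(x)
  L <- structureLength(x)
  frames <- baseFrames(x)
  polar <- vector("list", L)
  centroid <- matrix(NA_real_, L, 3)
  bases <- character(L)
  chains <- character(L)
  for (i in seq_len(L)) {
    res <- a[a$residx == i, , drop = FALSE]
    bases[i] <- res$base[1]
    chains[i] <- res$chain[1]
    pol <- res[res$name %in% .POLAR_BASE_ATOMS[[bases[i]]], , drop = FALSE]
    polar[[i]] <- as.matrix(pol[, c("x", "y", "z")])
    if (!is.null(frames[[i]])) centroid[i, ] <- frames[[i]]$origin
  }
  list(frames = frames, polar = polar, centroid = centroid,
       bases = bases, chains = chains, L = L)
}

.planeAngle <- function(zi, zj) {
  c <- abs(sum(zi * zj))
  acos(min(1, c)) * 180 / pi
}

.emptyPairs <- function() {
  data.frame(i = integer(), j = integer(), base_i = character(),
             base_j = character(), rho = numeric(), theta = numeric(),
             z = numeric(), sector_i = character(), sector_j = character(),
             n_hbonds = integer(), plane_angle = numeric(),
             canonical = logical(), lw_label = character(),
             source = character(), stringsAsFactors = FALSE)
}

#' Detect base pairs geometrically
#'
#' A pair (i, j) is accepted when (1) at least \code{hbMin} polar heavy-atom
#' contacts shorter than \code{hbDist} link the two base moieties, (2) the
#' base planes are within \code{planeMax} degrees of each other, and (3) the
#' out-of-plane offset |z| is below \code{zPairMax} in both partners'
#' frames.  Interacting edges are classified from the cylindrical angle of
#' the partner in each base's frame; a pair is canonical iff its bases are
#' C-G, A-U or G-U and both edges are Watson-Crick.  A residue may appear
#' in several pairs (multiplets are allowed).
#'
#' @param x an [RNAStructure-class].
#' @param params thresholds from [pairDetectionParams()].
#' @return data.frame with one row per pair (i < j): indices, bases,
#'   cylindrical geometry of j in i's frame (rho, theta, z), the two edge
#'   sectors, contact count, inter-plane angle, canonical flag, empty
#'   \code{lw_label} and \code{source = "builtin"}.
#' @examples
#' fx <- makeDuplex("GGCAGC")
#' detectBasePairs(fx$structure)[, c("i", "j", "canonical")]
#' @export
detectBasePairs <- function(x, params = pairDetectionParams()) {
  ctx <- .baseContext(x)
  out <- .emptyPairs()
  if (ctx$L < 2L) return(out)
  cand <- .candidatePairs(ctx, cutoff = 12)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    fi <- ctx$frames[[i]]; fj <- ctx$frames[[j]]
    if (is.null(fi) || is.null(fj)) next
    pi_ <- ctx$polar[[i]]; pj_ <- ctx$polar[[j]]
    if (!nrow(pi_) || !nrow(pj_)) next
    d2 <- outer(rowSums(pi_^2), rowSums(pj_^2), "+") - 2 * pi_ %*% t(pj_)
    nhb <- sum(d2 < params$hbDist^2)
    if (nhb < params$hbMin) next
    ang <- .planeAngle(fi$Z, fj$Z)
    if (ang >= params$planeMax) next
    cij <- relativeCylindrical(fi, fj)
    cji <- relativeCylindrical(fj, fi)
    if (abs(cij["z"]) >= params$zPairMax ||
        abs(cji["z"]) >= params$zPairMax) next
    si <- edgeSectorOf(cij["theta"], params$sectorBoundaries)
    sj <- edgeSectorOf(cji["theta"], params$sectorBoundaries)
    out[nrow(out) + 1L, ] <-
      list(i, j, ctx$bases[i], ctx$bases[j],
           unname(cij["rho"]), unname(cij["theta"]), unname(cij["z"]),
           si, sj, nhb, ang,
           .canonicalBaseSet(ctx$bases[i], ctx$bases[j]) &&
             si == "WC" && sj == "WC",
           NA_character_, "builtin")
  }
  rownames(out) <- NULL
  out
}

.candidatePairs <- function(ctx, cutoff = 12) {
  ok <- which(!is.na(ctx$centroid[, 1]))
  if (length(ok) < 2L) return(matrix(integer(), 0, 2))
  cm <- ctx$centroid[ok, , drop = FALSE]
  d <- as.matrix(stats::dist(cm))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  cbind(ok[idx[, 1]], ok[idx[, 2]])
}

#' Detect base stacking geometrically
#'
#' Two bases stack when the partner sits in the |z| band
#' [\code{zStackMin}, \code{zStackMax}] of both frames, the in-plane offset
#' rho is at most \code{rhoStackMax}, and the base planes are within
#' \code{stackPlaneMax} degrees.  Sequence-adjacent and non-adjacent stacks
#' are both reported and flagged.
#'
#' @inheritParams detectBasePairs
#' @return data.frame: i, j, bases, cylindrical geometry of j in i's frame,
#'   \code{adjacent} (same chain, consecutive residues), \code{source}.
#' @export
detectStacking <- function(x, params = pairDetectionParams()) {
  ctx <- .baseContext(x)
  out <- data.frame(i = integer(), j = integer(), base_i = character(),
                    base_j = character(), rho = numeric(),
                    theta = numeric(), z = numeric(), adjacent = logical(),
                    source = character(), stringsAsFactors = FALSE)
  if (ctx$L < 2L) return(out)
  cand <- .candidatePairs(ctx, cutoff = 8)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    fi <- ctx$frames[[i]]; fj <- ctx$frames[[j]]
    if (is.null(fi) || is.null(fj)) next
    if (.planeAngle(fi$Z, fj$Z) > params$stackPlaneMax) next
    cij <- relativeCylindrical(fi, fj)
    cji <- relativeCylindrical(fj, fi)
    if (abs(cij["z"]) < params$zStackMin ||
        abs(cij["z"]) > params$zStackMax) next
    if (abs(cji["z"]) < params$zStackMin ||
        abs(cji["z"]) > params$zStackMax) next
    if (cij["rho"] > params$rhoStackMax) next
    out[nrow(out) + 1L, ] <-
      list(i, j, ctx$bases[i], ctx$bases[j],
           unname(cij["rho"]), unname(cij["theta"]), unname(cij["z"]),
           j == i + 1L && ctx$chains[i] == ctx$chains[j], "builtin")
  }
  rownames(out) <- NULL
  out
}

# --- DSSR JSON ingestion --------------------------------------------------

.parseDssrNt <- function(nt) {
  # "A.G12" or "A.G12^B" or "1:A.G12"; returns chain, base, resno
  m <- regmatches(nt, regexec("([^.:]+)\\.([A-Za-z0-9]+?)(-?[0-9]+)\\^?",
                              nt))[[1]]
  if (length(m) < 4) stop("cannot parse DSSR nucleotide id: ", nt)
  list(chain = m[2], base = toupper(m[3]), resno = as.integer(m[4]))
}

#' Read a DSSR JSON annotation file
#'
#' Ingests the documented \code{pairs}, \code{stems}, \code{hairpins},
#' \code{bulges}, \code{iloops} and \code{junctions} blocks of DSSR JSON
#' output (absent blocks are tolerated), mapping nucleotide identifiers
#' onto the internal residue indexing of \code{structure} when one is
#' given.  The Leontis-Westhof label of each pair is preserved verbatim in
#' \code{lw_label}; the canonical flag is recomputed by the package's rule
#' (bases C-G/A-U/G-U on Watson-Crick/Watson-Crick edges, i.e. a WW label).
#'
#' @param path path to a DSSR JSON file.
#' @param structure optional [RNAStructure-class] used to translate
#'   chain/author numbering into internal indices.
#' @return list with \code{pairs} (data.frame as in [detectBasePairs()],
#'   \code{source = "dssr"}), \code{stems} (list of pair matrices) and
#'   \code{loops} (data.frame kind/length as reported).
#' @export
readDSSRAnnotation <- function(path, structure = NULL) {
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("malformed DSSR JSON in ", path,
                                          ": ", conditionMessage(e)))
  if (!is.list(js) || !("pairs" %in% names(js)))
    stop("DSSR ingestion error: missing 'pairs' section in ", path)
  resolve <- function(pnt) {
    if (is.null(structure)) return(NA_integer_)
    rt <- residueTable(structure)
    k <- which(rt$chain == pnt$chain & rt$resno == pnt$resno &
               rt$base == pnt$base)
    if (!length(k))
      k <- which(rt$chain == pnt$chain & rt$resno == pnt$resno)
    if (!length(k)) NA_integer_ else rt$residx[k[1]]
  }
  pairs <- .emptyPairs()
  for (p in js$pairs) {
    n1 <- .parseDssrNt(p$nt1); n2 <- .parseDssrNt(p$nt2)
    i1 <- resolve(n1); i2 <- resolve(n2)
    if (!is.na(i1) && !is.na(i2) && i1 > i2) {
      tmp <- n1; n1 <- n2; n2 <- tmp
      tmp <- i1; i1 <- i2; i2 <- tmp
    }
    lw <- if (!is.null(p$LW)) p$LW else NA_character_
    canon <- .canonicalBaseSet(n1$base, n2$base) &&
      !is.na(lw) && grepl("WW", lw, ignore.case = TRUE)
    pairs[nrow(pairs) + 1L, ] <-
      list(i1, i2, n1$base, n2$base, NA_real_, NA_real_, NA_real_,
           NA_character_, NA_character_, NA_integer_, NA_real_,
           canon, lw, "dssr")
  }
  stems <- lapply(js$stems, function(st) {
    do.call(rbind, lapply(st$pairs, function(p) {
      n1 <- .parseDssrNt(p$nt1); n2 <- .parseDssrNt(p$nt2)
      c(i = resolve(n1), j = resolve(n2))
    }))
  })
  loopRows <- list()
  blockKinds <- c(hairpins = "hairpin", bulges = "bulge",
                  iloops = "internal", junctions = "junction")
  for (blk in names(blockKinds)) {
    for (lp in js[[blk]]) {
      len <- if (!is.null(lp$num_nts)) lp$num_nts else NA_integer_
      loopRows[[length(loopRows) + 1L]] <-
        data.frame(kind = blockKinds[[blk]], length = len,
                   stringsAsFactors = FALSE)
    }
  }
  loops <- if (length(loopRows)) do.call(rbind, loopRows)
           else data.frame(kind = character(), length = integer())
  rownames(loops) <- NULL
  list(pairs = pairs, stems = stems, loops = loops)
}

#' Export pair/stack annotation as DSSR-dialect JSON
#'
#' Writes the package's pair list in the DSSR JSON dialect so that
#' annotations can be re-ingested with [readDSSRAnnotation()] (round-trip
#' identity on indices, bases, LW labels and canonical flags).
#'
#' @param pairs pair data.frame (see [detectBasePairs()]).
#' @param structure the [RNAStructure-class] the indices refer to.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationJSON <- function(pairs, structure, path) {
  rt <- residueTable(structure)
  ntid <- function(k) {
    r <- rt[rt$residx == k, ]
    sprintf("%s.%s%d", r$chain, r$base, r$resno)
  }
  plist <- lapply(seq_len(nrow(pairs)), function(r) {
    lw <- pairs$lw_label[r]
    if (is.na(lw))
      lw <- if (isTRUE(pairs$sector_i[r] == "WC" &&
                       pairs$sector_j[r] == "WC")) "cWW" else "c--"
    list(nt1 = ntid(pairs$i[r]), nt2 = ntid(pairs$j[r]), LW = lw,
         name = if (isTRUE(pairs$canonical[r])) "WC" else "other")
  })
  jsonlite::write_json(list(pairs = plist), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
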