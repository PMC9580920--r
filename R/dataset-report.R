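# Dataset-level aggregation and curve fitting.
#
# Size follows a Flory-type scaling law Rg = a * L^b, fitted by unweighted
# least squares in log-log space; base-pair counts grow linearly with
# length and are fitted through the origin.  Pair-geometry classes are
# summarised by per-coordinate Gaussians, with circular statistics for the
# angle.

#' Fit a power law Rg = a * L^b
#'
#' Unweighted least squares of log(Rg) on log(L).
#'
#' @param L sequence lengths (> 0).
#' @param rg radii of gyration (> 0), same length as \code{L}.
#' @return named numeric \code{c(a, b)}.
#' @examples
#' L <- c(20, 50, 100, 200, 500)
#' fitPowerLaw(L, 6.7 * L^0.31)   # recovers a = 6.7, b = 0.31
#' @export
fitPowerLaw <- function(L, rg) {
  if (length(L) != length(rg)) stop("L and rg must have equal length")
  if (any(L <= 0) || any(rg <= 0))
    stop("power-law fit requires positive lengths and radii")
  if (length(unique(L)) < 2L)
    stop("need at least 2 distinct lengths")
  fit <- stats::lm(log(rg) ~ log(L))
  co <- stats::coef(fit)
  c(a = unname(exp(co[1])), b = unname(co[2]))
}

#' Fit a line through the origin, count = k * L
#'
#' Least-squares slope minimising sum (count - k L)^2.
#'
#' @param L sequence lengths (> 0).
#' @param count base-pair counts.
#' @return slope k.
#' @examples
#' fitLinearThroughOrigin(c(50, 100), 0.48 * c(50, 100))   # 0.48
#' @export
fitLinearThroughOrigin <- function(L, count) {
  if (length(L) != length(count)) stop("L and count must have equal length")
  if (!length(L)) stop("need at least one point")
  if (any(L <= 0)) stop("lengths must be positive")
  sum(L * count) / sum(L^2)
}

.circularStats <- function(thetaDeg) {
  th <- thetaDeg * pi / 180
  s <- mean(sin(th)); c <- mean(cos(th))
  R <- sqrt(s^2 + c^2)
  mu <- (atan2(s, c) * 180 / pi) %% 360
  if (mu >= 360 - 1e-9) mu <- 0
  sd <- if (R >= 1 - 1e-15) 0 else sqrt(-2 * log(R)) * 180 / pi
  c(mean = mu, sd = sd)
}

#' Per-class Gaussian fits of base-pair geometry
#'
#' Groups geometry records by class (the DSSR Leontis-Westhof label when
#' available, otherwise the base combination plus edge/edge sectors) and
#' reports mean and standard deviation of rho and z, and circular mean and
#' circular standard deviation of theta.  Classes with fewer than
#' \code{minN} records are reported unfitted (NA) with their count.
#'
#' @param geometry data.frame with columns \code{class}, \code{rho},
#'   \code{theta} (degrees), \code{z}; see [pairGeometryRecords()].
#' @param minN minimum records per class to fit (default 2).
#' @return data.frame: class, n, rho_mean, rho_sd, theta_mean, theta_sd,
#'   z_mean, z_sd.
#' @export
fitPairGaussians <- function(geometry, minN = 2L) {
  if (!nrow(geometry))
    return(data.frame(class = character(), n = integer(),
                      rho_mean = numeric(), rho_sd = numeric(),
                      theta_mean = numeric(), theta_sd = numeric(),
                      z_mean = numeric(), z_sd = numeric()))
  cls <- sort(unique(geometry$class))
  rows <- lapply(cls, function(cl) {
    g <- geometry[geometry$class == cl, , drop = FALSE]
    n <- nrow(g)
    if (n < minN)
      return(data.frame(class = cl, n = n, rho_mean = NA_real_,
                        rho_sd = NA_real_, theta_mean = NA_real_,
                        theta_sd = NA_real_, z_mean = NA_real_,
                        z_sd = NA_real_))
    circ <- .circularStats(g$theta)
    sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    data.frame(class = cl, n = n,
               rho_mean = mean(g$rho), rho_sd = sd0(g$rho),
               theta_mean = unname(circ["mean"]),
               theta_sd = unname(circ["sd"]),
               z_mean = mean(g$z), z_sd = sd0(g$z))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Geometry records of a pair list, keyed by class
#'
#' @param pairs pair data.frame from [detectBasePairs()] or DSSR ingestion
#'   (must carry rho/theta/z; DSSR pairs without geometry are recomputed
#'   from \code{structure} when given).
#' @param structure optional [RNAStructure-class] to (re)compute geometry.
#' @return data.frame class, base_i, base_j, rho, theta, z.
#' @export
pairGeometryRecords <- function(pairs, structure = NULL) {
  if (!nrow(pairs))
    return(data.frame(class = character(), base_i = character(),
                      base_j = character(), rho = numeric(),
                      theta = numeric(), z = numeric()))
  p <- pairs
  if (!is.null(structure) && any(is.na(p$rho))) {
    frames <- baseFrames(structure)
    for (r in which(is.na(p$rho))) {
      fi <- frames[[p$i[r]]]; fj <- frames[[p$j[r]]]
      if (is.null(fi) || is.null(fj)) next
      cyl <- relativeCylindrical(fi, fj)
      p$rho[r] <- cyl["rho"]; p$theta[r] <- cyl["theta"]
      p$z[r] <- cyl["z"]
    }
  }
  cls <- ifelse(!is.na(p$lw_label),
                paste(.pairLabel(p$base_i, p$base_j), p$lw_label),
                paste(.pairLabel(p$base_i, p$base_j),
                      paste(p$sector_i, p$sector_j, sep = "/")))
  out <- data.frame(class = cls, base_i = p$base_i, base_j = p$base_j,
                    rho = p$rho, theta = p$theta, z = p$z,
                    stringsAsFactors = FALSE)
  out[!is.na(out$rho), , drop = FALSE]
}

#' Annotate a single structure end to end
#'
#' Runs the full per-structure pipeline: base-pair and stack detection (or
#' DSSR ingestion), multiplet filtering of canonical pairs, pseudoknot
#' resolution and per-chain motif decomposition.  Inter-chain pairs are
#' kept in the pair statistics but excluded from loop decomposition.
#'
#' @param x an [RNAStructure-class].
#' @param params thresholds from [pairDetectionParams()].
#' @param dssr optional path to a DSSR JSON file; when given, DSSR
#'   annotations take precedence over the built-in detector.
#' @return list: \code{id}, \code{L}, \code{bases}, \code{chains},
#'   \code{pairs}, \code{stacks}, \code{secstruct} (list of
#'   [SecondaryStructure-class], one per chain), \code{shape}
#'   (a [ShapeDescriptors-class]).
#' @export
annotateStructure <- function(x, params = pairDetectionParams(),
                              dssr = NULL) {
  rt <- residueTable(x)
  if (is.null(dssr)) {
    pairs <- detectBasePairs(x, params)
  } else {
    pairs <- readDSSRAnnotation(dssr, structure = x)$pairs
    pairs <- pairs[!is.na(pairs$i) & !is.na(pairs$j), , drop = FALSE]
  }
  stacks <- detectStacking(x, params)
  canon <- filterMultiplets(pairs[pairs$canonical, , drop = FALSE])
  chains <- unique(rt$chain)
  secstruct <- list()
  for (ch in chains) {
    resIdx <- rt$residx[rt$chain == ch]
    intra <- canon[canon$i %in% resIdx & canon$j %in% resIdx, ,
                   drop = FALSE]
    # reindex to chain-local coordinates
    loc <- match(c(intra$i, intra$j), resIdx)
    m <- matrix(loc, ncol = 2)
    pk <- resolvePseudoknots(cbind(i = m[, 1], j = m[, 2]))
    secstruct[[ch]] <- decomposeSecondaryStructure(length(resIdx),
                                                   pk$nested, pk$removed)
  }
  list(id = structureID(x), L = structureLength(x), bases = rt$base,
       chains = rt$chain, pairs = pairs, stacks = stacks,
       secstruct = secstruct, shape = shapeDescriptors(x))
}

#' Aggregate per-structure annotations into a dataset summary
#'
#' Deterministic and invariant to the input order (rows are sorted by
#' structure id).  Scaling-law and linear fits are skipped with a warning
#' when fewer than two distinct lengths are present.
#'
#' @param annotations list of results from [annotateStructure()].
#' @return a [DatasetSummary-class].
#' @export
summarizeDataset <- function(annotations) {
  if (!length(annotations)) stop("need at least one annotated structure")
  if (!is.null(annotations$secstruct)) annotations <- list(annotations)
  ord <- order(vapply(annotations, `[[`, character(1), "id"))
  annotations <- annotations[ord]
  rows <- lapply(annotations, function(ann) {
    sh <- ann$shape
    data.frame(id = ann$id, L = ann$L, n_atoms = sh@nAtoms, rg = sh@rg,
               lambda1 = sh@eigenvalues[1], lambda2 = sh@eigenvalues[2],
               lambda3 = sh@eigenvalues[3], asphericity = sh@asphericity,
               shape = sh@shape, n_bp = nrow(ann$pairs),
               n_bp_noncanonical = sum(!ann$pairs$canonical),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fits <- list(power_law = NULL, power_law_short = NULL,
               bp_slope = NULL, bp_noncanonical_slope = NULL)
  if (length(unique(tab$L)) >= 2L) {
    fits$power_law <- fitPowerLaw(tab$L, tab$rg)
    short <- tab$L < 100
    if (length(unique(tab$L[short])) >= 2L)
      fits$power_law_short <- fitPowerLaw(tab$L[short], tab$rg[short])
    fits$bp_slope <- fitLinearThroughOrigin(tab$L, tab$n_bp)
    fits$bp_noncanonical_slope <-
      fitLinearThroughOrigin(tab$L, tab$n_bp_noncanonical)
  } else {
    warning("fewer than two distinct lengths: fits skipped")
  }
  hists <- motifHistograms(annotations)
  geom <- do.call(rbind, lapply(annotations, function(ann)
    pairGeometryRecords(ann$pairs)))
  gfits <- fitPairGaussians(geom)
  new("DatasetSummary",
      nStructures = length(annotations), perStructure = tab, fits = fits,
      histograms = hists[c("stem", "hairpin", "bulge", "internal",
                           "junction")],
      frequencies = hists[c("nucleotide", "pair", "stack")],
      geometryFits = gfits,
      asphericityBelow02 = mean(tab$asphericity < 0.2))
}
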