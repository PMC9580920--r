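#' @import methods
NULL

#' RNAStructure: a validated heavy-atom model of an RNA 3D structure
#'
#' Container for the coordinates of one RNA structure after filtering to
#' standard nucleotides (A, C, G, U) and heavy atoms (C, N, O, P).  Residues
#' carry both the author numbering from the source file and a sequential
#' internal index (\code{residx}, 1..L across chains in file order) that all
#' algorithms use.
#'
#' @slot id single character, the structure identifier (PDB id or file stem).
#' @slot atoms data.frame with one row per atom and columns \code{chain},
#'   \code{resno} (author numbering), \code{residx} (internal sequential
#'   index), \code{base} (A/C/G/U), \code{name} (atom label, PDB prime
#'   convention, e.g. \code{"C4'"}), \code{element} (C/N/O/P) and Cartesian
#'   coordinates \code{x}, \code{y}, \code{z} in Angstrom.
#' @slot log character vector of processing notes (dropped chains, skipped
#'   residues, altloc choices).
#'
#' @seealso [readRNAStructure()], [residueTable()], [shapeDescriptors()]
#' @export
setClass("RNAStructure",
  representation(id = "character", atoms = "data.frame", log = "character"),
  prototype(id = NA_character_,
            atoms = data.frame(chain = character(), resno = integer(),
                               residx = integer(), base = character(),
                               name = character(), element = character(),
                               x = numeric(), y = numeric(), z = numeric()),
            log = character()))

setValidity("RNAStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "residx", "base", "name", "element",
            "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (length(object@id) != 1L)
    return("id must be a single string")
  if (nrow(a) == 0L)
    return("structure must contain at least one residue with atoms")
  if (!all(a$base %in% c("A", "C", "G", "U")))
    return("bases must be one of A, C, G, U")
  if (!all(a$element %in% c("C", "N", "O", "P")))
    return("only heavy atoms (C, N, O, P) are allowed")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("coordinates must be finite")
  # residx sequential 1..L
  u <- unique(a$residx)
  if (!identical(sort(u), seq_along(u)))
    return("residx must be sequential 1..L")
  # atom names unique within residue
  if (anyDuplicated(paste(a$residx, a$name)))
    return("atom names must be unique within a residue")
  TRUE
})

#' ShapeDescriptors: global size/shape summary of one structure
#'
#' @slot rg radius of gyration, Angstrom.
#' @slot eigenvalues numeric(3), gyration-tensor eigenvalues (lambda1 >=
#'   lambda2 >= lambda3), Angstrom^2; their sum equals \code{rg^2}.
#' @slot asphericity dimensionless, in [0, 1]; 0 for spherically symmetric
#'   mass distributions.
#' @slot shape dimensionless, in [-1/4, 2]; positive prolate, negative oblate.
#' @slot nAtoms number of heavy atoms used.
#'
#' @export
setClass("ShapeDescriptors",
  representation(rg = "numeric", eigenvalues = "numeric",
                 asphericity = "numeric", shape = "numeric",
                 nAtoms = "integer"))

setValidity("ShapeDescriptors", function(object) {
  if (length(object@eigenvalues) != 3L) return("eigenvalues must be length 3")
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev))) return("eigenvalues must be sorted descending")
  if (ev[3] < -1e-9 * max(ev[1], 1)) return("eigenvalues must be >= 0")
  if (object@asphericity < -1e-9 || object@asphericity > 1 + 1e-9)
    return("asphericity must lie in [0, 1]")
  if (object@shape < -0.25 - 1e-9 || object@shape > 2 + 1e-9)
    return("shape must lie in [-1/4, 2]")
  tr <- sum(ev)
  if (abs(tr - object@rg^2) > 1e-9 * max(tr, 1))
    return("sum of eigenvalues must equal rg^2")
  TRUE
})

#' SecondaryStructure: stems, loops and pseudoknots of one chain/structure
#'
#' Result of decomposing a crossing-free canonical pair list.  Stems are
#' maximal runs of consecutively stacked pairs (i,j),(i+1,j-1),...; stems of
#' length 1 are reported separately as lone pairs.  Loops are classified by
#' the number of bordering stems: hairpin (1), bulge/internal (2; bulge has
#' one empty side), junction (>= 3).  Loop length is the total number of
#' unpaired nucleotides in the loop, without distinguishing 5' and 3' sides.
#'
#' @slot length chain length L (nt).
#' @slot stems list of integer matrices, each with columns i, j, one row per
#'   pair, consecutive rows nested; only stems with >= 2 pairs.
#' @slot lonePairs integer matrix (i, j) of isolated canonical pairs.
#' @slot loops data.frame with columns \code{kind} (hairpin/bulge/internal/
#'   junction), \code{length} (unpaired nt), \code{branches} (bordering
#'   stems) and list-column \code{positions}.
#' @slot pseudoknotPairs integer matrix (i, j) of pairs removed to make the
#'   structure crossing-free.
#' @slot dotbracket dot-bracket string; pseudoknot pairs use bracket tiers
#'   [], {}, <>.
#'
#' @export
setClass("SecondaryStructure",
  representation(length = "integer", stems = "list", lonePairs = "matrix",
                 loops = "data.frame", pseudoknotPairs = "matrix",
                 dotbracket = "character"))

#' DatasetSummary: aggregated statistics over a set of RNA structures
#'
#' @slot nStructures number of structures aggregated.
#' @slot perStructure data.frame, one row per structure: id, L, n_atoms, rg,
#'   lambda1..3, asphericity, shape, n_bp, n_bp_noncanonical.
#' @slot fits list: \code{power_law} (a, b over all L), \code{power_law_short}
#'   (L < 100), \code{bp_slope}, \code{bp_noncanonical_slope}.
#' @slot histograms list of motif length histograms (stem, hairpin, bulge,
#'   internal, junction) as named integer vectors.
#' @slot frequencies list: \code{nucleotide}, \code{pair}, \code{stack}
#'   tables, each normalised to sum 1.
#' @slot geometryFits data.frame of per-pair-class Gaussian fits of
#'   (rho, theta, z), circular statistics for theta.
#' @slot asphericityBelow02 fraction of structures with asphericity < 0.2.
#'
#' @export
setClass("DatasetSummary",
  representation(nStructures = "integer", perStructure = "data.frame",
                 fits = "list", histograms = "list", frequencies = "list",
                 geometryFits = "data.frame", asphericityBelow02 = "numeric"))
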