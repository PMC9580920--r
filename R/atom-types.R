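# Heavy-atom typing for standard ribonucleotides.
#
# Each type is a (base, atom-name) combination.  Twelve backbone/ribose names
# are shared by all four bases; base moieties contribute 10 (A), 11 (G) and 8
# (C, U) names, giving 22 + 23 + 20 + 20 = 85 types.  Hydrogens, the terminal
# OP3 phosphate oxygen and modified-base extras are untyped.

.BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "O2'", "C1'")

.BASE_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"))

# ring systems (no exocyclic substituents); used for frame construction checks
.RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"))

# base-moiety polar atoms used as hydrogen-bond donors/acceptors by the
# geometric pair detector
.POLAR_BASE_ATOMS <- list(
  A = c("N1", "N3", "N6", "N7"),
  G = c("N1", "N2", "N3", "O6", "N7"),
  C = c("O2", "N3", "N4"),
  U = c("O2", "N3", "O4"))

#' The 85-type heavy-atom scheme for standard ribonucleotides
#'
#' Enumerates every (base, atom name) heavy-atom type used when tabulating
#' atom-pair distance distributions: the 12 backbone/ribose atoms of each
#' nucleotide plus the base heavy atoms of A (10), G (11), C (8) and U (8),
#' for 85 types in total.  OP3 (terminal phosphates) and hydrogens are
#' deliberately not part of the scheme.
#'
#' @return data.frame with columns \code{base} and \code{name}; 85 rows.
#' @examples
#' nrow(atomTypeTable())              # 85
#' table(atomTypeTable()$base)        # A:22 C:20 G:23 U:20
#' @export
atomTypeTable <- function() {
  do.call(rbind, lapply(c("A", "C", "G", "U"), function(b)
    data.frame(base = b, name = c(.BACKBONE_ATOMS, .BASE_ATOMS[[b]]),
               stringsAsFactors = FALSE)))
}

#' Look up the heavy-atom type of a (base, atom name) combination
#'
#' Total function: combinations outside the 85-type scheme (e.g. (U, "N2"),
#' OP3, hydrogens) return \code{NA} rather than an error.
#'
#' @param base base code(s), one of "A","C","G","U" (vectorised).
#' @param name atom label(s), PDB prime convention.
#' @return character vector of type labels \code{"<base>.<name>"}, \code{NA}
#'   where the combination is not a typed heavy atom.
#' @examples
#' atomTypeOf("G", "N2")   # "G.N2"
#' atomTypeOf("U", "N2")   # NA
#' @export
atomTypeOf <- function(base, name) {
  n <- max(length(base), length(name))
  base <- rep_len(base, n); name <- rep_len(name, n)
  tab <- atomTypeTable()
  key <- paste(base, name, sep = ".")
  ok <- key %in% paste(tab$base, tab$name, sep = ".")
  ifelse(ok, key, NA_character_)
}
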