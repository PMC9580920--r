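# Coordinate file ingestion.
#
# mmCIF atom_site loops are parsed directly (header-driven, so column order
# and optional columns do not matter); legacy PDB goes through
# bio3d::read.pdb.  Both paths converge on .buildStructure(), which applies
# the heavy-atom / standard-residue filtering contract.

# small map of common modified residues to their standard parent, used only
# when mapModified = TRUE
.MODIFIED_PARENT <- c(PSU = "U", "5MU" = "U", "4SU" = "U", H2U = "U",
                      OMU = "U", UMS = "U",
                      "1MA" = "A", MIA = "A", OMA = "A", A2M = "A",
                      "2MG" = "G", "7MG" = "G", M2G = "G", OMG = "G",
                      YG = "G", G7M = "G",
                      "5MC" = "C", OMC = "C", CBV = "C")

#' Read an RNA 3D structure from an mmCIF or PDB coordinate file
#'
#' Reads atomic coordinates and returns a validated [RNAStructure-class]
#' containing only standard RNA residues (A, C, G, U) and only heavy atoms
#' (C, N, O, P).  Waters, ions, ligands, protein/DNA chains and hydrogens are
#' dropped; for multi-model (NMR) files only the first model is used; for
#' alternate locations the highest-occupancy conformer is kept (ties broken
#' by altloc label order).  Everything dropped is recorded in the processing
#' log (see [processingLog()]).
#'
#' @param path path to the coordinate file.
#' @param format \code{"auto"} (default; decided from the file extension,
#'   then content), \code{"mmcif"} or \code{"pdb"}.
#' @param mapModified if \code{TRUE}, a small set of common modified
#'   nucleotides (e.g. PSU, 2MG) is mapped to its standard parent, keeping
#'   only the parent's heavy atoms; the default \code{FALSE} drops modified
#'   residues, because the 85-type atom scheme covers standard bases only.
#' @param id structure identifier; defaults to the file name stem.
#' @return an [RNAStructure-class] object.
#' @examples
#' fx <- makeDuplex("GGCAGC")
#' f <- tempfile(fileext = ".cif")
#' writeMmCIF(fx$structure, f)
#' s <- readRNAStructure(f)
#' structureLength(s)
#' @export
readRNAStructure <- function(path, format = c("auto", "mmcif", "pdb"),
                             mapModified = FALSE, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .sniffFormat(path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  raw <- switch(format,
                mmcif = .readMmCIFAtoms(path),
                pdb = .readPDBAtoms(path))
  .buildStructure(raw, id = id, mapModified = mapModified)
}

.sniffFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- readLines(path, n = 200L, warn = FALSE)
  if (any(grepl("^_atom_site\\.", head))) return("mmcif")
  if (any(grepl("^(ATOM|HETATM)", head))) return("pdb")
  stop("cannot determine coordinate format of ", path,
       "; pass format = 'mmcif' or 'pdb'")
}

# --- mmCIF ---------------------------------------------------------------

.cifTokens <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  unlist(lapply(lines, function(l)
    scan(text = l, what = "", quote = "\"", quiet = TRUE)), use.names = FALSE)
}

.readMmCIFAtoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop: a loop_ whose first tags are _atom_site.*
  tagIdx <- grep("^\\s*_atom_site\\.", lines)
  if (!length(tagIdx))
    stop("no _atom_site loop found in mmCIF file ", path)
  tags <- sub("^\\s*_atom_site\\.", "", trimws(lines[tagIdx]))
  dataStart <- max(tagIdx) + 1L
  dataEnd <- length(lines)
  stopPat <- "^\\s*(loop_|_[A-Za-z]|data_|#\\s*$)"
  for (k in dataStart:length(lines)) {
    if (grepl(stopPat, lines[k]) && !grepl("^(ATOM|HETATM)", lines[k])) {
      dataEnd <- k - 1L
      break
    }
  }
  toks <- .cifTokens(lines[dataStart:dataEnd])
  ncol <- length(tags)
  if (length(toks) %% ncol != 0L)
    stop("malformed mmCIF atom_site loop in ", path,
         ": token count is not a multiple of the column count")
  m <- matrix(toks, ncol = ncol, byrow = TRUE)
  colnames(m) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  data.frame(
    group = pick("group_PDB"),
    name = pick("auth_atom_id", "label_atom_id"),
    alt = pick("label_alt_id"),
    resname = pick("auth_comp_id", "label_comp_id"),
    chain = pick("auth_asym_id", "label_asym_id"),
    resno = as.integer(num(pick("auth_seq_id", "label_seq_id"))),
    element = pick("type_symbol"),
    x = num(m[, "Cartn_x"]), y = num(m[, "Cartn_y"]), z = num(m[, "Cartn_z"]),
    occ = num(pick("occupancy")),
    model = pick("pdbx_PDB_model_num"),
    stringsAsFactors = FALSE)
}

# --- PDB -----------------------------------------------------------------

.readPDBAtoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  data.frame(group = a$type, name = a$elety, alt = a$alt,
             resname = a$resid, chain = a$chain,
             resno = as.integer(a$resno),
             element = a$elesy, x = a$x, y = a$y, z = a$z,
             occ = a$o, model = "1", stringsAsFactors = FALSE)
}

# --- common filtering pipeline -------------------------------------------

.elementFromName <- function(name) {
  # first alphabetic character of the label; covers C/N/O/P and H variants
  toupper(substr(gsub("[^A-Za-z].*|[0-9]", "", sub("^[0-9]+", "", name)),
                 1, 1))
}

.buildStructure <- function(raw, id, mapModified = FALSE) {
  log <- character()
  if (!nrow(raw)) stop("no atoms found in input for ", id)

  # model 1 only
  if (!all(is.na(raw$model))) {
    models <- unique(raw$model[!is.na(raw$model)])
    if (length(models) > 1L) {
      raw <- raw[is.na(raw$model) | raw$model == models[1], , drop = FALSE]
      log <- c(log, sprintf("multi-model file: kept model %s of %d",
                            models[1], length(models)))
    }
  }

  raw$resname <- toupper(trimws(raw$resname))
  raw$name <- trimws(raw$name)
  # '*' is the old ribose-prime convention
  raw$name <- gsub("\\*", "'", raw$name)

  std <- raw$resname %in% c("A", "C", "G", "U")
  if (mapModified) {
    mod <- raw$resname %in% names(.MODIFIED_PARENT)
    if (any(mod)) {
      mapped <- unique(raw$resname[mod])
      parent <- .MODIFIED_PARENT[raw$resname[mod]]
      keepName <- raw$name[mod] %in%
        paste0(c(.BACKBONE_ATOMS, "OP3"), "") |
        mapply(function(nm, p) nm %in% .BASE_ATOMS[[p]],
               raw$name[mod], parent)
      raw$resname[mod] <- parent
      drop <- which(mod)[!keepName]
      if (length(drop)) raw <- raw[-drop, , drop = FALSE]
      std <- raw$resname %in% c("A", "C", "G", "U")
      log <- c(log, sprintf("mapped modified residues to parents: %s",
                            paste(mapped, collapse = ", ")))
    }
  }
  nDropRes <- length(unique(paste(raw$chain, raw$resno,
                                  raw$resname)[!std]))
  if (nDropRes > 0)
    log <- c(log, sprintf(
      "dropped %d non-standard residue(s) (waters/ions/ligands/protein/modified)",
      nDropRes))
  raw <- raw[std, , drop = FALSE]
  if (!nrow(raw)) stop("no standard RNA residues (A,C,G,U) in ", id)

  # heavy atoms only
  el <- toupper(trimws(raw$element))
  bad <- is.na(el) | el == "" | el == "?" | el == "."
  el[bad] <- .elementFromName(raw$name[bad])
  heavy <- el %in% c("C", "N", "O", "P")
  if (any(!heavy))
    log <- c(log, sprintf("dropped %d non-heavy atom(s) (hydrogens etc.)",
                          sum(!heavy)))
  raw <- raw[heavy, , drop = FALSE]
  el <- el[heavy]
  if (!nrow(raw)) stop("no heavy atoms left in ", id)
  raw$element <- el

  # altloc: keep highest occupancy, ties by altloc label order
  alt <- raw$alt
  alt[is.na(alt) | alt %in% c("", ".", "?")] <- ""
  occ <- raw$occ
  occ[is.na(occ)] <- 1
  key <- paste(raw$chain, raw$resno, raw$resname, raw$name, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -occ, alt)
    raw <- raw[ord, , drop = FALSE]
    dup <- duplicated(key[ord])
    raw <- raw[!dup, , drop = FALSE]
    log <- c(log, sprintf("resolved %d alternate-location atom(s)", sum(dup)))
    # restore file order
    raw <- raw[order(as.integer(rownames(raw))), , drop = FALSE]
  }

  # residue indexing in order of appearance
  rkey <- paste(raw$chain, raw$resno, sep = "\r")
  residx <- match(rkey, unique(rkey))
  atoms <- data.frame(chain = raw$chain, resno = raw$resno,
                      residx = as.integer(residx), base = raw$resname,
                      name = raw$name, element = raw$element,
                      x = raw$x, y = raw$y, z = raw$z,
                      stringsAsFactors = FALSE)
  # drop duplicate atom names inside a residue defensively (e.g. symmetry
  # copies); keep first
  akey <- paste(atoms$residx, atoms$name)
  if (anyDuplicated(akey)) {
    log <- c(log, sprintf("dropped %d duplicated atom record(s)",
                          sum(duplicated(akey))))
    atoms <- atoms[!duplicated(akey), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  new("RNAStructure", id = id, atoms = atoms, log = log)
}

# --- fixture writer ------------------------------------------------------

#' Write an RNAStructure as a minimal mmCIF file
#'
#' Emits a single-model atom_site loop with the standard PDBx column set.
#' Coordinates are written at 1e-3 Angstrom precision, so
#' write/read round trips are exact to that precision.
#'
#' @param x an [RNAStructure-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMmCIF <- function(x, path) {
  stopifnot(is(x, "RNAStructure"))
  a <- atomTable(x)
  q <- function(v) ifelse(grepl("'", v), paste0('"', v, '"'), v)
  hdr <- c(paste0("data_", gsub("[^A-Za-z0-9_]", "_", x@id)),
           "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s 1",
                  seq_len(nrow(a)), a$element, q(a$name), a$base, a$chain,
                  a$residx, a$x, a$y, a$z, a$resno, a$chain)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Detect chain breaks from backbone connectivity
#'
#' Two consecutive residues of the same chain are considered covalently
#' linked when the O3'(i)-P(i+1) distance is <= 2.5 Angstrom.  Used to
#' exclude the bonded phosphodiester O3'-P atom pair from non-bonded
#' distance statistics and to define nearest-neighbour phosphates.
#'
#' @param x an [RNAStructure-class].
#' @return logical vector of length L-1; element i is TRUE when residues
#'   with internal indices i and i+1 are linked.
#' @export
chainLinks <- function(x) {
  a <- atomTable(x)
  L <- structureLength(x)
  if (L < 2L) return(logical(0))
  o3 <- a[a$name == "O3'", ]
  p <- a[a$name == "P", ]
  res <- vapply(seq_len(L - 1L), function(i) {
    ci <- a$chain[match(i, a$residx)]
    cj <- a$chain[match(i + 1L, a$residx)]
    if (!identical(ci, cj)) return(FALSE)
    oi <- o3[o3$residx == i, ]
    pj <- p[p$residx == i + 1L, ]
    if (!nrow(oi) || !nrow(pj)) return(FALSE)
    d <- sqrt((oi$x - pj$x)^2 + (oi$y - pj$y)^2 + (oi$z - pj$z)^2)
    d <= 2.5
  }, logical(1))
  res
}
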