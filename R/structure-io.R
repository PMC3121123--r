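.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
.dna_codes <- c("DA", "DC", "DG", "DT", "DI", "DU")
.rna_codes <- c("A", "C", "G", "U", "I")

#' Classify a residue code by polymer type
#'
#' Pure, total mapping from residue names to polymer classes: the 20
#' standard amino acids (plus any configured non-standard protein codes)
#' map to \code{"protein"}, deoxyribonucleotide codes (DA/DC/DG/DT and
#' variants) to \code{"dna"}, ribonucleotide codes (A/C/G/U) to
#' \code{"rna"}, and anything else -- waters, ions, ligands, unknown
#' codes -- to \code{"other"}. Unknown codes never error.
#'
#' @param resName character vector of residue codes (case-insensitive,
#'   whitespace-trimmed).
#' @param proteinExtra extra residue codes to treat as protein (e.g.
#'   \code{"MSE"} for selenomethionine).
#' @return character vector over
#'   \code{c("protein","dna","rna","other")}.
#' @examples
#' classifyPolymer(c("ALA", "DG", "U", "HOH"))
#' @export
classifyPolymer <- function(resName, proteinExtra = character()) {
  rn <- toupper(trimws(resName))
  out <- rep("other", length(rn))
  out[rn %in% c(.standard_aa, toupper(proteinExtra))] <- "protein"
  out[rn %in% .dna_codes] <- "dna"
  out[rn %in% .rna_codes] <- "rna"
  out
}

# element symbol from a PDB atom name when the element column is blank
.element_from_name <- function(atom) {
  a <- gsub("[0-9' ]", "", toupper(atom))
  two <- substr(a, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA"),
         two, substr(a, 1, 1))
}

#' Read a protein--DNA complex from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records of a PDB-format file into a
#' [ComplexStructure], resolving alternate locations, applying the
#' multi-model policy, and classifying every chain's residues by polymer
#' type. Parsing is delegated to \pkg{bio3d}; the policies below are applied
#' on top because they differ from that reader's defaults.
#'
#' @param file path to a PDB-format file.
#' @param structureID identifier recorded in the result; defaults to the
#'   file base name.
#' @param model \code{"first"} (default) keeps the first MODEL of a
#'   multi-model file; \code{"strict"} raises an error when more than one
#'   MODEL is present.
#' @param altLoc alternate-location policy: \code{"highest"} (default)
#'   keeps the highest-occupancy conformer of each atom, ties broken by
#'   altloc letter order; \code{"first"} keeps altloc \code{"A"} (or the
#'   first seen); \code{"all"} keeps every conformer.
#' @param keepHetero keep HETATM records (default FALSE: waters and
#'   ligands are dropped so they cannot create spurious contacts).
#' @param removeHydrogens drop hydrogen atoms (default FALSE: all atoms
#'   of a residue count towards contact distances).
#' @param proteinExtra non-standard residue codes treated as protein;
#'   HETATM records with these codes are retained and classified as
#'   protein even when \code{keepHetero} is FALSE.
#' @return a [ComplexStructure].
#' @seealso [writeComplex()], [chainMap()], [annotateByDistance()]
#' @export
readComplex <- function(file, structureID = NULL,
                        model = c("first", "strict"),
                        altLoc = c("highest", "first", "all"),
                        keepHetero = FALSE, removeHydrogens = FALSE,
                        proteinExtra = character()) {
  model <- match.arg(model)
  altLoc <- match.arg(altLoc)
  .stop_if(!file.exists(file), "PDB file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  .stop_if(!length(lines) || !any(nzchar(trimws(lines))),
           "PDB format error: input is empty")
  rec <- substr(lines, 1, 6)
  has_atom <- grepl("^ATOM", rec) | grepl("^HETATM", rec)
  .stop_if(!any(grepl("^ATOM", rec)),
           "PDB format error: no ATOM record; first offending line: ",
           dQuote(lines[[1]]))
  n_models <- sum(grepl("^MODEL", rec))
  .stop_if(model == "strict" && n_models > 1L,
           "multi-model file (", n_models,
           " models) with model policy 'strict'")

  pdb <- suppressWarnings(
    bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  a <- pdb$atom
  df <- data.frame(
    chain   = ifelse(is.na(a$chain), "", a$chain),
    resno   = a$resno,
    insert  = ifelse(is.na(a$insert), "", a$insert),
    resname = trimws(a$resid),
    atom    = trimws(a$elety),
    element = toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                                    .element_from_name(a$elety), a$elesy))),
    x = a$x, y = a$y, z = a$z,
    occ = a$o,
    alt = ifelse(is.na(a$alt), "", a$alt),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)

  if (altLoc != "all" && any(df$alt != "")) {
    key <- paste(df$chain, df$resno, df$insert, df$resname, df$atom)
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
      if (length(idx) == 1L || all(df$alt[idx] == "")) return(idx)
      if (altLoc == "first") {
        idx[order(df$alt[idx])][1L]
      } else {
        occ <- ifelse(is.na(df$occ[idx]), 1, df$occ[idx])
        idx[order(-occ, df$alt[idx])][1L]
      }
    }), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
  }

  df$polymer <- classifyPolymer(df$resname, proteinExtra)
  if (!keepHetero)
    df <- df[!df$hetero | df$polymer == "protein", , drop = FALSE]
  if (removeHydrogens)
    df <- df[df$element != "H", , drop = FALSE]
  rownames(df) <- NULL

  if (is.null(structureID))
    structureID <- sub("\\.(pdb|ent)$", "", basename(file))
  new("ComplexStructure", structureID = structureID, atoms = df)
}

#' Write a complex to a PDB file
#'
#' Writes the atoms of a [ComplexStructure] as fixed-width PDB ATOM/HETATM
#' records (via \pkg{bio3d}), suitable for round-tripping toy fixtures.
#'
#' @param x a [ComplexStructure].
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeComplex <- function(x, file) {
  a <- atoms(x)
  .stop_if(!nrow(a), "cannot write an empty structure")
  bio3d::write.pdb(
    pdb = NULL, file = file,
    type = ifelse(a$hetero, "HETATM", "ATOM"),
    eleno = seq_len(nrow(a)), elety = a$atom,
    alt = ifelse(a$alt == "", NA, a$alt),
    resid = a$resname, chain = ifelse(a$chain == "", NA, a$chain),
    resno = a$resno, insert = ifelse(a$insert == "", NA, a$insert),
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    o = ifelse(is.na(a$occ), 1, a$occ), b = rep(0, nrow(a)),
    elesy = a$element)
  invisible(file)
}

#' @describeIn ComplexStructure-class accessor for the structure identifier.
#' @param x a [ComplexStructure].
#' @export
structureID <- function(x) x@structureID

#' @describeIn ComplexStructure-class accessor for the atom table.
#' @export
atoms <- function(x) x@atoms

#' Residue-level view of a complex
#'
#' One row per residue, in file order, with its chain, identity, residue
#' name, polymer class and atom count.
#'
#' @param x a [ComplexStructure].
#' @param polymer optional filter, e.g. \code{"protein"}.
#' @return data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resname}, \code{polymer}, \code{nAtoms}.
#' @export
residueTable <- function(x, polymer = NULL) {
  a <- atoms(x)
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resname = a$resname[first],
                    polymer = a$polymer[first],
                    nAtoms = as.integer(table(factor(key, levels = key[first]))),
                    stringsAsFactors = FALSE)
  if (!is.null(polymer)) out <- out[out$polymer %in% polymer, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue-numbering to sequence-index map
#'
#' Sequence positions for prediction tracks are 0-based and half-open
#' while PDB residue numbering is arbitrary; this emits the explicit
#' mapping for each chain: residue identity (chain, number, insertion
#' code) to 0-based index in chain order.
#'
#' @param x a [ComplexStructure].
#' @param file optional path; when given the map is also written as TSV.
#' @return data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{index0}, \code{resname}.
#' @export
chainMap <- function(x, file = NULL) {
  rt <- residueTable(x)
  idx <- unlist(lapply(split(seq_len(nrow(rt)), rt$chain),
                       function(i) seq_along(i) - 1L), use.names = FALSE)
  out <- rt[, c("chain", "resno", "insert")]
  out$index0 <- NA_integer_
  out$index0[unlist(split(seq_len(nrow(rt)), rt$chain), use.names = FALSE)] <- idx
  out$resname <- rt$resname
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

setMethod("show", "ComplexStructure", function(object) {
  rt <- residueTable(object)
  cat("ComplexStructure", dQuote(object@structureID), "\n")
  cat("  atoms:", nrow(object@atoms), " residues:", nrow(rt), "\n")
  tab <- table(rt$polymer)
  cat("  residues by polymer:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  chains:", paste(unique(rt$chain), collapse = ", "), "\n")
})

setMethod("show", "ResidueLabelTrack", function(object) {
  cat("ResidueLabelTrack ", object@structureID, " chain ", object@chainID,
      ": ", sum(object@labels), "/", length(object@labels),
      " binding (criterion=", object@criterion,
      ", threshold=", object@threshold, " ", object@unit, ")\n", sep = "")
})
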