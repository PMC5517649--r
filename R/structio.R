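# Structure and sequence input/output.

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records of one model through bio3d and resolves
#' alternate locations. HETATM records (ligands, waters, modified
#' residues) are retained but flagged in the `het` column; protein-level
#' selections exclude them by default.
#'
#' @param path path to a PDB file.
#' @param altloc alternate-location policy: `"occupancy"` keeps the
#'   highest-occupancy copy of each atom (ties resolved by file order),
#'   `"first"` keeps the first copy in the file, `"all"` keeps every copy.
#' @param model 1-based model index for multi-model files.
#' @param id entry identifier recorded in the result (defaults to the
#'   file base name).
#' @return A [ProteinStructure-class].
#' @examples
#' pdb <- system.file("extdata", "toy3.pdb", package = "TrefoilForge")
#' s <- readPDB(pdb)
#' nrow(atoms(s))
#' @export
readPDB <- function(path, altloc = c("occupancy", "first", "all"),
                    model = 1L, id = NULL) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- p$atom
  if (!any(at$type == "ATOM")) stop("no ATOM records in ", path)
  nmodel <- nrow(p$xyz)
  if (model < 1L || model > nmodel)
    stop("model index ", model, " out of range (file has ", nmodel, ")")
  xyz <- matrix(p$xyz[model, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resseq = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1L, 1L), at$elesy),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)

  if (altloc != "all" && any(atoms$altloc != "")) {
    key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      if (length(i) == 1L) return(i)
      if (altloc == "first") return(i[1L])
      i[which.max(atoms$occupancy[i])]  # which.max: first on ties
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
    rownames(atoms) <- NULL
  }
  new("ProteinStructure", atoms = atoms,
      id = if (is.null(id)) sub("\\.(pdb|ent)$", "", basename(path)) else id,
      source = path)
}

#' Write a structure to a PDB file
#'
#' Coordinates are written with the conventional three decimals.
#'
#' @param x a [ProteinStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  stopifnot(is(x, "ProteinStructure"))
  a <- x@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resseq, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = ifelse(a$chain == "", "A", a$chain),
                   insert = a$icode, alt = ifelse(a$altloc == "", "", a$altloc),
                   o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Access the atom table
#'
#' @param x a [ProteinStructure-class].
#' @return data.frame of atom records in file order.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @export
setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  prot <- a[!a$het, , drop = FALSE]
  cat("ProteinStructure '", object@id, "': ",
      nrow(a), " atoms (", sum(a$het), " HETATM), ",
      length(unique(paste(prot$chain, prot$resseq, prot$icode))),
      " protein residues, chains: ",
      paste(unique(a$chain), collapse = " "), "\n", sep = "")
})

# Unique protein residues of a chain, ordered by resseq then icode.
.residueTable <- function(x, chain, includeHet = FALSE) {
  a <- x@atoms
  a <- a[a$chain == chain, , drop = FALSE]
  if (!includeHet) a <- a[!a$het | a$resname == "MSE", , drop = FALSE]
  if (!nrow(a)) stop("no such chain in structure: ", chain)
  r <- unique(a[, c("chain", "resseq", "icode", "resname")])
  r[order(r$resseq, r$icode), , drop = FALSE]
}

#' Extract the one-letter sequence of a chain
#'
#' Residues are reported in residue-number order (insertion codes sort
#' after their base number). Non-standard residues map to `X`;
#' selenomethionine maps to `M` when `mseToMet` is `TRUE`. The attribute
#' `offset` carries the first residue number so that conventions such as
#' "the initiator methionine is numbered zero" can be honoured by the
#' caller.
#'
#' @param x a [ProteinStructure-class].
#' @param chain chain identifier.
#' @param mseToMet map selenomethionine (MSE) to `M` instead of `X`.
#' @return A one-letter character string with attributes `id`, `resno`
#'   (integer residue numbers) and `offset` (first residue number).
#' @export
extractSequence <- function(x, chain, mseToMet = TRUE) {
  r <- .residueTable(x, chain)
  code <- unname(.AA3[r$resname])
  code[is.na(code)] <- ifelse(r$resname[is.na(code)] == "MSE" & mseToMet,
                              "M", "X")
  seq <- paste(code, collapse = "")
  structure(seq, id = paste0(x@id, "_", chain), resno = r$resseq,
            offset = r$resseq[1L])
}

#' Extract an ordered C-alpha trace
#'
#' @param x a [ProteinStructure-class].
#' @param chain chain identifier.
#' @param ranges optional residue ranges as a length-2 numeric
#'   `c(start, end)` or a data.frame with `start` and `end` columns;
#'   `NULL` selects the whole chain.
#' @return data.frame with `resseq`, `icode`, `x`, `y`, `z` for residues
#'   that have a CA atom; residues in the selection lacking a CA are
#'   reported in the `missing` attribute (integer resseq), never silently
#'   skipped.
#' @export
caTrace <- function(x, chain, ranges = NULL) {
  r <- .residueTable(x, chain)
  if (!is.null(ranges)) {
    if (is.numeric(ranges)) ranges <- data.frame(start = ranges[1L],
                                                 end = ranges[2L])
    keep <- rep(FALSE, nrow(r))
    for (i in seq_len(nrow(ranges)))
      keep <- keep | (r$resseq >= ranges$start[i] & r$resseq <= ranges$end[i])
    r <- r[keep, , drop = FALSE]
  }
  if (!nrow(r)) stop("empty residue selection for chain ", chain)
  a <- x@atoms
  ca <- a[a$chain == chain & trimws(a$name) == "CA" & a$resname != "HOH", ,
          drop = FALSE]
  key <- paste(r$resseq, r$icode)
  cakey <- paste(ca$resseq, ca$icode)
  idx <- match(key, cakey)
  missing <- r$resseq[is.na(idx)]
  got <- !is.na(idx)
  out <- data.frame(resseq = r$resseq[got], icode = r$icode[got],
                    x = ca$x[idx[got]], y = ca$y[idx[got]],
                    z = ca$z[idx[got]])
  attr(out, "missing") <- as.integer(missing)
  out
}

#' Read/write protein FASTA
#'
#' Thin wrappers over Biostrings keeping the package's sequence
#' representation (named character vector) at the interface.
#'
#' @param path FASTA file path.
#' @return `readFastaSequences`: named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname readFastaSequences
#' @param seqs named character vector of sequences.
#' @export
writeFastaSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path)
  invisible(path)
}

# Build a ProteinStructure from a CA coordinate matrix (internal, used by
# fixture generators and backbone realisation).
.structureFromCA <- function(coords, resname = "GLY", chain = "A",
                             id = "model", resseq = NULL, metadata = list()) {
  n <- nrow(coords)
  if (length(resname) == 1L) resname <- rep(resname, n)
  if (is.null(resseq)) resseq <- seq_len(n)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", altloc = "", resname = resname,
    chain = chain, resseq = resseq, icode = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, element = "C", het = FALSE, stringsAsFactors = FALSE)
  new("ProteinStructure", atoms = atoms, id = id, source = "memory",
      metadata = metadata)
}
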