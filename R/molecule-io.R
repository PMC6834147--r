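## Molecule input/output: PDB reading (via bio3d), vdW radius assignment,
## synthetic chain generation and PDB export.

#' Bondi van der Waals radii
#'
#' Standard Bondi radii for the elements common in proteins, with a 1.50 A
#' fallback for anything else.
#'
#' @param default fallback radius in Angstrom for unknown elements.
#' @return a \linkS4class{RadiiTable}.
#' @export
bondiRadii <- function(default = 1.50) {
  new("RadiiTable",
      radii = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80),
      default = default)
}

#' Read a PDB file into a Molecule
#'
#' Parses fixed-column ATOM (and optionally HETATM) records, keeps only
#' blank or "A" alternate locations, drops waters (HOH), takes model 1 of
#' multi-model files, groups atoms into residues by (chain, residue number,
#' insertion code) and assigns Bondi van der Waals radii.
#'
#' @param path path to a PDB file.
#' @param includeHetero also accept HETATM records (waters stay excluded).
#' @param radii a \linkS4class{RadiiTable}; defaults to Bondi.
#' @return a \linkS4class{Molecule}.
#' @export
readPDB <- function(path, includeHetero = FALSE, radii = bondiRadii()) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file: ", conditionMessage(e)))
  a <- pdb$atom
  keep <- a$type == "ATOM"
  if (includeHetero) keep <- keep | a$type == "HETATM"
  keep <- keep & a$resid != "HOH"
  alt <- a$alt
  alt[is.na(alt)] <- ""
  keep <- keep & alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("no atoms accepted from ", path,
         if (!includeHetero) " (HETATM records need includeHetero = TRUE)")
  elem <- .resolveElement(a$elesy, a$elety)
  ins <- a$insert
  ins[is.na(ins)] <- ""
  chain <- a$chain
  chain[is.na(chain)] <- "_"
  atoms <- data.frame(
    element = elem, x = a$x, y = a$y, z = a$z, radius = 1,
    resKey = paste(chain, a$resno, ins, sep = ":"),
    resName = a$resid, stringsAsFactors = FALSE)
  mol <- .newMolecule(atoms)
  assignVdwRadii(mol, radii)
}

## element from PDB columns 77-78 when present, else from the atom-name
## field with leading digits stripped (legacy files)
.resolveElement <- function(elesy, elety) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fb <- toupper(gsub("^[0-9']+", "", trimws(elety)))
  fb2 <- substr(fb, 1L, 2L)
  ## two-letter candidates only when chemically plausible; else first letter
  two <- fb2 %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "SE")
  fb <- ifelse(two, fb2, substr(fb, 1L, 1L))
  out <- ifelse(e == "", fb, e)
  out[out == ""] <- "X"
  out
}

.newMolecule <- function(atoms) {
  rownames(atoms) <- NULL
  keys <- atoms$resKey
  residues <- split(seq_len(nrow(atoms)), factor(keys, levels = unique(keys)))
  new("Molecule", atoms = atoms, residues = residues)
}

#' Assign van der Waals radii from a lookup table
#'
#' Sets every atom's radius from its element symbol; unknown elements fall
#' back to the table default (with a logged message).  Idempotent.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param radii a \linkS4class{RadiiTable}.
#' @return the molecule with radii set.
#' @export
assignVdwRadii <- function(mol, radii = bondiRadii()) {
  stopifnot(is(mol, "Molecule"), is(radii, "RadiiTable"))
  el <- mol@atoms$element
  r <- unname(radii@radii[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    .log("INFO", sprintf("unknown element(s) %s: using default radius %.2f A",
                         paste(unique(el[unknown]), collapse = ", "),
                         radii@default))
    r[unknown] <- radii@default
  }
  mol@atoms$radius <- r
  validObject(mol)
  mol
}

#' Generate a synthetic residue chain
#'
#' Places residue centers along a smooth helical curve (consecutive centers
#' about 4.1 A apart) and scatters atoms around each center with a 1.0 A
#' spread, so residues form spatially coherent blobs as in a real peptide
#' chain.  Elements are drawn from C/N/O/S with protein-like frequencies,
#' giving Bondi radii in the 1.5-1.8 A van der Waals range.  Fully
#' deterministic for a fixed seed.
#'
#' @param nResidues number of residues (>= 1).
#' @param atomsPerResidue atoms per residue (>= 1).
#' @param seed integer seed.
#' @return a \linkS4class{Molecule} with \code{nResidues * atomsPerResidue}
#'   atoms.
#' @export
generateSyntheticMolecule <- function(nResidues, atomsPerResidue, seed = 1L) {
  if (nResidues < 1L || atomsPerResidue < 1L)
    stop("nResidues and atomsPerResidue must be >= 1")
  nResidues <- as.integer(nResidues)
  atomsPerResidue <- as.integer(atomsPerResidue)
  rng <- .localRNG(seed)
  on.exit(rng())

  ## helix: radius 6 A, 0.6 rad and 2 A rise per residue -> ~4.1 A spacing
  i <- seq_len(nResidues) - 1L
  theta <- 0.6 * i
  centers <- cbind(6 * cos(theta), 6 * sin(theta), 2 * i)

  n <- nResidues * atomsPerResidue
  elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                     prob = c(0.60, 0.20, 0.15, 0.05))
  offsets <- matrix(stats::rnorm(3L * n, sd = 1.0), ncol = 3L)
  resIdx <- rep(seq_len(nResidues), each = atomsPerResidue)
  pos <- centers[resIdx, , drop = FALSE] + offsets
  atoms <- data.frame(
    element = elements,
    x = pos[, 1], y = pos[, 2], z = pos[, 3], radius = 1,
    resKey = sprintf("A:%d:", resIdx),
    resName = "ALA", stringsAsFactors = FALSE)
  assignVdwRadii(.newMolecule(atoms), bondiRadii())
}

## run code under a deterministic private RNG state, restoring the caller's
.localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a Molecule as a PDB file
#'
#' Emits standard fixed-column ATOM records (element in columns 77-78) so
#' synthetic molecules can be inspected in any structure viewer.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePDB <- function(mol, path) {
  stopifnot(is(mol, "Molecule"))
  a <- mol@atoms
  resno <- match(a$resKey, unique(a$resKey))
  chain <- substr(vapply(strsplit(a$resKey, ":", fixed = TRUE), `[`, "", 1L),
                  1L, 1L)
  chain[chain == "_" | chain == ""] <- "A"
  name <- sprintf(" %-3s", substr(paste0(a$element, seq_len(nrow(a))), 1L, 3L))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, a$resName, chain, resno,
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.log <- function(level, msg) {
  message(sprintf("%s [%s] %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, msg))
}
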