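## Fixture builders shared across test files.

pdbAtomLine <- function(serial, name, resName, chain, resSeq, x, y, z,
                        altLoc = " ", element = " C", record = "ATOM  ") {
  sprintf("%s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altLoc, resName, chain, resSeq,
          x, y, z, 1.0, 0.0, element)
}

## molecule built directly from coordinates/radii (one residue per group)
makeMolecule <- function(pos, radii, resIdx = rep(1L, nrow(pos)),
                         element = "C") {
  atoms <- data.frame(
    element = rep_len(element, nrow(pos)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3], radius = radii,
    resKey = sprintf("A:%d:", resIdx), resName = "ALA",
    stringsAsFactors = FALSE)
  keys <- atoms$resKey
  new("Molecule", atoms = atoms,
      residues = split(seq_len(nrow(atoms)), factor(keys, unique(keys))))
}

## display list straight from a list of Sphere/Ellipsoid glyphs
makeDisplayList <- function(geometry, levels = NULL) {
  kind <- vapply(geometry, function(g)
    if (is(g, "Sphere")) "sphere" else "ellipsoid", "")
  if (is.null(levels))
    levels <- ifelse(kind == "sphere", "ATOM", "MOLECULE")
  new("DisplayList",
      entries = data.frame(id = seq_along(geometry), kind = kind,
                           level = as.character(levels),
                           height = rep(0L, length(geometry)),
                           stringsAsFactors = FALSE),
      geometry = geometry, resKey = sprintf("A:%d:", seq_along(geometry)))
}

## partition check: do the listed nodes' atom sets tile the molecule?
isAtomPartition <- function(tree, dl) {
  mem <- unlist(lapply(displayEntries(dl)$id,
                       function(id) nodeMembers(tree, id)))
  length(mem) == nAtoms(molecule(tree)) &&
    identical(sort(mem), seq_len(nAtoms(molecule(tree))))
}

## annotated 6x5 reference tree, built once per test run
annotatedTree65 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- annotateTree(buildClusterTree(
        generateSyntheticMolecule(6, 5, 1)))
    cache
  }
})
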