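#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname accessors
#' @export
setGeneric("residueGroups", function(x) standardGeneric("residueGroups"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nodeData", function(x) standardGeneric("nodeData"))

#' @rdname accessors
#' @export
setGeneric("rootId", function(x) standardGeneric("rootId"))

#' @rdname accessors
#' @export
setGeneric("molecule", function(x) standardGeneric("molecule"))

#' @rdname accessors
#' @param id integer node id.
#' @export
setGeneric("nodeMembers", function(x, id) standardGeneric("nodeMembers"))

#' @rdname accessors
#' @export
setGeneric("nodeMVEE", function(x, id) standardGeneric("nodeMVEE"))

#' @rdname accessors
#' @export
setGeneric("isAnnotated", function(x) standardGeneric("isAnnotated"))

#' @rdname accessors
#' @export
setGeneric("displayEntries", function(x) standardGeneric("displayEntries"))

#' @rdname accessors
#' @export
setGeneric("displayGeometry", function(x) standardGeneric("displayGeometry"))

#' Volume of a geometric object
#' @param x a \linkS4class{Sphere} or \linkS4class{Ellipsoid}.
#' @return volume in cubic Angstrom.
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))

## -- accessor methods ------------------------------------------------------

#' Accessors for EllipsoidLOD objects
#'
#' Small read-only accessors: atom/residue tables of a
#' \linkS4class{Molecule}, node table, members and per-node MVEE of a
#' \linkS4class{ClusterTree}, and the entry table and glyph geometry of a
#' \linkS4class{DisplayList}.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("nAtoms", "Molecule", function(x) nrow(x@atoms))

#' @rdname accessors
setMethod("nResidues", "Molecule", function(x) length(x@residues))

#' @rdname accessors
setMethod("atomData", "Molecule", function(x) x@atoms)

#' @rdname accessors
setMethod("residueGroups", "Molecule", function(x) x@residues)

#' @rdname accessors
setMethod("nNodes", "ClusterTree", function(x) nrow(x@nodes))

#' @rdname accessors
setMethod("nodeData", "ClusterTree", function(x) x@nodes)

#' @rdname accessors
setMethod("rootId", "ClusterTree", function(x) x@rootId)

#' @rdname accessors
setMethod("molecule", "ClusterTree", function(x) x@molecule)

#' @rdname accessors
setMethod("nodeMembers", "ClusterTree", function(x, id) {
  .checkNodeId(x, id)
  x@members[[id]]
})

#' @rdname accessors
setMethod("nodeMVEE", "ClusterTree", function(x, id) {
  .checkNodeId(x, id)
  x@mvees[[id]]
})

#' @rdname accessors
setMethod("isAnnotated", "ClusterTree", function(x) {
  length(x@mvees) == nNodes(x) && !any(vapply(x@mvees, is.null, TRUE))
})

#' @rdname accessors
setMethod("displayEntries", "DisplayList", function(x) x@entries)

#' @rdname accessors
setMethod("displayGeometry", "DisplayList", function(x) x@geometry)

#' @rdname volume
setMethod("volume", "Sphere", function(x) 4 / 3 * pi * x@radius^3)

#' @rdname volume
setMethod("volume", "Ellipsoid", function(x) 4 / 3 * pi * prod(x@semiAxes))

.checkNodeId <- function(tree, id) {
  if (length(id) != 1L || is.na(id) || id < 1L || id > nNodes(tree))
    stop("unknown node id: ", id)
  invisible(TRUE)
}

## -- show methods ----------------------------------------------------------

setMethod("show", "Sphere", function(object) {
  cat(sprintf("Sphere: center (%.3f, %.3f, %.3f), radius %.3f A\n",
              object@center[1], object@center[2], object@center[3],
              object@radius))
})

setMethod("show", "Ellipsoid", function(object) {
  cat(sprintf(
    "Ellipsoid: center (%.3f, %.3f, %.3f), semi-axes %.3f >= %.3f >= %.3f A\n",
    object@center[1], object@center[2], object@center[3],
    object@semiAxes[1], object@semiAxes[2], object@semiAxes[3]))
})

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %d atoms in %d residues\n",
              nAtoms(object), nResidues(object)))
  cat("  elements:",
      paste(names(sort(table(object@atoms$element), decreasing = TRUE)),
            collapse = " "), "\n")
})

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree: %d nodes over %d atoms (root id %d)\n",
              nNodes(object), nAtoms(object@molecule), object@rootId))
  tb <- table(factor(object@nodes$level, levels = .NODE_LEVELS))
  for (lv in names(tb)) cat(sprintf("  %-17s %d\n", lv, tb[[lv]]))
  cat(if (isAnnotated(object)) "  annotated with MVEEs\n"
      else "  not yet annotated (run annotateTree)\n")
})

setMethod("show", "DisplayList", function(object) {
  cat(sprintf("DisplayList: %d glyphs (%d spheres, %d ellipsoids)\n",
              nrow(object@entries), sum(object@entries$kind == "sphere"),
              sum(object@entries$kind == "ellipsoid")))
})

setMethod("show", "FrameBuffer", function(object) {
  fg <- sum(is.finite(object@depth))
  cat(sprintf("FrameBuffer: %d x %d, %d foreground pixels (%.1f%%)\n",
              ncol(object@depth), nrow(object@depth), fg,
              100 * fg / length(object@depth)))
})
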