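## Distance-dependent level-of-detail selection: top-down traversal of the
## cluster tree emitting the frontier of nodes abstract enough for their
## distance to the camera.

#' LOD predicate
#'
#' A cluster of subtree height D at camera distance dis is abstract enough
#' when \code{D <= (dis - inival) / interval}.  The threshold is compared
#' as a real number (no flooring) and may be negative, in which case only
#' leaves qualify.
#'
#' @param D integer subtree height (>= 0).
#' @param dis camera distance to the cluster center, Angstrom (>= 0).
#' @param params a \linkS4class{LODParams}.
#' @return logical.
#' @export
lodPredicate <- function(D, dis, params = LODParams()) {
  stopifnot(D >= 0, dis >= 0)
  D <= (dis - params@inival) / params@interval
}

#' Select the display list for a camera pose
#'
#' Starting at the root, a node is emitted when it is a leaf or when the
#' LOD predicate holds for its subtree height and its own center's distance
#' to the camera; otherwise both children are visited.  Distances are
#' measured per cluster to its own center (MVEE center in ellipsoid mode,
#' minimal-sphere center in sphere mode), so one frame can mix abstraction
#' bands across the molecule.  Mode "vdw" always emits all leaves.  The
#' emitted nodes' atom sets partition the molecule's atoms.
#'
#' @param tree an annotated \linkS4class{ClusterTree}.
#' @param cameraPosition numeric(3), Angstrom.
#' @param params a \linkS4class{LODParams}.
#' @param mode "ellipsoid", "sphere" or "vdw".
#' @return a \linkS4class{DisplayList}.
#' @export
selectDisplayList <- function(tree, cameraPosition, params = LODParams(),
                              mode = c("ellipsoid", "sphere", "vdw")) {
  mode <- match.arg(mode)
  stopifnot(is(tree, "ClusterTree"), length(cameraPosition) == 3L)
  if (!isAnnotated(tree))
    stop("tree must be annotated (annotateTree) before LOD selection")
  nd <- tree@nodes
  cam <- as.numeric(cameraPosition)

  ids <- integer(0)
  if (mode == "vdw") {
    ids <- which(is.na(nd$child1))
  } else {
    centerOf <- function(id) {
      if (mode == "ellipsoid") tree@mvees[[id]]@center
      else c(nd$ex[id], nd$ey[id], nd$ez[id])
    }
    stack <- tree@rootId
    while (length(stack)) {
      id <- stack[1L]
      stack <- stack[-1L]
      leaf <- is.na(nd$child1[id])
      dis <- sqrt(sum((cam - centerOf(id))^2))
      if (leaf || lodPredicate(nd$height[id], dis, params)) {
        ids <- c(ids, id)
      } else {
        stack <- c(nd$child1[id], nd$child2[id], stack)
      }
    }
  }

  leaf <- is.na(nd$child1[ids])
  kind <- if (mode == "sphere") rep("sphere", length(ids))
          else ifelse(leaf, "sphere", "ellipsoid")
  geometry <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    if (kind[i] == "sphere") {
      if (leaf[i]) {
        m <- tree@members[[id]]
        a <- tree@molecule@atoms
        Sphere(c(a$x[m], a$y[m], a$z[m]), a$radius[m])
      } else Sphere(c(nd$ex[id], nd$ey[id], nd$ez[id]), nd$er[id])
    } else tree@mvees[[id]]
  })
  firstAtom <- vapply(ids, function(id) tree@members[[id]][1L], 1L)
  new("DisplayList",
      entries = data.frame(id = ids, kind = kind, level = nd$level[ids],
                           height = nd$height[ids], stringsAsFactors = FALSE),
      geometry = geometry,
      resKey = tree@molecule@atoms$resKey[firstAtom])
}
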