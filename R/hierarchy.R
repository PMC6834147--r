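## Residue-restricted agglomerative clustering (AFHC) with the volume-based
## distance metric (VDM) and average linkage.
##
## Two-phase agglomeration: atoms merge only with atoms of the same residue
## until every residue is a single cluster; only then do residue clusters
## merge with each other, up to the molecule root.  Dissimilarity between
## two clusters is the unweighted average, over all leaf-atom pairs, of the
## volume of the smallest sphere enclosing the two atoms' vdW spheres
## (maintained with the Lance-Williams average-linkage update).

#' Smallest sphere enclosing two spheres
#'
#' If one sphere contains the other, the larger is returned unchanged;
#' otherwise the enclosing sphere has radius (d + r_a + r_b)/2 with its
#' center on the segment between the two centers.
#'
#' @param a,b \linkS4class{Sphere} objects.
#' @return the minimal enclosing \linkS4class{Sphere}.
#' @export
enclosingSphere <- function(a, b) {
  d <- sqrt(sum((a@center - b@center)^2))
  if (d + b@radius <= a@radius) return(a)
  if (d + a@radius <= b@radius) return(b)
  R <- (d + a@radius + b@radius) / 2
  ## center R - ra along the a->b direction from a's center
  Sphere(a@center + (R - a@radius) / d * (b@center - a@center), R)
}

#' Volume-based distance metric between two spheres
#'
#' The volume (4/3) pi R^3 of the smallest sphere enclosing both inputs.
#' Symmetric, and never smaller than either input's own volume, so merging
#' the pair with minimal VDM keeps the new cluster's bounding volume
#' smallest.
#'
#' @param a,b \linkS4class{Sphere} objects.
#' @return enclosing volume in cubic Angstrom.
#' @export
vdm <- function(a, b) volume(enclosingSphere(a, b))

## radius of the enclosing sphere for coordinate/radius vectors (vectorized
## over b); used to build the full atom-pair VDM matrix
.encRadius <- function(ca, ra, cb, rb) {
  d <- sqrt((ca[1] - cb[, 1])^2 + (ca[2] - cb[, 2])^2 + (ca[3] - cb[, 3])^2)
  R <- (d + ra + rb) / 2
  pmax(R, ra, rb)
}

## n x n matrix of pairwise atom VDM volumes
.atomVDMMatrix <- function(pos, rad) {
  n <- nrow(pos)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    R <- .encRadius(pos[i, ], rad[i], pos, rad)
    M[i, ] <- 4 / 3 * pi * R^3
  }
  M
}

#' Build the residue-restricted cluster tree
#'
#' @param mol a \linkS4class{Molecule}.
#' @param linkage linkage rule; only "average" (UPGMA over leaf-pair VDM)
#'   is supported.
#' @return a \linkS4class{ClusterTree} with 2n-1 nodes for n atoms,
#'   labelled with the five node levels.  Ties in dissimilarity are broken
#'   towards the pair whose (min id, max id) is lexicographically smallest,
#'   so trees are fully deterministic.
#' @export
buildClusterTree <- function(mol, linkage = "average") {
  stopifnot(is(mol, "Molecule"))
  linkage <- match.arg(linkage, "average")
  a <- mol@atoms
  n <- nrow(a)
  pos <- cbind(a$x, a$y, a$z)
  rad <- a$radius

  total <- 2L * n - 1L
  env <- new.env()
  env$child1 <- rep(NA_integer_, total)
  env$child2 <- rep(NA_integer_, total)
  env$height <- integer(total)
  env$level <- rep("ATOM", total)
  env$residueRoot <- logical(total)
  env$sC <- matrix(0, total, 3L)
  env$sR <- numeric(total)
  env$members <- vector("list", total)
  env$sC[seq_len(n), ] <- pos
  env$sR[seq_len(n)] <- rad
  env$members[seq_len(n)] <- as.list(seq_len(n))
  env$nextId <- n + 1L

  M <- .atomVDMMatrix(pos, rad)

  ## phase 1: within-residue agglomeration
  resRoots <- integer(nResidues(mol))
  for (ri in seq_along(mol@residues)) {
    idx <- mol@residues[[ri]]
    root <- .agglomerate(env, ids = idx,
                         D = M[idx, idx, drop = FALSE],
                         sizes = rep(1L, length(idx)),
                         level = "RESIDUE_INTERIOR", topLevel = "RESIDUE")
    env$residueRoot[root] <- TRUE
    resRoots[ri] <- root
  }

  ## phase 2: between-residue agglomeration of the per-residue roots
  if (length(resRoots) > 1L) {
    nr <- length(resRoots)
    D <- matrix(0, nr, nr)
    for (i in seq_len(nr)) {
      mi <- mol@residues[[i]]
      for (j in seq_len(nr)) if (j != i)
        D[i, j] <- mean(M[mi, mol@residues[[j]], drop = FALSE])
    }
    root <- .agglomerate(env, ids = resRoots, D = D,
                         sizes = vapply(mol@residues, length, 1L),
                         level = "RESIDUE_LINK", topLevel = "MOLECULE")
  } else {
    root <- resRoots[1L]
    if (n > 1L) env$level[root] <- "MOLECULE"
  }

  nodes <- data.frame(
    id = seq_len(total), level = env$level,
    child1 = env$child1, child2 = env$child2, height = env$height,
    residueRoot = env$residueRoot,
    cx = env$sC[, 1], cy = env$sC[, 2], cz = env$sC[, 3], cr = env$sR,
    ex = NA_real_, ey = NA_real_, ez = NA_real_, er = NA_real_,
    stringsAsFactors = FALSE)
  new("ClusterTree", nodes = nodes, members = env$members,
      mvees = vector("list", total), rootId = as.integer(root),
      molecule = mol)
}

## Lance-Williams average-linkage agglomeration of the clusters `ids`,
## writing new nodes into env; returns the id of the final cluster.
## Internal merges get `level`; the last merge gets `topLevel`.
.agglomerate <- function(env, ids, D, sizes, level, topLevel) {
  active <- seq_along(ids)
  while (length(active) > 1L) {
    k <- length(active)
    sub <- D[active, active, drop = FALSE]
    sub[!upper.tri(sub)] <- Inf
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      ## deterministic tie-break: lexicographically smallest (min id, max id)
      lo <- pmin(ids[active[cand[, 1]]], ids[active[cand[, 2]]])
      hi <- pmax(ids[active[cand[, 1]]], ids[active[cand[, 2]]])
      cand <- cand[order(lo, hi)[1L], , drop = FALSE]
    }
    i <- active[cand[1, 1]]
    j <- active[cand[1, 2]]

    id <- env$nextId
    env$nextId <- id + 1L
    c1 <- min(ids[i], ids[j])
    c2 <- max(ids[i], ids[j])
    env$child1[id] <- c1
    env$child2[id] <- c2
    env$height[id] <- 1L + max(env$height[c1], env$height[c2])
    env$level[id] <- if (k == 2L) topLevel else level
    env$members[[id]] <- sort(c(env$members[[c1]], env$members[[c2]]))
    s <- enclosingSphere(Sphere(env$sC[c1, ], env$sR[c1]),
                         Sphere(env$sC[c2, ], env$sR[c2]))
    env$sC[id, ] <- s@center
    env$sR[id] <- s@radius

    ## average-linkage update into slot i; drop slot j
    ni <- sizes[i]; nj <- sizes[j]
    upd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- upd
    D[, i] <- upd
    D[i, i] <- 0
    sizes[i] <- ni + nj
    ids[i] <- id
    active <- active[active != j]
  }
  ids[active]
}

#' Subtree height of a node
#'
#' Number of edges on the longest path from the node down to a leaf (the
#' quantity compared against the LOD threshold); 0 for leaves.
#'
#' @param tree a \linkS4class{ClusterTree}.
#' @param id node id.
#' @return integer height.
#' @export
subtreeHeight <- function(tree, id) {
  .checkNodeId(tree, id)
  tree@nodes$height[id]
}
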