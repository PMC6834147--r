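#' @import methods
#' @importFrom stats optim runif
NULL

.NODE_LEVELS <- c("ATOM", "RESIDUE_INTERIOR", "RESIDUE", "RESIDUE_LINK",
                  "MOLECULE")

#' Sphere in 3-space
#'
#' A plain geometric sphere with a center in Angstrom coordinates and a
#' non-negative radius.  Used both for atom van der Waals spheres and for
#' cluster bounding spheres.
#'
#' @slot center numeric(3), Angstrom.
#' @slot radius numeric(1), Angstrom, >= 0.
#' @export
setClass("Sphere", representation(center = "numeric", radius = "numeric"))

setValidity("Sphere", function(object) {
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    return("center must be a finite 3-vector")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius < 0)
    return("radius must be a single finite value >= 0")
  TRUE
})

#' @param center numeric(3) center, Angstrom.
#' @param radius numeric(1) radius, Angstrom.
#' @rdname Sphere-class
#' @export
Sphere <- function(center, radius) {
  new("Sphere", center = as.numeric(center), radius = as.numeric(radius))
}

#' Ellipsoid in axes/semi-axes form
#'
#' An arbitrarily oriented ellipsoid with center \code{c}, orthonormal axis
#' matrix \code{V} (axes as columns) and semi-axis lengths sorted in
#' descending order.  It is equivalent to the quadric
#' \eqn{(x-c)^T A (x-c) = 1} with \eqn{A = V diag(\lambda^{-2}) V^T}
#' positive definite: the eigenvectors of \eqn{A} are the principal axes and
#' its eigenvalues the reciprocal squared semi-axes.
#'
#' @slot center numeric(3), Angstrom.
#' @slot axes 3x3 orthonormal matrix, axis directions as columns.
#' @slot semiAxes numeric(3), positive, descending.
#' @export
setClass("Ellipsoid", representation(center = "numeric", axes = "matrix",
                                     semiAxes = "numeric"))

setValidity("Ellipsoid", function(object) {
  if (length(object@center) != 3L) return("center must be a 3-vector")
  if (!all(dim(object@axes) == c(3L, 3L))) return("axes must be 3x3")
  if (max(abs(crossprod(object@axes) - diag(3))) > 1e-9)
    return("axes must be orthonormal (V'V = I to 1e-9)")
  l <- object@semiAxes
  if (length(l) != 3L || any(!is.finite(l)) || any(l <= 0))
    return("semiAxes must be 3 positive lengths")
  if (is.unsorted(rev(l))) return("semiAxes must be sorted descending")
  TRUE
})

#' @param center numeric(3) center.
#' @param axes 3x3 orthonormal axis matrix (columns).
#' @param semiAxes numeric(3) semi-axis lengths; reordered descending
#'   (with the axis columns) if needed.
#' @rdname Ellipsoid-class
#' @export
Ellipsoid <- function(center, axes = diag(3), semiAxes) {
  semiAxes <- as.numeric(semiAxes)
  ord <- order(semiAxes, decreasing = TRUE)
  new("Ellipsoid", center = as.numeric(center),
      axes = as.matrix(axes)[, ord, drop = FALSE],
      semiAxes = semiAxes[ord])
}

#' Molecule: atoms plus residue partition
#'
#' Container for a set of atoms (positions, elements, van der Waals radii)
#' grouped into residues.  The residue groups always partition the atom
#' index set, and atom order from the source file is preserved.
#'
#' @slot atoms data.frame with one row per atom: \code{element}, \code{x},
#'   \code{y}, \code{z} (Angstrom), \code{radius} (Angstrom), \code{resKey}
#'   (opaque residue identifier) and \code{resName} (3-letter code).
#' @slot residues named list of integer vectors of atom indices (1-based),
#'   one entry per residue in order of first appearance.
#' @export
setClass("Molecule", representation(atoms = "data.frame", residues = "list"))

setValidity("Molecule", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "radius", "resKey", "resName")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("molecule must contain at least one atom")
  if (any(a$radius <= 0)) return("all atom radii must be > 0")
  idx <- sort(unlist(object@residues, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(nrow(a))))
    return("residue groups must partition the atom index set")
  if (any(vapply(object@residues, length, 1L) == 0L))
    return("residue groups must be non-empty")
  TRUE
})

#' Residue-restricted hierarchical cluster tree
#'
#' Complete binary agglomeration tree over a molecule's atoms.  Leaves are
#' single atoms; each internal node merges exactly two children, so a
#' molecule of n atoms yields 2n-1 nodes.  Merging is restricted so that
#' atoms of one residue cluster together before residues merge with each
#' other, which induces the five node levels ATOM, RESIDUE_INTERIOR,
#' RESIDUE, RESIDUE_LINK and MOLECULE.
#'
#' @slot nodes data.frame, one row per node: \code{id}, \code{level},
#'   \code{child1}, \code{child2} (NA for leaves), \code{height} (edges to
#'   the deepest leaf), \code{residueRoot} (logical), clustering bounding
#'   sphere \code{cx}, \code{cy}, \code{cz}, \code{cr}, and (after
#'   \code{annotateTree}) exact minimal enclosing sphere \code{ex},
#'   \code{ey}, \code{ez}, \code{er}.
#' @slot members list of integer vectors: atom indices under each node.
#' @slot mvees list of \linkS4class{Ellipsoid} (or NULL before annotation).
#' @slot rootId integer id of the root node.
#' @slot molecule the \linkS4class{Molecule} the tree was built over.
#' @export
setClass("ClusterTree",
         representation(nodes = "data.frame", members = "list",
                        mvees = "list", rootId = "integer",
                        molecule = "Molecule"))

setValidity("ClusterTree", function(object) {
  nd <- object@nodes
  n <- sum(nd$level == "ATOM" & is.na(nd$child1))
  if (nrow(nd) != 2L * n - 1L)
    return(sprintf("tree must have 2n-1 nodes (n=%d leaves, %d nodes)",
                   n, nrow(nd)))
  if (!all(nd$level %in% .NODE_LEVELS))
    return("unknown node level")
  leaf <- is.na(nd$child1)
  if (!all(leaf == (nd$height == 0L)))
    return("leaves must be exactly the height-0 nodes")
  if (!all(leaf == (vapply(object@members, length, 1L) == 1L)))
    return("leaves must be exactly the single-atom nodes")
  TRUE
})

#' Level-of-detail selection parameters
#'
#' Distance thresholds of the LOD predicate: a node of subtree height D is
#' abstract enough for a camera at distance dis from its center when
#' \code{D <= (dis - inival) / interval}.  \code{inival} is the camera
#' distance at which simplification begins; \code{interval} is the depth
#' extent of each abstraction band.
#'
#' @slot inival numeric(1), Angstrom.
#' @slot interval numeric(1), Angstrom, > 0.
#' @export
setClass("LODParams", representation(inival = "numeric", interval = "numeric"),
         prototype(inival = 100, interval = 20))

setValidity("LODParams", function(object) {
  if (length(object@interval) != 1L || object@interval <= 0)
    return("interval must be a single value > 0")
  if (length(object@inival) != 1L || !is.finite(object@inival))
    return("inival must be a single finite value")
  TRUE
})

#' @param inival numeric(1) distance at which simplification begins, Angstrom.
#' @param interval numeric(1) band width, Angstrom (> 0).
#' @rdname LODParams-class
#' @export
LODParams <- function(inival = 100, interval = 20) {
  new("LODParams", inival = as.numeric(inival), interval = as.numeric(interval))
}

#' Surface sampling / MVEE solver configuration
#'
#' @slot pointsPerSurface integer, samples per sphere or ellipsoid surface
#'   (Fibonacci lattice), >= 4.
#' @slot tolerance numeric, relative tolerance epsilon of the Khachiyan-type
#'   MVEE solver; points are guaranteed inside the (1+epsilon)-inflated
#'   ellipsoid.
#' @slot maxIterations integer, iteration cap of the MVEE solver.
#' @export
setClass("SamplingConfig",
         representation(pointsPerSurface = "integer", tolerance = "numeric",
                        maxIterations = "integer"),
         prototype(pointsPerSurface = 32L, tolerance = 1e-3,
                   maxIterations = 10000L))

setValidity("SamplingConfig", function(object) {
  if (object@pointsPerSurface < 4L) return("pointsPerSurface must be >= 4")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  TRUE
})

#' @param pointsPerSurface samples per surface (>= 4).
#' @param tolerance MVEE solver tolerance epsilon (> 0).
#' @param maxIterations MVEE solver iteration cap.
#' @rdname SamplingConfig-class
#' @export
SamplingConfig <- function(pointsPerSurface = 32L, tolerance = 1e-3,
                           maxIterations = 10000L) {
  new("SamplingConfig", pointsPerSurface = as.integer(pointsPerSurface),
      tolerance = as.numeric(tolerance),
      maxIterations = as.integer(maxIterations))
}

#' Display list: the LOD frontier for one camera pose
#'
#' The set of tree nodes selected by the top-down LOD traversal.  The atom
#' sets of the listed nodes always partition the molecule's atoms.
#'
#' @slot entries data.frame: \code{id} (node id), \code{kind}
#'   ("sphere"/"ellipsoid"), \code{level}, \code{height}.
#' @slot geometry list of \linkS4class{Sphere} / \linkS4class{Ellipsoid}
#'   glyphs, parallel to \code{entries}.
#' @slot resKey character, residue key of each entry's first atom (for
#'   per-residue coloring).
#' @export
setClass("DisplayList",
         representation(entries = "data.frame", geometry = "list",
                        resKey = "character"))

#' Pinhole camera
#'
#' Right-handed pinhole camera; pixel (0,0) is top-left and rays pass
#' through pixel centers.
#'
#' @slot position numeric(3), Angstrom.
#' @slot target numeric(3), look-at point.
#' @slot up numeric(3), up hint (not parallel to the view direction).
#' @slot fov numeric(1), vertical field of view, degrees, in (0, 180).
#' @slot width,height integer image size in pixels, >= 1.
#' @export
setClass("Camera",
         representation(position = "numeric", target = "numeric",
                        up = "numeric", fov = "numeric", width = "integer",
                        height = "integer"),
         prototype(up = c(0, 1, 0), fov = 45, width = 512L, height = 512L))

setValidity("Camera", function(object) {
  if (object@fov <= 0 || object@fov >= 180)
    return("fov must be in (0, 180) degrees")
  if (object@width < 1L || object@height < 1L)
    return("width and height must be >= 1")
  f <- object@target - object@position
  if (sqrt(sum(f^2)) == 0) return("target must differ from position")
  f <- f / sqrt(sum(f^2))
  u <- object@up / sqrt(sum(object@up^2))
  if (1 - abs(sum(f * u)) < 1e-9)
    return("up must not be parallel to the view direction")
  TRUE
})

#' @param position,target,up camera pose vectors.
#' @param fov vertical field of view in degrees.
#' @param width,height image size in pixels.
#' @rdname Camera-class
#' @export
Camera <- function(position, target = c(0, 0, 0), up = c(0, 1, 0), fov = 45,
                   width = 512L, height = 512L) {
  new("Camera", position = as.numeric(position), target = as.numeric(target),
      up = as.numeric(up), fov = as.numeric(fov), width = as.integer(width),
      height = as.integer(height))
}

#' Renderer settings
#'
#' @slot shading "diffuse" (Lambert with ambient floor 0.2) or "constant"
#'   (flat albedo).
#' @slot contours logical, draw depth-dependent silhouettes.
#' @slot ssao logical, apply screen-space ambient occlusion.
#' @slot lightDirection numeric(3) unit vector pointing towards the light;
#'   NA means headlight (light along the view direction).
#' @slot ssaoSamples integer, hemisphere samples per pixel.
#' @slot ssaoRadius numeric, sampling radius, Angstrom.
#' @slot ssaoSeed integer, seed of the deterministic sample sequence.
#' @slot silhouetteThreshold numeric > 0, base depth-difference threshold,
#'   Angstrom.
#' @slot silhouetteDepthScale numeric >= 0, per-Angstrom growth of the
#'   silhouette threshold with depth.
#' @slot background numeric(3) RGB in [0,1].
#' @slot colorMode "level" (palette by node level) or "residue".
#' @export
setClass("RenderSettings",
         representation(shading = "character", contours = "logical",
                        ssao = "logical", lightDirection = "numeric",
                        ssaoSamples = "integer", ssaoRadius = "numeric",
                        ssaoSeed = "integer", silhouetteThreshold = "numeric",
                        silhouetteDepthScale = "numeric",
                        background = "numeric", colorMode = "character"),
         prototype(shading = "diffuse", contours = FALSE, ssao = FALSE,
                   lightDirection = c(NA_real_, NA_real_, NA_real_),
                   ssaoSamples = 16L, ssaoRadius = 3, ssaoSeed = 7L,
                   silhouetteThreshold = 1.0, silhouetteDepthScale = 0.01,
                   background = c(1, 1, 1), colorMode = "level"))

setValidity("RenderSettings", function(object) {
  if (!object@shading %in% c("diffuse", "constant"))
    return("shading must be 'diffuse' or 'constant'")
  if (object@ssao && object@ssaoSamples < 1L)
    return("ssaoSamples must be >= 1 when ssao is on")
  if (object@silhouetteThreshold <= 0)
    return("silhouetteThreshold must be > 0")
  if (object@silhouetteDepthScale < 0)
    return("silhouetteDepthScale must be >= 0")
  if (!object@colorMode %in% c("level", "residue"))
    return("colorMode must be 'level' or 'residue'")
  TRUE
})

#' @param ... slot values overriding the defaults (see slot documentation).
#' @rdname RenderSettings-class
#' @export
RenderSettings <- function(...) {
  args <- list(...)
  for (nm in c("ssaoSamples", "ssaoSeed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("RenderSettings"), args))
}

#' Frame buffer produced by the ray caster
#'
#' @slot color height x width x 3 RGB array in [0,1].
#' @slot depth height x width matrix of eye-space hit distances t
#'   (Angstrom); Inf at background pixels.
#' @slot normal height x width x 3 array of unit surface normals
#'   (undefined, zero, at background).
#' @slot position height x width x 3 array of world-space hit points.
#' @slot node height x width matrix of display-list entry indices (0 at
#'   background).
#' @export
setClass("FrameBuffer",
         representation(color = "array", depth = "matrix", normal = "array",
                        position = "array", node = "matrix"))

#' Van der Waals radii lookup table
#'
#' @slot radii named numeric, element symbol to radius (Angstrom), all > 0.
#' @slot default numeric(1), fallback radius for unknown elements.
#' @export
setClass("RadiiTable",
         representation(radii = "numeric", default = "numeric"))

setValidity("RadiiTable", function(object) {
  if (any(object@radii <= 0) || object@default <= 0)
    return("all radii must be > 0")
  if (is.null(names(object@radii))) return("radii must be named by element")
  TRUE
})
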