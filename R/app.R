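## Serialization, configuration and the command-line front end.

.TREE_FORMAT_VERSION <- 1L

#' Serialize a cluster tree to JSON
#'
#' Versioned, human-inspectable JSON holding the molecule's atoms and every
#' node (level, children, members, bounding spheres, MVEE as center + axes
#' + semi-axes).  Geometry is stored in axes/semi-axes form rather than as
#' the quadric matrix so reloading does not redo an eigendecomposition.
#'
#' @param tree a \linkS4class{ClusterTree} (annotated or not).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeClusterTree <- function(tree, path) {
  stopifnot(is(tree, "ClusterTree"))
  a <- tree@molecule@atoms
  nd <- tree@nodes
  annotated <- isAnnotated(tree)
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    rec <- list(
      id = nd$id[i], level = nd$level[i],
      children = if (is.na(nd$child1[i])) integer(0)
                 else c(nd$child1[i], nd$child2[i]),
      height = nd$height[i], residueRoot = nd$residueRoot[i],
      members = tree@members[[i]],
      clusterSphere = list(center = c(nd$cx[i], nd$cy[i], nd$cz[i]),
                           radius = nd$cr[i]))
    if (annotated) {
      e <- tree@mvees[[i]]
      rec$minSphere <- list(center = c(nd$ex[i], nd$ey[i], nd$ez[i]),
                            radius = nd$er[i])
      rec$mvee <- list(center = e@center, axes = as.vector(e@axes),
                       semiAxes = e@semiAxes)
    }
    rec
  })
  doc <- list(
    format = "EllipsoidLOD-tree", version = .TREE_FORMAT_VERSION,
    rootId = tree@rootId,
    atoms = list(element = a$element, x = a$x, y = a$y, z = a$z,
                 radius = a$radius, resKey = a$resKey, resName = a$resName),
    nodes = nodes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a serialized cluster tree
#'
#' @param path path to a JSON file written by \code{writeClusterTree}.
#' @return a \linkS4class{ClusterTree}.
#' @export
readClusterTree <- function(path) {
  if (!file.exists(path)) stop("cannot read tree file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "EllipsoidLOD-tree"))
    stop("not an EllipsoidLOD tree file: ", path)
  if (doc$version > .TREE_FORMAT_VERSION)
    stop("unsupported tree format version: ", doc$version)
  at <- doc$atoms
  atoms <- data.frame(
    element = unlist(at$element), x = unlist(at$x), y = unlist(at$y),
    z = unlist(at$z), radius = unlist(at$radius),
    resKey = unlist(at$resKey), resName = unlist(at$resName),
    stringsAsFactors = FALSE)
  mol <- .newMolecule(atoms)
  total <- length(doc$nodes)
  nd <- data.frame(
    id = integer(total), level = character(total),
    child1 = NA_integer_, child2 = NA_integer_, height = integer(total),
    residueRoot = logical(total), cx = 0, cy = 0, cz = 0, cr = 0,
    ex = NA_real_, ey = NA_real_, ez = NA_real_, er = NA_real_,
    stringsAsFactors = FALSE)
  members <- vector("list", total)
  mvees <- vector("list", total)
  for (rec in doc$nodes) {
    i <- rec$id
    nd$id[i] <- as.integer(i)
    nd$level[i] <- rec$level
    if (length(rec$children)) {
      nd$child1[i] <- as.integer(rec$children[[1]])
      nd$child2[i] <- as.integer(rec$children[[2]])
    }
    nd$height[i] <- as.integer(rec$height)
    nd$residueRoot[i] <- isTRUE(rec$residueRoot)
    members[[i]] <- as.integer(unlist(rec$members))
    cs <- rec$clusterSphere
    nd[i, c("cx", "cy", "cz")] <- unlist(cs$center)
    nd$cr[i] <- cs$radius
    if (!is.null(rec$mvee)) {
      nd[i, c("ex", "ey", "ez")] <- unlist(rec$minSphere$center)
      nd$er[i] <- rec$minSphere$radius
      mvees[[i]] <- new("Ellipsoid",
                        center = unlist(rec$mvee$center),
                        axes = matrix(unlist(rec$mvee$axes), 3L, 3L),
                        semiAxes = unlist(rec$mvee$semiAxes))
    }
  }
  new("ClusterTree", nodes = nd, members = members, mvees = mvees,
      rootId = as.integer(doc$rootId), molecule = mol)
}

#' Export a display list as plain text
#'
#' One line per entry: node id, glyph kind, center, then geometry (radius
#' for spheres; semi-axes and axis columns for ellipsoids), full precision.
#'
#' @param dl a \linkS4class{DisplayList}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDisplayList <- function(dl, path) {
  stopifnot(is(dl, "DisplayList"))
  num <- function(x) paste(sprintf("%.9g", x), collapse = " ")
  lines <- vapply(seq_len(nrow(dl@entries)), function(i) {
    g <- dl@geometry[[i]]
    if (is(g, "Sphere"))
      sprintf("%d sphere %s %s", dl@entries$id[i], num(g@center),
              num(g@radius))
    else
      sprintf("%d ellipsoid %s %s %s", dl@entries$id[i], num(g@center),
              num(g@semiAxes), num(as.vector(g@axes)))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' TOML-style \code{key = value} lines; '#' starts a comment.  Values:
#' numbers, true/false, comma-separated numeric vectors, or bare strings.
#'
#' @param path config file path.
#' @return named list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- .parseConfigValue(val)
  }
  out
}

.parseConfigValue <- function(val) {
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  nums <- suppressWarnings(as.numeric(parts))
  if (length(parts) >= 1L && !any(is.na(nums))) {
    if (length(nums) == 1L) return(nums)
    return(nums)
  }
  val
}

## assemble Camera / RenderSettings / LODParams / mode from a config list
.configScene <- function(cfg) {
  gv <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  camera <- Camera(
    position = gv("camera.position", c(0, 0, 100)),
    target = gv("camera.target", c(0, 0, 0)),
    up = gv("camera.up", c(0, 1, 0)),
    fov = gv("camera.fov", 45),
    width = gv("image.width", 512), height = gv("image.height", 512))
  light <- gv("render.light_direction", c(NA_real_, NA_real_, NA_real_))
  settings <- RenderSettings(
    shading = gv("render.shading", "diffuse"),
    contours = isTRUE(gv("render.contours", FALSE)),
    ssao = isTRUE(gv("render.ssao", FALSE)),
    lightDirection = light,
    ssaoSamples = gv("ssao.samples", 16),
    ssaoRadius = gv("ssao.radius", 3),
    ssaoSeed = gv("ssao.seed", 7),
    silhouetteThreshold = gv("silhouette.threshold", 1.0),
    silhouetteDepthScale = gv("silhouette.depth_scale", 0.01),
    background = gv("render.background", c(1, 1, 1)),
    colorMode = gv("render.color_mode", "level"))
  params <- LODParams(inival = gv("lod.inival", 100),
                      interval = gv("lod.interval", 20))
  list(camera = camera, settings = settings, params = params,
       mode = gv("lod.mode", "ellipsoid"))
}

## ------------------------------------------------------------------------
## CLI

.USAGE <- paste(
  "usage: ellipsoidlod <command> [options]",
  "",
  "commands:",
  "  build   --pdb FILE | --synthetic R,A,SEED [--hetero] [--k N]",
  "          [--eps E] --out TREE.json",
  "  select  --tree TREE.json --camera X,Y,Z [--inival F] [--interval F]",
  "          [--mode ellipsoid|sphere|vdw] --out LIST.txt",
  "  render  --tree TREE.json --config FILE.cfg --out IMG.png|IMG.ppm",
  "  stats   --tree TREE.json",
  "",
  "Global: --help prints this message.", sep = "\n")

.parseArgs <- function(args, flags, switches = character(0)) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    key <- sub("^--", "", a)
    if (!startsWith(a, "--")) stop("usage: unexpected argument: ", a)
    if (key %in% switches) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else if (key %in% flags) {
      if (i == length(args)) stop("usage: missing value for --", key)
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else stop("usage: unknown option --", key)
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: \code{build} (PDB or synthetic molecule to an annotated
#' serialized tree), \code{select} (tree + camera to a display-list text
#' file), \code{render} (tree + config to a PNG/PPM image) and \code{stats}
#' (node counts per level and the sphere-vs-ellipsoid total bounding-volume
#' comparison).  Log lines go to standard error with timestamps.
#'
#' @param args character vector of command-line arguments (default: the
#'   actual command line).
#' @return integer exit code: 0 success, 1 runtime/input error, 2 usage
#'   error.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[[1L]] %in% c("--help", "-h", "help")) {
    cat(.USAGE, "\n")
    return(invisible(0L))
  }
  cmd <- args[[1L]]
  rest <- args[-1L]
  if ("--help" %in% rest) {
    cat(.USAGE, "\n")
    return(invisible(0L))
  }
  handler <- switch(cmd,
                    build = .cmdBuild, select = .cmdSelect,
                    render = .cmdRender, stats = .cmdStats, NULL)
  if (is.null(handler)) {
    .log("ERROR", paste("unknown command:", cmd))
    cat(.USAGE, "\n")
    return(invisible(2L))
  }
  code <- tryCatch({
    handler(rest)
    0L
  }, error = function(e) {
    .log("ERROR", conditionMessage(e))
    if (grepl("^usage:", conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}

.cmdBuild <- function(args) {
  o <- .parseArgs(args, flags = c("pdb", "synthetic", "out", "k", "eps"),
                  switches = "hetero")
  if (is.null(o$out)) stop("usage: build requires --out")
  cfg <- SamplingConfig(
    pointsPerSurface = if (is.null(o$k)) 32L else as.integer(o$k),
    tolerance = if (is.null(o$eps)) 1e-3 else as.numeric(o$eps))
  mol <- if (!is.null(o$pdb)) {
    .log("INFO", paste("reading PDB", o$pdb))
    readPDB(o$pdb, includeHetero = isTRUE(o$hetero))
  } else if (!is.null(o$synthetic)) {
    spec <- as.integer(strsplit(o$synthetic, ",")[[1]])
    if (length(spec) != 3L || any(is.na(spec)))
      stop("usage: --synthetic expects R,A,SEED")
    generateSyntheticMolecule(spec[1], spec[2], spec[3])
  } else stop("usage: build requires --pdb or --synthetic")
  .log("INFO", sprintf("building tree over %d atoms in %d residues",
                       nAtoms(mol), nResidues(mol)))
  tree <- annotateTree(buildClusterTree(mol), cfg)
  writeClusterTree(tree, o$out)
  .log("INFO", paste("wrote", o$out))
}

.cmdSelect <- function(args) {
  o <- .parseArgs(args, flags = c("tree", "camera", "inival", "interval",
                                  "mode", "out"))
  if (is.null(o$tree) || is.null(o$camera) || is.null(o$out))
    stop("usage: select requires --tree, --camera and --out")
  tree <- readClusterTree(o$tree)
  cam <- as.numeric(strsplit(o$camera, ",")[[1]])
  if (length(cam) != 3L || any(is.na(cam)))
    stop("usage: --camera expects X,Y,Z")
  params <- LODParams(
    inival = if (is.null(o$inival)) 100 else as.numeric(o$inival),
    interval = if (is.null(o$interval)) 20 else as.numeric(o$interval))
  mode <- if (is.null(o$mode)) "ellipsoid" else o$mode
  dl <- selectDisplayList(tree, cam, params, mode)
  writeDisplayList(dl, o$out)
  .log("INFO", sprintf("display list: %d glyphs -> %s",
                       nrow(displayEntries(dl)), o$out))
}

.cmdRender <- function(args) {
  o <- .parseArgs(args, flags = c("tree", "config", "out"))
  if (is.null(o$tree) || is.null(o$out))
    stop("usage: render requires --tree and --out")
  tree <- readClusterTree(o$tree)
  cfg <- if (is.null(o$config)) list() else readConfig(o$config)
  sc <- .configScene(cfg)
  dl <- selectDisplayList(tree, sc$camera@position, sc$params, sc$mode)
  .log("INFO", sprintf("rendering %d glyphs at %dx%d",
                       nrow(displayEntries(dl)), sc$camera@width,
                       sc$camera@height))
  fb <- renderFrame(dl, sc$camera, sc$settings)
  img <- compositeFrame(fb, sc$camera, sc$settings)
  writeImage(img, o$out)
  .log("INFO", paste("wrote", o$out))
}

.cmdStats <- function(args) {
  o <- .parseArgs(args, flags = "tree")
  if (is.null(o$tree)) stop("usage: stats requires --tree")
  tree <- readClusterTree(o$tree)
  nd <- nodeData(tree)
  cat(sprintf("nodes: %d (atoms: %d)\n", nNodes(tree),
              nAtoms(molecule(tree))))
  tb <- table(factor(nd$level, levels = .NODE_LEVELS))
  for (lv in names(tb)) cat(sprintf("%-17s %d\n", lv, tb[[lv]]))
  if (isAnnotated(tree)) {
    internal <- which(!is.na(nd$child1))
    sphereVol <- sum(4 / 3 * pi * nd$er[internal]^3)
    mveeVol <- sum(vapply(internal, function(i) volume(tree@mvees[[i]]),
                          numeric(1)))
    cat(sprintf("total internal-node bounding volume (A^3):\n"))
    cat(sprintf("  minimal spheres: %.3f\n", sphereVol))
    cat(sprintf("  MVEEs:           %.3f\n", mveeVol))
    cat(sprintf("  ellipsoid/sphere ratio: %.4f\n", mveeVol / sphereVol))
  }
}
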