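## CPU glyph ray caster.  Spheres and ellipsoids are rendered as implicit
## surfaces by per-pixel ray-quadric intersection; ellipsoid rays are
## transformed into glyph space (translate by -c, rotate by V') where the
## quadric is axis-aligned, and the glyph-space normal (x/a^2, y/b^2,
## z/c^2) is rotated back.  A concentric agent sphere of radius equal to
## the longest semi-axis bounds each glyph; its conservative screen-space
## rectangle restricts the per-glyph pixel loop.  The depth buffer stores
## the eye-space ray parameter t in Angstrom.

#' Ray with unit direction
#'
#' @slot origin numeric(3).
#' @slot direction numeric(3), unit length.
#' @export
setClass("Ray", representation(origin = "numeric", direction = "numeric"))

setValidity("Ray", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-12)
    return("direction must be unit length")
  TRUE
})

#' @param origin numeric(3) ray origin.
#' @param direction numeric(3) direction (normalized by the constructor).
#' @rdname Ray-class
#' @export
Ray <- function(origin, direction) {
  direction <- as.numeric(direction)
  new("Ray", origin = as.numeric(origin),
      direction = direction / sqrt(sum(direction^2)))
}

## orthonormal camera frame + pixel size on the unit-distance image plane
.cameraBasis <- function(camera) {
  f <- camera@target - camera@position
  f <- f / sqrt(sum(f^2))
  r <- .cross3(f, camera@up)
  r <- r / sqrt(sum(r^2))
  u <- .cross3(r, f)
  list(f = f, right = r, up = u,
       pixSize = 2 * tan(camera@fov / 2 * pi / 180) / camera@height)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Primary ray through a pixel center
#'
#' Right-handed pinhole camera; pixel (0,0) is the top-left corner, x grows
#' to the right and y downwards, and the ray passes through the pixel
#' center.
#'
#' @param camera a \linkS4class{Camera}.
#' @param px,py 0-based pixel column / row.
#' @return a \linkS4class{Ray}.
#' @export
generateRay <- function(camera, px, py) {
  if (px < 0 || px >= camera@width || py < 0 || py >= camera@height)
    stop("pixel out of range: (", px, ", ", py, ")")
  b <- .cameraBasis(camera)
  xi <- (px + 0.5 - camera@width / 2) * b$pixSize
  yi <- (camera@height / 2 - (py + 0.5)) * b$pixSize
  Ray(camera@position, b$f + xi * b$right + yi * b$up)
}

## direction matrix (m x 3, unnormalized length recorded) for 0-based pixel
## coordinate vectors
.pixelDirs <- function(camera, b, px, py) {
  xi <- (px + 0.5 - camera@width / 2) * b$pixSize
  yi <- (camera@height / 2 - (py + 0.5)) * b$pixSize
  d <- cbind(b$f[1] + xi * b$right[1] + yi * b$up[1],
             b$f[2] + xi * b$right[2] + yi * b$up[2],
             b$f[3] + xi * b$right[3] + yi * b$up[3])
  d / sqrt(rowSums(d^2))
}

#' Ray-sphere intersection
#'
#' Smallest positive root of the quadratic; the normal is the outward
#' radial direction at the hit point (also when the origin is inside).
#'
#' @param ray a \linkS4class{Ray}.
#' @param s a \linkS4class{Sphere}.
#' @return a hit as \code{list(t, point, normal)}, or NULL on miss.
#' @export
raySphereIntersect <- function(ray, s) {
  o <- ray@origin - s@center
  b <- 2 * sum(ray@direction * o)
  cc <- sum(o^2) - s@radius^2
  disc <- b^2 - 4 * cc
  if (disc < 0) return(NULL)
  sq <- sqrt(disc)
  t <- (-b - sq) / 2
  if (t <= 0) t <- (-b + sq) / 2
  if (t <= 0) return(NULL)
  p <- ray@origin + t * ray@direction
  list(t = t, point = p, normal = (p - s@center) / s@radius)
}

#' Ray-ellipsoid intersection in glyph space
#'
#' The ray is translated by -c and rotated by V' into glyph space, where
#' the ellipsoid is the canonical quadric x^2/a^2 + y^2/b^2 + z^2/c^2 = 1;
#' the quadratic is solved there and the glyph-space normal is rotated
#' back.  Because the rotation preserves lengths, the ray parameter t is
#' identical in both spaces, giving the correct eye-space depth.
#'
#' @param ray a \linkS4class{Ray}.
#' @param e an \linkS4class{Ellipsoid}.
#' @return a hit as \code{list(t, point, normal)}, or NULL on miss.
#' @export
rayEllipsoidIntersect <- function(ray, e) {
  Vt <- t(e@axes)
  o <- drop(Vt %*% (ray@origin - e@center))
  d <- drop(Vt %*% ray@direction)
  inv <- 1 / e@semiAxes
  os <- o * inv
  ds <- d * inv
  a <- sum(ds^2)
  b <- 2 * sum(os * ds)
  cc <- sum(os^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NULL)
  sq <- sqrt(disc)
  t <- (-b - sq) / (2 * a)
  if (t <= 0) t <- (-b + sq) / (2 * a)
  if (t <= 0) return(NULL)
  pg <- o + t * d                        # glyph-space hit
  ng <- pg * inv^2                       # glyph-space normal
  nw <- drop(e@axes %*% ng)
  nw <- nw / sqrt(sum(nw^2))
  list(t = t, point = ray@origin + t * ray@direction, normal = nw)
}

#' Conservative screen-space bound of a glyph's agent sphere
#'
#' Bounds the projection of the concentric sphere of radius \code{lmax}
#' (the longest semi-axis) around the glyph center: every pixel whose ray
#' can hit the glyph lies inside the returned rectangle.  Returns NULL for
#' glyphs fully behind the camera and the full frame when the agent sphere
#' reaches behind the image plane.
#'
#' @param center numeric(3) glyph center.
#' @param lmax agent sphere radius (> 0), Angstrom.
#' @param camera a \linkS4class{Camera}.
#' @return \code{list(x0, x1, y0, y1)} of inclusive 0-based pixel bounds,
#'   or NULL when the glyph cannot appear on screen.
#' @export
screenBound <- function(center, lmax, camera) {
  stopifnot(lmax > 0)
  b <- .cameraBasis(camera)
  v <- as.numeric(center) - camera@position
  zf <- sum(b$f * v)
  if (zf + lmax <= 0) return(NULL)       # fully behind the camera
  w <- camera@width; h <- camera@height
  if (zf - lmax <= 0)                    # straddles the image plane
    return(list(x0 = 0L, x1 = w - 1L, y0 = 0L, y1 = h - 1L))
  xr <- sum(b$right * v)
  yu <- sum(b$up * v)
  den <- c(zf - lmax, zf + lmax)
  qx <- c((xr - lmax) / den, (xr + lmax) / den)
  qy <- c((yu - lmax) / den, (yu + lmax) / den)
  s <- b$pixSize
  x0 <- floor(min(qx) / s + w / 2 - 0.5) - 1
  x1 <- ceiling(max(qx) / s + w / 2 - 0.5) + 1
  y0 <- floor(h / 2 - max(qy) / s - 0.5) - 1
  y1 <- ceiling(h / 2 - min(qy) / s - 0.5) + 1
  x0 <- max(0L, as.integer(x0)); x1 <- min(w - 1L, as.integer(x1))
  y0 <- max(0L, as.integer(y0)); y1 <- min(h - 1L, as.integer(y1))
  if (x0 > x1 || y0 > y1) return(NULL)
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

## vectorized glyph intersection for a matrix of unit directions from a
## common origin; returns t (NA on miss) and normals
.intersectGrid <- function(origin, dirs, geom) {
  if (is(geom, "Sphere")) {
    V <- diag(3); inv <- rep(1 / geom@radius, 3L); ctr <- geom@center
  } else {
    V <- geom@axes; inv <- 1 / geom@semiAxes; ctr <- geom@center
  }
  o <- drop(crossprod(V, origin - ctr)) * inv
  D <- dirs %*% V
  D <- sweep(D, 2L, inv, `*`)
  a <- rowSums(D^2)
  bq <- 2 * (D[, 1] * o[1] + D[, 2] * o[2] + D[, 3] * o[3])
  cc <- sum(o^2) - 1
  disc <- bq^2 - 4 * a * cc
  hit <- disc >= 0
  t <- rep(NA_real_, nrow(dirs))
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-bq - sq) / (2 * a)
  t2 <- (-bq + sq) / (2 * a)
  tt <- ifelse(t1 > 0, t1, t2)
  t[hit & tt > 0] <- tt[hit & tt > 0]
  ok <- !is.na(t)
  N <- matrix(NA_real_, nrow(dirs), 3L)
  if (any(ok)) {
    pg <- sweep(D[ok, , drop = FALSE], 1L, t[ok], `*`)
    pg <- sweep(pg, 2L, o, `+`)          # glyph-space (scaled) hit
    ng <- sweep(pg, 2L, inv, `*`)        # normal in glyph space
    nw <- ng %*% t(V)
    nw <- nw / sqrt(rowSums(nw^2))
    N[ok, ] <- nw
  }
  list(t = t, normal = N)
}

#' Lambert shading with ambient floor
#'
#' \code{albedo * (0.2 + 0.8 * max(0, n . l))}, clamped to [0, 1];
#' back-facing normals receive the ambient floor only.
#'
#' @param normal unit surface normal (or m x 3 matrix).
#' @param light unit vector towards the light.
#' @param albedo RGB in [0, 1] (or m x 3 matrix).
#' @return RGB (same shape as albedo).
#' @export
shadeDiffuse <- function(normal, light, albedo) {
  ambient <- 0.2
  if (is.matrix(normal)) {
    ndl <- pmax(0, normal %*% as.numeric(light))
    out <- albedo * drop(ambient + (1 - ambient) * ndl)
  } else {
    ndl <- max(0, sum(normal * light))
    out <- albedo * (ambient + (1 - ambient) * ndl)
  }
  pmin(pmax(out, 0), 1)
}

.LEVEL_PALETTE <- rbind(
  ATOM             = c(0.55, 0.60, 0.75),
  RESIDUE_INTERIOR = c(0.40, 0.65, 0.45),
  RESIDUE          = c(0.85, 0.65, 0.25),
  RESIDUE_LINK     = c(0.70, 0.40, 0.55),
  MOLECULE         = c(0.45, 0.45, 0.80))

.RESIDUE_PALETTE <- rbind(
  c(0.894, 0.102, 0.110), c(0.216, 0.494, 0.722), c(0.302, 0.686, 0.290),
  c(0.596, 0.306, 0.639), c(1.000, 0.498, 0.000), c(0.651, 0.337, 0.157),
  c(0.969, 0.506, 0.749), c(0.400, 0.761, 0.647), c(0.988, 0.553, 0.384),
  c(0.553, 0.627, 0.796), c(0.906, 0.541, 0.765), c(0.651, 0.847, 0.329),
  c(1.000, 0.851, 0.184), c(0.898, 0.769, 0.580), c(0.702, 0.702, 0.702),
  c(0.122, 0.471, 0.706), c(0.682, 0.780, 0.910), c(0.200, 0.628, 0.173),
  c(0.698, 0.875, 0.541), c(0.984, 0.604, 0.600))

## per-entry albedo for a display list
.entryAlbedo <- function(dl, settings) {
  if (settings@colorMode == "residue") {
    idx <- (match(dl@resKey, unique(dl@resKey)) - 1L) %%
      nrow(.RESIDUE_PALETTE) + 1L
    .RESIDUE_PALETTE[idx, , drop = FALSE]
  } else {
    .LEVEL_PALETTE[dl@entries$level, , drop = FALSE]
  }
}

#' Render a display list into a frame buffer
#'
#' For each glyph, only the pixels inside its conservative screen bound are
#' ray-tested; the nearest hit per pixel wins the depth test.  Shading
#' (diffuse or constant) is applied at the surviving hit; depth (eye-space
#' t), world-space hit point and unit normal are stored per pixel,
#' background pixels keep the background color and depth Inf.
#'
#' @param dl a \linkS4class{DisplayList}.
#' @param camera a \linkS4class{Camera}.
#' @param settings a \linkS4class{RenderSettings}.
#' @return a \linkS4class{FrameBuffer}.
#' @export
renderFrame <- function(dl, camera, settings = RenderSettings()) {
  stopifnot(is(dl, "DisplayList"), is(camera, "Camera"))
  w <- camera@width; h <- camera@height
  b <- .cameraBasis(camera)
  depth <- matrix(Inf, h, w)
  node <- matrix(0L, h, w)
  normal <- array(0, c(h, w, 3L))
  position <- array(0, c(h, w, 3L))
  color <- array(rep(settings@background, each = h * w), c(h, w, 3L))

  for (ei in seq_along(dl@geometry)) {
    geom <- dl@geometry[[ei]]
    if (is(geom, "Sphere")) { ctr <- geom@center; lmax <- geom@radius }
    else { ctr <- geom@center; lmax <- geom@semiAxes[1L] }
    rect <- screenBound(ctr, lmax, camera)
    if (is.null(rect)) next
    px <- rep(rect$x0:rect$x1, times = rect$y1 - rect$y0 + 1L)
    py <- rep(rect$y0:rect$y1, each = rect$x1 - rect$x0 + 1L)
    dirs <- .pixelDirs(camera, b, px, py)
    res <- .intersectGrid(camera@position, dirs, geom)
    ok <- which(!is.na(res$t))
    if (!length(ok)) next
    lin <- (py[ok] + 1L) + (px[ok]) * h   # [row, col] linear index
    closer <- res$t[ok] < depth[lin]
    ok <- ok[closer]; lin <- lin[closer]
    if (!length(ok)) next
    depth[lin] <- res$t[ok]
    node[lin] <- ei
    pts <- sweep(dirs[ok, , drop = FALSE] * res$t[ok], 2L, camera@position, `+`)
    nsz <- h * w
    for (ch in 1:3) {
      normal[lin + (ch - 1L) * nsz] <- res$normal[ok, ch]
      position[lin + (ch - 1L) * nsz] <- pts[, ch]
    }
  }

  ## shading pass
  albedo <- .entryAlbedo(dl, settings)
  fg <- which(node > 0L)
  if (length(fg)) {
    nsz <- h * w
    N <- cbind(normal[fg], normal[fg + nsz], normal[fg + 2L * nsz])
    P <- cbind(position[fg], position[fg + nsz], position[fg + 2L * nsz])
    alb <- albedo[node[fg], , drop = FALSE]
    if (settings@shading == "constant") {
      shaded <- alb
    } else if (any(is.na(settings@lightDirection))) {
      ## headlight: per-pixel light towards the camera
      L <- rep(camera@position, each = length(fg)) - P
      dim(L) <- c(length(fg), 3L)
      L <- L / sqrt(rowSums(L^2))
      ndl <- pmax(0, rowSums(N * L))
      shaded <- pmin(pmax(alb * (0.2 + 0.8 * ndl), 0), 1)
    } else {
      shaded <- shadeDiffuse(N, settings@lightDirection, alb)
    }
    for (ch in 1:3) color[fg + (ch - 1L) * nsz] <- shaded[, ch]
  }
  new("FrameBuffer", color = color, depth = depth, normal = normal,
      position = position, node = node)
}

#' Depth-dependent silhouette mask
#'
#' A pixel is marked when the maximum absolute depth difference to its 8
#' neighbors exceeds \code{silhouetteThreshold * (1 + silhouetteDepthScale
#' * depth)}.  Boundaries between objects and background (depth Inf) always
#' exceed the threshold, so object outlines are always marked.
#'
#' @param fb a rendered \linkS4class{FrameBuffer}.
#' @param settings a \linkS4class{RenderSettings}.
#' @return logical height x width matrix.
#' @export
silhouettePass <- function(fb, settings = RenderSettings()) {
  D <- fb@depth
  h <- nrow(D); w <- ncol(D)
  pad <- matrix(NA_real_, h + 2L, w + 2L)   # out-of-frame: no neighbor
  pad[2:(h + 1), 2:(w + 1)] <- D
  maxdiff <- matrix(0, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2:(h + 1)) + dy, (2:(w + 1)) + dx]
    diff <- abs(D - nb)
    diff[is.infinite(D) & is.infinite(nb)] <- 0   # bg-bg: no edge
    diff[is.nan(diff) | is.na(diff)] <- 0
    maxdiff <- pmax(maxdiff, diff)
  }
  thr <- settings@silhouetteThreshold *
    (1 + settings@silhouetteDepthScale * D)       # Inf at background
  maxdiff > thr
}

## Park-Miller stream of deterministic uniforms in (0,1)
.lcgUniforms <- function(seed, n) {
  s <- as.double(seed %% 2147483647L)
  if (s == 0) s <- 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (16807 * s) %% 2147483647
    out[i] <- s / 2147483647
  }
  out
}

#' Screen-space ambient occlusion
#'
#' For every foreground pixel, a deterministic cosine-weighted kernel of
#' \code{ssaoSamples} offsets in the normal-oriented hemisphere of radius
#' \code{ssaoRadius} is placed at the surface point; each sample is
#' projected to the screen and counts as occluded when the stored depth
#' there is closer than the sample (within a 2x radius range check).  The
#' occlusion value is the occluded fraction; background pixels get 0.
#' Colors are meant to be darkened multiplicatively by (1 - occlusion).
#'
#' @param fb a rendered \linkS4class{FrameBuffer}.
#' @param camera the \linkS4class{Camera} used to render it.
#' @param settings a \linkS4class{RenderSettings}.
#' @return height x width occlusion matrix in [0, 1].
#' @export
ssaoPass <- function(fb, camera, settings = RenderSettings()) {
  h <- nrow(fb@depth); w <- ncol(fb@depth)
  occ <- matrix(0, h, w)
  fg <- which(fb@node > 0L)
  if (!length(fg)) return(occ)
  ns <- settings@ssaoSamples
  radius <- settings@ssaoRadius
  uu <- .lcgUniforms(settings@ssaoSeed, 3L * ns)
  u1 <- uu[seq(1L, by = 3L, length.out = ns)]
  u2 <- uu[seq(2L, by = 3L, length.out = ns)]
  u3 <- uu[seq(3L, by = 3L, length.out = ns)]
  kr <- sqrt(u1)
  kern <- cbind(kr * cos(2 * pi * u2), kr * sin(2 * pi * u2), sqrt(1 - u1))
  klen <- radius * (0.1 + 0.9 * u3^2)

  nsz <- h * w
  N <- cbind(fb@normal[fg], fb@normal[fg + nsz], fb@normal[fg + 2L * nsz])
  P <- cbind(fb@position[fg], fb@position[fg + nsz],
             fb@position[fg + 2L * nsz])
  ## tangent frame per pixel
  useX <- abs(N[, 1]) < 0.9
  A <- cbind(ifelse(useX, 1, 0), ifelse(useX, 0, 1), 0)
  Tv <- A - N * rowSums(A * N)
  Tv <- Tv / sqrt(rowSums(Tv^2))
  B <- cbind(N[, 2] * Tv[, 3] - N[, 3] * Tv[, 2],
             N[, 3] * Tv[, 1] - N[, 1] * Tv[, 3],
             N[, 1] * Tv[, 2] - N[, 2] * Tv[, 1])
  b <- .cameraBasis(camera)
  bias <- 0.025 * radius
  count <- numeric(length(fg))
  for (j in seq_len(ns)) {
    S <- P + (Tv * kern[j, 1] + B * kern[j, 2] + N * kern[j, 3]) * klen[j]
    v1 <- S[, 1] - camera@position[1]
    v2 <- S[, 2] - camera@position[2]
    v3 <- S[, 3] - camera@position[3]
    zf <- v1 * b$f[1] + v2 * b$f[2] + v3 * b$f[3]
    xr <- v1 * b$right[1] + v2 * b$right[2] + v3 * b$right[3]
    yu <- v1 * b$up[1] + v2 * b$up[2] + v3 * b$up[3]
    px <- round(xr / zf / b$pixSize + w / 2 - 0.5)
    py <- round(h / 2 - yu / zf / b$pixSize - 0.5)
    valid <- zf > 1e-9 & px >= 0 & px < w & py >= 0 & py < h
    sampleDist <- sqrt(v1^2 + v2^2 + v3^2)
    stored <- rep(Inf, length(fg))
    vi <- which(valid)
    stored[vi] <- fb@depth[cbind(py[vi] + 1L, px[vi] + 1L)]
    occluded <- is.finite(stored) & stored < sampleDist - bias &
      (sampleDist - stored) < 2 * radius
    count <- count + occluded
  }
  occ[fg] <- count / ns
  occ
}

#' Composite a frame with post-processing
#'
#' Applies, per the settings flags, SSAO darkening (multiplicative
#' 1 - occlusion) and then black silhouette contours on top of the shaded
#' color buffer.
#'
#' @param fb a rendered \linkS4class{FrameBuffer}.
#' @param camera the \linkS4class{Camera} used to render it.
#' @param settings a \linkS4class{RenderSettings}.
#' @return height x width x 3 RGB array in [0, 1].
#' @export
compositeFrame <- function(fb, camera, settings = RenderSettings()) {
  img <- fb@color
  if (settings@ssao) {
    occ <- ssaoPass(fb, camera, settings)
    img <- img * as.vector(1 - occ)
  }
  if (settings@contours) {
    mask <- silhouettePass(fb, settings)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- 0
      img[, , ch] <- plane
    }
  }
  img
}

#' Write an image to PNG or PPM
#'
#' PPM output is binary P6 with one byte per channel, quantized from the
#' float buffer by round-half-up on 255 * value; PNG goes through the png
#' package.  Both are bit-reproducible across runs.
#'
#' @param x a \linkS4class{FrameBuffer} (its color buffer is written) or a
#'   height x width x 3 RGB array in [0, 1].
#' @param path output file path.
#' @param format "png" or "ppm" (default: from the file extension).
#' @return the path, invisibly.
#' @export
writeImage <- function(x, path, format = tools::file_ext(path)) {
  img <- if (is(x, "FrameBuffer")) x@color else x
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  format <- tolower(format)
  if (!format %in% c("png", "ppm"))
    stop("unknown image format: ", format)
  img <- pmin(pmax(img, 0), 1)
  if (format == "png") {
    png::writePNG(img, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", dim(img)[2], dim(img)[1]),
              con, eos = NULL)
    ## interleave RGB row-major, round half up
    arr <- aperm(img, c(3L, 2L, 1L))
    writeBin(as.raw(floor(255 * arr + 0.5)), con)
  }
  invisible(path)
}
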