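## Bounding volumes per cluster: minimum-volume enclosing ellipsoids
## (Khachiyan-type (1+eps)-approximation with the Kumar-Yildirim stopping
## rule) fitted to surface samples, and exact minimal enclosing spheres of
## the member atom spheres.

#' Deterministic samples on a sphere surface
#'
#' Fibonacci (golden-angle) lattice: k points at exactly the sphere radius,
#' affinely well spread (not coplanar for k >= 4).
#'
#' @param s a \linkS4class{Sphere}.
#' @param k number of points (>= 4).
#' @return a k x 3 matrix of points.
#' @export
sampleSphereSurface <- function(s, k) {
  stopifnot(is(s, "Sphere"), k >= 4L)
  i <- seq_len(k) - 1L
  z <- 1 - 2 * (i + 0.5) / k
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  u <- unname(cbind(r * cos(phi), r * sin(phi), z))
  sweep(u * s@radius, 2L, s@center, `+`)
}

#' Deterministic samples on an ellipsoid surface
#'
#' Unit-sphere Fibonacci samples u mapped through
#' p = c + V diag(lambda) u, so every point satisfies the ellipsoid quadric
#' exactly.
#'
#' @param e an \linkS4class{Ellipsoid}.
#' @param k number of points (>= 4).
#' @return a k x 3 matrix of points.
#' @export
sampleEllipsoidSurface <- function(e, k) {
  stopifnot(is(e, "Ellipsoid"), k >= 4L)
  u <- sampleSphereSurface(Sphere(c(0, 0, 0), 1), k)
  p <- u %*% diag(e@semiAxes) %*% t(e@axes)
  sweep(p, 2L, e@center, `+`)
}

#' Minimum-volume enclosing ellipsoid of a point set
#'
#' Khachiyan's first-order (Frank-Wolfe) ascent on the dual D-optimal
#' design problem, with the Kumar-Yildirim stopping rule: iteration stops
#' once the largest dual violation is below (1+eps)(d+1), which guarantees
#' (i) every input point lies inside the ellipsoid inflated by (1+eps) and
#' (ii) the volume is within a factor (1+eps)^3 of the true minimum.
#' Fully deterministic.
#'
#' @param points m x 3 matrix, m >= 4, affinely full-dimensional.
#' @param cfg a \linkS4class{SamplingConfig} (tolerance and iteration cap).
#' @return an \linkS4class{Ellipsoid}.
#' @export
mvee <- function(points, cfg = SamplingConfig()) {
  P <- as.matrix(points)
  m <- nrow(P)
  if (m < 4L) stop("degenerate input: need at least 4 points")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2L, ctr))$d
  if (sv[3L] <= 1e-12 * max(sv[1L], 1))
    stop("degenerate input: points are not affinely full-dimensional")

  eps <- cfg@tolerance
  d <- 3L
  Q <- t(cbind(P, 1))                    # 4 x m lifted points
  u <- rep(1 / m, m)
  bound <- (1 + eps) * (d + 1)
  for (it in seq_len(cfg@maxIterations)) {
    X <- Q %*% (u * t(Q))                # 4 x 4
    Minv <- solve(X, Q)                  # 4 x m
    Mdiag <- colSums(Q * Minv)           # q_i' X^{-1} q_i
    j <- which.max(Mdiag)
    mx <- Mdiag[j]
    if (mx <= bound) break
    step <- (mx - d - 1) / ((d + 1) * (mx - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  ctr <- drop(crossprod(u, P))
  S <- crossprod(P, u * P) - tcrossprod(ctr)
  A <- solve(S) / d                      # (x-c)' A (x-c) = 1
  .ellipsoidFromQuadric(ctr, A)
}

## eigen-decompose a positive definite quadric matrix into an Ellipsoid,
## with deterministic axis signs
.ellipsoidFromQuadric <- function(center, A) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-18)
  semi <- rev(1 / sqrt(vals))            # eigenvalues desc -> semi-axes asc
  V <- eg$vectors[, 3:1, drop = FALSE]
  for (j in 1:3) {                       # canonical sign: largest entry > 0
    mj <- which.max(abs(V[, j]))
    if (V[mj, j] < 0) V[, j] <- -V[, j]
  }
  Ellipsoid(center = center, axes = V, semiAxes = semi)
}

#' Quadric matrix of an ellipsoid
#'
#' Returns the positive definite matrix A with
#' \eqn{(x-c)^T A (x-c) = 1}, i.e. \eqn{A = V diag(\lambda^{-2}) V^T}.
#'
#' @param e an \linkS4class{Ellipsoid}.
#' @return a 3 x 3 symmetric positive definite matrix.
#' @export
quadricMatrix <- function(e) {
  stopifnot(is(e, "Ellipsoid"))
  e@axes %*% diag(1 / e@semiAxes^2) %*% t(e@axes)
}

#' Exact minimal enclosing sphere of a set of spheres
#'
#' Minimizes the convex function max_i (|c - c_i| + r_i) over the center c:
#' a Badoiu-Clarkson style averaging pass from the centroid followed by a
#' Nelder-Mead polish.  One input returns itself; two inputs use the exact
#' pairwise construction.
#'
#' @param spheres non-empty list of \linkS4class{Sphere} objects.
#' @return the minimal enclosing \linkS4class{Sphere} (radius within 1e-6
#'   relative of the optimum).
#' @export
minEnclosingSphere <- function(spheres) {
  if (length(spheres) == 0L) stop("need at least one sphere")
  if (length(spheres) == 1L) return(spheres[[1L]])
  if (length(spheres) == 2L) return(enclosingSphere(spheres[[1]], spheres[[2]]))
  C <- t(vapply(spheres, function(s) s@center, numeric(3)))
  r <- vapply(spheres, function(s) s@radius, numeric(1))
  f <- function(c0) {
    max(sqrt((c0[1] - C[, 1])^2 + (c0[2] - C[, 2])^2 +
               (c0[3] - C[, 3])^2) + r)
  }
  c0 <- colMeans(C)
  for (k in seq_len(400L)) {             # subgradient/averaging warm start
    d <- sqrt((c0[1] - C[, 1])^2 + (c0[2] - C[, 2])^2 + (c0[3] - C[, 3])^2)
    i <- which.max(d + r)
    if (d[i] < 1e-12) break
    far <- C[i, ] - r[i] * (c0 - C[i, ]) / d[i]      # farthest surface point
    c0 <- c0 + (far - c0) / (k + 1)
  }
  opt <- stats::optim(c0, f, method = "Nelder-Mead",
                      control = list(maxit = 4000L,
                                     reltol = .Machine$double.eps))
  ## polish once more from the optimum (Nelder-Mead restart helps accuracy)
  opt <- stats::optim(opt$par, f, method = "Nelder-Mead",
                      control = list(maxit = 4000L,
                                     reltol = .Machine$double.eps))
  Sphere(opt$par, f(opt$par))
}

#' Annotate a cluster tree with bounding volumes
#'
#' Every node receives (a) the exact minimal enclosing sphere of its member
#' atom spheres and (b) an MVEE: Residue-Interior and Residue nodes fit the
#' MVEE to k Fibonacci surface samples of every member atom sphere;
#' Residue-Link and Molecule nodes fit it to k surface samples of each of
#' the two children's MVEEs, so inflation from lower levels does not have
#' to be recomputed from all atoms.  Leaves carry their atom sphere as an
#' equal-axis ellipsoid.  Rank-deficient sample sets are regularized with
#' six axis-aligned points at +-1e-6 A and semi-axes are floored at 1e-6 A.
#'
#' @param tree a \linkS4class{ClusterTree}.
#' @param cfg a \linkS4class{SamplingConfig}.
#' @return the annotated tree.
#' @export
annotateTree <- function(tree, cfg = SamplingConfig()) {
  stopifnot(is(tree, "ClusterTree"), is(cfg, "SamplingConfig"))
  mol <- tree@molecule
  a <- mol@atoms
  nd <- tree@nodes
  total <- nrow(nd)
  k <- cfg@pointsPerSurface
  mvees <- vector("list", total)

  atomSphere <- function(i) Sphere(c(a$x[i], a$y[i], a$z[i]), a$radius[i])

  for (id in seq_len(total)) {           # children always precede parents
    mem <- tree@members[[id]]
    if (is.na(nd$child1[id])) {
      s <- atomSphere(mem)
      nd[id, c("ex", "ey", "ez", "er")] <- c(s@center, s@radius)
      mvees[[id]] <- Ellipsoid(s@center, diag(3), rep(s@radius, 3L))
      next
    }
    ms <- minEnclosingSphere(lapply(mem, atomSphere))
    nd[id, c("ex", "ey", "ez", "er")] <- c(ms@center, ms@radius)
    pts <- if (nd$level[id] %in% c("RESIDUE_INTERIOR", "RESIDUE")) {
      do.call(rbind, lapply(mem, function(i) sampleSphereSurface(atomSphere(i), k)))
    } else {
      rbind(sampleEllipsoidSurface(mvees[[nd$child1[id]]], k),
            sampleEllipsoidSurface(mvees[[nd$child2[id]]], k))
    }
    e <- tryCatch(mvee(pts, cfg), error = function(err) {
      reg <- rbind(pts, sweep(rbind(diag(3) * 1e-6, -diag(3) * 1e-6),
                              2L, colMeans(pts), `+`))
      mvee(reg, cfg)
    })
    if (any(e@semiAxes < 1e-6))
      e <- Ellipsoid(e@center, e@axes, pmax(e@semiAxes, 1e-6))
    mvees[[id]] <- e
  }
  tree@nodes <- nd
  tree@mvees <- mvees
  tree
}
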