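## Independent oracles used across the suite.  Each deliberately takes a
## different algorithmic route than the package implementation.

## --- naive residue-restricted average-linkage agglomeration --------------
## Recomputes the full average-linkage dissimilarity matrix from the atom
## pair VDM at every step (O(n^3)); returns the multiset of member sets of
## all internal nodes, an id-free signature of the merge structure.
naiveMergeSignature <- function(mol) {
  a <- atomData(mol)
  n <- nrow(a)
  sph <- lapply(seq_len(n), function(i)
    Sphere(c(a$x[i], a$y[i], a$z[i]), a$radius[i]))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    M[i, j] <- vdm(sph[[i]], sph[[j]])
  resOf <- integer(n)
  for (ri in seq_along(residueGroups(mol))) resOf[residueGroups(mol)[[ri]]] <- ri

  clusters <- as.list(seq_len(n))
  ids <- seq_len(n)
  sig <- character(0)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    cres <- vapply(clusters, function(m) resOf[m[1]], 1L)
    pure <- vapply(seq_len(k), function(i)
      all(resOf[clusters[[i]]] == cres[i]), TRUE)
    complete <- vapply(seq_len(k), function(i)
      setequal(clusters[[i]], residueGroups(mol)[[cres[i]]]), TRUE)
    phase1 <- any(pure & !complete)    # some residue not yet one cluster
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (phase1) {
        ## only within-residue merges of incomplete residues are allowed
        if (!(pure[i] && pure[j] && cres[i] == cres[j])) next
      }
      d <- mean(M[clusters[[i]], clusters[[j]]])
      key <- c(min(ids[i], ids[j]), max(ids[i], ids[j]))
      if (is.null(best) || d < best$d ||
          (d == best$d && (key[1] < best$key[1] ||
                           (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- list(i = i, j = j, d = d, key = key)
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    sig <- c(sig, paste(merged, collapse = ","))
    clusters[[best$i]] <- merged
    ids[best$i] <- max(ids) + 1L
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  sort(sig)
}

treeMergeSignature <- function(tree) {
  nd <- nodeData(tree)
  internal <- which(!is.na(nd$child1))
  sort(vapply(internal, function(i)
    paste(nodeMembers(tree, i), collapse = ","), ""))
}

## --- penalty-method MVEE oracle ------------------------------------------
## Minimizes -log det L subject to ||L'(x_i - c)|| <= 1 via an increasing
## quadratic penalty and nlminb, then rescales to exact feasibility.
## Parametrization: c (3), log-diagonal (3) and off-diagonals (3) of the
## lower-triangular factor L with A = L L'.
mveeOracleVolume <- function(P) {
  P <- as.matrix(P)
  ctr0 <- colMeans(P)
  S <- stats::cov(P) * 3
  L0 <- tryCatch(t(chol(solve(S))), error = function(e) diag(3) * 0.5)
  par0 <- c(ctr0, log(diag(L0)), L0[lower.tri(L0)])
  unpack <- function(par) {
    L <- diag(exp(par[4:6]))
    L[lower.tri(L)] <- par[7:9]
    list(c = par[1:3], L = L)
  }
  maxq <- function(c0, L) {
    Y <- sweep(P, 2L, c0) %*% L
    max(rowSums(Y^2))
  }
  par <- par0
  for (mu in 10^(2:9)) {
    obj <- function(par) {
      u <- unpack(par)
      Y <- sweep(P, 2L, u$c) %*% u$L
      viol <- pmax(0, rowSums(Y^2) - 1)
      -sum(par[4:6]) + mu * sum(viol^2)
    }
    par <- stats::nlminb(par, obj,
                         control = list(iter.max = 2000, eval.max = 4000))$par
  }
  u <- unpack(par)
  s <- sqrt(maxq(u$c, u$L))            # rescale so all points are inside
  detL <- prod(exp(par[4:6])) / s^3
  4 / 3 * pi / detL
}

## --- brute-force renderer ------------------------------------------------
## Per-pixel nearest hit by scalar ray casting over all glyphs.
bruteForceDepth <- function(dl, camera) {
  w <- camera@width; h <- camera@height
  depth <- matrix(Inf, h, w)
  geo <- displayGeometry(dl)
  for (py in 0:(h - 1L)) for (px in 0:(w - 1L)) {
    ray <- generateRay(camera, px, py)
    for (g in geo) {
      hit <- if (is(g, "Sphere")) raySphereIntersect(ray, g)
             else rayEllipsoidIntersect(ray, g)
      if (!is.null(hit) && hit$t < depth[py + 1L, px + 1L])
        depth[py + 1L, px + 1L] <- hit$t
    }
  }
  depth
}

## --- multi-start minimal-enclosing-sphere oracle --------------------------
minSphereOracleRadius <- function(spheres, nStarts = 30L, seed = 42L) {
  C <- t(vapply(spheres, function(s) s@center, numeric(3)))
  r <- vapply(spheres, function(s) s@radius, numeric(1))
  f <- function(c0) max(sqrt(rowSums(sweep(C, 2L, c0)^2)) + r)
  set.seed(seed)
  starts <- rbind(colMeans(C),
                  C[sample(nrow(C), min(nStarts, nrow(C))), , drop = FALSE] +
                    matrix(rnorm(3 * min(nStarts, nrow(C)), sd = 0.5),
                           ncol = 3))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                      control = list(maxit = 5000,
                                     reltol = .Machine$double.eps))
    o <- stats::optim(o$par, f, method = "Nelder-Mead",
                      control = list(maxit = 5000,
                                     reltol = .Machine$double.eps))
    best <- min(best, o$value)
  }
  best
}

## --- misc helpers ---------------------------------------------------------
randomRotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}

## 8-connected component count of a logical matrix
componentCount <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    h <- nrow(mask)
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      py <- (p - 1L) %% h + 1L
      px <- (p - 1L) %/% h + 1L
      for (dy in -1:1) for (dx in -1:1) {
        ny <- py + dy; nx <- px + dx
        if (ny < 1 || ny > h || nx < 1 || nx > ncol(mask)) next
        q <- (nx - 1L) * h + ny
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  cur
}

## tiny two-residue PDB fixture written programmatically
writeFixturePDB <- function(path, lines) {
  writeLines(lines, path)
  path
}
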