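camFixture <- function(w = 64L, h = 64L, pos = c(0, 0, 10),
                       target = c(0, 0, 0))
  Camera(pos, target = target, fov = 45, width = w, height = h)

test_that("primary rays go through pixel centers of a pinhole camera", {
  cam <- camFixture(65L, 65L)
  center <- generateRay(cam, 32, 32)    # odd-sized image: principal pixel
  expect_equal(center@direction, c(0, 0, -1))
  expect_equal(center@origin, c(0, 0, 10))
  ## all rays unit length
  for (p in list(c(0, 0), c(64, 0), c(13, 57))) {
    ray <- generateRay(cam, p[1], p[2])
    expect_equal(sqrt(sum(ray@direction^2)), 1, tolerance = 1e-12)
  }
  ## horizontally adjacent pixels differ only along camera right = +x
  r1 <- generateRay(cam, 31, 32)@direction
  r2 <- generateRay(cam, 33, 32)@direction
  expect_equal(r1[2], r2[2])
  expect_true(r1[1] < 0 && r2[1] > 0)
  expect_error(generateRay(cam, 65, 0), "out of range")
})

test_that("ray-sphere intersection returns nearest hit, miss and interior", {
  s <- Sphere(c(0, 0, 0), 1)
  hit <- raySphereIntersect(Ray(c(0, 0, 10), c(0, 0, -1)), s)
  expect_equal(hit$t, 9)
  expect_equal(hit$point, c(0, 0, 1))
  expect_equal(hit$normal, c(0, 0, 1))
  expect_null(raySphereIntersect(Ray(c(2, 0, 10), c(0, 0, -1)), s))
  ## origin inside: back-face hit, positive t
  inside <- raySphereIntersect(Ray(c(0, 0, 0), c(0, 0, -1)), s)
  expect_equal(inside$t, 1)
  expect_equal(inside$normal, c(0, 0, -1))
})

test_that("ray-ellipsoid intersection matches the canonical quadric", {
  e <- Ellipsoid(c(0, 0, 0), diag(3), c(2, 1, 1))
  hit <- rayEllipsoidIntersect(Ray(c(-10, 0, 0), c(1, 0, 0)), e)
  expect_equal(hit$t, 8)
  expect_equal(hit$point, c(-2, 0, 0))
  expect_equal(hit$normal, c(-1, 0, 0))
})

test_that("equal-axis ellipsoids intersect exactly like spheres", {
  set.seed(50)
  s <- Sphere(c(1, -2, 0.5), 1.7)
  e <- Ellipsoid(s@center, diag(3), rep(s@radius, 3))
  for (i in 1:1000) {
    ray <- Ray(rnorm(3, sd = 6), rnorm(3))
    hs <- raySphereIntersect(ray, s)
    he <- rayEllipsoidIntersect(ray, e)
    expect_equal(is.null(hs), is.null(he))
    if (!is.null(hs)) expect_lte(abs(hs$t - he$t), 1e-9)
  }
})

test_that("glyph-space intersection equals the world-space quadric", {
  ## ellipsoid rotated 45 degrees about z, oblique rays; the oracle solves
  ## (x-c)' A (x-c) = 1 directly in world space
  th <- pi / 4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e <- Ellipsoid(c(1, 2, -1), R, c(3, 1.5, 0.8))
  A <- quadricMatrix(e)
  set.seed(60)
  nchecked <- 0L
  for (i in 1:200) {
    origin <- rnorm(3, sd = 8)
    ## aim at the neighborhood of the ellipsoid so a good share of rays hit
    ray <- Ray(origin, e@center + rnorm(3, sd = 2) - origin)
    o <- ray@origin - e@center
    a <- drop(ray@direction %*% A %*% ray@direction)
    b <- 2 * drop(o %*% A %*% ray@direction)
    cc <- drop(o %*% A %*% o) - 1
    disc <- b^2 - 4 * a * cc
    tOracle <- if (disc < 0) NA_real_ else {
      t1 <- (-b - sqrt(disc)) / (2 * a)
      t2 <- (-b + sqrt(disc)) / (2 * a)
      if (t1 > 0) t1 else if (t2 > 0) t2 else NA_real_
    }
    hit <- rayEllipsoidIntersect(ray, e)
    if (is.na(tOracle)) {
      expect_null(hit)
    } else {
      nchecked <- nchecked + 1L
      expect_lte(abs(hit$t - tOracle), 1e-9)
    }
  }
  expect_gt(nchecked, 20L)
})

test_that("screen bounds are conservative for every hit pixel", {
  cam <- camFixture()
  ## centered glyph: rectangle centered on the principal pixel
  rect <- screenBound(c(0, 0, 0), 1, cam)
  expect_equal(rect$x0 + rect$x1, 63)
  expect_equal(rect$y0 + rect$y1, 63)
  ## glyph fully behind the camera is culled
  expect_null(screenBound(c(0, 0, 20), 1, cam))
  ## brute-force 64x64 scan: every hit pixel lies inside the rectangle
  set.seed(70)
  for (i in 1:8) {
    e <- Ellipsoid(c(rnorm(2, sd = 3), runif(1, -4, 4)),
                   randomRotation(i), sort(runif(3, 0.3, 2),
                                           decreasing = TRUE))
    rect <- screenBound(e@center, e@semiAxes[1], cam)
    for (py in 0:63) for (px in 0:63) {
      hit <- rayEllipsoidIntersect(generateRay(cam, px, py), e)
      if (!is.null(hit)) {
        expect_false(is.null(rect))
        expect_true(px >= rect$x0 && px <= rect$x1 &&
                      py >= rect$y0 && py <= rect$y1)
      }
    }
  }
})

test_that("renderFrame fills color, depth and normals per nearest hit", {
  cam <- camFixture(65L, 65L)
  empty <- renderFrame(makeDisplayList(list()), cam)
  expect_true(all(is.infinite(empty@depth)))
  expect_true(all(empty@color == 1))    # white background

  one <- renderFrame(makeDisplayList(list(Sphere(c(0, 0, 0), 1))), cam)
  expect_equal(one@depth[33, 33], 9)    # axial hit at the center pixel
  expect_equal(one@normal[33, 33, ], c(0, 0, 1))
  ## finite depth exactly at foreground
  expect_identical(is.finite(one@depth), one@node > 0L)

  ## nearer of two spheres on the view axis wins the depth test
  two <- renderFrame(makeDisplayList(list(Sphere(c(0, 0, 0), 1),
                                          Sphere(c(0, 0, 5), 0.5))), cam)
  expect_equal(two@depth[33, 33], 4.5)
  expect_equal(two@node[33, 33], 2L)
})

test_that("rendered depth equals brute-force nearest-hit casting", {
  tree <- annotatedTree65()
  ctr <- nodeMVEE(tree, rootId(tree))@center
  campos <- ctr + c(5, -8, 130)
  cam <- Camera(campos, target = ctr, width = 64L, height = 64L)
  dl <- selectDisplayList(tree, campos, LODParams(100, 20), "ellipsoid")
  fb <- renderFrame(dl, cam)
  bf <- bruteForceDepth(dl, cam)
  expect_lte(max(abs(fb@depth - bf)[is.finite(bf)]), 1e-9)
  expect_identical(is.finite(fb@depth), is.finite(bf))
})

test_that("equal-axis ellipsoid scenes render pixel-identically to spheres", {
  cam <- camFixture()
  spheres <- list(Sphere(c(0, 0, 0), 1.2), Sphere(c(1.5, 1, -2), 0.8))
  ells <- lapply(spheres, function(s)
    Ellipsoid(s@center, diag(3), rep(s@radius, 3)))
  fbS <- renderFrame(makeDisplayList(spheres), cam)
  fbE <- renderFrame(makeDisplayList(ells, levels = c("ATOM", "ATOM")), cam)
  expect_lte(max(abs(fbS@depth - fbE@depth)[is.finite(fbS@depth)]), 1e-6)
  expect_equal(fbS@color, fbE@color, tolerance = 1e-12)
})

test_that("projected silhouette radius doubles with the resolution", {
  radiusOf <- function(cam) {
    fb <- renderFrame(makeDisplayList(list(Sphere(c(0, 0, 0), 2))), cam)
    fg <- which(is.finite(fb@depth), arr.ind = TRUE)
    max(sqrt((fg[, 2] - (cam@width + 1) / 2)^2 +
               (fg[, 1] - (cam@height + 1) / 2)^2))
  }
  r1 <- radiusOf(camFixture(64L, 64L))
  r2 <- radiusOf(camFixture(128L, 128L))
  expect_lte(abs(r2 - 2 * r1), 2)
})

test_that("diffuse shading is Lambert with an ambient floor", {
  alb <- c(0.8, 0.4, 0.2)
  l <- c(0, 0, 1)
  expect_equal(shadeDiffuse(c(0, 0, 1), l, alb), alb)              # aligned
  expect_equal(shadeDiffuse(c(1, 0, 0), l, alb), 0.2 * alb)        # grazing
  expect_equal(shadeDiffuse(c(0, 0, -1), l, alb), 0.2 * alb)       # clamped
  ## matrix form matches scalar form
  N <- rbind(c(0, 0, 1), c(1, 0, 0))
  expect_equal(unname(shadeDiffuse(N, l, rbind(alb, alb))),
               unname(rbind(alb, 0.2 * alb)))
})

test_that("silhouettes trace the projected outline of a sphere", {
  ## uniform-depth plane: no interior edges
  flat <- new("FrameBuffer", color = array(0.5, c(16, 16, 3)),
              depth = matrix(5, 16, 16), normal = array(0, c(16, 16, 3)),
              position = array(0, c(16, 16, 3)), node = matrix(1L, 16, 16))
  expect_false(any(silhouettePass(flat)))

  cam <- camFixture()
  r <- 2; d <- 10
  fb <- renderFrame(makeDisplayList(list(Sphere(c(0, 0, 0), r))), cam)
  mask <- silhouettePass(fb)
  expect_gt(sum(mask), 0)
  ## analytic projected circle: tangent rays at angle asin(r/d)
  s <- 2 * tan(cam@fov / 2 * pi / 180) / cam@height
  rho0 <- tan(asin(r / d)) / s
  marked <- which(mask, arr.ind = TRUE)
  rho <- sqrt((marked[, 2] - 0.5 - cam@width / 2)^2 +
                (marked[, 1] - 0.5 - cam@height / 2)^2)
  expect_lte(max(abs(rho - rho0)), 2)

  ## two isolated spheres give two connected edge components
  fb2 <- renderFrame(makeDisplayList(list(Sphere(c(-3, 0, 0), 1),
                                          Sphere(c(3, 0, 0), 1))), cam)
  expect_equal(componentCount(silhouettePass(fb2)), 2L)
})

test_that("SSAO darkens crevices more than exposed surface", {
  cam <- camFixture(64L, 64L, pos = c(0, 0, 12))
  settings <- RenderSettings(ssao = TRUE, ssaoSamples = 32L, ssaoRadius = 2,
                             ssaoSeed = 11L)
  ## isolated sphere: the pole facing the camera is unoccluded
  fbIso <- renderFrame(makeDisplayList(list(Sphere(c(0, 0, 0), 2))), cam)
  occIso <- ssaoPass(fbIso, cam, settings)
  expect_true(all(occIso[!is.finite(fbIso@depth)] == 0))   # background
  poleOcc <- occIso[33, 33]
  ## two overlapping spheres: the crevice pixel at the image center
  fbTwo <- renderFrame(makeDisplayList(list(Sphere(c(-1.9, 0, 0), 2),
                                            Sphere(c(1.9, 0, 0), 2))), cam)
  occTwo <- ssaoPass(fbTwo, cam, settings)
  creviceOcc <- occTwo[33, 33]
  expect_gt(creviceOcc, poleOcc)
  ## deterministic under a fixed seed
  expect_identical(occTwo, ssaoPass(fbTwo, cam, settings))
  expect_false(identical(occTwo,
                         ssaoPass(fbTwo, cam,
                                  RenderSettings(ssao = TRUE,
                                                 ssaoSamples = 32L,
                                                 ssaoRadius = 2,
                                                 ssaoSeed = 12L))))
})

test_that("compositing applies occlusion darkening and black contours", {
  cam <- camFixture()
  dl <- makeDisplayList(list(Sphere(c(0, 0, 0), 2)))
  settings <- RenderSettings(contours = TRUE, ssao = TRUE)
  fb <- renderFrame(dl, cam, settings)
  img <- compositeFrame(fb, cam, settings)
  mask <- silhouettePass(fb, settings)
  expect_true(all(img[, , 1][mask] == 0))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("PPM output is bit-exact and reproducible", {
  img <- array(1, c(2, 2, 3))
  path <- withr::local_tempfile(fileext = ".ppm")
  writeImage(img, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  header <- rawToChar(bytes[1:11])
  expect_equal(header, "P6\n2 2\n255\n")
  expect_equal(length(bytes), 11 + 12)
  expect_true(all(as.integer(bytes[12:23]) == 255L))
  ## round-half-up quantization
  img2 <- array(0.5 + 1e-9, c(1, 1, 3))
  path2 <- withr::local_tempfile(fileext = ".ppm")
  writeImage(img2, path2)
  b2 <- readBin(path2, "raw", file.info(path2)$size)
  expect_true(all(as.integer(tail(b2, 3)) == 128L))
  ## byte-identical across runs
  path3 <- withr::local_tempfile(fileext = ".ppm")
  writeImage(img, path3)
  expect_identical(readBin(path3, "raw", 1e3), bytes)
  expect_error(writeImage(img, path, format = "gif"), "unknown image format")
})

test_that("PNG output round-trips through the png reader", {
  cam <- camFixture(32L, 32L)
  fb <- renderFrame(makeDisplayList(list(Sphere(c(0, 0, 0), 2))), cam)
  path <- withr::local_tempfile(fileext = ".png")
  writeImage(fb, path)
  back <- png::readPNG(path)
  expect_equal(dim(back), c(32L, 32L, 3L))
  expect_equal(max(abs(back - fb@color)), 0, tolerance = 1 / 255)
})
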