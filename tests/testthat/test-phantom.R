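test_that("phantom generation is deterministic and respects insert counts", {
  spec <- dentalPhantomSpec()
  p1 <- makeDentalPhantom(spec, seed = 5)
  p2 <- makeDentalPhantom(spec, seed = 5)
  expect_identical(p1$map@labels, p2$map@labels)
  expect_identical(p1$texture, p2$texture)
  p0 <- makeDentalPhantom(dentalPhantomSpec(nMetal = 0), seed = 5)
  expect_false(any(p0$metalMask))
  # metal sits inside bone sockets
  expect_true(all(p1$map@labels[p1$metalMask] == 4L))
  grown <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(p1$metalMask * 1),
    EBImage::makeBrush(3, "box"))) > 0.5
  ring <- grown & !p1$metalMask
  # inserts are seated in bone sockets: the immediate neighbourhood is
  # predominantly bone (a socket rim pixel may fall on soft tissue)
  expect_gt(mean(p1$map@labels[ring] %in% c(3L, 4L)), 0.6)
})

test_that("two well-separated cylinders yield two mask components", {
  spec <- dentalPhantomSpec(nMetal = 2, jitter = 0)
  ph <- makeDentalPhantom(spec, seed = 3)
  lab <- EBImage::bwlabel(EBImage::Image(ph$metalMask * 1))
  expect_equal(max(EBImage::imageData(lab)), 2)
})

test_that("monoenergetic noise-free simulation collapses to Beer-Lambert", {
  ph <- makeDentalPhantom(dentalPhantomSpec(), seed = 2)
  g <- fxGeom()
  s <- simulatePolychromatic(ph$map, monoSpectrum(60), g, Inf)
  fp <- forwardProject(muImage(ph$map, 60), g)
  expect_lt(max(abs(sinoValues(s) - sinoValues(fp))), 1e-10)
})

test_that("material table is physical and spectrum normalized", {
  tab <- materialTable()
  expect_true(all(tab$mu >= 0))
  expect_true(all(apply(tab$mu, 1, function(r) all(diff(r) <= 1e-12))))
  # attenuation ordering soft < bone < metal at every energy
  expect_true(all(tab$mu["soft_tissue", ] < tab$mu["bone", ]))
  expect_true(all(tab$mu["bone", ] < tab$mu["metal", ]))
  sp <- makeSpectrum()
  expect_equal(sum(sp@weights), 1)
  # zero-weight spectra are rejected at construction
  expect_error(new("XraySpectrum", energies = c(30, 60), weights = c(0, 0)),
               "sum to 1")
  ph <- makeDentalPhantom(dentalPhantomSpec(), seed = 1)
  expect_error(simulatePolychromatic(ph$map, sp, fxGeom(),
                                     photonsPerRay = 0),
               "photonsPerRay")
})

test_that("polychromatic acquisition of a uniform disc shows cupping", {
  tab <- materialTable()
  n <- 64
  lab <- matrix(1L, n, n)
  gx <- (col(lab) - (n + 1) / 2) * 3; gy <- ((n + 1) / 2 - row(lab)) * 3
  lab[gx^2 + gy^2 <= 70^2] <- 2L
  map <- new("MaterialMap", labels = lab, materials = tab$materials,
             energies = tab$energies, mu = tab$mu, pixelSize = 3)
  # two-bin spectrum, no noise
  sp <- new("XraySpectrum", energies = c(35, 80), weights = c(0.5, 0.5))
  r <- fbpReconstruct(simulatePolychromatic(map, sp, fxGeom(), Inf), n, 3)
  ctr <- mean(r@values[gx^2 + gy^2 <= 20^2])
  edge <- mean(r@values[gx^2 + gy^2 > 50^2 & gx^2 + gy^2 <= 65^2])
  expect_lt(ctr, edge)
})

test_that("two metal rods produce a dark band between them", {
  pair <- makePhantomPair(dentalPhantomSpec(nMetal = 2), fxGeom(),
                          seed = 42)
  cl <- pair$clean@values; co <- pair$corrupted@values
  # soft-tissue ROI around the midpoint of the two rods
  msk <- pair$metalMask
  cc <- which(msk, arr.ind = TRUE)
  km <- suppressWarnings(kmeans(cc, 2))
  mid <- colMeans(km$centers)
  d2 <- (row(msk) - mid[1])^2 + (col(msk) - mid[2])^2
  roi <- d2 <= 16 & pair$phantom$map@labels == 2L
  expect_gt(sum(roi), 10)
  expect_lt(mean(co[roi]), mean(cl[roi]))
})

test_that("artifact map extraction obeys its algebra", {
  pair <- fxSuite()$pairs[[1]]
  amap <- extractArtifactMap(pair$corrupted, pair$clean)
  expect_equal(pair$clean@values + amap@values, pair$corrupted@values)
  same <- extractArtifactMap(pair$clean, pair$clean)
  expect_true(all(same@values == 0))
  expect_error(extractArtifactMap(pair$clean, ctImage(matrix(0, 32, 32), 3)),
               "grid")
  # artifact support covers the metal pixels
  expect_true(all(abs(amap@values[pair$metalMask]) > 0))
})

test_that("artifact overlay identities hold", {
  pair <- fxSuite()$pairs[[1]]
  tgt <- fxCleanSlices()[[1]]
  zmap <- ctImage(matrix(0, 64, 64), 3)
  o0 <- overlayArtifact(zmap, tgt, rotationDeg = 123)
  expect_equal(o0$image@values, tgt@values)
  amap <- extractArtifactMap(pair$corrupted, pair$clean)
  oA <- overlayArtifact(amap, tgt, metalMask = pair$metalMask,
                        rotationDeg = 0)
  expect_equal(oA$image@values, tgt@values + amap@values, tolerance = 1e-12)
  o360 <- overlayArtifact(amap, tgt, metalMask = pair$metalMask,
                          rotationDeg = 360)
  expect_lt(max(abs(o360$image@values - oA$image@values)), 1e-6)
  expect_identical(o360$mask, oA$mask)
})

test_that("paired-data contract: metal drives the corruption", {
  g <- fxGeom()
  sp <- dentalPhantomSpec()
  pm <- makePhantomPair(sp, g, seed = 42)
  p0 <- makePhantomPair(dentalPhantomSpec(nMetal = 0), g, seed = 42)
  rmseMetal <- imageRMSE(pm$corrupted, pm$clean, !pm$metalMask)
  rmseNoMetal <- imageRMSE(p0$corrupted, p0$clean)
  expect_lt(rmseNoMetal, rmseMetal)
})

test_that("Poisson log-transform noise grows with the line integral", {
  ph <- makeDentalPhantom(dentalPhantomSpec(), seed = 8)
  g <- fxGeom()
  clean <- sinoValues(simulatePolychromatic(ph$map, makeSpectrum(), g, Inf))
  reps <- lapply(1:6, function(k)
    sinoValues(simulatePolychromatic(ph$map, makeSpectrum(), g, 8e3,
                                     seed = 100 + k)))
  devs <- sapply(reps, function(r) (r - clean))
  pos <- as.vector(clean) > 0.5          # rays crossing the object
  brk <- quantile(as.vector(clean)[pos], c(0, .25, .5, .75, 1))
  qs <- cut(as.vector(clean)[pos], brk, include.lowest = TRUE)
  bandVar <- tapply(rowMeans(devs^2)[pos], qs, mean)
  expect_true(all(diff(bandVar) > 0))
})

test_that("a seed manifest reproduces the suite exactly", {
  s1 <- simulationSuite(2, seed = 77)
  s2 <- simulationSuite(2, seed = 77)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$pairs[[2]]$corrupted@values,
                   s2$pairs[[2]]$corrupted@values)
  expect_identical(s1$pairs[[1]]$metalMask, s2$pairs[[1]]$metalMask)
})
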