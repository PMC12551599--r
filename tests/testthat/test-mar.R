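test_that("metal trace matches brute-force ray-pixel intersection", {
  g <- fanBeamGeometry(400, 800, 96, 6, 36)
  n <- 64; px <- 3
  mask <- matrix(FALSE, n, n)
  mask[32, 32] <- TRUE       # near-centre pixel
  tr <- computeMetalTrace(mask, g, px, margin = 0)
  # brute force: does the ray to detector j at view ia pass within the
  # pixel's square?
  cx <- (32 - (n + 1) / 2) * px
  cy <- ((n + 1) / 2 - 32) * px
  ang <- viewAngles(g)
  u <- ((1:96) - (96 + 1) / 2) * 6
  oracle <- matrix(FALSE, 36, 96)
  for (ia in 1:36) {
    b <- ang[ia]
    S <- 400 * c(cos(b), sin(b))
    a <- -c(cos(b), sin(b)); uv <- c(-sin(b), cos(b))
    for (j in 1:96) {
      d <- 800 * a + u[j] * uv; d <- d / sqrt(sum(d^2))
      t0 <- sum((c(cx, cy) - S) * d)
      close <- S + t0 * d - c(cx, cy)
      # conservative: within the bilinear interpolation footprint
      oracle[ia, j] <- sqrt(sum(close^2)) <= px * 1.5
    }
  }
  # every ray that clearly crosses the pixel core must be flagged
  core <- matrix(FALSE, 36, 96)
  for (ia in 1:36) for (j in 1:96) {
    b <- ang[ia]
    S <- 400 * c(cos(b), sin(b))
    a <- -c(cos(b), sin(b)); uv <- c(-sin(b), cos(b))
    d <- 800 * a + u[j] * uv; d <- d / sqrt(sum(d^2))
    t0 <- sum((c(cx, cy) - S) * d)
    close <- S + t0 * d - c(cx, cy)
    core[ia, j] <- sqrt(sum(close^2)) <= px / 2 * 0.9
  }
  expect_true(all(tr[core]))          # no missed core intersections
  expect_true(all(oracle[tr]))        # no flags outside the pixel band
  expect_true(all(rowSums(tr) >= 1))  # flagged at every view
})

test_that("trace utilities behave at the edges", {
  g <- fanBeamGeometry(400, 800, 96, 6, 12)
  empty <- computeMetalTrace(matrix(FALSE, 64, 64), g, 3)
  expect_false(any(empty))
  mask <- matrix(FALSE, 64, 64); mask[30:33, 30:33] <- TRUE
  t0 <- computeMetalTrace(mask, g, 3, margin = 0)
  t2 <- computeMetalTrace(mask, g, 3, margin = 2)
  expect_true(all(t2[t0]))        # dilation is monotone
  expect_gt(sum(t2), sum(t0))
})

test_that("LIMAR reproduces analytic linear interpolation exactly", {
  g <- fanBeamGeometry(400, 800, 4, 6, 2)
  v <- matrix(c(4, 0, 0, 8), 2, 4, byrow = TRUE)
  v[1, ] <- c(4, 1, 2, 8)
  tr <- matrix(FALSE, 2, 4)
  tr[1, 2:3] <- TRUE
  out <- sinoValues(limar(sinogram(v, g), tr))
  expect_identical(out[1, 1], 4)
  expect_equal(out[1, 2], 16 / 3)
  expect_equal(out[1, 3], 20 / 3)
  expect_identical(out[1, 4], 8)
  expect_identical(out[2, ], v[2, ])          # untouched row bit-identical
  # edge run: constant extension of the only neighbour
  tr2 <- matrix(FALSE, 2, 4); tr2[1, 1:2] <- TRUE
  out2 <- sinoValues(limar(sinogram(v, g), tr2))
  expect_equal(out2[1, 1:2], c(2, 2))
  # empty trace: exact identity
  s <- sinogram(v, g)
  expect_identical(sinoValues(limar(s, matrix(FALSE, 2, 4))), v)
  # fully traced view falls back to the nearest untraced view
  tr3 <- matrix(FALSE, 2, 4); tr3[1, ] <- TRUE
  expect_warning(out3 <- limar(sinogram(v, g), tr3), "fully traced")
  expect_identical(sinoValues(out3)[1, ], v[2, ])
})

test_that("threshold prior maps tissue classes as specified", {
  img <- ctImage(matrix(0.02, 8, 8), 3)
  pr <- buildThresholdPrior(img, 0.01, 0.035, softValue = 0.021)
  expect_true(all(pr@values == 0.021))
  air <- buildThresholdPrior(ctImage(matrix(0.001, 8, 8), 3), 0.01, 0.035,
                             0.021)
  expect_true(all(air@values == 0))
  v <- matrix(0.02, 8, 8); v[3:4, 3:4] <- 0.05
  two <- buildThresholdPrior(ctImage(v, 3), 0.01, 0.035, softValue = 0.021)
  expect_true(all(two@values[v == 0.05] == 0.05))
  expect_true(all(two@values[v == 0.02] == 0.021))
  expect_error(buildThresholdPrior(img, 0.04, 0.01, 0.02), "tSoft < tBone")
})

test_that("NMAR identities: empty trace, oracle prior, off-trace preservation", {
  g <- fanBeamGeometry(400, 800, 96, 6, 45)
  set.seed(11)
  v <- matrix(runif(45 * 96) + 0.5, 45, 96)
  s <- sinogram(v, g)
  prior <- discPhantom(64, 3, 45, 0.02)
  # empty trace -> exact identity
  out <- nmarCorrect(s, prior, matrix(FALSE, 45, 96))
  expect_identical(sinoValues(out), v)
  # oracle prior whose projection equals the sinogram -> global identity
  fp <- forwardProject(prior, g)
  tr <- matrix(FALSE, 45, 96); tr[, 40:50] <- TRUE
  out2 <- nmarCorrect(fp, prior, tr)
  expect_equal(sinoValues(out2), sinoValues(fp), tolerance = 1e-10)
  # randomized trials: off-trace entries bit-identical
  for (k in 1:5) {
    set.seed(k)
    vr <- matrix(runif(45 * 96) + 0.2, 45, 96)
    trR <- matrix(runif(45 * 96) < 0.1, 45, 96)
    outR <- nmarCorrect(sinogram(vr, g), prior, trR,
                        inpaint = sample(c("harmonic", "linear"), 1))
    expect_identical(sinoValues(outR)[!trR], vr[!trR])
  }
  expect_error(nmarCorrect(s, prior, matrix(FALSE, 45, 96), eps = -1),
               "eps")
})

test_that("harmonic inpainting fills constant fields exactly", {
  v <- matrix(2.5, 20, 30)
  tr <- matrix(FALSE, 20, 30); tr[8:12, 10:20] <- TRUE
  out <- inpaintTrace(v + 0, tr)
  expect_equal(out, matrix(2.5, 20, 30), tolerance = 1e-6)
  # linear mode on a linear row profile is exact
  v2 <- matrix(rep(seq(0, 1, length.out = 30), each = 20), 20, 30)
  out2 <- inpaintTrace(v2, tr, method = "linear")
  expect_equal(out2, v2, tolerance = 1e-12)
})

test_that("metal reinsertion swaps exactly the masked pixels", {
  a <- ctImage(matrix(1, 8, 8), 3)
  b <- ctImage(matrix(2, 8, 8), 3)
  m <- matrix(FALSE, 8, 8)
  expect_identical(reinsertMetal(a, m, b)@values, a@values)
  m2 <- matrix(TRUE, 8, 8)
  expect_identical(reinsertMetal(a, m2, b)@values, b@values)
  m3 <- matrix(FALSE, 8, 8); m3[2:3, 4] <- TRUE
  out <- reinsertMetal(a, m3, b)
  expect_true(all(out@values[m3] == b@values[m3]))
  expect_true(all(out@values[!m3] == a@values[!m3]))
})

test_that("prior fidelity improves NMAR reconstruction", {
  pair <- fxSuite()$pairs[[3]]
  g <- fxGeom()
  tr <- computeMetalTrace(pair$metalMask, g, 3)
  nm <- !pair$metalMask
  recT <- fbpReconstruct(nmarCorrect(pair$corruptedSino,
                                     buildThresholdPrior(pair$corrupted),
                                     tr), 64, 3)
  recO <- fbpReconstruct(nmarCorrect(pair$corruptedSino, pair$clean, tr),
                         64, 3)
  expect_lt(imageRMSE(recO, pair$clean, nm), imageRMSE(recT, pair$clean, nm))
})
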