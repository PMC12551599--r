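test_that("codec round trip obeys the shape contract", {
  cdc <- vqCodec(64, seed = 3)
  img <- ctImage(matrix(runif(64 * 64, 0, 0.05), 64, 64), 3)
  code <- encodeImage(cdc, img)
  expect_equal(dim(code$grid), c(16, 16, 4))
  expect_equal(dim(code$indices), c(16, 16))
  expect_equal(dim(code$quantized), c(16, 16, 4))
  rec <- decodeLatent(cdc, code, 3)
  expect_equal(dim(rec@values), c(64, 64))
  # quantized grid entries are codebook rows
  k <- code$indices[3, 5]
  expect_equal(as.numeric(code$quantized[3, 5, ]),
               as.numeric(cdc$codebook$vectors[k, ]))
  expect_error(encodeImage(cdc, matrix(0, 30, 30)), "divisible")
  expect_error(vqCodec(30), "divisible")
})

test_that("quantization is idempotent", {
  cdc <- vqCodec(64, seed = 5)
  set.seed(9)
  z <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  q1 <- quantizeLatent(cdc$codebook, z)
  q2 <- quantizeLatent(cdc$codebook, q1$zq)
  expect_identical(q1$indices, q2$indices)
  expect_identical(q1$zq, q2$zq)
})

test_that("codec loss decomposes and vanishes on identical inputs", {
  set.seed(2)
  z <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  cb <- list(K = 5L, D = 3L, vectors = matrix(rnorm(15), 5, 3),
             usage = numeric(5))
  q <- quantizeLatent(cb, z)
  f <- matrix(runif(16), 4, 4)
  lp <- codecLoss(f, f, z, q$zq, beta = 0.25)
  expect_equal(lp$recon, 0)
  expect_equal(lp$codebook + lp$commit, 1.25 * mean((z - q$zq)^2))
  expect_equal(lp$total, lp$recon + lp$codebook + lp$commit)
  # perfect quantization and identical images: total loss 0
  lp0 <- codecLoss(f, f, q$zq, q$zq, beta = 0.25,
                   fe = perceptualExtractor(1))
  expect_equal(lp0$total, 0)
  expect_error(codecLoss(f, f, z, q$zq, beta = -1), "nonnegative")
})

test_that("stop-gradient routing matches finite differences on a 2x2 latent", {
  set.seed(4)
  z <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  cb <- list(K = 6L, D = 3L, vectors = matrix(rnorm(18), 6, 3),
             usage = numeric(6))
  q <- quantizeLatent(cb, z)
  gr <- codecLossGrads(z, q$zq, q$indices, cb$K, beta = 0.25)
  eps <- 1e-7
  # encoder gradient carries only the commitment term
  for (i in c(1, 5, 9)) {
    fz <- function(v) {
      z2 <- z; z2[i] <- v
      0.25 * mean((z2 - q$zq)^2)     # zq held fixed (stop-gradient)
    }
    fd <- (fz(z[i] + eps) - fz(z[i] - eps)) / (2 * eps)
    expect_equal(gr$gEncoder[i], fd, tolerance = 1e-6)
  }
  # codebook gradient carries only the codebook term
  usedCode <- q$indices[1, 1]
  fc <- function(v) {
    cb2 <- cb; cb2$vectors[usedCode, 2] <- v
    zq2 <- array(cb2$vectors[as.vector(q$indices), ], dim(z))
    mean((z - zq2)^2)                # z held fixed (stop-gradient)
  }
  fd <- (fc(cb$vectors[usedCode, 2] + eps) -
           fc(cb$vectors[usedCode, 2] - eps)) / (2 * eps)
  expect_equal(gr$gCodebook[usedCode, 2], fd, tolerance = 1e-6)
  # a code never assigned receives zero gradient
  unused <- setdiff(seq_len(cb$K), unique(as.vector(q$indices)))
  if (length(unused)) expect_true(all(gr$gCodebook[unused, ] == 0))
})

test_that("dead-code refresh re-anchors unused codes deterministically", {
  cb <- list(K = 4L, D = 2L,
             vectors = rbind(c(0, 0), c(1, 1), c(50, 50), c(-40, 7)),
             usage = c(10, 10, 0, 0))
  feats <- matrix(rnorm(40, mean = 5, sd = 0.1), 20, 2)
  cb1 <- withr::with_seed(1, refreshDeadCodes(cb, feats, threshold = 1))
  cb2 <- withr::with_seed(1, refreshDeadCodes(cb, feats, threshold = 1))
  expect_identical(cb1$vectors, cb2$vectors)
  # healthy codes untouched, dead codes moved into the feature cluster
  expect_identical(cb1$vectors[1:2, ], cb$vectors[1:2, ])
  dOld <- min(sqrt(colSums((t(feats) - cb$vectors[3, ])^2)))
  dNew <- min(sqrt(colSums((t(feats) - cb1$vectors[3, ])^2)))
  expect_lt(dNew, dOld)
  # all codes above threshold: unchanged
  cbH <- cb; cbH$usage <- c(5, 5, 5, 5)
  expect_identical(refreshDeadCodes(cbH, feats)$vectors, cb$vectors)
})

test_that("perceptual distance is a seeded pseudometric at zero", {
  fe <- perceptualExtractor(3)
  a <- matrix(runif(64 * 64), 64, 64)
  expect_equal(perceptualDistance(fe, a, a), 0)
  b <- a + 0.1
  expect_gt(perceptualDistance(fe, a, b), 0)
  fe2 <- perceptualExtractor(3)
  expect_equal(perceptualDistance(fe, a, b), perceptualDistance(fe2, a, b))
  # gradient agrees with finite differences
  pd <- perceptualDistance(fe, a, b, grad = TRUE)
  i <- 200; eps <- 1e-6
  a1 <- a; a1[i] <- a[i] + eps
  a2 <- a; a2[i] <- a[i] - eps
  fd <- (perceptualDistance(fe, a1, b) - perceptualDistance(fe, a2, b)) /
    (2 * eps)
  expect_equal(pd$grad[i], fd, tolerance = 1e-5)
})

test_that("short codec training decreases the loss and uses the codebook", {
  imgs <- lapply(fxSuite()$pairs[1:4], function(p) p$clean)
  cdc <- vqCodec(64, nCodes = 32L, seed = 2)
  cdc2 <- trainCodec(cdc, imgs, epochs = 6, lr = 1e-3, seed = 5)
  expect_lt(tail(cdc2$lossHistory, 1), cdc2$lossHistory[1])
  # refresh keeps codebook usage healthier than no-refresh on the same seed
  cdcNo <- trainCodec(cdc, imgs, epochs = 6, lr = 1e-3, seed = 5,
                      refreshEvery = 0)
  usedRefresh <- sum(cdc2$codebook$usage > 0.5)
  usedNo <- sum(cdcNo$codebook$usage > 0.5)
  expect_gte(usedRefresh, usedNo)
})
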