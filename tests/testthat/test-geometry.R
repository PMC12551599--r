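test_that("forward projection of a centred disc matches the chord-length formula", {
  g <- fanBeamGeometry(400, 800, 96, 6, 90)
  mu <- 0.02; rad <- 40
  p <- discPhantom(64, 3, radius = rad, mu = mu)
  vals <- sinoValues(forwardProject(p, g))
  ang <- viewAngles(g)
  u <- ((1:96) - (96 + 1) / 2) * 6
  obs <- c(); oracle <- c()
  for (ia in c(1, 23, 45)) {
    b <- ang[ia]
    S <- 400 * c(cos(b), sin(b))
    a <- -c(cos(b), sin(b)); uv <- c(-sin(b), cos(b))
    for (j in seq(20, 78)) {
      d <- 800 * a + u[j] * uv; d <- d / sqrt(sum(d^2))
      t0 <- -sum(S * d)
      dist <- sqrt(sum((S + t0 * d)^2))   # ray-centre distance
      obs <- c(obs, vals[ia, j])
      oracle <- c(oracle, if (dist < rad) 2 * mu * sqrt(rad^2 - dist^2) else 0)
    }
  }
  sel <- oracle > 0
  expect_gte(sum(sel), 50)
  relL2 <- sqrt(sum((obs[sel] - oracle[sel])^2) / sum(oracle[sel]^2))
  expect_lt(relL2, 0.01)
})

test_that("projector is linear and zero maps to zero", {
  g <- fanBeamGeometry(400, 800, 64, 8, 30)
  z <- forwardProject(ctImage(matrix(0, 32, 32), 5), g)
  expect_true(all(sinoValues(z) == 0))
  set.seed(4)
  X <- ctImage(matrix(rnorm(32 * 32), 32, 32), 5)
  Y <- ctImage(matrix(rnorm(32 * 32), 32, 32), 5)
  a <- 1.7; b <- -0.4
  lhs <- sinoValues(forwardProject(ctImage(a * X@values + b * Y@values, 5), g))
  rhs <- a * sinoValues(forwardProject(X, g)) + b * sinoValues(forwardProject(Y, g))
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("forward/backprojection pair is adjoint", {
  g <- fanBeamGeometry(400, 800, 64, 8, 45)
  set.seed(7)
  x <- ctImage(matrix(rnorm(32 * 32), 32, 32), 5)
  y <- matrix(rnorm(45 * 64), 45, 64)
  lhs <- sum(sinoValues(forwardProject(x, g)) * y)
  rhs <- sum(x@values * backProject(sinogram(y, g), 32, 5)@values)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-4)
})

test_that("FBP round trip reconstructs a piecewise-constant phantom", {
  g <- fanBeamGeometry(400, 800, 160, 3.6, 360)
  p <- discPhantom(128, 1.5, radius = 60, mu = 0.02)
  # add an off-centre insert to make it genuinely piecewise-constant
  p2 <- discPhantom(128, 1.5, radius = 15, mu = 0.03, center = c(20, -10))
  ph <- ctImage(p@values + p2@values, 1.5)
  rec <- fbpReconstruct(forwardProject(ph, g), 128, 1.5)
  err <- imageRMSE(rec, ph)
  expect_lt(err, 0.05 * max(ph@values))
})

test_that("FBP is linear and zero maps to zero", {
  g <- fanBeamGeometry(400, 800, 64, 8, 60)
  z <- fbpReconstruct(sinogram(matrix(0, 60, 64), g), 32, 5)
  expect_true(all(imageValues(z) == 0))
  set.seed(1)
  s <- matrix(abs(rnorm(60 * 64)), 60, 64)
  r1 <- fbpReconstruct(sinogram(s, g), 32, 5)@values
  r2 <- fbpReconstruct(sinogram(2 * s, g), 32, 5)@values
  expect_lt(max(abs(r2 - 2 * r1)) / max(abs(r1)), 1e-8)
})

test_that("projecting a rotated disc equals a view shift of the sinogram", {
  g <- fanBeamGeometry(400, 800, 96, 6, 90)   # 4 deg per view
  d1 <- discPhantom(64, 3, radius = 12, mu = 0.02, center = c(40, 0))
  th <- 8 * pi / 180
  d2 <- discPhantom(64, 3, radius = 12, mu = 0.02,
                    center = 40 * c(cos(th), sin(th)))
  s1 <- sinoValues(forwardProject(d1, g))
  s2 <- sinoValues(forwardProject(d2, g))
  # rotating the object by +2 views should match a circular row shift
  shift <- 2
  s1s <- rbind(s1[(90 - shift + 1):90, ], s1[1:(90 - shift), ])
  expect_lt(mean(abs(s2 - s1s)) / max(s1), 0.02)
})

test_that("FBP round-trip error decreases with view count", {
  p <- discPhantom(64, 3, radius = 50, mu = 0.02)
  errs <- vapply(c(90, 180, 360), function(nv) {
    g <- fanBeamGeometry(400, 800, 96, 6, nv)
    imageRMSE(fbpReconstruct(forwardProject(p, g), 64, 3), p)
  }, numeric(1))
  expect_ordered_desc(errs)
})

test_that("geometry and interface errors are explicit", {
  # FOV smaller than the image support
  gSmall <- fanBeamGeometry(400, 800, 16, 4, 10)
  expect_error(forwardProject(discPhantom(64, 3, 40, 0.02), gSmall),
               "field of view")
  g <- fanBeamGeometry(400, 800, 64, 8, 10)
  s <- sinogram(matrix(0, 10, 64), g)
  expect_error(fbpReconstruct(s, 32, 5, filter = "hann"),
               "supported filters")
  expect_error(fanBeamGeometry(800, 400, 64, 8, 10), "sdd > sid")
  expect_error(sinogram(matrix(0, 5, 64), g), "view angles")
})

test_that("cosine-apodized filter is accepted and smooths noise", {
  g <- defaultGeometry()
  disc <- discPhantom(64, 3, radius = 70, mu = 0.02)
  s <- sinoValues(forwardProject(disc, g))
  set.seed(2)
  noisy <- sinogram(s + matrix(rnorm(length(s), 0, 0.02), nrow(s)), g)
  ramp <- fbpReconstruct(noisy, 64, 3, filter = "ramp")
  cosf <- fbpReconstruct(noisy, 64, 3, filter = "cosine")
  interior <- imageValues(discPhantom(64, 3, radius = 45, mu = 1)) == 1
  expect_lt(sd(cosf@values[interior]), sd(ramp@values[interior]))
})
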