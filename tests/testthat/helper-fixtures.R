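# Shared, lazily built fixtures. Everything is generated in code from fixed
# seeds; heavier objects (simulation suites, trained networks) are built on
# first use and cached for the remainder of the test run.

.fx <- new.env(parent = emptyenv())

fxCache <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fxGeom <- function() fxCache("geom", function() defaultGeometry())

# 6 paired slices for module-level checks
fxSuite <- function() fxCache("suite", function()
  simulationSuite(6, seed = 100))

# 20 paired slices for the ordering studies
fxSuite20 <- function() fxCache("suite20", function()
  simulationSuite(20, seed = 100))

fxCleanSlices <- function() fxCache("cleans", function()
  lapply(1:5, function(k)
    makePhantomPair(dentalPhantomSpec(nMetal = 0), fxGeom(),
                    seed = 500 + k)$clean))

fxSegNet <- function() fxCache("segnet", function() {
  tr <- synthesizeSegDataset(fxSuite()$pairs, fxCleanSlices(), 600,
                             seed = 1)
  trainSegNet(segNet(channels = 12, seed = 1), tr, epochs = 10,
              lr = 1e-3, seed = 2)
})

fxSegTest <- function() fxCache("segtest", function()
  synthesizeSegDataset(fxSuite()$pairs, fxCleanSlices(), 40, seed = 777))

# trained codec + conditional LDM (desk scale)
fxCodecLdm <- function() fxCache("codecldm", function() {
  pairs <- fxSuite20()$pairs[1:10]
  imgs <- c(lapply(pairs, function(p) p$clean),
            lapply(pairs, function(p) p$corrupted))
  cdc <- trainCodec(vqCodec(64, nCodes = 256L, channels = c(24L, 48L),
                            seed = 1),
                    imgs, epochs = 45, lr = 1.5e-3, seed = 3)
  zc <- lapply(pairs, function(p) encodeImage(cdc, p$clean)$grid)
  zy <- lapply(pairs, function(p) encodeImage(cdc, p$corrupted)$grid)
  allz <- array(unlist(zc), c(dim(zc[[1]]), length(zc)))
  stats <- list(mean = apply(allz, 3, mean),
                sd = pmax(apply(allz, 3, sd), 1e-6))
  zcn <- lapply(zc, ctmar:::.latNorm, stats = stats)
  zyn <- lapply(zy, ctmar:::.latNorm, stats = stats)
  sch <- diffusionSchedule(200)
  mdl <- trainDiffusion(epsNet(4, channels = 32, seed = 2), zcn, zyn, sch,
                        steps = 4000, lr = 2e-3, batch = 8, seed = 4)
  list(codec = cdc, model = mdl, stats = stats, sched = sch,
       trainPairs = pairs)
})

# held-out pairs never used in any training
fxHeldOut <- function() fxCache("heldout", function()
  simulationSuite(4, seed = 9000))

expect_ordered_desc <- function(x) {
  testthat::expect_true(all(diff(x) < 0),
                        label = paste(signif(x, 4), collapse = " > "))
}
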