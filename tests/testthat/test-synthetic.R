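test_that("config validates fields and reads defaults from one place", {
  cfg <- syntheticConfig(seed = 1)
  expect_s3_class(cfg, "SyntheticConfig")
  expect_equal(cfg$nRegions, 8L)
  expect_equal(cfg$totalStreamlines, 1000000L)
  expect_error(syntheticConfig(nRegions = 2), "nRegions")
  expect_error(syntheticConfig(edgeDensity = 0), "edgeDensity")
  expect_error(syntheticConfig(bogus = 1), "bogus")
})

test_that("ground truth honors density, seed and the lognormal model", {
  cfg <- syntheticConfig(edgeDensity = 1, seed = 3)
  gt <- generateGroundTruth(cfg)
  W <- connMatrix(gt$truth)
  off <- row(W) != col(W)
  expect_true(all(W[off] > 0))              # complete graph at density 1
  expect_error(generateGroundTruth(syntheticConfig(nRegions = 2, seed = 1)))

  # same seed, same world
  gt2 <- generateGroundTruth(cfg)
  expect_identical(connMatrix(gt2$truth), W)
  expect_identical(regionCentroids(gt2$regions), regionCentroids(gt$regions))

  # with no distance decay the log-weight spread recovers sigma
  cfgBig <- syntheticConfig(nRegions = 200, edgeDensity = 1, lambda = 0,
                            sigma = 1.5, seed = 5)
  Wb <- connMatrix(generateGroundTruth(cfgBig)$truth)
  lw <- log(Wb[row(Wb) != col(Wb)])
  expect_lt(abs(sd(lw) - 1.5) / 1.5, 0.05)

  # full reciprocity couples the two directions' existence
  cfgR <- syntheticConfig(edgeDensity = 0.5, reciprocity = 1, seed = 7,
                          nRegions = 30)
  Wr <- connMatrix(generateGroundTruth(cfgR)$truth)
  expect_identical((Wr > 0), t(Wr > 0))
})

test_that("tracer sampling is multinomial per injection site", {
  cfg <- syntheticConfig(edgeDensity = 1, seed = 11)
  gt <- generateGroundTruth(cfg)
  tr <- sampleTracer(gt$truth, M = 500, seed = 1)
  cnt <- connMatrix(tr)
  expect_true(isDirected(tr))
  expect_equal(unname(colSums(cnt)), rep(500, 8))   # columns sum to M
  expect_true(all(cnt[connMatrix(gt$truth) == 0] == 0))

  # a single incoming edge takes the whole injection
  rs <- RegionSet(c("a", "b", "c"))
  W1 <- matrix(0, 3, 3); W1[2, 1] <- 3; W1[1, 2] <- 1; W1[1, 3] <- 2
  tt <- Connectome(W1, rs, kind = "weight", directed = TRUE)
  one <- connMatrix(sampleTracer(tt, M = 50, seed = 2))
  expect_equal(one[2, 1], 50)

  # an injection with no incoming projections is rejected by name
  W0 <- matrix(0, 3, 3); W0[1, 2] <- 1; W0[1, 3] <- 1
  t0 <- Connectome(W0, rs, kind = "weight", directed = TRUE)
  expect_error(sampleTracer(t0, M = 10, seed = 1), "a")

  # multinomial concentration at M = 1e6: each cell stays within 1%
  # relative error plus four standard errors of its true probability
  big <- sampleTracer(gt$truth, M = 1000000, seed = 3)
  FLN <- connMatrix(computeFLN(big))
  Wt <- connMatrix(gt$truth)
  P <- sweep(Wt, 2, colSums(Wt), "/")
  nz <- which(P > 0)
  M <- 1e6
  bound <- 0.01 * P[nz] + 4 * sqrt(P[nz] * (1 - P[nz]) / M)
  expect_gt(mean(abs(FLN[nz] - P[nz]) <= bound), 0.95)
  # cells with non-vanishing probability really are recovered to 1%
  bigCells <- which(P >= 0.05)
  expect_lt(max(abs(FLN[bigCells] - P[bigCells]) / P[bigCells]), 0.01)
})

test_that("tractography sampling respects the budget, floor and dropout", {
  cfg <- syntheticConfig(edgeDensity = 0.5, reciprocity = 1, epsilon = 0,
                         gamma = 0, totalStreamlines = 20000, seed = 13)
  gt <- generateGroundTruth(cfg)
  st <- sampleTractography(gt$truth, cfg, seed = 5)
  S <- connMatrix(st)
  expect_false(isDirected(st))
  expect_equal(sum(S[upper.tri(S)]), 20000)         # total is exactly T
  # epsilon = 0: no streamline lands on a non-edge of the truth
  wbar <- symmetrize(connMatrix(gt$truth))
  expect_true(all(S[wbar == 0] == 0))

  # poisson allocation is supported and seeded
  cfgP <- syntheticConfig(edgeDensity = 0.5, reciprocity = 1,
                          allocation = "poisson", totalStreamlines = 20000,
                          seed = 13)
  sp1 <- sampleTractography(gt$truth, cfgP, seed = 5)
  sp2 <- sampleTractography(gt$truth, cfgP, seed = 5)
  expect_identical(connMatrix(sp1), connMatrix(sp2))
  expect_lt(abs(sum(connMatrix(sp1)[upper.tri(S)]) - 20000) / 20000, 0.1)
})

test_that("noise-free sampling converges to the deterministic limit", {
  # With gamma = 0, epsilon = 0 and large M, T, the only randomness is the
  # multinomial sampling; the observed tracing/tractography Spearman must
  # converge to its closed-form infinite-sample value, computed here
  # independently from the exact normalized probabilities.
  for (s in 1:3) {
    cfg <- syntheticConfig(gamma = 0, epsilon = 0, seed = 7000 + s)
    sim <- generateGroundTruth(cfg)
    W <- connMatrix(sim$truth)
    FLNlim <- sweep(W, 2, colSums(W), "/")
    FLNlimSym <- (FLNlim + t(FLNlim)) / 2
    wbar <- (W + t(W)) / 2
    FSlim <- wbar / outer(rowSums(wbar), rowSums(wbar), "+")
    up <- upper.tri(W)
    rhoLimit <- cor(rank(FLNlimSym[up]), rank(FSlim[up]))

    tracer <- sampleTracer(sim$truth, M = 1000000, seed = s)
    tract <- sampleTractography(sim$truth, cfg, seed = s + 50)
    tb <- buildEdgeTable(symmetrize(computeFLN(tracer)),
                         fractionalScaling(tract), mode = "symmetric")
    rhoSampled <- coefficient(edgeSpearman(tb))
    expect_lt(abs(rhoSampled - rhoLimit), 0.05)
    expect_gt(rhoSampled, 0.8)   # strong agreement, bounded below 1 by the
                                 # FLN-vs-FS normalization mismatch itself
  }
})
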