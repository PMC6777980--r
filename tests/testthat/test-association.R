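makePair <- function(n = 8, seed = 1) {
  rs <- randRegionSet(n, seed = seed)
  tracing <- symmetrize(computeFLN(
    randCountConnectome(rs, directed = TRUE, seed = seed)))
  tract <- fractionalScaling(
    randCountConnectome(rs, directed = FALSE, seed = seed + 100))
  list(rs = rs, tracing = tracing, tract = tract,
       D = euclideanDistances(rs))
}

test_that("edge tables have the right combinatorics and alignment", {
  p <- makePair(8, seed = 1)
  tbS <- buildEdgeTable(p$tracing, p$tract, p$D, "symmetric")
  expect_equal(nrow(tbS), 28)                       # 8 choose 2
  expect_false(any(tbS$from == tbS$to))

  dirFLN <- computeFLN(randCountConnectome(p$rs, directed = TRUE, seed = 1))
  tbD <- buildEdgeTable(dirFLN, p$tract, p$D, "directed")
  expect_equal(nrow(tbD), 56)                       # 8 * 7 ordered pairs
  # each unordered pair appears once per direction with the same y
  key <- apply(cbind(pmin(tbD$from, tbD$to), pmax(tbD$from, tbD$to)), 1,
               paste, collapse = "|")
  expect_true(all(table(key) == 2))
  expect_true(all(tapply(tbD$y, key, function(v) length(unique(v))) == 1))

  # mismatched region sets are refused
  other <- makePair(7, seed = 9)
  expect_error(buildEdgeTable(p$tracing, other$tract, mode = "symmetric"),
               "region")
  # symmetric mode demands a symmetrized tracing matrix
  expect_error(buildEdgeTable(dirFLN, p$tract, mode = "symmetric"),
               "symmetr")
})

test_that("permuting region order leaves the edge multiset unchanged", {
  p <- makePair(6, seed = 3)
  tb <- buildEdgeTable(p$tracing, p$tract, p$D, "symmetric")
  set.seed(7)
  perm <- sample(6)
  rsP <- RegionSet(regionLabels(p$rs)[perm], regionCentroids(p$rs)[perm, ])
  permM <- function(cc) Connectome(connMatrix(cc)[perm, perm], rsP,
                                   kind = connKind(cc),
                                   directed = isDirected(cc))
  tbP <- buildEdgeTable(permM(p$tracing), permM(p$tract),
                        euclideanDistances(rsP), "symmetric")
  canon <- function(tb) {
    k <- order(paste(pmin(tb$from, tb$to), pmax(tb$from, tb$to)))
    tb[k, c("x", "y", "dist")]
  }
  expect_equal(canon(tbP), canon(tb), ignore_attr = TRUE)
  # and hence identical statistics
  expect_equal(coefficient(edgeSpearman(tbP)), coefficient(edgeSpearman(tb)))
})

test_that("Spearman handles monotone, antitone and midrank-tied tables", {
  x <- c(1, 2, 5, 9, 20)
  up <- data.frame(x = x, y = exp(x))
  expect_equal(coefficient(edgeSpearman(up)), 1)
  down <- data.frame(x = x, y = -x^3)
  expect_equal(coefficient(edgeSpearman(down)), -1)

  # tied zeros (absent connections) get midranks
  tied <- data.frame(x = c(0, 0, 1, 2), y = c(0, 0, 2, 3))
  expect_equal(coefficient(edgeSpearman(tied)), 1)
  expect_equal(coefficient(edgeSpearman(tied)),
               oracleSpearman(tied$x, tied$y))

  expect_error(edgeSpearman(data.frame(x = c(1, 1, 1), y = 1:3)),
               "constant")
  expect_error(edgeSpearman(data.frame(x = 1:2, y = 2:1)), "3 edges")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  for (seed in 1:10) {
    tb <- randEdgeTable(20, seed = seed)
    base <- coefficient(edgeSpearman(tb))
    tb2 <- transform(tb, x = log1p(x), y = y^3)
    expect_equal(coefficient(edgeSpearman(tb2)), base, tolerance = 1e-14)
  }
})

test_that("exact permutation p-value matches enumeration logic", {
  tb <- data.frame(x = c(3, 1, 4, 1.5, 9), y = c(2, 1, 3, 1.2, 8))
  res <- edgeSpearman(tb, exact = TRUE)
  expect_equal(coefficient(res), 1)
  # only the identity and the full reversal reach |rho| = 1 among 5! pairings
  expect_equal(pValue(res), 2 / 120)
  expect_error(edgeSpearman(randEdgeTable(12, seed = 1), exact = TRUE),
               "8 edges")
})

test_that("log-Pearson matches the covariance-formula oracle", {
  tb <- data.frame(x = 1:4, y = 1:4)
  expect_equal(coefficient(edgePearsonLog(tb)), 1)
  tb2 <- data.frame(x = 1:4, y = 10 - 2 * (1:4))
  expect_equal(coefficient(edgePearsonLog(tb2)), -1)

  for (seed in 1:20) {
    tb <- randEdgeTable(28, seed = seed)
    expect_lt(abs(coefficient(edgePearsonLog(tb)) -
                    oraclePearson(tb$x, tb$y)), 1e-12)
    # p-value agrees with the classical t test for correlation
    ct <- suppressWarnings(cor.test(tb$x, tb$y))
    expect_equal(pValue(edgePearsonLog(tb)), unname(ct$p.value),
                 tolerance = 1e-10)
  }
})

test_that("bootstrap CI is deterministic, leaves the RNG alone, and is
          degenerate for perfectly monotone tables", {
  tb <- data.frame(x = 1:10, y = (1:10)^2)
  r1 <- bootstrapCI(tb, "spearman", B = 200, seed = 5)
  expect_equal(unname(confInt(r1)), c(1, 1))  # every valid resample has rho 1

  tb2 <- randEdgeTable(28, seed = 2)
  a <- bootstrapCI(tb2, "spearman", B = 300, seed = 11)
  b <- bootstrapCI(tb2, "spearman", B = 300, seed = 11)
  expect_identical(confInt(a), confInt(b))
  c2 <- bootstrapCI(tb2, "spearman", B = 300, seed = 12)
  expect_false(identical(confInt(a), confInt(c2)))

  # caller's RNG stream must be untouched by a seeded bootstrap
  set.seed(99); before <- get(".Random.seed", globalenv())
  invisible(bootstrapCI(tb2, "pearson_log", B = 150, seed = 3))
  expect_identical(get(".Random.seed", globalenv()), before)

  expect_error(bootstrapCI(tb2, "spearman", B = 300, level = 1.2), "level")
  expect_error(bootstrapCI(tb2, "spearman", B = 50), "at least 100")
  # interval brackets the full-sample coefficient
  expect_true(confInt(a)["low"] <= coefficient(a) &&
                coefficient(a) <= confInt(a)["high"])
})

test_that("partial Spearman removes the distance-explained association", {
  # constant distances: regression only centers, so plain Spearman returns
  tb <- randEdgeTable(20, seed = 4)
  tb$dist <- 7
  expect_equal(coefficient(partialSpearmanDistance(tb)),
               coefficient(edgeSpearman(tb)), tolerance = 1e-12)

  # hand-solved OLS on 4 edges via the normal equations
  tb4 <- data.frame(x = c(1.2, 0.4, -0.3, 2.2), y = c(0.3, 1.4, 0.2, -0.9),
                    dist = c(2, 5, 9, 14))
  rx <- oracleResiduals(tb4$x, tb4$dist)
  ry <- oracleResiduals(tb4$y, tb4$dist)
  expect_equal(coefficient(partialSpearmanDistance(tb4)),
               oraclePearson(oracleRanks(rx), oracleRanks(ry)),
               tolerance = 1e-10)

  # when distance explains all shared signal, the partial coefficient
  # hovers near zero
  rhos <- vapply(1:100, function(seed) {
    set.seed(seed)
    d <- runif(56, 1, 30)
    x <- -0.3 * d + rnorm(56, sd = 0.3)
    y <- -0.3 * d + rnorm(56, sd = 1.5)
    coefficient(partialSpearmanDistance(data.frame(x = x, y = y, dist = d)))
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.2)

  expect_error(partialSpearmanDistance(transform(tb, dist = NA_real_)),
               "distance")
})
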