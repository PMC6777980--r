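test_that("FLN divides each injection column by its labeled-neuron total", {
  rs <- RegionSet(c("a", "b", "c"))
  N <- rbind(c(0, 20, 10), c(10, 0, 0), c(0, 30, 0))
  cc <- Connectome(N, rs, kind = "count", directed = TRUE)
  FLN <- connMatrix(computeFLN(cc))
  # single-source column normalizes to 1
  expect_equal(unname(FLN[, "a"]), c(0, 1, 0))
  # hand-computed 20/50, 30/50
  expect_equal(unname(FLN[, "b"]), c(0.4, 0, 0.6))
  expect_equal(unname(colSums(FLN)), c(1, 1, 1))

  # an injection with no labeled neurons is not interpretable
  N0 <- N; N0[, 3] <- 0
  cc0 <- Connectome(N0, rs, kind = "count", directed = TRUE)
  expect_error(computeFLN(cc0), "c")
})

test_that("fractional scaling follows the two-total denominator", {
  rs2 <- RegionSet(c("a", "b"))
  S2 <- rbind(c(0, 10), c(10, 0))
  fs2 <- connMatrix(fractionalScaling(
    Connectome(S2, rs2, kind = "count", directed = FALSE)))
  expect_equal(fs2["a", "b"], 0.5)   # symmetry forces 1/2 for two regions

  rs3 <- RegionSet(c("a", "b", "c"))
  S3 <- matrix(0, 3, 3, dimnames = list(NULL, NULL))
  S3[1, 2] <- S3[2, 1] <- 10
  S3[1, 3] <- S3[3, 1] <- 30
  S3[2, 3] <- S3[3, 2] <- 60
  cc3 <- Connectome(S3, rs3, kind = "count", directed = FALSE)
  fs3 <- connMatrix(fractionalScaling(cc3))
  expect_equal(fs3[1, 2], 10 / ((10 + 30) + (10 + 60)))  # literal formula
  expect_equal(fs3[1, 3], 30 / ((10 + 30) + (30 + 60)))

  # documented variant: the shared count enters the denominator once
  fs3b <- connMatrix(fractionalScaling(cc3, subtractShared = TRUE))
  expect_equal(fs3b[1, 2], 10 / (40 + 70 - 10))

  # scale invariance: S and 7S give identical FS
  cc7 <- Connectome(7 * S3, rs3, kind = "count", directed = FALSE)
  expect_equal(connMatrix(fractionalScaling(cc7)), fs3)
})

test_that("symmetrize averages reciprocal weights and is idempotent", {
  rs <- RegionSet(c("a", "b"))
  m <- Connectome(rbind(c(0, 0.2), c(0.4, 0)), rs, kind = "weight",
                  directed = TRUE)
  sm <- symmetrize(m)
  expect_false(isDirected(sm))
  expect_equal(connMatrix(sm)["a", "b"], 0.3)
  expect_equal(connMatrix(sm)["b", "a"], 0.3)

  for (seed in 1:10) {
    set.seed(seed)
    M <- matrix(runif(36), 6, 6); diag(M) <- 0
    once <- symmetrize(M)
    expect_identical(symmetrize(once), once)        # bit-exact idempotence
    expect_identical(symmetrize(once), (once + t(once)) / 2)
  }
})

test_that("pseudocount-log chain is finite, exact on a toy, and monotone", {
  rs <- RegionSet(c("a", "b"))
  # a zero count must map to a finite log value
  N <- rbind(c(0, 0), c(7, 0))
  cc <- Connectome(N, rs, kind = "count", directed = TRUE)
  L <- connMatrix(pseudocountLog(cc, "fln"))
  expect_true(all(is.finite(L)))
  # hand-chained: +1 -> FLN -> ln on the 2x2 toy
  expect_equal(L["a", "b"], log(1 / 1), tolerance = 1e-12)
  expect_equal(L["b", "a"], log(8 / 8), tolerance = 1e-12)

  rs3 <- RegionSet(c("a", "b", "c"))
  N3 <- rbind(c(0, 5, 1), c(2, 0, 9), c(11, 3, 0))
  cc3 <- Connectome(N3, rs3, kind = "count", directed = TRUE)
  L3 <- connMatrix(pseudocountLog(cc3, "fln"))
  hand <- log((N3 + 1) / rbind(colSums(N3 + 1) - 1, colSums(N3 + 1) - 1,
                               colSums(N3 + 1) - 1))
  off <- row(N3) != col(N3)
  expect_equal(L3[off], hand[off], tolerance = 1e-12)

  # larger raw count implies larger log value within a column
  expect_true(L3[3, 1] > L3[2, 1])
  expect_true(L3[1, 2] > L3[3, 2])

  # FLN without direction information is refused
  sym <- Connectome(pmax(N3, t(N3)) - diag(diag(pmax(N3, t(N3)))), rs3,
                    kind = "count", directed = FALSE)
  expect_error(pseudocountLog(sym, "fln"), "directed")
})

test_that("normalization invariants hold over random count matrices", {
  for (seed in 1:25) {
    rs <- randRegionSet(6, seed = seed, centroids = FALSE)
    dcc <- randCountConnectome(rs, directed = TRUE, seed = seed)
    FLN <- connMatrix(computeFLN(dcc))
    expect_lt(max(abs(colSums(FLN) - 1)), 1e-12)

    scc <- randCountConnectome(rs, directed = FALSE, seed = seed + 100)
    FS <- connMatrix(fractionalScaling(scc))
    expect_identical(FS, t(FS))
    FS3 <- connMatrix(fractionalScaling(
      Connectome(3 * connMatrix(scc), rs, kind = "count", directed = FALSE)))
    expect_equal(FS3, FS, tolerance = 1e-14)

    expect_true(all(is.finite(connMatrix(pseudocountLog(scc, "fs")))))
  }
})
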