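test_that("windowed correlation reproduces elementary identities", {
  N <- 64
  tt <- seq_len(N)
  x <- sin(2 * pi * tt / 16)
  sig <- rbind(x, x, -x)
  C <- windowedCorrelation(sig, frame = 32, Tw = 32, dt = 1)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(C, t(C))
  expect_true(all(diag(C) == 1))
})

test_that("sin and cos are uncorrelated over whole periods", {
  # the 41-sample window spans exactly 4 periods of 41/4 samples, so the
  # discrete orthogonality sum vanishes identically
  tt <- 0:99
  x <- sin(2 * pi * 4 * tt / 41)
  y <- cos(2 * pi * 4 * tt / 41)
  C <- windowedCorrelation(rbind(x, y), frame = 50, Tw = 40, dt = 1)
  expect_lt(abs(C[1, 2]), 1e-10)
})

test_that("zero-variance windows yield NA entries that never create edges", {
  sig <- rbind(sin(1:50), rep(1, 50), cos(1:50))
  C <- windowedCorrelation(sig, 25, Tw = 20, dt = 1)
  expect_true(is.na(C[1, 2]))
  A <- functionalGraph(C, 0.5)
  expect_false(any(A[2, ]))
  expect_error(windowedCorrelation(sig, 25, Tw = -1, dt = 1), "positive")
})

test_that("the connectivity cutoff is strict: exactly theta is no edge", {
  C <- matrix(c(1, 0.90, 0.95,
                0.90, 1, 0.20,
                0.95, 0.20, 1), 3, 3)
  A <- functionalGraph(C, 0.90)
  expect_false(A[1, 2])   # == cutoff, "exceeds" not satisfied
  expect_true(A[1, 3])
  expect_false(A[2, 3])
  expect_error(functionalGraph(C, 1), "cutoff")
})

test_that("edge count is monotone non-increasing in the cutoff", {
  set.seed(5)
  sig <- matrix(rnorm(20 * 80), 20, 80)
  C <- windowedCorrelation(sig, 40, Tw = 30, dt = 1)
  cuts <- seq(0.02, 0.97, length.out = 20)
  E <- vapply(cuts, function(th) {
    A <- functionalGraph(C, th)
    sum(A[upper.tri(A)])
  }, numeric(1))
  expect_true(all(diff(E) <= 0))
})

test_that("clustering coefficients match the hand-worked graphs", {
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(localClustering(K3), rep(1, 3))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1; star[2:4, 1] <- 1
  expect_equal(localClustering(star), rep(0, 4))

  # vertices {1,2,3,4}, edges {1-2, 1-3, 2-3, 1-4}
  A <- matrix(0, 4, 4)
  A[cbind(c(1, 1, 2, 1), c(2, 3, 3, 4))] <- 1
  A <- A + t(A)
  Cm <- localClustering(A)
  expect_equal(Cm, c(1 / 3, 1, 1, 0))
  expect_equal(meanClustering(A), 7 / 12)
})

test_that("clustering matches brute-force triangle enumeration on random graphs", {
  set.seed(77)
  for (i in 1:200) {
    M <- sample(4:12, 1)
    A <- randomAdjacency(M, runif(1, 0.2, 0.8))
    expect_equal(localClustering(A), bruteLocalClustering(A))
  }
})

test_that("clustering agrees with the igraph reference implementation", {
  set.seed(42)
  for (i in 1:20) {
    A <- randomAdjacency(15, 0.4)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    ref <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    # igraph returns NaN->0 handling via isolates; degree-1 vertices are 0
    ref[is.na(ref)] <- 0
    expect_equal(localClustering(A), ref)
  }
})

test_that("ER null graphs preserve the exact edge count of every realization", {
  set.seed(8)
  A <- randomAdjacency(30, 0.2)
  E <- sum(A[upper.tri(A)])
  nulls <- erNull(A, n = 25, seed = 123)
  for (g in nulls) {
    expect_equal(sum(g[upper.tri(g)]), E)
    expect_true(isSymmetric(g))
    expect_false(any(diag(g)))
  }
  # seeded reproducibility
  nulls2 <- erNull(A, n = 25, seed = 123)
  expect_identical(nulls, nulls2)
})

test_that("degenerate ER edge counts give empty and complete graphs", {
  g0 <- erNull(M = 6, nEdges = 0, n = 1, seed = 1)[[1]]
  expect_false(any(g0))
  expect_equal(meanClustering(g0), 0)
  gFull <- erNull(M = 6, nEdges = 15, n = 1, seed = 1)[[1]]
  expect_true(all(gFull[upper.tri(gFull)]))
  expect_equal(meanClustering(gFull), 1)
  expect_error(erNull(M = 4, nEdges = 7), "exceeds")
})

test_that("ER null mean clustering converges to the density p", {
  M <- 200; p <- 0.05
  E <- round(p * M * (M - 1) / 2)
  st <- erNullClustering(M = M, nEdges = E, n = 100, seed = 2024)
  expect_lt(abs(st$mean - p), 0.01)
})

test_that("mean field is 1 for identical signals and small for noise", {
  x <- sin(2 * pi * (1:120) / 30)
  sigSame <- MitoSignalSet(rbind(x, x, x, x) + 10, dt = 1,
                           gridRow = c(1, 1, 2, 2), gridCol = c(1, 2, 1, 2))
  mf <- meanField(sigSame, frame = 60, Tw = 60)
  expect_equal(mf$mean, 1)
  expect_equal(mf$perMito, rep(1, 4))

  set.seed(31)
  noise <- MitoSignalSet(matrix(rnorm(50 * 200), 50, 200), dt = 1,
                         gridRow = rep(1:5, each = 10),
                         gridCol = rep(1:10, times = 5))
  vals <- vapply(seq(60, 140, by = 10), function(t) {
    meanField(noise, t, Tw = 100)$mean
  }, numeric(1))
  expect_true(all(abs(vals) < 0.1))
})

test_that("mean field distinguishes coherent halves across a seam", {
  x <- sin(2 * pi * (1:100) / 25)
  # 2 x 4 lattice: columns 1-2 run x, columns 3-4 run -x
  sig <- rbind(x, x, -x, -x, x, x, -x, -x) + 5
  s <- MitoSignalSet(sig[c(1, 2, 3, 4, 5, 6, 7, 8), ], dt = 1,
                     gridRow = rep(1:2, each = 4), gridCol = rep(1:4, 2))
  mf <- meanField(s, 50, Tw = 50)
  # interior vertices (all neighbours in the same half) score 1
  expect_equal(mf$perMito[c(1, 4, 5, 8)], rep(1, 4))
  # seam vertices average one +1 and one -1 neighbour with a same-half one
  expect_true(all(mf$perMito[c(2, 3, 6, 7)] < 1))
  expect_equal(mf$perMito[2], mean(c(1, 1, -1)))
})

test_that("isolated lattice vertices are excluded with a warning", {
  x <- sin(2 * pi * (1:60) / 15)
  s <- MitoSignalSet(rbind(x, x, x), dt = 1,
                     latticeEdges = matrix(c(1L, 2L), 1))
  expect_warning(mf <- meanField(s, 30, Tw = 30), "isolated")
  expect_true(is.na(mf$perMito[3]))
  expect_equal(mf$mean, 1)
})

test_that("clusteringSeries ties the stages together reproducibly", {
  sim <- simulateNetwork(syntheticConfig(gridRows = 4, gridCols = 4,
                                         nFrames = 400, seed = 19))
  s1 <- clusteringSeries(sim$signals, frames = c(100, 200), Tw = 70,
                         nNull = 10, seed = 5)
  s2 <- clusteringSeries(sim$signals, frames = c(100, 200), Tw = 70,
                         nNull = 10, seed = 5)
  expect_identical(s1$C, s2$C)
  expect_identical(s1$CNullMean, s2$CNullMean)
  expect_true(all(s1$C >= 0 & s1$C <= 1))
  localC <- attr(s1, "localC")
  expect_equal(colMeans(localC), s1$C)
})

test_that("correlation maps interpolate linearly between lattice sites", {
  pos <- data.frame(row = c(0, 0, 4, 4), col = c(0, 4, 0, 4),
                    gridRow = c(1, 1, 2, 2), gridCol = c(1, 2, 1, 2))
  # constant field
  mp <- correlationMap(rep(0.7, 4), pos, shape = c(5, 5))
  expect_true(all(abs(mp[!is.na(mp)] - 0.7) < 1e-12))
  # data sites reproduce their values
  vals <- c(0, 1, 0.5, 0.25)
  mp2 <- correlationMap(vals, pos, shape = c(5, 5))
  expect_equal(mp2[1, 1], 0)
  expect_equal(mp2[1, 5], 1)
  expect_equal(mp2[5, 1], 0.5)
  expect_equal(mp2[5, 5], 0.25)
  # midpoint between sites 0 and 1 is 0.5
  expect_equal(mp2[1, 3], 0.5)
  # collinear positions are rejected
  badPos <- data.frame(row = c(0, 0, 0), col = c(0, 2, 4),
                       gridRow = c(1, 1, 1), gridCol = 1:3)
  expect_error(correlationMap(1:3, badPos, c(3, 5)), "collinear")
})
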