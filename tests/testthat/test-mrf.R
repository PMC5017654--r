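test_that("buildNeighborhood produces the expected lattice edges", {
  expect_equal(nEdges(buildNeighborhood(1, 1, 4)), 0L)
  expect_equal(nEdges(buildNeighborhood(2, 2, 4)), 4L)
  # 3x3 8-connectivity: brute-force count of pairs at Chebyshev distance 1
  coords <- expand.grid(r = 1:3, c = 1:3)
  cnt <- 0L
  for (a in 1:8) for (b in (a + 1):9) {
    ch <- max(abs(coords[a, 1] - coords[b, 1]), abs(coords[a, 2] - coords[b, 2]))
    if (ch == 1) cnt <- cnt + 1L
  }
  expect_equal(cnt, 20L)
  expect_equal(nEdges(buildNeighborhood(3, 3, 8)), cnt)
  # interior pixel degree
  g4 <- buildNeighborhood(5, 5, 4)
  g8 <- buildNeighborhood(5, 5, 8)
  center <- 13L  # (3,3) column-major
  expect_length(neighborsOf(g4, center)$idx, 4L)
  expect_length(neighborsOf(g8, center)$idx, 8L)
  expect_error(buildNeighborhood(3, 3, 6), "connectivity")
})

test_that("neighborhood graphs are symmetric with no self-edges (all shapes to 4x4)", {
  for (h in 1:4) for (w in 1:4) for (conn in c(4L, 8L)) {
    g <- buildNeighborhood(h, w, conn)
    n <- h * w
    for (i in seq_len(n)) {
      nb <- neighborsOf(g, i)
      expect_false(i %in% nb$idx)
      for (k in seq_along(nb$idx)) {
        back <- neighborsOf(g, nb$idx[k])
        pos <- match(i, back$idx)
        expect_false(is.na(pos))
        expect_equal(back$w[pos], nb$w[k])
      }
    }
  }
})

test_that("agreementSum counts weighted neighbor votes for a candidate label", {
  g <- buildNeighborhood(3, 3, 4)
  lab <- matrix(1L, 3, 3)
  expect_equal(agreementSum(5, 2L, lab, g), 0)      # nobody has label 2
  expect_equal(agreementSum(5, 1L, lab, g), 4)      # all 4 interior neighbors
  # 3x3 checkerboard, corner pixel: its 2 rook neighbors have the other color
  cb <- matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L), 3, 3)
  expect_equal(agreementSum(1, cb[1, 1], cb, g), 0)
  expect_equal(agreementSum(1, 2L, cb, g), 2)
})

test_that("each neighbor votes for exactly one label (agreement partitions weight)", {
  set.seed(7)
  for (conn in c(4L, 8L)) {
    g <- buildNeighborhood(4, 5, conn)
    lab <- matrix(sample(1:3, 20, replace = TRUE), 4, 5)
    for (i in 1:20) {
      tot <- sum(neighborsOf(g, i)$w)
      acc <- sum(sapply(1:3, function(k) agreementSum(i, k, lab, g)))
      expect_equal(acc, tot)
    }
  }
})

test_that("mrfLogFactor is linear and vanishes when smoothing is off", {
  expect_equal(mrfLogFactor(3.7, 0), 0)
  expect_equal(mrfLogFactor(0, 0.5), 0)
  expect_equal(mrfLogFactor(4, 0.001), 0.004)
  expect_equal(mrfLogFactor(2.5, 0.02), 2 * mrfLogFactor(2.5, 0.01))
  expect_error(mrfLogFactor(1, -0.1), "non-negative")
})
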