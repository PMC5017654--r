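test_that("jaccardIndex follows |A.B|/|AuB|", {
  expect_equal(jaccardIndex(1:4, 1:4), 1)
  expect_equal(jaccardIndex(1:3, 4:6), 0)
  expect_equal(jaccardIndex(1:3, 2:5), 0.4)
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(jaccardIndex(m, m), 1)
  expect_error(jaccardIndex(integer(0), logical(0)), "empty")
})

test_that("jaccardIndex is symmetric (property over random sets)", {
  set.seed(5)
  for (rep in 1:1000) {
    A <- sample(20, sample(1:10, 1))
    B <- sample(20, sample(1:10, 1))
    expect_identical(jaccardIndex(A, B), jaccardIndex(B, A))
  }
})

test_that("matchLabels is permutation invariant and pessimistic about merges", {
  truth <- matrix(c(1L, 1L, 2L, 2L, 3L, 3L), 2, 3)
  perm <- matrix(c(7L, 7L, 5L, 5L, 6L, 6L), 2, 3)
  mr <- matchLabels(perm, truth)
  expect_equal(unname(objectJaccard(mr)), c(1, 1, 1))
  expect_equal(labelMapping(mr), c("5" = 2L, "6" = 3L, "7" = 1L))
  # pred merges two truth objects: one matched with JI < 1, the other 0
  truth2 <- matrix(c(1L, 1L, 2L, 2L), 1)
  merged <- matrix(1L, 1, 4)
  mr2 <- matchLabels(merged, truth2)
  ji <- objectJaccard(mr2)
  expect_equal(sort(unname(ji)), c(0, 0.5))
  # checkerboard pred vs uniform truth on 2x2: best mapping scores 0.5
  cb <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  uni <- matrix(1L, 2, 2)
  expect_equal(unname(objectJaccard(matchLabels(cb, uni))), 0.5)
  expect_length(matchLabels(cb, uni)@unmatchedPred, 1L)
  expect_error(matchLabels(matrix(1L, 2, 2), matrix(1L, 2, 3)), "shape")
})

test_that("matchLabels total overlap is optimal (vs brute force, <= 5 labels/side)", {
  set.seed(8)
  for (rep in 1:20) {
    np <- sample(2:5, 1); nt <- sample(2:5, 1)
    pred <- matrix(sample(seq_len(np), 36, replace = TRUE), 6, 6)
    truth <- matrix(sample(seq_len(nt), 36, replace = TRUE), 6, 6)
    mr <- matchLabels(pred, truth)
    got <- sum(vapply(names(labelMapping(mr)), function(p)
      sum(pred == as.integer(p) & truth == labelMapping(mr)[[p]]), 1.0))
    M <- unclass(table(pred, truth))
    expect_equal(got, bruteBestOverlap(M))
  }
})

test_that("scoreRun tabulates per-image per-object Jaccard", {
  ph <- generatePhantoms(defaultLungSpec(2, seed = 3))
  perfect <- scoreRun(truthLabels(ph), ph)
  expect_true(all(perfect$jaccard == 1))
  expect_equal(names(perfect), c("image", "object", "jaccard"))
  expect_equal(sum(perfect$image == 2), 3)  # image 2 lacks the tumor
  # all-one-label segmentation of a half/half 2-class truth -> JI 0.5
  truth <- list(matrix(rep(c(1L, 2L), each = 8), 4, 4))
  allone <- list(matrix(1L, 4, 4))
  tab <- scoreRun(allone, truth)
  expect_equal(sort(tab$jaccard), c(0, 0.5))
  expect_error(scoreRun(allone, rep(truth, 2)), "mismatch")
})

test_that("scoreRun on an end-to-end phantom run is finite and complete", {
  ph <- generatePhantoms(defaultLungSpec(2, seed = 8))
  res <- runSampler(ph, hyperParameters(),
                    samplerConfig(nSweeps = 80, burnIn = 30, seed = 2))
  tab <- scoreRun(res, ph)
  expect_true(all(is.finite(tab$jaccard)))
  expect_true(all(tab$jaccard >= 0 & tab$jaccard <= 1))
  expect_equal(nrow(tab), 4 + 3)  # 4 objects in image 1, 3 in image 2
})
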