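test_that("phantom generation is deterministic and restores the RNG state", {
  spec <- defaultLungSpec(3, seed = 17)
  set.seed(999)
  before <- .Random.seed
  a <- generatePhantoms(spec)
  expect_identical(.Random.seed, before)
  b <- generatePhantoms(spec)
  expect_identical(images(a), images(b))
  expect_identical(truthLabels(a), truthLabels(b))
})

test_that("the noise-free limit is piecewise constant at the class means", {
  spec <- phantomSpec(1, 8, 8, classMeans = c(-2, 3), classSd = 1e-12,
    shapes = list(list(shape = "rectangle", class = 2L, center = c(4, 4),
                       radii = c(2, 2))), seed = 1)
  ph <- generatePhantoms(spec)
  expect_equal(images(ph)[[1]],
               array(spec@classMeans[truthLabels(ph)[[1]]], c(8, 8)),
               tolerance = 1e-9)
})

test_that("per-region empirical means and variances match the generating classes", {
  spec <- defaultLungSpec(4, seed = 2)
  ph <- generatePhantoms(spec)
  sd0 <- spec@classSd
  for (i in 1:4) {
    lab <- truthLabels(ph)[[i]]
    img <- images(ph)[[i]]
    for (k in unique(as.vector(lab))) {
      xs <- img[lab == k]
      expect_lt(abs(mean(xs) - spec@classMeans[k]),
                3 * sd0 / sqrt(length(xs)))
    }
  }
  # within-region variance at 10^4 pixels within 10%
  big <- phantomSpec(1, 100, 100, classMeans = 0, classSd = 0.5, seed = 9)
  xb <- images(generatePhantoms(big))[[1]]
  expect_lt(abs(var(as.vector(xb)) - 0.25), 0.025)
})

test_that("geometric truth regions are spatially coherent (single components)", {
  ph <- generatePhantoms(defaultLungSpec(1, seed = 4))
  lab <- truthLabels(ph)[[1]]
  # lungs are two ellipses -> 2 components; vertebra and tumor single
  expect_equal(nComponents(lab == 2L), 2L)
  expect_equal(nComponents(lab == 3L), 1L)
  expect_equal(nComponents(lab == 4L), 1L)
})

test_that("defaultLungSpec encodes the canonical fixture", {
  s1 <- defaultLungSpec(1, seed = 1)
  expect_true(validObject(s1))
  expect_equal(s1@subsets[[1]], 1:4)
  s4 <- defaultLungSpec(4, seed = 1)
  expect_true(validObject(s4))
  expect_equal(s4@subsets[[2]], 1:3)  # image 2 lacks the tumor class
  expect_equal(s4@classNames[4], "tumor")
  expect_gte(meanSeparation(s4), 4)
  expect_equal(dim(images(generatePhantoms(s4))[[3]]), c(64L, 64L))
})

test_that("phantom validity guards degenerate specs", {
  expect_error(phantomSpec(1, 8, 8, classMeans = c(0, 1), classSd = 0.5,
    shapes = list(list(shape = "disk", class = 2L, center = c(4, 4),
                       radii = 0)), seed = 1), "radius")
  expect_error(phantomSpec(2, 8, 8, classMeans = c(0, 1), classSd = 0.5,
    subsets = list(1L, 1L), seed = 1), "every class")
  expect_error(phantomSpec(1, 8, 8, classMeans = c(0, 1), classSd = -1,
    seed = 1), "classSd")
})

test_that("the Potts layout draws coherent labels from the declared subset", {
  spec <- phantomSpec(2, 12, 12, classMeans = c(-1, 0, 1), classSd = 0.3,
                      subsets = list(c(1L, 2L), c(2L, 3L)),
                      layout = "potts", potts = list(beta = 1.5, sweeps = 8),
                      seed = 6)
  ph <- generatePhantoms(spec)
  expect_true(all(truthLabels(ph)[[1]] %in% c(1L, 2L)))
  expect_true(all(truthLabels(ph)[[2]] %in% c(2L, 3L)))
  # coherence: at beta = 1.5 most 4-neighbor pairs agree
  lab <- truthLabels(ph)[[1]]
  agree <- mean(lab[-12, ] == lab[-1, ])
  expect_gt(agree, 0.6)
  expect_identical(truthLabels(generatePhantoms(spec)), truthLabels(ph))
})
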