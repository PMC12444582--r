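test_that("features on the unit-gradient sawtooth match hand enumeration", {
  # transitions per period: 0->1, 1->2, 2->3 (prob 1/4 each) and 3->0
  g <- gradientGLCM(ng = 4, nabla = 1, d = 1, periods = 3)
  expect_equal(haralickASM(g), 0.25)
  expect_equal(haralickContrast(g), 1^2 * 3 / 4 + 3^2 * 1 / 4)  # = 3
  expect_equal(haralickCorrelation(g), (2 - 2.25) / 1.25)       # = -0.2
  expect_equal(haralickIDM(g, "abs"), (3 / 2 + 1 / 4) / 4)      # 0.4375
  expect_equal(haralickIDM(g, "squared"), (3 / 2 + 1 / 10) / 4) # 0.4
  g72 <- gradientGLCM(ng = 7, nabla = 2, d = 1)
  expect_equal(haralickContrast(g72), 12)
})

test_that("point-mass and diagonal GLCMs hit the feature extremes", {
  const <- GrayImage(matrix(3L, 4, 4), nLevels = 8)
  g <- computeGLCM(const, 0, 1)
  expect_equal(haralickASM(g), 1)
  expect_equal(haralickContrast(g), 0)
  expect_equal(haralickIDM(g, "abs"), 1)
  expect_equal(haralickIDM(g, "squared"), 1)
  expect_warning(f3 <- haralickCorrelation(g), "undefined")
  expect_true(is.nan(f3))

  # identity-like diagonal GLCM with >= 2 levels: perfect correlation
  img <- GrayImage(matrix(rep(c(0L, 2L), each = 4), 4, 2), nLevels = 4)
  gd <- computeGLCM(img, 0, 1)  # within-column pairs only
  expect_equal(sum(glcmCounts(gd) * upper.tri(glcmCounts(gd))), 0)
  expect_equal(haralickCorrelation(gd), 1)
})

test_that("each feature equals its naive double-loop oracle on random GLCMs", {
  withr::local_seed(2024)
  for (rep in 1:40) {
    ng <- sample(2:8, 1)
    img <- GrayImage(randomGrayMatrix(sample(3:12, 1), sample(3:12, 1), ng),
                     nLevels = ng)
    g <- computeGLCM(img, sample(0:2, 1), sample(1:2, 1),
                     cyclic = rep %% 2 == 0)
    p <- glcmProbs(g)
    expect_equal(haralickASM(g), refASM(p), tolerance = 1e-12)
    expect_equal(haralickContrast(g), refContrast(p), tolerance = 1e-12)
    expect_equal(haralickIDM(g, "abs"), refIDM(p), tolerance = 1e-12)
    expect_equal(haralickIDM(g, "squared"), refIDM(p, squared = TRUE),
                 tolerance = 1e-12)
    f3 <- suppressWarnings(haralickCorrelation(g))
    expect_equal(f3, refCorrelation(p), tolerance = 1e-12)
  }
})

test_that("feature bounds hold on random GLCMs", {
  withr::local_seed(99)
  for (rep in 1:30) {
    ng <- sample(2:8, 1)
    img <- GrayImage(randomGrayMatrix(sample(2:10, 1), sample(2:10, 1), ng),
                     nLevels = ng)
    g <- computeGLCM(img, 1, 0, cyclic = TRUE)
    fs <- haralickFeatures(g)
    v <- featureValues(fs)
    expect_gte(v[["f1ASM"]], 1 / fs@nNonzero)
    expect_lte(v[["f1ASM"]], 1)
    expect_gte(v[["f2Contrast"]], 0)
    if (!is.nan(v[["f3Correlation"]])) {
      expect_gte(v[["f3Correlation"]], -1 - 1e-12)
      expect_lte(v[["f3Correlation"]], 1 + 1e-12)
    }
    expect_lte(v[["f5IDMSq"]], v[["f5IDMAbs"]])
    expect_gt(v[["f5IDMSq"]], 0)
    expect_lte(v[["f5IDMAbs"]], 1)
    # contrast is zero iff all mass on the diagonal
    offDiag <- sum(glcmCounts(g)[.row(dim(glcmCounts(g))) !=
                                   .col(dim(glcmCounts(g)))])
    expect_equal(v[["f2Contrast"]] == 0, offDiag == 0)
  }
})

test_that("features are invariant to transposing the image with the offset", {
  withr::local_seed(5)
  px <- randomGrayMatrix(7, 5, 6)
  a <- computeGLCM(GrayImage(px, nLevels = 6), 2, 1, cyclic = TRUE)
  b <- computeGLCM(GrayImage(t(px), nLevels = 6), 1, 2, cyclic = TRUE)
  expect_equal(featureValues(haralickFeatures(a)),
               featureValues(haralickFeatures(b)))
})

test_that("normalization schemes apply the documented factors", {
  g <- gradientGLCM(ng = 4, nabla = 1, d = 1)
  fs <- haralickFeatures(g)
  paper <- featureValues(normalizeFeatures(fs, "paper"))
  expect_equal(paper[["f1Tilde"]], 0.25 * 4)  # = 1
  expect_equal(paper[["f2Tilde"]], 3 / 4)
  expect_equal(paper[["f3Tilde"]], -0.2)
  expect_equal(paper[["f5Tilde"]], 0.4375)
  lof <- featureValues(normalizeFeatures(fs, "lofstedt"))
  expect_equal(lof[["f1Tilde"]], 0.25 * 16)   # = 4
  expect_equal(lof[["f2Tilde"]], 3 / 16)
  # rescaled IDM weight 1/(1 + ((i-j)/Ng)^2), recomputed from the GLCM:
  # 3/4 pairs at |i-j| = 1, 1/4 at 3
  expect_equal(lof[["f5Tilde"]],
               3 / 4 / (1 + (1 / 4)^2) + 1 / 4 / (1 + (3 / 4)^2))
  # the rescaled weight is < 1 off the diagonal, so the sum stays below 1
  expect_lt(lof[["f5Tilde"]], 1)
})

test_that("analytically normalized Energy is invariant across bit depths", {
  f1Tilde <- vapply(c(16L, 64L, 256L), function(ng) {
    fs <- haralickFeatures(gradientGLCM(ng, nabla = 1, d = 1))
    featureValues(normalizeFeatures(fs, "paper"))[["f1Tilde"]]
  }, numeric(1))
  expect_equal(f1Tilde, rep(1, 3))
})
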