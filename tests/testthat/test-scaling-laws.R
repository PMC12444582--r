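test_that("effective level count follows the floor law", {
  expect_identical(effectiveLevels(7, 2), 4L)
  expect_identical(effectiveLevels(4, 1), 4L)
  expect_identical(effectiveLevels(256, 3), 86L)
  expect_identical(effectiveLevels(256, 1), 256L)
  expect_identical(effectiveLevels(9, 4), 3L)
  expect_identical(effectiveLevels(16, -3), 6L)  # sign irrelevant
  expect_error(effectiveLevels(1, 1))
  expect_error(effectiveLevels(8, 8), "nabla")
  expect_error(effectiveLevels(8, 0), "nabla")
})

test_that("diagonal split places m1 above and m2 wrapped below", {
  s <- diagonalSplit(4, 1, 1)
  expect_equal(s[c("m1", "m2", "kAbove", "kBelow")],
               list(m1 = 3L, m2 = 1L, kAbove = 1L, kBelow = -3L))
  s <- diagonalSplit(7, 2, 1)
  expect_equal(s[c("m1", "m2", "kAbove", "kBelow")],
               list(m1 = 3L, m2 = 1L, kAbove = 2L, kBelow = -6L))
  expect_equal(diagonalSplit(4, 1, 3)[c("m1", "m2")],
               list(m1 = 1L, m2 = 3L))
  # complement identity and offset signs across a grid
  for (ng in c(5L, 9L, 16L)) for (nb in 1:3) {
    nt <- effectiveLevels(ng, nb)
    for (d in seq_len(nt - 1L)) {
      s <- diagonalSplit(ng, nb, d)
      expect_equal(s$m1 + s$m2, nt)
      expect_equal(s$kAbove, d * nb)
      expect_equal(s$kBelow, -s$m1 * nb)
    }
  }
  # whole-period displacement: degenerate, flagged not thrown
  s <- diagonalSplit(4, 1, 4)
  expect_true(s$degenerate)
  expect_equal(s$dEff, 0L)
})

test_that("the split matches nonzero entries counted from a real GLCM", {
  for (case in list(c(4, 1, 1), c(7, 2, 1), c(16, 3, 2), c(9, 4, 2))) {
    g <- gradientGLCM(case[1], case[2], case[3])
    cts <- glcmCounts(g)
    s <- diagonalSplit(case[1], case[2], case[3])
    expect_equal(sum(cts > 0), s$nTilde)
    expect_equal(sum(cts[upper.tri(cts)] > 0), s$m1)
    expect_equal(sum(cts[lower.tri(cts)] > 0), s$m2)
    nz <- which(cts > 0, arr.ind = TRUE)
    k <- nz[, "col"] - nz[, "row"]
    expect_setequal(unique(k), c(s$kAbove, s$kBelow))
  }
})

test_that("closed-form feature predictions reproduce the worked values", {
  expect_equal(predictASM(4, 1), 0.25)
  expect_equal(predictASM(7, 2), 0.25)
  expect_equal(predictASM(256, 1), 1 / 256)
  expect_equal(predictContrast(4, 1, 1), 3)
  expect_equal(predictContrast(7, 2, 1), 12)
  expect_equal(predictContrast(4, 1, 4), 0)  # dEff = 0
  expect_equal(predictCorrelation(4, 1, 1), -0.2)
  expect_equal(predictCorrelation(7, 2, 1), -0.2)  # nabla-independent
  expect_equal(predictCorrelation(4, 1, 4), 1)
  expect_equal(predictIDM(4, 1, 1, "abs"), 0.4375)
  expect_equal(predictIDM(4, 1, 1, "squared"), 0.4)
  expect_equal(predictIDM(4, 1, 4), 1)
})

test_that("contrast-from-energy reproduces the contrast law on a grid", {
  expect_equal(contrastFromASM(0.25, 1, 1), 3)
  expect_equal(contrastFromASM(0.25, 2, 1), 12)
  expect_equal(contrastFromASM(0.25, 1, 4), 0)  # full period
  for (ng in c(4L, 7L, 16L, 256L)) for (nb in 1:3) {
    nt <- effectiveLevels(ng, nb)
    for (d in seq_len(min(nt - 1L, 6L))) {
      expect_equal(contrastFromASM(predictASM(ng, nb), nb, d),
                   predictContrast(ng, nb, d))
    }
  }
})

test_that("contrast law is symmetric in d and peaks at half period", {
  for (ng in c(7L, 16L)) for (nb in 1:3) {
    nt <- effectiveLevels(ng, nb)
    d <- seq_len(nt - 1L)
    f2 <- vapply(d, function(x) predictContrast(ng, nb, x), numeric(1))
    expect_equal(f2, rev(f2))
    expect_equal(which.max(f2), floor(nt / 2))
  }
})

test_that("energy is monotone in Ng and nabla; correlation tends to 1", {
  f1ByNg <- vapply(c(4, 8, 16, 64, 256), function(ng) predictASM(ng, 2),
                   numeric(1))
  expect_true(all(diff(f1ByNg) < 0))
  f1ByNabla <- vapply(1:7, function(nb) predictASM(256, nb), numeric(1))
  expect_true(all(diff(f1ByNabla) > 0))
  gap <- vapply(c(8, 32, 128, 1024), function(ng)
    1 - predictCorrelation(ng, 1, 2), numeric(1))
  expect_true(all(diff(gap) < 0))
  # 1 - f3 = 6 d (nTilde - d) / ((nTilde-1)(nTilde+1)) ~ 6 d / nTilde
  expect_lt(gap[length(gap)], 6 * 2 / 1024 * 1.01)
})

test_that("all predictions are invariant to the gradient sign", {
  for (nb in c(1L, 3L)) {
    expect_equal(predictAll(16, nb, 2), predictAll(16, -nb, 2))
  }
})

test_that("gradient estimation inverts the energy law, non-uniquely", {
  expect_identical(estimateGradient(0.25, 7), 2L)
  expect_identical(estimateGradient(0.25, 4), 1L)
  expect_identical(estimateGradient(1 / 3, 9), c(3L, 4L))
  expect_identical(estimateGradient(0.3, 4), integer(0))  # 1/f1 = 3.33
  # recovery across the full validation grid
  for (ng in c(4L, 7L, 8L, 16L, 256L)) {
    for (nb in seq_len(min(7L, ng - 1L))) {
      expect_true(nb %in% estimateGradient(predictASM(ng, nb), ng))
    }
  }
  # contrast refinement disambiguates the (Ng = 9, nTilde = 3) pair
  cands <- estimateGradient(1 / 3, 9, f2 = predictContrast(9, 4, 1), d = 1)
  expect_identical(cands, 4L)
})

test_that("predictAll bundles the split and the four laws coherently", {
  p <- predictAll(4, 1, 1)
  expect_equal(p@nTilde, 4L)
  expect_equal(p@m1, 3L)
  expect_equal(p@m2, 1L)
  expect_equal(unname(featureValues(p)),
               c(0.25, 3, -0.2, 0.4375, 0.4))
  p <- predictAll(7, 2, 1)
  expect_equal(p@nTilde, 4L)
  expect_equal(p@f2Contrast, 12)
  p <- predictAll(256, 1, 1)
  expect_equal(p@f1ASM, 1 / 256)
  # degenerate bundle: diagonal GLCM values
  p <- predictAll(4, 1, 8)
  expect_true(p@degenerate)
  expect_equal(unname(featureValues(p)), c(0.25, 0, 1, 1, 1))
})
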