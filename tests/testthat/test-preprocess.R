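test_that("gain coefficient follows the exponential intra-class form", {
  expect_identical(gainCoefficient(0.3, 0), 1)
  expect_lt(gainCoefficient(0.3, 1e6), 1e-10)
  expect_equal(gainCoefficient(0.5, 0.0025, k = 0.1, eps = 1e-8),
               exp(-1), tolerance = 1e-4)
  expect_error(gainCoefficient(0.5, -1), "non-negative")
  ## monotone non-increasing in variance for fixed mean
  v <- seq(0, 1, length.out = 100)
  g <- gainCoefficient(0.4, v, k = 0.5)
  expect_true(all(diff(g) <= 0))
})

test_that("diffusion eigenvalue ladder is ordered for gains in [0,1]", {
  set.seed(42)
  for (i in 1:50) {
    g <- runif(3)
    a <- gainTriple(g[1], g[2], g[3])
    expect_true(a$alpha1 >= 0 && a$alpha1 <= a$alpha2 && a$alpha2 <= a$alpha3)
  }
  expect_error(gainTriple(1.5, 0, 0), "0,1")
})

test_that("local stencil statistics match direct stencil sums", {
  const <- matrix(0.7, 16, 16)
  st <- localStats(const, c(8, 8), e2 = c(0, 1))
  expect_equal(st$mean, 0.7)
  expect_equal(st$var, 0)
  expect_equal(st$varPlanar, 0)
  expect_equal(st$meanLinear, 0.7)

  ## genuine 5x5 planar stencil: alternating 0/1 checkerboard has 13 zeros
  ## and 12 ones around an even-parity center
  chk <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  st <- localStats(chk, c(8, 8), e2 = c(0, 1), e3 = c(1, 0))
  expect_equal(st$meanPlanar, 12 / 25)

  ## 7-sample linear stencil along the column axis
  ramp <- matrix(rep((1:16) / 10, each = 16), 16, 16)
  st <- localStats(ramp, c(8, 4), e2 = c(1, 0), e3 = c(0, 1))
  expect_equal(st$meanLinear, mean((1:7) / 10))
})

test_that("diffusion fixes constant images and conserves intensity", {
  const <- matrix(0.4, 32, 32)
  expect_equal(iadfDenoise(const, iterations = 3), const, ignore_attr = TRUE)

  noisy <- addNoise(matrix(0.5, 64, 64), list(kind = "gaussian", sigma = 0.05), 1L)
  for (it in c(1L, 5L)) {
    den <- iadfDenoise(noisy, iterations = it, clip = FALSE)
    expect_lt(abs(sum(den) - sum(noisy)) / sum(noisy), 1e-6)
  }
})

test_that("diffusion reduces total variation of a noisy constant image", {
  noisy <- addNoise(matrix(0.5, 48, 48), list(kind = "gaussian", sigma = 0.05), 2L)
  tv <- function(x) sum(abs(diff(x))) + sum(abs(t(diff(t(x)))))
  cur <- noisy
  last <- tv(cur)
  for (i in 1:8) {
    cur <- iadfDenoise(cur, iterations = 1L)
    expect_lt(tv(cur), last)
    last <- tv(cur)
  }
})

test_that("diffusion improves PSNR on a noisy phantom", {
  clean <- phantomImage(generatePhantom(phantomSpec(seed = 11L, noise = "none")))
  noisy <- phantomImage(fixturePhantom())
  den <- fixturePre()$denoised
  expect_gt(msePsnr(clean, den)["psnr"], msePsnr(clean, noisy)["psnr"])
})

test_that("overlarge time steps are rejected with the stability bound", {
  noisy <- addNoise(matrix(0.5, 32, 32), list(kind = "gaussian", sigma = 0.05), 3L)
  expect_error(iadfDenoise(noisy, dt = 1), "stability bound")
})

test_that("contrast stretching maps the stated percentiles", {
  span <- matrix(seq(0, 1, length.out = 256), 16, 16)
  expect_equal(contrastStretch(span, 0, 100), span, ignore_attr = TRUE)
  expect_identical(contrastStretch(matrix(0.3, 16, 16), 0, 100),
                   matrix(0, 16, 16))
  two <- matrix(rep(c(0.2, 0.6), each = 32), 8, 8)
  expect_equal(sort(unique(round(as.vector(contrastStretch(two, 0, 100)), 12))),
               c(0, 1))
  expect_error(contrastStretch(span, 50, 50), "lowPct")
})

test_that("lung-field extraction recovers the phantom lungs", {
  pre <- fixturePre()
  tr <- phantomTruth(fixturePhantom())
  expect_gte(diceScore(pre$mask, tr@lungMask), 0.90)
  ## region is the masked image
  expect_identical(pre$region[!pre$mask], rep(0, sum(!pre$mask)))
  ## mask is convex per component
  lab <- lungscreen:::label8(pre$mask)
  hull <- matrix(FALSE, nrow(lab), ncol(lab))
  for (l in seq_len(max(lab)))
    hull <- hull | lungscreen:::convexHullMask(lab == l)
  expect_identical(pre$mask, hull)
})

test_that("images without a lung field raise an error", {
  expect_error(extractLungRegion(matrix(0, 64, 64)), "no lung field")
})

test_that("unsharp masking enhances edges and fixes flat input", {
  img <- phantomImage(fixturePhantom())
  expect_identical(unsharpEnhance(img, eta = 0), img)
  const <- matrix(0.5, 32, 32)
  expect_equal(unsharpEnhance(const, eta = 2), const, tolerance = 1e-7,
               ignore_attr = TRUE)
  step <- twoRegionImage(32, 0.3, 0.6)
  enh <- unsharpEnhance(step, eta = 1, sigma = 1.5)
  gradIn <- max(abs(diff(step[16, ])))
  gradOut <- max(abs(diff(enh[16, ])))
  expect_gt(gradOut, gradIn)
  expect_error(unsharpEnhance(step, eta = -1), "eta")
})

test_that("the preprocessing chain is deterministic", {
  img <- phantomImage(fixturePhantom())
  a <- preprocessImage(img)
  b <- preprocessImage(img)
  expect_identical(a$enhanced, b$enhanced)
})
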