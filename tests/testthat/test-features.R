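test_that("gradient statistics locate histogram modes and moments", {
  ## two delta modes in bins 10 and 40 of the 64-bin [0,1] histogram
  g <- c(rep((10 - 0.5) / 64, 200), rep((40 - 0.5) / 64, 150))
  st <- gradientStats(g)
  expect_identical(st[["mode_spacing"]], 30)
  expect_equal(st[["area_mode1"]], 200 / 350)
  expect_equal(st[["area_mode2"]], 150 / 350)
  expect_equal(st[["mode_ratio_norm"]], (200 / 150) / 30)

  ## moment block against a brute-force oracle
  x <- withr::with_seed(8L, pmin(pmax(rnorm(5000, 0.4, 0.08), 0), 1))
  st <- gradientStats(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5; b2 <- m4 / m2^2
  expect_equal(st[["skewness"]], g1, tolerance = 1e-9)
  expect_equal(st[["kurtosis"]], b2, tolerance = 1e-9)
  expect_equal(st[["bimodality"]], (g1^2 + 1) / b2, tolerance = 1e-9)

  ## degenerate contracts
  st0 <- gradientStats(numeric(0))
  expect_identical(st0[["mode_spacing"]], 1)
  expect_identical(st0[["skewness"]], 0)
  const <- gradientStats(rep(0.2, 50))
  expect_identical(const[["skewness"]], 0)
  expect_identical(const[["mode_spacing"]], 1)
  expect_true(all(is.finite(gradientFeatures(matrix(0.5, 16, 16),
                                             matrix(TRUE, 16, 16)))))
})

test_that("spectral flatness obeys its limit cases and the AM-GM bound", {
  expect_identical(spectralFlatness(matrix(0.5, 16, 16), matrix(TRUE, 16, 16)), 0)
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  expect_equal(spectralFlatness(imp, matrix(TRUE, 16, 16)), 1, tolerance = 1e-12)
  noise <- withr::with_seed(1L, matrix(runif(256), 16, 16))
  smooth <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16)
  m <- matrix(TRUE, 16, 16)
  expect_gt(spectralFlatness(noise, m), spectralFlatness(smooth, m))
  for (s in 1:10) {
    x <- withr::with_seed(s, matrix(runif(144), 12, 12))
    f <- spectralFlatness(x, matrix(TRUE, 12, 12))
    expect_true(f >= 0 && f <= 1)
  }
})

test_that("profile statistics match hand-computed toy profiles", {
  st <- profileStats(c(0, 1, 0, 2, 0), smoothWindow = 1L)
  expect_identical(st[["peak_ratio"]], 2)
  st <- profileStats(c(0, 1, 2, 3), smoothWindow = 1L)
  expect_identical(st[["slope_ratio"]], 1)
  expect_identical(st[["slope_smoothness"]], 0)
  lin <- profileStats(seq(0.1, 0.9, by = 0.1), smoothWindow = 1L)
  expect_equal(lin[["slope_smoothness"]], 0, tolerance = 1e-12)
  expect_error(profileStats(c(1, 2)), "3 samples")
})

test_that("profile block errors when every profile is too short", {
  edge <- matrix(0.5, 16, 16)
  thin <- matrix(FALSE, 16, 16); thin[8, 4:12] <- TRUE  # 1-sample columns
  expect_error(profileFeatures(edge, thin), "skipped")
  expect_error(profileFeatures(edge, matrix(FALSE, 16, 16)), "empty")
})

test_that("edge chains report geometry of constructed lines", {
  expect_length(detectEdges(matrix(0, 32, 32), "rib"), 0L)
  line <- matrix(0, 64, 64); line[32, 12:51] <- 1
  ribs <- detectEdges(line, "rib")
  expect_length(ribs, 1L)
  expect_lt(abs(ribs[[1]]$slope), 0.05)
  expect_gte(ribs[[1]]$eccentricity, 0.99)
  expect_gte(ribs[[1]]$length, 30)

  two <- matrix(0, 64, 64); two[22, 12:51] <- 1; two[42, 12:51] <- 1
  ribs2 <- detectEdges(two, "rib")
  expect_length(ribs2, 2L)
  rows <- sort(vapply(ribs2, function(ch) ch$centroid[["row"]], numeric(1)))
  expect_equal(rows[2] - rows[1], 20, tolerance = 0.5)
})

test_that("on-rib block compares centroid distance with rib spacing", {
  mk <- function(row) list(pixels = cbind(row, 1:40),
                           centroid = c(row = row, col = 20.5),
                           length = 40, slope = 0, eccentricity = 1)
  chains <- list(mk(20), mk(60))
  hit <- onRibFeatures(c(30, 20), chains)
  expect_identical(hit$dMin, 10)
  expect_identical(hit$interRib, 40)
  expect_identical(hit$flag, 1)
  on <- onRibFeatures(c(20, 20), chains)
  expect_identical(on$dMin, 0)
  expect_identical(on$flag, 1)
  none <- onRibFeatures(c(30, 20), list())
  expect_identical(none$flag, 0)
  expect_identical(none$dMin, Inf)
  expect_identical(none$length, 0)
})

test_that("on-vessel block follows the length-product and inverse-distance forms", {
  expect_identical(onVesselFeatures(c(100, 100), list()),
                   c(Vessel1 = 0, Vessel2 = 0))
  mk <- function(len, row) list(pixels = cbind(row, seq_len(len)),
                                centroid = c(row, len / 2),
                                length = len, slope = 0, eccentricity = 1)
  ch <- list(mk(30, 10), mk(20, 90))
  v <- onVesselFeatures(c(100, 100), ch)
  expect_equal(v[["Vessel1"]], 600 / 10000)
  center <- list(list(pixels = cbind(50.5, seq(35.5, 64.5)),
                      centroid = c(50.5, 50), length = 30, slope = 0,
                      eccentricity = 1))  # passes through the center
  v2 <- onVesselFeatures(c(100, 100), center)
  expect_identical(v2[["Vessel2"]], 1 / 0.5)
})

test_that("nodule candidate finds the brightest blob or degenerates", {
  img <- matrix(0.3, 32, 32); img[10:13, 20:23] <- 0.9
  cand <- noduleCandidate(img, matrix(TRUE, 32, 32))
  expect_equal(cand$peak, 0.9)
  expect_equal(unname(cand$centroid), c(11.5, 21.5), tolerance = 0.1)
  flat <- noduleCandidate(matrix(0.4, 16, 16), matrix(TRUE, 16, 16))
  expect_identical(flat$peak, 0)
})

test_that("the assembled feature vector is complete, named and finite", {
  f <- extractFeatures(fixtureSeg(), fixturePre()$enhanced)
  expect_length(f, 84L)
  expect_identical(names(f), featureNames())
  expect_true(all(is.finite(f)))
})

test_that("degenerate sub-images yield all-zero vessel and rib flags", {
  lungMask <- matrix(FALSE, 64, 64); lungMask[20:44, 20:44] <- TRUE
  masks <- replicate(4, matrix(FALSE, 64, 64), simplify = FALSE)
  seg <- new("SegmentationResult", seeds = cbind(rep(30L, 4), rep(30L, 4)),
             masks = masks, thresholds = rep(0.1, 4), lungMask = lungMask)
  f <- extractFeatures(seg, matrix(0, 64, 64))
  expect_true(all(is.finite(f)))
  expect_true(all(f[grep("Vessel", names(f))] == 0))
  expect_true(all(f[grep("on_rib_flag", names(f))] == 0))
  expect_true(all(f[grep("nodule_peak", names(f))] == 0))
})

test_that("an on-rib lesion flips the on-rib flag relative to a distant one", {
  ## controlled quadrant geometry: two closely spaced rib bands, a bright
  ## lesion either on a band or far from both (farther than the inter-rib
  ## spacing)
  mkCase <- function(lesionRow) {
    img <- matrix(0, 96, 96)
    lungMask <- matrix(FALSE, 96, 96); lungMask[11:90, 11:90] <- TRUE
    img[lungMask] <- 0.3
    img[19:21, 14:46] <- 0.75
    img[29:31, 14:46] <- 0.75
    rr <- (lesionRow - 3):(lesionRow + 3)
    img[rr, 27:33] <- 0.9
    quads <- lungscreen:::.quadrantMasks(lungMask)
    masks <- lapply(quads, function(q) q & lungMask)
    seeds <- rbind(c(40L, 40L), c(40L, 60L), c(60L, 40L), c(60L, 60L))
    seg <- new("SegmentationResult", seeds = seeds, masks = masks,
               thresholds = rep(0.1, 4), lungMask = lungMask)
    extractFeatures(seg, img)
  }
  onRib <- mkCase(30)   # lesion centered on the second band
  free <- mkCase(46)    # lesion 16 px below it, inter-band spacing 10
  expect_identical(onRib[["q1_on_rib_flag"]], 1)
  expect_identical(free[["q1_on_rib_flag"]], 0)
  expect_lt(onRib[["q1_rib_dmin"]], free[["q1_rib_dmin"]])
})

test_that("translating line geometry shifts distances by at most a pixel", {
  base <- matrix(0, 64, 64); base[30, 10:49] <- 1; base[44, 10:49] <- 1
  shifted <- augmentImage(base, "translate", dr = 3, dc = 2,
                          interpolation = "nearest")
  rb <- detectEdges(base, "rib"); rs <- detectEdges(shifted, "rib")
  ob <- onRibFeatures(c(36, 30), rb)
  os <- onRibFeatures(c(39, 32), rs)
  expect_lt(abs(ob$dMin - os$dMin), 1.01)
  expect_lt(abs(ob$interRib - os$interRib), 1.01)
})
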