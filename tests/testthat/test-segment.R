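test_that("Bates draws have the stated moments and phi=1 is uniform", {
  x <- withr::with_seed(1L, batesRandom(1e5, phi = 3L))
  expect_lt(abs(mean(x) - 0.5), 0.003)
  expect_lt(abs(var(x) - 1 / 36), 0.1 / 36)
  u <- withr::with_seed(2L, batesRandom(1e4, phi = 1L))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  expect_error(batesRandom(10, phi = 0L), "phi")
})

test_that("population initialization respects bounds and seeds", {
  bounds <- list(lower = c(-2, 1), upper = c(3, 4))
  sphere <- function(x) sum(x^2)
  pop <- withr::with_seed(1L, coaInit(bounds, 10L, sphere))
  expect_true(all(pop$positions >= rep(bounds$lower, each = 10)))
  expect_true(all(pop$positions <= rep(bounds$upper, each = 10)))
  expect_identical(pop$fitness, apply(pop$positions, 1, sphere))
  pop2 <- withr::with_seed(1L, coaInit(bounds, 10L, sphere))
  expect_identical(pop, pop2)
  narrow <- list(lower = c(0, 0), upper = c(1e-9, 1e-9))
  pn <- withr::with_seed(1L, coaInit(narrow, 5L, sphere))
  expect_true(all(abs(pn$positions) <= 1e-9))
  expect_error(coaInit(bounds, 2L, sphere), "m must be")
})

test_that("optimizer steps are greedy and converge on the sphere", {
  sphere <- function(x) sum(x^2)
  bounds <- list(lower = c(-5, -5), upper = c(5, 5))
  res <- coatiOptimize(sphere, bounds, m = 20L, Tn = 50L, seed = 1L)
  expect_lt(res$bestFitness, 1e-2)
  expect_true(all(diff(res$trace) <= 0))
  ## greedy acceptance: one step never worsens the best fitness
  pop <- withr::with_seed(3L, coaInit(bounds, 8L, sphere))
  stepped <- withr::with_seed(4L, coaStep(pop, sphere))
  expect_lte(min(stepped$fitness), min(pop$fitness))
  expect_error(withr::with_seed(1L, coaStep(pop, function(x) NaN)),
               "non-finite")
})

test_that("region growing recovers exact regions", {
  img <- twoRegionImage(32, 0.3, 0.8)
  mask <- regionGrow(img, c(10, 5), threshold = 0.2)
  expect_identical(mask, img == 0.3)   # Dice 1.0 against the true region
  uniform <- matrix(0.5, 16, 16)
  expect_true(all(regionGrow(uniform, c(4, 4), threshold = 0.1)))
  ramp <- matrix(seq(0, 1, length.out = 256), 16, 16)
  grown <- regionGrow(ramp, c(8, 8), threshold = 0)
  expect_identical(which(grown), which(ramp == ramp[8, 8]))
  expect_error(regionGrow(img, c(100, 1), 0.1), "outside")
  expect_error(regionGrow(img, c(5, 5), -0.1), "threshold")
  expect_error(regionGrow(img, c(5, 5), 0.1, connectivity = 6), "connectivity")
})

test_that("grown regions are connected and contain the seed", {
  img <- phantomImage(fixturePhantom())
  mask <- regionGrow(img, c(60, 40), threshold = 0.1)
  expect_true(mask[60, 40])
  lab <- lungscreen:::label8(mask)
  expect_identical(max(lab), 1L)
})

test_that("seeds land inside homogeneous quadrant blobs", {
  img <- matrix(0.05, 64, 64)
  blobs <- list(c(16, 16), c(16, 48), c(48, 16), c(48, 48))
  lungMask <- matrix(FALSE, 64, 64)
  for (b in blobs) {
    img[(b[1] - 8):(b[1] + 8), (b[2] - 8):(b[2] + 8)] <- 0.5
    lungMask[(b[1] - 8):(b[1] + 8), (b[2] - 8):(b[2] + 8)] <- TRUE
  }
  seeds <- selectSeeds(img, lungMask, seed = 5L)
  for (q in 1:4) {
    expect_true(lungMask[seeds[q, 1], seeds[q, 2]])
    expect_lte(max(abs(seeds[q, ] - blobs[[q]])), 8)
  }
  seeds2 <- selectSeeds(img, lungMask, seed = 5L)
  expect_identical(seeds, seeds2)
  expect_error(selectSeeds(img, matrix(FALSE, 64, 64)), "empty")
})

test_that("overlap resolution assigns contested pixels by gray value", {
  img <- matrix(0.5, 16, 16)
  img[, 1:8] <- 0.2
  a <- matrix(FALSE, 16, 16); a[, 1:10] <- TRUE
  b <- matrix(FALSE, 16, 16); b[, 7:16] <- TRUE
  seeds <- rbind(c(8, 2), c(8, 15))   # gray values 0.2 and 0.5
  out <- resolveOverlaps(list(a, b), img, seeds)
  expect_false(any(out[[1]] & out[[2]]))
  ## contested dark columns 7:8 go to the dark seed, bright 9:10 to bright
  expect_true(all(out[[1]][, 7:8]))
  expect_true(all(out[[2]][, 9:10]))
  ## ties go to the lower mask index
  tie <- resolveOverlaps(list(a, a), img, rbind(c(8, 2), c(8, 2)))
  expect_true(all(tie[[1]][, 1:10]) && !any(tie[[2]]))
})

test_that("four-part segmentation is consistent and reproducible", {
  seg <- fixtureSeg()
  tr <- phantomTruth(fixturePhantom())
  masks <- segMasks(seg)
  expect_length(masks, 4L)
  ## disjoint, inside the lung mask, seeds inside masks
  expect_lte(max(Reduce(`+`, masks)), 1)
  for (q in 1:4) {
    expect_true(all(!(masks[[q]] & !seg@lungMask)))
    expect_true(masks[[q]][segSeeds(seg)[q, 1], segSeeds(seg)[q, 2]])
  }
  expect_gte(mean(quadrantTruthDice(seg, tr)), 0.80)
  pre <- fixturePre()
  again <- segmentLungs(pre$enhanced, pre$mask, seed = 11L)
  expect_identical(segMasks(again), masks)
  expect_identical(segSeeds(again), segSeeds(seg))
})
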