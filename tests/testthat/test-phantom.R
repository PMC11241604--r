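test_that("phantom labels follow the nodule list", {
  normal <- generatePhantom(phantomSpec(seed = 1L, noise = "none"))
  expect_identical(phantomTruth(normal)@classLabel, "Normal")
  expect_identical(phantomTruth(normal)@riskLabel, "none")

  onrib <- generatePhantom(phantomSpec(
    nodules = list(noduleSpec(5, "on_rib")), noise = "none", seed = 2L))
  expect_identical(phantomTruth(onrib)@classLabel, "Abnormal")
  expect_identical(phantomTruth(onrib)@riskLabel, "high")

  big <- generatePhantom(phantomSpec(
    nodules = list(noduleSpec(9, "free")), noise = "none", seed = 2L))
  expect_identical(phantomTruth(big)@riskLabel, "high")

  small <- generatePhantom(phantomSpec(
    nodules = list(noduleSpec(4, "free")), noise = "none", seed = 2L))
  expect_identical(phantomTruth(small)@riskLabel, "low")
})

test_that("rendering is deterministic and intensity-ordered", {
  sp <- phantomSpec(nodules = list(noduleSpec(6, "on_vessel")), seed = 9L)
  a <- generatePhantom(sp); b <- generatePhantom(sp)
  expect_identical(phantomImage(a), phantomImage(b))
  expect_true(all(phantomImage(a) >= 0 & phantomImage(a) <= 1))

  clean <- generatePhantom(phantomSpec(
    nodules = list(noduleSpec(5, "on_rib")), noise = "none", seed = 4L))
  img <- phantomImage(clean); tr <- phantomTruth(clean)
  lungMedian <- median(img[tr@lungMask & !tr@ribMask & !tr@vesselMask])
  expect_identical(mean(img[tr@noduleMasks[[1]]] > lungMedian), 1)
  parenchyma <- tr@lungMask & !tr@ribMask & !tr@vesselMask & !tr@noduleMasks[[1]]
  background <- img < 0.1
  expect_lt(mean(img[background]), mean(img[parenchyma]))
  expect_lt(mean(img[parenchyma]), mean(img[tr@vesselMask]))
  expect_lt(mean(img[tr@vesselMask & !tr@noduleMasks[[1]]]),
            mean(img[tr@noduleMasks[[1]]]))
})

test_that("nodule centers outside the lung fields are rejected", {
  sp <- phantomSpec(nodules = list(noduleSpec(4, "free", center = c(5, 5))),
                    noise = "none", seed = 1L)
  expect_error(generatePhantom(sp), "outside the lung")
})

test_that("lung fields are hull-friendly (per-component convexity)", {
  tr <- phantomTruth(fixturePhantom())
  lab <- lungscreen:::label8(tr@lungMask)
  hull <- matrix(FALSE, nrow(lab), ncol(lab))
  for (l in seq_len(max(lab)))
    hull <- hull | lungscreen:::convexHullMask(lab == l)
  expect_gte(diceScore(tr@lungMask, hull), 0.95)
})

test_that("gaussian noise has the stated spread and limits", {
  img <- matrix(0.5, 256, 256)
  expect_identical(addNoise(img, list(kind = "gaussian", sigma = 0), 1L), img)
  out <- addNoise(img, list(kind = "gaussian", sigma = 0.05), 7L)
  expect_true(abs(sd(out - img) - 0.05) < 0.005)
  expect_error(addNoise(img, list(kind = "gaussian", sigma = -1), 1L), "sigma")
})

test_that("poisson noise keeps the mean at high count scale", {
  img <- matrix(0.5, 256, 256)
  out <- addNoise(img, list(kind = "poisson", scale = 1e4), 3L)
  expect_lt(abs(mean(out) - 0.5), 0.01)
  expect_error(addNoise(img, list(kind = "poisson", scale = 0), 1L), "scale")
})

test_that("augmentation identities hold", {
  img <- phantomImage(fixturePhantom())
  expect_identical(augmentImage(img, "rotate", angle = 0), unname(img))
  flipped <- augmentImage(augmentImage(img, "flip", axis = "horizontal"),
                          "flip", axis = "horizontal")
  expect_identical(flipped, unname(img))
  fwd <- augmentImage(img, "translate", dr = 5, dc = 0)
  back <- augmentImage(fwd, "translate", dr = -5, dc = 0)
  interior <- 10:(nrow(img) - 10)
  expect_equal(back[interior, ], img[interior, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(augmentImage(img, "scale", factor = 0), "factor")
})

test_that("mask transforms with nearest interpolation stay boolean", {
  m <- phantomTruth(fixturePhantom())@lungMask * 1
  r <- augmentImage(m, "rotate", angle = 15, interpolation = "nearest")
  expect_true(all(r %in% c(0, 1)))
})
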