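test_that("parametric ReLU covers its limit cases", {
  expect_identical(prelu(5, 0.7), 5)
  expect_identical(prelu(-2, 0.25), -0.5)
  x <- c(-3, -0.5, 0, 1, 4)
  expect_identical(prelu(x, 0), pmax(x, 0))
  expect_identical(prelu(x, 1), x)
  ## continuity and monotonicity on a grid for J >= 0
  g <- seq(-2, 2, length.out = 101)
  for (J in c(0, 0.25, 1)) expect_true(all(diff(prelu(g, J)) >= 0))
  expect_error(prelu(1, Inf), "finite")
})

test_that("configuration invariants are enforced", {
  expect_error(presnetConfig(nBlocks = 0), "nBlocks")
  expect_error(presnetConfig(jInit = 1), "jInit")
  expect_error(presnetConfig(kappa = 0), "kappa")
})

test_that("model building is seeded and well-posed", {
  cfg <- presnetConfig(seed = 3L)
  m1 <- buildPresnet(cfg, 12L)
  m2 <- buildPresnet(cfg, 12L)
  expect_identical(m1@params, m2@params)
  z <- presnetForward(m1, matrix(0, 4, 12))
  expect_true(all(is.finite(z)))
  expect_identical(dim(z), c(4L, 2L))
  expect_error(buildPresnet(presnetConfig(kappa = 16L), 12L), "pooling footprint")
})

test_that("skip connections are live", {
  m <- buildPresnet(presnetConfig(seed = 2L), 10L)
  x <- withr::with_seed(1L, matrix(rnorm(30), 3, 10))
  expect_gt(max(abs(presnetForward(m, x) -
                    presnetForward(m, x, useSkips = FALSE))), 1e-8)
})

test_that("training separates two Gaussian classes and descends", {
  set.seed(10)
  n <- 200; d <- 8
  y <- rep(c("Normal", "Abnormal"), each = n / 2)
  x <- matrix(rnorm(n * d), n, d)
  x[y == "Abnormal", 1:2] <- x[y == "Abnormal", 1:2] + 4
  hold <- c(1:20, (n / 2 + 1):(n / 2 + 20))
  cfg <- presnetConfig(seed = 4L, epochs = 25L)
  fit <- trainPresnet(buildPresnet(cfg, d), x[-hold, ], y[-hold])
  pred <- predictPresnet(fit$model, x[hold, ])
  expect_gte(mean(pred$classLabel == y[hold]), 0.95)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  ## same seed, same parameters
  fit2 <- trainPresnet(buildPresnet(cfg, d), x[-hold, ], y[-hold])
  expect_identical(fit$model@params, fit2$model@params)
})

test_that("softmax predictions are coherent and batch-consistent", {
  m <- buildPresnet(presnetConfig(seed = 6L), 6L)
  x <- withr::with_seed(2L, matrix(rnorm(120), 20, 6))
  batch <- predictPresnet(m, x)
  expect_true(all(batch$abnormalScore >= 0 & batch$abnormalScore <= 1))
  expect_identical(batch$classLabel, ifelse(batch$abnormalScore > 0.5,
                                            "Abnormal", "Normal"))
  expect_true(all(batch$riskLabel == "none"))
  for (i in c(1L, 7L, 20L)) {
    single <- predictPresnet(m, x[i, ])
    expect_equal(single$abnormalScore, batch$abnormalScore[i], tolerance = 1e-12)
  }
  expect_error(predictPresnet(m, matrix(0, 2, 4)), "shape mismatch")
})

test_that("saved models reload and reproduce predictions exactly", {
  m <- buildPresnet(presnetConfig(seed = 8L), 6L)
  x <- withr::with_seed(3L, matrix(rnorm(60), 10, 6))
  p1 <- predictPresnet(m, x)
  path <- tempfile(fileext = ".rds")
  savePresnet(m, path)
  p2 <- predictPresnet(loadPresnet(path), x)
  expect_identical(p1, p2)
})

test_that("risk screening applies the on-rib and intensity rules", {
  feats <- setNames(numeric(84), featureNames())
  pred <- data.frame(classLabel = "Normal", abnormalScore = 0.1,
                     riskLabel = "none", stringsAsFactors = FALSE)
  expect_identical(riskScreen(pred, feats)$riskLabel, "none")

  pred$classLabel <- "Abnormal"; pred$abnormalScore <- 0.9
  lowFeats <- feats; lowFeats["q2_nodule_peak"] <- 0.5
  expect_identical(riskScreen(pred, lowFeats)$riskLabel, "low")
  flagFeats <- lowFeats; flagFeats["q3_on_rib_flag"] <- 1
  expect_identical(riskScreen(pred, flagFeats)$riskLabel, "high")
  hotFeats <- lowFeats; hotFeats["q1_nodule_peak"] <- 0.95
  expect_identical(riskScreen(pred, hotFeats)$riskLabel, "high")
  expect_error(riskScreen(pred, feats[1:10]), "on-rib block")
})

test_that("image mode builds and runs 2-D convolutions", {
  cfg <- presnetConfig(mode = "image", nBlocks = 1L, width = 8L, seed = 5L)
  m <- buildPresnet(cfg, c(16L, 16L))
  x <- withr::with_seed(4L, array(runif(2 * 16 * 16), c(2, 16, 16)))
  z <- presnetForward(m, x)
  expect_identical(dim(z), c(2L, 2L))
  expect_true(all(is.finite(z)))
  m2 <- buildPresnet(cfg, c(16L, 16L))
  expect_identical(presnetForward(m2, x), z)
})
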