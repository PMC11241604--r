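## PResNet: a small residual network with a (learnable) parametric ReLU,
## trained with Adam on selected feature vectors (1-D convolutions) or on
## raster inputs (2-D convolutions). Implemented directly with array
## algebra and explicit backpropagation; everything is seeded, so builds,
## training runs and predictions are bit-reproducible.

#' Parametric rectified linear unit
#'
#' \code{x} for positive inputs, \code{J x} otherwise, elementwise.
#' \code{J = 0} reduces to ReLU; \code{J = 1} is the identity.
#'
#' @param x numeric vector/array.
#' @param J negative slope (finite).
#' @return same shape as \code{x}.
#' @export
prelu <- function(x, J) {
  if (!is.finite(J)) stop("J must be finite")
  ifelse(x > 0, x, J * x)
}

#' PResNet hyperparameter configuration
#'
#' @param nBlocks residual blocks (>= 1, default 3).
#' @param width channels (default 32).
#' @param jInit initial negative slope (0 <= jInit < 1, default 0.25).
#' @param jLearnable learn the slope during training (default TRUE).
#' @param kappa pooling stride (>= 1, default 2).
#' @param epochs,batchSize,lr,weightDecay training-loop parameters.
#' @param seed RNG seed for initialization and batch shuffling.
#' @param mode \code{"feature_vector"} (1-D convolutions over the selected
#'   feature vector, the canonical mode) or \code{"image"} (2-D
#'   convolutions).
#' @return named list.
#' @export
presnetConfig <- function(nBlocks = 3L, width = 32L, jInit = 0.25,
                          jLearnable = TRUE, kappa = 2L, epochs = 50L,
                          batchSize = 32L, lr = 1e-3, weightDecay = 1e-4,
                          seed = 1L, mode = c("feature_vector", "image")) {
  mode <- match.arg(mode)
  if (nBlocks < 1L) stop("nBlocks must be >= 1")
  if (jInit < 0 || jInit >= 1) stop("require 0 <= jInit < 1")
  if (kappa < 1L) stop("kappa must be >= 1")
  list(nBlocks = as.integer(nBlocks), width = as.integer(width),
       jInit = jInit, jLearnable = isTRUE(jLearnable),
       kappa = as.integer(kappa), epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), lr = lr,
       weightDecay = weightDecay, seed = as.integer(seed), mode = mode)
}

## ---- 1-D convolution primitives ----------------------------------------

.conv1 <- function(A, W, b) {
  d <- dim(A); n <- d[1]; L <- d[2]; Cin <- d[3]; Cout <- dim(W)[3]
  Ap <- array(0, c(n, L + 2L, Cin)); Ap[, 2:(L + 1), ] <- A
  Y <- array(rep(b, each = n * L), c(n, L, Cout))
  for (o in 1:3) {
    Xo <- matrix(Ap[, o:(o + L - 1), , drop = FALSE], n * L, Cin)
    Y <- Y + array(Xo %*% matrix(W[o, , ], Cin, Cout), c(n, L, Cout))
  }
  Y
}

.conv1Grad <- function(A, W, dY) {
  d <- dim(A); n <- d[1]; L <- d[2]; Cin <- d[3]; Cout <- dim(W)[3]
  Ap <- array(0, c(n, L + 2L, Cin)); Ap[, 2:(L + 1), ] <- A
  dW <- array(0, dim(W)); dAp <- array(0, dim(Ap))
  dYm <- matrix(dY, n * L, Cout)
  for (o in 1:3) {
    Xo <- matrix(Ap[, o:(o + L - 1), , drop = FALSE], n * L, Cin)
    dW[o, , ] <- crossprod(Xo, dYm)
    dXo <- dYm %*% t(matrix(W[o, , ], Cin, Cout))
    dAp[, o:(o + L - 1), ] <- dAp[, o:(o + L - 1), , drop = FALSE] +
      array(dXo, c(n, L, Cin))
  }
  list(dA = dAp[, 2:(L + 1), , drop = FALSE], dW = dW, db = colSums(dYm))
}

.pool1 <- function(A, kappa) {
  d <- dim(A); n <- d[1]; L <- d[2]; C <- d[3]
  nw <- L %/% kappa
  if (nw < 1L) stop("input smaller than the pooling footprint")
  Ar <- array(A[, seq_len(nw * kappa), , drop = FALSE], c(n, kappa, nw, C))
  M <- array(Ar[, 1, , ], c(n, nw, C)); idx <- array(1L, c(n, nw, C))
  if (kappa > 1) for (j in 2:kappa) {
    Aj <- array(Ar[, j, , ], c(n, nw, C))
    better <- Aj > M
    M[better] <- Aj[better]; idx[better] <- j
  }
  list(M = M, idx = idx, L = L)
}

.pool1Grad <- function(pool, dM, kappa, C) {
  d <- dim(dM); n <- d[1]; nw <- d[2]
  dA <- array(0, c(n, pool$L, C))
  for (j in seq_len(kappa)) {
    sel <- pool$idx == j
    dAt <- array(0, c(n, nw, C)); dAt[sel] <- dM[sel]
    cols <- seq(j, nw * kappa, by = kappa)
    dA[, cols, ] <- dA[, cols, , drop = FALSE] + dAt
  }
  dA
}

## ---- 2-D convolution primitives ----------------------------------------

.conv2 <- function(A, W, b) {
  d <- dim(A); n <- d[1]; Hh <- d[2]; Ww <- d[3]; Cin <- d[4]; Cout <- dim(W)[4]
  Ap <- array(0, c(n, Hh + 2L, Ww + 2L, Cin)); Ap[, 2:(Hh + 1), 2:(Ww + 1), ] <- A
  Y <- array(rep(b, each = n * Hh * Ww), c(n, Hh, Ww, Cout))
  for (o1 in 1:3) for (o2 in 1:3) {
    Xo <- matrix(Ap[, o1:(o1 + Hh - 1), o2:(o2 + Ww - 1), , drop = FALSE],
                 n * Hh * Ww, Cin)
    Y <- Y + array(Xo %*% matrix(W[o1, o2, , ], Cin, Cout), c(n, Hh, Ww, Cout))
  }
  Y
}

.conv2Grad <- function(A, W, dY) {
  d <- dim(A); n <- d[1]; Hh <- d[2]; Ww <- d[3]; Cin <- d[4]; Cout <- dim(W)[4]
  Ap <- array(0, c(n, Hh + 2L, Ww + 2L, Cin)); Ap[, 2:(Hh + 1), 2:(Ww + 1), ] <- A
  dW <- array(0, dim(W)); dAp <- array(0, dim(Ap))
  dYm <- matrix(dY, n * Hh * Ww, Cout)
  for (o1 in 1:3) for (o2 in 1:3) {
    Xo <- matrix(Ap[, o1:(o1 + Hh - 1), o2:(o2 + Ww - 1), , drop = FALSE],
                 n * Hh * Ww, Cin)
    dW[o1, o2, , ] <- crossprod(Xo, dYm)
    dXo <- dYm %*% t(matrix(W[o1, o2, , ], Cin, Cout))
    dAp[, o1:(o1 + Hh - 1), o2:(o2 + Ww - 1), ] <-
      dAp[, o1:(o1 + Hh - 1), o2:(o2 + Ww - 1), , drop = FALSE] +
      array(dXo, c(n, Hh, Ww, Cin))
  }
  list(dA = dAp[, 2:(Hh + 1), 2:(Ww + 1), , drop = FALSE], dW = dW,
       db = colSums(dYm))
}

.pool2 <- function(A, kappa) {
  d <- dim(A); n <- d[1]; Hh <- d[2]; Ww <- d[3]; C <- d[4]
  nh <- Hh %/% kappa; nw <- Ww %/% kappa
  if (nh < 1L || nw < 1L) stop("input smaller than the pooling footprint")
  Ar <- array(A[, seq_len(nh * kappa), seq_len(nw * kappa), , drop = FALSE],
              c(n, kappa, nh, kappa, nw, C))
  M <- array(Ar[, 1, , 1, , ], c(n, nh, nw, C))
  idx <- array(1L, c(n, nh, nw, C))
  k2 <- kappa * kappa
  if (k2 > 1) for (q in 2:k2) {
    j1 <- (q - 1) %% kappa + 1; j2 <- (q - 1) %/% kappa + 1
    Aj <- array(Ar[, j1, , j2, , ], c(n, nh, nw, C))
    better <- Aj > M
    M[better] <- Aj[better]; idx[better] <- q
  }
  list(M = M, idx = idx, H = Hh, W = Ww)
}

.pool2Grad <- function(pool, dM, kappa, C) {
  d <- dim(dM); n <- d[1]; nh <- d[2]; nw <- d[3]
  dA <- array(0, c(n, pool$H, pool$W, C))
  for (q in seq_len(kappa * kappa)) {
    j1 <- (q - 1) %% kappa + 1; j2 <- (q - 1) %/% kappa + 1
    sel <- pool$idx == q
    if (!any(sel)) next
    dAt <- array(0, c(n, nh, nw, C)); dAt[sel] <- dM[sel]
    rows <- seq(j1, nh * kappa, by = kappa); cols <- seq(j2, nw * kappa, by = kappa)
    dA[, rows, cols, ] <- dA[, rows, cols, , drop = FALSE] + dAt
  }
  dA
}

## ---- model construction -------------------------------------------------

#' Build a PResNet model
#'
#' Topology: convolution stem, then \code{nBlocks} residual blocks, each
#' \code{conv -> p-ReLU -> conv} plus an identity skip, then max pooling
#' with stride \code{kappa}, then a fully connected head with 2 logits.
#' He-style initialization, fully seeded.
#'
#' @param config see [presnetConfig()].
#' @param inputDim feature-vector length (feature_vector mode) or c(H, W)
#'   (image mode).
#' @return a [PresnetModel-class].
#' @export
buildPresnet <- function(config = presnetConfig(), inputDim) {
  w <- config$width
  img <- config$mode == "image"
  inputDim <- as.integer(inputDim)
  if (img && length(inputDim) != 2L) stop("image mode needs inputDim = c(H, W)")
  if (!img && length(inputDim) != 1L) stop("feature_vector mode needs scalar inputDim")
  if (any(inputDim < config$kappa))
    stop("input smaller than the pooling footprint (kappa = ", config$kappa, ")")
  withSeed(config$seed, {
    rnd <- function(dims, fanIn) array(stats::rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)
    params <- list()
    if (img) {
      params$stem <- list(W = rnd(c(3, 3, 1, w), 9), b = numeric(w))
      for (i in seq_len(config$nBlocks))
        params[[paste0("block", i)]] <-
          list(AW = rnd(c(3, 3, w, w), 9 * w), Ab = numeric(w),
               BW = rnd(c(3, 3, w, w), 9 * w), Bb = numeric(w))
      flat <- (inputDim[1] %/% config$kappa) * (inputDim[2] %/% config$kappa) * w
    } else {
      params$stem <- list(W = rnd(c(3, 1, w), 3), b = numeric(w))
      for (i in seq_len(config$nBlocks))
        params[[paste0("block", i)]] <-
          list(AW = rnd(c(3, w, w), 3 * w), Ab = numeric(w),
               BW = rnd(c(3, w, w), 3 * w), Bb = numeric(w))
      flat <- (inputDim %/% config$kappa) * w
    }
    params$J <- config$jInit
    params$fc <- list(W = rnd(c(flat, 2), flat), b = numeric(2))
    new("PresnetModel", config = config, params = params,
        inputDim = inputDim, featureNames = character(0))
  })
}

#' Forward pass of a PResNet model
#'
#' @param model a [PresnetModel-class].
#' @param x input matrix (n x d) in feature_vector mode, or an n x H x W
#'   array (or single H x W matrix) in image mode.
#' @param useSkips include the identity skip connections (default TRUE;
#'   disabling them is an ablation probe).
#' @param withCache keep intermediates for backpropagation (internal).
#' @return n x 2 logit matrix (or a list with \code{logits} and
#'   \code{cache}).
#' @export
presnetForward <- function(model, x, useSkips = TRUE, withCache = FALSE) {
  cfg <- model@config; p <- model@params
  img <- cfg$mode == "image"
  if (img) {
    if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
    if (!identical(as.integer(dim(x)[2:3]), model@inputDim)) stop("shape mismatch")
    A <- array(x, c(dim(x), 1L))
    convF <- .conv2; poolF <- .pool2
  } else {
    if (is.null(dim(x))) x <- matrix(x, 1L)
    if (ncol(x) != model@inputDim)
      stop("shape mismatch: expected ", model@inputDim, " features, got ", ncol(x))
    nrm <- cfg$norm
    if (!is.null(nrm))
      x <- sweep(sweep(x, 2, nrm$mu), 2, nrm$sd, "/")
    A <- array(x, c(nrow(x), ncol(x), 1L))
    convF <- .conv1; poolF <- .pool1
  }
  J <- p$J
  cache <- list(A0 = A)
  S <- convF(A, p$stem$W, p$stem$b)
  Hh <- prelu(S, J)
  cache$S <- S
  blocksIn <- list(); blocksT1 <- list(); blocksT2 <- list()
  for (i in seq_len(cfg$nBlocks)) {
    bl <- p[[paste0("block", i)]]
    blocksIn[[i]] <- Hh
    T1 <- convF(Hh, bl$AW, bl$Ab)
    T2 <- prelu(T1, J)
    T3 <- convF(T2, bl$BW, bl$Bb)
    Hh <- if (useSkips) T3 + blocksIn[[i]] else T3
    blocksT1[[i]] <- T1; blocksT2[[i]] <- T2
  }
  cache$blocksIn <- blocksIn; cache$blocksT1 <- blocksT1; cache$blocksT2 <- blocksT2
  pool <- poolF(Hh, cfg$kappa)
  cache$pool <- pool; cache$Hlast <- Hh
  n <- dim(A)[1]
  flat <- matrix(pool$M, n, length(pool$M) / n)
  logits <- flat %*% p$fc$W + matrix(p$fc$b, n, 2, byrow = TRUE)
  cache$flat <- flat
  if (withCache) list(logits = logits, cache = cache) else logits
}

.softmaxCE <- function(logits, y) {
  ## y: integer class (1 = Normal, 2 = Abnormal)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  pr <- ex / rowSums(ex)
  n <- nrow(logits)
  loss <- -mean(log(pmax(pr[cbind(seq_len(n), y)], 1e-300)))
  dZ <- pr
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  list(loss = loss, dZ = dZ / n, prob = pr)
}

.presnetBackward <- function(model, fw, dZ) {
  cfg <- model@config; p <- model@params
  img <- cfg$mode == "image"
  convG <- if (img) .conv2Grad else .conv1Grad
  poolG <- if (img) .pool2Grad else .pool1Grad
  cache <- fw$cache
  J <- p$J
  g <- list()
  g$fc <- list(W = crossprod(cache$flat, dZ), b = colSums(dZ))
  dFlat <- dZ %*% t(p$fc$W)
  dM <- array(dFlat, dim(cache$pool$M))
  dH <- poolG(cache$pool, dM, cfg$kappa, cfg$width)
  dJ <- 0
  for (i in rev(seq_len(cfg$nBlocks))) {
    bl <- p[[paste0("block", i)]]
    T1 <- cache$blocksT1[[i]]; T2 <- cache$blocksT2[[i]]
    gB <- convG(T2, bl$BW, dH)
    dT2 <- gB$dA
    dT1 <- dT2 * ifelse(T1 > 0, 1, J)
    dJ <- dJ + sum(dT2 * T1 * (T1 <= 0))
    gA <- convG(cache$blocksIn[[i]], bl$AW, dT1)
    g[[paste0("block", i)]] <- list(AW = gA$dW, Ab = gA$db, BW = gB$dW, Bb = gB$db)
    dH <- gA$dA + dH   # identity skip
  }
  S <- cache$S
  dS <- dH * ifelse(S > 0, 1, J)
  dJ <- dJ + sum(dH * S * (S <= 0))
  gS <- convG(cache$A0, p$stem$W, dS)
  g$stem <- list(W = gS$dW, b = gS$db)
  g$J <- dJ
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a PResNet model
#'
#' Feature inputs are z-scored by the training-set statistics (stored in
#' the model, so prediction applies the identical transform). Minimizes
#' softmax cross-entropy with Adam over seeded mini-batches; biases and the
#' p-ReLU slope are exempt from weight decay and the slope is only updated
#' when \code{jLearnable}. Two runs with the same seed produce identical
#' parameters.
#'
#' @param model a freshly built (or warm-start checkpoint) model.
#' @param x training inputs (n x d matrix, or n x H x W array in image
#'   mode).
#' @param labels class labels (\code{"Normal"} / \code{"Abnormal"}).
#' @param epochs,batchSize,lr override the config values when non-NULL.
#' @return list with the trained \code{model} and a \code{history} data
#'   frame (epoch, loss, accuracy).
#' @export
trainPresnet <- function(model, x, labels, epochs = NULL, batchSize = NULL,
                         lr = NULL) {
  cfg <- model@config
  epochs <- epochs %||% cfg$epochs
  batchSize <- batchSize %||% cfg$batchSize
  lr <- lr %||% cfg$lr
  y <- ifelse(labels == "Abnormal", 2L, 1L)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (cfg$mode == "feature_vector") x <- as.matrix(x)
  n <- if (cfg$mode == "image") dim(x)[1] else nrow(x)
  if (length(y) != n) stop("labels must match the number of samples")
  if (cfg$mode == "feature_vector" && !is.null(colnames(x)))
    model@featureNames <- colnames(x)
  if (cfg$mode == "feature_vector" && is.null(cfg$norm)) {
    ## z-score the features by the training statistics; stored in the model
    ## so prediction applies the identical transform
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd); sd[sd == 0] <- 1
    cfg$norm <- list(mu = mu, sd = sd)
    model@config <- cfg
  }
  params <- model@params
  state <- new.env(); state$m <- list(); state$v <- list()
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  t <- 0L
  withSeed(deriveSeed(cfg$seed, 5L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = batchSize)) {
        take <- ord[start:min(start + batchSize - 1L, n)]
        xb <- if (cfg$mode == "image") x[take, , , drop = FALSE]
              else x[take, , drop = FALSE]
        model@params <- params
        fw <- presnetForward(model, xb, withCache = TRUE)
        ce <- .softmaxCE(fw$logits, y[take])
        if (!is.finite(ce$loss))
          stop("non-finite training loss at epoch ", ep,
               "; reduce the learning rate")
        losses <- c(losses, ce$loss)
        g <- .presnetBackward(model, fw, ce$dZ)
        t <- t + 1L
        params <- .applyAdam(params, g, state, lr, cfg$weightDecay, t,
                             cfg$jLearnable)
      }
      model@params <- params
      pr <- presnetForward(model, x)
      acc <- mean((pr[, 2] > pr[, 1]) + 1L == y)
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses), accuracy = acc))
    }
  })
  model@params <- params
  list(model = model, history = history)
}

## walk the parameter tree explicitly; weight arrays get decay, biases and
## the slope do not
.applyAdam <- function(params, grads, state, lr, wd, t, jLearnable) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  upd <- function(key, w, gr, decay) {
    if (is.null(state$m[[key]])) { state$m[[key]] <- 0 * w; state$v[[key]] <- 0 * w }
    if (decay) gr <- gr + wd * w
    state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * gr
    state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * gr^2
    mh <- state$m[[key]] / (1 - b1^t)
    vh <- state$v[[key]] / (1 - b2^t)
    w - lr * mh / (sqrt(vh) + eps)
  }
  for (nm in names(params)) {
    if (nm == "J") {
      if (jLearnable) params$J <- upd("J", params$J, grads$J, FALSE)
      next
    }
    for (slot in names(params[[nm]]))
      params[[nm]][[slot]] <- upd(paste(nm, slot, sep = "."),
                                  params[[nm]][[slot]], grads[[nm]][[slot]],
                                  slot %in% c("W", "AW", "BW"))
  }
  params
}

#' Predict with a PResNet model
#'
#' Softmax over the two logits; the class is Abnormal iff the abnormal
#' probability exceeds 0.5 (ties go to Normal). The risk label is a
#' placeholder (\code{"none"}) until [riskScreen()] is applied.
#'
#' @param model a trained [PresnetModel-class].
#' @param x a feature vector, an n x d matrix/data.frame (columns aligned
#'   by name when the model stores feature names), or image array.
#' @return data.frame with \code{classLabel}, \code{abnormalScore},
#'   \code{riskLabel}.
#' @export
predictPresnet <- function(model, x) {
  cfg <- model@config
  if (cfg$mode == "feature_vector") {
    if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
    x <- as.matrix(x)
    if (length(model@featureNames) && !is.null(colnames(x))) {
      miss <- setdiff(model@featureNames, colnames(x))
      if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
      x <- x[, model@featureNames, drop = FALSE]
    }
  }
  logits <- presnetForward(model, x)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  pr <- ex / rowSums(ex)
  data.frame(classLabel = ifelse(pr[, 2] > 0.5, "Abnormal", "Normal"),
             abnormalScore = pr[, 2], riskLabel = "none",
             stringsAsFactors = FALSE)
}

#' Risk screening of abnormal predictions
#'
#' Normal predictions get risk \code{"none"}. Abnormal predictions are
#' \code{"high"} when any quadrant's on-rib flag is set or the largest
#' nodule-candidate peak intensity exceeds \code{tauRisk}, else
#' \code{"low"}.
#'
#' @param prediction data.frame from [predictPresnet()] (one or more rows).
#' @param features the full engineered feature vector(s) from
#'   [extractFeatures()] (named vector, or matrix with one row per
#'   prediction).
#' @param tauRisk intensity threshold (default 0.8).
#' @return the prediction data.frame with \code{riskLabel} filled in.
#' @export
riskScreen <- function(prediction, features, tauRisk = 0.8) {
  if (is.null(dim(features)))
    features <- matrix(features, 1L, dimnames = list(NULL, names(features)))
  features <- as.matrix(features)
  flagCols <- paste0("q", 1:4, "_on_rib_flag")
  peakCols <- paste0("q", 1:4, "_nodule_peak")
  if (!all(c(flagCols, peakCols) %in% colnames(features)))
    stop("missing on-rib block in the feature vector")
  if (nrow(features) != nrow(prediction)) stop("row mismatch")
  risk <- vapply(seq_len(nrow(prediction)), function(i) {
    if (prediction$classLabel[i] == "Normal") "none"
    else if (any(features[i, flagCols] == 1) ||
             max(features[i, peakCols]) > tauRisk) "high"
    else "low"
  }, character(1))
  prediction$riskLabel <- risk
  prediction
}

#' Save / load a PResNet model
#'
#' Serialization round-trips exactly: a reloaded model reproduces
#' predictions bit-for-bit.
#'
#' @param model a [PresnetModel-class].
#' @param path file path.
#' @return \code{loadPresnet} returns the model.
#' @export
savePresnet <- function(model, path) saveRDS(model, path)

#' @rdname savePresnet
#' @export
loadPresnet <- function(path) {
  m <- readRDS(path)
  if (!is(m, "PresnetModel")) stop("not a PresnetModel checkpoint: ", path)
  m
}
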