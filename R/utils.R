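## Shared raster helpers. Throughout the package a "raster" is a plain numeric
## matrix in [0,1], indexed [row, col] with origin at the top-left (0-based
## positions in the user-facing seed/centroid coordinates are NOT used: R's
## 1-based indexing is kept everywhere and documented as such).

#' Coerce an image-like object to a numeric raster matrix
#'
#' Accepts a numeric matrix or an \code{EBImage::Image} (grayscale). Values are
#' checked to be finite; dimensions must be at least 8x8.
#'
#' @param x matrix or grayscale \code{Image}.
#' @return numeric matrix.
#' @keywords internal
asRaster <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.array(x) && length(dim(x)) > 2L) {
    if (all(dim(x)[-(1:2)] == 1L)) x <- array(x, dim(x)[1:2])
    else stop("expected a single-channel 2-D image")
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric matrix or grayscale Image")
  if (any(!is.finite(x))) stop("image contains non-finite values")
  if (nrow(x) < 8L || ncol(x) < 8L) stop("image must be at least 8x8")
  x
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Reflected (mirror) index into 1..n for out-of-range stencil samples.
reflectIndex <- function(i, n) {
  i <- abs(i - 1L)
  m <- 2L * n - 2L
  if (n == 1L) return(rep(1L, length(i)))
  i <- i %% m
  ifelse(i >= n, m - i, i) + 1L
}

## 8-connected labeling built on EBImage::bwlabel (4-connected) plus a
## union-find merge across diagonal adjacencies.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- findp(a); rb <- findp(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  w <- which(a > 0 & b > 0 & a != b)
  if (length(w)) mapply(unite, a[w], b[w])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]
  w <- which(a > 0 & b > 0 & a != b)
  if (length(w)) mapply(unite, a[w], b[w])
  roots <- vapply(seq_len(k), findp, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

## Rasterize the convex hull of the TRUE pixels of a mask (scanline fill of the
## chull polygon). Returns a logical matrix of the same shape.
convexHullMask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(idx) == 0L) return(out)
  if (nrow(idx) <= 2L) { out[idx] <- TRUE; return(out) }
  h <- grDevices::chull(idx[, 1], idx[, 2])
  vr <- idx[h, 1]; vc <- idx[h, 2]
  n <- length(vr)
  for (r in seq(min(vr), max(vr))) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      r1 <- vr[i]; r2 <- vr[j]
      if (r1 == r2) { if (r1 == r) xs <- c(xs, vc[i], vc[j]) }
      else if ((r >= min(r1, r2)) && (r <= max(r1, r2)))
        xs <- c(xs, vc[i] + (r - r1) * (vc[j] - vc[i]) / (r2 - r1))
    }
    if (length(xs)) out[r, seq(ceiling(min(xs) - 1e-9), floor(max(xs) + 1e-9))] <- TRUE
  }
  out
}

## Evaluate a thunk under a temporary RNG state seeded with `seed`; the
## caller's RNG state is untouched. All seeded operations in the package go
## through this, which is what makes them bit-reproducible.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic seed-splitting: one global seed fans out to per-stage,
## per-item seeds, all < 2^31. Documented in the methods vignette.
deriveSeed <- function(seed, stage, item = 0L) {
  s <- (as.double(seed) * 48271 + stage * 10007 + item * 101) %% 2147483399
  as.integer(s) + 1L
}

## Sobel gradient magnitude, normalized so a unit-range image maps into [0,1].
sobelMagnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), kx, boundary = "replicate"))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), t(kx), boundary = "replicate"))
  pmin(sqrt(gx^2 + gy^2) / (4 * sqrt(2)), 1)
}
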