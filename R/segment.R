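## Seeded region-growing segmentation. Seed ("knuckle") points are chosen by
## a coati optimization metaheuristic whose random steps are Bates
## distributed; one seed is selected per lung-field quadrant and a region is
## grown from each, giving the four-part segmentation.

#' Bates-distributed random draws
#'
#' The Bates distribution of order \code{phi} is the mean of \code{phi}
#' i.i.d. uniform(0,1) variables: mean 1/2, variance 1/(12 phi). Draws use
#' the current R RNG stream (seed with [withSeed()] or \code{set.seed}).
#'
#' @param n number of draws.
#' @param phi order (integer >= 1).
#' @return numeric vector of n values in [0,1].
#' @export
batesRandom <- function(n = 1L, phi = 3L) {
  if (phi < 1L) stop("phi must be >= 1")
  if (n < 1L) return(numeric(0))
  colMeans(matrix(stats::runif(as.integer(phi) * n), nrow = as.integer(phi)))
}

#' Initialize a coati population
#'
#' Positions are drawn as \code{lower + s * (upper - lower)} with \code{s}
#' Bates-distributed per entry, and fitness is evaluated for every row.
#'
#' @param bounds list with numeric vectors \code{lower} and \code{upper}
#'   (elementwise lower < upper).
#' @param m population size (>= 4).
#' @param fitnessFn function mapping a position vector to a finite scalar
#'   (minimization convention).
#' @param phi Bates order.
#' @return list with \code{positions} (m x n), \code{fitness} (length m),
#'   \code{tn} (iteration counter, starts at 1) and \code{bounds}.
#' @export
coaInit <- function(bounds, m, fitnessFn, phi = 3L) {
  if (m < 4L) stop("m must be >= 4")
  lw <- bounds$lower; up <- bounds$upper
  if (any(lw >= up)) stop("bounds must satisfy lower < upper")
  n <- length(lw)
  s <- matrix(batesRandom(m * n, phi), m, n)
  P <- matrix(lw, m, n, byrow = TRUE) + s * matrix(up - lw, m, n, byrow = TRUE)
  fit <- apply(P, 1, fitnessFn)
  if (any(!is.finite(fit))) stop("fitness function returned a non-finite value")
  list(positions = P, fitness = fit, tn = 1L, bounds = bounds)
}

.clampRows <- function(P, lw, up) {
  pmin(pmax(P, matrix(lw, nrow(P), ncol(P), byrow = TRUE)),
       matrix(up, nrow(P), ncol(P), byrow = TRUE))
}

#' One iteration of the coati optimizer
#'
#' Phase 1 ("iguana hunt"): the first half of the population moves toward
#' the best position (the iguana in the tree); the second half reacts to an
#' iguana dropped at a random ground position, moving toward it if it is
#' fitter and away otherwise. Phase 2 ("predator escape"): every coati takes
#' a Bates-perturbed step inside local bounds that shrink as 1/tn. Both
#' phases accept a candidate only if it strictly improves that row's
#' fitness, so the best fitness never increases. All candidates are clamped
#' to the bounds.
#'
#' @param pop population list from [coaInit()] (or a previous step).
#' @param fitnessFn fitness function (finite scalar, minimized).
#' @param phi Bates order.
#' @return updated population list with \code{tn} incremented.
#' @export
coaStep <- function(pop, fitnessFn, phi = 3L) {
  P <- pop$positions; fit <- pop$fitness
  lw <- pop$bounds$lower; up <- pop$bounds$upper
  m <- nrow(P); n <- ncol(P); tn <- pop$tn
  evalFit <- function(x) {
    f <- fitnessFn(x)
    if (!is.finite(f)) stop("fitness function returned a non-finite value")
    f
  }
  iguana <- P[which.min(fit), ]
  half <- floor(m / 2)
  for (x in seq_len(half)) {
    s <- batesRandom(n, phi)
    th <- sample(1:2, 1L)
    cand <- pmin(pmax(P[x, ] + s * (iguana - th * P[x, ]), lw), up)
    f <- evalFit(cand)
    if (f < fit[x]) { P[x, ] <- cand; fit[x] <- f }
  }
  for (x in seq.int(half + 1L, m)) {
    s <- batesRandom(n, phi)
    gnd <- lw + s * (up - lw)
    fGnd <- evalFit(gnd)
    s2 <- batesRandom(n, phi)
    th <- sample(1:2, 1L)
    cand <- if (fGnd < fit[x]) P[x, ] + s2 * (gnd - th * P[x, ])
            else P[x, ] + s2 * (P[x, ] - gnd)
    cand <- pmin(pmax(cand, lw), up)
    f <- evalFit(cand)
    if (f < fit[x]) { P[x, ] <- cand; fit[x] <- f }
  }
  lwLoc <- lw / tn; upLoc <- up / tn
  for (x in seq_len(m)) {
    s <- batesRandom(n, phi)
    cand <- P[x, ] + (1 - 2 * s) * (lwLoc + s * (upLoc - lwLoc))
    cand <- pmin(pmax(cand, lw), up)
    f <- evalFit(cand)
    if (f < fit[x]) { P[x, ] <- cand; fit[x] <- f }
  }
  list(positions = P, fitness = fit, tn = tn + 1L, bounds = pop$bounds)
}

#' Run the coati optimizer
#'
#' @param fitnessFn fitness function (finite scalar, minimized).
#' @param bounds list with \code{lower} and \code{upper}.
#' @param m population size (default 20).
#' @param Tn iterations (default 50).
#' @param phi Bates order (default 3).
#' @param seed RNG seed.
#' @return list with \code{best} position, \code{bestFitness}, the
#'   per-iteration best-so-far \code{trace}, and the final population.
#' @export
coatiOptimize <- function(fitnessFn, bounds, m = 20L, Tn = 50L, phi = 3L,
                          seed = 1L) {
  withSeed(seed, {
    pop <- coaInit(bounds, m, fitnessFn, phi)
    trace <- numeric(Tn)
    for (i in seq_len(Tn)) {
      pop <- coaStep(pop, fitnessFn, phi)
      trace[i] <- min(pop$fitness)
    }
    b <- which.min(pop$fitness)
    list(best = pop$positions[b, ], bestFitness = pop$fitness[b],
         trace = trace, population = pop)
  })
}

#' Grow a region from a seed point
#'
#' Breadth-first region growing: a pixel joins the region iff its absolute
#' intensity difference from the seed pixel is below \code{threshold} and it
#' is connectivity-adjacent to the region. With \code{threshold = 0} the
#' region is exactly the connected set of pixels equal to the seed value.
#'
#' @param image raster.
#' @param seed c(row, col) inside the image.
#' @param threshold intensity tolerance (>= 0).
#' @param connectivity 4 or 8.
#' @return logical raster: one connected component containing the seed.
#' @export
regionGrow <- function(image, seed, threshold, connectivity = 8L) {
  image <- asRaster(image)
  r <- round(seed[1]); c <- round(seed[2])
  if (r < 1 || r > nrow(image) || c < 1 || c > ncol(image))
    stop("seed lies outside the image")
  if (threshold < 0) stop("threshold must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  d <- abs(image - image[r, c])
  eligible <- if (threshold == 0) d == 0 else d < threshold
  lab <- if (connectivity == 4L) EBImage::imageData(EBImage::bwlabel(eligible))
         else label8(eligible)
  lab == lab[r, c]
}

#' Default segmentation configuration
#'
#' \code{coa}: seed-search population size, iterations and Bates order
#' (smaller than the standalone [coatiOptimize()] defaults; four quadrant
#' searches run per image). \code{grow}: threshold rule
#' \code{c * sd(5x5 window at seed) + floor}, connectivity, and the minimum
#' grown-region size (fraction of the quadrant's lung-field area) a seed
#' must anchor to be considered a valid knuckle point.
#' @return nested list.
#' @export
segmentConfig <- function() {
  list(coa = list(m = 10L, Tn = 15L, phi = 3L),
       grow = list(c = 3, floor = 0.05, connectivity = 8L, minFrac = 0.2,
                   close = 5L))
}

## threshold rule: c * sd of the 5x5 neighborhood of the seed + floor
.seedThreshold <- function(image, seed, cfg) {
  r <- reflectIndex((seed[1] - 2):(seed[1] + 2), nrow(image))
  c <- reflectIndex((seed[2] - 2):(seed[2] + 2), ncol(image))
  cfg$c * stats::sd(image[r, c]) + cfg$floor
}

## quadrant index masks (TL, TR, BL, BR) from the lung-mask bounding box
.quadrantMasks <- function(lungMask) {
  idx <- which(lungMask, arr.ind = TRUE)
  rmid <- floor(mean(range(idx[, 1]))); cmid <- floor(mean(range(idx[, 2])))
  H <- nrow(lungMask); W <- ncol(lungMask)
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  list(TL = rr <= rmid & cc <= cmid, TR = rr <= rmid & cc > cmid,
       BL = rr > rmid & cc <= cmid, BR = rr > rmid & cc > cmid)
}

#' Select one seed point per lung-field quadrant
#'
#' Runs one coati-optimizer instance per quadrant of the lung mask (bounds =
#' the quadrant's bounding box), minimizing the within-region variance of
#' the region grown from the candidate; candidates anchoring less than
#' \code{grow$minFrac} of the quadrant's lung-field pixels are penalized so
#' degenerate micro-regions (single bright structures) cannot win. Returned
#' seeds are integer pixels inside the lung mask, in order TL, TR, BL, BR.
#'
#' @param image raster (typically the enhanced image E).
#' @param lungMask logical lung-field mask (nonempty).
#' @param config see [segmentConfig()].
#' @param seed RNG seed.
#' @return 4 x 2 integer matrix of (row, col) seeds.
#' @export
selectSeeds <- function(image, lungMask, config = segmentConfig(), seed = 1L) {
  image <- asRaster(image)
  if (!any(lungMask)) stop("lung mask is empty")
  quads <- .quadrantMasks(lungMask)
  seeds <- matrix(NA_integer_, 4, 2, dimnames = list(names(quads), c("row", "col")))
  for (q in 1:4) {
    qmask <- lungMask & quads[[q]]
    if (!any(qmask)) next
    idx <- which(qmask, arr.ind = TRUE)
    bounds <- list(lower = c(min(idx[, 1]), min(idx[, 2])),
                   upper = c(max(idx[, 1]) + 0.999, max(idx[, 2]) + 0.999))
    minSize <- config$grow$minFrac * nrow(idx)
    cache <- new.env(hash = TRUE)
    fitness <- function(pos) {
      r <- min(max(round(pos[1]), 1L), nrow(image))
      c <- min(max(round(pos[2]), 1L), ncol(image))
      key <- paste0(r, "_", c)
      if (!is.null(cache[[key]])) return(cache[[key]])
      f <- if (!qmask[r, c]) {
        1e6 + min(sqrt((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
      } else {
        thr <- .seedThreshold(image, c(r, c), config$grow)
        reg <- regionGrow(image, c(r, c), thr, config$grow$connectivity) & qmask
        size <- sum(reg)
        if (size < minSize) 1e3 + (minSize - size) / minSize
        else stats::var(image[reg])
      }
      cache[[key]] <- f
      f
    }
    res <- coatiOptimize(fitness, bounds, m = config$coa$m, Tn = config$coa$Tn,
                         phi = config$coa$phi, seed = deriveSeed(seed, 2L, q))
    p <- round(res$best)
    if (!qmask[p[1], p[2]]) {  # snap to the nearest lung-mask pixel
      j <- which.min((idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2)
      p <- idx[j, ]
    }
    seeds[q, ] <- as.integer(p)
  }
  for (q in which(is.na(seeds[, 1]))) {
    warning("quadrant ", q, " has no lung pixels; borrowing the nearest seed")
    src <- which(!is.na(seeds[, 1]))[1]
    seeds[q, ] <- seeds[src, ]
  }
  seeds
}

#' Resolve overlaps between grown region masks
#'
#' Contested pixels (claimed by more than one mask) are assigned to the mask
#' whose seed has the closest gray value; ties go to the lower mask index.
#'
#' @param masks list of logical rasters.
#' @param image raster the regions were grown on.
#' @param seeds matrix of (row, col) seed points, one row per mask.
#' @return list of disjoint logical rasters.
#' @export
resolveOverlaps <- function(masks, image, seeds) {
  image <- asRaster(image)
  count <- Reduce(`+`, masks)
  contested <- which(count > 1)
  if (length(contested) == 0L) return(masks)
  seedVals <- image[seeds]
  vals <- image[contested]
  for (p in seq_along(contested)) {
    px <- contested[p]
    claim <- which(vapply(masks, function(m) m[px], logical(1)))
    win <- claim[which.min(abs(vals[p] - seedVals[claim]))]
    for (q in setdiff(claim, win)) masks[[q]][px] <- FALSE
  }
  masks
}

#' Four-part region-growing segmentation of the lung fields
#'
#' Selects one knuckle seed per quadrant via [selectSeeds()], grows a region
#' from each with a per-seed threshold \code{c * sd(5x5 at seed) + floor},
#' closes thin gaps (crossing vessels and rib bands) with a small disc,
#' intersects each region with the lung mask and its own quadrant, and
#' resolves any remaining overlaps by the gray-value rule. Reproducible
#' bit-exactly for a fixed seed.
#'
#' @param image raster (the enhanced image E).
#' @param lungMask logical lung-field mask.
#' @param config see [segmentConfig()].
#' @param seed RNG seed.
#' @return a [SegmentationResult-class] (masks in order TL, TR, BL, BR).
#' @export
segmentLungs <- function(image, lungMask, config = segmentConfig(), seed = 1L) {
  image <- asRaster(image)
  seeds <- selectSeeds(image, lungMask, config, seed)
  quads <- .quadrantMasks(lungMask)
  masks <- vector("list", 4)
  thresholds <- numeric(4)
  for (q in 1:4) {
    thresholds[q] <- .seedThreshold(image, seeds[q, ], config$grow)
    grown <- regionGrow(image, seeds[q, ], thresholds[q],
                        config$grow$connectivity)
    cl <- config$grow$close %||% 1L
    if (cl > 1L) {   # fill thin vessel/rib gaps inside the grown parenchyma
      br <- EBImage::makeBrush(cl, "disc")
      grown <- EBImage::imageData(EBImage::erode(
        EBImage::dilate(EBImage::Image(grown * 1), br), br)) > 0.5
    }
    grown <- grown & lungMask
    inQuad <- quads[[q]][seeds[q, 1], seeds[q, 2]]
    masks[[q]] <- if (inQuad) grown & quads[[q]] else grown
  }
  masks <- resolveOverlaps(masks, image, seeds)
  new("SegmentationResult", seeds = unname(seeds), masks = masks,
      thresholds = thresholds, lungMask = lungMask)
}
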