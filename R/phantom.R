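## Synthetic chest phantom: two elliptical lung fields inside a brighter
## thorax, curved rib bands entering the lung fields from the lateral chest
## wall, thin vessel lines fanning out of the hilum, and optional bright
## nodule blobs. Every rendered structure has a ground-truth mask, so all
## downstream stages are testable without any external data.

## Fixed intensity palette (the ordering the feature operators assume).
.palette <- list(background = 0.05, thorax = 0.45, lung = 0.25,
                 vessel = 0.65, rib = 0.75, nodule = 0.9)

#' Describe one nodule for a phantom
#'
#' @param radius radius in pixels (>= 2).
#' @param placement one of \code{"on_rib"}, \code{"on_vessel"},
#'   \code{"free"}. When \code{center} is \code{NULL} the generator picks a
#'   center consistent with the placement (on a rib band, on a vessel line,
#'   or in free parenchyma).
#' @param center optional c(row, col) center; must fall inside a lung field.
#' @return a list usable in the \code{nodules} argument of [phantomSpec()].
#' @export
noduleSpec <- function(radius, placement = c("free", "on_rib", "on_vessel"),
                       center = NULL) {
  placement <- match.arg(placement)
  if (radius < 2) stop("nodule radii must be >= 2 px")
  list(center = center, radius = radius, placement = placement)
}

#' Construct a phantom specification
#'
#' @param height,width image size in pixels (>= 64 each).
#' @param nRibs rib bands per lung (default 3).
#' @param nVessels vessel lines per lung (default 3).
#' @param nodules list of [noduleSpec()] descriptors; empty for a normal
#'   phantom.
#' @param noise one of \code{"none"}, \code{"gaussian"}, \code{"poisson"}.
#' @param sigma gaussian noise standard deviation (intensity units).
#' @param scale poisson photon scale (counts per unit intensity).
#' @param seed integer RNG seed; the rendered phantom is a pure function of
#'   the spec.
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(nodules = list(noduleSpec(6, "on_rib")), seed = 7)
#' ph <- generatePhantom(spec)
#' phantomTruth(ph)@classLabel
#' @export
phantomSpec <- function(height = 128L, width = 128L, nRibs = 3L,
                        nVessels = 3L, nodules = list(),
                        noise = c("gaussian", "none", "poisson"),
                        sigma = 0.05, scale = 1e4, seed = 1L) {
  noise <- match.arg(noise)
  nm <- switch(noise,
               none = list(kind = "none"),
               gaussian = list(kind = "gaussian", sigma = sigma),
               poisson = list(kind = "poisson", scale = scale))
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      nRibs = as.integer(nRibs), nVessels = as.integer(nVessels),
      nodules = nodules, noiseModel = nm, seed = as.integer(seed))
}

## Ellipse interior mask on an H x W grid.
.ellipseMask <- function(H, W, cr, cc, ar, ac) {
  rr <- matrix(seq_len(H), H, W)
  cc2 <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((rr - cr) / ar)^2 + ((cc2 - cc) / ac)^2 <= 1
}

## Thick line segment mask (stroke of given half-width around the segment).
.segmentMask <- function(H, W, r1, c1, r2, c2, halfwidth) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  vr <- r2 - r1; vc <- c2 - c1
  len2 <- max(vr^2 + vc^2, 1e-9)
  t <- pmin(pmax(((rr - r1) * vr + (cc - c1) * vc) / len2, 0), 1)
  dr <- rr - (r1 + t * vr); dc <- cc - (c1 + t * vc)
  sqrt(dr^2 + dc^2) <= halfwidth
}

#' Generate a synthetic chest phantom with ground truth
#'
#' Renders the spec deterministically (same spec, same seed: bit-identical
#' output). Intensities follow the fixed palette background 0.05, lung field
#' 0.25, vessels 0.65, ribs 0.75, nodules 0.9, so that background < lung
#' parenchyma < vessels < ribs < nodules. Rib bands enter each lung from the
#' lateral chest wall and span about three quarters of the lung width,
#' leaving a medial corridor so the parenchyma stays connected; vessels fan
#' out of the hilum without reaching the lung boundary.
#'
#' @param spec a [PhantomSpec-class].
#' @param riskRadius nodules at least this radius (px) are labeled high
#'   risk even off-rib (default 8).
#' @return a [ChestPhantom-class] with image, [PhantomTruth-class] and spec.
#' @export
generatePhantom <- function(spec, riskRadius = 8) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  H <- spec@height; W <- spec@width
  withSeed(spec@seed, {
    jit <- stats::runif(6, -0.01, 0.01)   # mild per-phantom anatomy jitter
    img <- matrix(.palette$background, H, W)
    thorax <- .ellipseMask(H, W, H * (0.50 + jit[1]), W * 0.5,
                           H * 0.44, W * 0.47)
    img[thorax] <- .palette$thorax
    lungL <- .ellipseMask(H, W, H * (0.52 + jit[2]), W * (0.30 + jit[3]),
                          H * 0.27, W * 0.16)
    lungR <- .ellipseMask(H, W, H * (0.52 + jit[4]), W * (0.70 + jit[5]),
                          H * 0.27, W * 0.16)
    lungMask <- lungL | lungR
    img[lungMask] <- .palette$lung

    ribMask <- matrix(FALSE, H, W)
    halfw <- max(1, round(H / 128))
    for (side in 1:2) {
      lm <- if (side == 1) lungL else lungR
      idx <- which(lm, arr.ind = TRUE)
      rmin <- min(idx[, 1]); rmax <- max(idx[, 1])
      cmin <- min(idx[, 2]); cmax <- max(idx[, 2])
      lat <- if (side == 1) cmin else cmax     # lateral chest-wall side
      span <- round(0.55 * (cmax - cmin))      # penetration into the lung
      dir <- if (side == 1) 1 else -1
      for (i in seq_len(spec@nRibs)) {
        r0 <- rmin + (rmax - rmin) * i / (spec@nRibs + 1)
        cols <- lat + dir * seq(-6, span)      # start in the chest wall
        # gentle downward curve away from the lateral wall (|slope| < 0.5)
        rows <- r0 + 0.35 * seq(0, span + 6)^2 / max(span + 6, 1)
        keep <- cols >= 1 & cols <= W & rows >= 1 & rows <= H
        cols <- cols[keep]; rows <- rows[keep]
        for (j in seq_along(cols)) {
          rs <- max(1, round(rows[j]) - halfw):min(H, round(rows[j]) + halfw)
          ribMask[rs, cols[j]] <- TRUE
        }
      }
    }
    ribMask <- ribMask & thorax
    img[ribMask] <- .palette$rib

    vesselMask <- matrix(FALSE, H, W)
    for (side in 1:2) {
      lm <- if (side == 1) lungL else lungR
      idx <- which(lm, arr.ind = TRUE)
      cmin <- min(idx[, 2]); cmax <- max(idx[, 2])
      hilR <- round(mean(range(idx[, 1])))
      hilC <- if (side == 1) cmax - 2 else cmin + 2  # medial hilum
      dir <- if (side == 1) -1 else 1
      angles <- seq(-55, 55, length.out = max(spec@nVessels, 1)) * pi / 180
      len <- 0.55 * (cmax - cmin)
      for (a in angles[seq_len(spec@nVessels)]) {
        r2 <- hilR + len * sin(a)
        c2 <- hilC + dir * len * cos(a)
        seg <- .segmentMask(H, W, hilR, hilC, r2, c2, 0.7)
        vesselMask <- vesselMask | (seg & lm)
      }
    }
    img[vesselMask] <- .palette$vessel

    ## nodules: resolve placements, then paint last (they sit on top)
    noduleMasks <- list()
    placements <- character(0)
    radii <- numeric(0)
    interior <- function(rad) {
      # lung pixels at least rad/2 away from the lung boundary
      er <- EBImage::erode(EBImage::Image(lungMask * 1),
                           EBImage::makeBrush(2 * max(1, round(rad / 2)) + 1, "disc"))
      EBImage::imageData(er) > 0.5
    }
    for (nd in spec@nodules) {
      ctr <- nd$center
      if (is.null(ctr)) {
        cand <- switch(nd$placement,
          on_rib = which(ribMask & interior(nd$radius), arr.ind = TRUE),
          on_vessel = which(vesselMask & interior(nd$radius), arr.ind = TRUE),
          free = {
            far <- !(EBImage::imageData(EBImage::dilate(
              EBImage::Image((ribMask | vesselMask) * 1),
              EBImage::makeBrush(2 * ceiling(nd$radius) + 3, "disc"))) > 0.5)
            which(far & interior(nd$radius), arr.ind = TRUE)
          })
        if (nrow(cand) == 0L)
          stop("no valid ", nd$placement, " position for a nodule of radius ",
               nd$radius)
        ctr <- cand[sample.int(nrow(cand), 1L), ]
      }
      if (!lungMask[round(ctr[1]), round(ctr[2])])
        stop("invalid geometry: nodule center (", round(ctr[1]), ",",
             round(ctr[2]), ") lies outside the lung-field ellipses")
      m <- .ellipseMask(H, W, ctr[1], ctr[2], nd$radius, nd$radius)
      noduleMasks <- c(noduleMasks, list(m))
      placements <- c(placements, nd$placement)
      radii <- c(radii, nd$radius)
      img[m] <- .palette$nodule
    }

    classLabel <- if (length(noduleMasks)) "Abnormal" else "Normal"
    riskLabel <- if (classLabel == "Normal") "none"
      else if (any(placements == "on_rib") || any(radii >= riskRadius)) "high"
      else "low"

    noiseSeed <- deriveSeed(spec@seed, stage = 9L)
    img <- switch(spec@noiseModel$kind,
                  none = img,
                  gaussian = addNoise(img, spec@noiseModel, noiseSeed),
                  poisson = addNoise(img, spec@noiseModel, noiseSeed))

    truth <- new("PhantomTruth", lungMask = lungMask, ribMask = ribMask,
                 vesselMask = vesselMask, noduleMasks = noduleMasks,
                 classLabel = classLabel, riskLabel = riskLabel)
    new("ChestPhantom", image = img, truth = truth, spec = spec)
  })
}

#' Add Gaussian or Poisson noise to a raster
#'
#' Gaussian noise adds i.i.d. zero-mean samples of the stated sigma; Poisson
#' noise draws counts at \code{scale} photons per unit intensity and
#' rescales. Output is clipped to [0,1].
#'
#' @param image raster in [0,1].
#' @param model list with \code{kind} in \code{"none"}, \code{"gaussian"}
#'   (with \code{sigma}) or \code{"poisson"} (with \code{scale}).
#' @param seed integer RNG seed.
#' @return noisy raster, same shape.
#' @export
addNoise <- function(image, model, seed = 1L) {
  image <- asRaster(image)
  if (any(image < 0 | image > 1)) stop("image must lie in [0,1]")
  kind <- model$kind
  if (is.null(kind)) stop("noise model needs a 'kind'")
  withSeed(seed, switch(kind,
    none = image,
    gaussian = {
      if (is.null(model$sigma) || model$sigma < 0) stop("sigma must be >= 0")
      if (model$sigma == 0) image
      else clip01(image + matrix(stats::rnorm(length(image), 0, model$sigma),
                                 nrow(image)))
    },
    poisson = {
      if (is.null(model$scale) || model$scale <= 0) stop("scale must be > 0")
      clip01(matrix(stats::rpois(length(image), lambda = image * model$scale),
                    nrow(image)) / model$scale)
    },
    stop("unknown noise kind: ", kind)))
}

#' Augment an image (rotation, scaling, flips, translation)
#'
#' Output keeps the input shape; uncovered pixels are padded with \code{bg}.
#' Use \code{interpolation = "nearest"} to transform masks with the same op.
#'
#' @param image raster.
#' @param op one of \code{"rotate"}, \code{"scale"}, \code{"flip"},
#'   \code{"translate"}.
#' @param angle rotation angle in degrees (rotate).
#' @param factor scale factor > 0 (scale).
#' @param axis \code{"horizontal"} (mirror columns) or \code{"vertical"}
#'   (flip).
#' @param dr,dc integer translation in rows / columns (translate).
#' @param interpolation \code{"bilinear"} (images) or \code{"nearest"}
#'   (masks).
#' @param bg background fill value.
#' @return transformed raster, same shape as the input.
#' @export
augmentImage <- function(image, op = c("rotate", "scale", "flip", "translate"),
                         angle = 0, factor = 1,
                         axis = c("horizontal", "vertical"),
                         dr = 0, dc = 0,
                         interpolation = c("bilinear", "nearest"), bg = 0) {
  op <- match.arg(op)
  interpolation <- match.arg(interpolation)
  image <- asRaster(image)
  filt <- if (interpolation == "bilinear") "bilinear" else "none"
  d <- dim(image)
  out <- switch(op,
    rotate = {
      if (angle %% 360 == 0) image
      else EBImage::imageData(EBImage::rotate(EBImage::Image(image), angle,
             filter = filt, output.dim = d, bg.col = bg))
    },
    flip = {
      axis <- match.arg(axis)
      if (axis == "horizontal") image[, rev(seq_len(d[2])), drop = FALSE]
      else image[rev(seq_len(d[1])), , drop = FALSE]
    },
    translate = EBImage::imageData(EBImage::translate(EBImage::Image(image),
                  c(dr, dc), filter = filt, bg.col = bg)),
    scale = {
      if (factor <= 0) stop("scale factor must be > 0")
      if (factor == 1) image
      else {
        nd <- pmax(round(d * factor), 1L)
        sc <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                w = nd[1], h = nd[2], filter = filt))
        out <- matrix(bg, d[1], d[2])
        # center-crop or center-pad back to the input shape
        sr <- max(0L, (nd[1] - d[1]) %/% 2L); tr <- max(0L, (d[1] - nd[1]) %/% 2L)
        scc <- max(0L, (nd[2] - d[2]) %/% 2L); tc <- max(0L, (d[2] - nd[2]) %/% 2L)
        nr2 <- min(nd[1], d[1]); nc2 <- min(nd[2], d[2])
        out[tr + seq_len(nr2), tc + seq_len(nc2)] <-
          sc[sr + seq_len(nr2), scc + seq_len(nc2)]
        out
      }
    })
  unname(out)
}

#' Draw a reproducible random phantom specification
#'
#' Convenience for building phantom corpora: abnormal phantoms get 1 or 2
#' nodules with radius uniform in 3..10 px and a random placement.
#'
#' @param seed integer seed (also the rendering seed).
#' @param abnormal logical; include nodules?
#' @param noise,sigma passed to [phantomSpec()].
#' @return a [PhantomSpec-class].
#' @export
randomPhantomSpec <- function(seed, abnormal = FALSE,
                              noise = "gaussian", sigma = 0.05) {
  nodules <- if (abnormal) withSeed(deriveSeed(seed, stage = 8L), {
    n <- sample(1:2, 1L)
    lapply(seq_len(n), function(i)
      noduleSpec(radius = sample(3:10, 1L),
                 placement = sample(c("free", "on_rib", "on_vessel"), 1L)))
  }) else list()
  phantomSpec(nodules = nodules, noise = noise, sigma = sigma, seed = seed)
}
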