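## Preprocessing chain: structure-adaptive anisotropic diffusion denoising
## driven by intra-class variance (I-ADF), robust contrast stretching,
## convex-hull lung-field extraction, and unsharp-mask edge enhancement.

#' Diffusion gain coefficient
#'
#' Maps local first and second moments to a gain in [0,1]:
#' \code{exp(-variance / (k^2 * mean^2 + eps))}. The gain is 1 where the
#' neighborhood is perfectly homogeneous and decays monotonically as the
#' intra-class variance grows; the diffusion eigenvalues are built from
#' \code{1 - gain}.
#'
#' @param mean local mean intensity.
#' @param variance local intra-class variance (sum of squared deviations
#'   over the stencil, unnormalized); must be >= 0.
#' @param k gain sensitivity (> 0, default 0.1).
#' @param eps regularizer (> 0, default 1e-8).
#' @return gain value(s) in [0,1]; vectorized.
#' @examples
#' gainCoefficient(0.5, 0.0025, k = 0.1)  # about exp(-1)
#' @export
gainCoefficient <- function(mean, variance, k = 0.1, eps = 1e-8) {
  if (any(variance < 0)) stop("variance must be non-negative")
  if (k <= 0 || eps <= 0) stop("k and eps must be positive")
  exp(-variance / (k^2 * mean^2 + eps))
}

#' Eigenvalue ladder of the diffusion matrix
#'
#' Builds the three diffusion-matrix eigenvalues from the isotropic, planar
#' and linear gains: \code{alpha1 = 1 - C},
#' \code{alpha2 = alpha1 + (3/2) (1 - Cplanar)},
#' \code{alpha3 = alpha2 + 3 (1 - Clinear)}. For gains in [0,1] the ladder
#' satisfies 0 <= alpha1 <= alpha2 <= alpha3.
#'
#' @param C,Cplanar,Clinear gains in [0,1]; vectorized.
#' @return list with elements \code{alpha1}, \code{alpha2}, \code{alpha3}.
#' @export
gainTriple <- function(C, Cplanar, Clinear) {
  if (any(c(C, Cplanar, Clinear) < 0) || any(c(C, Cplanar, Clinear) > 1))
    stop("gains must lie in [0,1]")
  a1 <- 1 - C
  a2 <- a1 + 1.5 * (1 - Cplanar)
  a3 <- a2 + 3 * (1 - Clinear)
  list(alpha1 = a1, alpha2 = a2, alpha3 = a3)
}

## Nearest-neighbour sample of image at (possibly fractional, possibly
## out-of-range) positions, with mirrored boundary.
.sampleNN <- function(image, rows, cols) {
  r <- reflectIndex(round(rows), nrow(image))
  c <- reflectIndex(round(cols), ncol(image))
  image[cbind(r, c)]
}

#' Local stencil statistics for the diffusion gains
#'
#' At one pixel, computes the mean and the intra-class variance (sum of
#' squared deviations, unnormalized) over three stencils: the full 5x5
#' axis-aligned window (1/25 mean normalization), a 5x5 stencil spanned by
#' the eigenvector pair (e2, e3) (1/25), and a 7-sample stencil along e3
#' (1/7). Out-of-image samples are mirrored. For a single 2-D slice, pass
#' \code{e3 = NULL}: the out-of-plane axis then contributes no in-plane
#' offset (the planar stencil collapses onto e2, each sample counted five
#' times) and the linear stencil runs along e2 as a surrogate.
#'
#' @param image raster.
#' @param position c(row, col).
#' @param e2 in-plane unit vector c(dr, dc) orthogonal to the dominant
#'   gradient direction.
#' @param e3 second stencil direction c(dr, dc), or \code{NULL} for the
#'   out-of-plane axis.
#' @return list with \code{mean}, \code{meanPlanar}, \code{meanLinear},
#'   \code{var}, \code{varPlanar}, \code{varLinear}.
#' @export
localStats <- function(image, position, e2, e3 = NULL) {
  image <- asRaster(image)
  r0 <- position[1]; c0 <- position[2]
  ## full 5x5 axis window
  off <- as.matrix(expand.grid(-2:2, -2:2))
  full <- .sampleNN(image, r0 + off[, 1], c0 + off[, 2])
  m <- sum(full) / 25
  v <- sum((full - m)^2)
  ## planar 5x5 stencil over span(e2, e3)
  bc <- as.matrix(expand.grid(-2:2, -2:2))
  if (is.null(e3)) { e3r <- 0; e3c <- 0 } else { e3r <- e3[1]; e3c <- e3[2] }
  pl <- .sampleNN(image, r0 + bc[, 1] * e2[1] + bc[, 2] * e3r,
                         c0 + bc[, 1] * e2[2] + bc[, 2] * e3c)
  mp <- sum(pl) / 25
  vp <- sum((pl - mp)^2)
  ## linear 7-sample stencil along e3 (e2 surrogate for a single slice)
  dir <- if (is.null(e3)) e2 else e3
  ln <- .sampleNN(image, r0 + (-3:3) * dir[1], c0 + (-3:3) * dir[2])
  ml <- sum(ln) / 7
  vl <- sum((ln - ml)^2)
  list(mean = m, meanPlanar = mp, meanLinear = ml,
       var = v, varPlanar = vp, varLinear = vl)
}

## shift a matrix by (dr, dc) with mirrored boundary (vectorized gather)
.shiftM <- function(x, dr, dc) {
  x[reflectIndex(seq_len(nrow(x)) + dr, nrow(x)),
    reflectIndex(seq_len(ncol(x)) + dc, ncol(x)), drop = FALSE]
}

## separable 5-tap box sums (mirrored boundary)
.boxSum5 <- function(x) {
  s <- x
  for (d in c(-2, -1, 1, 2)) s <- s + .shiftM(x, d, 0)
  out <- s
  for (d in c(-2, -1, 1, 2)) out <- out + .shiftM(s, 0, d)
  out
}

## 3x3 binomial smoothing (mirrored)
.smooth3 <- function(x) {
  s <- 0.5 * x + 0.25 * (.shiftM(x, -1, 0) + .shiftM(x, 1, 0))
  0.5 * s + 0.25 * (.shiftM(s, 0, -1) + .shiftM(s, 0, 1))
}

#' Intra-class-variance anisotropic diffusion denoising
#'
#' Explicit-Euler integration of a divergence-form diffusion whose tensor
#' eigenvalues come from the [gainTriple()] ladder: at each pixel the local
#' structure tensor supplies the dominant gradient direction e1 and its
#' in-plane orthogonal e2; gains are computed from the full 5x5 window (C),
#' the stencil along e2 (Cplanar) and the 7-sample e2 stencil (Clinear,
#' in-plane surrogate for single slices), and the tensor diffuses with
#' eigenvalue \code{alpha1 = 1 - C} along e1 and the full ladder value
#' along e2. The scheme is conservative (face fluxes, zero-flux Neumann
#' boundaries), so the global intensity sum is preserved exactly before
#' clipping. Stacks with a third dimension are denoised slice by slice.
#'
#' @param image raster (or H x W x D array of slices).
#' @param iterations number of Euler steps (default 10).
#' @param dt time step; must satisfy dt <= 1/(2 d maxAlpha) with d = 2 and
#'   maxAlpha the largest attained diffusion eigenvalue (default 0.01,
#'   safe for the worst-case ladder value 5.5 and small enough that noise
#'   removal in homogeneous regions outpaces edge erosion over the default
#'   10 iterations).
#' @param k,eps gain parameters, see [gainCoefficient()]; the denoiser
#'   default k = 1 makes the gains span (0,1) on noisy phantoms given the
#'   unnormalized (sum of squared deviations) stencil variance.
#' @param clip clip the result to [0,1] (default TRUE). Disable to verify
#'   conservation.
#' @return denoised raster, same shape.
#' @export
iadfDenoise <- function(image, iterations = 10L, dt = 0.01, k = 1.0,
                        eps = 1e-8, clip = TRUE) {
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] > 1L) {
    out <- image
    for (d in seq_len(dim(image)[3]))
      out[, , d] <- iadfDenoise(image[, , d], iterations, dt, k, eps, clip)
    return(out)
  }
  I <- asRaster(image)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (dt <= 0) stop("dt must be > 0")
  H <- nrow(I); W <- ncol(I)
  for (it in seq_len(iterations)) {
    gr <- (.shiftM(I, 1, 0) - .shiftM(I, -1, 0)) / 2
    gc <- (.shiftM(I, 0, 1) - .shiftM(I, 0, -1)) / 2
    J11 <- .smooth3(gr * gr); J22 <- .smooth3(gc * gc); J12 <- .smooth3(gr * gc)
    theta <- 0.5 * atan2(2 * J12, J11 - J22)   # orientation of e1 (gradient)
    e1r <- cos(theta); e1c <- sin(theta)
    e2r <- -e1c; e2c <- e1r

    ## full-window gain
    s1 <- .boxSum5(I); s2 <- .boxSum5(I * I)
    mFull <- s1 / 25
    vFull <- pmax(s2 - 25 * mFull^2, 0)
    C <- gainCoefficient(mFull, vFull, k, eps)

    ## stencil gains along e2 (planar 5-sample / linear 7-sample)
    R <- matrix(seq_len(H), H, W); Cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    gather <- function(b) {
      rr <- reflectIndex(round(R + b * e2r), H)
      cc <- reflectIndex(round(Cc + b * e2c), W)
      matrix(I[cbind(as.vector(rr), as.vector(cc))], H, W)
    }
    sampP <- lapply(-2:2, gather)
    mP <- Reduce(`+`, sampP) / 5
    vP <- 5 * Reduce(`+`, lapply(sampP, function(s) (s - mP)^2))
    Cp <- gainCoefficient(mP, vP, k, eps)
    sampL <- lapply(-3:3, gather)
    mL <- Reduce(`+`, sampL) / 7
    vL <- Reduce(`+`, lapply(sampL, function(s) (s - mL)^2))
    Cl <- gainCoefficient(mL, vL, k, eps)

    al <- gainTriple(C, Cp, Cl)
    lam1 <- al$alpha1           # along e1 (across structure)
    lam2 <- al$alpha3           # along e2 (in-plane ladder incl. linear term)

    if (it == 1L) {
      bound <- 1 / (2 * 2 * max(max(lam2), max(lam1), 1e-12))
      if (dt > bound)
        stop(sprintf("dt = %g exceeds the stability bound 1/(2*d*maxAlpha) = %g",
                     dt, bound))
    }

    Drr <- lam1 * e1r^2 + lam2 * e2r^2
    Dcc <- lam1 * e1c^2 + lam2 * e2c^2
    Drc <- lam1 * e1r * e1c + lam2 * e2r * e2c

    ## conservative face fluxes; boundary faces carry zero flux
    FcD <- 0.5 * (Dcc[, -W] + Dcc[, -1]) * (I[, -1] - I[, -W]) +
           0.5 * (Drc[, -W] + Drc[, -1]) * 0.5 * (gr[, -W] + gr[, -1])
    FrD <- 0.5 * (Drr[-H, ] + Drr[-1, ]) * (I[-1, ] - I[-H, ]) +
           0.5 * (Drc[-H, ] + Drc[-1, ]) * 0.5 * (gc[-H, ] + gc[-1, ])
    div <- matrix(0, H, W)
    div[, -W] <- div[, -W] + FcD
    div[, -1] <- div[, -1] - FcD
    div[-H, ] <- div[-H, ] + FrD
    div[-1, ] <- div[-1, ] - FrD
    I <- I + dt * div
  }
  if (clip) I <- clip01(I)
  unname(I)
}

#' Percentile contrast stretching
#'
#' Linear map sending the \code{lowPct} percentile to 0 and the
#' \code{highPct} percentile to 1, clipped to [0,1]. A degenerate input
#' (equal percentiles) maps to all zeros.
#'
#' @param image raster.
#' @param lowPct,highPct percentiles in [0,100], \code{lowPct < highPct}.
#' @return stretched raster.
#' @export
contrastStretch <- function(image, lowPct = 1, highPct = 99) {
  image <- asRaster(image)
  if (lowPct < 0 || highPct > 100 || lowPct >= highPct)
    stop("require 0 <= lowPct < highPct <= 100")
  q <- stats::quantile(image, c(lowPct, highPct) / 100, names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(image), ncol(image)))
  clip01((image - q[1]) / (q[2] - q[1]))
}

#' Extract the lung fields by thresholding and convex hulls
#'
#' Thresholds the (contrast-stretched) image with a two-threshold Otsu
#' criterion (the upper split separates the lung-field class from the
#' brighter thorax); the lung fields appear as the dark components enclosed
#' by the bright thorax. Components touching
#' the image border (outside air) are discarded, the two largest remaining
#' components above \code{minFrac} of the image area are kept, and the mask
#' is the union of their convex hulls (the smallest convex polygons around
#' each lung field). The returned region is the image with everything
#' outside the mask set to 0.
#'
#' @param image contrast-stretched raster.
#' @param minFrac minimum component size as a fraction of the image
#'   (default 0.005).
#' @param bridge diameter (px) of the closing brush used to bridge thin
#'   bright structures (rib bands, vessels) that would otherwise split a
#'   lung field into several components; 1 disables bridging.
#' @return list with \code{mask} (logical raster) and \code{region}
#'   (masked raster).
#' @export
## Two-threshold (3-class) Otsu on a 256-bin histogram: maximizes the
## between-class variance over (t1, t2). The upper threshold separates the
## lung-field class from the brighter thorax.
.otsu2 <- function(image, bins = 256L) {
  h <- tabulate(pmin(floor(image * bins) + 1L, bins), nbins = bins)
  p <- h / sum(h)
  mu <- (seq_len(bins) - 0.5) / bins
  P <- cumsum(p); M <- cumsum(p * mu)
  Ptot <- P[bins]; Mtot <- M[bins]
  best <- -1; t1b <- 1L; t2b <- 2L
  for (t1 in 1:(bins - 2L)) {
    w0 <- P[t1]; m0 <- M[t1]
    if (w0 == 0) next
    for (t2 in (t1 + 1L):(bins - 1L)) {
      w1 <- P[t2] - w0; w2 <- Ptot - P[t2]
      if (w1 == 0 || w2 == 0) next
      m1 <- M[t2] - m0; m2 <- Mtot - M[t2]
      v <- m0^2 / w0 + m1^2 / w1 + m2^2 / w2
      if (v > best) { best <- v; t1b <- t1; t2b <- t2 }
    }
  }
  c(lower = t1b / bins, upper = t2b / bins)
}

## Three-threshold (4-class) Otsu; returns the thresholds sorted ascending.
## Used as a fallback when bright lesions add a fourth intensity class.
.otsu3 <- function(image, bins = 128L) {
  h <- tabulate(pmin(floor(image * bins) + 1L, bins), nbins = bins)
  p <- h / sum(h)
  mu <- (seq_len(bins) - 0.5) / bins
  P <- c(0, cumsum(p)); M <- c(0, cumsum(p * mu))
  term <- function(a, b) {   # between-class term for bins (a, b]
    w <- P[b + 1L] - P[a + 1L]
    m <- M[b + 1L] - M[a + 1L]
    ifelse(w > 0, m^2 / w, 0)
  }
  best <- -1; tb <- c(1L, 2L, 3L)
  for (t1 in 1:(bins - 3L)) {
    v1 <- term(0L, t1)
    for (t2 in (t1 + 1L):(bins - 2L)) {
      t3 <- (t2 + 1L):(bins - 1L)
      v <- v1 + term(t1, t2) + term(t2, t3) + term(t3, bins)
      j <- which.max(v)
      if (v[j] > best) { best <- v[j]; tb <- c(t1, t2, t3[j]) }
    }
  }
  tb / bins
}

extractLungRegion <- function(image, minFrac = 0.005, bridge = 7L) {
  image <- asRaster(image)
  thr <- .otsu2(image)
  ## the upper split usually separates lung field from thorax; when large
  ## bright lesions grab the top class a 4-class split is needed, tried
  ## middle threshold first
  for (t in c(thr["upper"], thr["lower"])) {
    found <- .lungComponents(image, t, minFrac, bridge)
    if (!is.null(found)) return(found)
  }
  t3 <- .otsu3(image)
  for (t in t3[c(2L, 1L, 3L)]) {
    found <- .lungComponents(image, t, minFrac, bridge)
    if (!is.null(found)) return(found)
  }
  stop("no lung field found")
}

.lungComponents <- function(image, thr, minFrac, bridge) {
  dark <- image <= thr
  ## despeckle (small opening) so isolated dark noise pixels cannot chain
  ## into bridges, then close thin bright structures (ribs, vessels)
  ## crossing the lung field so one lung stays one component; sizes and
  ## hulls use the original pixels
  core <- dark
  if (bridge > 1L) {
    b3 <- EBImage::makeBrush(3, "box")
    core <- EBImage::imageData(EBImage::dilate(
      EBImage::erode(EBImage::Image(dark * 1), b3), b3)) > 0.5
    br <- EBImage::makeBrush(bridge, "disc")
    core <- EBImage::imageData(EBImage::erode(
      EBImage::dilate(EBImage::Image(core * 1), br), br)) > 0.5 | core
  }
  lab <- EBImage::imageData(EBImage::bwlabel(core))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0] * dark[lab > 0])
  keep <- setdiff(which(sizes >= minFrac * length(image)), border)
  if (length(keep) == 0L) return(NULL)
  keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(min(2L, length(keep)))]
  mask <- matrix(FALSE, nrow(image), ncol(image))
  for (kk in keep) mask <- mask | convexHullMask(lab == kk & dark)
  list(mask = mask, region = image * mask)
}

#' Unsharp-mask edge enhancement
#'
#' Adds back a scaled high-pass component: \code{A = region -
#' gaussianBlur(region, sigma)} and \code{E = region + eta * A}, clipped to
#' [0,1].
#'
#' @param region raster (typically the masked lung region).
#' @param eta gain factor >= 0 controlling the potency of the enhancement.
#' @param sigma standard deviation of the Gaussian boundary-mining kernel.
#' @return enhanced raster.
#' @export
unsharpEnhance <- function(region, eta = 1, sigma = 1.5) {
  region <- asRaster(region)
  if (eta < 0) stop("eta must be >= 0")
  if (eta == 0) return(region)
  blur <- EBImage::imageData(EBImage::gblur(EBImage::Image(region), sigma))
  clip01(region + eta * (region - blur))
}

#' Default preprocessing configuration
#' @return nested list of stage parameters.
#' @export
preprocessConfig <- function() {
  list(iadf = list(iterations = 10L, dt = 0.01, k = 1.0, eps = 1e-8),
       stretch = list(lowPct = 1, highPct = 99),
       unsharp = list(eta = 1, sigma = 1.5))
}

#' Run the full preprocessing chain
#'
#' Denoise, contrast-stretch, extract the lung fields, and edge-enhance.
#' Deterministic: identical inputs give identical outputs.
#'
#' @param image raw raster in [0,1].
#' @param config nested list as produced by [preprocessConfig()].
#' @return list with \code{denoised}, \code{stretched}, \code{mask},
#'   \code{region}, \code{enhanced}.
#' @export
preprocessImage <- function(image, config = preprocessConfig()) {
  den <- iadfDenoise(image, iterations = config$iadf$iterations,
                     dt = config$iadf$dt, k = config$iadf$k,
                     eps = config$iadf$eps)
  st <- contrastStretch(den, config$stretch$lowPct, config$stretch$highPct)
  lr <- extractLungRegion(st)
  enh <- unsharpEnhance(lr$region, config$unsharp$eta, config$unsharp$sigma)
  list(denoised = den, stretched = st, mask = lr$mask, region = lr$region,
       enhanced = enh)
}
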