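## Engineered features per segmented sub-image: gradient-histogram block,
## spectral flatness, profile block, on-rib block, on-vessel block, plus the
## nodule-candidate peak intensity. Concatenated over the four quadrants in
## fixed order; every degenerate case maps to a finite value.

#' Default feature-extraction configuration
#' @return list of tunables: histogram bins, number of vertical profiles,
#'   profile smoothing window, Canny sigma and strong-edge quantile (0.97:
#'   on unsharp-enhanced images the 0.90 default of [cannyEdges()] sits
#'   inside the amplified-noise gradient population and strings spurious
#'   edges between distinct structures), minimum rib chain length and
#'   maximum rib slope, vessel distance floor, nodule-candidate quantile.
#' @export
featureConfig <- function() {
  list(bins = 64L, nProfiles = 16L, smoothWindow = 5L,
       cannySigma = 1.0, cannyHigh = 0.97, Lrib = 15, sMax = 0.5,
       dFloor = 0.5, noduleQuantile = 0.99)
}

#' Gradient-histogram statistics of a gradient sample
#'
#' Builds a 64-bin histogram of gradient magnitudes (fixed range [0,1]),
#' locates the two tallest histogram modes (local maxima), and returns the
#' mode spacing (bins), the areas under each mode (+/- 2 bins, as fractions
#' of the sample), the sample skewness g1 and excess-free kurtosis b2, the
#' bimodality coefficient (g1^2 + 1)/b2, and the mode height ratio
#' normalized by the spacing. Degenerate samples (empty, constant) return
#' spacing 1 and zeros elsewhere.
#'
#' @param g numeric vector of gradient magnitudes in [0,1].
#' @param bins histogram bins (default 64).
#' @return named numeric vector of 7 features.
#' @export
gradientStats <- function(g, bins = 64L) {
  out <- c(mode_spacing = 1, area_mode1 = 0, area_mode2 = 0, bimodality = 0,
           skewness = 0, kurtosis = 0, mode_ratio_norm = 0)
  if (length(g) == 0L) return(out)
  bin <- pmin(pmax(floor(g * bins) + 1L, 1L), bins)
  counts <- tabulate(bin, nbins = bins)
  ## local maxima of the histogram (boundary bins allowed)
  padded <- c(-1, counts, -1)
  isMax <- counts > padded[seq_len(bins)] & counts >= padded[seq_len(bins) + 2L] &
           counts > 0
  modes <- which(isMax)
  if (length(modes) == 0L) modes <- which.max(counts)
  modes <- modes[order(counts[modes], decreasing = TRUE)]
  m1 <- modes[1]
  m2 <- if (length(modes) >= 2L) modes[2] else m1
  spacing <- max(abs(m1 - m2), 1)
  area <- function(m) sum(counts[max(1, m - 2):min(bins, m + 2)]) / length(g)
  if (stats::var(g) > 0) {
    g1 <- e1071::skewness(g, type = 1)
    b2 <- e1071::kurtosis(g, type = 1) + 3   # excess-free kurtosis m4/m2^2
    out["skewness"] <- g1
    out["kurtosis"] <- b2
    out["bimodality"] <- (g1^2 + 1) / b2
  }
  out["mode_spacing"] <- spacing
  out["area_mode1"] <- area(m1)
  out["area_mode2"] <- area(m2)
  h2 <- counts[m2]
  out["mode_ratio_norm"] <- if (h2 > 0) (counts[m1] / h2) / spacing else 0
  out
}

#' Gradient block of a sub-image
#'
#' Sobel gradient magnitudes over the mask pixels, summarized by
#' [gradientStats()].
#'
#' @param subImage raster.
#' @param mask logical raster, same shape.
#' @param bins histogram bins.
#' @return named numeric vector of 7 features.
#' @export
gradientFeatures <- function(subImage, mask, bins = 64L) {
  subImage <- asRaster(subImage)
  gradientStats(sobelMagnitude(subImage)[mask], bins)
}

#' Spectral flatness of a masked sub-image
#'
#' Geometric over arithmetic mean of the non-DC Fourier magnitude
#' coefficients of the zero-mean masked crop: 1 for a flat spectrum (an
#' impulse), approaching 0 for tonal or concentrated spectra; an all-zero
#' spectrum returns 0 by contract.
#'
#' @param subImage raster.
#' @param mask logical raster, same shape (bounding box at least 8x8 after
#'   padding within the sub-image).
#' @return value in [0,1].
#' @export
spectralFlatness <- function(subImage, mask) {
  subImage <- asRaster(subImage)
  if (!any(mask)) return(0)
  idx <- which(mask, arr.ind = TRUE)
  r <- range(idx[, 1]); c <- range(idx[, 2])
  ## pad the bounding box within the image so the crop is at least 8x8
  while (r[2] - r[1] < 7 && (r[1] > 1 || r[2] < nrow(subImage))) {
    r[1] <- max(1, r[1] - 1); r[2] <- min(nrow(subImage), r[2] + 1)
  }
  while (c[2] - c[1] < 7 && (c[1] > 1 || c[2] < ncol(subImage))) {
    c[1] <- max(1, c[1] - 1); c[2] <- min(ncol(subImage), c[2] + 1)
  }
  crop <- subImage[r[1]:r[2], c[1]:c[2]] * mask[r[1]:r[2], c[1]:c[2]]
  crop <- crop - mean(crop)
  mag <- Mod(stats::fft(crop))
  mag <- mag[-1]                      # drop the DC coefficient
  am <- mean(mag)
  if (am < 1e-300) return(0)
  gm <- exp(mean(log(mag)))           # log(0) = -Inf => gm = 0
  if (!is.finite(gm)) gm <- 0
  gm / am
}

#' Per-profile statistics
#'
#' For one intensity profile (typically a vertical column through an edge
#' image): \code{rib_cross} is 1 when any peak of the smoothed profile
#' exceeds mean + 2 sd of the profile; \code{peak_ratio} is the ratio of
#' the largest to the smallest (positive) peak; \code{slope_ratio} is
#' min(diff)/max(diff) of the raw profile; \code{slope_smoothness} is the
#' mean absolute second difference.
#'
#' @param profile numeric vector (at least 3 samples).
#' @param smoothWindow moving-average window (1 disables smoothing).
#' @return named numeric vector of 4 values.
#' @export
profileStats <- function(profile, smoothWindow = 5L) {
  if (length(profile) < 3L) stop("profile needs at least 3 samples")
  sp <- profile
  if (smoothWindow > 1L) {
    f <- stats::filter(profile, rep(1 / smoothWindow, smoothWindow), sides = 2)
    sp <- ifelse(is.na(f), profile, as.numeric(f))
  }
  n <- length(sp)
  interior <- 2:(n - 1)
  pk <- interior[sp[interior] > sp[interior - 1] & sp[interior] > sp[interior + 1]]
  s <- stats::sd(sp)
  ribCross <- as.numeric(length(pk) > 0 && s > 0 &&
                         any(sp[pk] > mean(sp) + 2 * s))
  pv <- sp[pk]; pv <- pv[pv > 0]
  peakRatio <- if (length(pv)) max(pv) / min(pv) else 1
  d <- diff(profile)
  slopeRatio <- if (max(d) == 0) 0 else min(d) / max(d)
  slopeSmooth <- mean(abs(diff(profile, differences = 2)))
  c(rib_cross = ribCross, peak_ratio = peakRatio,
    slope_ratio = slopeRatio, slope_smoothness = slopeSmooth)
}

#' Profile block of a sub-image
#'
#' Takes \code{nProfiles} equally spaced vertical columns through the mask
#' of the edge image (ribs are roughly horizontal, so vertical profiles
#' cross them) and averages [profileStats()] over them. Profiles with fewer
#' than 3 samples are skipped; an error is raised if all are.
#'
#' @param edgeImage gradient-magnitude raster of the enhanced sub-image.
#' @param mask logical raster.
#' @param nProfiles number of columns (default 16).
#' @param smoothWindow smoothing window for [profileStats()].
#' @return named numeric vector of 4 features.
#' @export
profileFeatures <- function(edgeImage, mask, nProfiles = 16L,
                            smoothWindow = 5L) {
  edgeImage <- asRaster(edgeImage)
  if (!any(mask)) stop("mask is empty; all profiles skipped")
  cols <- which(colSums(mask) > 0)
  take <- unique(round(seq(min(cols), max(cols), length.out = nProfiles)))
  acc <- NULL; nOK <- 0L
  for (cc in take) {
    rows <- which(mask[, cc])
    if (length(rows) < 3L) next
    st <- profileStats(edgeImage[rows, cc], smoothWindow)
    acc <- if (is.null(acc)) st else acc + st
    nOK <- nOK + 1L
  }
  if (nOK == 0L) stop("all profiles skipped (fewer than 3 samples each)")
  acc / nOK
}

#' Canny edge detection
#'
#' Gaussian blur, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and double-threshold hysteresis (weak
#' edges are kept only when 8-connected to a strong edge). Thresholds are
#' data-driven quantiles of the positive gradient magnitudes.
#'
#' @param image raster.
#' @param sigma blur standard deviation.
#' @param highQuantile quantile of positive magnitudes for the strong
#'   threshold (default 0.90); the weak threshold is 0.4 times the strong.
#' @return logical edge raster.
#' @export
cannyEdges <- function(image, sigma = 1.0, highQuantile = 0.90) {
  image <- asRaster(image)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(image), sigma))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gc <- EBImage::imageData(EBImage::filter2(EBImage::Image(sm), kx, boundary = "replicate"))
  gr <- EBImage::imageData(EBImage::filter2(EBImage::Image(sm), t(kx), boundary = "replicate"))
  mag <- sqrt(gr^2 + gc^2)
  pos <- mag[mag > 1e-9]
  if (length(pos) == 0L) return(matrix(FALSE, nrow(image), ncol(image)))
  high <- stats::quantile(pos, highQuantile, names = FALSE)
  low <- 0.4 * high
  ## non-maximum suppression along the quantized gradient direction
  ang <- atan2(gr, gc)                 # direction of the gradient
  sector <- (round(ang / (pi / 4)) %% 4)
  dr <- c(0, 1, 1, 1)[sector + 1]      # 0, 45, 90, 135 degrees
  dc <- c(1, 1, 0, -1)[sector + 1]
  H <- nrow(mag); W <- ncol(mag)
  R <- matrix(seq_len(H), H, W); Cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  nb <- function(sgn) {
    rr <- reflectIndex(R + sgn * dr, H); cc2 <- reflectIndex(Cc + sgn * dc, W)
    matrix(mag[cbind(as.vector(rr), as.vector(cc2))], H, W)
  }
  nms <- mag >= nb(1) & mag >= nb(-1)
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(strong)) return(matrix(FALSE, H, W))
  lab <- label8(weak)
  keep <- unique(lab[strong])
  weak & matrix(lab %in% keep, H, W)
}

#' Detect rib and vessel edge chains
#'
#' Canny edges are grouped into chains (8-connected, with a one-pixel
#' closing so the two contours of a thin structure form one chain). Each
#' chain reports its span along its principal axis (length, px), its
#' least-squares slope (principal-axis slope, capped at |100|), the
#' eccentricity of its second-moment ellipse, and its centroid. Rib
#' candidates are chains with length >= \code{Lrib} and |slope| <=
#' \code{sMax} (long, near-horizontal); all remaining chains are vessel
#' candidates.
#'
#' @param subImage raster.
#' @param kind \code{"rib"} or \code{"vessel"}.
#' @param config see [featureConfig()].
#' @param exclude optional logical raster; edge pixels inside it are
#'   suppressed before chains are built (used to remove the spurious
#'   contour traced by the lung-field mask rim, which is a masking
#'   artifact rather than anatomy and would otherwise merge with the
#'   chains of structures that touch the boundary).
#' @return list of chains; each a list with \code{length}, \code{slope},
#'   \code{eccentricity}, \code{centroid} (row, col), \code{pixels}
#'   (n x 2 matrix). Empty list when nothing is detected.
#' @export
detectEdges <- function(subImage, kind = c("rib", "vessel"),
                        config = featureConfig(), exclude = NULL) {
  kind <- match.arg(kind)
  edges <- cannyEdges(subImage, config$cannySigma,
                      config$cannyHigh %||% 0.90)
  if (!is.null(exclude)) edges <- edges & !exclude
  if (!any(edges)) return(list())
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(edges * 1),
           EBImage::makeBrush(3, "box"))) > 0.5
  lab <- label8(dil)
  chains <- list()
  for (l in sort(unique(lab[edges]))) {
    px <- which(edges & lab == l, arr.ind = TRUE)
    if (nrow(px) < 5L) next
    ctr <- colMeans(px)
    cv <- stats::cov(px)
    ev <- eigen(cv, symmetric = TRUE)
    v <- ev$vectors[, 1]
    span <- diff(range(px %*% v)) + 1
    slope <- if (abs(v[2]) < 1e-6) 100 else max(min(v[1] / v[2], 100), -100)
    l2 <- max(ev$values[2], 0); l1 <- max(ev$values[1], 1e-12)
    ecc <- sqrt(max(1 - l2 / l1, 0))
    chains[[length(chains) + 1L]] <-
      list(length = span, slope = slope, eccentricity = ecc,
           centroid = c(row = ctr[[1]], col = ctr[[2]]), pixels = px)
  }
  isRib <- vapply(chains, function(ch)
    ch$length >= config$Lrib && abs(ch$slope) <= config$sMax, logical(1))
  if (kind == "rib") chains[isRib] else chains[!isRib]
}

#' On-rib block for a lesion centroid
#'
#' \code{d_min} is the minimum distance from the centroid to any rib-chain
#' pixel; \code{inter_rib} is the median distance between consecutive
#' rib-chain centroids (Inf with fewer than two chains); the on-rib flag is
#' 1 iff \code{d_min < inter_rib}. Also reports the nearest chain's length,
#' slope and eccentricity. With no rib chains: d_min = Inf, flag 0, chain
#' attributes 0.
#'
#' @param centroid c(row, col) of the lesion candidate.
#' @param ribChains chains from [detectEdges()] with kind "rib".
#' @return named list: dMin, interRib, flag, length, slope, eccentricity.
#' @export
onRibFeatures <- function(centroid, ribChains) {
  if (length(ribChains) == 0L)
    return(list(dMin = Inf, interRib = Inf, flag = 0,
                length = 0, slope = 0, eccentricity = 0))
  dists <- vapply(ribChains, function(ch)
    min(sqrt((ch$pixels[, 1] - centroid[1])^2 +
             (ch$pixels[, 2] - centroid[2])^2)), numeric(1))
  dMin <- min(dists)
  nearest <- ribChains[[which.min(dists)]]
  interRib <- if (length(ribChains) >= 2L) {
    ctrs <- t(vapply(ribChains, function(ch) ch$centroid, numeric(2)))
    ctrs <- ctrs[order(ctrs[, 1]), , drop = FALSE]
    stats::median(sqrt(rowSums(diff(ctrs)^2)))
  } else Inf
  list(dMin = dMin, interRib = interRib,
       flag = as.numeric(dMin < interRib),
       length = nearest$length, slope = nearest$slope,
       eccentricity = nearest$eccentricity)
}

#' On-vessel block
#'
#' \code{Vessel1} is the product of the two longest vessel-chain lengths
#' over the sub-image area; \code{Vessel2} is the inverse of the minimum
#' distance from any chain to the sub-image center, with the distance
#' floored at \code{dFloor} px (so a chain through the center gives
#' 1/dFloor). No chains: both 0.
#'
#' @param shape c(height, width) of the sub-image.
#' @param vesselChains chains from [detectEdges()] with kind "vessel".
#' @param dFloor distance floor in px (default 0.5).
#' @return named numeric vector c(Vessel1, Vessel2).
#' @export
onVesselFeatures <- function(shape, vesselChains, dFloor = 0.5) {
  if (length(vesselChains) == 0L) return(c(Vessel1 = 0, Vessel2 = 0))
  lens <- sort(vapply(vesselChains, `[[`, numeric(1), "length"),
               decreasing = TRUE)
  v1 <- if (length(lens) >= 2L) lens[1] * lens[2] / (shape[1] * shape[2]) else 0
  center <- (shape + 1) / 2
  dmin <- min(vapply(vesselChains, function(ch)
    min(sqrt((ch$pixels[, 1] - center[1])^2 +
             (ch$pixels[, 2] - center[2])^2)), numeric(1)))
  c(Vessel1 = v1, Vessel2 = 1 / max(dmin, dFloor))
}

#' Locate the nodule-candidate blob in a sub-image
#'
#' The largest connected blob of pixels above the \code{q} quantile of the
#' search-mask intensities. Returns its centroid and peak intensity; when
#' no pixel exceeds the quantile (e.g. a constant sub-image) the centroid
#' falls back to the mask centroid and the peak is 0.
#'
#' @param subImage raster.
#' @param mask logical search mask.
#' @param q quantile (default 0.99).
#' @return list with \code{centroid} (row, col) and \code{peak}.
#' @export
noduleCandidate <- function(subImage, mask, q = 0.99) {
  subImage <- asRaster(subImage)
  idx <- which(mask, arr.ind = TRUE)
  fallback <- if (nrow(idx)) colMeans(idx) else (dim(subImage) + 1) / 2
  if (!nrow(idx)) return(list(centroid = fallback, peak = 0))
  vals <- subImage[mask]
  thr <- stats::quantile(vals, q, names = FALSE)
  ## >= so a saturated top class still qualifies; strictly above the
  ## minimum so a constant sub-image stays degenerate
  cand <- mask & subImage >= thr & subImage > min(vals)
  if (!any(cand)) return(list(centroid = fallback, peak = 0))
  lab <- label8(cand)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  px <- which(lab == big, arr.ind = TRUE)
  list(centroid = colMeans(px), peak = max(subImage[lab == big]))
}

#' Names of the assembled feature vector
#' @return character vector of length 84 (21 features x 4 quadrants).
#' @export
featureNames <- function() {
  block <- c("mode_spacing", "area_mode1", "area_mode2", "bimodality",
             "skewness", "kurtosis", "mode_ratio_norm", "spectral_flatness",
             "rib_cross", "peak_ratio", "slope_ratio", "slope_smoothness",
             "rib_dmin", "inter_rib_dist", "on_rib_flag", "rib_seg_length",
             "rib_seg_slope", "rib_seg_eccentricity",
             "Vessel1", "Vessel2", "nodule_peak")
  as.vector(vapply(paste0("q", 1:4), function(q) paste(q, block, sep = "_"),
                   character(length(block))))
}

#' Extract the full feature vector for a segmented image
#'
#' For each of the four quadrant sub-images (the enhanced image cropped to
#' the quadrant's lung-field bounding box): the gradient and spectral and
#' profile blocks are computed over the grown region mask; edge chains are
#' detected on the whole sub-image and split into rib and vessel
#' candidates; the on-rib block is computed at the nodule-candidate
#' centroid (brightest blob above the 99th percentile of the quadrant's
#' lung field); and the candidate's peak intensity is appended. Infinite
#' degenerate distances are mapped to the sub-image diagonal. The result
#' is a fixed-order, all-finite vector of 4 x 21 = 84 named features.
#'
#' @param seg a [SegmentationResult-class].
#' @param enhanced the enhanced raster E the segmentation was computed on.
#' @param config see [featureConfig()].
#' @param reference optional raster on the original intensity scale
#'   (typically the denoised image) used to read the nodule-candidate peak
#'   intensity; the contrast-stretched enhanced image saturates its top
#'   percentiles, which would erase the rib/nodule intensity contrast the
#'   risk screen thresholds on. Defaults to \code{enhanced}.
#' @return named numeric vector of length 84.
#' @export
extractFeatures <- function(seg, enhanced, config = featureConfig(),
                            reference = enhanced) {
  enhanced <- asRaster(enhanced)
  reference <- asRaster(reference)
  if (!identical(dim(reference), dim(enhanced)))
    stop("reference must match the enhanced image shape")
  quads <- .quadrantMasks(seg@lungMask)
  out <- numeric(0)
  for (q in 1:4) {
    lungQ <- seg@lungMask & quads[[q]]
    regQ <- seg@masks[[q]]
    if (!any(lungQ)) { out <- c(out, .degenerateBlock()); next }
    idx <- which(lungQ, arr.ind = TRUE)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    rr <- c(max(1, rr[1] - 2), min(nrow(enhanced), rr[2] + 2))
    cc <- c(max(1, cc[1] - 2), min(ncol(enhanced), cc[2] + 2))
    ## keep the crop at least 8x8 (thin lung slices near the poles)
    while (diff(rr) < 7 && (rr[1] > 1 || rr[2] < nrow(enhanced))) {
      rr[1] <- max(1, rr[1] - 1); rr[2] <- min(nrow(enhanced), rr[2] + 1)
    }
    while (diff(cc) < 7 && (cc[1] > 1 || cc[2] < ncol(enhanced))) {
      cc[1] <- max(1, cc[1] - 1); cc[2] <- min(ncol(enhanced), cc[2] + 1)
    }
    sub <- enhanced[rr[1]:rr[2], cc[1]:cc[2]]
    maskC <- regQ[rr[1]:rr[2], cc[1]:cc[2]]
    lungC <- lungQ[rr[1]:rr[2], cc[1]:cc[2]]
    diagLen <- sqrt(sum(dim(sub)^2))

    gb <- if (any(maskC)) gradientFeatures(sub, maskC, config$bins)
          else gradientStats(numeric(0), config$bins)
    sf <- spectralFlatness(sub, maskC)
    pb <- tryCatch(profileFeatures(sobelMagnitude(sub), maskC,
                                   config$nProfiles, config$smoothWindow),
                   error = function(e) c(rib_cross = 0, peak_ratio = 0,
                                         slope_ratio = 0, slope_smoothness = 0))
    ## suppress the chain traced by the lung-field rim (masking artifact)
    rim <- lungC & !EBImage::imageData(EBImage::erode(
      EBImage::Image(lungC * 1), EBImage::makeBrush(5, "disc"))) > 0.5
    rim <- rim | !lungC
    ribs <- detectEdges(sub, "rib", config, exclude = rim)
    vessels <- detectEdges(sub, "vessel", config, exclude = rim)
    refC <- reference[rr[1]:rr[2], cc[1]:cc[2]]
    cand <- noduleCandidate(refC, lungC, config$noduleQuantile)
    orib <- onRibFeatures(cand$centroid, ribs)
    fin <- function(x) if (is.finite(x)) x else diagLen
    ov <- onVesselFeatures(dim(sub), vessels, config$dFloor)
    out <- c(out, gb, spectral_flatness = sf, pb,
             rib_dmin = fin(orib$dMin), inter_rib_dist = fin(orib$interRib),
             on_rib_flag = orib$flag, rib_seg_length = orib$length,
             rib_seg_slope = orib$slope,
             rib_seg_eccentricity = orib$eccentricity,
             ov, nodule_peak = cand$peak)
  }
  stats::setNames(out, featureNames())
}

.degenerateBlock <- function() {
  c(gradientStats(numeric(0)), spectral_flatness = 0,
    rib_cross = 0, peak_ratio = 0, slope_ratio = 0, slope_smoothness = 0,
    rib_dmin = 0, inter_rib_dist = 0, on_rib_flag = 0, rib_seg_length = 0,
    rib_seg_slope = 0, rib_seg_eccentricity = 0,
    Vessel1 = 0, Vessel2 = 0, nodule_peak = 0)
}
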