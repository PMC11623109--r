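#' Create an augmentation specification
#'
#' Defaults are mild, label-preserving perturbations: rotation within +/-25
#' degrees, independent horizontal/vertical flips with probability 0.5,
#' isotropic scaling in `[0.9, 1.1]` and a 0.9-fraction crop window resized
#' back to the full frame.
#'
#' @param rotationDegrees rotation interval in degrees.
#' @param flipHorizontal,flipVertical flip probabilities.
#' @param scaleFactor isotropic scale interval.
#' @param cropFraction crop-window side as a fraction of the frame, in (0,1].
#' @param seed transform seed.
#' @return a validated [AugmentSpec-class].
#' @export
augmentSpec <- function(rotationDegrees = c(-25, 25),
                        flipHorizontal = 0.5, flipVertical = 0.5,
                        scaleFactor = c(0.9, 1.1), cropFraction = 0.9,
                        seed = 1L) {
  new("AugmentSpec", rotationDegrees = as.numeric(rotationDegrees),
      flipHorizontal = as.numeric(flipHorizontal),
      flipVertical = as.numeric(flipVertical),
      scaleFactor = as.numeric(scaleFactor),
      cropFraction = as.numeric(cropFraction), seed = asInt(seed))
}

# Resample `m` under the affine map taking output pixel coordinates to input
# coordinates: p_in = center + R(-theta)/scale * flip * (p_out*cropf +
# cropOffset - center). Bilinear or nearest-neighbour gather; out-of-frame
# samples are 0.
resampleAffine <- function(m, angle = 0, scale = 1, flipH = FALSE,
                           flipV = FALSE, cropFraction = 1, cropCx = NULL,
                           cropCy = NULL, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- rep(seq_len(W), each = H) - cx
  ys <- rep(seq_len(H), W) - cy
  # crop window: output spans a window of side fraction*dim centred at
  # (cropCx, cropCy) in input coordinates
  if (is.null(cropCx)) cropCx <- cx
  if (is.null(cropCy)) cropCy <- cy
  xs <- xs * cropFraction + (cropCx - cx)
  ys <- ys * cropFraction + (cropCy - cy)
  if (flipH) xs <- -xs
  if (flipV) ys <- -ys
  th <- -angle * pi / 180
  xr <- (cos(th) * xs - sin(th) * ys) / scale
  yr <- (sin(th) * xs + cos(th) * ys) / scale
  px <- xr + cx; py <- yr + cy
  if (method == "nearest") {
    ix <- round(px); iy <- round(py)
    ok <- ix >= 1 & ix <= W & iy >= 1 & iy <= H
    out <- numeric(H * W)
    out[ok] <- m[cbind(iy[ok], ix[ok])]
  } else {
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    out <- numeric(H * W)
    gather <- function(iy, ix) {
      ok <- ix >= 1 & ix <= W & iy >= 1 & iy <= H
      v <- numeric(length(ix))
      v[ok] <- m[cbind(iy[ok], ix[ok])]
      v
    }
    out <- gather(y0, x0) * (1 - fx) * (1 - fy) +
      gather(y0, x0 + 1) * fx * (1 - fy) +
      gather(y0 + 1, x0) * (1 - fx) * fy +
      gather(y0 + 1, x0 + 1) * fx * fy
  }
  matrix(out, H, W)
}

drawTransform <- function(spec, H, W) {
  angle <- runif(1, spec@rotationDegrees[1], spec@rotationDegrees[2])
  scale <- runif(1, spec@scaleFactor[1], spec@scaleFactor[2])
  flipH <- runif(1) < spec@flipHorizontal
  flipV <- runif(1) < spec@flipVertical
  cf <- spec@cropFraction
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  if (cf < 1) {
    mx <- W * (1 - cf) / 2; my <- H * (1 - cf) / 2
    cx <- runif(1, cx - mx, cx + mx)
    cy <- runif(1, cy - my, cy + my)
  }
  list(angle = angle, scale = scale, flipH = flipH, flipV = flipV,
       cropFraction = cf, cropCx = cx, cropCy = cy)
}

#' Apply one random geometric transform to an image/mask pair
#'
#' The same rotation, flips, scaling and crop are applied to both: the image
#' is interpolated bilinearly, the mask by nearest neighbour so it stays
#' exactly binary. Output dims equal input dims. Deterministic given the
#' seed.
#'
#' @param image grayscale matrix.
#' @param mask binary matrix of the same dims.
#' @param spec an [AugmentSpec-class].
#' @param seed optional override of `spec`'s seed (used by the training loop
#'   to vary transforms across epochs deterministically).
#' @return list with transformed `image` and `mask`.
#' @export
augmentPair <- function(image, mask, spec, seed = spec@seed) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dims do not match")
  tr <- withSeed(seed, drawTransform(spec, nrow(image), ncol(image)))
  img <- resampleAffine(image, tr$angle, tr$scale, tr$flipH, tr$flipV,
                        tr$cropFraction, tr$cropCx, tr$cropCy, "bilinear")
  msk <- resampleAffine(mask, tr$angle, tr$scale, tr$flipH, tr$flipV,
                        tr$cropFraction, tr$cropCx, tr$cropCy, "nearest")
  list(image = img, mask = msk)
}
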