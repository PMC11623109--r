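# Parametric B-mode breast phantom: smooth echogenicity background times
# multiplicative gamma speckle, hypoechoic star-convex lesions, bright
# punctate calcifications and optional posterior shadowing. Everything is a
# pure function of (params, seed).

#' Create phantom simulation parameters
#'
#' Class-label defaults encode the usual sonographic picture: benign masses
#' have smooth, near-elliptical margins (low boundary irregularity), while
#' malignant masses are spiculated/irregular (higher irregularity); normal
#' frames contain no lesion.
#'
#' @param height,width frame size in pixels.
#' @param classLabel `"normal"`, `"benign"` or `"malignant"`.
#' @param lesionCountRange integer interval; forced to `c(0,0)` for normal.
#' @param lesionRadiusRange semi-axis interval in pixels; default scales with
#'   the frame (8-16 % of the short side).
#' @param boundaryIrregularity radial perturbation amplitude as a fraction of
#'   the radius; defaults 0.08 (benign) / 0.25 (malignant).
#' @param lesionContrast fractional intensity drop inside the lesion.
#' @param speckleShape gamma shape of the multiplicative speckle (mean 1,
#'   variance `1/shape`).
#' @param calcificationCountRange integer interval of bright deposits.
#' @param shadowProbability per-lesion probability of a posterior shadow.
#' @param seed integer seed.
#' @return a validated [PhantomParams-class].
#' @examples
#' phantomParams(64, 64, "malignant", seed = 3)
#' @export
phantomParams <- function(height = 256L, width = 256L,
                          classLabel = c("benign", "malignant", "normal"),
                          lesionCountRange = NULL,
                          lesionRadiusRange = NULL,
                          boundaryIrregularity = NULL,
                          lesionContrast = 0.5,
                          speckleShape = 4,
                          calcificationCountRange = c(0L, 3L),
                          shadowProbability = 0.3,
                          seed = 1L) {
  classLabel <- match.arg(classLabel)
  if (is.null(lesionCountRange))
    lesionCountRange <- if (classLabel == "normal") c(0L, 0L) else c(1L, 2L)
  if (classLabel == "normal") lesionCountRange <- c(0L, 0L)
  if (is.null(lesionRadiusRange)) {
    m <- min(height, width)
    lesionRadiusRange <- c(0.08, 0.16) * m
  }
  if (is.null(boundaryIrregularity))
    boundaryIrregularity <- switch(classLabel, malignant = 0.25, benign = 0.08,
                                   normal = 0)
  new("PhantomParams",
      height = asInt(height), width = asInt(width),
      lesionCountRange = asInt(lesionCountRange),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      boundaryIrregularity = as.numeric(boundaryIrregularity),
      lesionContrast = as.numeric(lesionContrast),
      speckleShape = as.numeric(speckleShape),
      calcificationCountRange = asInt(calcificationCountRange),
      shadowProbability = as.numeric(shadowProbability),
      classLabel = classLabel, seed = asInt(seed))
}

# one star-convex blob: an ellipse whose radius is modulated by a few random
# sinusoidal harmonics of total amplitude `irr` (fraction of the radius)
drawBlob <- function(H, W, cx, cy, a, b, phi, irr) {
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H), W), H, W) - cy
  xr <- cos(phi) * xs + sin(phi) * ys
  yr <- -sin(phi) * xs + cos(phi) * ys
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  if (irr > 0) {
    theta <- atan2(yr / b, xr / a)
    ks <- sample(2:6, 3)
    amps <- runif(3); amps <- amps / sum(amps) * irr
    phis <- runif(3, 0, 2 * pi)
    mod <- 1 + amps[1] * sin(ks[1] * theta + phis[1]) +
      amps[2] * sin(ks[2] * theta + phis[2]) +
      amps[3] * sin(ks[3] * theta + phis[3])
  } else mod <- 1
  (rho <= mod) * 1
}

#' Generate a ground-truth lesion mask
#'
#' Draws `lesionCountRange` star-convex blobs (ellipses with sinusoidal
#' radial perturbation of amplitude `boundaryIrregularity`), all fully
#' inside the frame. Deterministic given the params' seed.
#'
#' @param params a [PhantomParams-class].
#' @return binary `height x width` matrix.
#' @export
generateLesionMask <- function(params) {
  validObject(params)
  H <- params@height; W <- params@width
  rmax <- max(params@lesionRadiusRange) * (1 + params@boundaryIrregularity)
  if (rmax > min(H, W) / 2)
    stop(sprintf("lesion radius range (max effective %.1f px) exceeds half the frame", rmax))
  withSeed(childSeed(params@seed, 1L), {
    n <- sampleRange(params@lesionCountRange[1], params@lesionCountRange[2])
    mask <- matrix(0, H, W)
    if (n > 0) {
      margin <- rmax + 2
      for (i in seq_len(n)) {
        a <- runif(1, params@lesionRadiusRange[1], params@lesionRadiusRange[2])
        b <- runif(1, params@lesionRadiusRange[1], params@lesionRadiusRange[2])
        cx <- runif(1, margin, W - margin)
        cy <- runif(1, margin, H - margin)
        phi <- runif(1, 0, pi)
        mask <- pmax(mask, drawBlob(H, W, cx, cy, a, b, phi,
                                    params@boundaryIrregularity))
      }
    }
    mask
  })
}

#' Render a speckled B-mode image for a lesion mask
#'
#' A smooth echogenicity background (mild depth attenuation plus a
#' low-frequency field) is multiplied by gamma-distributed speckle of shape
#' `speckleShape`; the mean intensity inside the lesion is reduced by the
#' factor `1 - lesionContrast` (hypoechoic), calcifications are drawn as
#' bright discs of radius <= 3 px, and each lesion may cast a posterior
#' shadow column. Output is clipped to `[0,1]`.
#'
#' @param mask binary lesion mask matching the params' dims.
#' @param params a [PhantomParams-class].
#' @return grayscale matrix in `[0,1]`.
#' @export
renderUltrasound <- function(mask, params) {
  H <- params@height; W <- params@width
  if (!identical(dim(mask), c(H, W)))
    stop("mask dims do not match params")
  withSeed(childSeed(params@seed, 2L), {
    depth <- matrix(rep(seq_len(H) / H, W), H, W)
    field <- gaussBlur(matrix(rnorm(H * W), H, W), min(H, W) / 16)
    field <- field / max(1e-9, max(abs(field))) * 0.08
    base <- 0.55 - 0.12 * depth + field
    # soften the lesion boundary slightly before applying the contrast drop
    soft <- if (any(mask > 0)) gaussBlur(mask, 1.2) else mask
    soft <- pmin(soft, 1)
    echo <- base * (1 - params@lesionContrast * soft)
    # calcifications: small bright deposits, inside lesions when present
    nc <- sampleRange(params@calcificationCountRange[1],
                      params@calcificationCountRange[2])
    if (nc > 0) {
      inside <- which(mask == 1)
      for (i in seq_len(nc)) {
        if (length(inside) > 0) {
          p <- inside[sample(length(inside), 1L)]
          cy <- (p - 1) %% H + 1; cx <- (p - 1) %/% H + 1
        } else {
          cy <- sample(4:(H - 3), 1L); cx <- sample(4:(W - 3), 1L)
        }
        r <- sample(1:3, 1L)
        ys <- pmax(1, cy - r):pmin(H, cy + r)
        xs <- pmax(1, cx - r):pmin(W, cx + r)
        for (x in xs) for (y in ys)
          if ((x - cx)^2 + (y - cy)^2 <= r^2) echo[y, x] <- 0.95
      }
    }
    # posterior shadowing: darken the column below a lesion
    if (any(mask > 0) && params@shadowProbability > 0) {
      cols <- which(colSums(mask) > 0)
      if (length(cols) && runif(1) < params@shadowProbability) {
        for (x in cols) {
          bottom <- max(which(mask[, x] == 1))
          if (bottom < H) {
            rows <- (bottom + 1):H
            fade <- 0.45 + 0.25 * (rows - bottom) / H
            echo[rows, x] <- echo[rows, x] * fade
          }
        }
      }
    }
    speckle <- matrix(rgamma(H * W, shape = params@speckleShape,
                             rate = params@speckleShape), H, W)
    clamp01(echo * speckle)
  })
}

#' Generate one phantom sample
#'
#' @param params a [PhantomParams-class].
#' @return an [UltrasoundSample-class] (image, pixel-aligned mask, label).
#' @export
generatePhantom <- function(params) {
  mask <- generateLesionMask(params)
  img <- renderUltrasound(mask, params)
  new("UltrasoundSample", image = img, mask = mask,
      label = params@classLabel, seed = params@seed)
}

# per-class variant of a template params object
classParams <- function(base, label, seed) {
  phantomParams(height = base@height, width = base@width, classLabel = label,
                lesionRadiusRange = base@lesionRadiusRange,
                lesionContrast = base@lesionContrast,
                speckleShape = base@speckleShape,
                calcificationCountRange =
                  if (label == "normal") c(0L, 0L) else base@calcificationCountRange,
                shadowProbability = base@shadowProbability,
                seed = seed)
}

#' Generate and write a BUSI-style phantom dataset
#'
#' Writes `<class> (k).png` / `<class> (k)_mask.png` pairs (8-bit grayscale;
#' masks use {0, 255}); normal-class images get an all-zero mask file so the
#' reader contract is uniform. Byte-identical across runs for a fixed seed.
#'
#' @param nPerClass named or positional counts for (benign, malignant,
#'   normal); a single number is recycled.
#' @param params template [PhantomParams-class]; class label and seed are
#'   overridden per sample.
#' @param outDir destination directory (created if missing).
#' @param seed base seed; sample k of class c uses a derived child seed.
#' @return a [DatasetIndex-class] over the written tree.
#' @export
generateDataset <- function(nPerClass, params = phantomParams(),
                            outDir, seed = params@seed) {
  classes <- c("benign", "malignant", "normal")
  if (length(nPerClass) == 1L) nPerClass <- rep(nPerClass, 3L)
  if (is.null(names(nPerClass))) names(nPerClass) <- classes
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop(sprintf("cannot create output dir '%s'", outDir))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    n <- nPerClass[[cl]]
    if (is.null(n) || n == 0) next
    for (k in seq_len(n)) {
      p <- classParams(params, cl, childSeed(seed, ci, k))
      s <- generatePhantom(p)
      img8 <- round(s@image * 255) / 255
      png::writePNG(img8, file.path(outDir, sprintf("%s (%d).png", cl, k)))
      png::writePNG(s@mask, file.path(outDir, sprintf("%s (%d)_mask.png", cl, k)))
    }
  }
  indexDataset(outDir)
}

setMethod("show", "PhantomParams", function(object) {
  cat(sprintf("PhantomParams: %d x %d '%s' frame\n", object@height,
              object@width, object@classLabel))
  cat(sprintf("  lesions %d-%d, radius %.1f-%.1f px, irregularity %.2f, contrast %.2f\n",
              object@lesionCountRange[1], object@lesionCountRange[2],
              object@lesionRadiusRange[1], object@lesionRadiusRange[2],
              object@boundaryIrregularity, object@lesionContrast))
  cat(sprintf("  speckle shape %.1f, calcifications %d-%d, shadow p=%.2f, seed %d\n",
              object@speckleShape, object@calcificationCountRange[1],
              object@calcificationCountRange[2], object@shadowProbability,
              object@seed))
})

setMethod("show", "UltrasoundSample", function(object) {
  cat(sprintf("UltrasoundSample: %d x %d '%s', %d mask px (%.1f%%)\n",
              nrow(object@image), ncol(object@image), object@label,
              sum(object@mask), 100 * mean(object@mask)))
})
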