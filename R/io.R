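#' Index a BUSI-style PNG directory
#'
#' Pairs each `<stem>.png` with every `<stem>_mask*.png`; images with no
#' mask file are kept with an explicit empty-mask marker (and a warning).
#' The class label is parsed from the leading word of the file name.
#'
#' @param root dataset directory.
#' @return a [DatasetIndex-class].
#' @export
indexDataset <- function(root) {
  if (!dir.exists(root)) stop(sprintf("dataset root '%s' does not exist", root))
  all <- list.files(root, pattern = "\\.png$", ignore.case = TRUE)
  isMask <- grepl("_mask", all)
  imgs <- sort(all[!isMask])
  masks <- all[isMask]
  stems <- sub("\\.png$", "", imgs, ignore.case = TRUE)
  maskPaths <- vector("list", length(imgs))
  used <- character()
  for (i in seq_along(imgs)) {
    pat <- paste0(stems[i], "_mask")
    mine <- masks[startsWith(masks, pat)]
    maskPaths[[i]] <- file.path(root, sort(mine))
    used <- c(used, mine)
    if (length(mine) == 0)
      warning(sprintf("image '%s' has no mask file; using an empty mask", imgs[i]))
  }
  orphan <- setdiff(masks, used)
  if (length(orphan))
    warning(sprintf("unmatched mask files: %s", paste(orphan, collapse = ", ")))
  label <- tolower(sub("^([A-Za-z]+).*", "\\1", imgs))
  label[!label %in% c("normal", "benign", "malignant")] <- "benign"
  rec <- data.frame(image = file.path(root, imgs), label = label,
                    nMasks = lengths(maskPaths), stringsAsFactors = FALSE)
  new("DatasetIndex", root = root, records = rec, maskPaths = maskPaths)
}

readGrayPNG <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop(sprintf("cannot read PNG '%s': %s", path, conditionMessage(e))))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  img
}

resizeImage <- function(m, targetH, targetW, method = "bilinear") {
  if (nrow(m) == targetH && ncol(m) == targetW) return(m)
  # affine resample on the target grid: output pixel centres map linearly
  # onto the source grid
  H <- nrow(m); W <- ncol(m)
  px <- (seq_len(targetW) - 0.5) * W / targetW + 0.5
  py <- (seq_len(targetH) - 0.5) * H / targetH + 0.5
  px <- pmin(pmax(px, 1), W); py <- pmin(pmax(py, 1), H)
  if (method == "nearest") {
    m[round(py), round(px), drop = FALSE]
  } else {
    x0 <- pmin(floor(px), W - 1); y0 <- pmin(floor(py), H - 1)
    fx <- px - x0; fy <- py - y0
    a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1, drop = FALSE]
    c_ <- m[y0 + 1, x0, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
    FY <- matrix(fy, targetH, targetW); FX <- matrix(fx, targetH, targetW,
                                                     byrow = TRUE)
    a * (1 - FX) * (1 - FY) + b * FX * (1 - FY) + c_ * (1 - FX) * FY +
      d * FX * FY
  }
}

#' Load one indexed sample
#'
#' Reads the image as grayscale in `[0,1]` (luminance conversion for RGB),
#' resizes it bilinearly to the target, thresholds each 8-bit mask at > 127,
#' combines multiple masks by union, and resizes the mask by nearest
#' neighbour so it stays binary.
#'
#' @param index a [DatasetIndex-class].
#' @param i record number.
#' @param targetSize output side length in pixels (`c(h, w)` or a scalar);
#'   `NULL` keeps the source size.
#' @return an [UltrasoundSample-class].
#' @export
loadSample <- function(index, i, targetSize = NULL) {
  rec <- index@records[i, ]
  img <- readGrayPNG(rec$image)
  masks <- index@maskPaths[[i]]
  if (length(masks) == 0) {
    mask <- matrix(0, nrow(img), ncol(img))
  } else {
    mask <- matrix(0, nrow(img), ncol(img))
    for (mp in masks) {
      mm <- readGrayPNG(mp)
      mask <- pmax(mask, (mm > 127 / 255) * 1)
    }
  }
  if (!is.null(targetSize)) {
    if (length(targetSize) == 1L) targetSize <- c(targetSize, targetSize)
    img <- resizeImage(img, targetSize[1], targetSize[2], "bilinear")
    mask <- resizeImage(mask, targetSize[1], targetSize[2], "nearest")
  }
  new("UltrasoundSample", image = clamp01(img), mask = mask,
      label = rec$label, seed = NA_integer_)
}

#' Load every indexed sample
#'
#' @param index a [DatasetIndex-class].
#' @param targetSize passed to [loadSample()].
#' @return list of [UltrasoundSample-class].
#' @export
loadSamples <- function(index, targetSize = NULL) {
  lapply(seq_len(nrow(index@records)), function(i)
    loadSample(index, i, targetSize))
}

# reflective padding to targetH x targetW (centre placement)
padReflect <- function(m, targetH, targetW) {
  H <- nrow(m); W <- ncol(m)
  if (H == targetH && W == targetW) return(m)
  top <- (targetH - H) %/% 2L
  left <- (targetW - W) %/% 2L
  reflIdx <- function(n, pre, post) {
    idx <- c(rev(seq_len(pre) + 1L), seq_len(n), n - seq_len(post))
    pmin(pmax(idx, 1L), n)
  }
  m[reflIdx(H, top, targetH - H - top), reflIdx(W, left, targetW - W - left),
    drop = FALSE]
}

cropCenter <- function(m, H, W) {
  top <- (nrow(m) - H) %/% 2L
  left <- (ncol(m) - W) %/% 2L
  m[top + seq_len(H), left + seq_len(W), drop = FALSE]
}

#' Train/evaluate one model per image resolution
#'
#' Resamples the same dataset to each requested size, trains a model per
#' size on an identical train/eval split, and reports the evaluation metrics
#' per size. Sizes not divisible by 16 are padded reflectively to the next
#' multiple of 16 for the network (500 pads to 512) and the predictions are
#' cropped back before scoring.
#'
#' @param samples list of [UltrasoundSample-class] at their native size.
#' @param sizes integer vector of side lengths.
#' @param hp a [Hyperparams-class].
#' @param filterSchedule filter schedule for the per-size models.
#' @param trainFraction train split fraction (default 0.85).
#' @return data.frame with one row per size: `size`, `f1`, `dice`,
#'   `precision`, `recall`.
#' @export
resolutionHarness <- function(samples, sizes, hp,
                              filterSchedule = c(8L, 16L, 32L, 64L, 128L),
                              trainFraction = 0.85) {
  labels <- vapply(samples, function(s) s@label, character(1))
  sp <- splitDataset(length(samples), trainFraction, seed = hp@seed,
                     labels = labels)
  rows <- lapply(sizes, function(size) {
    eff <- 16L * as.integer(ceiling(size / 16))
    resized <- lapply(samples, function(s) {
      img <- resizeImage(s@image, size, size, "bilinear")
      msk <- resizeImage(s@mask, size, size, "nearest")
      if (eff != size) {
        img <- padReflect(img, eff, eff)
        msk <- padReflect(msk, eff, eff)
      }
      new("UltrasoundSample", image = img, mask = msk, label = s@label,
          seed = s@seed)
    })
    cfg <- modelConfig(eff, eff, filterSchedule = filterSchedule,
                       seed = hp@seed)
    graph <- assembleModel(cfg)
    trainIdx <- sp$train
    nVal <- max(1L, floor(0.1 * length(trainIdx)))
    valIdx <- withSeed(childSeed(hp@seed, 7L, size), sample(trainIdx, nVal))
    fit <- fitModel(graph, resized[setdiff(trainIdx, valIdx)],
                    resized[valIdx], hp)
    # score on the unpadded frame: crop predictions back to size x size
    tp <- fp <- fn <- 0
    for (i in sp$eval) {
      p <- segmentImage(resized[[i]]@image, graph, fit$weights)
      pred <- binarizeProbs(cropCenter(p, size, size))
      truth <- cropCenter(resized[[i]]@mask, size, size)
      tp <- tp + sum(pred == 1 & truth == 1)
      fp <- fp + sum(pred == 1 & truth == 0)
      fn <- fn + sum(pred == 0 & truth == 1)
    }
    f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    pre <- if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp)
    rec <- if (tp + fn == 0) 1 else tp / (tp + fn)
    data.frame(size = size, f1 = f1, dice = f1, precision = pre, recall = rec)
  })
  do.call(rbind, rows)
}

#' @describeIn datasetIndex-accessors the records data.frame.
#' @export
setMethod("sampleRecords", "DatasetIndex", function(object) object@records)

setMethod("show", "DatasetIndex", function(object) {
  tab <- table(object@records$label)
  cat(sprintf("DatasetIndex: %d samples under '%s' (%s)\n",
              nrow(object@records), object@root,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})
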