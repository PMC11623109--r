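#' Create training hyperparameters
#'
#' Defaults follow the common recipe for this architecture family: Adam at
#' learning rate 0.001, batch size 8, 100 epochs, reduce-on-plateau with
#' patience 5, factor 0.5 and floor 1e-5.
#'
#' @param learningRate initial Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param plateauPatience epochs without validation-loss improvement before
#'   a reduction.
#' @param plateauFactor multiplicative learning-rate factor in (0,1).
#' @param minLr learning-rate floor.
#' @param seed seed for shuffling/augmentation/initialisation.
#' @return a validated [Hyperparams-class].
#' @export
hyperparams <- function(learningRate = 0.001, batchSize = 8L, epochs = 100L,
                        plateauPatience = 5L, plateauFactor = 0.5,
                        minLr = 1e-5, seed = 1L) {
  new("Hyperparams", learningRate = learningRate, batchSize = asInt(batchSize),
      epochs = asInt(epochs), plateauPatience = asInt(plateauPatience),
      plateauFactor = plateauFactor, minLr = minLr, seed = asInt(seed))
}

#' Split sample indices into train and evaluation sets
#'
#' Training set size is `floor(trainFraction * n)`; the split is a shuffled
#' partition, stratified by class when labels are supplied (per-class floors
#' topped up by largest remainders).
#'
#' @param n number of samples.
#' @param trainFraction fraction in (0,1).
#' @param seed shuffle seed.
#' @param labels optional class labels of length `n` for stratification.
#' @return list with integer vectors `train` and `eval`.
#' @examples
#' lengths(splitDataset(697, 0.85, seed = 1))  # 592 / 105
#' @export
splitDataset <- function(n, trainFraction, seed = 1L, labels = NULL) {
  if (n < 2) stop("need at least 2 samples to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0,1)")
  nTrain <- floor(trainFraction * n)
  withSeed(seed, {
    if (is.null(labels)) {
      idx <- sample.int(n)
      train <- sort(idx[seq_len(nTrain)])
    } else {
      stopifnot(length(labels) == n)
      byClass <- split(seq_len(n), labels)
      want <- vapply(byClass, function(ix) trainFraction * length(ix), numeric(1))
      take <- floor(want)
      short <- nTrain - sum(take)
      if (short > 0) {
        ord <- order(want - take, decreasing = TRUE)
        take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
      } else if (short < 0) {
        ord <- order(want - take)
        take[ord[seq_len(-short)]] <- take[ord[seq_len(-short)]] - 1
      }
      train <- sort(unlist(lapply(seq_along(byClass), function(i) {
        ix <- sample(byClass[[i]])
        ix[seq_len(take[i])]
      }), use.names = FALSE))
    }
    list(train = train, eval = setdiff(seq_len(n), train))
  })
}

#' Build a k-fold plan
#'
#' @param n number of samples.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return a validated [FoldPlan-class]: near-equal disjoint folds covering
#'   all indices (sizes differ by at most 1).
#' @export
makeFolds <- function(n, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop(sprintf("cannot make %d folds from %d samples", k, n))
  withSeed(seed, {
    assignment <- integer(n)
    assignment[sample.int(n)] <- rep_len(seq_len(k), n)
    new("FoldPlan", k = asInt(k), assignment = assignment)
  })
}

#' @describeIn foldPlan-accessors per-fold sizes.
#' @export
setMethod("foldSizes", "FoldPlan", function(object)
  tabulate(object@assignment, nbins = object@k))

#' @describeIn foldPlan-accessors indices belonging to `fold`.
#' @export
setMethod("foldIndices", "FoldPlan", function(object, fold)
  which(object@assignment == fold))

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d samples in %d folds (sizes %s)\n",
              length(object@assignment), object@k,
              paste(foldSizes(object), collapse = ", ")))
})

#' Reduce-on-plateau learning-rate step
#'
#' If the validation loss has not improved by more than `1e-4` for
#' `plateauPatience` consecutive epochs, the learning rate is multiplied by
#' `plateauFactor`, floored at `minLr`. `state` carries `lr`, `best` and
#' `wait` between epochs; pass `NULL` to initialise.
#'
#' @param valLoss the epoch's validation loss.
#' @param state scheduler state from the previous call, or `NULL`.
#' @param hp a [Hyperparams-class].
#' @return updated state list with elements `lr`, `best`, `wait`.
#' @export
reduceOnPlateau <- function(valLoss, state, hp) {
  if (is.null(state))
    state <- list(lr = hp@learningRate, best = Inf, wait = 0L)
  if (valLoss < state$best - 1e-4) {
    state$best <- valLoss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= hp@plateauPatience) {
      state$lr <- max(state$lr * hp@plateauFactor, hp@minLr)
      state$wait <- 0L
    }
  }
  state
}

## ---- Adam over the nested weight list ----

# walk trainable leaves (running BN statistics are not trainable)
adamInit <- function(grads) {
  rapply(grads, function(a) list(m = a * 0, v = a * 0), how = "list")
}

adamStep <- function(w, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  step <- function(wn, gn, sn) {
    if (is.list(gn)) {
      for (nm in names(gn)) {
        r <- step(wn[[nm]], gn[[nm]], sn[[nm]])
        wn[[nm]] <- r$w; sn[[nm]] <- r$s
      }
      list(w = wn, s = sn)
    } else {
      m <- b1 * sn$m + (1 - b1) * gn
      v <- b2 * sn$v + (1 - b2) * gn * gn
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      list(w = wn - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
    }
  }
  step(w, grads, state)
}

samplesToBatch <- function(samples, idx) {
  H <- nrow(samples[[idx[1]]]@image); W <- ncol(samples[[idx[1]]]@image)
  x <- array(0, c(H, W, 1L, length(idx)))
  y <- array(0, c(H, W, 1L, length(idx)))
  for (i in seq_along(idx)) {
    x[, , 1, i] <- samples[[idx[i]]]@image
    y[, , 1, i] <- samples[[idx[i]]]@mask
  }
  list(x = x, y = y)
}

#' Evaluate a model on a set of samples
#'
#' Pools pixelwise confusion counts over all samples (inference-mode batch
#' norm, threshold 0.5 with ties to foreground) and derives the full metric
#' suite; AUC is computed on the pooled probabilities and is `NA` when the
#' pooled truth is single-class.
#'
#' @param weights trained weights.
#' @param graph the [ModelGraph-class] they belong to.
#' @param samples list of [UltrasoundSample-class].
#' @param batchSize evaluation batch size.
#' @return named metric vector (`acc`, `sen`, `spe`, `pre`, `f1`, `dice`,
#'   `auc`) plus `loss`.
#' @export
evaluateModel <- function(weights, graph, samples, batchSize = 8L) {
  tp <- tn <- fp <- fn <- 0
  inter <- num <- den <- 0
  loss <- 0; npix <- 0
  allp <- list(); allt <- list()
  idxs <- split(seq_along(samples), ceiling(seq_along(samples) / batchSize))
  for (ix in idxs) {
    b <- samplesToBatch(samples, ix)
    p <- netForward(weights, b$x, graph, training = FALSE)$probs
    pred <- (p >= 0.5) * 1
    tp <- tp + sum(pred == 1 & b$y == 1); tn <- tn + sum(pred == 0 & b$y == 0)
    fp <- fp + sum(pred == 1 & b$y == 0); fn <- fn + sum(pred == 0 & b$y == 1)
    loss <- loss + bceLoss(b$y, p) * length(p)
    npix <- npix + length(p)
    allp[[length(allp) + 1]] <- as.vector(p)
    allt[[length(allt) + 1]] <- as.vector(b$y)
  }
  cc <- new("ConfusionCounts", tp = tp, tn = tn, fp = fp, fn = fn)
  bm <- basicMetrics(cc)
  d <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  tv <- unlist(allt)
  auc <- if (length(unique(tv)) == 2) rocAuc(unlist(allp), tv) else NA_real_
  c(bm, dice = d, auc = auc, loss = loss / npix)
}

#' Train the network with BCE/Adam and reduce-on-plateau
#'
#' Minibatch Adam on the mean pixelwise binary cross-entropy, with optional
#' on-the-fly geometric augmentation of the training pairs, per-epoch
#' validation loss/Dice, and a reduce-on-plateau learning-rate schedule.
#' Deterministic given `hp@seed` (and a fixed BLAS thread policy).
#'
#' @param graph a [ModelGraph-class].
#' @param trainSamples,valSamples lists of [UltrasoundSample-class]; the
#'   validation set drives the plateau callback.
#' @param hp a [Hyperparams-class].
#' @param augment optional [AugmentSpec-class] applied to training pairs.
#' @param weights optional initial weights (default: fresh [initWeights()]
#'   seeded from `hp@seed`).
#' @param verbose print a line per epoch.
#' @return list with `weights` and a [TrainHistory-class] `history`.
#' @export
fitModel <- function(graph, trainSamples, valSamples, hp,
                     augment = NULL, weights = NULL, verbose = FALSE) {
  if (length(trainSamples) == 0) stop("empty training set")
  cfg <- graph@config
  for (s in trainSamples)
    if (!identical(dim(s@image), c(cfg@inputHeight, cfg@inputWidth)))
      stop("sample dims do not match the model config")
  if (is.null(weights)) weights <- initWeights(graph, seed = hp@seed)
  adam <- adamInit(netZeroGrads(weights))
  sched <- NULL
  t <- 0L
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), valDice = numeric(), lr = numeric())
  lr <- hp@learningRate
  for (epoch in seq_len(hp@epochs)) {
    ord <- withSeed(childSeed(hp@seed, 3L, epoch), sample(length(trainSamples)))
    batches <- split(ord, ceiling(seq_along(ord) / hp@batchSize))
    eloss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      samp <- trainSamples[idx]
      if (!is.null(augment)) {
        samp <- lapply(seq_along(samp), function(i) {
          a <- augmentPair(samp[[i]]@image, samp[[i]]@mask, augment,
                           seed = childSeed(hp@seed, 4L, epoch, idx[i]))
          new("UltrasoundSample", image = a$image, mask = a$mask,
              label = samp[[i]]@label, seed = samp[[i]]@seed)
        })
      }
      b <- samplesToBatch(samp, seq_along(samp))
      fw <- netForward(weights, b$x, graph, training = TRUE)
      loss <- bceLoss(b$y, fw$probs)
      gz <- (fw$probs - b$y) / length(fw$probs)
      grads <- netBackward(weights, fw$caches, gz, graph)
      t <- t + 1L
      res <- adamStep(weights, grads, adam, lr, t)
      weights <- res$w   # untouched entries (BN running stats) are preserved
      adam <- res$s
      eloss <- eloss + loss * length(idx)
    }
    eloss <- eloss / length(trainSamples)
    # refresh inference-time batch-norm statistics for the current weights
    weights <- recalibrateBnStats(weights, graph, trainSamples, hp@batchSize)
    ev <- if (length(valSamples)) evaluateModel(weights, graph, valSamples,
                                                hp@batchSize)
          else c(loss = eloss, dice = NA_real_)
    sched <- reduceOnPlateau(unname(ev["loss"]), if (is.null(sched))
      list(lr = lr, best = Inf, wait = 0L) else sched, hp)
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = eloss,
                                   valLoss = unname(ev["loss"]),
                                   valDice = unname(ev["dice"]), lr = lr))
    lr <- sched$lr
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.3f  lr %.2g",
                      epoch, eloss, ev["loss"], ev["dice"], lr))
  }
  list(weights = weights,
       history = new("TrainHistory", epochs = hist))
}

# grads have the trainable-leaf structure; build a zero template from weights
netZeroGrads <- function(w) {
  drop <- c("rmean", "rvar", "nupd")
  prune <- function(x) {
    if (!is.list(x)) return(x * 0)
    out <- list()
    for (nm in names(x)) {
      if (nm %in% drop) next
      out[[nm]] <- prune(x[[nm]])
    }
    out
  }
  prune(w)
}

#' K-fold cross-validation
#'
#' Trains one model per fold (a fresh initialisation each time), evaluates
#' it on the held-out fold, and aggregates the per-fold metric reports by
#' unweighted mean and sample standard deviation. Within each fold's
#' training portion, 10% is held out as a validation split for the plateau
#' callback.
#'
#' @param samples list of [UltrasoundSample-class].
#' @param k number of folds.
#' @param graph a [ModelGraph-class].
#' @param hp a [Hyperparams-class].
#' @param augment optional [AugmentSpec-class].
#' @param verbose print per-epoch progress.
#' @return an aggregated [MetricReport-class] with `nFolds = k`.
#' @export
crossValidate <- function(samples, k, graph, hp, augment = NULL,
                          verbose = FALSE) {
  plan <- makeFolds(length(samples), k, seed = hp@seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- foldIndices(plan, f)
    trainIdx <- setdiff(seq_along(samples), testIdx)
    nVal <- max(1L, floor(0.1 * length(trainIdx)))
    valIdx <- withSeed(childSeed(hp@seed, 5L, f),
                       sample(trainIdx, nVal))
    fitIdx <- setdiff(trainIdx, valIdx)
    hpf <- hp
    hpf@seed <- childSeed(hp@seed, 6L, f)
    fit <- fitModel(graph, samples[fitIdx], samples[valIdx], hpf,
                    augment = augment, verbose = verbose)
    m <- evaluateModel(fit$weights, graph, samples[testIdx], hp@batchSize)
    reports[[f]] <- metricReport(m[metricNames()], fold = f)
  }
  out <- aggregateFolds(reports)
  attr(out, "plan") <- plan
  out
}

#' @describeIn trainHistory-accessors the per-epoch data.frame.
#' @export
setMethod("historyTable", "TrainHistory", function(object) object@epochs)

setMethod("show", "TrainHistory", function(object) {
  e <- object@epochs
  cat(sprintf("TrainHistory: %d epochs; final train %.4f, val %.4f, dice %.3f, lr %.2g\n",
              nrow(e), e$trainLoss[nrow(e)], e$valLoss[nrow(e)],
              e$valDice[nrow(e)], e$lr[nrow(e)]))
})

setMethod("show", "Hyperparams", function(object) {
  cat(sprintf("Hyperparams: lr %.4g, batch %d, epochs %d, plateau (patience %d, factor %.2f, min %.1e), seed %d\n",
              object@learningRate, object@batchSize, object@epochs,
              object@plateauPatience, object@plateauFactor, object@minLr,
              object@seed))
})

#' Desk-scale learning surrogate
#'
#' A small, CPU-scale stand-in for the full clinical training run: a reduced
#' model (filter schedule 8-128) is trained for up to 30 epochs on 64 x 64
#' high-contrast benign phantoms (contrast 0.7, one lesion of radius 8-16 px,
#' mild irregularity, no shadowing) under the standard hyperparameters
#' (Adam, lr 0.001, batch 8), with an 85/15 train/eval split. Returns the
#' held-out metrics and the training history so loss/learning-rate traces
#' can be inspected.
#'
#' @param seed controls phantom generation, split, initialisation and
#'   shuffling.
#' @param nSamples phantom count (default 60).
#' @param epochs training epochs (default 30).
#' @param size frame side in pixels (default 64).
#' @return list with `metrics` (named vector incl. `dice`), `history`
#'   (a [TrainHistory-class]), `weights` and `graph`.
#' @export
learningSurrogate <- function(seed, nSamples = 60L, epochs = 30L, size = 64L) {
  samples <- lapply(seq_len(nSamples), function(i) {
    p <- phantomParams(size, size, "benign",
                       lesionCountRange = c(1L, 1L),
                       lesionRadiusRange = c(8, 16) * size / 64,
                       boundaryIrregularity = 0.1,
                       lesionContrast = 0.7, speckleShape = 6,
                       calcificationCountRange = c(0L, 2L),
                       shadowProbability = 0,
                       seed = childSeed(seed, 10L, i))
    generatePhantom(p)
  })
  sp <- splitDataset(nSamples, 0.85, seed = seed)
  cfg <- modelConfig(size, size, filterSchedule = c(8L, 16L, 32L, 64L, 128L),
                     seed = seed)
  graph <- assembleModel(cfg)
  hp <- hyperparams(epochs = epochs, batchSize = 8L, seed = seed)
  fit <- fitModel(graph, samples[sp$train], samples[sp$eval], hp)
  m <- evaluateModel(fit$weights, graph, samples[sp$eval])
  list(metrics = m, history = fit$history, weights = fit$weights,
       graph = graph)
}
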