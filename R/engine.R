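# Forward/backward execution of the assembled graph.
#
# Activations are [H, W, C, N] double arrays; the dense kernels live in
# src/layers.cpp. Gradients are hand-derived per block and verified against
# finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

as3 <- function(x4) { d <- dim(x4); dim(x4) <- c(d[1] * d[2], d[3], d[4]); x4 }
as4 <- function(x3, H, W) { d <- dim(x3); dim(x3) <- c(H, W, d[2], d[3]); x3 }

# concatenate [H,W,C,N] arrays along the channel axis
ccat <- function(xs) {
  d <- dim(xs[[1]])
  Cs <- vapply(xs, function(a) dim(a)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(Cs), d[4]))
  off <- 0L
  for (a in xs) {
    out[, , off + seq_len(dim(a)[3]), ] <- a
    off <- off + dim(a)[3]
  }
  out
}

netSpec <- function(graph) {
  cfg <- graph@config
  list(f = cfg@filterSchedule, cin = cfg@inputChannels,
       inter = cfg@attentionInter, H = cfg@inputHeight, W = cfg@inputWidth)
}

rnorm4 <- function(dims, sd) array(stats::rnorm(prod(dims), sd = sd), dims)

initConv <- function(k, ic, oc) {
  list(W = rnorm4(c(k, k, ic, oc), sqrt(2 / (k * k * ic))), b = numeric(oc))
}
initBn <- function(ch) {
  list(gamma = rep(1, ch), beta = numeric(ch),
       rmean = numeric(ch), rvar = rep(1, ch), nupd = 0)
}
initMr <- function(ic, oc) {
  t <- filterThirds(oc)
  list(conv1 = initConv(3L, ic, t[1]), bn1 = initBn(t[1]),
       conv2 = initConv(3L, t[1], t[2]), bn2 = initBn(t[2]),
       conv3 = initConv(3L, t[2], t[3]), bn3 = initBn(t[3]),
       convr = initConv(1L, ic, oc), bnr = initBn(oc))
}
initGate <- function(ic, inter) {
  list(W = rnorm4(c(1L, 1L, ic, inter), sqrt(2 / ic)))
}

#' Initialise network weights
#'
#' He-normal initialisation for convolutions, unit-gamma/zero-beta batch
#' norms, and bias-free gate projections; fully determined by `seed`
#' (defaulting to the config's).
#'
#' @param graph a [ModelGraph-class].
#' @param seed integer seed; defaults to the graph config's seed.
#' @return nested named list of weight arrays.
#' @export
initWeights <- function(graph, seed = graph@config@seed) {
  ns <- netSpec(graph)
  f <- ns$f
  withSeed(seed, {
    w <- list()
    cin <- ns$cin
    for (i in 1:5) {
      w[[paste0("enc", i)]] <- initMr(cin, f[i])
      w[[paste0("egate", i)]] <- initGate(f[i], ns$inter)
      cin <- f[i]
    }
    for (j in 5:2) {
      lev <- j - 1L
      ic <- if (j == 5) f[5] else f[j]
      w[[paste0("dec", j)]] <- initMr(ic, f[lev])
      w[[paste0("dgate", j)]] <- initGate(f[lev], ns$inter)
    }
    w$dec1 <- initMr(f[1], f[1])
    w$dgate1 <- initGate(f[1], ns$inter)
    w$out <- initConv(1L, f[1], 1L)
    w
  })
}

## ---- conv + batchnorm + relu unit ----

cbrForward <- function(x, conv, bn, training) {
  cc <- .conv2dForward(x, conv$W, conv$b)
  if (training) {
    bf <- .bnForward(cc, bn$gamma, bn$beta, 1e-5)
    a <- .reluForward(bf$y)
    list(y = a, cache = list(xin = x, xhat = bf$xhat, invstd = bf$invstd,
                             a = a, mean = bf$mean, var = bf$var))
  } else {
    y <- .bnForwardInference(cc, bn$gamma, bn$beta, bn$rmean, bn$rvar, 1e-5)
    list(y = .reluForward(y), cache = NULL)
  }
}

cbrBackward <- function(conv, bn, cache, gy) {
  g <- .reluBackward(cache$a, gy)
  bb <- .bnBackward(cache$xhat, cache$invstd, bn$gamma, g)
  cb <- .conv2dBackward(cache$xin, conv$W, bb$gx, TRUE)
  list(gx = cb$gx,
       grads = list(conv = list(W = cb$gw, b = cb$gb),
                    bn = list(gamma = bb$ggamma, beta = bb$gbeta)))
}

## ---- MultiRes block: three serial 3x3 conv-BN-ReLU units whose outputs are
## concatenated (the multi-scale path F) plus a 1x1 residual projection H;
## y = relu(F(x) + H(x)) ----

mrForward <- function(x, wb, training) {
  r1 <- cbrForward(x, wb$conv1, wb$bn1, training)
  r2 <- cbrForward(r1$y, wb$conv2, wb$bn2, training)
  r3 <- cbrForward(r2$y, wb$conv3, wb$bn3, training)
  Fcat <- ccat(list(r1$y, r2$y, r3$y))
  cr <- .conv2dForward(x, wb$convr$W, wb$convr$b)
  if (training) {
    br <- .bnForward(cr, wb$bnr$gamma, wb$bnr$beta, 1e-5)
    hy <- br$y
  } else {
    hy <- .bnForwardInference(cr, wb$bnr$gamma, wb$bnr$beta,
                              wb$bnr$rmean, wb$bnr$rvar, 1e-5)
  }
  pre <- Fcat + hy
  y <- .reluForward(pre)
  cache <- if (training) {
    list(x = x, r1 = r1$cache, r2 = r2$cache, r3 = r3$cache,
         rxhat = br$xhat, rinvstd = br$invstd, pre = pre,
         t = c(dim(r1$y)[3], dim(r2$y)[3], dim(r3$y)[3]),
         bnStats = list(bn1 = list(mean = r1$cache$mean, var = r1$cache$var),
                        bn2 = list(mean = r2$cache$mean, var = r2$cache$var),
                        bn3 = list(mean = r3$cache$mean, var = r3$cache$var),
                        bnr = list(mean = br$mean, var = br$var)))
  } else NULL
  list(y = y, cache = cache)
}

mrBackward <- function(wb, cache, gy) {
  gpre <- .reluBackward(cache$pre, gy)
  t <- cache$t
  ga1c <- gpre[, , seq_len(t[1]), , drop = FALSE]
  ga2c <- gpre[, , t[1] + seq_len(t[2]), , drop = FALSE]
  ga3c <- gpre[, , t[1] + t[2] + seq_len(t[3]), , drop = FALSE]
  # residual path
  bb <- .bnBackward(cache$rxhat, cache$rinvstd, wb$bnr$gamma, gpre)
  cb <- .conv2dBackward(cache$x, wb$convr$W, bb$gx, TRUE)
  # serial path, deepest first (a1 and a2 feed both the concat and the next conv)
  g3 <- cbrBackward(wb$conv3, wb$bn3, cache$r3, ga3c)
  g2 <- cbrBackward(wb$conv2, wb$bn2, cache$r2, ga2c + g3$gx)
  g1 <- cbrBackward(wb$conv1, wb$bn1, cache$r1, ga1c + g2$gx)
  list(gx = g1$gx + cb$gx,
       grads = list(conv1 = g1$grads$conv, bn1 = g1$grads$bn,
                    conv2 = g2$grads$conv, bn2 = g2$grads$bn,
                    conv3 = g3$grads$conv, bn3 = g3$grads$bn,
                    convr = list(W = cb$gw, b = cb$gb),
                    bnr = list(gamma = bb$ggamma, beta = bb$gbeta)))
}

## ---- attention gate: z = Conv1x1(x) (bias-free), a = sigmoid(channel mean
## of z), y = a*x + (1-a)*x_up elementwise; a is a per-pixel scalar gate ----

gateForwardCore <- function(x, xup, W) {
  d <- dim(x)
  z <- .conv2dForward(x, W, NULL)
  z3 <- as3(z)
  inter <- dim(z3)[2]
  zm <- rowSums(aperm(z3, c(1, 3, 2)), dims = 2) / inter      # [H*W, N]
  a <- sigmoid(zm)
  x3 <- as3(x); xup3 <- as3(xup)
  aarr <- array(a, c(d[1] * d[2], 1, d[4]))
  ab <- aarr[, rep(1L, d[3]), , drop = FALSE]
  y3 <- ab * x3 + (1 - ab) * xup3
  list(y = as4(y3, d[1], d[2]), a = a, ab = ab)
}

gateBackwardCore <- function(x, xup, W, cache, gy) {
  d <- dim(x)
  inter <- dim(W)[4]
  gy3 <- as3(gy); x3 <- as3(x); xup3 <- as3(xup)
  dd <- (x3 - xup3) * gy3
  da <- rowSums(aperm(dd, c(1, 3, 2)), dims = 2)              # [H*W, N]
  gzm <- da * cache$a * (1 - cache$a) / inter
  gzarr <- array(gzm, c(d[1] * d[2], 1, d[4]))
  gz3 <- gzarr[, rep(1L, inter), , drop = FALSE]
  cb <- .conv2dBackward(x, W, as4(gz3, d[1], d[2]), FALSE)
  gx <- as4(cache$ab * gy3, d[1], d[2]) + cb$gx
  gxup <- as4((1 - cache$ab) * gy3, d[1], d[2])
  list(gx = gx, gxup = gxup, gW = cb$gw)
}

## ---- whole-network forward/backward ----

netForward <- function(w, x, graph, training = FALSE) {
  ns <- netSpec(graph)
  s <- vector("list", 5L); encC <- vector("list", 5L)
  poolIdx <- vector("list", 4L)
  cur <- x
  for (i in 1:5) {
    r <- mrForward(cur, w[[paste0("enc", i)]], training)
    s[[i]] <- r$y; encC[[i]] <- r$cache
    # the encoder stage's self-paired gate is the identity (gate(x, x) = x)
    if (i < 5) {
      p <- .maxpool2Forward(r$y)
      poolIdx[[i]] <- p$idx
      cur <- p$y
    }
  }
  d <- s[[5]]
  decC <- list(); gateC <- list(); ups <- list(); mrs <- list()
  for (j in 5:2) {
    lev <- j - 1L
    u <- .upsample2Forward(d)
    m <- mrForward(u, w[[paste0("dec", j)]], training)
    g <- gateForwardCore(s[[lev]], m$y, w[[paste0("dgate", j)]]$W)
    decC[[paste0("dec", j)]] <- m$cache
    gateC[[paste0("dgate", j)]] <- list(a = g$a, ab = g$ab, x = s[[lev]],
                                        xup = m$y, u = u)
    mrs[[paste0("dec", j)]] <- m$y
    d <- g$y
  }
  m1 <- mrForward(d, w$dec1, training)
  # decoder block 1's self-paired gate is again the identity
  z <- .conv2dForward(m1$y, w$out$W, w$out$b)
  probs <- sigmoid(z)
  caches <- if (training) list(enc = encC, pool = poolIdx, dec = decC,
                               gate = gateC, dec1 = m1$cache, dec1in = d,
                               m1y = m1$y) else NULL
  list(probs = probs, z = z, caches = caches,
       acts = list(enc = s, dec = mrs, dec1 = m1$y))
}

netBackward <- function(w, caches, gz, graph) {
  grads <- list()
  cb <- .conv2dBackward(caches$m1y, w$out$W, gz, TRUE)
  grads$out <- list(W = cb$gw, b = cb$gb)
  m1b <- mrBackward(w$dec1, caches$dec1, cb$gx)
  grads$dec1 <- m1b$grads
  gd <- m1b$gx
  gskip <- vector("list", 5L)   # gradient flowing into encoder outputs s[[i]]
  for (j in 2:5) {
    lev <- j - 1L
    gc <- caches$gate[[paste0("dgate", j)]]
    gb <- gateBackwardCore(gc$x, gc$xup, w[[paste0("dgate", j)]]$W, gc, gd)
    grads[[paste0("dgate", j)]] <- list(W = gb$gW)
    gskip[[lev]] <- gb$gx
    mb <- mrBackward(w[[paste0("dec", j)]], caches$dec[[paste0("dec", j)]],
                     gb$gxup)
    grads[[paste0("dec", j)]] <- mb$grads
    gd <- .upsample2Backward(mb$gx)
  }
  gskip[[5]] <- gd
  gcur <- NULL
  for (i in 5:1) {
    g <- gskip[[i]]
    if (!is.null(gcur)) g <- g + gcur
    eb <- mrBackward(w[[paste0("enc", i)]], caches$enc[[i]], g)
    grads[[paste0("enc", i)]] <- eb$grads
    grads[[paste0("egate", i)]] <- list(W = array(0, dim(w[[paste0("egate", i)]]$W)))
    if (i > 1) {
      xd <- dim(caches$enc[[i - 1]]$pre)
      gcur <- .maxpool2Backward(caches$pool[[i - 1]], eb$gx, as.integer(xd))
    }
  }
  grads$dgate1 <- list(W = array(0, dim(w$dgate1$W)))
  grads
}

# Fold a forward pass's batch statistics into the accumulating inference
# statistics as a cumulative moving average over batches. Used by
# recalibrateBnStats(), which recomputes the inference statistics exactly
# over the training set with the current weights after every epoch: with the
# small datasets this package trains on there are few optimiser steps per
# epoch, and momentum-style running averages lag badly behind the weights,
# which miscalibrates validation losses (and through them the plateau
# scheduler) and held-out predictions.
updateRunningStats <- function(w, caches, momentum = NULL) {
  upd <- function(wb, st) {
    for (nm in names(st)) {
      n <- wb[[nm]]$nupd + 1
      a <- if (is.null(momentum)) 1 / n else (1 - momentum)
      wb[[nm]]$rmean <- (1 - a) * wb[[nm]]$rmean + a * st[[nm]]$mean
      wb[[nm]]$rvar <- (1 - a) * wb[[nm]]$rvar + a * st[[nm]]$var
      wb[[nm]]$nupd <- n
    }
    wb
  }
  for (i in 1:5) {
    nm <- paste0("enc", i)
    w[[nm]] <- upd(w[[nm]], caches$enc[[i]]$bnStats)
  }
  for (j in 5:2) {
    nm <- paste0("dec", j)
    w[[nm]] <- upd(w[[nm]], caches$dec[[nm]]$bnStats)
  }
  w$dec1 <- upd(w$dec1, caches$dec1$bnStats)
  w
}

resetBnStats <- function(w) {
  wipe <- function(x) {
    if (!is.list(x)) return(x)
    if (!is.null(x$nupd)) {
      x$rmean[] <- 0; x$rvar[] <- 1; x$nupd <- 0
      return(x)
    }
    for (nm in names(x)) x[[nm]] <- wipe(x[[nm]])
    x
  }
  wipe(w)
}

# Recompute every batch norm's inference-time statistics from scratch by
# streaming the given samples through the network in training mode with the
# current weights (batch-averaged means and variances).
recalibrateBnStats <- function(w, graph, samples, batchSize = 8L) {
  w <- resetBnStats(w)
  idxs <- split(seq_along(samples), ceiling(seq_along(samples) / batchSize))
  for (ix in idxs) {
    b <- samplesToBatch(samples, ix)
    fw <- netForward(w, b$x, graph, training = TRUE)
    w <- updateRunningStats(w, fw$caches)
  }
  w
}

## ---- exported single-sample operations ----

ensure3d <- function(x, what = "feature map") {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop(sprintf("%s must be H x W x C", what))
  if (any(!is.finite(x))) stop(sprintf("%s contains non-finite values", what))
  x
}

#' Attention-gate forward pass
#'
#' Computes `z = Conv1x1(x)` (bias-free projection), reduces `z` to a
#' per-pixel scalar by a parameter-free channel mean, applies a sigmoid to
#' obtain the gate `a`, and returns the elementwise convex combination
#' `a * x + (1 - a) * x_up`. Every output element therefore lies in the
#' closed interval between the two inputs.
#'
#' @param x encoder feature map, `H x W x C` array (or matrix for C = 1).
#' @param xup upsampled decoder feature map with identical dims.
#' @param weights gate projection: `1 x 1 x C x inter` array or `C x inter`
#'   matrix.
#' @return gated feature map with the dims of `x`.
#' @examples
#' x <- array(rnorm(32), c(4, 4, 2)); xup <- array(rnorm(32), c(4, 4, 2))
#' w <- array(0, c(1, 1, 2, 8))
#' all.equal(attentionGateForward(x, xup, w), (x + xup) / 2)
#' @export
attentionGateForward <- function(x, xup, weights) {
  x <- ensure3d(x); xup <- ensure3d(xup, "x_up")
  if (!identical(dim(x), dim(xup)))
    stop("x and x_up must have identical dims")
  if (is.matrix(weights)) weights <- array(weights, c(1L, 1L, dim(weights)))
  if (dim(weights)[3] != dim(x)[3])
    stop("gate weights do not match the input channel count")
  x4 <- array(x, c(dim(x), 1L)); xup4 <- array(xup, c(dim(xup), 1L))
  y <- gateForwardCore(x4, xup4, weights)$y
  array(y, dim(x))
}

#' MultiRes block forward pass
#'
#' Runs one multi-resolution residual block: three serial 3x3
#' conv-batchnorm-ReLU units whose outputs are concatenated (the multi-scale
#' path), plus a 1x1 residual projection of the input, summed and passed
#' through a final ReLU. Spatial dims are preserved ("same" padding).
#'
#' @param x `H x W x C` input (or matrix for C = 1).
#' @param weights one block's weight list, as produced by [initWeights()]
#'   (e.g. `weights$enc1`).
#' @param training logical; batch statistics (TRUE) or running statistics
#'   (FALSE) for the batch norms.
#' @return `H x W x outChannels` activation.
#' @export
multiresForward <- function(x, weights, training = FALSE) {
  x <- ensure3d(x)
  if (dim(weights$conv1$W)[3] != dim(x)[3])
    stop(sprintf("block expects %d input channels, got %d",
                 dim(weights$conv1$W)[3], dim(x)[3]))
  x4 <- array(x, c(dim(x), 1L))
  y <- mrForward(x4, weights, training)$y
  array(y, dim(y)[1:3])
}

#' Hard binary masking of a feature map
#'
#' Keeps features where the mask is 1 and zeroes them elsewhere, across all
#' channels: `I(x,y) = F(x,y)` if `(x,y)` is in the mask, else 0. Applying
#' the same mask twice equals applying it once.
#'
#' @param features `H x W x C` array or `H x W` matrix.
#' @param mask binary `H x W` matrix.
#' @return masked features with the input's shape.
#' @export
maskFeatures <- function(features, mask) {
  wasMat <- is.matrix(features)
  features <- ensure3d(features)
  if (!identical(dim(features)[1:2], dim(mask)))
    stop("mask spatial dims do not match the feature map")
  if (!all(mask %in% c(0, 1))) stop("mask must be exactly binary")
  out <- features * array(mask, dim(features))
  if (wasMat) out[, , 1] else out
}

#' Segment an image
#'
#' Full forward pass: per-pixel foreground probabilities in (0,1) with the
#' input's spatial dims.
#'
#' @param image `H x W` grayscale matrix matching the graph's input dims.
#' @param graph a [ModelGraph-class].
#' @param weights weight list from [initWeights()] or [fitModel()].
#' @return `H x W` probability matrix.
#' @export
segmentImage <- function(image, graph, weights) {
  cfg <- graph@config
  if (!identical(dim(image), c(cfg@inputHeight, cfg@inputWidth)))
    stop(sprintf("image dims %s do not match the config's %d x %d",
                 paste(dim(image), collapse = " x "),
                 cfg@inputHeight, cfg@inputWidth))
  x4 <- array(image, c(dim(image), 1L, 1L))
  p <- netForward(weights, x4, graph, training = FALSE)$probs
  matrix(p, nrow(image), ncol(image))
}

#' Threshold a probability map into a binary mask
#'
#' @param probs probability matrix from [segmentImage()].
#' @param threshold decision threshold; ties (exactly equal) map to
#'   foreground.
#' @return binary matrix.
#' @export
binarizeProbs <- function(probs, threshold = 0.5) {
  (probs >= threshold) * 1
}

#' Extract an intermediate activation
#'
#' Returns the named MultiRes-block output, for inspecting the network's
#' multi-scale feature extraction.
#'
#' @param image input image matrix matching the graph dims.
#' @param graph a [ModelGraph-class].
#' @param weights network weights.
#' @param stage one of `"encoder-1"` .. `"encoder-5"`, `"decoder-5"` ..
#'   `"decoder-1"`.
#' @return `H x W x C` activation array.
#' @export
extractFeatures <- function(image, graph, weights, stage) {
  valid <- c(paste0("encoder-", 1:5), paste0("decoder-", 5:1))
  if (!stage %in% valid)
    stop(sprintf("unknown stage '%s'; valid stages: %s", stage,
                 paste(valid, collapse = ", ")))
  x4 <- array(image, c(dim(image), 1L, 1L))
  fw <- netForward(weights, x4, graph, training = FALSE)
  part <- sub("-.*", "", stage)
  idx <- as.integer(sub(".*-", "", stage))
  a <- if (part == "encoder") fw$acts$enc[[idx]]
       else if (idx == 1L) fw$acts$dec1
       else fw$acts$dec[[paste0("dec", idx)]]
  array(a, dim(a)[1:3])
}
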