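# Shared fixtures: everything is generated in code at test time.

# tiny valid config whose whole forward/backward pass runs in milliseconds
tinyConfig <- function(seed = 7L, size = 16L)
  modelConfig(size, size, filterSchedule = c(3L, 4L, 6L, 8L, 10L), seed = seed)

tinyGraph <- function(seed = 7L, size = 16L) assembleModel(tinyConfig(seed, size))

# quick low-noise phantom parameters for training smoke tests
quickPhantomParams <- function(seed, size = 32L)
  phantomParams(size, size, "benign", lesionCountRange = c(1L, 1L),
                lesionRadiusRange = c(5, 8) * size / 32,
                boundaryIrregularity = 0.1, lesionContrast = 0.7,
                speckleShape = 6, calcificationCountRange = c(0L, 0L),
                shadowProbability = 0, seed = seed)

quickPhantoms <- function(n, seed = 1L, size = 32L)
  lapply(seq_len(n), function(i) generatePhantom(quickPhantomParams(seed + i, size)))

# independent elementwise BCE oracle (plain summation)
bceOracle <- function(y, p) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  s <- 0
  for (i in seq_along(y))
    s <- s + y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i])
  -s / length(y)
}

# independent confusion oracle (exhaustive per-pixel enumeration)
confusionOracle <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# independent AUC oracle (exhaustive positive/negative pair enumeration)
aucOracle <- function(probs, truth) {
  pos <- probs[truth == 1]; neg <- probs[truth == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
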