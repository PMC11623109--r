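metricNames <- function() c("acc", "sen", "spe", "pre", "f1", "dice", "auc")

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state so library code never perturbs user-level reproducibility.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream-specific child seed below 2^31.
childSeed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + as.double(o) + 1) %% 2147483647
  as.integer(s)
}

asInt <- function(x) as.integer(round(x))

# draw one integer uniformly from [lo, hi], robust to lo == hi
sampleRange <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(seq.int(lo, hi), 1L)
}

# separable box-ish Gaussian blur with replicate padding; small sigmas only
gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(2.5 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(v, r) c(rep(v[1], r), v, rep(v[length(v)], r))
  blur1 <- function(v) {
    vp <- pad(v, r)
    stats::convolve(vp, rev(k), type = "filter")
  }
  m2 <- apply(m, 2, blur1)          # blur along rows (vertical)
  t(apply(m2, 1, blur1))            # then along columns (horizontal)
}
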