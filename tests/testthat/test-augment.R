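fixedSpec <- function(angle = 0, flipH = 0, flipV = 0, scale = 1, crop = 1,
                      seed = 1L)
  augmentSpec(rotationDegrees = c(angle, angle), flipHorizontal = flipH,
              flipVertical = flipV, scaleFactor = c(scale, scale),
              cropFraction = crop, seed = seed)

blobPair <- function(size = 32L) {
  img <- matrix(0, size, size)
  img[6:10, 20:24] <- 0.8
  mask <- (img > 0) * 1
  list(image = img, mask = mask)
}

test_that("the identity transform returns the pair unchanged", {
  p <- blobPair()
  out <- augmentPair(p$image, p$mask, fixedSpec())
  expect_equal(out$image, p$image)
  expect_equal(out$mask, p$mask)
})

test_that("a horizontal flip is an involution", {
  p <- blobPair()
  sp <- fixedSpec(flipH = 1)
  once <- augmentPair(p$image, p$mask, sp)
  expect_false(isTRUE(all.equal(once$image, p$image)))
  twice <- augmentPair(once$image, once$mask, sp)
  expect_equal(twice$image, p$image)
  expect_equal(twice$mask, p$mask)
})

test_that("a 90-degree rotation moves the blob centroid as predicted", {
  p <- blobPair()
  out <- augmentPair(p$image, p$mask, fixedSpec(angle = 90))
  centroid <- function(m) {
    w <- which(m == 1, arr.ind = TRUE)
    colMeans(w)
  }
  c0 <- centroid(p$mask); c1 <- centroid(out$mask)
  ctr <- (32 + 1) / 2
  # output (r,c) samples the input rotated by +90 about the centre
  pred <- c(ctr + (c0[2] - ctr), ctr - (c0[1] - ctr))
  expect_lt(max(abs(c1 - unname(pred))), 1)
})

test_that("masks stay binary and area is roughly preserved without scaling", {
  p <- blobPair(48L)
  for (s in 1:15) {
    sp <- augmentSpec(rotationDegrees = c(-30, 30), flipHorizontal = 0.5,
                      flipVertical = 0.5, scaleFactor = c(1, 1),
                      cropFraction = 1, seed = s)
    out <- augmentPair(p$image, p$mask, sp)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_lt(abs(sum(out$mask) - sum(p$mask)) / sum(p$mask), 0.1)
  }
})

test_that("the drawn transform is deterministic in the seed", {
  p <- blobPair()
  sp <- augmentSpec(seed = 42L)
  a <- augmentPair(p$image, p$mask, sp)
  b <- augmentPair(p$image, p$mask, sp)
  expect_identical(a, b)
  c2 <- augmentPair(p$image, p$mask, sp, seed = 43L)
  expect_false(identical(a$image, c2$image))
})
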