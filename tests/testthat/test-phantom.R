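test_that("lesion masks are binary, seeded, and geometrically faithful", {
  pn <- phantomParams(64, 64, "normal", seed = 3L)
  expect_equal(sum(generateLesionMask(pn)), 0)

  pb <- phantomParams(96, 96, "benign", seed = 5L)
  m1 <- generateLesionMask(pb)
  m2 <- generateLesionMask(pb)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% c(0, 1)))

  # a zero-irregularity single lesion is an exact ellipse: pixel area
  # within 2% of pi*a*b
  p0 <- phantomParams(128, 128, "benign", lesionCountRange = c(1L, 1L),
                      lesionRadiusRange = c(20, 20),
                      boundaryIrregularity = 0, seed = 9L)
  area <- sum(generateLesionMask(p0))
  expect_lt(abs(area - pi * 20 * 20) / (pi * 20 * 20), 0.02)

  expect_error(generateLesionMask(
    phantomParams(64, 64, "benign", lesionRadiusRange = c(30, 40), seed = 1L)),
    "half the frame")
})

test_that("rendered intensities express the configured lesion contrast", {
  insideOutside <- function(contrast, seed) {
    p <- phantomParams(64, 64, "benign", lesionCountRange = c(1L, 1L),
                       lesionRadiusRange = c(8, 12),
                       boundaryIrregularity = 0.05,
                       lesionContrast = contrast, speckleShape = 6,
                       calcificationCountRange = c(0L, 0L),
                       shadowProbability = 0, seed = seed)
    m <- generateLesionMask(p)
    img <- renderUltrasound(m, p)
    expect_true(all(img >= 0 & img <= 1))
    c(inside = mean(img[m == 1]), outside = mean(img[m == 0]))
  }
  d0 <- vapply(1:20, function(s) {
    v <- insideOutside(0, s); v["inside"] - v["outside"]
  }, numeric(1))
  expect_lt(abs(mean(d0)), 0.02)
  d6 <- vapply(21:40, function(s) {
    v <- insideOutside(0.6, s); v["inside"] < v["outside"]
  }, logical(1))
  expect_gte(sum(d6), 19)
})

test_that("malignant boundaries are more tortuous than benign ones", {
  tort <- function(mask) {
    H <- nrow(mask); W <- ncol(mask)
    up <- rbind(mask[-1, ], 0); dn <- rbind(0, mask[-H, ])
    lf <- cbind(mask[, -1], 0); rt <- cbind(0, mask[, -W])
    b <- mask == 1 & (up == 0 | dn == 0 | lf == 0 | rt == 0)
    sum(b)^2 / (4 * pi * sum(mask))
  }
  tb <- tm <- numeric(20)
  for (s in 1:20) {
    tb[s] <- tort(generateLesionMask(
      phantomParams(128, 128, "benign", lesionCountRange = c(1L, 1L), seed = s)))
    tm[s] <- tort(generateLesionMask(
      phantomParams(128, 128, "malignant", lesionCountRange = c(1L, 1L), seed = s)))
  }
  expect_gt(mean(tm), mean(tb))
})

test_that("generateDataset writes a reproducible BUSI-style tree", {
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  p <- phantomParams(32, 32, seed = 2L)
  idx <- generateDataset(c(benign = 2, malignant = 2, normal = 2), p, d1,
                         seed = 2L)
  files <- list.files(d1)
  expect_length(grep("_mask", files, invert = TRUE, value = TRUE), 6)
  expect_length(grep("_mask", files, value = TRUE), 6)
  expect_equal(nrow(sampleRecords(idx)), 6)
  expect_setequal(sampleRecords(idx)$label,
                  c("benign", "malignant", "normal"))
  # normal-class masks exist and are all-zero
  nm <- png::readPNG(file.path(d1, "normal (1)_mask.png"))
  expect_equal(sum(nm), 0)
  # byte-identical across runs for the same seed
  generateDataset(c(benign = 2, malignant = 2, normal = 2), p, d2, seed = 2L)
  h1 <- unname(tools::md5sum(file.path(d1, sort(files))))
  h2 <- unname(tools::md5sum(file.path(d2, sort(files))))
  expect_identical(h1, h2)
})
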