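test_that("assembleModel produces the five-level encoder/decoder geometry", {
  g <- assembleModel(modelConfig(256, 256))
  sh <- inferShapes(g)
  enc <- sh[sh$name == "Multi-Res Block" & grepl("Encoder", sh$block), ]
  expect_equal(enc$height, c(256, 128, 64, 32, 16))
  expect_equal(enc$channels, c(32, 64, 128, 256, 512))
  bott <- sh[sh$block == "Encoder Block 5" & sh$name == "Multi-Res Block", ]
  expect_equal(c(bott$height, bott$width, bott$channels), c(16, 16, 512))

  g2 <- assembleModel(modelConfig(32, 32))
  sh2 <- inferShapes(g2)
  b2 <- sh2[sh2$block == "Encoder Block 5" & sh2$name == "Multi-Res Block", ]
  expect_equal(c(b2$height, b2$width), c(2, 2))

  expect_error(modelConfig(250, 250), "250")
})

test_that("inferShapes matches the layer table and ends at the input dims", {
  g <- assembleModel(modelConfig(256, 256))
  sh <- inferShapes(g)
  d2 <- sh[sh$block == "Decoder Block 2" & sh$name == "Multi-Res Block", ]
  expect_equal(c(d2$height, d2$width, d2$channels), c(256, 256, 32))
  mp1 <- sh[sh$block == "Encoder Block 1" & sh$name == "Maxpool 2 x 2", ]
  expect_equal(c(mp1$height, mp1$width, mp1$channels), c(128, 128, 32))
  out <- sh[nrow(sh), ]
  expect_equal(c(out$height, out$width, out$channels), c(256, 256, 1))

  # pooling halves and upsampling doubles exactly, for any valid config
  b <- g@blocks
  for (i in which(b$kind == "maxpool"))
    expect_equal(c(b$outHeight[i], b$outWidth[i]),
                 c(b$outHeight[i - 1] / 2, b$outWidth[i - 1] / 2))
  for (i in which(b$kind == "upsample"))
    expect_equal(c(b$outHeight[i], b$outWidth[i]),
                 c(b$outHeight[i - 1] * 2, b$outWidth[i - 1] * 2))
})

test_that("countParams reproduces the printed audit arithmetic", {
  expect_equal(countParams(list(kind = "attention_gate", inChannels = 32,
                                outChannels = 32), "table_audit"), 1024)
  expect_equal(countParams(list(kind = "multires", inChannels = 64,
                                outChannels = 128), "table_audit"), 73856)
  expect_equal(countParams(list(kind = "output_conv", inChannels = 1,
                                outChannels = 1), "table_audit"), 2)
  expect_equal(countParams(list(kind = "maxpool", inChannels = 8,
                                outChannels = 8), "table_audit"), 0)
  # canonical counts equal the element count of the actual weight arrays
  g <- tinyGraph()
  w <- initWeights(g)
  nElems <- function(wb) {
    drop <- c("rmean", "rvar", "nupd")
    sum(unlist(lapply(names(wb), function(nm) {
      part <- wb[[nm]]
      sum(vapply(setdiff(names(part), drop), function(k) length(part[[k]]),
                 numeric(1)))
    })))
  }
  b <- g@blocks
  mrRows <- which(b$kind == "multires")
  wNames <- c(paste0("enc", 1:5), paste0("dec", 5:1))
  for (i in seq_along(mrRows))
    expect_equal(b$paramsCanonical[mrRows[i]], nElems(w[[wNames[i]]]))
  expect_equal(b$paramsCanonical[b$kind == "output_conv"],
               length(w$out$W) + length(w$out$b))
  expect_error(countParams(list(kind = "nonsense", inChannels = 1,
                                outChannels = 1)), "unknown")
})

test_that("every encoder stage 1-4 has exactly one skip consumer", {
  g <- assembleModel(modelConfig(64, 64, filterSchedule = c(4L, 8L, 16L, 32L, 64L)))
  expect_equal(sort(g@skips$encoderStage), 1:4)
  expect_equal(anyDuplicated(g@skips$decoderBlock), 0L)
})

test_that("audit table exports round-trip through CSV and JSON", {
  g <- tinyGraph()
  tab <- auditTable(g)
  expect_named(tab, c("Block", "Name", "Filters", "Dimensions", "Params",
                      "Operation"))
  expect_equal(sum(tab$Name == "Multi-Res Block"), 10)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeAuditTable(g, csv)
  writeAuditTable(g, js)
  expect_equal(read.csv(csv, colClasses = "character")$Dimensions,
               tab$Dimensions)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$Params,
               tab$Params)
})
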