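#' Create a model configuration
#'
#' @param inputHeight,inputWidth input dims in pixels, each divisible by 16.
#' @param inputChannels number of input channels.
#' @param filterSchedule 5 strictly increasing filter counts, one per encoder
#'   level; the default doubles from 32 to 512.
#' @param attentionInter channel width of the attention gates' 1x1 projection.
#' @param blockVariant `"canonical"` or `"table_audit"` (see
#'   [ModelConfig-class]).
#' @param upsampleMode `"bilinear"` or `"transpose"`.
#' @param seed weight-initialisation seed.
#' @return a validated [ModelConfig-class].
#' @examples
#' cfg <- modelConfig(256, 256)
#' cfg
#' @export
modelConfig <- function(inputHeight = 256L, inputWidth = 256L,
                        inputChannels = 1L,
                        filterSchedule = c(32L, 64L, 128L, 256L, 512L),
                        attentionInter = 32L,
                        blockVariant = c("canonical", "table_audit"),
                        upsampleMode = c("bilinear", "transpose"),
                        seed = 1L) {
  for (d in c(inputHeight, inputWidth)) {
    if (d %% 16 != 0)
      stop(sprintf("input dimension %d is not divisible by 16 (four 2x2 poolings)", d))
  }
  new("ModelConfig",
      inputHeight = asInt(inputHeight), inputWidth = asInt(inputWidth),
      inputChannels = asInt(inputChannels),
      filterSchedule = asInt(filterSchedule),
      attentionInter = asInt(attentionInter),
      blockVariant = match.arg(blockVariant),
      upsampleMode = match.arg(upsampleMode), seed = asInt(seed))
}

newBlock <- function(block, name, kind, stage, filters, inC, outC, h, w, inter) {
  data.frame(block = block, name = name, kind = kind, stage = stage,
             filters = filters, inChannels = inC, outChannels = outC,
             outHeight = h, outWidth = w,
             paramsAudit = countParams(
               list(kind = kind, inChannels = inC, outChannels = outC),
               "table_audit", attentionInter = inter),
             paramsCanonical = countParams(
               list(kind = kind, inChannels = inC, outChannels = outC),
               "canonical", attentionInter = inter),
             stringsAsFactors = FALSE)
}

#' Assemble the attention-gated MultiRes U-Net graph
#'
#' Builds the declarative block graph: five encoder stages (MultiRes block +
#' attention gate, with a 2x2 maxpool after stages 1-4), four upsampling
#' decoder blocks (bilinear upsample, MultiRes channel reduction, then the
#' attention gate that fuses the matching encoder skip as the elementwise
#' convex combination `a*x + (1-a)*x_up`), a final same-resolution MultiRes
#' refinement block with a self-paired (identity) gate, and a 1x1 output
#' convolution with sigmoid activation.
#'
#' @param config a [ModelConfig-class].
#' @return a validated [ModelGraph-class].
#' @examples
#' g <- assembleModel(modelConfig(256, 256))
#' head(inferShapes(g))
#' @export
assembleModel <- function(config) {
  validObject(config)
  f <- config@filterSchedule
  inter <- config@attentionInter
  H <- config@inputHeight; W <- config@inputWidth
  rows <- list()
  h <- H; w <- W; cin <- config@inputChannels
  for (i in 1:5) {
    lab <- sprintf("Encoder Block %d", i)
    rows[[length(rows) + 1L]] <-
      newBlock(lab, "Multi-Res Block", "multires", i, f[i], cin, f[i], h, w, inter)
    rows[[length(rows) + 1L]] <-
      newBlock(lab, "Attention Gate", "attention_gate", i, NA, f[i], f[i], h, w, inter)
    if (i < 5) {
      h <- h %/% 2L; w <- w %/% 2L
      rows[[length(rows) + 1L]] <-
        newBlock(lab, "Maxpool 2 x 2", "maxpool", i, NA, f[i], f[i], h, w, inter)
    }
    cin <- f[i]
  }
  # decoder blocks labelled 5..2 (deepest first, matching the layer table)
  curC <- f[5]
  for (j in 5:2) {
    lev <- j - 1L                       # encoder level this block restores
    lab <- sprintf("Decoder Block %d", j)
    h <- h * 2L; w <- w * 2L
    rows[[length(rows) + 1L]] <-
      newBlock(lab, "UpSample 2 x 2", "upsample", j, NA, curC, curC, h, w, inter)
    rows[[length(rows) + 1L]] <-
      newBlock(lab, "Multi-Res Block", "multires", j, f[lev], curC, f[lev], h, w, inter)
    rows[[length(rows) + 1L]] <-
      newBlock(lab, "Attention Gate", "attention_gate", j, NA, f[lev], f[lev], h, w, inter)
    curC <- f[lev]
  }
  rows[[length(rows) + 1L]] <-
    newBlock("Decoder Block 1", "Multi-Res Block", "multires", 1L, f[1], f[1], f[1], h, w, inter)
  rows[[length(rows) + 1L]] <-
    newBlock("Decoder Block 1", "Attention Gate", "attention_gate", 1L, NA, f[1], f[1], h, w, inter)
  rows[[length(rows) + 1L]] <-
    newBlock("Output", "Conv 1 x 1", "output_conv", 0L, 1L, f[1], 1L, h, w, inter)
  blocks <- do.call(rbind, rows)
  skips <- data.frame(encoderStage = 4:1, decoderBlock = 5:2)
  new("ModelGraph", config = config, blocks = blocks, skips = skips)
}

#' Count trainable parameters of one block
#'
#' Under `"table_audit"`, a MultiRes block is counted as a single 3x3
#' convolution `inChannels -> outChannels` with additive bias
#' (`9*ic*oc + oc`), an attention gate as one bias-free 1x1 projection
#' `inChannels -> attentionInter` (`ic * inter`), and pooling/bilinear
#' upsampling as 0: this is the reading under which the reference layer
#' table's printed counts are reproducible. Under `"canonical"`, the full
#' block is counted: three serial biased 3x3 convolutions with output filters
#' allocated as near-equal thirds (remainder to the last), batch
#' normalisation (2 parameters per channel) after each, plus the 1x1 residual
#' projection with its own batch norm.
#'
#' @param block a one-row data.frame or list with fields `kind`,
#'   `inChannels`, `outChannels`.
#' @param interpretation `"table_audit"` or `"canonical"`.
#' @param attentionInter gate projection width (default 32).
#' @return integer parameter count.
#' @examples
#' countParams(list(kind = "multires", inChannels = 64, outChannels = 128),
#'             "table_audit")  # 73856
#' @export
countParams <- function(block, interpretation = c("table_audit", "canonical"),
                        attentionInter = 32L) {
  interpretation <- match.arg(interpretation)
  kind <- block$kind
  ic <- as.numeric(block$inChannels)
  oc <- as.numeric(block$outChannels)
  if (kind %in% c("maxpool", "upsample")) return(0L)
  if (kind == "attention_gate") return(asInt(ic * attentionInter))
  if (kind == "output_conv") return(asInt(ic * oc + oc))
  if (kind != "multires") stop(sprintf("unknown block kind '%s'", kind))
  if (interpretation == "table_audit") return(asInt(9 * ic * oc + oc))
  t <- filterThirds(oc)
  convs <- 9 * ic * t[1] + t[1] + 9 * t[1] * t[2] + t[2] + 9 * t[2] * t[3] + t[3]
  bns <- 2 * sum(t) + 2 * oc
  res <- ic * oc + oc
  asInt(convs + bns + res)
}

# output-filter allocation of the three serial convolutions
filterThirds <- function(out) {
  t1 <- out %/% 3L
  c(t1, t1, out - 2L * t1)
}

#' @describeIn inferShapes shape records for every block of the graph.
#' @export
setMethod("inferShapes", "ModelGraph", function(object, ...) {
  b <- object@blocks
  data.frame(block = b$block, name = b$name, stage = b$stage,
             height = b$outHeight, width = b$outWidth,
             channels = b$outChannels, stringsAsFactors = FALSE)
})

#' @describeIn auditTable layer table under the table-audit interpretation.
#' @param interpretation which parameter accounting to print.
#' @export
setMethod("auditTable", "ModelGraph", function(object,
    interpretation = c("table_audit", "canonical"), ...) {
  interpretation <- match.arg(interpretation)
  b <- object@blocks
  params <- if (interpretation == "table_audit") b$paramsAudit else b$paramsCanonical
  op <- c(multires = "Convolution", attention_gate = "Attention",
          maxpool = "Pooling", upsample = "Up-sampling",
          output_conv = "Convolution")[b$kind]
  data.frame(Block = b$block, Name = b$name,
             Filters = ifelse(is.na(b$filters), "-", as.character(b$filters)),
             Dimensions = sprintf("%d x %d x %d", b$outHeight, b$outWidth,
                                  b$outChannels),
             Params = ifelse(params == 0, "-", format(params, big.mark = ",",
                                                      trim = TRUE)),
             Operation = unname(op), stringsAsFactors = FALSE)
})

#' Write the audit table to disk
#'
#' @param graph a [ModelGraph-class].
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @param interpretation parameter accounting to export.
#' @return the exported data.frame, invisibly.
#' @export
writeAuditTable <- function(graph, path,
                            interpretation = c("table_audit", "canonical")) {
  tab <- auditTable(graph, match.arg(interpretation))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(tab)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %d x %d x %d input\n", object@inputHeight,
              object@inputWidth, object@inputChannels))
  cat("  filters:", paste(object@filterSchedule, collapse = "-"),
      " gate width:", object@attentionInter, "\n")
  cat("  variant:", object@blockVariant, " upsample:", object@upsampleMode,
      " seed:", object@seed, "\n")
})

setMethod("show", "ModelGraph", function(object) {
  b <- object@blocks
  cat(sprintf("ModelGraph: %d blocks (%d MultiRes, %d attention gates)\n",
              nrow(b), sum(b$kind == "multires"),
              sum(b$kind == "attention_gate")))
  cat(sprintf("  input %d x %d, bottleneck %d x %d x %d\n",
              object@config@inputHeight, object@config@inputWidth,
              b$outHeight[b$block == "Encoder Block 5" & b$kind == "multires"],
              b$outWidth[b$block == "Encoder Block 5" & b$kind == "multires"],
              b$outChannels[b$block == "Encoder Block 5" & b$kind == "multires"]))
  cat(sprintf("  trainable params (canonical): %s; (table audit): %s\n",
              format(sum(b$paramsCanonical), big.mark = ","),
              format(sum(b$paramsAudit), big.mark = ",")))
})
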