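test_that("splitDataset reproduces the 85/15 arithmetic and partitions", {
  sp <- splitDataset(697, 0.85, seed = 1L)
  expect_length(sp$train, 592)
  expect_length(sp$eval, 105)
  sp2 <- splitDataset(100, 0.85, seed = 2L)
  expect_equal(lengths(sp2), c(train = 85L, eval = 15L))
  expect_equal(sort(c(sp2$train, sp2$eval)), 1:100)
  expect_length(intersect(sp2$train, sp2$eval), 0)
  # stratified split respects totals and class balance
  labels <- rep(c("benign", "malignant", "normal"), c(40, 40, 20))
  sps <- splitDataset(100, 0.85, seed = 3L, labels = labels)
  expect_length(sps$train, 85)
  expect_equal(as.integer(table(labels[sps$train])), c(34L, 34L, 17L))
  expect_error(splitDataset(1, 0.85), "at least 2")
})

test_that("makeFolds builds near-equal disjoint folds", {
  p1 <- makeFolds(100, 5, seed = 1L)
  expect_equal(foldSizes(p1), rep(20L, 5))
  p2 <- makeFolds(103, 5, seed = 1L)
  expect_setequal(foldSizes(p2), c(21L, 20L))
  expect_equal(sort(foldSizes(p2)), c(20L, 20L, 21L, 21L, 21L))
  expect_equal(sort(unlist(lapply(1:5, function(f) foldIndices(p2, f)))), 1:103)
  expect_error(makeFolds(3, 5), "folds")
})

test_that("reduce-on-plateau halves only after a sustained plateau", {
  hp <- hyperparams(plateauPatience = 3L, plateauFactor = 0.5, minLr = 1e-4)
  st <- NULL
  for (loss in c(1, 0.9, 0.8, 0.7)) st <- reduceOnPlateau(loss, st, hp)
  expect_equal(st$lr, 0.001)
  for (loss in rep(0.7, 3)) st <- reduceOnPlateau(loss, st, hp)
  expect_equal(st$lr, 0.0005)
  # floor is respected under a continuing plateau
  for (i in 1:30) st <- reduceOnPlateau(0.7, st, hp)
  expect_equal(st$lr, 1e-4)
})

test_that("fitModel honours the epoch contract and the zero-lr limit", {
  g <- tinyGraph(size = 16L)
  samples <- quickPhantoms(8, seed = 50L, size = 16L)
  hp <- hyperparams(epochs = 1L, batchSize = 4L, seed = 1L)
  fit <- fitModel(g, samples, samples[1:2], hp)
  expect_equal(nrow(historyTable(fit$history)), 1)

  hp0 <- hyperparams(learningRate = 1e-300, epochs = 2L, batchSize = 4L,
                     seed = 1L)
  w0 <- initWeights(g, seed = 1L)
  fit0 <- fitModel(g, samples, samples[1:2], hp0, weights = w0)
  expect_equal(fit0$weights$enc1$conv1$W, w0$enc1$conv1$W, tolerance = 1e-12)
  h <- historyTable(fit0$history)
  # with frozen weights the recalibrated validation loss cannot move
  # (train loss varies slightly with the epoch's batch statistics)
  expect_equal(h$valLoss[1], h$valLoss[2], tolerance = 1e-10)
  expect_error(fitModel(g, list(), samples, hp), "empty")
})

test_that("training reduces the loss and is reproducible with a fixed seed", {
  g <- assembleModel(modelConfig(32, 32, filterSchedule = c(4L, 8L, 12L, 16L, 24L),
                                 seed = 2L))
  samples <- quickPhantoms(16, seed = 70L, size = 32L)
  hp <- hyperparams(epochs = 5L, batchSize = 8L, seed = 2L)
  fit <- fitModel(g, samples[1:12], samples[13:16], hp)
  h <- historyTable(fit$history)
  expect_lt(h$trainLoss[nrow(h)], h$trainLoss[1])
  expect_true(all(diff(h$lr) <= 1e-12))
  fit2 <- fitModel(g, samples[1:12], samples[13:16], hp)
  expect_equal(historyTable(fit2$history)$trainLoss, h$trainLoss,
               tolerance = 1e-12)
})

test_that("cross-validation aggregates exactly the fold plan's held-out sets", {
  g <- tinyGraph(size = 16L)
  samples <- quickPhantoms(12, seed = 90L, size = 16L)
  hp <- hyperparams(epochs = 2L, batchSize = 4L, seed = 3L)
  rep2 <- crossValidate(samples, 2L, g, hp)
  expect_s4_class(rep2, "MetricReport")
  expect_equal(rep2@nFolds, 2L)
  pf <- perFoldMetrics(rep2)
  expect_true(all(pf[, c("acc", "sen", "spe", "pre", "f1", "dice", "auc")] >= 0 & pf[, c("acc", "sen", "spe", "pre", "f1", "dice", "auc")] <= 1,
                  na.rm = TRUE))
  plan <- attr(rep2, "plan")
  expect_s4_class(plan, "FoldPlan")
  expect_equal(sort(unlist(lapply(1:2, function(f) foldIndices(plan, f)))),
               1:12)
  # the plan is the one implied by the hyperparameter seed
  expect_equal(plan@assignment, makeFolds(12, 2, seed = hp@seed)@assignment)
})
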