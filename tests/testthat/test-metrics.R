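test_that("bceLoss matches analytic values and the summation oracle", {
  expect_lt(bceLoss(c(1, 1, 0), c(1 - 1e-7, 1 - 1e-7, 1e-7)), 1e-5)
  expect_equal(bceLoss(matrix(c(1, 0, 1, 0), 2), matrix(0.5, 2, 2)), log(2))
  expect_equal(bceLoss(c(1, 0, 1), c(0.9, 0.2, 0.8)), 0.18388, tolerance = 1e-4)
  for (s in 1:200) {
    set.seed(s)
    n <- sample(2:30, 1)
    y <- rbinom(n, 1, 0.5)
    p <- runif(n)
    expect_equal(bceLoss(y, p), bceOracle(y, p), tolerance = 1e-12)
  }
  expect_error(bceLoss(numeric(0), numeric(0)), "empty")
})

test_that("over constant predictors, BCE is minimised at the foreground rate", {
  y <- c(rep(1, 3), rep(0, 7))
  grid <- seq(0.01, 0.99, by = 0.01)
  losses <- vapply(grid, function(q) bceLoss(y, rep(q, 10)), numeric(1))
  expect_equal(grid[which.min(losses)], 0.3)
})

test_that("confusion tallies agree with exhaustive enumeration", {
  m <- matrix(0, 10, 10); m[1, 1:10] <- 1
  cc <- confusion(m, m)
  expect_equal(c(cc@tp, cc@tn, cc@fp, cc@fn), c(10, 90, 0, 0))
  cc2 <- confusion(matrix(0, 2, 4), matrix(c(1, 1, 1, 0, 0, 0, 0, 0), 2, 4))
  expect_equal(c(cc2@tp, cc2@fn, cc2@tn, cc2@fp), c(0, 3, 5, 0))
  for (s in 1:200) {
    set.seed(s)
    pred <- matrix(rbinom(16, 1, 0.5), 4, 4)
    truth <- matrix(rbinom(16, 1, 0.5), 4, 4)
    cc <- confusion(pred, truth)
    o <- confusionOracle(pred, truth)
    expect_equal(c(cc@tp, cc@tn, cc@fp, cc@fn), unname(o[c("tp", "tn", "fp", "fn")]))
    expect_equal(cc@tp + cc@tn + cc@fp + cc@fn, 16)
  }
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "dims")
})

test_that("basicMetrics implements the confusion formulas with fallbacks", {
  m <- basicMetrics(new("ConfusionCounts", tp = 8, fp = 2, fn = 5, tn = 85))
  expect_equal(unname(m["pre"]), 0.8)
  expect_equal(unname(m["sen"]), 8 / 13, tolerance = 1e-4)
  expect_equal(unname(m["f1"]), 16 / 23, tolerance = 1e-4)
  expect_equal(unname(m["acc"]), 0.93)
  perfect <- basicMetrics(new("ConfusionCounts", tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(perfect == 1))
  allneg <- basicMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 3, tn = 7))
  expect_equal(unname(allneg["sen"]), 0)
  expect_equal(unname(allneg["pre"]), 0)
})

test_that("sensitivity and specificity swap under joint label complement", {
  for (s in 1:50) {
    set.seed(s)
    pred <- matrix(rbinom(25, 1, 0.4), 5, 5)
    truth <- matrix(rbinom(25, 1, 0.4), 5, 5)
    if (sum(truth) %in% c(0, 25)) next
    m1 <- basicMetrics(confusion(pred, truth))
    m2 <- basicMetrics(confusion(1 - pred, 1 - truth))
    expect_equal(unname(m1["sen"]), unname(m2["spe"]))
    expect_equal(unname(m1["spe"]), unname(m2["sen"]))
  }
})

test_that("dice matches set overlap and equals F1 numerically", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1 - a), 0)
  expect_equal(dice(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  for (s in 1:200) {
    set.seed(s)
    pred <- matrix(rbinom(36, 1, runif(1)), 6, 6)
    truth <- matrix(rbinom(36, 1, runif(1)), 6, 6)
    d <- dice(pred, truth)
    f1 <- unname(basicMetrics(confusion(pred, truth))["f1"])
    expect_equal(d, f1, tolerance = 1e-12)
  }
})

test_that("rank AUC equals exhaustive pair enumeration and is monotone-invariant", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  for (s in 1:200) {
    set.seed(s)
    n <- sample(4:20, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))   # both classes guaranteed
    probs <- round(runif(n), 2)               # ties likely
    expect_equal(rocAuc(probs, truth), aucOracle(probs, truth))
    expect_equal(rocAuc(qlogis(pmin(pmax(probs, 0.01), 0.99)), truth),
                 rocAuc(pmin(pmax(probs, 0.01), 0.99), truth))
  }
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("fold aggregation reproduces independent mean/sd recomputation", {
  r <- metricReport(c(acc = 0.9, sen = 0.8, spe = 0.95, pre = 0.7, f1 = 0.74,
                      dice = 0.74, auc = 0.9))
  same <- aggregateFolds(list(r, r, r))
  expect_equal(unname(same@sd["dice"]), 0)
  expect_equal(same@nFolds, 3L)
  two <- aggregateFolds(list(metricReport(c(dice = 0.9)),
                             metricReport(c(dice = 0.94))))
  expect_equal(unname(two@mean["dice"]), 0.92)
  set.seed(4)
  vals <- replicate(5, runif(7), simplify = FALSE)
  reps <- lapply(vals, function(v) metricReport(setNames(v, c("acc", "sen",
    "spe", "pre", "f1", "dice", "auc"))))
  agg <- aggregateFolds(reps)
  mat <- do.call(rbind, vals)
  expect_equal(unname(agg@mean), unname(colMeans(mat)))
  expect_equal(unname(agg@sd), unname(apply(mat, 2, sd)))
  expect_error(aggregateFolds(list()), "no reports")
})

test_that("metric reports round-trip to CSV and JSON with summary rows", {
  r <- aggregateFolds(list(metricReport(c(dice = 0.9, acc = 0.95)),
                           metricReport(c(dice = 0.94, acc = 0.97))))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeMetricReport(r, csv)
  writeMetricReport(r, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 4)   # 2 folds + mean + sd
  expect_equal(tab$dice[tab$fold == "mean"], 0.92)
  jj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(jj$dice[jj$fold == "sd"], sd(c(0.9, 0.94)), tolerance = 1e-12)
})
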