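# small separable toy: positives around (1,1), negatives around (0,0)
separable_toy <- function(n = 40, jitter = 0.1, seed = 2) {
  set.seed(seed)
  y <- rep(c(1L, -1L), each = n / 2)
  x <- cbind(f1 = ifelse(y == 1, 1, 0) + runif(n, -jitter, jitter),
             f2 = ifelse(y == 1, 1, 0) + runif(n, -jitter, jitter))
  list(x = x, y = y)
}

test_that("undersampling keeps all positives and hits the ratio", {
  y <- c(rep(1, 10), rep(-1, 100))
  keep <- undersampleNegatives(y, ratio = 1, seed = 4)
  expect_equal(sum(y[keep] == 1), 10)
  expect_equal(sum(y[keep] == -1), 10)
  expect_true(all(which(y == 1) %in% keep))
  # cap rule: fewer negatives than the target keeps them all
  y2 <- c(rep(1, 10), rep(-1, 5))
  expect_equal(sort(undersampleNegatives(y2, 1, seed = 4)), 1:15)
  # non-unit ratios
  keep3 <- undersampleNegatives(y, ratio = 3, seed = 4)
  expect_equal(sum(y[keep3] == -1), 30)
  expect_error(undersampleNegatives(rep(-1, 5), 1, 1), "no positive")
})

test_that("undersampling is deterministic per seed and varies across seeds", {
  y <- c(rep(1, 10), rep(-1, 100))
  expect_identical(undersampleNegatives(y, 1, seed = 9),
                   undersampleNegatives(y, 1, seed = 9))
  sets <- vapply(1:20, function(s)
    paste(undersampleNegatives(y, 1, seed = s), collapse = ","), character(1))
  expect_gt(length(unique(sets)), 15)
})

test_that("fold sizes differ by at most one unit (pigeonhole)", {
  fold <- makeFolds(103, 10, seed = 1)
  expect_equal(sort(as.integer(table(fold)), decreasing = TRUE),
               c(11L, 11L, 11L, rep(10L, 7)))
  expect_equal(length(fold), 103)
  expect_error(makeFolds(5, 10), "more folds")
})

test_that("protein-level folds never split a protein", {
  groups <- rep(paste0("p", 1:10), each = 20)
  fold <- makeFolds(200, 10, "protein", groups = groups, seed = 3)
  expect_equal(as.integer(table(fold)), rep(20L, 10))
  for (cfg in 1:50) {
    set.seed(cfg)
    np <- sample(5:15, 1)
    sizes <- sample(3:30, np, replace = TRUE)
    g <- rep(paste0("q", seq_len(np)), times = sizes)
    k <- sample(2:np, 1)
    f <- makeFolds(length(g), k, "protein", groups = g, seed = cfg)
    expect_true(all(tapply(f, g, function(v) length(unique(v))) == 1L))
    # fold sizes in protein units differ by <= 1
    per_fold <- tapply(g, f, function(v) length(unique(v)))
    expect_lte(diff(range(per_fold)), 1L)
  }
})

test_that("a separable toy is fit perfectly and recalled exactly", {
  toy <- separable_toy()
  cfg <- stackerConfig(seed = 1, tune = "none", fixedCost = 10)
  model <- trainStacker(toy$x, toy$y, cfg)
  p <- predict(model, toy$x)
  expect_equal(p$call, toy$y)
  expect_equal(model@composition$positives, 20)
  expect_equal(model@composition$negativesAfter, 20)
})

test_that("prediction is deterministic and row-order equivariant", {
  toy <- separable_toy(60)
  model <- trainStacker(toy$x, toy$y, stackerConfig(seed = 5, tune = "none"))
  p1 <- predict(model, toy$x)
  p2 <- predict(model, toy$x)
  expect_identical(p1$score, p2$score)
  perm <- sample.int(60)
  p3 <- predict(model, toy$x[perm, ])
  expect_equal(p3$score, p1$score[perm])
})

test_that("column mismatches and empty feature sets are rejected", {
  toy <- separable_toy()
  model <- trainStacker(toy$x, toy$y, stackerConfig(seed = 1, tune = "none"))
  xx <- toy$x
  colnames(xx) <- c("f2", "f1")
  expect_error(predict(model, xx), "feature columns")
  expect_error(predict(model, toy$x[0, , drop = FALSE]), "empty")
  expect_error(predict(model, toy$x[, 1, drop = FALSE]), "feature column")
})

test_that("training rejects degenerate label sets", {
  toy <- separable_toy()
  expect_error(trainStacker(toy$x, rep(-1, 40), stackerConfig()),
               "no positive")
  expect_error(trainStacker(toy$x, rep(1, 40), stackerConfig()),
               "single-class")
})

test_that("a perfectly informative feature yields perfect pooled CV", {
  set.seed(12)
  y <- rbinom(400, 1, 0.25)
  x <- cbind(oracle = y, noise = runif(400))
  cv <- crossValidate(x, y, config = stackerConfig(nFolds = 10, seed = 2,
                                                   tune = "none",
                                                   fixedCost = 10))
  v <- metricValues(pooledMetrics(cv))
  expect_equal(v[["sensitivity"]], 1)
  expect_equal(v[["specificity"]], 1)
})

test_that("label-independent features cross-validate to chance strength", {
  strengths <- vapply(1:10, function(s) {
    set.seed(s)
    y <- rbinom(1200, 1, 0.25)
    x <- matrix(runif(1200 * 4), ncol = 4,
                dimnames = list(NULL, paste0("n", 1:4)))
    cv <- crossValidate(x, y, config = stackerConfig(nFolds = 5, seed = s,
                                                     tune = "none"))
    metricValues(pooledMetrics(cv))[["strength"]]
  }, numeric(1))
  expect_true(all(abs(strengths - 0.5) < 0.07))
  expect_lt(abs(mean(strengths) - 0.5), 0.03)
})

test_that("cross-validation conserves rows and never undersamples tests", {
  sim <- simulateStackingDataset(n = 2500, seed = 31)
  cfg <- stackerConfig(nFolds = 5, seed = 31, tuneMax = 600)
  cv <- crossValidate(sim$features, sim$labels, config = cfg)
  fr <- foldReport(cv)
  # every row in exactly one test fold; pooled cells cover the dataset
  expect_equal(sum(fr$nTest), 2500)
  expect_equal(sort(unique(cv@foldAssign)), 1:5)
  expect_equal(unname(sum(countCells(pooledCounts(cv)))), 2500)
  # test folds evaluated at natural imbalance
  expect_equal(fr$testPositives + fr$testNegatives, fr$nTest)
  expect_equal(sum(fr$testPositives), sum(sim$labels))
  # training portions rebalanced to 1:1
  expect_equal(fr$trainNegativesAfter, fr$trainPositives)
  expect_true(all(fr$trainNegativesBefore > fr$trainNegativesAfter))
})

test_that("the whole CV run is reproducible bit-for-bit at count level", {
  sim <- simulateStackingDataset(n = 2000, seed = 8)
  cfg <- stackerConfig(nFolds = 5, seed = 8, tuneMax = 500)
  cv1 <- crossValidate(sim$features, sim$labels, config = cfg)
  cv2 <- crossValidate(sim$features, sim$labels, config = cfg)
  expect_identical(foldReport(cv1), foldReport(cv2))
  expect_identical(countCells(pooledCounts(cv1)), countCells(pooledCounts(cv2)))
})

test_that("model artifacts round-trip through serialization", {
  toy <- separable_toy()
  model <- trainStacker(toy$x, toy$y, stackerConfig(seed = 1, tune = "none"))
  f <- tempfile(fileext = ".rds")
  saveStackerModel(model, f)
  back <- readStackerModel(f)
  expect_identical(predict(back, toy$x)$score, predict(model, toy$x)$score)
  expect_identical(back@featureOrder, model@featureOrder)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(readStackerModel(bad), "not a stacker model")
})

test_that("grid search selects hyperparameters and records the grid", {
  sim <- simulateStackingDataset(n = 1500, seed = 13)
  cfg <- stackerConfig(seed = 13, tuneMax = 400,
                       costGrid = c(0.5, 8), gammaGrid = c(0.125, 2))
  model <- trainStacker(sim$features, sim$labels, cfg)
  expect_true(model@cost %in% cfg@costGrid)
  expect_true(model@gamma %in% cfg@gammaGrid)
  expect_equal(nrow(model@tuning), 4)
  expect_true(all(is.finite(model@tuning$strength)))
})
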