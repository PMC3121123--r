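test_that("confusion tallies match direct definitions", {
  truth <- c(rep(1, 5), rep(0, 15))
  cc <- confusionCounts(truth, truth)
  expect_equal(countCells(cc), c(TP = 5, TN = 15, FP = 0, FN = 0))
  cc2 <- confusionCounts(1 - truth, truth)
  expect_equal(countCells(cc2), c(TP = 0, TN = 0, FP = 15, FN = 5))
})

test_that("confusion counts equal a brute-force element-wise tally", {
  set.seed(14)
  pred <- rbinom(100, 1, 0.4)
  truth <- rbinom(100, 1, 0.2)
  cc <- countCells(confusionCounts(pred, truth))
  tally <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:100) {
    cell <- if (pred[i] == 1 && truth[i] == 1) "TP"
    else if (pred[i] == 0 && truth[i] == 0) "TN"
    else if (pred[i] == 1 && truth[i] == 0) "FP" else "FN"
    tally[cell] <- tally[cell] + 1
  }
  expect_equal(cc, tally)
  expect_error(confusionCounts(pred, truth[1:50]), "equal length")
})

test_that("chance counts give sensitivity = specificity = 0.5 and zero MCC", {
  m <- metricValues(computeMetrics(confusionCountsFromCells(10, 30, 30, 10)))
  expect_equal(m[["sensitivity"]], 0.5)
  expect_equal(m[["specificity"]], 0.5)
  expect_equal(m[["strength"]], 0.5)
  expect_equal(m[["mcc"]], 0)
})

test_that("zero denominators flag measures as undefined, never 0", {
  ms <- computeMetrics(confusionCountsFromCells(0, 10, 0, 0))
  expect_false(metricDefined(ms)[["sensitivity"]])   # no positives at all
  expect_true(is.na(metricValues(ms)[["sensitivity"]]))
  expect_true(metricDefined(ms)[["specificity"]])
  expect_error(computeMetrics(confusionCountsFromCells(0, 0, 0, 0)),
               "all-zero")
})

test_that("MCC is symmetric under the TP<->TN, FP<->FN swap", {
  set.seed(6)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    a <- metricValues(computeMetrics(
      confusionCountsFromCells(cells[1], cells[2], cells[3], cells[4])))
    b <- metricValues(computeMetrics(
      confusionCountsFromCells(cells[2], cells[1], cells[4], cells[3])))
    expect_equal(a[["mcc"]], b[["mcc"]])
    expect_equal(a[["strength"]],
                 mean(a[c("sensitivity", "specificity")]))
  }
})

test_that("count reconstruction inverts the printed rates exactly", {
  cc <- reconstructCounts(1.0, 1.0, 10, 90)
  expect_equal(countCells(cc), c(TP = 10, TN = 90, FP = 0, FN = 0))
  set.seed(19)
  for (i in 1:20) {
    sens <- runif(1); spec <- runif(1)
    cc <- reconstructCounts(sens, spec, 500, 4000)
    v <- metricValues(computeMetrics(cc))
    expect_equal(v[["sensitivity"]], sens)
    expect_equal(v[["specificity"]], spec)
  }
  expect_error(reconstructCounts(1.2, 0.5, 10, 10), "rates")
  expect_error(reconstructCounts(0.5, 0.5, 0, 10), "totals")
})

test_that("published rows reconstruct their printed strength and MCC", {
  bm <- publishedBenchmark()
  expect_equal(bm$positives, 5342)
  expect_equal(bm$negatives, 67396)
  grid <- checkBenchmarkTable(bm)
  for (m in c("strength", "mcc"))
    expect_true(all(grid$match[grid$measure == m]),
                info = paste("measure:", m))
  # spot values: the meta row rounds to 0.32 MCC / 0.33 F; a 0.54/0.80 row
  # gives strength 0.67; a 0.19/0.98 row gives accuracy 0.92
  meta <- grid[grid$method == "meta", ]
  expect_equal(meta$reconstructed[meta$measure == "mcc"], 0.32)
  expect_equal(meta$reconstructed[meta$measure == "f_measure"], 0.33)
  expect_equal(grid$reconstructed[grid$method == "bindn" &
                                    grid$measure == "strength"], 0.67)
  expect_equal(grid$reconstructed[grid$method == "disis" &
                                    grid$measure == "accuracy"], 0.92)
  expect_equal(grid$reconstructed[grid$method == "dpbind" &
                                    grid$measure == "mcc"], 0.29)
})

test_that("accuracy reconstructs for all rows but one known rounding clash", {
  grid <- checkBenchmarkTable()
  acc <- grid[grid$measure == "accuracy", ]
  expect_true(all(acc$match[acc$method != "dbs_pred"]))
  # the printed rates of that row are themselves rounded; the cells they
  # imply give 0.7431, one count short of the printed 0.75
  expect_equal(acc$reconstructed[acc$method == "dbs_pred"], 0.74)
})

test_that("half-up rounding behaves at the .5 boundary", {
  expect_equal(roundHalfUp(0.645), 0.65)
  expect_equal(roundHalfUp(0.644999), 0.64)
  expect_equal(roundHalfUp(-0.645), -0.65)
  expect_equal(roundHalfUp(c(0.125, 0.135), 2), c(0.13, 0.14))
})

test_that("metric report TSV mirrors the conventional column order", {
  ms <- computeMetrics(reconstructCounts(0.77, 0.77, 5342, 67396))
  f <- tempfile(fileext = ".tsv")
  writeMetricsReport(list(meta = ms), f)
  d <- read.delim(f)
  expect_named(d, c("method", "accuracy", "sensitivity", "specificity",
                    "strength", "mcc", "f_measure"))
  expect_equal(roundHalfUp(d$mcc), 0.32)
})
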