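# run expr with a fixed RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

#' Build a stacker training configuration
#'
#' @param nFolds cross-validation folds (default 10).
#' @param ratio negatives per positive retained by undersampling
#'   (default 1, i.e. a balanced 1:1 training set).
#' @param seed integer seed; undersampling, fold assignment and tuning all
#'   derive their streams from it.
#' @param foldUnit \code{"residue"} (rows partitioned directly) or
#'   \code{"protein"} (whole proteins kept within one fold; avoids
#'   same-protein leakage and requires \code{groups} at fit time).
#' @param costGrid,gammaGrid hyperparameter grid searched by internal
#'   cross-validation on strength (defaults: cost 2^-3..2^7, kernel width
#'   2^-7..2^3, in steps of 2^2).
#' @param tune \code{"once"}, \code{"per-fold"} or \code{"none"}; see
#'   [StackerConfig].
#' @param innerFolds folds of the tuning cross-validation (default 3).
#' @param tuneMax row cap for the tuning search (default 1500).
#' @param fixedCost,fixedGamma used when \code{tune = "none"} (gamma
#'   default 1/ncol at fit time when NA).
#' @return a [StackerConfig].
#' @export
stackerConfig <- function(nFolds = 10L, ratio = 1, seed = 1L,
                          foldUnit = c("residue", "protein"),
                          costGrid = 2^seq(-3, 7, by = 2),
                          gammaGrid = 2^seq(-7, 3, by = 2),
                          tune = c("once", "per-fold", "none"),
                          innerFolds = 3L, tuneMax = 1500L,
                          fixedCost = 1, fixedGamma = NA_real_) {
  new("StackerConfig", nFolds = as.integer(nFolds), ratio = ratio,
      seed = as.integer(seed), foldUnit = match.arg(foldUnit),
      costGrid = costGrid, gammaGrid = gammaGrid, tune = match.arg(tune),
      innerFolds = as.integer(innerFolds), tuneMax = as.integer(tuneMax),
      fixedCost = fixedCost, fixedGamma = fixedGamma)
}

#' Undersample negative rows to a target class ratio
#'
#' A heavily imbalanced training set (roughly 1:12 binding to non-binding
#' residues) drives a maximum-margin classifier towards the all-negative
#' rule, so training sets are rebalanced by discarding a random selection
#' of the negatives. All positives are always retained; negatives are
#' drawn uniformly without replacement down to
#' \code{ceiling(ratio * positives)}, capped at the number available.
#'
#' @param labels vector coded 0/1 or -1/+1.
#' @param ratio negatives retained per positive (default 1).
#' @param seed integer seed; the retained set is a deterministic function
#'   of (labels, ratio, seed).
#' @return sorted integer vector of retained row indices.
#' @export
undersampleNegatives <- function(labels, ratio = 1, seed = 1L) {
  y <- .as_pm1(labels)
  pos <- which(y == 1L)
  neg <- which(y == -1L)
  .stop_if(!length(pos), "degenerate training set: no positive samples")
  .stop_if(ratio <= 0, "ratio must be > 0")
  target <- min(length(neg), ceiling(ratio * length(pos)))
  kept_neg <- if (target == length(neg)) neg else
    .with_seed(seed, sample(neg, target))
  sort(c(pos, kept_neg))
}

#' Assign rows to cross-validation folds
#'
#' Partitions rows into \code{k} roughly equal folds (sizes differing by
#' at most one unit). In residue mode rows are partitioned directly; in
#' protein mode whole proteins are assigned to folds, so no protein's
#' residues ever span two folds.
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param foldUnit \code{"residue"} or \code{"protein"}.
#' @param groups protein identifier per row (required in protein mode).
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), length n.
#' @export
makeFolds <- function(n, k, foldUnit = c("residue", "protein"),
                      groups = NULL, seed = 1L) {
  foldUnit <- match.arg(foldUnit)
  n <- as.integer(n)
  k <- as.integer(k)
  if (foldUnit == "residue") {
    .stop_if(k > n, "more folds (", k, ") than rows (", n, ")")
    fold <- integer(n)
    perm <- .with_seed(seed, sample.int(n))
    fold[perm] <- rep(seq_len(k), length.out = n)
    fold
  } else {
    .stop_if(is.null(groups), "protein mode requires groups")
    .stop_if(length(groups) != n, "one group per row is required")
    g <- unique(groups)
    .stop_if(k > length(g), "more folds (", k, ") than proteins (",
             length(g), ")")
    perm <- .with_seed(seed, sample(g))
    gf <- rep(seq_len(k), length.out = length(g))
    names(gf) <- perm
    unname(gf[as.character(groups)])
  }
}

.feature_matrix_of <- function(features) {
  if (is(features, "FeatureMatrix")) featureValues(features)
  else as.matrix(features)
}

.fit_svm <- function(x, y, cost, gamma) {
  e1071::svm(x, factor(y, levels = c(-1L, 1L)), type = "C-classification",
             kernel = "radial", cost = cost, gamma = gamma, scale = FALSE)
}

.svm_decision <- function(fit, x) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  score <- as.numeric(dv[, 1])
  # libsvm's decision sign favours the first training class; normalise so
  # that positive score always means the +1 class
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first != "1") score <- -score
  list(call = ifelse(score > 0, 1L, -1L), score = score)
}

.pooled_strength <- function(tp, tn, fp, fn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  (sens + spec) / 2
}

# grid search over (cost, gamma) by internal CV on strength
.tune_svm <- function(x, y, config, seed) {
  n <- nrow(x)
  idx <- seq_len(n)
  if (n > config@tuneMax)
    idx <- sort(.with_seed(seed, sample.int(n, config@tuneMax)))
  xs <- x[idx, , drop = FALSE]
  ys <- y[idx]
  k <- min(config@innerFolds, sum(ys == 1L), sum(ys == -1L))
  .stop_if(k < 2L, "too few samples per class for tuning")
  fold <- makeFolds(length(ys), k, "residue", seed = .substream_seed(seed, 7L))
  grid <- expand.grid(cost = config@costGrid, gamma = config@gammaGrid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$strength <- NA_real_
  for (i in seq_len(nrow(grid))) {
    tp <- tn <- fp <- fn <- 0
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(ys[tr])) < 2L) { ok <- FALSE; break }
      fit <- .fit_svm(xs[tr, , drop = FALSE], ys[tr], grid$cost[i],
                      grid$gamma[i])
      cl <- .svm_decision(fit, xs[!tr, , drop = FALSE])$call
      yt <- ys[!tr]
      tp <- tp + sum(cl == 1L & yt == 1L)
      tn <- tn + sum(cl == -1L & yt == -1L)
      fp <- fp + sum(cl == 1L & yt == -1L)
      fn <- fn + sum(cl == -1L & yt == 1L)
    }
    if (ok) grid$strength[i] <- .pooled_strength(tp, tn, fp, fn)
  }
  best <- which.max(grid$strength)
  .stop_if(!length(best), "tuning failed on every grid point")
  list(cost = grid$cost[best], gamma = grid$gamma[best], grid = grid)
}

#' Train the RBF-kernel meta-classifier
#'
#' Rebalances the training rows by [undersampleNegatives()], selects the
#' cost and kernel-width hyperparameters by an internal cross-validated
#' grid search maximising strength (unless \code{tune = "none"}), and
#' fits a radial-basis-function SVM (via \pkg{e1071}/libsvm) with labels
#' encoded +1 (binding) / -1 (non-binding).
#'
#' @param features a [FeatureMatrix] or numeric matrix.
#' @param labels vector coded 0/1 or -1/+1, one per row.
#' @param config a [StackerConfig].
#' @return a [TrainedModel].
#' @export
trainStacker <- function(features, labels, config = stackerConfig()) {
  x <- .feature_matrix_of(features)
  y <- .as_pm1(labels)
  .stop_if(nrow(x) != length(y), "rows and labels disagree")
  keep <- undersampleNegatives(y, config@ratio, config@seed)
  xs <- x[keep, , drop = FALSE]
  ys <- y[keep]
  .stop_if(length(unique(ys)) < 2L,
           "single-class training set after undersampling")
  if (config@tune == "none") {
    cost <- config@fixedCost
    gamma <- if (is.na(config@fixedGamma)) 1 / ncol(x) else config@fixedGamma
    tuning <- data.frame()
  } else {
    sel <- .tune_svm(xs, ys, config, .substream_seed(config@seed, 11L))
    cost <- sel$cost
    gamma <- sel$gamma
    tuning <- sel$grid
  }
  fit <- .fit_svm(xs, ys, cost, gamma)
  new("TrainedModel", fit = fit, cost = cost, gamma = gamma,
      featureOrder = colnames(x) %||% character(),
      composition = list(positives = sum(ys == 1L),
                         negativesBefore = sum(y == -1L),
                         negativesAfter = sum(ys == -1L),
                         ratio = config@ratio),
      tuning = tuning)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict binding residues with a trained meta-classifier
#'
#' @param object a [TrainedModel].
#' @param features a [FeatureMatrix] or numeric matrix whose columns match
#'   the model's recorded feature order.
#' @return list with \code{call} (+1 binding / -1 non-binding per row) and
#'   \code{score} (real-valued decision value, positive towards binding).
#' @export
setMethod("predict", "TrainedModel", function(object, features) {
  x <- .feature_matrix_of(features)
  .stop_if(!nrow(x), "empty feature set")
  if (length(object@featureOrder) && !is.null(colnames(x)))
    .stop_if(!identical(colnames(x), object@featureOrder),
             "feature columns do not match the model (expected: ",
             paste(object@featureOrder, collapse = ", "), ")")
  .stop_if(ncol(x) != ncol(object@fit$SV),
           "feature column count does not match the model")
  .svm_decision(object@fit, x)
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel (RBF SVM): cost=", object@cost, ", gamma=",
      object@gamma, "\n", sep = "")
  cat("  features:", paste(object@featureOrder, collapse = ", "), "\n")
  cmp <- object@composition
  cat("  training set: ", cmp$positives, " positives, ",
      cmp$negativesAfter, "/", cmp$negativesBefore,
      " negatives after undersampling (ratio ", cmp$ratio, ":1)\n",
      sep = "")
})

#' Cross-validate the meta-classifier
#'
#' Splits rows into \code{nFolds} folds (residue- or protein-level), and
#' for each fold trains on the remaining folds -- undersampling applied to
#' the training portion only -- then evaluates on the held-out fold at its
#' natural class imbalance. Confusion counts are summed over folds before
#' the pooled measures are computed. With the default \code{tune = "once"}
#' the hyperparameter grid is searched once on the first fold's training
#' portion and reused, so every fold sees an identical configuration.
#'
#' @inheritParams trainStacker
#' @param groups protein id per row, required when
#'   \code{config@foldUnit == "protein"}.
#' @return a [CrossValResult].
#' @export
crossValidate <- function(features, labels, groups = NULL,
                          config = stackerConfig()) {
  x <- .feature_matrix_of(features)
  y <- .as_pm1(labels)
  .stop_if(nrow(x) != length(y), "rows and labels disagree")
  k <- config@nFolds
  fold <- makeFolds(nrow(x), k, config@foldUnit, groups,
                    seed = .substream_seed(config@seed, 1L))

  sel <- NULL
  per_fold <- vector("list", k)
  hp <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    ytr <- y[tr]
    keep <- tr[undersampleNegatives(ytr, config@ratio,
                                    .substream_seed(config@seed, 100L + f))]
    .stop_if(length(unique(y[keep])) < 2L,
             "single-class training set in fold ", f)
    xs <- x[keep, , drop = FALSE]
    ys <- y[keep]
    if (config@tune == "none") {
      cost <- config@fixedCost
      gamma <- if (is.na(config@fixedGamma)) 1 / ncol(x) else config@fixedGamma
    } else if (config@tune == "per-fold" || is.null(sel)) {
      sel <- .tune_svm(xs, ys, config,
                       .substream_seed(config@seed, 200L + f))
      cost <- sel$cost
      gamma <- sel$gamma
    } else {
      cost <- sel$cost
      gamma <- sel$gamma
    }
    fit <- .fit_svm(xs, ys, cost, gamma)
    cl <- .svm_decision(fit, x[te, , drop = FALSE])$call
    yt <- y[te]
    per_fold[[f]] <- data.frame(
      fold = f, nTest = length(te),
      TP = sum(cl == 1L & yt == 1L), TN = sum(cl == -1L & yt == -1L),
      FP = sum(cl == 1L & yt == -1L), FN = sum(cl == -1L & yt == 1L),
      trainPositives = sum(ys == 1L),
      trainNegativesBefore = sum(ytr == -1L),
      trainNegativesAfter = sum(ys == -1L),
      testPositives = sum(yt == 1L), testNegatives = sum(yt == -1L))
    hp[[f]] <- list(cost = cost, gamma = gamma)
  }
  folds <- do.call(rbind, per_fold)
  for (m in .metric_names) folds[[m]] <- NA_real_
  for (f in seq_len(k)) {
    ms <- computeMetrics(confusionCountsFromCells(folds$TP[f], folds$TN[f],
                                                  folds$FP[f], folds$FN[f]))
    folds[f, .metric_names] <- metricValues(ms)
  }
  pooled <- confusionCountsFromCells(sum(folds$TP), sum(folds$TN),
                                     sum(folds$FP), sum(folds$FN))
  new("CrossValResult", folds = folds, pooled = pooled,
      pooledMetrics = computeMetrics(pooled), foldAssign = fold,
      composition = lapply(per_fold, function(d)
        d[, c("trainPositives", "trainNegativesBefore",
              "trainNegativesAfter", "testPositives", "testNegatives")]),
      hyperparameters = hp)
}

#' @describeIn crossValidate pooled [MetricSet] of a [CrossValResult].
#' @param cv a [CrossValResult].
#' @export
pooledMetrics <- function(cv) cv@pooledMetrics

#' @describeIn crossValidate pooled [ConfusionCounts].
#' @export
pooledCounts <- function(cv) cv@pooled

#' @describeIn crossValidate per-fold report data.frame.
#' @export
foldReport <- function(cv) cv@folds

setMethod("show", "CrossValResult", function(object) {
  cat("CrossValResult:", nrow(object@folds), "folds,",
      sum(object@folds$nTest), "rows\n")
  v <- metricValues(object@pooledMetrics)
  cat("  pooled:",
      paste(sprintf("%s=%.3f", names(v), v), collapse = " "), "\n")
})

#' Write the per-fold cross-validation report as TSV
#'
#' Columns: fold, TP, TN, FP, FN and the six measures.
#'
#' @param cv a [CrossValResult].
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeCVReport <- function(cv, file) {
  d <- foldReport(cv)[, c("fold", "TP", "TN", "FP", "FN", .metric_names)]
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Serialize / restore a trained model
#'
#' The artifact is a single RDS file holding a version header, the feature
#' column manifest, the selected hyperparameters, the training-set
#' composition record and the fitted SVM.
#'
#' @param model a [TrainedModel].
#' @param file artifact path.
#' @return \code{saveStackerModel}: invisibly, \code{file};
#'   \code{readStackerModel}: the restored [TrainedModel].
#' @export
saveStackerModel <- function(model, file) {
  saveRDS(list(format = "DNABindStack-model", version = 1L,
               featureOrder = model@featureOrder,
               cost = model@cost, gamma = model@gamma,
               composition = model@composition, tuning = model@tuning,
               fit = model@fit), file)
  invisible(file)
}

#' @rdname saveStackerModel
#' @export
readStackerModel <- function(file) {
  obj <- readRDS(file)
  .stop_if(!identical(obj$format, "DNABindStack-model"),
           "not a stacker model artifact: ", file)
  new("TrainedModel", fit = obj$fit, cost = obj$cost, gamma = obj$gamma,
      featureOrder = obj$featureOrder, composition = obj$composition,
      tuning = obj$tuning)
}
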