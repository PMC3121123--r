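#' Parsed protein--DNA complex
#'
#' Coordinate model of a protein--nucleic-acid complex parsed from a PDB
#' file. Atoms are stored as one data.frame row per atom, grouped into
#' residues by (chain, residue number, insertion code), and every residue
#' carries a polymer class (\code{"protein"}, \code{"dna"}, \code{"rna"} or
#' \code{"other"}) assigned by [classifyPolymer()].
#'
#' @slot structureID single string identifying the structure.
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resname}, \code{atom}, \code{element}, \code{x},
#'   \code{y}, \code{z}, \code{occ}, \code{alt}, \code{hetero},
#'   \code{polymer}. Row order follows file order.
#'
#' @seealso [readComplex()], [writeComplex()], [chainMap()]
#' @export
setClass("ComplexStructure",
         representation(structureID = "character", atoms = "data.frame"))

.atom_cols <- c("chain", "resno", "insert", "resname", "atom", "element",
                "x", "y", "z", "occ", "alt", "hetero", "polymer")

setValidity("ComplexStructure", function(object) {
  a <- object@atoms
  if (length(object@structureID) != 1L)
    return("structureID must be a single string")
  miss <- setdiff(.atom_cols, names(a))
  if (length(miss))
    return(paste("atoms is missing columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (nrow(a) && !all(is.finite(xyz)))
    return("atom coordinates must all be finite")
  occ <- a$occ[!is.na(a$occ)]
  if (length(occ) && (any(occ < 0) || any(occ > 1)))
    return("occupancies must lie in [0, 1]")
  key <- paste(a$chain, a$resno, a$insert, a$resname)
  pc <- tapply(a$polymer, key, function(p) length(unique(p)))
  if (length(pc) && any(pc > 1))
    return("a residue must have a single polymer class")
  TRUE
})

#' Per-residue binding-site label track
#'
#' Gold-standard binary labels (1 = DNA-binding, 0 = non-binding) for the
#' protein residues of one chain, together with the criterion and threshold
#' that produced them.
#'
#' @slot structureID,chainID strings identifying the source chain.
#' @slot residues data.frame with columns \code{resno}, \code{insert},
#'   \code{resname}, \code{index0} (0-based sequence index within the chain).
#' @slot labels integer vector in \{0, 1\}, one per residue.
#' @slot criterion \code{"distance"} or \code{"delta_asa"}.
#' @slot threshold positive numeric, in the unit given by \code{unit}.
#' @slot unit \code{"angstrom"}, \code{"angstrom^2"} or \code{"fraction"}.
#' @slot detail numeric vector with the per-residue quantity the criterion
#'   thresholded (minimum distance or delta-ASA), for reporting.
#'
#' @export
setClass("ResidueLabelTrack",
         representation(structureID = "character", chainID = "character",
                        residues = "data.frame", labels = "integer",
                        criterion = "character", threshold = "numeric",
                        unit = "character", detail = "numeric"))

setValidity("ResidueLabelTrack", function(object) {
  if (nrow(object@residues) != length(object@labels))
    return("one label per residue is required")
  if (!all(object@labels %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    return("threshold must be a single positive number")
  if (!object@criterion %in% c("distance", "delta_asa"))
    return("criterion must be 'distance' or 'delta_asa'")
  key <- with(object@residues, paste(resno, insert))
  if (anyDuplicated(key))
    return("residue identities must be unique within a chain")
  TRUE
})

#' Solvent-accessible surface area result
#'
#' Output of the Shrake--Rupley estimator in [computeSASA()]: per-atom
#' areas and, when atom grouping was supplied, per-residue sums.
#'
#' @slot atomArea numeric vector of per-atom areas (A^2, >= 0).
#' @slot residueArea named numeric vector of per-group sums (A^2), empty
#'   when no grouping was supplied.
#' @slot probeRadius probe sphere radius in A.
#' @slot nPoints number of test points per atom.
#'
#' @export
setClass("SasaResult",
         representation(atomArea = "numeric", residueArea = "numeric",
                        probeRadius = "numeric", nPoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@atomArea < -1e-9)) return("atom areas must be >= 0")
  if (length(object@residueArea) && any(object@residueArea < -1e-9))
    return("residue areas must be >= 0")
  if (object@probeRadius < 0) return("probe radius must be >= 0")
  TRUE
})

#' One base predictor's per-residue output
#'
#' Holds the output of one upstream binding-site predictor aligned to a
#' target sequence: a continuous score per residue for \code{kind =
#' "scoring"} predictors, or a 0/1 call per residue for \code{kind =
#' "binary"} predictors. A track whose server returned nothing is marked
#' unavailable and carries no values.
#'
#' @slot predictorID string; see [defaultPredictors()] for the registered set.
#' @slot kind \code{"scoring"} or \code{"binary"}.
#' @slot values numeric vector (length 0 when unavailable).
#' @slot available logical flag.
#'
#' @export
setClass("BasePredictionTrack",
         representation(predictorID = "character", kind = "character",
                        values = "numeric", available = "logical"))

setValidity("BasePredictionTrack", function(object) {
  if (!object@kind %in% c("scoring", "binary"))
    return("kind must be 'scoring' or 'binary'")
  if (object@available && object@kind == "binary" &&
      length(object@values) && !all(object@values %in% c(0, 1)))
    return("binary-kind values must be 0 or 1")
  if (!object@available && length(object@values))
    return("an unavailable track must carry no values")
  TRUE
})

#' Encoded per-residue feature matrix
#'
#' Fixed-width design matrix assembled by [encodeTracks()]: one row per
#' residue, one column per registered predictor in a stable order. Cells
#' whose predictor was unavailable were imputed and are flagged in
#' \code{mask}.
#'
#' @slot values numeric matrix, no missing cells.
#' @slot mask logical matrix, TRUE where the value is an observed predictor
#'   output, FALSE where it was imputed.
#' @slot predictors character vector naming the columns, in column order.
#'
#' @export
setClass("FeatureMatrix",
         representation(values = "matrix", mask = "matrix",
                        predictors = "character"))

setValidity("FeatureMatrix", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  if (ncol(object@values) != length(object@predictors))
    return("one predictor name per column is required")
  if (anyNA(object@values)) return("encoded values must have no missing cells")
  TRUE
})

#' Confusion-matrix counts
#'
#' TP/TN/FP/FN cells. Counts are stored as reals so that cells
#' reconstructed from published rates (see [reconstructCounts()]) can be
#' represented exactly.
#'
#' @slot tp,tn,fp,fn non-negative numerics.
#' @export
setClass("ConfusionCounts",
         representation(tp = "numeric", tn = "numeric",
                        fp = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (length(v) != 4L || anyNA(v)) return("all four cells are required")
  if (any(v < 0)) return("counts must be >= 0")
  TRUE
})

#' The six performance measures
#'
#' Accuracy, sensitivity, specificity, strength (mean of sensitivity and
#' specificity), Matthews correlation coefficient and F-measure computed
#' from a [ConfusionCounts] object. A measure whose denominator is zero is
#' reported as NA with its \code{defined} flag set to FALSE, never coerced
#' to 0.
#'
#' @slot values named numeric vector over
#'   \code{c("accuracy","sensitivity","specificity","strength","mcc","f_measure")}.
#' @slot defined named logical vector over the same names.
#' @export
setClass("MetricSet",
         representation(values = "numeric", defined = "logical"))

.metric_names <- c("accuracy", "sensitivity", "specificity",
                   "strength", "mcc", "f_measure")

setValidity("MetricSet", function(object) {
  if (!identical(names(object@values), .metric_names) ||
      !identical(names(object@defined), .metric_names))
    return("values and defined must be named by the six measures")
  v <- object@values[object@defined]
  bounded01 <- setdiff(.metric_names, "mcc")
  b <- v[names(v) %in% bounded01]
  if (length(b) && (any(b < -1e-12) || any(b > 1 + 1e-12)))
    return("rate measures must lie in [0, 1]")
  if (object@defined[["mcc"]] &&
      abs(object@values[["mcc"]]) > 1 + 1e-12)
    return("mcc must lie in [-1, 1]")
  TRUE
})

#' Stacker training configuration
#'
#' Settings for the RBF-kernel SVM meta-classifier: label encoding is fixed
#' at +1 (binding) / -1 (non-binding); negatives are randomly undersampled
#' in each training set to \code{ratio} negatives per positive (default
#' 1:1); folds are built at residue or protein granularity; the cost /
#' kernel-width grid is searched by internal cross-validation maximising
#' strength.
#'
#' @slot nFolds integer >= 2 (default 10).
#' @slot ratio negatives retained per positive during undersampling.
#' @slot seed integer seed governing undersampling, folds and tuning.
#' @slot foldUnit \code{"residue"} or \code{"protein"}.
#' @slot costGrid,gammaGrid numeric vectors searched during tuning.
#' @slot tune \code{"once"} (grid search on the first training split only,
#'   then reused), \code{"per-fold"}, or \code{"none"} (use
#'   \code{fixedCost}/\code{fixedGamma}).
#' @slot innerFolds folds of the internal tuning cross-validation.
#' @slot tuneMax cap on rows entering the tuning search.
#' @slot fixedCost,fixedGamma hyperparameters used when \code{tune="none"}.
#' @export
setClass("StackerConfig",
         representation(nFolds = "integer", ratio = "numeric",
                        seed = "integer", foldUnit = "character",
                        costGrid = "numeric", gammaGrid = "numeric",
                        tune = "character", innerFolds = "integer",
                        tuneMax = "integer", fixedCost = "numeric",
                        fixedGamma = "numeric"))

setValidity("StackerConfig", function(object) {
  if (object@nFolds < 2L) return("nFolds must be >= 2")
  if (object@ratio <= 0) return("undersampling ratio must be > 0")
  if (!length(object@costGrid) || !length(object@gammaGrid))
    return("hyperparameter grid must be non-empty")
  if (!object@foldUnit %in% c("residue", "protein"))
    return("foldUnit must be 'residue' or 'protein'")
  if (!object@tune %in% c("once", "per-fold", "none"))
    return("tune must be 'once', 'per-fold' or 'none'")
  TRUE
})

#' Fitted meta-classifier
#'
#' An RBF-kernel SVM fitted on encoded base-predictor features, with the
#' selected hyperparameters, the feature column order it expects, and a
#' record of the training-set composition before and after undersampling.
#'
#' @slot fit the underlying \pkg{e1071} svm fit.
#' @slot cost,gamma selected hyperparameters.
#' @slot featureOrder character vector of feature column names.
#' @slot composition list with \code{positives}, \code{negativesBefore},
#'   \code{negativesAfter}, \code{ratio}.
#' @slot tuning data.frame of the grid search (empty when tune="none").
#' @export
setClass("TrainedModel",
         representation(fit = "ANY", cost = "numeric", gamma = "numeric",
                        featureOrder = "character", composition = "list",
                        tuning = "data.frame"))

#' Cross-validation result
#'
#' Per-fold confusion counts evaluated on held-out folds at natural class
#' imbalance, the pooled counts (summed over folds), and the pooled
#' [MetricSet].
#'
#' @slot folds data.frame: fold, nTest, TP, TN, FP, FN plus the six measures.
#' @slot pooled [ConfusionCounts] summed over folds.
#' @slot pooledMetrics [MetricSet] computed from the pooled counts.
#' @slot foldAssign integer fold id per input row.
#' @slot composition list of per-fold training-set composition records.
#' @slot hyperparameters list with cost and gamma used per fold.
#' @export
setClass("CrossValResult",
         representation(folds = "data.frame", pooled = "ConfusionCounts",
                        pooledMetrics = "MetricSet", foldAssign = "integer",
                        composition = "list", hyperparameters = "list"))
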