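#' The registered base predictors
#'
#' The default set of six upstream per-residue DNA-binding predictors that
#' the meta-classifier stacks: four return a continuous score per residue
#' (\code{"scoring"}) and two return only a binary call
#' (\code{"binary"}). The row order here is the fixed feature-column order
#' used by [encodeTracks()].
#'
#' @return data.frame with columns \code{id} and \code{kind}.
#' @export
defaultPredictors <- function() {
  data.frame(
    id = c("disis", "dnabindr", "bindn", "bindn_rf", "dpbind", "dbs_pred"),
    kind = c("scoring", "scoring", "scoring", "scoring", "binary", "binary"),
    stringsAsFactors = FALSE)
}

#' Construct a base-predictor track
#'
#' @param predictorID predictor name (see [defaultPredictors()]).
#' @param values per-residue numeric scores (scoring kind) or 0/1 calls
#'   (binary kind); ignored when \code{available = FALSE}.
#' @param kind \code{"scoring"} or \code{"binary"}; defaults to the
#'   registered kind when the id is registered.
#' @param available FALSE marks a predictor that returned nothing (its
#'   column will be imputed by [encodeTracks()]).
#' @return a [BasePredictionTrack].
#' @export
predictionTrack <- function(predictorID, values = numeric(), kind = NULL,
                            available = TRUE) {
  if (is.null(kind)) {
    reg <- defaultPredictors()
    m <- match(predictorID, reg$id)
    .stop_if(is.na(m), "unregistered predictor ", dQuote(predictorID),
             " needs an explicit kind")
    kind <- reg$kind[m]
  }
  new("BasePredictionTrack", predictorID = predictorID, kind = kind,
      values = if (available) as.numeric(values) else numeric(),
      available = available)
}

#' Encode base-predictor tracks as a feature matrix
#'
#' Builds the fixed-width per-residue design matrix for the
#' meta-classifier: one column per registered predictor, in registration
#' order. Binary-kind tracks are encoded as +1 for a binding call and 0
#' for a non-binding call. Scoring-kind tracks are passed through the
#' selected normalisation -- per-track min-max to [0, 1] by default, since
#' the downstream RBF kernel is scale-sensitive and the upstream scoring
#' functions are heterogeneous; a track with no score spread is mapped to
#' the constant 0.5. Unavailable tracks are imputed with a neutral
#' constant and flagged in the mask.
#'
#' @param tracks list of [BasePredictionTrack]; at least one must be
#'   available, and every available track must have \code{seqLength}
#'   values.
#' @param seqLength number of residues (rows).
#' @param normalization \code{"minmax"} (default) or \code{"raw"}.
#' @param predictors registry data.frame (see [defaultPredictors()])
#'   fixing the column set and order.
#' @param imputeValue constant filled into unavailable columns (default 0).
#' @return a [FeatureMatrix] of dimension seqLength x nrow(predictors).
#' @export
encodeTracks <- function(tracks, seqLength,
                         normalization = c("minmax", "raw"),
                         predictors = defaultPredictors(),
                         imputeValue = 0) {
  normalization <- match.arg(normalization)
  .stop_if(!length(tracks), "no tracks supplied")
  ids <- vapply(tracks, function(t) t@predictorID, character(1))
  .stop_if(anyDuplicated(ids) > 0L, "duplicated predictor tracks: ",
           paste(ids[duplicated(ids)], collapse = ", "))
  avail <- vapply(tracks, function(t) t@available, logical(1))
  .stop_if(!any(avail), "no available predictor track; need at least one")
  for (t in tracks[avail])
    .stop_if(length(t@values) != seqLength,
             "track length mismatch for predictor ", dQuote(t@predictorID),
             ": ", length(t@values), " values for ", seqLength, " residues")

  n <- as.integer(seqLength)
  p <- nrow(predictors)
  values <- matrix(imputeValue, n, p, dimnames = list(NULL, predictors$id))
  mask <- matrix(FALSE, n, p, dimnames = list(NULL, predictors$id))
  for (t in tracks) {
    col <- match(t@predictorID, predictors$id)
    .stop_if(is.na(col), "predictor ", dQuote(t@predictorID),
             " is not in the registry")
    if (!t@available) next
    v <- t@values
    if (t@kind == "binary") {
      v <- ifelse(v > 0, 1, 0)                    # +1 binding / 0 non-binding
    } else if (normalization == "minmax") {
      rng <- range(v)
      v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, n)
    }
    values[, col] <- v
    mask[, col] <- TRUE
  }
  new("FeatureMatrix", values = values, mask = mask,
      predictors = predictors$id)
}

#' @describeIn FeatureMatrix-class the encoded value matrix.
#' @param x a [FeatureMatrix].
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureMatrix-class the availability mask.
#' @export
featureMask <- function(x) x@mask

#' @describeIn FeatureMatrix-class the column (predictor) order.
#' @export
featureOrder <- function(x) x@predictors

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "residues x",
      ncol(object@values), "predictors\n")
  cat("  columns:", paste(object@predictors, collapse = ", "), "\n")
  na_cols <- colSums(!object@mask)
  if (any(na_cols == nrow(object@mask)))
    cat("  imputed columns:",
        paste(object@predictors[na_cols == nrow(object@mask)],
              collapse = ", "), "\n")
})

setMethod("show", "BasePredictionTrack", function(object) {
  cat("BasePredictionTrack", dQuote(object@predictorID),
      paste0("(", object@kind, "):"),
      if (object@available) paste(length(object@values), "values")
      else "unavailable", "\n")
})

#' Read one predictor's track from TSV
#'
#' Expected columns: \code{index} (0-based), \code{residue} (letter),
#' \code{value}.
#'
#' @param file path to the TSV.
#' @param predictorID,kind as in [predictionTrack()].
#' @return a [BasePredictionTrack] with rows ordered by index.
#' @export
readTrackTSV <- function(file, predictorID, kind = NULL) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  .stop_if(!all(c("index", "value") %in% names(d)),
           "track TSV needs columns 'index' and 'value'")
  d <- d[order(d$index), , drop = FALSE]
  .stop_if(!identical(as.integer(d$index), seq_len(nrow(d)) - 1L),
           "track indices must be 0-based and contiguous")
  predictionTrack(predictorID, d$value, kind = kind)
}

#' Write an encoded feature matrix as TSV
#'
#' @param x a [FeatureMatrix].
#' @param file output path; header row names the predictor columns.
#' @return invisibly, \code{file}.
#' @export
writeFeatureMatrix <- function(x, file) {
  d <- as.data.frame(featureValues(x))
  d <- cbind(index = seq_len(nrow(d)) - 1L, d)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a protein sequence from FASTA
#'
#' Thin wrapper over \pkg{Biostrings} returning the first sequence as a
#' plain character string.
#'
#' @param file FASTA path.
#' @return single character string (amino-acid sequence).
#' @export
readProteinFasta <- function(file) {
  s <- Biostrings::readAAStringSet(file)
  .stop_if(!length(s), "no sequence in ", file)
  as.character(s[[1]])
}
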