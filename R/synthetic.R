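#' Specification of a toy protein--DNA complex
#'
#' Describes an idealised complex used to exercise the annotation and
#' SASA machinery without downloading structures: DNA pseudo-atoms on a
#' B-form-like helical trace (rise 3.4 A, twist 36 deg), and
#' two-pseudo-atom protein residues (CA plus a side-chain carbon) placed
#' so that each residue's minimum distance to any DNA atom equals a
#' scripted value.
#'
#' @slot minDistances scripted per-residue minimum protein--DNA distances
#'   (A, all > 0).
#' @slot dnaLength number of DNA pseudo-atoms (base steps, >= 1).
#' @slot structureID identifier written into the structure.
#' @slot seed integer recorded for provenance (the geometry itself is
#'   deterministic).
#' @export
setClass("ToyComplexSpec",
         representation(minDistances = "numeric", dnaLength = "integer",
                        structureID = "character", seed = "integer"))

setValidity("ToyComplexSpec", function(object) {
  if (!length(object@minDistances)) return("at least one residue required")
  if (any(!is.finite(object@minDistances)) || any(object@minDistances <= 0))
    return("unsatisfiable geometry: scripted distances must be positive")
  if (object@dnaLength < 1L) return("dnaLength must be >= 1")
  TRUE
})

#' @describeIn ToyComplexSpec-class constructor.
#' @param minDistances,dnaLength,structureID,seed see slots.
#' @export
toyComplexSpec <- function(minDistances, dnaLength = 12L,
                           structureID = "toy", seed = 1L) {
  new("ToyComplexSpec", minDistances = as.numeric(minDistances),
      dnaLength = as.integer(dnaLength), structureID = structureID,
      seed = as.integer(seed))
}

.helix_radius <- 9

#' Build a toy protein--DNA complex with scripted contact distances
#'
#' DNA pseudo-atoms (phosphorus, residue code DA, chain B) are placed on a
#' helix of radius 9 A around the z axis with 3.4 A rise and 36 deg twist
#' per step. Each protein residue (alanine, chain A) anchors to one DNA
#' atom in turn: its side-chain carbon sits exactly the scripted distance
#' radially outward from the anchor, with the CA a further 3.8 A out, so
#' the residue's minimum distance to the whole DNA equals the scripted
#' value (the outward direction strictly increases the distance to every
#' other helix atom). The construction is fully deterministic: the same
#' spec always yields byte-identical PDB output.
#'
#' @param spec a [ToyComplexSpec].
#' @return list with \code{complex} (a [ComplexStructure]) and
#'   \code{truth} (data.frame: resno, targetDistance).
#' @export
buildToyComplex <- function(spec) {
  validObject(spec)
  nd <- spec@dnaLength
  step <- seq_len(nd) - 1L
  theta <- step * 36 * pi / 180
  dna <- data.frame(
    chain = "B", resno = seq_len(nd), insert = "", resname = "DA",
    atom = "P", element = "P",
    x = .helix_radius * cos(theta), y = .helix_radius * sin(theta),
    z = 3.4 * step, occ = 1, alt = "", hetero = FALSE, polymer = "dna",
    stringsAsFactors = FALSE)

  d <- spec@minDistances
  n <- length(d)
  anchor <- ((seq_len(n) - 1L) %% nd) + 1L
  u <- cbind(cos(theta[anchor]), sin(theta[anchor]), 0)
  cb <- cbind(dna$x[anchor], dna$y[anchor], dna$z[anchor]) + u * d
  ca <- cbind(dna$x[anchor], dna$y[anchor], dna$z[anchor]) + u * (d + 3.8)
  prot <- data.frame(
    chain = "A", resno = rep(seq_len(n), each = 2L), insert = "",
    resname = "ALA", atom = rep(c("CA", "CB"), n),
    element = "C",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    occ = 1, alt = "", hetero = FALSE, polymer = "protein",
    stringsAsFactors = FALSE)

  cx <- new("ComplexStructure", structureID = spec@structureID,
            atoms = rbind(prot, dna))
  list(complex = cx,
       truth = data.frame(resno = seq_len(n), targetDistance = d))
}

#' Simulate a per-residue label track
#'
#' Independent Bernoulli draws at a fixed positive (binding) fraction;
#' deterministic given the seed. The benchmark-scale imbalance is 5342
#' binding in 72738 residues (about 1 positive per 12.6 negatives).
#'
#' @param n number of residues.
#' @param positiveFraction probability of a binding label, in (0, 1).
#' @param seed integer seed.
#' @return integer vector of 1 (binding) / 0 (non-binding).
#' @export
simulateLabels <- function(n, positiveFraction = 5342 / 72738, seed = 1L) {
  .stop_if(positiveFraction <= 0 || positiveFraction >= 1,
           "positiveFraction must lie strictly inside (0, 1)")
  .with_seed(seed, as.integer(stats::runif(n) < positiveFraction))
}

#' Default simulated base-predictor profiles
#'
#' Class-conditional Gaussian score models for the six registered
#' predictors, sharing one latent factor so that inter-predictor
#' correlation -- the realistic obstacle to stacking gains -- is present.
#' Each predictor's separation \code{d = meanPos - meanNeg} (unit
#' variance) is set so its strength at the midpoint threshold,
#' \code{pnorm(d/2)}, matches the published strength of the corresponding
#' real predictor (0.59--0.75 band). Binary-kind predictors threshold
#' their latent score at the midpoint, which is where sensitivity equals
#' specificity.
#'
#' @param loading shared latent-factor loading in [0, 1) (default 0.5;
#'   pairwise score correlation within a class is loading^2).
#' @return data.frame: id, kind, meanNeg, meanPos, sd, loading, threshold.
#' @export
predictorProfiles <- function(loading = 0.5) {
  .stop_if(loading < 0 || loading >= 1, "loading must lie in [0, 1)")
  strengths <- c(disis = 0.59, dnabindr = 0.70, bindn = 0.67,
                 bindn_rf = 0.75, dpbind = 0.74, dbs_pred = 0.65)
  reg <- defaultPredictors()
  d <- 2 * stats::qnorm(strengths[reg$id])
  data.frame(id = reg$id, kind = reg$kind,
             meanNeg = 0, meanPos = as.numeric(d), sd = 1,
             loading = loading,
             threshold = ifelse(reg$kind == "binary", as.numeric(d) / 2,
                                NA_real_),
             stringsAsFactors = FALSE)
}

#' Simulate base-predictor tracks for a label track
#'
#' For residue i with label y_i and predictor j, the latent score is
#' \code{mean_j(y_i) + sd_j * (loading_j * z_i + sqrt(1 - loading_j^2) *
#' e_ij)} with a shared standard-normal factor z_i and independent noise
#' e_ij. Scoring-kind predictors emit the score; binary-kind predictors
#' emit the 0/1 call \code{score > threshold}.
#'
#' @param labels 0/1 (or -1/+1) label vector.
#' @param profiles data.frame as from [predictorProfiles()].
#' @param seed integer seed.
#' @return named list of [BasePredictionTrack], one per profile row.
#' @export
simulateTracks <- function(labels, profiles = predictorProfiles(),
                           seed = 1L) {
  .stop_if(!nrow(profiles), "no predictor profiles supplied")
  .stop_if(any(profiles$meanPos < profiles$meanNeg),
           "profiles must be informative: meanPos >= meanNeg")
  .stop_if(any(profiles$sd <= 0), "profile scales must be > 0")
  y <- .as_pm1(labels)
  n <- length(y)
  .with_seed(seed, {
    z <- stats::rnorm(n)
    tracks <- lapply(seq_len(nrow(profiles)), function(j) {
      p <- profiles[j, ]
      mu <- ifelse(y == 1L, p$meanPos, p$meanNeg)
      score <- mu + p$sd * (p$loading * z +
                              sqrt(1 - p$loading^2) * stats::rnorm(n))
      if (p$kind == "binary")
        predictionTrack(p$id, as.integer(score > p$threshold), kind = "binary")
      else
        predictionTrack(p$id, score, kind = "scoring")
    })
    names(tracks) <- profiles$id
    tracks
  })
}

#' Analytic class separation of a simulated predictor
#'
#' The rank separation (area under the ROC curve, ties counted half) a
#' profile attains in expectation: \code{pnorm(d / sqrt(2))} for a
#' scoring-kind Gaussian profile with standardised separation d, and the
#' tie-averaged value \code{(sensitivity + specificity) / 2} for a
#' binary-kind profile thresholded at \code{threshold}.
#'
#' @param profile one row of a [predictorProfiles()] data.frame.
#' @return expected AUC in [0.5, 1].
#' @export
analyticSeparation <- function(profile) {
  d <- (profile$meanPos - profile$meanNeg) / profile$sd
  if (profile$kind == "scoring") return(stats::pnorm(d / sqrt(2)))
  sens <- 1 - stats::pnorm((profile$threshold - profile$meanPos) / profile$sd)
  spec <- stats::pnorm((profile$threshold - profile$meanNeg) / profile$sd)
  (sens + spec) / 2
}

#' Best achievable strength of a single score track
#'
#' Sweeps every cut point of a continuous (or binary) score and returns
#' the maximum of (sensitivity + specificity) / 2, the strength an oracle
#' threshold would attain. Used as the single-predictor baseline that the
#' stacked classifier has to beat.
#'
#' @param values per-residue scores (higher = more binding-like).
#' @param labels 0/1 or -1/+1 vector.
#' @return list with \code{strength} and \code{threshold}.
#' @export
bestThresholdStrength <- function(values, labels) {
  y <- .as_pm1(labels)
  P <- sum(y == 1L)
  N <- sum(y == -1L)
  .stop_if(!P || !N, "both classes are required")
  o <- order(values, decreasing = TRUE)
  ys <- y[o]
  vs <- values[o]
  cum_tp <- cumsum(ys == 1L)
  cum_fp <- cumsum(ys == -1L)
  # candidate cuts: after each distinct value block, plus the empty cut
  last <- which(vs != c(vs[-1], NA))
  sens <- c(0, cum_tp[last]) / P
  spec <- c(N, N - cum_fp[last]) / N
  s <- (sens + spec) / 2
  best <- which.max(s)
  thr <- if (best == 1L) Inf else vs[last[best - 1L]]
  list(strength = s[best], threshold = thr)
}

#' Simulate a full stacking dataset
#'
#' Convenience wrapper: draws labels at the benchmark-scale imbalance,
#' simulates the six default predictor tracks, and encodes them.
#'
#' @param n residues (default 20000).
#' @param positiveFraction binding fraction (default 5342/72738).
#' @param profiles predictor profiles.
#' @param seed integer seed.
#' @return list with \code{labels} (0/1), \code{tracks},
#'   \code{features} (a [FeatureMatrix]).
#' @export
simulateStackingDataset <- function(n = 20000L,
                                    positiveFraction = 5342 / 72738,
                                    profiles = predictorProfiles(),
                                    seed = 1L) {
  labels <- simulateLabels(n, positiveFraction, seed = seed)
  tracks <- simulateTracks(labels, profiles,
                           seed = .substream_seed(seed, 3L))
  features <- encodeTracks(tracks, n)
  list(labels = labels, tracks = tracks, features = features)
}

#' Write simulated tracks as per-predictor TSV files
#'
#' @param tracks named list of [BasePredictionTrack].
#' @param dir output directory; one \code{<id>.tsv} per track with
#'   columns index (0-based), residue, value.
#' @param sequence optional residue letters (defaults to "X").
#' @return invisibly, the written paths.
#' @export
writeTrackTSVs <- function(tracks, dir, sequence = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(tracks, function(t) {
    n <- length(t@values)
    res <- if (is.null(sequence)) rep("X", n) else
      strsplit(sequence, "")[[1]][seq_len(n)]
    d <- data.frame(index = seq_len(n) - 1L, residue = res,
                    value = t@values)
    path <- file.path(dir, paste0(t@predictorID, ".tsv"))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}
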