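.xyz_of <- function(a) unname(as.matrix(a[, c("x", "y", "z")]))

# minimum Euclidean distance from each protein atom block to any partner
# atom; computed block-wise with exact arithmetic (results identical to the
# full all-pairs scan)
.min_dist_atoms <- function(pxyz, dxyz) {
  n <- nrow(pxyz)
  out <- numeric(n)
  chunk <- max(1L, as.integer(2e6 / max(1L, nrow(dxyz))))
  dn2 <- rowSums(dxyz^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    b <- pxyz[s:e, , drop = FALSE]
    d2 <- outer(rowSums(b^2), dn2, "+") - 2 * (b %*% t(dxyz))
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

.partner_atoms <- function(x, includeRNA) {
  a <- atoms(x)
  cls <- if (includeRNA) c("dna", "rna") else "dna"
  a[a$polymer %in% cls, , drop = FALSE]
}

.protein_chain_split <- function(x) {
  a <- atoms(x)
  p <- a[a$polymer == "protein", , drop = FALSE]
  .stop_if(!nrow(p), "complex has no protein chain")
  split(p, factor(p$chain, levels = unique(p$chain)))
}

.residues_of <- function(chain_atoms) {
  key <- paste(chain_atoms$resno, chain_atoms$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(resno = chain_atoms$resno[first],
             insert = chain_atoms$insert[first],
             resname = chain_atoms$resname[first],
             index0 = seq_len(sum(first)) - 1L,
             stringsAsFactors = FALSE)
}

#' Annotate DNA-binding residues by the distance criterion
#'
#' A protein residue is labelled DNA-binding when the distance between any
#' of its atoms and any atom of the DNA is strictly less than the cutoff;
#' every other protein residue is non-binding. The default cutoff of 3.5 A
#' is the threshold at which sensitivity of downstream prediction is
#' highest across the commonly used 3.5--6.0 A range.
#'
#' @param x a [ComplexStructure] with at least one protein and one DNA
#'   chain.
#' @param cutoff distance threshold in A, in the conventional 2--10 range.
#' @param includeRNA also count RNA chains as the binding partner
#'   (default FALSE).
#' @return named list of [ResidueLabelTrack], one per protein chain.
#' @export
annotateByDistance <- function(x, cutoff = 3.5, includeRNA = FALSE) {
  .stop_if(cutoff < 2 || cutoff > 10,
           "cutoff must be in the 2-10 A range, got ", cutoff)
  dna <- .partner_atoms(x, includeRNA)
  .stop_if(!nrow(dna), "complex has no DNA chain")
  dxyz <- .xyz_of(dna)
  chains <- .protein_chain_split(x)
  out <- lapply(names(chains), function(cid) {
    ca <- chains[[cid]]
    .stop_if(!nrow(ca), "empty protein chain ", cid)
    md_atom <- .min_dist_atoms(.xyz_of(ca), dxyz)
    key <- factor(paste(ca$resno, ca$insert, sep = "\r"),
                  levels = unique(paste(ca$resno, ca$insert, sep = "\r")))
    md <- as.numeric(tapply(md_atom, key, min))
    res <- .residues_of(ca)
    new("ResidueLabelTrack", structureID = structureID(x), chainID = cid,
        residues = res, labels = as.integer(md < cutoff),
        criterion = "distance", threshold = cutoff, unit = "angstrom",
        detail = md)
  })
  names(out) <- names(chains)
  out
}

#' Annotate DNA-binding residues by loss of accessible surface area
#'
#' Computes each protein residue's solvent-accessible surface area with
#' the DNA absent and present; the per-residue decrease (delta-ASA) is
#' thresholded to call binding residues. With \code{mode = "absolute"}
#' (default) a residue binds when it loses at least \code{threshold} A^2
#' (default 1); with \code{mode = "relative"} when it loses at least
#' \code{threshold} as a fraction of its unbound area (use e.g. 0.01 for
#' a 1\% loss). The point placement is deterministic, so delta-ASA is
#' non-negative by construction and results are bit-reproducible.
#'
#' @inheritParams annotateByDistance
#' @param threshold area loss calling a residue binding; A^2 in absolute
#'   mode, fraction of unbound residue area in relative mode.
#' @param mode \code{"absolute"} or \code{"relative"}.
#' @param probeRadius,nPoints,radii passed to [computeSASA()].
#' @return named list of [ResidueLabelTrack], one per protein chain; the
#'   \code{detail} slot holds the per-residue delta-ASA (A^2).
#' @export
annotateByDeltaASA <- function(x, threshold = 1, mode = c("absolute", "relative"),
                               probeRadius = 1.4, nPoints = 960L,
                               radii = defaultVdwRadii(), includeRNA = FALSE) {
  mode <- match.arg(mode)
  .stop_if(threshold <= 0, "threshold must be > 0")
  dna <- .partner_atoms(x, includeRNA)
  .stop_if(!nrow(dna), "complex has no DNA chain")
  a <- atoms(x)
  prot <- a[a$polymer == "protein", , drop = FALSE]
  .stop_if(!nrow(prot), "complex has no protein chain")

  res_key <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  unbound <- computeSASA(.xyz_of(prot), prot$element, probeRadius, nPoints,
                         radii, groups = res_key)
  ctx <- rbind(prot[, c("x", "y", "z")], dna[, c("x", "y", "z")])
  bound_all <- computeSASA(as.matrix(ctx), c(prot$element, dna$element),
                           probeRadius, nPoints, radii)
  bound_atom <- sasaAreas(bound_all)[seq_len(nrow(prot))]
  bound <- tapply(bound_atom, factor(res_key, levels = unique(res_key)), sum)
  delta <- residueAreas(unbound) - as.numeric(bound)

  is_binding <- if (mode == "absolute") {
    delta >= threshold
  } else {
    residueAreas(unbound) > 0 & delta >= threshold * residueAreas(unbound)
  }

  chains <- split(seq_along(delta),
                  factor(prot$chain[!duplicated(res_key)],
                         levels = unique(prot$chain)))
  first <- prot[!duplicated(res_key), , drop = FALSE]
  out <- lapply(names(chains), function(cid) {
    i <- chains[[cid]]
    res <- data.frame(resno = first$resno[i], insert = first$insert[i],
                      resname = first$resname[i],
                      index0 = seq_along(i) - 1L, stringsAsFactors = FALSE)
    new("ResidueLabelTrack", structureID = structureID(x), chainID = cid,
        residues = res, labels = as.integer(is_binding[i]),
        criterion = "delta_asa", threshold = threshold,
        unit = if (mode == "absolute") "angstrom^2" else "fraction",
        detail = as.numeric(delta[i]))
  })
  names(out) <- names(chains)
  out
}

#' @describeIn ResidueLabelTrack-class the 0/1 label vector.
#' @param x a [ResidueLabelTrack].
#' @export
siteLabels <- function(x) x@labels

#' @describeIn ResidueLabelTrack-class the per-residue criterion quantity
#'   (minimum distance in A, or delta-ASA in A^2).
#' @export
labelDetail <- function(x) x@detail

#' @describeIn ResidueLabelTrack-class the residue identity table.
#' @export
trackResidues <- function(x) x@residues

#' Positive/negative totals over label tracks
#'
#' Counts binding and non-binding residues over one or more
#' [ResidueLabelTrack] objects and reports the class imbalance.
#'
#' @param tracks a [ResidueLabelTrack] or a (possibly nested) list of them.
#' @return list with \code{positives}, \code{negatives} and \code{ratio}
#'   (positives / negatives).
#' @export
labelSummary <- function(tracks) {
  if (is(tracks, "ResidueLabelTrack")) tracks <- list(tracks)
  tracks <- unlist(tracks, recursive = TRUE)
  .stop_if(!length(tracks), "no label tracks supplied")
  labs <- unlist(lapply(tracks, siteLabels))
  .stop_if(!length(labs), "label tracks are empty")
  pos <- sum(labs == 1L)
  neg <- sum(labs == 0L)
  list(positives = pos, negatives = neg,
       ratio = if (neg > 0) pos / neg else NA_real_)
}

#' Write label tracks as TSV
#'
#' One row per residue: structure_id, chain_id, seq_number,
#' insertion_code, res_name, index0, label, criterion, threshold.
#'
#' @param tracks a [ResidueLabelTrack] or list of them.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeLabelTracks <- function(tracks, file) {
  if (is(tracks, "ResidueLabelTrack")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(structure_id = t@structureID, chain_id = t@chainID,
               seq_number = t@residues$resno,
               insertion_code = t@residues$insert,
               res_name = t@residues$resname,
               index0 = t@residues$index0,
               label = t@labels, criterion = t@criterion,
               threshold = t@threshold, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
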