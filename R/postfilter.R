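#' Spatial-cluster filter for predicted binding residues
#'
#' Sequence-only predictors scatter false-positive calls over the protein
#' surface, while many true binding residues sit near each other in
#' space. When the structure is known, predicted binding residues can be
#' clustered on their C-alpha coordinates and small clusters discarded as
#' presumed false positives. Clusters are single-linkage connected
#' components: two sites are linked when their CA distance is at most
#' \code{linkDistance} (coincident CAs are linked at distance 0), and a
#' component with fewer than \code{minClusterSize} members is removed.
#'
#' Because filtering can only turn predicted positives into negatives, on
#' any labelled set specificity never decreases and sensitivity never
#' increases -- true binding sites of 3 or fewer residues sitting alone on
#' the surface are the sensitivity price.
#'
#' @param sites data.frame of predicted binding residues with CA
#'   coordinates in columns \code{x}, \code{y}, \code{z}; any identity or
#'   score columns are carried through. Missing (NA) coordinates are an
#'   error naming the offending rows.
#' @param linkDistance single-linkage threshold in A (default 8).
#' @param minClusterSize smallest cluster retained (default 3; 1 keeps
#'   everything).
#' @return list with \code{retained} (the filtered data.frame),
#'   \code{removed}, and \code{clusters} (data.frame: cluster id, size,
#'   retained flag, member row indices as a comma-separated string).
#' @export
filterBySpatialClusters <- function(sites, linkDistance = 8,
                                    minClusterSize = 3L) {
  .stop_if(linkDistance <= 0, "linkDistance must be > 0")
  .stop_if(minClusterSize < 1L, "minClusterSize must be >= 1")
  .stop_if(!all(c("x", "y", "z") %in% names(sites)),
           "sites needs CA coordinate columns x, y, z")
  n <- nrow(sites)
  if (!n)
    return(list(retained = sites, removed = sites,
                clusters = data.frame(cluster = integer(), size = integer(),
                                      retained = logical(),
                                      members = character())))
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  bad <- which(!stats::complete.cases(xyz) | !apply(is.finite(xyz), 1, all))
  .stop_if(length(bad), "missing CA coordinate for predicted residue row(s): ",
           paste(bad, collapse = ", "))

  comp <- if (n == 1L) 1L else {
    hc <- stats::hclust(stats::dist(xyz), method = "single")
    stats::cutree(hc, h = linkDistance)
  }
  sizes <- table(comp)
  keep_cluster <- as.integer(names(sizes))[sizes >= minClusterSize]
  keep <- comp %in% keep_cluster
  clusters <- data.frame(
    cluster = as.integer(names(sizes)),
    size = as.integer(sizes),
    retained = as.integer(names(sizes)) %in% keep_cluster,
    members = vapply(as.integer(names(sizes)), function(cid)
      paste(which(comp == cid), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  list(retained = sites[keep, , drop = FALSE],
       removed = sites[!keep, , drop = FALSE],
       clusters = clusters)
}

#' Write a cluster report TSV
#'
#' @param filtered result of [filterBySpatialClusters()].
#' @param file output path; columns cluster, size, retained, members.
#' @return invisibly, \code{file}.
#' @export
writeClusterReport <- function(filtered, file) {
  utils::write.table(filtered$clusters, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Predicted-site table from calls and a structure
#'
#' Joins positive predictions on a protein chain to the chain's C-alpha
#' coordinates, producing the input of [filterBySpatialClusters()].
#'
#' @param x a [ComplexStructure].
#' @param chain protein chain id.
#' @param calls 0/1 or -1/+1 vector, one per residue of the chain (chain
#'   order).
#' @param scores optional decision scores carried through.
#' @return data.frame of the predicted-positive residues: resno, insert,
#'   resname, index0, x, y, z (CA), score.
#' @export
predictedSites <- function(x, chain, calls, scores = NULL) {
  a <- atoms(x)
  ca <- a[a$polymer == "protein" & a$chain == chain & a$atom == "CA", ,
          drop = FALSE]
  .stop_if(!nrow(ca), "no CA atoms on protein chain ", chain)
  y <- .as_pm1(calls)
  .stop_if(length(y) != nrow(ca),
           "one call per residue of chain ", chain, " is required (",
           nrow(ca), " residues, ", length(y), " calls)")
  pos <- which(y == 1L)
  data.frame(resno = ca$resno[pos], insert = ca$insert[pos],
             resname = ca$resname[pos], index0 = pos - 1L,
             x = ca$x[pos], y = ca$y[pos], z = ca$z[pos],
             score = if (is.null(scores)) NA_real_ else scores[pos],
             stringsAsFactors = FALSE)
}
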