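#' Default van der Waals radii
#'
#' Per-element radii (A) used by the SASA engine. Elements absent from the
#' table fall back to \code{default} when \code{useDefault} is allowed by
#' the caller.
#'
#' @return named numeric vector of radii, with a \code{default} entry.
#' @export
defaultVdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    default = 1.80)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake--Rupley)
#'
#' Estimates per-atom solvent-accessible surface area by the
#' Shrake--Rupley method: \code{nPoints} quasi-uniform test points are
#' placed on each atom's solvent-expanded sphere (radius r_atom + probe,
#' golden-spiral placement, fully deterministic), and the accessible
#' fraction -- points strictly outside every neighbouring expanded
#' sphere -- is multiplied by the expanded sphere's area
#' 4*pi*(r+probe)^2.
#'
#' @param xyz numeric matrix (n x 3) of atom centres in A.
#' @param elements character vector of element symbols, length n.
#' @param probeRadius solvent probe radius in A (default 1.4, water).
#' @param nPoints test points per atom (default 960; >= 100 required).
#' @param radii named per-element radii table; a \code{default} entry, if
#'   present, covers unknown elements, otherwise unknown elements are an
#'   error naming them.
#' @param groups optional factor/vector of length n; when given, per-group
#'   (per-residue) area sums are returned as well.
#' @return a [SasaResult].
#' @examples
#' # isolated carbon: closed form 4*pi*(1.70+1.4)^2
#' sasaAreas(computeSASA(matrix(0, 1, 3), "C"))
#' @export
computeSASA <- function(xyz, elements, probeRadius = 1.4, nPoints = 960L,
                        radii = defaultVdwRadii(), groups = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  .stop_if(!n, "no atoms supplied")
  .stop_if(ncol(xyz) != 3L, "xyz must be an n x 3 matrix")
  .stop_if(length(elements) != n, "one element symbol per atom is required")
  .stop_if(nPoints < 100L, "nPoints must be >= 100")
  el <- toupper(elements)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown)) {
    .stop_if(!"default" %in% names(radii),
             "no radius for element(s): ", paste(unknown, collapse = ", "))
    radii[unknown] <- radii[["default"]]
  }
  re <- unname(radii[el]) + probeRadius       # expanded radii
  pts <- .sphere_points(as.integer(nPoints))

  area <- numeric(n)
  maxre <- max(re)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (re[i] + re)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * re[i]^2
      next
    }
    p <- pts * re[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, nPoints)
    # nearest neighbours first: buried points are culled sooner
    for (j in nb[order(d2[nb])]) {
      if (!any(free)) break
      idx <- which(free)
      dj2 <- (p[idx, 1] - xyz[j, 1])^2 + (p[idx, 2] - xyz[j, 2])^2 +
        (p[idx, 3] - xyz[j, 3])^2
      free[idx[dj2 < re[j]^2]] <- FALSE
    }
    area[i] <- sum(free) / nPoints * 4 * pi * re[i]^2
  }

  resArea <- numeric(0)
  if (!is.null(groups)) {
    .stop_if(length(groups) != n, "one group per atom is required")
    s <- tapply(area, factor(groups, levels = unique(groups)), sum)
    resArea <- as.numeric(s)
    names(resArea) <- names(s)
  }
  new("SasaResult", atomArea = area, residueArea = resArea,
      probeRadius = probeRadius, nPoints = as.integer(nPoints))
}

#' @describeIn computeSASA per-atom areas of a [SasaResult].
#' @param object a [SasaResult].
#' @export
sasaAreas <- function(object) object@atomArea

#' @describeIn computeSASA per-group (residue) area sums.
#' @export
residueAreas <- function(object) object@residueArea

setMethod("show", "SasaResult", function(object) {
  cat("SasaResult:", length(object@atomArea), "atoms, total",
      sprintf("%.2f", sum(object@atomArea)), "A^2 (probe",
      object@probeRadius, "A,", object@nPoints, "points/atom)\n")
})
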