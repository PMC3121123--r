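toy30 <- local({
  set.seed(5)
  d <- round(runif(30, 2.0, 9.0), 2)
  buildToyComplex(toyComplexSpec(d, dnaLength = 15L, structureID = "t30"))
})

test_that("the distance criterion is a strict less-than at the cutoff", {
  toy <- buildToyComplex(toyComplexSpec(c(3.40, 3.60)))
  tr <- annotateByDistance(toy$complex, 3.5)$A
  expect_identical(siteLabels(tr), c(1L, 0L))
  # boundary equality is non-binding
  toy_eq <- buildToyComplex(toyComplexSpec(c(3.5)))
  expect_identical(siteLabels(annotateByDistance(toy_eq$complex, 3.5)$A), 0L)
})

test_that("labels at several cutoffs match the brute-force all-pairs scan", {
  oracle_dist <- brute_min_residue_dist(toy30$complex)
  expect_equal(max(abs(oracle_dist - toy30$truth$targetDistance)), 0,
               tolerance = 0.05)
  for (cutoff in c(3.5, 4.5, 5.5, 6.0)) {
    tr <- annotateByDistance(toy30$complex, cutoff)$A
    expect_identical(siteLabels(tr), as.integer(oracle_dist < cutoff))
    expect_equal(labelDetail(tr), oracle_dist, tolerance = 1e-9)
  }
})

test_that("binding sets are nested as the cutoff grows", {
  cutoffs <- c(2.5, 3.5, 4.5, 5.5, 6.0, 8.0)
  sets <- lapply(cutoffs, function(co)
    which(siteLabels(annotateByDistance(toy30$complex, co)$A) == 1L))
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("distance labels are invariant under rigid-body motion", {
  cx <- toy30$complex
  a <- atoms(cx)
  moved <- a
  xyz <- random_rigid_transform(as.matrix(a[, c("x", "y", "z")]), seed = 17)
  moved[, c("x", "y", "z")] <- xyz
  cx2 <- new("ComplexStructure", structureID = "moved", atoms = moved)
  for (co in c(3.5, 6.0))
    expect_identical(siteLabels(annotateByDistance(cx2, co)$A),
                     siteLabels(annotateByDistance(cx, co)$A))
})

test_that("annotation demands a DNA partner and a sane cutoff", {
  toy <- buildToyComplex(toyComplexSpec(c(3, 4)))
  a <- atoms(toy$complex)
  protein_only <- new("ComplexStructure", structureID = "p",
                      atoms = a[a$polymer == "protein", ])
  expect_error(annotateByDistance(protein_only), "no DNA chain")
  dna_only <- new("ComplexStructure", structureID = "d",
                  atoms = a[a$polymer == "dna", ])
  expect_error(annotateByDistance(dna_only), "no protein chain")
  expect_error(annotateByDistance(toy$complex, cutoff = 1), "2-10")
  expect_error(annotateByDistance(toy$complex, cutoff = 15), "2-10")
})

test_that("distant DNA produces zero delta-ASA and no binding labels", {
  toy <- buildToyComplex(toyComplexSpec(c(25, 30, 28), dnaLength = 6L))
  tr <- annotateByDeltaASA(toy$complex)$A
  expect_identical(siteLabels(tr), c(0L, 0L, 0L))
  expect_equal(labelDetail(tr), c(0, 0, 0))
})

test_that("a DNA atom 3 A from a residue's face buries over 1 A^2", {
  toy <- buildToyComplex(toyComplexSpec(c(3.0, 24, 26), dnaLength = 4L))
  tr <- annotateByDeltaASA(toy$complex, threshold = 1)$A
  expect_identical(siteLabels(tr), c(1L, 0L, 0L))
  # cross-check the buried area with the Monte-Carlo oracle
  a <- atoms(toy$complex)
  prot <- a[a$polymer == "protein", ]
  all_xyz <- as.matrix(a[, c("x", "y", "z")])
  unbound <- mc_sasa_oracle(as.matrix(prot[, c("x", "y", "z")]), prot$element,
                            n_points = 24000L)
  bound <- mc_sasa_oracle(all_xyz, a$element, n_points = 24000L)[1:nrow(prot)]
  delta_oracle <- tapply(unbound - bound,
                         factor(prot$resno, levels = unique(prot$resno)), sum)
  expect_equal(labelDetail(tr), as.numeric(delta_oracle), tolerance = 0.1)
})

test_that("delta-ASA is non-negative and bit-reproducible", {
  tr1 <- annotateByDeltaASA(toy30$complex)$A
  tr2 <- annotateByDeltaASA(toy30$complex)$A
  expect_identical(labelDetail(tr1), labelDetail(tr2))
  expect_true(all(labelDetail(tr1) >= 0))
})

test_that("relative-mode delta-ASA thresholds on fractional area loss", {
  toy <- buildToyComplex(toyComplexSpec(c(3.0, 24), dnaLength = 4L))
  tr <- annotateByDeltaASA(toy$complex, threshold = 0.01, mode = "relative")$A
  expect_identical(siteLabels(tr), c(1L, 0L))
})

test_that("label summaries add up and reject empties", {
  t1 <- annotateByDistance(toy30$complex, 3.5)$A
  s <- labelSummary(t1)
  expect_equal(s$positives + s$negatives, 30)
  expect_equal(s$ratio, s$positives / s$negatives)
  expect_error(labelSummary(list()), "no label tracks")
  # two tracks with 3+2 binding of 10+10 residues -> 5/15
  mk <- function(labs) new("ResidueLabelTrack", structureID = "s",
    chainID = "A", residues = data.frame(resno = seq_along(labs), insert = "",
      resname = "ALA", index0 = seq_along(labs) - 1L),
    labels = as.integer(labs), criterion = "distance", threshold = 3.5,
    unit = "angstrom", detail = as.numeric(labs))
  s2 <- labelSummary(list(mk(c(rep(1, 3), rep(0, 7))),
                          mk(c(rep(1, 2), rep(0, 8)))))
  expect_equal(s2$positives, 5)
  expect_equal(s2$negatives, 15)
  expect_equal(s2$ratio, 1 / 3)
})

test_that("label tracks export the declared TSV surface", {
  tr <- annotateByDistance(toy30$complex, 3.5)
  f <- tempfile(fileext = ".tsv")
  writeLabelTracks(tr, f)
  d <- read.delim(f)
  expect_named(d, c("structure_id", "chain_id", "seq_number",
                    "insertion_code", "res_name", "index0", "label",
                    "criterion", "threshold"))
  expect_equal(nrow(d), 30)
  expect_identical(as.integer(d$label), siteLabels(tr$A))
})
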