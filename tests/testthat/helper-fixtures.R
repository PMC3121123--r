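# ---- hand-written PDB fixtures ---------------------------------------------

minimal_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  P    DA B   1       1.000   2.000   3.000  1.00  0.00           P",
    "TER",
    "END", sep = "\n")
}

altloc_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      12.000   7.000  -5.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1      12.100   7.100  -5.100  0.60  0.00           C",
    "ATOM      4  P    DA B   1       1.000   2.000   3.000  1.00  0.00           P",
    "END", sep = "\n")
}

multimodel_pdb_text <- function() {
  body1 <- minimal_pdb_text()
  body2 <- gsub("11.104", "99.000", body1, fixed = TRUE)
  paste("MODEL        1", sub("\nEND$", "", body1), "ENDMDL",
        "MODEL        2", sub("\nEND$", "", body2), "ENDMDL", "END",
        sep = "\n")
}

write_pdb_fixture <- function(text) {
  f <- tempfile(fileext = ".pdb")
  writeLines(text, f)
  f
}

# ---- independent oracles ---------------------------------------------------

# all-pairs brute-force minimum residue-to-DNA distance, plain double loop
brute_min_residue_dist <- function(cx) {
  a <- atoms(cx)
  prot <- a[a$polymer == "protein", ]
  dna <- a[a$polymer == "dna", ]
  keys <- unique(paste(prot$chain, prot$resno, prot$insert, sep = "\r"))
  vapply(keys, function(k) {
    ra <- prot[paste(prot$chain, prot$resno, prot$insert, sep = "\r") == k, ]
    best <- Inf
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(dna))) {
      d <- sqrt((ra$x[i] - dna$x[j])^2 + (ra$y[i] - dna$y[j])^2 +
                  (ra$z[i] - dna$z[j])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
}

# Monte-Carlo SASA oracle: independent random directions instead of the
# deterministic golden spiral, at much higher point density
mc_sasa_oracle <- function(xyz, elements, probe = 1.4, n_points = 96000L,
                           radii = defaultVdwRadii(), seed = 99L) {
  set.seed(seed)
  el <- toupper(elements)
  r <- ifelse(el %in% names(radii), radii[el], radii[["default"]]) + probe
  n <- nrow(xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    dir <- matrix(rnorm(n_points * 3), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    p <- sweep(dir * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= r[j]^2
    }
    areas[i] <- mean(free) * 4 * pi * r[i]^2
  }
  areas
}

# connected components of the <= cutoff distance graph by union-find
union_find_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# same partition irrespective of component numbering
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}

random_rigid_transform <- function(xyz, seed = 1L) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 20)
  sweep(xyz %*% R, 2, shift, "+")
}
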