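---
title: "Stacked prediction of protein DNA-binding residues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked prediction of protein DNA-binding residues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DNABindStack)
```

## The problem

Transcription factors, polymerases and repair enzymes act through
protein–DNA contacts, but only a few hundred protein–DNA complex
structures exist against millions of known protein sequences. Sequence-based
predictors of DNA-binding residues therefore matter, and several are
available online — each trained on its own dataset, with its own
binding-site definition and output convention, which makes them hard to
compare and leaves complementary signal on the table. DNABindStack
implements the stacking answer to this: treat the per-residue outputs of
six established base predictors as a six-component feature vector and
learn a second-level maximum-margin classifier on top, together with the
structural machinery needed to build gold-standard labels and to evaluate
residue-level predictions honestly on heavily imbalanced data.

## Gold-standard annotation

Given a complex structure, `annotateByDistance()` labels residue $i$
binding iff

$$\min_{a \in \mathrm{atoms}(i),\; b \in \mathrm{atoms}(\mathrm{DNA})}
  \lVert a-b \rVert < t,$$

with a strict inequality (boundary equality is non-binding) and the
default $t = 3.5$ Å. Thresholds between 3.5 and 6.0 Å are all in common
use; growing $t$ only ever grows the binding set (the label sets are
nested, which the tests assert as a property), and the 3.5 Å default is
the choice that favours sensitivity of the downstream predictor. "Any
atom" means any atom present in the coordinate file: hydrogens are kept
if present (a flag strips them), HETATM records are excluded by default
so waters and ligands cannot create false contacts (modified residues can
be whitelisted via `proteinExtra`), and RNA chains are excluded from the
partner set unless requested.

The alternative criterion, `annotateByDeltaASA()`, calls a residue
binding when it loses solvent-accessible surface area upon DNA binding:
$\Delta ASA_i = ASA_i(\text{protein alone}) - ASA_i(\text{protein+DNA})
\ge \tau$. Two conventions for $\tau$ circulate — an absolute loss
(default, 1 Å²) and a relative loss (1 % of the residue's unbound area) —
and they are not equivalent; both are implemented (`mode = "absolute"` /
`"relative"`) and neither is claimed to be the other's substitute.

### The SASA engine

SASA is computed by the Shrake–Rupley method: for each atom, $n$
quasi-uniform points are placed on its solvent-expanded sphere (van der
Waals radius + probe radius), and the accessible fraction — points
strictly outside every neighbour's expanded sphere — times the expanded
sphere's area $4\pi(r+p)^2$ estimates the atom's accessible area.
Choices that matter:

* **Point placement** is a deterministic golden spiral, not random
  sampling, so annotation is bit-reproducible and $\Delta ASA \ge 0$
  holds exactly (adding context atoms can only bury points).
* **Defaults**: probe 1.4 Å (water), 960 points/atom (closed-form
  agreement within 1 % for an isolated atom; at least 100 points are
  required), radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 Å with
  a 1.80 Å fallback for unlisted elements.
* **Limits**: a small atom strictly inside a larger one is fully buried;
  two equal nearly-coincident atoms each keep about half their sphere
  (their union tends to a single sphere's area). The test suite checks
  both limits and compares 20-atom clusters against an independent
  Monte-Carlo estimator run at 100-fold point density.

## Feature encoding

`encodeTracks()` assembles one row per residue and one column per
registered predictor, in a fixed registration order (disis, dnabindr,
bindn, bindn_rf, dpbind, dbs_pred). Binary predictors (DP-Bind,
DBS-PRED analogues) contribute $+1$ for a binding call and $0$
otherwise. The four scoring predictors publish no common scale, so their
scores are min–max-normalised per track to $[0,1]$ by default — the RBF
kernel is scale-sensitive, and normalisation is idempotent and the
identity on $\{0,1\}$-valued tracks; a `raw` pass-through mode exists for
pre-scaled inputs. A track with no spread maps to the constant $0.5$. A
predictor that returned nothing is imputed with a neutral constant 0 and
flagged in an availability mask (kept out of the feature width by
default, preserving the six-column design); at least one track must be
available.

## The meta-classifier

Labels are encoded $+1$ (binding) / $-1$ (non-binding). At the
gold-standard imbalance (5342 binding / 67396 non-binding residues,
about 1:12.6) a margin classifier collapses to the all-negative rule, so
each *training* set is rebalanced by `undersampleNegatives()`: all
positives are kept and negatives are drawn uniformly without replacement
down to `ceiling(ratio * positives)` (default ratio 1, capped at the
negatives available). Held-out folds are never touched — evaluation is
always at natural imbalance, and the per-fold composition records in
`CrossValResult` assert it.

The classifier is an RBF-kernel SVM (libsvm through e1071,
`scale = FALSE` since encoding already fixes the scale). Hyperparameters
are selected by a cross-validated grid search maximising strength over
cost $\in \{2^{-3}, 2^{-1}, \ldots, 2^{7}\}$ and kernel width
$\gamma \in \{2^{-7}, 2^{-5}, \ldots, 2^{3}\}$. Design choices:

* **Tuning scope** (`tune`): the default `"once"` searches the grid on
  the first fold's training portion only — never on held-out data — and
  reuses the selection for every fold, so all folds run an identical
  configuration and the full grid is not refitted ten times.
  `"per-fold"` re-tunes inside every fold; `"none"` uses fixed values.
* **Tuning cost control**: the search subsamples to at most `tuneMax`
  rows (default 1500) and uses 3 inner folds; undersampling happens once
  per fold, not per grid point, for determinism.
* **Folds** (`makeFolds()`): sizes differ by at most one unit. The
  default `foldUnit = "residue"` partitions residues directly, mirroring
  the residue-level convention of the published cross-validation;
  `"protein"` keeps whole proteins within one fold and is the
  recommended setting when proteins contribute many residues each, since
  residue-level folds let a protein's residues appear on both sides of a
  split.
* **Decision rule**: sign of the decision value (0 cut), with the sign
  normalised so positive always means binding; no probability
  calibration.
* **Determinism**: undersampling, folds and tuning each draw from a
  substream derived from the config seed; a `(data, config)` pair fully
  determines the cross-validation counts.

Evaluation uses the six standard measures. Strength — the mean of
sensitivity and specificity — is the headline balance measure on
imbalanced residue data. Measures with zero denominators are reported as
undefined (NA with a flag), never coerced to 0. `reconstructCounts()`
inverts printed (sensitivity, specificity, class totals) into real-valued
confusion cells so published summary tables can be re-derived;
`checkBenchmarkTable()` does this for the shipped benchmark rates and
compares half-up-rounded values cell by cell. Comparisons against printed
tables use half-up rounding (`roundHalfUp()`), because printed tables are
conventionally rounded half away from zero while R's `round()` is
half-to-even. Reconstruction from 2-decimal printed rates reproduces most
but not all printed cells exactly — the rates themselves are rounded, and
the check grid reports each cell's outcome rather than asserting them.

## Spatial post-filtering

`filterBySpatialClusters()` clusters predicted binding residues on their
CA coordinates with single linkage — two sites connect when their
distance is at most the link distance (coincident CAs link at 0) — and
drops components smaller than `minClusterSize`. Single linkage on a
distance threshold is the minimal parameterisation consistent with
"spatial clustering then removing small clusters"; defaults (8 Å, 3
residues) are exposed as configuration, not claimed optimal. Because the
filter only demotes positives, specificity can only rise and sensitivity
only fall — a theorem, tested as a property, and the reason the filter is
optional: genuine binding patches of 3 or fewer residues sitting alone on
the surface (a real occurrence, since a helical DNA track does not force
binding residues into one blob) are removed along with the false
positives.

## The synthetic-data generator

The generator exists so every stage is testable offline; it emulates two
things and deliberately not a third.

**Geometry** (`buildToyComplex()`): DNA as phosphorus pseudo-atoms on an
idealised helix (radius 9 Å, rise 3.4 Å, twist 36°) and protein residues
as CA + side-chain-carbon pairs placed radially so each residue's minimum
distance to the DNA equals a scripted value (within 0.05 Å; the outward
radial direction strictly increases the distance to every other helix
atom, so the scripted atom is provably the nearest). This is sufficient
for exercising distance annotation, SASA occlusion and the CA-based
filter, and is *not* chemically realistic: no full nucleotides, no side
chain diversity, no packing.

**Predictor tracks** (`simulateTracks()`): per residue, predictor $j$
emits $\mu_j(y) + \sigma_j(\lambda_j z + \sqrt{1-\lambda_j^2}\,
\varepsilon_{ij})$ with a shared standard-normal factor $z$ — the
minimal structure that makes tracks *correlated* (pairwise within-class
correlation $\lambda^2$), because inter-predictor correlation is exactly
what limits stacking gains in reality; independent simulated predictors
would make dominance trivially easy. Default separations are set so each
predictor's midpoint-threshold strength $\Phi(d/2)$ equals one of the six
published single-predictor strengths (0.59–0.75), with loading
$\lambda = 0.5$; binary-kind profiles threshold at the midpoint, where
sensitivity equals specificity. Labels are drawn i.i.d. at the benchmark
fraction $5342/72738 \approx 0.073$. What the simulation does **not**
model: sequence autocorrelation along the chain, per-protein
heterogeneity, systematic (non-Gaussian) predictor failure modes, and
missing-track patterns. Passing the stacking-dominance test therefore
shows the pipeline extracts complementary signal under realistic
imbalance and correlation — it does not certify performance on real
server outputs.

## Problem sizes and numerical notes

The test-suite simulations use $n = 2\times10^4$ residues over 10 seeds
for the stacking-dominance property (the meta-classifier's pooled
cross-validated strength must beat the best single predictor's
oracle-threshold strength in at least 9 of 10 seeds — the single
predictor gets an in-sample oracle threshold, the stacker does not, so
the comparison is conservative) and $n = 4000$ at positive fraction 0.2
for the null calibration (pooled strength within $0.45$–$0.55$ per seed;
at 800 positives the binomial noise of pooled sensitivity is about
0.018, comfortably inside the band). Distance computations are exact
block-wise vectorised scans — identical to the brute-force all-pairs
result, which the tests assert — rather than approximate neighbour
indexing; at these sizes an index would add code paths without measurable
benefit. PDB parsing and writing go through bio3d, with the altloc
policy (keep highest occupancy, ties by altloc letter) and the
multi-model policy (first model by explicit default; `"strict"` errors)
applied on top.

## Known limitations

* The six real base predictors are represented by a file-based track
  interface and the simulator; no HTTP clients are provided, so end-to-end
  accuracy against the original servers is out of reach by design.
* mmCIF input, biological assemblies and symmetry mates are not handled.
* Treatment of modified amino acids/nucleotides is configuration
  (`proteinExtra`), not inference: coordinate files vary and no single
  default is right.
* The ΔASA criterion's absolute-vs-relative threshold ambiguity is left
  as an explicit mode rather than resolved.
* Fold-unit choice changes what cross-validation measures (residue- vs
  protein-level generalisation); both are supported and the residue-level
  default mirrors the published protocol rather than endorsing it.
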