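---
title: "Estimating the size of the plant chemical space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the size of the plant chemical space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytospace)
```

# The problem

Plants produce two broad classes of metabolites: primary compounds shared
across most species, and specialized (secondary) metabolites that are often
species- or clade-specific. Because only a small fraction of the ~400,000
known plant species has been profiled chemically, the total number of
distinct plant metabolites is unknown; literature databases document on the
order of a hundred thousand unique structures, while untargeted LC-MS/MS
datasets suggest the true number is far larger. `phytospace` estimates that
number by (i) counting unique structures as species accumulate, under
several annotation strategies with different failure modes, and (ii)
extrapolating the accumulation with a power law.

This vignette records the package's model, its tunable parameters, the
numerical choices behind them, and what the synthetic-data experiments do
and do not demonstrate.

# Counting unit: the stereochemistry-free structure key

All structure counting uses the first 14 characters of the standard
InChIKey. This block hashes skeleton and connectivity only — stereochemistry
lives in the second block — so stereoisomers collapse to one key. That is
deliberate: MS2-based annotation cannot distinguish stereoisomers, and
counting them separately would inflate every estimate. Standard InChI
settings are used, with no desalting or charge neutralization before keying
(no further standardization is assumed of the inputs; a pre-standardized
table can always be supplied).

Malformed SMILES are rejected before conversion by a light well-formedness
check (balanced parentheses and brackets, paired ring-closure digits, legal
tokens). The underlying toolkit accepts some structurally broken strings
silently, so this screen is what gives `load_compound_table()` its audited
rejection counts.

Murcko scaffolds (ring systems plus the linkers between them, side chains
removed) provide a coarser counting unit for diversity analyses. The
implementation prunes terminal atoms of the molecular graph to a fixed
point — what survives is exactly rings plus linkers — then re-attaches atoms
multiple-bonded directly to that framework (exocyclic carbonyls and imines
are conventionally part of the scaffold). Acyclic molecules have no
scaffold and are excluded from scaffold curves rather than keyed as an
empty scaffold, which would merge all acyclic compounds into one spurious
class. The unit tests pin this behaviour to an independent cheminformatics
implementation on a frozen panel of ring-bearing structures.

# Taxon harmonization

Literature tables carry free-text species names. Names are
whitespace-normalized and matched case-insensitively and exactly — no fuzzy
matching, which would trade silent errors for coverage. A name present in
several nomenclatures is assigned exclusively by the priority NCBITaxon >
ITIS > WFO. Plant status is decided by NCBI ancestry (descent from
Viridiplantae, NCBITaxon:33090); for ITIS and WFO, which carry no ancestry
here, an `is_plant` column in the lookup tables substitutes. Synonym
mapping is supported but off by default.

# Spectrum quality and adduct filters

Three filters precede any estimate, each with an exact boundary:

* **Minimum peaks** — spectra with *fewer than* 5 peaks are removed; a
  5-peak spectrum stays.
* **Dominating peak** — spectra whose largest peak carries *strictly more
  than* 90% of total intensity are flagged as uninformative; exactly 90% is
  not flagged. The flag statistic is computed on unfiltered spectra, before
  the peak-count filter.
* **Adduct** — only features predicted as `[M+H]+` are kept for
  structure-based curves, avoiding one-molecule-many-adducts overcounting
  at the cost of discarding other ionization forms (a conservative bias).
  The formula curve skips this filter, since formula prediction accounts
  for adducts itself.

Library-search annotations split into *known* (confidence ≥ 0.5, inclusive
— the threshold itself counts as known) and *unknown*; the hybrid strategy
uses library keys for known features and de novo keys for the rest.

# Entropy similarity and clustering

The spectral entropy of a spectrum is the Shannon entropy of its
intensity-normalized peaks, `S = −Σ pᵢ ln pᵢ`. Similarity between two
spectra is

```
sim(A, B) = 1 − (2·S_AB − S_A − S_B) / ln 4
```

where `S_AB` is the entropy of the merged spectrum placing `(p_A + p_B)/2`
on the matched peak union. Identical spectra score exactly 1; peak-disjoint
spectra score exactly 0 (the merged entropy `ln 2 + (S_A + S_B)/2` cancels
in closed form). In the metric's standard weighted form, any spectrum with
`S < 3` is first reweighted `pᵢ ← pᵢ^(0.25 + 0.25·S)` and renormalized,
damping spectra dominated by one or two peaks; self-similarity remains 1
because both copies are reweighted identically.

Numerical choices:

* **Peak matching** is greedy-nearest within `mz_tol` (default 0.02 Th, a
  typical fragment tolerance for high-resolution instruments; the metric's
  reference does not fix one).
* **Blocking**: only pairs whose precursors differ by at most `ppm_window`
  (default 10 ppm, alternative 200 ppm) are ever compared; all other pairs
  are similarity 0 by definition. The ppm is computed relative to the pair
  mean m/z, a symmetric convention. The implementation sorts by precursor
  and sweeps a window, but the contract is exact pair semantics, which the
  tests verify against an all-pairs oracle.
* **Thresholding** is inclusive: an edge at exactly the threshold is kept.
  Clusters are connected components; spectra with no retained edge are
  singletons. Cluster ids are assigned in ascending order of each
  component's minimum feature id, so labels are dense from 0 and invariant
  to input order.
* Cluster counts are non-increasing as the threshold drops (edges only
  accumulate), and a 10-ppm edge set is a subset of the 200-ppm one — both
  are asserted as properties.

Each connected component is treated as one chemical structure. This
undercounts when distinct molecules share fragmentation patterns within a
ppm block and overcounts when acquisition differences split one compound —
the generator's noise model (below) exercises exactly this trade-off.

# Saturation curves and power-law projection

For each strategy (unique formulas, de novo structure keys, hybrid keys,
cluster ids) the cumulative count of distinct keys `y[k]` is computed over
species `1..k` in a fixed ordering — lexicographic by taxon id, a
deterministic stand-in for an arbitrary-but-fixed ordering; permutation
analysis (`permutation_stability()`) confirms the final value is
order-free and summarizes the envelope of intermediate values.

`fit_power_law()` fits `y = a·xᵇ` by nonlinear least squares on the
original scale, initialized from OLS on `log y ~ log x`. The log-log
initialization makes convergence essentially immediate on accumulation
curves; fitting in linear rather than log space weights the (larger,
better-determined) tail of the curve rather than its first points. `x` is
the 1-based species index. The form has no intercept: an accumulation
curve passes near the origin region by construction. Holdout validation
withholds the last 10/20/30% of species, refits on the prefix, and reports
MAPE and RMSE on the suffix; on an exact power law the error is zero at
machine precision, and on curves that plateau the error grows with the
holdout fraction — both are test assertions. `project()` evaluates the
fitted law at a target species count (default 400,000, the approximate
size of the plant kingdom). Power-law extrapolation is an assumption, not
a consequence of the data: if real accumulation flattens beyond the fitted
domain, projections are upper-biased, which is why the holdout report
accompanies every fit.

Literature-versus-MS coverage (`coverage_ratio()`) asks, per species with
at least 20 unique literature structures, what fraction of those structures
has *some* adduct-shifted precursor m/z within tolerance (default 10 ppm,
matching the clustering window) of *some* observed feature. The default
adduct table covers the common positive electrospray forms ([M+H]+,
[M+Na]+, [M+K]+, [M+NH4]+, [M+H−H2O]+, all singly charged, shifts in Da
with the electron mass accounted); it is a configurable default, not an
exhaustive list. The ratio is an upper bound on coverage: a matching m/z
need not be the same compound. MS1 fold curves round precursor masses to 2
decimals (round-half-even) and report the multiplicative growth of unique
masses as samples accumulate.

# The synthetic plantome

The generator emulates the structure of the real study inputs so every
stage is testable with planted truth:

* **Incidence** — each of `n_species` species draws `core_per_species`
  compounds from a shared pool of `core_pool_size` (recurring primary
  metabolites) plus `Poisson(novel_per_species_mean)` species-unique
  specialized metabolites. The defaults (200 species, pool 500, 8 core +
  mean 22 novel) plant roughly 5,000 unique compounds — a scale at which
  per-species specialized chemistry dominates, as it does in plants, while
  the full pipeline stays interactive on one CPU. Compound masses are
  uniform in 100–1500 Da, the usual LC-MS/MS acquisition range.
* **Spectra** — each compound owns a deterministic 5–30-peak fragment
  template (seeded by compound id, so its spectra are recognizably similar
  wherever it occurs). Replicate acquisitions (default 3) add log-normal
  intensity noise (sdlog 0.2), fragment m/z jitter within ±0.01 Th (half
  the default match tolerance), 2 ppm precursor jitter, and 3% chances of
  dropping or gaining a peak — the magnitude of variation between replicate
  acquisitions of one extract. Ten percent of features are assigned
  `[M+Na]+` instead of `[M+H]+`, with the matching precursor shift, so the
  adduct filter has something to do.
* **Annotations** — library-search rows are correct with probability
  `q_library` with Beta(8,2) confidences when correct and Beta(2,8) when
  wrong (so the 0.5 threshold separates them imperfectly, as real
  confidence scores do); de novo rows are correct with probability
  `q_denovo`, otherwise perturbed to a key guaranteed disjoint from the
  truth (true keys begin A–M, perturbed keys N–Z); formula rows are correct
  with probability `q_formula`.

All three generators are bit-for-bit reproducible from (parameters, seed).

What passing tests on this synthetic world show: the clustering machinery
recovers a planted compound inventory (within ±10% at threshold 0.7 /
10 ppm under default noise — in practice within a fraction of a percent),
perfect annotations reproduce the truth curve exactly, and fitting plus
projection closes the loop on planted power laws. What they do not show:
real fragmentation chemistry (templates are random peaks, not bond
cleavages), isotope envelopes, retention behaviour, correlated annotation
errors, or the taxonomic sampling biases of public repositories. The
synthetic recovery rate is therefore a check of the estimator's internal
consistency, not a field-accuracy claim.

# Degenerate inputs and edge cases

Empty spectra, all-zero intensities, non-positive masses, empty adduct
tables and too-short curves raise immediate errors naming the violated
precondition. Curves of fewer than 3 points cannot be fitted; a first MS1
sample with no masses has no defined fold. Jaccard overlap of two empty
sets is defined as 0 with a warning. Unresolvable species names stay in
the output as unresolved records rather than disappearing, and taxa whose
ids are missing from the ancestry table are dropped with a count.

# Pipeline scale and reproducibility

`run_full_estimate()` snapshots its full config (every threshold above in
one list) into the run manifest together with per-stage record counts, so
raw ≥ after-min-peaks ≥ after-adduct is checkable after the fact and a rerun
from the same config and seed reproduces curve TSVs and model JSONs
byte-for-byte. The default simulated run — 200 species, ~18,000 spectra,
~40,000 candidate pairs — completes in well under a minute; the test suite
and the acceptance script use this scale, with smaller universes (40–60
species) where only mechanics are under test.

# Known limitations

* Cluster counting inherits the resolution of entropy similarity: isomers
  co-eluting within a ppm block and fragmenting alike are one cluster.
* The adduct table is a pragmatic default; real acquisitions see more
  forms, and multiply-charged species are supported but not defaulted.
* Power-law projection assumes the accumulation regime continues far
  beyond the fitted domain; the holdout report quantifies only
  within-domain stability.
* Scaffold keys require a parseable, kekulizable structure; exotic
  organometallics may fail where the literature databases contain them.
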