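---
title: "Scoring metabolite modification of membrane-binding sites in PX domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metabolite modification of membrane-binding sites in PX domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstop)
```

## The problem

PX domains localize proteins to organelle membranes by reading
phosphoinositide (PIP) signals. Their basic residues — lysines and arginines
that hydrogen-bond PIP headgroups — are also frequent targets of
metabolite-based post-translational modification (acetylation, methylation,
succinylation, malonylation, butyrylation, glycation and relatives). A
modification on a membrane-binding residue is positioned to erase the
domain's membrane-reading function, the same way phosphorylation of
Ser/Thr/Tyr in the binding sites ("PIP-stops") does. This package implements
the indices and the statistical battery needed to study that intersection
quantitatively on the human PX superfamily, plus a synthetic generator so
every stage can be exercised with known ground truth.

## The indices

**Lipid Specificity Index (LSI).** The seven PIPs split into two classes by
the count of phosphates on the inositol ring: mono (PI3P, PI4P, PI5P; codes
`3`, `4`, `5`) and poly (`34`, `35`, `45`, `345`). A domain is assigned to
the class holding the majority of its ligands, and

$$\mathrm{LSI} = 10 - n_1 - 2 n_2,$$

where $n_1$ is the number of *additional* in-class ligands and $n_2$ the
number of out-of-class ligands. A single-PIP binder scores 10, a binder of
all seven scores 1, and a domain with no detectable PIP binding is the
sentinel 0 — a category, not the bottom of the scale, which is why the
monotonicity property (adding a ligand never raises the LSI) is stated for
binders only. When the class counts tie, the two assignments give identical
LSI — with $m$ ligands per class the penalty is $(m-1) + 2m$ either way — so
no tie-break is needed; `compute_lsi()` labels such domains `"tie"` and the
test suite proves the equality exhaustively over all $2^7$ ligand subsets.
LSI bins define the selectivity classes: 10 absolute, 8–9 high, 5–7 medium,
1–4 low.

**MET-stop and PIP-stop scores (MSS, PSS).** Modification evidence is
weighted by its reproducibility: a modification reported by one study adds
1, by 2–4 studies adds 2, by 5 or more adds 3 (`stop_weight()`). A
modification contributes to a domain's score only if its residue falls
inside one of the three consensus membrane-binding site windows; `mode =
"met"` counts metabolite chemistry on K/R (the MSS), `mode = "pip"` counts
phosphorylation on S/T/Y (the PSS). A modification is keyed by (protein,
species, residue, type); rows sharing a key are pooled by the maximum study
count so no study is double-counted, and records from homolog species count
toward the human domain's score by default (restrictable via `species`),
since cross-species evidence is part of how the published scores were
tallied. Whether one should instead pool counts per residue *across* species
is not decidable from the published description; we score each species
record separately by default and expose the `species` filter as the
alternative.

**Membrane Affinity Index (MAI).** A three-way label — S (strong,
approximately nanomolar affinity for bilayers containing the cognate PIP), W
(weak, micromolar), N (no binding). The published definition gives only the
order-of-magnitude anchors, so the numeric classifier cuts at Kd = 1 µM;
the boundary value itself classifies W.

## Site windows

The three consensus membrane-binding elements — the β1–β2 membrane-insertion
loop (site 1), the β3 strand into helix α1 with the RRY motif (site 2), and
the proline-rich-element loop into α2 (site 3) — are represented as
inclusive 1-based alignment-column ranges (`site_windows()`), and a residue
is classified by the column its position maps to. The packaged default
(`default_site_windows()`) is a *reconstruction*: the original analysis
chose its boundaries on a manually adjusted superfamily alignment that was
never published as machine-readable columns. Stop-score recomputation from
raw modification records is therefore validated on synthetic alignments with
known windows, not against the published per-domain score columns, which the
package treats as fixture data. For SNX5/SNX6/SNX32, whose site-1 loop is a
protein-binding element rather than a membrane inserter, the uniform window
rule still applies by default, matching the published tallies' lack of any
stated exclusion.

Per-residue membrane-propensity profiles are an optional input: scores
strictly above 30 flag a probable docking role (`membrane_interactive()`),
and `total_site_score()` sums the in-site scores. All index computation and
statistics run without profiles.

## The statistical battery

`run_paper_battery()` runs the five analyses relating the per-domain
indices — PSS~MSS, PSS~LSI, MSS~LSI, expression~MSS, expression~PSS — each
as a simple least-squares regression (F on (1, n−2) df) plus the matching
Pearson correlation (p from the t transform on n−2 df), all two-sided.
Missing values are deleted pairwise per analysis, not listwise: that is what
produces the mixed pattern where MSS/PSS/expression analyses use all 50
domains but LSI-based analyses use 49 (PXDC1, whose ligands are
undetermined, drops out). Undetermined cells are typed sentinels (`NA`),
never zeros, precisely so that exclusion works per analysis without
corrupting the others. No multiple-testing correction is applied, matching
the original analysis.

The paired enrichment test compares, per domain, the proportion of K/R
residues carrying a metabolite modification inside the site windows versus
outside, with a paired t-test across domains. The proportion denominator —
all K/R residues in the region — is the natural reading of "relative
proportion of modified arginine and lysine residues", but the original
denominator is unstated, so this normalization is flagged as a
reconstruction. The published t value cannot be reproduced directly because
per-domain outside-site modification inventories were never printed; the
test is instead validated by simulation (below).

## The synthetic generator

`gen_domain_set()` emulates the study's inputs with known ground truth:
`n_domains` sequences of `sequence_length` residues, K/R placed
independently at `kr_density`, three site windows covering `site_fraction`
of the columns (equal windows centered in each third of the sequence), and
metabolite modifications planted on K/R at rate `base_mod_rate` outside and
`enrichment * base_mod_rate` inside. Study counts follow a unit-shifted
Poisson by default (skewed like citation counts while keeping all three
weight bins reachable). Defaults — 50 domains, 120 residues, site fraction
0.25, K/R density 0.3, enrichment 3, base rate 0.1 — mirror the family size
and the basic-residue-rich character of PX membrane-binding surfaces.
Sequences are generated gap-free at a single length, so the emitted
alignment is the identity mapping; real alignments with gaps are exercised
separately in the unit tests. A single integer seed drives every draw, and
emitted text files are byte-reproducible under it.

`gen_feature_table()` draws latent multivariate-normal (MSS, PSS, LSI,
expression) vectors under a configurable correlation matrix (defaulting to
the empirical pattern of the published feature table), then integerises:
MSS/PSS as rounded latent Gaussians truncated at zero, LSI rounded and
clamped to 0–10, expression truncated at zero. The truth attribute stores
the *latent* correlations because truncation and rounding shrink the
observable correlations slightly; the recovery test's ±0.05 band at n = 5000
is honest about that discretisation bias.

What the generator does *not* emulate: phylogenetic structure among homolog
records, realistic amino-acid composition beyond the K/R density, gapped
alignments, 3D structure or propensity surfaces (optionally uniform-random
only). Passing tests on synthetic data therefore demonstrate the pipeline's
correctness and the test's calibration, not the biological claims
themselves.

## Calibration results the suite computes

The acceptance tests run `simulate_enrichment_test()` at `enrichment = 1`
(1000 replicates: the type-I error of the paired test must sit in
0.05 ± 0.02) and at `enrichment = 3` with the default rates (500
replicates: power must reach 0.8). The regression/correlation/t formulas are
additionally checked against hand-rolled covariance and normal-equation
oracles to 1e−10. Replicate counts were chosen so the whole suite runs in a
few minutes on one CPU; the binomial standard error at 1000 replicates
(≈0.007) is comfortably inside the ±0.02 acceptance band.

## Numerical and degenerate-input choices

Zero variance in a correlate, fewer than 3 complete pairs, or all-zero
paired differences raise typed errors rather than returning NaN. The battery
skips an analysis that errors, records why in its notes, and fails only if
*no* analysis can run. Domains with no K/R on one side of the window
partition are dropped from the paired test (their proportion is undefined)
with a message. The propensity threshold is strict (a score of exactly 30 is
not membrane-interactive). Flanking nonamers pad with `-` at termini and are
validated to carry exactly one lowercase letter at the center; the
residue-token letter is cross-checked against that center on load.

## Known limitations

* The default site windows are a reconstruction; recomputed MSS/PSS values
  on real alignments depend on the user's window choice.
* The packaged modification table carries `study_count = 1` everywhere
  because per-modification reference tallies were not published; weight bins
  2 and 3 are exercised on declared or synthetic counts.
* Two of the published statistics (the MSS–LSI correlation and the
  expression-on-MSS regression equation) are internally inconsistent with
  the published feature table itself; the package reports what the table
  yields (r = 0.0855; slope 3.7153, intercept 17.1619) while the matching
  F, R² and correlation statistics reproduce the printed values exactly.
* Ubiquitination is outside the MET-stop definition and is not handled.
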