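---
title: "Methods: degron discovery, mutation annotation, and resistance calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degron discovery, mutation annotation, and resistance calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronr)
```

This vignette documents the models and procedures implemented in `degronr`,
the assumptions behind them, the parameters that matter, and the design
choices made where the design was genuinely open. It states no empirical
result that the package's tests and acceptance script do not themselves
compute.

## The biological setting

Most regulated intracellular protein degradation runs through the
ubiquitin–proteasome system: an E3 ubiquitin ligase binds a *degron* — a
short linear motif on the substrate — positioning nearby lysines for
ubiquitin transfer. Degrons are compact (roughly 3–10 residues), tend to sit
in disordered, solvent-exposed regions, are more conserved than their
immediate neighborhood, and are frequently gated by post-translational
modifications (phosphorylation on S/T/Y, ubiquitination on K) in or near the
motif. Missense mutations that alter the motif, remove a regulatory PTM
site, or substitute the acceptor lysine can stabilize the protein; in tumor
cell lines such mutations are associated with drug resistance.

All residue coordinates in the package are 1-based inclusive, matching
protein variant nomenclature (T368M means position 368).

## Motif scanning

Consensus patterns are compiled under a deliberately small, auditable
grammar rather than full regular expressions: uppercase literals, the
wildcard `x`/`.`, residue classes `[...]` and `[^...]`, and bounded
repetition `{m,n}` with `n ≤ 10`. Full regex is intentionally not exposed so
a motif table remains reviewable at a glance. Three semantic rules are fixed:

* the unknown residue `X` satisfies a wildcard (an unknown residue is *some*
  residue) but never a literal or a class — including negated classes,
  which are compiled to their positive complement over the 20-letter
  alphabet;
* matching reports, at every start offset, the maximal (greedy) match, so
  there is exactly one match per (motif, start) and overlapping matches are
  all kept; duplicates are removed only at identical
  (motif, protein, start, end);
* with `internal_only` (the default) matches touching either terminus are
  discarded, restricting the scan to internal motifs; terminal
  (N-/C-end) degron chemistry is out of scope.

The scanner is tested for exact equivalence against a brute-force
every-offset oracle on hundreds of random sequences, and for order
independence of its sorted output.

The per-proteome diagnostic `match_length_correlation()` reports the Pearson
correlation between per-protein match count and protein length. Raw
consensus matches are dominated by chance hits, which scale with length;
genuine degrons do not. A drop in this correlation after probability
filtering is therefore used as a global false-positive indicator.

## Feature aggregation

Each candidate span is summarized into a fixed registry of features:
per-residue track means over the span (disorder, accessibility,
coil/helix/sheet, rigidity, stabilization, domain flag), a conservation
contrast `mean(span) − mean(flanks)` (positive = span more conserved than
its neighborhood), PTM counts within the span ±11 residues (clipped at the
termini), and the flanking-lysine distribution (count, nearest distance,
presence flag — distance is 0 with presence 0 when there is no flank
lysine, so the pair is unambiguous). The 11-residue flank is the package-wide
default window half-width, shared with mutation mapping.

Two conventions are stated explicitly because they are otherwise arbitrary:

* the midpoint of an even-length span rounds toward the N-terminus
  (`c = floor((start + end)/2)`), used by both the 20-residue logo fragments
  and the 50-residue classifier windows; fragment/window positions beyond
  the termini are `X`-padded, and every position before residue 1 or after
  the last residue counts as one pad;
* proteins missing from the track table have track features imputed by the
  proteome-wide mean and the row flagged `imputed`, so models can exclude
  such rows rather than silently learning from imputation.

How disorder, accessibility, conservation, rigidity, or stabilization are
*predicted* is delegated to the track producer: the package consumes tracks
as input. `proxy_tracks()` provides a crude, clearly labeled fallback
(window-smoothed inverse hydropathy for disorder/accessibility, flat values
elsewhere) whose only purpose is to keep the pipeline runnable with no
external predictor.

Background peptides are drawn per positive: same protein, same length,
uniform over all placements that do not overlap any annotated degron span,
seeded. This makes the positive and background length distributions
identical by construction whenever every request is satisfiable, which is
what the downstream distributional comparisons assume.

## The classifier

The main model is an ensemble of 10 gradient-boosted tree classifiers
(xgboost). Each member is fit on an independent bootstrap resample (with
replacement, resample size equal to the full training set — the classical
bootstrap), with hyperparameters selected once by stratified 5-fold
cross-validation over a small declared grid (tree depth 2–3, learning rate
0.1/0.3, 60 rounds, subsample 0.8 by default; all overridable). The degron
probability is the arithmetic mean of the 10 member scores — invariant under
member permutation — and the pass threshold is strict (`p > 0.5`). The
training manifest (seed stream, bootstrap indices, selected
hyperparameters, CV scores) is kept on the fitted object so a fit can be
reproduced.

Guard rails: at least 20 rows per class, no all-constant feature, and class
imbalance capped at 100:1 (beyond that the caller is told to re-sample; the
default background ratio is 10 per positive, a compromise between
distributional coverage and training cost, adjustable via
`k_per_positive`).

A *high-priority* call is one that passed the threshold and scores above the
lowest probability observed among verified degrons of the same motif class.
Classes with no verified member yield no high-priority calls (with a
warning) rather than falling back to a global minimum.

For candidates with no usable tracks there is a sequence-only fallback: the
50-residue window around the span is embedded by an injectable provider and
fed to a fixed dense head (128 ReLU → 64 ReLU → 1 sigmoid) trained with
binary cross-entropy, Adam, and early stopping on a 20% held-out split. The
default provider is a deterministic physicochemical pooled encoding
(hydropathy/charge/volume means and maxima plus residue composition,
27 dimensions); a pretrained protein-language-model embedding can be
injected as any function from windows to a numeric matrix, but is never a
dependency. The same strict 0.5 rule is applied to the fallback's
probabilities, for want of a reason to treat it differently. The head is
implemented directly in R matrix operations; at this parameter count
(~20k weights) there is nothing a framework would add.

## Mutation annotation

A mutation hits a degron when its position falls within the span ±11
residues (inclusive, clipped). Hits are classified into exactly one of five
categories by the first matching rule in a configurable precedence order;
the default places the PTM-blocking rules first, because an annotated PTM
site names a specific mechanism, then the in-degron rule, then the
flanking-lysine rule, with network rewiring as the fallback. The ordering is
a configuration value — logged, testable, and flippable in one edit —
because no canonical tie-break exists for, say, a mutation at an annotated
phosphosite inside the motif. Whether a "blocking" PTM site must lie inside
the degron or anywhere in the window is similarly open; the default uses the
full window. The five categories partition every mapped hit, so category
counts always sum to the number of annotations — a property the tests check
on every fixture. A mutation hitting k degrons yields k annotations,
preserving record-level granularity.

## The impact score

Each annotated mutation receives
`score = w_category + w_biochem · mean(|Δh|/9, |Δq|/2, |Δv|/v_range)`,
clamped to [0, 1], where Δh is the Kyte–Doolittle hydropathy change, Δq the
formal side-chain charge change at pH 7, and Δv the side-chain volume change
(Zamyatnin volumes; range 167.7 Å³). Scores above 0.5 (strict) are
*actionable*. The published weighting scheme's exact constants are not
public, so the entire scheme is configuration-driven; the defaults (0.6 for
the three direct-disruption categories, 0.4 for flanking-lysine
substitution, 0.2 for rewiring, biochemical weight 0.4) are this package's
reimplementation defaults, validated so that the maximum attainable raw
score is exactly 1. Normalization is therefore by construction, not
per-batch min–max, so a score never depends on what else was scored with
it. Documented consequences of the formula, all under test: every score lies
in [0, 1] for all 380 ordered substitutions in every category; scores are
monotone in each category weight and each property change; and for an
identical substitution a motif-altering annotation never scores below a
rewiring one.

## Drug-resistance calling

For each treatment — a (drug, substrate, cancer type) triple, restricted to
drugs with a target mapping — cell lines of that cancer type are split into
G1 (carrying ≥ 1 mutation mapped to any degron of the substrate, same ±11
window rule) and G2 (the rest), a partition by construction. The call
compares arithmetic mean IC50 on the linear micromolar scale and flags
resistance on strict inequality of means. No significance test is applied,
because the procedure being implemented defines none; the consequence — the
flag is a coin flip under no effect — is treated as a documented property
and verified (≈50% flag rate at fold change 1), not hidden. `min_group`
defaults to 1 so a single-mutant-line worked example reproduces; with real
cohorts ≥ 3 per group is statistically saner. An arithmetic mean on the
linear scale is sensitive to outliers; a log-scale comparison is a
reasonable alternative but is not the default because the implemented rule
is the linear-mean comparison.

## Synthetic fixtures

The generators define the package's study conditions rather than adapting
to them:

* proteomes of uniform-random sequences (default 100 proteins, lengths
  80–300 — long enough for internal placement and ±11 windows, short enough
  for second-scale tests) with one implanted degron per protein at
  `implant_rate = 1`; implants instantiate their motif pattern, so scanner
  recall of implants is 100% by construction;
* tracks with baseline 0.3 ± 0.1 (clipped Gaussian) and configured effect
  sizes at implanted spans — the default +0.4 on disorder, accessibility,
  and conservation encodes "degrons are disordered, exposed, conserved" at
  an effect size a well-powered proteome study would show clearly;
* PTM sites at 2% background and 15% near-degron per-residue rates on
  eligible residues (S/T/Y and K), giving the PTM-enrichment contrast;
* mutations engineered per category by inverting the default precedence
  rules, so intended and assigned categories agree exactly when the rules
  are implemented correctly — making label recovery a test of the
  classifier, not of the generator;
* IC50 tables lognormal around 1 μM with σ(log10) = 0.2 and a configured
  fold change multiplying the G1 lines (defaults 5 vs 5 lines). At fold
  change 8 the mean comparison recovers essentially every engineered event;
  at fold change 1 it flags about half, which is the documented null
  behavior of a mean-comparison rule.

Every generator is a pure function of (parameters, seed), and downstream
recovery tests read only the manifest. What the fixtures do *not* emulate:
real residue composition, real mutation spectra, correlated annotation
tracks, multi-degron proteins (implants never overlap; scanner overlap
handling is tested with explicit constructions instead), or real
pharmacology. Passing recovery tests therefore demonstrates correctness of
the implemented procedures under their stated assumptions, not performance
on real proteomes.

One fixture choice deserves emphasis: the correlation-drop diagnostic is
exercised with a scan set that adds a deliberately degenerate
low-information motif (`Lxx[LIVM]`) to the realistic patterns. Its chance
matches scale with protein length, reproducing the false-positive-rich
regime the diagnostic exists to detect; the specific implanted motifs alone
would match too rarely for the raw correlation to be meaningfully positive
at desk scale.

## Numerical choices

* **Rank test.** The two-sample comparison battery uses a two-tailed
  Mann–Whitney U test: exact by enumeration of all group assignments for
  combined n ≤ 12 (ties handled naturally; the two-tailed p is the null
  probability of a U at least as far from n₁n₂/2 as observed), and a
  tie-corrected normal approximation with continuity correction above. The
  switch point balances fidelity and cost and is exposed as a parameter.
  The exact branch is verified against an independent exhaustive oracle for
  every n₁+n₂ ≤ 10 and against `wilcox.test` on untied cases; no
  multiple-testing correction is applied to the per-feature p-values, with
  a Benjamini–Hochberg column appended as an additive extra.
* **Position preferences.** Logo matrices renormalize each position over
  observed (non-`X`) residues; an all-`X` position is returned as `NA` and
  listed in an attribute rather than propagating NaN.
* **Determinism.** All stochastic steps (background sampling, bootstrap,
  CV folds, fixture generation, xgboost fits with `nthread = 1`) are scoped
  to explicit seeds via `withr::with_seed`, so identical inputs and seeds
  give byte-identical outputs, a property the command-line smoke tests
  assert.
* **Problem sizes.** The shipped tests and acceptance script use 100-protein
  fixtures, 10 background peptides per positive, 100 null replicates, and
  200 resistance simulations — sizes chosen so the full suite completes in
  well under a minute while keeping Monte-Carlo rates (e.g. the ≥ 90%
  non-significance bound, the ≥ 95% recovery bound) comfortably inside
  their tolerances.

## Known limitations

The package does not predict terminal degrons, does not model cooperation
between nearby degrons, takes PTM tables and annotation tracks as given,
treats each protein ID as an independent sequence (isoform mapping is the
caller's concern), and ships no trained human model: the classifier is a
procedure to be trained on the user's curated degron set, and the impact
weights are declared defaults, not fitted constants.
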