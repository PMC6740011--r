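---
title: "Methods: combinatorial tetramer screening, deconvolution and hit calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial tetramer screening, deconvolution and hit calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrascreen)
```

## The screening model

A combinatorial triple-coded tetramer screen labels each peptide-MHC
multimer with a unique unordered set of 3 of 12 metal-tagged
streptavidins, so up to C(12,3) = 220 peptide specificities share one
mass-cytometry tube. A CD8+ T cell carrying a T cell receptor for peptide
*p* binds only *p*'s tetramer and is therefore signal-positive in exactly
the three tetramer channels of *p*'s code. Decoding is purely
combinatorial and only sound under an exact-match rule: an event whose
positive tetramer-channel set equals a code is assigned to that peptide;
an event positive in more than three tetramer channels is a
multi-positive artifact and is quarantined, never force-assigned, because
coincident extra positivity (doublets, aggregates, background) would
otherwise be mis-decoded as a different specificity.

Each screen is stained in two independent *configurations* with
completely different peptide-to-code assignments. We operationalize
"completely different" minimally: for every peptide, its configuration-2
code differs from its configuration-1 code; assignments are otherwise
uniformly random under a recorded seed. Nothing in the decoding requires
disjoint metal sets, and we deliberately do not impose constraints beyond
per-peptide inequality.

## Hit criteria

For each (sample, peptide) the pipeline evaluates, in order:

1. **Count threshold.** At least 2 decoded events in *each* of the two
   configurations, or at least 4 events when only one configuration is
   available. Populations failing this are excluded from all further
   criteria. Expressed against the gated CD8 denominator this gives the
   per-sample detection threshold in percent,
   `100 * min_events / n_CD8`.
2. **CD4 comparison.** The CD8-gate frequency must strictly exceed the
   CD4-gate frequency of the same code in every configuration that met
   the per-configuration minimum; triple-positivity among CD4 cells for a
   class I tetramer is background.
3. **Concordance.** The two configuration frequencies must agree within
   strictly less than two-fold (`max/min < 2`). If one frequency is zero
   the ratio is reported as infinite and the criterion fails; if both are
   zero it is not applicable and cannot pass. (This zero handling is our
   decision; the rule itself only speaks of a ratio.)

The verdict is `count AND (cd4 OR concordance)`. Two further quantities
are computed as *audit metrics only* and never gate the verdict:

* **Phenotypic homogeneity** — the mean pairwise Euclidean distance among
  a hit's events in transformed descriptive-marker space, expressed as a
  percentile of the same statistic over `n_boot` equal-sized random
  subsets of bulk CD8 cells (lower = more homogeneous = more clone-like).
  The precise statistic used in earlier automated-gating work is not
  published; percentile-of-mean-pairwise-distance is our documented
  stand-in and is calibrated (a random bulk subset scores uniformly, as
  the test suite checks).
* **Donor background** — the patient CD8-gate frequency over the
  corresponding frequency among APC-negative healthy-donor buffer cells
  stained in the same tube, with the donor frequency floored at one event
  over the donor gate total so the ratio stays finite.

Unique hits are counted once per peptide within a patient (a specificity
re-detected at a second time point is one hit); the discovery rate is
unique neoantigen hits over neoantigen candidates screened.

## Pre-processing choices

**Logicle transform.** All channels are transformed with the logicle
(biexponential) scale, default parameters w = 0.25 decades, t = 16409,
m = 4.5 decades, a = 0 — the conventional settings for HELIOS mass
cytometry data. No cytometry library is a dependency; the transform is
implemented from the standard Parks/Moore parameterization: the
biexponential coefficients follow from (w, t, m, a) with the auxiliary
root `d` solved by `uniroot` to near machine precision, the closed-form
inverse is exact, and the forward transform inverts it numerically (a
4096-point grid provides the initial guess, refined by vectorized Newton
steps to a relative tolerance of 1e-10; the test suite verifies
round-trips at 1e-6 and strict monotonicity). Exact zeros — undetected
metal — are kept as zeros for analysis; `randomize_zeros()` provides the
conventional display-only uniform (-1, 0) jitter and is never applied to
anything a statistic consumes.

**Positivity cutoffs.** Positivity is evaluated on the transformed scale,
so any cutoff above the transform of zero classifies exact zeros as
negative, matching mass-cytometry zero semantics. The default
`channel_threshold` method is a two-component split: the kernel-density
valley between the zero-inflated negative mode and the positive mode,
falling back to the 99.5th percentile of a designated negative-control
population when no second mode exists. Tetramer channels need different
handling: a real population can be 0.01% of events — far too rare to
raise a density mode — yet cleanly separated from the negative tail. For
those channels the screen driver uses the same operation's `"gap"`
method: the cutoff is the midpoint of the widest empty interval among the
upper order statistics (top 2% by default). With well-separated staining
this lands in the true gap whatever the population size, and on a
channel with no positives at all it sits above all but the most extreme
negative events, keeping the per-channel false-positive rate near 1/n.
The five palladium channels are pooled into a single valley cutoff:
their staining intensities are comparable, and pooling guarantees both
modes are represented regardless of which barcode a sample carries.

**De-barcoding and gating.** Sample de-barcoding is the deterministic
exactly-k-positive rule (k = 2 of 5 palladium channels): events with any
other positive multiplicity, or a pair matching no sample, go to an
unassigned pool, and assigned plus unassigned is an exact partition.
Manual de-barcoding review is out of scope. The lineage hierarchy is
live (DNA+, cisplatin−) → CD45+ → exclude CD14+ monocytes → exclude
CD56+CD16+ NK cells → exclude CD3+TCRγδ+ cells → CD3+ → CD8+ (sibling
CD4+), with patient cells identified by anti-APC positivity and
healthy-donor buffer cells by its absence. Dead cells are
cisplatin-positive or DNA-negative. Bead-based signal normalization is
assumed already applied to inputs.

## The synthetic generator

The generator exists so that every pipeline stage has ground truth. Per
channel it draws from a zero-inflated log-normal: a point mass at exact
zero (default rate 0.8 for marker-negative states, emulating undetected
metal) plus a log-normal component — meanlog log(2), sdlog 0.5 for
negative states and meanlog log(500), sdlog 0.35 for positive states on
the raw scale, which puts the two components about 2.4 decades apart
after transformation. No published per-channel intensity distributions
exist for this assay; these are fixture choices, not estimates of any
real dataset.

Planted antigen-specific populations are exact: each population
contributes `round_half_up(frequency/100 * n_CD8)` events (round-half-up
is used and documented so count expectations in tests are exact), each
positive in precisely the three channels of its code per configuration
and background-clean in the other tetramer channels. Every *non-planted*
event is positive in each tetramer channel independently with probability
1e-3 (configurable), so spurious triple coincidences arise at roughly
1e-9 per code per event and hit-calling robustness can be probed by
raising the rate. Channels are independent: no spillover or isotope
impurity is simulated, nor instrument drift, doublets, or
acquisition-time effects — so passing tests demonstrate correctness of
the decoding and calling logic under the stated noise model, not
robustness to every artifact of real acquisitions. Phenotypes come from
per-marker Bernoulli templates (late-effector: high KLRG-1, 2B4, CD57,
CD161, TIGIT, CD25; memory-like: high CD127, CD28, CD27, CCR7;
activated: high HLA-DR, CD38, PD-1, CD39), with bulk CD8 drawn from a
mixture over the four CD45RO × CCR7 memory subsets — which is what makes
bulk phenotypically diffuse relative to a planted clone, the property the
homogeneity score measures.

## Phenotype profiling choices

* **Group comparison.** The responder/non-responder contrast is between
  independent groups, so the default test is the unpaired two-sided
  rank-sum test; a paired signed-rank option exists behind a flag. (The
  source analysis names a signed-rank test for an unpaired contrast,
  which is internally inconsistent; we record the choice rather than
  guess intent.) Exact p-values are used whenever ties permit, and the
  suite checks them against full permutation enumeration at group sizes
  up to 8. Benjamini–Hochberg q-values across the 21 markers are
  reported alongside unadjusted p-values.
* **PCA and clustering.** Marker columns are centered and, by default,
  scaled to unit variance (whether the original figures scaled is not
  stated; scaling makes markers comparable and is the default, with
  `scale. = FALSE` available). k-means with k = 3 (mirroring the
  three-cluster annotation convention; k is a parameter) runs on the
  first two component scores with at least 10 restarts under a fixed
  seed. Component signs are fixed deterministically — PC1 is oriented so
  the summed loading of the effector markers is positive — and cluster
  labels are renumbered by descending mean PC1, so labels are stable
  across runs.
* **t-SNE.** Events are down-sampled without replacement to at most
  20,000 per sample, seeded. The embedding is exact t-SNE (full pairwise
  affinities, per-point perplexity calibration by bisection, momentum
  gradient descent with early exaggeration; default perplexity 30). At
  post-gating event counts the exact O(n²) gradient is affordable and
  avoids approximation parameters; the embedding is visualization-only
  and no downstream statistic depends on it.

## Neoepitope selection choices

The cascade consumes precomputed tables; no binding predictor or variant
caller is run. Mutations need >= 2 RNA reads concordant with the mutated
allele; the stated rules leave exactly-one-read mutations in a gap, and
we discard them with a warning so the borderline cases are auditable.
Window enumeration is 1-based and inclusive (stated to avoid off-by-one
drift), covering every 8-11mer containing the mutated residue. Selection
keeps alleles in the intersection of the patient genotype and the
supported six-allele panel with predicted IC50 strictly below 500 nM —
exactly 500 nM is excluded. The per-mutation optimal pair is the IC50
argmin with deterministic tie-breaks: shorter peptide, then lexicographic
allele, then lexicographic peptide.

## Problem sizes and reproducibility

All randomness is seeded: scheme assignment, the generator, k-means
restarts, bootstrap nulls and t-SNE initialization each take explicit
seeds, and seeded helpers save and restore the caller's RNG state. The
test suite exercises the full pipeline at 30,000 gated CD8 events with a
0.65% planted population (50 seeds), 50,000 CD8 events with a 0.01%
population — five events per configuration, the detection floor — (100
seeds), unplanted 220-code screens for specificity (100 seeds, 8,000 CD8
events), and profile-level clustering cohorts of 13 + 7 template hits
(20 seeds); unit tests run at a few thousand events. The clustering
check is deliberately run at the profile level (template populations
profiled directly) because what it probes — separability of effector
versus memory profiles under PCA + k-means — does not depend on the
event-level pipeline, which the recovery and specificity checks already
exercise end to end.

## Known limitations

* Real per-channel cutoffs in published screens were set by expert
  review; the automated valley/gap thresholds here are a stand-in whose
  agreement with manual gates cannot be verified from published material.
* The generator's independence assumptions (no spillover, no doublets)
  mean specificity estimates are lower bounds on what messy acquisitions
  produce.
* FCS I/O is not provided; event tables are exchanged as CSV mirrors or
  built in memory.
* Cohort-level findings from real patient screens (hit splits between
  clinical response groups, actual phenotype values) are properties of
  the original cohort data and are not reproduced here; synthetic
  cohorts mirror their structure only.
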