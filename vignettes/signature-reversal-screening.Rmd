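---
title: "Signature-reversal screening: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal screening: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revscreen)
```

## The screening model

The screen rests on one hypothesis: an agent whose induced expression
changes are anti-correlated with a disease's expression changes is a
candidate for counteracting the disease state.  `revscreen` quantifies
that anti-correlation with two complementary statistics per agent and
combines them into a deterministic ranking.

**Signatures.** A contrast (disease vs normal, treated vs untreated, agent
vs vehicle) is summarized as a fold-change profile: gene → linear FC.  The
gene signature of a contrast is defined purely by inclusive FC cutoffs —
up = {FC ≥ 1.50}, down = {FC ≤ 0.67} for screening; 2.0 / 0.5 for calling
DEGs.  No p-values enter the signature definition: with very small control
groups (the disease contrasts this screen is aimed at can have as few as
two normal samples) a variance estimate per gene is unreliable, and the
thresholds are calibrated for that regime.  Comparisons are inclusive
exactly as the cutoffs are printed, so a gene at exactly 1.50 is in the
signature and FC = 1 never is.

**Signed overlap and the odds ratio.** The disease and agent signatures
are crossed into a 2×2 table over genes in at least one direction of
*both* signatures: a = |up~D~ ∩ up~A~|, b = |up~D~ ∩ down~A~|,
c = |down~D~ ∩ up~A~|, d = |down~D~ ∩ down~A~|.  Genes unchanged in either
contrast carry no directional information and are excluded; this
restriction is a package design choice (the screen's behaviour on genes
outside both signatures is otherwise undefined), and it makes "smallest
odds ratio ⇔ strongest reversal" literally true: a reverser loads b and c,
so its cross-ratio OR = (a·d)/(b·c) falls below 1.  Zero cells get the
Haldane–Anscombe +0.5 on all four cells for the reported (and
ranking-relevant) OR; the raw cross-ratio, with 0/∞ allowed, is kept for
reference.  The Fisher p-value is the exact conditional hypergeometric
probability of cell a given the margins; the default is two-sided, with
one-sided options exposed because the sidedness conventions of
connectivity-style screens vary.

**Spearman correlation.** Independently of the thresholded sets, Spearman's
ρ is computed between the two fold-change vectors over their full shared
gene universe (midranks, Pearson on ranks).  Rank correlation is the right
tool here: FC profiles from different platforms are on incomparable
scales, and ρ is invariant under any strictly monotone rescaling, so
linear vs log input makes no difference.  The p-value uses the standard
t approximation with n − 2 degrees of freedom; for overlaps under ~10
genes a seeded permutation p is available instead, since the
approximation is poor there.  A restricted universe (disease-signature
genes only) is provided as an option because published screens differ in
this choice; the default is the whole profile intersection.

**Ranking.** Agents are ordered by ascending ρ, ties broken by ascending
OR, then agent id.  The composite "top ten" orderings of production
screens are proprietary; this explicit rule is the package's own, chosen
to be deterministic and to put the strongest reversers (most negative ρ,
smallest OR) first.  Benjamini–Hochberg adjustment is applied across
agents within one screen, separately for the Fisher and Spearman
p-values — a screen is a multiple-testing exercise even when the
underlying tool reports only raw p-values.  Agents with zero signature
overlap are not assigned a rank; they are reported in a separate exclusion
table so that every library member is accounted for exactly once.

## Fold changes from expression matrices

`compute_fc()` is intentionally minimal: per gene,
FC = (mean~case~ + ε)/(mean~control~ + ε), arithmetic means by default,
with ε = 1 expression unit.  The pseudocount keeps ratios finite and
stable for low-expression genes and tiny groups.  Optional per-sample
library-size scaling (to the mean library size) removes depth artifacts;
because ε is applied after scaling, a global rescaling of all samples
cancels only up to the pseudocount, exactly for ε → 0.  There is no
dispersion modeling and there are no per-gene p-values — the signature
definition downstream is FC-only, and moderated estimators can be imported
from external DE tools via `import_external_de()` (which accepts the
conventional `log2FoldChange` column) when preferred.

## Over-representation analysis

`ora()` is plain one-sided hypergeometric over-representation:
P(X ≥ overlap) with the universe as population, the set as successes, and
the DEGs-in-universe as draws, BH-adjusted across sets.  Weighted
enrichment schemes exist, but their weights are tool-specific; the output
carries a `method` attribute naming the test as unweighted so downstream
reports cannot misattribute it.  The default universe is the union of the
collection's sets; supplying the measured-gene universe of the experiment
is recommended and supported, since the union default understates the
background and inflates significance.

## What the synthetic data emulates — and what it does not

The generator reproduces the statistical skeleton of a screening study:

* **Disease contrast** (`simulate_expression()`): baseline log2 expression
  ~ Normal(5, 2) per gene; a fraction (default 10%) of genes planted DE
  with |log2FC| ~ Normal(1.5, 0.5) and random sign; per-sample log2 noise
  Normal(0, 0.5); 10 case vs 10 control samples, 5,000 genes.  The planted
  effect size makes the 1.50/0.67 cutoffs recover most planted genes
  (recall ≈ 0.93 at the default seed) without being trivial — a planted
  log2FC near 0.585 sits exactly at the threshold.
* **Agent library** (`simulate_agent_library()`): 200 agents — 20
  reversers (log2 profile = −0.8 × disease truth + Normal(0, 0.3)), 20
  mimickers (+0.8 × …), 160 nulls (permuted disease magnitudes with random
  signs, preserving the marginal effect-size distribution while destroying
  gene-level association).
* **Enriched gene sets** (`simulate_gene_sets()`): random sets from the
  universe, one designated set over-sampling a supplied gene list at 5×
  weight.
* **Planted correlation** (`simulate_reversal_pair()`): bivariate-normal
  log2 profiles with Pearson r = 2·sin(πρ\*/6), the inverse of the
  normal-score relation ρ~S~ = (6/π)·asin(r/2), so the population Spearman
  correlation equals the requested ρ\* exactly.  This provides the one
  closed-form target in the package; the expected ρ of a noisy reverser
  against an *estimated* disease profile has no simple closed form, so
  reverser recovery is checked against seeded empirical runs instead.

The generator is log-normal with additive Gaussian log-noise, not a
negative-binomial count model.  That is deliberate: the screen consumes
only fold changes, so mean–variance realism beyond FC structure would add
parameters without exercising any additional code path.  Consequently,
passing tests demonstrate correctness of the scoring and ranking
machinery and its statistical calibration — they do not demonstrate that
the FC-threshold signature is biologically optimal for any particular
dataset, nor do they model batch effects, probe-level artifacts, or
count-level overdispersion.

## Numerical choices and degenerate inputs

* Fisher two-sided p sums hypergeometric point probabilities ≤ the
  observed one, with a 1 + 1e−7 relative guard so that margin-symmetric
  tables whose tied probabilities differ only by floating-point rounding
  are not split.  The whole-table grid with margins ≤ 15 agrees with a
  brute-force `lchoose` enumeration to 1e−10.
* Spearman ρ on fewer than 3 shared genes, or against a constant vector,
  is an error, not an NA — silent NAs would propagate into rankings.
* Duplicate gene symbols after upper-casing are an error by default;
  `keep-max` (largest |log2FC|) is available because expression tables
  from public repositories routinely carry case duplicates.
* All floating-point outputs are written with 6 significant digits;
  equality in tests is asserted at stated tolerances, never on strings.
* Generators take a mandatory integer seed; library generation draws from
  a stream offset by +1 (and gene-set simulation by +2 in the pipeline) so
  the stages are mutually independent but jointly reproducible —
  identical seeds give byte-identical output files.

## Problem sizes

The shipped validation runs use the default study shape: 5,000 genes,
10 + 10 samples, 200 agents (20 planted reversers), a 10,000-gene planted
correlation pair, and a 1,000-replicate ORA null calibration on a
20,000-gene universe with DEG lists of 2,000 and set sizes 500–3,000.
The calibration sizes were fixed a priori at transcriptome scale because
the exact hypergeometric test is conservative on coarse supports: with
small universes the attainable rejection level sits visibly below α, which
is a property of discrete exact tests, not a miscalibration.

## Known limitations

* The signed-overlap construction, Fisher sidedness, Spearman universe
  and ranking rule of proprietary connectivity screens are unpublished;
  all four are configurable here and the defaults documented above are
  the package's own choices, so rank lists will not reproduce any
  specific external tool verbatim.
* KS-statistic (connectivity-map-style) enrichment scoring is out of
  scope, as are probe-to-gene mapping, cross-species ortholog mapping and
  raw-array normalization.
* `compute_fc()` is an estimator of convenience for end-to-end runs;
  for real count data a dedicated DE tool should be used upstream and its
  table imported.
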