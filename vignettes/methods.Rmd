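---
title: "Methods: sweep and divergence screening with matched controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep and divergence screening with matched controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhewscan)
```

## The problem

A recurring design in molecular population genetics: a curated set of
*focal* genes (a pathway, a functional class) is screened for
signatures of natural selection, using nearby genes of similar length
as *matched controls* so that regional effects — local recombination
and mutation rate, chromosomal environment, shared demography — cancel
out of the comparison. `dhewscan` implements this screen end to end
for coding-sequence alignments of a large haploid population sample
(on the order of 150 lines), optionally with a small sister-species
sample and an outgroup for polarization.

Two selection regimes are targeted. *Recent selective sweeps* purge
linked variation and leave three site-frequency/haplotype signatures:
an excess of rare variants (negative Tajima's D), an excess of
high-frequency derived alleles (negative normalized Fay & Wu's H), and
elevated haplotype homozygosity (high Ewens–Watterson F). *Recurrent
adaptive protein divergence* leaves an excess of non-synonymous fixed
differences relative to the within-species polymorphism ratio
(McDonald–Kreitman test, positive Direction of Selection).

## Statistics

For a filtered alignment of $n$ haplotypes with $S$ segregating sites
(complete-case columns only, see below):

- $\hat\theta_w = S/a_1$ with $a_1 = \sum_{i=1}^{n-1} 1/i$, and $\pi$
  the mean number of pairwise differences. Both are reported **per
  gene** (summed over sites), the scale on which per-gene screens
  tabulate them.
- Tajima's $D = (\pi - \hat\theta_w)/\sqrt{e_1 S + e_2 S(S-1)}$ with
  the standard constants derived from $n$. Undefined at $S=0$ and
  returned as `NA`, never as 0.
- Normalized Fay & Wu's $H$: derived-allele counts $\xi_i$ are
  obtained by strict parsimony — a site is polarized only when all
  designated outgroups agree on an ancestral base that is one of the
  two in-group alleles; multiallelic or discordant sites are dropped
  from $H$ (and counted). With $\hat\theta_L = \frac{1}{n-1}\sum i\,\xi_i$,
  the statistic is $(\pi - \hat\theta_L)/\sqrt{\widehat{\mathrm{Var}}}$,
  using the variance of $\pi - \hat\theta_L$ with moment plug-ins
  $\hat\theta = S_p/a_1$ and
  $\widehat{\theta^2} = S_p(S_p-1)/(a_1^2 + a_2)$, where $S_p$ is the
  polarized-site count. Because the package restricts $\pi$ and
  $\hat\theta_L$ to the polarized sites, genes with many unpolarizable
  sites lose power rather than gaining bias; in the coalescent null
  every site is root-polarized, so observed and null statistics are
  computed identically.
- Ewens–Watterson homozygosity $F = \sum_i p_i^2$ over haplotype
  frequencies, with haplotypes built from the usable segregating
  columns only (invariant columns cannot change $F$).

### Missing data

Preprocessing applies the missing-data rule in two stages:
sequences with more than 10% `N` are removed (`filter_missing`), then
any column still containing `N` or a gap in a retained sequence is
excluded from *all* statistics. The exclusion keeps $n$ constant
across sites, which the variance formulas above assume. The phrasing
of the underlying filter rule is ambiguous between sequence-level and
site-level exclusion; this package does both, in that order, and
treats gaps as missing rather than as a fifth allele. A consequence
worth knowing: with $n$ around 150, the fraction of usable columns is
roughly $(1-r)^n$ for a per-base missing rate $r$ — at $r = 0.001$
about 86% of sites survive, at $r = 0.01$ almost none do. The
synthetic-data generator therefore defaults to $r = 0.001$, which
mimics a post-filter high-quality haplotype panel.

## Coalescent nulls and DHEW

P-values for D, H and EW come from the standard neutral coalescent
with no recombination, conditioned on the observed $S$: a Kingman
genealogy is drawn (coalescence rate $\binom{k}{2}$), then exactly $S$
mutations are placed on branches with probability proportional to
branch length. Conditioning on $S$ rather than on $\theta$ is the
standard choice for these tests; each (n, S) cell is simulated once
per run (default 10,000 replicates) and cached. Empirical p-values use
the Monte-Carlo pseudocount $(1 + \#\text{extreme})/(R+1)$, lower tail
for D and H, upper tail for F. No-recombination nulls are conservative
for D and H when the true locus recombines.

The DHEW compound test combines the three component p-values. The
package reduces the observed vector $(p_D, p_H, p_{EW})$ to a
joint-exceedance statistic $T$ — the fraction of null replicates whose
own p-vector is component-wise $\le$ the observed one — and then, in a
second calibration step, ranks $T$ against the null distribution of
$T$ itself. The second step matters: the three components are
positively dependent, so $T$ alone is far from uniform (empirically a
fifth of neutral replicates have $T \le 0.05$ at $n = 20$, $S = 20$);
after recalibration the rejection rate at the 5% level is within
Monte-Carlo error of 5% for all four tests, which the acceptance suite
verifies. The construction is one defensible reading of "combine the
p-values into a vector and test its deviation from neutrality"; it is
simulation-consistent but need not be numerically identical to other
DHEW implementations. EW p-values are read in the upper tail of
homozygosity (small p = excess homozygosity = sweep-like), matching
how the per-gene tables treat them.

## McDonald–Kreitman and DoS

The classifier walks in-frame codons of focal sample + sister sample +
outgroup. A codon is *fully analyzable* (counted in `MKcodons`) when
it contains no missing data and at most one variable-or-divergent
nucleotide position. In an analyzable codon, a focal-species
polymorphism is classified synonymous/non-synonymous in its codon
context (Ps/Pn); a fixed inter-species difference is assigned by
parsimony to the lineage whose allele differs from the outgroup base,
and classified Ds/Dn when that lineage is the focal one. Codons with
more than one hit are excluded entirely (deterministic and
conservative; no pathway averaging), sites polymorphic in the sister
species never yield fixed-difference calls, lineage-unassignable
substitutions exclude their codon from `MKcodons`, and
stop-codon-creating variants are never counted. `mk_test` is the
two-sided Fisher's exact test on $[[D_n, D_s], [P_n, P_s]]$;
`DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps)` is reported only when both margins are
positive. Corrections use Benjamini–Hochberg across the focal gene
set, per statistic.

## The comparison framework

For each statistic, each focal gene gets a *comparison score*: focal
value minus the median of its matched controls (controls must be
within 0.5–2× the focal CDS length and within ±60 kb of its start;
focal genes with fewer than three surviving controls are dropped).
Group-level departure is tested with a one-sample t-test and Wilcoxon
signed-rank test on the scores; significance is read as the 95% CI
excluding zero.

Scores are ranked by extremeness with a per-statistic orientation —
most negative for D and H, most positive for DoS (and EW) — because
that is the direction each statistic moves under the selection regime
being screened. Dense ranks are reported with a percentile that places
the most extreme score at 100, so "top 10%" means percentile ≥ 90.
(Published per-gene screens print the same information in either
orientation; one consistent convention is used here and the calling
rule is orientation-invariant.)

The *rank against null* step builds a pooled permutation null: every
control gene of every pairing takes a turn as pseudo-focal, scored
against the remaining controls of its pairing (`enumerate` mode; with
68 pairings of 3–4 controls this pools roughly 245 pseudo-scores,
matching the pool sizes the design implies). A seeded Monte-Carlo mode
drawing one control per pairing per replicate is available. The true
score's percentile within the pool is reported; under exchangeability
these percentiles are uniform, which is verified by a KS test in the
acceptance suite. Genes with undefined statistics are excluded from
the affected distributions rather than imputed.

### Calling criteria

A gene is a *candidate sweep* iff (1) its DHEW p-value is below 0.05,
(2) at least two of the corrected D/H/EW p-values are below 0.05 (DHEW
itself is not counted here — it is criterion 1), and (3) at least one
of the D, H or DoS comparison scores is in the top 10% of ranks *and*
the top 5% of rank-against-null percentiles. *Adaptive divergence* is
called iff the corrected MK p-value is below 0.05 and DoS > 0. All
thresholds are configurable; genes with missing components are
`NA` ("not callable"), distinct from a negative call.

## Synthetic data

The generator emulates the study design rather than any particular
data set: per-gene coding alignments for 149 in-group lines (14 in the
small-sample species mode), 14 sister lines with their own small
coalescent, one outgroup, CDS lengths 0.3–3 kb, per-gene θ drawn from
2–12 (per-gene scale, matching the magnitudes such screens tabulate),
outgroup divergence 10 and sister divergence 5 coalescent units, and
in-group stem substitutions so the focal lineage accumulates fixed
differences. Sweeps are modeled genealogically: a fraction $f$
(default 0.9) of sampled lineages is forced to coalesce into one
ancestor at time $\tau$ (default 0.005), with the neutral coalescent
above — a parameter-sparse stand-in for a recent hard sweep that
produces exactly the targeted signal classes (negative D, negative H,
high F) without forward simulation. Adaptive divergence is planted by
a separate codon-aware generator that places synonymous and
(purifying-reduced) non-synonymous events one per codon, never
creating stops, so the planted Pn/Ps/Dn/Ds equal the classifier's
counts identically — recovery tests read the recorded truth table, not
re-derived signals. Control genes share their focal gene's θ and sit
within the pairing rules by construction on a synthetic chromosome.

What the generator does *not* emulate: within-gene recombination,
demographic history (bottlenecks, admixture, ancestry masking),
linked-selection backgrounds, alignment error, and tract-structured
missingness. Passing recovery tests therefore show that the pipeline
detects its targeted signal classes at study scale under clean
conditions; they do not certify behavior under demographic
confounding, which the matched-control design is meant to absorb in
real applications.

## Numerical and design choices

- **Determinism.** Every stochastic stage takes a seed; a master seed
  is expanded into per-stage, per-gene seeds by a counter-based scheme
  (`derive_seed`), so per-gene results do not depend on iteration
  order. RNG state is saved and restored around seeded internals.
- **Problem sizes.** The acceptance suite uses 10,000-replicate nulls
  with 2,000 neutral trials for calibration, 50 + 50 study-scale
  bundle replicates (68 pairings, 149 lines) for the pathway-level EW
  recovery, 1,000 pairings for permutation calibration, and 200 + 60
  genes for MK recovery — sizes at which the targeted effects are
  resolvable on a single CPU in minutes. Bundle replicates for the EW
  recovery omit the sister sample, which the EW statistic never reads.
- **Ties.** Dense ranks share the more extreme rank; Monte-Carlo
  p-values count ties as extreme (conservative); even-count medians
  average the central pair.
- **Degenerate inputs.** S = 0 yields `NA` statistics; all-identical
  comparison scores yield a flagged degenerate t-test; empty
  alignments and impossible subsamples are errors, not warnings.
- **Known limitations.** The no-recombination null is conservative for
  D/H at recombining loci; the H variance uses moment plug-ins (not a
  likelihood); the complete-case column rule discards real sites when
  missingness is high; DHEW's numerical values are
  construction-specific, though calibrated by simulation.
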