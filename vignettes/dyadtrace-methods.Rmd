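---
title: "Methods: transfer-event detection and strain identity in mother-infant dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transfer-event detection and strain identity in mother-infant dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadtrace)
```

## The question and the two analyses

Whether maternal vaginal bacteria colonise the newborn gut is usually
argued from shared presence: the same organism seen in a mother's vaginal
microbiome and in her own infant's stool, but not in unrelated infants.
`dyadtrace` implements that argument at two resolutions.

At **amplicon resolution**, the tracking unit is the ASV (an exact,
denoised amplicon sequence). Shared presence is only meaningful above an
abundance floor — at trace abundance, index hopping, contamination and
chance detection dominate — so a *potential transfer event* for dyad $d$
and ASV $a$ is defined by a symmetric relative-abundance gate:

$$ p(\mathrm{mother}_d, a) \ge t \quad\text{and}\quad
   \max_{i \in \mathrm{infants}(d)} p(i, a) \ge t $$

with $p$ the within-sample relative abundance and $t$ the threshold
(default $10^{-3}$). One event is recorded per (dyad, ASV) however many
infant samples pass; the category (10-day only, 3-month only, both)
records persistence. "Potential" matters: shared presence cannot prove
direction or rule out a common external source, and the package makes no
such claim.

At **genome resolution**, cultured isolates from both halves of a dyad are
compared as genomes: pairwise SNP distances, average nucleotide identity,
and gene content. The strain-sharing signal is the contrast between
within-dyad and between-dyad pairwise values; transmission-scale
thresholds (tens of SNPs, ANI above 99.9%) turn pairs into per-dyad
identical/nonidentical calls.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.001 | relative-abundance gate (fraction; 0.001 = 0.1%) |
| `inclusive` | `TRUE` | gate compares with `>=`; `FALSE` gives strict `>` |
| `k` | 21 | k-mer size for ANI estimation (odd, canonical k-mers) |
| `sketch_size` | 1000 | bottom-sketch size in MinHash mode |
| `ani_threshold` | 0.999 | per-pair ANI above which a pair is "identical" (strict `>`) |
| `snp_threshold` | 25 | per-pair SNP count at/below which a pair is "identical" (inclusive `<=`) |
| `p_adjust` | bonferroni | Dunn post hoc adjustment (raw p times number of comparisons, capped at 1) |
| `correction` | none | chi-square continuity correction (`yates` available, 2x2 only) |

The threshold gate is applied to both the maternal and the infant
abundance, and inclusively (`>=`), since a printed threshold of "0.1%"
naturally includes values at the boundary; the strict variant is one flag
away. The boundary conventions of the identity calls are asymmetric on
purpose: SNP bounds in the transmission literature are quoted as "up to
*n* SNPs" (inclusive), while ANI identity is quoted as "above 99.9%"
(exclusive).

The chi-square default is **uncorrected**. For the 2x2
strain-typing-by-exposure tables this package was built around, the
printed p-values of the source data are reproduced by the uncorrected
statistic and not by the Yates-corrected one, despite captions saying
otherwise; both modes are available and the choice is explicit in every
result object. One published time-point row ("<0.01") is not reproduced
exactly by either mode (uncorrected gives 0.011); it is left as context.

Dunn's post hoc has no implementation in the installed dependency set, so
the pairwise $z$ statistics are computed here from pooled mid-ranks with
the tie-corrected variance
$\sigma^2_{ij} = \left(\frac{N(N+1)}{12} - \frac{\sum_s (t_s^3-t_s)}{12(N-1)}\right)\left(\frac{1}{n_i}+\frac{1}{n_j}\right)$,
and validated in the test suite against an exact permutation enumeration
on a two-group example. The omnibus H comes from `stats::kruskal.test`;
the Mann-Whitney U from `stats::wilcox.test` with the tie-corrected
normal approximation and no continuity correction (the convention of
common GUI statistics packages, and appropriate for the large
pairwise-distance samples it is applied to here).

## ANI from k-mers

The paper-scale workflow computes ANI with external alignment-based
tools; `dyadtrace` instead estimates it from canonical k-mer sets, which
is deterministic, dependency-free and fast at desk scale. With Jaccard
similarity $J$ of the two k-mer sets, the Mash relation

$$ \mathrm{ANI} = 1 + \frac{1}{k}\ln\frac{2J}{1+J} $$

recovers planted per-base mutation rates within ±0.005 for rates up to
0.05 at $k = 21$ (verified per run in the acceptance script). Exact sets
are the default; a bottom-$s$ MinHash sketch over a fixed affine hash
ordering gives the same answer within 0.002 at $s = 5000$ on the fixtures
tested, and is provided for large genomes. $J = 0$ is reported as ANI 0
with an `unrelated` flag rather than $-\infty$. Because k-mer ANI and
alignment ANI differ systematically at high divergence, published ANI
values from alignment tools are treated as context, not as values this
estimator must reproduce.

## SNP distances and UPGMA

SNP counting follows snp-dists semantics exactly: a column counts if and
only if both sequences carry an unambiguous `A/C/G/T` (case-insensitive)
and they differ; gaps and `N` skip the column. The implementation is an
integer-encoded vectorised scan, and the test suite holds it equal to a
brute-force per-column loop on hundreds of random fixtures.

UPGMA is size-weighted average-linkage agglomeration
(`stats::hclust(method = "average")` on the distance matrix), returned as
an `ape::phylo` tree whose node heights are half the merge heights, so
root-to-leaf depths are equal (ultrametric within 1e-9, asserted in
tests). Labels are sorted lexicographically before clustering and
children are rotated toward the sorted tip order, so newick serialization
is deterministic under distance ties. The maximum-likelihood tree of the
full workflow is out of scope; the UPGMA tree on SNP distances is the
package's dendrogram over genomes.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the study conditions the analyses were
designed for: 585 dyads by default, a maternal vaginal profile dominated
by one Lactobacillus-like ASV (40-80% of reads), ~6 further maternal ASVs
placed 2-30x above the threshold, infant sample availability 568/585
(10 days) and 459/585 (3 months), and a per-ASV transfer probability of
0.06 across the 7 transferable ASVs — in expectation 0.42 events per dyad
with ~35% of dyads positive, matching the scale of the cohort the design
mirrors. Planted transfer categories follow the 147:72:41 split between
10-day-only, 3-month-only and both. Delivery modes (0.6 vaginal / 0.2
elective / 0.2 emergency CS) and intrapartum antibiotics (0.6/0.4) are
label proportions only — transfer probability is mode-independent by
default, making the generator a null model for the group comparisons; a
named `p_transfer` vector makes it mode-dependent.

Two placement choices make ground truth exact rather than probable.
First, planted counts (shared ASVs at >=2x threshold, leaked unshared
ASVs at <=0.5x threshold) are set deterministically, and only the residual
read depth is drawn multinomially from a Dirichlet background — so a
planted event can never fall below the gate through sampling noise.
Second, infant background ASVs are drawn from the pool *excluding*
everything present in the maternal sample, so shared presence above
threshold occurs exactly where planted. The cost is realism at the
margins: real transferred ASVs straddle the threshold, real mothers and
infants share taxa without transmission, and real data contain
contamination, index hopping and compositional noise. Passing
recovery tests therefore validate the detection logic, not the biological
error rate of the threshold on real data.

`simulate_genome_cohort()` evolves each dyad ancestor from a global root
at a Poisson($rL$) substitution load (default $r = 0.02$) and each
maternal/infant genome a further fixed `within_subs` substitutions from
the ancestor, substitution-only — so the output is a gap-free alignment
and SNP ground truth is exact. Note the observable within-dyad pairwise
distance is ~2x `within_subs` (two independent branches). Pairwise truth
is computed from per-genome mutation bookkeeping (composing substitution
maps, with reversions to the root base removed), never by rescanning
sequences, so it is an independent oracle for the SNP code. Indels,
recombination, rearrangement and assembly artefacts are all absent; real
SNP matrices from draft genomes will not be bit-identical to any
simulation.

`simulate_gene_matrix()` plants a shared core, one private accessory
block per dyad, and independent Bernoulli accessory noise. It reproduces
the qualitative structure that makes dyad-mates cluster as cherries under
UPGMA, nothing more.

## Numerical and degenerate-input choices

- Zero-read samples are retained in the sample ledger, flagged, and
  excluded from abundance-based computation (no divide-by-zero; cohort
  counts stay honest).
- Dyads with no infant sample are kept in the cohort report but excluded
  from transfer detection and per-dyad counts.
- All-tied Kruskal-Wallis input (every value identical) returns H = 0 and
  p = 1 rather than NaN.
- A chi-square table with a zero row or column total is an error
  (expected counts undefined), as is Yates correction outside 2x2.
- Per-ASV summaries sort by transfer count descending with ties broken by
  ASV identifier, so output order is deterministic.
- Empty gene sets are at Jaccard distance 0 from each other and 1 from
  any non-empty set.
- `partition_by_dyad()` with an empty side (e.g. all genomes in one dyad)
  reports medians and returns no test rather than failing.

## Problem sizes

The test suite and acceptance script run entirely on generated data:
oracle equivalence on cohorts up to 10 dyads x 20 ASVs and 200 random
alignment fixtures; ANI recovery on 100-kb genomes; partition recovery on
6-dyad, 20-kb alignments; 50 seeded gene-matrix simulations for cherry
recovery; and 100 seeded 100-dyad null cohorts for Kruskal-Wallis
calibration. These sizes were chosen to make every property decidable in
seconds to a couple of minutes while keeping the planted effects at the
scales the analyses target (tens of within-dyad SNPs, tens of thousands
between; abundances bracketing a 0.1% gate).

## Known limitations

- Shared presence is not transmission: no directionality, no source
  attribution, and no modelling of alternative maternal sources (gut,
  breast milk) — those channels are discussed in the literature precisely
  because vaginal ASV sharing alone under-determines them.
- Pairwise-distance tests treat each genome pair as independent; with
  $n$ genomes the $\binom{n}{2}$ pairs are pseudo-replicated. The
  Mann-Whitney results are reported under that convention (as in the
  workflows this package mirrors) and should be read as descriptive.
- Twin pregnancies (one mother, two infants) are unsupported; the cohort
  model is strictly one infant record per dyad.
- The SNP threshold for identity calls is an absolute count and does not
  scale with alignment length; for alignments much shorter or longer than
  a bacterial genome, adjust `snp_threshold` accordingly.
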