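---
title: "Pocket-level fine-mapping of HLA class II case-control associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket-level fine-mapping of HLA class II case-control associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlapocket)
```

## The problem and the model

HLA class II molecules (DR, DQ, DP) present peptides to CD4 T cells. DQ
and DP are heterodimers of an α chain (A1 gene) and a β chain (B1 gene),
both polymorphic, and the peptide sits in a groove whose nine sub-sites
(pockets P1–P9) are each formed by a fixed set of α- and β-chain
positions. A disease association that appears at the allele level is
therefore plausibly carried by a much smaller set of pocket residues
shared across alleles. `hlapocket` operationalises that reduction for
case-control cohorts typed at two-field resolution.

Every association in the package is the same model: for a per-subject
dosage $d_i \in [0, 2]$ (copies of an allele, a residue, a haplotype, or
a pocket combination),

$$\operatorname{logit} P(\text{case}_i) = \beta_0 + \beta\, d_i,$$

fitted by maximum likelihood (binomial IRLS, convergence $10^{-10}$ on
the deviance scale, at most 100 iterations). The per-copy odds ratio is
$e^{\beta}$ with a Wald 95% interval and a two-sided Wald p-value. Models
are deliberately unadjusted — no covariates — and stratum analyses are
re-fits on subsets, not interaction models, because comorbid atopic
phenotypes are plausibly on the causal pathway and adjustment would
condition on mediators. Complete or quasi-complete separation (a rare
allele seen only in cases, say) is flagged on the result row with an
infinite or zero OR and missing interval rather than raised as an error,
so a full table scan never aborts on a degenerate cell.

Frequencies are counted on chromosomes: a typed subject contributes two,
a homozygote contributes both to one allele, and a subject missing a gene
is excluded from that gene's analyses only (per-gene Ns differ, as they
do in real cohorts). Frequency intervals are Wald intervals clipped to
$[0,1]$; at the sample sizes involved (several hundred chromosomes per
scope) they are indistinguishable from score intervals, and the choice is
isolated in `frequency_estimate()` should a user want to swap it.

### Multiplicity

Corrections are per-family Bonferroni, with the family defined by what is
scanned together: the alleles of one gene (so m = 4 gives p < 0.0125),
the haplotypes of one gene pair, the 10 targeted pocket combinations
(p < 0.005), or the 3 TCE groups. `bonferroni_family()` keeps the
arithmetic exact. The discovery screen (below) intentionally uses the
*uncorrected* 0.05 level: it nominates candidates for a targeted
follow-up analysis that carries its own family, and a corrected screen
would be unable to nominate moderately significant features in the first
place.

## Two-locus EM haplotype estimation

Genotype calls are unphased, so cis A1∼B1 pairing is inferred. For two
loci only double heterozygotes are ambiguous, and only between two phase
configurations. `em_fit()` implements the classical EM under
Hardy-Weinberg equilibrium:

* **E-step** — each configuration gets weight proportional to the product
  of current haplotype frequencies (the HWE multiplicity 2 is common to
  both configurations of a double heterozygote and cancels);
* **M-step** — frequencies are re-estimated from expected chromosome
  counts;
* **initialisation** — the product of marginal allele frequencies,
  deterministically, so fits are reproducible without a seed;
* **convergence** — $|\Delta \ell| < 10^{-8}$ (cap 1000 iterations), with
  the log-likelihood asserted non-decreasing at every iteration.

Subjects with identical genotype pairs are grouped, so the per-iteration
cost is the number of distinct genotype combinations, not the cohort
size. Per-haplotype tests form a 2×2 of EM-expected chromosome counts
(this haplotype vs all others × case vs control) with a 1-df chi-squared
statistic and a Woolf interval on the OR. Haplotypes with expected count
below 5 in either phenotype group are pooled into a `binned`
pseudo-haplotype first; 5 is the usual chi-squared validity rule of
thumb. Whether haplotype ORs should come from chromosome-level 2×2
tables or subject-level regressions is genuinely open; the 2×2 choice is
what `haplotype_test()` implements, and a subject-level alternative is a
one-liner with `fit_additive()` on an EM dosage.

The EM-free sensitivity recoding — drop double heterozygotes and count
haplotypes directly (`direct_count_frequencies()`) — agrees with EM to
< 0.005 when ≥ 95% of subjects are unambiguous. On cohorts like the
packaged default, where roughly a third of subjects are double
heterozygous at DPA1/DPB1, the two estimators visibly diverge, which is
precisely why the EM stage exists.

## The opposing-directionality screen

Candidates come from contrast: among features significant at 0.05,
protective (OR < 1) and susceptible (OR > 1) allele groups are formed per
gene — haplotype hits contribute the relevant gene's allele — and
`differing_pocket_residues()` reports the positions at which the two
groups' residue *sets differ*. A stricter rule (requiring the sets to be
disjoint) was considered and rejected as a design choice: susceptible
groups routinely contain one allele that shares the protective residue at
a position while another member departs from it (β69 is the canonical
example, where some susceptible alleles carry the protective K), and
disjointness would silently discard exactly the positions the contrast is
meant to surface. With a singleton protective group the implemented rule
reads simply: report every position where some susceptible allele differs
from the protective sequence. Positions are then intersected with pocket
membership; a position belonging to several pockets is reported with all
of them (β69 sits in P4, P5 and P7 by the packaged pocket table), never
collapsed.

## Pocket-combination dosages: cis by default

A combination such as `a31:M + b84:G|V` is a conjunction across chains
with alternatives within a term. Because the α and β chains pair on one
chromosome to form the dimer, the default dosage is *cis*: the expected
number of DPA1∼DPB1 haplotypes satisfying both chain conditions, under
the subject's EM phase posterior. The expectation is in $[0,2]$ and
non-integral only for double heterozygotes whose two phasings disagree on
the qualifying count. Note a structural fact of conjunctive specs: a
configuration can exceed its alternative by at most one qualifying
haplotype, so a 50/50 posterior contributes exactly 0.5 to the dosage. An
`"independent"` sensitivity mode ignores phase and pairs the chains'
satisfying counts at random ($n_\alpha n_\beta / 2$); it is provided
because published analyses of this design rarely state whether cis
pairing was enforced, and comparing the two modes bounds the phasing
sensitivity of any combination result.

## rs9277534, TCE groups and LD

The 3' UTR SNP rs9277534 tags DPB1 expression (A low, G high) and is in
fixed correspondence with the two-field DPB1 allele, so the package
treats it as a deterministic allele annotation, never a genotyped
marker; no expression quantity is modelled. TCE groups 1/2/3 are a
packaged classification with an exon-2 protein-signature fallback for
novel alleles, mirroring how novel alleles differing only outside exon 2
inherit their group.

LD between two chromosome-level binary features uses
$D = p_{AB} - p_A p_B$ and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$. The
$D^2$ numerator is the standard definition; a linear-$D$ variant that
sometimes appears in print is dimensionally inconsistent and cannot
produce the unit-interval values it is reported with. Within-DPB1 pairs
(any residue vs the SNP class, or two residues) are counted directly on
chromosomes — both features are functions of the same allele call — and
the implementation uses the integer-count form of $r^2$ so that perfect
correspondence yields exactly 1.0 in floating point. Cross-gene (α vs β)
pairs take marginal and joint frequencies from the EM haplotype
estimate.

## The synthetic cohort generator

`generate_cohort()` draws, per subject: a stratum; two DPA1∼DPB1
haplotypes i.i.d. from the stratum's frequency table (HWE); two alleles
per remaining gene independently (linkage equilibrium across genes — the
analysis never consumes cross-gene LD, and DP is recombinationally
separated from DQ); case status from the logistic model on *true phased*
dosages; then missing-completely-at-random per-gene dropout; and finally
unphasing. A single integer seed and a documented draw order make
cohorts byte-reproducible, and the truth ledger (phased haplotypes, true
dosages, linear predictor) always unphases exactly to the emitted table.

`gad_like_config()` is the packaged default and defines the study-like
conditions used throughout the tests: n = 849, expected case fraction
0.546 (the baseline log-odds is solved exactly against the enumerated
dosage distribution, not tuned), strata White/Black/other at
0.592/0.371/0.037, per-stratum haplotype tables interpolated from the
published stratum allele frequencies and observed A1∼B1 pairings with
remainder mass on a pseudo-allele (`99:99`, present in all packaged maps
so every generated chromosome stays resolvable), per-gene missingness
matching the published per-gene Ns, and one planted effect: the P1
combination `a31:M + b84:G|V` at log(0.57) per cis copy.

What the generator does *not* emulate: genotyping error, population
admixture within strata, cross-gene LD, age/sex structure, and
deviations from HWE. Passing tests therefore demonstrate that the
*methods* recover known truth under the study's sampling structure — not
that any particular biological conclusion transfers to a real cohort.

## Numerical choices and degenerate inputs

* Logistic fits: IRLS, $\epsilon = 10^{-10}$, 100 iterations; separation
  flagged at $|\beta| > 10$ or SE > 100, reported not raised.
* EM: tolerance $10^{-8}$ on the log-likelihood, 1000 iterations,
  deterministic marginal-product start; monotonicity asserted.
* Wald intervals everywhere (frequencies, ORs); clipping to $[0,1]$ for
  frequencies.
* Residue lookups never default silently: an unmapped allele or
  untracked position is an error naming the offending key.
* Ties: positions in several pockets are all reported; an allele group
  appearing on both sides of the screen is kept protective.

## Packaged mapping fixtures

Residues at the positions covered by published classifications (β11, β36, β55,
β69, β76, β84, β96, β170 across the 44-allele DPB1 universe; the α11/α31
combinations) are transcribed as data; the remaining tracked positions
(β8, β9, β56, β57, β65, β85–87 and the monomorphic pocket fill-ins, plus
α66) are synthetic assignments consistent with every printed constraint,
and the files say so in their `#provenance=` headers. Coordinates are
mature-protein numbering (position 1 follows the signal peptide). The
packaged TCE classification follows the field-standard three-group split.
Users with database access can drop in full replacement TSVs via
`hla_registry(residues = ..., snp = ..., tce = ...)`.

## Test problem sizes

The acceptance suite runs at deliberately chosen sizes: 200 replicate
cohorts of n = 1000 for EM frequency recovery (per-haplotype mean
absolute error < 0.01); exhaustive-oracle agreement on 3×3-allele,
50-subject instances to $10^{-4}$; 100 random datasets for the Newton
oracle at $10^{-6}$; 2000 null cohorts for type-I calibration
(rejection fraction in [0.04, 0.06]); 200 study-scale (n = 849)
replicates for recovery and interval coverage of the planted OR-0.57
combination; and 100 replicates for the screen nomination rate (≥ 95%
must nominate α31→P1 and β84→P1). These sizes balance Monte-Carlo error
against runtime and are fixed in `tests/testthat/test-acceptance.R`.

## Limitations

Only two-locus phasing is implemented (no DP∼DQ extended haplotypes, no
reference-panel phasing); pocket membership is taken as data, not
computed from structures; rs9277534 inference presumes the packaged
allele universe; and the Wald machinery is asymptotic — for very rare
features the flagged-separation path, not a small-sample exact test, is
what the package offers.
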