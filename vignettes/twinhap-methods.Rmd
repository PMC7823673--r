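---
title: "Methods: noninvasive paternity, zygosity and fetal fraction in twin pregnancies from microhaplotype cfDNA"
author: "twinhap"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinhap)
```

## The problem

Cell-free DNA (cfDNA) in the plasma of a pregnant woman is a mixture: mostly
maternal fragments, plus a minor fetal contribution (the *fetal fraction*,
FF). In a twin pregnancy the fetal portion itself may come from one genome
(monozygotic, MZ) or two (dizygotic, DZ), and in a paternity dispute the two
fetuses need not even share a father (heteropaternal superfecundation, HS).
`twinhap` interprets read counts over a panel of *microhaplotypes* — short
(<200 bp) segments spanning several linked SNPs whose haplotypes act as
single multiallelic alleles — to answer three questions from one plasma
specimen, noninvasively:

1. **Paternity.** Is the alleged father (AF) the father of both twins, one
   twin, or neither?
2. **Zygosity.** Are the twins MZ or DZ?
3. **Fetal fraction.** How much cfDNA does each fetus contribute?

The package takes as input (a) a per-locus allele frequency table, (b)
genotype profiles for mother, alleged father, and optionally the fetuses
(for validation), and (c) per-allele read depths per locus in plasma, i.e.
the output of upstream sequencing, alignment and haplotype assignment, which
are out of scope here.

## Detecting fetal alleles and classifying loci

Each fetus inherits one allele per locus from its mother and one from its
father. A plasma allele absent from the maternal genotype must therefore be
paternally inherited fetal material (or noise). With the maternal genotype
as reference, `detect_nonmaternal()` flags alleles whose read ratio
$d_a / D_i$ (allele depth over total locus depth $D_i$) is at least a
detection threshold, by default **1.0%** (the comparison is `>=`: an allele
at exactly 1.0% is detected). Loci are classified by the count of such
assumed paternal alleles (PAs):

* **Type I** — none (both fetal paternal alleles coincide with maternal ones);
* **Type II** — one;
* **Type III** — two. Because a single fetus carries at most one nonmaternal
  allele per locus, a Type III pattern requires two genetically distinct
  fetuses: it is *informative* for dizygosity.

More than two nonmaternal alleles can only arise through noise; such loci
are marked UNCLASSIFIED and excluded from zygosity, fetal-fraction and LR
computations (a conservative choice; they are logged as suspected drop-in).
The allele-ratio denominator is always the total locus depth $D_i$,
maternal reads included — the same denominator used by the fetal-fraction
estimator, keeping the two stages consistent.

A per-locus depth QC (`min_depth`, default **50 reads**) guards the 1%
threshold: at 50 reads, 1% of the depth is below a single read, so
shallower loci cannot support the detection rule and are excluded. The QC
is configurable; no depth cut is applied upstream of it.

## Zygosity

`call_zygosity()` calls **DZ** when at least `min_informative` Type III loci
are present (default **1**) and **MZ** otherwise. In the published cohort
this rule separates cleanly (DZ cases showed 3–10 informative loci, MZ cases
zero). The default of 1 follows that behaviour; because a single Type III
locus can be manufactured by one drop-in event at a Type II locus, the
threshold is exposed and the informative-locus count is always reported, so
users can harden the call (the simulated-cohort analysis script demonstrates
exactly this failure and its remedy with `min_informative = 2`).

## Fetal fraction

At a Type III locus of a DZ case, each of the two fetus-specific alleles
carries one genome copy of its fetus, i.e. half that fetus's contribution.
Ordering the two depths as $d(l)_i \le d(h)_i$ and assuming the lower-depth
allele always comes from the fetus with the lower FF:

$$\overline{FF}(l) = \frac{1}{N}\sum_{i=1}^{N} \frac{2\,d(l)_i}{D_i},
\qquad
\overline{FF}(h) = \frac{1}{N}\sum_{i=1}^{N} \frac{2\,d(h)_i}{D_i},$$

with $N$ the number of informative loci; the combined FF is their sum, so
`ff_combined == ff_lower + ff_higher` holds exactly by construction. Type II
loci are excluded from the DZ estimate: a single shared allele cannot be
attributed to one fetus. For MZ twins the pattern is singleton-like and the
combined FF is the mean of $2 d_f_i / D_i$ over Type II loci; per-fetus
values are reported as `NA`. The factor 2 assumes the fetus is heterozygous
for its fetus-specific allele; the simulator's truth ledger records the
(rare) homozygous-nonmaternal loci that violate this so recovery tests can
stratify on them.

**A known, deliberate bias.** When the two true FFs are close, per-locus
min/max ordering assigns sampling noise asymmetrically: it deflates
$\overline{FF}(l)$ and inflates $\overline{FF}(h)$. This is the method's
stated identifying assumption, not a defect, and the test suite demonstrates
it on equal-FF simulations. When the FFs are well separated (e.g. 4% vs 8%
at 2000x depth) recovery is within one percentage point per replicate.

Validation against fetal reference genotypes (`validate_against_fetal_genotypes()`)
counts the real fetus-specific alleles (fetal alleles absent from the
mother), dropouts (real alleles missed in plasma), drop-ins (assumed PAs
carried by neither fetus), and the detection rate
$(\text{real} - \text{dropout})/\text{real}$. Validated per-fetus FFs use the
true fetus-to-allele assignment at real informative loci, averaging
$2d/D$ per fetus (a dropped-out allele contributes depth 0) and taking the
smaller per-fetus mean as the lower FF; the published procedure is not
printed, and this construction reproduces the published validated columns'
internal structure (combined = lower + higher up to printed rounding).
Concordance between estimated and validated FFs is summarized by the squared
Pearson correlation (`ff_concordance()`), identical to the coefficient of
determination of the least-squares line through the scatter.

## The paternity likelihood model

Three hypotheses are compared:

* **H1** — the AF fathered both twins;
* **H2** — the AF fathered one twin, a random man the other (HS);
* **H3** — random men fathered both.

The evidence at a locus is *qualitative*: the set of alleles observed at or
above the detection threshold (maternal alleles included; the same evidence
set as the zygosity stage, not sub-threshold reads). Given maternal genotype
$M$ and fetal genotypes $g_1, g_2$:

* maternal allele copies are always observed (maternal dropout is fixed at 0
  — the mother is the major contributor — and deliberately not configurable);
* each allele copy of fetus $k$ drops out independently with probability
  $d_k$, so a fetal homozygote drops with $d_k^2$;
* at most one drop-in per locus: no drop-in with probability $1 - c$,
  drop-in of allele $a$ with probability $c\,p_a$, where $p_a$ is the
  population frequency with the unseen-allele floor.

Writing $q_a$ for the probability that every copy of allele $a$ drops out
($q_a = 0$ for maternal alleles, $q_a = d_1^{n_{1a}} d_2^{n_{2a}}$
otherwise), the likelihood of evidence set $E$ is

$$P(E) = (1-c)\prod_{a \in E}(1-q_a)\prod_{a \notin E} q_a
 \;+\; c \sum_{a \in E} p_a \prod_{b \in E \setminus \{a\}} (1-q_b)
 \prod_{b \notin E} q_b .$$

This closed form is verified in the test suite against an independent oracle
that exhaustively enumerates every per-copy dropout pattern and drop-in
event (agreement to 1e-12 relative on hundreds of random instances), and the
evidence-set probabilities sum to one over each locus's allele universe.

The locus likelihood under a hypothesis marginalizes over $(g_1, g_2)$ with
Mendelian genotype priors (`child_genotype_prior()`): each parent transmits
either of its alleles with probability $(1-r)/2$, mutating with probability
$r$ (default $10^{-8}$) to an allele drawn from population frequencies
(transmitted allele excluded, renormalized). Mutation lives only in
transmission — at $r = 10^{-8}$ it is numerically negligible but keeps LRs
finite at apparent exclusions. A random man's allele is drawn from the
frequency table (floor applied); with $\theta > 0$ the draw follows the
Balding–Nichols form conditional on the maternal alleles, and $\theta = 0$
(the default) reproduces Hardy–Weinberg. H2's twin-labeling ambiguity is
resolved by averaging the two assignments with equal prior, which is exact
under the main analysis's equal-dropout assumption ($d_1 = d_2$) and
principled otherwise. Silent alleles are accepted in the interface for
parity but rejected if positive.

Per-locus LRs are combined across loci by multiplication (the panel's loci
are treated as independent), accumulated in log10 to avoid underflow over 60
loci. By shared-denominator algebra,
$\log_{10} LR_{H1,H3} = \log_{10} LR_{H1,H2} + \log_{10} LR_{H2,H3}$ at
every locus and grid point, which the tests assert to 1e-9. Because the
dropout probabilities of the minor contributors are unknown, `compute_lr()`
evaluates the LRs over a grid of $(d_1, d_2)$, by default equal values in
{0.001, 0.01, 0.05, 0.1, ..., 0.9}, with 0.001 as the floor for a fetal
contributor (matching the sequencing error scale); an unequal cross-grid is
available via `default_dropout_grid(cross = TRUE)`. At unrealistically high
assumed dropout ($d \ge 0.5$) the model can explain away exclusions as
dropout, so `specificity_screen()` flags candidates whose $LR_{H2,H3}$
crosses 1 anywhere on the grid.

## Frequencies and the unseen-allele floor

Alleles absent from the frequency table never get probability zero: lookups
return an `unseen_freq` floor, default **0.002**, used both for random-man
draws and drop-in weights. Frequencies are *not* renormalized after applying
the floor — renormalization would silently change every printed LR; where a
proper distribution is required (transmission and random-man draws over a
locus's allele universe) the relevant vector is normalized explicitly at
that point. Input frequency tables are validated: each frequency in (0, 1],
per-locus sums at most $1 + 10^{-6}$.

## The synthetic-data generator

No raw data from the motivating study are public, so `simulate_*()` stands
in, with defaults chosen to emulate its study conditions: a **60-locus**
panel with **4–8 alleles** per locus (flat Dirichlet frequencies), parents
drawn under Hardy–Weinberg, twins by Mendelian transmission under the
scenario's zygosity/paternity (MZ twins share one draw; a `NEITHER` scenario
still carries an unrelated alleged-father profile so specificity can be
tested). Plasma counts are multinomial around expected proportions: the
mother contributes $1 - FF_{\text{total}}$ split equally over her two
copies, each fetus $FF_k/2$ per copy. Default fetal fractions are 5% and 9%
(DZ; reported ranges are roughly 3–8% and 5–20%) and 12% combined for MZ
(reported 9–18%). Total depth is negative binomial with mean **2000** and
dispersion 0.1 (variance $= \mu + 0.1\mu^2$; the assay's true depth
distribution is unpublished, so these are configurable placeholders;
dispersion 0 gives constant depth for deterministic tests). Optional noise:
per-copy fetal dropout, and per-locus drop-in of one spurious allele at a
0.5–1.5% ratio drawn by population frequency — deliberately straddling the
1% threshold to exercise the classifier boundary. All randomness flows from
a single integer seed; identical seeds give byte-identical TSV bundles.

What the simulator does **not** model: read-level errors, PCR stutter
(microhaplotypes have none, a key advantage of the marker), maternal
copy-number anomalies, or linkage between loci. Passing tests on synthetic
data therefore demonstrate the correctness of the estimators and the
likelihood machinery under the stated mixture model, not the assay's
wet-lab performance.

## Numerical and design choices

* Evidence, thresholds and ratios all use total locus depth $D_i$ as
  denominator.
* Tie-break for equal-depth nonmaternal alleles: depth descending, then
  allele string ascending — deterministic reports.
* Equal-depth Type III alleles contribute equally to both FF means
  ($d(l) = d(h)$).
* All genotype distributions are normalized to sum to 1 within 1e-12;
  likelihood accumulation is in log10.
* TSV (tab-delimited, header required) is the single input dialect; allele
  labels are opaque strings (no sequence validation). Reports render
  percentages with two decimals (round-half-to-even) and log10 LRs with
  three.
* The unseen-allele floor 0.002 is adopted as a constant; the derivation
  parenthetically attached to it in the source study does not reproduce the
  value, so the constant is taken at face value.

## Problem sizes in the test suite

The suite verifies the likelihood engine against exhaustive-enumeration
oracles on ~700 random small-locus instances; LR separation of true fathers
from unrelated men on 50 + 50 simulated 60-locus cases over an equal-d grid
up to 0.3; fetal-fraction recovery on 100 noise-free DZ replicates at
(4%, 8%) and 2000x (within 1 percentage point each) and 100 MZ replicates
at 12% combined and 20000x (within 0.5 points); and zygosity accuracy on
mixed replicates at combined FF at or above 8%. DZ replicates occasionally
(about 1 in 100) yield no informative locus at all; the per-fetus estimator
is undefined there by construction, which is itself the method's stated
limitation for panels with few informative loci.

## Limitations

* The LR model is qualitative: read depths inform detection but not the
  likelihood itself (no peak-height/coverage weighting).
* At most one drop-in per locus; loci with more than two nonmaternal alleles
  are excluded rather than modelled.
* The per-fetus FF estimator requires at least one informative locus and
  assumes consistent depth ordering between fetuses across loci; both fail
  exactly when the fetuses are genetically similar at the panel or
  contribute near-equal cfDNA.
* Two fetal contributors only; higher-order multiples are out of scope.
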