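---
title: "Measuring meiotic gene conversion from fluorescent pollen tetrads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meiotic gene conversion from fluorescent pollen tetrads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradgc)
```

## The assay and its statistics

In *Arabidopsis thaliana* carrying the *qrt1* mutation, the four pollen
grains of one meiosis stay attached, so each tetrad reports a complete
meiosis. A fluorescent tagged line (FTL) expresses a pollen-specific
fluorophore from a transgene; an EMS-derived non-fluorescent allele
(NFTL) of the same transgene provides a single-SNP heterozygosity at the
locus. In an FTL/NFTL heterozygote, fluorescence normally segregates
2:2. A meiotic gene conversion that copies the fluorescent allele onto
an NFTL chromatid produces a 3:1 tetrad; conversion in the other
direction produces 1:3.

Only 3:1 tetrads are scorable in practice: a single dark grain can also
arise from pollen-development defects, so 1:3 tetrads are recorded but
never counted as conversions. Assuming the two directions are equally
frequent, the **adjusted frequency** doubles the observed 3:1 rate,

$$\hat f = \frac{2\,n_{3:1}}{N},$$

with $N$ the number of scored tetrads. `estimate_frequency()` and
`pool_counts()` implement this, reporting frequencies at 3 significant
figures and "meioses per conversion" $N/(2 n_{3:1})$ rounded half-up —
the rounding convention that reproduces the published per-locus values
(e.g. $155{,}280/32 = 4852.5 \to 4853$), where banker's rounding would
not.

Locus-to-locus differences are tested with the G-test of independence
on the raw (not doubled) 2x2 table
$[[n_{3:1}^{(1)}, N_1 - n_{3:1}^{(1)}], [n_{3:1}^{(2)}, N_2 -
n_{3:1}^{(2)}]]$:

$$G = 2\sum_{\text{cells}} O \ln(O/E), \qquad p =
\Pr(\chi^2_1 \ge G),$$

with expected counts from the marginals and the convention
$0\ln(0/E)=0$. Doubled counts would inflate $G$ roughly twofold and do
not correspond to the scored observations. No continuity or Williams
correction is applied by default; a Williams option exists behind
`correction = "williams"` but the plain statistic is what reproduces
the published pairwise matrix (27 of its 28 locus-vs-locus cells match
at printed precision; the remaining cell computes $p = 0.0149$, printed
as 0.02, a rounding-edge case that `reproduce_study()` surfaces rather
than hides). Two published numbers are deliberately treated as
*reconstructions*: the control comparison $P = 0.008998$ is reproduced
exactly by testing 0/45,000 control tetrads against the 13/149,965
locus, and the locus-vs-pooled "total" column is not reproduced by any
plain G-test variant we evaluated, so `versus_pooled()` documents its
procedure (locus against the pool including itself) without asserting
agreement.

Conversion polarity along the gene is probed by ordinary least squares
of adjusted frequency on the SNP position within the fluorophore coding
sequence (`position_regression()`); $r^2$ is the squared Pearson
correlation and the p-value is the two-sided $t$-test on the slope with
$n-2$ df. Degenerate inputs are handled explicitly: identical positions
are an error (undefined slope); a constant response returns a flat fit
with $r^2 = 0$, slope 0 and $p = 1$ rather than the `NaN` a raw
least-squares summary would produce.

## CO/NCO classification

With hemizygous DsRed and AmCyan transgenes flanking the eYFP test
locus in coupling, a conversion tetrad can be assigned to the crossover
(DSBR) or non-crossover (SDSA) pathway from the flanking channels
(`classify_tetrad()`): parental flanking pairs (both present or both
absent in every grain) mean NCO; one red-only plus one cyan-only grain
means CO. Policy for the cases the operational definition leaves open:

* any unscorable flanking signal on a converted grain — or an
  unscorable test channel — yields `AMBIGUOUS`, never a guess;
* flanking channels that do not segregate 2:2, a 4:0/0:4 test channel,
  or more than one recombinant pair (a double-CO-like arrangement)
  yield `ABERRANT`;
* 1:3 tetrads are classified `GC_13` and reported, but never merged
  into conversion counts, mirroring the counting rule above.

Any flanking exchange is called CO even though an independent crossover
elsewhere in the interval co-occurring with an NCO conversion would be
miscalled; the simulator exists partly to quantify that miscall rate,
and the classifier-vs-ground-truth tests condition on "no additional CO
in the interval" for exactly this reason.

## The tract-length reconciliation

A single-SNP assay detects a conversion only when the tract covers the
SNP, so observed per-locus frequency = per-nucleotide frequency x tract
length. The per-nucleotide expectation comes from counting arguments:
$D \in [120, 222]$ DSBs per meiosis (RAD51 foci), a restoration
fraction $r = 0.5$ (MMR converts or restores 50:50), and genome size
$G \in [119{,}146{,}348, 141{,}146{,}348]$ nt (sequenced assembly,
plus ~22 Mb of unsequenced centromeres and rDNA for the upper bound).
Bounds are paired conservatively (fewest conversions over the largest
genome, and vice versa). Inverting with the *full-precision* pooled
frequency $2 \cdot 186/1{,}054{,}024$ gives tract bounds of 379-830 bp;
using the 2-significant-figure frequency would not reproduce them. The
mean (605 bp) is the rounded midpoint of the *unrounded* bounds
(378.8, 830.2). The expected CO:NCO balance reported by
`expected_co_nco_ratio()` is $(D - 9)/9$ per crossover, i.e.
denominators 12.3-23.7; we report the computed upper denominator
(213/9 = 23.7) rather than the commonly quoted 1:20.

## The forward simulator

`simulate_experiment()` is the package's synthetic-data generator: a
mechanistic forward model of DSB formation and repair in an FTL/NFTL
heterozygote. Its defaults are the baseline study conditions, chosen
once:

| parameter | default | rationale |
|---|---|---|
| `genome_length` | 119,146,348 nt | sequenced genome size |
| `dsb_mean` | 171 (Poisson) | midpoint of the 120-222 RAD51-focus range |
| `tract_mean` | 605 bp (geometric) | the reconciliation estimate |
| `p_homolog` | 1 | the counting argument assumes every DSB can form a tract |
| `p_co` | 9/171 | ~9 crossovers per meiosis among homolog-repaired DSBs |
| `p_conversion` | 0.5 | MMR converts:restores 50:50 |
| `reversion_rate` | 1e-7 | upper end of measured mitotic reversion rates |
| `misgrouping_rate` | 0 | the re-association control observed none in 45,000 |

Poisson DSB counts (no crossover interference) keep the closed form
exact; a fixed-count option exists. Tracts contain the initiating break
at a uniform offset, which makes the point-coverage probability exactly
$L/G$ for any tract-length law with mean $L$ — verified in the tests by
brute-force enumeration of every (position, offset) pair on a 100 nt
genome. Tracts may overhang the ends of the simulated chromosome;
clipping them would break the exact $L/G$ coverage near the boundaries
of what is anyway a circularity-free abstraction. Sister-templated
repair is phenotypically silent and acts purely as a frequency dial for
the inter-homolog bias hypothesis. Conversion copies the template
allele onto the broken chromatid (donor/recipient logic), unbiased by
default.

One timing choice matters numerically: within a meiosis, all
heteroduplex formation and mismatch repair is resolved *before* any
crossover exchange is applied. Resolving each DSB sequentially instead
would let an earlier crossover move the test allele between homologs
and erase the mismatch a later tract would need, deflating conversions
by roughly $p_{co} D/4$ and breaking the closed-form expectation
$\hat f = D\,p_{hom}\,(L/G)\,p_{conv}$. Since strand invasion and MMR
precede junction resolution, the phase-separated model is also the
mechanistically faithful one. The closed form in
`expected_segregation_rates()` is exact to first order; multi-conversion
tetrads (which can produce 4:0 or revert to 2:2) are quadratically rare
at realistic rates.

The per-tetrad expectation under the defaults,
$171 \times 605/119{,}146{,}348 \times 0.5 = 4.3\times10^{-4}$
conversions per meiosis, sits on the same order as the observed pooled
$3.5\times10^{-4}$ — the generator and the reconciliation model are two
views of the same arithmetic, and `recover_parameters()` closes the
loop by re-estimating the programmed tract length from simulated
counts.

What the generator deliberately does **not** emulate: DSB hotspots and
chromatin landscape, crossover interference and homeostasis, obligate
crossovers, GC-biased conversion, CO-vs-NCO tract-length differences,
and inter-locus linkage (multi-locus designs are independent
replicates). Passing simulation tests therefore show internal
consistency of estimator and generator under uniform-landscape
assumptions, not that real conversion landscapes are uniform.

## Problem sizes and numerical conventions

The test suite exercises the closed-form checks at 50,000-200,000
simulated tetrads and the estimator-recovery loop at 10^6 tetrads on a
reduced genome (10^6 nt with proportionally scaled tract lengths),
sizes at which the binomial 3-standard-error bands are a few percent of
the expectation; the matched-scale run under the full default genome
uses 149,965 tetrads, the size of the three-color experiment. All
randomness flows from a single explicit seed per experiment, and
identical seed plus parameters reproduce byte-identical outputs.
P-values below 10^-15 are displayed as "<1E-15" but kept at full float
precision internally; rounding to printed precision happens only in the
formatting layer (`format_p_printed()`, half-up, matching the
published tables' convention).

## Limitations

The frequency estimator is a point estimate; no confidence intervals
are attached (none were published, and the doubling adjustment is
exactly valid only under direction symmetry, which the intra-locus data
cannot test). The classifier's CO call is operational, not positional —
it does not locate the crossover within the interval. The tract-length
reconciliation inherits every assumption of its counting argument
(DSB counts from cytology, full homolog engagement, 50:50 MMR), so it
should be read as an order-of-magnitude consistency check, not a
measurement; its published companion estimate from sequenced tetrads
(median ~558 bp) is the independent corroboration.
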