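---
title: "Detecting and characterizing U/V sex-determining regions with uvsdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing U/V sex-determining regions with uvsdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Brown algae and other haploid-dioicous organisms determine sex in the
haploid phase: gametophytes carrying a U chromosome develop as females,
those carrying a V as males. Each sex chromosome carries a
sex-determining region (SDR) that never recombines with its counterpart,
flanked by pseudoautosomal regions (PARs) that still recombine. Because
the U- and V-SDR haplotypes diverged long ago, they can be located by
comparing a reference assembly of one sex against sequencing reads of the
other, and their gene content can then be traced over a species tree.

`uvsdr` implements that workflow as composable, tibble-first functions:

1. **k-mer subtraction (YGS-style)**: windows of a reference assembly are
   scored by the proportion of their genome-wide single-copy k-mers
   absent from the opposite-sex read k-mer database.
2. **coverage classification**: per-window read depth of each sex,
   normalized by that sex's genome-wide mean, classified with the
   75–125% / <50% rule.
3. **population statistics**: per-scaffold heterozygosity, the log10
   male:female heterozygosity ratio, and Weir–Cockerham FST between the
   sexes.
4. **gametologues**: reciprocal-best-hit pairing of U and V proteins,
   protein-guided codon back-alignment, and NG86 Ka/Ks.
5. **ancestral SDR content**: a two-state gain/loss model with
   discretized-gamma rate variation, fitted by maximum likelihood, with
   marginal ancestral posteriors and per-gain acquisition mechanisms.
6. **phylostratigraphy and compartment statistics**: relative gene ages
   from homology hits, TRG flags, window feature densities, and the
   Wilcoxon / permutation / chi-square battery with BH FDR control.

A synthetic-data module generates all inputs with known ground truth, so
the whole pipeline runs and is tested without external data.

## The k-mer subtraction statistic

For a window $w$ of the scored assembly, let $C(w)$ be the set of
canonical k-mers (default $k = 15$) starting in $w$ whose genome-wide
count is exactly one, and let $K_\text{opp}$ be the k-mer database of the
opposite sex's reads (canonical 15-mers, counts below 5 dropped, bases
under Phred 20 excluded). The window score is

$$\text{pct}(w) = 100 \cdot
  \frac{|\{x \in C(w) : x \notin K_\text{opp}\}|}{|C(w)|},$$

and windows with $\text{pct}(w) \ge 50$ are retained as candidate SDR
sequence (the threshold is inclusive) and merged when adjacent. Design
choices worth knowing:

* *single-copy is genome-wide*, not per-window, matching the original
  YGS formulation; repeat-derived k-mers therefore never enter the
  denominator.
* windows with no single-copy k-mers score `NA` and are never retained —
  this avoids 0/0 and spurious calls in repeat deserts.
* k is capped at 26 so packed 2-bit codes stay exactly representable in
  an IEEE double mantissa; the default of 15 is far below the cap.

## The coverage rule

Window depths are normalized per sample by the *length-weighted* mean
over all windows (the weighting matters only for trailing partial
windows). A window is a V-SDR candidate when male normalized coverage
lies within $[0.75, 1.25]$ (bounds inclusive — the bounds are read as a
closed range) while female coverage stays strictly below $0.50$; the
sex-swapped rule yields U-SDR candidates. Reads are placed by unique
exact match, and multi-mapping reads are discarded — the desk-scale
analogue of a MAPQ filter in a real mapping pipeline.

## Population statistics

Heterozygosity is the fraction of non-missing genotypes called
heterozygous. The sex-bias statistic is $\log_{10}(H_m/H_f)$ per
scaffold: zero for autosomes, positive on young sex-linked scaffolds
where every male is heterozygous. FST uses the Weir–Cockerham (1984)
two-allele, two-population variance components with $\theta =
a/(a+b+c)$ per site and ratio-of-sums aggregation; negative estimates
are reported as computed, and sites where either sex has fewer than two
called individuals are skipped, not imputed.

## NG86 Ka/Ks

Gametologue divergence uses the Nei–Gojobori (1986) counting method:
synonymous sites by the one-third-per-change rule averaged between the
two sequences, multi-hit codons averaged over all minimal substitution
paths (paths through stop codons are excluded whenever an alternative
exists; mutations *to* stop codons count as nonsynonymous so that
$S + N = 3 \times$ codons), and the Jukes–Cantor correction
$K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. When $p_s \ge 3/4$ the
synonymous distance is saturated: `Ks` is `NA` and a flag is set, which
is how anciently diverged gametologues present in practice. NG86 was
chosen over likelihood codon models because it is deterministic,
oracle-checkable (the test suite compares every codon pair against an
independent path-enumeration oracle), and sufficient for the pipeline's
comparative use of relative Ks; the `ng86_kaks()` interface leaves room
for alternative estimators.

## The gain/loss model

SDR gene content over a species tree is coded 0/1 per family (an
orthologue counts as present only when SDR-linked; PAR, autosomal,
absent and unplaced orthologues code 0). Evolution follows a two-state
chain with gain rate $g$ and loss rate $l$ per unit branch length,

$$P_{01}(t) = \pi_1\,(1 - e^{-(g+l)t}), \qquad \pi_1 = \frac{g}{g+l},$$

with a mean-1 discretized gamma (shape $\alpha$, 10 categories) of
family rate multipliers applied jointly to both rates; whether the
source data's gamma categories modulate gain and loss jointly or
independently is ambiguous, so the simulator exposes both (`gamma_mode`)
and the joint form is the default. The root prior defaults to the
stationary distribution, with a fixed-root option. Likelihoods come from
Felsenstein pruning; fitting maximizes the summed per-family
log-likelihood over $(\log g, \log l, \log\alpha)$ with multi-start
Nelder–Mead, stopping early once additional rounds stop improving the
log-likelihood by at least 0.1. Marginal ancestral posteriors use the
up–down algorithm mixed over categories with per-family weights; node
states are called at posterior $\ge 0.5$ (ties count as present), gains
and losses are read off parent→child state changes, and each gain's
mechanism is voted by the orthologue locations of species outside the
gained clade: mostly PAR → boundary expansion (engulfment), mostly
autosomal → translocation, none anywhere → gene birth, PAR/autosome tie
→ ambiguous. Global rates (scaled by branch length) are used rather than
free per-branch rates: per-branch parameters are not identifiable at the
matrix sizes this package targets. No ascertainment correction is
applied for families observed because they are SDR-linked somewhere;
all-absent families are unobservable by construction and the likelihood
is not conditioned on observability, a known caveat shared with standard
gene-content reconstructions.

## Phylostratigraphy

Gene ages are ranks on an ordered taxonomy ladder (rank 1 = oldest, rank
R = the focal species). A gene's age is the oldest stratum holding a hit
with e-value $\le 10^{-5}$; self-hits are ignored (every gene matches
itself), and genes with no other qualifying hit get rank R.
Taxonomically restricted genes are those at or above a configurable
cutoff rank — the source analyses use species-specific clade boundaries,
so the cutoff is a parameter rather than a constant. Two monotonicity
properties are tested: deleting hits can only make a gene younger, and
tightening the threshold can never make it older.

## Compartment statistics

Window feature densities union overlapping features before computing
covered fractions. The test battery mirrors common practice:
two-sided Wilcoxon rank-sum (exact null when the smaller group has at
most 8 untied observations, otherwise tie- and continuity-corrected
normal approximation), BH FDR across contrasts, seeded permutation tests
with $p = (1 + \#\{|T^*| \ge |T|\})/(B + 1)$ (never exactly zero; B
defaults to 10,000), per-chromosome orthologue-depletion chi-squares
(each chromosome against the rest, expected counts proportional to gene
counts), Pearson standardized residuals with a 2.4 flagging threshold,
OLS $R^2$, a 2×2 enrichment chi-square without continuity correction by
default (switchable — the source's choice is unstated), and the
transcriptional-activity rule $\log_2(\text{TPM}+1) > 2$ (strict).
Windows with NA features are dropped per test, never imputed.

## What the simulator emulates — and what it does not

`sim_config()` defaults are the package's study conditions: three 2-Mb
autosomes plus a 4-Mb U/V chromosome whose central 500 kb is the SDR
(10 Mb total), error-free 100-bp reads at 15×, 20 gametologue pairs at
target Ks 0.5, 10 sex-specific genes per SDR, repeat densities of 10%
(autosome/PAR) and 30% (SDR) built from 20 repeat families whose copies
diverge by 10% per base, ~100 genes/Mb outside the SDR, a 24-individual
population (12 per sex) with 2,000 SNPs at expected heterozygosity 0.3
and 100 young sex-linked sites, and a gain 0.5 / loss 1.0 / shape 1
model over 500 families on a fixed 6-tip tree. The SDR is placed on the
500-kb window grid so window-resolution evaluation is exact. These sizes
keep the full demonstration under a few minutes on one CPU while giving
every statistic enough data to be stable; the methods themselves have no
scale-specific logic.

Deliberate simplifications, and what they imply about test coverage:

* SDR haplotypes are *independent random sequences* rather than
  sequences diverged from a common ancestor — old U/V SDRs are at Ks
  saturation, and the k-mer statistic only needs non-identity.
  Gametologue CDSs are the controlled-divergence exception: their
  synonymous (fourfold) sites are mutated to hit a target Ks in NG86
  expectation.
* The read simulator is substitution-only with uniform sampling; no
  indels, no quality gradients, no GC bias. Passing tests therefore
  show correctness of the statistics, not robustness to real-world
  mapping artefacts (real pipelines should feed `read_depth_bed()` with
  mapper+mosdepth output instead of `window_depth_from_reads()`).
* Repeat copies diverge by point substitution only, so unique exact
  placement succeeds for nearly all repeat-overlapping reads; real TE
  landscapes multi-map more heavily.
* The population simulator draws allele frequencies from a symmetric
  Beta chosen so expected heterozygosity matches the configured value;
  there is no linkage, drift history, or missingness structure.

## Numerical and degenerate-input choices

* Trailing partial windows are kept and flagged so statistics can
  exclude them; their handling in the source analyses is unstated.
* `log2_fold_change(m, 0)` returns `Inf` (a real signal on V-specific
  windows) and `NA` when both coverages are zero; a pseudocount option
  is provided.
* RBH score ties break by longer alignment, then lexicographic id; the
  demonstration pipeline additionally requires an alignment score of at
  least 100, which cleanly separates true gametologues (scores in the
  thousands) from chance local alignments of unrelated proteins (scores
  below ~90 at these lengths).
* Boundary rate estimates (all-identical matrices) are reported with a
  `boundary` flag and a warning rather than an error.
* All generators and tests derive their randomness from explicit seeds;
  identical configuration and seed reproduce outputs byte-identically.

## Problem sizes used by the checks

The packaged checks run the full default simulation once (10-Mb genome,
two 15× read sets), the 61×61 codon-pair NG86 sweep, brute-force
pruning oracles on trees of up to 4 tips, a 500-family rate-recovery
fit, and permutation/Wilcoxon calibrations with up to 100,000
permutations / 1,000 replicates. Together they complete in roughly ten
minutes on a single CPU.

## Known limitations

* k-mer structures are held in memory; genomes far beyond ~100 Mb need
  disk-based counting, which is out of scope.
* The exact read placer requires error-free reads of equal length; it is
  a stand-in for a mapper on synthetic data, not a mapper.
* The gain/loss model is binary — it reconstructs SDR linkage, not copy
  number.
* FST is the two-population Weir–Cockerham estimator only.
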