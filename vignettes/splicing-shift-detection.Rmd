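---
title: "Detecting genotype-dependent splicing shifts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genotype-dependent splicing shifts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshift)
```

## The statistical model

`spliceshift` asks, feature by feature, whether the *relative* usage of a
splicing outcome differs between two genotypes, using biological replicates
as independent confirmations rather than as inputs to a pooled model.

For **intron retention**, the evidence in one sample is the pair (intron
average depth, background depth), where the background is the unweighted
mean of the two flanking exons' average depths. Under the null hypothesis
that the chance of retaining the intron is the same in both genotypes, the
2×2 table

|            | intron depth | background |
|------------|--------------|------------|
| mutant     | $a$          | $b$        |
| wild type  | $c$          | $d$        |

has no association, and the Pearson statistic
$X^2 = N(ad-bc)^2 / (r_1 r_2 c_1 c_2)$ with margins $r_i, c_j$ is
asymptotically $\chi^2_1$. Depth values enter as (possibly fractional)
reals; the $\chi^2$ formula tolerates that. A zero margin is treated as "no
evidence" (statistic 0, $p = 1$) rather than an error. The same test
compares skip-junction reads to inclusion-junction reads for **exon
skipping**. **Alternative splice-site** usage is tested on integer junction
counts with the Fisher exact test (two-sided, sum of hypergeometric
probabilities not exceeding that of the observed table), twice per variant:
against the intron's other junctions and, as confirmation, against the
gene's unique read count. Fractional entries are rounded half-up before the
exact test.

### The all-replicates rule

An event is reported only if its p-value(s) are below $\alpha = 0.01$ in
*every* replicate pair **and** the direction (the intron/exon depth ratio,
skip ratio, or gene-normalized junction usage ratio, compared between
genotypes) agrees in every pair. No multiple-testing correction is applied
— deliberately: the conjunction over five replicate pairs is already far
more stringent than any marginal FDR control (null pass rate $\approx
\alpha^k$ for $k$ pairs, $10^{-10}$ at $k = 5$), and this mirrors the
analysis style the pipeline reproduces. Users should be aware the rule is
*conservative* for discovery and *anti-conservative* for nothing.

Replicates are paired by index (mutant $i$ vs. wild type $i$) by default.
The alternative (`pairing = "pooled"`: each mutant replicate against the
summed wild-type replicates) gains background precision at the cost of the
five tests sharing their reference; index pairing keeps them independent and
is the default for that reason.

### Direction labels and ties

The direction rules are binary with an "otherwise" branch: an intron is
*more efficiently spliced* (MES) when its mutant depth ratio is smaller,
otherwise it is *increased retention* (IR); a junction variant is *enhanced*
when its gene-normalized usage is greater in the mutant, otherwise
*reduced*. Exact ties therefore fall into the "otherwise" branch per pair;
since a tied pair essentially cannot also be significant, ties never create
calls in practice. Discordant directions across pairs veto the call even
when every p-value passes, because one event gets one direction.

## Differential expression

Counts are normalized with TMM (trimmed mean of M-values): per sample, the
inverse-variance-weighted mean of library-size-scaled log2 ratios against a
reference column, after trimming 30% of each tail of the M-values and 5% of
each tail of the A-values, rescaled to geometric mean 1. The implementation
mirrors the standard algorithm (including f75 reference selection and
rank-based trimming) and is checked against edgeR as an independent oracle
in the tests. Worth knowing: with library sizes taken as column sums, a
single extreme outlier gene changes the column sum itself, so the factors
are *not* (1, 1) — they are exactly the values that equalize the effective
library sizes, which is the meaningful invariance. With explicitly equal
library sizes the factors are identically 1.

logCPM is the offset-stabilized transform
$\log_2\big((x + 0.5)/(N f + 1)\cdot 10^6\big)$; no precision weights are
computed (only the transform is needed ahead of plain t-tests). "Adjusted
RPKM" is interpreted as the log-scale length correction
$\mathrm{logCPM} - \log_2(L/1000)$ — the source analysis did not spell out
its construction, and this is the declared reading: it is monotone,
length-comparable, and leaves t-tests invariant to any per-gene constant.
Genes are tested with two-sided Welch t-tests (the safer default where only
"t-test" is specified; pooled-variance is available via `var_equal`), and
called iff $p < 0.01$ (strict) and $|\log_2 FC| \ge 0.6$ (inclusive).

## Counting definitions

* **Average depth** = aligned bases overlapping the feature / feature
  length.
* **Junction read**: a fragment supports a junction iff one of its
  alignment gaps equals the intron coordinates *exactly*. Near-miss gaps
  sharing exactly one end (donor or acceptor) with an annotated intron are
  retained as that intron's observed alternative junctions — the input to
  the A5SS/A3SS scan. Gaps sharing neither end are kept unattached (the
  reporter quantifier looks junctions up by exact coordinates, since the
  nested GT–AG junction shares neither end with the outer AT–AC intron).
* **Boundary reads**: a single aligned block contiguously covering `anchor`
  nt (default 8, configurable) on each side of an exon–intron boundary —
  the unspliced-transcript evidence. 8 nt balances specificity (a spliced
  read cannot fake it) against yield; the value is a package choice where
  the source was silent.
* **Unique gene reads**: fragments attributable to exactly one gene; a
  fragment overlapping two genes counts toward both genes' totals but not
  toward either's unique count. Paired mates are blocks of one fragment and
  count once.
* **Identity filter**: alignments with identity < 0.90 (from the `NM` tag
  over aligned bases) are discarded, as are secondary/supplementary records
  and mapping-quality-0 (ambiguous) records.

One exon/intron chain is used per gene — per-intron depth statistics
presuppose it. When the annotation has several transcripts per gene the
representative chain is the longest by summed exon length (configurable to
the lexicographically first); which transcript the original analysis used
when isoforms exist is unknowable from the text, so this is an explicit,
configurable guess. Exon skipping is only meaningful against that chain.
Skip junctions are excluded from the alternative-splice-site variant sets so
one physical junction is never reported both as ES and as two alt-SS
events.

## What the simulator states, and why

The generator emulates the study design it is meant to exercise: two
genotypes × five biological replicates; per-gene expression
$X \sim \mathrm{NB}(\mu, \phi)$ with $\mathrm{Var} = \mu + \phi\mu^2$
(dispersion $\phi = 0.05$, typical for biological replicates); Poisson
feature depths around each replicate's gene coverage; binomial junction
reads at the intron's splicing efficiency; and perturbations injected as
odds folds on the mutant side (retention odds for IR/MES, skip odds for ES,
variant-usage odds for alt-SS), clamped to $[0,1]$ with a truth-table flag.

Defaults: baseline splicing efficiency 0.8 (20% baseline retention —
retention must be measurable for a retention *shift* to be definable),
baseline skip and alternative-usage rates 0.05 (minor outcomes), read
length 100 nt, exon lengths 50–500 nt and intron lengths 60–1,000 nt
(compact plant-like genes, mean six exons).

**Mean depth 400** is the one default chosen by explicit power analysis
rather than convention, fixed *a priori*: with baseline retention 0.2 and a
4-fold retention-odds increase (to 0.5), the per-pair Pearson noncentrality
at exon depth $d$ is $\approx 0.072\,d$; the all-replicates rule needs
per-pair power $0.99$ ($0.99^5 \approx 0.95$), i.e. noncentrality
$\approx (z_{0.005} + z_{0.01})^2 \approx 24$, hence $d \approx 350{-}400$.
At 2 kb genes and 100 nt reads this is ~16 M counted fragments per library
— ordinary bulk RNA-seq depth for well-expressed genes. The inverse MES
fold (odds ÷ 4) is the power bottleneck (smaller counts on the mutant
side); depth 400 puts it at ~0.98 per event.

What the simulator does **not** emulate: sequence-level effects (GC and
positional bias, sequencing error), transcript-count conservation between
skip and inclusion reads, correlated efficiencies along a gene, and any
coupling between injected retention changes and junction-read depletion. A
green recovery test therefore establishes that the statistics detect the
stated effect sizes at the stated depths under clean sampling noise — not
that they are robust to alignment artifacts or covariate structure in real
libraries.

## Numerical choices

* χ² on fractional depths, no continuity correction, df = 1; zero margin →
  $(0, 1)$.
* Fisher p-values sum hypergeometric probabilities $\le p_{obs}(1+10^{-7})$
  (the customary tie tolerance); entries rounded half-up.
* The DEG log-FC boundary is inclusive at exactly 0.6; the p boundary is
  strict at 0.01. (Floating point: a mean difference constructed as
  `x + 0.6 - x` can land one ulp below 0.6 — the rule is exact on its
  inputs, and the boundary test exercises the rule, not double rounding.)
* Zero-variance-equal-means genes get $p = 1$; zero-variance-unequal-means
  get $p = 0$ (the t statistic diverges).
* All randomness flows from a single integer seed per design; the pipeline
  rerun under a fixed config is byte-identical apart from the log.

## Known limitations

* Only annotated introns (plus their skip and attached alternative
  junctions) are tested; no de novo junction discovery.
* The all-replicates rule's stringency depends on replicate count: with
  more replicates it becomes *harder* to call events, not easier.
* No multiple-testing correction means per-pair p-values should not be
  quoted as calibrated event-level error rates; the conjunction is the
  control.
* The reporter quantifier assumes junction and boundary evidence are
  comparable without length normalization because their anchor widths
  match; mixtures with extreme length asymmetry among variants would need
  the `use_both_boundaries` option or external calibration.
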