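---
title: "Tumor-only variant filtering with unmatched normal controls: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only variant filtering with unmatched normal controls: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umnvar)
library(dplyr)
```

## The problem

Most clinical tumor sequencing arrives without a matched normal sample.
Calling somatic mutations then means separating four things that all look
like "non-reference bases in the tumor": true somatic variants, the
patient's private germline variants, positions where the reference genome
or the capture protocol make allele fractions unreliable, and sequencing
or sample-preparation artifacts (oxidised guanine, formalin damage,
strand-biased calls). This package implements a filtering workflow that
calls the tumor against each member of a panel of *unmatched* normal
controls (UMNs) and exploits two things a panel provides that no database
can: locus-specific behaviour of allele fractions under the exact
sequencing protocol, and a consensus signal across independent calling
runs.

Every variant receives a full verdict row — per-criterion flags, the
germline-equilibrium posterior, artifact labels, consensus fraction and
the final call. Nothing is pre-filtered away, because excluded variants
carry the genomic context needed to interpret the retained ones.

## Genotyping normal allele fractions

For one control, the alt counts $a_i$ at depth $d_i$ across loci are
modelled as a four-component mixture

$$ a_i \sim \pi_e\,\mathrm{Bin}(d_i, p_e) + \pi_h\,\mathrm{Bin}(d_i, p_h)
   + \pi_m\,\mathrm{Bin}(d_i, p_m) + \pi_0\,\mathrm{U}\{0,\dots,d_i\}, $$

the components being sequencing error (near 0), heterozygous (near 0.5),
homozygous (near 1) and a discrete-uniform *noise* class with mass
$1/(d_i+1)$. The binomial-plus-uniform pairing is deliberate: wildly
variable allele fractions should land in the noise class, whereas an
over-dispersed beta-binomial would absorb them into a "genotype" and hide
exactly the loci the next stage needs to see. The fit is by EM with
deterministic initialisation $p = (0.01, 0.50, 0.99)$ and uniform
weights; after each M-step the success probabilities are clamped to
$(10^{-4}, 0.15)$, $(0.3, 0.7)$ and $(0.85, 1-10^{-4})$, which pins the
genotype identity of each component (no label switching is possible).
Convergence is $|\Delta \log L| < 10^{-6}$ with at most 500 iterations,
and the log-likelihood is asserted non-decreasing in the test suite. Hard
labels are the posterior argmax with ties resolved to noise, the
conservative direction (ambiguous loci stay out of the heterozygous
pool). Fitting is per control by default; each control's error profile is
its own.

## Hard-to-map (H2M) regions

Loci labelled `error` or `hom` are discarded; the heterozygous-like
remainder is pooled across controls. Per locus $i$ (in genomic order
within a chromosome) the statistic

$$ m_i = \frac{1}{|C_i|}\sum_{c \in C_i} \left| \mathrm{nVAF}_{ic} - 0.5 \right| $$

is segmented by deterministic binary segmentation: the best least-squares
split of a segment is accepted when it reduces the within-segment squared
error by more than $6 \log n$ noise variances, with the noise variance
estimated robustly from the median absolute successive difference of
$m_i$ *within the segment under consideration*. Two numerical choices
matter here and were made on constructed fixtures:

* The gain is measured as a raw SSE reduction in noise units, not as a
  likelihood ratio with per-side refitted variance. A narrow deviant
  window in a long chromosome barely moves a refitted variance, and the
  likelihood form can miss it; the scaled SSE form detects it with
  orders-of-magnitude margin.
* The penalty multiplier 6 is deliberately above the textbook BIC value
  of 2, because the split point is chosen as a maximum over all candidate
  positions, which inflates the null distribution of the best gain. At
  2–4 the segmenter occasionally split homogeneous stretches; at 6 it
  does not, while the deviant-region regimes of interest exceed the
  penalty by factors of $10^3$–$10^4$.

A (locus, control) observation is *deviant* when its alt count falls
outside the central 99% binomial interval around 0.5 at its depth
(`h2m.alpha = 0.01`; the published rule names no interval, only
"deviates from 0.5"). A segment is flagged H2M when deviant observations
form a strict majority (`> 0.5`, taken verbatim from "the majority").
Flagged segments that are adjacent in locus order merge into intervals,
which can be exported as BED. H2M is computed on the fly per tumor on
that tumor's detected loci — it reflects the capture design, depth and
aligner, not a fixed genome catalogue, and no gene-level exclusion list
is involved.

## Variants in germline equilibrium (VIGE)

A private germline variant is invisible to every unmatched normal, but it
sits at the *local* germline allele-fraction band — the B-allele fraction
(BAF) shared by known SNPs in its copy-number segment. Per segment the
band $b$ is the median folded tumor VAF $\min(v, 1-v)$ of database-known
heterozygous SNPs (population AF $\ge$ 0.01 in either germline database,
depth $\ge$ 10, VAF in (0.1, 0.9) to exclude homozygous database hits);
with fewer than 5 supporting SNPs the band — and every posterior in the
segment — is reported missing rather than guessed. Segment gaps are
filled to the midpoint between neighbouring segments, so every position
on a segmented chromosome maps somewhere.

For a non-database variant with alt count $a$ at depth $d$ the
germline-equilibrium posterior is

$$ \gamma = \frac{w\,L_g}{w\,L_g + (1-w)\,L_s}, \qquad
   L_g = \max\{\mathrm{Bin}(a \mid d, b),\ \mathrm{Bin}(a \mid d, 1-b)\}, $$

with prior $w = 0.5$ (so $\gamma > 0.5$ is exactly a likelihood-ratio
test at 1) and a somatic alternative that integrates a binomial over a
uniform grid of sub-band success probabilities
$p \in (0.01,\ 0.9\,\min(b, 1-b))$ in steps of $10^{-4}$, evaluated as
the strand-symmetric average
$\tfrac12\{\mathrm{Bin}(a \mid d, p) + \mathrm{Bin}(a \mid d, 1-p)\}$.
The symmetric form makes the posterior exactly invariant to which allele
is called B ($\gamma(a, d; b) = \gamma(d-a, d; 1-b)$), which the test
suite asserts on a grid. A uniform sub-band alternative rather than a
point alternative avoids branding every impure-tumor somatic variant as
germline. Variants with $\gamma > 0.5$ fail the germline criterion; the
posterior is attached to the verdict either way.

The known limitation is inherent: as purity approaches one, a clonal
somatic variant sits on the band and becomes indistinguishable from a
heterozygous germline variant. The suite pins this down as documented
behaviour — at purity 0.9 and depth 800 a substantial fraction of clonal
variants receive $\gamma > 0.5$, at purity 0.6 essentially none.

## Artifact classes

**Strand bias.** Two-sided Fisher exact test on
$[[\mathrm{ref}_F, \mathrm{ref}_R], [\mathrm{alt}_F, \mathrm{alt}_R]]$,
flagged at $p < 0.05$. The p-value is the textbook conditional
(hypergeometric) two-sided sum with the standard $1 + 10^{-7}$ tie
tolerance, computed vectorised over variants; agreement with
`stats::fisher.test` to $10^{-12}$ and with a full enumeration oracle
over every table of total $\le 60$ is asserted. The test is
context-free — no trinucleotide modelling.

**oxoG and FFPE.** Artifact families form coherent, usually low,
genome-wide tumor-VAF clusters (oxidised-guanine calls typically at 1–3%
allele fraction). BASE-passing consensus variants are clustered with the
same EM machinery (free component locations, noise component, component
count chosen by BIC over 1–5 — a fixed count either splits or merges
coherent bands). For each cluster and mode, the fraction of the mode's
substitution class (oxoG: C>A/G>T; FFPE: C>T/G>A plus indels, on the
reference-strand representation with complementary pairs pooled) is
tested against the background class rate with a one-sided binomial test.
A cluster is *characterised by* the class when its class fraction is at
least 0.8 **and** the enrichment p-value is below 0.01 — the published
rule is qualitative ("characterised by"), and these two knobs make it
operational. Class members of characterised clusters are flagged; a
variant can carry several raw flags, and the single `artifact` label
follows the ladder order OXOG → STRANDBIAS → FFPE.

## The cumulative ladder

Per calling run, BASE applies depth $\ge 10$, quality $\ge 10$, target
membership, impact in {LOW, MODERATE, HIGH} and maximum population AF
below 0.01 (missing AF counts as 0; missing impact as MODIFIER, which
fails). Control quality control (UMNQC) excludes panel members whose
median coverage, fraction of targets at 100×, or attracted call count is
a robust-z outlier (|z| > 3 on median/MAD) in the unfavourable direction
*and* deviates more than 20% from the panel median — the relative guard
exists because a homogeneous panel has a near-zero MAD, and without it
trivial fluctuations get excluded. Consensus is
$f = \#\{\text{QC-passing runs containing the variant}\} / \#\{\text{QC-passing runs}\}$
with inclusive comparison $f \ge \tau$, $\tau = 0.90$ (18 of 20 passes;
excluded controls leave both numerator and denominator). The cumulative
stages BASE → UMNQC → H2MGERM → OXOG → STRAND → FFPE intersect
independent per-criterion booleans, so permuting the artifact stages
provably cannot change the final set — asserted as a test anyway. A
variant with COSMIC recurrence $\ge 10$ is retained regardless of every
other criterion; rescue can of course re-admit artifacts, which is the
price the published design pays knowingly.

## Benchmarking

The gold standard starts from matched tumor-normal calls and removes
calls inside H2M intervals unless rescued by COSMIC recurrence $\ge 10$ —
such regions are unreliable even with a matched normal. Calls are scored
as SENS = TP/(TP+FN), PPV = TP/(TP+FP), F1 their harmonic mean, with
empty denominators reported missing. Association of noise status with
annotation covariates uses the sample odds ratio of a 2×2 table with the
Wald interval $\exp(\log \hat{OR} \pm 1.96\,SE)$,
$SE = \sqrt{1/a + 1/b + 1/c + 1/d}$; this is evidently the published
method, since all four printed univariate intervals reproduce to their
two decimals from the printed counts. Zero cells get the
Haldane–Anscombe 0.5 correction, flagged in the output. A logistic
companion (`nonmendelian_logit`) is provided for multivariate use but
carries no reproducible published inputs.

## The synthetic cohort

`simulate_cohort()` generates the complete input bundle — per-run VCFs,
per-control genotype tables, targets BED, annotation TSV and a truth
table — with every structure the pipeline detects. Defaults are the
study conditions of the targeted-panel setting the workflow was built
for: 20 controls, mean target coverage 800×, tumor purity 0.65 (clonal
somatic VAF = purity/2 under the diploid assumption), 80 germline
heterozygous sites (10% private to the tumor patient, hence absent from
all controls), 20 homozygous, 12 somatic variants of which 40% are
COSMIC-recurrent hotspots (a targeted actionable panel is hotspot-heavy,
and this exercises the rescue path), one contiguous 15-locus hard-to-map
region whose per-observation deviation from 0.5 is at least 0.2, 30 oxoG
artifacts at VAF 1–3%, 15 FFPE artifacts (one third indels) at 4–8%, 10
strand-bias variants with all alt reads on one strand, a 3% per-run
dropout of true variants (so $\tau = 0.9$ is stressed but typically
met — unanimity would not be), around five run-private calls per run,
and one designated bad control with half coverage and five-fold private
calls to exercise UMNQC.

What the generator does *not* emulate: read-level errors (no FASTQ/BAM),
sequence context, subclonal architecture, copy-number variation of the
germline band (the BAF is 0.5 everywhere), and control-to-control
correlation of artifacts. Passing end-to-end checks therefore
demonstrates that the machinery recovers the structures it models, at
realistic depths and panel sizes — not performance on real tumors.

```{r}
cfg <- sim_config(seed = 42)
b <- simulate_cohort(cfg)
count(b$truth, truth)
```

## Problem sizes used in the packaged checks

The test suite and the acceptance script run: the exact-test enumeration
over all 635,375 tables with total $\le 60$; EM weight recovery over 50
replicates of 500 observations at depth 100; hard-to-map detection over
100 replicates of a 100-locus chromosome with 20 controls at depth 300
(12-locus injected window, deviation $\ge 0.15$) plus 100 clean
replicates for specificity; 100 random posterior/oracle triples; and 20
end-to-end replicates of the default cohort with 10 controls drawn from
the QC-screened panel. These sizes give stable Monte-Carlo estimates
while keeping a full run in the low minutes on one core.

## Known limitations

* Left-alignment of indels requires the reference FASTA; only shared
  prefix/suffix trimming is performed when keying variants across runs.
  Callers that emit anchored indels (the common case) are unaffected.
* The germline band is estimated per segment from database SNPs; in
  segments with fewer than 5 such SNPs the posterior is missing and
  private germline variants there can only be caught by the consensus or
  artifact criteria.
* The binomial components ignore over-dispersion by design; see the
  noise-class discussion above for why.
* High-purity tumors lose clonal founder variants to the germline
  criterion; users suspecting purity near 1 should inspect variants with
  $\gamma$ slightly above 0.5 rather than discard them.
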