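---
title: "Discriminating monozygotic twins from replicated SNV genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating monozygotic twins from replicated SNV genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinsnv)
```

## The problem and the model

Monozygotic twins inherit one zygotic genome and are therefore
indistinguishable by STR profiling. Differences can arise only after the
zygote splits, and they come in two flavours with very different read-level
signatures:

* **post-zygotic (constitutional) mutations** — present in essentially every
  cell of one twin. At a heterozygous site the alternate allele is carried
  by one of two chromosome copies in every cell, so its expected alt-read
  fraction is 0.5 in any tissue.
* **tissue-specific somatic variants** — present in a fraction of one
  tissue's cells, so the alt-read fraction is skewed, typically in the
  5–20% range reported for blood/buccal comparisons in large twin cohorts.

When the trace and the reference come from *different tissues* (blood at a
scene, a buccal reference swab), somatic variants are the dominant source of
false inter-twin differences. The workflow therefore filters heterozygous
calls on the **heterozygote balance**

$$\mathrm{Hb} = \frac{\mathrm{alt}}{\mathrm{ref}+\mathrm{alt}},$$

keeping a window around 0.5 that constitutional heterozygotes satisfy with
high probability while skewed somatic variants rarely do. For a true
heterozygote at depth $d$ the probability of passing a window $[l, h]$ is
the exact binomial sum

$$P_\text{pass}(d) = \sum_{k:\; l \le k/d \le h} \binom{d}{k} 2^{-d},$$

which the test suite uses as an independent oracle against Monte-Carlo rates
from the simulator.

### Why Hb is the alt fraction

Forensic STR practice sometimes defines heterozygote balance as a min/max
peak ratio. Here Hb is the *alternate-allele read fraction*: every window
this workflow uses (0.2–0.8, 0.4–0.6, 0.45–0.55, 0.3–0.7) is symmetric about
0.5, which is the natural parameterisation for an allele fraction and makes
the windows non-redundant. Window bounds are **inclusive** (`0.4 ≤ Hb ≤
0.6`); the homozygote noise test is **strict** (`noise < 0.05`). Reads
supporting neither allele are excluded from the Hb denominator but do count
toward the noise, which is why `other_count` is carried through the whole
pipeline.

## Acceptance filters and replicate concordance

Two preset regimes (`filter_preset()`):

| parameter | shotgun | targeted | meaning |
|---|---|---|---|
| `dp_min` | 8 | 100 | minimum total read depth (reads) |
| `gq_min` | 10 | 10 | minimum Phred-scaled genotype quality |
| Hb window | 0.4–0.6 | 0.3–0.7 | heterozygote balance bounds (inclusive) |
| `noise_max` | — | 0.05 | homozygote noise ceiling (strict) |

Rejection reasons are evaluated in the fixed order *missing, depth, quality,
balance, noise*, so rejection statistics are deterministic. A heterozygote
with zero allele-informative reads has undefined Hb and is rejected with
reason `balance`.

**Replicate concordance is both-must-pass.** A locus contributes a consensus
genotype only when *every* replicate's call individually passes the active
filter *and* all genotypes agree. The open alternative — accepting a
genotype wherever the callable replicates agree — would admit
single-replicate evidence into the comparison, which is exactly what
duplicate sequencing is meant to exclude; counting "detected in both
duplicates" is the conservative reading and the one implemented. Hb is
always computed per replicate, never on pooled counts, because pooling masks
replicate-level imbalance.

**The comparison domain** is the set of loci with an accepted consensus in
*both* samples where at least one consensus is not `hom_ref`. Requiring a
variant in both samples would make hom-vs-het discordances — the only
pattern a real post-zygotic mutation produces — structurally impossible, so
the at-least-one reading is the only self-consistent one. Hom-ref/hom-ref
loci are vacuous and excluded.

**The Hb sweep** (`hb_sweep()`) re-runs consensus, domain and discordance
detection per scheme, varying *only* the Hb window; depth and quality floors
stay at the base configuration. Because the windows nest, retained
genotypes, compared loci and discordances are non-increasing with
stringency — the suite asserts this as set inclusion, not just counts.

**Coverage summaries** (`coverage_summary()`) count positions at depth
`dp_min` or more in both replicates; breadth divides by a caller-supplied
genome-size denominator (the summed VCF-header contig lengths when present,
3.2 Gb as a fallback) because variant-only VCFs cannot determine the
normalizer themselves. When no per-position depth track is supplied, the
`compare` subcommand reports a VCF-record-based proxy labelled
`coverage_proxy_vcf_records_only`.

## The panel-validation stage

Candidates from the shotgun comparison are re-genotyped under the targeted
regime. Verdict rules:

* `confirmed_discordant` — accepted consensus in both samples, genotypes
  differ;
* `rejected_concordant` — accepted identical genotypes;
* `inconclusive` — dropped from the panel (undesignable primers), allele
  mismatch against the panel VCF, or no consensus in at least one sample.
  A locus with an accepted genotype in only one sample is *inconclusive*,
  never confirmed: absence of evidence in one sample cannot establish a
  difference.

Identity-SNP controls are validated identically, reported separately, and
never influence the case outcome; any discordant control marks the run
`suspect`, since controls are chosen to be rock-solid concordant loci. The
case verdict is `distinguishable` iff at least one target is confirmed;
otherwise `no_detectable_difference` with the explicit caveat that a
same-source trace and genetically identical twins cannot be separated.

## The simulator: what it states and what it omits

`simulate_twin_pair()` states a small world:

1. `n_loci` variant-capable positions on one contig (chr1 coordinates);
   germline genotypes drawn i.i.d. with `p_het = 0.45`,
   `p_hom_alt = 0.25`. These defaults describe typical genotype proportions
   at polymorphic SNV sites in a single genome — roughly half heterozygous —
   and are configurable; nothing downstream depends on them finely.
2. Per twin, `Poisson(lambda_postzygotic = 14)` hom-ref loci flip to
   constitutional het (alt fraction 0.5 in every tissue of that twin). The
   default is the cohort median for informative inter-twin variants;
   `postzygotic_exact = TRUE` plants exactly `round(lambda)` per twin when a
   scenario needs a fixed count. Setting `lambda = 0` emulates the ~10% of
   MZ pairs with no detectable differences.
3. Per *sample*, `n_somatic = 50` tissue-specific variants at alt fractions
   `Uniform(0.05, 0.20)` — parameterised directly by read fraction, because
   that is how the phenomenon is observed, rather than via a latent cell
   fraction.
4. Read counts: depth `Poisson(mean_depth)` (defaults 39.7× trace, 25.8×
   reference — genome-typical values for a good trace and a buccal
   reference), then a three-way draw with
   `p_alt = f(1−ε) + (1−f)ε/3`, `p_other = 2ε/3` (miscalls uniform over the
   three non-true bases). Default `error_rate ε = 0.002`, a realistic
   post-filter short-read miscall rate.
5. Genotypes and GQ are re-called from the counts with a binomial
   likelihood over alt probabilities `ε/3`, `0.5`, `1−ε`;
   `GQ = round(10·log10(L_best/L_second))` capped at 99. This is a
   deliberately simple stand-in for an upstream caller — GQ ≥ 10 behaves
   comparably — computed in log space, with ties broken toward the first
   genotype in (hom_ref, het, hom_alt) order and zero allele-informative
   reads yielding a missing call with GQ 0.
6. Replicates are independent read-count draws from the same tissue
   fractions, so replicate discordance arises purely from sampling — the
   thing the concordance filter absorbs. All randomness flows from one seed;
   panel and control-selection draws use fixed seed offsets so adding a
   stage never perturbs earlier draws, and fixed-seed runs are
   byte-identical.

The simulator does **not** emulate: alignment and mapping artifacts,
duplicate reads, indels or multiallelic sites, linked haplotypes, GC or
coverage waves, population allele-frequency structure, or panel primer
chemistry (undesignable loci are a configurable drop rate, anchored at the
observed 11/28). A green test therefore establishes that the *filtering and
comparison logic* behaves as specified under honest sampling noise — not
that the pipeline is robust to alignment pathology, which must come from the
upstream caller.

## Design choices in the acceptance scenarios

Two choices deserve an explicit record:

* **Planted-recovery checks run without an Hb window.** The medium window
  0.4–0.6 removes ~3.5% of *true* heterozygotes per replicate at 100×
  (binomial mass outside [0.4d, 0.6d]), i.e. ~7% per sample with duplicate
  concordance. A recovery bound of 19/20 planted variants is then a coin
  flip by construction, whereas with the window disabled recovery is
  essentially certain. The window is a somatic guard, not a recovery aid, so
  the recovery scenario measures the pipeline's mechanics (consensus,
  comparison, confirmation, pattern classification) with the guard off; the
  guard's own operating characteristic is measured separately against the
  exact binomial oracle.
* **The somatic-leakage oracle is closed-form.** Integrating the binomial
  over `f ~ U(0.05, 0.20)` gives incomplete-beta terms,
  $\big(I_{0.20}(k{+}1, d{-}k{+}1) - I_{0.05}(k{+}1, d{-}k{+}1)\big)/\big((d{+}1)\,(0.15)\big)$,
  summed over Poisson-weighted depths and het-called read-count states. The
  leakage fixture draws reads error-free (genotype calling keeps its model
  ε = 0.002) so that the enumeration is exact rather than approximate.

## Numerical and degenerate-input conventions

* Hb of a call with `ref + alt = 0` is an error at the API surface and a
  `balance` rejection inside the filter; noise at `DP = 0` likewise rejects.
* Genotype ontology is diploid biallelic `{hom_ref, het, hom_alt, missing}`;
  phasing is ignored (`1|0 ≡ 0/1`). Multiallelic and non-SNV records are
  skipped at ingestion and *counted*, never silently dropped — the counters
  travel with the call set and appear in the compare summary.
* `AD` is authoritative for ref/alt counts; `DP − sum(AD)` excess is stored
  as `other_count` (it feeds the noise filter).
* Output tables are written in (chrom, pos) order with LF line endings, so
  identical analyses are byte-identical regardless of input order.

## Limitations

The workflow reports discordance *counts*, not an evidential likelihood
ratio; turning confirmed differences into court-ready weight-of-evidence is
a separate statistical problem. With only one twin's reference available, a
`no_detectable_difference` outcome is irreducibly ambiguous. And because the
comparison consumes called genotypes, loci lost upstream (low mapping
quality, undesignable primers) are invisible to it — the panel stage makes
that loss explicit through `inconclusive` verdicts rather than hiding it.
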