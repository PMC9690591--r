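---
title: "Methods: CNV population genomics with cnvpopscan"
author: "cnvpopscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV population genomics with cnvpopscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpopscan)
```

# Scope and model

`cnvpopscan` analyzes copy-number variants (deletions, duplications,
insertions of 50 bp and larger) genotyped across a two-population diploid
cohort. The pipeline starts from genotyped SV records — a VCF 4.2 dialect
with `SVTYPE`, `SVLEN` and (for interval events) `END` in INFO and `GT` as
the first FORMAT field — and proceeds through group-level de-redundancy,
site-level quality control, a per-variant Fst selection scan, gene-model
annotation, allele-frequency summaries, and structure inference (PCA, NJ
tree). Upstream read alignment and SV discovery/genotyping are out of
scope: the package consumes their output. Only biallelic DEL/DUP/INS
records are handled; multiallelic records are rejected rather than split,
and phased genotypes are collapsed to dosages because every downstream
statistic depends on dosage alone.

Coordinates are stored VCF-native (1-based, inclusive `[pos, end]`; an
insertion is the single base at `pos`), and interval arithmetic is done
directly on that convention, which keeps VCF round trips bit-exact.

# Merging redundant calls

Per-sample SV calling produces near-duplicate records of the same event
across a cohort. Two same-type, same-chromosome records are considered the
same event when they satisfy a location criterion *and* their genotypes
agree:

* **DEL**: reciprocal overlap $\min(I/\ell_a, I/\ell_b) \ge 0.5$;
* **DUP**: reciprocal overlap $\ge 0.9$;
* **INS**: breakpoints within 100 bp and length ratio
  $\min(\ell_a,\ell_b)/\max(\ell_a,\ell_b) \ge 0.9$ (an insertion is a
  point event, so interval overlap is undefined; this mirrors common
  SV-merging tools, and the window is exposed in `merge_config()`);
* **genotype concordance** $\ge 0.95$ over the samples genotyped in both
  records. Missingness never counts as agreement: a record with no
  jointly genotyped samples has concordance 0 and can never merge.

Reciprocal (rather than one-directional) overlap is used because a
one-sided fraction would happily merge a 50 bp call into a 10 kb call.
All thresholds are inclusive. Equivalence classes are single-linkage
connected components within each (chromosome, type) stratum, computed by a
sorted sweep that only evaluates pairs within reachable distance; the
partition is provably identical to brute-force all-pairs connected
components, and tests verify this against an independent graph-library
oracle on random callsets. The cluster representative is the member with
the fewest missing genotypes (ties broken by smallest position, end,
record id), which maximizes downstream call rate and is deterministic, so
merging is idempotent and invariant to input order.

# Quality control

Four independent site filters are applied after merging, with the
inclusive/exclusive senses exactly as written:

| rule | keep when | default |
|------|-----------|---------|
| length cap | $|{\rm SVLEN}| \le$ `max_abs_svlen` | $10^7$ bp |
| excess heterozygosity | $p_{\rm ExcHet} \ge$ `min_exchet_p` | 0.05 |
| missingness | $F_{\rm MISSING} \le$ `max_f_missing` | 0.2 |
| frequency | ${\rm MAF} >$ `min_maf` | 0 |

The excess-heterozygosity test is the one-sided upper tail of Levene's
exact conditional distribution of the heterozygote count given the allele
counts,
$P(n_{het}=k) \propto \frac{N!}{n_{AA}!\,k!\,n_{aa}!} 2^k$,
the ExcHet semantics of standard VCF toolchains; mid-p is not used. The
implementation builds the distribution by the parity recurrence
$P(k+2)/P(k) = (n_A-k)(n_a-k)/\{(k+1)(k+2)\}$ and normalizes, which is
numerically stable for any cohort size; the test suite checks it against
an independent log-factorial enumeration to $10^{-12}$ for every genotype
table of up to 50 diploids. MAF uses non-missing genotypes only (missing
is never treated as reference). A record with zero genotyped samples has
undefined ExcHet/MAF and fails those rules — it always also fails the
missingness cap at any meaningful threshold, so the filters stay total and
commuting. The filter report lists every failed rule per removed record.

# Fst selection scan

For each autosomal variant with alternate-allele frequencies $p_a$, $p_b$,
with $\bar p = (p_a + p_b)/2$:

$$H_t = 2\bar p(1-\bar p), \qquad
  H_s = \tfrac12\left\{2p_a(1-p_a) + 2p_b(1-p_b)\right\}, \qquad
  F_{st} = \frac{H_t - H_s}{H_t}.$$

Design choices worth stating explicitly:

* $\bar p$ and $H_s$ use **unweighted** means of the two populations; the
  heterozygosity formula itself carries no weights, and a sample-size
  weighted variant is available behind `weight_by_n`.
* **No Nei or Weir–Cockerham sample-size correction** is applied: the
  statistic is the raw heterozygosity ratio. Per-variant values are
  therefore upward-biased at small sample sizes. This is documented, not
  "fixed", because the scan consumes ranks, which the bias shifts little.
* Sites monomorphic in the pool ($H_t = 0$) get $F_{st} = 0$ rather than
  NaN — they carry no differentiation signal and keeping them preserves
  scan totals.
* Sex chromosomes (default name set `{X, Y}`, configurable because
  references differ) are excluded from the scan.

Selection takes the top fraction (default 1%): $k = \lceil f N\rceil$
variants after sorting by (Fst descending, record id ascending). The
deterministic tie-break means ties at the boundary never inflate $k$; with
28,720 ranked variants the rule selects exactly 288.

Frequency spectra bin segregating variants ($p > 0$) into ten right-closed
bins $((k-1)/10, k/10]$, matching the conventional 0–0.1, …, 0.9–1 class
labels while keeping bins disjoint; $p = 0.1$ falls in the first bin. The
shared/unique comparison defines "present in a population" as a defined,
positive allele frequency there — a frequency-based operationalization of
callset sharing.

# Annotation

Variants are classified against transcript models into eleven mutually
exclusive classes using the ANNOVAR-style vocabulary and precedence:
exonic (CDS overlap of a coding transcript) > splicing (intron overlap
within 2 bp of an exon boundary) > ncRNA (exon overlap of a non-coding
transcript) > UTR5/UTR3 (with a combined class when both are hit, possibly
via different transcripts) > intronic > upstream/downstream (strand-aware
1 kb windows, with a combined class) > intergenic. A variant spanning
several genes takes the highest-precedence hit. The window sizes are
configurable defaults, recorded here as this package's interpretation —
classification vocabulary of this kind rarely ships with its parameters.
Widening the flank windows is monotone: it can only move variants from
intergenic toward the flank classes, never the reverse, and the test suite
checks this property alongside a full round trip of coordinates planted
in every class by the gene-model simulator.

# Structure inference

Genotypes become a samples × variants dosage matrix (0/1/2, missing
masked). PCA mean-imputes missing entries per variant, centers, and by
default scales each variant by $\sqrt{\hat p(1-\hat p)}$ — the SMARTPCA
normalization — before a deterministic LAPACK SVD; explained fractions are
$\lambda_k / \sum\lambda$. There is no randomized solver, so coordinates
are bit-reproducible.

The between-sample distance is the allele-sharing distance: the mean of
$|d_i - d_j|/2$ over jointly genotyped variants. The tree is Saitou–Nei
neighbor joining implemented in-package: ties on the Q-criterion are
broken by the smallest index pair (determinism), negative branch lengths
are clamped to zero with the difference moved to the sister branch
(standard practice; raw lengths behind `clamp = FALSE`), and the output is
an unrooted Newick string. On additive matrices NJ reproduces the
generating tree exactly, which the tests verify on random trees of up to
8 taxa, alongside a cross-check against the reference NJ implementation
in `ape`.

# The synthetic cohort generator

No public CNV genotype matrix ships with the package, so validation runs
on simulated cohorts built to match the data regime the pipeline assumes:
two populations of 45 and 19 diploid samples by default. Differentiation
follows the Balding–Nichols model — ancestral frequency
$p \sim U(0.05, 0.95)$, population frequencies
$p_{a,b} \sim {\rm Beta}\!\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$
independently — chosen because its explicit $F$ parameter is directly
comparable to the scan's Fst. Genotypes are ${\rm Binomial}(2, p_{pop})$:
Hardy–Weinberg within populations and, deliberately, **no linkage
disequilibrium between variants**, no demographic history, and no
genotyping-error model beyond missingness. Passing tests on this generator
therefore demonstrate correctness of the statistics under their own
assumptions, not robustness to LD or call-error structure in real data.

Defaults: type mix 70% DEL / 5% DUP / 25% INS (deletion-dominated, as SV
callsets typically are), log-uniform lengths 50–100,000 bp for DEL/DUP and
50–1000 bp for insertions (echoing the working definition of CNVs from
50 bp up to megabases, kept below chromosome scale), 2% missingness, and a
genome of four autosomes plus a small X so sex-chromosome exclusion is
exercised. Ancestral frequencies are bounded away from 0/1 to limit — not
eliminate — monomorphic draws; residual monomorphic sites are kept on
purpose to exercise the MAF filter. A configurable fraction (default 10%)
of variants is re-emitted with jittered coordinates and copied genotypes
(independent missingness per copy); the jitter is capped at 5% of the
variant length, so injected duplicates always satisfy the default merge
thresholds by construction. The whole module is a pure function of its
seed.

For two demes the ratio-of-averages estimator
$\sum(H_t - H_s)/\sum H_t$ computed from the *true* Balding–Nichols
frequencies has expectation $F/(2-F)$ (because
${\rm Var}(\bar p) = F p(1-p)/2$), not $F$ itself. The acceptance suite
checks the statistic against 99% Monte-Carlo intervals of exactly this
distribution, established once by a 100-replicate brute-force simulation
and frozen; the pipeline's reported `fst_param_estimate` inverts the map
($F = 2R/(1+R)$) to put the estimate back on the $F$ scale.

# Numerical and procedural choices

* Sorting of records is total — (chrom, pos, end, svtype, record id) — so
  every callset has one canonical form and reruns are byte-identical.
* The ExcHet recurrence rescales when weights exceed $10^{300}$; only
  ratios matter.
* PCA drops zero-variance variants after imputation and errors on
  all-constant input.
* A sample pair with no jointly genotyped variant makes the allele-sharing
  distance undefined; this is an error naming the pair, never a silent 0.
* The pipeline driver writes plain-text artifacts only, and its manifest
  records an MD5 digest per artifact; identical configurations reproduce
  identical digests.

## Problem sizes used in validation

The test suite exercises: every exact-test table up to 50 diploids
(~23,000 tables) against the enumeration oracle; 1000 random callsets of
up to 30 records against the brute-force merge oracle; random additive
distance matrices up to 8 taxa for NJ; Balding–Nichols cohorts of 2000
variants at $F \in \{0.05, 0.2, 0.5\}$ for the recovery checks; and a
10,000-sample population for the Hardy–Weinberg goodness-of-fit check.
These sizes give the oracles full coverage of the combinatorial space
(QC, merge, NJ) or tight Monte-Carlo intervals (simulation) while keeping
the suite fast.

# A worked run

```{r run, eval = FALSE}
cfg <- pipeline_config(simulation = list(n_variants = 2000, fst_param = 0.2),
                       out_dir = "run", seed = 1)
run_pipeline(cfg)
```

This writes the simulated inputs, the merged and QC'd VCFs, the Fst scan
with its top-1% flags, spectra, Venn counts, summaries, annotation tables,
PCA coordinates and explained fractions, the NJ tree, and a manifest.
`scripts/acceptance.R` performs the same computation headlessly and emits
the key quantities as JSON.

# Known limitations

* Fst carries no sample-size correction (by design, see above).
* Annotation windows are defaults, not fitted to any particular annotator
  run; only the vocabulary, exclusivity and additivity of the classes are
  guaranteed.
* The simulator omits LD, demography and genotyping error, so it validates
  statistical machinery rather than end-to-end realism.
* Cross-type merging (e.g., a DEL call against a DUP call) is out of
  scope, as are BND/INV records and symbolic-ALT resolution against a
  reference FASTA.
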