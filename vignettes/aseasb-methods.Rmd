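---
title: "Methods: allele-specific expression and binding across tissues"
author: "aseasb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression and binding across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseasb)
```

## The problem

A heterozygous SNP inside an expressed exon lets RNA-seq reads be assigned
to the maternal or paternal gene copy; unequal counts are allele-specific
expression (ASE). The same logic under a ChIP-seq peak gives allele-specific
binding (ASB) of a histone modification or transcription factor. Because
both alleles sit in the same nucleus, each allele is an internal control for
the other: trans-acting environment and genetic background cancel, and what
remains is (mostly) cis-acting regulatory variation, plus known nuisances
such as reference-mapping bias and copy-number differences.

If a regulatory region controls a gene in cis, the parental direction of
its binding imbalance should match the parental direction of the gene's
expression imbalance in the same sample. This package implements the full
chain needed to test that prediction in a pedigreed multi-tissue design:
masked-reference construction, parent-of-origin assignment, SNP filtering
and per-feature combination, per-sample imbalance tests, cross-tissue
heterogeneity, consensus peaks, cross-tissue peak–exon correlation, and
direction concordance in correlated pairs.

## Masked reference

Reads carrying the non-reference allele of a heterozygous SNP mismatch the
reference and are preferentially lost at alignment, inflating reference
allele counts. `build_masked_fasta()` substitutes, at every site
heterozygous in any of the study animals, a third allele carried by
neither haplotype, so reads from both real alleles pay the same one-mismatch
penalty. The substitute is deterministic: the first base in the fixed order
C, G, T, A not among the observed alleles, so an A/T site becomes C. Only
the A/T case pins this rule down externally; the rest of the ordering is
this package's convention and is recorded per site in the emitted mask plan,
which also makes the masking exactly invertible (`apply_mask_plan()` with
`reverse = TRUE` restores the input byte for byte). Sequences are handled
in the uppercase DNA alphabet of Biostrings; soft-masking case is not
preserved, a deliberate simplification since no downstream step reads case.
Indels are out of scope throughout: only biallelic SNVs are masked and
analysed, and multiallelic VCF records are skipped, not split.

## Parent of origin

At each heterozygous offspring site:

* sire homozygous — his only allele is the paternal one; the other allele
  is maternal;
* dam homozygous (when a dam genotype exists) — symmetrically fixes the
  maternal allele; when both rules fire they must agree, and a disagreement
  (possible under genotyping error or non-paternity) leaves the site
  unassigned rather than trusting either rule;
* sire heterozygous — fall back to phase linkage: the paternal allele is
  the one on the same phased haplotype as the paternal allele of the
  nearest upstream assigned SNP on that chromosome.

Two points the rules leave open were resolved as follows. First, "previous
SNP" is anchored greedily: every direct (sire- or dam-homozygous)
assignment re-anchors the haplotype side, so a phasing switch error
corrupts at most the run of consecutive sire-heterozygous sites after it.
Second, chromosome-initial sire-heterozygous sites have no anchor and stay
unassigned; they are excluded downstream with a logged reason. Statistical
phasing itself is out of scope — phase arrives as an input (here, the
generator's truth, optionally corrupted at a configurable per-site error
rate to probe the fallback's sensitivity).

## SNP filters and per-feature combination

Counts at homozygous SNPs are uninformative and removed. SNP-sample entries
where one allele has zero reads are removed as likely genotyping errors —
a conservative filter that also discards genuine complete silencing (e.g.
imprinting), which is accepted because a genotyping error masquerading as
perfect monoallelic expression is the worse failure mode.

Within a feature (consensus peak or exon) and sample, SNP counts form an
s × 2 table tested for a shared maternal:paternal ratio with the G-test:

$$G = 2\Big(\sum_{ij} n_{ij}\ln n_{ij} + n_{..}\ln n_{..}
  - \sum_j n_{.j}\ln n_{.j} - \sum_i n_{i.}\ln n_{i.}\Big),
  \qquad df = s - 1 .$$

Conventions: $0\ln 0 = 0$; rows with zero totals are dropped (they carry no
information and make the margins degenerate), reducing $s$; one remaining
row gives $G = 0$, $p = 1$. Exactly proportional tables are detected by
integer cross-multiplication and returned as exactly $G = 0$, avoiding
floating-point dust from the entropy cancellation; otherwise the statistic
agrees with the textbook $2\sum O\ln(O/E)$ form to at least nine decimal
digits (property-tested on random tables). Heterogeneous features are
flagged, never dropped: when SNPs within a feature disagree only slightly
more often than the test's nominal level, combining remains the right
default and the flag lets a caller filter. After combination, feature-sample
records with fewer than 10 total counts are excluded ("less than" strict:
a total of exactly 10 is kept).

## Imbalance and tissue specificity

The per-sample test of combined counts $(m, p)$ against 1:1 is the 1-df
chi-square $(m-p)^2/(m+p)$ with no continuity correction. The default
discovery threshold is $p < 0.01$; it is configurable because different
summaries of such designs legitimately use different levels (discovery at
0.01, concordance comparison at 0.05), and the package exposes all of them
in `pipeline_config()` rather than hard-coding one. **No multiple-testing
correction is applied anywhere.** Significant-feature counts at any level
therefore include the corresponding false-positive load; the calibration
properties below quantify it exactly on synthetic nulls.

Cross-tissue heterogeneity reuses the same G-test with tissues as rows,
within one animal; features measured in fewer than two tissues are reported
untestable. For features significant in exactly one tissue,
`direction_sharing_profile()` asks how often the remaining tested tissues
lean the same way regardless of significance, binning the sharing fraction
into quintiles (ties excluded from numerator and denominator; a fraction
exactly on a bin edge goes to the upper bin).

## Peaks, correlation, concordance

Consensus peaks are maximal runs of bases covered by peak calls from at
least two samples, called per mark (marks measure different chemistry and
are never pooled). Overlapping intervals within one sample are merged first
so a sample contributes at most one unit of support per base; the
interval-algebra implementation is property-tested against a per-base
counting oracle.

Counts are normalized to plain counts per million (no library-size
rescaling factors), and each exon is paired with every peak having any base
within 100 kb of the exon's stranded 5′ start (interval start on +, last
base on −). Any-base overlap was chosen over midpoint or full containment
as the most inclusive reading of a distance window; with peaks two to three
orders of magnitude narrower than the window the three choices almost
coincide. Pairing is cis-only (same chromosome) by construction.

Correlation across the samples shared by the two assays is Pearson on CPM
(Spearman available behind a flag), two-sided p-values via the exact t
transform, pairs with zero variance in either profile skipped as undefined.
Links are retained at $p < 0.05$ and labelled by sign.

For every retained link, each sample where both the peak's ASB and the
exon's ASE are individually significant at the concordance threshold is
scored: same direction iff both maternal fractions are on the same side of
0.5. The tally is split by mark and by correlation sign. Under true
cis-regulation positive correlations should give matching directions and
negative correlations opposite ones; under independence both tallies sit at
50%.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a pedigreed
multi-tissue study: 3 adult cows with individual sires, 2 foetuses sharing
a sire and having two of the adults as dams, 22 tissues, five ChIP targets
plus RNA, with each animal-tissue-assay library present with probability
0.5 (about half-full designs are what such studies achieve in practice).
Defaults: heterozygosity 0.4 per animal-site; sire heterozygous at 10% of
sites, the regime where the phase fallback is rarely exercised; 30× mean
allele coverage; 30% of features truly biased with maternal fractions drawn
Beta(2, 2) (broad around 0.5), half of those biased in only a random tissue
subset; per-sample peak sets are jittered subsets (presence 0.8, edges
±50 bp) of true loci laid out in non-overlapping slots. The default
pipeline-scale dataset is 2 chromosomes × 1 Mb, 5000 SNPs, 200 peaks per
assay and 100 exons — sizes chosen so a full run with truth evaluation
completes in about a minute on one core while every stage still sees
hundreds to tens of thousands of records.

Cross-tissue count profiles come from a shared latent factor per coupled
peak-exon pair, scaled so the latent correlation is `r_true` (default 0.8
for a default 15% of exons); the Poisson count layer attenuates this
slightly. The cis-coupling `kappa` sets a linked exon's maternal fraction
to `kappa * peak fraction + (1 - kappa) * independent draw`. `kappa = 0`
(the default) makes binding and expression bias independent — significantly
correlated pairs then agree in direction 50% of the time; `kappa = 1` makes
them agree up to binomial noise. `concordance_kappa_sweep()` traces the
curve between the endpoints with common random numbers across the sweep,
so the monotone response to coupling is not masked by Monte-Carlo noise.

Allele counts are pure binomial by default because that is the sampling
model the chi-square and G tests assume; an optional beta-binomial
`overdispersion` probes robustness to extra-binomial noise. What the
generator does **not** emulate — and what passing tests therefore do not
certify about real data: read-level mapping bias (masking is tested for
correctness of construction, not for its biological effect), linkage
disequilibrium and realistic allele-frequency spectra, copy-number
variation, overlapping features, replicate libraries, assay-specific
coverage profiles, or any trans-acting structure. Results on real data
additionally depend on upstream peak calling, variant calling and phasing
quality, all outside this package.

## Numerical and degenerate-input choices

* G-test: exact-zero on proportional tables; zero-total rows dropped;
  `max(G, 0)` guards the remaining floating cancellation.
* `chisq_1to1()` refuses zero-total inputs (the upstream count filter makes
  them impossible in the pipeline).
* Ties ($m = p$) have direction "tie", are never significant, and are
  excluded from direction-sharing and concordance comparisons on both
  sides.
* Exons of unknown strand are window-anchored as plus-strand with a
  warning.
* Consensus calling with fewer input samples than the support threshold
  returns an empty set with a warning rather than an error, so per-assay
  loops degrade gracefully.
* All intervals are 0-based half-open internally (the BED convention);
  GTF's 1-based closed coordinates are converted at the boundary in
  `read_intervals()`, and `interval_to_granges()`/`granges_to_interval()`
  localize the shift to one pair of functions.
* Every pipeline output TSV carries a `# config_hash=` header line keyed to
  the analysis parameters (not the input/output paths), and reruns with
  identical inputs and configuration are byte-identical.

## Known limitations

Raw-threshold significance counts are inflated by multiple testing, by
design, and should be compared across conditions rather than read as
absolute discovery counts. The monoallelic filter removes true imprinting.
Parent-of-origin assignment inherits any phasing switch errors between
anchors. The concordance comparison conditions on double significance,
which biases the compared set toward strong effects; under independence
this does not bias the 50% expectation, but under partial coupling it
raises the observed proportion relative to the unconditional one. Window
pairing uses the exon's own 5′ end, not the transcript TSS, which is the
right unit for exon-level counts but differs from promoter-centric
definitions.
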