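---
title: "Detecting m1A from MeRIP-seq coverage signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting m1A from MeRIP-seq coverage signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m1ascope)
```

## The measurement problem

N1-methyladenosine (m1A) sits on the Watson-Crick face of adenosine, so a
reverse transcriptase hitting an m1A either stops — truncating the cDNA —
or reads through while misreading the base, most often as an A-to-T
substitution in the sequenced read.  MeRIP-seq adds antibody enrichment:
fragments carrying the modification are immunoprecipitated, so IP
coverage rises relative to the input library around a genuine site.
Finally, heat/alkaline (Dimroth) rearrangement converts m1A to m6A, which
base-pairs normally; libraries built from converted RNA lose the
truncation and misincorporation signatures while — because conversion is
applied to the already-immunoprecipitated eluate — keeping the enrichment
peak, now with a "normal" shape.

These four observables give four partially independent detection methods:

* **conventional** — IP-vs-input enrichment peaks;
* **mismatch** — A-to-T misincorporation above the sequencing error rate
  inside peaks;
* **trough** — a coverage depression in the middle of a peak at or next
  to an adenosine, caused by RT termination;
* **treatment** — disappearance of the RT signatures after conversion
  while a normally shaped peak persists.

The package calls a site a **consensus site** when at least two methods
support it, and can roll consensus sites up to the RNA level.  All
coordinates are 0-based half-open transcript coordinates; only
human-readable reports use 1-based positions.

## The synthetic-data generator

`sim_config()` fixes the study design the package emulates: three
conditions (a control and two oxygen-glucose-deprivation/reoxygenation
time points) with three biological replicates, paired IP and input
libraries, each also in an untreated and a converted ("treated") version.
The generator works at pileup level — per-position coverage, A-to-T
mismatch and read-start counts — rather than simulating reads, which
keeps fixtures desk-scale and removes any aligner dependence.

Per library and position the model is:

* input coverage ~ Poisson(depth x expression factor), with a log-normal
  (sdlog 0.5) expression factor per transcript;
* IP coverage additionally carries each site's enrichment factor
  `e` (default 8) inside a window of one read span (default 100 nt, the
  fragment size of the emulated protocol) around the site, scaled by the
  site's methylated fraction `f`;
* a fraction `f * t` of molecules truncates at the site (`t` default
  0.5): their contribution to positions 5' of the site decays linearly
  over the read span, and each truncation adds a read start at the site —
  so a planted site shows both a local coverage depression and a
  read-start spike;
* among methylated, non-truncated molecules covering the site, a
  fraction `m` (default 0.15) is recorded as an A-to-T mismatch, on top
  of a background error rate of 0.1% (a typical Illumina substitution
  scale) at every reference A;
* in treated libraries a fraction `c` (default 0.9) of methylated
  molecules behaves as unmethylated for reverse transcription — both RT
  signatures shrink toward background — while IP enrichment is
  unchanged, because conversion happens after immunoprecipitation.

Truncation and misincorporation apply to input libraries too: the RNA is
modified whether or not it was enriched.  The enrichment window equals
the read span because an antibody-selected fragment extends up to a
fragment length on either side of the site; a narrower window would put
the truncation shadow outside the enriched region, a geometry no
fragment-based protocol can produce.

Planted sites are constitutive by default (condition multiplier 1
everywhere); condition-specific methylation is expressed through the
per-site `mult_<condition>` columns and is exercised explicitly by the
differential-methylation fixtures.  Site counts per transcript are the
first Poisson draws of a dedicated RNG stream, so an auditor can
reproduce them with the same child seed.  All randomness derives from
one master seed through `child_seed()`; identical configurations produce
byte-identical outputs.

What the generator does **not** emulate: fragment-level biases (GC,
priming), paired-end geometry, multimapping, antibody off-target
binding, positional autocorrelation of coverage noise, and isoform
ambiguity.  Passing the recovery tests therefore demonstrates that the
detection logic is correct under the stated generative model, not that
real-data sensitivity will match.

## Peak calling

`call_peaks()` slides a window (default 100 nt, step 25) along each
transcript.  The input count in the window, scaled by the ratio of total
library counts and floored at a pseudo-rate of 1, is the Poisson
background `lambda`; the window p value is the upper tail
`P(X >= ip_count | lambda)`, and a window qualifies when
`-10 * log10(p) > 3` — the conventional threshold, deliberately
permissive (it corresponds to p < 0.5), which is why the conventional
method always reports the most candidates and why peak-only support is
never sufficient for the consensus.  Qualifying windows separated by at
most one window width merge into a peak; the summit is the IP coverage
argmax (leftmost on ties).  Replicate consolidation keeps regions covered
by at least `min_reps` (default 2 of 3) replicate peak sets, with
coordinates the intersection of the supporting intervals.

## Site-level methods

**Mismatch.**  Every reference A inside a peak with pooled IP coverage of
at least 20 is tested one-sided against a binomial background error of
0.1%; BH adjustment across all tested positions, a call needs adjusted
p <= 0.05 **and** an observed rate of at least 2%.  The coverage gate
keeps the binomial approximation honest; the rate floor removes
statistically significant but biologically negligible calls at very deep
positions.

**Trough.**  Within a peak the IP coverage is smoothed by a 5-nt moving
average; interior local minima at or adjacent (+/-1 nt) to an A are
candidates.  A candidate qualifies when its smoothed depth is at most
`1 - min_drop` (default 0.3 drop) of the lower of the two shoulder maxima
(each searched within 50 nt), with two additional conditions that encode
"a depression in the *middle* of the peak":

1. both shoulders must reach at least half the peak's smoothed maximum —
   otherwise incidental dips in the low flanks of a peak qualify;
2. when read-start data are available, the dip must carry an RT-stop
   spike (a read-start count of at least 5 times the peak median within
   20 nt), and the site is placed at the spike.  Truncation
   mechanistically produces excess read starts; a depression without
   them — for example the valley between the enrichment bumps of two
   nearby sites — is not an RT signature.  The spike also pinpoints the
   modified base more precisely than the smoothed coverage minimum,
   whose position jitters by 5-20 nt at fixture depth.

Ties are resolved deepest-first, then leftmost.  Tracks without any
read-start signal fall back to coverage-only calling so the method stays
usable on plain coverage data.

**Treatment.**  Candidates from the mismatch or trough methods are
"rescued" when a treated-library peak still overlaps them, the treated
mismatch rate has fallen to at most 0.25 of the untreated rate (when a
mismatch signature existed), and the treated trough has filled back to at
least 0.85 of the shoulder level (when a trough existed).  Without a
treated library the method is skipped with a warning and the consensus
runs over three methods.

**Consensus.**  Base-resolution calls cluster per transcript by single
linkage with a 5-nt gap tolerance; a cluster inherits conventional
support when its representative position lies in a peak, and peaks
containing no base-resolution call are retained as peak-level candidates
represented by their summit.  Consensus requires support of at least 2
of the 4 methods (configurable in [1, 4]); the consensus set is monotone
non-increasing in that threshold.

**Methylation level.**  The only quantity computable from MeRIP coverage
alone is relative enrichment, so the level of a site interval is
`log2((sf_ip * mean(IP) + psi) / (sf_in * mean(input) + psi))` with
psi = 1.  Size factors default to the median of position-wise IP/input
ratios: background positions dominate that median, so globally enriched
IP libraries are equalized on their background rather than on total
counts — total-count scaling would subtract the library-wide enrichment
from every site's level.

## Annotation statistics

Region assignment uses half-open bounds with boundary positions going to
the downstream region.  The metagene profile allocates 20/50/30 bins to
5'UTR/CDS/3'UTR, mirroring the three-segment axis such profiles are
drawn on; each site maps to the fractional position within its region.
The lncRNA source taxonomy (exon sense-overlapping > intron
sense-overlapping > antisense > bidirectional > intergenic) and the
circRNA taxonomy (exonic > intronic > sense-overlapping > antisense >
intergenic) use standard conventions for the categories the underlying
figures leave implicit, with a 1-kb opposite-strand TSS window for
bidirectional promoters.  Distribution shifts between conditions are
tested with the Pearson chi-squared homogeneity test (no continuity
correction), and group means with the classic equal-variance one-way
ANOVA.

**GA-richness.**  Motif discovery proper is out of scope; the package
scores the purine clustering that underlies GA-rich motifs.  The
per-sequence statistic is the maximum {G,A} fraction over 50-nt sliding
windows, flagged GA-rich at 0.70.  The cohort z score compares the
observed mean statistic with its distribution under Altschul-Erikson
dinucleotide-preserving shuffles.  The statistic must be a *local* one:
any composition-based quantity (overall purine fraction, dinucleotide
counts) is exactly invariant under a dinucleotide-preserving shuffle and
would make the z score degenerate; the window maximum responds to
clustering while the shuffle holds composition fixed.

## Differential statistics

**Methylation.**  Per site, size-factor-normalized pooled counts (IP and
input in each condition, geometric-mean scaling, rounded) form a 2x2
table tested by Fisher's exact test; the fold change is the ratio of
IP/input enrichments with 0.5 pseudocounts.  Significance uses the
inclusive thresholds |FC| >= 2 and BH FDR <= 1e-4.

**Expression.**  miRNA counts are normalized as tags per million; mRNA
counts by library size.  The test is a two-group negative-binomial Wald
test: a common method-of-moments dispersion pooled across features
(median of per-feature moment estimates), a delta-method standard error
of the log mean ratio, and a t reference with `n1 + n2 - 2 + 6` degrees
of freedom.  The six prior degrees of freedom credit the pooled
dispersion in the spirit of moderated statistics: with a plain normal
reference the test is anticonservative at n = 3 + 3 (empirical size
0.07-0.09), with the residual 4 df it is far too conservative (~0.01),
while the moderated reference holds the size at 0.04-0.05 across
dispersion and depth settings.  Thresholds are inclusive: |FC| >= 2 and
adjusted p <= 0.05.  Designs with a single replicate per group fall back
to a Poisson exact test with a loud warning.

**Distribution and enrichment tests.**  The two-sample KS test uses the
exact D distribution when `n * m <= 1e4` and the asymptotic Kolmogorov
distribution otherwise.  Over-representation is the hypergeometric upper
tail with BH q values; default cutoffs are p and q <= 0.005 with set
sizes in [2, 500] (the GO convention), with 0.05/0.05 for pathway-style
annotations.

## Networks

Interaction sources enter as plain tables, which keeps the module fully
testable offline.  miRNA-mRNA edges require the pair to be predicted by
all three prediction sources; lncRNA-miRNA and circRNA-miRNA edges come
from their single source table; every edge must connect two features
from the differential sets of the chosen mode (expression or
methylation), and carries a provenance tag traceable to an input row.
The lncRNA-RBP network keeps pairs with CLIP evidence >= 2 (the
medium-stringency convention).  Seed matching scans 3'UTRs for exact
reverse complements of the miRNA seed, 7mer-m8 (miRNA positions 2-8) by
default with 6mer and 8mer selectable; a miRNA-mRNA pair is
"m1A-overlapped" in a condition when its seed site intersects a
consensus interval under half-open semantics.

## Modification patterns, TF activity, pathway scores

The pattern matrix is consensus-site methylation levels across the nine
samples (3 conditions x 3 replicates), min-shifted to non-negativity.
Factorization is Lee-Seung multiplicative updates on Frobenius loss
(monotone non-increasing, seeded uniform initialization, stop at 1e-5
relative change or 500 iterations).  Consensus clustering runs 30
restarts per rank, each on a random 80% feature subsample — the
resampling device of consensus clustering.  Without it, restarts of a
desk-scale problem converge to the same optimum, every consensus matrix
is binary, and the cophenetic coefficient cannot discriminate ranks.
Samples are assigned to the argmax row of H (lowest index on ties); the
cophenetic coefficient rho(k) correlates the consensus dissimilarities
with their average-linkage cophenetic distances; k = 1 is defined as
rho = 1.

Rank selection returns the k at which rho *begins to decrease* — the end
of the initial non-decreasing stretch, with decreases below 1e-6 treated
as flat.  An alternative "largest consecutive drop" reading is available
via `rule = "largest_drop"`; it suits cliff-shaped profiles but
systematically overshoots by one when instability grows steadily with k,
which is what planted-pattern fixtures produce, so it is not the
default.

TF activity is the signed weighted mean of a gene statistic over a
regulon, `sum(mor * w * stat) / sum(|w|)`, normalized against 1000
permutations of equal-size random target sets; the empirical two-sided p
uses (b + 1)/(times + 1) smoothing, and regulons with fewer than 5
usable targets are never scored.  Pathway activity is deliberately
simpler than kernel-based enrichment scores: genes are z-scored across
samples and a pathway's score is the mean member z — adequate for
rank-level comparisons between patterns, not a GSVA replica.  Regulator-
pathway association is Pearson (or Spearman) correlation with BH
adjustment.

## Numerical conventions and degenerate inputs

One master seed; every stochastic operation derives an independent
31-bit child stream from it (`child_seed()`), so stages are reproducible
in isolation and byte-identical end to end.  Ties break deterministically
(leftmost summit, deepest-then-leftmost trough, lowest-index argmax,
smallest rank).  Writers emit stable column order and 6-significant-digit
floats; readers reject mismatch counts above coverage, duplicate
positions, inverted intervals, region bounds that fail to partition the
transcript, and unknown configuration keys (with a nearest-key
suggestion).  Degenerate inputs have defined behavior: all-constant
ANOVA groups are an error, zero-variance genes are dropped from pathway
scores with a log entry, all-zero count columns fail normalization
loudly, and transcripts without adenosines are skipped with a warning.

## Problem sizes

The recovery fixture uses 200 transcripts (~300 planted sites, depth 30,
three replicates, one condition) — large enough that sensitivity and FDR
estimates have standard errors near 0.01 while a full run stays under a
minute.  Signature-collapse checks run at 60 transcripts; the pattern
fixture is 200 sites x 9 samples with 30 restarts per rank; null
calibrations use 1000 replicates per test.  The end-to-end demo
(`demo_config()`) runs 50 transcripts through all eight stages.

## Known limitations

Single-nucleotide stoichiometry is not estimated — the methylation level
is a relative enrichment, not a methylated fraction.  Antibody
cross-reactivity and off-target binding are not modeled, so the
false-discovery behavior on real MeRIP data may be worse than on the
generator.  The trough method depends on read-start fidelity; protocols
whose library chemistry erases RT-stop positions degrade it to
coverage-only mode.  The NB Wald test has no per-feature dispersion
shrinkage and is not a substitute for a full DE framework on real data.
Genome-coordinate liftover is out of scope: all site arithmetic lives in
transcript coordinates.
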