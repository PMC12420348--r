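---
title: "Quantifying transcript variants through discriminating regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcript variants through discriminating regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoregion)
```

## The problem

Short-read RNA-seq cannot directly distinguish transcript variants of one
gene that share most of their sequence. Probabilistic quantifiers
(Salmon-style) apportion reads across all annotated variants, which makes
their output sensitive to the annotation set — a real problem for genes
whose variant catalogue is large, similar, and changing between database
releases. The alternative implemented here sidesteps the annotation churn:
pick, for each variant of interest, a genomic interval covered by that
variant alone (its *discriminating region*), and count only the fragments
that align there. The count is unambiguous by construction; the cost is
that it measures transcription over one interval rather than the whole
transcript, so quantities derived from it are strictly **intra-sample**
measures.

This package implements that quantification plus the three analyses that
naturally surround it: per-sample variant ratios with cohort tertile
grouping, polyA-site detection from 3′-end sequencing (which determines
how long a variant's 3′UTR — and hence its usable discriminating region —
really is), and a rank-correlation screen for ceRNA sponge relationships.

## Region model and coordinate conventions

Internally every region is 1-based inclusive with `start <= end`, the GTF
convention. Two deliberate accommodations:

* **Descending coordinate pairs are accepted** and silently normalized.
  Minus-strand regions are conventionally communicated 5′→3′, i.e. in
  descending genomic order (e.g. `chr7:140725145-140719327`); rejecting
  them would make the most natural input illegal.
* **BED input/output converts at the boundary** (`start = bed_start + 1`),
  and the conversion round-trips exactly, which the tests assert.

Regions must be pairwise disjoint — otherwise "specifically mapping" is
not well defined — and this is validated at construction, with the
offending pair named. Strand is stored but not used to filter fragments by
default, because strandedness of the counting step is a library-protocol
property the user must opt into (`strand_mode` in the policy). Chromosome
naming differences between annotation and BAM (`chr7` vs `7`) are handled
by an explicit alias map rather than guessed.

## Counting and the FPKM formula

A *fragment* is a read pair (keyed by query name; unpaired reads count as
single-read fragments) or, in `per_read` mode, each read separately. Under
the default `any_overlap` rule a fragment is assigned to a region when at
least one aligned reference base of either mate overlaps it; under
`full_containment` every aligned base of every mate must lie inside.
Fragments touching two or more regions are counted as *ambiguous* and
discarded — unique assignment is the point of discriminating regions. With
disjoint regions ambiguity can only arise from mates or split alignments
reaching different regions, and the diagnostics report how often.

The published filtering policy for this kind of quantification is usually
unstated, so all filters are explicit and configurable
(`counting_policy()`): defaults are MAPQ ≥ 1, primary alignments only,
supplementary records dropped, duplicates kept, unstranded. These mirror
common assembler-style counting defaults; every choice is recorded in the
output metadata.

Region FPKM is `q / (l * N) * 1e9`. Three library-size modes:

* `provided` — *N* from an aligner log (the normal case);
* `bam_scan` — *N* counted from a complete BAM as distinct primary mapped
  fragments (the closest reproducible analogue of an aligner's
  mapped-fragment total);
* `absent` — sliced mode. A locus-sliced BAM cannot yield *N*, and the
  package deliberately refuses to invent one: it degrades to per-bp rates
  `q / l`. Since `FPKM_i = rate_i / N * 1e9`, any within-sample ratio of
  rates equals the ratio of FPKMs exactly, so ratio-based downstream
  analyses are unaffected. This exactness is asserted to 1e-12 in the
  tests.

## Ratios, pseudocounts and tertile groups

The per-sample statistic is `log2((A + c) / (B + c))` with pseudocount
`c = 0.01`, finite for any non-negative inputs (0/0 maps to 0). The
parenthesization matters: the pseudocount is added to numerator and
denominator separately, consistent with the per-variant display transform
`log2(x + 0.01)`. Note that with one common pseudocount the chain identity
`log_ratio(a,b) + log_ratio(b,c) = log_ratio(a,c)` is exact — the middle
term cancels algebraically — and as `c -> 0` the statistic converges to
the plain log fold change; both properties are tested.

Cohort grouping cuts at the 33rd and 66th percentiles — as printed, not at
33⅓/66⅔ — computed by linear interpolation between order statistics
(quantile type 7), with boundary rules: Group 1 iff ratio ≤ P33, Group 2
iff P33 < ratio ≤ P66, Group 3 otherwise. The quantile convention is a
genuine degree of freedom across statistics environments, so the cutpoints
and convention are written into the output sidecar; any monotone transform
of the ratios (including raw vs log scale) yields identical groups, which
is tested. For ratios `1..9` this gives P33 = 3.64, P66 = 6.28 and group
sizes 3/3/3. Degenerate cohorts (all ratios identical) put every sample in
Group 1 with a warning rather than failing.

## PolyA-site peaks

3′-end (QuantSeq REV style) reads pile up next to polyA sites. Peak
calling uses two criteria: per-base depth strictly above 5% of the track's
maximum depth, and run length ≥ 80 bp. Two readings of the height rule are
possible — per-base thresholding versus comparing peak maxima — and the
per-base reading is the default with the other available as
`threshold_mode = "peak_max"`. No smoothing is applied (a configurable
`max_gap` exists, default 0): smoothing choices change peak boundaries and
are better left visible than implicit. Because the threshold is relative,
peak intervals are invariant to uniform depth scaling, which is tested.

Cross-sample consensus clusters peaks by single-linkage on ≥ 1 bp overlap
(implemented with interval reduction at zero gap width, so book-ended but
non-overlapping peaks do not merge) and keeps clusters supported by
**strictly more than** the support fraction (default 0.5) of all samples —
"more than half" is a strict inequality. The consensus interval is the
union of its members; single-linkage is order-independent, and a
single-sample consensus at support threshold 0 reproduces that sample's
peaks exactly.

## The correlation screen

Spearman's rho is computed as Pearson correlation of mid-ranks with a
two-sided p-value from the t approximation
`t = rho * sqrt((n-2)/(1-rho^2))` — the standard large-sample treatment,
appropriate for the cohort sizes (tens to hundreds of samples) this screen
targets; the test suite cross-checks it against the independent reference
implementation. Zero-variance features are reported as *untestable* rather
than assigned rho = 0, which would silently manufacture false negatives.
Benjamini–Hochberg adjustment is applied **within each correlation
family** (transcript–miRNA, transcript–target, miRNA–target) rather than
pooled, mirroring a two-stage screen in which miRNAs are screened first
and targets second; expression transforms `log2(TPM + 1)` / `log2(RPM +
1)` are applied at ingest and provably do not change any rank statistic
(tested). A sponge triad requires the sign pattern (−, +, −) across the
three families with all adjusted p below alpha, optionally restricted to a
whitelist of validated miRNA–target interactions.

## What the simulator emulates — and what it does not

The simulator produces the three data regimes the analyses consume, with
ground truth:

* **Two-variant mixtures**: fragments drawn from variant A with
  probability `pi`, placed uniformly on the transcript truncated at a
  polyA site drawn per molecule, written as a sorted indexed BAM; spans
  crossing the shared/discriminating junction become split (N-gap)
  alignments. The default geometry uses a 2000 bp shared span and
  discriminating spans of 5819 and 1900 bp — the published lengths of the
  two *BRAF* variant regions — with two polyA sites (offsets 400 and
  1900 bp, usage 0.3/0.7) on the short variant and one terminal site on
  the long one, so both truncated and full-length 3′UTR forms are present,
  as observed in patient cohorts. Fragment length is 250 ± 30 bp, read
  length 100 bp, on a neutral contig `sim1`.
* **3′-end reads**: read 3′ ends at a usage-drawn polyA site with
  Gaussian positional jitter (sd 20 bp, read length 60 bp), giving peaks
  of realistic width (~100–130 bp) around planted sites.
* **Expression cohorts**: a latent signal, a planted positively-coupled
  target and negatively-coupled miRNA (slope 0.8, noise sd 0.5), all other
  features independent noise.

`estimate_mixture()` closes the loop: it divides each region count by the
closed-form probability that a fragment of that variant shows a sequenced
base in the discriminating span (computed by integrating over the exact
discretized fragment-length distribution the simulator uses), and
normalizes. Across `pi` in {0.1, 0.3, 0.5, 0.7, 0.9} at 10^5 fragments the
recovery error stays below 0.02 and the log ratio is strictly increasing
in `pi` — both asserted in the acceptance tests.

Deliberately **not** emulated: sequencing errors and base qualities
(alignments are synthesized directly, so aligner behaviour is out of the
loop), multi-gene backgrounds, internal-priming artifacts in 3′-end data,
library-preparation biases, and correlated noise structures in expression
cohorts. Passing tests therefore demonstrate correctness of the counting,
calling and screening logic under clean alignments — not robustness to
alignment artifacts, which real data will add on top.

## Numerical and degenerate-input choices

* Quantiles: type 7 everywhere (cutpoints, median, IQR), recorded in
  outputs.
* FPKM is evaluated as `q / (l * N) * 1e9`; scale invariance in `(q, N)`
  is exact in floating point for integer scale factors (products stay
  below 2^53), and the tests assert identity, not approximate equality.
* Ties in ranks use mid-ranks; the t approximation handles `|rho| = 1` by
  reporting p = 0.
* Peak calling on an all-zero track returns no peaks (no threshold is
  defined); `conserved_peaks` requires zero-peak samples to be present in
  the input so the support denominator is the whole cohort.
* Tertile grouping refuses cohorts of fewer than 3 samples; boundary
  samples go to the lower group per the ≤ / > rules.
* Mixture estimation with both counts zero returns `NA` with a warning
  rather than 0/0.
* Fragments longer than their transcript are resampled (capped at 100
  rounds); with the default geometry the cap is unreachable because the
  shortest transcript (2400 bp) far exceeds the fragment-length support.

## Problem sizes used by the test suite

The suite exercises counting against a brute-force per-fragment oracle on
fixtures of 100 fragments (200 alignment records), mixture recovery at
10^5 fragments per grid point, 3′-end cohorts of 3–5 samples at 3000–5000
reads, correlation screens at 50–200 samples × 20–100 features, and a
six-sample end-to-end cohort at 5000 fragments per sample. These sizes
make every statistical assertion sharp (binomial tolerances computed at
the stated n) while keeping the full suite around a minute.

## Known limitations

* Region FPKM is an intra-sample measure; comparing absolute FPKM across
  samples requires consistent library-size definitions, which sliced mode
  cannot provide by design.
* The counting policy defaults are reasonable but not canonical; analyses
  sensitive to duplicates or multimappers should set the policy
  explicitly.
* `bam_scan` library sizes hold every distinct query name in memory; for
  genome-scale BAMs supply the aligner's totals instead.
* Consensus peak intervals grow with single-linkage chains; very dense
  peak landscapes can merge distinct sites (mitigated by the 5% height
  rule upstream).
* The ceRNA screen is correlational by construction; a triad passing the
  sign/significance pattern is a candidate for experimental follow-up, not
  evidence of mechanism.
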