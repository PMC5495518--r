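---
title: "Quantifying break-induced siRNA formation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying break-induced siRNA formation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbsirna)
library(dplyr)
```

# The biological setting

In *Drosophila* cells, a DNA double-strand break (DSB) inside a transcribed
gene triggers the production of ~21-nt small interfering RNAs (siRNAs) from
the region between the transcription start site (TSS) and the break. The
current model is that the normal sense transcript base-pairs with a
break-induced antisense transcript; the resulting double-stranded RNA is
diced into siRNAs. Splicing of the damaged transcript strongly stimulates
this response: cuts in intron-less genes yield barely any siRNAs, while cuts
placed downstream of an intron yield strong siRNA production.

`dsbsirna` implements the three quantitative arms of this analysis:

1. **Cut-site coverage statistics** — strand-resolved reads-per-million (RPM)
   coverage over the damaged transcript and the upstream/downstream per-base
   density ratio around the cut, with the sgRNA-derived read peak excluded.
2. **Per-feature coverage** — siRNA density per exon, intron and splice
   junction (size-normalized), junction-spanning read classification on the
   genomic and spliced axes, replicate t-tests, and a 2x2 enrichment test.
3. **Screen scoring** — plate-median normalization of 384-well dual-luciferase
   RNAi screens, LOESS-residual z-scores, control-derived candidate calling,
   2-of-3 trigger validation.
4. **qPCR** — 2^-ddCt relative quantification, splicing efficiency per
   amplicon class, and cut/uncut fold changes.

Every analysis has a matching seeded simulator that generates its inputs with
recorded ground truth, so the whole pipeline is exercised end to end by
parameter-recovery tests.

# The cut-ratio statistic

For a library of mapped reads and a gene model, `build_coverage()` computes
per-base coverage in RPM, split into gene-relative sense and antisense reads,
plus "end traces" that place each sense read at its 5' end and each antisense
read at its 3' end (for a plus-strand gene, both are the read's leftmost
coordinate; an antisense read extends from its 3' end downstream).

`cut_ratio()` then averages per-base RPM over the region from the TSS to the
cut ("upstream") and from the cut to the transcript 3' end ("downstream"),
and reports their ratio. Ratios near 1 mean no break-induced siRNAs; the
analysis of real loci yields low single digits for intron-less genes and
ratios of several tens for cuts well downstream of an intron.

Numerical and design choices:

* **Coordinates** are 0-based half-open everywhere internally; GFF3 (1-based
  closed) and BED (0-based half-open) conversions happen only in the readers
  and writers. This removes off-by-one ambiguity from all interval logic.
* **Minus-strand genes** are handled by resolving "upstream" through the
  strand at analysis time, so upstream always means 5' of the transcript.
* **sgRNA exclusion** is positional: bases inside the protospacer interval
  padded by `exclusion_pad` (default 5 bases each side) are excluded from
  both the coverage sum and the per-base divisor. Positional exclusion is
  robust to sequencing errors in sgRNA-derived reads; whether the exclusion
  should also span the PAM is unsettled, which is exactly what the pad
  parameter absorbs.
* **Strands**: the ratio is reported for both strands combined (the headline
  number) and per strand, since the field's convention is not fixed.
* **Degenerate ratios**: a zero downstream mean yields `ratio = NA` with an
  explicit `ratio_defined = FALSE` flag, never an infinity, so tabulation
  across replicates and cut sites stays well-defined.
* **Boundary reads** contribute per overlapping base to each region's
  coverage; the excluded protospacer zone (which always straddles the cut)
  absorbs the boundary-straddling reads in practice.

# Feature-level coverage and junction reads

`derive_features()` enumerates exons, introns, the 5' (exon|intron) and 3'
(intron|exon) splice boundaries on the genomic axis, and exon-exon junctions
on the spliced (cDNA) axis. A read "spans" a junction if it has at least
`min_overhang` bases on each side (default 1; the acceptance suite also runs
3). The junction normalizer is the number of valid spanning start positions,
`L - 2*o + 1` for read length `L` and overhang `o`: under uniform read
placement this makes junction densities directly comparable to per-base
exon/intron densities. The normalizer is a package choice — exposed in the
configuration — because no standard exists for junction-size normalization.

`count_spliced_junction_reads()` maps reads to the spliced transcript
sequence and counts exon-exon junction-spanning reads, by default excluding
any read that also maps to the unspliced genomic sequence. Only reads that
can *only* derive from a spliced product are counted; the option
`exclude_genomic = FALSE` disables this (the stricter default is a declared
design decision). In simulations where all siRNAs derive from unspliced
pre-mRNA, these counts are zero by construction — the computational analogue
of the observation that exon-exon junction-spanning siRNAs are essentially
absent at damaged loci.

`compare_features()` runs a **paired** two-sided Student's t-test on
per-replicate normalized coverages (groups averaged within replicate before
testing). The paired form is used because replicates share library-level
scaling; zero variance of the paired differences is flagged as degenerate
rather than producing a spurious p-value. `enrichment_test()` is a plain
Pearson chi-square on a 2x2 hit table (optional Yates correction). Both
table constructions of the Prp19-complex enrichment — the as-printed
8/16 vs 26/138 and the disjoint 8/16 vs 18/122 — are supported and clear
p <= 0.04.

# Read processing and the locus mapper

`demultiplex()` assigns reads by exact barcode prefix; `trim_adapter()`
removes a full internal adapter match (and everything 3' of it) or the
longest read suffix matching an adapter prefix of at least `min_overlap`
bases (default 3), rejecting reads shorter than `min_len` (default 18) after
trimming. Exact-match trimming with declared defaults stands in for the
original unpublished trimming scripts.

`map_reads()` performs ungapped, mismatch-free mapping of reads against a
locus-scale reference on both strands (the matching engine is a Biostrings
pattern dictionary over the unique read sequences; a property test checks it
against an exhaustive string scan). `max_hits` defaults to 1 (unique mappers
only), a conservative choice that prevents multi-mapping from inflating the
sgRNA-peak region. At locus scale with perfect 21-mers this reproduces what a
genome-scale aligner restricted to the region of interest would do; mismatch
tolerance is deliberately out of scope. The RPM denominator is the number of
reads entering mapping (not only locus-mapped reads); externally mapped
SAM/BED6 alignments can be ingested instead, with unmapped SAM records
counted into the denominator.

# Screen normalization and scoring

Raw two-channel luminescence is log-transformed per channel and centered on
the plate median of the *sample* wells (controls, thread and empty wells do
not move the median; the log base is irrelevant after centering). Replicate
plates are averaged per well. A LOESS curve of normalized RLuc on normalized
FLuc — span 0.9, tricube weights, local degree-2 polynomials — captures the
reporter-vs-transfection trend; its residuals, standardized on the
sample-well distribution (mean/SD by default, median/MAD as a robust
option), are the per-gene z-scores.

The **sign convention**: siRNAs generated at the break repress the Renilla
reporter, so knocking down a factor required for siRNA biogenesis lifts RLuc
above the fitted curve — positive residual, positive z. Candidate thresholds
sit at the negative-control z mean plus/minus one negative-control SD;
wells whose FLuc falls below the mean of the thread-control (apoptosis
inhibitor knockdown) wells are excluded as predominantly dead cells before
fitting. Controls are scored against the curve but do not shape it by
default, since whether the original analysis included controls in the fit is
not recorded.

The LOESS is computed exactly at every point (per-point weighted least
squares over the `ceiling(span * n)` nearest neighbours), not via an
interpolation surface, so `loess_local()` predictions agree with a
brute-force per-point solve to machine precision; `stats::loess` with its
exact "direct" surface is used as an independent cross-check in the tests
(the two differ only in neighbourhood rounding).

`validate_candidates()` applies the downstream validation logic: a gene is
retained only if at least two of three independent RNAi triggers score
positive and a miR-277-reporter counter-screen shows the core silencing
machinery and reporter transcription are unaffected. `compare_screens()`
joins per-gene effect strengths from two assays (e.g. DSB-induced versus
high-copy-transgene-induced siRNA reporters) and classifies genes as shared
or assay-specific by the per-assay thresholds.

# qPCR quantification

`ddct()` implements 2^-ddCt with amplification efficiency fixed at 2:
per replicate, dCt = Ct(target) - Ct(reference); ddCt = dCt(test) -
dCt(control); fold = 2^-ddCt; replicate folds are summarized as mean +/- SD
(replicate-wise computation matches the mean-of-replicates convention;
unmatched replicate indices fall back to condition means). Amplicon classes
follow the assay design: intron-exon junction amplicons detect unspliced
pre-mRNA, exon-exon junction amplicons detect spliced message, and an
exon-internal amplicon measures total transcript and serves as the
reference. `splicing_efficiency()` reports each species relative to total;
`cut_uncut_ratio()` reports per-amplicon cut/uncut folds so that only
DNA-break-induced changes remain.

# What the simulators emulate — and what they do not

**siRNA libraries** (`simulate_sirna_library()`): a piecewise-uniform
positional model — uniform background over the whole transcript at
`background_rate` expected reads per start position, an induced zone between
TSS and cut whose per-base density is `induction_ratio` times background,
sense reads drawn from the unspliced pre-mRNA and antisense reads from its
reverse complement, an sgRNA-derived read peak (exact protospacer copies) at
`sgRNA_peak_fraction` of the library, and random off-locus filler reads
padding the library to `library_size` (real small-RNA libraries are
dominated by miRNAs and other off-locus species; the filler keeps the RPM
denominator realistic). A ratio that cannot be realized at the given library
size and background errors out with the feasible bound. When no complete
intron lies between the TSS and the cut, the induced excess is damped by
`intronless_damping = 0.04`, chosen so that at an induction strength giving
intron-containing ratios near 50 the intron-less configuration lands in the
low single digits — the relationship the real loci display. The positional
model is deliberately minimal: it is the structure the cut-ratio statistic
assumes, consistent with the relatively uniform observed coverage. It does
not model Dicer processivity, phasing (none is reported), sequencing errors,
or transcription kinetics, so passing recovery tests validates the
*estimator*, not any mechanistic model of dicing.

**Screen plates** (`simulate_screen()`): multiplicative channel intensities
`baseline x plate effect x well effect x gene effect x lognormal noise`,
with RLuc coupled to FLuc through an exponent (default 0.8) so the LOESS has
a genuine trend to remove. Defaults: 10 distinct plates, each measured in
triplicate and averaged (the averaging step is why a consistent gene effect
of `hit_effect = 3` per-measurement residual SDs stands well clear of the
averaged-well noise); 40 spiked hit genes; positive controls (Ago2/Dcr-2
strong, Ago1 weaker) that de-repress RLuc; an RLuc-knockdown control that
suppresses it; thread wells at 2% signal marking the dead-cell floor. FLuc,
the high-signal transfection channel, carries less measurement noise (0.1
log-SD) than its biological well-to-well spread (0.5), while RLuc carries
the 0.25 log-SD that defines the residual unit. Negative-control wells carry
an extra between-well lognormal component (1.2 residual-SD units, consistent
across replicates), emulating between-aliquot variability of control dsRNA
preparations; this matters because a "negative-control mean + 1 SD" cutoff
is only a meaningful stringency rule when control wells spread wider than
the null sample population — with identically distributed controls that rule
would flag ~16% of nulls regardless of scale. The simulator does not model
spatial plate gradients or edge effects, so median centering is the only
plate correction the pipeline needs or applies.

**qPCR tables** (`simulate_qpcr()`): Ct = baseline - log2(planted fold) +
Gaussian cycle noise, per replicate. Defaults plant a 1.6-fold increase of
unspliced (intron-exon junction) signal at the junction nearest the cut in
the "cut" condition and leave spliced/total amplicons unchanged — the
nascent-RNA signature of a downstream DNA break — with 0.1-cycle noise and
three biological replicates.

All simulators take a single integer seed, leave the global RNG state
untouched, and write their full configuration into a machine-readable truth
record.

# Problem sizes, tolerances and reproducibility

The recovery analyses are sized to what the statistics need, not more:
ratio recovery uses full-size libraries of 10^6 reads at induction ratios
1, 5 and 50 (three seeds each) and is expected within 15% of truth — the
dominant error is multinomial sampling of ~10^4–10^5 locus reads; the
oracle equivalence checks (coverage, junction counts, LOESS) are exact to
enumeration or to 1e-8 relative error on hundreds of points; screen
recovery uses 10 plates x 3 replicates (11,520 wells) and expects >= 95%
spiked-hit recall with <= 5% false positives among nulls; qPCR recovery at
zero noise inverts the generator exactly, and the noisy 1.6-fold scenario
is expected within [1.4, 1.8]. `scripts/acceptance.R` recomputes all of
these from scratch under a caller-supplied seed. Unit and property tests
use smaller libraries (10^3–10^5 reads) where only correctness, not
statistical precision, is at stake.

# Known limitations

* One transcript model per gene; multi-isoform loci are out of scope (the
  analyzed loci are effectively single-isoform).
* The mapper is exact-match and ungapped; it is not a general-purpose
  aligner and deliberately refuses mismatches (hook present, default 0).
* No multiple-testing correction across features (raw p-values are
  reported, matching the source analyses); no GO enrichment.
* qPCR assumes perfect doubling per cycle; standard-curve efficiency
  correction is not implemented.
* The screen pipeline models no spatial plate artifacts beyond the plate
  median, and the candidate thresholds inherit the sampling noise of the
  negative-control wells (80 wells across 10 plates).
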