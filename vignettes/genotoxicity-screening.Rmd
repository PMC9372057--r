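---
title: "Screening nuclease-edited cell populations for genotoxic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening nuclease-edited cell populations for genotoxic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotoxscreen)
```

## The problem

Therapeutic genome editing of primary cells raises a concrete safety
question: after electroporating a Cas9 ribonucleoprotein into, say,
hematopoietic stem and progenitor cells and culturing them for days, do any
of the variants called in the edited population trace back to nuclease
activity? At face value the variant lists are dominated by things that have
nothing to do with the nuclease — heterozygous and homozygous germline
variants (allele fractions near 0.5 and 1.0), low-frequency sequencing
artifacts, and occasionally donor chimerism at intermediate allele
fractions. The analysis problem is therefore one of *subtraction*: remove
everything explainable without the nuclease, and characterize whatever
remains for the nuclease's fingerprints (indels, spatial clustering at a cut
site, sequence homology to the guide).

`genotoxscreen` implements that analysis for cohorts structured as
donor × treatment (mock electroporation or one of several guides) ×
timepoint × technical replicate, as produced by deep targeted panels,
exomes, or genomes. Everything operates on plain variant tables
(chrom, pos, ref, alt, alt reads, depth) keyed by `(chrom, pos, ref, alt)`;
indels are reduced to a minimal, left-aligned representation on ingestion so
that key equality is meaningful across samples and databases.

## The filter cascade

Within each condition (donor × treatment × timepoint) the cascade runs:

1. **Replicate concordance.** The reproducible set is the *intersection* of
   the technical replicates' key sets; the reported concordance is
   |∩| / |∪|. The union is the natural denominator when the quantity of
   interest is "fraction of all observed calls seen in every replicate";
   published panel data report this type of concordance at a median near
   98%, and the generator's defaults land there. Depth and alt reads of
   reproducible variants are summed across replicates, so the pooled depth
   drives the pooled detection limit below.
2. **Synonymous filter.** Variants positively annotated `synonymous` are
   removed. Unannotated variants pass with a warning (fail-open): stages of
   this cascade only remove what is positively identified as
   non-pathogenic.
3. **Germline-database filter.** Variants whose occurrence count in a
   germline database is *strictly greater than 10* are removed; a count of
   exactly 10, or an absent key, is retained. The strictness mirrors the
   published wording ("reported to occur more than 10 times"), and the
   boundary is tested explicitly.
4. **Mock subtraction.** Any variant whose key appears in the donor's mock
   reproducible set — at *any* timepoint, regardless of allele fraction —
   is removed: a variant present without nuclease cannot have been caused
   by it. A day-0 baseline subtraction could be layered on the same
   mechanism but is deliberately not a default stage; the mock arms already
   carry the donor's background at every timepoint.
5. **Strict nuclease filter (optional, off by default).** Removes all SNVs,
   then removes remaining variants without guide homology (below). This is
   the maximally specific secondary view; the primary cascade is kept
   permissive so that anything unexpected surfaces rather than being
   filtered away.

Every stage is recorded in a ledger with exact conservation
(`n_in = n_out + n_removed`, asserted on every run) and monotone
non-increasing counts. The synonymous and germline stages are independent
per-variant predicates, so their order does not change the result (also
tested). Samples whose median exon coverage (MEC) falls below the panel's
lower specification limit of 1300 are flagged in the summary but not
excluded — the limit is a QC reference line, not a validity gate. Variants
in clonal-hematopoiesis-associated genes (CHIP) are flagged for reporting
and never removed.

## The detection-limit model

A panel's validated operating point ties a depth to a minimum detectable
allele fraction at a stated sensitivity: here, LoD 0.205% VAF at MEC 3550
with 95% sensitivity. The package treats that pair as a *calibration
anchor*, not a derivable quantity: the vendor's noise model behind it is not
public, and no simple binomial read-count threshold reproduces the printed
pair exactly for any integer threshold. The default model therefore keeps
the expected number of alternate reads at the detection limit constant,

$$\mathrm{LoD}(d) = \frac{\lambda^{*}}{d}, \qquad
  \lambda^{*} = d_0 \cdot \mathrm{LoD}_0 = 3550 \times 0.00205 = 7.2775,$$

which scales exactly as 1/depth: pooling three replicates at the anchor
depth gives LoD(10 650) = 0.0683% VAF, consistent with the published
pooled bound of <0.07%. For sensitivity analyses a binomial mode is
provided: with a minimum alt-read count $k$, the detection probability at
true fraction $p$ and depth $d$ is $P(X \ge k)$, $X \sim \mathrm{Bin}(d,p)$
(stable upper-tail computation), and the LoD is the smallest $p$ reaching
the sensitivity target, found by bisection to an absolute tolerance of
1e-9. The bisection contract (sensitivity at the returned point ≥ target;
at the point minus 1e-6, below target) is tested.

## Guide homology and on-target assignment

The homology rule asks whether the sequence context of a variant resembles
the guide: slide the 23-mer (20-nt spacer + 3-nt PAM) across every placement
of a window spanning 20 bp on each side of the variant's REF span, on both
strands, counting positional matches, with `N` in the PAM pattern matching
any base. A variant is *guide-homologous* when the best placement matches at
10 or more of the 23 positions. Two readings of "10-bp match" are possible —
a total match count or a contiguous run; the implemented default is the
total count (the source rule is phrased as "10 or more matches", a count),
with a contiguous-run mode available as an option. Ties between equal-count
placements break toward the smallest offset, plus strand first, for
determinism. The scorer is verified against a brute-force enumeration of
every placement on random windows.

Windows are extended 22 bases beyond each flank so that every 23-mer
placement overlapping the nominal window is scored; at contig edges the
window truncates with a warning and errors only below 23 bases.

On-target assignment is geometric: a variant is on-target when it lies on
the guide's target chromosome within an inclusive distance (default 50 bp,
configurable — the choice of window is not prescribed by the source
analysis) between its REF span and the cut position. The cut position is
taken 3 bp 5′ of the PAM — between protospacer positions 17 and 18 — the
standard blunt SpCas9 geometry, which the source analysis never states
explicitly.

## Somatic comparison and inversion control

For exome- and genome-scale comparisons the edited arm is contrasted
against the mock arm the way a tumor is contrasted against a matched
normal. The production pipelines behind such analyses are proprietary; the
package documents its stand-in precisely: for each variant called in the
"tumor", a one-sided exact test on the 2×2 table (alt, ref) × (tumor,
normal) — the hypergeometric tail $P(X \ge \mathrm{alt}_T)$ — with
significance level α = 0.01 (configurable), and the additional requirement
that the tumor allele fraction exceed the normal one. A site absent from
the normal call set is backfilled with zero alt reads at the normal's local
depth (from a depth track when available, else its MEC): absence of a call
is not absence of coverage.

The published allele-fraction filters are implemented with their boundaries
exactly as printed: exome mode removes calls at mock VAF *strictly above*
0.01; genome mode removes calls *below* 0.001 tumor VAF and *above* 0.01
mock VAF. Background subtraction reports
`adjusted_vaf = max(0, tumor_vaf − normal_vaf)` without changing set
membership, so it commutes with the filters (tested).

The inversion control re-runs the whole comparison with labels swapped.
On edit-free, symmetric inputs the two directions should produce counts of
the same order; the package reports both counts and their ratio rather than
asserting equality, because the counts are small-sample Poisson-like
quantities. Coverage checks complete the picture: Pearson correlation
between the two arms' depth tracks (low-coverage sites in one arm should be
low-coverage in the other), and a cut-site dropout check comparing mean
depth in a window around the cut to the median of the remaining track. The
dropout flag threshold of 0.5 is a package choice — the source observation
is qualitative ("no apparent drop") — and is configurable.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's guarantees are demonstrated.

* **Design grid.** Three donors; mock plus three guide treatments; harvests
  at days 0 (mock only, single sample per donor), 4 and 10; three technical
  replicates — 75 samples by default.
* **Reference and genes.** A random chromosome with non-overlapping,
  CDS-only gene models on alternating strands (ATG start, stop end, frame
  length — validated), a perfect protospacer+PAM embedded mid-gene per
  guide, and engineered off-target sites built by mutating `23 − k`
  positions of the 23-mer (never the PAM's N position) for a configured
  match count `k`.
* **Germline.** 120 SNVs per donor inside CDS, true VAF 0.5 (two-thirds,
  heterozygous) or 1.0; a quarter synonymous by construction; all emitted
  to the occurrence database with counts above 10 except a 5% holdout at
  counts ≤ 10, which exercises the database boundary and must be caught by
  mock subtraction instead.
* **Depth and reads.** Per-exon mean depth is negative-binomial around the
  target MEC of 3550 (size 40) times a lognormal donor factor (depth varies
  more by donor than by treatment in the emulated data); per-variant depth
  is Poisson around the exon mean, floored at 1; alt reads are binomial at
  the true VAF; variants drawn with zero alt reads are not emitted, because
  the pipeline's inputs are call-based (the somatic module backfills
  zeros).
* **Noise.** Poisson(1) artifact variants per sample at uniform exonic
  positions with VAF uniform in [5×10⁻⁴, 3×10⁻³]. The rate of one per
  sample was chosen so that the simulated replicate concordance sits near
  the ~98% observed in the emulated panel data; it is a property of the
  emulated conditions, not a tuning knob.
* **Planted edits.** Each guide carries an on-target indel burden
  (total VAF 0.80 at day 4, 0.75 at day 10 — high-efficiency editing) and
  the last guide additionally an engineered off-target site at match count
  20 with the published trajectory 0.217 → 0.169, the template for a real
  off-target decaying under selective disadvantage. The burden is split
  across net indel lengths −1, +1, −2, −3 with weights 0.5/0.25/0.15/0.10,
  a plausible spectrum for a blunt double-strand break repaired by
  end-joining; the spectrum is configured globally for all planted sites.
* **Chimerism.** Intermediate-VAF donor variants present in every sample of
  a donor and listed in the germline database. Their default count is zero:
  the emulated data describe them qualitatively ("optional"), without a
  frequency or VAF distribution, so they are available as a configuration
  (`chimerism_count`, uniform VAF in [0.05, 0.35]) rather than imposed on
  every cohort.

Determinism is strict: each stage derives its own seed from the master seed,
and identical configurations produce byte-identical output bundles
(tested). What the generator does *not* emulate — and what passing tests
therefore do not demonstrate about real data — includes read-level error
profiles (no trinucleotide-context substitution bias, no UMI consensus
artifacts), alignment ambiguity around repeats, structural variants and
chromothripsis, multi-allelic germline sites, germline indels, and
panel-specific capture bias. The recovery guarantees (precision = recall = 1
for planted homologous off-target indels well above the detection limit)
are statements about this generative model, not about any sequencing
platform.

## Numerical and degenerate-input choices

* VAF is always recomputed as alt reads / depth on load, even when the
  source file carries an AF field — one definition throughout.
* Multi-allelic records split into one row per alternate allele, conserving
  the allele count; adjacent SNVs are *not* merged into MNVs (how upstream
  callers represent MNVs is not standardized; the package classifies
  whatever representation it receives).
* Concordance of an empty union is defined as 1 (nothing to disagree on);
  a single replicate is its own reproducible set.
* Variants straddling a CDS boundary annotate as `noncoding` with a warning
  rather than guessing a coding consequence; only the synonymous /
  non-synonymous distinction matters downstream, and a straddling variant
  is never synonymous.
* Zero-variance depth tracks make the coverage correlation undefined; a
  flagged `NA` sentinel is returned instead of an error.
* Sites with zero depth in both arms of the somatic comparison are skipped
  with a warning.
* The exact-test p-value uses `phyper`'s upper tail directly; equivalence
  with explicit hypergeometric enumeration is tested for all tables with
  margins up to 30, and against one-sided `fisher.test` on larger sampled
  tables.

## Problem sizes used in the test suite

The shipped tests run the default 75-sample cohort across ten seeds for the
recovery properties, a reduced cohort (two donors, 30 germline variants,
five genes) where only ledger mechanics are at stake, 200 random windows
for the homology oracle, all 64 × 9 codon substitutions for the effect
oracle, and 20 seeds of paired edit-free samples for the inversion control.
These sizes were chosen to keep the full suite within a few minutes on one
CPU while leaving every property with comfortable statistical margin.

## Known limitations

The somatic stand-in is a marginal per-site test without realignment,
strand-bias or mapping-quality modeling; its absolute call counts will not
match any production tumor–normal pipeline, which is why the inversion
control reports ratios rather than absolute rates. The effect annotator is
deliberately minimal (single transcript, CDS-only, no splice or UTR
effects). The homology scorer is ungapped: a bulged off-target site scores
lower than a gapped aligner would report. No systematic-noise blacklist is
applied; inputs may be pre-filtered upstream if one exists.
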