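---
title: "FusionChip: model and methods"
author: "FusionChip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FusionChip: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FusionChip)
```

## The assay being modeled

FusionChip models a multiplex RT-PCR plus microarray screen for the fifteen
chromosomal translocations most frequently seen in acute and chronic
leukemia. The chemistry it abstracts has four stages:

1. **Chimeric-primer reverse transcription.** Sixteen reverse primers, each
   a gene-specific 3' portion tailed with the SP6 promoter sequence
   (`ATTTAGGTGACACTATAGA`), prime cDNA synthesis; every cDNA therefore
   starts with the SP6 tag. The GUS (beta-glucuronidase) reverse primer is
   always present, so every sample with intact RNA yields a control cDNA.
2. **First-round PCR** with fourteen T7-tailed
   (`TAATACGACTCACTATAGGGA`) gene-specific forward primers and the
   universal SP6 primer.
3. **Second-round PCR** with the universal T7 / biotin-SP6 pair only; the
   sequence content is unchanged and every product becomes biotinylated.
4. **Hybridization** of the denatured, biotinylated product to an array of
   20–39 nt oligo probes spotted in triplicate: per splice variant one
   *junction* probe spanning the breakpoint, per fusion partner gene a
   *partner* probe, one GUS control probe spotted at three positions, and
   biotin positional controls along the top row and left column.

The package's claim is not fidelity to reaction kinetics — no polymerase
errors, no melting temperatures, no template competition, no
cycle-dependent yield — but fidelity to the *combinatorial logic* of the
design: which primers can prime where, which amplicons exist, which probes
can bind them, and what the decision rules then conclude.

## Sequence model

Transcripts are sense-strand `DNAStringSet`s, strictly ACGT. Primer and
probe matching is Hamming-distance matching with no indels
(`Biostrings::matchPattern`, `with.indels = FALSE`); the assay oligos are
short and designed as exact transcript substrings, so the default tolerance
is 0 mismatches everywhere, exposed as `max_mismatch` without any claim
about the real hybridization chemistry. Coordinates are 1-based closed
intervals (`IRanges`), the native Bioconductor convention.

A reverse primer binding at sites `[a, b]` yields a cDNA
`SP6tag + primer + revcomp(transcript[1, a-1])`. A forward-primer site
`[c, d]` with `d < a` (fully 5' of the reverse site, i.e. inside the
cDNA-covered region) yields an amplicon with top strand
`T7tag + transcript[c, b] + revcomp(SP6tag)`; products longer than
`max_len` (default 2000 nt, a PCR-efficiency proxy) are dropped. A probe is
bound if it, or its reverse complement, occurs within tolerance in a
*biotinylated* amplicon's top strand — the product is double-stranded, so
binding is strand-symmetric. Primer dimers are modeled as perfectly
removed (the real protocol digests them enzymatically before
hybridization), so they are simply never generated.

Two structural properties follow and are enforced by tests: every amplicon
is tag-conserved (T7 prefix, reverse-complemented SP6 suffix), and all
outputs are monotone non-decreasing in `max_mismatch`.

## Synthetic fixtures

`makeFusionTranscript()` assembles a pseudo-transcript from the panel's own
sequences, in biological order: forward-primer site, 5' partner probe,
junction probe(s) of the chosen variant, 3' partner probe,
reverse-complemented reverse-primer site, separated by random spacers
(default 30 nt). This mirrors the role of the constructed fusion-fragment
plasmids used to validate such assays: the molecule is not a real fusion
mRNA, but it presents exactly the binding sites the assay interrogates.
Spacers are rejection-sampled against the full oligo set (both strands) so
that they can never create a spurious primer or probe site — this is what
makes the zero-noise end-to-end oracle exact. `variant_label = "NOVEL"`
omits the junction probe, emulating a breakpoint isoform unknown to the
panel whose partner probes still hybridize; MLL-style rules have no
junction probe by design.

`simulateIntensityGrid()` stands in for the scanner. Each spot draws a
lognormal intensity: bound-probe spots at `signal_mu` (default
`log(20000)`), unbound and blank spots at `baseline_mu` (default
`log(200)`), biotin controls at `biotin_level` (default `log(30000)`, upper
half of a 16-bit scanner range), all with `noise_sigma` (default 0.25), and
a `dropout_rate` at which a bound spot falls back to baseline (default 0).
The defaults were chosen once, as plausible scanner-like values that put
the 15% biotin cutoff (≈4500) between the two populations; the published
work reports no quantitative intensity distributions, so these parameters
are synthetic by construction and the tests exercise the *decision rules*,
not scanner physics. What passing tests show about real data is therefore
limited: they demonstrate the logic is correct when signals separate, and
they quantify robustness only under this noise model.

`makeCohort()` derives one grid per sample. The hybridization outcome of a
genotype is deterministic — spacers cannot create sites — so the bound-probe
set is computed once per distinct genotype and reused, while intensity
noise is drawn per sample from a seed derived as
`(seed + 7919 * index) mod (2^31 - 1)`. Whole-cohort generation is
bitwise-reproducible given the seed, the software analogue of the repeated
operator/experiment precision study.

## The decision procedure

Replicate intensities are arithmetically averaged per probe. Two thresholds
gate every probe, and a true signal must *strictly* exceed both (the
source description says "higher than"; `strict_inequality = FALSE` is
available):

* **background**, per probe: the pooled mean of that probe's
  replicate-averaged signal over the supplied reference arrays (each
  array's averaged blank value enters the pool as well) plus
  `sd_multiplier` (default 3) times the pooled *sample* SD (n−1
  denominator — the published rule says only "3× SD"). At least two pooled
  values are required, else the SD is undefined and the function stops
  naming the probe.
* **cutoff**, per array: `cutoff_fraction` (default 0.15) of the mean
  biotin-control intensity *of the same array*. Whether the original
  protocol used all biotin spots or a designated subset is ambiguous; the
  mean of all is used.

The set of reference arrays is an explicit input. In the simulated
pipeline, no-template blank arrays are used: negative *patient* samples
carry a true GUS signal, and pooling them would push the GUS background
above its own true level and invalidate every sample. With real data the
user chooses the reference set; the function is agnostic.

Calls then follow the published rule: a standard fusion variant is positive
when its junction probe and its hard-wired 5' and 3' partner probes are all
true (for BCR-ABL the pairing is per form — p190↔BCR190, b2a2/b3a2↔BCR210,
p230↔BCR230 — so a stray ABL signal alone never calls); an MLL
rearrangement is positive on its MLL + partner pair, with both calls and a
warning when two different MLL partners light up; a fusion whose partner
probes are all true while *every* junction probe of that fusion is false is
reported as `variant_flag` — the inference that identified a V-form
PML-RARA transcript from PML-L + RARA signals alone. A sample without a
true GUS signal is invalid and carries no calls (conservative: such samples
were excluded from the original assay results). Coexisting variants of one
fusion (e.g. TEL-AML1 ex2 + ex3) produce one call per variant but count
once toward positivity.

Raising `cutoff_fraction` or `sd_multiplier` can only shrink the
true-signal set and the call set; this monotonicity is property-tested.

## Cohort statistics

`summarizeCohort()` counts, per group, samples with at least one detected
fusion — a `variant_flag` counts as a detection, which is what makes the
10/74 PML-RARA rate include the V-form patient — with per-fusion
percentages of the group size; BCR-ABL rows are split into p190/p210/p230
display forms. `variantDistribution()` shares use the detected-sample
denominator, so a two-variant sample contributes to both numerators.
`concordance()` compares detections with reference diagnoses at the fusion
level: negative↔`none` is concordant, `other_translocation` (a lesion
outside the panel) is always discordant, and a QC-failed sample is
concordant exactly when its reference is `none`.

Percentages are kept unrounded internally; the presentation value uses
round-half-up to one decimal. The published percentage table itself mixes
rounding and truncation (e.g. 5/74 = 6.76 printed as 6.8, but 18/115 =
15.65 printed as 15.6 and 5/11 = 45.45 printed as 45.4), so no single
deterministic presenter reproduces every printed digit; compatibility
checks therefore compare exact values within one unit of the last printed
digit, and counts exactly.

## The bundled 200-patient cohort

`screeningCohortGenotypes()` encodes the screening-cohort composition: 74 AML (8
AML1-ETO; 5 L-form, 4 S-form and 1 junction-free NOVEL PML-RARA; 5 type-A
CBFB-MYH11; one each MLL-AF9/ENL/ELL/AF6/AF10; 4 off-panel; 6 QC-fail), 115
ALL (4 MLL-AF4; 15 ex2, 2 ex2+ex3 and 1 ex3 TEL-AML1; 2 (I) and 1 (Ia)
E2A-PBX1; 2 BCR-ABL p190; 3 off-panel; 9 QC-fail) and 11 CML (5 b3a2, 3
b2a2). The 15 QC-fail samples all carry reference `none`; this is the only
assignment consistent with 193/200 concordance, with all seven discordant
samples being the off-panel lesions.

## Numerical and design choices

* Exact matching by default; tolerance is a parameter, not a chemistry claim.
* Printed sequences win over stated lengths/positions when the panel tables
  conflict; `validatePanel()` reports all four such primers and the probes
  outside the stated 20–30 nt range (several printed probes run 31–39 nt).
* Start positions from the primer composition strings are stored as 1-based
  metadata only; no live sequence-database lookup is ever performed.
* Probe roles are assigned from naming and the assay description: hyphenated
  gene-pair names (and the p190/p210/p230 junction names) are junction
  probes, single-gene names partner probes, GUS the control; AF10-A/AF10-B
  are partner probes for two MLL-AF10 breakpoint regions (either suffices);
  NPM1-RARA-L-2 is treated as a second junction probe of the L-form.
* Spacer rejection-sampling retries up to 50 times (a spurious 15+ nt exact
  site in a 30 nt random spacer is vanishingly rare; failure stops loudly).
* Ties at a threshold are negative under the default strict comparison.
* Problem sizes in the tests and acceptance script — the 200-sample cohort,
  27-variant recovery sweep, 100-seed noise study — were chosen to mirror
  the study's own scales while completing in seconds to a couple of minutes.

## Known limitations

* No RNA degradation, expression-level, or dilution-series modeling: the
  wet-lab sensitivity results (10^-2–10^-3 dilutions) have no software
  counterpart beyond the abstract `dropout_rate` knob.
* The lognormal spot model ignores spatial artifacts, saturation and
  segmentation errors; the GPR reader ingests only `Name` and `F532
  Median`/`Mean` columns, not quality flags.
* Cross-hybridization is purely sequence-identity-based; probes sharing
  long motifs (the RARA-fusion junction family, the CBFB-MYH11 prefix) are
  only distinguished as far as Hamming distance distinguishes them.
* Real GenBank transcripts can be substituted for the pseudo-transcripts
  transparently (`readFasta()`), but the package never fetches them.
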