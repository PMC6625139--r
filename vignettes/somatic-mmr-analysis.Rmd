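---
title: "Somatic signatures, LOH and microsatellite instability in MMR-deficient tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic signatures, LOH and microsatellite instability in MMR-deficient tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrsig)
```

## The analysis problem

Carriers of a germline mutation in a mismatch-repair (MMR) gene — *MLH1*,
*MSH2*, *MSH6* or *PMS2* — develop tumors in which the remaining wild-type
allele is somatically inactivated (the "second hit"), either by a point
mutation or by loss of heterozygosity (LOH). The resulting MMR-deficient
tumors accumulate a characteristic somatic profile: a high mutation burden,
instability at microsatellite repeats, and base-substitution patterns
captured by mutational signatures 6 and 15 of the classical 30-signature
panel. `mmrsig` implements the full per-sample analysis needed to measure
these features from paired tumor/germline exome variant calls and to compare
MMR-deficient against MMR-proficient lesions, together with a synthetic-data
generator so that every stage is testable without access to sequence data.

The pipeline consumes, per sample: a germline VCF, two tumor VCFs from
independent somatic callers (only one of which calls indels), an indexed
reference, capture and exon BEDs, and a 30 x 96 signature-probability table.

## Somatic variant selection and burden

Somatic SNVs are accepted only when called by **both** callers (exact
`(chrom, pos, ref, alt)` agreement after splitting multi-allelic records);
indels, available from a single caller, bypass the intersection. All calls
are then filtered to **depth >= 40 reads** and **VAF >= 10%** (both
inclusive: a minimum is read as at-least) and restricted to the capture
region; a 1-based position `p` lies in a half-open BED interval `[s, e)` iff
`s < p <= e`. Tumor mutational burden is the filtered SSNV count per
megabase of *merged* capture interval. Which caller's depth/VAF fields are
reported for intersected records is not determined by the method itself;
caller A is the documented default (`stats_from`).

```{r, eval = FALSE}
f <- filter_somatic_variants(tumor_a, tumor_b, capture)
f$summary     # counts along the chain, monotone non-increasing, plus TMB
```

## The 96-context catalog and signature refitting

Each SNV is assigned to one of 96 trinucleotide contexts: six substitution
classes (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flank pairs, in the row
order of the public signature tables. Purine-reference variants are
reverse-complemented (substitution and flanks together) so the reference
base is always a pyrimidine. Variants with non-ACGT flanks are tallied as
unclassifiable rather than thrown, so catalog total plus tally always equals
the SNV count.

Refitting finds non-negative signature exposures `w` maximizing the cosine
similarity between the normalized catalog `m` and the reconstruction
`w' P`, where `P` is the 30 x 96 signature matrix:

* greedy forward selection from the empty model; each iteration searches
  every candidate signature and its mixing weight `w in [0, 1]` by a
  bounded scalar search (Brent's golden-section/parabolic method,
  tolerance 1e-4), accepting the best candidate only if it improves the
  objective by more than `improvement_tol = 1e-4`;
* ties go to the lowest signature index; the objective is non-decreasing
  across accepted iterations (asserted in tests);
* after convergence, exposures below `weight_floor = 0.06` are zeroed and
  the rest renormalized — the discard rule of the reference refitting tool;
  the method's description names cosine similarity as the objective, so
  that is the default, with a sum-of-squared-errors alternative
  (`objective = "sse"`) that agrees closely on clean mixtures;
* catalogs are normalized to frequencies first; exposures are
  mutation-fraction contributions, reported as percentages.

Two open choices are deliberately exposed rather than guessed: no
exome-to-genome trinucleotide renormalization is applied (off by default),
and no signature-subset restriction is imposed.

An all-zero catalog is refused; if no signature improves on the empty
model, the single best-cosine signature is returned with weight 1 (logged
degenerate fallback).

## The bundled signature panel is synthetic

The genuine 30-signature probability table is distributed by COSMIC and is
not redistributed here. The package ships a **synthetic** panel
(`synthetic_signature_matrix()`, also installed as
`extdata/signatures_synthetic_30x96.tsv`) whose rows are probability
distributions over the same 96 contexts: rows 1, 4, 6, 7, 15 and 29 are
shaped after well-known aetiologies (CpG deamination, tobacco, MMR
deficiency, ultraviolet light) and the rest are fixed sparse Dirichlet
draws. All refit, recovery and cohort machinery is exercised against this
panel; analyses of real tumors should load the genuine table with
`read_signature_matrix()`, which accepts the public TSV dialect.

## The LOH caller

LOH is detected from paired VAFs at germline heterozygous sites:

* a site is **informative** when its germline VAF lies in [0.3, 0.7]
  (inclusive) and the site is re-observed in the tumor caller's records
  (as real somatic callers emit germline-tagged records); sites without a
  tumor record are dropped and tallied — without read-level data, absence
  cannot be distinguished from no coverage;
* a site **supports LOH** when the somatic VAF differs from the germline
  VAF by strictly more than 0.3. A shift toward homozygous reference and
  toward homozygous alternate are together equivalent to the
  absolute-difference test on a single VAF axis. The comparison carries a
  1e-9 guard so that a shift of exactly 0.30 — including the
  floating-point residue of `0.8 - 0.5` — never qualifies. Whether the
  somatic VAF must additionally leave the heterozygous band itself is
  ambiguous in the source method's description; both readings are
  implemented (`require_homozygous`), defaulting to shift-only;
* sites are segmented by a sliding window of 10 consecutive sites
  requiring a supporting fraction of at least 0.5, with overlapping
  qualifying windows merged. The window parameters are this package's own
  segmentation rule (the underlying method plots per-site evidence
  without one) and are configuration, not doctrine.

The second hit for a gene is `somatic_mutation` when a moderate/high-impact
somatic variant falls in the gene, `LOH` when an LOH region overlaps it,
both (somatic mutation first) when both occur.

## Microsatellites and the MSI score

`find_microsatellites()` scans for maximal tandem repeats with units of
1-5 bp — homopolymers of >= 5 repeats and multimers of >= 3 repeats,
common scan settings for locus-based MSI tools. Periodic motifs reduce to
their smallest unit and overlapping candidates resolve in favour of the
smaller unit. The MSI score is the percentage of loci overlapped by at
least one somatic indel, and the exonic microsatellite indel count
requires overlap with both a locus and an exon. This is a **declared
proxy** for read-level MSI callers: it is faithful to the
"percentage of microsatellites affected by indels" definition, but its
absolute values are not comparable to tools that model per-read
repeat-length distributions, and published per-sample scores from such
tools are correspondingly not reproduction targets.

One geometric subtlety: a left-aligned insertion is anchored on the base
*before* the run it extends, so the insertion's affected span is taken as
the anchor plus the following base; with the anchor alone, every
microsatellite insertion would be systematically missed.

## Group statistics

All cohort comparisons use the pooled-variance two-tailed Student's t test
(`students_t_test()`), accepting raw values or `(n, mean, sd)` summaries
interchangeably — the pooled form needs nothing more, which matters when
one group is available only as a published summary. Group summaries use
the sample (n-1) standard deviation; the pooled form was validated by
reproducing all four published cohort p-values (0.03, 0.0018, 0.052,
0.08) from per-lesion values and printed summaries. Welch's correction is
available behind `var_equal = FALSE`. Degenerate cases are defined, not
thrown: identical constant groups give t = 0, p = 1; zero pooled variance
with unequal means warns and returns p = 0.

## What the synthetic generator emulates — and what it does not

`generate_reference()` builds a GC-controlled random sequence with planned
microsatellites embedded verbatim (placement failures are explicit errors,
never silent truncation). `simulate_sample()` then produces a germline
table and two pseudo-caller tumor tables with known truth:

* somatic SNVs are drawn multinomially from a declared signature mixture
  and placed at reference positions whose trinucleotide matches the
  sampled context, searched on both strands — the reference is never
  mutated to fit, which forces correct strand collapsing downstream;
* germline hets have binomial alt counts at p = 0.5, the simplest model
  consistent with a 0.3-0.7 heterozygous window;
* inside LOH segments the somatic re-observation is resampled at p = 0.9
  (or 0.1) until the VAF is >= 0.85 (or <= 0.15): safely beyond the 0.3
  shift threshold with room for noise, so truth is recoverable without
  tuning;
* a declared fraction of SNVs is emitted by both callers (the headline
  filter is a caller intersection, so disagreement must be exercised);
  indels — one repeat unit inserted or deleted, left-aligned — go to
  caller B only;
* everything is deterministic given the spec seed, down to VCF bytes.

Simulated tumor SNVs carry depth >= 40 and VAF >= 0.2 so they survive
default filters unless deliberately degraded. The generator does **not**
model FFPE artifacts, sequencing error, subclonality, purity, copy-number
beyond the VAF shift, or read-level data (no FASTQ/BAM). Passing tests
therefore demonstrate the correctness of the algorithms under clean
statistical structure, not robustness to the artifact spectrum of real
FFPE exomes.

Default study-scale conditions used throughout the test-suite and the
reproduction script, chosen once as realistic for this design: 100 kb
references with a poly-A locus every 200 bp, catalogs of 10,000 SNVs for
recovery runs, sequencing depth 80, 200 informative het sites with one
50-site LOH segment, and 20 replicate seeds for averaged recovery
statistics.

## Numerical and design notes

* Bin order is fixed by the signature-table convention
  (substitution-major, flanks alphabetical); the matrix dictates the
  catalog ordering, never the reverse.
* Multi-allelic VCF records are split into per-alt variants before any
  matching; balanced multi-base substitutions are classified `other` and
  excluded from catalogs with a tally.
* VAF precedence when reading VCFs: AD over an AF field; neither is an
  error, not a guess.
* Caller intersection excludes records tagged by the caller as germline;
  those records are exactly what the LOH caller consumes.
* Group labels (MMR-deficient/proficient) are user-declared metadata,
  never inferred from the data.
* Hotspot tables are user input with a recurrence-count filter
  (default >= 3); no recurrence threshold is asserted as canonical.

## Known limitations

Absolute per-sample values from the motivating study design (mutational
load, TMB, MSI scores of real lesions) are functions of the capture kit,
callers and annotation stack and are not recomputable from summary tables;
they are exercised here only through group statistics and synthetic truth.
The LOH caller cannot see allele-specific copy number; a balanced
copy-neutral event that preserves VAF is invisible to it. The MSI proxy
underestimates instability relative to read-level callers because it only
sees called indels.
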