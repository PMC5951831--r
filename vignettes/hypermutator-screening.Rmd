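---
title: "Screening for CpG>TpG deamination hypermutation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for CpG>TpG deamination hypermutation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deaminoscan)
```

# The model

Methylated cytosines deaminate spontaneously to thymine. When the MBD4
glycosylase that repairs the resulting T:G mismatches is lost, somatic
C>T transitions accumulate at CpG dinucleotides. A tumor with this
defect is detectable from exome variant calls alone by the conjunction
of two signals:

* a **hypermutated burden** — more than 200 somatic SNVs, where typical
  low-burden tumors (uveal melanoma being the motivating extreme) carry
  a few dozen;
* a **CpG>TpG-dominated spectrum** — the fraction of SNVs that are C>T
  at a CpG exceeds 0.6, where the background in the same tumor types
  stays below ~0.3.

Both cuts are strict inequalities and the hit decision is their
conjunction; each signal alone is unspecific (many hypermutated tumors
are MMR- or POLE-driven; small samples can have high CpG>TpG fractions
by chance at low counts).

## The 96-channel spectrum and strand collapse

SNVs are classified into the standard SBS96 channels: 6 substitution
classes times 16 flanking-base pairs. DNA is double-stranded, so a CpG
deamination event appears either as a plus-strand C>T or as a
minus-strand G>A with a C on its 5' side; the two are the same event.
`classify_channel()` therefore reverse-complements every
purine-reference substitution together with its context before lookup
(pyrimidine-centered collapse). The "CpG>TpG" statistic is then simply
the sum of the four `N[C>T]G` channels. Transcriptional
(sense/antisense) strand bias is deliberately **not** modeled: it
requires gene annotation and does not enter the screen decision.

Channel order is frozen — substitution-major (`C>A`, `C>G`, `C>T`,
`T>A`, `T>C`, `T>G`), 5' flank varying slowest, flanks alphabetical — so
serialized spectra are bit-comparable across runs. The full mapping is
exercised in the tests against a brute-force reverse-complement oracle
over all 192 valid `(ref, alt, context)` inputs (16 flank pairs × 4
reference bases × 3 alternate bases), together with the involution
property (classifying the reverse-complemented input yields the same
channel).

The denominator of the CpG>TpG fraction is **classifiable SNVs only**:
indels and SNVs whose trinucleotide context is unavailable (contig edge,
`N` in the 3-mer) are tallied separately and excluded from both
numerator and denominator. An empty spectrum reports fraction 0 with an
explicit undefined flag rather than `NaN`.

# Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `min_germline_depth` | 10 | reads | calls on thin germline coverage cannot be confidently somatic |
| `min_somatic_depth` | 10 | reads | burden estimates degrade below ~10× |
| `min_allele_depth` | 6 | reads | guards against sequencing-error alleles |
| `min_allele_fraction` | 0.05 | fraction | subclonal-noise floor (AD over somatic DP) |
| `max_pop_freq` | 0.01 | fraction | frequencies above 1% indicate germline polymorphism leakage |
| `min_callers` | 1 | callers | union merge; raise for intersection analyses |
| `min_snv` (screen) | 200 | SNVs | hypermutation cut, strict `>` |
| `min_fraction` (screen) | 0.6 | fraction | CpG>TpG enrichment cut, strict `>` |

Boundary semantics are uniform: every filter rule rejects on a **strict**
inequality, so a record exactly at a threshold (AD/DP = 0.05 with AD = 6
and DP = 120, population frequency = 0.01, DP = 10) is retained. Missing
annotations never fire a rule — a variant without a population frequency
is not frequency-filtered, because the rule exists to remove calls known
to be *common*, and likewise for missing depths. The AD/DP ratio uses
the somatic DP; this is a genuine ambiguity in multi-caller data (each
caller reports its own DP) and is resolved here by always filtering
against the merged record's somatic depth.

When caller call sets are merged by union, depth annotations of records
agreeing on `(chrom, pos, ref, alt)` are resolved by keeping the
contributing record with the highest somatic depth (ties broken by
allele depth). Union rather than intersection mirrors a permissive
merge; depth disagreement between callers is real and the
best-supported record is the least arbitrary single representative.
Manual review of calls (e.g. in IGV) is inherently interactive and is
not modeled.

# The screen

`summarize_sample()` reduces a spectrum to the screen quantities,
including the two cohort-scatter coordinates: CpG>TpG/SNVs and
(C>T outside CpG)/SNVs. `screen_cohort()` orders hits by descending
CpG>TpG fraction, then descending SNV count — a deterministic total
order so reports are reproducible; remaining ties (identical fraction
and count) fall back to input order after a deterministic sort by
cohort and sample identifier.

Fold-change of a sample's burden is computed against the arithmetic
mean of the *other* samples in its cohort. Excluding the index sample
matters: a single extreme outlier would otherwise inflate its own
baseline and shrink its reported fold-change. The median is available
(`baseline_statistic = "median"`) for cohorts with several outliers. A
baseline of zero yields an undefined (`NA`) fold-change, not an error.

The screen counts **SNVs only** toward the `> 200` cut (indels are
excluded with the rest of the spectrum machinery); the enrichment
fraction already excludes them by construction.

# Lineage analyses

Variant identity across a patient's samples is `(chrom, pos, ref, alt)`
— depths and annotations differ between samples by sequencing accident
and never enter the key. `shared_matrix()` is plain set intersection;
`polyphyly_check()` flags a metastasis as consistent with polyphyletic
seeding iff it shares strictly more variants with the primary than with
every sibling metastasis, and ties fail conservatively (flagged, not
claimed). Acquired mutations are the set difference against a reference
set: by default the primary sample's variants, a deliberate proxy for
the founding clone — full clonal deconvolution is out of scope, and the
report records that the proxy was used. The cluster-retention rule
applied to externally inferred clonal clusters keeps a cluster iff it
has at least 5 variants **and** its mean cancer-cell fraction reaches at
least 0.10 in at least one sample; both boundaries are inclusive
("at least").

# The synthetic-data generator

The generator exists so every pipeline stage can be tested against
planted truth. Design choices:

* **Exact GC**: the contig's G+C count is `round(gc * length)`; only the
  arrangement is random. Contigs below 1000 bases are refused.
* **Context-aware placement**: the channel of each simulated SNV is
  drawn first, and a position whose reference 3-mer matches that channel
  (on either strand) is sampled afterwards, without replacement within a
  sample. Planted spectra are therefore exact by construction — a
  CpG>TpG variant always sits on a genuine CpG site. Requesting more
  variants than there are free matching sites is a capacity error, not a
  silent shortfall.
* **Study conditions as defaults**: background per-sample SNV counts are
  negative binomial with mean 15 (a low-burden, uveal-melanoma-like
  cohort) and CpG>TpG weight 0.25 (below the <0.3 background band);
  hypermutators carry 300–1500 SNVs at weight 0.95 (within the 0.91–0.97
  band observed in MBD4-deficient tumors). `round(fraction × n)` samples
  per cohort are hypermutators.
* **Depth model**: germline/somatic depth `10 + Poisson(80)`, allele
  fraction `Beta(8, 12)` (mean 0.4); clean records always pass the
  default cascade, so planted filter violations are the *only* source of
  rejections. Violation planting modifies a disjoint set of records per
  rule such that each violates exactly that one rule — this makes the
  audit exactly checkable.
* **Single seed**: every generator consumes R's global RNG seeded from
  the one `seed` field (with small fixed offsets per stage so that
  regenerating one artifact does not shift another's stream). Identical
  configs give byte-identical FASTA/MAF output.

What the simulator does **not** emulate: read-level errors (no
FASTQ/BAM), mapping artifacts, copy number and LOH, transcriptional
strand asymmetry, non-uniform channel weights within the CpG and
non-CpG groups, inter-caller depth disagreement, and real exome target
geometry. Passing the recovery experiments therefore demonstrates the
*pipeline's* correctness on data matching its assumptions, not the
screen's operating characteristics on real exomes — on real data the
separation between background and MBD4-like tumors is expected to be
equally wide, but contamination, subclonality and target-size variation
will move individual samples.

# Validation experiments and problem sizes

Two packaged experiments drive the acceptance checks and are sized to
run in seconds to minutes on one CPU:

* `screen_recovery()`: 100 cohorts of 20 samples (2 planted
  hypermutators each) on a shared 100 kb contig; sensitivity and
  specificity of the hit list against planted truth. Under the default
  separation both are expected to be exactly 1.0: a weight-0.95 sample
  with ≥300 SNVs essentially cannot fall below fraction 0.6, and a
  background sample cannot exceed 200 SNVs.
* `estimator_recovery()`: 200 samples × 1000 SNVs at weight 0.95; the
  mean absolute error of the recovered fraction is binomial-limited at
  ≈ `sqrt(2 w (1-w) / (π n))` ≈ 0.0055, and the experiment checks it
  stays below 0.01.

The worked single-case fixture (`hypermutator_case()`: 474 SNVs, 460
CpG>TpG) reproduces, by construction, the totals of a published-scale
MBD4-deficient tumor and exercises spectrum + screen end to end.

# Known limitations

* Functional consequence (`functional_class`) is input metadata; the
  package never annotates variants, so non-synonymous counts are only as
  good as the upstream annotation and no transcript set is imposed.
* The hypermutation cut is calibrated for exome-scale variant tables;
  whole-genome inputs need a proportionally higher `min_snv`.
* The cohort fold-change compares against whatever cohort is supplied;
  it is a descriptive outlier statistic, not a calibrated test.
* Clonal clusters are consumed, never inferred; cancer-cell fractions
  are trusted as given.
* MAF parsing accepts the GDC dialect and a generic header; exotic MAF
  flavors need an explicit `dialect` mapping.
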