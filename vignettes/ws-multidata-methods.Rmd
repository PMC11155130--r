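---
title: "Methods: multi-data integration for undiagnosed Waardenburg syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-data integration for undiagnosed Waardenburg syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wsdecipher` packages a three-stage analysis for Waardenburg syndrome (WS), an
autosomal-dominant auditory–pigmentary disorder with seven confirmed genes
(*PAX3*, *MITF*, *SOX10*, *SNAI2*, *EDNRB*, *EDN3*, *KITLG*) and a sizeable
molecularly unexplained fraction of patients. This vignette is the package's
account of the underlying models, the tunable parameters, the numerical
choices, what the synthetic-data generators do and do not emulate, and the
design decisions that were genuinely open.

## Stage 1: candidate gene prioritization

Two independent lines of evidence are intersected.

**Interaction evidence (set A).** The seed genes are mapped into k ≥ 2 PPI
edge lists (the intended use is three independent databases). For each source,
`direct_partners()` collects the one-hop neighbors of any seed, excluding the
seeds themselves; `consensus_partners()` keeps the exact intersection across
sources. The consensus is a full intersection, not a majority vote: requiring
support in every source trades recall for precision, which is the right trade
when the next step is manual follow-up of a handful of genes. One-hop only —
no path expansion — because the biological claim being encoded is direct
physical interaction with a known disease protein.

**Phenotype evidence (set B).** The seed genes' phenotype-term annotations
are pooled into the disease set P~ws~ (cardinality N~ws~); every annotated
gene g is scored by the similarity weight W~g~ = N~g~/N~ws~ with
N~g~ = |P~g~ ∩ P~ws~|. Genes with W~g~ strictly above the threshold (default
0.2) form set B. The strict inequality matters at the boundary: with
N~ws~ = 70 the rule "W~g~ > 0.2" is exactly "more than 14 shared terms", so a
gene sharing 14 terms (W~g~ = 0.2) is excluded and one sharing 15
(W~g~ ≈ 0.214) is included. The weight is a ratio of exact set cardinalities;
no semantic similarity between ontology terms is attempted, so two terms
count as shared only under exact ID equality.

Preliminary candidates are A ∩ B with seed genes excluded from every reported
set (a seed is never its own candidate). An optional evidence table of
boolean flags per gene (e.g. "mutations cause hearing impairment in mouse")
filters preliminary candidates to high-priority ones; genes absent from the
evidence table are excluded and logged rather than passed through.

A rank-based cutoff ("top n by weight") was considered as an alternative to
the fixed threshold and left out of the default path: the threshold form is
self-documenting and scale-free in N~ws~, whereas a top-n rule silently
changes meaning when the annotation corpus grows. `select_set_B()` takes the
threshold as an argument, so a caller who wants rank selection can sort the
weights table directly.

## Stage 2: candidate variant nomination

`build_variant_report()` runs four stages in order; final candidates must
pass all of them, and per-gene counts are reported at every stage so the
monotone narrowing (filter ≥ novel ≥ conserved ≥ final) is visible.

**Consensus deleteriousness filter.** Five predictor cutoffs, all required
simultaneously: SIFT ≤ 0.001 (non-strict), PolyPhen2-HVAR > 0.957,
MutationTaster = 1, CADD-phred > 25, GERP++ RS > 4 (all strict). The boundary
directions are kept exactly as stated rather than harmonized, because the
asymmetry is part of the filter's definition; a variant sitting exactly on
the CADD or GERP++ boundary fails. "MutationTaster = 1" is read as the
converted score equal to 1 within a tolerance of 1e-9 (a score column, not
the categorical prediction); `filter_thresholds(mutationtaster_categorical =
TRUE)` switches to accepting categorical codes ("D"/"A") instead. Missing
scores fail closed: a variant missing any predictor can never reach the final
set, which avoids promoting variants merely because they were never scored.
Population-frequency columns are carried through untouched — the filter
deliberately imposes no allele-frequency cutoff.

**Known-variant cross-reference.** Exact ID match against a supplied
known-pathogenic list partitions survivors into known and novel; only novel
variants continue. IDs are compared after whitespace trimming only, so both
sides must use one ID scheme.

**Conservation.** The variant's 1-based protein position is mapped to the
alignment column holding the i-th non-gap residue of the designated reference
sequence. The column is conserved when no sequence is gapped there and the
modal residue is carried by at least `min_identity_fraction` of the sequences
— default 1.0, i.e. strict identity across all rows of the cross-species
alignment. Per-residue column identity was chosen over any windowed
"conserved region" notion because it is unambiguous and reproducible; the
fraction is a parameter for users who prefer a softer criterion. If the
reference residue at the mapped column disagrees with the variant's stated
reference amino acid, the check returns not-evaluable (NA) with a warning —
a coordinate-system mismatch should surface, not silently fail or pass.

**Domain localization.** Domains are user-supplied 1-based inclusive
intervals. Overlapping intervals are legal (domain annotations overlap in
practice); ties are broken deterministically by (start, end, name) order and
the first enclosing interval is reported. Only simple substitutions
(`p.<ref><pos><alt>`, one- or three-letter) are positioned; other HGVS
strings pass through untyped and cannot be conservation-checked or localized.

## Stage 3: genotype–phenotype association

The cohort table has one row per patient and one ternary column per
phenotype: present, absent, or unrecorded. Every denominator in the package
counts recorded patients only — this is why published prevalence fractions
like 345/408 have denominators below the cohort size — and unrecorded cells
are never imputed.

**Test selection.** For each phenotype, a 2×k present/absent × gene table is
built over recorded patients. The package uses Pearson's chi-square
(uncorrected) unless any expected count falls below 5, in which case it uses
the Fisher exact test; the same rule applies to every pairwise 2×2 sub-table.
The threshold 5 is the conventional expected-count rule; it is a package
decision (exposed as `expected_min`) since the analysis convention only
states that both tests were used. No continuity correction is applied by
default (`correct = FALSE`), matching how the uncorrected Pearson statistic
is conventionally reported; a flag enables Yates' correction. P-values are
two-sided and deliberately unadjusted for multiplicity, matching the raw
reporting convention; callers can feed the returned p-values to `p.adjust()`.

**Exact tests.** `fisher_exact()` is implemented by enumeration: for 2×2
tables, the two-sided p is the sum of hypergeometric probabilities of all
margin-fixed tables whose probability does not exceed the observed table's,
with a relative slack of 1e-12 for floating-point ties; for 2×3 tables the
Freeman–Halton extension enumerates every margin-fixed table under the
multivariate hypergeometric null. Enumeration bounds (total n ≤ 2000 for
2×2, ≤ 500 for 2×3) keep the computation exact and fast; beyond the bound
the function refuses with an instruction to use the chi-square test, and
`group_association_test()` applies that instruction automatically (with a
warning) when the selection rule wanted Fisher on an oversized table.

**Phi co-occurrence.** For two phenotypes, patients with both statuses
recorded form a 2×2 table (a, b; c, d) and
φ = (ad − bc)/√((a+b)(c+d)(a+c)(b+d)), with p from the uncorrected Pearson
chi-square on the same table — the identity χ² = n·φ² ties the two together
and is property-tested. φ is undefined when any margin is zero; undefined
values stay NA (never coerced to 0) and are never flagged significant. The
matrix diagonal is 1 by convention. The significance mask uses α = 0.05 by
default.

**Degenerate inputs.** Strata with no recorded patients are dropped with a
warning (fewer than two usable strata is an error); phenotypes that are
all-present or all-absent among recorded patients yield a "degenerate" test
with p = 1, since no association is detectable from a constant column.

## The synthetic-data module

The generators exist so that every stage runs and is verified without any
external download, with ground truth retained for recovery tests. Defaults
are the study conditions the pipeline targets: 7 seed genes; a disease
phenotype set of exactly N~ws~ = 70 terms over 4707 annotated genes; planted
candidate genes SIN3A/EP300/CHD7/KIT sharing 17/16/15/15 terms (all above
the 14-term boundary); three PPI sources; variant bundles for
*PAX3*/*MITF*/*SOX10* with 20/7/5 planted final variants and 8/4/4 planted
known ones; and a 443-patient cohort with gene mixture
138/161/124/13/4/2/1, ~8% per-cell phenotype missingness (giving recorded
denominators like 408/443), 27% unrecorded sex, and a strongly elevated
de novo rate for *SOX10* (0.617 vs 0.15/0.25). Per-gene phenotype
prevalences not fixed by published counts are set once to clinically
plausible values (e.g. hearing impairment 0.78/0.85/0.97 across
*PAX3*/*MITF*/*SOX10*; aganglionic megacolon 0.36 in *SOX10* and 0
elsewhere; telecanthus concentrated in *PAX3*; skin freckles 0.71 in *MITF*)
and are not tuned thereafter.

Design guarantees worth knowing when reading the tests:

- One integer master seed drives an independent child stream per generator
  (fixed affine offsets), so adding a generator never perturbs the others,
  and generation is byte-identical under a fixed seed.
- Planted consensus partners are adjacent to a seed in *every* source; decoy
  partners appear in only 1–2 sources, so the consensus recovers exactly the
  planted set. Background edges never touch seeds.
- Seed genes are annotated only with disease-set terms, so the pooled union
  has exactly the configured size; planted genes get exactly their target
  overlap plus off-target terms; background overlaps are binomial.
- Every variant-bundle stage has at least one decoy that it alone rejects
  (one score-failing, one known, one at a non-conserved column, one outside
  all domains), so stage ordering is testable.
- Cohort phenotype cells are independent Bernoulli draws given the patient's
  gene, masked unrecorded independently per cell. The real missingness
  mechanism in curated case reports is unknown and almost certainly not
  independent; independence is the documented simplification.

What the generators do **not** emulate — and hence what passing tests do not
show about real data: ontology structure among phenotype terms (terms are
opaque IDs, no ancestor sharing), realistic allele frequencies or
linkage, pedigree structure within families, correlated missingness (e.g.
whole phenotype panels unrecorded together), inter-database biases of real
PPI resources, and literature-curation noise such as inconsistent phenotype
naming. Recovery of planted signal demonstrates the pipeline's correctness,
not the biological validity of any particular candidate.

## Numerical and formatting choices

- Gene symbols: trimmed, optionally alias-mapped, uppercased; normalization
  is idempotent, and no other alias resolution is attempted.
- Protein coordinates: 1-based inclusive throughout, matching
  `p.Arg156Cys`-style substitution notation.
- Reports: TSV/JSON, UTF-8, LF newlines, deterministic lexicographic
  ordering of genes and terms, floats at 6 significant digits; writers and
  readers round-trip exactly because rounding happens before writing.
- Ternary cohort coding is configurable; any cell outside the declared codes
  is a schema error, never silently treated as missing. Score cells that are
  "." or empty are missing; unparseable score text is downgraded to missing
  with a counted warning, but a parseable out-of-range score is a schema
  error.
- All set outputs are sorted; all randomness flows from explicit seeds.

## Problem sizes used in the checks

The test suite and the acceptance script run the exact-test enumeration
sweep over every 2×2 table with total n ≤ 40 (135,750 tables), the χ² = n·φ²
identity on 10,000 random tables, full-size synthetic bundles (4707 genes,
443 patients) for planted-signal recovery, 1000 null cohorts of n = 300 for
the group test's type-I error at α = 0.05, 200 replicates of n = 400 for
detection of a planted φ = 0.5 pair, and 100 cohorts of n = 5000 for
prevalence recovery under 8% missingness. These sizes give Monte-Carlo
error small enough for the binomial confidence bands used in the
assertions while keeping a full run on one CPU in the low tens of seconds.

## Known limitations

- No semantic phenotype similarity: a gene annotated with a child term of a
  disease-set term scores no overlap.
- Only simple amino-acid substitutions are positioned on proteins; splice,
  frameshift and structural variants flow through the score filter but
  cannot be conservation-checked or domain-localized.
- The association stage tests one phenotype at a time against gene strata;
  no multivariate modelling, no family-structure correction (each patient is
  treated as independent, although real cohorts contain relatives).
- The exact-test enumeration bounds make `fisher_exact()` refuse very large
  sparse tables; the group test then falls back to chi-square, whose
  small-expected-count behaviour is the reason Fisher was selected in the
  first place. In practice tables that large never have expected counts
  below 5.
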