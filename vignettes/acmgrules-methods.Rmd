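---
title: "Classification model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmgrules)
```

## The classification model

Germline variants are interpreted under the ACMG/AMP 2015 framework:
28 named evidence codes (PVS1, PS1–4, PM1–6, PP1–5 on the pathogenic
side; BA1, BS1–4, BP1–7 on the benign side), combined by fixed rules
into five categories — pathogenic (P), likely pathogenic (LP),
uncertain significance (VUS), likely benign (LB), benign (B).
`acmgrules` evaluates 19 of the 28 codes automatically from variant
annotations and a preprocessed reference bundle. The other nine (PS2,
PM3, PM6, PP1, PP4, BS3, BS4, BP2, BP5) need patient-level evidence —
de novo status, phasing, segregation, phenotype specificity,
functional assays on patient material — and enter only through the
external call file, where a user can also re-weight or disable any
automated code.

Three properties organise the design:

1. **Dynamic strength weighting.** Every applied code carries an
   integer strength on the ladder 1 = supporting, 2 = moderate,
   3 = strong, 4 = very strong, 5 = stand-alone, and rules may move a
   code along this ladder based on the quality of its evidence (e.g.
   PVS1 drops below very strong in LoF-tolerant genes; PP3 rises when
   independent predictors agree).
2. **Configuration, not constants.** Every threshold lives in a single
   `acmg_config` object (`default_engine_config()`), serialisable to
   JSON; rule code contains no hard-coded numbers, and classification
   is a pure function of (variant annotations, reference bundle,
   config).
3. **Transparency.** Every evidence call carries a human-readable
   rationale and provenance details (tool scores, PubMed IDs, domain
   ids, repeat coordinates), which survive into the output TSV.

## ClinVar review-status weights

ClinVar-derived evidence is weighted by its review status rather than
taken at face value: practice guidelines / expert panel = 5,
multiple submitters without conflicts = 3, single submitter = 2,
conflicting interpretations = 1. Statuses without assertion criteria
weigh 0 and are excluded everywhere — both at runtime (PP5/BP6) and in
the reference builders (PS1/PM5 index, PM1 domain counts). This is
why PP5 is the one pathogenic code that can reach stand-alone: an
expert-panel ClinVar assertion is treated as the pathogenic parallel
of BA1.

## LOEUF-stratified frequency cutoffs

Population-frequency criteria (PM2, BA1, BS1, part of BS2) use
cutoffs stratified by gene constraint. Genes are placed into five bins
by their gnomAD LOEUF score with upper bounds 0.35, 0.6, 1.0, 1.5 and
unbounded; bin membership is upper-bound inclusive. A gene absent
from the constraint table falls into the middle bin, so missing
constraint data implies neither maximal stringency nor maximal
leniency. The default per-bin allele-frequency cutoffs
(`default_loeuf_bins()`) scale from the conventional recommendations:
PM2 standard cutoffs 1e-6 … 2e-5 with the supporting cutoff at five
times the standard; BS1 supporting cutoffs 5e-4 … 1e-2 with the
standard cutoff at five times the supporting; BA1 cutoffs 5e-3 …
5e-2, capped at the conventional 5% stand-alone threshold in the two
least-constrained bins. The ordering `pm2_standard < pm2_supporting
<= bs1_supporting < bs1_standard <= ba1` is validated per bin, which
is exactly what makes PM2 and BA1 (and BA1 and BS1) mutually
exclusive by construction. When gnomAD and 1000 Genomes disagree, the
**larger** frequency governs: for rarity evidence this is the
conservative choice, and for commonness evidence it matches the
"exceeds the threshold in either database" reading.

A note on BS1: the natural reading of frequency evidence makes BS1 a
*high*-frequency code, so it is implemented as supporting between the
bin's supporting and standard cutoffs and strong at or above the
standard cutoff (below BA1). The alternative low-frequency reading
would duplicate PM2 and be incoherent for a benign criterion.

## The automated criteria and their tunables

All defaults below sit in `default_engine_config()`; units are allele
frequencies in [0, 1], counts in alleles or individuals, lengths in
nucleotides (nt) or amino acids (aa).

* **PVS1** — loss-of-function consequences (frameshift, stop gained,
  start loss, splice donor/acceptor). With more than one annotated
  transcript the LoF effect must appear in more than one of them.
  Variants in the last `final_exon_window` (default 50 nt) of a
  transcript's final coding exon are excluded: a truncation there is
  unlikely to trigger nonsense-mediated decay. The window length is a
  design choice — the criterion's source material leaves the "extreme
  3' end" undefined — and the check is strand-naive (the window is
  taken at the high-coordinate end), a documented simplification.
  Very strong requires gene LOEUF < 1 (`loeuf_full_strength`);
  otherwise strong. Splice-site variants additionally downgrade one
  rung per failed ABSplice check: below `splice_impact` (0.2) and
  below `splice_low` (0.05) — mirroring the ABSplice authors'
  high/medium tiers — so a splice variant with ABSplice 0.03 in a
  constrained gene lands at moderate.
* **PS1 / PM5** — lookup in the builder-produced index of pathogenic
  amino-acid substitutions. An identical nucleotide change is skipped
  (that evidence belongs to PP5, and using it here would let a ClinVar
  variant support itself). Same substitution via a different
  nucleotide change gives PS1; a different substitution at the same
  residue gives PM5. The strength is the reference record's review
  weight, capped at strong for PS1 and moderate for PM5
  (`ps1_pm5$ps1_cap`, `pm5_cap`) so that dynamic weighting cannot push
  a code past its nominal ACMG level.
* **PS3** — functional-study literature. Genomic key first, then
  (gene, protein change). Strength grows with the number of unique
  publications: 1 supporting, 2–4 moderate, 5+ strong
  (`ps3$supporting_max`, `moderate_max`) — a design default, as the
  tiering is not prescribed anywhere. PubMed IDs are attached to the
  call.
* **PS4** — GWAS association at the position, tiered on odds ratio
  and p-value: p < 5e-8 with OR >= 3 strong, OR >= 1.5 moderate;
  p < 1e-5 with OR > 1 supporting (design defaults following
  genome-wide significance conventions). Without a GWAS entry, TOPMed
  acts as a prevalence proxy: fewer than 5 alternate alleles, or 3–9
  homozygotes, gives supporting.
* **PM1** — overlap with a retained mutational-hotspot domain.
  Moderate by default; supporting when the domain has < 75%
  pathogenic and > 15% benign variants; strong when > 90% pathogenic
  and < 10% benign. When domains overlap, the first retained domain
  in table order is used (a deterministic tie-break; retained domains
  rarely overlap in practice).
* **PM2** — absent from gnomAD and 1000 Genomes, or below the bin's
  standard cutoff: moderate; between standard and supporting cutoffs:
  supporting.
* **PM4** — stop-loss or in-frame indel outside repeat-coding
  regions, by aa length: < 4 supporting, 4–10 moderate, > 10 strong.
  A stop-loss substitution has indel length 0 and counts as an
  extension event at the supporting minimum.
* **PP2** — missense in a gene from the missense-constrained list;
  supporting, raised to moderate when the recorded missense
  observed/expected ratio is below 10% (`pp2$oe_moderate`).
* **PP3 / BP4** — in-silico consensus. Each tool has a four-rung
  cutoff ladder per side (supporting/moderate/strong/very strong);
  defaults follow the published calibrations for REVEL, phyloP and
  GERP, the ABSplice authors' tiers, and conservative values for DANN
  (which has no published calibration — only its customary 0.99
  damaging convention). A side is disqualified when any tool reaches
  the opposite side's strong rung. The base strength is the maximum
  contribution; two or more tools tying at the maximum up-weight the
  call one rung (capped at very strong); a lone supporting-level tool
  is suppressed. One additional arbitration rule is ours: when both
  sides survive their own rules (e.g. one predictor moderately
  pathogenic, two conservation scores weakly benign), the evidence is
  mixed and **neither** code is applied. Without this rule the two
  codes could co-fire on one score vector, which would inject
  manufactured conflict into the combiner; with it, PP3/BP4 exclusion
  is a structural invariant (property-tested over random score
  vectors).
* **PP5 / BP6** — top ClinVar assertion of the matching polarity,
  at its review weight (stand-alone only from practice-guidelines /
  expert-panel assertions).
* **BA1 / BS1 / BS2** — as in the frequency section above. BS2
  branches on inheritance mode: autosomal recessive applies above
  `recessive_hom` homozygotes (default 2), strong at twice the
  threshold and moderate in between (the printed rule names only the
  strong condition; the moderate band is our reading of "above the
  threshold but below twice"); autosomal dominant only in constrained
  genes (LOEUF < `ad_loeuf_max` = 0.5), requiring the allele frequency
  at or below the bin's `bs2_af` ceiling and at least
  `dominant_allele` (5) alleles in every available healthy-population
  count; X-linked applies strong above `x_linked` (2) hemizygous males
  or homozygous females. Several applicable modes resolve to the
  strongest result.
* **BP1** — missense in a gene where truncation is the established
  mechanism (builder-derived list): supporting.
* **BP3** — in-frame indel (length divisible by 3; at least 3 nt
  unless stop loss) inside a repeat-coding interval: strong below
  15 nt, supporting from 15 to below 60 nt, nothing at 60 nt and
  beyond. Strong for the *shorter* indels is implemented exactly as
  specified by the method this package reproduces, although the
  direction is surprising; the tiers are config
  (`bp3$strong_below_nt`, `supporting_below_nt`).
* **BP7** — synonymous (checked first), intronic or intergenic
  variants with PhyloP < 7.367 and ABSplice < 0.05: supporting;
  additionally ABSplice < 0.01 and PhyloP < 0.21: strong. Both scores
  must be present; all four bounds are exclusive.

## Reference builders

Builders turn generic local tables (a ClinVar-like variant table,
domain intervals, repeat and coding BED files, a gene-constraint
table, GWAS/literature/final-exon tables) into the runtime bundle.
They are pure and deterministic — identical inputs give byte-identical
serialized bundles — and never touch the network. Percentage filters
follow their printed comparators literally (">50%" strict, "fewer
than 50%" keeps exactly 50%), each boundary unit-tested:

* hotspot domains need >= 5 positively-reviewed variants, <= 50% VUS,
  >= 50% pathogenic, <= 25% benign; conflicting-significance records
  are dropped before counting (they are neither pathogenic, benign
  nor uncertain for this purpose);
* the PP2 list keeps constraint-backed genes with missense OE <= 0.4,
  and otherwise falls back to ClinVar-derived filters (>= 1 benign and
  >= 1 pathogenic missense, <= 50% VUS, >= 5 variants, <= 25% of
  missense benign, >= 50% of missense pathogenic);
* the BP1 list discards genes with no pathogenic truncating variant,
  > 50% VUS, < 75% of pathogenic variants truncating, or > 25% of
  truncating variants benign. "Truncating" means frameshift or stop
  gained; splice-disrupting consequences are deliberately excluded.

Coordinates follow the two standard conventions: variant records are
1-based (VCF), all interval files 0-based half-open (BED). Interval
indexes are backed by IRanges and validated in tests against a
brute-force overlap scan.

## Combining evidence

The combiner extends the published combining tables with a pathogenic
stand-alone rung (used only by PP5) and embeds them in an ordered
procedure with two conflict checks:

1. if the summed strengths of applied codes reach the high tolerance
   threshold (`conflict$high` = 4) **on both polarities**, the variant
   is Uncertain (stage "high");
2. pathogenic rules; 3. benign rules;
4. if both sums reach the low threshold (`conflict$low` = 2), the
   variant is Uncertain (stage "low");
5. likely-pathogenic rules; 6. likely-benign rules; 7. otherwise
   Uncertain.

The conflict thresholds are design defaults: the two-pass scheme is
prescribed but its numbers are not; 4 ("strong-level evidence on both
sides") and 2 ("at least moderate-level evidence on both sides") are
the natural readings of "strong" and "weaker" conflicting signals.

Because dynamic weighting moves codes off their nominal rungs, the
tables are interpreted over effective strengths: a rule is met when
distinct applied codes can be assigned one-to-one to its required
rungs, each at or above its requirement. This "at least" reading is
forced by coherence — under exact-level matching two very strong codes
would classify as VUS, which no reading of the framework supports —
and it is what makes the category monotone under evidence upgrades.
The implementation decides rule satisfaction by a counting argument
(for every rung t, at least as many codes at >= t as requirements at
>= t, exact here because threshold sets are nested); the test suite
checks it against an independently written backtracking oracle by
exhaustive enumeration of all evidence profiles with up to six codes
on both polarities (8008 profiles), plus a monotonicity property:
adding a pathogenic supporting code never moves the category
benign-ward except by triggering a conflict stage.

## The synthetic fixture generator

`generate_fixtures()` builds 26 scenarios — one per automated code
plus combined and conflict scenarios — as mutually consistent files:
the PVS1 scenario writes a LOEUF-0.3 gene into the constraint table
and a two-transcript stop-gain into the variant JSON; the PM1
scenario writes a domain and the ClinVar-like records whose counts
give the intended fractions; and so on. Truth categories are fixed by
each scenario's expected combining outcome, *not* re-derived by the
engine, so the suite detects combining regressions as well as rule
regressions. Generation is a pure function of (scenarios,
n_per_scenario, seed); scenario loci are spaced 100 kb apart with a
small seeded jitter, and the same seed yields byte-identical files.

The generator emulates the *logical* structure of annotated variant
data: which fields each criterion consumes and where its decision
boundaries lie. It does not emulate distributional features of real
data — linkage between annotations, annotation errors or missingness
patterns, transcript-set complexity, multi-gene overlaps, or realistic
allele-frequency spectra. A green fixture suite therefore shows that
the rule logic, the builders and the combiner implement the intended
decision surfaces; it says nothing about concordance with expert
curation on real cohorts, which requires an expert-labelled truth set
supplied through `read_truth_tsv()`.

## Numerical and degenerate-input choices

* All score and frequency comparisons use the exclusive/inclusive
  bounds stated per criterion; sweep tests pin each printed cutoff.
* Missing annotation is NULL ("not observed"), never 0; a criterion
  whose inputs are missing returns no call rather than a weak one
  (except PM2, where absence from both frequency databases is itself
  the evidence).
* Variant identity is an exact string match on (chrom, pos, ref, alt)
  after stripping any "chr" prefix; indels are not left-aligned or
  normalized, so all inputs must share one normalization convention —
  a documented limitation.
* Multi-allelic records must be split upstream: one alternate allele
  per record.
* The JSON reader parses the file in one pass and converts records
  one at a time; memory scales with the parsed document, which is
  acceptable for the per-chromosome or per-panel files this engine
  targets (a 100,000-record file is exercised in the tests).
* Per-variant failures inside `classify_variants()` degrade to an
  Uncertain result carrying the error message; a malformed bundle
  fails at startup.
* The unbounded LOEUF bin serializes its `Inf` bound as a string and
  parses back; config round-trips are exact.

## Problem sizes used in the checks

The shipped checks run at desk scale: 26 fixture scenarios (one
replicate each; `n_per_scenario` scales them), exhaustive
combining-oracle enumeration over 8008 evidence profiles, sweep grids
of 11–801 points per cutoff, 1000 random interval queries against the
brute-force scan, and one 100,000-record IO pass. These sizes were
chosen to cover every decision boundary exhaustively while keeping
the whole suite fast on a single CPU.

## Known limitations

* No NMD-escape modelling beyond the final-exon window; no
  per-transcript PVS1 strength differentiation (all listed
  transcripts count toward the multi-transcript rule).
* No gene- or disease-specific rule specifications (ClinGen VCEP
  customisations); the config is global.
* No coverage/QC gating of population frequencies.
* Genome build is carried through, never interpreted; inputs from
  mixed builds will silently mismatch.
* The nine patient-data codes are honoured from the external call
  file but never inferred.
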