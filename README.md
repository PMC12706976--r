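# acmgrules

Automated germline variant classification under the ACMG/AMP 2015
framework, for clinical bioinformaticians and variant curators who
need high-throughput, transparent, rule-level-traceable
interpretation.

The ACMG/AMP guidelines define 28 evidence codes (PVS1, PS1–4,
PM1–6, PP1–5; BA1, BS1–4, BP1–7) combined into five categories —
pathogenic (P), likely pathogenic (LP), uncertain significance (VUS),
likely benign (LB), benign (B) — but no implementation algorithm.
`acmgrules` implements a complete rule engine:

* **19 automated codes** evaluated from annotated variants plus a
  preprocessed reference bundle; the 9 codes that need patient-level
  data (PS2, PM3, PM6, PP1, PP4, BS3, BS4, BP2, BP5) enter through an
  external call file that can also override or disable any automated
  code.
* **Dynamic strength weighting** on the ladder supporting (1) <
  moderate (2) < strong (3) < very strong (4) < stand-alone (5):
  e.g. PVS1 is very strong only when the gene's LOEUF is below 1;
  PP3 is up-weighted when independent in-silico predictors agree;
  ClinVar-derived evidence is weighted by review status (expert panel
  = 5 … conflicting interpretations = 1, no assertion criteria = 0 and
  excluded).
* **LOEUF-stratified frequency cutoffs**: PM2/BS1/BA1 thresholds are
  binned by gene constraint (five bins, upper bounds 0.35 / 0.6 /
  1.0 / 1.5 / unbounded), so constrained genes face stricter rarity
  requirements.
* **A modified combining procedure**: the published combining tables
  extended with a pathogenic stand-alone rung (expert-panel ClinVar
  assertions, mirroring BA1) and embedded in an ordered two-pass
  conflict check — strong two-sided evidence (both strength sums >= 4)
  and weaker two-sided evidence (both >= 2) are routed to VUS instead
  of being silently resolved by evaluation order.
* **Deterministic reference builders** that reproduce the published
  preprocessing filters (pathogenic amino-acid index, mutational
  hotspot domains, missense-constrained and truncating-mechanism gene
  lists, repeat∩coding intervals, literature and GWAS indexes) from
  generic local tables — no network access.
* **Benchmark metrics**: per-category (P/LP, B/LB, VUS) and per-code
  sensitivity, specificity, precision and F1 against an expert truth
  set, plus a synthetic fixture generator covering every automated
  code.

Every threshold lives in one serialisable configuration object
(`default_engine_config()`); classification is a pure function of
(variant, bundle, config). See `vignette("acmgrules-methods")` for the
model, parameter semantics and design decisions.

## Worked example

A stop-gain in a constrained deafness gene, seen in both annotated
transcripts, absent from population databases, with a high REVEL
score:

```r
library(acmgrules)

bundle <- reference_bundle(
  gene_constraint = data.frame(gene = "KCNQ4", loeuf = 0.28, mis_oe = NA))

v <- annotated_variant(
  chrom = "1", pos = 40819438, ref = "C", alt = "T", gene = "KCNQ4",
  consequences = "stop gained",
  transcripts = list(
    list(id = "NM_004700.4",    consequences = "stop gained", canonical = TRUE),
    list(id = "XM_011541123.2", consequences = "stop gained")),
  scores = list(revel = 0.81))

res <- classify_variants(list(v), bundle, log_every = 0)[[1]]
print(res)
#> <acmg_classification> 1:40819438:C:T: Pathogenic (path 8 / benign 0)
#>   PVS1:very_strong
#>   PM2:moderate
#>   PP3:moderate
```

PVS1 applies at very strong (LoF consequence in 2/2 transcripts,
LOEUF 0.28 < 1), PM2 at moderate (absent from gnomAD and
1000 Genomes), PP3 at moderate (REVEL 0.81 crosses its moderate
calibration tier); the combination 1 very strong + 2 moderate meets a
pathogenic rule, the pathogenic strength sum is 8, the benign sum 0,
and no conflict stage triggers. `write_classifications()` emits the
same result as one TSV row with per-code rationales:

```text
chrom pos      ... classification codes                                     pathogenic_score benign_score conflict_stage
1     40819438 ... Pathogenic     PVS1:very_strong,PM2:moderate,PP3:moderate 8                0            none
```

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/acmgrules.R", package = "acmgrules"))')
Rscript "$CLI" build-refs --clinvar clinvar.tsv --repeats repeats.bed \
    --coding coding.bed --constraint constraint.tsv --out refs/
Rscript "$CLI" classify --variants annotated.json --refs refs/ \
    [--external-calls calls.tsv] --out results.tsv
Rscript "$CLI" simulate --seed 1 --out fixtures/
Rscript "$CLI" validate --results results.tsv --truth truth.tsv \
    --out metrics.tsv
```

The annotated-variant JSON dialect is documented in
`inst/extdata/annotated_variant_schema.json`; the external call file
is a TSV (`chrom pos ref alt code strength rationale`, strength 0 =
disable); truth sets are TSVs with a category and an optional
`"CODE:strength|..."` code list per variant.

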