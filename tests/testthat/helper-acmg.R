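# Shared test helpers: compact variant/bundle constructors.

mk_variant <- function(chrom = "1", pos = 1000L, ref = "A", alt = "G",
                       gene = "GENE1", consequences = "missense variant",
                       ...) {
  annotated_variant(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene = gene, consequences = consequences, ...)
}

# A stop-gained variant seen in both of two transcripts (PVS1-eligible).
mk_lof_variant <- function(gene = "GENE1", pos = 1000L, scores = list(),
                           consequences = "stop gained", ...) {
  mk_variant(pos = pos, ref = "C", alt = "T", gene = gene,
             consequences = consequences,
             transcripts = list(
               list(id = "TX1", consequences = consequences,
                    canonical = TRUE),
               list(id = "TX2", consequences = consequences)),
             scores = scores, ...)
}

mk_bundle <- function(...) reference_bundle(...)

constraint_df <- function(gene, loeuf = NA_real_, mis_oe = NA_real_) {
  data.frame(gene = gene, loeuf = rep_len(loeuf, length(gene)),
             mis_oe = rep_len(mis_oe, length(gene)),
             stringsAsFactors = FALSE)
}

# ClinVar-like record rows with derived weight/key columns, as
# read_clinvar_table() would produce.
clinvar_df <- function(pos, sig, status, consequence = "missense variant",
                       aa = "", gene = "GENE1", chrom = "1",
                       ref = "A", alt = "G", id = NULL) {
  n <- max(length(pos), length(sig), length(status), length(consequence),
           length(aa), length(ref), length(alt))
  df <- data.frame(
    chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    gene = rep_len(gene, n),
    significance = normalize_significance(rep_len(sig, n)),
    review_status = rep_len(status, n),
    consequence = rep_len(consequence, n), aa_change = rep_len(aa, n),
    clinvar_id = if (is.null(id)) sprintf("CV%03d", seq_len(n))
    else rep_len(id, n),
    stringsAsFactors = FALSE)
  df$weight <- strength_from_review_status(df$review_status)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

# Bundle holding one repeat-coding interval (0-based half-open).
repeat_bundle <- function(chrom = "1", start = 900L, end = 2000L) {
  mk_bundle(repeat_coding = data.frame(chrom = chrom, start = start,
                                       end = end, stringsAsFactors = FALSE))
}

# Evidence list from a compact "PVS1:4,PM2:2" spec string.
mk_evidence <- function(spec) {
  if (!nzchar(spec)) return(list())
  parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":",
                    fixed = TRUE)
  lapply(parts, function(p)
    evidence_call(p[1], as.integer(p[2]), rationale = "test"))
}
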