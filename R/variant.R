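`%||%` <- function(a, b) if (is.null(a)) b else a

# Consequence vocabulary is matched after normalizing underscores to
# spaces, so "stop_gained" and "stop gained" are equivalent.
normalize_consequence <- function(x) {
  if (is.null(x) || length(x) == 0) return(character(0))
  x <- tolower(gsub("_", " ", as.character(x)))
  x[x == "start lost"] <- "start loss"
  x[x == "stop lost"] <- "stop loss"
  unique(trimws(x))
}

lof_consequences <- function() {
  c("frameshift variant", "stop gained", "start loss",
    "splice donor variant", "splice acceptor variant")
}

#' Parse a compact protein change string
#'
#' Accepts "R175H" or "p.R175H" (one-letter amino-acid codes, `*` and
#' `X` allowed for stops). Returns NULL when the string is missing or
#' not in this form.
#'
#' @param x character scalar.
#' @return list(pos, ref, alt) or NULL.
#' @export
parse_aa_change <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) return(NULL)
  x <- sub("^p\\.", "", trimws(x))
  m <- regmatches(x, regexec("^([A-Za-z\\*])([0-9]+)([A-Za-z\\*])$", x))[[1]]
  if (length(m) != 4) return(NULL)
  list(pos = as.integer(m[3]), ref = toupper(m[2]), alt = toupper(m[4]))
}

format_aa_change <- function(aa) {
  if (is.null(aa)) return(NA_character_)
  paste0(aa$ref, aa$pos, aa$alt)
}

#' Canonical variant key
#'
#' Exact string match on (chrom, pos, ref, alt) after stripping any
#' leading "chr"; indels are not left-aligned or otherwise normalized
#' (a documented limitation — inputs are expected to share one
#' normalization convention).
#'
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @return character key "chrom:pos:ref:alt".
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(sub("^chr", "", as.character(chrom)), as.integer(pos),
        toupper(as.character(ref)), toupper(as.character(alt)), sep = ":")
}

indel_length <- function(ref, alt) abs(nchar(ref) - nchar(alt))

infer_variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1 && la == 1) "SNV"
  else if (lr == la) "MNV"
  else if (lr == 1 && la > 1 && substr(alt, 1, 1) == ref) "insertion"
  else if (la == 1 && lr > 1 && substr(ref, 1, 1) == alt) "deletion"
  else "delins"
}

#' Construct an annotated variant
#'
#' The in-memory representation of one variant with every annotation the
#' evidence criteria consume: coordinates and alleles, per-transcript
#' consequences, protein change, gene symbol, ClinVar top assertion,
#' PubMed links, gene-disease inheritance records, population
#' frequencies and in-silico scores. Unknown annotations are NULL
#' ("not observed"), never 0.
#'
#' @param chrom chromosome name (any "chr" prefix is stripped for keys).
#' @param pos 1-based position (VCF convention).
#' @param ref,alt reference/alternate allele strings (one alt per record).
#' @param gene gene symbol or NULL.
#' @param consequences character vector of consequence terms on the
#'   canonical transcript.
#' @param transcripts list of lists with `id`, `consequences`,
#'   `aa_change` (compact string or NULL), `canonical` (logical).
#' @param aa_change compact protein change string ("R175H") or NULL.
#' @param clinvar list(significance, review_status, id) or NULL.
#' @param pubmed_ids,dbsnp_ids character vectors.
#' @param gene_disease list of lists with `disease` and `inheritance`
#'   (one of "AR", "AD", "XL", "other").
#' @param variant_type one of SNV/insertion/deletion/delins/MNV;
#'   inferred from the alleles when NULL.
#' @param freq named list of population frequencies/counts (see Details).
#' @param scores named list of in-silico scores: phylop, gerp, revel,
#'   dann, absplice (each numeric or NULL).
#'
#' @details `freq` fields: `gnomad_af`, `gnomad_ac`, `gnomad_hom_count`,
#' `gnomad_controls_ac`, `thousand_genomes_af`, `thousand_genomes_ac`,
#' `topmed_af`, `topmed_ac`, `topmed_hom_count`, `hemizygous_male_count`,
#' `homozygous_female_count`. Frequencies must lie in [0, 1]; counts are
#' non-negative.
#'
#' @return object of class `acmg_variant`.
#' @export
annotated_variant <- function(chrom, pos, ref, alt, gene = NULL,
                              consequences = character(0),
                              transcripts = list(), aa_change = NULL,
                              clinvar = NULL, pubmed_ids = character(0),
                              gene_disease = list(),
                              dbsnp_ids = character(0),
                              variant_type = NULL,
                              freq = list(), scores = list()) {
  if (is.null(chrom) || is.na(chrom) || !nzchar(chrom)) stop("chrom is required")
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a positive integer")
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!nzchar(ref) || !nzchar(alt)) stop("ref and alt are required")
  if (identical(ref, alt)) stop("ref and alt must differ")
  v <- list(
    chrom = sub("^chr", "", as.character(chrom)), pos = pos,
    ref = ref, alt = alt,
    variant_type = variant_type %||% infer_variant_type(ref, alt),
    gene = gene,
    consequences = normalize_consequence(consequences),
    transcripts = lapply(transcripts, function(t) list(
      id = t$id,
      consequences = normalize_consequence(t$consequences),
      aa_change = t$aa_change %||% NULL,
      canonical = isTRUE(t$canonical))),
    aa_change = aa_change,
    clinvar = clinvar,
    pubmed_ids = as.character(pubmed_ids %||% character(0)),
    gene_disease = gene_disease %||% list(),
    dbsnp_ids = as.character(dbsnp_ids %||% character(0)),
    freq = validate_frequencies(freq),
    scores = validate_scores(scores)
  )
  class(v) <- "acmg_variant"
  v
}

frequency_fields <- function() {
  c("gnomad_af", "gnomad_ac", "gnomad_hom_count", "gnomad_controls_ac",
    "thousand_genomes_af", "thousand_genomes_ac", "topmed_af",
    "topmed_ac", "topmed_hom_count", "hemizygous_male_count",
    "homozygous_female_count")
}

validate_frequencies <- function(freq) {
  freq <- freq %||% list()
  out <- setNames(vector("list", length(frequency_fields())),
                  frequency_fields())
  for (f in frequency_fields()) {
    x <- freq[[f]]
    if (is.null(x) || length(x) == 0 || is.na(x)) next
    x <- as.numeric(x)
    if (x < 0) stop("negative population value for ", f)
    if (grepl("_af$", f) && x > 1) stop("allele frequency > 1 for ", f)
    out[[f]] <- x
  }
  out
}

score_fields <- function() c("phylop", "gerp", "revel", "dann", "absplice")

validate_scores <- function(scores) {
  scores <- scores %||% list()
  out <- setNames(vector("list", length(score_fields())), score_fields())
  for (f in score_fields()) {
    x <- scores[[f]]
    if (is.null(x) || length(x) == 0 || is.na(x)) next
    x <- as.numeric(x)
    if (f %in% c("revel", "dann", "absplice") && (x < 0 || x > 1)) {
      stop(f, " score must lie in [0, 1]")
    }
    out[[f]] <- x
  }
  out
}

#' @export
print.acmg_variant <- function(x, ...) {
  cat(sprintf("<acmg_variant> %s %s (%s)\n",
              variant_key(x$chrom, x$pos, x$ref, x$alt),
              x$gene %||% "-", x$variant_type))
  if (length(x$consequences)) {
    cat("  consequences:", paste(x$consequences, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct an evidence call
#'
#' One ACMG code applied at an effective strength with a human-readable
#' rationale and provenance details (tool scores, PubMed IDs, domain
#' ids, ...).
#'
#' @param code ACMG code name.
#' @param strength integer strength 1..5.
#' @param rationale non-empty character rationale.
#' @param source "auto" or "manual".
#' @param details named list of provenance items.
#' @return object of class `acmg_evidence`.
#' @export
evidence_call <- function(code, strength, rationale, source = "auto",
                          details = list()) {
  stopifnot(code %in% acmg_codes()$code, strength %in% 1:5,
            is.character(rationale), nzchar(rationale),
            source %in% c("auto", "manual"))
  structure(list(code = code, strength = as.integer(strength),
                 rationale = rationale, source = source,
                 details = details),
            class = "acmg_evidence")
}

#' @export
print.acmg_evidence <- function(x, ...) {
  cat(sprintf("%s:%s [%s] %s\n", x$code, strength_name(x$strength),
              x$source, x$rationale))
  invisible(x)
}
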