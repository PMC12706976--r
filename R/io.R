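# Readers and writers: annotated-variant JSON dialect, external call
# TSV, truth-set TSV and the classification TSV output.

#' Read annotated variants from JSON
#'
#' The file holds a top-level object with a `variants` array; each
#' record carries the fields of [annotated_variant()] (see
#' `inst/extdata/annotated_variant_schema.json` for the dialect).
#' Optional fields default to null; unknown fields are ignored.
#' Records violating the core invariants (missing chrom/pos/ref/alt,
#' non-positive position, ref equal to alt) raise an error naming the
#' record index; malformed JSON is fatal.
#'
#' @param path JSON file path.
#' @return list of `acmg_variant` in file order.
#' @export
read_annotated_variants <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  recs <- doc$variants
  if (is.null(recs)) stop("no top-level 'variants' array in ", path)
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    out[[i]] <- tryCatch(
      variant_from_record(recs[[i]]),
      error = function(e) stop("variant record ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}

variant_from_record <- function(r) {
  null_ok <- function(x) if (is.null(x) || (length(x) == 1 && is.na(x))) NULL else x
  annotated_variant(
    chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
    gene = null_ok(r$gene),
    consequences = unlist(r$consequences) %||% character(0),
    transcripts = lapply(r$transcripts %||% list(), function(t) list(
      id = t$id, consequences = unlist(t$consequences) %||% character(0),
      aa_change = null_ok(t$aa_change), canonical = isTRUE(t$canonical))),
    aa_change = null_ok(r$aa_change),
    clinvar = null_ok(r$clinvar),
    pubmed_ids = as.character(unlist(r$pubmed_ids) %||% character(0)),
    gene_disease = lapply(r$gene_disease %||% list(), function(g) list(
      disease = g$disease %||% NA_character_,
      inheritance = g$inheritance %||% "other")),
    dbsnp_ids = as.character(unlist(r$dbsnp_ids) %||% character(0)),
    variant_type = null_ok(r$variant_type),
    freq = r$freq %||% list(),
    scores = r$scores %||% list())
}

#' Write annotated variants to JSON
#'
#' Inverse of [read_annotated_variants()]; deterministic byte output
#' for identical input.
#'
#' @param variants list of `acmg_variant`.
#' @param path output path.
#' @export
write_annotated_variants <- function(variants, path) {
  drop_null <- function(x) x[!vapply(x, is.null, TRUE)]
  recs <- lapply(variants, function(v) {
    r <- unclass(v)
    r$freq <- drop_null(r$freq)
    r$scores <- drop_null(r$scores)
    r$transcripts <- lapply(r$transcripts, drop_null)
    r[!vapply(r, function(x) is.null(x) ||
                (is.list(x) && length(x) == 0), TRUE)]
  })
  jsonlite::write_json(list(variants = recs), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = FALSE)
  invisible(path)
}

#' Read an external call file
#'
#' TSV with header columns chrom, pos, ref, alt, code, strength,
#' rationale. Manual-only codes are additive; automated codes are
#' overridden; strength 0 disables the code for that variant.
#'
#' @param path TSV path.
#' @return list of external calls: each a list with `key`, `code`,
#'   `strength`, `rationale`.
#' @export
read_external_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "code", "strength", "rationale")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("external call file missing column(s): ",
                         paste(miss, collapse = ", "))
  all_codes <- acmg_codes()$code
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    code <- df$code[i]
    if (!(code %in% all_codes)) {
      stop("external call row ", i, ": unknown ACMG code '", code, "'")
    }
    s <- suppressWarnings(as.integer(df$strength[i]))
    if (is.na(s) || s < 0L || s > 5L) {
      stop("external call row ", i, ": strength must be an integer 0-5")
    }
    out[[i]] <- list(
      key = variant_key(df$chrom[i], as.integer(df$pos[i]), df$ref[i],
                        df$alt[i]),
      code = code, strength = s, rationale = df$rationale[i])
  }
  out
}

#' Read a truth-set TSV
#'
#' Columns chrom, pos, ref, alt, category, codes. Categories normalize
#' case-insensitively to P/LP/VUS/LB/B; the codes field is a
#' "|"-separated list of CODE:strength_name entries (strength optional)
#' and may be blank.
#'
#' @param path TSV path.
#' @return list of truth records: each a list with `key`, `category`,
#'   `codes` (data.frame code/strength, strength NA when unstated).
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "category", "codes")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("truth file missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- vector("list", nrow(df))
  all_codes <- acmg_codes()$code
  for (i in seq_len(nrow(df))) {
    cat_norm <- normalize_significance(df$category[i])
    if (is.na(cat_norm) || cat_norm == "conflicting") {
      stop("truth row ", i, ": unknown category '", df$category[i], "'")
    }
    codes <- data.frame(code = character(0), strength = integer(0),
                        stringsAsFactors = FALSE)
    if (nzchar(trimws(df$codes[i] %||% ""))) {
      parts <- strsplit(trimws(df$codes[i]), "|", fixed = TRUE)[[1]]
      cs <- strsplit(parts, ":", fixed = TRUE)
      codes <- data.frame(
        code = vapply(cs, `[[`, "", 1L),
        strength = vapply(cs, function(x)
          if (length(x) > 1) strength_value(x[2]) else NA_integer_, 1L),
        stringsAsFactors = FALSE)
      bad <- setdiff(codes$code, all_codes)
      if (length(bad)) stop("truth row ", i, ": unknown code(s) ",
                            paste(bad, collapse = ", "))
    }
    out[[i]] <- list(
      key = variant_key(df$chrom[i], as.integer(df$pos[i]), df$ref[i],
                        df$alt[i]),
      category = cat_norm, codes = codes)
  }
  out
}

#' Write classification results to TSV
#'
#' Fixed column order: chrom, pos, ref, alt, gene, classification,
#' codes (comma-joined "CODE:strength_name"), pathogenic_score,
#' benign_score, conflict_stage, rationales (semicolon-joined
#' "CODE=text"). The header row is always present and byte output is
#' deterministic for identical inputs.
#'
#' @param results list of `acmg_classification`.
#' @param path output TSV path.
#' @export
write_classifications <- function(results, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c("chrom", "pos", "ref", "alt", "gene", "classification",
                    "codes", "pathogenic_score", "benign_score",
                    "conflict_stage", "rationales"), collapse = "\t")
  writeLines(header, con, sep = "\n")
  for (res in results) {
    ev <- res$evidence
    ord <- order(vapply(ev, function(e) match(e$code, acmg_codes()$code), 1L))
    ev <- ev[ord]
    codes <- paste(vapply(ev, format_evidence, ""), collapse = ",")
    rationales <- paste(vapply(ev, function(e)
      paste0(e$code, "=", gsub("[\t\n;]", " ", e$rationale)), ""),
      collapse = ";")
    line <- paste(c(res$chrom, res$pos, res$ref, res$alt,
                    res$gene %||% "", unname(category_labels()[res$category]),
                    codes, res$pathogenic_score, res$benign_score,
                    res$conflict_stage, rationales), collapse = "\t")
    writeLines(line, con, sep = "\n")
  }
  invisible(path)
}

#' Re-read a classification TSV
#'
#' Parses the output of [write_classifications()] back into a
#' data.frame, with the evidence codes split out as a list column of
#' data.frames (code, strength).
#'
#' @param path TSV path.
#' @return data.frame with one row per variant.
#' @export
read_classifications <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$pos <- as.integer(df$pos)
  df$pathogenic_score <- as.integer(df$pathogenic_score)
  df$benign_score <- as.integer(df$benign_score)
  labels <- category_labels()
  df$category <- names(labels)[match(df$classification, labels)]
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df$code_calls <- lapply(df$codes, function(s) {
    if (!nzchar(s)) {
      return(data.frame(code = character(0), strength = integer(0),
                        stringsAsFactors = FALSE))
    }
    cs <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(code = vapply(cs, `[[`, "", 1L),
               strength = strength_value(vapply(cs, `[[`, "", 2L)),
               stringsAsFactors = FALSE)
  })
  df
}
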