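# Reference builders: deterministic transforms from generic local tables
# (ClinVar-like variant table, domain/repeat/coding BED, constraint,
# GWAS, literature, final-coding-exon tables) into the runtime
# reference bundle. No network access; byte-identical output for
# identical inputs.

#' Read a ClinVar-like variant table
#'
#' TSV columns: chrom, pos, ref, alt, gene, significance, review_status,
#' consequence (comma-separated terms), aa_change (compact, may be
#' blank), clinvar_id. A ClinVar-style VCF (INFO tags CLNSIG,
#' CLNREVSTAT, GENEINFO, MC) is accepted when `path` ends in .vcf and
#' the vcfR package is installed.
#'
#' @param path file path.
#' @return data.frame of ClinVar-like records with a `weight` column
#'   derived from the review status.
#' @param review_weights named map as [default_review_weights()].
#' @export
read_clinvar_table <- function(path, review_weights = default_review_weights()) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    df <- read_clinvar_vcf(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("chrom", "pos", "ref", "alt", "gene", "significance",
              "review_status", "consequence", "aa_change", "clinvar_id")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("ClinVar-like table missing column(s): ",
                           paste(miss, collapse = ", "))
    df$pos <- as.integer(df$pos)
  }
  if (any(!nzchar(df$significance)) || any(!nzchar(df$review_status))) {
    stop("significance and review_status must be non-empty")
  }
  df$significance <- normalize_significance(df$significance)
  df$weight <- strength_from_review_status(df$review_status, review_weights)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

read_clinvar_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading ClinVar-like VCF requires the vcfR package; ",
         "provide a TSV otherwise")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info1 <- function(tag) {
    x <- vcfR::extract.info(v, element = tag)
    ifelse(is.na(x), "", gsub("_", " ", x))
  }
  gene <- sub(":.*$", "", vcfR::extract.info(v, element = "GENEINFO"))
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, gene = ifelse(is.na(gene), "", gene),
    significance = info1("CLNSIG"), review_status = info1("CLNREVSTAT"),
    consequence = gsub("\\|", ",", sub("^SO:[0-9]+\\|", "",
                                       info1("MC"))),
    aa_change = if ("AACHANGE" %in% vcfR::vcf_field_names(v, tag = "INFO")$ID)
      info1("AACHANGE") else "",
    clinvar_id = fix$ID, stringsAsFactors = FALSE
  )
}

#' Read a BED file of 0-based half-open intervals
#' @param path BED path (first three columns used).
#' @return data.frame(chrom, start, end).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t")
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) stop("non-numeric BED coordinates in ", path)
  df
}

#' Build the pathogenic amino-acid substitution index (PS1/PM5)
#'
#' Keeps pathogenic / likely-pathogenic records with a review weight of
#' at least supporting (>= 1) and a parseable protein change, keyed by
#' gene and residue position.
#'
#' @param records ClinVar-like data.frame (see [read_clinvar_table()]).
#' @return data.frame(gene, residue, ref_aa, alt_aa, key, weight,
#'   clinvar_id).
#' @export
build_pathogenic_aa_index <- function(records) {
  keep <- records$significance %in% c("P", "LP") & records$weight >= 1L &
    nzchar(records$aa_change %||% "")
  rec <- records[which(keep), , drop = FALSE]
  parsed <- lapply(rec$aa_change, parse_aa_change)
  ok <- !vapply(parsed, is.null, TRUE)
  rec <- rec[ok, , drop = FALSE]; parsed <- parsed[ok]
  data.frame(
    gene = rec$gene,
    residue = vapply(parsed, function(p) p$pos, 1L),
    ref_aa = vapply(parsed, function(p) p$ref, ""),
    alt_aa = vapply(parsed, function(p) p$alt, ""),
    key = rec$key,
    weight = rec$weight,
    clinvar_id = rec$clinvar_id,
    stringsAsFactors = FALSE)
}

#' Build the ClinVar assertion index
#'
#' Variant key -> (significance, review weight, id) for records with
#' positive review weight.
#'
#' @param records ClinVar-like data.frame.
#' @return data.frame(key, significance, weight, clinvar_id).
#' @export
build_clinvar_assertion_index <- function(records) {
  rec <- records[records$weight >= 1L, , drop = FALSE]
  rec <- rec[!duplicated(rec$key), , drop = FALSE]
  data.frame(key = rec$key, significance = rec$significance,
             weight = rec$weight, clinvar_id = rec$clinvar_id,
             stringsAsFactors = FALSE)
}

#' Build mutational hotspot domains (PM1)
#'
#' Counts positively-reviewed (weight >= 1) P/LP, B/LB and VUS records
#' overlapping each candidate domain; records with conflicting
#' significance are dropped before counting. A domain survives only if
#' it holds at least five variants, at most 50% VUS, at least 50%
#' pathogenic and at most 25% benign (printed comparators applied
#' literally: ">50%" strict, "fewer than 50%" keeps exactly 50%).
#'
#' @param records ClinVar-like data.frame.
#' @param domains data.frame(id, chrom, start, end) — 0-based half-open.
#' @return data.frame of surviving domains with counts and fractions.
#' @export
build_hotspot_domains <- function(records, domains) {
  rec <- records[records$weight >= 1L, , drop = FALSE]
  bucket <- ifelse(rec$significance %in% c("P", "LP"), "path",
            ifelse(rec$significance %in% c("B", "LB"), "benign",
            ifelse(rec$significance == "VUS", "vus", NA)))
  rec <- rec[!is.na(bucket), , drop = FALSE]
  bucket <- bucket[!is.na(bucket)]
  out <- domains
  out$n_path <- out$n_benign <- out$n_vus <- 0L
  if (nrow(rec)) {
    idx <- interval_index(domains)
    for (i in seq_len(nrow(rec))) {
      hits <- interval_overlaps(idx, rec$chrom[i], rec$pos[i],
                                width = max(nchar(rec$ref[i]), 1L))
      if (!nrow(hits)) next
      j <- match(hits$id, out$id)
      col <- paste0("n_", bucket[i])
      out[[col]][j] <- out[[col]][j] + 1L
    }
  }
  out$n_total <- out$n_path + out$n_benign + out$n_vus
  out$path_frac <- ifelse(out$n_total > 0, out$n_path / out$n_total, 0)
  out$benign_frac <- ifelse(out$n_total > 0, out$n_benign / out$n_total, 0)
  out$vus_frac <- ifelse(out$n_total > 0, out$n_vus / out$n_total, 0)
  keep <- out$n_total >= 5L &          # fewer than five variants -> excluded
    out$vus_frac <= 0.5 &              # more than half VUS -> excluded
    out$path_frac >= 0.5 &             # fewer than 50% pathogenic -> excluded
    out$benign_frac <= 0.25            # more than 25% benign -> excluded
  res <- out[keep, c("id", "chrom", "start", "end", "n_total", "n_path",
                     "n_benign", "n_vus", "path_frac", "benign_frac",
                     "vus_frac")]
  rownames(res) <- NULL
  res
}

is_missense <- function(consequence) grepl("missense", consequence)
is_truncating <- function(consequence) {
  # "truncating" = frameshift or stop gained; splice-disrupting terms
  # are deliberately excluded.
  grepl("frameshift|stop gained|stop_gained", consequence)
}

#' Build the missense-constrained gene list (PP2)
#'
#' A gene is kept if its gnomAD missense observed/expected ratio is
#' available and at most 0.4. Genes without constraint data fall back to
#' ClinVar-derived filters: at least one benign and one pathogenic
#' missense variant, at most 50% VUS, at least five variants total, at
#' most 25% of missense variants benign and at least 50% of missense
#' variants pathogenic.
#'
#' @param records ClinVar-like data.frame.
#' @param constraint data.frame(gene, loeuf, mis_oe).
#' @return named numeric vector: gene -> missense OE (NA when kept via
#'   the ClinVar fallback).
#' @export
build_pp2_gene_list <- function(records, constraint) {
  genes <- unique(c(records$gene[nzchar(records$gene %||% "")],
                    constraint$gene))
  genes <- genes[nzchar(genes)]
  oe_of <- function(g) {
    i <- match(g, constraint$gene)
    if (is.na(i)) NA_real_ else constraint$mis_oe[i]
  }
  out <- numeric(0)
  for (g in genes) {
    oe <- oe_of(g)
    if (!is.na(oe)) {
      if (oe <= 0.4) out[g] <- oe      # excluded if OE greater than 0.4
      next
    }
    rec <- records[records$gene == g & records$weight >= 1L, , drop = FALSE]
    if (!nrow(rec)) next
    mis <- is_missense(rec$consequence)
    n_path_mis <- sum(mis & rec$significance %in% c("P", "LP"))
    n_ben_mis <- sum(mis & rec$significance %in% c("B", "LB"))
    n_mis <- sum(mis)
    n_vus <- sum(rec$significance == "VUS")
    n_tot <- sum(rec$significance %in% c("P", "LP", "B", "LB", "VUS"))
    keep <- n_ben_mis >= 1L && n_path_mis >= 1L &&
      n_vus <= 0.5 * n_tot &&          # more than 50% VUS -> discarded
      n_tot >= 5L &&                   # fewer than five variants -> discarded
      n_ben_mis <= 0.25 * n_mis &&     # benign missense more than 25% -> discarded
      n_path_mis >= 0.5 * n_mis        # pathogenic missense less than 50% -> discarded
    if (keep) out[g] <- NA_real_
  }
  out
}

#' Build the truncating-mechanism gene list (BP1)
#'
#' A gene survives unless any of the four discard rules fire: fewer than
#' one pathogenic truncating variant; more than 50% of its variants
#' VUS; less than 75% of its pathogenic variants truncating; or more
#' than 25% of its truncating variants benign.
#'
#' @param records ClinVar-like data.frame.
#' @return character vector of retained gene symbols.
#' @export
build_bp1_gene_list <- function(records) {
  rec <- records[records$weight >= 1L & nzchar(records$gene %||% ""), ,
                 drop = FALSE]
  out <- character(0)
  for (g in unique(rec$gene)) {
    r <- rec[rec$gene == g, , drop = FALSE]
    trunc <- is_truncating(r$consequence)
    path <- r$significance %in% c("P", "LP")
    ben <- r$significance %in% c("B", "LB")
    n_path_trunc <- sum(trunc & path)
    if (n_path_trunc < 1L) next
    n <- sum(r$significance %in% c("P", "LP", "B", "LB", "VUS"))
    if (sum(r$significance == "VUS") > 0.5 * n) next
    if (sum(path) > 0 && n_path_trunc < 0.75 * sum(path)) next
    if (sum(trunc) > 0 && sum(trunc & ben) > 0.25 * sum(trunc)) next
    out <- c(out, g)
  }
  sort(out)
}

#' Intersect repeat and coding intervals (PM4/BP3)
#'
#' Pairwise intersection of the two BED sets, merged into disjoint
#' sorted intervals — the coding-repeat regions where in-frame indels
#' are down-ranked (PM4) or treated as benign evidence (BP3).
#'
#' @param repeats,coding data.frame(chrom, start, end), 0-based
#'   half-open.
#' @return data.frame(chrom, start, end) of disjoint sorted intervals.
#' @export
build_repeat_coding_intervals <- function(repeats, coding) {
  intersect_interval_sets(repeats, coding)
}

#' Build the literature index (PS3)
#'
#' Two deduplicated maps of PubMed IDs: genomic variant key -> PMIDs,
#' and (gene, protein change) -> PMIDs.
#'
#' @param rows data.frame with columns `type` ("genomic"/"protein"),
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `protein_change`, `pmid`.
#' @return list(genomic = named list, protein = named list).
#' @export
build_literature_index <- function(rows) {
  gmap <- list(); pmap <- list()
  for (i in seq_len(nrow(rows))) {
    pmid <- as.character(rows$pmid[i])
    if (identical(rows$type[i], "genomic")) {
      k <- variant_key(rows$chrom[i], rows$pos[i], rows$ref[i], rows$alt[i])
      gmap[[k]] <- union(gmap[[k]], pmid)
    } else if (identical(rows$type[i], "protein")) {
      aa <- parse_aa_change(rows$protein_change[i])
      if (is.null(aa)) next
      k <- paste(rows$gene[i], format_aa_change(aa), sep = "|")
      pmap[[k]] <- union(pmap[[k]], pmid)
    } else {
      stop("literature row ", i, ": unknown type '", rows$type[i], "'")
    }
  }
  list(genomic = gmap, protein = pmap)
}

#' Build the GWAS association index (PS4)
#'
#' @param rows data.frame(chrom, pos, or, pvalue).
#' @return named list: "chrom:pos" -> list(or, pvalue).
#' @export
build_gwas_index <- function(rows) {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    k <- paste(sub("^chr", "", rows$chrom[i]), as.integer(rows$pos[i]),
               sep = ":")
    out[[k]] <- list(or = as.numeric(rows$or[i]),
                     pvalue = as.numeric(rows$pvalue[i]))
  }
  out
}

#' Assemble a reference bundle
#'
#' Bundles every preprocessed lookup structure the criteria consume.
#' All interval members are wrapped in immutable interval indexes at
#' assembly time; hotspot-domain invariants are re-checked.
#'
#' @param pathogenic_aa output of [build_pathogenic_aa_index()].
#' @param clinvar_assertions output of [build_clinvar_assertion_index()].
#' @param hotspot_domains output of [build_hotspot_domains()].
#' @param literature output of [build_literature_index()].
#' @param gwas output of [build_gwas_index()].
#' @param repeat_coding output of [build_repeat_coding_intervals()].
#' @param pp2_genes output of [build_pp2_gene_list()].
#' @param bp1_genes output of [build_bp1_gene_list()].
#' @param gene_constraint data.frame(gene, loeuf, mis_oe).
#' @param final_coding_exons data.frame(transcript, chrom, start, end)
#'   — the last coding exon per transcript, 0-based half-open.
#' @return object of class `acmg_reference_bundle`.
#' @export
reference_bundle <- function(pathogenic_aa = NULL, clinvar_assertions = NULL,
                             hotspot_domains = NULL, literature = NULL,
                             gwas = NULL, repeat_coding = NULL,
                             pp2_genes = NULL, bp1_genes = NULL,
                             gene_constraint = NULL,
                             final_coding_exons = NULL) {
  empty_df <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  pathogenic_aa <- pathogenic_aa %||% empty_df(
    gene = character(0), residue = integer(0), ref_aa = character(0),
    alt_aa = character(0), key = character(0), weight = integer(0),
    clinvar_id = character(0))
  clinvar_assertions <- clinvar_assertions %||% empty_df(
    key = character(0), significance = character(0), weight = integer(0),
    clinvar_id = character(0))
  hotspot_domains <- hotspot_domains %||% empty_df(
    id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), n_total = integer(0), n_path = integer(0),
    n_benign = integer(0), n_vus = integer(0), path_frac = numeric(0),
    benign_frac = numeric(0), vus_frac = numeric(0))
  check_hotspot_invariants(hotspot_domains)
  repeat_coding <- repeat_coding %||% empty_df(
    chrom = character(0), start = integer(0), end = integer(0))
  gene_constraint <- gene_constraint %||% empty_df(
    gene = character(0), loeuf = numeric(0), mis_oe = numeric(0))
  final_coding_exons <- final_coding_exons %||% empty_df(
    transcript = character(0), chrom = character(0), start = integer(0),
    end = integer(0))
  b <- list(
    pathogenic_aa = pathogenic_aa,
    clinvar_assertions = clinvar_assertions,
    hotspot_domains = hotspot_domains,
    hotspot_index = interval_index(hotspot_domains),
    literature = literature %||% list(genomic = list(), protein = list()),
    gwas = gwas %||% list(),
    repeat_coding = repeat_coding,
    repeat_index = interval_index(repeat_coding),
    pp2_genes = pp2_genes %||% stats::setNames(numeric(0), character(0)),
    bp1_genes = bp1_genes %||% character(0),
    gene_constraint = gene_constraint,
    final_coding_exons = final_coding_exons
  )
  class(b) <- "acmg_reference_bundle"
  b
}

check_hotspot_invariants <- function(d) {
  if (!nrow(d)) return(invisible(TRUE))
  ok <- d$n_total == d$n_path + d$n_benign + d$n_vus & d$n_total >= 5L &
    d$path_frac >= 0.5 & d$benign_frac <= 0.25 & d$vus_frac <= 0.5
  if (!all(ok)) stop("hotspot domain invariants violated for id(s): ",
                     paste(d$id[!ok], collapse = ", "))
  invisible(TRUE)
}

gene_loeuf <- function(bundle, gene) {
  if (is.null(gene)) return(NA_real_)
  i <- match(gene, bundle$gene_constraint$gene)
  if (is.na(i)) NA_real_ else bundle$gene_constraint$loeuf[i]
}

#' @export
print.acmg_reference_bundle <- function(x, ...) {
  cat("<acmg_reference_bundle>\n")
  cat(sprintf("  pathogenic aa records: %d\n", nrow(x$pathogenic_aa)))
  cat(sprintf("  hotspot domains: %d\n", nrow(x$hotspot_domains)))
  cat(sprintf("  repeat-coding intervals: %d\n", nrow(x$repeat_coding)))
  cat(sprintf("  PP2 genes: %d; BP1 genes: %d; constraint genes: %d\n",
              length(x$pp2_genes), length(x$bp1_genes),
              nrow(x$gene_constraint)))
  invisible(x)
}

#' Save / load a reference bundle as a directory of text files
#'
#' One TSV or JSON file per member plus a `manifest.json` recording the
#' package version and an md5 checksum of every file, so a bundle is
#' reproducible and auditable. Saving the same bundle twice yields
#' byte-identical files.
#'
#' @param bundle an `acmg_reference_bundle`.
#' @param dir directory path (created if absent).
#' @return `load_reference_bundle()` returns the bundle.
#' @export
save_reference_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(bundle$pathogenic_aa, "pathogenic_aa.tsv")
  wtsv(bundle$clinvar_assertions, "clinvar_assertions.tsv")
  wtsv(bundle$hotspot_domains, "hotspot_domains.tsv")
  wtsv(bundle$repeat_coding, "repeat_coding.tsv")
  wtsv(bundle$gene_constraint, "gene_constraint.tsv")
  wtsv(bundle$final_coding_exons, "final_coding_exons.tsv")
  jsonlite::write_json(list(pp2_genes = as.list(bundle$pp2_genes),
                            bp1_genes = bundle$bp1_genes,
                            literature = bundle$literature,
                            gwas = bundle$gwas),
                       file.path(dir, "lookups.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  files <- c("pathogenic_aa.tsv", "clinvar_assertions.tsv",
             "hotspot_domains.tsv", "repeat_coding.tsv",
             "gene_constraint.tsv", "final_coding_exons.tsv",
             "lookups.json")
  manifest <- list(
    format = "acmgrules_reference_bundle",
    version = as.character(utils::packageVersion("acmgrules")),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_reference_bundle
#' @export
load_reference_bundle <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("not a reference bundle (no manifest): ", dir)
  rtsv <- function(name, classes) {
    utils::read.delim(file.path(dir, name), stringsAsFactors = FALSE,
                      colClasses = classes)
  }
  lookups <- jsonlite::fromJSON(file.path(dir, "lookups.json"),
                                simplifyVector = FALSE)
  pp2 <- vapply(lookups$pp2_genes, function(x)
    if (is.null(x)) NA_real_ else as.numeric(x), 1.0)
  lit <- list(
    genomic = lapply(lookups$literature$genomic, function(x)
      as.character(unlist(x))),
    protein = lapply(lookups$literature$protein, function(x)
      as.character(unlist(x))))
  gwas <- lapply(lookups$gwas, function(x)
    list(or = as.numeric(x$or), pvalue = as.numeric(x$pvalue)))
  reference_bundle(
    pathogenic_aa = rtsv("pathogenic_aa.tsv",
                         c("character", "integer", "character", "character",
                           "character", "integer", "character")),
    clinvar_assertions = rtsv("clinvar_assertions.tsv",
                              c("character", "character", "integer",
                                "character")),
    hotspot_domains = rtsv("hotspot_domains.tsv",
                           c("character", "character", "integer", "integer",
                             "integer", "integer", "integer", "integer",
                             "numeric", "numeric", "numeric")),
    literature = lit,
    gwas = gwas,
    repeat_coding = rtsv("repeat_coding.tsv",
                         c("character", "integer", "integer")),
    pp2_genes = pp2,
    bp1_genes = as.character(unlist(lookups$bp1_genes)),
    gene_constraint = rtsv("gene_constraint.tsv",
                           c("character", "numeric", "numeric")),
    final_coding_exons = rtsv("final_coding_exons.tsv",
                              c("character", "character", "integer",
                                "integer")))
}
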