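# Synthetic fixture generator: mutually consistent annotated variants,
# reference tables and truth records, one scenario per automated code
# plus combined and conflict scenarios. Truth labels are fixed by each
# scenario's expected combining outcome (not re-derived by the engine),
# so the suite also detects combining regressions.

#' The default fixture scenario list
#'
#' Every automated code appears in at least one scenario; combined
#' scenarios exercise the P/LP/B/LB outcomes and the two conflict
#' stages. Each entry records the scenario name, the codes it is
#' designed to trigger with their expected strengths, and the expected
#' final category given those codes and the default combining
#' procedure.
#'
#' @return data.frame(name, codes, category); `codes` uses the truth
#'   "CODE:strength|..." syntax.
#' @export
fixture_scenarios <- function() {
  s <- function(name, codes, category) {
    data.frame(name = name, codes = codes, category = category,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    s("pvs1",          "PVS1:very_strong",                 "VUS"),
    s("ps1",           "PS1:strong",                       "VUS"),
    s("pm5",           "PM5:moderate",                     "VUS"),
    s("ps3",           "PS3:strong",                       "VUS"),
    s("ps4_gwas",      "PS4:strong",                       "VUS"),
    s("ps4_topmed",    "PS4:supporting",                   "VUS"),
    s("pm1",           "PM1:moderate",                     "VUS"),
    s("pm2",           "PM2:moderate",                     "VUS"),
    s("pm4",           "PM4:supporting",                   "VUS"),
    s("pp2",           "PP2:supporting",                   "VUS"),
    s("pp3",           "PP3:moderate",                     "VUS"),
    s("pp5",           "PP5:stand_alone",                  "P"),
    s("ba1",           "BA1:stand_alone",                  "B"),
    s("bs1",           "BS1:strong",                       "VUS"),
    s("bs2",           "BS2:strong",                       "VUS"),
    s("bp1",           "BP1:supporting",                   "VUS"),
    s("bp3",           "BP3:strong",                       "VUS"),
    s("bp4",           "BP4:moderate",                     "VUS"),
    s("bp6",           "BP6:stand_alone",                  "B"),
    s("bp7",           "BP7:supporting",                   "VUS"),
    s("bp7_strong",    "BP7:strong|BP4:moderate",          "LB"),
    s("combined_lp",   "PVS1:very_strong|PM2:moderate",    "LP"),
    s("combined_p",    "PVS1:very_strong|PM2:moderate|PP3:moderate", "P"),
    s("combined_b",    "BS1:strong|BS2:strong",            "B"),
    s("conflict_high", "PVS1:very_strong|BA1:stand_alone", "VUS"),
    s("conflict_low",  "PM2:moderate|BP4:moderate",        "VUS")
  ))
}

#' Generate a mutually consistent synthetic fixture suite
#'
#' Produces annotated variants, the reference tables that make each
#' scenario's target codes fire at the expected strength, the built
#' reference bundle, and a truth set whose categories follow the
#' expected combining outcome. Generation is a pure function of
#' (scenarios, n_per_scenario, seed): the same seed yields
#' byte-identical files.
#'
#' @param seed integer seed driving the (small) positional jitter.
#' @param n_per_scenario replicates per scenario, at distinct loci.
#' @param scenarios scenario table as [fixture_scenarios()].
#' @param out_dir when non-NULL, writes `variants.json`, `truth.tsv`
#'   and the bundle directory `refs/` under it.
#' @return list with `variants` (list of `acmg_variant`), `bundle`,
#'   `truth` (truth-record list), `scenarios`, and `paths` (when
#'   written).
#' @export
generate_fixtures <- function(seed = 1L, n_per_scenario = 1L,
                              scenarios = fixture_scenarios(),
                              out_dir = NULL) {
  set.seed(as.integer(seed))
  acc <- new.env(parent = emptyenv())
  acc$variants <- list(); acc$truth <- list()
  acc$clinvar <- list(); acc$constraint <- list(); acc$domains <- list()
  acc$repeats <- list(); acc$coding <- list(); acc$gwas <- list()
  acc$literature <- list(); acc$final_exons <- list()
  idx <- 0L
  for (i in seq_len(nrow(scenarios))) {
    for (j in seq_len(n_per_scenario)) {
      idx <- idx + 1L
      build_fixture_scenario(acc, scenarios$name[i], scenarios$codes[i],
                             scenarios$category[i], i, j,
                             jitter = sample.int(200L, 1L))
    }
  }
  bind <- function(x, proto) {
    if (length(x)) {
      df <- do.call(rbind, x); rownames(df) <- NULL; df
    } else proto
  }
  clinvar <- bind(acc$clinvar, data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), gene = character(0), significance = character(0),
    review_status = character(0), consequence = character(0),
    aa_change = character(0), clinvar_id = character(0),
    stringsAsFactors = FALSE))
  clinvar$significance <- normalize_significance(clinvar$significance)
  clinvar$weight <- strength_from_review_status(clinvar$review_status)
  clinvar$key <- variant_key(clinvar$chrom, clinvar$pos, clinvar$ref,
                             clinvar$alt)
  constraint <- bind(acc$constraint, data.frame(
    gene = character(0), loeuf = numeric(0), mis_oe = numeric(0),
    stringsAsFactors = FALSE))
  domains <- bind(acc$domains, data.frame(
    id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), stringsAsFactors = FALSE))
  repeats <- bind(acc$repeats, data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    stringsAsFactors = FALSE))
  coding <- bind(acc$coding, repeats[0, ])
  gwas <- bind(acc$gwas, data.frame(
    chrom = character(0), pos = integer(0), or = numeric(0),
    pvalue = numeric(0), stringsAsFactors = FALSE))
  literature <- bind(acc$literature, data.frame(
    type = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), gene = character(0),
    protein_change = character(0), pmid = character(0),
    stringsAsFactors = FALSE))
  final_exons <- bind(acc$final_exons, data.frame(
    transcript = character(0), chrom = character(0), start = integer(0),
    end = integer(0), stringsAsFactors = FALSE))
  bundle <- reference_bundle(
    pathogenic_aa = build_pathogenic_aa_index(clinvar),
    clinvar_assertions = build_clinvar_assertion_index(clinvar),
    hotspot_domains = build_hotspot_domains(clinvar, domains),
    literature = build_literature_index(literature),
    gwas = build_gwas_index(gwas),
    repeat_coding = build_repeat_coding_intervals(repeats, coding),
    pp2_genes = build_pp2_gene_list(clinvar, constraint),
    bp1_genes = build_bp1_gene_list(clinvar),
    gene_constraint = constraint,
    final_coding_exons = final_exons)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    vp <- file.path(out_dir, "variants.json")
    tp <- file.path(out_dir, "truth.tsv")
    rp <- file.path(out_dir, "refs")
    write_annotated_variants(acc$variants, vp)
    truth_df <- do.call(rbind, lapply(acc$truth, function(t)
      data.frame(chrom = t$chrom, pos = t$pos, ref = t$ref, alt = t$alt,
                 category = t$category, codes = t$codes,
                 stringsAsFactors = FALSE)))
    utils::write.table(truth_df, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    save_reference_bundle(bundle, rp)
    paths <- list(variants = vp, truth = tp, refs = rp)
  }
  truth <- lapply(acc$truth, function(t) {
    codes <- data.frame(code = character(0), strength = integer(0),
                        stringsAsFactors = FALSE)
    if (nzchar(t$codes)) {
      cs <- strsplit(strsplit(t$codes, "|", fixed = TRUE)[[1]], ":",
                     fixed = TRUE)
      codes <- data.frame(code = vapply(cs, `[[`, "", 1L),
                          strength = strength_value(vapply(cs, `[[`, "", 2L)),
                          stringsAsFactors = FALSE)
    }
    list(key = variant_key(t$chrom, t$pos, t$ref, t$alt),
         category = t$category, codes = codes)
  })
  list(variants = acc$variants, bundle = bundle, truth = truth,
       scenarios = scenarios, paths = paths)
}

# One scenario instance at its own locus. `i` indexes the scenario,
# `j` the replicate; every genomic feature of the instance lives in
# [base, base + 60000).
build_fixture_scenario <- function(acc, name, codes, category, i, j,
                                   jitter = 0L) {
  base <- 100000L * ((i - 1L) * 8L + (j - 1L)) + 1000L + jitter
  gene <- sprintf("SYG%02d", i)
  tx <- sprintf("TX%02d.%d", i, 1:2)
  chrom <- "1"
  pos <- base + 100L
  mid_af <- list(gnomad_af = 1e-4)     # inert under every bin's cutoffs
  push <- function(field, df) acc[[field]] <- c(acc[[field]], list(df))
  cv_row <- function(pos, ref, alt, sig, status, consequence, aa = "",
                     id = sprintf("CV%d", pos)) {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
               significance = sig, review_status = status,
               consequence = consequence, aa_change = aa, clinvar_id = id,
               stringsAsFactors = FALSE)
  }
  if (j == 1L) {
    # gene-level reference rows are added once per scenario
    loeuf <- switch(name, pvs1 = 0.3, combined_lp = 0.3, combined_p = 0.3,
                    conflict_high = 0.3, pp2 = 1.2, NA_real_)
    mis_oe <- switch(name, pp2 = 0.25, pm1 = 0.6, NA_real_)
    if (!is.na(loeuf) || !is.na(mis_oe)) {
      push("constraint", data.frame(gene = gene, loeuf = loeuf,
                                    mis_oe = mis_oe,
                                    stringsAsFactors = FALSE))
    }
  }
  lof_variant <- function(freq = mid_af, scores = list()) {
    push("final_exons", data.frame(transcript = tx[1], chrom = chrom,
                                   start = base + 50000L,
                                   end = base + 51000L,
                                   stringsAsFactors = FALSE))
    list(chrom = chrom, pos = pos, ref = "C", alt = "T",
         gene = gene, consequences = "stop gained",
         transcripts = list(
           list(id = tx[1], consequences = "stop gained", canonical = TRUE),
           list(id = tx[2], consequences = "stop gained")),
         freq = freq, scores = scores)
  }
  v <- switch(
    name,
    pvs1 = lof_variant(),
    ps1 = {
      push("clinvar", cv_row(pos + 50L, "G", "A", "P",
                             "criteria provided, multiple submitters, no conflicts",
                             "missense variant", aa = "R175H"))
      list(chrom = chrom, pos = pos, ref = "C", alt = "A", gene = gene,
           consequences = "missense variant", aa_change = "R175H",
           freq = mid_af)
    },
    pm5 = {
      push("clinvar", cv_row(pos + 50L, "G", "A", "P",
                             "criteria provided, multiple submitters, no conflicts",
                             "missense variant", aa = "R175H"))
      list(chrom = chrom, pos = pos, ref = "C", alt = "A", gene = gene,
           consequences = "missense variant", aa_change = "R175L",
           freq = mid_af)
    },
    ps3 = {
      push("literature", data.frame(
        type = "genomic", chrom = chrom, pos = pos, ref = "A", alt = "G",
        gene = gene, protein_change = "",
        pmid = sprintf("PMID%d", seq_len(6L) + 7000000L),
        stringsAsFactors = FALSE))
      list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
           consequences = "missense variant", freq = mid_af)
    },
    ps4_gwas = {
      push("gwas", data.frame(chrom = chrom, pos = pos, or = 4.2,
                              pvalue = 1e-12, stringsAsFactors = FALSE))
      list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
           consequences = "missense variant", freq = mid_af)
    },
    ps4_topmed = list(chrom = chrom, pos = pos, ref = "A", alt = "G",
                      gene = gene, consequences = "missense variant",
                      freq = c(mid_af, list(topmed_ac = 3))),
    pm1 = {
      push("domains", data.frame(id = sprintf("DOM%02d_%d", i, j),
                                 chrom = chrom, start = base,
                                 end = base + 500L,
                                 stringsAsFactors = FALSE))
      sig <- c(rep("P", 20), rep("B", 3), rep("VUS", 2))
      push("clinvar", do.call(rbind, lapply(seq_along(sig), function(k)
        cv_row(base + 10L * k, "A", "G", sig[k],
               "criteria provided, single submitter", "missense variant"))))
      list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
           consequences = "missense variant", freq = mid_af)
    },
    pm2 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant"),
    pm4 = list(chrom = chrom, pos = pos, ref = "TGCAGCAGCA", alt = "T",
               gene = gene, consequences = "inframe deletion",
               freq = mid_af),
    pp2 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant", freq = mid_af),
    pp3 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant", freq = mid_af,
               scores = list(revel = 0.8)),
    pp5 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant", freq = mid_af,
               clinvar = list(significance = "pathogenic",
                              review_status = "reviewed by expert panel",
                              id = sprintf("CVTOP%02d", i))),
    ba1 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant",
               freq = list(gnomad_af = 0.06)),
    bs1 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant",
               freq = list(gnomad_af = 0.012)),
    bs2 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant",
               gene_disease = list(list(disease = "synthetic recessive disorder",
                                        inheritance = "AR")),
               freq = c(mid_af, list(gnomad_hom_count = 4))),
    bp1 = {
      sig <- c(rep("P", 7), "P", "B", "VUS", "VUS")
      cons <- c(rep("stop gained", 7), "missense variant", "stop gained",
                "missense variant", "missense variant")
      push("clinvar", do.call(rbind, lapply(seq_along(sig), function(k)
        cv_row(base + 10L * k, "A", "G", sig[k],
               "criteria provided, single submitter", cons[k]))))
      list(chrom = chrom, pos = pos + 600L, ref = "A", alt = "G",
           gene = gene, consequences = "missense variant", freq = mid_af)
    },
    bp3 = {
      push("repeats", data.frame(chrom = chrom, start = base,
                                 end = base + 1000L,
                                 stringsAsFactors = FALSE))
      push("coding", data.frame(chrom = chrom, start = base,
                                end = base + 1000L,
                                stringsAsFactors = FALSE))
      list(chrom = chrom, pos = pos, ref = "TGCAGCAGCA", alt = "T",
           gene = gene, consequences = "inframe deletion", freq = mid_af)
    },
    bp4 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant", freq = mid_af,
               scores = list(revel = 0.10)),
    bp6 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "missense variant", freq = mid_af,
               clinvar = list(significance = "benign",
                              review_status = "practice guidelines",
                              id = sprintf("CVTOP%02d", i))),
    bp7 = list(chrom = chrom, pos = pos, ref = "A", alt = "G", gene = gene,
               consequences = "synonymous variant", freq = mid_af,
               scores = list(phylop = 3.0, absplice = 0.04)),
    bp7_strong = list(chrom = chrom, pos = pos, ref = "A", alt = "G",
                      gene = gene, consequences = "synonymous variant",
                      freq = mid_af,
                      scores = list(phylop = 0.1, absplice = 0.005)),
    combined_lp = lof_variant(freq = list()),
    combined_p = lof_variant(freq = list(), scores = list(revel = 0.8)),
    combined_b = list(chrom = chrom, pos = pos, ref = "A", alt = "G",
                      gene = gene, consequences = "missense variant",
                      gene_disease = list(list(disease = "synthetic recessive disorder",
                                               inheritance = "AR")),
                      freq = list(gnomad_af = 0.012, gnomad_hom_count = 4)),
    conflict_high = lof_variant(freq = list(gnomad_af = 0.06)),
    conflict_low = list(chrom = chrom, pos = pos, ref = "A", alt = "G",
                        gene = gene, consequences = "missense variant",
                        scores = list(revel = 0.10)),
    stop("unknown fixture scenario: ", name)
  )
  variant <- do.call(annotated_variant, v)
  acc$variants <- c(acc$variants, list(variant))
  acc$truth <- c(acc$truth, list(list(
    chrom = variant$chrom, pos = variant$pos, ref = variant$ref,
    alt = variant$alt, category = category, codes = codes)))
  invisible(NULL)
}
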