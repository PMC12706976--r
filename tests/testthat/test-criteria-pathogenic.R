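cfg <- default_engine_config()

test_that("PVS1 weighs LoF variants by constraint and transcript support", {
  bundle <- mk_bundle(gene_constraint = constraint_df("GENE1", loeuf = 0.3))
  e <- evaluate_pvs1(mk_lof_variant(), bundle, cfg)
  expect_identical(e$code, "PVS1")
  expect_identical(e$strength, strength_value("very_strong"))
  # LoF-tolerant gene drops to strong
  b2 <- mk_bundle(gene_constraint = constraint_df("GENE1", loeuf = 1.2))
  expect_identical(evaluate_pvs1(mk_lof_variant(), b2, cfg)$strength,
                   strength_value("strong"))
  # missing constraint entry also caps at strong
  expect_identical(evaluate_pvs1(mk_lof_variant(), mk_bundle(), cfg)$strength,
                   strength_value("strong"))
  # LoF in only 1 of 3 transcripts -> not applied
  v3 <- mk_variant(ref = "C", alt = "T", consequences = "stop gained",
                   transcripts = list(
                     list(id = "TX1", consequences = "stop gained"),
                     list(id = "TX2", consequences = "synonymous variant"),
                     list(id = "TX3", consequences = "synonymous variant")))
  expect_null(evaluate_pvs1(v3, bundle, cfg))
  # non-LoF consequence -> not applied
  expect_null(evaluate_pvs1(mk_variant(), bundle, cfg))
})

test_that("PVS1 honours the final-coding-exon exclusion window", {
  fce <- data.frame(transcript = "TX1", chrom = "1", start = 500L,
                    end = 1040L, stringsAsFactors = FALSE)
  bundle <- mk_bundle(gene_constraint = constraint_df("GENE1", loeuf = 0.3),
                      final_coding_exons = fce)
  # pos 1000 is within the last 50 bp of the exon ending at 1040
  expect_null(evaluate_pvs1(mk_lof_variant(pos = 1000L), bundle, cfg))
  # pos 990 is exactly outside (1040 - 50 = 990 boundary is excluded
  # only above it)
  expect_identical(
    evaluate_pvs1(mk_lof_variant(pos = 990L), bundle, cfg)$strength, 4L)
})

test_that("PVS1 downgrades low-impact splice variants one rung per check", {
  bundle <- mk_bundle(gene_constraint = constraint_df("GENE1", loeuf = 0.3))
  splice <- function(absplice) {
    mk_lof_variant(consequences = "splice donor variant",
                   scores = if (is.null(absplice)) list()
                   else list(absplice = absplice))
  }
  expect_identical(evaluate_pvs1(splice(0.5), bundle, cfg)$strength, 4L)
  expect_identical(evaluate_pvs1(splice(0.1), bundle, cfg)$strength, 3L)
  expect_identical(evaluate_pvs1(splice(0.03), bundle, cfg)$strength, 2L)
  # no splicing score -> no downgrade evidence
  expect_identical(evaluate_pvs1(splice(NULL), bundle, cfg)$strength, 4L)
  # a stop-gain with the same low score is not a splice-only variant
  expect_identical(
    evaluate_pvs1(mk_lof_variant(scores = list(absplice = 0.03)),
                  bundle, cfg)$strength, 4L)
})

test_that("PVS1 strength is monotone non-increasing in LOEUF", {
  last <- 5L
  for (loeuf in seq(0.1, 2.0, by = 0.1)) {
    b <- mk_bundle(gene_constraint = constraint_df("GENE1", loeuf = loeuf))
    s <- evaluate_pvs1(mk_lof_variant(), b, cfg)$strength
    expect_lte(s, last)
    last <- s
  }
})

test_that("PS1/PM5 distinguish same and different substitutions at a site", {
  idx <- build_pathogenic_aa_index(clinvar_df(
    pos = 500, ref = "G", alt = "A", sig = "P",
    status = "criteria provided, multiple submitters, no conflicts",
    aa = "R175H"))
  bundle <- mk_bundle(pathogenic_aa = idx)
  # different nucleotide, same substitution -> PS1 at the review weight
  ps1 <- evaluate_ps1_pm5(mk_variant(pos = 501L, ref = "C", alt = "A",
                                     aa_change = "R175H"), bundle, cfg)
  expect_identical(ps1$code, "PS1")
  expect_identical(ps1$strength, 3L)
  # different substitution at the indexed residue -> PM5, capped moderate
  pm5 <- evaluate_ps1_pm5(mk_variant(pos = 501L, ref = "C", alt = "T",
                                     aa_change = "R175L"), bundle, cfg)
  expect_identical(pm5$code, "PM5")
  expect_identical(pm5$strength, 2L)
  # identical nucleotide change -> skipped (PP5 territory)
  expect_null(evaluate_ps1_pm5(mk_variant(pos = 500L, ref = "G", alt = "A",
                                          aa_change = "R175H"), bundle, cfg))
  # non-missense or aa-less variants are not evaluated
  expect_null(evaluate_ps1_pm5(mk_variant(consequences = "synonymous variant",
                                          aa_change = "R175H"), bundle, cfg))
  expect_null(evaluate_ps1_pm5(mk_variant(pos = 501L), bundle, cfg))
})

test_that("PS1 strength caps at strong even for expert-panel references", {
  idx <- build_pathogenic_aa_index(clinvar_df(
    pos = 500, ref = "G", alt = "A", sig = "P",
    status = "reviewed by expert panel", aa = "R175H"))
  bundle <- mk_bundle(pathogenic_aa = idx)
  ps1 <- evaluate_ps1_pm5(mk_variant(pos = 501L, ref = "C", alt = "A",
                                     aa_change = "R175H"), bundle, cfg)
  expect_identical(ps1$strength, 3L)  # weight 5 capped at strong
})

test_that("PS3 tiers publications and prefers the genomic key", {
  lit <- list(genomic = list("1:1000:A:G" = c("p1")),
              protein = list("GENE1|R175H" = paste0("p", 1:6)))
  bundle <- mk_bundle(literature = lit)
  # genomic hit with one publication -> supporting
  e <- evaluate_ps3(mk_variant(aa_change = "R175H"), bundle, cfg)
  expect_identical(e$strength, 1L)
  expect_identical(e$details$pubmed_ids, "p1")
  # no genomic hit, protein hit with 6 publications -> strong
  e2 <- evaluate_ps3(mk_variant(pos = 2000L, aa_change = "R175H"),
                     bundle, cfg)
  expect_identical(e2$strength, 3L)
  expect_identical(e2$details$matched_by, "protein")
  # 2..4 publications -> moderate
  b3 <- mk_bundle(literature = list(
    genomic = list("1:1000:A:G" = c("p1", "p2")), protein = list()))
  expect_identical(evaluate_ps3(mk_variant(), b3, cfg)$strength, 2L)
  # no hits -> none
  expect_null(evaluate_ps3(mk_variant(pos = 3000L), bundle, cfg))
})

test_that("PS4 tiers GWAS hits and falls back to the TOPMed proxy", {
  gwas <- build_gwas_index(data.frame(chrom = "1", pos = 1000L, or = 4.2,
                                      pvalue = 1e-12))
  expect_identical(evaluate_ps4(mk_variant(), mk_bundle(gwas = gwas),
                                cfg)$strength, 3L)
  gwas2 <- build_gwas_index(data.frame(chrom = "1", pos = 1000L, or = 2.0,
                                       pvalue = 1e-9))
  expect_identical(evaluate_ps4(mk_variant(), mk_bundle(gwas = gwas2),
                                cfg)$strength, 2L)
  gwas3 <- build_gwas_index(data.frame(chrom = "1", pos = 1000L, or = 1.2,
                                       pvalue = 1e-6))
  expect_identical(evaluate_ps4(mk_variant(), mk_bundle(gwas = gwas3),
                                cfg)$strength, 1L)
  # a GWAS entry failing every tier yields nothing (no TOPMed fallback)
  gwas4 <- build_gwas_index(data.frame(chrom = "1", pos = 1000L, or = 1.01,
                                       pvalue = 0.5))
  expect_null(evaluate_ps4(mk_variant(freq = list(topmed_ac = 1)),
                           mk_bundle(gwas = gwas4), cfg))
  # TOPMed: fewer than 5 alternate alleles -> supporting
  empty <- mk_bundle()
  expect_identical(
    evaluate_ps4(mk_variant(freq = list(topmed_ac = 3)), empty, cfg)$strength,
    1L)
  # 3..9 homozygotes -> supporting even with many alleles
  expect_identical(
    evaluate_ps4(mk_variant(freq = list(topmed_ac = 50, topmed_hom_count = 4)),
                 empty, cfg)$strength, 1L)
  # boundary: 5 alleles and 0 homozygotes -> none
  expect_null(evaluate_ps4(
    mk_variant(freq = list(topmed_ac = 5, topmed_hom_count = 0)), empty, cfg))
  expect_null(evaluate_ps4(mk_variant(), empty, cfg))
})

test_that("PM1 tiers hotspot domains on their pathogenic/benign fractions", {
  mk_dom_bundle <- function(path_frac, benign_frac, n = 60L) {
    n_path <- round(path_frac * n); n_ben <- round(benign_frac * n)
    dom <- data.frame(id = "D1", chrom = "1", start = 900L, end = 1100L,
                      n_total = n, n_path = n_path, n_benign = n_ben,
                      n_vus = n - n_path - n_ben,
                      path_frac = n_path / n, benign_frac = n_ben / n,
                      vus_frac = (n - n_path - n_ben) / n,
                      stringsAsFactors = FALSE)
    mk_bundle(hotspot_domains = dom)
  }
  expect_identical(
    evaluate_pm1(mk_variant(), mk_dom_bundle(0.80, 0.10), cfg)$strength, 2L)
  # fewer than 75% pathogenic and more than 15% benign -> supporting
  expect_identical(
    evaluate_pm1(mk_variant(), mk_dom_bundle(40 / 60, 10 / 60), cfg)$strength,
    1L)
  # more than 90% pathogenic and fewer than 10% benign -> strong
  expect_identical(
    evaluate_pm1(mk_variant(), mk_dom_bundle(0.95, 0.05), cfg)$strength, 3L)
  # no overlap -> none
  expect_null(evaluate_pm1(mk_variant(pos = 5000L),
                           mk_dom_bundle(0.95, 0.05), cfg))
})

test_that("PM2 applies the LOEUF-binned rarity cutoffs", {
  bundle <- mk_bundle()  # no constraint -> default middle bin
  # absent from both databases -> moderate
  e <- evaluate_pm2(mk_variant(), bundle, cfg)
  expect_identical(e$strength, 2L)
  # below the standard cutoff -> moderate
  expect_identical(
    evaluate_pm2(mk_variant(freq = list(gnomad_af = 1e-6)), bundle,
                 cfg)$strength, 2L)
  # between standard and supporting cutoffs -> supporting
  expect_identical(
    evaluate_pm2(mk_variant(freq = list(gnomad_af = 1e-5)), bundle,
                 cfg)$strength, 1L)
  # above the supporting cutoff -> none
  expect_null(evaluate_pm2(mk_variant(freq = list(gnomad_af = 1e-3)),
                           bundle, cfg))
  # the larger of the two AFs governs
  expect_null(evaluate_pm2(
    mk_variant(freq = list(gnomad_af = 1e-6, thousand_genomes_af = 1e-3)),
    bundle, cfg))
  # constrained gene in bin 1 uses stricter cutoffs
  b1 <- mk_bundle(gene_constraint = constraint_df("GENE1", loeuf = 0.2))
  expect_null(evaluate_pm2(mk_variant(freq = list(gnomad_af = 1e-5)),
                           b1, cfg))
})

test_that("PM4 weighs in-frame length changes outside repeats", {
  empty <- mk_bundle()
  del <- function(aa_n, consequences = "inframe deletion", pos = 1000L) {
    mk_variant(pos = pos, ref = paste(rep("A", aa_n * 3 + 1), collapse = ""),
               alt = "A", consequences = consequences)
  }
  expect_identical(evaluate_pm4(del(3), empty, cfg)$strength, 1L)
  expect_identical(evaluate_pm4(del(4), empty, cfg)$strength, 2L)
  expect_identical(evaluate_pm4(del(10), empty, cfg)$strength, 2L)
  expect_identical(evaluate_pm4(del(11), empty, cfg)$strength, 3L)
  # stop loss SNV counts as an extension event at supporting
  sl <- mk_variant(ref = "T", alt = "C", consequences = "stop loss")
  expect_identical(evaluate_pm4(sl, empty, cfg)$strength, 1L)
  # inside a repeat-coding interval -> excluded
  expect_null(evaluate_pm4(del(3), repeat_bundle(), cfg))
  # ineligible consequence -> none
  expect_null(evaluate_pm4(mk_variant(), empty, cfg))
})

test_that("PP2 requires the gene list and missense term, upgrading on low OE", {
  b <- mk_bundle(pp2_genes = c(GENE1 = 0.25, GENE2 = 0.08))
  expect_identical(evaluate_pp2(mk_variant(), b, cfg)$strength, 1L)
  expect_identical(evaluate_pp2(mk_variant(gene = "GENE2"), b, cfg)$strength,
                   2L)
  expect_null(evaluate_pp2(mk_variant(consequences = "synonymous variant"),
                           b, cfg))
  expect_null(evaluate_pp2(mk_variant(gene = "OTHER"), b, cfg))
  # fallback-listed genes (no OE) stay at supporting
  b2 <- mk_bundle(pp2_genes = c(GENE1 = NA_real_))
  expect_identical(evaluate_pp2(mk_variant(), b2, cfg)$strength, 1L)
})

test_that("PP3 maps tool ladders, upweights agreement and disqualifies", {
  empty <- mk_bundle()
  pp3 <- function(...) evaluate_pp3(mk_variant(scores = list(...)), empty, cfg)
  # single tool at its moderate tier -> moderate
  expect_identical(pp3(revel = 0.8)$strength, 2L)
  # two tools tied at supporting -> upweighted to moderate
  e <- pp3(revel = 0.7, gerp = 3.0)
  expect_identical(e$strength, 2L)
  expect_setequal(e$details$tools, c("revel", "gerp"))
  # a lone supporting-level tool is suppressed
  expect_null(pp3(revel = 0.7))
  # any tool below its strong-benign threshold disqualifies
  expect_null(pp3(revel = 0.8, phylop = -5.0))
  expect_null(pp3(dann = 0.9995, revel = 0.01))
  expect_null(pp3())
})

test_that("PP3 is invariant to tool evaluation order", {
  empty <- mk_bundle()
  scores <- list(revel = 0.8, dann = 0.995, phylop = 8.0, gerp = 3.0)
  e1 <- evaluate_pp3(mk_variant(scores = scores), empty, cfg)
  e2 <- evaluate_pp3(mk_variant(scores = rev(scores)), empty, cfg)
  expect_identical(e1$strength, e2$strength)
  expect_setequal(e1$details$tools, e2$details$tools)
})

test_that("PP5 weighs the top ClinVar pathogenic assertion by review status", {
  empty <- mk_bundle()
  pp5 <- function(sig, status) {
    evaluate_pp5(mk_variant(clinvar = list(significance = sig,
                                           review_status = status,
                                           id = "CV1")), empty, cfg)
  }
  expect_identical(pp5("pathogenic", "reviewed by expert panel")$strength, 5L)
  expect_identical(pp5("likely pathogenic",
                       "criteria provided, single submitter")$strength, 2L)
  expect_identical(pp5("pathogenic",
                       "criteria provided, multiple submitters, no conflicts")$strength,
                   3L)
  expect_identical(pp5("pathogenic",
                       "criteria provided, conflicting interpretations")$strength,
                   1L)
  expect_null(pp5("pathogenic", "no assertion criteria provided"))
  expect_null(pp5("uncertain significance", "reviewed by expert panel"))
  expect_null(evaluate_pp5(mk_variant(), empty, cfg))
})
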