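test_that("pathogenic amino-acid index keeps weighted P/LP missense records", {
  rec <- clinvar_df(
    pos = c(100, 200, 300, 400),
    sig = c("P", "P", "B", "P"),
    status = c("reviewed by expert panel",
               "no assertion criteria provided",
               "reviewed by expert panel",
               "criteria provided, single submitter"),
    aa = c("R175H", "R175H", "G12D", ""))
  idx <- build_pathogenic_aa_index(rec)
  # zero-weight and benign and aa-less records are excluded
  expect_identical(nrow(idx), 1L)
  expect_identical(idx$residue, 175L)
  expect_identical(idx$ref_aa, "R")
  expect_identical(idx$alt_aa, "H")
  expect_identical(idx$weight, 5L)
})

test_that("hotspot domain filters apply the printed boundaries literally", {
  dom <- data.frame(id = c("D1", "D2", "D3", "D4", "D5"),
                    chrom = "1",
                    start = c(0, 1000, 2000, 3000, 4000),
                    end = c(500, 1500, 2500, 3500, 4500),
                    stringsAsFactors = FALSE)
  rows <- function(start, sig) {
    clinvar_df(pos = start + 10 + seq_along(sig),
               sig = sig, status = "criteria provided, single submitter")
  }
  rec <- rbind(
    rows(0, c(rep("P", 4), "B", "VUS")),          # D1: 66.7/16.7/16.7 -> keep
    rows(1000, c("P", "P", "P", "B")),            # D2: only 4 variants -> drop
    rows(2000, c("P", "P", "P", "VUS", "VUS", "VUS")),  # D3: vus 50%, path 50% -> keep
    rows(3000, c(rep("P", 5), rep("VUS", 6))),    # D4: vus > 50% -> drop
    rows(4000, c(rep("P", 6), rep("B", 2))))      # D5: benign 25% -> keep
  hs <- build_hotspot_domains(rec, dom)
  expect_setequal(hs$id, c("D1", "D3", "D5"))
  d1 <- hs[hs$id == "D1", ]
  expect_equal(d1$path_frac, 4 / 6)
  expect_equal(d1$benign_frac, 1 / 6)
  expect_identical(d1$n_total, 6L)
  # one more benign pushes D5 over 25% -> dropped
  rec2 <- rbind(rec, rows(4000 + 50, "B"))
  expect_false("D5" %in% build_hotspot_domains(rec2, dom)$id)
})

test_that("hotspot counting drops conflicting and zero-weight records", {
  dom <- data.frame(id = "D1", chrom = "1", start = 0, end = 500,
                    stringsAsFactors = FALSE)
  rec <- rbind(
    clinvar_df(pos = 1:6, sig = c(rep("P", 5), "B"),
               status = "criteria provided, single submitter"),
    clinvar_df(pos = 7, sig = "conflicting",
               status = "criteria provided, single submitter"),
    clinvar_df(pos = 8, sig = "P",
               status = "no assertion criteria provided"))
  hs <- build_hotspot_domains(rec, dom)
  expect_identical(hs$n_total, 6L)
  expect_identical(hs$n_path, 5L)
})

test_that("PP2 gene list honours the OE rule and the ClinVar fallback", {
  # constraint-backed: kept at OE <= 0.4, excluded above
  pp2 <- build_pp2_gene_list(
    clinvar_df(pos = 1, sig = "P",
               status = "criteria provided, single submitter",
               gene = "GX"),
    data.frame(gene = c("G03", "G041", "GX"),
               loeuf = NA_real_, mis_oe = c(0.3, 0.41, NA),
               stringsAsFactors = FALSE))
  expect_true("G03" %in% names(pp2))
  expect_equal(unname(pp2[["G03"]]), 0.3)
  expect_false("G041" %in% names(pp2))
  # fallback: 6 variants, 4 path missense, 1 benign missense, 1 VUS -> kept
  rec <- clinvar_df(pos = 1:6,
                    sig = c("P", "P", "P", "P", "B", "VUS"),
                    status = "criteria provided, single submitter",
                    gene = "GY")
  pp2 <- build_pp2_gene_list(rec, constraint_df(character(0)))
  expect_true("GY" %in% names(pp2))
  expect_true(is.na(pp2[["GY"]]))
  # without a benign missense the fallback fails
  rec2 <- rec; rec2$consequence[5] <- "stop gained"
  expect_false("GY" %in% names(build_pp2_gene_list(rec2, constraint_df(character(0)))))
  # fewer than five variants fails
  expect_false("GY" %in% names(build_pp2_gene_list(rec[1:4 + 1, ], constraint_df(character(0)))))
})

test_that("BP1 gene list applies the four discard rules at their boundaries", {
  status <- "criteria provided, single submitter"
  mk <- function(sig, cons, gene = "GB") {
    clinvar_df(pos = seq_along(sig), sig = sig, status = status,
               consequence = cons, gene = gene)
  }
  # 8 pathogenic (7 truncating), 1 of 8 truncating benign, 2 VUS of 11 -> keep
  keep <- mk(c(rep("P", 7), "P", "B", "VUS", "VUS"),
             c(rep("stop gained", 7), "missense variant", "stop gained",
               "missense variant", "missense variant"))
  expect_identical(build_bp1_gene_list(keep), "GB")
  # zero pathogenic truncating -> discard
  none <- mk(c("P", "P", "B", "VUS", "VUS"),
             c("missense variant", "missense variant", "stop gained",
               "missense variant", "missense variant"))
  expect_length(build_bp1_gene_list(none), 0L)
  # 70% of pathogenic variants truncating (< 75%) -> discard
  low <- mk(c(rep("P", 10), "B"),
            c(rep("stop gained", 7), rep("missense variant", 3),
              "missense variant"))
  expect_length(build_bp1_gene_list(low), 0L)
  # exactly 75% pathogenic truncating is retained
  at75 <- mk(c(rep("P", 4), "B"),
             c(rep("stop gained", 3), "missense variant",
               "missense variant"))
  expect_identical(build_bp1_gene_list(at75), "GB")
  # more than 25% of truncating variants benign -> discard
  ben <- mk(c(rep("P", 3), rep("B", 2)),
            c(rep("frameshift variant", 3), rep("frameshift variant", 2)))
  expect_length(build_bp1_gene_list(ben), 0L)
})

test_that("repeat-coding intersection matches the interval examples", {
  rep1 <- data.frame(chrom = "1", start = 100L, end = 200L)
  cod1 <- data.frame(chrom = "1", start = 150L, end = 250L)
  out <- build_repeat_coding_intervals(rep1, cod1)
  expect_identical(out$start, 150L)
  expect_identical(out$end, 200L)
  # disjoint inputs -> empty index
  out2 <- build_repeat_coding_intervals(
    data.frame(chrom = "1", start = 0L, end = 10L),
    data.frame(chrom = "1", start = 50L, end = 60L))
  expect_identical(nrow(out2), 0L)
  # overlapping outputs merge into one interval
  rep3 <- data.frame(chrom = c("1", "1"), start = c(100L, 180L),
                     end = c(200L, 300L))
  cod3 <- data.frame(chrom = "1", start = 0L, end = 1000L)
  out3 <- build_repeat_coding_intervals(rep3, cod3)
  expect_identical(nrow(out3), 1L)
  expect_identical(c(out3$start, out3$end), c(100L, 300L))
})

test_that("interval index agrees with a brute-force scan on random queries", {
  set.seed(42)
  n <- 60L
  df <- data.frame(chrom = sample(c("1", "2", "X"), n, replace = TRUE),
                   start = sample.int(500L, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  df$end <- df$start + sample.int(40L, n, replace = TRUE)
  df$id <- sprintf("iv%02d", seq_len(n))
  idx <- interval_index(df)
  for (q in seq_len(1000L)) {
    chrom <- sample(c("1", "2", "X", "7"), 1L)
    pos <- sample.int(560L, 1L)
    width <- sample.int(5L, 1L)
    got <- sort(interval_overlaps(idx, chrom, pos, width)$id)
    # brute force on the 0-based half-open definition
    want <- sort(df$id[df$chrom == chrom &
                         df$start < pos + width - 1L & df$end >= pos])
    expect_identical(got, want)
  }
})

test_that("literature index deduplicates PubMed IDs per key", {
  rows <- data.frame(
    type = c("genomic", "genomic", "genomic", "protein", "protein"),
    chrom = c("1", "1", "1", "", ""),
    pos = c(100L, 100L, 100L, NA, NA),
    ref = c("A", "A", "A", "", ""), alt = c("G", "G", "G", "", ""),
    gene = c("", "", "", "TP53", "TP53"),
    protein_change = c("", "", "", "R273H", "R273H"),
    pmid = c("11", "22", "22", "33", "33"),
    stringsAsFactors = FALSE)
  lit <- build_literature_index(rows)
  expect_setequal(lit$genomic[["1:100:A:G"]], c("11", "22"))
  expect_identical(lit$protein[["TP53|R273H"]], "33")
})

test_that("BED reader enforces three-column tab layout", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo", "chr1\t10\t20\tname", "2\t5\t9"), path)
  bed <- read_bed(path)
  expect_identical(nrow(bed), 2L)
  expect_identical(bed$start, c(10L, 5L))
  writeLines("chr1\t10", path)
  expect_error(read_bed(path), "malformed BED")
})

test_that("bundle save/load round-trips every member byte-deterministically", {
  fx <- generate_fixtures(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_reference_bundle(fx$bundle, d1)
  back <- load_reference_bundle(d1)
  expect_equal(back$pathogenic_aa, fx$bundle$pathogenic_aa)
  expect_equal(back$hotspot_domains, fx$bundle$hotspot_domains)
  expect_equal(back$repeat_coding, fx$bundle$repeat_coding)
  expect_equal(back$pp2_genes, fx$bundle$pp2_genes)
  expect_equal(back$bp1_genes, fx$bundle$bp1_genes)
  expect_equal(back$gene_constraint, fx$bundle$gene_constraint)
  expect_equal(back$literature, fx$bundle$literature)
  expect_equal(back$gwas, fx$bundle$gwas)
  # the loaded bundle classifies identically to the in-memory one
  r1 <- classify_variants(fx$variants, fx$bundle, log_every = 0)
  r2 <- classify_variants(fx$variants, back, log_every = 0)
  expect_equal(lapply(r1, `[[`, "category"), lapply(r2, `[[`, "category"))
  # byte-identical serialization of the same bundle
  save_reference_bundle(fx$bundle, d2)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
  # tampering is caught by the hotspot invariant re-check
  hs <- utils::read.delim(file.path(d1, "hotspot_domains.tsv"))
  if (nrow(hs)) {
    hs$n_path[1] <- hs$n_path[1] - 1L
    utils::write.table(hs, file.path(d1, "hotspot_domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(load_reference_bundle(d1), "invariant")
  }
})

test_that("ClinVar-like TSV reader derives weights and keys", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("chrom", "pos", "ref", "alt", "gene", "significance",
                       "review_status", "consequence", "aa_change",
                       "clinvar_id"), collapse = "\t"),
               "chr17\t7674220\tC\tT\tTP53\tPathogenic\treviewed by expert panel\tmissense_variant\tR175H\tCV1"),
             path)
  rec <- read_clinvar_table(path)
  expect_identical(rec$key, "17:7674220:C:T")
  expect_identical(rec$weight, 5L)
  expect_identical(rec$significance, "P")
})
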