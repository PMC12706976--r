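# Automated benign criteria (BA1, BS1, BS2, BP1, BP3, BP4, BP6, BP7).

#' Evaluate BA1 / BS1 (population frequency too high for disease)
#'
#' The larger of the gnomAD and 1000 Genomes allele frequencies is
#' compared with the gene's LOEUF-bin cutoffs: above the BA1 cutoff the
#' variant gets stand-alone BA1 (and no BS1); at or above the BS1
#' standard cutoff, strong BS1; between the BS1 supporting and standard
#' cutoffs, supporting BS1. Absence from both databases yields no
#' benign frequency evidence. BA1 and BS1 are mutually exclusive, and a
#' valid cutoff ordering makes BA1 and PM2 mutually exclusive too.
#'
#' @inheritParams evaluate_pvs1
#' @return list of 0..1 `acmg_evidence` calls.
#' @export
evaluate_ba1_bs1 <- function(v, bundle, config = default_engine_config()) {
  af <- population_af(v)
  if (is.na(af)) return(list())
  bin <- variant_loeuf_bin(v, bundle, config)
  cut <- config$loeuf_bins[bin, ]
  if (af > cut$ba1) {
    return(list(evidence_call(
      "BA1", strength_value("stand_alone"),
      sprintf("AF %.3g above BA1 cutoff %.3g (LOEUF bin %d)",
              af, cut$ba1, bin),
      details = list(af = af, loeuf_bin = bin))))
  }
  if (af >= cut$bs1_standard) {
    return(list(evidence_call(
      "BS1", strength_value("strong"),
      sprintf("AF %.3g at or above BS1 standard cutoff %.3g (LOEUF bin %d)",
              af, cut$bs1_standard, bin),
      details = list(af = af, loeuf_bin = bin))))
  }
  if (af >= cut$bs1_supporting) {
    return(list(evidence_call(
      "BS1", strength_value("supporting"),
      sprintf("AF %.3g between BS1 supporting %.3g and standard %.3g cutoffs (LOEUF bin %d)",
              af, cut$bs1_supporting, cut$bs1_standard, bin),
      details = list(af = af, loeuf_bin = bin))))
  }
  list()
}

#' Evaluate BS2 (observed in healthy individuals)
#'
#' Branches on the inheritance mode of the gene-disease records.
#' Autosomal recessive: homozygote count above the recessive threshold
#' applies BS2 (strong at twice the threshold, else moderate).
#' Autosomal dominant: only in LoF-constrained genes (LOEUF below 0.5);
#' requires the allele frequency at or below the bin's BS2 AF ceiling
#' and the minimum of the available allele counts (gnomAD controls,
#' gnomAD all, 1000 Genomes) at or above the dominant threshold, giving
#' strong. X-linked: hemizygous males or homozygous females above the
#' X-linked threshold give strong. With several applicable modes the
#' strongest result wins.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_bs2 <- function(v, bundle, config = default_engine_config()) {
  gd <- v$gene_disease
  if (!length(gd)) return(NULL)
  modes <- unique(vapply(gd, function(x) x$inheritance %||% "other", ""))
  cf <- config$bs2
  calls <- list()
  if ("AR" %in% modes) {
    hom <- v$freq$gnomad_hom_count
    if (!is.null(hom) && hom > cf$recessive_hom) {
      strength <- if (hom >= 2L * cf$recessive_hom) strength_value("strong")
      else strength_value("moderate")
      calls <- c(calls, list(evidence_call(
        "BS2", strength,
        sprintf("recessive condition: %d homozygote(s) in gnomAD (threshold %d)",
                as.integer(hom), cf$recessive_hom),
        details = list(mode = "AR", hom_count = hom))))
    }
  }
  if ("AD" %in% modes) {
    loeuf <- gene_loeuf(bundle, v$gene)
    if (!is.na(loeuf) && loeuf < cf$ad_loeuf_max) {
      bin <- variant_loeuf_bin(v, bundle, config)
      af <- population_af(v)
      acs <- c(v$freq$gnomad_controls_ac, v$freq$gnomad_ac,
               v$freq$thousand_genomes_ac)
      if (length(acs) && (is.na(af) || af <= config$loeuf_bins$bs2_af[bin]) &&
          min(acs) >= cf$dominant_allele) {
        calls <- c(calls, list(evidence_call(
          "BS2", strength_value("strong"),
          sprintf("dominant condition in constrained gene (LOEUF %.3g): %d allele(s) in healthy populations",
                  loeuf, as.integer(min(acs))),
          details = list(mode = "AD", min_allele_count = min(acs),
                         loeuf = loeuf))))
      }
    }
  }
  if ("XL" %in% modes) {
    hemi <- v$freq$hemizygous_male_count %||% 0
    homf <- v$freq$homozygous_female_count %||% 0
    if (hemi > cf$x_linked || homf > cf$x_linked) {
      calls <- c(calls, list(evidence_call(
        "BS2", strength_value("strong"),
        sprintf("X-linked condition: %d hemizygous male(s), %d homozygous female(s)",
                as.integer(hemi), as.integer(homf)),
        details = list(mode = "XL", hemizygous_males = hemi,
                       homozygous_females = homf))))
    }
  }
  if (!length(calls)) return(NULL)
  calls[[which.max(vapply(calls, function(x) x$strength, 1L))]]
}

#' Evaluate BP1 (missense in a truncating-mechanism gene)
#'
#' Supporting when the gene is on the precomputed truncating-mechanism
#' list and the consequence contains "missense".
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_bp1 <- function(v, bundle, config = default_engine_config()) {
  if (is.null(v$gene) || !(v$gene %in% bundle$bp1_genes)) return(NULL)
  if (!any(is_missense(v$consequences))) return(NULL)
  evidence_call(
    "BP1", strength_value("supporting"),
    sprintf("missense variant in gene %s where truncating variants are the pathogenic mechanism",
            v$gene),
    details = list(gene = v$gene))
}

#' Evaluate BP3 (in-frame indel in a repeat region)
#'
#' Requires an in-frame indel (length divisible by 3, at least 3 nt
#' unless the consequence is stop loss) overlapping a repeat-coding
#' interval. Indels shorter than 15 nt are strong; 15 to below 60 nt
#' supporting; 60 nt and longer are not applied. The overlapped repeat
#' interval is recorded in the details.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_bp3 <- function(v, bundle, config = default_engine_config()) {
  len <- indel_length(v$ref, v$alt)
  if (len %% 3L != 0L) return(NULL)
  if (len < 3L && !("stop loss" %in% v$consequences)) return(NULL)
  hits <- interval_overlaps(bundle$repeat_index, v$chrom, v$pos,
                            width = variant_span(v))
  if (!nrow(hits)) return(NULL)
  cf <- config$bp3
  strength <- if (len < cf$strong_below_nt) strength_value("strong")
  else if (len < cf$supporting_below_nt) strength_value("supporting")
  else return(NULL)
  r <- hits[1, ]
  evidence_call(
    "BP3", strength,
    sprintf("%d-nt in-frame indel within repeat region %s:%d-%d",
            len, r$chrom, r$start, r$end),
    details = list(indel_nt = len,
                   repeat_interval = sprintf("%s:%d-%d", r$chrom,
                                             r$start, r$end)))
}

#' @rdname evaluate_pp3
#' @export
evaluate_bp4 <- function(v, bundle, config = default_engine_config()) {
  insilico_calls(v, config)$bp4
}

#' Evaluate BP6 (reputable-source benign assertion)
#'
#' Same mechanism as PP5 with the polarity reversed: applies to
#' variants whose top ClinVar entry is benign or likely benign, at the
#' review-status weight.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_bp6 <- function(v, bundle, config = default_engine_config()) {
  clinvar_assertion_call(v, config, c("B", "LB"), "BP6")
}

#' Evaluate BP7 (synonymous / non-coding with no predicted impact)
#'
#' Eligible consequences are synonymous (checked first), intronic and
#' intergenic. Supporting when PhyloP is below 7.367 and ABSplice below
#' 0.05; strong when additionally ABSplice is below 0.01 and PhyloP
#' below 0.21. Both scores must be present; they are recorded in the
#' call details.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_bp7 <- function(v, bundle, config = default_engine_config()) {
  cons <- v$consequences
  eligible <- any(grepl("synonymous", cons)) || any(grepl("intron", cons)) ||
    any(grepl("intergenic", cons))
  if (!eligible) return(NULL)
  phylop <- v$scores$phylop; absplice <- v$scores$absplice
  if (is.null(phylop) || is.null(absplice)) return(NULL)
  cf <- config$bp7
  if (!(phylop < cf$phylop_eligible && absplice < cf$absplice_eligible)) {
    return(NULL)
  }
  strength <- if (absplice < cf$absplice_strong && phylop < cf$phylop_strong)
    strength_value("strong") else strength_value("supporting")
  evidence_call(
    "BP7", strength,
    sprintf("low conservation (PhyloP %.3g) and no predicted splice impact (ABSplice %.3g)",
            phylop, absplice),
    details = list(phylop = phylop, absplice = absplice))
}
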