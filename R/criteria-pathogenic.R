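# Automated pathogenic criteria. Each evaluator is a pure function of
# (variant, bundle, config) returning an acmg_evidence or NULL.

variant_span <- function(v) max(nchar(v$ref), 1L)

# Max of the non-null gnomAD / 1000 Genomes allele frequencies; the
# larger value governs the frequency criteria (conservative choice when
# the resources disagree). NA when absent from both.
population_af <- function(v) {
  afs <- c(v$freq$gnomad_af, v$freq$thousand_genomes_af)
  afs <- afs[!is.null(afs) & !is.na(afs)]
  if (!length(afs)) NA_real_ else max(afs)
}

variant_loeuf_bin <- function(v, bundle, config) {
  loeuf_bin(gene_loeuf(bundle, v$gene), config)
}

#' Evaluate PVS1 (predicted loss of function)
#'
#' Applies to variants with a loss-of-function consequence (frameshift,
#' stop gained, start loss, splice donor/acceptor). With more than one
#' annotated transcript the LoF consequence must be seen in more than
#' one transcript. Variants within the configured window at the 3' end
#' of the final coding exon are excluded. Full (very strong) weight
#' needs a gene LOEUF below 1; LoF-tolerant genes are downgraded to
#' strong. Splice-site variants are further downgraded one rung per
#' failed ABSplice impact check (below `splice_impact`, then below
#' `splice_low`).
#'
#' @param v an `acmg_variant`.
#' @param bundle an `acmg_reference_bundle`.
#' @param config an `acmg_config`.
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_pvs1 <- function(v, bundle, config = default_engine_config()) {
  lof <- lof_consequences()
  tx <- v$transcripts
  if (length(tx) > 1) {
    lof_tx <- vapply(tx, function(t) any(t$consequences %in% lof), TRUE)
    if (sum(lof_tx) < 2L) return(NULL)
    lof_here <- unique(unlist(lapply(tx[lof_tx], function(t)
      intersect(t$consequences, lof))))
    n_lof_tx <- sum(lof_tx); n_tx <- length(tx)
  } else {
    cons <- if (length(tx) == 1) tx[[1]]$consequences else v$consequences
    lof_here <- intersect(cons, lof)
    if (!length(lof_here)) return(NULL)
    n_lof_tx <- length(tx); n_tx <- max(length(tx), 1L)
  }
  # final-coding-exon exclusion window
  fce <- bundle$final_coding_exons
  tx_ids <- vapply(tx, function(t) t$id %||% NA_character_, "")
  hit <- fce[fce$transcript %in% tx_ids, , drop = FALSE]
  win <- config$pvs1$final_exon_window
  if (nrow(hit)) {
    in_window <- v$chrom == sub("^chr", "", hit$chrom) &
      v$pos > hit$end - win & v$pos <= hit$end
    if (any(in_window)) return(NULL)
  }
  loeuf <- gene_loeuf(bundle, v$gene)
  strength <- if (!is.na(loeuf) && loeuf < config$pvs1$loeuf_full_strength)
    strength_value("very_strong") else strength_value("strong")
  splice_only <- all(lof_here %in% c("splice donor variant",
                                     "splice acceptor variant"))
  absplice <- v$scores$absplice
  if (splice_only && !is.null(absplice)) {
    if (absplice < config$pvs1$splice_impact) strength <- downweight(strength)
    if (absplice < config$pvs1$splice_low) strength <- downweight(strength)
  }
  evidence_call(
    "PVS1", strength,
    sprintf("LoF consequence (%s) in %d/%d transcript(s); gene LOEUF %s",
            paste(lof_here, collapse = ", "), n_lof_tx, n_tx,
            if (is.na(loeuf)) "unavailable" else format(loeuf)),
    details = list(loeuf = loeuf, consequences = lof_here,
                   absplice = absplice))
}

#' Evaluate PS1 / PM5 (known pathogenic amino-acid site)
#'
#' Missense variants are compared with the reference index of
#' pathogenic amino-acid substitutions. An identical nucleotide change
#' is skipped (that evidence belongs to PP5). A different nucleotide
#' change producing the same substitution gives PS1; a different
#' substitution at the same residue gives PM5. The strength is the
#' reference record's review weight, capped at strong (PS1) or moderate
#' (PM5).
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` (PS1 or PM5) or NULL.
#' @export
evaluate_ps1_pm5 <- function(v, bundle, config = default_engine_config()) {
  if (!any(is_missense(v$consequences))) return(NULL)
  aa <- parse_aa_change(v$aa_change)
  if (is.null(aa) || is.null(v$gene)) return(NULL)
  idx <- bundle$pathogenic_aa
  site <- idx[idx$gene == v$gene & idx$residue == aa$pos &
                idx$ref_aa == aa$ref, , drop = FALSE]
  if (!nrow(site)) return(NULL)
  key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  if (any(site$key == key)) return(NULL)  # exact match reserved for PP5
  same_sub <- site[site$alt_aa == aa$alt, , drop = FALSE]
  if (nrow(same_sub)) {
    best <- same_sub[which.max(same_sub$weight), ]
    strength <- min(best$weight, config$ps1_pm5$ps1_cap)
    return(evidence_call(
      "PS1", strength,
      sprintf("same amino acid substitution %s as known pathogenic variant %s (review weight %d)",
              format_aa_change(aa), best$clinvar_id, best$weight),
      details = list(clinvar_id = best$clinvar_id,
                     reference_key = best$key, review_weight = best$weight)))
  }
  best <- site[which.max(site$weight), ]
  strength <- min(best$weight, config$ps1_pm5$pm5_cap)
  evidence_call(
    "PM5", strength,
    sprintf("novel substitution %s at residue %d with known pathogenic %s%d%s (review weight %d)",
            format_aa_change(aa), aa$pos, best$ref_aa, best$residue,
            best$alt_aa, best$weight),
    details = list(clinvar_id = best$clinvar_id,
                   reference_key = best$key, review_weight = best$weight))
}

#' Evaluate PS3 (functional-study literature evidence)
#'
#' Looks up the variant in the literature index, first by genomic key,
#' then by (gene, protein change). The strength grows with the number
#' of unique publications: 1 -> supporting, 2..4 -> moderate, 5+ ->
#' strong (configurable tiers). The PubMed IDs are carried in the call
#' details.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_ps3 <- function(v, bundle, config = default_engine_config()) {
  key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  pmids <- bundle$literature$genomic[[key]]
  matched_by <- "genomic"
  if (is.null(pmids)) {
    aa <- parse_aa_change(v$aa_change)
    if (!is.null(aa) && !is.null(v$gene)) {
      pmids <- bundle$literature$protein[[paste(v$gene, format_aa_change(aa),
                                                sep = "|")]]
      matched_by <- "protein"
    }
  }
  pmids <- unique(pmids)
  n <- length(pmids)
  if (n == 0) return(NULL)
  strength <- if (n <= config$ps3$supporting_max) strength_value("supporting")
  else if (n <= config$ps3$moderate_max) strength_value("moderate")
  else strength_value("strong")
  evidence_call(
    "PS3", strength,
    sprintf("%d unique publication(s) with functional evidence (%s match)",
            n, matched_by),
    details = list(pubmed_ids = pmids, matched_by = matched_by))
}

#' Evaluate PS4 (case-control / prevalence evidence)
#'
#' A GWAS catalog hit at the variant position is tiered on odds ratio
#' and p-value. Without a GWAS entry, the TOPMed cohort acts as a
#' prevalence proxy: fewer than 5 alternate alleles, or 3 to 9
#' homozygotes, gives supporting weight.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_ps4 <- function(v, bundle, config = default_engine_config()) {
  k <- paste(v$chrom, v$pos, sep = ":")
  g <- bundle$gwas[[k]]
  cf <- config$ps4
  if (!is.null(g)) {
    strength <- if (g$pvalue < cf$gwas_p_strong && g$or >= cf$or_strong)
      strength_value("strong")
    else if (g$pvalue < cf$gwas_p_strong && g$or >= cf$or_moderate)
      strength_value("moderate")
    else if (g$pvalue < cf$gwas_p_supporting && g$or > 1)
      strength_value("supporting")
    else return(NULL)
    return(evidence_call(
      "PS4", strength,
      sprintf("GWAS association at %s: OR %.3g, p %.3g", k, g$or, g$pvalue),
      details = list(odds_ratio = g$or, pvalue = g$pvalue)))
  }
  ac <- v$freq$topmed_ac; hom <- v$freq$topmed_hom_count
  ac_hit <- !is.null(ac) && ac < cf$topmed_ac_max
  hom_hit <- !is.null(hom) && hom >= cf$topmed_hom_min &&
    hom <= cf$topmed_hom_max
  if (!ac_hit && !hom_hit) return(NULL)
  evidence_call(
    "PS4", strength_value("supporting"),
    sprintf("TOPMed prevalence proxy: %s",
            if (ac_hit) sprintf("%d alternate allele(s)", as.integer(ac))
            else sprintf("%d homozygote(s)", as.integer(hom))),
    details = list(topmed_ac = ac, topmed_hom_count = hom))
}

#' Evaluate PM1 (mutational hotspot / functional domain)
#'
#' Applies when the variant overlaps a retained hotspot domain. Default
#' weight is moderate; lowered to supporting when the domain holds
#' fewer than 75% pathogenic and more than 15% benign variants; raised
#' to strong when it holds more than 90% pathogenic and fewer than 10%
#' benign variants.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_pm1 <- function(v, bundle, config = default_engine_config()) {
  hits <- interval_overlaps(bundle$hotspot_index, v$chrom, v$pos,
                            width = variant_span(v))
  if (!nrow(hits)) return(NULL)
  d <- hits[1, ]
  cf <- config$pm1
  strength <- strength_value("moderate")
  if (d$path_frac < cf$supporting_path_below &&
      d$benign_frac > cf$supporting_benign_above) {
    strength <- strength_value("supporting")
  }
  if (d$path_frac > cf$strong_path_above &&
      d$benign_frac < cf$strong_benign_below) {
    strength <- strength_value("strong")
  }
  evidence_call(
    "PM1", strength,
    sprintf("in hotspot domain %s (%.1f%% pathogenic, %.1f%% benign of %d variants)",
            d$id, 100 * d$path_frac, 100 * d$benign_frac, d$n_total),
    details = list(domain_id = d$id, path_frac = d$path_frac,
                   benign_frac = d$benign_frac, n_total = d$n_total))
}

#' Evaluate PM2 (absent or ultra-rare in population databases)
#'
#' The larger of the gnomAD and 1000 Genomes allele frequencies is
#' compared with the gene's LOEUF-bin cutoffs: absent from both, or
#' below the standard cutoff, gives moderate; between the standard and
#' supporting cutoffs gives supporting.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_pm2 <- function(v, bundle, config = default_engine_config()) {
  bin <- variant_loeuf_bin(v, bundle, config)
  cut <- config$loeuf_bins[bin, ]
  af <- population_af(v)
  if (is.na(af)) {
    return(evidence_call(
      "PM2", strength_value("moderate"),
      "absent from gnomAD and 1000 Genomes",
      details = list(loeuf_bin = bin)))
  }
  if (af < cut$pm2_standard) {
    evidence_call(
      "PM2", strength_value("moderate"),
      sprintf("AF %.3g below standard cutoff %.3g (LOEUF bin %d)",
              af, cut$pm2_standard, bin),
      details = list(af = af, loeuf_bin = bin))
  } else if (af < cut$pm2_supporting) {
    evidence_call(
      "PM2", strength_value("supporting"),
      sprintf("AF %.3g between standard %.3g and supporting %.3g cutoffs (LOEUF bin %d)",
              af, cut$pm2_standard, cut$pm2_supporting, bin),
      details = list(af = af, loeuf_bin = bin))
  } else NULL
}

#' Evaluate PM4 (protein-length change outside repeats)
#'
#' Stop-loss and in-frame indel variants outside repeat-coding regions
#' score by amino-acid length: below 4 residues supporting, 4 to 10
#' moderate, above 10 strong. Stop-loss changes are treated as
#' extension events with a minimum of supporting.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_pm4 <- function(v, bundle, config = default_engine_config()) {
  eligible <- c("stop loss", "inframe insertion", "inframe deletion")
  if (!any(v$consequences %in% eligible)) return(NULL)
  hits <- interval_overlaps(bundle$repeat_index, v$chrom, v$pos,
                            width = variant_span(v))
  if (nrow(hits)) return(NULL)  # repeat-region indels are excluded
  aa_len <- indel_length(v$ref, v$alt) / 3
  cf <- config$pm4
  strength <- if (aa_len < cf$supporting_aa_below) strength_value("supporting")
  else if (aa_len <= cf$strong_aa_above) strength_value("moderate")
  else strength_value("strong")
  evidence_call(
    "PM4", strength,
    sprintf("%s of %.0f amino acid(s) outside repeat regions",
            intersect(v$consequences, eligible)[1], aa_len),
    details = list(aa_length = aa_len))
}

#' Evaluate PP2 (missense in a missense-constrained gene)
#'
#' Requires the gene to appear in the precomputed missense-constrained
#' list and the consequence to contain "missense". Supporting by
#' default; moderate when the gene's recorded missense OE is below 10%.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_pp2 <- function(v, bundle, config = default_engine_config()) {
  if (is.null(v$gene) || !(v$gene %in% names(bundle$pp2_genes))) return(NULL)
  if (!any(is_missense(v$consequences))) return(NULL)
  oe <- unname(bundle$pp2_genes[[v$gene]])
  strength <- if (!is.na(oe) && oe < config$pp2$oe_moderate)
    strength_value("moderate") else strength_value("supporting")
  evidence_call(
    "PP2", strength,
    sprintf("missense variant in missense-constrained gene %s%s", v$gene,
            if (is.na(oe)) "" else sprintf(" (missense OE %.3g)", oe)),
    details = list(gene = v$gene, missense_oe = oe))
}

#' Evaluate PP3 / BP4 (in-silico predictor consensus)
#'
#' Each non-null tool score is mapped onto its configured ladder:
#' pathogenic contributions for scores at or above the pathogenic
#' thresholds, benign contributions for scores at or below the benign
#' thresholds. A side is disqualified when any tool reaches the
#' opposite side's strong rung. The base strength is the maximum
#' contribution; two or more tools tying at that level up-weight the
#' call one rung (capped at very strong); a lone supporting-level tool
#' is not enough. When both sides survive their own rules, the evidence
#' is treated as mixed and neither code is applied.
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_pp3 <- function(v, bundle, config = default_engine_config()) {
  insilico_calls(v, config)$pp3
}

ladder_level <- function(score, thresholds, side) {
  # highest rung whose threshold the score crosses; 0 = none
  lvl <- 0L
  for (i in 1:4) {
    thr <- thresholds[i]
    if (is.na(thr)) next
    hit <- if (side == "pathogenic") score >= thr else score <= thr
    if (hit) lvl <- i
  }
  lvl
}

insilico_calls <- function(v, config) {
  tools_cfg <- config$insilico
  path_lvl <- benign_lvl <- integer(0)
  for (tool in names(tools_cfg)) {
    score <- v$scores[[tool]]
    if (is.null(score)) next
    path_lvl[tool] <- ladder_level(score, tools_cfg[[tool]]$pathogenic,
                                   "pathogenic")
    benign_lvl[tool] <- ladder_level(score, tools_cfg[[tool]]$benign,
                                     "benign")
  }
  side_call <- function(lvl, opp_lvl, code) {
    # disqualified if any tool reaches strong on the opposite side
    if (any(opp_lvl >= strength_value("strong"))) return(NULL)
    contrib <- lvl[lvl > 0]
    if (!length(contrib)) return(NULL)
    base <- max(contrib)
    n_at_max <- sum(contrib == base)
    if (base == strength_value("supporting") && length(contrib) == 1) {
      return(NULL)  # a lone supporting-level tool is not applied
    }
    strength <- if (n_at_max >= 2)
      min(base + 1L, strength_value("very_strong")) else base
    evidence_call(
      code, strength,
      sprintf("%d tool(s) support a %s effect (max level %s%s): %s",
              length(contrib),
              if (code == "PP3") "pathogenic" else "benign",
              strength_name(base),
              if (n_at_max >= 2) ", up-weighted on agreement" else "",
              paste(names(contrib), collapse = ", ")),
      details = list(tools = names(contrib),
                     levels = stats::setNames(as.integer(contrib),
                                              names(contrib))))
  }
  pp3 <- side_call(path_lvl, benign_lvl, "PP3")
  bp4 <- side_call(benign_lvl, path_lvl, "BP4")
  if (!is.null(pp3) && !is.null(bp4)) {
    # mixed in-silico evidence: suppress both sides
    return(list(pp3 = NULL, bp4 = NULL))
  }
  list(pp3 = pp3, bp4 = bp4)
}

#' Evaluate PP5 (reputable-source pathogenic assertion)
#'
#' Applies to variants whose top ClinVar entry is pathogenic or likely
#' pathogenic; the strength is the review-status weight (practice
#' guidelines / expert panel give the stand-alone rung — the engine's
#' pathogenic parallel to BA1).
#'
#' @inheritParams evaluate_pvs1
#' @return `acmg_evidence` or NULL.
#' @export
evaluate_pp5 <- function(v, bundle, config = default_engine_config()) {
  clinvar_assertion_call(v, config, c("P", "LP"), "PP5")
}

clinvar_assertion_call <- function(v, config, sigs, code) {
  cv <- v$clinvar
  if (is.null(cv)) return(NULL)
  sig <- normalize_significance(cv$significance)
  if (is.na(sig) || !(sig %in% sigs)) return(NULL)
  w <- strength_from_review_status(
    cv$review_status, unlist(config$review_weights))
  if (w == 0L) return(NULL)
  evidence_call(
    code, w,
    sprintf("ClinVar %s assertion with review status '%s'",
            sig, cv$review_status),
    details = list(clinvar_id = cv$id %||% NA_character_,
                   significance = sig, review_status = cv$review_status))
}
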