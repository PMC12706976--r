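# Orchestration: run all automated criteria on a variant, apply
# external calls/overrides, then combine evidence with the modified
# ACMG procedure (pathogenic stand-alone extension + ordered two-pass
# conflict checks).

#' Run all automated criteria and apply external calls
#'
#' Evaluates the 17 automated evaluators (19 codes) and then applies
#' any external calls for this variant: a strength of 0 removes the
#' code; any other strength sets or overrides it with source "manual".
#' At most one call per code survives; duplicate external calls for the
#' same code resolve last-wins with a warning.
#'
#' @param v an `acmg_variant`.
#' @param bundle an `acmg_reference_bundle`.
#' @param config an `acmg_config`.
#' @param external list of external calls for this variant (see
#'   [read_external_calls()]); keys are not re-checked here.
#' @return named list of `acmg_evidence`, keyed by code.
#' @export
evaluate_variant <- function(v, bundle, config = default_engine_config(),
                             external = list()) {
  calls <- list()
  add <- function(x) {
    if (is.null(x)) return()
    if (inherits(x, "acmg_evidence")) x <- list(x)
    for (e in x) calls[[e$code]] <<- e
  }
  add(evaluate_pvs1(v, bundle, config))
  add(evaluate_ps1_pm5(v, bundle, config))
  add(evaluate_ps3(v, bundle, config))
  add(evaluate_ps4(v, bundle, config))
  add(evaluate_pm1(v, bundle, config))
  add(evaluate_pm2(v, bundle, config))
  add(evaluate_pm4(v, bundle, config))
  add(evaluate_pp2(v, bundle, config))
  ic <- insilico_calls(v, config)
  add(ic$pp3)
  add(ic$bp4)
  add(evaluate_pp5(v, bundle, config))
  add(evaluate_ba1_bs1(v, bundle, config))
  add(evaluate_bs2(v, bundle, config))
  add(evaluate_bp1(v, bundle, config))
  add(evaluate_bp3(v, bundle, config))
  add(evaluate_bp6(v, bundle, config))
  add(evaluate_bp7(v, bundle, config))
  if (length(external)) {
    codes <- vapply(external, function(x) x$code, "")
    dup <- unique(codes[duplicated(codes)])
    if (length(dup)) {
      warning("duplicate external calls for code(s) ",
              paste(dup, collapse = ", "), "; last call wins")
    }
    for (ec in external) {
      if (ec$strength == 0L) {
        calls[[ec$code]] <- NULL
      } else {
        calls[[ec$code]] <- evidence_call(
          ec$code, ec$strength,
          if (nzchar(ec$rationale %||% "")) ec$rationale
          else "manual external call",
          source = "manual")
      }
    }
  }
  calls
}

# The published combining rules, written as multisets of required
# strength rungs (5 = stand-alone .. 1 = supporting). A rule is met
# when distinct applied codes of the right polarity can be assigned
# one-to-one to its requirements, each at or above its rung — so a
# dynamically up-weighted code satisfies any lower requirement.
combining_rules <- function() {
  list(
    pathogenic = list(
      c(5L),                 # pathogenic stand-alone (engine extension)
      c(4L, 3L), c(4L, 2L, 2L), c(4L, 2L, 1L), c(4L, 1L, 1L),
      c(3L, 3L),
      c(3L, 2L, 2L, 2L), c(3L, 2L, 2L, 1L, 1L),
      c(3L, 2L, 1L, 1L, 1L, 1L)),
    likely_pathogenic = list(
      c(4L, 2L), c(3L, 2L), c(3L, 1L, 1L),
      c(2L, 2L, 2L), c(2L, 2L, 1L, 1L), c(2L, 1L, 1L, 1L, 1L)),
    benign = list(c(5L), c(3L, 3L)),
    likely_benign = list(c(3L, 1L), c(1L, 1L))
  )
}

# levels: integer vector of applied strengths for one polarity.
# req: rule requirement rungs. Nested threshold sets make Hall's
# condition exact: for every rung t, at least as many codes at >= t as
# requirements at >= t.
rule_met <- function(levels, req) {
  if (length(levels) < length(req)) return(FALSE)
  for (t in 1:5) {
    if (sum(levels >= t) < sum(req >= t)) return(FALSE)
  }
  TRUE
}

any_rule_met <- function(levels, rules) {
  for (r in rules) if (rule_met(levels, r)) return(TRUE)
  FALSE
}

#' Combine evidence calls into a five-tier classification
#'
#' Ordered procedure: (1) high-tolerance conflict check — pathogenic
#' and benign strength sums both at or above `conflict$high` routes the
#' variant to Uncertain; (2) pathogenic rules (including the pathogenic
#' stand-alone extension); (3) benign rules; (4) low-tolerance conflict
#' check at `conflict$low`; (5) likely-pathogenic rules; (6)
#' likely-benign rules; (7) otherwise Uncertain. Codes count at their
#' effective (dynamically weighted) strength, and an up-weighted code
#' satisfies any lower rung of a rule.
#'
#' @param evidence list of `acmg_evidence` (at most one per code).
#' @param config an `acmg_config` (for the conflict thresholds).
#' @param variant optional `acmg_variant` for the result key.
#' @return object of class `acmg_classification` with fields
#'   `category` (P/LP/VUS/LB/B), `evidence`, `conflict_stage`
#'   (none/high/low), `pathogenic_score`, `benign_score`.
#' @export
combine_evidence <- function(evidence, config = default_engine_config(),
                             variant = NULL) {
  evidence <- evidence[!vapply(evidence, is.null, TRUE)]
  codes <- vapply(evidence, function(e) e$code, "")
  if (anyDuplicated(codes)) stop("more than one evidence call per code")
  pol <- if (length(codes)) code_polarity(codes) else character(0)
  strengths <- vapply(evidence, function(e) e$strength, 1L)
  p_lv <- strengths[pol == "pathogenic"]
  b_lv <- strengths[pol == "benign"]
  p_sum <- as.integer(sum(p_lv)); b_sum <- as.integer(sum(b_lv))
  rules <- combining_rules()
  cf <- config$conflict
  category <- NULL; conflict <- "none"
  if (p_sum >= cf$high && b_sum >= cf$high) {
    category <- "VUS"; conflict <- "high"
  } else if (any_rule_met(p_lv, rules$pathogenic)) {
    category <- "P"
  } else if (any_rule_met(b_lv, rules$benign)) {
    category <- "B"
  } else if (p_sum >= cf$low && b_sum >= cf$low) {
    category <- "VUS"; conflict <- "low"
  } else if (any_rule_met(p_lv, rules$likely_pathogenic)) {
    category <- "LP"
  } else if (any_rule_met(b_lv, rules$likely_benign)) {
    category <- "LB"
  } else {
    category <- "VUS"
  }
  res <- list(
    chrom = variant$chrom %||% NA_character_,
    pos = variant$pos %||% NA_integer_,
    ref = variant$ref %||% NA_character_,
    alt = variant$alt %||% NA_character_,
    gene = variant$gene %||% NA_character_,
    category = category,
    evidence = unname(evidence),
    conflict_stage = conflict,
    pathogenic_score = p_sum,
    benign_score = b_sum
  )
  res$key <- if (!is.na(res$chrom))
    variant_key(res$chrom, res$pos, res$ref, res$alt) else NA_character_
  class(res) <- "acmg_classification"
  res
}

category_labels <- function() {
  c(P = "Pathogenic", LP = "Likely pathogenic",
    VUS = "Uncertain significance", LB = "Likely benign", B = "Benign")
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat(sprintf("<acmg_classification> %s: %s (path %d / benign %d%s)\n",
              x$key, category_labels()[x$category], x$pathogenic_score,
              x$benign_score,
              if (x$conflict_stage != "none")
                paste0(", conflict ", x$conflict_stage) else ""))
  for (e in x$evidence) cat("  ", format_evidence(e), "\n", sep = "")
  invisible(x)
}

format_evidence <- function(e) {
  sprintf("%s:%s", e$code, strength_name(e$strength))
}

#' Classify a list of variants
#'
#' Order-preserving; a per-variant failure produces an Uncertain result
#' with an error rationale instead of aborting the run. A structured
#' progress message is emitted every `log_every` variants.
#'
#' @param variants list of `acmg_variant`.
#' @param bundle an `acmg_reference_bundle`.
#' @param config an `acmg_config`.
#' @param external_calls list of external calls (see
#'   [read_external_calls()]); matched to variants by key.
#' @param log_every emit a progress message every this many variants
#'   (0 disables).
#' @return list of `acmg_classification`, one per input variant.
#' @export
classify_variants <- function(variants, bundle,
                              config = default_engine_config(),
                              external_calls = list(),
                              log_every = 10000L) {
  required <- c("pathogenic_aa", "hotspot_index", "literature", "gwas",
                "repeat_index", "pp2_genes", "bp1_genes",
                "gene_constraint", "final_coding_exons")
  missing <- setdiff(required, names(bundle))
  if (length(missing)) stop("reference bundle missing required index(es): ",
                            paste(missing, collapse = ", "))
  ext_by_key <- split(external_calls,
                      vapply(external_calls, function(x) x$key, ""))
  out <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    out[[i]] <- tryCatch({
      ext <- ext_by_key[[variant_key(v$chrom, v$pos, v$ref, v$alt)]] %||%
        list()
      combine_evidence(evaluate_variant(v, bundle, config, ext),
                       config, variant = v)
    }, error = function(e) {
      res <- combine_evidence(list(), config, variant = v)
      res$category <- "VUS"
      res$error <- conditionMessage(e)
      res
    })
    if (log_every > 0 && i %% log_every == 0) {
      message(sprintf("classified %d/%d variants", i, length(variants)))
    }
  }
  out
}

#' Classify a variant JSON file end to end
#'
#' Reads annotated variants, classifies them against a loaded reference
#' bundle and writes the classification TSV.
#'
#' @param variants_path annotated-variant JSON path.
#' @param bundle_dir reference bundle directory.
#' @param out_path output TSV path.
#' @param config an `acmg_config` or path to a config JSON.
#' @param external_path optional external call TSV path.
#' @return the classification list, invisibly.
#' @export
classify_file <- function(variants_path, bundle_dir, out_path,
                          config = default_engine_config(),
                          external_path = NULL) {
  if (is.character(config)) config <- read_engine_config(config)
  bundle <- load_reference_bundle(bundle_dir)
  variants <- read_annotated_variants(variants_path)
  ext <- if (!is.null(external_path)) read_external_calls(external_path)
  else list()
  results <- classify_variants(variants, bundle, config, ext)
  write_classifications(results, out_path)
  invisible(results)
}
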