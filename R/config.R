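#' Default LOEUF bin table
#'
#' Population-frequency cutoffs are stratified into five gene-constraint
#' bins keyed by the gnomAD LOEUF score (loss-of-function observed /
#' expected upper bound fraction). Constrained genes (low LOEUF) get
#' stricter cutoffs; tolerant genes get more lenient ones. The bin of a
#' gene is the first row whose `upper` bound is >= its LOEUF (upper bound
#' inclusive); genes missing from the constraint table fall into the
#' middle bin (see `default_loeuf_bin` in [default_engine_config()]).
#'
#' Columns: `upper` (LOEUF upper bound), allele-frequency cutoffs
#' `pm2_standard` < `pm2_supporting` <= `bs1_supporting` < `bs1_standard`
#' <= `ba1`, and `bs2_af` (the allele-frequency ceiling for the
#' autosomal-dominant BS2 branch).
#'
#' @return data.frame with five rows (most to least constrained).
#' @export
default_loeuf_bins <- function() {
  bs1_supporting <- c(5e-4, 1e-3, 2e-3, 5e-3, 1e-2)
  data.frame(
    upper          = c(0.35, 0.6, 1.0, 1.5, Inf),
    pm2_standard   = c(1e-6, 2e-6, 5e-6, 1e-5, 2e-5),
    pm2_supporting = 5 * c(1e-6, 2e-6, 5e-6, 1e-5, 2e-5),
    bs1_supporting = bs1_supporting,
    bs1_standard   = 5 * bs1_supporting,
    ba1            = c(5e-3, 1e-2, 2e-2, 5e-2, 5e-2),
    bs2_af         = bs1_supporting
  )
}

#' Resolve the LOEUF bin for a gene constraint value
#'
#' @param loeuf numeric LOEUF value or NA/NULL for genes absent from the
#'   constraint table.
#' @param config engine configuration (for the bin table and default bin).
#' @return integer bin index in 1..5 (1 = most constrained).
#' @export
loeuf_bin <- function(loeuf, config = default_engine_config()) {
  bins <- config$loeuf_bins
  if (is.null(loeuf) || length(loeuf) == 0 || is.na(loeuf)) {
    return(as.integer(config$default_loeuf_bin))
  }
  as.integer(which(bins$upper >= loeuf)[1])
}

#' Default per-tool cutoff ladders for PP3/BP4
#'
#' For each in-silico tool, four pathogenic thresholds (score at or above
#' which the tool contributes at supporting / moderate / strong /
#' very_strong) and four benign thresholds (score at or below which it
#' contributes on the benign side). NA marks an unreachable rung.
#' Values are configuration data drawn from the published calibrations
#' for REVEL, phyloP and GERP, the ABSplice authors' tiers for ABSplice,
#' and conservative defaults for DANN (which has no published
#' calibration).
#'
#' @return named list of per-tool lists with `pathogenic` and `benign`
#'   numeric vectors of length 4 (supporting, moderate, strong,
#'   very_strong).
#' @export
default_insilico_ladders <- function() {
  lad <- function(p, b) list(pathogenic = p, benign = b)
  list(
    revel    = lad(c(0.644, 0.773, 0.932, NA), c(0.290, 0.183, 0.016, 0.003)),
    dann     = lad(c(0.99, 0.999, NA, NA),     c(0.30, 0.05, NA, NA)),
    phylop   = lad(c(7.367, 9.88, NA, NA),     c(0.21, -1.04, -4.0, NA)),
    gerp     = lad(c(2.7, NA, NA, NA),         c(-4.54, NA, NA, NA)),
    absplice = lad(c(0.05, 0.2, NA, NA),       c(0.01, NA, NA, NA))
  )
}

#' Default engine configuration
#'
#' Every tunable number the rule engine consumes lives here; rule code
#' contains no hard-coded thresholds. The classification of a variant is
#' a pure function of (variant annotations, reference bundle, config).
#'
#' @return list of class `acmg_config`.
#' @export
default_engine_config <- function() {
  cfg <- list(
    loeuf_bins = default_loeuf_bins(),
    default_loeuf_bin = 3L,
    review_weights = as.list(default_review_weights()),
    insilico = default_insilico_ladders(),
    pvs1 = list(loeuf_full_strength = 1.0, splice_impact = 0.2,
                splice_low = 0.05, final_exon_window = 50L),
    ps1_pm5 = list(ps1_cap = 3L, pm5_cap = 2L),
    ps3 = list(supporting_max = 1L, moderate_max = 4L),
    ps4 = list(gwas_p_strong = 5e-8, or_strong = 3, or_moderate = 1.5,
               gwas_p_supporting = 1e-5, topmed_ac_max = 5L,
               topmed_hom_min = 3L, topmed_hom_max = 9L),
    pm1 = list(supporting_path_below = 0.75, supporting_benign_above = 0.15,
               strong_path_above = 0.90, strong_benign_below = 0.10),
    pm4 = list(supporting_aa_below = 4L, strong_aa_above = 10L),
    pp2 = list(oe_exclude = 0.4, oe_moderate = 0.10),
    bs2 = list(recessive_hom = 2L, dominant_allele = 5L, x_linked = 2L,
               ad_loeuf_max = 0.5),
    bp3 = list(strong_below_nt = 15L, supporting_below_nt = 60L),
    bp7 = list(phylop_eligible = 7.367, absplice_eligible = 0.05,
               absplice_strong = 0.01, phylop_strong = 0.21),
    conflict = list(high = 4L, low = 2L)
  )
  class(cfg) <- "acmg_config"
  validate_engine_config(cfg)
  cfg
}

#' Validate an engine configuration
#'
#' Checks the LOEUF bin cutoff ordering within each bin
#' (pm2_standard < pm2_supporting <= bs1_supporting < bs1_standard <= ba1;
#' the last pair may be equal in the least-constrained bins) and
#' non-decreasing cutoffs from most- to least-constrained bin, plus
#' finiteness of every scalar threshold.
#'
#' @param config an `acmg_config` list.
#' @return the config, invisibly; errors on violation.
#' @export
validate_engine_config <- function(config) {
  b <- config$loeuf_bins
  stopifnot(nrow(b) == 5L, all(diff(b$upper) > 0))
  ok <- b$pm2_standard < b$pm2_supporting &
    b$pm2_supporting <= b$bs1_supporting &
    b$bs1_supporting < b$bs1_standard &
    b$bs1_standard <= b$ba1
  if (!all(ok)) stop("LOEUF bin cutoffs out of order in bin(s): ",
                     paste(which(!ok), collapse = ", "))
  for (col in c("pm2_standard", "pm2_supporting", "bs1_supporting",
                "bs1_standard", "ba1", "bs2_af")) {
    if (any(diff(b[[col]]) < 0)) {
      stop("cutoff column not non-decreasing across bins: ", col)
    }
  }
  scalars <- unlist(config[c("pvs1", "ps1_pm5", "ps3", "ps4", "pm1", "pm4",
                             "pp2", "bs2", "bp3", "bp7", "conflict")])
  stopifnot(all(is.finite(scalars)))
  stopifnot(config$default_loeuf_bin %in% seq_len(nrow(b)))
  invisible(config)
}

#' Read / write an engine configuration as JSON
#'
#' The full configuration serializes to a single JSON file and parses
#' back to an identical object, so a deployment can pin and audit every
#' threshold.
#'
#' @param config an `acmg_config`.
#' @param path file path.
#' @return `read_engine_config()` returns an `acmg_config`.
#' @export
write_engine_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_engine_config
#' @export
read_engine_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- raw
  cfg$loeuf_bins <- as.data.frame(lapply(raw$loeuf_bins, function(x) {
    x <- suppressWarnings(as.numeric(x))  # "Inf"/null round-trip
    x[is.na(x)] <- Inf
    x
  }))
  cfg$default_loeuf_bin <- as.integer(raw$default_loeuf_bin)
  cfg$review_weights <- lapply(raw$review_weights, as.integer)
  cfg$insilico <- lapply(raw$insilico, function(t) {
    list(pathogenic = as.numeric(t$pathogenic), benign = as.numeric(t$benign))
  })
  int_fields <- list(
    pvs1 = "final_exon_window", ps1_pm5 = c("ps1_cap", "pm5_cap"),
    ps3 = c("supporting_max", "moderate_max"),
    ps4 = c("topmed_ac_max", "topmed_hom_min", "topmed_hom_max"),
    pm4 = c("supporting_aa_below", "strong_aa_above"),
    bs2 = c("recessive_hom", "dominant_allele", "x_linked"),
    bp3 = c("strong_below_nt", "supporting_below_nt"),
    conflict = c("high", "low"))
  for (sec in names(int_fields)) {
    for (f in int_fields[[sec]]) cfg[[sec]][[f]] <- as.integer(cfg[[sec]][[f]])
  }
  class(cfg) <- "acmg_config"
  validate_engine_config(cfg)
  cfg
}
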