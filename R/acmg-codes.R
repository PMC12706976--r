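#' The five-level evidence strength ladder
#'
#' Evidence strengths are integers 1..5: 1 = supporting, 2 = moderate,
#' 3 = strong, 4 = very strong, 5 = stand-alone. 0 means "not applied".
#' Dynamic weighting moves an applied code up or down this ladder.
#'
#' @return Named integer vector mapping strength names to values.
#' @export
strength_levels <- function() {
  c(supporting = 1L, moderate = 2L, strong = 3L,
    very_strong = 4L, stand_alone = 5L)
}

#' @rdname strength_levels
#' @param x integer strength value(s) in 0..5.
#' @export
strength_name <- function(x) {
  stopifnot(all(x %in% 0:5))
  nm <- c("not_applied", names(strength_levels()))
  nm[as.integer(x) + 1L]
}

#' @rdname strength_levels
#' @param name strength name(s), lower_snake vocabulary ("very_strong").
#' @export
strength_value <- function(name) {
  lv <- strength_levels()
  out <- unname(lv[name])
  if (anyNA(out)) stop("unknown strength name: ",
                       paste(setdiff(name, names(lv)), collapse = ", "))
  out
}

#' Move an applied code one rung up or down the strength ladder
#'
#' `upweight()` saturates at stand-alone (5); `downweight()` saturates at
#' supporting (1) — an applied code is never down-weighted to "not applied".
#'
#' @param level integer strength in 1..5.
#' @return integer strength in 1..5.
#' @export
upweight <- function(level) {
  stopifnot(all(level %in% 1:5))
  pmin(as.integer(level) + 1L, 5L)
}

#' @rdname upweight
#' @export
downweight <- function(level) {
  stopifnot(all(level %in% 1:5))
  pmax(as.integer(level) - 1L, 1L)
}

#' The 28 ACMG/AMP evidence codes
#'
#' Returns the full code table: code name, polarity (pathogenic or benign)
#' and whether the engine evaluates it automatically. 19 codes are
#' automated; the remaining 9 (PS2, PM3, PM6, PP1, PP4, BS3, BS4, BP2,
#' BP5) need patient-level information (de novo status, segregation,
#' phenotype specificity, trans phasing) and enter only through the
#' external call file.
#'
#' @return data.frame with columns `code`, `polarity`, `automated`.
#' @export
acmg_codes <- function() {
  path_codes <- c("PVS1",
                  paste0("PS", 1:4),
                  paste0("PM", 1:6),
                  paste0("PP", 1:5))
  benign_codes <- c("BA1",
                    paste0("BS", 1:4),
                    paste0("BP", 1:7))
  automated <- c("PVS1", "PS1", "PS3", "PS4", "PM1", "PM2", "PM4", "PM5",
                 "PP2", "PP3", "PP5", "BA1", "BS1", "BS2", "BP1", "BP3",
                 "BP4", "BP6", "BP7")
  data.frame(
    code = c(path_codes, benign_codes),
    polarity = c(rep("pathogenic", length(path_codes)),
                 rep("benign", length(benign_codes))),
    automated = c(path_codes, benign_codes) %in% automated,
    stringsAsFactors = FALSE
  )
}

#' @rdname acmg_codes
#' @param code character vector of code names.
#' @export
code_polarity <- function(code) {
  tbl <- acmg_codes()
  i <- match(code, tbl$code)
  if (anyNA(i)) stop("unknown ACMG code: ",
                     paste(code[is.na(i)], collapse = ", "))
  tbl$polarity[i]
}

#' Default ClinVar review-status evidence weights
#'
#' Review statuses map onto the strength ladder; statuses carrying no
#' assertion criteria weigh zero and are excluded from all evidence.
#'
#' @return named integer vector, review status -> strength value.
#' @export
default_review_weights <- function() {
  c("practice guidelines" = 5L,
    "reviewed by expert panel" = 5L,
    "criteria provided, multiple submitters, no conflicts" = 3L,
    "criteria provided, single submitter" = 2L,
    "criteria provided, conflicting interpretations" = 1L,
    "no assertion criteria provided" = 0L)
}

#' Map a ClinVar review status to an evidence strength
#'
#' Unknown statuses map to 0 (excluded) rather than erroring, so a
#' reference table with unexpected status strings degrades gracefully.
#'
#' @param status character review status string(s).
#' @param weights named integer map as [default_review_weights()].
#' @return integer strength value(s) in 0..5.
#' @export
strength_from_review_status <- function(status,
                                        weights = default_review_weights()) {
  names(weights) <- tolower(names(weights))
  w <- weights[trimws(tolower(status))]
  as.integer(ifelse(is.na(w), 0L, w))
}

#' Normalize a clinical significance string to one of P/LP/VUS/LB/B/conflicting
#' @param sig character significance values.
#' @return character vector over {"P","LP","VUS","LB","B","conflicting"} or NA.
#' @export
normalize_significance <- function(sig) {
  s <- trimws(tolower(sig))
  out <- rep(NA_character_, length(s))
  out[s %in% c("p", "pathogenic")] <- "P"
  out[s %in% c("lp", "likely pathogenic", "likely_pathogenic")] <- "LP"
  out[s %in% c("vus", "uncertain significance", "uncertain_significance",
               "uncertain")] <- "VUS"
  out[s %in% c("lb", "likely benign", "likely_benign")] <- "LB"
  out[s %in% c("b", "benign")] <- "B"
  out[grepl("conflict", s)] <- "conflicting"
  out
}
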