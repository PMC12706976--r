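# Independent brute-force oracle for the evidence-combining procedure.
# Written deliberately in a different style from the package: rules are
# checked by exhaustive backtracking assignment of codes to rule slots
# (the package uses a counting argument), and the stage order is
# restated from scratch.

oracle_rules_pathogenic <- list(
  c(5),
  c(4, 3), c(4, 2, 2), c(4, 2, 1), c(4, 1, 1),
  c(3, 3), c(3, 2, 2, 2), c(3, 2, 2, 1, 1), c(3, 2, 1, 1, 1, 1))
oracle_rules_likely_pathogenic <- list(
  c(4, 2), c(3, 2), c(3, 1, 1), c(2, 2, 2), c(2, 2, 1, 1),
  c(2, 1, 1, 1, 1))
oracle_rules_benign <- list(c(5), c(3, 3))
oracle_rules_likely_benign <- list(c(3, 1), c(1, 1))

# Can `levels` (one entry per applied code) fill every slot of `req`,
# each slot taking a distinct code with level >= the slot's rung?
# Exhaustive backtracking over all assignments.
oracle_slots_fillable <- function(levels, req) {
  if (length(req) == 0) return(TRUE)
  for (i in seq_along(levels)) {
    if (levels[i] >= req[1] &&
        oracle_slots_fillable(levels[-i], req[-1])) {
      return(TRUE)
    }
  }
  FALSE
}

oracle_meets_any <- function(levels, rules) {
  any(vapply(rules, function(r) oracle_slots_fillable(levels, r), TRUE))
}

# p, b: integer vectors of applied strengths per polarity.
oracle_combine <- function(p, b, high = 4, low = 2) {
  if (sum(p) >= high && sum(b) >= high) {
    return(list(category = "VUS", conflict = "high"))
  }
  if (oracle_meets_any(p, oracle_rules_pathogenic)) {
    return(list(category = "P", conflict = "none"))
  }
  if (oracle_meets_any(b, oracle_rules_benign)) {
    return(list(category = "B", conflict = "none"))
  }
  if (sum(p) >= low && sum(b) >= low) {
    return(list(category = "VUS", conflict = "low"))
  }
  if (oracle_meets_any(p, oracle_rules_likely_pathogenic)) {
    return(list(category = "LP", conflict = "none"))
  }
  if (oracle_meets_any(b, oracle_rules_likely_benign)) {
    return(list(category = "LB", conflict = "none"))
  }
  list(category = "VUS", conflict = "none")
}

# Enumerate all evidence profiles with at most `max_codes` codes drawn
# from levels 1..5 on both polarities, as count matrices
# (p1..p5, b1..b5).
enumerate_profiles <- function(max_codes = 6L) {
  out <- list()
  rec <- function(slot, counts, remaining) {
    if (slot > 10L) {
      out[[length(out) + 1L]] <<- counts
      return(invisible(NULL))
    }
    for (k in 0:remaining) {
      counts[slot] <- k
      rec(slot + 1L, counts, remaining - k)
    }
  }
  rec(1L, integer(10L), max_codes)
  out
}

profile_levels <- function(counts) {
  list(p = rep(1:5, counts[1:5]), b = rep(1:5, counts[6:10]))
}

# Run the package combiner on a profile by materializing evidence
# calls on distinct codes of each polarity.
combine_profile <- function(counts, config = default_engine_config()) {
  lv <- profile_levels(counts)
  tbl <- acmg_codes()
  p_codes <- tbl$code[tbl$polarity == "pathogenic"]
  b_codes <- tbl$code[tbl$polarity == "benign"]
  ev <- c(
    mapply(function(code, s) evidence_call(code, s, "enum"),
           p_codes[seq_along(lv$p)], lv$p, SIMPLIFY = FALSE),
    mapply(function(code, s) evidence_call(code, s, "enum"),
           b_codes[seq_along(lv$b)], lv$b, SIMPLIFY = FALSE))
  combine_evidence(ev, config)
}
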