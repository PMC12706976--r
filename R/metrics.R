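# Benchmark concordance metrics: per-category (P/LP, B/LB, VUS) and
# per-code confusion statistics against an expert truth set.

category_bucket <- function(category) {
  ifelse(category %in% c("P", "LP"), "P/LP",
         ifelse(category %in% c("B", "LB"), "B/LB", "VUS"))
}

round_half_up <- function(x, digits = 2) {
  # percentages are reported with half-up rounding, matching clinical
  # benchmarking convention (R's round() is half-even)
  ifelse(is.na(x), NA_real_, floor(x * 10^digits + 0.5) / 10^digits)
}

pct <- function(num, den) {
  ifelse(den > 0, round_half_up(100 * num / den), NA_real_)
}

results_table <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("key", "category", "code_calls") %in% names(results)))
    return(results[, c("key", "category", "code_calls")])
  }
  data.frame(
    key = vapply(results, function(r) r$key, ""),
    category = vapply(results, function(r) r$category, ""),
    code_calls = I(lapply(results, function(r) data.frame(
      code = vapply(r$evidence, function(e) e$code, ""),
      strength = vapply(r$evidence, function(e) e$strength, 1L),
      stringsAsFactors = FALSE))),
    stringsAsFactors = FALSE)
}

truth_table <- function(truth) {
  data.frame(
    key = vapply(truth, function(t) t$key, ""),
    category = vapply(truth, function(t) t$category, ""),
    codes = I(lapply(truth, function(t) t$codes)),
    stringsAsFactors = FALSE)
}

join_results_truth <- function(results, truth) {
  rt <- results_table(results)
  tt <- truth_table(truth)
  if (anyDuplicated(rt$key)) stop("duplicate variant keys in results")
  if (anyDuplicated(tt$key)) stop("duplicate variant keys in truth set")
  common <- intersect(rt$key, tt$key)
  if (!length(common)) stop("no variant keys shared between results and truth")
  unmatched <- length(setdiff(rt$key, tt$key)) +
    length(setdiff(tt$key, rt$key))
  if (unmatched > 0) {
    warning(unmatched, " unmatched variant key(s) dropped from metrics")
  }
  list(results = rt[match(common, rt$key), , drop = FALSE],
       truth = tt[match(common, tt$key), , drop = FALSE])
}

#' Per-category benchmark metrics
#'
#' Collapses the five tiers into the three clinical buckets (P/LP,
#' B/LB, VUS) and computes a one-vs-rest confusion matrix per bucket:
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), precision =
#' tp/(tp+fp) and F1 = 2*precision*sensitivity/(precision+sensitivity).
#' Percentages carry two decimals (half-up); undefined denominators
#' yield NA, never 0. Metrics are invariant to input order.
#'
#' @param results list of `acmg_classification` (or a data.frame from
#'   [read_classifications()]).
#' @param truth list of truth records (see [read_truth_tsv()]).
#' @return data.frame with one row per bucket: tp, fp, tn, fn,
#'   sensitivity, specificity, precision, f1 (percent).
#' @export
category_metrics <- function(results, truth) {
  j <- join_results_truth(results, truth)
  pred <- category_bucket(j$results$category)
  truth_b <- category_bucket(j$truth$category)
  buckets <- c("P/LP", "B/LB", "VUS")
  rows <- lapply(buckets, function(b) {
    tp <- sum(pred == b & truth_b == b)
    fp <- sum(pred == b & truth_b != b)
    fn <- sum(pred != b & truth_b == b)
    tn <- sum(pred != b & truth_b != b)
    sens <- pct(tp, tp + fn)
    prec <- pct(tp, tp + fp)
    f1 <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_
    else round_half_up(2 * prec * sens / (prec + sens))
    data.frame(bucket = b, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = sens, specificity = pct(tn, tn + fp),
               precision = prec, f1 = f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-code concordance with an expert truth set
#'
#' For each ACMG code, counts the variants where the engine and the
#' truth set applied it (strength is ignored for concordance and
#' reported separately as the agreement rate among shared calls).
#'
#' @inheritParams category_metrics
#' @return data.frame with one row per code: predicted_count,
#'   truth_count, tp, fp, fn, sensitivity, precision, f1 (percent; NA
#'   when undefined), strength_agreement (percent among tp pairs with a
#'   stated truth strength).
#' @export
code_concordance <- function(results, truth) {
  j <- join_results_truth(results, truth)
  n <- nrow(j$results)
  codes <- acmg_codes()$code
  pred_sets <- lapply(j$results$code_calls, function(d) d$code)
  truth_sets <- lapply(j$truth$codes, function(d) d$code)
  rows <- lapply(codes, function(code) {
    p <- vapply(pred_sets, function(s) code %in% s, TRUE)
    t <- vapply(truth_sets, function(s) code %in% s, TRUE)
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
    tn <- n - tp - fp - fn
    sens <- pct(tp, tp + fn); prec <- pct(tp, tp + fp)
    f1 <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_
    else round_half_up(2 * prec * sens / (prec + sens))
    agree <- NA_real_; n_pairs <- 0L
    if (tp > 0) {
      both <- which(p & t)
      eq <- vapply(both, function(k) {
        ps <- j$results$code_calls[[k]]
        ts <- j$truth$codes[[k]]
        s_pred <- ps$strength[ps$code == code][1]
        s_true <- ts$strength[ts$code == code][1]
        if (is.na(s_true)) NA else s_pred == s_true
      }, TRUE)
      n_pairs <- sum(!is.na(eq))
      if (n_pairs > 0) agree <- pct(sum(eq, na.rm = TRUE), n_pairs)
    }
    data.frame(code = code, predicted_count = sum(p), truth_count = sum(t),
               tp = tp, fp = fp, fn = fn,
               sensitivity = sens, specificity = pct(tn, tn + fp),
               precision = prec, f1 = f1,
               strength_agreement = agree, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
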