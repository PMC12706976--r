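#' Build an immutable interval index
#'
#' Wraps a set of genomic intervals (0-based half-open, BED convention)
#' in per-chromosome IRanges objects for point and range overlap
#' queries. Extra columns in `df` travel with the index and come back
#' from queries.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) plus arbitrary metadata columns.
#' @return object of class `acmg_interval_index`.
#' @export
interval_index <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (nrow(df) && any(df$end < df$start)) stop("interval with end < start")
  by_chrom <- split(seq_len(nrow(df)), df$chrom)
  ranges <- lapply(by_chrom, function(i) {
    # IRanges are closed 1-based: [start+1, end]
    IRanges::IRanges(start = df$start[i] + 1L, end = df$end[i])
  })
  structure(list(df = df, rows = by_chrom, ranges = ranges),
            class = "acmg_interval_index")
}

#' Query an interval index
#'
#' Returns the rows of the indexed table whose interval overlaps the
#' query range. `pos` is 1-based (VCF convention); the query covers
#' `pos .. pos + width - 1`.
#'
#' @param index an `acmg_interval_index`.
#' @param chrom chromosome name.
#' @param pos 1-based start position of the query.
#' @param width query width in bases (default 1 = point query).
#' @return data.frame subset of the indexed table (possibly 0 rows).
#' @export
interval_overlaps <- function(index, chrom, pos, width = 1L) {
  stopifnot(inherits(index, "acmg_interval_index"))
  chrom <- sub("^chr", "", as.character(chrom))
  r <- index$ranges[[chrom]]
  if (is.null(r)) return(index$df[0, , drop = FALSE])
  q <- IRanges::IRanges(start = as.integer(pos),
                        end = as.integer(pos) + as.integer(width) - 1L)
  hits <- IRanges::findOverlaps(q, r)
  rows <- index$rows[[chrom]][S4Vectors::subjectHits(hits)]
  index$df[rows, , drop = FALSE]
}

#' @export
print.acmg_interval_index <- function(x, ...) {
  cat(sprintf("<acmg_interval_index> %d intervals on %d chromosome(s)\n",
              nrow(x$df), length(x$ranges)))
  invisible(x)
}

# Intersect two 0-based half-open interval sets and merge the result
# into disjoint sorted intervals (per chromosome).
intersect_interval_sets <- function(a, b) {
  chroms <- intersect(unique(sub("^chr", "", a$chrom)),
                      unique(sub("^chr", "", b$chrom)))
  out <- list()
  for (ch in sort(chroms)) {
    ra <- a[sub("^chr", "", a$chrom) == ch, ]
    rb <- b[sub("^chr", "", b$chrom) == ch, ]
    ia <- IRanges::reduce(IRanges::IRanges(ra$start + 1L, ra$end))
    ib <- IRanges::reduce(IRanges::IRanges(rb$start + 1L, rb$end))
    ov <- IRanges::intersect(ia, ib)
    if (length(ov)) {
      out[[ch]] <- data.frame(chrom = ch,
                              start = IRanges::start(ov) - 1L,
                              end = IRanges::end(ov),
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
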