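# Cohort-identification impact statistics.
#
# For a pair of query phrases denoting the same concept with different
# numeric variants (Arabic "stage 3 ..." vs Roman "stage iii ..."), the
# patient cohort splits into three parts: phrase-1-only (b), both (d), and
# phrase-2-only (e). The missed percentage of each single-variant search is
# the share of the combined cohort it fails to retrieve:
#   c = 100 * e / (b + d + e)   (missed when searching only phrase 1)
#   f = 100 * b / (b + d + e)   (missed when searching only phrase 2)
# Percentages are rounded half-away-from-zero to one decimal, the rule
# consistent with all published values these statistics mirror.

# Round half away from zero to `digits` decimals; ties at the half are
# decided after clearing binary-float fuzz at the 9th decimal.
.round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

#' Missed percentages for a phrase-variant pair
#'
#' Given the patient counts `b` (phrase 1 only), `d` (both), and `e`
#' (phrase 2 only), returns the percentage of the combined cohort missed
#' when searching only phrase 1 (`pct_missed_p1 = 100 e / (b+d+e)`) and only
#' phrase 2 (`pct_missed_p2 = 100 b / (b+d+e)`), rounded half-away-from-zero
#' to one decimal. An all-zero triple has no defined percentage and raises
#' an error: silently reporting 0 would mask a broken search.
#'
#' @param b,d,e Non-negative patient counts.
#' @return Named numeric vector `c(pct_missed_p1, pct_missed_p2)`.
#' @export
#' @examples
#' missed_percentages(43777, 7919, 6053)  # 10.5, 75.8
#' missed_percentages(2, 1, 1)            # 25.0, 50.0
missed_percentages <- function(b, d, e) {
  stopifnot(length(b) == 1L, length(d) == 1L, length(e) == 1L,
            b >= 0, d >= 0, e >= 0)
  total <- b + d + e
  if (total < 1) stop("undefined percentage: all counts are zero")
  c(pct_missed_p1 = .round_half_away(100 * e / total),
    pct_missed_p2 = .round_half_away(100 * b / total))
}

#' Combined cohort size from the overlap triple
#'
#' @param b,d,e Non-negative counts (phrase-1-only, both, phrase-2-only).
#' @return `b + d + e`, the size of the union of the two cohorts.
#' @export
#' @examples
#' union_size(42, 27, 40)  # 109
union_size <- function(b, d, e) {
  stopifnot(b >= 0, d >= 0, e >= 0)
  b + d + e
}

#' Overlap count by inclusion-exclusion
#'
#' Recovers the number of patients found by both searches from the two
#' single-search totals and the size of their union.
#'
#' @param total1,total2 Patient counts of the two single-phrase searches.
#' @param union Size of the combined cohort.
#' @return `total1 + total2 - union`.
#' @export
#' @examples
#' intersection_by_inclusion_exclusion(69, 67, 109)  # 27
intersection_by_inclusion_exclusion <- function(total1, total2, union) {
  stopifnot(total1 >= 0, total2 >= 0, union >= 0)
  if (total1 + total2 < union || union < max(total1, total2)) {
    stop("inconsistent counts: need max(total1, total2) <= union <= total1 + total2")
  }
  total1 + total2 - union
}

#' Count phrase pairs with a majority of the cohort missed
#'
#' @param rows A `cohort_overlap` data frame (see [compute_overlap()] or
#'   [run_table18_demo()]).
#' @param threshold Percentage threshold; rows whose larger missed
#'   percentage strictly exceeds it are counted.
#' @return Integer count.
#' @export
count_majority_missed <- function(rows, threshold = 50) {
  stopifnot(threshold > 0, threshold < 100)
  if (!nrow(rows)) return(0L)
  sum(pmax(rows$pct_missed_p1, rows$pct_missed_p2) > threshold)
}

#' Patient-level overlap of two phrase searches
#'
#' Runs both phrase searches, aggregates document hits to distinct
#' patients, and splits the combined cohort into phrase-1-only / both /
#' phrase-2-only counts with the derived missed percentages.
#'
#' @param index A `note_index`.
#' @param phrase1,phrase2 Query phrases (conventionally phrase 1 carries the
#'   Arabic numeral variant and phrase 2 the Roman one).
#' @return A one-row data frame of class `cohort_overlap` with columns
#'   `phrase1`, `n1_only`, `pct_missed_p1`, `n_both`, `n2_only`,
#'   `pct_missed_p2`, `phrase2`, `total`.
#' @export
compute_overlap <- function(index, phrase1, phrase2) {
  p1 <- patient_set(index, phrase_search(index, phrase1))
  p2 <- patient_set(index, phrase_search(index, phrase2))
  b <- length(setdiff(p1, p2))
  d <- length(intersect(p1, p2))
  e <- length(setdiff(p2, p1))
  pct <- missed_percentages(b, d, e)
  out <- data.frame(phrase1 = phrase1, n1_only = b,
                    pct_missed_p1 = pct[["pct_missed_p1"]],
                    n_both = d, n2_only = e,
                    pct_missed_p2 = pct[["pct_missed_p2"]],
                    phrase2 = phrase2, total = b + d + e,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_overlap", class(out))
  out
}

#' @export
print.cohort_overlap <- function(x, ...) {
  show <- x
  show$pct_missed_p1 <- sprintf("%.1f", show$pct_missed_p1)
  show$pct_missed_p2 <- sprintf("%.1f", show$pct_missed_p2)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' Distinct-document frequency of each term
#'
#' @param index A `note_index`.
#' @param terms Character vector of words or phrases; input order (and any
#'   repetition) is preserved in the output.
#' @return Data frame with columns `term` and `document_count`.
#' @export
frequency_table <- function(index, terms) {
  stopifnot(is.character(terms), length(terms) >= 1L)
  counts <- vapply(terms, function(t) length(phrase_search(index, t)),
                   integer(1), USE.NAMES = FALSE)
  data.frame(term = terms, document_count = counts, stringsAsFactors = FALSE)
}

#' Write a cohort-overlap report
#'
#' Tab-separated mirror of the seven-column overlap table (phrase 1, the
#' three counts, the two missed percentages formatted to one decimal, and
#' phrase 2) plus the combined total. `write_overlap_json` writes the same
#' fields as structured JSON.
#'
#' @param rows A `cohort_overlap` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_overlap_report <- function(rows, path) {
  out <- as.data.frame(rows)
  out$pct_missed_p1 <- sprintf("%.1f", out$pct_missed_p1)
  out$pct_missed_p2 <- sprintf("%.1f", out$pct_missed_p2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_overlap_report
#' @export
write_overlap_json <- function(rows, path) {
  jsonlite::write_json(as.data.frame(rows), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Frequency report writer
#'
#' @param report Output of [frequency_table()].
#' @param path Output path (two-column tab-separated text).
#' @return The path, invisibly.
#' @export
write_frequency_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
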