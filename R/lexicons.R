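# Shared word tables and lexicon resources.
#
# Lexicons that double as data (scale words, decade-of-age terms, informal
# quantity phrases, ambiguous abbreviations) ship as plain-text files under
# extdata so users can inspect or extend them; everything here loads them
# lazily and caches the result for the session.

.clinnum_cache <- new.env(parent = emptyenv())

.ones <- c("one", "two", "three", "four", "five", "six", "seven", "eight", "nine")
.teens <- c("ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
            "sixteen", "seventeen", "eighteen", "nineteen")
.tens <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy",
           "eighty", "ninety")
.months <- c("january", "february", "march", "april", "may", "june", "july",
             "august", "september", "october", "november", "december")
.ordinal_words <- c("first", "second", "third", "fourth", "fifth", "sixth",
                    "seventh", "eighth", "ninth")
.ary_words <- c("primary", "secondary", "tertiary", "quaternary", "quinary",
                "senary", "septenary")
.fraction_singular <- c("half", "third", "fourth", "fifth", "sixth", "seventh",
                        "eighth", "ninth", "tenth")  # denominators 2..10
.fraction_plural <- c("halves", "thirds", "fourths", "fifths", "sixths",
                      "sevenths", "eighths", "ninths", "tenths")
.tuple_base <- c("single", "double", "triple", "quadruple", "quintuple",
                 "sextuple", "septuple", "octuple")
.tuple_offspring <- c("singleton", "twins", "triplets", "quadruplets",
                      "quintuplets", "sextuplets", "septuplets", "octuplets")
.class_prefixes <- c("type", "phase", "grade", "stage", "class", "score")

#' The twelve numeric lexical-variant categories
#'
#' Category names used throughout the package for surface forms: positive and
#' negative integers, fractions, dimensions, ranges/odds, dates (including
#' invalid ones), Roman numerals, medical classifications, ages (including
#' implausible values), quantity expressions, ordering/ranking, and tuples.
#'
#' @return Character vector of the twelve category names.
#' @export
#' @examples
#' variant_categories()
variant_categories <- function() {
  c("positive_integer", "negative_integer", "fraction", "dimension",
    "range_odds", "date", "roman_numeral", "medical_classification", "age",
    "quantity_expression", "ordering_ranking", "tuple")
}

#' Construct a numeric surface form record
#'
#' A surface form is the unit of variant generation and detection: a
#' lowercase surface string together with its category, canonical value
#' (encoded as a string; `NA` when absent), and a validity flag.
#' `"malformed"` marks strings with a well-formed counterpart denoting the
#' same value (e.g. `"iiii"` vs `"iv"`, `"1rd"` vs `"1st"`);
#' `"invalid_value"` marks values violating a domain rule (invalid date,
#' implausible age).
#'
#' @param text Surface string (stored lowercase).
#' @param category One of [variant_categories()] or `"unclassified"`.
#' @param canonical_value Canonical value encoding, or `NA`.
#' @param validity `"well_formed"`, `"malformed"`, `"invalid_value"`, or `NA`
#'   for unclassified input.
#' @param note Free-text annotation.
#' @return A one-row data frame of class `surface_form`.
#' @export
surface_form <- function(text, category, canonical_value = NA_character_,
                         validity = "well_formed", note = "") {
  stopifnot(is.character(text), all(nzchar(text)))
  out <- data.frame(text = tolower(text),
                    category = as.character(category),
                    canonical_value = as.character(canonical_value),
                    validity = as.character(validity),
                    note = as.character(note),
                    stringsAsFactors = FALSE)
  class(out) <- c("surface_form", class(out))
  out
}

.bind_forms <- function(...) {
  out <- do.call(rbind, Filter(Negate(is.null), list(...)))
  rownames(out) <- NULL
  out
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "clinnum")
  if (!nzchar(path)) stop("missing packaged resource: ", file)
  path
}

#' Scale-word lexicon for very large quantities
#'
#' Short-scale power-of-ten words from "hundred" (10^2) through
#' "undecillion" (10^36), plus the named curiosities "googol" (10^100) and
#' "googolplex" (not representable as an exponent) and the non-finite
#' "infinity" forms. The exponent is `NA` for non-finite or non-representable
#' entries; the `kind` column distinguishes them.
#'
#' @param path Optional path to a user-supplied TSV with columns
#'   `word`, `exponent`, `kind` replacing the packaged lexicon.
#' @return Data frame with columns `word`, `exponent`, `kind`.
#' @export
scale_words <- function(path = NULL) {
  if (!is.null(path)) {
    return(utils::read.delim(path, stringsAsFactors = FALSE))
  }
  if (is.null(.clinnum_cache$scale_words)) {
    .clinnum_cache$scale_words <-
      utils::read.delim(.extdata("scale_words.tsv"), stringsAsFactors = FALSE)
  }
  .clinnum_cache$scale_words
}

#' Decade-of-age term lexicon
#'
#' Single words denoting an age bracket: quinquagenarian (50-59) through
#' nonagenarian (90-99), then the open-ended centenarian (100+) and
#' supercentenarian (110+). `age_high` is `NA` for open-ended brackets.
#'
#' @param path Optional replacement TSV with columns `word`, `age_low`,
#'   `age_high`.
#' @return Data frame with columns `word`, `age_low`, `age_high`.
#' @export
decade_terms <- function(path = NULL) {
  if (!is.null(path)) {
    return(utils::read.delim(path, stringsAsFactors = FALSE))
  }
  if (is.null(.clinnum_cache$decade_terms)) {
    .clinnum_cache$decade_terms <-
      utils::read.delim(.extdata("decade_terms.tsv"), stringsAsFactors = FALSE)
  }
  .clinnum_cache$decade_terms
}

#' Informal quantity-expression lexicon
#'
#' Imprecise and informal expressions of quantity observed in clinical text
#' ("gobs of", "too many to count", "gazillion", ...), one phrase per line.
#'
#' @param path Optional replacement plain-text file, one phrase per line.
#' @return Character vector of phrases.
#' @export
informal_quantities <- function(path = NULL) {
  if (!is.null(path)) {
    return(readLines(path, warn = FALSE))
  }
  if (is.null(.clinnum_cache$informal)) {
    .clinnum_cache$informal <-
      readLines(.extdata("informal_quantities.txt"), warn = FALSE)
  }
  .clinnum_cache$informal
}

#' Ambiguous numeric-lookalike tokens
#'
#' Tokens that read as Roman numerals or classification compounds but also
#' carry common non-numeric senses in clinical text: single-letter Roman
#' numerals ("i", "v", "x"), "iv" (intravenous), "va", "ic", "id", "if",
#' "1g", "3d". Document annotation flags these as ambiguous and leaves them
#' un-normalized; no contextual disambiguation is attempted.
#'
#' @param path Optional replacement plain-text file, one token per line.
#' @return Character vector of lowercase tokens.
#' @export
ambiguous_terms <- function(path = NULL) {
  if (!is.null(path)) {
    return(readLines(path, warn = FALSE))
  }
  if (is.null(.clinnum_cache$ambiguous)) {
    .clinnum_cache$ambiguous <-
      readLines(.extdata("ambiguous_terms.txt"), warn = FALSE)
  }
  .clinnum_cache$ambiguous
}

# Inverse cardinal-word map ("thirty-three" -> 33), built once over 0..999.
.cardinal_map <- function() {
  if (is.null(.clinnum_cache$cardinal_map)) {
    m <- new.env(parent = emptyenv())
    for (i in 0:999) {
      w <- int_to_cardinal_words(i)
      assign(w, i, envir = m)
      # tokenizers split hyphens, so "thirty three" must resolve too
      assign(gsub("-", " ", w, fixed = TRUE), i, envir = m)
    }
    .clinnum_cache$cardinal_map <- m
  }
  .clinnum_cache$cardinal_map
}

# Value of a cardinal word phrase, or NA if not one.
.cardinal_value <- function(w) {
  get0(w, envir = .cardinal_map(), ifnotfound = NA_integer_)
}

# Value of a token that is either a digit string or a cardinal word phrase.
.number_value <- function(w) {
  if (grepl("^[0-9]+$", w)) return(as.integer(w))
  .cardinal_value(w)
}

# Tuple word -> n map, covering base, -ing, -ed, -s, and offspring forms.
.tuple_map <- function() {
  if (is.null(.clinnum_cache$tuple_map)) {
    m <- new.env(parent = emptyenv())
    for (n in seq_along(.tuple_base)) {
      for (w in .tuple_word_set(n)) assign(w, n, envir = m)
    }
    .clinnum_cache$tuple_map <- m
  }
  .clinnum_cache$tuple_map
}

.tuple_word_set <- function(n) {
  base <- .tuple_base[n]
  stem <- sub("e$", "", base)
  c(base, paste0(stem, "ing"), paste0(base, "d"), paste0(base, "s"),
    .tuple_offspring[n])
}
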