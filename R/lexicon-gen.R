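# Deterministic generators for numeric lexical variants.
#
# Each generator emits surface_form records (see surface_form()) covering
# both well-formed strings and the deliberately malformed or invalid
# counterparts observed in clinical notes: additive Roman numerals ("iiii"),
# wrong ordinal suffixes ("1rd"), hybrid ordinals ("1stly", "2ndary"),
# invalid month/day dates ("june 31"), and biologically implausible ages.
# All emitted text is lowercase; detection (classify_surface) is the inverse
# of every generator.

.roman_vals <- c(1000L, 900L, 500L, 400L, 100L, 90L, 50L, 40L, 10L, 9L, 5L, 4L, 1L)
.roman_syms <- c("M", "CM", "D", "CD", "C", "XC", "L", "XL", "X", "IX", "V", "IV", "I")

#' Convert an integer to a strict Roman numeral
#'
#' Returns the unique subtractive-notation numeral (uppercase), e.g. 4 is
#' `"IV"` and never the additive `"IIII"`. Supported range is 1-3999, the
#' standard boundary of subtractive notation without overlines.
#'
#' @param n Integer in 1..3999.
#' @return Uppercase Roman numeral string.
#' @export
#' @examples
#' int_to_roman(28)  # "XXVIII"
#' int_to_roman(39)  # "XXXIX"
int_to_roman <- function(n) {
  if (length(n) != 1L || is.na(n) || n != trunc(n)) {
    stop("n must be a single integer")
  }
  n <- as.integer(n)
  if (n < 1L || n > 3999L) stop("n must be between 1 and 3999")
  out <- character(0)
  for (k in seq_along(.roman_vals)) {
    while (n >= .roman_vals[k]) {
      out <- c(out, .roman_syms[k])
      n <- n - .roman_vals[k]
    }
  }
  paste(out, collapse = "")
}

# Pure-additive spelling using only the non-subtractive symbol values.
.roman_additive <- function(n) {
  vals <- c(1000L, 500L, 100L, 50L, 10L, 5L, 1L)
  syms <- c("m", "d", "c", "l", "x", "v", "i")
  out <- character(0)
  for (k in seq_along(vals)) {
    while (n >= vals[k]) {
      out <- c(out, syms[k])
      n <- n - vals[k]
    }
  }
  paste(out, collapse = "")
}

#' Generate malformed (additive) Roman numeral spellings
#'
#' Emits incorrectly formed Roman numerals that still denote `n`. By default
#' only the pure repeated-"i" run (`"iiii"` for 4 up to `"iiiiiiiii"` for 9)
#' is produced, the malformation actually observed in notes. With
#' `include_other = TRUE` the general additive spelling (e.g. `"viiii"` for
#' 9, `"xxxx"` for 40) is added when it differs from both the strict form
#' and the i-run. The strict subtractive form is never emitted.
#'
#' @param n Target value, `n >= 4`.
#' @param max_run Longest repeated-"i" run to emit; the i-run for `n`
#'   requires `max_run >= n`. Default 9.
#' @param include_other Also emit the general additive spelling.
#' @return A `surface_form` data frame (possibly zero rows), every row with
#'   `validity = "malformed"` and canonical value `n`.
#' @export
#' @examples
#' generate_malformed_romans(4)$text   # "iiii"
#' generate_malformed_romans(9)$text   # "iiiiiiiii"
generate_malformed_romans <- function(n, max_run = 9, include_other = FALSE) {
  stopifnot(length(n) == 1L, !is.na(n), n == trunc(n), n >= 4)
  n <- as.integer(n)
  strict <- tolower(int_to_roman(n))
  texts <- character(0)
  if (n <= max_run) texts <- strrep("i", n)
  if (include_other) {
    add <- .roman_additive(n)
    if (!add %in% c(strict, texts)) texts <- c(texts, add)
  }
  if (!length(texts)) {
    return(surface_form("x", "roman_numeral", "10")[0, ])
  }
  surface_form(texts, "roman_numeral", as.character(n), "malformed",
               note = "additive form")
}

#' Spell an integer as English cardinal words
#'
#' Lowercase words with hyphenated tens-units compounds ("thirty-three") and
#' no "and" ("one hundred one"). Supported range 0-999; larger magnitudes
#' are covered by the scale-word lexicon, not full conversion.
#'
#' @param n Integer in 0..999.
#' @return Lowercase English cardinal phrase.
#' @export
#' @examples
#' int_to_cardinal_words(33)  # "thirty-three"
#' int_to_cardinal_words(0)   # "zero"
int_to_cardinal_words <- function(n) {
  if (length(n) != 1L || is.na(n) || n != trunc(n)) {
    stop("n must be a single integer")
  }
  n <- as.integer(n)
  if (n < 0L || n > 999L) stop("n must be between 0 and 999")
  if (n == 0L) return("zero")
  parts <- character(0)
  if (n >= 100L) {
    parts <- c(parts, paste(.ones[n %/% 100L], "hundred"))
    n <- n %% 100L
  }
  if (n >= 20L) {
    tens <- .tens[n %/% 10L - 1L]
    unit <- n %% 10L
    parts <- c(parts, if (unit > 0L) paste0(tens, "-", .ones[unit]) else tens)
  } else if (n >= 10L) {
    parts <- c(parts, .teens[n - 9L])
  } else if (n >= 1L) {
    parts <- c(parts, .ones[n])
  }
  paste(parts, collapse = " ")
}

#' Ordinal suffix for an integer
#'
#' The two-letter ending (st/nd/rd/th) determined by the last two digits:
#' 11, 12, 13 (and any number whose last two digits are 11-13) take "th";
#' otherwise the last digit decides.
#'
#' @param n Integer `>= 1`.
#' @return One of `"st"`, `"nd"`, `"rd"`, `"th"`.
#' @export
#' @examples
#' ordinal_suffix(1)   # "st"
#' ordinal_suffix(11)  # "th"
#' ordinal_suffix(21)  # "st"
ordinal_suffix <- function(n) {
  stopifnot(length(n) == 1L, !is.na(n), n == trunc(n), n >= 1)
  n <- as.integer(n)
  if ((n %% 100L) %in% 11:13) return("th")
  switch(as.character(n %% 10L), "1" = "st", "2" = "nd", "3" = "rd", "th")
}

#' Generate ordinal surface variants for a digit
#'
#' For `n` in 1..9, emits the digit with all four suffixes (the correct one
#' well-formed, the other three malformed, e.g. "1st" vs "1rd"), the ordinal
#' word ("first"), the adverbial "-ly" word ("firstly") and its digit hybrid
#' ("1stly", malformed), and -- where such forms are attested -- the "-ary"
#' series: the word ("primary", 1-4), digit+suffix hybrids ("2ndary",
#' "3rdary") and bare digit+"ary" forms ("1ary", "2ary", "3ary", "4ary"),
#' all malformed.
#'
#' @param n Integer in 1..9.
#' @return A `surface_form` data frame.
#' @export
generate_ordinal_variants <- function(n) {
  stopifnot(length(n) == 1L, !is.na(n), n == trunc(n), n >= 1, n <= 9)
  n <- as.integer(n)
  ok <- ordinal_suffix(n)
  val <- as.character(n)
  suffixes <- c("st", "nd", "rd", "th")
  forms <- list(
    surface_form(paste0(n, ok), "ordering_ranking", val, "well_formed"),
    surface_form(paste0(n, setdiff(suffixes, ok)), "ordering_ranking", val,
                 "malformed", note = "wrong suffix"),
    surface_form(.ordinal_words[n], "ordering_ranking", val, "well_formed"),
    surface_form(paste0(.ordinal_words[n], "ly"), "ordering_ranking", val,
                 "well_formed"),
    surface_form(paste0(n, ok, "ly"), "ordering_ranking", val, "malformed",
                 note = "digit hybrid")
  )
  if (n <= 4L) {
    forms <- c(forms, list(
      surface_form(.ary_words[n], "ordering_ranking", val, "well_formed")))
    ary <- switch(n, "1ary", c("2ndary", "2ary"), c("3rdary", "3ary"), "4ary")
    forms <- c(forms, list(
      surface_form(ary, "ordering_ranking", val, "malformed",
                   note = "digit hybrid")))
  }
  do.call(.bind_forms, forms)
}

#' Spell a fraction in words
#'
#' Produces the word form with correct singular/plural agreement ("one
#' third", "two thirds", "one half", "two halves"). With
#' `include_errors = TRUE`, the plural-mismatch counterpart ("one thirds",
#' "two third") is added, flagged malformed.
#'
#' @param numerator Integer 1..10.
#' @param denominator Integer 2..10.
#' @param include_errors Also emit the agreement-error form.
#' @return A `surface_form` data frame; canonical value
#'   `"numerator/denominator"`.
#' @export
#' @examples
#' fraction_phrase(1, 3)$text                       # "one third"
#' fraction_phrase(1, 3, include_errors = TRUE)$text
fraction_phrase <- function(numerator, denominator, include_errors = FALSE) {
  stopifnot(numerator >= 1, numerator <= 10, denominator >= 2,
            denominator <= 10)
  num <- as.integer(numerator)
  den <- as.integer(denominator)
  numw <- if (num == 10L) "ten" else .ones[num]
  singular <- .fraction_singular[den - 1L]
  plural <- .fraction_plural[den - 1L]
  good <- paste(numw, if (num == 1L) singular else plural)
  val <- paste0(num, "/", den)
  out <- surface_form(good, "fraction", val, "well_formed")
  if (include_errors) {
    bad <- paste(numw, if (num == 1L) plural else singular)
    out <- .bind_forms(out, surface_form(bad, "fraction", val, "malformed",
                                         note = "plural mismatch"))
  }
  out
}

#' Spell a dimension expression
#'
#' @param a,b Integers 1..10.
#' @return The phrase `"<word-a> by <word-b>"`, e.g. `"two by four"`.
#' @export
dimension_phrase <- function(a, b) {
  stopifnot(a >= 1, a <= 10, b >= 1, b <= 10)
  paste(int_to_cardinal_words(as.integer(a)), "by",
        int_to_cardinal_words(as.integer(b)))
}

#' Spell a range (or odds) expression
#'
#' @param a,b Integers 1..10; `a == b` gives a degenerate range.
#' @return The phrase `"<word-a> to <word-b>"`, e.g. `"one to three"`.
#' @export
range_phrase <- function(a, b) {
  stopifnot(a >= 1, a <= 10, b >= 1, b <= 10)
  paste(int_to_cardinal_words(as.integer(a)), "to",
        int_to_cardinal_words(as.integer(b)))
}

#' Generate negative-integer surface forms
#'
#' The four spelled/mixed forms seen in notes: "minus five", "minus 5",
#' "negative five", "negative 5".
#'
#' @param n Integer 1..10 (the magnitude).
#' @return A `surface_form` data frame with canonical value `-n`.
#' @export
negative_forms <- function(n) {
  stopifnot(length(n) == 1L, n >= 1, n <= 10)
  n <- as.integer(n)
  word <- int_to_cardinal_words(n)
  texts <- c(paste("minus", word), paste("minus", n),
             paste("negative", word), paste("negative", n))
  surface_form(texts, "negative_integer", as.character(-n))
}

#' Generate month-day date strings, including invalid dates
#'
#' Emits `"<monthname> <day>"` and, with `with_suffix = TRUE`, the ordinal
#' form `"<monthname> <day><suffix>"` (always with the correct suffix for
#' the day). Validity is decided by calendar rules without a year: days
#' beyond the month's length (June 31, February 30, any day 32-39) are
#' `invalid_value`.
#'
#' @param month Integer 1..12.
#' @param day Integer 1..39.
#' @param with_suffix Also emit the ordinal-suffix form.
#' @param leap_policy Passed to [is_valid_date()]; default treats
#'   February 29 as valid.
#' @return A `surface_form` data frame; canonical value `"mm-dd"`.
#' @export
#' @examples
#' date_strings(1, 35)$validity   # invalid_value
#' date_strings(1, 31)$validity   # well_formed
date_strings <- function(month, day, with_suffix = FALSE,
                         leap_policy = "lenient_feb29") {
  stopifnot(month >= 1, month <= 12, day >= 1, day <= 39)
  month <- as.integer(month)
  day <- as.integer(day)
  validity <- if (is_valid_date(month, day, leap_policy)) "well_formed" else "invalid_value"
  texts <- paste(.months[month], day)
  if (with_suffix) {
    texts <- c(texts, paste0(.months[month], " ", day, ordinal_suffix(day)))
  }
  surface_form(texts, "date", sprintf("%02d-%02d", month, day), validity)
}

#' Generate age phrases, including implausible ages
#'
#' Emits `"<age> year old"` and `"<age>-year-old"`. Ages above the
#' plausibility bound (default 122 years, the longest documented human
#' lifespan) are flagged `invalid_value`.
#'
#' @param age Integer 0..999.
#' @param bound Plausibility bound in years.
#' @return A `surface_form` data frame; canonical value the age in years.
#' @export
#' @examples
#' age_phrases(135)$validity  # invalid_value
#' age_phrases(122)$validity  # well_formed
age_phrases <- function(age, bound = 122) {
  stopifnot(length(age) == 1L, age >= 0, age <= 999)
  age <- as.integer(age)
  validity <- if (is_plausible_age(age, bound)) "well_formed" else "invalid_value"
  texts <- c(paste(age, "year old"), paste0(age, "-year-old"))
  surface_form(texts, "age", as.character(age), validity)
}

#' Decade-of-age term for an age
#'
#' Looks up the decade lexicon word whose bracket contains `age`, preferring
#' the most specific bracket (supercentenarian over centenarian for 110+).
#' Ages below 50 have no lexicon term and return `NA`.
#'
#' @param age Integer `>= 0`.
#' @return The term, or `NA_character_` when no bracket applies.
#' @export
#' @examples
#' decade_age_term(75)   # "septuagenarian"
#' decade_age_term(45)   # NA
decade_age_term <- function(age) {
  stopifnot(length(age) == 1L, age >= 0)
  lex <- decade_terms()
  hi <- ifelse(is.na(lex$age_high), Inf, lex$age_high)
  hit <- which(lex$age_low <= age & age <= hi)
  if (!length(hit)) return(NA_character_)
  lex$word[hit[which.max(lex$age_low[hit])]]
}

#' Generate tuple terms
#'
#' The multiplicative base term (single, double, ..., octuple) plus its
#' morphological forms (-ing, -ed, -s) and the offspring term (singleton,
#' twins, triplets, ..., octuplets).
#'
#' @param n Integer 1..8.
#' @return A `surface_form` data frame with canonical value `n`.
#' @export
#' @examples
#' tuple_terms(3)$text
tuple_terms <- function(n) {
  stopifnot(length(n) == 1L, n >= 1, n <= 8)
  n <- as.integer(n)
  surface_form(.tuple_word_set(n), "tuple", as.character(n))
}

#' Generate medical classification variants
#'
#' For a classification prefix (type/phase/grade/stage/class/score) and a
#' number, emits the Arabic and Roman phrase forms ("stage 3", "stage iii")
#' and, when a letter is given, the compound tokens ("3b", "iiib") used in
#' stagings such as "stage 3b lung cancer". A Roman compound whose
#' concatenation is itself a readable Roman numeral (e.g. "i" + "v" =
#' "iv") is inherently ambiguous without context and is skipped.
#'
#' @param prefix One of `"type"`, `"phase"`, `"grade"`, `"stage"`,
#'   `"class"`, `"score"`.
#' @param n Integer 1..5.
#' @param letter Optional single letter a-j for compound forms.
#' @return A `surface_form` data frame.
#' @export
#' @examples
#' classification_variants("type", 2)$text        # "type 2", "type ii"
#' classification_variants("stage", 3, "b")$text
classification_variants <- function(prefix, n, letter = NULL) {
  prefix <- tolower(prefix)
  if (!prefix %in% .class_prefixes) {
    stop("prefix must be one of: ", paste(.class_prefixes, collapse = ", "))
  }
  stopifnot(length(n) == 1L, n >= 1, n <= 5)
  n <- as.integer(n)
  roman <- tolower(int_to_roman(n))
  out <- .bind_forms(
    surface_form(paste(prefix, n), "medical_classification",
                 paste0(prefix, ":", n)),
    surface_form(paste(prefix, roman), "medical_classification",
                 paste0(prefix, ":", n)))
  if (!is.null(letter)) {
    letter <- tolower(letter)
    stopifnot(length(letter) == 1L, grepl("^[a-j]$", letter))
    out <- .bind_forms(out,
      surface_form(paste0(n, letter), "medical_classification",
                   paste0(n, letter)))
    compound <- paste0(roman, letter)
    if (is.null(.try_parse_roman(compound))) {
      out <- .bind_forms(out,
        surface_form(compound, "medical_classification", paste0(n, letter)))
    }
  }
  out
}

#' Expand a phrase across numeric surface variants
#'
#' Query-expansion helper: finds the single numeric token in a phrase (an
#' Arabic digit string, a strict Roman numeral up to 39, or a cardinal word
#' up to 39) and returns the set of phrases obtained by substituting its
#' Arabic, strict-Roman, and cardinal-word spellings. Phrases without a
#' numeric token map to the singleton set of themselves; phrases with more
#' than one numeric token (e.g. "2 by 4") are not supported and raise an
#' error. Output is lowercase, deterministic, and always contains the input
#' phrase.
#'
#' @param phrase Phrase with at most one numeric token.
#' @return Sorted character vector of expanded phrases.
#' @export
#' @examples
#' expand_phrase("stage 3 chronic kidney disease")
#' expand_phrase("type 2 diabetes mellitus")
expand_phrase <- function(phrase) {
  stopifnot(is.character(phrase), length(phrase) == 1L, nzchar(phrase))
  p <- tolower(trimws(phrase))
  toks <- regmatches(p, gregexpr("[a-z0-9]+(-[a-z0-9]+)*", p))[[1]]
  vals <- vapply(toks, .expand_token_value, integer(1))
  num_idx <- which(!is.na(vals))
  if (length(num_idx) > 1L) {
    stop("unsupported: phrase contains more than one numeric token")
  }
  if (!length(num_idx)) return(p)
  v <- vals[num_idx]
  reprs <- as.character(v)
  if (v >= 1L && v <= 3999L) reprs <- c(reprs, tolower(int_to_roman(v)))
  if (v <= 999L) reprs <- c(reprs, int_to_cardinal_words(v))
  variants <- vapply(reprs, function(r) {
    tt <- toks
    tt[num_idx] <- r
    paste(tt, collapse = " ")
  }, character(1))
  sort(unique(c(p, variants)))
}

# Value of a token treated as numeric for expansion: digits, strict Roman
# numeral <= 39, or cardinal word <= 39. NA otherwise.
.expand_token_value <- function(tok) {
  if (grepl("^[0-9]+$", tok)) return(as.integer(tok))
  if (grepl("^[ivx]+$", tok)) {
    pr <- .try_parse_roman(tok)
    if (!is.null(pr) && pr$well_formed && pr$value <= 39L) {
      return(as.integer(pr$value))
    }
  }
  v <- .cardinal_value(tok)
  if (!is.na(v) && v >= 0L && v <= 39L) return(v)
  NA_integer_
}
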