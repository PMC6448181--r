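# Parsers, validators, and classifiers: the inverse of the generators.
#
# classify_surface() maps an arbitrary surface string to its category,
# canonical value, and validity flag by trying parsers in a fixed priority
# (date > age > classification > roman > ordinal > negative > dimension >
# range > fraction > cardinal > tuple > quantity lexicons). It is total:
# unrecognized input yields an "unclassified" record, never an error.

.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.subtractive_pairs <- c(IV = 4L, IX = 9L, XL = 40L, XC = 90L, CD = 400L,
                        CM = 900L)
.roman_symbol_vals <- c(I = 1L, V = 5L, X = 10L, L = 50L, C = 100L, D = 500L,
                        M = 1000L)

#' Parse a Roman numeral, strictly or leniently
#'
#' Strict mode accepts only the canonical subtractive spelling (the output
#' of [int_to_roman()]); anything else is a parse error. Lenient mode
#' additionally accepts additive spellings such as `"IIII"` (4) or
#' `"VIIII"` (9): the input is scanned left to right into units (standard
#' subtractive pairs IV/IX/XL/XC/CD/CM, else single symbols), unit values
#' must be non-increasing, and the value is their sum. Lenient results carry
#' `well_formed = FALSE` when the spelling is not canonical.
#'
#' @param s Roman numeral string, case-insensitive, letters from IVXLCDM.
#' @param mode `"strict"` or `"lenient"`.
#' @return A list of class `roman_parse` with elements `value`,
#'   `well_formed`, and `input`.
#' @export
#' @examples
#' parse_roman("XV", "strict")$value     # 15
#' parse_roman("IIII", "lenient")$value  # 4, well_formed FALSE
parse_roman <- function(s, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(is.character(s), length(s) == 1L)
  u <- toupper(s)
  if (!nzchar(u) || grepl("[^IVXLCDM]", u)) {
    stop("not a Roman numeral: ", s)
  }
  chars <- strsplit(u, "", fixed = TRUE)[[1]]
  units <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    if (i < length(chars)) {
      pair <- paste0(chars[i], chars[i + 1L])
      pv <- .subtractive_pairs[pair]
      if (!is.na(pv)) {
        units <- c(units, pv)
        i <- i + 2L
        next
      }
    }
    units <- c(units, .roman_symbol_vals[[chars[i]]])
    i <- i + 1L
  }
  if (length(units) > 1L && any(diff(units) > 0L)) {
    stop("not a parseable Roman numeral: ", s)
  }
  value <- sum(units)
  well_formed <- value >= 1L && value <= 3999L && u == int_to_roman(value)
  if (mode == "strict" && !well_formed) {
    stop("not a canonical Roman numeral: ", s)
  }
  structure(list(value = as.integer(value), well_formed = well_formed,
                 input = s),
            class = "roman_parse")
}

.try_parse_roman <- function(s) {
  tryCatch(parse_roman(s, "lenient"), error = function(e) NULL)
}

#' @export
print.roman_parse <- function(x, ...) {
  cat(sprintf("Roman numeral '%s' = %d (%s)\n", x$input, x$value,
              if (x$well_formed) "canonical" else "non-canonical"))
  invisible(x)
}

#' Validate a month-day date without a year
#'
#' A day is valid when it does not exceed the month's length (31/28/31/30/
#' 31/30/31/31/30/31/30/31). Because the studied patterns carry no year,
#' February 29 is treated as valid under the default `"lenient_feb29"`
#' policy and invalid under `"strict_feb29"`.
#'
#' @param month Integer 1..12.
#' @param day Integer `>= 1`.
#' @param leap_policy `"lenient_feb29"` (default) or `"strict_feb29"`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_valid_date(6, 31)  # FALSE
#' is_valid_date(1, 31)  # TRUE
is_valid_date <- function(month, day,
                          leap_policy = c("lenient_feb29", "strict_feb29")) {
  leap_policy <- match.arg(leap_policy)
  stopifnot(length(month) == 1L, length(day) == 1L, !is.na(month), !is.na(day))
  if (month < 1 || month > 12) stop("month must be between 1 and 12")
  if (day < 1) stop("day must be >= 1")
  month <- as.integer(month)
  day <- as.integer(day)
  limit <- .month_days[month]
  if (month == 2L && leap_policy == "lenient_feb29") limit <- 29L
  day <= limit
}

#' Is a stated age biologically plausible?
#'
#' Plausible means not exceeding the bound; the default bound of 122 years
#' is the longest documented human lifespan.
#'
#' @param age Age in years, `>= 0`.
#' @param bound Plausibility bound in years.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_plausible_age(122)  # TRUE
#' is_plausible_age(123)  # FALSE
is_plausible_age <- function(age, bound = 122) {
  stopifnot(length(age) == 1L, !is.na(age))
  if (age < 0) stop("age must be >= 0")
  age <= bound
}

#' Check a digit ordinal's suffix
#'
#' @param number_text Digit string.
#' @param suffix One of `"st"`, `"nd"`, `"rd"`, `"th"`.
#' @return `TRUE` iff the suffix is the correct one for the number.
#' @export
#' @examples
#' check_ordinal("1", "st")  # TRUE
#' check_ordinal("1", "rd")  # FALSE
check_ordinal <- function(number_text, suffix) {
  stopifnot(grepl("^[0-9]+$", number_text),
            suffix %in% c("st", "nd", "rd", "th"))
  identical(suffix, ordinal_suffix(as.integer(number_text)))
}

# --- classify_surface matchers (fixed priority order) ---------------------

.match_date <- function(x, age_bound, leap_policy) {
  g <- regmatches(x, regexec("^([a-z]+) ([0-9]{1,2})(st|nd|rd|th)?$", x))[[1]]
  if (!length(g)) return(NULL)
  mi <- match(g[2], .months)
  if (is.na(mi)) return(NULL)
  day <- as.integer(g[3])
  if (day < 1L) return(NULL)
  valid <- is_valid_date(mi, day, leap_policy)
  suffix_ok <- !nzchar(g[4]) || identical(g[4], ordinal_suffix(day))
  validity <- if (!valid) "invalid_value" else if (!suffix_ok) "malformed" else "well_formed"
  surface_form(x, "date", sprintf("%02d-%02d", mi, day), validity)
}

.match_age <- function(x, age_bound, leap_policy) {
  g <- regmatches(x, regexec("^([0-9]{1,3})[- ]year[- ]old$", x))[[1]]
  if (!length(g)) return(NULL)
  age <- as.integer(g[2])
  validity <- if (is_plausible_age(age, age_bound)) "well_formed" else "invalid_value"
  surface_form(x, "age", as.character(age), validity)
}

.match_classification <- function(x, age_bound, leap_policy) {
  pat <- paste0("^(", paste(.class_prefixes, collapse = "|"),
                ") ([0-9]{1,2}|[ivxlcdm]+)([a-j])?$")
  g <- regmatches(x, regexec(pat, x))[[1]]
  if (length(g)) {
    num <- g[3]
    if (grepl("^[0-9]+$", num)) {
      n <- as.integer(num)
      validity <- "well_formed"
    } else {
      pr <- .try_parse_roman(num)
      if (is.null(pr)) return(NULL)
      n <- pr$value
      validity <- if (pr$well_formed) "well_formed" else "malformed"
    }
    return(surface_form(x, "medical_classification",
                        paste0(g[2], ":", n, g[4]), validity))
  }
  g <- regmatches(x, regexec("^([0-9]{1,2})([a-j])$", x))[[1]]
  if (length(g)) {
    return(surface_form(x, "medical_classification", paste0(g[2], g[3])))
  }
  g <- regmatches(x, regexec("^([ivxlcdm]+)([a-j])$", x))[[1]]
  if (length(g) && is.null(.try_parse_roman(x))) {
    pr <- .try_parse_roman(g[2])
    if (is.null(pr)) return(NULL)
    validity <- if (pr$well_formed) "well_formed" else "malformed"
    return(surface_form(x, "medical_classification",
                        paste0(pr$value, g[3]), validity))
  }
  NULL
}

.match_roman <- function(x, age_bound, leap_policy) {
  if (!grepl("^[ivxlcdm]+$", x)) return(NULL)
  pr <- .try_parse_roman(x)
  if (is.null(pr)) return(NULL)
  surface_form(x, "roman_numeral", as.character(pr$value),
               if (pr$well_formed) "well_formed" else "malformed")
}

.match_ordinal <- function(x, age_bound, leap_policy) {
  g <- regmatches(x, regexec("^([0-9]+)(st|nd|rd|th)?(ly|ary)?$", x))[[1]]
  if (length(g)) {
    n <- as.integer(g[2])
    suffix <- g[3]
    tail <- g[4]
    if (!nzchar(suffix) && !identical(tail, "ary")) return(NULL)
    if (n < 1L) return(NULL)
    validity <- if (!nzchar(tail) && identical(suffix, ordinal_suffix(n))) {
      "well_formed"
    } else {
      "malformed"
    }
    return(surface_form(x, "ordering_ranking", as.character(n), validity))
  }
  i <- match(x, .ordinal_words)
  if (!is.na(i)) {
    return(surface_form(x, "ordering_ranking", as.character(i)))
  }
  i <- match(x, paste0(.ordinal_words, "ly"))
  if (!is.na(i)) {
    return(surface_form(x, "ordering_ranking", as.character(i)))
  }
  i <- match(x, .ary_words)
  if (!is.na(i)) {
    return(surface_form(x, "ordering_ranking", as.character(i)))
  }
  NULL
}

.match_negative <- function(x, age_bound, leap_policy) {
  g <- regmatches(x, regexec("^(minus|negative) (.+)$", x))[[1]]
  if (!length(g)) return(NULL)
  v <- .number_value(g[3])
  if (is.na(v)) return(NULL)
  surface_form(x, "negative_integer", as.character(-v))
}

.match_dimension <- function(x, age_bound, leap_policy) {
  g <- regmatches(x, regexec("^(.+) by (.+)$", x))[[1]]
  if (!length(g)) return(NULL)
  a <- .number_value(g[2])
  b <- .number_value(g[3])
  if (is.na(a) || is.na(b)) return(NULL)
  surface_form(x, "dimension", paste0(a, "x", b))
}

.match_range <- function(x, age_bound, leap_policy) {
  g <- regmatches(x, regexec("^(.+) to (.+)$", x))[[1]]
  if (!length(g)) return(NULL)
  a <- .number_value(g[2])
  b <- .number_value(g[3])
  if (is.na(a) || is.na(b)) return(NULL)
  surface_form(x, "range_odds", paste0(a, "-", b))
}

.match_fraction <- function(x, age_bound, leap_policy) {
  g <- regmatches(x, regexec("^([a-z-]+) ([a-z]+)$", x))[[1]]
  if (!length(g)) return(NULL)
  num <- .cardinal_value(g[2])
  if (is.na(num) || num < 1L) return(NULL)
  den_s <- match(g[3], .fraction_singular)
  den_p <- match(g[3], .fraction_plural)
  if (is.na(den_s) && is.na(den_p)) return(NULL)
  den <- (if (is.na(den_s)) den_p else den_s) + 1L
  agrees <- if (num == 1L) !is.na(den_s) else !is.na(den_p)
  surface_form(x, "fraction", paste0(num, "/", den),
               if (agrees) "well_formed" else "malformed",
               note = if (agrees) "" else "plural mismatch")
}

.match_cardinal <- function(x, age_bound, leap_policy) {
  if (grepl("^[0-9]+$", x)) {
    return(surface_form(x, "positive_integer", as.character(as.integer(x))))
  }
  v <- .cardinal_value(x)
  if (is.na(v)) return(NULL)
  surface_form(x, "positive_integer", as.character(v))
}

.match_tuple <- function(x, age_bound, leap_policy) {
  n <- get0(x, envir = .tuple_map(), ifnotfound = NA_integer_)
  if (is.na(n)) return(NULL)
  surface_form(x, "tuple", as.character(n))
}

.match_quantity <- function(x, age_bound, leap_policy) {
  sw <- scale_words()
  i <- match(x, sw$word)
  if (!is.na(i)) {
    val <- if (is.na(sw$exponent[i])) NA_character_ else as.character(sw$exponent[i])
    return(surface_form(x, "quantity_expression", val, note = sw$kind[i]))
  }
  if (x %in% informal_quantities()) {
    return(surface_form(x, "quantity_expression", NA_character_,
                        note = "informal"))
  }
  NULL
}

.surface_matchers <- list(.match_date, .match_age, .match_classification,
                          .match_roman, .match_ordinal, .match_negative,
                          .match_dimension, .match_range, .match_fraction,
                          .match_cardinal, .match_tuple, .match_quantity)

#' Classify a surface string
#'
#' Total classifier mapping an arbitrary string to a [surface_form()]
#' record: parsers are tried in a fixed priority (date > age >
#' classification > Roman numeral > ordinal > negative > dimension > range >
#' fraction > cardinal > tuple > quantity lexicons). Unrecognized input
#' returns an `"unclassified"` record rather than raising.
#'
#' @param s Non-empty string; matching is case-insensitive.
#' @param age_bound Age plausibility bound in years.
#' @param leap_policy Calendar policy for February 29, see
#'   [is_valid_date()].
#' @return A one-row `surface_form` data frame.
#' @export
#' @examples
#' classify_surface("january 35")$validity  # invalid_value
#' classify_surface("xv")$canonical_value   # "15"
#' classify_surface("hello")$category       # "unclassified"
classify_surface <- function(s, age_bound = 122,
                             leap_policy = "lenient_feb29") {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s), nzchar(s))
  x <- tolower(trimws(s))
  x <- gsub("[ ]+", " ", x)
  if (!nzchar(x)) {
    return(surface_form(s, "unclassified", NA_character_, NA_character_))
  }
  for (m in .surface_matchers) {
    sf <- m(x, age_bound, leap_policy)
    if (!is.null(sf)) return(sf)
  }
  surface_form(x, "unclassified", NA_character_, NA_character_)
}

#' Annotate numeric spans in a tokenized document
#'
#' Scans a token sequence left to right, trying spans of up to four tokens
#' (longest first) against [classify_surface()]. Matched spans do not
#' overlap. Two-token classification phrases ("type ii") are not annotated
#' as a whole; the numeral token alone is, so the annotation layer stays a
#' pure number normalizer. Tokens in the ambiguous lexicon
#' ([ambiguous_terms()]: single-letter Roman numerals, "iv", "va", "3d",
#' ...) are flagged `ambiguous = TRUE` and their canonical value is withheld
#' rather than normalized.
#'
#' @param tokens Character vector from [tokenize()].
#' @param age_bound,leap_policy Passed to [classify_surface()].
#' @return Data frame with columns `start`, `end` (half-open token indices),
#'   `surface`, `category`, `canonical_value`, `validity`, `ambiguous`.
#' @export
#' @examples
#' annotate_document(c("type", "ii", "diabetes"))
annotate_document <- function(tokens, age_bound = 122,
                              leap_policy = "lenient_feb29") {
  empty <- data.frame(start = integer(0), end = integer(0),
                      surface = character(0), category = character(0),
                      canonical_value = character(0),
                      validity = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(tokens)) return(empty)
  stopifnot(is.character(tokens))
  amb <- ambiguous_terms()
  rows <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    advanced <- FALSE
    for (L in seq.int(min(4L, n - i + 1L), 1L)) {
      s <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      sf <- classify_surface(s, age_bound = age_bound,
                             leap_policy = leap_policy)
      if (identical(sf$category, "unclassified")) next
      if (L > 1L && identical(sf$category, "medical_classification")) next
      is_amb <- L == 1L && tokens[i] %in% amb
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, end = i + L, surface = s, category = sf$category,
        canonical_value = if (is_amb) NA_character_ else sf$canonical_value,
        validity = sf$validity, ambiguous = is_amb,
        stringsAsFactors = FALSE)
      i <- i + L
      advanced <- TRUE
      break
    }
    if (!advanced) i <- i + 1L
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write span annotations as delimited text
#'
#' @param annotations Output of [annotate_document()].
#' @param doc_id Document identifier recorded in the first column.
#' @param path Output file path (tab-separated, with header).
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, doc_id, path) {
  out <- cbind(doc_id = doc_id, annotations)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
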